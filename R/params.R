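#' Model parameters
#'
#' Builds the full parameter set of the model: the transcription layer
#' (maximum promoter activity `p_max`, degradation constant `delta`, basal
#' polymerase weight `q_p`), the H3K4me3 modification chain (`k_m`, `k_d`
#' and the binding energies), the replication-coupled DNA-methylation
#' scheme (`d_main`, `d_novo0`, `eps_methyl`) and the two-compartment
#' population dynamics (`rho_alpha`, `rho_omega`, `r_div`, `q0`).
#'
#' All rates are per computational time step `dt`; with the default
#' proliferation rate `r_div = 0.005` one cell generation corresponds to
#' roughly 200 steps. Energies are in units of kT with the convention that
#' positive `eps_bs` / `eps_hm` favour binding, i.e. the binding probability
#' of the methyltransferase complex is
#' `1 / (1 + exp(eps0 - w_bs * eps_bs - (n_hm / n_h) * eps_hm))`.
#'
#' The chromatin defaults were calibrated once (see
#' `tools/tune_defaults.R`) so that under the default energies the
#' stationary law of the modification chain is bimodal for genes with
#' eight or more cooperative nucleosomes and unimodal for six or fewer,
#' the fully modified state of an eight-nucleosome gene is metastable on
#' simulation horizons, and a methylated regulatory region pins marker
#' expression far below the phenotype threshold `ts`.
#'
#' @param ... Named overrides of any default listed below.
#'
#' @return An object of class `epidrift_params`: a named list with elements
#'   `p_max`, `delta`, `q_p`, `k_m`, `k_d`, `eps0`, `eps_bs`, `eps_hm`,
#'   `eps_methyl`, `d_main`, `d_novo0`, `dt`, `ts`, `rho_alpha`,
#'   `rho_omega`, `r_div`, `q0`, and the per-phenotype multipliers
#'   `aged_q_mult`, `aged_r_mult`, `aged_rho_alpha_mult`,
#'   `aged_rho_omega_mult`.
#' @examples
#' p <- epidrift_params()
#' p$k_m
#' epidrift_params(k_m = 0.6 * 0.7)$k_m
#' @export
epidrift_params <- function(...) {
  defaults <- list(
    # transcription (explicit-Euler update of de/dt = p_max * theta_pro * Theta - delta * e)
    p_max = 1000,
    delta = 0.2,
    q_p   = 1,
    # histone modification chain, per nucleosome per dt
    k_m   = 0.7,
    k_d   = 0.014,
    eps0   = 13.7,
    eps_bs = 8,
    eps_hm = 16,
    # replication-coupled DNA methylation
    eps_methyl = 0.75,
    d_main  = 0.8,
    d_novo0 = 0.3,
    dt = 1,
    # age-related phenotype threshold on mean marker transcription
    ts = 2,
    # population dynamics, per dt
    rho_alpha = 5e-4,
    rho_omega = 0.05,
    r_div = 0.005,
    q0    = 5e-4,
    # aged-phenotype multipliers (identity: no phenotype feedback)
    aged_q_mult = 1,
    aged_r_mult = 1,
    aged_rho_alpha_mult = 1,
    aged_rho_omega_mult = 1
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(defaults))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    defaults[names(dots)] <- dots
  }
  p <- structure(defaults, class = "epidrift_params")
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks ranges and the per-step probability bounds (`k_m * dt <= 1`,
#' `k_d * dt <= 1`, `delta * dt < 1`). All violations are reported at once.
#'
#' @param p An `epidrift_params` object.
#' @return `p`, invisibly, if valid; otherwise an error listing every
#'   offending field.
#' @export
validate_params <- function(p) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(p$p_max > 0, "p_max must be > 0")
  chk(p$delta > 0, "delta must be > 0")
  chk(p$delta * p$dt < 1, "delta * dt must be < 1 (Euler stability)")
  chk(p$q_p > 0, "q_p must be > 0")
  chk(p$k_m >= 0 && p$k_m * p$dt <= 1, "k_m * dt must lie in [0, 1]")
  chk(p$k_d >= 0 && p$k_d * p$dt <= 1, "k_d * dt must lie in [0, 1]")
  chk(p$eps_bs >= 0, "eps_bs must be >= 0")
  chk(p$eps_hm >= 0, "eps_hm must be >= 0")
  chk(p$eps_methyl >= 0, "eps_methyl must be >= 0")
  chk(p$d_main >= 0 && p$d_main <= 1, "d_main must lie in [0, 1]")
  chk(p$d_novo0 >= 0 && p$d_novo0 <= 1, "d_novo0 must lie in [0, 1]")
  chk(p$dt > 0, "dt must be > 0")
  chk(p$ts >= 0, "ts must be >= 0")
  for (f in c("rho_alpha", "rho_omega", "r_div", "q0",
              "aged_q_mult", "aged_r_mult",
              "aged_rho_alpha_mult", "aged_rho_omega_mult")) {
    chk(p[[f]] >= 0, paste(f, "must be >= 0"))
  }
  if (length(errs)) {
    stop("invalid parameters:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  }
  invisible(p)
}

#' @export
print.epidrift_params <- function(x, ...) {
  cat("<epidrift_params>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}
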