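#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration describing a scenario run:
#' \preformatted{
#' preset: hsc            # optional scenario preset
#' seed: 1
#' steps: 6000
#' burn_in: 0
#' record_every: 50
#' n0: 20
#' n_alpha: 10
#' force_phenotype: none
#' genome:                # optional; defaults shown
#'   length: 120000
#'   seed: 1
#' params:                # overrides of epidrift_params() defaults
#'   k_m: 0.42
#' arp:                   # optional explicit phenotype definition
#'   marker_ids: [3, 7, 12]
#'   ts: 2
#'   q_mult: 0.3333
#' }
#' Unknown keys anywhere and out-of-range parameter values are all
#' reported together in a single error.
#'
#' @param path Path to a `.yml`/`.yaml`/`.json` file.
#' @return A validated config list with every field present (defaults
#'   filled in), of class `epidrift_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  defaults <- list(preset = NULL, seed = 1L, steps = 2000L, burn_in = 0L,
                   record_every = 20L, n0 = 20L, n_alpha = NULL,
                   force_phenotype = "none",
                   genome = list(length = 120000L, seed = 1L),
                   params = list(), arp = NULL)
  errs <- character()
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad)) errs <- c(errs, paste("unknown key(s):",
                                         paste(bad, collapse = ", ")))
  merged <- defaults
  merged[intersect(names(cfg), names(defaults))] <-
    cfg[intersect(names(cfg), names(defaults))]
  if (is.null(merged$n_alpha)) merged$n_alpha <- floor(merged$n0 / 2)

  gk <- setdiff(names(merged$genome),
                c("length", "seed", "promoter_motif", "gene_length_range",
                  "cpg_motif", "tf_prefix", "tf_max_mismatch"))
  if (length(gk)) errs <- c(errs, paste("unknown genome key(s):",
                                        paste(gk, collapse = ", ")))
  p <- tryCatch(do.call(epidrift_params, merged$params),
                error = function(e) {errs <<- c(errs, conditionMessage(e)); NULL})
  if (!is.null(merged$preset) &&
      !merged$preset %in% c("no-arp-isolated", "no-arp-exchange",
                            "low-differentiation", "low-proliferation", "hsc")) {
    errs <- c(errs, paste("unknown preset:", merged$preset))
  }
  if (!merged$force_phenotype %in% c("none", "young", "aged")) {
    errs <- c(errs, paste("invalid force_phenotype:", merged$force_phenotype))
  }
  if (!is.null(merged$arp)) {
    ak <- setdiff(names(merged$arp),
                  c("marker_ids", "ts", "q_mult", "r_mult",
                    "rho_alpha_mult", "rho_omega_mult"))
    if (length(ak)) errs <- c(errs, paste("unknown arp key(s):",
                                          paste(ak, collapse = ", ")))
  }
  for (f in c("seed", "steps", "burn_in", "record_every", "n0")) {
    if (!is.numeric(merged[[f]]) || merged[[f]] < 0) {
      errs <- c(errs, paste(f, "must be a non-negative number"))
    }
  }
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  merged$params_full <- unclass(p)
  structure(merged, class = "epidrift_config")
}

#' Run a simulation from a configuration
#'
#' Builds (or reads) the genome, applies the preset and overrides, runs
#' the scenario and, when `out_dir` is given, writes the trajectory CSVs
#' together with a byte-stable YAML echo of the fully resolved
#' configuration.
#'
#' @param cfg An `epidrift_config` from [load_config()], or a path.
#' @param out_dir Optional output directory.
#' @param genome Optional pre-built `epidrift_genome` (skips generation).
#' @return The `epidrift_trajectory`, invisibly when writing.
#' @export
run_config <- function(cfg, out_dir = NULL, genome = NULL) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "epidrift_config"))
  if (is.null(genome)) genome <- do.call(generate_genome, cfg$genome)
  p <- do.call(epidrift_params, cfg$params)
  arp <- if (!is.null(cfg$arp)) do.call(arp_definition, cfg$arp)
  traj <- run_scenario(genome, preset = cfg$preset, params = p, arp = arp,
                       steps = cfg$steps, burn_in = cfg$burn_in,
                       record_every = cfg$record_every, seed = cfg$seed,
                       n0 = cfg$n0, n_alpha = cfg$n_alpha,
                       force_phenotype = cfg$force_phenotype)
  if (!is.null(out_dir)) {
    write_trajectory(traj, out_dir)
    return(invisible(traj))
  }
  traj
}
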