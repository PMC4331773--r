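#' Chromatin state of one gene
#'
#' A per-gene, per-cell record of the chromatin layer: the number of
#' H3K4me3-modified nucleosomes `n_hm` out of the gene's `n_h` cooperative
#' nucleosomes, and the methylation status of each CpG-analog site.
#'
#' @param n_h Number of cooperative nucleosomes (>= 0).
#' @param n_hm Modified-nucleosome count in `[0, n_h]`; defaults to fully
#'   modified.
#' @param cpg_meth Logical vector, one entry per CpG site; defaults to all
#'   unmethylated.
#' @param n_cpg Number of CpG sites (used when `cpg_meth` is not given).
#' @return A `chromatin_state` list with elements `n_hm`, `n_h`, `cpg_meth`.
#' @examples
#' cs <- chromatin_state(n_h = 8, n_cpg = 6)
#' unmethylated_fraction(cs)
#' @export
chromatin_state <- function(n_h, n_hm = n_h, cpg_meth = NULL, n_cpg = 0) {
  if (is.null(cpg_meth)) cpg_meth <- rep(FALSE, n_cpg)
  stopifnot(n_h >= 0, n_hm >= 0, n_hm <= n_h)
  structure(list(n_hm = as.integer(n_hm), n_h = as.integer(n_h),
                 cpg_meth = as.logical(cpg_meth)),
            class = "chromatin_state")
}

#' Fraction of unmethylated CpGs
#'
#' The probability of finding a CpG binding site unmethylated, i.e. the
#' fraction of unmethylated CpGs in the gene's regulatory region. A gene
#' without CpGs has no DNA binding sites for the methyltransferase complex
#' and returns 0 by convention.
#'
#' @param cs A `chromatin_state`.
#' @return `w_bs` in `[0, 1]`.
#' @export
unmethylated_fraction <- function(cs) {
  n <- length(cs$cpg_meth)
  if (n == 0) return(0)
  sum(!cs$cpg_meth) / n
}

#' Binding probability of the histone-methyltransferase complex
#'
#' Two-state Boltzmann form
#' `Theta = 1 / (1 + exp(eps0 - w_bs * eps_bs - (n_hm / n_h) * eps_hm))`,
#' strictly increasing in the modified fraction `n_hm / n_h` (recruitment
#' feedback) and in the unmethylated fraction `w_bs` (DNA binding).
#' Genes without nucleosomes (`n_h = 0`) have nothing to recruit to and
#' return 0.
#'
#' @param n_hm Modified-nucleosome count (vectorised).
#' @param n_h Nucleosome count (vectorised).
#' @param w_bs Unmethylated CpG fraction (vectorised).
#' @param p An `epidrift_params` object.
#' @return Binding probability in `[0, 1]`.
#' @examples
#' p <- epidrift_params(eps0 = 0, eps_bs = 1, eps_hm = 4)
#' hmt_binding_probability(4, 8, 1, p)  # logistic(1)
#' @export
hmt_binding_probability <- function(n_hm, n_h, w_bs, p) {
  k <- max(length(n_hm), length(n_h), length(w_bs))
  n_hm <- rep_len(n_hm, k); n_h <- rep_len(n_h, k); w_bs <- rep_len(w_bs, k)
  x <- ifelse(n_h > 0, n_hm / pmax(n_h, 1L), 0)
  ifelse(n_h > 0,
         plogis(w_bs * p$eps_bs + x * p$eps_hm - p$eps0),
         0)
}

#' One stochastic histone (de-)modification step
#'
#' Over one time step `dt`, each unmodified nucleosome gains the mark
#' independently with probability `k_m * Theta * dt` and each modified
#' nucleosome loses it with probability `k_d * dt`, so the expected change
#' obeys `d<n_hm> = (k_m * Theta * (n_h - n_hm) - k_d * n_hm) * dt`.
#'
#' @param cs A `chromatin_state`.
#' @param theta Binding probability of the modifying complex.
#' @param p An `epidrift_params` object.
#' @return The updated `chromatin_state`.
#' @export
step_histones <- function(cs, theta, p) {
  p_gain <- p$k_m * theta * p$dt
  p_loss <- p$k_d * p$dt
  if (p_gain > 1 || p_loss > 1) {
    stop("per-step (de-)modification probability exceeds 1; reduce rates or dt",
         call. = FALSE)
  }
  gains <- rbinom(1L, cs$n_h - cs$n_hm, p_gain)
  losses <- rbinom(1L, cs$n_hm, p_loss)
  cs$n_hm <- cs$n_hm + gains - losses
  cs
}

# exact one-step transition matrix of the simultaneous binomial update,
# states 0..n_h (row = from, column = to)
histone_transition_matrix <- function(n_h, w_bs, p) {
  stopifnot(n_h >= 1)
  states <- 0:n_h
  theta <- hmt_binding_probability(states, n_h, w_bs, p)
  pg <- pmin(p$k_m * theta * p$dt, 1)
  pl <- min(p$k_d * p$dt, 1)
  P <- matrix(0, n_h + 1L, n_h + 1L)
  for (n in states) {
    dg <- dbinom(0:(n_h - n), n_h - n, pg[n + 1L])
    dl <- dbinom(0:n, n, pl)
    for (g in 0:(n_h - n)) {
      to <- n + g - (0:n)
      P[n + 1L, to + 1L] <- P[n + 1L, to + 1L] + dg[g + 1L] * dl
    }
  }
  P
}

#' Stationary law of the histone-modification chain
#'
#' Computes the exact stationary distribution of the per-step update chain
#' of [step_histones()] on states `0..n_h` by solving the stationary
#' linear system of its transition matrix, and flags bimodality. Because
#' several nucleosomes can flip within one `dt`, this chain generalises
#' the single-jump birth-death chain with rates
#' `k_m * Theta(n) * (n_h - n)` and `k_d * n`; as `dt -> 0` the two laws
#' coincide (detailed balance).
#'
#' The bimodality flag requires two local maxima *and* at least
#' `minor_mass` of probability in the minor basin (split at the interior
#' minimum between the outermost maxima): a formal second maximum carrying
#' negligible mass is not treated as bistability.
#'
#' @param n_h Number of cooperative nucleosomes (>= 1).
#' @param w_bs Unmethylated CpG fraction held fixed.
#' @param p An `epidrift_params` object.
#' @param minor_mass Minimum probability mass of the minor basin for the
#'   bimodality flag (default 0.1).
#' @return A list with `pi` (stationary probabilities over `0:n_h`),
#'   `bimodal` (flag), `n_modes` (local-maxima count) and
#'   `minor_basin_mass`.
#' @examples
#' p <- epidrift_params()
#' histone_stationary_distribution(8, 1, p)$bimodal
#' histone_stationary_distribution(4, 1, p)$bimodal
#' @export
histone_stationary_distribution <- function(n_h, w_bs, p, minor_mass = 0.1) {
  stopifnot(n_h >= 1)
  P <- histone_transition_matrix(n_h, w_bs, p)
  k <- n_h + 1L
  # solve pi (P - I) = 0 with sum(pi) = 1
  A <- rbind(t(P) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- as.numeric(qr.solve(A, b))
  pi <- pmax(pi, 0); pi <- pi / sum(pi)
  is_max <- vapply(seq_len(k), function(i) {
    l <- if (i > 1) pi[i - 1] else -Inf
    r <- if (i < k) pi[i + 1] else -Inf
    pi[i] > l + 1e-14 && pi[i] > r + 1e-14
  }, logical(1))
  n_modes <- sum(is_max)
  mbm <- 0
  if (n_modes >= 2) {
    mx <- which(is_max)
    v <- which.min(pi[min(mx):max(mx)]) + min(mx) - 1L
    mbm <- min(sum(pi[1:v]), sum(pi[(v + 1):k]))
  }
  list(pi = pi, bimodal = n_modes >= 2 && mbm >= minor_mass,
       n_modes = n_modes, minor_basin_mass = mbm)
}

#' De novo methylation rate gated by the histone state
#'
#' `d_novo = d_novo0 * exp(-eps_methyl * n_hm / n_h)`, clipped to `[0, 1]`:
#' H3K4me3 repels the de novo methyltransferase, so a fully unmodified
#' gene methylates at the full constant `d_novo0` and full modification
#' suppresses de novo methylation exponentially. Nucleosome-free genes
#' (`n_h = 0`) carry no protective mark and use `d_novo0` directly.
#'
#' @param n_hm,n_h Modified and total nucleosome counts (vectorised).
#' @param p An `epidrift_params` object.
#' @return Per-CpG de novo methylation probability at division.
#' @examples
#' p <- epidrift_params(d_novo0 = 0.3, eps_methyl = 6)
#' denovo_rate(4, 8, p)  # 0.3 * exp(-3)
#' @export
denovo_rate <- function(n_hm, n_h, p) {
  x <- ifelse(n_h > 0, n_hm / pmax(n_h, 1L), 0)
  pmin(pmax(p$d_novo0 * exp(-p$eps_methyl * x), 0), 1)
}

#' Replication step of the DNA-methylation layer
#'
#' Applied only at cell division: independently per CpG, a methylated site
#' stays methylated with the maintenance probability `d_main` (otherwise
#' reverts), and an unmethylated site becomes methylated with probability
#' `d_novo`.
#'
#' @param cs A `chromatin_state`.
#' @param d_novo De novo methylation probability (see [denovo_rate()]).
#' @param p An `epidrift_params` object.
#' @return The `chromatin_state` with a freshly drawn `cpg_meth`.
#' @export
replicate_methylation <- function(cs, d_novo, p) {
  m <- cs$cpg_meth
  keep <- m & (runif(length(m)) < p$d_main)
  gain <- !m & (runif(length(m)) < d_novo)
  cs$cpg_meth <- keep | gain
  cs
}

#' One explicit-Euler transcription step
#'
#' Updates expression by `e' = e + (p_max * theta_pro * theta - delta * e) * dt`,
#' the Euler discretisation of transcription proportional to promoter
#' occupancy and methyltransferase-complex binding, with first-order
#' degradation. The fixed point is `p_max * theta_pro * theta / delta`.
#'
#' @param e Current expression level (vectorised, >= 0).
#' @param theta_pro Polymerase-II promoter occupancy in `[0, 1]`.
#' @param theta Binding probability of the modifying complex in `[0, 1]`.
#' @param p An `epidrift_params` object.
#' @return Updated expression.
#' @export
step_expression <- function(e, theta_pro, theta, p) {
  if (p$delta * p$dt >= 1) {
    stop("delta * dt must be < 1 for a stable Euler update", call. = FALSE)
  }
  e + (p$p_max * theta_pro * theta - p$delta * e) * p$dt
}

#' Polymerase-II promoter occupancy
#'
#' Thermodynamic occupancy
#' `theta_pro = q_p * (1 + S_act) / (1 + S_rep + q_p * (1 + S_act))`
#' where `S_act` and `S_rep` sum `weight * e_j * delta / p_max` over the
#' gene's activating and repressing regulators. Monotone increasing in
#' activator expression, decreasing in repressor expression, and equal to
#' the basal `q_p / (1 + q_p)` for an unregulated gene.
#'
#' @param gene_id Target gene id.
#' @param g An `epidrift_genome`.
#' @param expression Numeric vector of expression levels indexed by gene id.
#' @param p An `epidrift_params` object.
#' @return Occupancy in `(0, 1)`.
#' @export
promoter_occupancy <- function(gene_id, g, expression, p) {
  ints <- g$interactions[g$interactions$target == gene_id, ]
  e_norm <- expression * p$delta / p$p_max
  s_act <- sum(ints$weight[ints$sign == "activating"] *
               e_norm[ints$regulator[ints$sign == "activating"]])
  s_rep <- sum(ints$weight[ints$sign == "repressing"] *
               e_norm[ints$regulator[ints$sign == "repressing"]])
  p$q_p * (1 + s_act) / (1 + s_rep + p$q_p * (1 + s_act))
}
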