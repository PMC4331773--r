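#' Age-related phenotype definition
#'
#' A cell adopts the aged phenotype whenever the mean transcription of the
#' marker genes falls strictly below the threshold `ts`; the phenotype is
#' re-evaluated every time step, so switching is reversible. Aged cells
#' have their differentiation coefficient, proliferation rate and niche
#' exchange coefficients multiplied by the given factors.
#'
#' @param marker_ids Gene ids of the (typically three) bistable aging
#'   marker genes.
#' @param ts Transcription threshold.
#' @param q_mult,r_mult,rho_alpha_mult,rho_omega_mult Aged-phenotype
#'   multipliers on `q0`, `r_div`, `rho_alpha`, `rho_omega`.
#' @return An `arp_definition` object.
#' @export
arp_definition <- function(marker_ids, ts = 2, q_mult = 1, r_mult = 1,
                           rho_alpha_mult = 1, rho_omega_mult = 1) {
  stopifnot(length(marker_ids) >= 1, ts >= 0, q_mult >= 0, r_mult >= 0,
            rho_alpha_mult >= 0, rho_omega_mult >= 0)
  structure(list(marker_ids = as.integer(marker_ids), ts = ts,
                 q_mult = q_mult, r_mult = r_mult,
                 rho_alpha_mult = rho_alpha_mult,
                 rho_omega_mult = rho_omega_mult),
            class = "arp_definition")
}

#' Default aging markers of a genome
#'
#' Selects the first `n` genes with at least `min_n_h` cooperative
#' nucleosomes: bistable genes whose silencing requires many cell cycles,
#' i.e. C1a candidates.
#'
#' @param g An `epidrift_genome`.
#' @param n Number of markers.
#' @param min_n_h Minimum nucleosome count for a marker.
#' @return Integer gene ids.
#' @export
default_markers <- function(g, n = 3, min_n_h = 8) {
  ids <- g$genes$id[g$genes$n_h >= min_n_h]
  if (length(ids) < n) {
    stop("genome has fewer than ", n, " genes with n_h >= ", min_n_h,
         call. = FALSE)
  }
  head(ids, n)
}

#' Per-cell compartment transition probabilities
#'
#' `p_alpha = rho_alpha * n_alpha * dt` is the probability for a niche cell
#' to leave (crowding pushes cells out); `p_omega = rho_omega / n_omega`
#' is the probability for a proliferating cell to home to the niche, so the
#' total inflow `p_omega * n_omega` is constant as long as the compartment
#' is occupied. Both are clipped to `[0, 1]`; `p_omega` is 0 when
#' `n_omega` is 0.
#'
#' @param n_alpha,n_omega Compartment cell counts.
#' @param p An `epidrift_params` object.
#' @param rho_alpha_mult,rho_omega_mult Phenotype multipliers.
#' @return Named numeric vector `c(p_alpha, p_omega)`.
#' @examples
#' transition_probabilities(10, 10, epidrift_params(rho_omega = 1))
#' @export
transition_probabilities <- function(n_alpha, n_omega, p,
                                     rho_alpha_mult = 1, rho_omega_mult = 1) {
  p_alpha <- min(1, p$rho_alpha * rho_alpha_mult * n_alpha * p$dt)
  p_omega <- if (n_omega >= 1) {
    min(1, p$rho_omega * rho_omega_mult / n_omega * p$dt)
  } else 0
  c(p_alpha = p_alpha, p_omega = p_omega)
}

#' Mean-field stationary compartment sizes
#'
#' At stationarity the exchange flows balance (`rho_omega = rho_alpha *
#' n_alpha^2`) and proliferation balances differentiation
#' (`r_div = q0 * n_omega`), giving `n_alpha* = sqrt(rho_omega/rho_alpha)`
#' and `n_omega* = r_div / q0`.
#'
#' @param p An `epidrift_params` object.
#' @return Named numeric vector `c(n_alpha, n_omega)`.
#' @examples
#' stationary_cell_numbers(epidrift_params())
#' @export
stationary_cell_numbers <- function(p) {
  if (p$rho_alpha <= 0 || p$rho_omega <= 0 || p$r_div <= 0 || p$q0 <= 0) {
    stop("stationary sizes require strictly positive rho_alpha, rho_omega, r_div, q0",
         call. = FALSE)
  }
  c(n_alpha = sqrt(p$rho_omega / p$rho_alpha), n_omega = p$r_div / p$q0)
}

# ---- vectorised population engine ------------------------------------------

# cached per-genome arrays used in the hot loop
genome_cache <- function(g, p) {
  G <- nrow(g$genes)
  n_h <- g$genes$n_h
  n_cpg <- g$genes$n_cpg
  w_act <- matrix(0, G, G)
  w_rep <- matrix(0, G, G)
  if (nrow(g$interactions)) {
    ia <- g$interactions
    act <- ia$sign == "activating"
    w_act[cbind(ia$target[act], ia$regulator[act])] <- ia$weight[act]
    w_rep[cbind(ia$target[!act], ia$regulator[!act])] <- ia$weight[!act]
  }
  list(G = G, n_h = n_h, n_cpg = n_cpg, w_act = w_act, w_rep = w_rep,
       nuc = n_h > 0, cpg = n_cpg > 0)
}

# row-replicated per-gene scaling matrices, rebuilt only when the number
# of cells changes (hot-loop optimisation)
row_cache <- function(cache, n) {
  list(n = n,
       nh = matrix(cache$n_h, n, cache$G, byrow = TRUE),
       nh1 = matrix(pmax(cache$n_h, 1L), n, cache$G, byrow = TRUE),
       ncpg1 = matrix(pmax(cache$n_cpg, 1L), n, cache$G, byrow = TRUE))
}

# w_bs matrix (cells x genes): fraction of unmethylated CpGs, 0 for genes
# without CpGs
wbs_matrix <- function(M, cache, rc = NULL) {
  W <- if (is.null(rc)) 1 - sweep(M, 2L, pmax(cache$n_cpg, 1L), "/")
       else 1 - M / rc$ncpg1
  W[, !cache$cpg] <- 0
  W
}

# Theta matrix (cells x genes); genes without nucleosomes are fully
# permissive for transcription (Theta = 1)
theta_matrix <- function(H, W, cache, p, rc = NULL) {
  X <- if (is.null(rc)) sweep(H, 2L, pmax(cache$n_h, 1L), "/")
       else H / rc$nh1
  Th <- plogis(W * p$eps_bs + X * p$eps_hm - p$eps0)
  Th[, !cache$nuc] <- 1
  Th
}

theta_pro_matrix <- function(E, cache, p) {
  En <- E * (p$delta / p$p_max)
  s_act <- En %*% t(cache$w_act)
  s_rep <- En %*% t(cache$w_rep)
  p$q_p * (1 + s_act) / (1 + s_rep + p$q_p * (1 + s_act))
}

# coupled fixed point of the transcription layer for one chromatin state
# (single row H, M); returns expression vector
expression_fixed_point <- function(H, M, cache, p, tol = 1e-8, max_iter = 10000) {
  W <- wbs_matrix(M, cache)
  Th <- theta_matrix(H, W, cache, p)
  E <- matrix(0, 1L, cache$G)
  for (i in seq_len(max_iter)) {
    E_new <- p$p_max * theta_pro_matrix(E, cache, p) * Th / p$delta
    if (max(abs(E_new - E)) < tol * max(1, max(abs(E_new)))) {
      return(as.numeric(E_new))
    }
    E <- E_new
  }
  stop("expression fixed-point iteration did not converge after ",
       max_iter, " iterations (max residual ",
       format(max(abs(E - p$p_max * theta_pro_matrix(E, cache, p) * Th / p$delta))),
       ")", call. = FALSE)
}

#' Create an initial stem-cell population
#'
#' All cells start in the reference chromatin state: every nucleosome
#' H3K4me3-modified and every CpG unmethylated; expression is initialised
#' at the fixed point of the coupled transcription system under these
#' conditions. Each cell receives its own clone barcode.
#'
#' @param g An `epidrift_genome`.
#' @param p An `epidrift_params` object.
#' @param n0 Initial number of cells.
#' @param n_alpha How many of them start in the niche compartment.
#' @param arp Optional [arp_definition()]; `NULL` disables phenotype
#'   feedback.
#' @param force_phenotype `"none"` (evaluate from marker expression),
#'   `"young"` or `"aged"` (pin every cell's phenotype).
#' @return An `epidrift_population` object.
#' @export
new_population <- function(g, p = epidrift_params(), n0 = 20,
                           n_alpha = floor(n0 / 2), arp = NULL,
                           force_phenotype = c("none", "young", "aged")) {
  force_phenotype <- match.arg(force_phenotype)
  cache <- genome_cache(g, p)
  e0 <- expression_fixed_point(matrix(cache$n_h, 1L), matrix(0L, 1L, cache$G),
                               cache, p)
  n0 <- as.integer(n0)
  pop <- list(
    genome = g, params = p, arp = arp, cache = cache,
    force_phenotype = force_phenotype,
    E = matrix(e0, n0, cache$G, byrow = TRUE),
    H = matrix(as.integer(cache$n_h), n0, cache$G, byrow = TRUE),
    M = matrix(0L, n0, cache$G),
    env = c(rep(1L, n_alpha), rep(2L, n0 - n_alpha)),  # 1 = alpha, 2 = omega
    aged = rep(force_phenotype == "aged", n0),
    clone = seq_len(n0),
    gen = rep(0L, n0),
    prog = rep(0, n0),
    t = 0L, status = "running",
    n_divisions = 0L, n_removed = 0L, n_clip = 0L
  )
  class(pop) <- "epidrift_population"
  pop
}

#' @export
print.epidrift_population <- function(x, ...) {
  cat(sprintf("<epidrift_population> t=%d, %d cells (alpha %d / omega %d), %d clones, aged %d, status %s\n",
              x$t, length(x$env), sum(x$env == 1L), sum(x$env == 2L),
              length(unique(x$clone)), sum(x$aged), x$status))
  invisible(x)
}

# multipliers per cell given phenotype
aged_mult <- function(aged, arp, field) {
  if (is.null(arp)) return(rep(1, length(aged)))
  ifelse(aged, arp[[field]], 1)
}

#' Advance the population by one time step
#'
#' Fixed update order per step: (1) intracellular dynamics of every cell
#' (histone step, then transcription Euler step; DNA methylation only
#' changes at division); (2) phenotype evaluation; (3) niche exits with
#' probability `rho_alpha * n_alpha`; (4) niche entries with per-phenotype
#' probability `rho_omega / n_omega`; (5) divisions in the proliferative
#' compartment; (6) differentiation removals with probability
#' `q0 * n_omega`. Compartment counts are recomputed between stages.
#' Niche-crowding pressure (`n_alpha` in stage 3) and differentiation
#' crowding (`n_omega` in stage 6) use total counts across phenotypes;
#' the constant-inflow term in stage 4 is phenotype-specific.
#'
#' @param pop An `epidrift_population`.
#' @return The updated population; its `status` becomes `"extinct"` when
#'   the last cell is removed.
#' @export
step_population <- function(pop) {
  p <- pop$params; cache <- pop$cache; arp <- pop$arp
  n <- length(pop$env)
  if (n == 0L) { pop$status <- "extinct"; return(pop) }

  # (1) intracellular update
  if (is.null(pop$rc) || pop$rc$n != n) pop$rc <- row_cache(cache, n)
  rc <- pop$rc
  W <- wbs_matrix(pop$M, cache, rc)
  Th <- theta_matrix(pop$H, W, cache, p, rc)
  pg <- p$k_m * p$dt * Th   # <= 1 by the validated bound k_m * dt <= 1
  nuc <- cache$nuc
  Hn <- pop$H
  free <- rc$nh[, nuc, drop = FALSE] - Hn[, nuc, drop = FALSE]
  gains <- rbinom(length(free), as.vector(free), as.vector(pg[, nuc, drop = FALSE]))
  losses <- rbinom(length(free), as.vector(Hn[, nuc, drop = FALSE]), p$k_d * p$dt)
  Hn[, nuc] <- Hn[, nuc, drop = FALSE] + gains - losses
  pop$H <- Hn
  tp <- theta_pro_matrix(pop$E, cache, p)
  pop$E <- pop$E + (p$p_max * tp * Th - p$delta * pop$E) * p$dt

  # (2) phenotype
  if (pop$force_phenotype == "none" && !is.null(arp)) {
    marker_mean <- rowMeans(pop$E[, arp$marker_ids, drop = FALSE])
    pop$aged <- marker_mean < arp$ts
  }

  # (3) alpha -> omega
  in_a <- which(pop$env == 1L)
  if (length(in_a)) {
    pa <- p$rho_alpha * aged_mult(pop$aged[in_a], arp, "rho_alpha_mult") *
      length(in_a) * p$dt
    pop$n_clip <- pop$n_clip + sum(pa > 1)
    leave <- runif(length(in_a)) < pmin(pa, 1)
    pop$env[in_a[leave]] <- 2L
  }

  # (4) omega -> alpha (constant inflow per phenotype)
  in_o <- which(pop$env == 2L)
  if (length(in_o)) {
    n_o_ph <- ifelse(pop$aged[in_o],
                     sum(pop$aged[in_o]), sum(!pop$aged[in_o]))
    po <- p$rho_omega * aged_mult(pop$aged[in_o], arp, "rho_omega_mult") /
      pmax(n_o_ph, 1L) * p$dt
    pop$n_clip <- pop$n_clip + sum(po > 1)
    home <- runif(length(in_o)) < pmin(po, 1)
    pop$env[in_o[home]] <- 1L
  }

  # (5) divisions in omega: memoryless growth hazard (unit jumps with
  # probability r_div * dt), so inter-division times are geometric with
  # mean 1/r_div and the mean-field stationarity n_omega* = r_div/q0 holds
  in_o <- which(pop$env == 2L)
  if (length(in_o)) {
    rate <- p$r_div * aged_mult(pop$aged[in_o], arp, "r_mult") * p$dt
    pop$n_clip <- pop$n_clip + sum(rate > 1)
    inc <- as.numeric(runif(length(in_o)) < pmin(rate, 1))
    pop$prog[in_o] <- pop$prog[in_o] + inc
    dividing <- in_o[pop$prog[in_o] >= 1]
    for (i in dividing) pop <- divide_cell(pop, i)
  }

  # (6) differentiation removals
  in_o <- which(pop$env == 2L)
  if (length(in_o)) {
    pq <- p$q0 * aged_mult(pop$aged[in_o], arp, "q_mult") * length(in_o) * p$dt
    pop$n_clip <- pop$n_clip + sum(pq > 1)
    out <- in_o[runif(length(in_o)) < pmin(pq, 1)]
    if (length(out)) {
      keep <- setdiff(seq_along(pop$env), out)
      pop <- subset_cells(pop, keep)
      pop$n_removed <- pop$n_removed + length(out)
    }
  }

  pop$t <- pop$t + 1L
  if (length(pop$env) == 0L) pop$status <- "extinct"
  pop
}

# binomial histone partition + replication-coupled methylation for cell i;
# mother row becomes daughter 1, daughter 2 is appended
divide_cell <- function(pop, i) {
  cache <- pop$cache; p <- pop$params
  G <- cache$G
  h <- pop$H[i, ]
  n1 <- rbinom(G, h, 0.5)
  n2 <- h - n1
  m <- pop$M[i, ]
  meth_child <- function(nd) {
    dn <- denovo_rate(nd, cache$n_h, p)
    rbinom(G, m, p$d_main) + rbinom(G, cache$n_cpg - m, dn)
  }
  m1 <- meth_child(n1)
  m2 <- meth_child(n2)
  pop$H[i, ] <- n1; pop$M[i, ] <- m1
  pop$H <- rbind(pop$H, n2)
  pop$M <- rbind(pop$M, m2)
  pop$E <- rbind(pop$E, pop$E[i, ])
  pop$env <- c(pop$env, pop$env[i])
  pop$aged <- c(pop$aged, pop$aged[i])
  pop$clone <- c(pop$clone, pop$clone[i])
  pop$gen[i] <- pop$gen[i] + 1L
  pop$gen <- c(pop$gen, pop$gen[i])
  pop$prog[i] <- 0
  pop$prog <- c(pop$prog, 0)
  pop$n_divisions <- pop$n_divisions + 1L
  pop
}

subset_cells <- function(pop, keep) {
  pop$E <- pop$E[keep, , drop = FALSE]
  pop$H <- pop$H[keep, , drop = FALSE]
  pop$M <- pop$M[keep, , drop = FALSE]
  for (f in c("env", "aged", "clone", "gen", "prog")) pop[[f]] <- pop[[f]][keep]
  pop
}

#' Export the population as a tidy cell table
#'
#' One row per cell and gene with the cell's compartment, phenotype, clone
#' barcode, generation and the gene's expression, H3K4me3 fraction and
#' methylated-CpG fraction.
#'
#' @param pop An `epidrift_population`.
#' @return A tibble.
#' @export
cell_table <- function(pop) {
  n <- length(pop$env); G <- pop$cache$G
  if (n == 0L) {
    return(tibble(time = integer(), cell = integer(), clone = integer(),
                  environment = character(), phenotype = character(),
                  generation = integer(), gene = integer(),
                  expression = numeric(), h3k4me3 = numeric(),
                  methylation = numeric()))
  }
  tibble(
    time = pop$t,
    cell = rep(seq_len(n), each = G),
    clone = rep(pop$clone, each = G),
    environment = rep(c("alpha", "omega")[pop$env], each = G),
    phenotype = rep(ifelse(pop$aged, "aged", "young"), each = G),
    generation = rep(pop$gen, each = G),
    gene = rep(pop$genome$genes$id, times = n),
    expression = as.vector(t(pop$E)),
    h3k4me3 = as.vector(t(sweep(pop$H, 2L, pmax(pop$cache$n_h, 1L), "/"))) *
      rep(as.numeric(pop$cache$nuc), times = n),
    methylation = as.vector(t(sweep(pop$M, 2L, pmax(pop$cache$n_cpg, 1L), "/"))) *
      rep(as.numeric(pop$cache$cpg), times = n)
  )
}
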