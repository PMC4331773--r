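#' Create a cell in the reference epigenetic state
#'
#' Every nucleosome carries the H3K4me3 mark and every CpG is
#' unmethylated; the transcription state is the fixed point of the coupled
#' expression system under these chromatin conditions, found by iterating
#' the fixed-point map to tolerance.
#'
#' @param g An `epidrift_genome`.
#' @param p An `epidrift_params` object.
#' @param clone_id Clone barcode inherited by all descendants.
#' @return A `cell_state` object: per-gene `expression`, a list of
#'   [chromatin_state()]s, `environment` (`"alpha"` or `"omega"`),
#'   `clone_id`, `generation`, `phenotype` and `division_progress`.
#' @export
initial_cell <- function(g, p = epidrift_params(), clone_id = 1L) {
  cache <- genome_cache(g, p)
  e0 <- expression_fixed_point(matrix(cache$n_h, 1L),
                               matrix(0L, 1L, cache$G), cache, p)
  chrom <- lapply(seq_len(cache$G), function(i) {
    chromatin_state(n_h = cache$n_h[i], n_hm = cache$n_h[i],
                    n_cpg = cache$n_cpg[i])
  })
  structure(list(expression = e0, chromatin = chrom, environment = "alpha",
                 clone_id = as.integer(clone_id), generation = 0L,
                 phenotype = "young", division_progress = 0),
            class = "cell_state")
}

#' One intracellular time step of a single cell
#'
#' Per time step, in order: the unmethylated CpG fraction and the
#' methyltransferase-complex binding probability are evaluated per gene,
#' the histone chain takes one stochastic step, promoter occupancies are
#' computed from current expression, and expression takes one Euler step.
#' DNA methylation is untouched: it changes at replication only.
#'
#' @param cell A `cell_state`.
#' @param g The `epidrift_genome` the cell carries.
#' @param p An `epidrift_params` object.
#' @return The updated `cell_state`.
#' @export
step_cell <- function(cell, g, p = epidrift_params()) {
  G <- length(cell$chromatin)
  w <- vapply(cell$chromatin, unmethylated_fraction, numeric(1))
  n_hm <- vapply(cell$chromatin, `[[`, integer(1), "n_hm")
  n_h <- vapply(cell$chromatin, `[[`, integer(1), "n_h")
  theta <- hmt_binding_probability(n_hm, n_h, w, p)
  theta_tx <- ifelse(n_h > 0, theta, 1)  # nucleosome-free genes transcribe freely
  for (i in seq_len(G)) {
    if (n_h[i] > 0) {
      cell$chromatin[[i]] <- step_histones(cell$chromatin[[i]], theta[i], p)
    }
  }
  tp <- vapply(g$genes$id, promoter_occupancy, numeric(1),
               g = g, expression = cell$expression, p = p)
  cell$expression <- step_expression(cell$expression, tp, theta_tx, p)
  cell
}

#' Attempt a cell division
#'
#' Only cells in the proliferative compartment divide. Division progress
#' accumulates memoryless stochastic increments (unit jumps with
#' probability `r_div * dt`, i.e. mean increment `r_div * dt` per step),
#' so inter-division times are geometric with mean `1 / r_div`. When
#' progress crosses 1 the cell divides: per gene, the mother's modified nucleosomes
#' are partitioned binomially between the daughters (the vacated positions
#' are filled by fresh unmodified nucleosomes) and each daughter's CpG
#' states are redrawn by [replicate_methylation()] with the de novo rate
#' evaluated from that daughter's post-partition modification level.
#' Generation increases by one; the clone barcode is inherited; progress
#' resets.
#'
#' @param cell A `cell_state` with `environment == "omega"`.
#' @param g An `epidrift_genome`.
#' @param p An `epidrift_params` object.
#' @param r_div Division rate per time step (defaults to `p$r_div`).
#' @return `NULL` if the threshold was not reached, otherwise a list of
#'   two daughter `cell_state`s.
#' @export
attempt_division <- function(cell, g, p = epidrift_params(), r_div = p$r_div) {
  if (cell$environment != "omega") {
    stop("cells divide only in the omega environment (r = 0 in the niche)",
         call. = FALSE)
  }
  cell$division_progress <- cell$division_progress +
    as.numeric(runif(1L) < min(r_div * p$dt, 1))
  if (cell$division_progress < 1) return(NULL)
  d1 <- cell; d2 <- cell
  for (i in seq_along(cell$chromatin)) {
    cs <- cell$chromatin[[i]]
    n1 <- rbinom(1L, cs$n_hm, 0.5)
    n2 <- cs$n_hm - n1
    c1 <- cs; c1$n_hm <- n1
    c2 <- cs; c2$n_hm <- n2
    d1$chromatin[[i]] <- replicate_methylation(c1, denovo_rate(n1, cs$n_h, p), p)
    d2$chromatin[[i]] <- replicate_methylation(c2, denovo_rate(n2, cs$n_h, p), p)
  }
  d1$generation <- d2$generation <- cell$generation + 1L
  d1$division_progress <- d2$division_progress <- 0
  list(d1, d2)
}

#' Evaluate the age-related phenotype of a cell
#'
#' Aged if and only if the mean expression of the marker genes is strictly
#' below the threshold `ts` (a mean exactly at the threshold is young).
#'
#' @param cell A `cell_state`.
#' @param arp An [arp_definition()].
#' @return `"young"` or `"aged"`.
#' @export
evaluate_phenotype <- function(cell, arp) {
  if (mean(cell$expression[arp$marker_ids]) < arp$ts) "aged" else "young"
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state> clone %d, gen %d, %s, %s; %d genes\n",
              x$clone_id, x$generation, x$environment, x$phenotype,
              length(x$expression)))
  invisible(x)
}
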