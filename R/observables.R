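#' Per-gene regulatory-state summary
#'
#' Averages the recorded gene states over a time window, separately per
#' compartment: mean and variance of expression, H3K4me3 fraction and
#' methylated-CpG fraction. Expression and H3K4me3 means are also
#' normalised to their maximum across genes, and genes are ranked by the
#' average H3K4me3 modification in the proliferative compartment.
#'
#' @param x An `epidrift_trajectory` or an `epidrift_population`.
#' @param window Time window `c(from, to)`; defaults to the full recording.
#' @return A tibble with one row per gene and environment.
#' @export
summarize_states <- function(x, window = NULL) {
  gs <- if (inherits(x, "epidrift_trajectory")) x$gene_state
        else if (inherits(x, "epidrift_population")) record_gene_state(x)
        else stop("x must be a trajectory or population", call. = FALSE)
  if (!is.null(window)) {
    gs <- dplyr::filter(gs, .data$time >= window[1], .data$time <= window[2])
  }
  out <- gs |>
    dplyr::group_by(.data$gene, .data$environment) |>
    dplyr::summarise(
      mean_expression = mean(.data$mean_expression),
      var_expression = mean(.data$var_expression),
      mean_h3k4me3 = mean(.data$mean_h3k4me3),
      var_h3k4me3 = mean(.data$var_h3k4me3),
      mean_methylation = mean(.data$mean_methylation),
      var_methylation = mean(.data$var_methylation),
      n_samples = dplyr::n(), .groups = "drop")
  norm <- function(v) if (max(v) > 0) v / max(v) else v
  out <- out |>
    dplyr::mutate(norm_expression = norm(.data$mean_expression),
                  norm_h3k4me3 = norm(.data$mean_h3k4me3))
  rank_tbl <- out |>
    dplyr::filter(.data$environment == "omega") |>
    dplyr::arrange(dplyr::desc(.data$mean_h3k4me3)) |>
    dplyr::mutate(rank_h3k4me3_omega = dplyr::row_number()) |>
    dplyr::select("gene", "rank_h3k4me3_omega")
  dplyr::left_join(out, rank_tbl, by = "gene") |>
    dplyr::arrange(.data$rank_h3k4me3_omega, .data$environment)
}

#' Classify genes into the C1/C1a/C2/C3 behavioural sets
#'
#' Behavioural rules, evaluated on the late part of a trajectory that
#' covers both compartments:
#' \describe{
#'   \item{C3}{no nucleosomes (`n_h = 0`).}
#'   \item{C2}{monostable chain (no bimodality flag at the silenced-state
#'     methylation level) that loses its H3K4me3 modification in the
#'     proliferative compartment.}
#'   \item{C1}{bistable or not, stably modified in the niche (late mean
#'     H3K4me3 in alpha above `stable_h`).}
#'   \item{C1a}{the C1 subset that acquired DNA methylation in the
#'     proliferative compartment (late mean methylation above `meth_gain`).}
#' }
#' The nucleosome-count shortcut (`C3 < 1 <= C2 <= 6 < C1`) is reported
#' alongside, with the agreement rate between the two classifications.
#'
#' @param traj An `epidrift_trajectory` with cells in both compartments.
#' @param p Parameters used for the bimodality flag (default: trajectory's).
#' @param w_bs Unmethylated fraction at which bistability is judged;
#'   defaults to the stationary silenced-state fraction
#'   `1 - d_novo0 / (1 - d_main + d_novo0)`, since bistability of a gene
#'   depends on the methylation state of its DNA.
#' @param window Late time window; default last half of the recording.
#' @param stable_h Niche H3K4me3 level above which a gene counts as stably
#'   modified.
#' @param lost_h Omega H3K4me3 level below which the mark counts as lost.
#' @param meth_gain Methylation fraction counting as acquired.
#' @return A list with a per-gene tibble (`classes`) and the
#'   `agreement` rate between behavioural and shortcut classes.
#' @export
classify_genes <- function(traj, p = NULL, w_bs = NULL, window = NULL,
                           stable_h = 0.5, lost_h = 0.3, meth_gain = 0.2) {
  stopifnot(inherits(traj, "epidrift_trajectory"))
  if (is.null(p)) p <- do.call(epidrift_params, traj$config$params)
  if (is.null(w_bs)) w_bs <- 1 - p$d_novo0 / (1 - p$d_main + p$d_novo0)
  times <- unique(traj$gene_state$time)
  if (length(times) < 4) stop("trajectory too short for a stable classification",
                              call. = FALSE)
  if (is.null(window)) window <- c(times[ceiling(length(times) / 2)], max(times))
  s <- summarize_states(traj, window)
  genes <- traj$final$genome$genes
  wide <- tidyr::pivot_wider(
    dplyr::select(s, "gene", "environment", "mean_h3k4me3", "mean_methylation"),
    names_from = "environment",
    values_from = c("mean_h3k4me3", "mean_methylation"))
  wide <- dplyr::left_join(dplyr::select(genes, "id", "n_h"), wide,
                           by = c(id = "gene"))
  bist <- vapply(wide$n_h, function(nh) {
    if (nh < 1) return(FALSE)
    histone_stationary_distribution(nh, w_bs, p)$bimodal
  }, logical(1))
  behavioural <- dplyr::case_when(
    wide$n_h == 0 ~ "C3",
    !bist & wide$mean_h3k4me3_omega < lost_h ~ "C2",
    wide$mean_h3k4me3_alpha >= stable_h &
      wide$mean_methylation_omega >= meth_gain ~ "C1a",
    wide$mean_h3k4me3_alpha >= stable_h ~ "C1",
    TRUE ~ "unstable"
  )
  shortcut <- dplyr::case_when(
    wide$n_h < 1 ~ "C3",
    wide$n_h <= 6 ~ "C2",
    TRUE ~ "C1"
  )
  classes <- tibble(gene = wide$id, n_h = wide$n_h,
                    class = behavioural, class_n_h = shortcut,
                    bistable = bist,
                    mean_h3k4me3_alpha = wide$mean_h3k4me3_alpha,
                    mean_h3k4me3_omega = wide$mean_h3k4me3_omega,
                    mean_methylation_omega = wide$mean_methylation_omega)
  coarse <- ifelse(behavioural == "C1a", "C1", behavioural)
  list(classes = classes,
       agreement = mean(coarse == shortcut, na.rm = TRUE))
}

#' Differential expression between the compartments
#'
#' Natural-log difference `ln(alpha) - ln(omega)` of per-gene mean
#' expression, with a pseudocount; positive values mean higher expression
#' in the niche.
#'
#' @param s A [summarize_states()] tibble.
#' @param pseudocount Added to both means before taking logs; defaults to
#'   `1e-3 * p_max / delta` of the default parameters.
#' @return A tibble with `gene` and `ln_alpha_minus_ln_omega`.
#' @export
differential_expression <- function(s, pseudocount = 1e-3 * 1000 / 0.2) {
  wide <- tidyr::pivot_wider(dplyr::select(s, "gene", "environment",
                                           "mean_expression"),
                             names_from = "environment",
                             values_from = "mean_expression")
  tibble(gene = wide$gene,
         ln_alpha_minus_ln_omega =
           log(wide$alpha + pseudocount) - log(wide$omega + pseudocount))
}

#' Clone census time series
#'
#' Exact clone bookkeeping from the recorded barcodes: number of surviving
#' clones, per-clone sizes and aged fractions, and the generation
#' distribution summary over time. Clone sizes partition the population at
#' every time.
#'
#' @param traj An `epidrift_trajectory`.
#' @return A list of tibbles `by_clone` (time, clone, size, aged fraction)
#'   and `summary` (time, clone count, total cells, mean generation).
#' @export
clone_census <- function(traj) {
  stopifnot(inherits(traj, "epidrift_trajectory"))
  by_clone <- dplyr::mutate(traj$clones,
                            aged_fraction = .data$n_aged / .data$n)
  summary <- by_clone |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(n_clones = dplyr::n(), n_cells = sum(.data$n),
                     mean_generation =
                       sum(.data$mean_generation * .data$n) / sum(.data$n),
                     aged_fraction = sum(.data$n_aged) / sum(.data$n),
                     .groups = "drop")
  list(by_clone = by_clone, summary = summary)
}

#' Fit the clonal decay exponent
#'
#' Least-squares slope of `log(clone count)` versus `log(time)` over the
#' decay window. Under neutral competition the clone number decays like
#' `1/t`, i.e. a slope of -1.
#'
#' By default the window starts when the clone count first drops below
#' `start_fraction` of its initial value (excluding the early plateau);
#' giving `min_count` instead starts it when the count first falls below
#' an absolute value, which is the appropriate rule at small scale where
#' the power-law regime only begins once surviving clones are much fewer
#' than cells. At such scales the ensemble-average count also saturates
#' at the absorbing monoclonal state (the last clone cannot die), so the
#' `1/t` law applies to the clone count in excess of 1; `survivor_floor`
#' subtracts that floor before fitting. With `n_bins` the (possibly
#' seed-averaged) series is resampled at log-spaced times so that the
#' densely sampled tail does not dominate the fit.
#'
#' @param census A [clone_census()] result (or its `summary` tibble,
#'   or any data frame with `time` and `n_clones`, e.g. averaged over
#'   seeds).
#' @param start_fraction Fraction of the initial clone count that opens
#'   the fit window.
#' @param min_count If given, the window opens when the count first falls
#'   below this absolute value (overrides `start_fraction`).
#' @param survivor_floor Subtract the absorbing floor of one surviving
#'   clone before fitting.
#' @param n_bins If given, number of log-spaced resampling points.
#' @return An object of class `clone_decay_fit` with the slope, its
#'   standard error, the window and the underlying data; `tidy()` and
#'   `glance()` methods are provided.
#' @examples
#' tb <- tibble::tibble(time = 1:100, n_clones = pmax(1, round(100 / 1:100)))
#' fit_clone_decay(list(summary = tb))$slope
#' @export
fit_clone_decay <- function(census, start_fraction = 0.9, min_count = NULL,
                            survivor_floor = FALSE, n_bins = NULL) {
  s <- if (is.data.frame(census)) census else census$summary
  stopifnot(all(c("time", "n_clones") %in% names(s)))
  floor_n <- if (survivor_floor) 1 else 0
  s <- dplyr::filter(s, .data$time > 0, .data$n_clones > floor_n)
  n0 <- s$n_clones[1]
  start <- if (is.null(min_count)) which(s$n_clones < start_fraction * n0)
           else which(s$n_clones < min_count)
  # a series that never decays has the whole recording as its window
  w <- if (length(start)) s[start[1]:nrow(s), ] else s
  # stop at the first absorbed time: a constant tail biases the slope
  mono <- which(w$n_clones <= 1)
  if (length(mono)) w <- w[seq_len(mono[1]), ]
  if (!is.null(n_bins)) {
    xo <- exp(seq(log(min(w$time)), log(max(w$time)), length.out = n_bins))
    w <- tibble(time = xo,
                n_clones = approx(w$time, w$n_clones, xout = xo, rule = 2)$y)
  }
  if (nrow(w) < 3) stop("fewer than 3 time points in the decay window; fit refused",
                        call. = FALSE)
  fit <- lm(log(n_clones - floor_n) ~ log(time), data = w)
  sm <- suppressWarnings(summary(fit))  # exact power laws fit perfectly
  structure(list(slope = unname(coef(fit)[2]),
                 se = sm$coefficients[2, 2],
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 window = range(w$time), n_points = nrow(w), data = w),
            class = "clone_decay_fit")
}

#' @export
print.clone_decay_fit <- function(x, ...) {
  cat(sprintf("<clone_decay_fit> slope %.3f (se %.3f), window %d..%d, %d points\n",
              x$slope, x$se, x$window[1], x$window[2], x$n_points))
  invisible(x)
}

#' First time of sustained phenotype dominance
#'
#' The first recorded time at which the aged fraction exceeds `threshold`
#' and stays above it for at least `sustain` time steps. Returns `Inf`
#' (censored) if dominance is not reached within the trajectory.
#'
#' @param traj An `epidrift_trajectory`.
#' @param threshold Aged-fraction threshold.
#' @param sustain Minimum duration in time steps.
#' @return A single number (possibly `Inf`).
#' @export
time_to_dominance <- function(traj, threshold = 0.95, sustain = 100) {
  s <- clone_census(traj)$summary
  above <- s$aged_fraction > threshold
  if (!any(above)) return(Inf)
  times <- s$time
  for (i in which(above)) {
    horizon <- times >= times[i] & times <= times[i] + sustain
    if (all(above[horizon]) && (max(times) >= times[i] + sustain ||
                                max(times) == times[i])) {
      return(times[i])
    }
  }
  Inf
}

#' Sensitivity sweep over a registered parameter
#'
#' Runs replicate simulations per multiplier of a registered sweepable
#' parameter (currently `k_m`, the histone methyltransferase rate) and
#' summarises each run: time to aged-phenotype dominance, final cell
#' numbers and aged fraction. With `heterogeneous = TRUE` each simulated
#' individual draws its multiplier from `multipliers` instead of keeping
#' one fixed value, which raises the across-individual variance of the
#' final cell number.
#'
#' @param g An `epidrift_genome`.
#' @param parameter Parameter name; only `"k_m"` is registered.
#' @param multipliers Numeric multipliers applied to the default value.
#' @param replicates Replicates ("individuals") per multiplier.
#' @param preset Scenario preset to run (default `"hsc"`).
#' @param steps,n0,record_every Passed to [run_scenario()].
#' @param seed Base seed; replicate `r` of multiplier `m` uses a distinct
#'   derived seed.
#' @param heterogeneous If `TRUE`, ignore the per-multiplier grouping and
#'   draw one multiplier per individual from `multipliers`.
#' @param params Base parameters.
#' @return A tibble with one row per run: `multiplier`, `replicate`,
#'   `seed`, `time_to_dominance` (censored at `steps` when not reached),
#'   `dominance_reached`, `final_cells`, `final_n_alpha`, `aged_fraction`.
#' @export
sensitivity_sweep <- function(g, parameter = "k_m",
                              multipliers = c(0.6, 1, 1.4), replicates = 3,
                              preset = "hsc", steps = 6000, n0 = 20,
                              record_every = 50, seed = 1,
                              heterogeneous = FALSE,
                              params = epidrift_params()) {
  if (!identical(parameter, "k_m")) {
    stop("parameter '", parameter, "' is not registered for sweeping; ",
         "registered: k_m", call. = FALSE)
  }
  grid <- if (heterogeneous) {
    # balanced assignment: individuals span the multiplier range evenly
    set.seed(seed)
    tibble(multiplier = sample(rep_len(sort(multipliers), replicates)),
           replicate = seq_len(replicates))
  } else {
    tidyr::expand_grid(multiplier = multipliers,
                       replicate = seq_len(replicates))
  }
  grid$seed <- seed + 1000L * seq_len(nrow(grid))
  runs <- purrr::pmap(grid, function(multiplier, replicate, seed) {
    p <- params
    p$k_m <- p$k_m * multiplier
    validate_params(p)
    traj <- run_scenario(g, preset = preset, params = p, steps = steps,
                         record_every = record_every, seed = seed, n0 = n0)
    ttd <- time_to_dominance(traj)
    cc <- clone_census(traj)$summary
    last <- cc[nrow(cc), ]
    # window-average the final sizes over the last tenth of the run so a
    # single demographic fluctuation does not dominate the readout
    w0 <- max(cc$time) - ceiling(steps / 10)
    cw <- dplyr::filter(traj$counts, .data$time >= w0)
    per_t <- dplyr::summarise(dplyr::group_by(cw, .data$time),
                              n_tot = sum(.data$n),
                              n_alpha = sum(.data$n[.data$environment == "alpha"]),
                              .groups = "drop")
    tibble(multiplier = multiplier, replicate = replicate, seed = seed,
           time_to_dominance = min(ttd, steps),
           dominance_reached = is.finite(ttd),
           final_cells = mean(per_t$n_tot),
           final_n_alpha = mean(per_t$n_alpha),
           aged_fraction = last$aged_fraction)
  })
  dplyr::bind_rows(runs)
}
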