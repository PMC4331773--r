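#' @importFrom generics tidy glance
#' @importFrom rlang .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a clone-decay fit
#'
#' @param x A `clone_decay_fit`.
#' @param ... Unused.
#' @return One row per coefficient with estimate and standard error.
#' @method tidy clone_decay_fit
#' @export
tidy.clone_decay_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "log(time)"),
         estimate = c(x$intercept, x$slope),
         std.error = c(NA_real_, x$se))
}

#' @rdname tidy.clone_decay_fit
#' @return For `glance()`: a one-row model summary.
#' @method glance clone_decay_fit
#' @export
glance.clone_decay_fit <- function(x, ...) {
  tibble(slope = x$slope, std.error = x$se, r.squared = x$r_squared,
         window_start = x$window[1], window_end = x$window[2],
         n_points = x$n_points)
}

#' Tidy a trajectory
#'
#' Long tibble of the recorded compartment counts (the primary population
#' observable); gene states and clone censuses have their own accessors
#' ([summarize_states()], [clone_census()]).
#'
#' @param x An `epidrift_trajectory`.
#' @param ... Unused.
#' @method tidy epidrift_trajectory
#' @export
tidy.epidrift_trajectory <- function(x, ...) x$counts

#' @rdname tidy.epidrift_trajectory
#' @return For `glance()`: one row with the run's headline outcomes.
#' @method glance epidrift_trajectory
#' @export
glance.epidrift_trajectory <- function(x, ...) {
  cc <- clone_census(x)$summary
  last <- cc[nrow(cc), ]
  tibble(preset = x$config$preset %||% "custom",
         seed = x$config$seed, steps = x$config$steps,
         status = x$config$status,
         final_cells = last$n_cells, final_clones = last$n_clones,
         final_aged_fraction = last$aged_fraction,
         mean_generation = last$mean_generation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
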