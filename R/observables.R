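#' Congression and bi-orientation predicates
#'
#' A cell has congressed when every chromosome lies in the central slab
#' `|x| <= eps a` around the metaphase plate; it is bi-oriented when every
#' chromosome's attachment state is amphitelically STABLE. Both predicates
#' are FALSE for a state without chromosomes.
#'
#' @param state a `spindle_state`.
#' @param eps slab half-width as a fraction of the major semi-axis.
#' @return logical.
#' @export
congression_state <- function(state, eps = 0.1) {
  stopifnot(eps > 0)
  nC <- n_chromosomes(state)
  nC > 0 && all(abs(state$chrom$pos[, 1]) <= eps * state$geom$a)
}

#' @rdname congression_state
#' @export
biorientation_state <- function(state) {
  nC <- n_chromosomes(state)
  nC > 0 && all(stability_codes(state) == 2L)
}

#' First-passage time of a monitored predicate
#'
#' @param times sampled times, s (non-decreasing).
#' @param flags logical vector, TRUE where the predicate held.
#' @param deadline censoring deadline, s (> 0).
#' @return list with `time` (first time the predicate held, or `NA`) and
#'   `censored` (TRUE when it never held before the deadline).
#' @export
first_passage <- function(times, flags, deadline) {
  stopifnot(deadline > 0, length(times) == length(flags))
  hit <- which(flags & times <= deadline)
  if (length(hit)) list(time = times[hit[1]], censored = FALSE)
  else list(time = NA_real_, censored = TRUE)
}

#' Empirical probability curve of an ensemble
#'
#' Cumulative fraction of runs in which the event had occurred by each
#' time. Censored runs never contribute an event but remain in the
#' denominator, so the curve plateaus at the per-run success fraction.
#'
#' @param runs a `spindle_ensemble` (or list of `spindle_run`).
#' @param which `"congression"` or `"biorientation"`.
#' @param times optional evaluation grid; defaults to the sorted event
#'   times.
#' @return data frame (`time`, `probability`), non-decreasing and bounded
#'   in [0, 1], with attribute `n_runs`.
#' @export
probability_curve <- function(runs, which = c("congression", "biorientation"),
                              times = NULL) {
  which <- match.arg(which)
  if (length(runs) == 0) stop("probability_curve needs at least one run")
  field <- if (which == "congression") "congression_time" else
    "biorientation_time"
  ev <- vapply(runs, function(r) r[[field]] %||% NA_real_, numeric(1))
  obs <- sort(ev[!is.na(ev)])
  if (is.null(times)) times <- unique(c(0, obs))
  prob <- vapply(times, function(t) mean(!is.na(ev) & ev <= t), numeric(1))
  structure(data.frame(time = times, probability = prob),
            n_runs = length(runs))
}

#' Median event time of a probability curve
#'
#' @param curve a [probability_curve()] result.
#' @return the smallest time with probability >= 1/2, or `NA` (with
#'   attribute `undefined = TRUE`) when the curve plateaus below one half.
#' @export
median_time <- function(curve) {
  i <- which(curve$probability >= 0.5)
  if (!length(i)) return(structure(NA_real_, undefined = TRUE))
  curve$time[i[1]]
}

#' MT-number window for successful division
#'
#' Scans a MT-number sweep for the range in which both the congression and
#' the bi-orientation probability exceed one half. The sweep must bracket
#' the window: the smallest and largest swept values must both fail,
#' otherwise the window is not resolved and an error is raised.
#'
#' @param sweep a data frame with columns `N_MT` (or first column = swept
#'   value), `p_congression` and `p_biorientation`.
#' @return named numeric vector `c(N_low, N_high)`.
#' @export
sweet_spot_bounds <- function(sweep) {
  v <- sweep[[1]]
  pass <- sweep$p_congression > 0.5 & sweep$p_biorientation > 0.5
  if (!any(pass)) stop("no MT number in the sweep passes both criteria")
  o <- order(v)
  pass <- pass[o]
  v <- v[o]
  if (pass[1] || pass[length(pass)])
    stop("sweep does not bracket the passing window (no failure at an end)")
  c(N_low = min(v[pass]), N_high = max(v[pass]))
}
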