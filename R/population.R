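#' Simulate the MT population in nucleation mode
#'
#' A birth-death simulation of the MT count with no chromosomes: MTs
#' nucleate at rate `k_nucl` per pole, follow unloaded dynamic instability
#' inside the cortex, and are removed when they shrink back to zero
#' length. The count relaxes to the plateau `k_nucl_total / k_out`, where
#' `k_out` is the per-MT collapse rate (the inverse mean MT lifetime).
#'
#' @param params a [spindle_params()] object; `mode`, `n_C` and `p_cat0`
#'   are overridden by the nucleation scenario preset unless
#'   `preset = FALSE`.
#' @param t_max simulated time, s.
#' @param seed integer seed.
#' @param record_dt cadence of the recorded count series, s.
#' @param preset apply [scenario_params()]`("nucleation_mode")` first.
#' @return list with `times`, `counts` (total over both poles),
#'   `k_nucl_total` (both poles), `collapses`, `mean_lifetime` (s, over
#'   completed MT lives) and the echoed parameters.
#' @export
run_population <- function(params = spindle_params(), t_max = 250, seed = 1L,
                           record_dt = 1, preset = TRUE) {
  p <- if (preset) scenario_params("nucleation_mode", params) else params
  stopifnot(p$mode == "nucleation")
  check_timestep(p)
  set.seed(seed)
  state <- init_state(p)
  n_rec <- floor(t_max / record_dt) + 1L
  times <- (seq_len(n_rec) - 1L) * record_dt
  counts <- integer(n_rec)
  k <- 1L
  eps <- 1e-9
  while (state$time < t_max - eps) {
    if (k <= n_rec && state$time >= times[k] - eps) {
      counts[k] <- n_mts(state)
      k <- k + 1L
    }
    state <- sim_step(state, p)
  }
  if (k <= n_rec) counts[k] <- n_mts(state)
  list(times = times, counts = counts,
       k_nucl_total = 2 * p$k_nucl,
       collapses = state$counts$collapses,
       mean_lifetime = if (state$counts$collapses > 0)
         state$counts$lifetime_sum / state$counts$collapses else NA_real_,
       params = p)
}

#' Ensemble-averaged MT population kinetics
#'
#' Averages [run_population()] over independent replicates (seeds
#' `base_seed + 0 ... n - 1`) and pools the per-MT lifetime statistics.
#'
#' @inheritParams run_population
#' @param n number of replicates.
#' @param base_seed seed of the first replicate.
#' @return list with `times`, `mean_counts`, `se` (standard error of the
#'   ensemble mean at each time), `n_runs`, `k_nucl_total`,
#'   `mean_lifetime` and `k_out_direct = 1 / mean_lifetime` (the directly
#'   measured collapse rate).
#' @export
population_ensemble <- function(params = spindle_params(), n = 100,
                                base_seed = 1L, t_max = 250, record_dt = 1) {
  stopifnot(n >= 1)
  runs <- lapply(seq_len(n) - 1L, function(i)
    run_population(params, t_max = t_max, seed = base_seed + i,
                   record_dt = record_dt))
  cnt <- do.call(rbind, lapply(runs, `[[`, "counts"))
  life_n <- sum(vapply(runs, `[[`, numeric(1), "collapses"))
  life_sum <- sum(vapply(runs, function(r) r$collapses * r$mean_lifetime,
                         numeric(1)), na.rm = TRUE)
  ml <- if (life_n > 0) life_sum / life_n else NA_real_
  list(times = runs[[1]]$times,
       mean_counts = colMeans(cnt),
       se = apply(cnt, 2, stats::sd) / sqrt(n),
       n_runs = n,
       k_nucl_total = runs[[1]]$k_nucl_total,
       mean_lifetime = ml,
       k_out_direct = 1 / ml)
}

#' Fit the closed-form population kinetics
#'
#' Least-squares fit of `N(t) = (k_nucl / k_out)(1 - exp(-k_out t))` to a
#' mean MT-count series. With `k_nucl` supplied the fit has the single
#' free parameter `k_out` (profiled exactly); with `k_nucl = NULL` both
#' parameters are free (for each trial `k_out` the optimal `k_nucl` is the
#' closed-form linear solution, so the search is one-dimensional and needs
#' no starting guess).
#'
#' @param times sample times, s (at least 10, spanning the transient).
#' @param counts mean MT counts at `times`.
#' @param k_nucl known total nucleation rate feeding the population
#'   (1/s), or `NULL` to fit it.
#' @param interval search interval for `k_out`, 1/s.
#' @return list of class `kout_fit`: `k_nucl_hat`, `k_out_hat`, `residual`
#'   (root-mean-square), and `fitted`.
#' @export
#' @examples
#' t <- 0:200
#' y <- expected_mt_count(18, 0.09, t)
#' fit_kout(t, y, k_nucl = 18)$k_out_hat
fit_kout <- function(times, counts, k_nucl = NULL,
                     interval = c(1e-4, 10)) {
  stopifnot(length(times) == length(counts), length(times) >= 10,
            all(diff(times) > 0))
  shape <- function(k) (1 - exp(-k * times)) / k
  sse <- function(k) {
    gkt <- shape(k)
    amp <- if (is.null(k_nucl)) sum(counts * gkt) / sum(gkt^2) else k_nucl
    sum((counts - amp * gkt)^2)
  }
  opt <- stats::optimize(sse, interval = interval, tol = 1e-10)
  k_out <- opt$minimum
  if (min(abs(k_out - interval)) < 1e-6)
    stop("fit_kout did not converge: k_out estimate stuck at the search ",
         "interval boundary (", format(k_out), "); counts may not span ",
         "the transient")
  gkt <- shape(k_out)
  amp <- if (is.null(k_nucl)) sum(counts * gkt) / sum(gkt^2) else k_nucl
  fitted <- amp * gkt
  structure(list(k_nucl_hat = amp, k_out_hat = k_out,
                 residual = sqrt(mean((counts - fitted)^2)),
                 fitted = fitted),
            class = "kout_fit")
}

#' @export
print.kout_fit <- function(x, ...) {
  cat(sprintf("<kout_fit> k_nucl = %.4g /s, k_out = %.4g /s (RMS residual %.3g)\n",
              x$k_nucl_hat, x$k_out_hat, x$residual))
  invisible(x)
}

#' Duration of the initial population transient
#'
#' Estimates the steady-state plateau as the mean count over the final
#' `plateau_window` seconds of the series, then reports the earliest time
#' at which the mean count reaches `frac` of that plateau.
#'
#' @param times sample times, s.
#' @param mean_counts ensemble-mean MT counts.
#' @param plateau_window length of the tail used for the plateau, s.
#' @param frac fraction of the plateau defining arrival (default 99%).
#' @return list with `t_transient`, `plateau`.
#' @export
transient_time <- function(times, mean_counts, plateau_window = 100,
                           frac = 0.99) {
  stopifnot(length(times) == length(mean_counts), frac > 0, frac < 1)
  tail_i <- times >= max(times) - plateau_window
  plateau <- mean(mean_counts[tail_i])
  hit <- which(mean_counts >= frac * plateau)
  if (!length(hit)) stop("mean counts never reach the plateau fraction")
  list(t_transient = times[hit[1]], plateau = plateau)
}
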