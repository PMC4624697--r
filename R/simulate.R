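#' Advance the simulation by one time step
#'
#' Each step has three phases, executed in order:
#' \enumerate{
#'   \item \strong{Stochastic events}, all sampled in parallel against the
#'     start-of-step state: end-on detachments (slip/catch bond, using the
#'     start-of-step tip forces and stability classes), catastrophes and
#'     rescues of dynamic MTs (force-dependent rates), and nucleation of
#'     new MTs (nucleation mode). Rates convert to per-step probabilities
#'     as `1 - exp(-rate dt)`.
#'   \item \strong{MT growth/shrinkage}: lengths advance by `+/- v dt`
#'     (velocities slowed exponentially by load for MTs in stable
#'     attachments), are clamped at the cortex, and MTs reaching zero
#'     length collapse: in fixed-N mode they are immediately renucleated
#'     in a fresh random direction from the same pole, in nucleation mode
#'     they are removed. Scaffold MTs never change.
#'   \item \strong{Chromosome update}: the motor program is refreshed
#'     (dynein-to-CENP-E switch at the poles), stale lateral links are
#'     dropped, new end-on and lateral attachments form from the
#'     interaction scan, and positions advance by `F dt / eta` under the
#'     summed motor forces with the hard cortex boundary.
#' }
#'
#' @param state a `spindle_state`.
#' @param params a [spindle_params()] object.
#' @param hook optional `function(phase, state)` called after each phase
#'   (`"events"`, `"mt"`, `"chrom"`), for instrumentation.
#' @return the advanced state.
#' @export
sim_step <- function(state, params, hook = NULL) {
  p <- params
  g <- state$geom
  dt <- p$dt
  m <- state$mt
  N <- length(m$pole)
  nC <- n_chromosomes(state)

  ## ---- phase 1: stochastic events (parallel, start-of-step state) ------
  Ftip <- numeric(N)
  if (N > 0) {
    att <- which(!is.na(m$att_chrom))
    if (length(att)) {
      tips <- g$poles[m$pole[att], , drop = FALSE] +
        m$dir[att, , drop = FALSE] * m$len[att]
      d <- tips - state$chrom$pos[m$att_chrom[att], , drop = FALSE]
      Ftip[att] <- p$k_k * sqrt(rowSums(d * d))
      # detachment: stability class is shared per chromosome, sampled per MT
      stab <- stability_codes(state)
      s_att <- stab[m$att_chrom[att]]
      rate <- ifelse(s_att == 2L,
                     p$p_detach_s0 * exp(-Ftip[att] / p$F_detach_s),
                     p$p_detach_u0 * exp(Ftip[att] / p$F_detach_u))
      det <- att[stats::runif(length(att)) < -expm1(-rate * dt)]
    } else det <- integer(0)

    dyn <- !m$scaffold
    u <- stats::runif(N)
    if (length(att)) {
      p_cat <- -expm1(-p$p_cat0 * exp(-Ftip / p$F_cat) * dt)
      p_res <- -expm1(-p$p_res0 * exp(Ftip / p$F_res) * dt)
    } else {
      # unloaded everywhere: scalar probabilities
      p_cat <- -expm1(-p$p_cat0 * dt)
      p_res <- -expm1(-p$p_res0 * dt)
    }
    sw_c <- dyn & m$growing & u < p_cat
    sw_r <- dyn & !m$growing & u < p_res

    m$growing[sw_c] <- FALSE
    m$growing[sw_r] <- TRUE
    if (length(det)) {
      # a detached MT stays refractory towards that chromosome (for
      # tau_refract, or until its tip leaves the interaction sphere) so
      # detachment is not undone by immediate re-binding of a tip still
      # in range
      m$refract_chrom[det] <- m$att_chrom[det]
      m$refract_until[det] <- state$time + p$tau_refract
      m$att_chrom[det] <- NA_integer_
      m$att_side[det] <- NA_integer_
      state$counts$detachments <- state$counts$detachments + length(det)
    }
    state$counts$catastrophes <- state$counts$catastrophes + sum(sw_c)
    state$counts$rescues <- state$counts$rescues + sum(sw_r)
  }
  if (state$mode == "nucleation" && p$k_nucl > 0) {
    k <- stats::rpois(2, p$k_nucl * dt)
    n_new <- sum(k)
    if (n_new > 0) {
      pole <- rep(1:2, k)
      dir <- sample_directions(n_new)
      origin <- g$poles[pole, , drop = FALSE]
      m$pole <- c(m$pole, pole)
      m$dir <- rbind(m$dir, dir)
      m$len <- c(m$len, numeric(n_new))
      m$growing <- c(m$growing, rep(TRUE, n_new))
      m$scaffold <- c(m$scaffold, rep(FALSE, n_new))
      m$birth <- c(m$birth, rep(state$time, n_new))
      m$maxlen <- c(m$maxlen, max_ray_length_vec(origin, dir, g))
      m$att_chrom <- c(m$att_chrom, rep(NA_integer_, n_new))
      m$att_side <- c(m$att_side, rep(NA_integer_, n_new))
      m$refract_chrom <- c(m$refract_chrom, rep(NA_integer_, n_new))
      m$refract_until <- c(m$refract_until, numeric(n_new))
      Ftip <- c(Ftip, numeric(n_new))
      state$counts$nucleations <- state$counts$nucleations + n_new
    }
  }
  state$mt <- m
  if (!is.null(hook)) hook("events", state)

  ## ---- phase 2: MT growth / shrinkage ---------------------------------
  m <- state$mt
  N <- length(m$pole)
  if (N > 0) {
    i_att <- which(!is.na(m$att_chrom))
    v <- rep(-p$v_s / 60, N)
    v[m$growing] <- p$v_g / 60
    if (length(i_att)) {
      stab2 <- stability_codes(state)
      loaded <- i_att[stab2[m$att_chrom[i_att]] == 2L]
      if (length(loaded))
        v[loaded] <- v[loaded] *
          exp(-Ftip[loaded] / ifelse(m$growing[loaded], p$F_g, p$F_s))
    }
    dlen <- v * dt
    dlen[m$scaffold] <- 0
    m$len <- pmin(m$len + dlen, m$maxlen)
    collapsed <- which(!m$scaffold & m$len <= 0)
    if (length(collapsed)) {
      state$counts$collapses <- state$counts$collapses + length(collapsed)
      state$counts$lifetime_sum <- state$counts$lifetime_sum +
        sum(state$time + dt - m$birth[collapsed])
      m$att_chrom[collapsed] <- NA_integer_
      m$att_side[collapsed] <- NA_integer_
      m$refract_chrom[collapsed] <- NA_integer_
      m$refract_until[collapsed] <- 0
      if (nC > 0) {
        lat <- state$chrom$lat_mt
        lat[lat %in% collapsed] <- NA_integer_
        state$chrom$lat_mt <- lat
      }
      if (state$mode == "fixed_n") {
        # renucleate in place: fresh direction from the same pole
        nd <- sample_directions(length(collapsed))
        m$dir[collapsed, ] <- nd
        m$maxlen[collapsed] <-
          max_ray_length_vec(g$poles[m$pole[collapsed], , drop = FALSE], nd, g)
        m$len[collapsed] <- 0
        m$growing[collapsed] <- TRUE
        m$birth[collapsed] <- state$time + dt
        state$counts$nucleations <- state$counts$nucleations +
          length(collapsed)
      } else {
        keep <- setdiff(seq_len(N), collapsed)
        remap <- integer(N)
        remap[keep] <- seq_along(keep)
        m <- list(pole = m$pole[keep], dir = m$dir[keep, , drop = FALSE],
                  len = m$len[keep], growing = m$growing[keep],
                  scaffold = m$scaffold[keep], birth = m$birth[keep],
                  maxlen = m$maxlen[keep],
                  att_chrom = m$att_chrom[keep], att_side = m$att_side[keep],
                  refract_chrom = m$refract_chrom[keep],
                  refract_until = m$refract_until[keep])
        if (nC > 0) {
          lat <- state$chrom$lat_mt
          live <- !is.na(lat)
          lat[live] <- remap[lat[live]]
          state$chrom$lat_mt <- lat
        }
      }
    }
  }
  state$mt <- m
  if (!is.null(hook)) hook("mt", state)

  ## ---- phase 3: chromosome update -------------------------------------
  if (nC > 0) {
    state <- drop_stale_lateral(state, p)
    state <- clear_expired_refractory(state, p)
    m <- state$mt
    origin <- g$poles[m$pole, , drop = FALSE]
    occ <- slot_counts(state)
    motor <- state$chrom$motor
    want_lat <- is.na(state$chrom$lat_mt) & rowSums(occ) == 0L
    # end-on attachments do not form in the pole regions, where polar
    # kinase activity destabilizes them; dynein-covered kinetochores never
    # form them
    want_con <- motor == 2L & (occ[, 1] < p$N_k | occ[, 2] < p$N_k) &
      !in_pole_region(state, p)
    # pole-region chromosomes grab a long-lived track anywhere in the
    # aster: dynein-held ones switch motor, trackless CENP-E ones re-latch
    probe <- pole_region_chromosomes(state, p, occ)
    elig <- cenpe_eligible(state, p)
    npole <- nearest_pole(state)
    scan <- scan_chromosomes_cpp(origin, m$dir, m$len, m$pole, elig,
                                 state$chrom$pos, motor, npole,
                                 want_lat, want_con,
                                 probe, p$delta_pole, p$r_C, p$r_k, p$F_PEF,
                                 if (p$arm_geometry == "disk") 0L else 1L)
    sw <- which(probe & scan$cenpe_track > 0L)
    for (i in sw) {
      if (state$chrom$motor[i] == 1L)
        state <- switch_to_cenpe(state, i, scan$cenpe_track[i])
      else
        state$chrom$lat_mt[i] <- scan$cenpe_track[i]
      state <- snap_to_track(state, i, scan$cenpe_track[i])
    }
    want_lat <- want_lat & !probe
    # end-on formation: fill free slots in (chromosome, MT-index) order
    gained <- rep(FALSE, nC)
    nc_new <- length(scan$contact_chrom)
    if (nc_new > 0) {
      for (k in seq_len(nc_new)) {
        j <- scan$contact_mt[k]
        if (!is.na(m$att_chrom[j])) next
        i <- scan$contact_chrom[k]
        if (!is.na(m$refract_chrom[j]) && m$refract_chrom[j] == i) next
        s <- scan$contact_side[k]
        if (occ[i, s] >= p$N_k) next
        m$att_chrom[j] <- i
        m$att_side[j] <- s
        occ[i, s] <- occ[i, s] + 1L
        gained[i] <- TRUE
      }
      if (any(gained)) {
        state$chrom$lat_mt[gained] <- NA_integer_
        state$counts$attachments <- state$counts$attachments + sum(gained)
      }
      state$mt <- m
    }
    # lateral formation for chromosomes that stayed unattached
    take <- which(want_lat & !gained & is.na(state$chrom$lat_mt) &
                    scan$lat_mt > 0L)
    if (length(take)) state$chrom$lat_mt[take] <- scan$lat_mt[take]

    f <- net_force(state, p, scan = scan)
    m <- state$mt
    occ_now <- slot_counts(state)
    n_grip <- rowSums(occ_now)
    pos <- state$chrom$pos
    free <- n_grip == 0L
    if (any(free))
      pos[free, ] <- pos[free, , drop = FALSE] +
        f$f_total[free, , drop = FALSE] * (dt / p$eta)
    if (any(!free)) {
      # end-on coupled chromosomes: the kinetochore spring (k_k) is stiff
      # and equilibrates much faster than the time step, so the position
      # relaxes to the force balance of the attached tips and the
      # remaining motor forces (quasi-static stiff-spring limit)
      att2 <- which(!is.na(m$att_chrom))
      tips2 <- g$poles[m$pole[att2], , drop = FALSE] +
        m$dir[att2, , drop = FALSE] * m$len[att2]
      cent <- rowsum(tips2, group = m$att_chrom[att2])
      ids <- as.integer(rownames(cent))
      other <- f$f_pef[ids, , drop = FALSE] + f$f_lateral[ids, , drop = FALSE]
      pos[ids, ] <- cent / n_grip[ids] + other / (p$k_k * n_grip[ids])
    }
    state$chrom$pos <- project_into_cortex(pos, g)
  }
  state$time <- state$time + dt
  if (!is.null(hook)) hook("chrom", state)
  state
}

# refractory (MT, chromosome) pairs expire once the tip has moved out of
# the kinetochore interaction sphere or the refractory period has passed
clear_expired_refractory <- function(state, params) {
  j <- which(!is.na(state$mt$refract_chrom))
  if (!length(j)) return(state)
  tips <- state$geom$poles[state$mt$pole[j], , drop = FALSE] +
    state$mt$dir[j, , drop = FALSE] * state$mt$len[j]
  d2 <- rowSums((tips -
    state$chrom$pos[state$mt$refract_chrom[j], , drop = FALSE])^2)
  gone <- d2 > params$r_k^2 | state$time >= state$mt$refract_until[j]
  if (any(gone)) state$mt$refract_chrom[j[gone]] <- NA_integer_
  state
}

# drop lateral links whose track no longer spans the chromosome: the
# chromosome has slid past the plus end (or behind the pole), the track
# was lost, the chromosome has strayed beyond twice the interaction
# radius, or the chromosome has crossed the mid-plane so the track's pole
# is no longer its nearest (a CENP-E chromosome then picks up a track of
# the opposite aster and is driven back towards the plate)
drop_stale_lateral <- function(state, params) {
  i <- which(!is.na(state$chrom$lat_mt))
  if (!length(i)) return(state)
  j <- state$chrom$lat_mt[i]
  g <- state$geom
  origin <- g$poles[state$mt$pole[j], , drop = FALSE]
  u <- state$mt$dir[j, , drop = FALSE]
  rel <- state$chrom$pos[i, , drop = FALSE] - origin
  t_proj <- rowSums(rel * u)
  perp2 <- rowSums(rel * rel) - t_proj^2
  stale <- t_proj < 0 | t_proj > state$mt$len[j] |
    perp2 > (2 * params$r_k)^2 |
    state$mt$pole[j] != nearest_pole(state)[i]
  if (any(stale)) state$chrom$lat_mt[i[stale]] <- NA_integer_
  state
}

# is each chromosome within delta_pole of either pole?
in_pole_region <- function(state, params) {
  pos <- state$chrom$pos
  half_a <- state$geom$a / 2
  yz2 <- pos[, 2]^2 + pos[, 3]^2
  d1 <- sqrt((pos[, 1] + half_a)^2 + yz2)
  d2 <- sqrt((pos[, 1] - half_a)^2 + yz2)
  pmin(d1, d2) <= params$delta_pole
}

# chromosomes inside the pole region (within delta_pole of either pole)
# that need a long-lived track: dynein-driven ones (awaiting the motor
# replacement) and trackless, unattached CENP-E ones
pole_region_chromosomes <- function(state, params, occ) {
  near <- in_pole_region(state, params)
  needs <- state$chrom$motor == 1L |
    (is.na(state$chrom$lat_mt) & rowSums(occ) == 0L)
  if (!params$cenpe_present) near[] <- FALSE
  near & needs
}

# reel the kinetochore onto the latched fiber (nearest point of the track)
snap_to_track <- function(state, i, j) {
  origin <- state$geom$poles[state$mt$pole[j], ]
  u <- state$mt$dir[j, ]
  t_proj <- sum((state$chrom$pos[i, ] - origin) * u)
  t_proj <- min(max(t_proj, 0), state$mt$len[j])
  state$chrom$pos[i, ] <- origin + t_proj * u
  state
}

# index (1 or 2) of the pole nearest to each chromosome
nearest_pole <- function(state) {
  pos <- state$chrom$pos
  half_a <- state$geom$a / 2
  yz2 <- pos[, 2]^2 + pos[, 3]^2
  d1 <- (pos[, 1] + half_a)^2 + yz2
  d2 <- (pos[, 1] - half_a)^2 + yz2
  ifelse(d1 <= d2, 1L, 2L)
}

#' Run a single simulation
#'
#' Initializes a state for the given scenario and integrates the
#' three-phase step until congression and bi-orientation have each either
#' occurred or passed their deadline (or `t_max`, if given, is reached).
#' First-passage times are monitored every step: congression is the first
#' instant all chromosomes lie in the central slab `|x| <= eps a`,
#' bi-orientation the first instant every chromosome is amphitelically
#' stable.
#'
#' @param params a [spindle_params()] object.
#' @param scenario scenario name passed to [scenario_params()], or `NULL`
#'   to use `params` as given.
#' @param seed integer seed; a run is fully reproducible from
#'   `(params, scenario, seed)`.
#' @param t_max optional hard stop, s (overrides both deadlines).
#' @param record_dt optional cadence, s, at which chromosome positions and
#'   the MT count are snapshotted into the returned trajectory.
#' @param return_state logical; keep the final state in the result.
#' @param hook optional phase hook passed to [sim_step()].
#' @return a list of class `spindle_run`: seed, scenario, event times with
#'   censoring flags, final chromosome table, event counts, optional
#'   trajectory (`t`, chromosome id, position, motor, end-on slot counts)
#'   and MT-count series, the echoed parameters, and optionally the final
#'   state.
#' @export
run_single <- function(params = spindle_params(), scenario = "wt_scattered",
                       seed = 1L, t_max = NULL, record_dt = NULL,
                       return_state = FALSE, hook = NULL) {
  p <- if (is.null(scenario)) params else scenario_params(scenario, params)
  check_timestep(p)
  seed <- as.integer(seed)
  set.seed(seed)
  state <- init_state(p)
  nC <- n_chromosomes(state)
  dl_c <- if (is.null(t_max)) p$deadline_congression else t_max
  dl_b <- if (is.null(t_max)) p$deadline_biorientation else t_max
  t_stop <- max(dl_c, dl_b)
  t_cong <- NA_real_
  t_bio <- NA_real_
  snap <- list()
  counts_t <- numeric(0)
  counts_n <- integer(0)
  next_rec <- 0
  eps <- 1e-9

  repeat {
    if (!is.null(record_dt) && state$time >= next_rec - eps) {
      if (nC > 0) snap[[length(snap) + 1L]] <- snapshot_chromosomes(state)
      counts_t <- c(counts_t, state$time)
      counts_n <- c(counts_n, n_mts(state))
      next_rec <- next_rec + record_dt
    }
    done_c <- nC == 0 || !is.na(t_cong) || state$time >= dl_c - eps
    done_b <- nC == 0 || !is.na(t_bio) || state$time >= dl_b - eps
    if ((done_c && done_b && nC > 0) || state$time >= t_stop - eps) break
    state <- sim_step(state, p, hook)
    if (nC > 0) {
      if (is.na(t_cong) && state$time <= dl_c + eps &&
          congression_state(state, p$eps_congression))
        t_cong <- state$time
      if (is.na(t_bio) && state$time <= dl_b + eps &&
          biorientation_state(state))
        t_bio <- state$time
    }
  }

  res <- list(
    seed = seed,
    scenario = if (is.null(scenario)) attr(params, "scenario") %||% "custom"
               else scenario,
    congression_time = t_cong,
    congression_censored = is.na(t_cong),
    biorientation_time = t_bio,
    biorientation_censored = is.na(t_bio),
    t_final = state$time,
    chromosomes = if (nC > 0) snapshot_chromosomes(state) else NULL,
    counts = state$counts,
    mt_count_series = if (length(counts_t))
      data.frame(t = counts_t, n_mt = counts_n) else NULL,
    trajectory = if (length(snap)) do.call(rbind, snap) else NULL,
    params = p
  )
  if (return_state) res$state <- state
  structure(res, class = "spindle_run")
}

snapshot_chromosomes <- function(state) {
  nC <- n_chromosomes(state)
  occ <- slot_counts(state)
  g <- state$geom
  d1 <- sqrt(rowSums(sweep(state$chrom$pos, 2, g$poles[1, ])^2))
  d2 <- sqrt(rowSums(sweep(state$chrom$pos, 2, g$poles[2, ])^2))
  data.frame(
    t = state$time,
    chromosome = seq_len(nC),
    x = state$chrom$pos[, 1], y = state$chrom$pos[, 2],
    z = state$chrom$pos[, 3],
    motor = c("DYNEIN", "CENPE")[state$chrom$motor],
    n_end_on_left = occ[, 1], n_end_on_right = occ[, 2],
    stability = classify_stability(state),
    pole_distance = pmin(d1, d2)
  )
}

#' @export
print.spindle_run <- function(x, ...) {
  fmt <- function(t, cens) if (cens) "censored" else sprintf("%.1f s", t)
  cat(sprintf("<spindle_run> scenario %s, seed %d\n", x$scenario, x$seed))
  cat(sprintf("  congression:    %s\n",
              fmt(x$congression_time, x$congression_censored)))
  cat(sprintf("  bi-orientation: %s\n",
              fmt(x$biorientation_time, x$biorientation_censored)))
  invisible(x)
}

#' Run an ensemble of independent simulations
#'
#' Runs `n` independent replicates with seeds `base_seed + 0 ... n - 1`.
#' Results do not depend on execution order.
#'
#' @inheritParams run_single
#' @param n number of runs (>= 1).
#' @param base_seed seed of the first run.
#' @param ... further arguments passed to [run_single()].
#' @return list of `spindle_run` objects, class `spindle_ensemble`; coerce
#'   with `as.data.frame()` to one row per run.
#' @export
run_ensemble <- function(params = spindle_params(), scenario = "wt_scattered",
                         n = 10, base_seed = 1L, ...) {
  stopifnot(n >= 1)
  runs <- lapply(seq_len(n) - 1L, function(i)
    run_single(params, scenario, seed = base_seed + i, ...))
  structure(runs, class = "spindle_ensemble")
}

#' @export
as.data.frame.spindle_ensemble <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) data.frame(
    seed = r$seed, scenario = r$scenario,
    congression_time = r$congression_time,
    congression_censored = r$congression_censored,
    biorientation_time = r$biorientation_time,
    biorientation_censored = r$biorientation_censored,
    t_final = r$t_final
  )))
}

#' Parameter sweep
#'
#' Runs an ensemble for every value of one parameter and tabulates the
#' success probabilities and median event times.
#'
#' @inheritParams run_ensemble
#' @param parameter name of the swept parameter (e.g. `"N_MT"`,
#'   `"p_cat0"`).
#' @param values numeric vector of parameter values.
#' @param n runs per value.
#' @return data frame with one row per value: the parameter value, run
#'   count, congression/bi-orientation success probabilities (censored runs
#'   count in the denominator) and median times (NA when the probability
#'   never reaches one half). The per-run results are attached as
#'   attribute `"runs"`.
#' @export
run_sweep <- function(params = spindle_params(), scenario = "wt_scattered",
                      parameter, values, n = 10, base_seed = 1L, ...) {
  stopifnot(parameter %in% names(params), length(values) >= 1)
  all_runs <- list()
  rows <- lapply(seq_along(values), function(k) {
    pk <- unclass(params)
    pk[[parameter]] <- values[k]
    pk <- validate_params(pk)
    ens <- run_ensemble(pk, scenario, n = n,
                        base_seed = base_seed + (k - 1L) * n, ...)
    all_runs[[k]] <<- ens
    cong <- probability_curve(ens, "congression")
    bio <- probability_curve(ens, "biorientation")
    data.frame(
      value = values[k], n = n,
      p_congression = max(c(0, cong$probability)),
      p_biorientation = max(c(0, bio$probability)),
      t_half_congression = median_time(cong),
      t_half_biorientation = median_time(bio)
    )
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- parameter
  attr(out, "runs") <- all_runs
  out
}
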