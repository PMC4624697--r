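#' Create an empty simulation state
#'
#' A state holds the cell geometry, the simulation clock, the MT population
#' (parallel vectors: pole index, unit direction, length, phase, scaffold
#' flag, birth time, cortex clamp, end-on link) and the chromosomes
#' (positions, active motor, lateral link). Fixture states for tests are
#' built by adding MTs and chromosomes explicitly with [add_microtubule()]
#' and [add_chromosome()].
#'
#' @param params a [spindle_params()] object.
#' @return a list of class `spindle_state`.
#' @export
new_state <- function(params) {
  g <- cell_geometry(params$a)
  structure(list(
    time = 0,
    geom = g,
    mode = params$mode,
    mt = list(
      pole = integer(0),
      dir = matrix(numeric(0), 0, 3),
      len = numeric(0),
      growing = logical(0),
      scaffold = logical(0),
      birth = numeric(0),
      maxlen = numeric(0),
      att_chrom = integer(0),
      att_side = integer(0),
      refract_chrom = integer(0),
      refract_until = numeric(0)
    ),
    chrom = list(
      pos = matrix(numeric(0), 0, 3),
      motor = integer(0),   # 1 = DYNEIN, 2 = CENPE
      lat_mt = integer(0)
    ),
    counts = list(
      catastrophes = 0L, rescues = 0L, collapses = 0L, nucleations = 0L,
      attachments = 0L, detachments = 0L, motor_switches = 0L,
      lifetime_sum = 0
    )
  ), class = "spindle_state")
}

#' Add a microtubule to a state
#'
#' @param state a [new_state()] object.
#' @param pole 1 (-x pole) or 2 (+x pole).
#' @param dir direction, length 3 (normalized internally).
#' @param len length, um (clamped to the cortex).
#' @param growing logical phase flag.
#' @param scaffold logical; scaffold MTs never change.
#' @param birth birth time, s (`-Inf` marks infinite age).
#' @return the updated state.
#' @export
add_microtubule <- function(state, pole, dir, len = 0, growing = TRUE,
                            scaffold = FALSE, birth = state$time) {
  dir <- dir / sqrt(sum(dir^2))
  g <- state$geom
  mx <- max_ray_length(g$poles[pole, ], dir, g)
  m <- state$mt
  m$pole <- c(m$pole, as.integer(pole))
  m$dir <- rbind(m$dir, dir)
  m$len <- c(m$len, min(len, mx))
  m$growing <- c(m$growing, growing)
  m$scaffold <- c(m$scaffold, scaffold)
  m$birth <- c(m$birth, birth)
  m$maxlen <- c(m$maxlen, mx)
  m$att_chrom <- c(m$att_chrom, NA_integer_)
  m$att_side <- c(m$att_side, NA_integer_)
  m$refract_chrom <- c(m$refract_chrom, NA_integer_)
  m$refract_until <- c(m$refract_until, 0)
  state$mt <- m
  state
}

#' Add a chromosome to a state
#'
#' @param state a [new_state()] object.
#' @param pos position, length 3 (must be inside the cortex).
#' @param motor `"DYNEIN"` or `"CENPE"`.
#' @return the updated state.
#' @export
add_chromosome <- function(state, pos, motor = "DYNEIN") {
  stopifnot(inside_cortex(pos, state$geom))
  motor <- match(match.arg(motor, c("DYNEIN", "CENPE")), c("DYNEIN", "CENPE"))
  ch <- state$chrom
  ch$pos <- rbind(ch$pos, pos)
  ch$motor <- c(ch$motor, motor)
  ch$lat_mt <- c(ch$lat_mt, NA_integer_)
  state$chrom <- ch
  state
}

#' Number of microtubules / chromosomes in a state
#'
#' @param state a `spindle_state`.
#' @return integer count.
#' @export
n_mts <- function(state) length(state$mt$pole)

#' @rdname n_mts
#' @export
n_chromosomes <- function(state) nrow(state$chrom$pos)

mt_origins <- function(state) {
  state$geom$poles[state$mt$pole, , drop = FALSE]
}

mt_tips <- function(state) {
  mt_origins(state) + state$mt$dir * state$mt$len
}

#' Mark the stable interpolar scaffold
#'
#' A fraction `p_sc` of the MTs (split evenly between the poles) is turned
#' into a permanent scaffold: directions are resampled so that each ray
#' passes within `0.45 a` of the cell centre (the interpolar region),
#' lengths span to the cortex, the phase never switches, and the age is
#' infinite so scaffold MTs are always eligible CENP-E tracks.
#'
#' @param state a state whose MT population is already built (fixed-N mode).
#' @param params a [spindle_params()] object.
#' @return the updated state.
#' @export
init_scaffold <- function(state, params) {
  stopifnot(state$mode == "fixed_n")
  N <- n_mts(state)
  n_sc <- round(params$p_sc * N)
  if (n_sc == 0) return(state)
  idx <- seq_len(n_sc)   # first MTs become the scaffold; half per pole below
  g <- state$geom
  m <- state$mt
  m$pole[idx] <- rep_len(c(1L, 2L), n_sc)
  for (i in idx) {
    d <- scaffold_direction(g$poles[m$pole[i], ], g)
    m$dir[i, ] <- d
    m$maxlen[i] <- max_ray_length(g$poles[m$pole[i], ], d, g)
    m$len[i] <- m$maxlen[i]
  }
  m$scaffold[idx] <- TRUE
  m$growing[idx] <- TRUE
  m$birth[idx] <- -Inf
  state$mt <- m
  state
}

# rejection-sample a direction whose forward ray passes within the
# interpolar shell (0.45 a of the origin)
scaffold_direction <- function(pole, g) {
  repeat {
    d <- as.numeric(sample_directions(1))
    t <- -sum(pole * d)
    if (t <= 0) next
    miss <- sqrt(sum((pole + t * d)^2))
    if (miss <= g$r_cenpe_shell) return(d)
  }
}

#' Initialize a full simulation state
#'
#' Builds poles and cortex, the MT population (fixed-N mode: `N_MT` MTs in
#' uniformly random directions with the scaffold fraction marked; nucleation
#' mode: empty population), and `n_C` chromosomes released uniformly in the
#' nuclear sphere with the motor program set by the CENP-E shell (CENP-E
#' active inside `0.45 a`, dynein outside). Dynamic MTs are given random
#' initial lengths (exponential with the mean unloaded growth excursion,
#' clamped to the cortex), a random phase and exponential random ages, so
#' the spindle starts formed rather than empty.
#'
#' @param params a [spindle_params()] object.
#' @return a `spindle_state`. Uses the session RNG; seed before calling.
#' @export
init_state <- function(params) {
  state <- new_state(params)
  g <- state$geom
  if (params$mode == "fixed_n") {
    N <- as.integer(params$N_MT)
    pole <- rep_len(c(1L, 2L), N)
    dir <- sample_directions(N)
    origin <- g$poles[pole, , drop = FALSE]
    maxlen <- max_ray_length_vec(origin, dir, g)
    lbar <- (params$v_g / 60) / max(params$p_cat0, 1e-6)
    len <- pmin(stats::rexp(N, 1 / lbar), maxlen * 0.999)
    state$mt <- list(
      pole = pole, dir = dir, len = len,
      growing = stats::runif(N) < 0.5,
      scaffold = rep(FALSE, N),
      birth = -stats::rexp(N, params$p_cat0),
      maxlen = maxlen,
      att_chrom = rep(NA_integer_, N),
      att_side = rep(NA_integer_, N),
      refract_chrom = rep(NA_integer_, N),
      refract_until = numeric(N)
    )
    state <- init_scaffold(state, params)
  }
  if (params$n_C > 0) {
    pos <- sample_initial_chromosomes(params$n_C, g,
                                      interpolar = params$interpolar_start)
    r <- sqrt(rowSums(pos^2))
    state$chrom <- list(
      pos = pos,
      motor = ifelse(r < g$r_cenpe_shell, 2L, 1L),
      lat_mt = rep(NA_integer_, params$n_C)
    )
  }
  state
}

#' @export
print.spindle_state <- function(x, ...) {
  cat(sprintf("<spindle_state> t = %.1f s, %d MTs (%d scaffold), %d chromosomes\n",
              x$time, n_mts(x), sum(x$mt$scaffold), n_chromosomes(x)))
  if (n_chromosomes(x) > 0) {
    s <- classify_stability(x)
    cat(sprintf("  motors: %d dynein / %d CENP-E; stability: %d none / %d unstable / %d stable\n",
                sum(x$chrom$motor == 1L), sum(x$chrom$motor == 2L),
                sum(s == "NONE"), sum(s == "UNSTABLE"), sum(s == "STABLE")))
  }
  invisible(x)
}
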