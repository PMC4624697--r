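# Shared fixtures and independent brute-force oracles.

# reduced-scale desk configuration used by the simulation-level tests:
# half-size cell with MT/tip densities comparable to the full-scale
# spindle; the congression slab is 2.25 um, between the plate thickness
# (~2 um, set by the absolute kinetochore geometry) and the pole regions
# (|x| > 3.2 um)
desk_params <- function(...) {
  spindle_params(a = 7.5, N_MT = 2000, n_C = 10,
                 deadline_congression = 1500,
                 deadline_biorientation = 4000,
                 eps_congression = 0.3, ...)
}

# --- scalar oracles ---------------------------------------------------------

# ellipsoid containment straight from the definition
oracle_inside <- function(p, g) {
  (p[1] / g$a)^2 + (p[2] / g$b)^2 + (p[3] / g$c)^2 < 1
}

# ray-boundary distance by root bracketing on the containment function
oracle_ray_length <- function(origin, dir, g, t_hi = 1e3) {
  f <- function(t) {
    q <- origin + t * dir
    (q[1] / g$a)^2 + (q[2] / g$b)^2 + (q[3] / g$c)^2 - 1
  }
  stats::uniroot(f, c(0, t_hi), tol = 1e-12)$root
}

# point-to-segment distance by dense sampling along the segment
oracle_segment_distance <- function(p, a, b, n = 20001) {
  t <- seq(0, 1, length.out = n)
  seg <- outer(t, b - a) + rep(a, each = n)
  sqrt(min(rowSums((seg - rep(p, each = n))^2)))
}

# arm-disk crossing by scanning the segment for a sign change through the
# plane and checking the in-plane distance at the crossing
oracle_disk_crossing <- function(origin, dir, len, centre, r_C) {
  if (dir[1] == 0) return(FALSE)
  t <- (centre[1] - origin[1]) / dir[1]
  if (t < 0 || t > len) return(FALSE)
  q <- origin + t * dir
  sqrt((q[2] - centre[2])^2 + (q[3] - centre[3])^2) <= r_C
}

# a tiny deterministic spindle: two poles, a few hand-placed MTs and
# chromosomes, for bookkeeping tests
tiny_state <- function(params = spindle_params(N_MT = 4, n_C = 1, a = 15)) {
  st <- new_state(params)
  st <- add_microtubule(st, pole = 1, dir = c(1, 0, 0), len = 7.0)
  st <- add_microtubule(st, pole = 2, dir = c(-1, 0, 0), len = 7.0)
  st <- add_microtubule(st, pole = 1, dir = c(1, 0.05, 0), len = 5)
  st <- add_microtubule(st, pole = 2, dir = c(-1, 0, 0.05), len = 5)
  st <- add_chromosome(st, c(0, 0, 0), motor = "CENPE")
  st
}

# random interior point of the cortex
random_interior_point <- function(g) {
  repeat {
    p <- c(stats::runif(1, -g$a, g$a), stats::runif(1, -g$b, g$b),
           stats::runif(1, -g$c, g$c))
    if (oracle_inside(p, g) && sum((p / c(g$a, g$b, g$c))^2) < 0.98)
      return(p)
  }
}
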