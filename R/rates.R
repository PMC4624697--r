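#' Force-dependent dynamic-instability rates
#'
#' Tension transmitted through an end-on kinetochore coupling suppresses
#' catastrophes and promotes rescues: `p_cat = p_cat0 exp(-F / F_cat)` and
#' `p_res = p_res0 exp(+F / F_res)`. `F` is the magnitude of the spring
#' force at the MT tip (zero for unattached MTs); compression is not
#' modelled.
#'
#' @param F tip force, pN (vectorized, must be >= 0).
#' @param p a [spindle_params()] object.
#' @return rate(s) in 1/s.
#' @export
#' @examples
#' p <- spindle_params()
#' catastrophe_rate(0, p)    # unloaded: 0.058 /s
#' rescue_rate(2.3, p)       # one sensitivity: 0.045 * exp(1)
catastrophe_rate <- function(F, p) {
  stopifnot(all(F >= 0))
  p$p_cat0 * exp(-F / p$F_cat)
}

#' @rdname catastrophe_rate
#' @export
rescue_rate <- function(F, p) {
  stopifnot(all(F >= 0))
  p$p_res0 * exp(F / p$F_res)
}

#' Loaded polymerization velocity
#'
#' The growth or shrinkage speed of an MT held in a stable end-on
#' attachment is slowed exponentially by the load at its tip:
#' `v(F) = v0 exp(-F / F_sens)`.
#'
#' @param v0 unloaded velocity (any unit; returned in the same unit).
#' @param F tip force, pN (>= 0, vectorized).
#' @param F_sens force sensitivity, pN.
#' @return the loaded velocity.
#' @export
loaded_velocity <- function(v0, F, F_sens) {
  stopifnot(v0 > 0, all(F >= 0), F_sens > 0)
  v0 * exp(-F / F_sens)
}

#' Detachment kinetics of end-on attachments
#'
#' Unstable attachments (monotelic or syntelic) are slip bonds: the
#' detachment rate grows with load, `p_detach_u0 exp(+F / F_detach_u)`.
#' Stable (amphitelic) attachments are catch bonds: load suppresses
#' detachment, `p_detach_s0 exp(-F / F_detach_s)`.
#'
#' @param F tip force, pN (vectorized).
#' @param stability `"UNSTABLE"` or `"STABLE"` (`"NONE"` is an error).
#' @param p a [spindle_params()] object.
#' @return `detachment_rate`: rate in 1/s. `detachment_probability`: the
#'   per-step probability `1 - exp(-rate * dt)`.
#' @export
detachment_rate <- function(F, stability, p) {
  stopifnot(all(F >= 0))
  if (!stability %in% c("UNSTABLE", "STABLE"))
    stop("stability must be 'UNSTABLE' or 'STABLE'")
  if (stability == "UNSTABLE") {
    p$p_detach_u0 * exp(F / p$F_detach_u)
  } else {
    p$p_detach_s0 * exp(-F / p$F_detach_s)
  }
}

#' @rdname detachment_rate
#' @param dt time step, s.
#' @export
detachment_probability <- function(F, stability, p, dt) {
  rate_to_prob(detachment_rate(F, stability, p), dt)
}

# exact probability that an exponential clock with the given rate fires
# within one step; correct even when rate * dt is not small
rate_to_prob <- function(rate, dt) -expm1(-rate * dt)

#' Harmonic end-on coupling force
#'
#' An end-on attached MT is coupled to its kinetochore by a zero-rest-length
#' spring: the force on the chromosome is `k_k (tip - r)` and the tip of
#' the MT carries a load of equal magnitude.
#'
#' @param tip MT tip position, length 3.
#' @param centre chromosome position, length 3.
#' @param p a [spindle_params()] object.
#' @return list with `force` (3-vector on the chromosome, pN) and
#'   `tip_force` (scalar load on the MT, pN).
#' @export
end_on_spring_force <- function(tip, centre, p) {
  f <- p$k_k * (tip - centre)
  list(force = f, tip_force = sqrt(sum(f^2)))
}

#' Closed-form MT population kinetics
#'
#' Mean MT count of the nucleation/collapse birth-death process:
#' `N(t) = (k_nucl / k_out) (1 - exp(-k_out t))`, rising from zero to the
#' plateau `k_nucl / k_out` with relaxation rate `k_out`.
#'
#' @param k_nucl nucleation rate feeding the population, 1/s.
#' @param k_out per-MT collapse rate, 1/s.
#' @param t time(s), s.
#' @return expected count(s).
#' @export
#' @examples
#' expected_mt_count(9, 0.09, Inf)  # plateau 100
expected_mt_count <- function(k_nucl, k_out, t) {
  stopifnot(k_out > 0, all(t >= 0))
  k_nucl / k_out * (1 - exp(-k_out * t))
}
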