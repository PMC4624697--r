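#' Forces on the chromosomes
#'
#' Assembles, for every chromosome, the three motor force contributions of
#' the overdamped equation of motion:
#' \itemize{
#'   \item polar ejection force: `F_PEF` along the (plus-end) direction of
#'     every MT crossing the arm cross-section within `r_C` of the centre;
#'   \item lateral motor force along the linked track: `+F_CENPE u` towards
#'     the plus end when CENP-E is active, `-F_DYN u` towards the pole for
#'     dynein (`u` the unit direction of the linked MT);
#'   \item end-on spring forces `k_k (tip - r)` summed over attached MTs.
#' }
#'
#' @param state a `spindle_state`.
#' @param params a [spindle_params()] object.
#' @param scan optional precomputed interaction scan (internal use).
#' @return list of n_C x 3 matrices `f_pef`, `f_lateral`, `f_spring` and
#'   their exact sum `f_total` (pN).
#' @export
net_force <- function(state, params, scan = NULL) {
  nC <- n_chromosomes(state)
  zero <- matrix(0, nC, 3)
  if (nC == 0)
    return(list(f_pef = zero, f_lateral = zero, f_spring = zero,
                f_total = zero))
  f_pef <- if (is.null(scan)) polar_ejection_force(state, params) else scan$pef
  f_lat <- lateral_motor_force(state, params)
  f_spr <- spring_forces(state, params)
  list(f_pef = f_pef, f_lateral = f_lat, f_spring = f_spr,
       f_total = f_pef + f_lat + f_spr)
}

#' @rdname net_force
#' @export
polar_ejection_force <- function(state, params) {
  nC <- n_chromosomes(state)
  out <- matrix(0, nC, 3)
  if (nC == 0 || n_mts(state) == 0 || params$F_PEF == 0) return(out)
  origin <- mt_origins(state)
  for (i in seq_len(nC)) {
    centre <- state$chrom$pos[i, ]
    for (j in seq_len(n_mts(state))) {
      if (arm_crossing_test(origin[j, ], state$mt$dir[j, ], state$mt$len[j],
                            centre, params$r_C, params$arm_geometry))
        out[i, ] <- out[i, ] + params$F_PEF * state$mt$dir[j, ]
    }
  }
  out
}

#' @rdname net_force
#' @export
lateral_motor_force <- function(state, params) {
  nC <- n_chromosomes(state)
  out <- matrix(0, nC, 3)
  i <- which(!is.na(state$chrom$lat_mt))
  if (!length(i)) return(out)
  j <- state$chrom$lat_mt[i]
  f <- ifelse(state$chrom$motor[i] == 2L, params$F_CENPE, -params$F_DYN)
  out[i, ] <- state$mt$dir[j, , drop = FALSE] * f
  out
}

#' @rdname net_force
#' @export
spring_forces <- function(state, params) {
  nC <- n_chromosomes(state)
  out <- matrix(0, nC, 3)
  att <- which(!is.na(state$mt$att_chrom))
  if (!length(att)) return(out)
  who <- state$mt$att_chrom[att]
  tips <- mt_origins(state)[att, , drop = FALSE] +
    state$mt$dir[att, , drop = FALSE] * state$mt$len[att]
  contrib <- params$k_k * (tips - state$chrom$pos[who, , drop = FALSE])
  acc <- rowsum(contrib, group = who)
  out[as.integer(rownames(acc)), ] <- acc
  out
}

#' Advance chromosome positions
#'
#' First-order (Euler) update of the overdamped equation of motion:
#' `r <- r + F dt / eta`, followed by the hard cortex boundary condition
#' (positions outside the ellipsoid are projected radially back inside).
#' In the interior the displacement equals `F dt / eta` exactly.
#'
#' @param state a `spindle_state`.
#' @param f_total n_C x 3 matrix of total forces, pN.
#' @param params a [spindle_params()] object.
#' @return the updated state.
#' @export
advance_chromosomes <- function(state, f_total, params) {
  if (n_chromosomes(state) == 0) return(state)
  pos <- state$chrom$pos + f_total * (params$dt / params$eta)
  state$chrom$pos <- project_into_cortex(pos, state$geom)
  state
}
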