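#' End-on slot occupancy
#'
#' @param state a `spindle_state`.
#' @return an n_C x 2 integer matrix of occupied end-on slots per
#'   kinetochore (columns LEFT, RIGHT).
#' @export
slot_counts <- function(state) {
  nC <- n_chromosomes(state)
  att <- which(!is.na(state$mt$att_chrom))
  out <- matrix(0L, nC, 2, dimnames = list(NULL, c("LEFT", "RIGHT")))
  if (length(att)) {
    for (s in 1:2) {
      i <- att[state$mt$att_side[att] == s]
      if (length(i))
        out[, s] <- tabulate(state$mt$att_chrom[i], nbins = nC)
    }
  }
  out
}

# integer stability codes per chromosome: 0 NONE, 1 UNSTABLE, 2 STABLE.
# STABLE is the amphitelic configuration: each sister kinetochore carries
# at least one end-on MT from the pole it faces (left hemisphere - left
# pole, right hemisphere - right pole). Monotelic, syntelic and crossed
# (merotelic-like) configurations are UNSTABLE.
stability_codes <- function(state) {
  nC <- n_chromosomes(state)
  codes <- integer(nC)
  att <- which(!is.na(state$mt$att_chrom))
  if (!length(att)) return(codes)
  chrom <- state$mt$att_chrom[att]
  side <- state$mt$att_side[att]
  pole <- state$mt$pole[att]
  any_att <- tabulate(chrom, nbins = nC) > 0L
  left_p1  <- tabulate(chrom[side == 1L & pole == 1L], nbins = nC) > 0L
  right_p2 <- tabulate(chrom[side == 2L & pole == 2L], nbins = nC) > 0L
  codes[any_att] <- 1L
  codes[left_p1 & right_p2] <- 2L
  codes
}

#' Attachment stability of each chromosome
#'
#' A chromosome with no end-on attachments is `NONE`. It is `STABLE`
#' (amphitelic) only when both kinetochores carry end-on attachments and
#' the attached MTs collectively stem from both poles; every other
#' configuration (monotelic, syntelic) is `UNSTABLE`.
#'
#' @param state a `spindle_state`.
#' @return character vector (`"NONE"`, `"UNSTABLE"`, `"STABLE"`) per
#'   chromosome.
#' @export
classify_stability <- function(state) {
  c("NONE", "UNSTABLE", "STABLE")[stability_codes(state) + 1L]
}

#' Update the motor program
#'
#' At release, CENP-E is the active motor for chromosomes inside the shell
#' of radius `0.45 a` and dynein for the peripheral rest (set by
#' [init_state()]). A dynein-driven chromosome is carried to (and held at)
#' the nearest pole; once it is within `delta_pole` of a pole \emph{and} a
#' long-lived CENP-E track (MT older than `tau_MT`, or scaffold) passes
#' within its interaction radius, dynein is permanently switched off and
#' replaced by CENP-E, which latches that track and slides the chromosome
#' away from the pole. Until such a track is found, dynein stays active
#' and keeps the chromosome at the pole against the polar ejection
#' forces. CENP-E never reverts. When CENP-E is deleted
#' (`cenpe_present = FALSE`) there is no motor to replace dynein, so the
#' switch is suppressed and dynein keeps chromosomes trapped at the pole.
#'
#' @param state a `spindle_state`.
#' @param params a [spindle_params()] object.
#' @return the updated state.
#' @export
update_motor_program <- function(state, params) {
  near <- near_pole_dynein(state, params)
  if (!length(near)) return(state)
  origin <- mt_origins(state)
  npole <- nearest_pole(state)
  for (i in near) {
    elig <- which(cenpe_eligible(state, params) & state$mt$pole == npole[i])
    if (!length(elig)) next
    centre <- state$chrom$pos[i, ]
    best <- NA_integer_
    best_d <- params$delta_pole   # the whole aster is within reach here
    for (j in elig) {
      d <- point_segment_distance(centre, origin[j, ],
                                  origin[j, ] + state$mt$len[j] * state$mt$dir[j, ])
      if (d <= best_d) {
        best_d <- d
        best <- j
      }
    }
    if (!is.na(best)) {
      state <- switch_to_cenpe(state, i, best)
      state <- snap_to_track(state, i, best)
    }
  }
  state
}

# dynein chromosomes currently within delta_pole of either pole (the
# candidates for the dynein -> CENP-E replacement); empty when CENP-E is
# knocked out
near_pole_dynein <- function(state, params) {
  if (!params$cenpe_present) return(integer(0))
  dyn <- which(state$chrom$motor == 1L)
  if (!length(dyn)) return(integer(0))
  pos <- state$chrom$pos[dyn, , drop = FALSE]
  half_a <- state$geom$a / 2
  yz2 <- pos[, 2]^2 + pos[, 3]^2
  d1 <- sqrt((pos[, 1] + half_a)^2 + yz2)
  d2 <- sqrt((pos[, 1] - half_a)^2 + yz2)
  dyn[pmin(d1, d2) <= params$delta_pole]
}

switch_to_cenpe <- function(state, i, track) {
  state$chrom$motor[i] <- 2L
  state$chrom$lat_mt[i] <- as.integer(track)
  state$counts$motor_switches <- state$counts$motor_switches + 1L
  state
}

# MTs eligible as CENP-E tracks: long-lived (older than tau_MT, or
# scaffold) and pointing towards the cell interior (plus end towards the
# mid-plane), the geometry of the detyrosinated spindle MTs that CENP-E
# walks on; riding such a track always moves the chromosome away from its
# pole towards the central plate
cenpe_eligible <- function(state, params) {
  interior <- ifelse(state$mt$pole == 1L, state$mt$dir[, 1] > 0,
                     state$mt$dir[, 1] < 0)
  (state$mt$scaffold | (state$time - state$mt$birth > params$tau_MT)) &
    interior
}

#' Form a lateral attachment
#'
#' Links a chromosome without a lateral track to the nearest MT passing its
#' kinetochore interaction sphere. Dynein rides any MT; CENP-E only rides
#' long-lived MTs (age above `tau_MT`; scaffold MTs are always eligible).
#' Ties are broken by the smallest MT index. A chromosome that currently
#' holds any end-on attachment does not form lateral links (end-on
#' dominates).
#'
#' @param state a `spindle_state`.
#' @param i chromosome index.
#' @param params a [spindle_params()] object.
#' @return the updated state (unchanged if no eligible MT is in reach).
#' @export
form_lateral <- function(state, i, params) {
  if (!is.na(state$chrom$lat_mt[i])) return(state)
  if (slot_total(state, i) > 0L) return(state)
  centre <- state$chrom$pos[i, ]
  origin <- mt_origins(state)
  elig <- if (state$chrom$motor[i] == 2L)
    cenpe_eligible(state, params) else rep(TRUE, n_mts(state))
  elig <- elig & state$mt$pole == nearest_pole(state)[i]
  best <- NA_integer_
  best_d <- Inf
  for (j in which(elig)) {
    d <- point_segment_distance(centre, origin[j, ],
                                origin[j, ] + state$mt$len[j] * state$mt$dir[j, ])
    if (d <= params$r_k && d < best_d) {
      best_d <- d
      best <- j
    }
  }
  if (!is.na(best)) state$chrom$lat_mt[i] <- best
  state
}

slot_total <- function(state, i) {
  sum(state$mt$att_chrom == i, na.rm = TRUE)
}

#' Form end-on attachments
#'
#' Attaches every MT whose tip contacts a kinetochore hemisphere
#' ([tip_contact_side()]) to that kinetochore, while free slots remain
#' (at most `N_k` per kinetochore) and the MT is not already attached.
#' Kinetochores of dynein-driven chromosomes are covered by dynein and
#' form no end-on attachments. Any lateral link of a chromosome gaining an
#' end-on attachment is dropped.
#'
#' @param state a `spindle_state`.
#' @param i chromosome index.
#' @param params a [spindle_params()] object.
#' @param candidates optional integer vector of MT indices to consider
#'   (defaults to all MTs).
#' @return the updated state.
#' @export
form_end_on <- function(state, i, params, candidates = seq_len(n_mts(state))) {
  if (state$chrom$motor[i] != 2L) return(state)
  centre <- state$chrom$pos[i, ]
  g <- state$geom
  if (min(sqrt(sum((centre - g$poles[1, ])^2)),
          sqrt(sum((centre - g$poles[2, ])^2))) <= params$delta_pole)
    return(state)   # pole regions destabilize end-on attachments
  origin <- mt_origins(state)
  occ <- slot_counts(state)[i, ]
  new <- 0L
  for (j in candidates) {
    if (!is.na(state$mt$att_chrom[j])) next
    if (!is.na(state$mt$refract_chrom[j]) &&
        state$mt$refract_chrom[j] == i) next
    side <- tip_contact_side(origin[j, ], state$mt$dir[j, ], state$mt$len[j],
                             centre, params$r_k, state$mt$pole[j])
    if (side == "NONE") next
    s <- if (side == "LEFT") 1L else 2L
    if (occ[s] >= params$N_k) next
    state$mt$att_chrom[j] <- i
    state$mt$att_side[j] <- s
    occ[s] <- occ[s] + 1L
    new <- new + 1L
  }
  if (new > 0L) {
    state$chrom$lat_mt[i] <- NA_integer_
    state$counts$attachments <- state$counts$attachments + new
  }
  state
}
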