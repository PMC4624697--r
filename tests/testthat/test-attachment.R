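# fixtures place one chromosome at (-2, 0, 0): its nearest pole is the -x
# pole, so eligible tracks all come from pole 1

test_that("stability classification distinguishes amphitelic from error states", {
  p <- spindle_params(N_MT = 4, n_C = 1)
  st <- new_state(p)
  st <- add_microtubule(st, 1, c(1, 0, 0), len = 5.45)   # tip left of centre
  st <- add_microtubule(st, 2, c(-1, 0, 0), len = 9.4)   # tip right of centre
  st <- add_microtubule(st, 1, c(1, 0.02, 0), len = 5.5)
  st <- add_chromosome(st, c(-2, 0, 0), motor = "CENPE")
  expect_identical(classify_stability(st), "NONE")
  # amphitelic: left kinetochore from pole 1, right kinetochore from pole 2
  st1 <- st
  st1$mt$att_chrom[1:2] <- 1L
  st1$mt$att_side[1:2] <- c(1L, 2L)
  expect_identical(classify_stability(st1), "STABLE")
  # monotelic: only one kinetochore attached
  st2 <- st
  st2$mt$att_chrom[1] <- 1L
  st2$mt$att_side[1] <- 1L
  expect_identical(classify_stability(st2), "UNSTABLE")
  # syntelic: both kinetochores held, all MTs from one pole
  st3 <- st
  st3$mt$att_chrom[c(1, 3)] <- 1L
  st3$mt$att_side[c(1, 3)] <- c(1L, 2L)
  expect_identical(classify_stability(st3), "UNSTABLE")
})

test_that("initial motor program follows the CENP-E shell", {
  p <- spindle_params(N_MT = 10, n_C = 40, a = 15)
  set.seed(21)
  st <- init_state(p)
  r <- sqrt(rowSums(st$chrom$pos^2))
  expect_identical(st$chrom$motor == 2L, r < 0.45 * 15)
})

test_that("dynein is replaced by CENP-E at the pole only with a track in reach", {
  p <- spindle_params(N_MT = 2, n_C = 2, a = 15, delta_pole = 2.5)
  st <- new_state(p)
  # an old interior-pointing MT from pole 1 and a young one
  st <- add_microtubule(st, 1, c(1, 0.02, 0), len = 10, birth = -1000)
  st <- add_microtubule(st, 1, c(1, -0.02, 0), len = 10, birth = 0)
  st <- add_chromosome(st, c(-7.0, 0.2, 0), motor = "DYNEIN")  # at the pole
  st <- add_chromosome(st, c(0, 5, 0), motor = "DYNEIN")       # far away
  st2 <- update_motor_program(st, p)
  expect_identical(st2$chrom$motor, c(2L, 1L))
  expect_identical(st2$chrom$lat_mt[1], 1L)   # latched the old track
  # the kinetochore is reeled onto the fiber
  expect_lt(point_segment_distance(st2$chrom$pos[1, ], c(-7.5, 0, 0),
                                   c(-7.5, 0, 0) + 10 * st2$mt$dir[1, ]), 1e-9)
  # with CENP-E deleted the switch never happens
  p_ko <- spindle_params(N_MT = 2, n_C = 2, a = 15, cenpe_present = FALSE)
  expect_identical(update_motor_program(st, p_ko)$chrom$motor, c(1L, 1L))
})

test_that("CENP-E only rides long-lived interior-pointing tracks", {
  p <- spindle_params(N_MT = 3, n_C = 1, a = 15, tau_MT = 60)
  mk <- function(birth, dirv = c(1, 0.01, 0)) {
    st <- new_state(p)
    st <- add_microtubule(st, 1, dirv, len = 12, birth = birth)
    st <- add_chromosome(st, c(-2, 0.1, 0), motor = "CENPE")
    st$time <- 100
    st
  }
  # young MT: no CENP-E link
  expect_true(is.na(form_lateral(mk(90), 1, p)$chrom$lat_mt[1]))
  # old MT: link forms
  expect_identical(form_lateral(mk(10), 1, p)$chrom$lat_mt[1], 1L)
  # outward-pointing old MT from the same pole: not a CENP-E track
  st_out <- new_state(p)
  st_out <- add_microtubule(st_out, 1, c(-0.5, 0.99, 0), len = 10, birth = -500)
  st_out <- add_chromosome(st_out, c(-9.75, 4.46, 0), motor = "CENPE")
  st_out$time <- 100
  expect_true(is.na(form_lateral(st_out, 1, p)$chrom$lat_mt[1]))
  # scaffold MTs are always eligible
  st_sc <- new_state(p)
  st_sc <- add_microtubule(st_sc, 1, c(1, 0.01, 0), len = 12, scaffold = TRUE,
                           birth = -Inf)
  st_sc <- add_chromosome(st_sc, c(-2, 0.1, 0), motor = "CENPE")
  expect_identical(form_lateral(st_sc, 1, p)$chrom$lat_mt[1], 1L)
  # dynein rides young MTs without the age filter
  st_dyn <- mk(95)
  st_dyn$chrom$motor[1] <- 1L
  expect_identical(form_lateral(st_dyn, 1, p)$chrom$lat_mt[1], 1L)
})

test_that("end-on attachments respect motor state, slots and pole regions", {
  p <- spindle_params(N_MT = 3, n_C = 1, a = 15, N_k = 2)
  base <- new_state(p)
  # three MTs whose tips all touch the left hemisphere of the kinetochore
  base <- add_microtubule(base, 1, c(1, 0, 0), len = 5.45)
  base <- add_microtubule(base, 1, c(1, 0.01, 0), len = 5.4)
  base <- add_microtubule(base, 1, c(1, -0.01, 0), len = 5.4)
  st <- add_chromosome(base, c(-2, 0, 0), motor = "CENPE")
  st1 <- form_end_on(st, 1, p)
  expect_identical(sum(!is.na(st1$mt$att_chrom)), 2L)  # capacity N_k = 2
  expect_true(all(slot_counts(st1) <= p$N_k))
  # dynein-covered kinetochores never attach end-on
  st_dyn <- add_chromosome(base, c(-2, 0, 0), motor = "DYNEIN")
  expect_identical(sum(!is.na(form_end_on(st_dyn, 1, p)$mt$att_chrom)), 0L)
  # inside the pole region no end-on attachment forms
  st_pole <- new_state(p)
  st_pole <- add_microtubule(st_pole, 1, c(1, 0, 0), len = 1.55)
  st_pole <- add_chromosome(st_pole, c(-6, 0, 0), motor = "CENPE")
  expect_identical(sum(!is.na(form_end_on(st_pole, 1, p)$mt$att_chrom)), 0L)
  # a refractory MT cannot re-bind the same kinetochore
  st_ref <- st
  st_ref$mt$refract_chrom[1] <- 1L
  st_ref$mt$refract_until[1] <- 100
  st2 <- form_end_on(st_ref, 1, p)
  expect_true(is.na(st2$mt$att_chrom[1]))
})

test_that("a lateral link is cleared the same step its track collapses", {
  p <- spindle_params(N_MT = 1, n_C = 1, a = 15, p_cat0 = 0, p_res0 = 0,
                      F_PEF = 0, F_CENPE = 0, F_DYN = 0)
  st <- new_state(p)
  st <- add_microtubule(st, 1, c(1, 0.02, 0), len = 0.01, growing = FALSE)
  st <- add_chromosome(st, c(-7.49, 0.05, 0), motor = "DYNEIN")
  st$chrom$lat_mt[1] <- 1L
  st2 <- sim_step(st, p)
  expect_identical(st2$counts$collapses, 1L)
  expect_true(is.na(st2$chrom$lat_mt[1]))
  # fixed-N mode renucleated the MT in place
  expect_identical(n_mts(st2), 1L)
  expect_identical(st2$mt$len[1], 0)
  expect_true(st2$mt$growing[1])
})

test_that("no end-on attachment ever exists on a dynein-driven chromosome", {
  p <- desk_params(N_MT = 300, n_C = 4)
  set.seed(77)
  st <- init_state(p)
  bad <- FALSE
  for (i in 1:150) {
    st <- sim_step(st, p)
    att <- which(!is.na(st$mt$att_chrom))
    if (length(att) &&
        any(st$chrom$motor[st$mt$att_chrom[att]] == 1L)) bad <- TRUE
  }
  expect_false(bad)
})

test_that("slot occupancy never exceeds the kinetochore capacity", {
  p <- desk_params(N_MT = 500, n_C = 3, N_k = 3)
  set.seed(78)
  st <- init_state(p)
  worst <- 0L
  for (i in 1:400) {
    st <- sim_step(st, p)
    worst <- max(worst, slot_counts(st))
  }
  expect_lte(worst, 3L)
})
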