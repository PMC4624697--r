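test_that("identical seeds give bit-identical runs", {
  p <- desk_params(N_MT = 300, n_C = 4, deadline_congression = 40,
                   deadline_biorientation = 40)
  r1 <- run_single(p, "wt_scattered", seed = 7, record_dt = 5,
                   return_state = TRUE)
  r2 <- run_single(p, "wt_scattered", seed = 7, record_dt = 5,
                   return_state = TRUE)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$state$mt, r2$state$mt)
  expect_identical(r1$state$chrom, r2$state$chrom)
  # different seed, different trajectory
  r3 <- run_single(p, "wt_scattered", seed = 8, record_dt = 5)
  expect_false(identical(r1$trajectory, r3$trajectory))
})

test_that("ensembles are reproducible and use consecutive seeds", {
  p <- desk_params(N_MT = 200, n_C = 2, deadline_congression = 20,
                   deadline_biorientation = 20)
  e1 <- run_ensemble(p, "wt_scattered", n = 3, base_seed = 10)
  e2 <- run_ensemble(p, "wt_scattered", n = 3, base_seed = 10)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_identical(vapply(e1, `[[`, integer(1), "seed"), 10:12)
  expect_error(run_ensemble(p, n = 0), "n >= 1")
})

test_that("a configuration file round-trips and rejects unknown keys", {
  p <- desk_params(N_MT = 123, n_C = 3, p_cat0 = 0.1)
  path <- tempfile(fileext = ".json")
  write_config(p, path, scenario = "ko_dynein", seed = 42L)
  cfg <- read_config(path)
  expect_identical(cfg$scenario, "ko_dynein")
  expect_identical(cfg$seed, 42L)
  expect_equal(unclass(cfg$params), unclass(p))
  # a re-run from the echoed configuration reproduces the original run
  r1 <- run_single(p, "ko_dynein", seed = 42, t_max = 15, return_state = TRUE)
  r2 <- run_single(cfg$params, cfg$scenario, seed = cfg$seed, t_max = 15,
                   return_state = TRUE)
  expect_identical(r1$state$chrom, r2$state$chrom)
  # unknown keys are errors
  bad <- jsonlite::read_json(path)
  bad$not_a_parameter <- 1
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE)
  expect_error(read_config(path2), "unknown configuration key")
})

test_that("each step resolves stochastic events before chromosomes move", {
  p <- desk_params(N_MT = 150, n_C = 3, deadline_congression = 10,
                   deadline_biorientation = 10)
  phases <- character(0)
  moved_before_events <- FALSE
  pos_at_events <- NULL
  pos_before <- NULL
  hook <- function(phase, state) {
    phases <<- c(phases, phase)
    if (phase == "events") {
      # chromosome positions must still be the start-of-step positions
      if (!is.null(pos_before) &&
          !identical(state$chrom$pos, pos_before)) moved_before_events <<- TRUE
    }
  }
  set.seed(3)
  st <- init_state(p)
  for (i in 1:50) {
    pos_before <- st$chrom$pos
    st <- sim_step(st, p, hook = hook)
  }
  expect_identical(unique(matrix(phases, nrow = 3)[, 1]),
                   c("events", "mt", "chrom"))
  expect_identical(phases, rep(c("events", "mt", "chrom"), 50))
  expect_false(moved_before_events)
})

test_that("the compiled interaction scan agrees with the scalar predicates", {
  p <- desk_params(N_MT = 250, n_C = 5)
  set.seed(91)
  st <- init_state(p)
  for (i in 1:30) st <- sim_step(st, p)
  m <- st$mt
  g <- st$geom
  origin <- g$poles[m$pole, , drop = FALSE]
  nC <- 5L
  scan <- spindlesim:::scan_chromosomes_cpp(
    origin, m$dir, m$len, m$pole, rep(TRUE, n_mts(st)),
    st$chrom$pos, rep(1L, nC), spindlesim:::nearest_pole(st),
    rep(TRUE, nC), rep(TRUE, nC), rep(FALSE, nC), 0,
    p$r_C, p$r_k, p$F_PEF, 0L)
  # polar ejection forces: scalar predicate sum
  f_ref <- polar_ejection_force(st, p)
  expect_equal(scan$pef, f_ref, tolerance = 1e-12)
  # lateral candidates: nearest in-reach MT of the nearest pole
  for (i in 1:nC) {
    cand <- 0L
    best <- Inf
    npole <- spindlesim:::nearest_pole(st)[i]
    for (j in seq_len(n_mts(st))) {
      if (m$pole[j] != npole) next
      d <- point_segment_distance(st$chrom$pos[i, ], origin[j, ],
                                  origin[j, ] + m$len[j] * m$dir[j, ])
      if (d <= p$r_k && d < best) { best <- d; cand <- j }
    }
    expect_identical(scan$lat_mt[i], cand)
  }
  # tip contacts: scalar predicate per (chromosome, MT)
  ref <- list()
  for (i in 1:nC) for (j in seq_len(n_mts(st))) {
    s <- tip_contact_side(origin[j, ], m$dir[j, ], m$len[j],
                          st$chrom$pos[i, ], p$r_k, m$pole[j])
    if (s != "NONE")
      ref[[length(ref) + 1L]] <- c(i, j, if (s == "LEFT") 1L else 2L)
  }
  ref <- if (length(ref)) do.call(rbind, ref) else matrix(0L, 0, 3)
  got <- cbind(scan$contact_chrom, scan$contact_mt, scan$contact_side)
  o1 <- order(ref[, 1], ref[, 2])
  o2 <- order(got[, 1], got[, 2])
  expect_equal(unname(got[o2, , drop = FALSE]),
               unname(ref[o1, , drop = FALSE]))
})

test_that("the run driver refuses an unresolvable time step", {
  p <- desk_params(dt = 50)
  expect_error(run_single(p, "wt_scattered", seed = 1), "dt")
})

test_that("the command-line interface runs a small configured simulation", {
  cli <- system.file("cli", "spindlesim", package = "spindlesim")
  expect_true(nzchar(cli))
  cfg <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".csv")
  write_config(desk_params(N_MT = 150, n_C = 2, deadline_congression = 10,
                           deadline_biorientation = 10),
               cfg, scenario = "wt_scattered", seed = 5L)
  res <- system2("Rscript", c(cli, "run", "--config", cfg, "--out", out),
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  tab <- read.csv(out)
  expect_identical(nrow(tab), 1L)
  expect_true(all(c("seed", "scenario", "congression_time",
                    "biorientation_time") %in% names(tab)))
})
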