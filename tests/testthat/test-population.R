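test_that("fixed-N mode conserves the MT count exactly", {
  p <- desk_params(N_MT = 600, n_C = 3)
  set.seed(41)
  st <- init_state(p)
  ok <- TRUE
  for (i in 1:300) {
    st <- sim_step(st, p)
    if (n_mts(st) != 600L) ok <- FALSE
  }
  expect_true(ok)
  expect_gt(st$counts$collapses, 0)   # turnover happened, count still fixed
})

test_that("all MT tips stay inside the cortex at every step", {
  p <- desk_params(N_MT = 400, n_C = 2)
  set.seed(42)
  st <- init_state(p)
  worst <- 0
  g <- st$geom
  for (i in 1:250) {
    st <- sim_step(st, p)
    tips <- g$poles[st$mt$pole, , drop = FALSE] + st$mt$dir * st$mt$len
    worst <- max(worst, (tips[, 1] / g$a)^2 + (tips[, 2] / g$b)^2 +
                   (tips[, 3] / g$c)^2)
  }
  expect_lte(worst, 1 + 1e-9)
})

test_that("unloaded catastrophe waiting times are exponential with rate p_cat0", {
  p <- spindle_params(N_MT = 10000, n_C = 0, p_sc = 0, dt = 0.05, a = 15)
  set.seed(43)
  st <- init_state(p)
  st$mt$growing[] <- TRUE
  st$mt$len[] <- 5
  n <- n_mts(st)
  first_cat <- rep(NA_real_, n)
  prev <- st$mt$growing
  for (i in 1:1600) {
    st <- sim_step(st, p)
    sw <- prev & !st$mt$growing & is.na(first_cat)
    first_cat[sw] <- st$time
    prev <- st$mt$growing
  }
  times <- first_cat[!is.na(first_cat)]
  expect_gt(length(times), 9000)
  # events are detected on the step grid; place each uniformly within its
  # step to undo the discretization before the continuous-law test
  times <- times - runif(length(times), 0, p$dt)
  expect_gt(ks.test(times, "pexp", p$p_cat0)$p.value, 0.01)
})

test_that("unloaded rescue waiting times are exponential with rate p_res0", {
  # huge cell so shrinking MTs rarely reach zero before rescuing
  p <- spindle_params(N_MT = 8000, n_C = 0, p_sc = 0, p_cat0 = 1e-9,
                      dt = 0.05, a = 40)
  set.seed(44)
  st <- init_state(p)
  st$mt$growing[] <- FALSE
  st$mt$len[] <- 25
  n <- n_mts(st)
  first_res <- rep(NA_real_, n)
  prev <- st$mt$growing
  for (i in 1:1600) {
    st <- sim_step(st, p)
    sw <- !prev & st$mt$growing & is.na(first_res)
    first_res[sw] <- st$time
    prev <- st$mt$growing
  }
  cut <- 80
  times <- first_res[!is.na(first_res)] - runif(sum(!is.na(first_res)), 0, p$dt)
  times <- times[times <= cut]
  trunc_cdf <- function(q) pexp(q, 0.045) / pexp(cut, 0.045)
  expect_gt(ks.test(times, trunc_cdf)$p.value, 0.01)
})

test_that("nucleation adds Poisson numbers of MTs per pole", {
  p <- scenario_params("nucleation_mode", spindle_params(k_nucl = 20, dt = 0.1))
  set.seed(45)
  st <- init_state(p)
  steps <- 1500
  for (i in seq_len(steps)) st <- sim_step(st, p)
  # mean additions per step over both poles = 2 k dt
  rate_hat <- st$counts$nucleations / steps
  expect_equal(rate_hat, 2 * 20 * 0.1, tolerance = 0.05)
})

test_that("scaffold MTs never change and stay CENP-E eligible", {
  p <- desk_params(N_MT = 300, n_C = 0, p_sc = 0.1)
  set.seed(46)
  st <- init_state(p)
  expect_identical(sum(st$mt$scaffold), 30L)   # round(p_sc N)
  sc <- which(st$mt$scaffold)
  len0 <- st$mt$len[sc]
  for (i in 1:300) st <- sim_step(st, p)
  expect_identical(st$mt$len[sc], len0)
  expect_true(all(st$mt$growing[sc]))
  # infinite age: always pass the CENP-E age filter
  expect_true(all(st$time - st$mt$birth[sc] > p$tau_MT))
  # p_sc = 0 marks nothing
  p0 <- desk_params(N_MT = 300, n_C = 0, p_sc = 0)
  set.seed(46)
  expect_identical(sum(init_state(p0)$mt$scaffold), 0L)
})

test_that("scaffold rays pass through the interpolar region", {
  p <- desk_params(N_MT = 500, n_C = 0)
  set.seed(47)
  st <- init_state(p)
  g <- st$geom
  sc <- which(st$mt$scaffold)
  miss <- sapply(sc, function(j) {
    o <- g$poles[st$mt$pole[j], ]
    t <- -sum(o * st$mt$dir[j, ])
    sqrt(sum((o + t * st$mt$dir[j, ])^2))
  })
  expect_true(all(miss <= g$r_cenpe_shell + 1e-9))
})

test_that("fit_kout recovers the generating parameters", {
  t <- seq(1, 200, by = 1)
  y <- expected_mt_count(18, 0.09, t)
  # noiseless: recovery to high precision, with k_nucl fixed or free
  expect_equal(fit_kout(t, y, k_nucl = 18)$k_out_hat, 0.09, tolerance = 1e-6)
  free <- fit_kout(t, y)
  expect_equal(free$k_out_hat, 0.09, tolerance = 1e-5)
  expect_equal(free$k_nucl_hat, 18, tolerance = 1e-3)
  # Poisson-noised ensemble mean of n = 100 runs: within 5%
  set.seed(48)
  noisy <- colMeans(matrix(rpois(100 * length(t), rep(y, each = 100)),
                           100, length(t)))
  expect_equal(fit_kout(t, noisy, k_nucl = 18)$k_out_hat, 0.09,
               tolerance = 0.05)
  # degenerate input: a population that is never there pushes the decay
  # rate to the search boundary
  expect_error(fit_kout(t, rep(0, length(t)), k_nucl = 18), "converge")
})

test_that("the fitted collapse rate does not depend on the nucleation rate", {
  p1 <- spindle_params(k_nucl = 4.5, dt = 0.1)
  p2 <- spindle_params(k_nucl = 13.5, dt = 0.1)
  e1 <- population_ensemble(p1, n = 15, base_seed = 49, t_max = 200)
  e2 <- population_ensemble(p2, n = 15, base_seed = 59, t_max = 200)
  f1 <- fit_kout(e1$times[-1], e1$mean_counts[-1], k_nucl = e1$k_nucl_total)
  f2 <- fit_kout(e2$times[-1], e2$mean_counts[-1], k_nucl = e2$k_nucl_total)
  expect_lt(abs(f1$k_out_hat - f2$k_out_hat) / f2$k_out_hat, 0.10)
})
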