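test_that("gini coefficient matches its definition", {
  expect_equal(gini_coefficient(c(0.3, 0.3, 0.3)), 0)
  expect_equal(gini_coefficient(c(0, 0, 1)), 2 / 3)
  expect_equal(gini_coefficient(rep(0, 5)), 0) # degenerate all-zero state
  expect_error(gini_coefficient(c(0.1, -0.2)), "negative")
  set.seed(71)
  for (rep in 1:5) {
    x <- runif(10)
    expect_equal(gini_coefficient(x), gini_oracle(x), tolerance = 1e-12)
  }
})

test_that("production rate is an anchored, clamped, increasing sigmoid", {
  expect_equal(infection_rate(0, beta0 = 0.7), 0)
  expect_equal(infection_rate(1, beta0 = 0.8), 0.8)
  expect_equal(infection_rate(1, beta0 = 5), 1) # amplitude clamped to 1
  # symmetric logistic: normalized value at the midpoint is exactly 1/2
  expect_equal(infection_rate(0.5, beta0 = 1, slope = 10, mid = 0.5), 0.5)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(infection_rate(p, beta0 = 0.6)) > 0))
})

test_that("clearance rate decays exponentially with deposition", {
  expect_equal(clearance_rate(0, delta0 = 0.4), 0.4)
  expect_equal(clearance_rate(1, delta0 = 1, decay = 1), exp(-1))
  expect_equal(clearance_rate(1, delta0 = 3, decay = 2), exp(-2)) # clamped
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(clearance_rate(p, delta0 = 0.5)) < 0))
})

test_that("the Gini split conserves the total production rate", {
  s <- split_rates(c(0.4), gini = 0.75)
  expect_equal(s$beta_ext, 0.3)
  expect_equal(s$beta_int, 0.1)
  s0 <- split_rates(c(0.2, 0.9), gini = 0)
  expect_equal(s0$beta_ext, c(0, 0))
  expect_equal(s0$beta_int, c(0.2, 0.9))
  set.seed(72)
  for (rep in 1:10) {
    bt <- runif(6)
    g <- runif(1, 0, 0.99)
    s <- split_rates(bt, g)
    expect_equal(s$beta_ext + s$beta_int, bt, tolerance = 1e-12)
  }
})

test_that("reception probability accumulates complement products", {
  expect_equal(reception_probability(c(0.5, 0.5), c(0, 0), 0), 0)
  expect_equal(reception_probability(c(0.5, 0.5), c(0.3, 0.9), 1), 1)
  # three senders with acp * beta_ext = 0.1, 0.2, 0.0 and beta_int = 0.05
  got <- reception_probability(c(1, 1, 1), c(0.1, 0.2, 0), 0.05)
  expect_equal(got, 1 - 0.95 * 0.9 * 0.8)
  expect_equal(reception_probability(c(1, 0.5, 1), c(0.2, 0.4, 0.3), 0.1,
                                     self = 1),
               1 - 0.9 * (1 - 0.2) * (1 - 0.3))
})

test_that("the compiled integrator agrees with the pure-R reference stepper", {
  conn <- random_connectome(4, seed = 81)
  params <- esm_params(beta0 = 0.6, delta0 = 0.3, horizon_days = 60,
                       velocity = 1) # short delays so they matter in 60 steps
  traj <- simulate_esm(conn, params, seeds = 1)
  ref <- r_reference_esm(conn, params, seeds = 1, n_steps = 60)
  expect_equal(unname(traj$p), ref, tolerance = 1e-12)
})

test_that("an isolated region with dominant clearance decays toward zero", {
  acp <- diag(1, 3)
  conn <- connectome(acp, matrix(0, 3, 3))
  params <- esm_params(beta0 = 0.5, delta0 = 0.5, noise_mean = 0,
                       horizon_days = 2000, p_seed_init = 0.01)
  traj <- simulate_esm(conn, params, seeds = 1)
  expect_true(all(diff(traj$p[, 1]) <= 1e-12))
  expect_lt(traj$p[2001, 1], 1e-6)
  # closed-form comparison over the first steps: dP = -P delta(P) when
  # production at trace levels is negligible
  p <- params$p_seed_init
  for (t in 1:10) {
    gain <- (1 - p) * (1 - gini_coefficient(c(p, 0, 0))) *
      infection_rate(p, 0.5, params$sigmoid_slope, params$sigmoid_mid)
    p <- p + gain - p * clearance_rate(p, 0.5, params$clearance_decay)
    expect_equal(unname(traj$p[t + 1, 1]), p, tolerance = 1e-10)
  }
})

test_that("without clearance or noise the state is non-decreasing", {
  conn <- random_connectome(5, seed = 82)
  params <- esm_params(beta0 = 0.6, delta0 = 0, noise_mean = 0.001,
                       horizon_days = 3000)
  traj <- simulate_esm(conn, params, seeds = c(1, 2))
  expect_true(all(apply(traj$p, 2, function(col) all(diff(col) >= -1e-12))))
})

test_that("stochastic trajectories are reproducible and bounded", {
  conn <- random_connectome(5, seed = 83)
  params <- esm_params(beta0 = 0.5, delta0 = 0.3, noise_sd = 0.05,
                       horizon_days = 500)
  t1 <- simulate_esm(conn, params, seeds = 1, rng_seed = 99)
  t2 <- simulate_esm(conn, params, seeds = 1, rng_seed = 99)
  expect_identical(t1$p, t2$p)
  t3 <- simulate_esm(conn, params, seeds = 1, rng_seed = 100)
  expect_false(identical(t1$p, t3$p))
  expect_true(all(t1$p >= 0 & t1$p <= 1))
})

test_that("before any transmission delay elapses only seeds are active", {
  conn <- random_connectome(6, seed = 84)
  params <- esm_params(beta0 = 0.8, delta0 = 0.2, noise_mean = 0,
                       horizon_days = 50) # delays ~ 1000+ steps at V = 0.01
  traj <- simulate_esm(conn, params, seeds = c(2, 4))
  expect_true(all(traj$p[2, -c(2, 4)] == 0))
  expect_true(all(traj$p[51, -c(2, 4)] == 0))
  expect_true(all(traj$p[2, c(2, 4)] > 0))
})

test_that("marginalized global rates match analytic integrals", {
  p1 <- esm_params(beta0 = 1, delta0 = 1, clearance_decay = 1)
  mr <- marginal_rates(p1)
  expect_equal(mr$delta_eff, 1 - exp(-1), tolerance = 1e-6)
  p0 <- esm_params(beta0 = 0, delta0 = 0.5)
  expect_equal(marginal_rates(p0)$beta_eff, 0)
  beffs <- vapply(c(0.2, 0.4, 0.6, 0.8), function(b) {
    marginal_rates(esm_params(beta0 = b, delta0 = 0.3))$beta_eff
  }, numeric(1))
  expect_true(all(diff(beffs) > 0))
})

test_that("trajectory export round-trips through TSV", {
  conn <- tiny_connectome()
  params <- esm_params(beta0 = 0.5, delta0 = 0.3, horizon_days = 20)
  traj <- simulate_esm(conn, params, seeds = 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_trajectory(traj, tsv, js)
  back <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(back$day, traj$time_days)
  expect_equal(as.matrix(back[, -1]), traj$p, tolerance = 1e-12,
               ignore_attr = TRUE)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$params$beta0, 0.5)
  expect_equal(unlist(meta$seeds), 1)
})
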