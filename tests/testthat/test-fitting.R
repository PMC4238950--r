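test_that("seed-set counts use exact integer arithmetic", {
  expect_equal(count_seed_sets(10, 1), 10)
  expect_equal(count_seed_sets(10, 4), ncol(combn(10, 4))) # enumeration oracle
  expect_equal(count_seed_sets(12, 3, cumulative = TRUE),
               12 + ncol(combn(12, 2)) + ncol(combn(12, 3)))
  expect_error(count_seed_sets(5, 6), "k <= n_regions")
  expect_error(count_seed_sets(5, 0))
})

test_that("a pattern equal to the initial condition is fitted at day zero", {
  conn <- tiny_connectome()
  cfg <- cheap_cfg(grid_n = 4,
                   params = esm_params(0.5, 0.3, horizon_days = 300))
  pattern <- c(0.6, 0, 0)
  f <- fit_subject(pattern, conn, seeds = 1, cfg)
  expect_equal(f$t_opt, 0)
  expect_lt(f$fit_distance, 1e-8)
  expect_equal(f$sigma, sd(c(0, 0, 0)))
  fa <- fit_subject(pattern, conn, seeds = 1, cfg, age_years = 70)
  expect_equal(fa$onset_age, 70)
})

test_that("parameters of a mid-course snapshot are recovered by trajectory matching", {
  spec <- synth_spec(rng_seed = 7)
  conn <- make_connectome(spec)
  true_b <- 0.6
  true_d <- 0.3
  t_snap <- 5700
  params <- esm_params(beta0 = true_b, delta0 = true_d)
  pattern <- simulate_esm(conn, params, seeds = c(1, 2))$p[t_snap + 1, ]
  f <- fit_subject(pattern, conn, seeds = c(1, 2))
  expect_lt(abs(f$beta0 - true_b) / true_b, 0.15)
  expect_lt(abs(f$delta0 - true_d) / true_d, 0.15)
  expect_lte(abs(f$t_opt - t_snap), 200)
  expect_lt(f$fit_distance, 1e-4)
  expect_gt(f$beta_eff, 0)
  expect_gt(f$delta_eff, 0)
})

test_that("clearance amplitude monotonically suppresses a non-seeded target", {
  spec <- synth_spec(n_regions = 5, rng_seed = 8, geometry = "chain",
                     length_scale_mm = 5, seeds = 1L)
  conn <- make_connectome(spec)
  zero_pattern <- rep(0, 5)
  dists <- vapply(c(0.1, 0.2, 0.4, 0.8), function(d0) {
    params <- esm_params(beta0 = 0.05, delta0 = d0, noise_mean = 0,
                         horizon_days = 4000)
    traj <- simulate_esm(conn, params, seeds = 1)
    min(sqrt(rowSums(sweep(traj$p, 2, zero_pattern)^2)))
  }, numeric(1))
  expect_true(all(diff(dists) < 1e-12))
})

test_that("fit distance is invariant under consistent region relabeling", {
  spec <- synth_spec(n_regions = 6, rng_seed = 9, cohort_size = 1)
  conn <- make_connectome(spec)
  pattern <- simulate_esm(conn, esm_params(0.5, 0.2), c(1, 2))$p[3001, ]
  perm <- c(2, 1, 4, 3, 6, 5)
  conn_p <- connectome(conn$acp[perm, perm], conn$fiber_length[perm, perm])
  cfg <- cheap_cfg(grid_n = 5)
  f1 <- fit_subject(pattern, conn, seeds = c(1, 2), cfg)
  f2 <- fit_subject(pattern[perm], conn_p, seeds = c(2, 1), cfg)
  expect_equal(f1$fit_distance, f2$fit_distance, tolerance = 1e-10)
  expect_equal(f1$t_opt, f2$t_opt)
})

test_that("exhaustive search ranks a planted singleton seed first", {
  spec <- synth_spec(n_regions = 8, rng_seed = 10, cohort_size = 1,
                     seeds = 3L)
  conn <- make_connectome(spec)
  pattern <- simulate_esm(conn, esm_params(0.6, 0.25), 3L)$p[6001, ]
  rank <- seed_search(matrix(pattern, 1), conn, max_k = 1,
                      strategy = "exhaustive", cfg = cheap_cfg(5))
  expect_equal(rank$seeds[[1]], 3L)
  greedy <- seed_search(matrix(pattern, 1), conn, max_k = 1,
                        strategy = "greedy", cfg = cheap_cfg(5))
  expect_equal(greedy$seeds[[1]], 3L) # strategies agree on a singleton plant
})

test_that("exhaustive search is budget-guarded", {
  conn <- tiny_connectome()
  expect_error(seed_search(matrix(0.1, 1, 3), conn, max_k = 3,
                           strategy = "exhaustive", cfg = cheap_cfg(3),
                           budget = 2),
               "greedy")
})

test_that("epicenter scan flags the construction's source region", {
  spec <- synth_spec(n_regions = 8, rng_seed = 11, geometry = "chain",
                     seeds = 1L)
  conn <- make_connectome(spec)
  pattern <- exp(-effective_distance(conn, 3))
  scan <- epicenter_scan(pattern, conn)
  expect_equal(which.min(scan), 3)
  expect_warning(flat <- epicenter_scan(rep(0.4, 8), conn), "constant")
  expect_true(all(is.nan(flat)))
  # permuting regions permutes the scan consistently
  perm <- c(3, 1, 2, 5, 4, 7, 8, 6)
  conn_p <- connectome(conn$acp[perm, perm], conn$fiber_length[perm, perm])
  scan_p <- epicenter_scan(pattern[perm], conn_p)
  expect_equal(scan_p, scan[perm], tolerance = 1e-10)
})

test_that("fit results export to TSV and JSON", {
  conn <- tiny_connectome()
  cfg <- cheap_cfg(grid_n = 3,
                   params = esm_params(0.5, 0.3, horizon_days = 100))
  fits <- list(fit_subject(c(0.6, 0, 0), conn, 1, cfg))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  df <- write_fits(fits, tsv, js)
  expect_equal(nrow(read.table(tsv, header = TRUE, sep = "\t")), 1)
  expect_equal(jsonlite::read_json(js)[[1]]$t_opt, 0)
  expect_equal(df$beta0, fits[[1]]$beta0)
})
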