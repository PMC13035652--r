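test_that("study-level parameter draws have the configured moments", {
  cfg <- load_condition(1)
  set.seed(31)
  draws <- replicate(1e5, unlist(draw_study_parameters(cfg)))
  means <- rowMeans(draws)
  vars <- apply(draws, 1, var)
  # 3 Monte Carlo SEs for a mean: 3 sqrt(tau2 / n); for a variance: ~ 3 tau2 sqrt(2/n)
  n <- ncol(draws)
  expect_lt(abs(means[["delta_m"]] - 0.80), 3 * sqrt(0.10 / n))
  expect_lt(abs(means[["delta_y"]] - 0.50), 3 * sqrt(0.10 / n))
  expect_lt(abs(means[["rho"]] - 0.40), 3 * sqrt(0.02 / n))
  expect_lt(abs(vars[["delta_m"]] - 0.10), 3 * 0.10 * sqrt(2 / n))
  expect_lt(abs(vars[["delta_y"]] - 0.10), 3 * 0.10 * sqrt(2 / n))
  expect_lt(abs(vars[["rho"]] - 0.02), 3 * 0.02 * sqrt(2 / n))

  # degenerate heterogeneity returns the means exactly
  cfg0 <- condition_config(NA, "simple", 0.5, target_n = 100,
                           tau2_delta_m = 0, tau2_delta_y = 0, tau2_rho = 0)
  expect_equal(draw_study_parameters(cfg0),
               list(delta_m = 0.8, delta_y = 0.5, rho = 0.4))
})

test_that("sample-size draws respect each sampling plan's bounds", {
  set.seed(7)
  simple <- load_condition(1)
  for (i in 1:200) {
    sz <- draw_sample_sizes(simple)
    N <- sz$n1 + sz$n0
    expect_true(N >= 800 && N <= 1200)
    expect_true(sz$n1 >= 2 && sz$n0 >= 2)
    expect_equal(sz$pi_study, 0.02)
  }
  strat <- load_condition(4)
  for (i in 1:200) {
    sz <- draw_sample_sizes(strat)
    expect_true(sz$n1 >= ceiling(0.8 * 13) && sz$n1 <= floor(1.2 * 13))
    expect_true(sz$n0 >= ceiling(0.8 * 13) && sz$n0 <= floor(1.2 * 13))
  }
  unbal <- load_condition(13)
  p_seen <- replicate(500, draw_sample_sizes(unbal)$p)
  expect_true(all(p_seen > 0.15 & p_seen < 0.65))
  ranged <- load_condition(10)
  N_seen <- replicate(200, {
    sz <- draw_sample_sizes(ranged)
    sz$n1 + sz$n0
  })
  expect_true(all(N_seen >= 0.8 * 26 & N_seen <= 1.2 * 600))
  # subpopulation prevalence spans +/-30% around the population value
  sub <- load_condition(19)
  pi_seen <- replicate(500, draw_sample_sizes(sub)$pi_study)
  expect_true(all(pi_seen >= 0.014 & pi_seen <= 0.026))
  expect_gt(diff(range(pi_seen)), 0.008)
})

test_that("the mixed plan assigns plans and targets by thirds", {
  cfg <- load_condition(16)
  set.seed(12)
  for (i in c(1, 10)) {
    sz <- draw_sample_sizes(cfg, i)
    expect_true(sz$n1 + sz$n0 >= 800)   # simple plan, target 1000
  }
  for (i in c(11, 20)) {
    sz <- draw_sample_sizes(cfg, i)
    expect_true(sz$n1 + sz$n0 <= 32)    # stratified, target 26
    expect_true(abs(sz$n1 - sz$n0) <= 5)
  }
  for (i in c(21, 30)) {
    sz <- draw_sample_sizes(cfg, i)
    N <- sz$n1 + sz$n0
    expect_true(N >= 2 * ceiling(0.8 * 64) && N <= 2 * floor(1.2 * 64))
  }
})

test_that("simulated study statistics match their generating parameters", {
  # one huge study: observed summaries approach the generating values
  set.seed(21)
  st <- simulate_study(0.8, 0.5, 0.4, 5e4, 5e4)
  # 3 sampling SEs of d at n = 5e4 per group is ~ 0.02
  expect_lt(abs(st$d_m - 0.8), 0.02)
  expect_lt(abs(st$d_y - 0.5), 0.02)
  spec <- population_spec(0.5)
  expect_lt(abs(st$r_ym - total_correlation(spec)), 3 / sqrt(1e5))
  # zero-rho large study: merged correlation matches the mixture closed form
  st0 <- simulate_study(0.8, 0.5, 0, 5e4, 5e4)
  spec0 <- population_spec(0.5, rho_within = 0)
  expect_lt(abs(st0$r_ym - total_correlation(spec0)), 3 / sqrt(1e5))
  # null effects average to zero across many small studies
  set.seed(22)
  dms <- replicate(400, simulate_study(0, 0, 0.4, 15, 15)$d_m)
  expect_lt(abs(mean(dms)), 3 * sd(dms) / sqrt(400))
})

test_that("datasets are reproducible and carry exactly the configured missingness", {
  cfg <- load_condition(4)
  a <- simulate_meta_dataset(cfg, seed = 123)
  b <- simulate_meta_dataset(cfg, seed = 123)
  expect_identical(a$studies, b$studies)
  c <- simulate_meta_dataset(cfg, seed = 124)
  expect_false(identical(a$studies, c$studies))

  incomplete <- with(a$studies, !(obs_x & obs_m & obs_y))
  expect_equal(sum(incomplete), 12)
  # removing one variable from 12 of 30 studies masks 24 of 90 correlations
  expect_equal(a$missing_rate, 24 / 90)

  # each variable is removed with frequency ~ 1/3
  set.seed(77)
  k <- 30
  counts <- c(X = 0, M = 0, Y = 0)
  n_ds <- 300
  for (i in 1:n_ds) {
    ds <- simulate_meta_dataset(cfg, seed = derive_seed(55, i))
    counts["X"] <- counts["X"] + sum(!ds$studies$obs_x)
    counts["M"] <- counts["M"] + sum(!ds$studies$obs_m)
    counts["Y"] <- counts["Y"] + sum(!ds$studies$obs_y)
  }
  total <- 12 * n_ds
  se <- sqrt(1 / 3 * 2 / 3 / total)
  expect_true(all(abs(counts / total - 1 / 3) < 3 * se))
})

test_that("observed effect sizes recover their generating means across studies", {
  cfg <- condition_config(NA, "stratified", 0.5, target_n = 128,
                          missing_studies = 0, k = 30)
  set.seed(99)
  n_studies <- 2000
  d_m <- d_y <- r_ym <- numeric(n_studies)
  p_s <- numeric(n_studies)
  for (i in seq_len(n_studies)) {
    par <- draw_study_parameters(cfg)
    sz <- draw_sample_sizes(cfg)
    st <- simulate_study(par$delta_m, par$delta_y, par$rho, sz$n1, sz$n0)
    d_m[i] <- st$d_m; d_y[i] <- st$d_y; r_ym[i] <- st$r_ym; p_s[i] <- sz$p
  }
  expect_equal(mean(d_m), 0.80, tolerance = 3 * sd(d_m) / sqrt(n_studies))
  expect_equal(mean(d_y), 0.50, tolerance = 3 * sd(d_y) / sqrt(n_studies))
  # back-transformed within-group correlations recover the mean rho = .40
  rw <- suppressWarnings(as.numeric(r_within(r_ym, d_m, d_y, p_s)))
  expect_equal(mean(rw), 0.40, tolerance = 3 * sd(rw) / sqrt(n_studies))
})

test_that("study tables round-trip through CSV with blank missing fields", {
  ds <- simulate_meta_dataset(load_condition(1), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_table(ds, path)
  expect_false(any(grepl("NA", readLines(path))))
  back <- read_study_table(path)
  expect_equal(back$d_m, ds$studies$d_m)
  expect_equal(back$obs_x, ds$studies$obs_x)
})
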