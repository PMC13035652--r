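test_that("sampling covariance has the textbook limits", {
  # all correlations zero: variances 1/n, covariances 0
  V <- sampling_covariance(c(0, 0, 0), rep(TRUE, 3), 50)
  expect_equal(V, diag(1 / 50, 3), ignore_attr = TRUE)
  # diagonal entries are (1 - r^2)^2 / n
  r <- c(0.3, -0.2, 0.5)
  V <- sampling_covariance(r, rep(TRUE, 3), 80)
  expect_equal(diag(V), (1 - r^2)^2 / 80, ignore_attr = TRUE)
  expect_equal(V, t(V))
  # vanishes as n grows
  expect_lt(max(abs(sampling_covariance(r, rep(TRUE, 3), 1e9))), 1e-8)
  # masked version is the corresponding sub-matrix
  Vs <- sampling_covariance(r, c(TRUE, FALSE, TRUE), 80)
  expect_equal(Vs, V[c(1, 3), c(1, 3)])
  expect_error(sampling_covariance(r, rep(TRUE, 3), 3), "at least 4")
})

test_that("sampling covariance matches the empirical covariance of correlations", {
  # simulation oracle: draw many samples of size n from a trivariate normal,
  # compute the three correlations, and compare n * empirical covariance with
  # the asymptotic form evaluated at the population correlations
  set.seed(8)
  rho <- c(0.25, 0.15, 0.45)  # (MX, YX, YM) with variable order X, M, Y
  R <- matrix(c(1, rho[1], rho[2],
                rho[1], 1, rho[3],
                rho[2], rho[3], 1), 3, 3)
  n <- 300
  M <- 10000
  big <- MASS::mvrnorm(n * M, c(0, 0, 0), R)
  idx <- rep(seq_len(M), each = n)
  rs <- t(vapply(split.data.frame(big, idx), function(m) {
    C <- cor(m)
    c(C[2, 1], C[3, 1], C[3, 2])
  }, numeric(3)))
  emp <- n * cov(rs)
  theo <- n * sampling_covariance(rho, rep(TRUE, 3), n)
  expect_lt(max(abs(emp - theo) / pmax(abs(theo), 0.05)), 0.05)
})

test_that("record building converts, masks, and passes r_YM untouched", {
  ds <- manual_dataset(d_m = c(0.9, 0.4), d_y = c(0.5, 0.2),
                       r_ym = c(0.41, 0.38), n1 = c(13, 14), n0 = c(13, 12))
  rec <- build_records(ds, "equal-groups")
  expect_equal(rec[[1]]$r[[1]], d_to_rpb(0.9, "equal-groups", 13, 13))
  expect_equal(rec[[1]]$r[[3]], 0.41)
  # balanced groups: equal-groups and p-based general records coincide
  rec_p <- build_records(ds, "p-general")
  expect_equal(rec[[1]]$r, rec_p[[1]]$r)
  # removed variables propagate to the mask
  ds$studies$obs_x[2] <- FALSE
  ds$studies$d_m[2] <- ds$studies$d_y[2] <- NA
  rec <- build_records(ds, "equal-groups")
  expect_equal(rec[[2]]$mask, c(FALSE, FALSE, TRUE))
  expect_length(rec[[2]]$r, 1)
  # zero d converts to exactly zero whatever the method
  ds0 <- manual_dataset(0, 0, 0.3, 15, 11)
  for (m in conversion_methods()) {
    rec0 <- build_records(ds0, m, prevalence = 0.2)
    expect_identical(unname(rec0[[1]]$r[1:2]), c(0, 0))
  }
  expect_error(build_records(ds0, "pi-general"), "prevalence")
})

test_that("a single complete study with fixed tau2 is returned exactly", {
  ds <- manual_dataset(0.7, 0.3, 0.42, 40, 40)
  rec <- build_records(ds, "equal-groups")
  fit <- fit_pooled_correlations(rec, fix_tau2 = c(0, 0, 0))
  expect_true(fit$converged)
  expect_equal(unname(fit$pooled_r), unname(rec[[1]]$r), tolerance = 1e-6)
})

test_that("fixed-effect ML agrees with closed-form GLS pooling", {
  set.seed(14)
  recs <- make_model_records(k = 12, rho = c(0.2, 0.1, 0.4),
                             tau2 = c(0, 0, 0), n = 150, seed = 14)
  fit <- fit_pooled_correlations(recs, fix_tau2 = c(0, 0, 0))
  expect_true(fit$converged)
  expect_equal(unname(fit$pooled_r), gls_pooled(recs), tolerance = 1e-5)
  # and with missingness: drop one position from a few studies
  for (i in 1:4) {
    keep <- c(TRUE, i %% 2 == 0, TRUE)
    recs[[i]]$mask <- keep
    recs[[i]]$r <- recs[[i]]$r[keep]
    recs[[i]]$V <- recs[[i]]$V[keep, keep, drop = FALSE]
  }
  fit <- fit_pooled_correlations(recs, fix_tau2 = c(0, 0, 0))
  expect_equal(unname(fit$pooled_r), gls_pooled(recs), tolerance = 1e-5)
})

test_that("the optimizer agrees with a dense grid search on a small instance", {
  # three studies observing only the M-Y correlation
  set.seed(3)
  r_obs <- c(0.30, 0.45, 0.52)
  n <- 60
  recs <- lapply(seq_along(r_obs), function(i) {
    mask <- c(FALSE, FALSE, TRUE)
    list(study = i, r = r_obs[i], mask = mask, n = n,
         V = sampling_covariance(c(0, 0, r_obs[i]), mask, n))
  })
  fit <- fit_pooled_correlations(recs)
  v_obs <- vapply(recs, function(r) r$V[1, 1], 0)
  grid <- grid_ml_single_position(
    r_obs, v_obs,
    rho_grid = seq(0.2, 0.6, by = 0.0005),
    tau2_grid = seq(0, 0.05, by = 0.0001)
  )
  expect_equal(fit$pooled_r[["rho_ym"]], grid$rho, tolerance = 1e-3)
  expect_equal(fit$tau2[["rho_ym"]], grid$tau2, tolerance = 2e-4)
  expect_equal(fit$logLik, grid$logLik, tolerance = 1e-3)
  # unobserved positions are excluded, not invented
  expect_true(all(is.na(fit$pooled_r[1:2])))
})

test_that("random-effects ML agrees with metafor on complete records", {
  recs <- make_model_records(k = 40, rho = c(0.25, 0.15, 0.40),
                             tau2 = c(0.01, 0.01, 0.02), n = 200, seed = 4)
  fit <- fit_pooled_correlations(recs)
  expect_true(fit$converged)

  yi <- unlist(lapply(recs, function(r) r$r))
  outcome <- factor(rep(1:3, length(recs)))
  study <- rep(seq_along(recs), each = 3)
  Vlist <- lapply(recs, function(r) r$V)
  mf <- metafor::rma.mv(yi, V = Vlist, mods = ~ outcome - 1,
                        random = ~ outcome | study, struct = "DIAG",
                        method = "ML", sparse = TRUE)
  expect_equal(unname(fit$pooled_r), unname(coef(mf)), tolerance = 1e-3)
  expect_equal(unname(fit$tau2), unname(mf$tau2), tolerance = 1e-3)
})

test_that("tau2 of the continuous correlation is recovered at scale", {
  tau2_true <- c(0.01, 0.01, 0.02)
  recs <- make_model_records(k = 200, rho = c(0.25, 0.15, 0.40),
                             tau2 = tau2_true, n = 500, seed = 6)
  fit <- fit_pooled_correlations(recs)
  v_bar <- mean(vapply(recs, function(r) r$V[3, 3], 0))
  se_tau2 <- sqrt(2 * (tau2_true[3] + v_bar)^2 / 200)
  expect_lt(abs(fit$tau2[["rho_ym"]] - tau2_true[3]), 3 * se_tau2)
})

test_that("full fits are saturated, prevalence-consistent, and adjustable", {
  # large clean balanced dataset at prevalence .50: estimates sit near the
  # population values of the mediation mixture
  cfg <- condition_config(NA, "stratified", 0.5, target_n = 2000, k = 40,
                          missing_studies = 0,
                          tau2_delta_m = 0, tau2_delta_y = 0, tau2_rho = 0)
  ds <- simulate_meta_dataset(cfg, seed = 42)
  fit <- fit_masem(ds, "equal-groups")
  pv <- population_values(population_spec(0.50))
  expect_true(fit$converged)
  expect_equal(fit$pooled_r[["rho_pb_mx"]], pv$rho_pb_mx, tolerance = 0.02)
  expect_equal(fit$pooled_r[["rho_pb_yx"]], pv$rho_pb_yx, tolerance = 0.02)
  expect_equal(fit$pooled_r[["rho_ym"]], pv$rho_ym, tolerance = 0.02)
  expect_equal(fit$beta[["beta_ym"]], pv$beta_ym, tolerance = 0.03)

  # path coefficients from exact population correlations reproduce the
  # published 3-decimal row at prevalence .02
  beta <- path_coefficients(0.1113041, 0.06982913, 0.4043165)
  expect_equal(unname(round(beta, 3)), c(0.111, 0.025, 0.402))

  # adjusting to the sample's own proportion changes nothing
  fit_adj <- fit_masem(ds, "equal-groups", adjust = TRUE,
                       target_prevalence = 0.50)
  expect_equal(fit_adj$pooled_r[["rho_ym"]], fit$pooled_r[["rho_ym"]],
               tolerance = 1e-3)

  # delta-method SEs are finite and positive when requested
  fit_se <- fit_masem(ds, "equal-groups", se = TRUE)
  expect_true(all(fit_se$se_pooled_r > 0))
  expect_true(all(fit_se$se_beta > 0))
})
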