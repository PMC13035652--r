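# Independent oracles used across test files.  These deliberately avoid the
# package's own code paths wherever they check one.

# closed-form GLS fixed-effect pooling of complete or incomplete correlation
# records: rho = (sum S' V^-1 S)^-1 sum S' V^-1 r
gls_pooled <- function(records) {
  A <- matrix(0, 3, 3)
  b <- numeric(3)
  for (rec in records) {
    idx <- which(rec$mask)
    Vinv <- solve(rec$V)
    A[idx, idx] <- A[idx, idx] + Vinv
    b[idx] <- b[idx] + Vinv %*% rec$r
  }
  keep <- which(diag(A) > 0)
  out <- rep(NA_real_, 3)
  out[keep] <- solve(A[keep, keep], b[keep])
  out
}

# records drawn directly from the random-effects model the engine assumes:
# r_i ~ N(rho, V_i + diag(tau2)), with V_i the known sampling covariance
make_model_records <- function(k, rho, tau2, n, seed) {
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    mu <- rho + rnorm(3, 0, sqrt(tau2))
    V <- pbmasem::sampling_covariance(rho, rep(TRUE, 3), n)
    L <- chol(V)
    r <- pmin(pmax(mu + drop(rnorm(3) %*% L), -0.98), 0.98)
    list(study = i, r = r, mask = rep(TRUE, 3), n = n,
         V = pbmasem::sampling_covariance(r, rep(TRUE, 3), n))
  })
}

# brute-force ML over a dense 2-D grid for a single-position problem
grid_ml_single_position <- function(r_obs, v_obs, rho_grid, tau2_grid) {
  best <- c(NA, NA)
  best_ll <- -Inf
  for (rho in rho_grid) {
    for (t2 in tau2_grid) {
      ll <- sum(dnorm(r_obs, rho, sqrt(v_obs + t2), log = TRUE))
      if (ll > best_ll) {
        best_ll <- ll
        best <- c(rho, t2)
      }
    }
  }
  list(rho = best[1], tau2 = best[2], logLik = best_ll)
}

# a small complete meta-dataset built by hand (no simulator involvement)
manual_dataset <- function(d_m, d_y, r_ym, n1, n0) {
  k <- length(d_m)
  studies <- data.frame(
    study = seq_len(k), n1 = n1, n0 = n0, p = n1 / (n1 + n0),
    pi_study = n1 / (n1 + n0),
    delta_m = d_m, delta_y = d_y, rho = r_ym,
    d_m = d_m, d_y = d_y, r_ym = r_ym,
    obs_x = TRUE, obs_m = TRUE, obs_y = TRUE
  )
  structure(list(studies = studies,
                 config = pbmasem::condition_config(
                   NA, "stratified", 0.5, target_n = max(n1 + n0), k = k,
                   missing_studies = 0
                 ),
                 seed = 0L, missing_rate = 0),
            class = "meta_dataset")
}
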