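#' Draw study-level population parameters
#'
#' Each primary study samples from its own subpopulation, so the study-level
#' standardized mean differences and within-group correlation are drawn from
#' independent normal distributions centred on the condition's means with the
#' condition's diagonal between-study variances.  A within-group correlation
#' falling outside (-0.99, 0.99) is redrawn (with the default tau^2 = 0.02
#' this virtually never triggers).
#'
#' Uses the current RNG stream; seed control lives in
#' [simulate_meta_dataset()].
#'
#' @param cfg a [condition_config()].
#' @return a list with `delta_m`, `delta_y`, `rho`.
#' @export
draw_study_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "condition_config"))
  delta_m <- rnorm(1, cfg$delta_m, sqrt(cfg$tau2_delta_m))
  delta_y <- rnorm(1, cfg$delta_y, sqrt(cfg$tau2_delta_y))
  repeat {
    rho <- rnorm(1, cfg$rho_within, sqrt(cfg$tau2_rho))
    if (abs(rho) < 0.99) break
  }
  list(delta_m = delta_m, delta_y = delta_y, rho = rho)
}

## discrete uniform on [ceiling(0.8 x), floor(1.2 x)]: +/-20% dropout band
dropout_draw <- function(x) {
  lo <- ceiling(0.8 * x)
  hi <- floor(1.2 * x)
  if (lo >= hi) return(as.integer(round(x)))
  sample(lo:hi, 1L)
}

#' Draw group sample sizes for one primary study
#'
#' Implements the sampling plans:
#' * `simple`: total N is drawn uniformly from the +/-20% dropout band around
#'   the target, then each participant belongs to the X = 1 group with
#'   probability equal to the study's prevalence (binomial split);
#' * `stratified`: each group size is drawn independently from the dropout
#'   band around `target_n / 2`;
#' * `unbalanced`: total N from the dropout band, sample proportion from
#'   U(.20, .60), `n1 = round(p N)`;
#' * `mixed`: studies in the first third use the simple plan with target 1000,
#'   the second third the stratified plan with target 26, the last third the
#'   stratified plan with target 128.
#'
#' When a target-size range is configured (varying-size conditions) the
#' per-study target is first drawn uniformly from that range.  When
#' `subpop_prevalence` is set, the study's prevalence is drawn from a uniform
#' distribution spanning +/-30% around the population prevalence (e.g.
#' \[.014, .026\] around .02).  Splits yielding a group smaller than 2 are
#' redrawn; the number of redraws is returned.
#'
#' @param cfg a [condition_config()].
#' @param study_index index of the study within the dataset (1..k); determines
#'   the plan under `mixed`.
#' @return a list with `n1`, `n0`, `p` (= n1/N), `pi_study`, `redraws`.
#' @export
draw_sample_sizes <- function(cfg, study_index = 1L) {
  stopifnot(inherits(cfg, "condition_config"))
  pi_study <- cfg$prevalence
  if (cfg$subpop_prevalence) {
    pi_study <- runif(1, 0.7 * cfg$prevalence, 1.3 * cfg$prevalence)
  }
  plan <- cfg$sampling_plan
  target <- cfg$target_n
  if (plan == "mixed") {
    third <- ceiling(3 * study_index / cfg$k)
    if (third <= 1) {
      plan <- "simple"; target <- 1000L
    } else {
      plan <- "stratified"; target <- if (third == 2) 26L else 128L
    }
  }
  if (is.null(target) && !is.null(cfg$target_n_min)) {
    target <- sample(cfg$target_n_min:cfg$target_n_max, 1L)
  }
  redraws <- 0L
  repeat {
    if (plan == "simple") {
      N <- dropout_draw(target)
      n1 <- rbinom(1L, N, pi_study)
      n0 <- N - n1
    } else if (plan == "stratified") {
      n1 <- dropout_draw(target / 2)
      n0 <- dropout_draw(target / 2)
    } else { # unbalanced
      N <- dropout_draw(target)
      p_i <- runif(1, 0.20, 0.60)
      n1 <- as.integer(round(p_i * N))
      n0 <- N - n1
    }
    if (n1 >= 2L && n0 >= 2L) break
    redraws <- redraws + 1L
  }
  list(n1 = as.integer(n1), n0 = as.integer(n0),
       p = n1 / (n1 + n0), pi_study = pi_study, redraws = redraws)
}

#' Simulate one primary study and compute its summary statistics
#'
#' Draws the two groups from bivariate normal distributions with unit
#' within-group SDs, group-0 means (0, 0), group-1 means
#' (`delta_m`, `delta_y`) and within-group correlation `rho`; then computes
#' Cohen's d for M and Y from the group summaries and the Pearson correlation
#' of M and Y on the merged sample.  Degenerate samples (zero within-group
#' variance) are redrawn.
#'
#' @param delta_m,delta_y study-level standardized mean differences.
#' @param rho study-level within-group correlation.
#' @param n1,n0 group sizes (each at least 2).
#' @return a list with `n1`, `n0`, `d_m`, `d_y`, `r_ym`.
#' @export
simulate_study <- function(delta_m, delta_y, rho, n1, n0) {
  stopifnot(n1 >= 2, n0 >= 2, abs(rho) < 1)
  Sigma <- matrix(c(1, rho, rho, 1), 2, 2)
  repeat {
    g0 <- MASS::mvrnorm(n0, c(0, 0), Sigma)
    g1 <- MASS::mvrnorm(n1, c(delta_m, delta_y), Sigma)
    s <- c(apply(g0, 2, sd), apply(g1, 2, sd))
    if (all(s > 0)) break
  }
  d_m <- cohens_d(mean(g1[, 1]), mean(g0[, 1]), sd(g1[, 1]), sd(g0[, 1]), n1, n0)
  d_y <- cohens_d(mean(g1[, 2]), mean(g0[, 2]), sd(g1[, 2]), sd(g0[, 2]), n1, n0)
  merged <- rbind(g0, g1)
  list(n1 = n1, n0 = n0, d_m = d_m, d_y = d_y,
       r_ym = cor(merged[, 1], merged[, 2]))
}

#' Randomly remove one variable from a subset of studies
#'
#' Selects `missing_studies` studies uniformly without replacement and removes
#' one variable (X, M or Y, chosen uniformly) from each: removing X drops both
#' Cohen's d values (only r_YM remains); removing M drops d_M and r_YM;
#' removing Y drops d_Y and r_YM.
#'
#' @param studies a study-level `data.frame` as built by
#'   [simulate_meta_dataset()].
#' @param cfg the [condition_config()].
#' @return the `data.frame` with updated `obs_x`, `obs_m`, `obs_y` flags and
#'   `NA` in the masked statistics.
#' @export
apply_missingness <- function(studies, cfg) {
  stopifnot(inherits(cfg, "condition_config"))
  if (cfg$missing_studies == 0L) return(studies)
  drop_idx <- sample(nrow(studies), cfg$missing_studies)
  dropped_var <- sample(c("X", "M", "Y"), cfg$missing_studies, replace = TRUE)
  for (j in seq_along(drop_idx)) {
    i <- drop_idx[j]
    if (dropped_var[j] == "X") {
      studies$obs_x[i] <- FALSE
      studies$d_m[i] <- NA_real_
      studies$d_y[i] <- NA_real_
    } else if (dropped_var[j] == "M") {
      studies$obs_m[i] <- FALSE
      studies$d_m[i] <- NA_real_
      studies$r_ym[i] <- NA_real_
    } else {
      studies$obs_y[i] <- FALSE
      studies$d_y[i] <- NA_real_
      studies$r_ym[i] <- NA_real_
    }
  }
  studies
}

#' Simulate a complete meta-analytic dataset
#'
#' Generates one dataset of `k` primary studies under a condition: per study,
#' the subpopulation parameters are drawn, the sampling plan yields the group
#' sizes, the raw two-group data are simulated and summarized (d_M, d_Y,
#' r_YM), and finally one variable is removed from `missing_studies` randomly
#' chosen studies.  Fully reproducible given the same condition and seed.
#'
#' @param cfg a [condition_config()].
#' @param seed integer seed for this dataset.
#' @return an object of class `"meta_dataset"`: a list with `studies` (a
#'   `data.frame` with columns `study`, `n1`, `n0`, `p`, `pi_study`,
#'   `delta_m`, `delta_y`, `rho`, `d_m`, `d_y`, `r_ym`, `obs_x`, `obs_m`,
#'   `obs_y`), the `config`, the `seed`, and the realized proportion of
#'   missing correlations (`missing_rate`).
#' @examples
#' ds <- simulate_meta_dataset(load_condition(4), seed = 1)
#' head(ds$studies)
#' @export
simulate_meta_dataset <- function(cfg, seed) {
  stopifnot(inherits(cfg, "condition_config"))
  set.seed(as.integer(seed))
  rows <- vector("list", cfg$k)
  for (i in seq_len(cfg$k)) {
    par <- draw_study_parameters(cfg)
    sz <- draw_sample_sizes(cfg, i)
    st <- simulate_study(par$delta_m, par$delta_y, par$rho, sz$n1, sz$n0)
    rows[[i]] <- data.frame(
      study = i, n1 = st$n1, n0 = st$n0, p = sz$p, pi_study = sz$pi_study,
      delta_m = par$delta_m, delta_y = par$delta_y, rho = par$rho,
      d_m = st$d_m, d_y = st$d_y, r_ym = st$r_ym,
      obs_x = TRUE, obs_m = TRUE, obs_y = TRUE
    )
  }
  studies <- apply_missingness(do.call(rbind, rows), cfg)
  n_obs_cor <- sum(studies$obs_x & studies$obs_m) +
    sum(studies$obs_x & studies$obs_y) + sum(studies$obs_m & studies$obs_y)
  structure(
    list(studies = studies, config = cfg, seed = as.integer(seed),
         missing_rate = 1 - n_obs_cor / (3 * cfg$k)),
    class = "meta_dataset"
  )
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat(sprintf(
    "Meta-analytic dataset: %d studies (seed %d), %.0f%% of correlations missing\n",
    nrow(x$studies), x$seed, 100 * x$missing_rate
  ))
  print(x$config)
  invisible(x)
}

#' Read and write per-study summary tables
#'
#' CSV with one row per study and empty fields (never sentinel numbers) for
#' statistics masked by a removed variable.
#'
#' @param dataset a `"meta_dataset"` (for writing).
#' @param path file path.
#' @return `write_study_table` returns `path` invisibly; `read_study_table`
#'   returns the study `data.frame`.
#' @export
write_study_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "meta_dataset"))
  utils::write.csv(dataset$studies, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  utils::read.csv(path, na.strings = "")
}
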