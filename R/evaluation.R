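#' Relative percentage bias
#'
#' `100 * (estimate - reference) / reference`.  Conventional acceptability
#' bounds are 5% for correlations and path coefficients and 10.25% for the
#' indirect effect (a product of two paths, since 1.05 * 1.05 = 1.1025).
#'
#' @param estimate mean estimate across replications (vectorized).
#' @param reference true (population) value; zero references yield `NA` with
#'   a warning, since relative bias is undefined there.
#' @return relative bias in percent.
#' @examples
#' relative_bias(0.105, 0.100)  # 5
#' @export
relative_bias <- function(estimate, reference) {
  out <- 100 * (estimate - reference) / reference
  if (any(reference == 0, na.rm = TRUE)) {
    warning("relative bias undefined for zero reference; returning NA",
            call. = FALSE)
    out[reference == 0] <- NA_real_
  }
  out
}

#' Run the Monte Carlo evaluation of one condition
#'
#' For each replication, one meta-analytic dataset is simulated and every
#' requested conversion method is fitted to that same dataset (so method
#' contrasts are paired).  Per-replication seeds are derived from the master
#' seed, the condition id and the replication index, so results do not depend
#' on execution order.
#'
#' @param cfg a [condition_config()].
#' @param methods character vector of conversion methods (see
#'   [conversion_methods()]).
#' @param reps number of replications.
#' @param seed master seed.
#' @param use_study_prevalence,adjust,target_prevalence passed to
#'   [fit_masem()] (pi-based methods receive the condition's prevalence).
#' @return an object of class `"condition_run"`: a list with `results` (one
#'   row per condition x method x replication, with pooled correlations,
#'   tau^2, path coefficients, indirect effect and convergence status) and
#'   `summary` (see [summarize_condition()]).
#' @examples
#' \donttest{
#' run <- run_condition(load_condition(4), "equal-groups", reps = 5, seed = 1)
#' run$summary
#' }
#' @export
run_condition <- function(cfg, methods, reps, seed,
                          use_study_prevalence = FALSE,
                          adjust = FALSE, target_prevalence = NULL) {
  stopifnot(inherits(cfg, "condition_config"), reps >= 1)
  methods <- vapply(methods, match.arg, "", choices = conversion_methods())
  rows <- vector("list", reps * length(methods))
  ri <- 0L
  for (rep_i in seq_len(reps)) {
    ds <- simulate_meta_dataset(
      cfg, derive_seed(seed, max(cfg$condition, 0L, na.rm = TRUE), rep_i)
    )
    for (meth in methods) {
      fit <- tryCatch(
        fit_masem(ds, meth, prevalence = cfg$prevalence,
                  use_study_prevalence = use_study_prevalence,
                  adjust = adjust, target_prevalence = target_prevalence),
        error = function(e) NULL
      )
      ri <- ri + 1L
      rows[[ri]] <- if (is.null(fit)) {
        data.frame(condition = cfg$condition, method = meth,
                   replication = rep_i,
                   rho_pb_mx = NA_real_, rho_pb_yx = NA_real_,
                   rho_ym = NA_real_,
                   tau2_mx = NA_real_, tau2_yx = NA_real_, tau2_ym = NA_real_,
                   beta_mx = NA_real_, beta_yx = NA_real_, beta_ym = NA_real_,
                   indirect = NA_real_, converged = FALSE, n_retries = NA_integer_)
      } else {
        data.frame(condition = cfg$condition, method = meth,
                   replication = rep_i,
                   rho_pb_mx = fit$pooled_r[[1]], rho_pb_yx = fit$pooled_r[[2]],
                   rho_ym = fit$pooled_r[[3]],
                   tau2_mx = fit$tau2[[1]], tau2_yx = fit$tau2[[2]],
                   tau2_ym = fit$tau2[[3]],
                   beta_mx = if (is.null(fit$beta)) NA_real_ else fit$beta[["beta_mx"]],
                   beta_yx = if (is.null(fit$beta)) NA_real_ else fit$beta[["beta_yx"]],
                   beta_ym = if (is.null(fit$beta)) NA_real_ else fit$beta[["beta_ym"]],
                   indirect = fit$indirect %||% NA_real_,
                   converged = fit$converged, n_retries = fit$n_retries)
      }
    }
  }
  results <- do.call(rbind, rows)
  structure(
    list(results = results, config = cfg, seed = seed,
         summary = summarize_condition(results, cfg)),
    class = "condition_run"
  )
}

#' Summarize replication results of one condition
#'
#' Means of the model-implied (= pooled, the model is saturated) correlations,
#' path coefficients and indirect effect across converged replications, per
#' conversion method, together with the relative bias against two references:
#' the population values at the condition's prevalence, and the
#' maximum-absolute values attained at prevalence .50.  Flags mark relative
#' bias beyond 5% (correlations, paths) and 10.25% (indirect effect).
#'
#' @param results the `results` data frame of a [run_condition()] output.
#' @param cfg the [condition_config()] that produced it.
#' @return a `data.frame` with one row per method.
#' @export
summarize_condition <- function(results, cfg) {
  pop <- population_table(cfg$prevalence, cfg$delta_m, cfg$delta_y,
                          cfg$rho_within)
  ref_max <- population_table(0.50, cfg$delta_m, cfg$delta_y, cfg$rho_within)
  pars <- c("rho_pb_mx", "rho_pb_yx", "rho_ym",
            "beta_mx", "beta_yx", "beta_ym", "indirect")
  rows <- lapply(unique(results$method), function(meth) {
    sub <- results[results$method == meth & results$converged, , drop = FALSE]
    means <- colMeans(sub[pars], na.rm = TRUE)
    out <- data.frame(condition = cfg$condition, method = meth,
                      reps = sum(results$method == meth),
                      converged = nrow(sub),
                      convergence_rate = nrow(sub) / sum(results$method == meth))
    for (p in pars) out[[paste0("mean_", p)]] <- means[[p]]
    for (p in pars) {
      out[[paste0("rb_pop_", p)]] <- relative_bias(means[[p]], pop[[p]][1])
      out[[paste0("rb_max_", p)]] <- relative_bias(means[[p]], ref_max[[p]][1])
    }
    rb_cols <- paste0("rb_pop_", c("rho_pb_mx", "rho_pb_yx", "rho_ym",
                                   "beta_mx", "beta_yx", "beta_ym"))
    out$rb_pop_flag <- any(abs(unlist(out[rb_cols])) > 5, na.rm = TRUE) ||
      isTRUE(abs(out$rb_pop_indirect) > 10.25)
    out
  })
  do.call(rbind, rows)
}

#' @export
print.condition_run <- function(x, digits = 3, ...) {
  cat(sprintf("Monte Carlo run: condition %s, %d replications, seed %d\n",
              x$config$condition, max(x$results$replication), x$seed))
  cols <- c("method", "convergence_rate",
            paste0("mean_", c("rho_pb_mx", "rho_pb_yx", "rho_ym", "indirect")))
  y <- x$summary[cols]
  y[-1] <- lapply(y[-1], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Wide correlation table across conditions
#'
#' Mean model-implied correlations with one row per conversion method and one
#' column block per condition (prevalence), mirroring how simulation results
#' for a sampling plan are usually tabulated.
#'
#' @param runs a list of `"condition_run"` objects.
#' @param digits rounding for display values.
#' @return a `data.frame`; the first row carries the population values at
#'   each condition's prevalence.
#' @export
correlation_table <- function(runs, digits = 3) {
  stopifnot(length(runs) > 0)
  methods <- unique(runs[[1]]$summary$method)
  out <- data.frame(method = c("population", methods))
  for (run in runs) {
    cfg <- run$config
    pop <- population_table(cfg$prevalence, cfg$delta_m, cfg$delta_y,
                            cfg$rho_within)
    for (p in c("rho_pb_mx", "rho_pb_yx", "rho_ym")) {
      col <- sprintf("pi%.2f_%s", cfg$prevalence, p)
      est <- run$summary[[paste0("mean_", p)]][
        match(methods, run$summary$method)]
      out[[col]] <- round(c(pop[[p]][1], est), digits)
    }
  }
  out
}

#' Write a condition run to disk with a reproducibility manifest
#'
#' Writes per-replication results and the method summary as CSV, plus a JSON
#' manifest (condition, seed, package version, convergence counts) sufficient
#' to reproduce the run exactly.
#'
#' @param run a `"condition_run"`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "condition_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$results, file.path(dir, "results.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(run$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE, na = "")
  manifest <- list(
    condition = run$config$condition,
    sampling_plan = run$config$sampling_plan,
    prevalence = run$config$prevalence,
    seed = run$seed,
    replications = max(run$results$replication),
    methods = unique(run$results$method),
    converged = sum(run$results$converged),
    package_version = as.character(utils::packageVersion("pbmasem")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    dput(manifest, file.path(dir, "manifest.R"))
  }
  invisible(dir)
}
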