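#' Define a simulation condition
#'
#' A condition fixes everything about one cell of the Monte Carlo design:
#' sampling plan, prevalence, target sample size(s), number of primary
#' studies, the population effect sizes and their between-study variances, and
#' the number of studies with a randomly removed variable.
#'
#' @param condition integer condition id (1-21 for the shipped grid, `NA` for
#'   ad-hoc conditions).
#' @param sampling_plan one of `"simple"` (simple random sampling with a
#'   binomial group split at the study's prevalence), `"stratified"`
#'   (per-group uniform draws around `target_n / 2`), `"unbalanced"`
#'   (stratified with the sample proportion drawn from U(.20, .60)), or
#'   `"mixed"` (thirds: simple/1000, stratified/26, stratified/128).
#' @param prevalence population proportion of X = 1, in (0, 1).
#' @param target_n target total sample size of a primary study (ignored for
#'   `"mixed"`; leave `NULL` when a range is given).
#' @param target_n_min,target_n_max bounds of a per-study discrete uniform
#'   draw of the target sample size (varying-size conditions).
#' @param k number of primary studies per meta-analytic dataset.
#' @param delta_m,delta_y mean population standardized mean differences.
#' @param rho_within mean within-group correlation of M and Y.
#' @param tau2_delta_m,tau2_delta_y,tau2_rho diagonal between-study variances
#'   of the study-level parameters.
#' @param missing_studies number of studies per dataset that lose one
#'   randomly chosen variable.
#' @param subpop_prevalence if `TRUE`, each study draws its own subpopulation
#'   prevalence from a uniform distribution spanning +/-30% around
#'   `prevalence`.
#' @return an object of class `"condition_config"`.
#' @seealso [load_condition()] for the 21 shipped conditions.
#' @export
condition_config <- function(condition = NA_integer_,
                             sampling_plan = c("simple", "stratified",
                                               "unbalanced", "mixed"),
                             prevalence,
                             target_n = NULL,
                             target_n_min = NULL, target_n_max = NULL,
                             k = 30,
                             delta_m = 0.80, delta_y = 0.50, rho_within = 0.40,
                             tau2_delta_m = 0.10, tau2_delta_y = 0.10,
                             tau2_rho = 0.02,
                             missing_studies = 12,
                             subpop_prevalence = FALSE) {
  sampling_plan <- match.arg(sampling_plan)
  check_proportion(prevalence, "prevalence")
  if (k < 1) stop("'k' must be positive", call. = FALSE)
  if (missing_studies < 0 || missing_studies > k) {
    stop("'missing_studies' must lie in [0, k]", call. = FALSE)
  }
  if (any(c(tau2_delta_m, tau2_delta_y, tau2_rho) < 0)) {
    stop("between-study variances must be non-negative", call. = FALSE)
  }
  has_range <- !is.null(target_n_min) && !is.null(target_n_max)
  if (has_range && target_n_min > target_n_max) {
    stop("'target_n_min' must not exceed 'target_n_max'", call. = FALSE)
  }
  if (sampling_plan != "mixed" && is.null(target_n) && !has_range) {
    stop("supply 'target_n' or a target_n_min/target_n_max range", call. = FALSE)
  }
  if (!is.null(target_n) && target_n < 8) {
    stop("'target_n' is too small to yield two groups of size >= 2", call. = FALSE)
  }
  structure(
    list(condition = as.integer(condition), sampling_plan = sampling_plan,
         prevalence = prevalence, target_n = target_n,
         target_n_min = target_n_min, target_n_max = target_n_max,
         k = as.integer(k),
         delta_m = delta_m, delta_y = delta_y, rho_within = rho_within,
         tau2_delta_m = tau2_delta_m, tau2_delta_y = tau2_delta_y,
         tau2_rho = tau2_rho,
         missing_studies = as.integer(missing_studies),
         subpop_prevalence = isTRUE(subpop_prevalence)),
    class = "condition_config"
  )
}

#' @export
print.condition_config <- function(x, ...) {
  n_lab <- if (!is.null(x$target_n)) x$target_n
    else if (!is.null(x$target_n_min)) sprintf("%d-%d", x$target_n_min, x$target_n_max)
    else "mixed (1000/26/128)"
  cat(sprintf(
    "Condition %s: %s sampling, prevalence %g, target N %s, k = %d, %d studies with a removed variable%s\n",
    ifelse(is.na(x$condition), "(ad hoc)", x$condition), x$sampling_plan,
    x$prevalence, n_lab, x$k, x$missing_studies,
    if (x$subpop_prevalence) ", subpopulation prevalences" else ""
  ))
  invisible(x)
}

#' Load a shipped or user-supplied simulation condition
#'
#' Conditions 1-21 are shipped as plain-text DCF fixtures: 1-3 simple random
#' sampling (N = 1000) at prevalences .02/.10/.50; 4-6 and 7-9 1:1 stratified
#' sampling at target N 26 and 128; 10-12 stratified with per-study target N
#' drawn from 26-600; 13-15 unbalanced stratified (N = 128, sample proportion
#' from U(.20, .60)); 16-18 mixed plans; 19-21 repeat 1-3 with study-level
#' subpopulation prevalences spanning +/-30% around the population value.
#'
#' @param x an integer id in 1-21, or the path to a DCF condition file.
#' @return a [condition_config()].
#' @examples
#' load_condition(1)
#' @export
load_condition <- function(x) {
  if (is.numeric(x) && length(x) == 1 && !is.na(x) && x == round(x)) {
    path <- system.file("extdata", "conditions",
                        sprintf("condition-%02d.dcf", as.integer(x)),
                        package = "pbmasem")
    if (!nzchar(path)) {
      stop(sprintf("no shipped condition with id %d (valid ids: 1-21)", x),
           call. = FALSE)
    }
  } else if (is.character(x) && length(x) == 1) {
    path <- x
    if (!file.exists(path)) stop("condition file not found: ", path, call. = FALSE)
  } else {
    stop("'x' must be a condition id (1-21) or a file path", call. = FALSE)
  }
  d <- as.list(read.dcf(path)[1, ])
  num <- function(key) if (is.null(d[[key]]) || !nzchar(d[[key]])) NULL
    else as.numeric(d[[key]])
  condition_config(
    condition = if (is.null(num("condition"))) NA_integer_ else num("condition"),
    sampling_plan = d[["sampling_plan"]],
    prevalence = num("prevalence"),
    target_n = num("target_n"),
    target_n_min = num("target_n_min"), target_n_max = num("target_n_max"),
    k = num("k"),
    delta_m = num("delta_m"), delta_y = num("delta_y"),
    rho_within = num("rho_within"),
    tau2_delta_m = num("tau2_delta_m"), tau2_delta_y = num("tau2_delta_y"),
    tau2_rho = num("tau2_rho"),
    missing_studies = num("missing_studies"),
    subpop_prevalence = identical(tolower(d[["subpop_prevalence"]]), "yes")
  )
}

#' Write a condition to a DCF file
#'
#' Serializes a [condition_config()] in the same plain-text format as the
#' shipped fixtures, so `load_condition(write_condition(cfg, path))` round
#' trips.
#'
#' @param cfg a [condition_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_condition <- function(cfg, path) {
  stopifnot(inherits(cfg, "condition_config"))
  fields <- c(
    condition = ifelse(is.na(cfg$condition), "", cfg$condition),
    sampling_plan = cfg$sampling_plan,
    prevalence = cfg$prevalence,
    target_n = if (is.null(cfg$target_n)) "" else cfg$target_n,
    target_n_min = if (is.null(cfg$target_n_min)) "" else cfg$target_n_min,
    target_n_max = if (is.null(cfg$target_n_max)) "" else cfg$target_n_max,
    k = cfg$k,
    delta_m = cfg$delta_m, delta_y = cfg$delta_y, rho_within = cfg$rho_within,
    tau2_delta_m = cfg$tau2_delta_m, tau2_delta_y = cfg$tau2_delta_y,
    tau2_rho = cfg$tau2_rho,
    missing_studies = cfg$missing_studies,
    subpop_prevalence = ifelse(cfg$subpop_prevalence, "yes", "no")
  )
  write.dcf(matrix(fields, 1, dimnames = list(NULL, names(fields))), path)
  invisible(path)
}

#' Overview of the shipped simulation conditions
#'
#' @return a `data.frame` with one row per shipped condition (ids 1-21).
#' @export
conditions <- function() {
  rows <- lapply(1:21, function(i) {
    cfg <- load_condition(i)
    data.frame(
      condition = cfg$condition, sampling_plan = cfg$sampling_plan,
      prevalence = cfg$prevalence,
      target_n = if (!is.null(cfg$target_n)) as.character(cfg$target_n)
        else if (!is.null(cfg$target_n_min))
          sprintf("%d-%d", cfg$target_n_min, cfg$target_n_max)
        else "1000/26/128",
      k = cfg$k, missing_studies = cfg$missing_studies,
      subpop_prevalence = cfg$subpop_prevalence
    )
  })
  do.call(rbind, rows)
}
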