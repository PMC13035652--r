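#' Specify the two-group mixture population of the mediation model
#'
#' Describes the population from which primary studies sample: a dichotomous
#' variable X (prevalence of the category coded 1 equal to `prevalence`)
#' shifting the means of two jointly normal continuous variables, the mediator
#' M and the outcome Y, with common within-group SDs and a common within-group
#' correlation.  The defaults are the mediation system used throughout the
#' simulation harness: delta_M = 0.80, delta_Y = 0.50, rho = .40 on unit
#' within-group SDs.
#'
#' @param prevalence population proportion of X = 1, strictly in (0, 1).
#' @param mu_m1,mu_m0 group means of M (X = 1 and X = 0).
#' @param mu_y1,mu_y0 group means of Y.
#' @param sigma_m,sigma_y common within-group standard deviations (positive).
#' @param rho_within within-group correlation of M and Y, equal across groups,
#'   strictly in (-1, 1).
#' @return an object of class `"population_spec"`.
#' @examples
#' spec <- population_spec(0.02)
#' total_correlation(spec)
#' @export
population_spec <- function(prevalence, mu_m1 = 0.40, mu_m0 = -0.40,
                            mu_y1 = 0.25, mu_y0 = -0.25,
                            sigma_m = 1, sigma_y = 1, rho_within = 0.40) {
  check_proportion(prevalence, "prevalence")
  stopifnot(is.numeric(mu_m1), is.numeric(mu_m0),
            is.numeric(mu_y1), is.numeric(mu_y0))
  if (sigma_m <= 0 || sigma_y <= 0) {
    stop("within-group standard deviations must be positive", call. = FALSE)
  }
  if (abs(rho_within) >= 1) {
    stop("'rho_within' must lie strictly in (-1, 1)", call. = FALSE)
  }
  structure(
    list(prevalence = prevalence,
         mu_m1 = mu_m1, mu_m0 = mu_m0, mu_y1 = mu_y1, mu_y0 = mu_y0,
         sigma_m = sigma_m, sigma_y = sigma_y, rho_within = rho_within),
    class = "population_spec"
  )
}

#' Mixture means and variances of the continuous variables
#'
#' Total (merged-population) means and variances of M and Y when the two
#' groups are mixed with weights `prevalence` and `1 - prevalence`.  The total
#' variance is the within-group variance plus the between-group spread of the
#' group means around the total mean.
#'
#' @param spec a [population_spec()].
#' @return a list with elements `mu_m`, `mu_y`, `var_m`, `var_y`.
#' @examples
#' mixture_moments(population_spec(0.02))  # mu_m = -0.384, var_m = 1.012544
#' @export
mixture_moments <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  pi <- spec$prevalence
  mu_m <- pi * spec$mu_m1 + (1 - pi) * spec$mu_m0
  mu_y <- pi * spec$mu_y1 + (1 - pi) * spec$mu_y0
  var_m <- pi * (spec$sigma_m^2 + (spec$mu_m1 - mu_m)^2) +
    (1 - pi) * (spec$sigma_m^2 + (spec$mu_m0 - mu_m)^2)
  var_y <- pi * (spec$sigma_y^2 + (spec$mu_y1 - mu_y)^2) +
    (1 - pi) * (spec$sigma_y^2 + (spec$mu_y0 - mu_y)^2)
  list(mu_m = mu_m, mu_y = mu_y, var_m = var_m, var_y = var_y)
}

#' Total correlation between the continuous variables in the mixture
#'
#' The Pearson correlation of M and Y in the merged population.  The total
#' covariance mixes the within-group covariance `rho sigma_m sigma_y` with the
#' cross-product of the group mean shifts, so the total correlation depends on
#' the prevalence even though the within-group correlation does not.
#'
#' @inheritParams mixture_moments
#' @return the total correlation `rho_YM`.
#' @examples
#' total_correlation(population_spec(0.02))  # .4043165
#' @export
total_correlation <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  pi <- spec$prevalence
  mm <- mixture_moments(spec)
  cov_w <- spec$rho_within * spec$sigma_m * spec$sigma_y
  cov_t <- pi * (cov_w + (spec$mu_m1 - mm$mu_m) * (spec$mu_y1 - mm$mu_y)) +
    (1 - pi) * (cov_w + (spec$mu_m0 - mm$mu_m) * (spec$mu_y0 - mm$mu_y))
  cov_t / sqrt(mm$var_m * mm$var_y)
}

#' Population point-biserial correlations of X with M and with Y
#'
#' Applies the population conversion [rpb_population()] to the standardized
#' group mean differences implied by the spec, at the spec's prevalence.
#'
#' @inheritParams mixture_moments
#' @return named vector `c(rho_pb_mx, rho_pb_yx)`.
#' @examples
#' population_point_biserials(population_spec(0.02))
#' @export
population_point_biserials <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  delta_m <- (spec$mu_m1 - spec$mu_m0) / spec$sigma_m
  delta_y <- (spec$mu_y1 - spec$mu_y0) / spec$sigma_y
  c(rho_pb_mx = rpb_population(delta_m, spec$prevalence),
    rho_pb_yx = rpb_population(delta_y, spec$prevalence))
}

#' Path coefficients of the saturated three-variable mediation model
#'
#' Standardized path coefficients of the mediation model X -> M -> Y with a
#' direct path X -> Y, computed from the three correlations.  Because the
#' model is saturated these are exactly the OLS regression coefficients:
#' `beta_mx = r_pb_mx`, and for the regression of Y on X and M,
#' `beta_yx = (r_pb_mx r_ym - r_pb_yx) / (r_pb_mx^2 - 1)` and
#' `beta_ym = (r_pb_mx r_pb_yx - r_ym) / (r_pb_mx^2 - 1)`.
#'
#' @param r_pb_mx,r_pb_yx point-biserial correlations of X with M and with Y.
#' @param r_ym correlation between M and Y.
#' @return named vector `c(beta_mx, beta_yx, beta_ym)`.
#' @examples
#' path_coefficients(.1113041, .06982913, .4043165)
#' @export
path_coefficients <- function(r_pb_mx, r_pb_yx, r_ym) {
  r <- c(r_pb_mx, r_pb_yx, r_ym)
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    if (any(abs(r_pb_mx) >= 1)) {
      stop("|r_pb_mx| >= 1: regression of Y on X and M is singular", call. = FALSE)
    }
    stop("correlations must be finite and strictly inside (-1, 1)", call. = FALSE)
  }
  R <- matrix(c(1, r_pb_mx, r_pb_yx,
                r_pb_mx, 1, r_ym,
                r_pb_yx, r_ym, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("the implied 3x3 correlation matrix is not positive definite",
         call. = FALSE)
  }
  denom <- r_pb_mx^2 - 1
  c(beta_mx = r_pb_mx,
    beta_yx = (r_pb_mx * r_ym - r_pb_yx) / denom,
    beta_ym = (r_pb_mx * r_pb_yx - r_ym) / denom)
}

#' Indirect effect of X on Y through M
#'
#' @param beta_mx path coefficient of X on M.
#' @param beta_ym path coefficient of M on Y.
#' @return the product `beta_mx * beta_ym`.
#' @examples
#' indirect_effect(.1113041, .4015185)  # .04469064
#' @export
indirect_effect <- function(beta_mx, beta_ym) {
  beta_mx * beta_ym
}

#' All population values implied by a mixture spec
#'
#' Convenience wrapper computing mixture moments, the total correlation, the
#' population point-biserial correlations, the path coefficients of the
#' saturated mediation model, and the indirect effect.
#'
#' @inheritParams mixture_moments
#' @return an object of class `"population_values"`: a list with elements
#'   `prevalence`, `moments`, `rho_pb_mx`, `rho_pb_yx`, `rho_ym`, `beta_mx`,
#'   `beta_yx`, `beta_ym`, `indirect`.
#' @examples
#' population_values(population_spec(0.02))
#' @export
population_values <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  mm <- mixture_moments(spec)
  rho_ym <- total_correlation(spec)
  pb <- population_point_biserials(spec)
  beta <- path_coefficients(pb[["rho_pb_mx"]], pb[["rho_pb_yx"]], rho_ym)
  structure(
    list(prevalence = spec$prevalence, moments = mm,
         rho_pb_mx = pb[["rho_pb_mx"]], rho_pb_yx = pb[["rho_pb_yx"]],
         rho_ym = rho_ym,
         beta_mx = beta[["beta_mx"]], beta_yx = beta[["beta_yx"]],
         beta_ym = beta[["beta_ym"]],
         indirect = indirect_effect(beta[["beta_mx"]], beta[["beta_ym"]])),
    class = "population_values"
  )
}

#' @export
print.population_values <- function(x, digits = 7, ...) {
  cat("Population values of the three-variable mediation mixture\n")
  cat(sprintf("  prevalence: %g\n", x$prevalence))
  v <- unlist(x[c("rho_pb_mx", "rho_pb_yx", "rho_ym",
                  "beta_mx", "beta_yx", "beta_ym", "indirect")])
  print(round(v, digits))
  invisible(x)
}

#' Population values over a grid of prevalences
#'
#' One row per prevalence with the population correlations, path coefficients
#' and indirect effect of the mediation mixture.  Values are stored at full
#' precision; the print method rounds for display (3 decimals by default).
#'
#' @param prevalences numeric vector of prevalences in (0, 1).
#' @param delta_m,delta_y population standardized mean differences of M and Y.
#' @param rho_within within-group correlation of M and Y.
#' @return a `data.frame` of class `"population_table"` with columns
#'   `prevalence`, `rho_pb_mx`, `rho_pb_yx`, `rho_ym`, `beta_mx`, `beta_yx`,
#'   `beta_ym`, `indirect`.
#' @examples
#' population_table(c(0.02, 0.10, 0.50))
#' @export
population_table <- function(prevalences, delta_m = 0.80, delta_y = 0.50,
                             rho_within = 0.40) {
  check_proportion(prevalences, "prevalences")
  rows <- lapply(prevalences, function(pi) {
    pv <- population_values(population_spec(
      pi,
      mu_m1 = delta_m / 2, mu_m0 = -delta_m / 2,
      mu_y1 = delta_y / 2, mu_y0 = -delta_y / 2,
      rho_within = rho_within
    ))
    data.frame(prevalence = pi,
               rho_pb_mx = pv$rho_pb_mx, rho_pb_yx = pv$rho_pb_yx,
               rho_ym = pv$rho_ym,
               beta_mx = pv$beta_mx, beta_yx = pv$beta_yx,
               beta_ym = pv$beta_ym, indirect = pv$indirect)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("population_table", "data.frame")
  out
}

#' @export
print.population_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
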