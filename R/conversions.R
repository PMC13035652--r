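#' Pooled standard deviation of two groups
#'
#' @param sd1,sd0 positive group standard deviations (target group coded 1,
#'   control group coded 0).
#' @param n1,n0 group sample sizes; `n1 + n0` must exceed 2.
#' @return the pooled standard deviation
#'   `sqrt(((n1-1) sd1^2 + (n0-1) sd0^2) / (n1+n0-2))`, vectorized over its
#'   arguments.
#' @examples
#' pooled_sd(1.2, 0.8, 10, 10)
#' @seealso [cohens_d()]
#' @export
pooled_sd <- function(sd1, sd0, n1, n0) {
  if (!is.numeric(sd1) || !is.numeric(sd0) || any(!is.finite(c(sd1, sd0)))) {
    stop("group standard deviations must be finite numeric", call. = FALSE)
  }
  if (any(sd1 <= 0) || any(sd0 <= 0)) {
    stop("group standard deviations must be positive", call. = FALSE)
  }
  if (any(n1 + n0 <= 2)) {
    stop("total sample size n1 + n0 must exceed 2", call. = FALSE)
  }
  sqrt(((n1 - 1) * sd1^2 + (n0 - 1) * sd0^2) / (n1 + n0 - 2))
}

#' Cohen's d from group summary statistics
#'
#' Standardized mean difference of the group coded 1 minus the group coded 0,
#' divided by the pooled standard deviation.  Unlike the point-biserial
#' correlation, d does not depend on the group size distribution.
#'
#' @param mean1,mean0 group means.
#' @inheritParams pooled_sd
#' @return Cohen's d, vectorized.
#' @examples
#' cohens_d(0.40, -0.40, 1, 1, 50, 50)  # 0.80
#' @export
cohens_d <- function(mean1, mean0, sd1, sd0, n1, n0) {
  sp <- pooled_sd(sd1, sd0, n1, n0)
  if (any(sp == 0)) {
    stop("pooled standard deviation is zero; Cohen's d is undefined", call. = FALSE)
  }
  (mean1 - mean0) / sp
}

#' Conversion method labels
#'
#' The six supported d-to-point-biserial conversions:
#' `"p-general"` (sample-proportion-based, exact t-based form),
#' `"pi-general"` (prevalence-based general form),
#' `"equal-groups"` (p = .50 substituted in the general form),
#' `"p-large"`, `"pi-large"`, `"ls-equal-groups"` (the corresponding
#' large-sample forms).
#'
#' @return character vector of the six method labels.
#' @export
conversion_methods <- function() {
  c("p-general", "pi-general", "equal-groups",
    "p-large", "pi-large", "ls-equal-groups")
}

#' Convert Cohen's d to a point-biserial correlation
#'
#' Implements the six conversions from a standardized mean difference d to the
#' point-biserial correlation r_pb.  Writing N = n1 + n0, p = n1/N and pi for
#' the population prevalence of the category coded 1, the denominators under
#' the radical `sqrt(d^2 + a)` are
#'
#' * `p-general`:       a = (N^2 - 2N) / (n1 n0)
#' * `pi-general`:      a = 1/(pi (1-pi)) - 2/(pi (1-pi) N)
#' * `equal-groups`:    a = 4 - 8/N
#' * `p-large`:         a = N^2 / (n1 n0)
#' * `pi-large`:        a = 1/(pi (1-pi))
#' * `ls-equal-groups`: a = 4
#'
#' The p-based methods estimate the point-biserial correlation under the
#' sample's own group split (appropriate under simple random sampling); the
#' prevalence-based methods re-express the effect under a stated population
#' prevalence; the equal-groups variants target the maximum absolute value
#' attained at a 50/50 split.
#'
#' @param d Cohen's d (vectorized).
#' @param method one of [conversion_methods()].
#' @param n1,n0 group sample sizes, required by the p-based, equal-groups and
#'   pi-general methods (the latter needs the total N).
#' @param prevalence population proportion of the category coded 1, strictly
#'   in (0, 1); required by the pi-based methods.  Supply proportions, never
#'   percentages.
#' @return the point-biserial correlation(s), strictly inside (-1, 1).
#' @examples
#' d_to_rpb(0.80, "pi-large", prevalence = 0.02)   # .1113041
#' d_to_rpb(0.80, "equal-groups", n1 = 13, n0 = 13)
#' @export
d_to_rpb <- function(d, method = conversion_methods(), n1 = NULL, n0 = NULL,
                     prevalence = NULL) {
  method <- match.arg(method)
  if (!is.numeric(d) || any(!is.finite(d))) {
    stop("'d' must be finite numeric", call. = FALSE)
  }
  needs_n <- method %in% c("p-general", "pi-general", "equal-groups", "p-large")
  needs_pi <- method %in% c("pi-general", "pi-large")
  if (needs_n) {
    if (is.null(n1) || is.null(n0)) {
      stop(sprintf("method '%s' requires group sizes n1 and n0", method),
           call. = FALSE)
    }
    if (any(n1 < 1) || any(n0 < 1)) {
      stop("group sizes must be positive", call. = FALSE)
    }
  }
  if (needs_pi) {
    if (is.null(prevalence)) {
      stop(sprintf("method '%s' requires a prevalence", method), call. = FALSE)
    }
    check_proportion(prevalence, "prevalence")
  }
  N <- if (needs_n) n1 + n0 else NULL
  a <- switch(method,
    "p-general"       = (N^2 - 2 * N) / (n1 * n0),
    "pi-general"      = 1 / (prevalence * (1 - prevalence)) -
                        2 / (prevalence * (1 - prevalence) * N),
    "equal-groups"    = 4 - 8 / N,
    "p-large"         = N^2 / (n1 * n0),
    "pi-large"        = 1 / (prevalence * (1 - prevalence)),
    "ls-equal-groups" = 4
  )
  if (any(a <= 0)) {
    stop("radicand term is non-positive (total sample size too small for this method)",
         call. = FALSE)
  }
  d / sqrt(d^2 + a)
}

#' Population point-biserial correlation from delta and prevalence
#'
#' The population-level relation `rho_pb = delta / sqrt(delta^2 +
#' 1/(pi (1-pi)))` between a standardized mean difference delta and the
#' point-biserial correlation at prevalence pi.  This is the large-sample
#' prevalence-based conversion applied at the population level, and is the
#' source of base-rate sensitivity: for fixed delta, |rho_pb| is maximized at
#' pi = .50 and shrinks towards 0 as pi approaches 0 or 1.
#'
#' @param delta population standardized mean difference.
#' @param prevalence population proportion of the category coded 1, in (0, 1).
#' @return the population point-biserial correlation, vectorized.
#' @examples
#' rpb_population(0.50, 0.02)  # .06982913
#' rpb_population(0.50, 0.50)  # maximum over prevalence
#' @export
rpb_population <- function(delta, prevalence) {
  d_to_rpb(delta, "pi-large", prevalence = prevalence)
}
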