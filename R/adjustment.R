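#' Within-group correlation from a reported total correlation
#'
#' Back-transforms a total (merged-sample) Pearson correlation between the two
#' continuous variables to the common within-group correlation, given the two
#' standardized mean differences and the sample proportion p under which the
#' total correlation was observed:
#' `r_W = r_YM sqrt(1 + d_M^2 p(1-p)) sqrt(1 + d_Y^2 p(1-p)) - d_M d_Y p(1-p)`.
#' Assumes equal within-group correlations across the two groups.
#'
#' @param r_ym reported total correlation, in (-1, 1).
#' @param d_m,d_y reported Cohen's d of the mediator and the outcome.
#' @param p sample proportion of the group coded 1 under which `r_ym` was
#'   observed, in (0, 1).
#' @return the within-group correlation `r_W` (vectorized).  If any resulting
#'   value falls outside (-1, 1) — which signals mutually inconsistent input
#'   summaries — a warning is raised and the attribute `"inadmissible"` marks
#'   the offending elements.
#' @examples
#' r_within(0.450, 0.80, 0.50, 0.50)
#' @export
r_within <- function(r_ym, d_m, d_y, p) {
  check_proportion(p, "p")
  if (any(abs(r_ym) >= 1)) {
    stop("'r_ym' must lie strictly in (-1, 1)", call. = FALSE)
  }
  q <- p * (1 - p)
  rw <- r_ym * sqrt(1 + d_m^2 * q) * sqrt(1 + d_y^2 * q) - d_m * d_y * q
  bad <- abs(rw) >= 1
  if (any(bad)) {
    warning("back-transformed within-group correlation outside (-1, 1); ",
            "the reported summaries are mutually inconsistent", call. = FALSE)
    attr(rw, "inadmissible") <- bad
  }
  rw
}

#' Total correlation implied at a target prevalence
#'
#' Forward transformation: re-expresses a within-group correlation `r_W` as
#' the total correlation of the two continuous variables when the groups are
#' mixed at a target prevalence pi, with the group mean shifts given by the
#' Cohen's d values (unit within-group SDs):
#' \deqn{r^*_{YM} = \frac{\pi(r_W + (d_M - \pi d_M)(d_Y - \pi d_Y)) +
#'   (1-\pi)(r_W + (-\pi d_M)(-\pi d_Y))}
#'   {\sqrt{1 + d_M^2 \pi(1-\pi)} \sqrt{1 + d_Y^2 \pi(1-\pi)}}}
#'
#' @param r_w within-group correlation, in (-1, 1).
#' @param d_m,d_y Cohen's d of the mediator and the outcome.
#' @param prevalence target prevalence pi, in (0, 1).
#' @return the adjusted total correlation (vectorized).
#' @examples
#' r_adjusted(r_within(0.450, 0.80, 0.50, 0.50), 0.80, 0.50, 0.02)  # ~ .404
#' @export
r_adjusted <- function(r_w, d_m, d_y, prevalence) {
  check_proportion(prevalence, "prevalence")
  if (any(abs(r_w) >= 1)) {
    stop("'r_w' must lie strictly in (-1, 1)", call. = FALSE)
  }
  pi <- prevalence
  num <- pi * (r_w + (d_m - pi * d_m) * (d_y - pi * d_y)) +
    (1 - pi) * (r_w + (0 - pi * d_m) * (0 - pi * d_y))
  num / (sqrt(1 + d_m^2 * pi * (1 - pi)) * sqrt(1 + d_y^2 * pi * (1 - pi)))
}

#' Adjust a reported total correlation to a target prevalence
#'
#' Composition of [r_within()] and [r_adjusted()]: a total correlation
#' observed under sample proportion `p` is first back-transformed to the
#' within-group correlation and then re-expressed under the target prevalence.
#' With `prevalence == p` the round trip is the identity.  This is the
#' adjustment a meta-analyst needs when primary studies use stratified
#' sampling (so p is near .50 regardless of the prevalence) but inference
#' targets the population: the d-to-r_pb conversion corrects the correlations
#' involving the dichotomous variable, and this adjustment corrects the
#' correlation between the continuous ones.
#'
#' @inheritParams r_within
#' @param prevalence target prevalence to generalize to, in (0, 1).
#' @return the adjusted total correlation `r*_YM`.
#' @examples
#' adjust_r_ym(0.450, 0.80, 0.50, p = 0.50, prevalence = 0.02)  # ~ .404
#' @export
adjust_r_ym <- function(r_ym, d_m, d_y, p, prevalence) {
  rw <- r_within(r_ym, d_m, d_y, p)
  bad <- attr(rw, "inadmissible")
  if (!is.null(bad)) {
    out <- rep(NA_real_, length(rw))
    out[!bad] <- r_adjusted(as.numeric(rw)[!bad],
                            rep_len(d_m, length(rw))[!bad],
                            rep_len(d_y, length(rw))[!bad], prevalence)
    attr(out, "inadmissible") <- bad
    return(out)
  }
  r_adjusted(rw, d_m, d_y, prevalence)
}
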