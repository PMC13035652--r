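## Correlation-vector layout used throughout the engine: with variable order
## X (dichotomous), M, Y, position 1 = r_pb(M,X), 2 = r_pb(Y,X), 3 = r(Y,M).
cor_positions <- function() c("rho_pb_mx", "rho_pb_yx", "rho_ym")
position_pairs <- list(c(2L, 1L), c(3L, 1L), c(3L, 2L))

#' Large-sample sampling covariance of a study's correlation vector
#'
#' The asymptotic (order 1/n) covariance matrix of sample Pearson
#' correlations sharing an index set (the Olkin-Siotani form), evaluated at a
#' supplied full correlation vector and restricted to the observed positions:
#' diagonal entries are `(1 - r^2)^2 / n`, off-diagonals
#' \deqn{cov(r_{ij}, r_{kl}) = [\tfrac12 r_{ij} r_{kl}
#'   (r_{ik}^2 + r_{il}^2 + r_{jk}^2 + r_{jl}^2) + r_{ik} r_{jl} +
#'   r_{il} r_{jk} - (r_{ij} r_{ik} r_{il} + r_{ji} r_{jk} r_{jl} +
#'   r_{ki} r_{kj} r_{kl} + r_{li} r_{lj} r_{lk})] / n.}
#' When a study does not observe all three correlations, the caller supplies
#' imputed values (the across-study means) for the unobserved positions so
#' that the off-diagonal terms are defined.
#'
#' @param r full length-3 correlation vector in the order
#'   (r_pb_mx, r_pb_yx, r_ym), all entries in (-1, 1).
#' @param mask logical length-3 vector of observed positions.
#' @param n study total sample size (at least 4).
#' @return the covariance matrix of the observed sub-vector.
#' @export
sampling_covariance <- function(r, mask = rep(TRUE, 3), n) {
  if (length(r) != 3 || any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("'r' must be a length-3 vector with entries strictly in (-1, 1)",
         call. = FALSE)
  }
  if (n < 4) stop("study sample size must be at least 4", call. = FALSE)
  R <- diag(3)
  for (pos in 1:3) {
    pr <- position_pairs[[pos]]
    R[pr[1], pr[2]] <- R[pr[2], pr[1]] <- r[pos]
  }
  obs <- which(mask)
  m <- length(obs)
  V <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in a:m) {
      ij <- position_pairs[[obs[a]]]
      kl <- position_pairs[[obs[b]]]
      i <- ij[1]; j <- ij[2]; k <- kl[1]; l <- kl[2]
      cv <- 0.5 * R[i, j] * R[k, l] *
        (R[i, k]^2 + R[i, l]^2 + R[j, k]^2 + R[j, l]^2) +
        R[i, k] * R[j, l] + R[i, l] * R[j, k] -
        (R[i, j] * R[i, k] * R[i, l] + R[j, i] * R[j, k] * R[j, l] +
           R[k, i] * R[k, j] * R[k, l] + R[l, i] * R[l, j] * R[l, k])
      V[a, b] <- V[b, a] <- cv / n
    }
  }
  dimnames(V) <- list(cor_positions()[obs], cor_positions()[obs])
  V
}

#' Build study-level correlation records for pooling
#'
#' Converts each study's Cohen's d values to point-biserial correlations with
#' the chosen method, passes r_YM through unchanged, masks positions touched
#' by a removed variable, and attaches each study's sampling covariance
#' matrix (evaluated at the observed correlations, with unobserved positions
#' imputed by the unweighted across-study mean of observed values).
#'
#' @param dataset a `"meta_dataset"` from [simulate_meta_dataset()], or any
#'   list with a compatible `studies` data frame.
#' @param method one of [conversion_methods()].
#' @param prevalence prevalence for the pi-based methods (ignored otherwise).
#' @param use_study_prevalence if `TRUE`, each study's own subpopulation
#'   prevalence (`pi_study` column) is plugged into the pi-based conversion
#'   instead of the single population value.
#' @param v_eval where to evaluate the sampling covariances: `"pooled"`
#'   (default) evaluates every study's covariance at the sample-size-weighted
#'   across-study mean correlations, so that the likelihood weights do not
#'   inherit the sampling noise of small studies (a study whose observed
#'   correlation happens to land near +/-1 would otherwise receive an
#'   enormous weight); `"study"` evaluates at each study's own observed
#'   correlations, with unobserved positions imputed by the across-study
#'   means.
#' @return a list of records, each with `study`, `r` (observed sub-vector),
#'   `mask` (logical length 3), `n`, `V`.
#' @export
build_records <- function(dataset, method, prevalence = NULL,
                          use_study_prevalence = FALSE,
                          v_eval = c("pooled", "study")) {
  v_eval <- match.arg(v_eval)
  st <- dataset$studies
  k <- nrow(st)
  method <- match.arg(method, conversion_methods())
  prev <- if (use_study_prevalence) st$pi_study else rep_len(prevalence %||% NA_real_, k)
  if (method %in% c("pi-general", "pi-large") && any(is.na(prev))) {
    stop(sprintf("method '%s' requires a prevalence", method), call. = FALSE)
  }
  rmat <- matrix(NA_real_, k, 3, dimnames = list(NULL, cor_positions()))
  mask <- cbind(st$obs_x & st$obs_m, st$obs_x & st$obs_y, st$obs_m & st$obs_y)
  for (i in seq_len(k)) {
    if (mask[i, 1]) {
      rmat[i, 1] <- d_to_rpb(st$d_m[i], method, n1 = st$n1[i], n0 = st$n0[i],
                             prevalence = if (is.na(prev[i])) NULL else prev[i])
    }
    if (mask[i, 2]) {
      rmat[i, 2] <- d_to_rpb(st$d_y[i], method, n1 = st$n1[i], n0 = st$n0[i],
                             prevalence = if (is.na(prev[i])) NULL else prev[i])
    }
    if (mask[i, 3]) rmat[i, 3] <- st$r_ym[i]
  }
  n_tot <- st$n1 + st$n0
  pos_means <- vapply(1:3, function(j) {
    ok <- !is.na(rmat[, j])
    if (!any(ok)) 0 else sum(n_tot[ok] * rmat[ok, j]) / sum(n_tot[ok])
  }, 0)
  lapply(seq_len(k), function(i) {
    r_full <- if (v_eval == "pooled") pos_means
      else ifelse(is.na(rmat[i, ]), pos_means, rmat[i, ])
    list(study = st$study[i], r = rmat[i, mask[i, ]], mask = mask[i, ],
         n = n_tot[i],
         V = sampling_covariance(r_full, mask[i, ], n_tot[i]))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## negative log-likelihood of the one-stage random-effects model restricted
## to the modeled positions; rho on the tanh scale, tau on the sd scale
masem_nll <- function(par, records, modeled, fix_tau2) {
  m <- length(modeled)
  rho <- tanh(par[seq_len(m)])
  tau2 <- if (is.null(fix_tau2)) par[m + seq_len(m)]^2 else fix_tau2[modeled]
  pos_of <- integer(3)
  pos_of[modeled] <- seq_len(m)
  total <- 0
  for (rec in records) {
    idx <- pos_of[which(rec$mask)]
    resid <- rec$r - rho[idx]
    Sig <- rec$V + diag(tau2[idx], length(idx))
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    z <- backsolve(ch, resid, transpose = TRUE)
    total <- total + 0.5 * sum(z^2) + sum(log(diag(ch))) +
      0.5 * length(idx) * log(2 * pi)
  }
  total
}

#' Pool study-level correlation vectors by one-stage random-effects ML
#'
#' Maximum-likelihood estimation of the pooled correlation vector rho and the
#' diagonal between-study variances tau^2 under the model
#' `r_i ~ N(S_i rho, S_i (V_i + diag(tau2)) S_i')`, where `S_i` selects study
#' i's observed positions and `V_i` is its (fixed) sampling covariance.  The
#' mediation model fitted downstream is saturated, so the model-implied
#' correlations equal the pooled correlations.
#'
#' Pooled correlations are parameterized on the tanh scale and tau^2 as a
#' square, so the optimizer is unconstrained while rho stays inside (-1, 1)
#' and tau^2 stays non-negative.  On optimizer failure the fit is retried
#' (up to `max_retries` times) from jittered starting values; a fit is
#' flagged non-converged if all attempts fail or the pooled correlation
#' matrix is not positive definite at the optimum.
#'
#' Positions never observed are excluded and reported as `NA`.  With tau^2
#' freely estimated every modeled position must be observed in at least two
#' studies; with `fix_tau2` supplied a single observation suffices.
#'
#' @param records list of records from [build_records()].
#' @param fix_tau2 optional length-3 non-negative vector fixing tau^2 (e.g.
#'   `c(0, 0, 0)` for a fixed-effect fit); `NULL` to estimate.
#' @param max_retries maximum number of jittered restarts after a failure.
#' @return an object of class `"masem_fit"` with elements `pooled_r`, `tau2`
#'   (length-3 named vectors, `NA` for unmodeled positions), `logLik`,
#'   `converged`, `n_retries`, `k`, and `beta`/`indirect` slots filled by
#'   [fit_masem()].
#' @export
fit_pooled_correlations <- function(records, fix_tau2 = NULL, max_retries = 5L) {
  if (!length(records)) stop("no records supplied", call. = FALSE)
  counts <- colSums(do.call(rbind, lapply(records, function(r) r$mask)))
  modeled <- which(counts > 0)
  min_needed <- if (is.null(fix_tau2)) 2L else 1L
  if (any(counts[modeled] < min_needed)) {
    stop(sprintf(
      "every modeled correlation position needs at least %d observing studies",
      min_needed
    ), call. = FALSE)
  }
  if (!is.null(fix_tau2)) {
    stopifnot(length(fix_tau2) == 3, all(fix_tau2 >= 0))
  }
  m <- length(modeled)

  ## starts: position means of observed correlations; half the empirical
  ## between-study variance for tau
  rmat <- matrix(NA_real_, length(records), 3)
  for (i in seq_along(records)) rmat[i, records[[i]]$mask] <- records[[i]]$r
  r_start <- pmin(pmax(colMeans(rmat, na.rm = TRUE)[modeled], -0.98), 0.98)
  par0 <- atanh(r_start)
  if (is.null(fix_tau2)) {
    v_emp <- apply(rmat, 2, var, na.rm = TRUE)[modeled]
    par0 <- c(par0, sqrt(pmax(0.5 * v_emp, 1e-4, na.rm = TRUE)))
  }

  best <- NULL
  n_retries <- 0L
  for (attempt in 0:max_retries) {
    start <- if (attempt == 0) par0 else par0 + rnorm(length(par0), 0, 0.1)
    fit <- tryCatch(
      optim(start, masem_nll, records = records, modeled = modeled,
            fix_tau2 = fix_tau2, method = "BFGS",
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    ok <- !is.null(fit) && fit$convergence == 0 && is.finite(fit$value) &&
      fit$value < 1e9
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) {
      best <- fit
      best$ok <- ok
    } else if (ok && !is.null(best) && !best$ok) {
      best <- fit
      best$ok <- TRUE
    }
    if (ok) break
    n_retries <- attempt + 1L
  }
  if (is.null(best)) {
    stop("optimization failed on every attempt", call. = FALSE)
  }

  pooled <- rep(NA_real_, 3)
  tau2 <- rep(NA_real_, 3)
  pooled[modeled] <- tanh(best$par[seq_len(m)])
  tau2[modeled] <- if (is.null(fix_tau2)) best$par[m + seq_len(m)]^2
    else fix_tau2[modeled]
  names(pooled) <- names(tau2) <- cor_positions()

  converged <- isTRUE(best$ok)
  if (converged && !any(is.na(pooled))) {
    R <- matrix(c(1, pooled[1], pooled[2],
                  pooled[1], 1, pooled[3],
                  pooled[2], pooled[3], 1), 3, 3)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      converged <- FALSE
    }
  }
  structure(
    list(pooled_r = pooled, tau2 = tau2, logLik = -best$value,
         converged = converged, n_retries = n_retries,
         k = length(records), beta = NULL, indirect = NULL),
    class = "masem_fit"
  )
}

#' Fit the mediation MASEM to a simulated (or imported) meta-analytic dataset
#'
#' End-to-end fit: convert each study's Cohen's d values with the chosen
#' method ([build_records()]), optionally adjust each study's r_YM from its
#' own sample proportion to a target prevalence ([adjust_r_ym()]), pool the
#' correlation vectors by one-stage random-effects ML
#' ([fit_pooled_correlations()]), and derive the path coefficients and
#' indirect effect of the saturated mediation model
#' ([path_coefficients()]).  Studies that lost variable X carry no d values,
#' so their r_YM cannot be adjusted and enters unchanged.
#'
#' @inheritParams build_records
#' @param adjust if `TRUE`, each study's r_YM is re-expressed at
#'   `target_prevalence` before pooling.
#' @param target_prevalence prevalence used by the adjustment (defaults to
#'   `prevalence`).
#' @param fix_tau2 passed to [fit_pooled_correlations()].
#' @param se if `TRUE`, attach delta-method standard errors of the pooled
#'   correlations and path coefficients (slower; off by default).
#' @return a `"masem_fit"` with `beta` and `indirect` filled in when all
#'   three correlations are estimable and the pooled matrix is positive
#'   definite.
#' @examples
#' ds <- simulate_meta_dataset(load_condition(4), seed = 1)
#' fit_masem(ds, "equal-groups")
#' @export
fit_masem <- function(dataset, method, prevalence = NULL,
                      use_study_prevalence = FALSE,
                      adjust = FALSE, target_prevalence = NULL,
                      fix_tau2 = NULL, max_retries = 5L, se = FALSE,
                      v_eval = c("pooled", "study")) {
  if (adjust) {
    target <- target_prevalence %||% prevalence
    if (is.null(target)) {
      stop("adjustment requires a target prevalence", call. = FALSE)
    }
    st <- dataset$studies
    can <- st$obs_x & st$obs_m & st$obs_y
    st$r_ym[can] <- suppressWarnings(as.numeric(adjust_r_ym(
      st$r_ym[can], st$d_m[can], st$d_y[can], st$p[can], target
    )))
    dataset$studies <- st
  }
  records <- build_records(dataset, method, prevalence, use_study_prevalence,
                           v_eval = v_eval)
  fit <- fit_pooled_correlations(records, fix_tau2 = fix_tau2,
                                 max_retries = max_retries)
  pr <- fit$pooled_r
  if (!any(is.na(pr))) {
    beta <- tryCatch(path_coefficients(pr[[1]], pr[[2]], pr[[3]]),
                     error = function(e) NULL)
    if (!is.null(beta)) {
      fit$beta <- beta
      fit$indirect <- indirect_effect(beta[["beta_mx"]], beta[["beta_ym"]])
    } else {
      fit$converged <- FALSE
    }
  }
  if (se) fit <- add_masem_se(fit, records)
  fit$method <- method
  fit
}

## delta-method SEs: numerical hessian of the profile over (atanh rho, tau)
## at the optimum, transformed back to the correlation scale and propagated
## to the path coefficients
add_masem_se <- function(fit, records) {
  modeled <- which(!is.na(fit$pooled_r))
  m <- length(modeled)
  par <- c(atanh(fit$pooled_r[modeled]), sqrt(fit$tau2[modeled]))
  H <- tryCatch(
    optimHess(par, masem_nll, records = records, modeled = modeled,
              fix_tau2 = NULL),
    error = function(e) NULL
  )
  if (is.null(H)) return(fit)
  cov_par <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov_par)) return(fit)
  ## d rho / d z = 1 - rho^2
  jac_z <- 1 - fit$pooled_r[modeled]^2
  cov_rho <- diag(jac_z, m) %*% cov_par[seq_len(m), seq_len(m), drop = FALSE] %*%
    diag(jac_z, m)
  se_r <- rep(NA_real_, 3)
  se_r[modeled] <- sqrt(pmax(diag(cov_rho), 0))
  names(se_r) <- cor_positions()
  fit$se_pooled_r <- se_r
  if (!is.null(fit$beta) && m == 3) {
    r <- fit$pooled_r
    eps <- 1e-6
    J <- sapply(1:3, function(j) {
      rp <- r; rp[j] <- rp[j] + eps
      rm <- r; rm[j] <- rm[j] - eps
      (path_coefficients(rp[1], rp[2], rp[3]) -
         path_coefficients(rm[1], rm[2], rm[3])) / (2 * eps)
    })
    cov_beta <- J %*% cov_rho %*% t(J)
    fit$se_beta <- stats::setNames(sqrt(pmax(diag(cov_beta), 0)),
                                   names(fit$beta))
  }
  fit
}

#' @export
print.masem_fit <- function(x, digits = 4, ...) {
  cat(sprintf("One-stage random-effects MASEM fit (%d studies%s)\n", x$k,
              if (!is.null(x$method)) paste0(", conversion: ", x$method) else ""))
  cat("  pooled correlations:\n")
  print(round(x$pooled_r, digits))
  cat("  between-study variances (tau^2):\n")
  print(round(x$tau2, digits))
  if (!is.null(x$beta)) {
    cat("  path coefficients:\n")
    print(round(x$beta, digits))
    cat(sprintf("  indirect effect: %.*f\n", digits, x$indirect))
  }
  cat(sprintf("  logLik %.3f; converged: %s (%d retries)\n",
              x$logLik, x$converged, x$n_retries))
  invisible(x)
}
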