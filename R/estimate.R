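# Estimation of the detection-rate distribution (mu, sigma) from field
# records, by maximum marginal likelihood with Gauss-Hermite quadrature over
# a lognormal random effect. These are simplified likelihoods capturing the
# distributional skeleton of the hierarchical models a full Bayesian fit
# would use: exponential time-to-detection (censored at session end) with a
# lognormal rate per observer-by-quadrat unit, and Poisson repeat-survey
# counts with a log-linear abundance effect and a lognormal visit deviate.

logsumexp_rows <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

rate_fit_ci <- function(value_log, grad, vcov, level = 0.95) {
  se <- sqrt(drop(t(grad) %*% vcov %*% grad))
  z <- stats::qnorm(1 - (1 - level) / 2)
  exp(value_log + c(-1, 1) * z * se)
}

new_rate_fit <- function(mu_hat, sigma_hat, coef, vcov, logLik, converged,
                         model, n_units, ci, boundary = FALSE, beta_ci = NULL) {
  structure(list(mu_hat = mu_hat, sigma_hat = sigma_hat,
                 theta_hat = sigma_hat / mu_hat, coef = coef, vcov = vcov,
                 logLik = logLik, converged = converged, model = model,
                 n_units = n_units, ci = ci, boundary = boundary,
                 beta_ci = beta_ci),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("Detection-rate fit (%s, %d units):\n", x$model, x$n_units))
  cat(sprintf("  mu = %.4g [%.4g, %.4g]\n", x$mu_hat,
              x$ci["mu", 1], x$ci["mu", 2]))
  cat(sprintf("  sigma = %.4g, theta = %.4g\n", x$sigma_hat, x$theta_hat))
  if (!is.null(x$beta_ci))
    cat(sprintf("  abundance exponent beta = %.4g [%.4g, %.4g]\n",
                x$coef["beta"], x$beta_ci[1], x$beta_ci[2]))
  cat(sprintf("  logLik = %.3f, converged: %s%s\n", x$logLik, x$converged,
              if (x$boundary) " (variance at boundary)" else ""))
  invisible(x)
}

#' Fit a failure-time model to censored time-to-first-detection records
#'
#' Time to first detection within an observer-by-quadrat search unit is
#' exponential given that unit's rate; rates vary across units following a
#' lognormal distribution. The random effect is integrated out by
#' Gauss-Hermite quadrature and the marginal likelihood maximized over the
#' lognormal parameters, which are then reported on the rate scale as
#' `mu_hat`, `sigma_hat` with Wald intervals (delta method on the log
#' scale). A search that ends at the session length without a detection
#' contributes the survival probability `exp(-lambda * session_length)`.
#'
#' @param records Data frame as returned by [read_detection_records()] or
#'   [gen_quadrat_experiment()]: columns `observer`, `quadrat`,
#'   `time_to_detection`, `session_length`, `censored`, optionally
#'   `species`.
#' @param n_nodes Gauss-Hermite nodes for the random-effect integral.
#' @return An object of class `rate_fit`.
#' @export
fit_time_to_detection <- function(records, n_nodes = 30L) {
  need <- c("observer", "quadrat", "time_to_detection", "session_length", "censored")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (all(records$censored))
    stop("non-identifiable: every record is censored", call. = FALSE)
  bad <- !records$censored &
    (records$time_to_detection <= 0 |
       records$time_to_detection > records$session_length + 1e-9)
  if (any(bad))
    stop("uncensored times must lie in (0, session_length]", call. = FALSE)
  unit <- interaction(records$observer, records$quadrat,
                      if (!is.null(records$species)) records$species else "",
                      drop = TRUE)
  d <- tapply(!records$censored, unit, sum)            # detections per unit
  S <- tapply(ifelse(records$censored, records$session_length,
                     records$time_to_detection), unit, sum)  # exposure per unit
  d <- as.numeric(d); S <- as.numeric(S)
  if (length(d) < 2L) {
    # fixed-rate reduction: a single unit cannot identify between-unit spread
    mu <- sum(d) / sum(S)
    ci <- matrix(mu * exp(c(-1, 1) * 1.96 / sqrt(max(sum(d), 1))), 1,
                 dimnames = list("mu", c("lower", "upper")))
    return(new_rate_fit(mu, 0, c(meanlog = log(mu), log_sdlog = -Inf),
                        matrix(NA, 2, 2), sum(d) * log(mu) - mu * sum(S),
                        converged = TRUE, model = "time_to_detection",
                        n_units = 1L, ci = ci, boundary = TRUE))
  }
  gh <- gh_rule(n_nodes)
  nll <- function(p) {
    l <- p[1] + sqrt(2) * exp(p[2]) * gh$x   # log-rate at the nodes
    M <- outer(d, l) - outer(S, exp(l)) + rep(log(gh$w / sqrt(pi)),
                                              each = length(d))
    -sum(logsumexp_rows(M))
  }
  # two spread starts: the likelihood can be flat near the sigma = 0
  # boundary, and a single interior start sometimes stalls there
  fits <- lapply(c(log(0.5), log(0.03)), function(s0) {
    stats::optim(c(log(sum(d) / sum(S)), s0), nll, method = "L-BFGS-B",
                 lower = c(-20, -8), upper = c(20, 3), hessian = TRUE)
  })
  opt <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  finish_lognormal_fit(opt, model = "time_to_detection", n_units = length(d))
}

# Shared tail: convert (meanlog, log sdlog) MLE to rate-scale estimates + CIs.
finish_lognormal_fit <- function(opt, model, n_units, extra_coef = NULL,
                                 vcov_idx = c(1L, 2L), full_vcov = NULL,
                                 beta_ci = NULL) {
  ml <- opt$par[vcov_idx[1]]
  q <- opt$par[vcov_idx[2]]
  sl2 <- exp(2 * q)
  mu <- exp(ml + sl2 / 2)
  sigma <- mu * sqrt(expm1(sl2))
  vc <- if (is.null(full_vcov)) {
    h <- opt$hessian
    out <- try(solve(h), silent = TRUE)
    if (inherits(out, "try-error")) matrix(NA, nrow(h), ncol(h)) else out
  } else full_vcov
  vsub <- vc[vcov_idx, vcov_idx]
  boundary <- sqrt(sl2) < 1e-3
  ci <- rbind(
    mu = rate_fit_ci(log(mu), c(1, sl2), vsub),
    sigma = if (boundary) c(NA, NA)
            else rate_fit_ci(log(sigma), c(1, sl2 + sl2 * exp(sl2) / expm1(sl2)), vsub),
    theta = if (boundary) c(NA, NA)
            else rate_fit_ci(0.5 * log(expm1(sl2)), c(0, sl2 * exp(sl2) / expm1(sl2)), vsub)
  )
  colnames(ci) <- c("lower", "upper")
  coef <- c(meanlog = ml, log_sdlog = q, extra_coef)
  new_rate_fit(mu, sigma, coef, vc, -opt$value,
               converged = opt$convergence == 0, model = model,
               n_units = n_units, ci = ci, boundary = boundary,
               beta_ci = beta_ci)
}

#' Fit a Poisson-lognormal model to repeat-survey count records
#'
#' Detections per visit are Poisson with exposure `search_time` and log rate
#' \eqn{\alpha + \beta \ln(\mathrm{abundance}) + \epsilon}, where
#' \eqn{\epsilon} is a normal visit-level deviate with s.d. `sdlog`
#' integrated out by Gauss-Hermite quadrature. The returned `mu_hat`,
#' `sigma_hat` describe the rate distribution at abundance 1; use
#' [predict_rate()] for other abundances.
#'
#' @param records Data frame as returned by [read_survey_counts()] or
#'   [gen_repeat_surveys()]: columns `site`, `visit`, `detections`,
#'   `search_time`, optionally `abundance`.
#' @param n_nodes Gauss-Hermite nodes.
#' @return An object of class `rate_fit` with the abundance exponent (if
#'   estimated) in `coef["beta"]` and its Wald interval in `beta_ci`.
#' @export
fit_rate_counts <- function(records, n_nodes = 30L) {
  need <- c("site", "visit", "detections", "search_time")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (length(unique(records$site)) < 2L)
    stop("need records from at least 2 sites", call. = FALSE)
  if (any(records$search_time <= 0) || any(records$detections < 0))
    stop("search_time must be > 0 and detections >= 0", call. = FALSE)
  y <- records$detections
  if (all(y == 0))
    stop("non-identifiable: no detections anywhere", call. = FALSE)
  tau <- records$search_time
  has_ab <- !is.null(records$abundance) &&
    length(unique(records$abundance)) > 1L
  la <- if (has_ab) log(records$abundance) else rep(0, length(y))
  if (has_ab && any(records$abundance <= 0))
    stop("abundance must be > 0", call. = FALSE)
  gh <- gh_rule(n_nodes)
  # Adaptive Gauss-Hermite: center the nodes at each row's conditional mode
  # of the random effect (Newton steps, vectorized over rows), scale by the
  # curvature there. Non-adaptive rules lose several digits when a large
  # count shifts the integrand far from zero.
  nll <- function(p) {
    alpha <- p[1]
    beta <- if (has_ab) p[2] else 0
    sl <- exp(p[length(p)])
    eta <- alpha + beta * la                     # per-row fixed part
    zhat <- rep(0, length(y))
    for (it in 1:25) {
      lam <- exp(eta + sl * zhat) * tau
      g1 <- sl * (y - lam) - zhat
      g2 <- -sl^2 * lam - 1
      step <- g1 / g2
      zhat <- zhat - pmax(pmin(step, 2), -2)
      if (max(abs(step)) < 1e-10) break
    }
    shat <- 1 / sqrt(sl^2 * exp(eta + sl * zhat) * tau + 1)
    Z <- outer(shat, sqrt(2) * gh$x) + zhat      # rows x nodes
    M <- eta + sl * Z
    LL <- y * (M + log(tau)) - exp(M) * tau - lgamma(y + 1) +
      stats::dnorm(Z, log = TRUE)
    LL <- LL + rep(log(gh$w) + gh$x^2, each = length(y)) + log(sqrt(2) * shat)
    -sum(logsumexp_rows(LL))
  }
  start <- if (has_ab) c(log(sum(y) / sum(tau)), 0, log(0.5))
           else c(log(sum(y) / sum(tau)), log(0.5))
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(-20, if (has_ab) -10, -8),
                      upper = c(20, if (has_ab) 10, 3), hessian = TRUE)
  vc <- try(solve(opt$hessian), silent = TRUE)
  if (inherits(vc, "try-error")) vc <- matrix(NA, length(opt$par), length(opt$par))
  idx <- c(1L, length(opt$par))
  beta_ci <- NULL
  extra <- NULL
  if (has_ab) {
    extra <- c(beta = opt$par[2])
    beta_ci <- opt$par[2] + c(-1, 1) * 1.96 * sqrt(vc[2, 2])
  }
  finish_lognormal_fit(opt, model = "counts", n_units = length(y),
                       extra_coef = extra, vcov_idx = idx, full_vcov = vc,
                       beta_ci = beta_ci)
}

#' Predict the detection-rate distribution at a given abundance
#'
#' For a count fit with an abundance effect, shifts the lognormal mean by
#' `abundance^beta` (the coefficient of variation is unchanged, since the
#' visit deviate's variance does not depend on abundance). For a
#' covariate-free fit the fitted `(mu_hat, sigma_hat)` are returned
#' unchanged.
#'
#' @param fit A [fit_rate_counts()] or [fit_time_to_detection()] result.
#' @param abundance Positive abundance; optional for covariate-free fits.
#' @return A [rate_prior()].
#' @export
predict_rate <- function(fit, abundance = NULL) {
  stopifnot(inherits(fit, "rate_fit"))
  if (is.null(abundance) || is.na(fit$coef["beta"]) || !"beta" %in% names(fit$coef))
    return(rate_prior(fit$mu_hat, sigma = fit$sigma_hat))
  if (!is.numeric(abundance) || length(abundance) != 1L || abundance <= 0)
    stop("'abundance' must be a single value > 0", call. = FALSE)
  mu <- fit$mu_hat * abundance^fit$coef[["beta"]]
  rate_prior(mu, theta = fit$theta_hat)
}

#' Read time-to-detection records from CSV
#'
#' Expects a header with columns `observer`, `quadrat`, `time_to_detection`,
#' `session_length`, `censored` (logical or 0/1), optionally `species`.
#' Times are in the file's native unit; the package never converts units.
#'
#' @param path CSV file.
#' @return A validated data frame of detection records.
#' @export
read_detection_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer", "quadrat", "time_to_detection", "session_length", "censored")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  x$censored <- as.logical(x$censored)
  if (any(is.na(x$censored))) stop("'censored' must be logical or 0/1", call. = FALSE)
  if (any(x$session_length <= 0)) stop("'session_length' must be > 0", call. = FALSE)
  x
}

#' Write time-to-detection records to CSV
#' @param records Data frame of detection records.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_detection_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read repeat-survey count records from CSV
#'
#' Expects a header with columns `site`, `visit`, `detections`,
#' `search_time`, optionally `abundance`.
#'
#' @param path CSV file.
#' @return A validated data frame of survey count records.
#' @export
read_survey_counts <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "visit", "detections", "search_time")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(x$search_time <= 0)) stop("'search_time' must be > 0", call. = FALSE)
  if (any(x$detections < 0)) stop("'detections' must be >= 0", call. = FALSE)
  x
}

#' Write repeat-survey count records to CSV
#' @param records Data frame of survey count records.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_survey_counts <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Export a rate fit as JSON
#'
#' @param fit A `rate_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rate_fit <- function(fit, path) {
  stopifnot(inherits(fit, "rate_fit"))
  out <- list(model = fit$model, mu = fit$mu_hat, sigma = fit$sigma_hat,
              theta = fit$theta_hat, coef = as.list(fit$coef),
              ci = as.data.frame(fit$ci), logLik = fit$logLik,
              converged = fit$converged, n_units = fit$n_units)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
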