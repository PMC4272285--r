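# Monte Carlo oracle: brute-force simulation of Q = exp(-t * sum(lambda_i))
# under independent or temporally correlated lognormal rates. Validates the
# moment-matched analytic layer and supports the correlation sensitivity
# analysis.

#' Between-visit correlation of detection rates
#'
#' Correlation is imposed on the log-rate scale through a Gaussian copula.
#' `"exchangeable"`: every pair of visits shares correlation `r`. `"ar1"`:
#' surveys are spread evenly over a season of length `T`, so consecutive
#' surveys are `T/n` time units apart and the correlation between visits
#' `i` and `j` is `r^(|i - j| * T/n)`, with `r` the correlation between
#' rates one time unit apart.
#'
#' @param r Correlation coefficient in `[0, 1]`.
#' @param structure `"exchangeable"` or `"ar1"`.
#' @param T Season length (time units); required for `"ar1"`.
#' @return An object of class `correlation_spec`.
#' @examples
#' correlation_spec(0.3, "ar1", T = 90)
#' @export
correlation_spec <- function(r = 0, structure = c("exchangeable", "ar1"), T = NULL) {
  structure_ <- match.arg(structure)
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 1)
    stop("'r' must be in [0, 1]", call. = FALSE)
  if (structure_ == "ar1" && (is.null(T) || !is.numeric(T) || T <= 0))
    stop("'ar1' requires a season length T > 0", call. = FALSE)
  structure(list(r = r, structure = structure_, T = T),
            class = "correlation_spec")
}

corr_matrix <- function(corr, n) {
  R <- diag(n)
  if (corr$r == 0 || n == 1L) return(R)
  if (corr$structure == "exchangeable") {
    R[] <- corr$r
    diag(R) <- 1
  } else {
    spacing <- corr$T / n
    R <- corr$r^(abs(outer(seq_len(n), seq_len(n), "-")) * spacing)
  }
  R
}

# Draw reps x n log-scale-correlated lognormal rates with mean mu, sd sigma.
draw_rates <- function(n, rate, corr, reps) {
  if (rate$sigma == 0) return(matrix(rate$mu, reps, n))
  sl2 <- log(1 + rate$theta^2)
  ml <- log(rate$mu) - sl2 / 2
  Z <- matrix(stats::rnorm(reps * n), reps, n)
  if (corr$r > 0 && n > 1L) {
    if (corr$r == 1 && corr$structure == "exchangeable") {
      Z <- matrix(Z[, 1L], reps, n)
    } else {
      R <- corr_matrix(corr, n)
      Z <- Z %*% chol(R)
    }
  }
  exp(ml + sqrt(sl2) * Z)
}

#' Simulate the failed-detection probability
#'
#' Per replicate, draws the `n` per-survey rates jointly lognormal (mean
#' `mu`, s.d. `sigma`, log-scale correlation per `corr`) and forms
#' \eqn{Q = \exp(-t \sum_i \lambda_i)}. This is the model itself with no
#' lognormal-sum approximation, so it serves as the independent oracle for
#' the analytic layer, and quantifies the Fenton-Wilkinson error.
#'
#' @param n Number of surveys.
#' @param t Search time per survey, > 0.
#' @param rate A [rate_prior()].
#' @param corr A [correlation_spec()]; default independent.
#' @param reps Number of replicates, >= 1.
#' @param seed Integer seed; identical seeds give identical samples.
#' @param target Optional [satisficing_target()]: estimate `Pr(Q < Q_c)`.
#' @return An object of class `q_sample`: list with `draws`, `reps`, `seed`,
#'   `est_expected_q`, `se_expected_q`, and with a target `est_prob_below`,
#'   `se_prob_below`.
#' @examples
#' qs <- simulate_q(3, 2.33, rate_prior(0.67, theta = 2.5), reps = 1e4, seed = 1)
#' qs$est_expected_q
#' @export
simulate_q <- function(n, t, rate, corr = correlation_spec(), reps = 1e5,
                       seed = 1L, target = NULL) {
  n <- check_n(n)
  stopifnot(inherits(rate, "rate_prior"), inherits(corr, "correlation_spec"))
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    stop("'t' must be > 0", call. = FALSE)
  if (!is.numeric(reps) || reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  reps <- as.integer(reps)
  set.seed(seed)
  lam <- draw_rates(n, rate, corr, reps)
  q <- exp(-t * rowSums(lam))
  out <- list(draws = q, reps = reps, seed = seed,
              est_expected_q = mean(q),
              se_expected_q = stats::sd(q) / sqrt(reps))
  if (!is.null(target)) {
    stopifnot(inherits(target, "satisficing_target"))
    hit <- q < target$Q_c
    out$est_prob_below <- mean(hit)
    out$se_prob_below <- stats::sd(hit) / sqrt(reps)
  }
  structure(out, class = "q_sample")
}

#' @export
print.q_sample <- function(x, ...) {
  cat(sprintf("Q sample: %d replicates (seed %d)\n", x$reps, x$seed))
  cat(sprintf("  E[Q] = %.5f (se %.2g)\n", x$est_expected_q, x$se_expected_q))
  if (!is.null(x$est_prob_below))
    cat(sprintf("  Pr(Q < Q_c) = %.5f (se %.2g)\n",
                x$est_prob_below, x$se_prob_below))
  invisible(x)
}

#' Error of the lognormal-sum (Fenton-Wilkinson) approximation
#'
#' The analytic layer treats the sum of `n` lognormal per-survey detection
#' totals as a single moment-matched lognormal. This helper measures the
#' resulting bias directly: analytic minus simulated value for both
#' objectives, with the simulation using the true sum. The bias grows with
#' the coefficient of variation (roughly +0.02 on `E[Q]` and up to -0.07 on
#' the assurance by `theta = 2.5`) and is negligible below `theta` of about
#' 1.
#'
#' @param n Number of surveys.
#' @param sp A [scaled_problem()] or [design_problem()].
#' @param target Optional [satisficing_target()].
#' @param reps Simulation replicates.
#' @param seed Integer seed.
#' @return A data frame with columns `quantity`, `analytic`, `simulated`,
#'   `bias`, `mc_se`.
#' @export
wilkinson_error <- function(n, sp, target = NULL, reps = 1e5, seed = 1L) {
  sp <- as_scaled(sp)
  t <- survey_time(n, sp$Bp, sp$cp)  # scaled time; rate below has mu = 1
  qs <- simulate_q(n, t, rate_prior(1, theta = sp$theta),
                   reps = reps, seed = seed, target = target)
  out <- data.frame(quantity = "expected_Q",
                    analytic = expected_q(n, sp),
                    simulated = qs$est_expected_q,
                    mc_se = qs$se_expected_q)
  if (!is.null(target))
    out <- rbind(out, data.frame(quantity = "prob_below_Qc",
                                 analytic = prob_target(n, sp, target),
                                 simulated = qs$est_prob_below,
                                 mc_se = qs$se_prob_below))
  out$bias <- out$analytic - out$simulated
  out[c("quantity", "analytic", "simulated", "bias", "mc_se")]
}

#' Sensitivity of the optimal design to temporal correlation
#'
#' For each correlation on the grid, estimates the objective for every
#' feasible number of surveys by simulation and reports the simulation-
#' optimal `n`. Independent rates (`r = 0`) reproduce the analytic
#' optimizer up to Monte Carlo error; strong positive correlation removes
#' the diversification benefit of repeat visits, pushing the optimum toward
#' a single survey for the expected-detection objective.
#'
#' @param problem A [design_problem()].
#' @param target Optional [satisficing_target()]; if supplied the
#'   satisficing objective is maximized, otherwise `E[Q]` is minimized.
#' @param r_grid Correlations to evaluate, each in `[0, 1]`.
#' @param corr_structure `"exchangeable"` or `"ar1"`.
#' @param T Season length for `"ar1"`.
#' @param reps Replicates per (r, n) cell.
#' @param seed Master seed; each cell uses a stream derived from it.
#' @return A data frame with columns `r`, `objective`, `optimal_n`,
#'   `estimate`, `se` (Monte Carlo standard error at the optimum).
#' @export
correlation_sensitivity <- function(problem, target = NULL, r_grid = c(0, 0.3, 0.6, 0.9),
                                    corr_structure = c("exchangeable", "ar1"),
                                    T = NULL, reps = 1e4, seed = 1L) {
  stopifnot(inherits(problem, "design_problem"))
  corr_structure <- match.arg(corr_structure)
  if (any(r_grid < 0 | r_grid > 1))
    stop("'r_grid' values must be in [0, 1]", call. = FALSE)
  sp <- scale_problem(problem)
  ns <- feasible_n(sp)
  objective <- if (is.null(target)) "expected_detection" else "satisficing"
  rows <- lapply(seq_along(r_grid), function(k) {
    r <- r_grid[k]
    corr <- correlation_spec(r, corr_structure, T)
    est <- se <- numeric(length(ns))
    for (i in seq_along(ns)) {
      qs <- simulate_q(ns[i], survey_time(ns[i], problem$B, problem$c),
                       problem$rate, corr, reps,
                       seed = seed + 1000L * k + i, target = target)
      if (is.null(target)) {
        est[i] <- qs$est_expected_q; se[i] <- qs$se_expected_q
      } else {
        est[i] <- qs$est_prob_below; se[i] <- qs$se_prob_below
      }
    }
    best <- if (is.null(target)) which.min(est) else which.max(est)
    data.frame(r = r, objective = objective, optimal_n = ns[best],
               estimate = est[best], se = se[best])
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
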