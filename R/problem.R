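#' Stochastic detection-rate prior
#'
#' Describes the between-visit distribution of the instantaneous detection
#' rate \eqn{\lambda}: detections are assumed to accrue as a Poisson process
#' during active search, at a rate that is itself a random variable with mean
#' `mu` and standard deviation `sigma` (lognormal across visits). Exactly one
#' of `sigma` or `theta` must be supplied; the other is derived from
#' \eqn{\theta = \sigma/\mu}.
#'
#' @param mu Mean detection rate (detections per unit search time), > 0.
#' @param sigma Standard deviation of the rate, same units, >= 0.
#' @param theta Coefficient of variation \eqn{\sigma/\mu}, dimensionless.
#' @return An object of class `rate_prior` with fields `mu`, `sigma`, `theta`.
#' @examples
#' rate_prior(mu = 0.67, theta = 2.5)
#' rate_prior(mu = 0.56, sigma = 0.64)
#' @export
rate_prior <- function(mu, sigma = NULL, theta = NULL) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("invalid rate: 'mu' must be a single finite value > 0", call. = FALSE)
  if (is.null(sigma) == is.null(theta))
    stop("supply exactly one of 'sigma' or 'theta'", call. = FALSE)
  if (is.null(sigma)) {
    if (theta < 0) stop("'theta' must be >= 0", call. = FALSE)
    sigma <- theta * mu
  } else {
    if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
    theta <- sigma / mu
  }
  structure(list(mu = mu, sigma = sigma, theta = theta), class = "rate_prior")
}

#' @export
print.rate_prior <- function(x, ...) {
  cat(sprintf("Detection rate prior: mu = %g, sigma = %g (theta = %g)\n",
              x$mu, x$sigma, x$theta))
  invisible(x)
}

#' Survey design problem
#'
#' A total time budget `B` is to be split over `n` surveys, each paying a
#' fixed non-search cost `c` (travel, setup) and searching for
#' \eqn{t = B/n - c}. `B`, `c` and the rate's time unit must agree; the
#' package never converts units.
#'
#' @param B Total time budget, > 0.
#' @param c Fixed non-search time per survey, >= 0 (optimization requires
#'   `c > 0` and `B > c`).
#' @param rate A [rate_prior()].
#' @return An object of class `design_problem`.
#' @examples
#' design_problem(B = 10, c = 1, rate = rate_prior(0.67, theta = 2.5))
#' @export
design_problem <- function(B, c, rate) {
  stopifnot(inherits(rate, "rate_prior"))
  if (!is.numeric(B) || length(B) != 1L || B <= 0)
    stop("'B' must be a single value > 0", call. = FALSE)
  if (!is.numeric(c) || length(c) != 1L || c < 0)
    stop("'c' must be a single value >= 0", call. = FALSE)
  structure(list(B = B, c = c, rate = rate), class = "design_problem")
}

#' @export
print.design_problem <- function(x, ...) {
  cat(sprintf("Survey design problem: B = %g, c = %g\n", x$B, x$c))
  print(x$rate)
  invisible(x)
}

#' Dimensionless (scaled) design problem
#'
#' Budgets are naturally expressed in units of the mean time to first
#' detection, \eqn{1/\mu}: the scaled budget \eqn{B' = B\mu} is the expected
#' number of detections if the whole budget were spent searching, and
#' \eqn{c' = c\mu} the expected number forgone per survey through fixed
#' costs. Both objective functions depend on the problem only through
#' \eqn{(B', c', \theta)}.
#'
#' @param Bp Scaled budget, > 0.
#' @param cp Scaled fixed cost, >= 0.
#' @param theta Coefficient of variation of the detection rate, >= 0.
#' @return An object of class `scaled_problem`.
#' @seealso [scale_problem()] to derive one from a [design_problem()].
#' @export
scaled_problem <- function(Bp, cp, theta) {
  if (!is.numeric(Bp) || length(Bp) != 1L || !is.finite(Bp) || Bp <= 0)
    stop("'Bp' must be a single finite value > 0", call. = FALSE)
  if (!is.numeric(cp) || length(cp) != 1L || !is.finite(cp) || cp < 0)
    stop("'cp' must be a single finite value >= 0", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta < 0)
    stop("'theta' must be a single finite value >= 0", call. = FALSE)
  structure(list(Bp = Bp, cp = cp, theta = theta), class = "scaled_problem")
}

#' @export
print.scaled_problem <- function(x, ...) {
  cat(sprintf("Scaled problem: B' = %g, c' = %g, theta = %g\n",
              x$Bp, x$cp, x$theta))
  invisible(x)
}

#' Scale a design problem to dimensionless form
#'
#' @param problem A [design_problem()].
#' @return A [scaled_problem()] with `Bp = B * mu`, `cp = c * mu` and the
#'   rate's coefficient of variation.
#' @examples
#' pr <- design_problem(10, 1, rate_prior(0.67, theta = 2.5))
#' scale_problem(pr)  # B' = 6.7, c' = 0.67
#' @export
scale_problem <- function(problem) {
  stopifnot(inherits(problem, "design_problem"))
  scaled_problem(problem$B * problem$rate$mu,
                 problem$c * problem$rate$mu,
                 problem$rate$theta)
}

#' Search time per survey under the budget constraint
#'
#' With `n` equal surveys, the time actually spent searching in each is
#' \eqn{t = B/n - c}. Designs with \eqn{t \le 0} spend the whole budget on
#' fixed costs and are infeasible.
#'
#' @param n Number of surveys, positive integer.
#' @param B Total budget.
#' @param c Fixed cost per survey.
#' @return Search time per survey, > 0.
#' @examples
#' survey_time(4, B = 10, c = 1)  # 1.5
#' @export
survey_time <- function(n, B, c) {
  n <- check_n(n)
  t <- B / n - c
  if (t <= 0)
    stop(sprintf("infeasible design: n = %d leaves no search time (need n < B/c = %g)",
                 n, B / c), call. = FALSE)
  t
}

#' Detection target for the satisficing objective
#'
#' The satisficing objective maximizes the probability that the realized
#' failed-detection probability `Q` falls below an acceptable level `Q_c`
#' (equivalently that the detection probability exceeds `1 - Q_c`). On the
#' log-total-detection scale the threshold is the complementary log-log
#' transform \eqn{X_c = \ln(-\ln Q_c)}.
#'
#' @param Q_c Acceptable probability of failed detection, in (0, 1).
#'   Alternatively supply `p` instead, the required detection probability;
#'   then `Q_c = 1 - p`.
#' @param p Optional required detection probability, in (0, 1).
#' @return An object of class `satisficing_target` with fields `Q_c`, `X_c`.
#' @examples
#' satisficing_target(Q_c = 0.05)
#' satisficing_target(p = 0.95)  # identical
#' @export
satisficing_target <- function(Q_c = NULL, p = NULL) {
  if (is.null(Q_c) == is.null(p))
    stop("supply exactly one of 'Q_c' or 'p'", call. = FALSE)
  if (is.null(Q_c)) {
    if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
      stop("'p' must be in (0, 1)", call. = FALSE)
    Q_c <- 1 - p
  }
  if (!is.numeric(Q_c) || length(Q_c) != 1L || Q_c <= 0 || Q_c >= 1)
    stop("'Q_c' must be in (0, 1)", call. = FALSE)
  structure(list(Q_c = Q_c, X_c = log(-log(Q_c))), class = "satisficing_target")
}

#' @export
print.satisficing_target <- function(x, ...) {
  cat(sprintf("Satisficing target: Q_c = %g (X_c = %g)\n", x$Q_c, x$X_c))
  invisible(x)
}

# Largest n with positive search time, and the feasible range 1..n_max.
n_max_feasible <- function(Bp, cp) {
  if (cp <= 0) return(Inf)
  nm <- ceiling(Bp / cp) - 1L
  while (nm >= 1L && Bp / nm - cp <= 0) nm <- nm - 1L
  as.integer(nm)
}

feasible_n <- function(sp) {
  nm <- n_max_feasible(sp$Bp, sp$cp)
  if (is.infinite(nm))
    stop("feasible range is unbounded when the scaled fixed cost is 0", call. = FALSE)
  if (nm < 1L)
    stop("no feasible design: the fixed cost exhausts the budget even for n = 1",
         call. = FALSE)
  seq_len(nm)
}

check_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 ||
      abs(n - round(n)) > 1e-8)
    stop("'n' must be a single positive integer", call. = FALSE)
  as.integer(round(n))
}

as_scaled <- function(x) {
  if (inherits(x, "scaled_problem")) return(x)
  if (inherits(x, "design_problem")) return(scale_problem(x))
  stop("expected a 'scaled_problem' or 'design_problem'", call. = FALSE)
}
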