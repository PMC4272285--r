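# Probabilistic engine: lognormal model for the total expected number of
# detections A over n surveys, the distribution of the failed-detection
# probability Q = exp(-A), and both design objectives at fixed n.

.surveyopt_env <- new.env(parent = emptyenv())

# Gauss-Hermite nodes/weights, cached; physicists' convention (weight e^{-x^2}).
gh_rule <- function(n_nodes = 120L) {
  key <- as.character(n_nodes)
  if (is.null(.surveyopt_env[[key]]))
    .surveyopt_env[[key]] <- pracma::gaussHermite(n_nodes)
  .surveyopt_env[[key]]
}

#' Lognormal moment match for the total expected detections
#'
#' Over `n` equal surveys of search length `t`, the total expected number of
#' detections is \eqn{A = t \sum_i \lambda_i} with mean
#' \eqn{\mu_A = n\mu t} and variance \eqn{\sigma_A^2 = n\sigma^2 t^2}. `A` is
#' approximated as lognormal with the same first two moments
#' (Fenton-Wilkinson): \eqn{X = \ln A} is normal with variance
#' \eqn{v = \ln(1 + \sigma_A^2/\mu_A^2)} and mean
#' \eqn{m = \ln\mu_A - v/2}. In scaled form \eqn{\mu_A = B' - n c'} and
#' \eqn{\sigma_A/\mu_A = \theta/\sqrt{n}}.
#'
#' @param n Number of surveys, positive integer.
#' @param sp A [scaled_problem()] (or [design_problem()], scaled internally).
#' @return An object of class `moment_match` with fields `mu_A`, `sigma_A`,
#'   `m`, `v`. When `theta = 0` the match is a point mass (`v = 0`,
#'   `m = log(mu_A)`).
#' @examples
#' moment_match(1, scaled_problem(2, 0.5, 1))
#' @export
moment_match <- function(n, sp) {
  sp <- as_scaled(sp)
  n <- check_n(n)
  mu_A <- sp$Bp - n * sp$cp
  if (mu_A <= 0)
    stop(sprintf("infeasible design: B' - n c' = %g <= 0 at n = %d", mu_A, n),
         call. = FALSE)
  if (sp$theta == 0) {
    mm <- list(mu_A = mu_A, sigma_A = 0, m = log(mu_A), v = 0)
  } else {
    v <- log(1 + sp$theta^2 / n)
    mm <- list(mu_A = mu_A, sigma_A = sp$theta * mu_A / sqrt(n),
               m = log(mu_A) - v / 2, v = v)
  }
  structure(mm, class = "moment_match")
}

#' @export
print.moment_match <- function(x, ...) {
  cat(sprintf("Moment match: mu_A = %g, sigma_A = %g; X ~ N(m = %g, v = %g)\n",
              x$mu_A, x$sigma_A, x$m, x$v))
  invisible(x)
}

#' Distribution function of the failed-detection probability
#'
#' For \eqn{Q = \exp(-A)} with \eqn{\ln A \sim N(m, v)},
#' \deqn{\Pr(Q \le q) = 1 - \Phi\left(\frac{\ln(-\ln q) - m}{\sqrt v}\right).}
#' Implemented through the standard normal cdf rather than the equivalent
#' error-function form. `q` must lie strictly inside (0, 1): the endpoints
#' are rejected, not clamped.
#'
#' @param q Probabilities at which to evaluate the cdf, each in (0, 1).
#' @param mm A [moment_match()].
#' @return `Pr(Q <= q)`, same length as `q`. For a degenerate match
#'   (`v = 0`) the cdf is a step at `exp(-exp(m))`.
#' @export
q_cdf <- function(q, mm) {
  stopifnot(inherits(mm, "moment_match"))
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("'q' must lie strictly within (0, 1)", call. = FALSE)
  if (mm$v == 0) return(as.numeric(q >= exp(-exp(mm$m))))
  1 - stats::pnorm((log(-log(q)) - mm$m) / sqrt(mm$v))
}

#' Expected probability of failed detection
#'
#' Objective 1 evaluates \eqn{E[Q] = E[\exp(-e^X)]} with
#' \eqn{X \sim N(m, v)} from the moment match, by Gauss-Hermite quadrature on
#' the X scale (120 nodes; the integrand is smooth and one-dimensional, and
#' the rule agrees with adaptive quadrature to well below 1e-10). With
#' `theta = 0` the closed form \eqn{\exp(-(B' - n c'))} is returned exactly.
#'
#' @param n Number of surveys; may be a vector, evaluated elementwise.
#' @param sp A [scaled_problem()] or [design_problem()].
#' @param n_nodes Number of quadrature nodes.
#' @return `E[Q]` in (0, 1), same length as `n`.
#' @examples
#' sp <- scale_problem(design_problem(10, 1, rate_prior(0.67, theta = 2.5)))
#' 1 - expected_q(3, sp)  # expected detection probability at n = 3
#' @export
expected_q <- function(n, sp, n_nodes = 120L) {
  sp <- as_scaled(sp)
  if (length(n) > 1L)
    return(vapply(n, expected_q, numeric(1), sp = sp, n_nodes = n_nodes))
  mm <- moment_match(n, sp)
  if (mm$v == 0) return(exp(-mm$mu_A))
  gh <- gh_rule(n_nodes)
  x <- mm$m + sqrt(2 * mm$v) * gh$x
  sum(gh$w * exp(-exp(x))) / sqrt(pi)
}

#' Probability of meeting the detection target
#'
#' Objective 2 evaluates \eqn{\Pr(Q < Q_c)}, the chance that the realized
#' failed-detection probability is acceptably small. Since
#' \eqn{Q < Q_c \iff X > X_c}, this is the closed form
#' \eqn{\Phi\big((m - X_c)/\sqrt v\big)}. With `theta = 0` it degenerates to
#' the indicator that \eqn{B' - n c' > -\ln Q_c}.
#'
#' @param n Number of surveys; may be a vector, evaluated elementwise.
#' @param sp A [scaled_problem()] or [design_problem()].
#' @param target A [satisficing_target()].
#' @return `Pr(Q < Q_c)` in `[0, 1]`, same length as `n`.
#' @export
prob_target <- function(n, sp, target) {
  sp <- as_scaled(sp)
  stopifnot(inherits(target, "satisficing_target"))
  if (length(n) > 1L)
    return(vapply(n, prob_target, numeric(1), sp = sp, target = target))
  mm <- moment_match(n, sp)
  if (mm$v == 0) return(as.numeric(mm$mu_A > -log(target$Q_c)))
  stats::pnorm((mm$m - target$X_c) / sqrt(mm$v))
}

#' Evaluate one candidate design
#'
#' Bundles both objective values for a fixed number of surveys: the search
#' time per survey, the expected detection probability, and (when a target is
#' given) the chance of meeting it.
#'
#' @param n Number of surveys.
#' @param problem A [design_problem()] or [scaled_problem()]. With a scaled
#'   problem, `t` is reported in scaled time units (multiples of
#'   \eqn{1/\mu}).
#' @param target Optional [satisficing_target()].
#' @return A one-row data frame with columns `n`, `t`, `expected_Q`,
#'   `prob_below_Qc` (`NA` without a target).
#' @export
evaluate_design <- function(n, problem, target = NULL) {
  sp <- as_scaled(problem)
  n <- check_n(n)
  B <- if (inherits(problem, "design_problem")) problem$B else sp$Bp
  c_ <- if (inherits(problem, "design_problem")) problem$c else sp$cp
  data.frame(
    n = n,
    t = survey_time(n, B, c_),
    expected_Q = expected_q(n, sp),
    prob_below_Qc = if (is.null(target)) NA_real_ else prob_target(n, sp, target)
  )
}
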