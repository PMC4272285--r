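# Optimal integer number of surveys for both objectives: exact by
# enumeration over the feasible range, and closed-form approximations.

#' Exact optimal number of surveys: expected-detection objective
#'
#' Enumerates every feasible integer `n` (those with positive search time
#' `B/n - c > 0`) and returns the one minimizing the expected failed-
#' detection probability `E[Q]`. Ties are broken toward smaller `n` (fewer
#' trips at equal performance). Enumeration is the ground truth against which
#' the closed-form approximations are judged.
#'
#' @param sp A [scaled_problem()] or [design_problem()] with `cp > 0` and
#'   `Bp > cp`.
#' @param target Optional [satisficing_target()]; if supplied, the assurance
#'   `Pr(Q < Q_c)` is reported alongside (it does not affect the optimum).
#' @return An object of class `survey_optim`: a list with `best` (one-row
#'   data frame), `evaluations` (data frame over all feasible `n`, with an
#'   `is_optimal` flag) and `objective = "expected_detection"`.
#' @examples
#' sp <- scale_problem(design_problem(10, 1, rate_prior(0.67, theta = 2.5)))
#' optimal_n_expected(sp)$best$n  # 3
#' @export
optimal_n_expected <- function(sp, target = NULL) {
  sp <- as_scaled(sp)
  if (sp$cp <= 0)
    stop("optimization requires a positive fixed cost (else n grows without bound)",
         call. = FALSE)
  ns <- feasible_n(sp)
  eq <- expected_q(ns, sp)
  new_survey_optim(sp, ns, eq, objective = "expected_detection",
                   value = 1 - eq, best = which.min(eq), target = target)
}

#' Exact optimal number of surveys: satisficing objective
#'
#' Enumerates every feasible integer `n` and returns the one maximizing the
#' assurance `Pr(Q < Q_c)` that the realized failed-detection probability is
#' below the acceptable level. Ties are broken toward smaller `n`.
#'
#' @inheritParams optimal_n_expected
#' @param target A [satisficing_target()].
#' @return An object of class `survey_optim` with
#'   `objective = "satisficing"`.
#' @examples
#' sp <- scale_problem(design_problem(10, 1, rate_prior(0.67, theta = 2.5)))
#' optimal_n_satisficing(sp, satisficing_target(Q_c = 0.05))$best$n  # 2
#' @export
optimal_n_satisficing <- function(sp, target) {
  sp <- as_scaled(sp)
  stopifnot(inherits(target, "satisficing_target"))
  if (sp$cp <= 0)
    stop("optimization requires a positive fixed cost", call. = FALSE)
  ns <- feasible_n(sp)
  pt <- prob_target(ns, sp, target)
  # argmax via the normal z-statistic (m - X_c)/sqrt(v), the monotone
  # transform of Pr(Q < Q_c): at small theta the probabilities saturate to
  # 1 in floating point and would tie arbitrarily
  z <- satisficing_z(ns, sp, target)
  new_survey_optim(sp, ns, expected_q(ns, sp), objective = "satisficing",
                   value = pt, best = which.max(z), target = target)
}

satisficing_z <- function(ns, sp, target) {
  vapply(ns, function(n) {
    mm <- moment_match(n, sp)
    if (mm$v == 0) {
      # point mass: rank deterministic designs by their margin over the bar
      if (mm$mu_A > -log(target$Q_c)) 1e6 + mm$mu_A else -1e6 + mm$mu_A
    } else (mm$m - target$X_c) / sqrt(mm$v)
  }, numeric(1))
}

new_survey_optim <- function(sp, ns, eq, objective, value, best, target) {
  ev <- data.frame(
    n = ns,
    t = sp$Bp / ns - sp$cp,
    expected_Q = eq,
    prob_below_Qc = if (is.null(target)) NA_real_
                    else prob_target(ns, sp, target),
    objective_value = value,
    is_optimal = FALSE
  )
  if (objective == "satisficing") ev$prob_below_Qc <- value
  ev$is_optimal[best] <- TRUE
  structure(list(best = ev[best, , drop = FALSE], evaluations = ev,
                 objective = objective, problem = sp, target = target),
            class = "survey_optim")
}

#' @export
print.survey_optim <- function(x, ...) {
  lab <- switch(x$objective,
                expected_detection = "maximize expected detection probability",
                satisficing = "maximize Pr(Q < Q_c)")
  cat(sprintf("Optimal design (%s):\n", lab))
  cat(sprintf("  n = %d surveys, search time %.4g each\n",
              x$best$n, x$best$t))
  cat(sprintf("  expected detection probability 1 - E[Q] = %.4f\n",
              1 - x$best$expected_Q))
  if (!is.na(x$best$prob_below_Qc))
    cat(sprintf("  Pr(Q < %g) = %.4f\n", x$target$Q_c, x$best$prob_below_Qc))
  cat(sprintf("  (%d feasible designs evaluated)\n", nrow(x$evaluations)))
  invisible(x)
}

#' @export
as.data.frame.survey_optim <- function(x, ...) x$evaluations

#' Write a design table to CSV
#'
#' @param x A `survey_optim` result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(x, path) {
  stopifnot(inherits(x, "survey_optim"))
  utils::write.csv(x$evaluations, path, row.names = FALSE)
  invisible(path)
}

#' Closed-form approximation: expected-detection objective
#'
#' Laplace's method applied to the one-dimensional integral defining `E[Q]`
#' yields a continuous approximate optimum that depends only on the
#' budget-to-fixed-cost ratio `B/c` and the coefficient of variation
#' \eqn{\theta}: the positive root of
#' \deqn{n^2 + 3\theta^2 n - 2 (B/c) \theta^2 = 0,}
#' i.e. \eqn{n^\ast = \tfrac{3\theta^2}{2}\left(\sqrt{1 + 8B/(9 c\,\theta^2)} - 1\right).}
#' The root is rounded to the nearest feasible integer (at least 1). As
#' \eqn{\theta \to 0} the root tends to 0, recovering the classical single
#' long visit; it grows with both \eqn{\theta} and `B/c`.
#'
#' @param B Total budget, > 0.
#' @param c Fixed cost per survey, with `B > c > 0`.
#' @param theta Coefficient of variation of the detection rate, >= 0.
#' @return A positive integer number of surveys.
#' @examples
#' approx_n_expected(10, 1, 2.5)  # 5
#' @export
approx_n_expected <- function(B, c, theta) {
  if (!is.numeric(B) || !is.numeric(c) || length(B) != 1L || length(c) != 1L ||
      c <= 0 || B <= c)
    stop("need B > c > 0", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0)
    stop("'theta' must be >= 0", call. = FALSE)
  N <- B / c
  n_cont <- if (theta == 0) 0 else
    (sqrt(9 * theta^4 + 8 * N * theta^2) - 3 * theta^2) / 2
  nm <- n_max_feasible(N, 1)  # feasibility depends on B/c only
  max(1L, min(nm, as.integer(round(n_cont))))
}

#' Closed-form approximation: satisficing objective
#'
#' For small \eqn{\theta}, maximizing \eqn{(m - X_c)/\sqrt v} in continuous
#' `n` reduces to the explicit solution
#' \deqn{n^\ast = \frac{B'}{c'}\left(1 - \frac{2}{W(2 B' e^{2 - X_c})}\right),}
#' where `W` is the Lambert W function and \eqn{X_c = \ln(-\ln Q_c)}. The
#' scaled fixed cost enters only as the leading factor, so doubling `c'`
#' halves the approximate optimum; a tougher target (smaller `Q_c`, larger
#' `X_c`) shrinks the Lambert-W argument and prescribes fewer, longer
#' surveys. The continuous value is rounded by evaluating the exact
#' assurance at its floor and ceiling and keeping the better, with ties and
#' degenerate cases resolved toward smaller `n`.
#'
#' @param sp A [scaled_problem()] or [design_problem()].
#' @param target A [satisficing_target()].
#' @return A positive integer number of surveys.
#' @examples
#' sp <- scale_problem(design_problem(10, 1, rate_prior(0.67, theta = 2.5)))
#' approx_n_satisficing(sp, satisficing_target(Q_c = 0.05))  # 2
#' @export
approx_n_satisficing <- function(sp, target) {
  sp <- as_scaled(sp)
  stopifnot(inherits(target, "satisficing_target"))
  if (sp$cp <= 0 || sp$Bp <= sp$cp)
    stop("need Bp > cp > 0", call. = FALSE)
  w <- pracma::lambertWp(2 * sp$Bp * exp(2 - target$X_c))
  n_cont <- (sp$Bp / sp$cp) * (1 - 2 / w)
  nm <- n_max_feasible(sp$Bp, sp$cp)
  cand <- unique(pmin(nm, pmax(1L, c(floor(n_cont), ceiling(n_cont)))))
  cand <- as.integer(cand)
  if (length(cand) == 1L) return(cand)
  val <- satisficing_z(cand, sp, target)
  cand[order(-val, cand)][1L]
}

#' Continuous stationary point of the satisficing objective
#'
#' Solves, in continuous `n`, the first-order condition for maximizing
#' \eqn{G(n) = (m(n) - X_c)/\sqrt{v(n)}}, namely
#' \eqn{2 v(n)\, m'(n) = (m(n) - X_c)\, v'(n)}, by bracketed root finding to
#' tolerance 1e-8. When an interior maximum exists (the side condition:
#' `G` increases then decreases through the root), the integer optimum from
#' enumeration is the floor or ceiling of this root.
#'
#' @inheritParams approx_n_satisficing
#' @return A list with `root` (continuous `n`, or `NA`), `status` (one of
#'   `"interior"`, `"boundary"`, `"degenerate"`) and
#'   `side_condition_holds` (logical: root is a local maximum of `G`).
#' @export
solve_implicit_satisficing <- function(sp, target) {
  sp <- as_scaled(sp)
  stopifnot(inherits(target, "satisficing_target"))
  if (sp$theta == 0)
    return(list(root = NA_real_, status = "degenerate",
                side_condition_holds = FALSE))
  if (sp$cp <= 0 || sp$Bp <= sp$cp)
    stop("need Bp > cp > 0", call. = FALSE)
  th2 <- sp$theta^2
  # H(n) = 2 v m' - (m - X_c) v'; same sign as dG/dn
  H <- function(n) {
    muA <- sp$Bp - n * sp$cp
    v <- log(1 + th2 / n)
    vp <- -th2 / (n * (n + th2))
    m <- log(muA) - v / 2
    mp <- -sp$cp / muA - vp / 2
    2 * v * mp - (m - target$X_c) * vp
  }
  nm <- n_max_feasible(sp$Bp, sp$cp)
  hi <- sp$Bp / sp$cp - 1e-9
  grid <- seq(1e-9 + .Machine$double.eps, hi, length.out = max(64L, 4L * nm))
  hv <- vapply(grid, H, numeric(1))
  sgn <- sign(hv)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flip))
    return(list(root = NA_real_, status = "boundary",
                side_condition_holds = FALSE))
  i <- flip[1]
  root <- stats::uniroot(H, c(grid[i], grid[i + 1]), tol = 1e-8)$root
  list(root = root, status = "interior",
       side_condition_holds = hv[i] > 0 && hv[i + 1] < 0)
}

#' Near-optimal designs
#'
#' All feasible survey numbers whose objective value lies within `delta`
#' probability units of the optimum, in the spirit of flagging the region of
#' designs "no more than 0.01 probability units away" from the best.
#'
#' @param sp A [scaled_problem()] or [design_problem()].
#' @param objective `"expected_detection"` or `"satisficing"`.
#' @param delta Allowed shortfall in probability units, >= 0.
#' @param target A [satisficing_target()]; required for the satisficing
#'   objective.
#' @return Sorted integer vector of near-optimal `n`; always contains the
#'   optimum.
#' @export
near_optimal_set <- function(sp, objective = c("expected_detection", "satisficing"),
                             delta = 0.01, target = NULL) {
  objective <- match.arg(objective)
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0)
  res <- if (objective == "expected_detection") optimal_n_expected(sp, target)
         else optimal_n_satisficing(sp, target)
  ev <- res$evaluations
  keep <- ev$objective_value >= max(ev$objective_value) - delta
  sort(ev$n[keep])
}
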