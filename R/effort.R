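# Minimum-survey-effort protocols: how performance grows with the scaled
# budget, and the smallest budget achieving a required level, assuming the
# number of surveys is re-optimized at every budget.

#' Performance as a function of the scaled budget
#'
#' For each budget on the grid, finds the best achievable expected detection
#' probability (objective 1) and, if a target is supplied, the best
#' achievable assurance `Pr(Q < Q_c)` (objective 2), each with the survey
#' number attaining it. Budgets not exceeding the scaled fixed cost are
#' flagged infeasible.
#'
#' @param cp Scaled fixed cost per survey, >= 0.
#' @param theta Coefficient of variation of the detection rate.
#' @param budgets Strictly positive, increasing grid of scaled budgets.
#' @param target Optional [satisficing_target()].
#' @return A data frame with columns `Bp`, `feasible`, `best_n_obj1`,
#'   `expected_detection`, and with a target also `best_n_obj2`,
#'   `assurance`.
#' @examples
#' performance_curve(0.5, 1.5, c(2, 4, 8), satisficing_target(Q_c = 0.1))
#' @export
performance_curve <- function(cp, theta, budgets, target = NULL) {
  if (!is.numeric(budgets) || any(budgets <= 0) || is.unsorted(budgets, strictly = TRUE))
    stop("'budgets' must be a strictly increasing positive grid", call. = FALSE)
  one <- function(Bp) {
    if (Bp <= cp || (cp > 0 && n_max_feasible(Bp, cp) < 1L))
      return(data.frame(Bp = Bp, feasible = FALSE, best_n_obj1 = NA_integer_,
                        expected_detection = NA_real_,
                        best_n_obj2 = NA_integer_, assurance = NA_real_))
    if (cp == 0) {
      # no fixed cost: splitting is free, performance approaches the
      # variance-free limit (exact when theta = 0, supremum otherwise)
      out <- data.frame(Bp = Bp, feasible = TRUE, best_n_obj1 = NA_integer_,
                        expected_detection = 1 - exp(-Bp),
                        best_n_obj2 = NA_integer_, assurance = NA_real_)
      if (!is.null(target)) out$assurance <- as.numeric(Bp > -log(target$Q_c))
      return(out)
    }
    sp <- scaled_problem(Bp, cp, theta)
    ns <- feasible_n(sp)
    eq <- expected_q(ns, sp)
    i1 <- which.min(eq)
    out <- data.frame(Bp = Bp, feasible = TRUE, best_n_obj1 = ns[i1],
                      expected_detection = 1 - eq[i1],
                      best_n_obj2 = NA_integer_, assurance = NA_real_)
    if (!is.null(target)) {
      pt <- prob_target(ns, sp, target)
      i2 <- which.max(pt)
      out$best_n_obj2 <- ns[i2]
      out$assurance <- pt[i2]
    }
    out
  }
  res <- do.call(rbind, lapply(budgets, one))
  if (is.null(target)) res$best_n_obj2 <- res$assurance <- NULL
  rownames(res) <- NULL
  res
}

best_objective <- function(Bp, cp, theta, target = NULL) {
  if (Bp <= cp || (cp > 0 && n_max_feasible(Bp, cp) < 1L)) return(0)
  if (cp == 0) {
    if (is.null(target)) return(1 - exp(-Bp))
    return(as.numeric(Bp > -log(target$Q_c)))
  }
  sp <- scaled_problem(Bp, cp, theta)
  ns <- feasible_n(sp)
  if (is.null(target)) max(1 - expected_q(ns, sp))
  else max(prob_target(ns, sp, target))
}

min_budget_bisect <- function(requirement, cp, theta, target, tol = 1e-6) {
  f <- function(Bp) best_objective(Bp, cp, theta, target) - requirement
  lo <- cp + 1e-6
  hi <- max(2 * lo, 1)
  while (f(hi) < 0) hi <- 2 * hi  # requirement is monotone in Bp
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  hi
}

#' Minimum scaled budget for a required expected detection probability
#'
#' Smallest `Bp` such that, with the number of surveys chosen optimally for
#' that budget, the expected detection probability `1 - E[Q]` reaches
#' `p_target`. Solved by bisection (tolerance 1e-6) on the inner
#' enumeration; the requirement is monotone in the budget.
#'
#' @param p_target Required expected detection probability, in (0, 1).
#' @param cp Scaled fixed cost, >= 0.
#' @param theta Coefficient of variation.
#' @return The minimal scaled budget.
#' @examples
#' min_budget_expected(0.9, cp = 0, theta = 0)    # -log(0.1)
#' min_budget_expected(0.9, cp = 0.5, theta = 1.5)
#' @export
min_budget_expected <- function(p_target, cp, theta) {
  if (!is.numeric(p_target) || length(p_target) != 1L || p_target <= 0 || p_target >= 1)
    stop("'p_target' must be in (0, 1)", call. = FALSE)
  if (theta == 0) return(-log(1 - p_target) + cp)  # one visit, one fixed cost
  min_budget_bisect(p_target, cp, theta, target = NULL)
}

#' Minimum scaled budget for a required assurance level
#'
#' Smallest `Bp` such that the best achievable `Pr(Q < Q_c)` over feasible
#' survey numbers reaches the assurance level `P_c`. With `theta = 0` the
#' rate is deterministic and the answer is the single-visit closed form
#' `-log(Q_c) + cp` for any `P_c`.
#'
#' @param target A [satisficing_target()].
#' @param P_c Required assurance, in (0, 1).
#' @param cp Scaled fixed cost, >= 0.
#' @param theta Coefficient of variation.
#' @return The minimal scaled budget.
#' @examples
#' min_budget_satisficing(satisficing_target(Q_c = 0.1), 0.9, 0.5, 1.5)
#' @export
min_budget_satisficing <- function(target, P_c, cp, theta) {
  stopifnot(inherits(target, "satisficing_target"))
  if (!is.numeric(P_c) || length(P_c) != 1L || P_c <= 0 || P_c >= 1)
    stop("'P_c' must be in (0, 1)", call. = FALSE)
  if (theta == 0) return(-log(target$Q_c) + cp)
  min_budget_bisect(P_c, cp, theta, target)
}
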