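# Model-free procedures from search-experiment data: empirical
# failed-detection probability (y/v)^n over observer-by-quadrat
# combinations, the empirical optimal number of quadrats, and the
# resampling test of the satisficing objective.

check_times <- function(times, censored) {
  if (!length(times)) stop("'times' must be nonempty", call. = FALSE)
  if (is.null(censored)) censored <- rep(FALSE, length(times))
  if (length(censored) != length(times))
    stop("'censored' must match 'times' in length", call. = FALSE)
  if (any(!censored & (!is.finite(times) | times <= 0)))
    stop("uncensored times must be finite and > 0", call. = FALSE)
  censored
}

#' Empirical probability of failed detection
#'
#' With search time `t = B/n - c` per quadrat, a combination counts as a
#' failure when it produced no detection by time `t` (its first-detection
#' time exceeds `t`, or it is censored). If `y` of the `v` combinations
#' fail, the chance of missing the species in all `n` independently drawn
#' quadrat searches is `(y/v)^n`.
#'
#' @param times First-detection time per observer-by-quadrat combination.
#' @param n Number of quadrats searched.
#' @param B Total time budget.
#' @param c Fixed travel cost per quadrat.
#' @param censored Optional logical vector: combination never detected
#'   within its session (its `times` entry is ignored).
#' @return The empirical failure probability `(y/v)^n`.
#' @examples
#' empirical_failure_prob(c(1, 2, 5, 9), n = 2, B = 6, c = 1)  # (2/4)^2
#' @export
empirical_failure_prob <- function(times, n, B, c, censored = NULL) {
  censored <- check_times(times, censored)
  n <- check_n(n)
  t <- survey_time(n, B, c)
  y <- sum(censored | times > t)
  (y / length(times))^n
}

#' Empirical optimal number of quadrats
#'
#' Minimizes the empirical failure probability `(y/v)^n` over every feasible
#' `n` (note `y` itself depends on `n` through `t = B/n - c`). Ties go to
#' the smaller `n`.
#'
#' @inheritParams empirical_failure_prob
#' @return A list of class `empirical_optim`: `optimal_n` and `grid`, a data
#'   frame with columns `n`, `t`, `y`, `v_total`, `failure_prob`.
#' @examples
#' empirical_optimal_n(c(1, 2, 5, 9), B = 6, c = 1)$optimal_n
#' @export
empirical_optimal_n <- function(times, B, c, censored = NULL) {
  censored <- check_times(times, censored)
  ns <- feasible_n(scaled_problem(B, c, 0))
  v <- length(times)
  grid <- do.call(rbind, lapply(ns, function(n) {
    t <- B / n - c
    y <- sum(censored | times > t)
    data.frame(n = n, t = t, y = y, v_total = v, failure_prob = (y / v)^n)
  }))
  best <- which.min(grid$failure_prob)  # which.min takes the first = smallest n
  structure(list(optimal_n = grid$n[best], grid = grid),
            class = "empirical_optim")
}

#' @export
print.empirical_optim <- function(x, ...) {
  cat(sprintf("Empirical optimum: n = %d (failure probability %.4g)\n",
              x$optimal_n, x$grid$failure_prob[x$grid$n == x$optimal_n]))
  invisible(x)
}

#' Resampling test of the satisficing objective
#'
#' Meeting the failed-detection target `Q_c` is equivalent to accruing an
#' expected number of detections of at least `-log(Q_c)` over the `n`
#' searches. Each replicate draws `n` empirical per-combination rates with
#' replacement (rate = detected individuals / time searched, computed
#' upstream) and succeeds when `(B/n - c) * sum(rates) >= -log(Q_c)`.
#'
#' @param rates Nonnegative empirical detection rates, one per
#'   observer-by-quadrat combination.
#' @param n Number of quadrats searched per replicate.
#' @param B Total budget.
#' @param c Fixed travel cost per quadrat.
#' @param target A [satisficing_target()].
#' @param reps Number of resampling replicates (the reference analysis used
#'   one million).
#' @param seed Integer seed.
#' @return The proportion of replicates meeting the target.
#' @examples
#' satisficing_resample(c(0, 1), n = 2, B = 6, c = 1,
#'                      satisficing_target(Q_c = exp(-3)), reps = 1e4, seed = 1)
#' @export
satisficing_resample <- function(rates, n, B, c, target, reps = 1e6, seed = 1L) {
  if (!length(rates)) stop("'rates' must be nonempty", call. = FALSE)
  if (any(rates < 0)) stop("'rates' must be >= 0", call. = FALSE)
  stopifnot(inherits(target, "satisficing_target"))
  if (!is.numeric(reps) || reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  n <- check_n(n)
  t <- survey_time(n, B, c)
  need <- -log(target$Q_c)
  reps <- as.integer(reps)
  set.seed(seed)
  hits <- 0L
  block <- 200000L
  done <- 0L
  while (done < reps) {
    k <- min(block, reps - done)
    tot <- colSums(matrix(sample(rates, k * n, replace = TRUE), nrow = n))
    hits <- hits + sum(t * tot >= need)
    done <- done + k
  }
  hits / reps
}

#' Empirical optimal number of quadrats for the satisficing objective
#'
#' Maximizes the resampled success proportion of [satisficing_resample()]
#' over every feasible `n`, using a per-`n` random stream derived from the
#' master seed so the proportions are comparable. Ties go to the smaller
#' `n`.
#'
#' @inheritParams satisficing_resample
#' @return A list of class `empirical_optim`: `optimal_n` and `grid` (data
#'   frame with `n`, `t`, `success_prob`).
#' @export
empirical_optimal_n_satisficing <- function(rates, B, c, target, reps = 1e6,
                                            seed = 1L) {
  ns <- feasible_n(scaled_problem(B, c, 0))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(ns))
  succ <- vapply(seq_along(ns), function(i) {
    satisficing_resample(rates, ns[i], B, c, target, reps, sub_seeds[i])
  }, numeric(1))
  grid <- data.frame(n = ns, t = B / ns - c, success_prob = succ)
  structure(list(optimal_n = ns[which.max(succ)], grid = grid),
            class = "empirical_optim")
}

#' Agreement between predicted and observed optima
#'
#' Ordinary least-squares slope (through the data, with intercept) and the
#' Pearson correlation between model-predicted and empirically observed
#' optimal survey numbers across design settings.
#'
#' @param predicted Numeric vector of model-predicted optima.
#' @param observed Numeric vector of observed optima, same length.
#' @return A list with `slope`, `se_slope`, `intercept`, `pearson_r`.
#' @export
predicted_vs_observed <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 3L)
  fit <- stats::lm(observed ~ predicted)
  s <- summary(fit)$coefficients
  list(slope = unname(s["predicted", "Estimate"]),
       se_slope = unname(s["predicted", "Std. Error"]),
       intercept = unname(s["(Intercept)", "Estimate"]),
       pearson_r = stats::cor(predicted, observed))
}
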