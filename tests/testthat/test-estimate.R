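test_that("degenerate and invalid inputs are handled explicitly", {
  one <- data.frame(observer = 1, quadrat = 1, time_to_detection = 4,
                    session_length = 15, censored = FALSE)
  # single uncensored record: fixed-rate exponential MLE
  f <- fit_time_to_detection(one)
  expect_equal(f$mu_hat, 1 / 4)
  expect_equal(f$sigma_hat, 0)
  allc <- data.frame(observer = 1:4, quadrat = 1, time_to_detection = 15,
                     session_length = 15, censored = TRUE)
  expect_error(fit_time_to_detection(allc), "censored")
  cnt <- data.frame(site = c(1, 1, 2, 2), visit = c(1, 2, 1, 2),
                    detections = 0L, search_time = 1)
  expect_error(fit_rate_counts(cnt), "no detections")
  expect_error(fit_rate_counts(cnt[1:2, ]), "2 sites")
})

test_that("the marginal likelihood matches brute-force integration", {
  spec <- scenario_spec(rate_prior(0.55, sigma = 0.60), n_observers = 3,
                        n_quadrats = 2, seed = 42)
  rec <- gen_quadrat_experiment(spec)
  unit <- interaction(rec$observer, rec$quadrat, drop = TRUE)
  d <- as.numeric(tapply(!rec$censored, unit, sum))
  S <- as.numeric(tapply(ifelse(rec$censored, rec$session_length,
                                rec$time_to_detection), unit, sum))
  for (p in list(c(-0.8, log(0.6)), c(-0.3, log(1.1)))) {
    # quadrature marginal likelihood per unit
    gh <- surveyopt:::gh_rule(30L)
    l <- p[1] + sqrt(2) * exp(p[2]) * gh$x
    quad <- vapply(seq_along(d), function(u)
      sum(gh$w / sqrt(pi) * exp(d[u] * l - S[u] * exp(l))), numeric(1))
    # brute-force Monte Carlo integration over the random effect
    set.seed(99)
    lmc <- p[1] + exp(p[2]) * rnorm(2e6)
    mc <- vapply(seq_along(d), function(u)
      mean(exp(d[u] * lmc - S[u] * exp(lmc))), numeric(1))
    expect_lt(max(abs(quad - mc)), 1e-3)
  }
})

test_that("the count likelihood agrees with an independent mixed-model fit", {
  spec <- scenario_spec(rate_prior(0.67, theta = 2.5), n_sites = 20,
                        visits = 4, search_time = 1, abundance = c(1, 3),
                        beta = 1.0824, seed = 5)
  rec <- gen_repeat_surveys(spec)
  mine <- fit_rate_counts(rec)
  rec$obs <- seq_len(nrow(rec))
  ref <- lme4::glmer(detections ~ log(abundance) + (1 | obs),
                     offset = log(rec$search_time), family = stats::poisson,
                     data = rec, nAGQ = 25L)
  expect_equal(unname(mine$coef["meanlog"]), unname(lme4::fixef(ref)[1]),
               tolerance = 1e-3)
  expect_equal(unname(mine$coef["beta"]), unname(lme4::fixef(ref)[2]),
               tolerance = 1e-3)
  expect_equal(unname(exp(mine$coef["log_sdlog"])),
               unname(sqrt(unlist(lme4::VarCorr(ref)))), tolerance = 1e-3)
})

test_that("fits recover the generating rate distribution", {
  spec <- scenario_spec(rate_prior(0.55, sigma = 0.60), seed = 11)
  f <- fit_time_to_detection(gen_quadrat_experiment(spec))
  expect_true(f$converged)
  expect_gt(f$mu_hat, 0.3); expect_lt(f$mu_hat, 0.9)
  expect_true(f$ci["mu", 1] < f$mu_hat & f$mu_hat < f$ci["mu", 2])

  specc <- scenario_spec(rate_prior(0.67, theta = 2.5), n_sites = 29,
                         visits = 3, search_time = 1, abundance = c(1, 3),
                         beta = 1.0824, seed = 12)
  fc <- fit_rate_counts(gen_repeat_surveys(specc))
  expect_true(fc$converged)
  expect_true(fc$ci["mu", 1] <= 0.67 * 2 && fc$ci["mu", 2] >= 0.67 / 2)
})

test_that("constant-rate data show no heterogeneity beyond chance", {
  # truth on the sigma = 0 boundary: the MLE of a variance component is 0
  # about half the time and a small positive value otherwise, so judge the
  # fitted spread by the likelihood-ratio statistic against the pure
  # exponential null (asymptotic null: half chi-square(1), 95% point 2.71)
  lrt <- theta_hat <- numeric(10)
  for (k in 1:10) {
    spec <- scenario_spec(rate_prior(0.5, sigma = 0), n_observers = 20,
                          n_quadrats = 10, seed = 300 + k)
    rec <- gen_quadrat_experiment(spec)
    f <- fit_time_to_detection(rec)
    d <- sum(!rec$censored)
    S <- sum(ifelse(rec$censored, rec$session_length, rec$time_to_detection))
    ll0 <- d * log(d / S) - d          # exponential MLE loglik
    lrt[k] <- 2 * (f$logLik - ll0)
    theta_hat[k] <- f$theta_hat
  }
  expect_gte(sum(lrt <= 2.71), 9)
  expect_lt(median(theta_hat), 0.1)
  # the random effect can only help the fit, up to the tiny slack left by
  # the optimizer's lower bound on log(sdlog)
  expect_true(all(lrt >= -1e-4))
})

test_that("abundance predictions scale log-linearly and reduce to identity", {
  spec <- scenario_spec(rate_prior(0.67, theta = 2.5), n_sites = 29,
                        visits = 4, search_time = 1, abundance = c(1, 3),
                        beta = 1.0824, seed = 21)
  f <- fit_rate_counts(gen_repeat_surveys(spec))
  r1 <- predict_rate(f, 1)
  r3 <- predict_rate(f, 3)
  expect_equal(r3$mu / r1$mu, 3^f$coef[["beta"]])
  expect_equal(r1$theta, r3$theta)     # visit spread is abundance-free
  expect_equal(r1$mu, f$mu_hat)
  expect_error(predict_rate(f, -1), "abundance")
  # covariate-free fit ignores abundance
  fttd <- fit_time_to_detection(gen_quadrat_experiment(
    scenario_spec(rate_prior(0.55, sigma = 0.6), seed = 2)))
  expect_equal(predict_rate(fttd, 3)$mu, fttd$mu_hat)
})

test_that("a null abundance effect is covered by its interval", {
  spec <- scenario_spec(rate_prior(0.6, theta = 1), n_sites = 40, visits = 4,
                        search_time = 1, abundance = c(1, 2, 4), beta = 0,
                        seed = 31)
  f <- fit_rate_counts(gen_repeat_surveys(spec))
  expect_true(f$beta_ci[1] <= 0 && 0 <= f$beta_ci[2])
})

test_that("record CSVs round-trip through the readers", {
  spec <- scenario_spec(rate_prior(0.55, sigma = 0.6), n_observers = 4,
                        n_quadrats = 3, seed = 8)
  rec <- gen_quadrat_experiment(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_detection_records(rec, path)
  back <- read_detection_records(path)
  expect_equal(back, rec, tolerance = 1e-12)

  cnt <- gen_repeat_surveys(scenario_spec(rate_prior(0.6, theta = 1),
                                          n_sites = 5, visits = 3, seed = 8))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_survey_counts(cnt, path2)
  expect_equal(read_survey_counts(path2), cnt, tolerance = 1e-12)
  expect_error(read_survey_counts(path), "missing columns")
})
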