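test_that("enumeration finds the published expected-detection optima", {
  expect_equal(optimal_n_expected(frog_sp(1))$best$n, 3L)
  expect_equal(optimal_n_expected(frog_sp(3))$best$n, 4L)
  expect_equal(optimal_n_expected(plant_sp("lomandra"))$best$n, 11L)
  # no variability: a single long visit minimizes fixed costs
  expect_equal(optimal_n_expected(scaled_problem(8, 0.4, 0))$best$n, 1L)
  expect_error(optimal_n_expected(scaled_problem(5, 0, 1)), "positive fixed cost")
})

test_that("enumeration finds the published satisficing optima", {
  expect_equal(optimal_n_satisficing(frog_sp(1), qc05())$best$n, 2L)
  expect_equal(optimal_n_satisficing(frog_sp(3), qc05())$best$n, 4L)
  expect_equal(optimal_n_satisficing(plant_sp("lomandra"), qc05())$best$n, 16L)
  expect_equal(optimal_n_satisficing(plant_sp("atriplex"), qc05())$best$n, 16L)
})

test_that("satisficing enumeration equals the closed-form argmax", {
  for (sp in list(frog_sp(1), frog_sp(3), plant_sp("lomandra"),
                  scaled_problem(12, 0.3, 0.8))) {
    ns <- seq_len(nrow(optimal_n_expected(sp)$evaluations))
    z <- vapply(ns, function(n) {
      mm <- moment_match(n, sp)
      (mm$m - qc05()$X_c) / sqrt(mm$v)
    }, numeric(1))
    expect_equal(optimal_n_satisficing(sp, qc05())$best$n, ns[which.max(z)])
  }
})

test_that("the expected-detection approximation depends only on B/c and theta", {
  expect_equal(approx_n_expected(10, 1, 2.5), 5L)
  expect_equal(approx_n_expected(100, 10, 2.5), approx_n_expected(10, 1, 2.5))
  expect_equal(approx_n_expected(30, 2, 1.2), approx_n_expected(15, 1, 1.2))
  expect_equal(approx_n_expected(7, 0.5, 0), 1L)
  expect_error(approx_n_expected(1, 2, 1), "B > c")
})

test_that("the approximation never beats enumeration and stays near it", {
  grid <- expand.grid(Bc = c(5, 10, 15, 25), theta = c(0.5, 1, 1.5, 3))
  for (i in seq_len(nrow(grid))) {
    sp <- scaled_problem(grid$Bc[i] * 0.5, 0.5, grid$theta[i])
    exact <- optimal_n_expected(sp)
    napp <- approx_n_expected(sp$Bp, sp$cp, sp$theta)
    gap <- expected_q(napp, sp) - exact$best$expected_Q
    expect_gte(gap, 0)          # enumeration is the ground truth
    expect_lte(gap, 0.07)       # worst corner: tiny budget, huge variability
    if (grid$theta[i] <= 1.5 && sp$Bp >= 5) expect_lte(gap, 0.02)
  }
  # frozen reference gaps on the B/c = 15 display grid (c' = 0.5), computed
  # by the enumeration oracle: negligible at moderate variability, about
  # 0.022 at theta = 3 where the ratio-only formula overshoots
  gaps <- vapply(c(0.5, 1, 3), function(th) {
    sp <- scaled_problem(7.5, 0.5, th)
    expected_q(approx_n_expected(7.5, 0.5, th), sp) -
      optimal_n_expected(sp)$best$expected_Q
  }, numeric(1))
  expect_lt(gaps[1], 0.001)
  expect_lt(gaps[2], 0.001)
  expect_equal(round(gaps[3], 3), 0.022)
})

test_that("the satisficing approximation matches enumeration where claimed", {
  # both frog abundance levels: approximation reproduces the exact optimum
  expect_equal(approx_n_satisficing(frog_sp(1), qc05()),
               optimal_n_satisficing(frog_sp(1), qc05())$best$n)
  expect_equal(approx_n_satisficing(frog_sp(3), qc05()),
               optimal_n_satisficing(frog_sp(3), qc05())$best$n)
  # the scaled fixed cost is a pure scaling factor: doubling it halves n
  n1 <- approx_n_satisficing(scaled_problem(20, 0.25, 0.1), qc05())
  n2 <- approx_n_satisficing(scaled_problem(20, 0.5, 0.1), qc05())
  expect_lte(abs(n2 - n1 / 2), 1)
  # small-theta regime: matches enumeration on most of a grid
  grid <- expand.grid(Bp = c(6, 10, 16), cp = c(0.25, 0.5, 1),
                      Qc = c(0.05, 0.1, 0.2))
  hits <- 0
  for (i in seq_len(nrow(grid))) {
    sp <- scaled_problem(grid$Bp[i], grid$cp[i], 0.1)
    tg <- satisficing_target(Q_c = grid$Qc[i])
    hits <- hits + (approx_n_satisficing(sp, tg) ==
                      optimal_n_satisficing(sp, tg)$best$n)
  }
  expect_gte(hits / nrow(grid), 0.9)
})

test_that("the continuous satisficing stationary point brackets the optimum", {
  sol <- solve_implicit_satisficing(frog_sp(1), qc05())
  expect_equal(sol$status, "interior")
  expect_true(sol$side_condition_holds)
  n_exact <- optimal_n_satisficing(frog_sp(1), qc05())$best$n
  expect_true(n_exact %in% c(floor(sol$root), ceiling(sol$root)))
  # local optimality of the root in continuous n
  g0 <- {
    muA <- 6.7 - sol$root * 0.67
    v <- log(1 + 2.5^2 / sol$root)
    (log(muA) - v / 2 - qc05()$X_c) / sqrt(v)
  }
  for (d in c(-0.5, 0.5)) {
    muA <- 6.7 - (sol$root + d) * 0.67
    v <- log(1 + 2.5^2 / (sol$root + d))
    expect_lte((log(muA) - v / 2 - qc05()$X_c) / sqrt(v), g0)
  }
  expect_equal(solve_implicit_satisficing(scaled_problem(5, 0.5, 0), qc05())$status,
               "degenerate")
})

test_that("near-optimal sets contain the optimum and grow with delta", {
  sp <- frog_sp(1)
  opt <- optimal_n_expected(sp)$best$n
  s0 <- near_optimal_set(sp, "expected_detection", delta = 0)
  expect_true(opt %in% s0)
  ev <- optimal_n_expected(sp)$evaluations
  expect_equal(s0, ev$n[ev$objective_value == max(ev$objective_value)])
  s1 <- near_optimal_set(sp, "expected_detection", delta = 0.01)
  expect_true(3 %in% s1)
  s2 <- near_optimal_set(sp, "expected_detection", delta = 0.05)
  expect_true(all(s1 %in% s2))
  ssat <- near_optimal_set(sp, "satisficing", delta = 0, target = qc05())
  expect_true(optimal_n_satisficing(sp, qc05())$best$n %in% ssat)
})

test_that("optimal survey numbers shift as theory predicts", {
  # more variable rates favor more, shorter surveys
  n_by_theta <- vapply(c(0, 0.5, 1, 1.5, 2, 3), function(th)
    optimal_n_expected(scaled_problem(7.5, 0.5, th))$best$n, integer(1))
  expect_true(all(diff(n_by_theta) >= 0))
  # with B/c fixed, a larger scaled budget favors more surveys
  n_by_Bp <- vapply(c(2, 5, 10, 25, 60), function(Bp)
    optimal_n_expected(scaled_problem(Bp, Bp / 10, 1.5))$best$n, integer(1))
  expect_true(all(diff(n_by_Bp) >= 0))
})

test_that("design tables round-trip through CSV", {
  res <- optimal_n_expected(frog_sp(1), qc05())
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_table(res, path)
  tab <- read.csv(path)
  expect_equal(tab$n, res$evaluations$n)
  expect_equal(tab$n[tab$is_optimal], 3L)
  expect_equal(tab$expected_Q, res$evaluations$expected_Q, tolerance = 1e-12)
})
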