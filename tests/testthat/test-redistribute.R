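test_that("no unknown population means identity redistribution", {
  cts <- toy_counts(rep(0, 13))
  ps <- redistribute_population(cts, 75, delta = 0.8)
  expect_equal(ps$p_star, cts$population[edu, ])
  expect_equal(unname(ps$unassigned), rep(0, 13))
})

test_that("delta = 0 leaves everything in the unknown pool above a*", {
  cts <- toy_counts(c(rep(0.01, 10), 0.5, 0.6, 0.7))
  ps <- redistribute_population(cts, 75, delta = 0)
  above <- as.character(c(80, 85, 90))
  expect_equal(ps$p_star[, above], cts$population[edu, above])
  expect_equal(ps$unassigned[above], cts$population["unknown", above])
  # below a* the small pools are folded regardless of delta
  expect_equal(unname(ps$unassigned[as.character(seq(30, 75, 5))]), rep(0, 10))
  expect_equal(colSums(ps$p_star) + ps$unassigned, colSums(cts$population))
})

test_that("the recursion evaluates the printed allocation rule", {
  # previous-group redistributed shares (0.6, 0.3, 0.1), no classified
  # population at the next age, unknown pool 100, delta 1 -> (60, 30, 10)
  cts <- toy_counts(rep(0, 13))
  cts$population[, "85"] <- c(600, 300, 100, 0)
  cts$population[, "90"] <- c(0, 0, 0, 100)
  cts$deaths[, "90"] <- c(0, 0, 0, 5)
  ps <- redistribute_population(cts, 85, delta = 1)
  expect_equal(unname(ps$p_star[, "90"]), c(60, 30, 10))
  expect_equal(unname(ps$unassigned[["90"]]), 0)
})

test_that("population accounting holds exactly at every age and delta", {
  cts <- toy_counts(c(rep(0.02, 10), 0.45, 0.55, 0.65))
  for (d in c(0, 0.3, 0.7, 1, 1.4)) {
    ps <- suppressWarnings(redistribute_population(cts, 75, d))
    expect_equal(colSums(ps$p_star) + ps$unassigned,
                 colSums(cts$population))
    expect_true(all(ps$p_star >= cts$population[edu, ] - 1e-9))
  }
  expect_error(redistribute_population(cts, 75, 3), "delta must lie")
  expect_error(redistribute_population(cts, 75, -0.1), "delta must lie")
})

test_that("raw and redistributed share bases differ as designed", {
  cts <- toy_counts(c(rep(0.01, 10), 0.5, 0.6, 0.7))
  ps_r <- redistribute_population(cts, 75, 1, "redistributed")
  ps_w <- redistribute_population(cts, 75, 1, "raw")
  # redistributed shares sum to 1, so at delta = 1 nothing remains unassigned
  expect_equal(unname(ps_r$unassigned[["85"]]), 0, tolerance = 1e-9)
  # raw shares have the total (incl. unknown) denominator, so they leak
  expect_gt(ps_w$unassigned[["85"]], 0)
})

test_that("implied deaths are exposure times hazard", {
  fi <- forward_instance()
  ps <- redistribute_population(fi$counts, 75, 0.5)
  dd <- redistributed_deaths(ps, fi$hazards)
  expect_equal(dd, ps$p_star * fi$hazards$mu[, colnames(ps$p_star)])
  # single-cell arithmetic
  expect_equal(unname(ps$p_star["low", "80"] * fi$hazards$mu["low", "80"]),
               unname(dd["low", "80"]))
  # monotonicity: larger delta never reduces implied deaths above a*
  dd2 <- redistributed_deaths(redistribute_population(fi$counts, 75, 1),
                              fi$hazards)
  above <- as.character(c(80, 85, 90))
  expect_true(all(dd2[, above] >= dd[, above] - 1e-9))
})

test_that("with no unknowns the pipeline reproduces observed deaths below a*", {
  cts <- toy_counts(rep(0, 13))
  obs <- observed_group_rates(cts, 75)
  hz <- reconstruct_hazards(obs, toy_reference(), a_star = 75)
  ps <- redistribute_population(cts, 75, 0)
  dd <- redistributed_deaths(ps, hz)
  below <- as.character(seq(30, 75, 5))
  expect_equal(dd[, below], cts$deaths[edu, below], tolerance = 1e-12)
})

test_that("the solver recovers the generating delta on forward instances", {
  for (basis in c("redistributed", "raw")) {
    fi <- forward_instance(0.7, recursion_basis = basis)
    sol <- solve_delta(fi$counts, fi$hazards, 75, seed = 11,
                       recursion_basis = basis)
    expect_lt(abs(sol$delta - 0.7), 1e-4)
    expect_true(sol$converged)
    d_tot <- colSums(fi$counts$deaths)[as.character(sol$fitted_ages)]
    expect_true(all(abs(sol$residuals) <= 1e-6 * d_tot))
  }
})

test_that("stochastic search, closed form and grid search agree", {
  fi <- suppressWarnings(forward_instance(1.15))
  expect_warning(
    s_de <- solve_delta(fi$counts, fi$hazards, 75, seed = 3),
    "exceeds 1")
  s_cf <- suppressWarnings(solve_delta(fi$counts, fi$hazards, 75, seed = 3,
                                       optimizer = "closed_form"))
  expect_lt(abs(s_de$delta - s_cf$delta), 1e-6)
  # two-stage grid oracle: coarse 401-point bracket, then step 1e-5
  obj <- function(d) {
    ps <- suppressWarnings(redistribute_population(fi$counts, 75, d))
    dd <- redistributed_deaths(ps, fi$hazards)
    ages <- as.character(c(80, 85, 90))
    sum((colSums(fi$counts$deaths)[ages] - colSums(dd[, ages]))^2)
  }
  coarse <- seq(0, 2, length.out = 401)
  d0 <- coarse[which.min(sapply(coarse, obj))]
  fine <- seq(max(0, d0 - 0.006), min(2, d0 + 0.006), by = 1e-5)
  d_grid <- fine[which.min(sapply(fine, obj))]
  expect_lt(abs(s_de$delta - d_grid), 2e-5)
  expect_lt(abs(d_grid - fi$delta_true), 1e-4)
})

test_that("identical seeds give identical solutions, distinct ones still agree", {
  fi <- forward_instance(0.4)
  a <- solve_delta(fi$counts, fi$hazards, 75, seed = 5)
  b <- solve_delta(fi$counts, fi$hazards, 75, seed = 5)
  expect_identical(a$delta, b$delta)
  expect_identical(a$residuals, b$residuals)
  c <- solve_delta(fi$counts, fi$hazards, 75, seed = 99)
  expect_lt(abs(a$delta - c$delta), 1e-6)
})

test_that("a flat objective returns the conventional delta = 1", {
  cts <- toy_counts(rep(0, 13))
  # make totals above a* exactly consistent with the reconstructed hazards
  obs <- observed_group_rates(cts, 75)
  hz <- reconstruct_hazards(obs, toy_reference(), a_star = 75)
  for (a in as.character(c(80, 85, 90))) {
    cts$deaths[edu, a] <- cts$population[edu, a] * hz$mu[, a]
  }
  sol <- solve_delta(cts, hz, 75, seed = 1)
  expect_identical(sol$delta, 1)
  expect_equal(max(abs(sol$residuals)), 0, tolerance = 1e-9)
  expect_true(sol$converged)
})
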