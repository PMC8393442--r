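test_that("a constant hazard gives e(x) = 1/m exactly under the exponential closure", {
  ages <- c(seq(30, 105, 5), 110)
  lt <- build_lifetable(rep(0.1, length(ages)), ages = ages,
                        convention = "exponential")
  expect_equal(lt$ex, rep(10, length(ages)), tolerance = 1e-9)
  expect_equal(lt$lx[1], 1e5)
})

test_that("the open terminal interval is closed with L = l/m", {
  ages <- c(seq(30, 105, 5), 110)
  lt <- build_lifetable(c(rep(0.02, 16), 0.5), ages = ages)
  k <- nrow(lt)
  expect_identical(lt$qx[k], 1)
  expect_equal(lt$Lx[k], lt$lx[k] / 0.5)
  expect_equal(lt$ex[k], 2)
  # the printed identity: l(omega) = 1000 would give L = 2000
  expect_equal(lt$Lx[k] / lt$lx[k] * 1000, 2000)
})

test_that("internal consistency identities hold for random rates", {
  set.seed(7)
  ages <- c(seq(30, 105, 5), 110)
  for (cv in c("midpoint", "exponential")) {
    for (i in 1:20) {
      m <- 5e-4 * exp(0.095 * (ages - 30)) * exp(rnorm(length(ages), 0, 0.15))
      lt <- build_lifetable(m, ages = ages, convention = cv)
      k <- nrow(lt)
      expect_true(all(lt$qx > 0 & lt$qx <= 1))
      expect_true(all(diff(lt$lx) <= 0))
      expect_equal(lt$dx[-k], lt$lx[-k] - lt$lx[-1])
      expect_equal(lt$Lx[-k], 5 * lt$lx[-1] + lt$ax[-k] * lt$dx[-k])
      expect_equal(lt$Tx, rev(cumsum(rev(lt$Lx))))
      expect_equal(lt$ex, lt$Tx / lt$lx)
    }
  }
})

test_that("e(30) matches fine-step survival integration of the step hazard", {
  set.seed(12)
  ages <- c(seq(30, 105, 5), 110)
  for (i in 1:10) {
    m <- 5e-4 * exp(0.095 * (ages - 30)) * exp(rnorm(length(ages), 0, 0.15))
    lt <- build_lifetable(m, ages = ages, convention = "exponential")
    expect_lt(abs(lt$ex[1] - e30_step_integration(m, ages)), 0.05)
  }
})

test_that("raising any death rate lowers life expectancy at all earlier ages", {
  ages <- c(seq(30, 105, 5), 110)
  m <- 5e-4 * exp(0.095 * (ages - 30))
  base <- build_lifetable(m, ages = ages)
  for (j in c(3, 9, 17)) {
    m2 <- m
    m2[j] <- m[j] * 1.5
    bumped <- build_lifetable(m2, ages = ages)
    expect_true(all(bumped$ex[seq_len(j)] < base$ex[seq_len(j)]))
  }
})

test_that("complete tables agree with the abridged at group boundaries", {
  ages <- c(seq(30, 105, 5), 110)
  m <- 6e-4 * exp(0.097 * (ages - 30))
  for (cv in c("midpoint", "exponential")) {
    ab <- build_lifetable(m, ages = ages, convention = cv)
    cp <- complete_from_abridged(ab)
    expect_identical(cp$age, c(30:109, 110))
    boundary <- match(ages, cp$age)
    expect_equal(cp$lx[boundary], ab$lx, tolerance = 1e-9)
    # person-years are preserved per group, so boundary e is exact
    expect_equal(cp$ex[boundary], ab$ex, tolerance = 1e-9)
    expect_lt(abs(cp$ex[1] - ab$ex[1]), 0.1)
  }
})

test_that("a constant-hazard abridged table grades to the same single-year rate", {
  ages <- c(seq(30, 70, 5), 75)
  ab <- build_lifetable(rep(0.05, length(ages)), ages = ages,
                        convention = "exponential")
  cp <- complete_from_abridged(ab)
  expect_equal(cp$mx, rep(0.05, nrow(cp)), tolerance = 1e-12)
  expect_equal(cp$ex[1], ab$ex[1], tolerance = 1e-9)
})

test_that("grading matches a direct single-year build from the same step hazard", {
  ages <- c(seq(30, 105, 5), 110)
  m_ab <- 6e-4 * exp(0.097 * (ages + 2.5 - 30))
  m_ab[length(ages)] <- 6e-4 * exp(0.097 * 80)
  yr <- c(30:109, 110)
  m_yr <- m_ab[pmin(findInterval(yr, ages), length(ages))]
  direct <- build_lifetable(m_yr, ages = yr, convention = "exponential")
  graded <- complete_from_abridged(
    build_lifetable(m_ab, ages = ages, convention = "exponential")
  )
  expect_equal(graded$ex, direct$ex, tolerance = 1e-9)
  # the mid-interval abridged convention grades to the same table within
  # its own within-interval approximation error
  graded_mid <- complete_from_abridged(
    build_lifetable(m_ab, ages = ages, convention = "midpoint")
  )
  expect_lt(abs(graded_mid$ex[1] - direct$ex[1]), 0.1)
})

test_that("published-value gaps reproduce the headline differences", {
  t1 <- table1_life_expectancy()
  sel <- function(cn, pd, ed, sx) {
    list(country = cn, period = pd, education = ed, sex = sx)
  }
  expect_identical(
    expectancy_gap(t1, sel("Sweden", "1991-1995", "high", "female"),
                   sel("Sweden", "1991-1995", "high", "male"), 30), 4.8)
  expect_identical(
    expectancy_gap(t1, sel("Denmark", "2011-2015", "high", "male"),
                   sel("Denmark", "1991-1995", "high", "male"), 30), 5.2)
  expect_error(
    expectancy_gap(t1, sel("Norway", "1991-1995", "high", "male"),
                   sel("Denmark", "1991-1995", "high", "male"), 30),
    "matches 0")
})

test_that("identical life tables have zero expectancy gap", {
  ages <- c(seq(30, 105, 5), 110)
  lt <- build_lifetable(6e-4 * exp(0.095 * (ages - 30)), ages = ages)
  expect_identical(expectancy_gap(lt, b = lt, age = 30), 0)
  expect_identical(expectancy_gap(lt, b = lt, age = 65), 0)
})
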