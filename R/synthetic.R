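#' Specification of a synthetic education-stratified register
#'
#' Defines a cell-level generator that emulates the structure of Nordic
#' education-stratified mortality registers: three ISCED-based education
#' strata with Gompertz hazards, cohort-driven education composition
#' (educational expansion: younger cohorts are more educated), stationary
#' cohort exposures, 5-year periods, and cohort-driven masking of education
#' — everyone born before a cutoff year carries unknown education, plus a
#' small residual unknown share that decays over periods. The result is an
#' unknown-education share that rises steeply with age in early periods and
#' recedes as the pre-cutoff cohorts die out, which is exactly the
#' missingness pattern the reconstruction method targets.
#'
#' @param alpha Named Gompertz levels at age 30 (per person-year) for
#'   low/middle/high education, female scale.
#' @param beta Named Gompertz slopes (per year of age).
#' @param male_excess Multiplier on `alpha` for males.
#' @param composition_early,composition_late Education shares (l, m, h,
#'   summing to 1) of cohorts born at or before `early_cohort` / at or after
#'   `late_cohort`; linear in birth year in between.
#' @param early_cohort,late_cohort Birth years anchoring the composition ramp.
#' @param cohort_cutoff Birth year before which education is always unknown
#'   (the Swedish analog is 1915, the Danish 1922).
#' @param partial_missing Residual probability of unknown education above
#'   `partial_missing_age` for post-cutoff cohorts in the first period.
#' @param partial_decay Per-period multiplicative decay of `partial_missing`.
#' @param partial_missing_age Age above which the residual unknown share
#'   applies.
#' @param base_missing Small unknown share at all ages (register noise).
#' @param population_base Persons per age group entering the period; exposure
#'   per cell is `population_base * 5` person-years scaled by stationary
#'   survival and cohort composition.
#' @param periods Period labels; anchors are the period midpoints
#'   (1993, 1998, ...).
#' @param omega Terminal model age.
#' @param deterministic If `TRUE` (default) death counts equal their
#'   expectations; if `FALSE` they are Poisson draws.
#' @param seed Integer seed (mandatory; used only in stochastic mode).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(alpha = c(low = 9e-4, middle = 7e-4, high = 5e-4),
                           beta = c(low = 0.092, middle = 0.095, high = 0.098),
                           male_excess = 1.5,
                           composition_early = c(low = 0.72, middle = 0.20, high = 0.08),
                           composition_late = c(low = 0.20, middle = 0.42, high = 0.38),
                           early_cohort = 1900L, late_cohort = 1985L,
                           cohort_cutoff = 1915L,
                           partial_missing = 0.03, partial_decay = 0.7,
                           partial_missing_age = 60L, base_missing = 0.01,
                           population_base = 1e5,
                           periods = c("1991-1995", "1996-2000", "2001-2005",
                                       "2006-2010", "2011-2015"),
                           omega = 110L, deterministic = TRUE, seed = 1L) {
  for (v in list(alpha, beta)) {
    if (!identical(names(v), education_levels) || any(v <= 0)) {
      stop("alpha and beta must be positive and named low, middle, high")
    }
  }
  for (v in list(composition_early, composition_late)) {
    if (abs(sum(v) - 1) > 1e-12 || any(v < 0)) {
      stop("composition shares must be non-negative and sum to 1")
    }
  }
  anchors <- vapply(strsplit(periods, "-"), function(p) {
    mean(as.numeric(p))
  }, numeric(1))
  structure(
    list(alpha = alpha, beta = beta, male_excess = male_excess,
         composition_early = composition_early,
         composition_late = composition_late,
         early_cohort = early_cohort, late_cohort = late_cohort,
         cohort_cutoff = cohort_cutoff,
         partial_missing = partial_missing, partial_decay = partial_decay,
         partial_missing_age = partial_missing_age,
         base_missing = base_missing,
         population_base = population_base,
         periods = periods, anchors = anchors,
         omega = as.integer(omega),
         deterministic = isTRUE(deterministic), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Gompertz hazard at exact age x (years), per education, one sex
.syn_hazard <- function(spec, sex) {
  a <- spec$alpha * if (sex == "male") spec$male_excess else 1
  function(x, e) a[[e]] * exp(spec$beta[[e]] * (x - 30))
}

# cumulative hazard from 30 to x
.syn_cumhaz <- function(spec, sex) {
  a <- spec$alpha * if (sex == "male") spec$male_excess else 1
  function(x, e) a[[e]] / spec$beta[[e]] * (exp(spec$beta[[e]] * (x - 30)) - 1)
}

# cohort education shares (low, middle, high) for a birth year
.syn_composition <- function(spec, birth) {
  w <- (birth - spec$early_cohort) / (spec$late_cohort - spec$early_cohort)
  w <- min(max(w, 0), 1)
  (1 - w) * spec$composition_early + w * spec$composition_late
}

# unknown-education fraction for (age-group midpoint, period index)
.syn_unknown_frac <- function(spec, age_mid, period_idx) {
  birth <- spec$anchors[period_idx] - age_mid
  if (birth < spec$cohort_cutoff) return(1)
  if (age_mid >= spec$partial_missing_age) {
    max(spec$base_missing,
        spec$partial_missing * spec$partial_decay^(period_idx - 1L))
  } else {
    spec$base_missing
  }
}

# stationary exposure (person-years over the 5-year period) per education
# for the group with lower bound a in the given period
.syn_exposure <- function(spec, sex, a, period_idx, grid) {
  mid <- a + grid$width / 2
  H <- .syn_cumhaz(spec, sex)
  comp <- .syn_composition(spec, spec$anchors[period_idx] - mid)
  vapply(education_levels, function(e) {
    spec$population_base * grid$width * comp[[e]] * exp(-H(mid, e))
  }, numeric(1))
}

#' Generate a synthetic education-stratified register
#'
#' Produces [stratified_counts()] per period and sex together with the
#' generating truth (noiseless education-specific hazards and the life
#' tables they imply), so that the full reconstruction pipeline can be run
#' and compared against a known answer. Expected deaths are exposure times
#' the Gompertz hazard at the group midpoint; in stochastic mode realized
#' deaths are Poisson with that mean. Education labels are masked to
#' "unknown" for the fraction of each cell given by the cohort cutoff and
#' the residual missingness (the fraction applies uniformly across education
#' groups, as cohort-driven masking does).
#'
#' @param spec A [synthetic_spec()].
#' @param country Country label stamped on the counts.
#' @param sexes Which sexes to generate.
#' @param grid Data [age_grid()].
#' @return A list with elements `counts` (named list `period|sex` of
#'   [stratified_counts()]), `truth` (per sex: `mu` matrices on the extended
#'   grid, `lifetables` per education, `e30`/`e65` vectors), `spec`.
#' @export
generate_register <- function(spec, country = "Synthia",
                              sexes = c("female", "male"),
                              grid = age_grid(omega = spec$omega)) {
  if (spec$cohort_cutoff <= min(spec$anchors) - (spec$omega + 5)) {
    warning("cohort cutoff precedes every simulated cohort; no cohort masking")
  }
  if (!spec$deterministic) set.seed(spec$seed)
  counts <- list()
  for (p in seq_along(spec$periods)) {
    for (sex in sexes) {
      hz <- .syn_hazard(spec, sex)
      deaths <- population <- matrix(
        0, 4L, length(grid$lower),
        dimnames = list(all_levels, as.character(grid$lower))
      )
      for (j in seq_along(grid$lower)) {
        a <- grid$lower[j]
        mid <- a + grid$width / 2
        expo <- .syn_exposure(spec, sex, a, p, grid)
        dexp <- vapply(education_levels, function(e) expo[[e]] * hz(mid, e),
                       numeric(1))
        if (!spec$deterministic) dexp <- stats::rpois(3L, dexp)
        u <- .syn_unknown_frac(spec, mid, p)
        population[education_levels, j] <- (1 - u) * expo
        population["unknown", j] <- u * sum(expo)
        deaths[education_levels, j] <- (1 - u) * dexp
        deaths["unknown", j] <- u * sum(dexp)
      }
      key <- paste(spec$periods[p], sex, sep = "|")
      counts[[key]] <- stratified_counts(country, spec$periods[p], sex,
                                         deaths, population, grid = grid)
    }
  }

  truth <- lapply(sexes, function(sex) {
    hz <- .syn_hazard(spec, sex)
    ages <- c(extended_lower(grid), grid$omega)
    eval_age <- c(group_midpoint(grid, extended_lower(grid)), grid$omega)
    mu <- t(vapply(education_levels,
                   function(e) vapply(eval_age, hz, numeric(1), e = e),
                   numeric(length(eval_age))))
    dimnames(mu) <- list(education_levels, as.character(ages))
    lts <- lapply(education_levels, function(e) {
      build_lifetable(mu[e, ], ages = ages, country = country, sex = sex,
                      education = e)
    })
    names(lts) <- education_levels
    list(mu = mu, ages = ages, lifetables = lts,
         e30 = vapply(lts, life_expectancy, numeric(1), age = 30),
         e65 = vapply(lts, life_expectancy, numeric(1), age = 65))
  })
  names(truth) <- sexes
  list(counts = counts, truth = truth, spec = spec)
}

#' National reference rates implied by the generating truth
#'
#' The all-education death rate at each single year of age is the
#' exposure-weighted mixture of the education-specific Gompertz hazards,
#' with weights from the stationary cohort exposures of the period, extended
#' to omega on the same curves. This plays the role of the national rates an
#' analysis of real registers would take from the Human Mortality Database.
#'
#' @param spec A [synthetic_spec()].
#' @param period Period label (must be one of `spec$periods`).
#' @param sex `"female"` or `"male"`.
#' @param min_age First age of the reference grid.
#' @return A single-year [reference_mortality()] on `min_age..omega`.
#' @export
reference_from_truth <- function(spec, period, sex = "female", min_age = 30L) {
  p <- match(period, spec$periods)
  if (is.na(p)) stop("period must be one of: ", paste(spec$periods, collapse = ", "))
  hz <- .syn_hazard(spec, sex)
  H <- .syn_cumhaz(spec, sex)
  ages <- seq(min_age, spec$omega)
  rates <- vapply(ages, function(x) {
    comp <- .syn_composition(spec, spec$anchors[p] - x)
    w <- vapply(education_levels,
                function(e) comp[[e]] * exp(-H(x, e)), numeric(1))
    sum(w * vapply(education_levels, hz, numeric(1), x = x)) / sum(w)
  }, numeric(1))
  reference_mortality(ages, rates, omega = spec$omega)
}
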