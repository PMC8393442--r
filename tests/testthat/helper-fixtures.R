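# Shared fixture builders; everything is generated in code.

edu <- c("low", "middle", "high")

# Counts with a prescribed unknown share per age (same share for deaths and
# population, so every criterion basis sees the same profile).
toy_counts <- function(unknown_share = rep(0, 13), grid = age_grid(),
                       pop_total = 1000, country = "X", period = "p",
                       sex = "female") {
  stopifnot(length(unknown_share) == length(grid$lower))
  pop <- deaths <- matrix(0, 4, length(grid$lower),
                          dimnames = list(c(edu, "unknown"),
                                          as.character(grid$lower)))
  rate <- 0.002 * exp(0.08 * (grid$lower - 30))
  for (j in seq_along(grid$lower)) {
    s <- unknown_share[j]
    pop[edu, j] <- (1 - s) * pop_total * c(0.5, 0.3, 0.2)
    pop["unknown", j] <- s * pop_total
    d_tot <- pop_total * rate[j]
    deaths[edu, j] <- (1 - s) * d_tot * c(0.5, 0.3, 0.2)
    deaths["unknown", j] <- s * d_tot
  }
  stratified_counts(country, period, sex, deaths, pop, grid)
}

# Gompertz-like national reference on single years 30..110
toy_reference <- function(level = 8e-4, slope = 0.092, omega = 110) {
  ages <- seq(30, omega)
  reference_mortality(ages, level * exp(slope * (ages - 30)), omega = omega)
}

# Brute-force reliable-age oracle: the largest age >= min_age such that the
# share at every age in [min_age, a] is known and <= threshold.
scan_reliable_age <- function(shares, ages, threshold = 0.05, min_age = 60) {
  best <- NA_integer_
  for (a in ages[ages >= min_age]) {
    s <- shares[as.character(a)]
    if (is.na(s) || s > threshold) break
    best <- a
  }
  best
}

# Forward-model instance: counts whose total deaths above a* = 75 are exactly
# those implied by the redistribution recursion at delta_true, so the solver
# has an exact zero of the residuals to find.
forward_instance <- function(delta_true = 0.7,
                             recursion_basis = "redistributed",
                             anchors = c(low = 1.3, middle = 1.0, high = 0.75),
                             unknown_frac_above = 0.6) {
  grid <- age_grid()
  ref <- toy_reference()
  lows <- grid$lower
  P <- sapply(lows, function(a) 60000 * exp(-0.04 * (a - 30)) * c(0.5, 0.3, 0.2))
  dimnames(P) <- list(edu, as.character(lows))
  pop <- rbind(P, unknown = 0)
  refg <- sapply(lows, function(a) mean(ref$rates[ref$ages >= a & ref$ages < a + 5]))
  d <- sapply(seq_along(lows), function(j) P[, j] * anchors[edu] * refg[j])
  dimnames(d) <- dimnames(P)
  deaths <- rbind(d, unknown = 0)
  for (a in c("80", "85", "90")) {
    u <- unknown_frac_above * sum(pop[edu, a])
    pop[edu, a] <- (1 - unknown_frac_above) * pop[edu, a]
    pop["unknown", a] <- u
  }
  cts0 <- stratified_counts("X", "p", "female", deaths, pop, grid)
  obs <- observed_group_rates(cts0, 75)
  hz <- reconstruct_hazards(obs, ref, grid, 75)
  ps <- redistribute_population(cts0, 75, delta_true,
                                recursion_basis = recursion_basis)
  dstar <- redistributed_deaths(ps, hz)
  for (a in c("80", "85", "90")) {
    tot <- sum(dstar[, a])
    deaths[edu, a] <- (1 - unknown_frac_above) * tot * c(0.5, 0.3, 0.2)
    deaths["unknown", a] <- unknown_frac_above * tot
  }
  counts <- stratified_counts("X", "p", "female", deaths, pop, grid)
  list(counts = counts, reference = ref, hazards = hz, grid = grid,
       a_star = 75, delta_true = delta_true)
}

# e(30) by fine-step (1-month) trapezoidal integration of the survival
# function of the step hazard (constant within each interval, constant at
# and above the terminal age).
e30_step_integration <- function(mx, ages, step = 1 / 12) {
  x <- seq(ages[1], ages[length(ages)], step)
  m_at <- mx[pmin(findInterval(x, ages), length(ages))]
  S <- exp(-cumsum(c(0, m_at[-length(m_at)] * step)))
  sum((S[-1] + S[-length(S)]) / 2 * step) + S[length(S)] / mx[length(mx)]
}
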