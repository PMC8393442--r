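#' Redistribute unknown-education population
#'
#' At and below the reliable age a* the (small) unknown pools are folded into
#' the known categories in proportion to the same-age known distribution.
#' Above a*, where the known same-age distribution is unreliable or absent,
#' the unknown population is allocated according to the education shares of
#' the previous age group, scaled by the factor delta, recursively up the
#' grid until age 90:
#' `P*_e(a) = P_e(a) + share_e(a-5) * P_u(a) * delta`.
#' Education shares are rigid across adjacent old-age cohorts, which is what
#' makes the previous group's composition a usable allocation key.
#'
#' @param counts A [stratified_counts()] object with population available
#'   through the open age group.
#' @param a_star Last reliable age.
#' @param delta Redistribution scale, >= 0 (values above 1 drive the
#'   remaining unknown pool negative and trigger a warning).
#' @param recursion_basis `"redistributed"` (default): the allocation shares
#'   at a-5 come from the already-redistributed population, so they always
#'   sum to 1; `"raw"`: the literal shares P_e(a-5)/P(a-5) of the raw counts
#'   (total including unknown in the denominator).
#' @param delta_max Upper admissible bound for `delta` (default 2).
#' @return Object of class `redistributed_population`: `p_star` (3 x n ages
#'   matrix over the data grid), `unassigned` (unknown population left in
#'   the pool per age), `delta`, `a_star`, `recursion_basis`.
#' @export
redistribute_population <- function(counts, a_star, delta,
                                    recursion_basis = c("redistributed", "raw"),
                                    delta_max = 2) {
  recursion_basis <- match.arg(recursion_basis)
  if (!is.finite(delta) || delta < 0 || delta > delta_max) {
    stop("delta must lie in [0, ", delta_max, "]")
  }
  ages <- counts$grid$lower
  p <- counts$population
  if (any(is.na(p))) stop("population must be available at every age and education")
  folded <- fold_unknown_matrix(p, which(ages <= a_star))
  p_star <- folded[education_levels, , drop = FALSE]
  unassigned <- stats::setNames(numeric(length(ages)), as.character(ages))
  for (j in which(ages > a_star)) {
    prev <- j - 1L
    p_u <- p["unknown", j]
    if (p_u * delta == 0) {
      p_star[, j] <- p[education_levels, j]
      unassigned[j] <- p_u
      next
    }
    if (recursion_basis == "redistributed") {
      base <- p_star[, prev]
      tot <- sum(base)
    } else {
      base <- p[education_levels, prev]
      tot <- sum(p[, prev])
    }
    if (tot == 0) {
      stop("no population at age ", ages[prev], " to set allocation shares")
    }
    add <- base / tot * p_u * delta
    p_star[, j] <- p[education_levels, j] + add
    unassigned[j] <- p_u - sum(add)
  }
  if (any(unassigned < -1e-9)) {
    warning("delta = ", format(delta), " over-allocates: unassigned unknown ",
            "population is negative at ", sum(unassigned < -1e-9), " age(s)")
  }
  structure(
    list(p_star = p_star, unassigned = unassigned, delta = delta,
         a_star = a_star, recursion_basis = recursion_basis,
         grid = counts$grid),
    class = "redistributed_population"
  )
}

#' Deaths implied by redistributed population and reconstructed hazards
#'
#' `D*_e(a) = P*_e(a) mu_e(a)` per education and age group of the data grid.
#'
#' @param p_star A [redistribute_population()] result.
#' @param hazards A [reconstruct_hazards()] result on the same grid.
#' @return 3 x n matrix of deaths (education x age group).
#' @export
redistributed_deaths <- function(p_star, hazards) {
  ages <- colnames(p_star$p_star)
  if (!all(ages %in% colnames(hazards$mu))) {
    stop("hazards do not cover the ages of the redistributed population")
  }
  p_star$p_star * hazards$mu[, ages, drop = FALSE]
}

# Minimal bounded 1-D (or k-D) differential evolution: rand/1/bin scheme.
# Deterministic given the RNG state at entry.
.de_optim <- function(fn, lower, upper, np = 10L * length(lower) + 5L,
                      generations = 60L, f = 0.8, cr = 0.9) {
  k <- length(lower)
  pop <- matrix(stats::runif(np * k, lower, upper), np, k, byrow = TRUE)
  cost <- apply(pop, 1L, fn)
  for (g in seq_len(generations)) {
    for (i in seq_len(np)) {
      idx <- sample(setdiff(seq_len(np), i), 3L)
      trial <- pop[idx[1], ] + f * (pop[idx[2], ] - pop[idx[3], ])
      cross <- stats::runif(k) < cr
      cross[sample.int(k, 1L)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      tc <- fn(trial)
      if (tc <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- tc
      }
    }
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best])
}

#' Solve for the redistribution scale delta
#'
#' Chooses delta so that the deaths implied by the redistributed population
#' and the reconstructed hazards exhaust the observed total deaths above a*:
#' the residual unknown deaths `D_u*(a) = D(a) - sum_e D*_e(a)` are driven
#' to zero in least squares over the ages above a* with observed totals.
#' The default optimizer is a bounded differential-evolution search followed
#' by scalar refinement with [stats::optimize()]; `"closed_form"` instead
#' uses the (near-)affine structure of the residuals in delta via
#' Gauss-Newton, exact in one step when `recursion_basis = "raw"`.
#'
#' @param counts A [stratified_counts()] object.
#' @param hazards A [reconstruct_hazards()] result.
#' @param a_star Last reliable age.
#' @param bounds Admissible delta interval, default `c(0, 2)`.
#' @param tolerance Convergence tolerance, relative to total deaths per age
#'   (default 1e-6): converged when `|D_u*(a)| <= tolerance * max(D(a), 1)`
#'   at every fitted age.
#' @param seed Integer seed for the stochastic search (mandatory for
#'   reproducibility).
#' @param optimizer `"de_refine"` (default) or `"closed_form"`.
#' @param recursion_basis Passed to [redistribute_population()].
#' @return Object of class `delta_solution`: `delta`, `residuals` (named by
#'   age), `objective`, `converged`, `evaluations`, `optimizer`,
#'   `recursion_basis`, `bounds`, `fitted_ages`.
#' @export
solve_delta <- function(counts, hazards, a_star, bounds = c(0, 2),
                        tolerance = 1e-6, seed = 1L,
                        optimizer = c("de_refine", "closed_form"),
                        recursion_basis = c("redistributed", "raw")) {
  optimizer <- match.arg(optimizer)
  recursion_basis <- match.arg(recursion_basis)
  if (length(bounds) != 2L || bounds[1] < 0 || diff(bounds) <= 0) {
    stop("bounds must be an increasing non-negative interval")
  }
  ages <- counts$grid$lower
  d_tot <- total_deaths(counts)
  fit_idx <- which(ages > a_star & !is.na(d_tot))
  if (!length(fit_idx)) {
    # a* is the last data age (or totals above it are masked): there is
    # nothing to fit and delta is immaterial; return the conventional 1
    if (sum(counts$population["unknown", ages > a_star], na.rm = TRUE) > 0) {
      warning("unknown population above a* but no observed total deaths ",
              "there; returning the conventional delta = 1 unfitted")
    }
    return(structure(
      list(delta = 1, residuals = stats::setNames(numeric(0), character(0)),
           objective = 0, converged = TRUE, evaluations = 0L,
           optimizer = optimizer, recursion_basis = recursion_basis,
           bounds = bounds, fitted_ages = integer(0)),
      class = "delta_solution"
    ))
  }
  fit_ages <- as.character(ages[fit_idx])
  evals <- 0L

  resid_fn <- function(delta) {
    ps <- suppressWarnings(
      redistribute_population(counts, a_star, delta,
                              recursion_basis = recursion_basis,
                              delta_max = bounds[2])
    )
    dd <- redistributed_deaths(ps, hazards)
    d_tot[fit_ages] - colSums(dd[, fit_ages, drop = FALSE])
  }
  obj_fn <- function(delta) {
    evals <<- evals + 1L
    v <- sum(resid_fn(delta)^2)
    if (!is.finite(v)) stop("delta objective is not finite at delta = ", delta)
    v
  }

  # flat objective when there is nothing to redistribute above a*
  unknown_above <- sum(counts$population["unknown", fit_idx], na.rm = TRUE) +
    sum(counts$deaths["unknown", fit_idx], na.rm = TRUE)
  if (unknown_above == 0) {
    delta_hat <- 1
  } else if (optimizer == "closed_form") {
    # Gauss-Newton on the residual vector; r(delta) is affine for the raw
    # recursion basis, so the first step is already exact there
    delta_hat <- mean(bounds)
    for (it in 1:25) {
      r0 <- resid_fn(delta_hat); evals <- evals + 1L
      h <- 1e-4
      r1 <- resid_fn(delta_hat + h); evals <- evals + 1L
      jac <- (r1 - r0) / h
      step <- -sum(jac * r0) / sum(jac * jac)
      delta_new <- min(max(delta_hat + step, bounds[1]), bounds[2])
      if (abs(delta_new - delta_hat) < 1e-12) {
        delta_hat <- delta_new
        break
      }
      delta_hat <- delta_new
    }
  } else {
    rng_state <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(
      if (!is.null(rng_state)) assign(".Random.seed", rng_state, globalenv()),
      add = TRUE
    )
    set.seed(seed)
    de <- .de_optim(obj_fn, bounds[1], bounds[2])
    ref <- stats::optimize(obj_fn, interval = bounds, tol = 1e-10)
    delta_hat <- if (ref$objective <= de$value) ref$minimum else de$par
    # polish in a narrow bracket around the incumbent
    br <- c(max(bounds[1], delta_hat - 0.01), min(bounds[2], delta_hat + 0.01))
    pol <- stats::optimize(obj_fn, interval = br, tol = 1e-12)
    if (pol$objective <= sum(resid_fn(delta_hat)^2)) delta_hat <- pol$minimum
  }

  res <- resid_fn(delta_hat)
  converged <- all(abs(res) <= tolerance * pmax(d_tot[fit_ages], 1))
  if (delta_hat > 1) {
    warning("solved delta = ", format(delta_hat), " exceeds 1; the residual ",
            "unknown population pool is negative at some ages")
  }
  structure(
    list(delta = delta_hat, residuals = res, objective = sum(res^2),
         converged = converged, evaluations = evals, optimizer = optimizer,
         recursion_basis = recursion_basis, bounds = bounds,
         fitted_ages = as.integer(fit_ages)),
    class = "delta_solution"
  )
}

#' @export
print.delta_solution <- function(x, ...) {
  cat("<delta_solution> delta = ", format(x$delta),
      if (x$converged) " (converged)" else " (NOT converged)",
      "\n  max |residual| = ", format(max(abs(x$residuals))),
      " deaths over ages ", paste(range(x$fitted_ages), collapse = "-"),
      "; ", x$evaluations, " objective evaluations\n", sep = "")
  invisible(x)
}
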