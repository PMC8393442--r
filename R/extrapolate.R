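#' Linear hazard-ratio extrapolation toward the national level
#'
#' Above the last reliable age the ratio of an education group's hazard to
#' the national hazard is assumed to converge linearly in age to 1, reaching
#' it exactly at the terminal age omega ("everyone becomes similar at the
#' end"): R(a) = 1 + (R(a*) - 1) (omega - a) / (omega - a*).
#'
#' @param anchor_ratio Observed ratio R(a*) = mu_e(a*) / mu(a*), > 0.
#' @param a_star Anchor age in years (a point age; for group-level work this
#'   is typically the midpoint of the a* group).
#' @param omega Terminal age, > `a_star`.
#' @param eval_ages Ages in `[a_star, omega]` at which to tabulate the ratio
#'   (default: none; the returned curve evaluates lazily via [ratio_at()]).
#' @param education Optional label carried on the curve.
#' @return Object of class `hazard_ratio_curve` with fields `education`,
#'   `anchor_age`, `anchor_ratio`, `omega`, and `ratios` (named vector over
#'   `eval_ages`).
#' @examples
#' extrapolate_ratios(0.5, 75, 110, eval_ages = 96)$ratios  # 0.8
#' @export
extrapolate_ratios <- function(anchor_ratio, a_star, omega = 110,
                               eval_ages = numeric(0), education = NA_character_) {
  if (!is.finite(anchor_ratio) || anchor_ratio <= 0) {
    stop("anchor_ratio must be a positive number")
  }
  if (omega <= a_star) stop("omega must exceed the anchor age a*")
  if (length(eval_ages) && (any(eval_ages < a_star) || any(eval_ages > omega))) {
    stop("eval_ages must lie within [a*, omega]")
  }
  curve <- structure(
    list(education = education, anchor_age = a_star,
         anchor_ratio = anchor_ratio, omega = omega),
    class = "hazard_ratio_curve"
  )
  curve$ratios <- stats::setNames(ratio_at(curve, eval_ages),
                                  as.character(eval_ages))
  curve
}

#' Evaluate a hazard-ratio curve
#'
#' @param curve A [extrapolate_ratios()] curve.
#' @param ages Ages in `[a*, omega]`.
#' @return Ratios at `ages`; exactly `anchor_ratio` at a* and exactly 1 at
#'   omega.
#' @export
ratio_at <- function(curve, ages) {
  if (!length(ages)) return(numeric(0))
  r <- 1 + (curve$anchor_ratio - 1) *
    (curve$omega - ages) / (curve$omega - curve$anchor_age)
  r[ages == curve$omega] <- 1  # exact endpoint, no rounding residue
  r
}

#' @export
print.hazard_ratio_curve <- function(x, ...) {
  cat("<hazard_ratio_curve>", if (!is.na(x$education)) x$education else "",
      " R(", x$anchor_age, ") = ", format(x$anchor_ratio),
      " -> R(", x$omega, ") = 1\n", sep = "")
  invisible(x)
}

#' Reconstruct education-specific hazards over the full age range
#'
#' Combines observed group rates (at and below a*) with ratio-extrapolated
#' rates above a*: the anchor ratio of each education group is its observed
#' rate at the a* group over the national group rate there; above a* the
#' hazard is the linearly-converging ratio times the national rate, so every
#' group meets the national hazard exactly at omega. Group-level hazards use
#' the group-midpoint convention: the ratio is evaluated at the midpoint of
#' each 5-year group, the terminal age omega is a point.
#'
#' @param observed Output of [observed_group_rates()].
#' @param reference A [reference_mortality()] covering the grid up to omega.
#' @param grid The [age_grid()] of the counts.
#' @param a_star Last reliable age (defaults to the one stored in `observed`).
#' @return Object of class `reconstructed_hazards`: `ages` (group lower
#'   bounds 30..omega-5 plus the point omega), `mu` (3 x length(ages)
#'   matrix), `source` (`"observed"`/`"extrapolated"` per age), `anchors`,
#'   `curves`, `grid`, `a_star`.
#' @export
reconstruct_hazards <- function(observed, reference, grid = age_grid(),
                                a_star = observed$a_star) {
  omega <- grid$omega
  ext <- extended_lower(grid)
  ages <- c(ext, omega)
  refg <- vapply(ext, reference_group_rate, numeric(1), width = grid$width,
                 ref = reference)
  names(refg) <- as.character(ext)
  ref_as <- refg[[as.character(a_star)]]
  if (!is.finite(ref_as) || ref_as <= 0) {
    stop("national reference rate at a* = ", a_star, " is not positive")
  }

  pooled <- character(0)
  anchors <- vapply(education_levels, function(e) {
    r_obs <- observed$rate[e, as.character(a_star)]
    d_obs <- observed$deaths[e, as.character(a_star)]
    if (is.na(r_obs) || d_obs == 0) {
      pooled <<- c(pooled, e)
      # no deaths in this group at a*: pool the last two reliable age groups
      cols <- as.character(c(a_star - grid$width, a_star))
      cols <- cols[cols %in% colnames(observed$deaths)]
      pool_d <- sum(observed$deaths[e, cols])
      pool_p <- sum(observed$population[e, cols])
      if (pool_d == 0 || pool_p == 0) {
        stop("cannot anchor ratio for '", e, "': no deaths near a*")
      }
      warning("anchor for '", e, "' pooled over ages ",
              paste(cols, collapse = ", "), " (zero deaths at a*)")
      pool_ref <- mean(refg[cols])
      (pool_d / pool_p) / pool_ref
    } else {
      r_obs / ref_as
    }
  }, numeric(1))

  mid_star <- group_midpoint(grid, a_star)
  curves <- lapply(education_levels, function(e) {
    extrapolate_ratios(anchors[[e]], a_star = mid_star, omega = omega,
                       education = e)
  })
  names(curves) <- education_levels

  mu <- matrix(NA_real_, 3L, length(ages),
               dimnames = list(education_levels, as.character(ages)))
  below <- ext[ext <= a_star]
  mu[, as.character(below)] <- observed$rate[, as.character(below)]
  # a pooled anchor also stands in for the (zero) observed rate at a*
  for (e in pooled) mu[e, as.character(a_star)] <- anchors[[e]] * ref_as
  above <- ext[ext > a_star]
  for (e in education_levels) {
    if (length(above)) {
      mids <- group_midpoint(grid, above)
      mu[e, as.character(above)] <- ratio_at(curves[[e]], mids) * refg[as.character(above)]
    }
    mu[e, as.character(omega)] <- reference_omega_rate(reference)
  }
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("reconstructed hazards must be positive everywhere; ",
         "check observed rates and the reference")
  }
  structure(
    list(ages = ages, mu = mu,
         source = ifelse(ages <= a_star, "observed", "extrapolated"),
         anchors = anchors, curves = curves, grid = grid, a_star = a_star,
         reference_group_rates = refg,
         reference_omega = reference_omega_rate(reference)),
    class = "reconstructed_hazards"
  )
}

#' @export
print.reconstructed_hazards <- function(x, ...) {
  cat("<reconstructed_hazards> ages ", x$ages[1], "-", x$grid$omega,
      ", a* = ", x$a_star, "\n  anchors: ",
      paste(sprintf("%s %.3f", names(x$anchors), x$anchors), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
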