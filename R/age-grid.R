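#' Abridged age grid for register data
#'
#' Describes the age layout of education-stratified register counts: closed
#' 5-year groups addressed by their lower bound (30-34, ..., 85-89), an open
#' terminal group (90+), and a terminal model age omega at which all
#' education-specific hazards are assumed to meet the national hazard.
#'
#' @param lower Integer lower bounds of the age groups, strictly increasing
#'   and contiguous. The last bound is the lower bound of the open interval.
#' @param width Width in years of each closed group (default 5).
#' @param omega Terminal model age in years; must exceed the open-interval
#'   lower bound. Default 110.
#' @return An object of class `age_grid`.
#' @examples
#' g <- age_grid()
#' g$lower
#' @export
age_grid <- function(lower = seq(30L, 90L, by = 5L), width = 5L, omega = 110L) {
  lower <- as.integer(lower)
  width <- as.integer(width)
  omega <- as.integer(omega)
  if (length(lower) < 2L) stop("age grid needs at least two groups")
  if (any(diff(lower) <= 0L)) stop("age-group lower bounds must be strictly increasing")
  if (any(diff(lower) != width)) {
    stop("age-group lower bounds must be contiguous with width ", width)
  }
  open_lower <- lower[length(lower)]
  if (omega <= open_lower) {
    stop("omega (", omega, ") must exceed the open-interval lower bound (", open_lower, ")")
  }
  structure(
    list(lower = lower, width = width, open_lower = open_lower, omega = omega),
    class = "age_grid"
  )
}

#' @export
print.age_grid <- function(x, ...) {
  cat("<age_grid> ", x$lower[1], "-", x$open_lower, "+ by ", x$width,
      ", omega = ", x$omega, "\n", sep = "")
  invisible(x)
}

# lower bounds of the extended 5-year grid used for reconstructed hazards:
# the data grid's closed groups continued up to omega - width
extended_lower <- function(grid) {
  seq(grid$lower[1], grid$omega - grid$width, by = grid$width)
}

# midpoint of the group addressed by lower bound a
group_midpoint <- function(grid, a) a + grid$width / 2

education_levels <- c("low", "middle", "high")
all_levels <- c(education_levels, "unknown")
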