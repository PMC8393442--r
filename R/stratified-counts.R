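#' Education-stratified death and exposure counts
#'
#' Container for the raw input of the reconstruction: deaths and population
#' exposure (person-years over a 5-year period) by 5-year age group and
#' educational attainment (low/middle/high per ISCED, plus an explicit
#' unknown category) for one country, period and sex. Cells reported as
#' missing by the register are carried as `NA` (masked), never silently
#' zeroed: a masked cell means "not available", a zero means "observed zero".
#'
#' @param country Country label.
#' @param period Period label, e.g. `"1991-1995"`.
#' @param sex `"female"` or `"male"`.
#' @param deaths,population Numeric matrices with rows
#'   `c("low","middle","high","unknown")` and one column per age group
#'   (named by lower bound). Non-negative; `NA` marks a masked cell.
#' @param grid An [age_grid()] describing the columns.
#' @return An object of class `stratified_counts`.
#' @export
stratified_counts <- function(country, period, sex, deaths, population,
                              grid = age_grid()) {
  sex <- match.arg(sex, c("female", "male"))
  deaths <- as.matrix(deaths)
  population <- as.matrix(population)
  n_age <- length(grid$lower)
  for (nm in c("deaths", "population")) {
    m <- get(nm)
    if (!identical(dim(m), c(4L, n_age))) {
      stop(nm, " must be a 4 x ", n_age, " matrix (education x age group)")
    }
    if (is.null(rownames(m)) || !identical(rownames(m), all_levels)) {
      stop(nm, " rows must be named ", paste(all_levels, collapse = ", "))
    }
    if (any(m < 0, na.rm = TRUE)) stop("negative ", nm, " are not allowed")
  }
  colnames(deaths) <- colnames(population) <- as.character(grid$lower)
  # crude rate sanity bound: deaths over 5-year exposure cannot plausibly
  # exceed 1.5 per person-year
  rate <- deaths / population
  bad <- which(is.finite(rate) & rate >= 1.5)
  if (length(bad)) stop("implausible death rate >= 1.5 in ", length(bad), " cell(s)")
  structure(
    list(country = country, period = period, sex = sex,
         grid = grid, deaths = deaths, population = population),
    class = "stratified_counts"
  )
}

#' @export
print.stratified_counts <- function(x, ...) {
  cat("<stratified_counts> ", x$country, " ", x$period, " ", x$sex,
      ": ages ", x$grid$lower[1], "-", x$grid$open_lower, "+\n", sep = "")
  cat("  total deaths: ", format(sum(x$deaths, na.rm = TRUE)),
      "  total exposure: ", format(sum(x$population, na.rm = TRUE)), "\n", sep = "")
  n_mask <- sum(is.na(x$deaths)) + sum(is.na(x$population))
  if (n_mask) cat("  masked cells: ", n_mask, "\n", sep = "")
  invisible(x)
}

# age-group totals across all education codes incl. unknown; NA if any cell masked
total_deaths <- function(counts) colSums(counts$deaths)
total_population <- function(counts) colSums(counts$population)

#' Share of counts with unknown education by age
#'
#' @param counts A [stratified_counts()] object.
#' @param basis `"population"`, `"deaths"`, or `"both"`; with `"both"` the
#'   share reported per age is the larger of the two (an age qualifies as
#'   reliable only if both shares are small).
#' @return Named numeric vector of unknown shares by age-group lower bound;
#'   `NA` where the needed cells are masked.
#' @export
unknown_share <- function(counts, basis = c("both", "population", "deaths")) {
  basis <- match.arg(basis)
  sh <- function(m) m["unknown", ] / colSums(m)
  switch(basis,
    population = sh(counts$population),
    deaths = sh(counts$deaths),
    both = pmax(sh(counts$population), sh(counts$deaths))
  )
}
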