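#' Select the last reliable age
#'
#' Finds the largest age group a* at which the share of records with unknown
#' education is still small enough for the observed education-specific rates
#' to be trusted. The scan starts at `min_age` and walks up the grid; the
#' first age that fails the criterion (share above `threshold`, or the needed
#' cells masked) stops it, so a* is the last age of the contiguous reliable
#' run — an isolated "good" age beyond a run of bad ones is never selected.
#'
#' @param counts A [stratified_counts()] object.
#' @param threshold Maximum tolerated unknown share (default 0.05).
#' @param min_age Youngest age admissible as a* (default 60).
#' @param basis Which share governs the criterion: `"population"`,
#'   `"deaths"`, or `"both"` (default; an age qualifies only if both the
#'   population and the deaths share are at or below the threshold).
#' @return An object of class `reliable_age`: list with `a_star`, the
#'   `criterion_shares` used per scanned age, `threshold`, `min_age`, `basis`.
#' @examples
#' # a Swedish-style profile: deaths unknown share 4% at 75 but 56% at 80
#' # selects a* = 75
#' @export
select_reliable_age <- function(counts, threshold = 0.05, min_age = 60L,
                                basis = c("both", "population", "deaths")) {
  basis <- match.arg(basis)
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  shares <- unknown_share(counts, basis)
  ages <- counts$grid$lower
  cand <- ages[ages >= min_age]
  if (!length(cand)) stop("no age group at or above min_age = ", min_age)
  a_star <- NA_integer_
  used <- numeric(0)
  for (a in cand) {
    s <- shares[[as.character(a)]]
    used[as.character(a)] <- s
    if (is.na(s) || s > threshold) break
    a_star <- a
  }
  if (is.na(a_star)) {
    stop("no reliable age: unknown share at age ", cand[1], " is ",
         formatC(used[[1]], digits = 3, format = "g"),
         " (threshold ", threshold, ")")
  }
  structure(
    list(a_star = a_star, criterion_shares = used, threshold = threshold,
         min_age = as.integer(min_age), basis = basis),
    class = "reliable_age"
  )
}

#' @export
print.reliable_age <- function(x, ...) {
  cat("<reliable_age> a* = ", x$a_star, " (basis ", x$basis,
      ", threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

# Fold unknown-education counts at one age into the known categories in
# proportion to the same-age known distribution. m is a 4 x n matrix.
fold_unknown_matrix <- function(m, age_cols) {
  for (j in age_cols) {
    known <- m[education_levels, j]
    u <- m["unknown", j]
    if (is.na(u) || u == 0) {
      if (!is.na(u)) m["unknown", j] <- 0
      next
    }
    if (any(is.na(known)) || sum(known) == 0) {
      stop("cannot fold unknown counts at age ", colnames(m)[j],
           ": no known-education counts to set the shares")
    }
    m[education_levels, j] <- known + known / sum(known) * u
    m["unknown", j] <- 0
  }
  m
}

#' Observed education-specific death rates up to the reliable age
#'
#' For ages at or below a* the unknown-education deaths and exposures (a few
#' per cent at most, by construction of a*) are first folded into the known
#' categories in proportion to the same-age known distribution; rates are
#' then deaths over exposure per education and age group.
#'
#' @param counts A [stratified_counts()] object.
#' @param a_star The reliable age, e.g. from [select_reliable_age()].
#' @return Object of class `observed_rates`: list with `rate` (3 x n matrix,
#'   education x age for ages <= a*), the folded `deaths` and `population`
#'   matrices, and `a_star`.
#' @export
observed_group_rates <- function(counts, a_star) {
  ages <- counts$grid$lower
  cols <- which(ages <= a_star)
  d <- counts$deaths
  p <- counts$population
  if (any(is.na(d[, cols])) || any(is.na(p[, cols]))) {
    bad <- which(is.na(d[, cols, drop = FALSE]) | is.na(p[, cols, drop = FALSE]),
                 arr.ind = TRUE)[1, ]
    stop("masked cell at or below a*: education ", all_levels[bad[1]],
         ", age ", ages[cols][bad[2]])
  }
  d <- fold_unknown_matrix(d, cols)
  p <- fold_unknown_matrix(p, cols)
  dk <- d[education_levels, cols, drop = FALSE]
  pk <- p[education_levels, cols, drop = FALSE]
  if (any(pk == 0 & dk > 0)) stop("zero exposure with positive deaths")
  rate <- dk / pk
  empty <- pk == 0 & dk == 0
  if (any(empty)) {
    warning(sum(empty), " cell(s) with zero exposure and zero deaths; rate masked")
    rate[empty] <- NA_real_
  }
  structure(
    list(rate = rate, deaths = d[, cols, drop = FALSE],
         population = p[, cols, drop = FALSE], a_star = a_star),
    class = "observed_rates"
  )
}
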