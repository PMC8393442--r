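#' Build a period life table from age-specific death rates
#'
#' Standard abridged (or single-year) period life-table construction from
#' death rates m(x): probabilities of dying via the chosen within-interval
#' convention, survivorship from radix 100000, person-years, and remaining
#' life expectancy. The last age is treated as an open interval closed with
#' `L = l / m` (everyone alive at the terminal age dies at its constant
#' rate), so `q = 1` and `e = 1/m` there.
#'
#' @param mx Positive death rates, one per age.
#' @param ages Lower bounds of the age intervals; the last is the open
#'   terminal age. Default: 5-year groups 30..105 plus terminal 110.
#' @param radix Survivors at the first age (default 100000).
#' @param convention Within-interval assumption for closed intervals:
#'   `"midpoint"` (deaths at mid-interval on average,
#'   `q = n m / (1 + (n/2) m)`, `a = n/2`) or `"exponential"`
#'   (piecewise-constant hazard, `q = 1 - exp(-n m)`). Intervals with
#'   `n m >= 1` — only the very oldest groups of a 5-year grid — always use
#'   the constant-hazard form, where the mid-interval assumption is no
#'   longer tenable and would push q toward or past 1.
#' @param country,period,sex,education Optional metadata carried as
#'   attributes (used by [write_lifetables()]).
#' @return A data.frame of class `life_table` with columns
#'   `age, mx, qx, ax, lx, dx, Lx, Tx, ex`.
#' @examples
#' lt <- build_lifetable(rep(0.1, 10), ages = c(seq(30, 70, 5), 75),
#'                       convention = "exponential")
#' lt$ex  # all exactly 10 under a constant hazard of 0.1
#' @export
build_lifetable <- function(mx, ages = c(seq(30L, 105L, 5L), 110L),
                            radix = 1e5,
                            convention = c("midpoint", "exponential"),
                            country = NA_character_, period = NA_character_,
                            sex = NA_character_, education = NA_character_) {
  convention <- match.arg(convention)
  mx <- as.numeric(mx)
  if (length(mx) != length(ages)) stop("mx and ages differ in length")
  if (any(!is.finite(mx)) || any(mx <= 0)) stop("all death rates must be > 0")
  if (any(diff(ages) <= 0)) stop("ages must be strictly increasing")
  k <- length(ages)
  n <- c(diff(ages), Inf)

  qx <- ax <- numeric(k)
  for (i in seq_len(k - 1L)) {
    if (convention == "midpoint" && n[i] * mx[i] < 1) {
      qx[i] <- n[i] * mx[i] / (1 + n[i] / 2 * mx[i])
      ax[i] <- n[i] / 2
    } else {
      # constant-hazard form; also the fallback where mortality is so high
      # (n m >= 1) that the deaths-at-mid-interval assumption breaks down
      qx[i] <- 1 - exp(-n[i] * mx[i])
      # a consistent with L = d/m: a = (L - n l(x+n)) / d
      ax[i] <- 1 / mx[i] - n[i] * (1 - qx[i]) / qx[i]
    }
  }
  qx[k] <- 1
  ax[k] <- 1 / mx[k]

  lx <- radix * cumprod(c(1, 1 - qx[-k]))
  dx <- lx * qx
  Lx <- numeric(k)
  for (i in seq_len(k - 1L)) {
    Lx[i] <- n[i] * (lx[i] - dx[i]) + ax[i] * dx[i]
  }
  Lx[k] <- lx[k] / mx[k]
  Tx <- rev(cumsum(rev(Lx)))
  ex <- Tx / lx

  out <- data.frame(age = ages, mx = mx, qx = qx, ax = ax,
                    lx = lx, dx = dx, Lx = Lx, Tx = Tx, ex = ex)
  class(out) <- c("life_table", "data.frame")
  attr(out, "country") <- country; attr(out, "period") <- period
  attr(out, "sex") <- sex; attr(out, "education") <- education
  attr(out, "convention") <- convention
  out
}

#' Remaining life expectancy at an exact age
#'
#' @param lt A [build_lifetable()] table.
#' @param age An age present in the table.
#' @return `e(age)` in years.
#' @export
life_expectancy <- function(lt, age) {
  i <- match(age, lt$age)
  if (is.na(i)) stop("age ", age, " is not in the life table")
  lt$ex[i]
}

#' Complete (single-year) life table from an abridged one
#'
#' Graduation by piecewise-constant hazard, constrained to the parent table:
#' within each closed n-year group the single-year hazard is the constant
#' rate consistent with the group's survival probability,
#' `h = -log(1 - q) / n`, so survivorship l at the group boundaries
#' reproduces the abridged table exactly; the single-year person-years are
#' then rescaled so each group's total L equals the parent's (the a column
#' absorbs the adjustment). Survivorship, person-years above any group
#' boundary and hence remaining life expectancy at every boundary age are
#' preserved exactly. The terminal open row is carried over unchanged.
#'
#' @param lt An abridged [build_lifetable()] table.
#' @return A single-year `life_table` from the first to the terminal age.
#' @export
complete_from_abridged <- function(lt) {
  k <- nrow(lt)
  ages <- lt$age
  n <- diff(ages)
  yr_age <- yr_m <- numeric(0)
  for (i in seq_len(k - 1L)) {
    h <- -log(1 - lt$qx[i]) / n[i]
    yr_age <- c(yr_age, seq(ages[i], ages[i + 1L] - 1L))
    yr_m <- c(yr_m, rep(h, n[i]))
  }
  yr_age <- c(yr_age, ages[k])
  yr_m <- c(yr_m, lt$mx[k])
  out <- build_lifetable(yr_m, ages = yr_age, radix = lt$lx[1],
                         convention = "exponential",
                         country = attr(lt, "country"),
                         period = attr(lt, "period"),
                         sex = attr(lt, "sex"),
                         education = attr(lt, "education"))
  for (i in seq_len(k - 1L)) {
    idx <- which(out$age >= ages[i] & out$age < ages[i + 1L])
    scale <- lt$Lx[i] / sum(out$Lx[idx])
    out$Lx[idx] <- out$Lx[idx] * scale
    pos <- out$dx[idx] > 0
    out$ax[idx][pos] <- (out$Lx[idx][pos] - out$lx[idx + 1L][pos]) /
      out$dx[idx][pos]
  }
  out$Tx <- rev(cumsum(rev(out$Lx)))
  out$ex <- out$Tx / out$lx
  attr(out, "grid") <- "complete"
  out
}

#' @export
print.life_table <- function(x, ...) {
  meta <- c(attr(x, "country"), attr(x, "period"), attr(x, "sex"),
            attr(x, "education"))
  meta <- meta[!is.na(meta)]
  cat("<life_table>", if (length(meta)) paste(meta, collapse = " "),
      " ages ", x$age[1], "-", x$age[nrow(x)], "+, e(", x$age[1], ") = ",
      formatC(x$ex[1], digits = 2, format = "f"), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Difference in remaining life expectancy between two groups
#'
#' Computes `e_a(age) - e_b(age)` either from the packaged published values
#' (pass the [table1_life_expectancy()] data.frame and selector lists) or
#' from two life tables. Differences taken from the published fixture are
#' rounded to 1 decimal, the precision at which the values are printed.
#'
#' @param x A fixture data.frame (columns country, period, education, sex,
#'   age, ex) or a `life_table`.
#' @param a,b If `x` is a fixture: named lists selecting one cell each, e.g.
#'   `list(country = "Sweden", period = "1991-1995", education = "high",
#'   sex = "female")`. If `x` is a life table: `a` is ignored and `b` must
#'   be the second life table.
#' @param age Age (30 or 65 for the fixture) at which to difference.
#' @return The gap in years.
#' @examples
#' \dontrun{
#' t1 <- table1_life_expectancy()
#' expectancy_gap(t1,
#'   list(country = "Sweden", period = "1991-1995", education = "high",
#'        sex = "female"),
#'   list(country = "Sweden", period = "1991-1995", education = "high",
#'        sex = "male"), age = 30)  # 4.8
#' }
#' @export
expectancy_gap <- function(x, a, b, age) {
  if (inherits(x, "life_table")) {
    if (!inherits(b, "life_table")) stop("b must be a second life table")
    return(life_expectancy(x, age) - life_expectancy(b, age))
  }
  pick <- function(sel) {
    rows <- x$age == age
    for (f in names(sel)) rows <- rows & x[[f]] == sel[[f]]
    v <- x$ex[rows]
    if (length(v) != 1L) {
      stop("selector matches ", length(v), " fixture cells (need exactly 1)")
    }
    v
  }
  round(pick(a) - pick(b), 1)
}
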