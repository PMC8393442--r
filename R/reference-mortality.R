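#' National all-education reference mortality
#'
#' Death rates of the whole national population by age, the convergence
#' target of the reconstruction: at the terminal age omega every
#' education-specific hazard is assumed equal to the national hazard. In
#' practice these rates come from the Human Mortality Database (period Mx),
#' supplied as a local file; the synthetic module can also derive them from
#' generating truth.
#'
#' @param ages Integer ages (single-year, e.g. 30..110) or 5-year group lower
#'   bounds ending at omega. Must cover 30..omega without gaps.
#' @param rates Strictly positive death rates per person-year, one per age.
#' @param omega Terminal age; the last age must equal it.
#' @return Object of class `reference_mortality`.
#' @export
reference_mortality <- function(ages, rates, omega = 110L) {
  ages <- as.integer(ages)
  rates <- as.numeric(rates)
  if (length(ages) != length(rates)) stop("ages and rates differ in length")
  if (any(diff(ages) <= 0L)) stop("ages must be strictly increasing")
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all reference rates must be finite and > 0")
  }
  if (ages[length(ages)] != omega) {
    stop("reference rates must extend to omega = ", omega,
         " (last age is ", ages[length(ages)], ")")
  }
  step <- unique(diff(ages))
  if (!length(step) %in% c(1L, 2L)) stop("reference ages must be on a regular grid")
  single_year <- step[1] == 1L
  if (single_year) {
    gaps <- setdiff(seq(ages[1], omega), ages)
    if (length(gaps)) {
      stop("reference rates have gaps at ages ", paste(gaps, collapse = ", "))
    }
  }
  structure(
    list(ages = ages, rates = rates, omega = as.integer(omega),
         single_year = single_year),
    class = "reference_mortality"
  )
}

#' @export
print.reference_mortality <- function(x, ...) {
  cat("<reference_mortality> ages ", x$ages[1], "-", x$omega,
      if (x$single_year) " (single-year)" else " (grouped)", "\n", sep = "")
  invisible(x)
}

# National rate aggregated to the 5-year group with lower bound a.
# Single-year input: unweighted mean of the rates in [a, a + width);
# grouped input: the stored group rate.
reference_group_rate <- function(ref, a, width = 5L) {
  if (ref$single_year) {
    idx <- ref$ages >= a & ref$ages < a + width
    if (!any(idx)) stop("reference rates do not cover age group ", a)
    mean(ref$rates[idx])
  } else {
    i <- match(a, ref$ages)
    if (is.na(i)) stop("reference rates do not cover age group ", a)
    ref$rates[i]
  }
}

# Point rate at the terminal age omega
reference_omega_rate <- function(ref) ref$rates[length(ref$rates)]
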