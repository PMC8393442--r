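#' Read education-stratified counts from delimited text
#'
#' Long-form reader: one row per (age group, education) cell with columns
#' `country, period, sex, age_low, education, deaths, population`. Cells
#' absent from the file are recorded as masked (`NA`), mirroring registers
#' in which, e.g., death counts at the oldest ages are simply not available
#' in early periods.
#'
#' @param path Path to a comma- or tab-separated file with a header row.
#' @param dialect `"auto"` (default; sniffs the separator), `"csv"` or `"tsv"`.
#' @param grid The [age_grid()] the file is expected to cover.
#' @return A list of [stratified_counts()], one per (country, period, sex)
#'   present in the file, named `country|period|sex`; a single object if the
#'   file holds exactly one stratum.
#' @export
read_stratified_counts <- function(path, dialect = c("auto", "csv", "tsv"),
                                   grid = age_grid()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- switch(dialect,
    csv = ",", tsv = "\t",
    auto = if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  )
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("country", "period", "sex", "age_low", "education", "deaths", "population")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$education %in% all_levels)) {
    bad <- setdiff(unique(df$education), all_levels)
    stop("unknown education code(s): ", paste(bad, collapse = ", "))
  }
  for (col in c("deaths", "population")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      row <- which(!grepl("^\\s*(NA|[-+0-9.eE]*)\\s*$", as.character(v)))[1]
      stop("malformed ", col, " at data line ", if (is.na(row)) "?" else row)
    }
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative ", col, " at data line ", which(v < 0)[1])
    }
  }
  if (!all(df$age_low %in% grid$lower)) {
    bad <- setdiff(unique(df$age_low), grid$lower)
    stop("age_low outside the grid: ", paste(bad, collapse = ", "))
  }
  key <- interaction(df$country, df$period, df$sex, sep = "|", drop = TRUE)
  out <- lapply(split(df, key), function(d) {
    dup <- duplicated(d[c("age_low", "education")])
    if (any(dup)) {
      stop("duplicate cell for age ", d$age_low[dup][1], ", education ",
           d$education[dup][1])
    }
    deaths <- population <- matrix(
      NA_real_, 4L, length(grid$lower),
      dimnames = list(all_levels, as.character(grid$lower))
    )
    i <- cbind(match(d$education, all_levels), match(d$age_low, grid$lower))
    deaths[i] <- d$deaths
    population[i] <- d$population
    stratified_counts(d$country[1], d$period[1], d$sex[1],
                      deaths, population, grid = grid)
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Write stratified counts to delimited text
#'
#' Inverse of [read_stratified_counts()]: long form, one row per available
#' cell; masked cells are omitted so that a round trip preserves the mask.
#'
#' @param counts A [stratified_counts()] or list of them.
#' @param path Output path; separator follows the file extension
#'   (`.csv` comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_stratified_counts <- function(counts, path) {
  if (inherits(counts, "stratified_counts")) counts <- list(counts)
  rows <- lapply(counts, function(x) {
    g <- expand.grid(education = all_levels, age_low = x$grid$lower,
                     stringsAsFactors = FALSE)
    i <- cbind(match(g$education, all_levels), match(g$age_low, x$grid$lower))
    d <- data.frame(country = x$country, period = x$period, sex = x$sex,
                    age_low = g$age_low, education = g$education,
                    deaths = x$deaths[i], population = x$population[i])
    d[!(is.na(d$deaths) & is.na(d$population)), ]
  })
  df <- do.call(rbind, rows)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read national reference death rates
#'
#' Reads all-education death rates by single year of age, either from the
#' Human Mortality Database period death-rate layout (whitespace-aligned
#' columns `Year Age Female Male Total`, terminal age written `110+`) or
#' from a plain two-column delimited file `age<sep>rate`.
#'
#' @param path Path to the rates file.
#' @param layout `"delimited"` or `"hmd_fixed"`.
#' @param sex For the HMD layout, which column to use
#'   (`"female"`, `"male"`, `"total"`).
#' @param min_age,omega Age range the rates must cover (gaps are an error).
#' @param year For multi-year HMD files, the year to extract (default: first).
#' @return A [reference_mortality()].
#' @export
read_reference_rates <- function(path, layout = c("delimited", "hmd_fixed"),
                                 sex = c("total", "female", "male"),
                                 min_age = 30L, omega = 110L, year = NULL) {
  layout <- match.arg(layout)
  sex <- match.arg(sex)
  if (!file.exists(path)) stop("file not found: ", path)
  if (layout == "hmd_fixed") {
    lines <- readLines(path)
    hdr <- grep("\\bYear\\b.*\\bAge\\b", lines)[1]
    if (is.na(hdr)) stop("no HMD header line (Year ... Age ...) found")
    cols <- strsplit(trimws(lines[hdr]), "\\s+")[[1]]
    body <- lines[-seq_len(hdr)]
    body <- body[nzchar(trimws(body))]
    fields <- strsplit(trimws(body), "\\s+")
    ok <- lengths(fields) == length(cols)
    tab <- as.data.frame(do.call(rbind, fields[ok]), stringsAsFactors = FALSE)
    names(tab) <- cols
    if (!is.null(year)) tab <- tab[tab$Year == as.character(year), ]
    if (!nrow(tab)) stop("no rows for the requested year")
    tab <- tab[tab$Year == tab$Year[1], ]
    age <- suppressWarnings(as.integer(sub("\\+$", "", tab$Age)))
    col <- c(total = "Total", female = "Female", male = "Male")[[sex]]
    if (!col %in% names(tab)) stop("HMD file has no column ", col)
    rate <- suppressWarnings(as.numeric(tab[[col]]))
    keep <- !is.na(age) & age >= min_age & age <= omega
    age <- age[keep]; rate <- rate[keep]
  } else {
    sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, strip.white = TRUE)
    if (ncol(df) < 2L) stop("delimited rates file needs columns age, rate")
    age <- as.integer(df[[1]])
    rate <- as.numeric(df[[2]])
    keep <- age >= min_age & age <= omega
    age <- age[keep]; rate <- rate[keep]
  }
  gaps <- setdiff(seq(min_age, omega), age)
  if (length(gaps)) {
    stop("reference rates missing for ages ", paste(gaps, collapse = ", "))
  }
  if (any(is.na(rate)) || any(rate <= 0)) {
    stop("non-positive or unreadable rate in ", path)
  }
  o <- order(age)
  reference_mortality(age[o], rate[o], omega = omega)
}

#' Write life tables to tab-separated text
#'
#' Long form, HMD-like column order: one row per (country, period, sex,
#' education, age) with columns `Age mx qx ax lx dx Lx Tx ex`.
#'
#' @param tables A [life_table()] or a list of them; metadata is taken from
#'   each table's attributes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lifetables <- function(tables, path) {
  if (inherits(tables, "life_table")) tables <- list(tables)
  cols <- c("country", "period", "sex", "education",
            "Age", "mx", "qx", "ax", "lx", "dx", "Lx", "Tx", "ex")
  rows <- lapply(tables, function(lt) {
    meta <- attributes(lt)[c("country", "period", "sex", "education")]
    meta <- lapply(meta, function(v) if (is.null(v)) "" else v)
    data.frame(country = meta$country, period = meta$period, sex = meta$sex,
               education = meta$education, Age = lt$age,
               mx = lt$mx, qx = lt$qx, ax = lt$ax, lx = lt$lx,
               dx = lt$dx, Lx = lt$Lx, Tx = lt$Tx, ex = lt$ex)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "Age"
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 6, format = "f"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read life tables written by [write_lifetables()]
#'
#' @param path Path to the tab-separated file.
#' @return A list of [life_table()] objects (possibly empty), named
#'   `country|period|sex|education`.
#' @export
read_lifetables <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!nrow(df)) return(list())
  key <- interaction(df$country, df$period, df$sex, df$education,
                     sep = "|", drop = TRUE)
  lapply(split(df, key), function(d) {
    lt <- d[c("Age", "mx", "qx", "ax", "lx", "dx", "Lx", "Tx", "ex")]
    names(lt)[1] <- "age"
    class(lt) <- c("life_table", "data.frame")
    attr(lt, "country") <- d$country[1]; attr(lt, "period") <- d$period[1]
    attr(lt, "sex") <- d$sex[1]; attr(lt, "education") <- d$education[1]
    rownames(lt) <- NULL
    lt
  })
}

#' Published remaining life expectancies by education (packaged fixture)
#'
#' Remaining life expectancy at ages 30 and 65 by country (Denmark, Sweden),
#' period (1991-1995, 2011-2015), education (low/middle/high/total) and sex,
#' as published for the reconstructed Danish and Swedish life tables. Used
#' for arithmetic on the published values, e.g. with [expectancy_gap()].
#'
#' @return A data.frame with columns
#'   `country, period, education, sex, age, ex`.
#' @export
table1_life_expectancy <- function() {
  path <- system.file("extdata", "table1_life_expectancy.tsv",
                      package = "edumort", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(df$ex[df$age == 30] > df$ex[df$age == 65]))
  df
}
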