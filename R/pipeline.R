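#' Configuration of a reconstruction run
#'
#' Collects every tunable of the pipeline with its documented default.
#' Unknown keys are rejected so a typo cannot silently fall back to a
#' default.
#'
#' @param threshold Maximum unknown share for a reliable age (default 0.05).
#' @param min_age Youngest admissible reliable age (default 60).
#' @param basis Reliable-age criterion basis
#'   (`"both"`/`"population"`/`"deaths"`).
#' @param delta_bounds Admissible interval for delta (default `c(0, 2)`).
#' @param delta_tolerance Relative per-age tolerance on residual unknown
#'   deaths (default 1e-6).
#' @param optimizer `"de_refine"` or `"closed_form"` (see [solve_delta()]).
#' @param recursion_basis `"redistributed"` or `"raw"` (see
#'   [redistribute_population()]).
#' @param convention Life-table within-interval convention
#'   (`"midpoint"`/`"exponential"`).
#' @param seed Integer seed for the stochastic delta search.
#' @return Object of class `reconstruction_config`.
#' @export
reconstruction_config <- function(threshold = 0.05, min_age = 60L,
                                  basis = "both",
                                  delta_bounds = c(0, 2),
                                  delta_tolerance = 1e-6,
                                  optimizer = "de_refine",
                                  recursion_basis = "redistributed",
                                  convention = "midpoint",
                                  seed = 1L) {
  cfg <- list(
    threshold = threshold, min_age = as.integer(min_age),
    basis = match.arg(basis, c("both", "population", "deaths")),
    delta_bounds = delta_bounds, delta_tolerance = delta_tolerance,
    optimizer = match.arg(optimizer, c("de_refine", "closed_form")),
    recursion_basis = match.arg(recursion_basis, c("redistributed", "raw")),
    convention = match.arg(convention, c("midpoint", "exponential")),
    seed = as.integer(seed)
  )
  structure(cfg, class = "reconstruction_config")
}

#' Reconstruct education-specific mortality for one stratum
#'
#' Runs the full method for one (country, period, sex): select the last
#' reliable age, form observed education-specific rates (folding the small
#' unknown pools below it), extrapolate hazard ratios linearly to 1 at
#' omega, solve for the redistribution scale delta so that unknown deaths
#' are exhausted above a*, and build abridged and complete life tables per
#' education group plus the national total.
#'
#' @param counts A [stratified_counts()] object.
#' @param reference A [reference_mortality()] for the same stratum.
#' @param config A [reconstruction_config()].
#' @return Object of class `edu_reconstruction`: `reliable_age`, `observed`,
#'   `hazards`, `delta` ([solve_delta()] result), `population`
#'   (redistributed, at the solved delta), `deaths_star`, `lifetables`
#'   (abridged, per education + `total`), `complete` (single-year tables),
#'   `summary` (data.frame of e(30)/e(65) per group), `config`.
#' @export
reconstruct_education_mortality <- function(counts, reference,
                                            config = reconstruction_config()) {
  ra <- select_reliable_age(counts, threshold = config$threshold,
                            min_age = config$min_age, basis = config$basis)
  obs <- observed_group_rates(counts, ra$a_star)
  hz <- reconstruct_hazards(obs, reference, grid = counts$grid,
                            a_star = ra$a_star)
  dl <- solve_delta(counts, hz, ra$a_star, bounds = config$delta_bounds,
                    tolerance = config$delta_tolerance, seed = config$seed,
                    optimizer = config$optimizer,
                    recursion_basis = config$recursion_basis)
  ps <- suppressWarnings(
    redistribute_population(counts, ra$a_star, dl$delta,
                            recursion_basis = config$recursion_basis,
                            delta_max = config$delta_bounds[2])
  )
  ds <- redistributed_deaths(ps, hz)

  lts <- lapply(education_levels, function(e) {
    build_lifetable(hz$mu[e, ], ages = hz$ages,
                    convention = config$convention,
                    country = counts$country, period = counts$period,
                    sex = counts$sex, education = e)
  })
  names(lts) <- education_levels
  total_rates <- c(hz$reference_group_rates, hz$reference_omega)
  lts$total <- build_lifetable(total_rates, ages = hz$ages,
                               convention = config$convention,
                               country = counts$country,
                               period = counts$period,
                               sex = counts$sex, education = "total")
  complete <- lapply(lts, complete_from_abridged)
  summary <- data.frame(
    country = counts$country, period = counts$period, sex = counts$sex,
    education = names(lts),
    a_star = ra$a_star, delta = dl$delta,
    e30 = vapply(lts, life_expectancy, numeric(1), age = 30),
    e65 = vapply(lts, life_expectancy, numeric(1), age = 65),
    row.names = NULL
  )
  structure(
    list(reliable_age = ra, observed = obs, hazards = hz, delta = dl,
         population = ps, deaths_star = ds, lifetables = lts,
         complete = complete, summary = summary, config = config),
    class = "edu_reconstruction"
  )
}

#' @export
print.edu_reconstruction <- function(x, ...) {
  s <- x$summary
  cat("<edu_reconstruction> ", s$country[1], " ", s$period[1], " ", s$sex[1],
      ": a* = ", x$reliable_age$a_star,
      ", delta = ", formatC(x$delta$delta, digits = 4, format = "f"),
      if (!x$delta$converged) " (delta NOT converged)", "\n", sep = "")
  print(s[c("education", "e30", "e65")], row.names = FALSE, ...)
  invisible(x)
}

#' Run the reconstruction pipeline over files
#'
#' Reads stratified counts and national reference rates from disk, runs
#' [reconstruct_education_mortality()] for every (country, period, sex)
#' stratum in the counts file, and writes per-stratum outputs: abridged and
#' complete life tables, an e(30)/e(65) summary, delta diagnostics and a
#' run manifest echoing the configuration and seed.
#'
#' @param counts_path Counts file for [read_stratified_counts()].
#' @param reference_path Reference rates file; `reference_layout` selects
#'   the parser. With the HMD layout the sex column follows each stratum.
#' @param out_dir Output directory (created if needed).
#' @param config A [reconstruction_config()].
#' @param reference_layout `"delimited"` or `"hmd_fixed"`.
#' @return Invisibly, the list of `edu_reconstruction` results keyed by
#'   `country|period|sex`.
#' @export
run_reconstruction <- function(counts_path, reference_path, out_dir,
                               config = reconstruction_config(),
                               reference_layout = c("delimited", "hmd_fixed")) {
  reference_layout <- match.arg(reference_layout)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- read_stratified_counts(counts_path)
  if (inherits(counts, "stratified_counts")) {
    counts <- stats::setNames(
      list(counts),
      paste(counts$country, counts$period, counts$sex, sep = "|")
    )
  }
  results <- list()
  for (key in names(counts)) {
    cts <- counts[[key]]
    ref <- if (reference_layout == "hmd_fixed") {
      read_reference_rates(reference_path, "hmd_fixed", sex = cts$sex,
                           omega = cts$grid$omega)
    } else {
      read_reference_rates(reference_path, "delimited", omega = cts$grid$omega)
    }
    res <- tryCatch(
      reconstruct_education_mortality(cts, ref, config),
      error = function(e) {
        stop("reconstruction failed for ", key, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    results[[key]] <- res
    message(sprintf("%s: a* = %d, delta = %.4f%s", key,
                    res$reliable_age$a_star, res$delta$delta,
                    if (res$delta$converged) "" else " (not converged)"))
  }

  all_abridged <- unlist(lapply(results, `[[`, "lifetables"),
                         recursive = FALSE, use.names = FALSE)
  all_complete <- unlist(lapply(results, `[[`, "complete"),
                         recursive = FALSE, use.names = FALSE)
  write_lifetables(all_abridged, file.path(out_dir, "lifetables_abridged.tsv"))
  write_lifetables(all_complete, file.path(out_dir, "lifetables_complete.tsv"))
  summary <- do.call(rbind, lapply(results, `[[`, "summary"))
  rownames(summary) <- NULL
  utils::write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  delta_rows <- do.call(rbind, lapply(names(results), function(key) {
    d <- results[[key]]$delta
    if (!length(d$fitted_ages)) {
      return(data.frame(stratum = key, age = NA_integer_,
                        residual_deaths = NA_real_,
                        delta = d$delta, converged = d$converged))
    }
    data.frame(stratum = key, age = d$fitted_ages,
               residual_deaths = as.numeric(d$residuals),
               delta = d$delta, converged = d$converged)
  }))
  utils::write.table(delta_rows, file.path(out_dir, "delta_residuals.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- c(
    sprintf("edumort %s", as.character(utils::packageVersion("edumort"))),
    sprintf("counts: %s", normalizePath(counts_path)),
    sprintf("reference: %s (%s)", normalizePath(reference_path),
            reference_layout),
    sprintf("strata: %d", length(results)),
    vapply(names(unclass(config)), function(k) {
      sprintf("config %s: %s", k, paste(format(config[[k]]), collapse = " "))
    }, character(1))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(results)
}

#' Write a synthetic register bundle to disk
#'
#' Materializes a [generate_register()] draw as the text files the
#' reconstruction pipeline consumes: one counts file covering all periods
#' and sexes, one delimited reference-rates file per (period, sex), and the
#' truth life tables.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory.
#' @param country Country label.
#' @return Invisibly, the [generate_register()] bundle.
#' @export
simulate_register_files <- function(spec, out_dir, country = "Synthia") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reg <- generate_register(spec, country = country)
  write_stratified_counts(reg$counts, file.path(out_dir, "counts.tsv"))
  for (key in names(reg$counts)) {
    cts <- reg$counts[[key]]
    ref <- reference_from_truth(spec, cts$period, cts$sex)
    utils::write.table(
      data.frame(age = ref$ages, rate = ref$rates),
      file.path(out_dir, sprintf("reference_%s_%s.tsv", cts$period, cts$sex)),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  truth_tables <- unlist(lapply(reg$truth, `[[`, "lifetables"),
                         recursive = FALSE, use.names = FALSE)
  write_lifetables(truth_tables, file.path(out_dir, "truth_lifetables.tsv"))
  invisible(reg)
}

#' Summarize life-table files as an e(30)/e(65) table
#'
#' @param path A life-table file written by [write_lifetables()].
#' @return A data.frame with one row per (country, period, sex, education)
#'   and columns `e30`, `e65`, printed in aligned form.
#' @export
summarize_tables <- function(path) {
  tabs <- read_lifetables(path)
  out <- do.call(rbind, lapply(tabs, function(lt) {
    data.frame(country = attr(lt, "country"), period = attr(lt, "period"),
               sex = attr(lt, "sex"), education = attr(lt, "education"),
               e30 = if (30 %in% lt$age) life_expectancy(lt, 30) else NA_real_,
               e65 = if (65 %in% lt$age) life_expectancy(lt, 65) else NA_real_)
  }))
  rownames(out) <- NULL
  out <- out[order(out$country, out$period, out$sex,
                   match(out$education, c(education_levels, "total"))), ]
  print(out, row.names = FALSE, digits = 4)
  invisible(out)
}
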