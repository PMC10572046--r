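# Screening-cohort flow statistics and the prevalence-slope analysis.
#
# Cohort tables are one row per mutation-positive subject:
#   id, vaf_baseline (%), vaf_followup (% or NA), survived (logical),
#   diagnosed_interim (diagnosed between screening and re-examination),
#   diagnosed_at_followup (diagnosed at the re-examination itself).
# The number screened is carried as the attribute "n_screened" (written
# and read by the CSV helpers).

#' Classify the change in allele burden between baseline and follow-up
#'
#' The default rule is the strict diagonal of the baseline/follow-up plot:
#' any increase counts as `increase`, any decrease as `decrease`. An
#' optional symmetric noise band treats changes of at most `band`
#' percentage points as `stable`.
#'
#' @param baseline,followup Allele burdens in percent (vectorized).
#' @param band Half-width of the noise band in percentage points
#'   (default 0 = strict rule).
#' @return Factor with levels `increase`, `decrease`, `stable`; `NA` where
#'   the follow-up is missing.
#' @export
classify_vaf_change <- function(baseline, followup, band = 0) {
  if (band < 0) abort("band must be non-negative")
  delta <- followup - baseline
  out <- ifelse(is.na(delta), NA_character_,
                ifelse(delta > band, "increase",
                       ifelse(delta < -band, "decrease", "stable")))
  factor(out, levels = c("increase", "decrease", "stable"))
}

#' Cohort-flow summary
#'
#' Reduces a screening cohort to the headline flow counts and percentages:
#' screened, mutation-positive, surviving (re-invited), undiagnosed at
#' re-examination, diagnosed at the re-examination, and the final
#' undiagnosed group interpreted as being in a temporary dormant
#' equilibrium, split into increasing/decreasing allele burden by
#' [classify_vaf_change()]. Two headline percentages are reported, both
#' rounded to whole percent: the share of the final undiagnosed group with
#' *decreasing* burden (non-progressing), and the equilibrium share of all
#' re-invited subjects.
#'
#' `cohort_flow()` is generic: pass either a cohort table (data frame, see
#' [generate_screening_cohort()]) or a named list of printed counts with
#' fields `n_screened`, `n_positive`, `n_reinvited`,
#' `n_undiagnosed_at_reexam`, `n_diagnosed_at_followup`, `n_increase`,
#' `n_decrease`.
#'
#' @param x Cohort table or named list of counts.
#' @param ... Passed on to methods.
#' @return A one-row tibble with the counts and percentages.
#' @export
cohort_flow <- function(x, ...) UseMethod("cohort_flow")

#' @rdname cohort_flow
#' @param band Noise band for [classify_vaf_change()].
#' @param n_screened Number screened; defaults to the table's
#'   `"n_screened"` attribute.
#' @export
cohort_flow.data.frame <- function(x, band = 0, n_screened = NULL, ...) {
  need <- c("vaf_baseline", "vaf_followup", "survived",
            "diagnosed_interim", "diagnosed_at_followup")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("cohort table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  n_screened <- n_screened %||% attr(x, "n_screened") %||% nrow(x)
  reinvited <- x$survived
  undiag <- reinvited & !x$diagnosed_interim
  diag_fu <- undiag & x$diagnosed_at_followup
  final <- undiag & !x$diagnosed_at_followup
  chg <- classify_vaf_change(x$vaf_baseline[final], x$vaf_followup[final],
                             band = band)
  if (anyNA(chg)) {
    warn(sprintf("%d undiagnosed subject(s) without follow-up excluded",
                 sum(is.na(chg))))
  }
  .flow_summary(
    n_screened = n_screened,
    n_positive = nrow(x),
    n_reinvited = sum(reinvited),
    n_undiagnosed_at_reexam = sum(undiag),
    n_diagnosed_at_followup = sum(diag_fu),
    n_stable = sum(final),
    n_increase = sum(chg == "increase", na.rm = TRUE),
    n_decrease = sum(chg == "decrease", na.rm = TRUE)
  )
}

#' @rdname cohort_flow
#' @export
cohort_flow.list <- function(x, ...) {
  need <- c("n_screened", "n_positive", "n_reinvited",
            "n_undiagnosed_at_reexam", "n_diagnosed_at_followup",
            "n_increase", "n_decrease")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("missing count(s): ", paste(miss, collapse = ", ")))
  }
  .flow_summary(
    n_screened = x$n_screened,
    n_positive = x$n_positive,
    n_reinvited = x$n_reinvited,
    n_undiagnosed_at_reexam = x$n_undiagnosed_at_reexam,
    n_diagnosed_at_followup = x$n_diagnosed_at_followup,
    n_stable = x$n_undiagnosed_at_reexam - x$n_diagnosed_at_followup,
    n_increase = x$n_increase,
    n_decrease = x$n_decrease
  )
}

.flow_summary <- function(n_screened, n_positive, n_reinvited,
                          n_undiagnosed_at_reexam, n_diagnosed_at_followup,
                          n_stable, n_increase, n_decrease) {
  steps <- c(n_screened = n_screened, n_positive = n_positive,
             n_reinvited = n_reinvited,
             n_undiagnosed_at_reexam = n_undiagnosed_at_reexam)
  if (any(diff(steps) > 0)) {
    i <- which(diff(steps) > 0)[1]
    abort(sprintf("inconsistent flow: %s (%d) exceeds %s (%d)",
                  names(steps)[i + 1], steps[i + 1], names(steps)[i], steps[i]))
  }
  if (n_diagnosed_at_followup > n_undiagnosed_at_reexam) {
    abort("n_diagnosed_at_followup exceeds n_undiagnosed_at_reexam")
  }
  if (n_increase + n_decrease > n_stable) {
    abort("n_increase + n_decrease exceeds the final undiagnosed group")
  }
  pct_nonprog <- if (n_stable > 0) round(100 * n_decrease / n_stable)
                 else NA_real_
  pct_equil <- if (n_reinvited > 0) round(100 * n_stable / n_reinvited)
               else NA_real_
  tibble(
    n_screened = n_screened, n_positive = n_positive,
    n_reinvited = n_reinvited,
    n_undiagnosed_at_reexam = n_undiagnosed_at_reexam,
    n_diagnosed_at_followup = n_diagnosed_at_followup,
    n_stable = n_stable, n_increase = n_increase, n_decrease = n_decrease,
    pct_nonprogressing_of_undiagnosed = pct_nonprog,
    pct_equilibrium_of_reinvited = pct_equil
  )
}

#' The published Copenhagen screening flow counts
#'
#' Convenience constructor for the printed cohort flow: 49,488 screened, 63
#' mutation-positive, 52 surviving and re-invited, 26 undiagnosed at the
#' re-examination of whom 18 were diagnosed then, leaving 8 undiagnosed
#' (5 with a modest increase, 3 with a decrease in allele burden).
#'
#' @return A named list accepted by [cohort_flow()].
#' @export
copenhagen_counts <- function() {
  list(n_screened = 49488, n_positive = 63, n_reinvited = 52,
       n_undiagnosed_at_reexam = 26, n_diagnosed_at_followup = 18,
       n_increase = 5, n_decrease = 3)
}

#' Fit the prevalence-versus-age slope
#'
#' Ordinary least squares of prevalence (percent) on the age-bin midpoint,
#' optionally neglecting the first and last bins (whose small counts and
#' cohort edge effects distort the linear trend). Decade bins use
#' arithmetic midpoints; an open-ended last bin uses its lower edge plus 5
#' years.
#'
#' @param table Prevalence table: columns `age_lo`, `age_hi` (upper edge,
#'   `NA` for an open-ended last bin), `n_screened`, `n_positive` (see
#'   [generate_prevalence_table()]).
#' @param drop_first_last Drop the first and last bins before fitting.
#' @return An object of class `ric_prevalence_fit`: list with `table`
#'   (augmented with `age_mid`, `prevalence`, `se`, `used`), `fit` (`lm`),
#'   `slope_per_year`, `slope_per_decade`, `intercept`, `r_squared`.
#' @export
fit_prevalence_slope <- function(table, drop_first_last = TRUE) {
  need <- c("age_lo", "age_hi", "n_screened", "n_positive")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    abort(paste0("prevalence table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  tb <- dplyr::arrange(tibble::as_tibble(table), .data$age_lo)
  tb$age_mid <- ifelse(is.na(tb$age_hi), tb$age_lo + 5,
                       (tb$age_lo + tb$age_hi) / 2)
  tb$prevalence <- 100 * tb$n_positive / tb$n_screened
  # binomial standard error on the percent scale
  tb$se <- 100 * sqrt(pmax(tb$prevalence / 100 * (1 - tb$prevalence / 100), 0) /
                        tb$n_screened)
  tb$used <- TRUE
  if (drop_first_last) {
    tb$used[c(1, nrow(tb))] <- FALSE
  }
  if (sum(tb$used) < 3) abort("need at least 3 bins after dropping ends")
  fit <- stats::lm(prevalence ~ age_mid, data = tb[tb$used, ])
  structure(list(table = tb, fit = fit,
                 slope_per_year = unname(stats::coef(fit)[2]),
                 slope_per_decade = 10 * unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared),
            class = "ric_prevalence_fit")
}

#' @export
print.ric_prevalence_fit <- function(x, ...) {
  cat(sprintf(
    "<ric_prevalence_fit> slope %.4g %%/year (%.4g %%/decade), R^2 = %.3f\n",
    x$slope_per_year, x$slope_per_decade, x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_prevalence_slope
#' @param x A `ric_prevalence_fit` object.
#' @param ... Unused.
#' @method tidy ric_prevalence_fit
#' @export
tidy.ric_prevalence_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_prevalence_slope
#' @method glance ric_prevalence_fit
#' @export
glance.ric_prevalence_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared,
         slope_per_year = x$slope_per_year,
         slope_per_decade = x$slope_per_decade,
         intercept = x$intercept,
         n_bins_used = sum(x$table$used))
}

#' Compare the model escape slope with the epidemiological prevalence slope
#'
#' Reports the escape-probability slope of an [escape_curve()] (percent per
#' year; requires a calibrated curve), the fitted prevalence slope, and
#' their ratio, flagging agreement within a stated factor. With an
#' uncalibrated escape curve the slope is reported in arbitrary units and
#' the ratio is suppressed.
#'
#' @param escape A `ric_escape` object.
#' @param prevalence_slope Fitted prevalence slope in percent per year (for
#'   example `fit$slope_per_year` from [fit_prevalence_slope()]).
#' @param factor Agreement factor (default 2).
#' @return A one-row tibble with `escape_slope`, `escape_units`,
#'   `prevalence_slope`, `ratio`, `within_factor`.
#' @export
compare_model_to_epidemiology <- function(escape, prevalence_slope,
                                          factor = 2) {
  stopifnot(inherits(escape, "ric_escape"))
  if (!escape$calibrated) {
    warn("escape curve not calibrated to %/year; ratio suppressed")
    return(tibble(escape_slope = escape$slope, escape_units = "a.u./year",
                  prevalence_slope = prevalence_slope, ratio = NA_real_,
                  within_factor = NA))
  }
  ratio <- if (is.finite(prevalence_slope) && prevalence_slope != 0) {
    escape$slope / prevalence_slope
  } else NA_real_
  tibble(escape_slope = escape$slope, escape_units = "%/year",
         prevalence_slope = prevalence_slope, ratio = ratio,
         within_factor = if (is.na(ratio)) NA
                         else ratio <= factor && ratio >= 1 / factor)
}

#' Read or write cohort and prevalence tables as CSV
#'
#' Plain-CSV serialization with a documented header contract. Cohort CSVs
#' carry the screened total in a `n_screened` column (constant across
#' rows); prevalence CSVs have columns `age_lo`, `age_hi`, `n_screened`,
#' `n_positive`.
#'
#' @param table Table to write.
#' @param path CSV path.
#' @return The table (invisibly for writers).
#' @export
write_cohort_csv <- function(table, path) {
  tb <- tibble::as_tibble(table)
  tb$n_screened <- attr(table, "n_screened") %||% nrow(table)
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(table)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tb <- tibble::as_tibble(utils::read.csv(path))
  n_screened <- tb$n_screened[1]
  tb$n_screened <- NULL
  attr(tb, "n_screened") <- n_screened
  tb
}
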