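# --- healing trajectories and method comparison ----------------------------

#' Weekly percentage contraction of the wound area
#'
#' `100 * (S0 - Si) / S0`: the percentage of the baseline surface area lost
#' by week i. Positive values mean shrinkage, negative values growth (as
#' seen transiently after debridement).
#'
#' @param S0 baseline area in cm^2 (> 0).
#' @param Si area at week i in cm^2 (>= 0), vectorized.
#' @return Contraction in percent.
#' @examples
#' contraction_percentage(10, 7.5)  # 25
#' @export
contraction_percentage <- function(S0, Si) {
  if (any(S0 <= 0))
    stop_planim("invalid_baseline", "baseline area S0 must be > 0")
  if (any(Si < 0))
    stop_planim("invalid_parameter", "areas must be >= 0")
  100 * (S0 - Si) / S0
}

#' Build a healing series from weekly areas
#'
#' @param areas ordered weekly areas in cm^2 (week 0 first, > 0 at week 0).
#' @param weeks optional strictly increasing integer week indices
#'   (default `0, 1, ...`).
#' @return A `healing_series` list: `week`, `areas`, `coi` (percentage
#'   contraction vs. week 0), `normalized` (`areas / S0`).
#' @examples
#' build_series(c(10, 9, 8))
#' @export
build_series <- function(areas, weeks = seq_along(areas) - 1L) {
  if (length(areas) < 2L)
    stop_planim("insufficient_series", "need at least 2 weekly areas")
  if (areas[1L] <= 0)
    stop_planim("invalid_baseline", "baseline area must be > 0")
  if (any(areas < 0))
    stop_planim("invalid_parameter", "areas must be >= 0")
  weeks <- as.integer(weeks)
  if (length(weeks) != length(areas) || any(diff(weeks) <= 0L))
    stop_planim("invalid_parameter",
                "weeks must be strictly increasing and match areas")
  structure(list(week = weeks, areas = areas,
                 coi = contraction_percentage(areas[1L], areas),
                 normalized = areas / areas[1L]),
            class = "healing_series")
}

#' @export
print.healing_series <- function(x, ...) {
  print(data.frame(week = x$week, area_cm2 = x$areas,
                   coi_pct = round(x$coi, 2), normalized = round(x$normalized, 4)),
        row.names = FALSE)
  invisible(x)
}

.coi_at <- function(series, week) {
  i <- match(week, series$week)
  if (is.na(i))
    stop_planim("insufficient_series",
                sprintf("series has no week-%d entry, required by this rule", week))
  series$coi[i]
}

#' Classify a healing trajectory against published predictor thresholds
#'
#' Four literal threshold rules from the wound-care literature:
#' \describe{
#'   \item{`weekly_10_15`}{mean per-week contraction of 10--15% predicts
#'     healing; the mean of consecutive-week contractions is compared to
#'     the 10% lower bound.}
#'   \item{`two_week_25`}{>= 25% area reduction by week 2.}
#'   \item{`two_to_four_week_20_40`}{>= 20% reduction reached in weeks
#'     2--4; if the window is incomplete and the threshold not yet met the
#'     verdict is `indeterminate`.}
#'   \item{`four_week_40`}{>= 40% reduction by week 4, else clinical
#'     reassessment is recommended.}
#' }
#' Boundaries are inclusive: reaching the lower threshold exactly counts
#' as predicted to heal.
#'
#' @param series a [build_series()] result.
#' @param rule one of the four rule names above.
#' @return A list: `verdict` (`"predicted_to_heal"`, `"reassess"` or
#'   `"indeterminate"`), `rule`, `statistic` (the compared percentage) and
#'   `rationale` text.
#' @export
classify_healing <- function(series,
                             rule = c("weekly_10_15", "two_week_25",
                                      "two_to_four_week_20_40",
                                      "four_week_40")) {
  stopifnot(inherits(series, "healing_series"))
  rule <- match.arg(rule)
  out <- switch(rule,
    weekly_10_15 = {
      a <- series$areas
      # consecutive-reading contraction, each relative to the preceding week
      prev <- a[-length(a)]
      rate <- ifelse(prev > 0, 100 * (prev - a[-1L]) / prev, 0)
      per_week <- rate / diff(series$week)
      m <- mean(per_week)
      list(verdict = if (m >= 10) "predicted_to_heal" else "reassess",
           statistic = m,
           rationale = sprintf(
             "mean weekly contraction %.1f%% %s the 10%% weekly predictor threshold",
             m, if (m >= 10) "meets" else "is below"))
    },
    two_week_25 = {
      v <- .coi_at(series, 2L)
      list(verdict = if (v >= 25) "predicted_to_heal" else "reassess",
           statistic = v,
           rationale = sprintf(
             "area reduction at week 2 is %.1f%% (threshold 25%%)", v))
    },
    two_to_four_week_20_40 = {
      wks <- intersect(2:4, series$week)
      if (!length(wks))
        stop_planim("insufficient_series",
                    "rule needs at least a week-2 entry")
      v <- max(vapply(wks, function(w) .coi_at(series, w), numeric(1L)))
      verdict <- if (v >= 20) "predicted_to_heal"
                 else if (max(series$week) < 4L) "indeterminate"
                 else "reassess"
      list(verdict = verdict, statistic = v,
           rationale = sprintf(
             "best reduction in weeks 2-4 is %.1f%% (threshold 20-40%%)%s", v,
             if (verdict == "indeterminate") "; week-4 reading not yet available"
             else ""))
    },
    four_week_40 = {
      v <- .coi_at(series, 4L)
      list(verdict = if (v >= 40) "predicted_to_heal" else "reassess",
           statistic = v,
           rationale = sprintf(
             "area reduction at week 4 is %.1f%% (threshold 40%%)", v))
    })
  c(list(rule = rule), out)
}

#' Signed percentage difference against a reference area
#'
#' `100 * (value - reference) / reference`.
#'
#' @param value measured area (cm^2).
#' @param reference reference-method area (cm^2, > 0).
#' @return Signed percentage difference.
#' @export
percent_difference <- function(value, reference) {
  if (any(reference <= 0))
    stop_planim("invalid_reference", "reference area must be > 0")
  100 * (value - reference) / reference
}

#' Mean of signed percentage errors
#'
#' Arithmetic mean with sign preserved (positive and negative errors are
#' allowed to cancel, as in method-comparison tables).
#'
#' @param errors numeric vector of signed percentage errors.
#' @return The mean, in percent.
#' @export
mean_error <- function(errors) {
  if (!length(errors))
    stop_planim("empty_input", "no errors supplied")
  mean(errors)
}

#' Pearson correlation between two methods' area vectors
#'
#' @param x,y equal-length numeric vectors (length >= 3) with non-zero
#'   variance.
#' @return Sample Pearson product-moment correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_planim("invalid_parameter",
                "x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_planim("undefined_correlation",
                "zero variance: correlation is undefined")
  stats::cor(x, y)
}

#' Compare measurement methods against a reference
#'
#' Given per-wound areas for several methods, computes the signed
#' percentage difference of each method against the reference method for
#' every wound, per-method mean errors, and pairwise Pearson correlations
#' between the methods' area vectors.
#'
#' @param measurements a data frame with columns `wound`, `method`,
#'   `area_cm2` (long format; one row per wound x method).
#' @param reference_label the method treated as the standard.
#' @return A `comparison_report` list: `reference_label`, `per_wound_errors`
#'   (wound x method matrix of signed percent differences), `mean_errors`
#'   (named per-method vector), `correlations` (method x method Pearson
#'   matrix, `NULL` when fewer than 3 complete wounds), and `table` (long
#'   data frame with a `pct_diff_vs_reference` column).
#' @export
compare_methods <- function(measurements, reference_label) {
  df <- as.data.frame(measurements)
  need <- c("wound", "method", "area_cm2")
  if (!all(need %in% names(df)))
    stop_planim("invalid_parameter",
                "measurements needs columns wound, method, area_cm2")
  if (!reference_label %in% df$method)
    stop_planim("incomplete_data",
                sprintf("no measurements for reference method '%s'",
                        reference_label))
  wide <- stats::reshape(df[need], direction = "wide", idvar = "wound",
                         timevar = "method")
  names(wide) <- sub("^area_cm2\\.", "", names(wide))
  ref <- wide[[reference_label]]
  if (anyNA(ref)) {
    missing <- wide$wound[is.na(ref)]
    stop_planim("incomplete_data",
                sprintf("wound(s) without a reference area: %s",
                        paste(missing, collapse = ", ")))
  }
  methods <- setdiff(names(wide), "wound")
  err <- sapply(methods, function(m) percent_difference(wide[[m]], ref))
  err <- matrix(err, nrow = nrow(wide), dimnames = list(wide$wound, methods))
  mean_errors <- colMeans(err, na.rm = TRUE)
  correlations <- NULL
  areas <- as.matrix(wide[methods])
  complete <- stats::complete.cases(areas)
  if (sum(complete) >= 3L) {
    ok <- apply(areas[complete, , drop = FALSE], 2L, stats::sd) > 0
    if (sum(ok) >= 2L)
      correlations <- stats::cor(areas[complete, ok, drop = FALSE])
  }
  tab <- df[need]
  tab$pct_diff_vs_reference <- err[cbind(match(tab$wound, rownames(err)),
                                         match(tab$method, colnames(err)))]
  structure(list(reference_label = reference_label,
                 per_wound_errors = err,
                 mean_errors = mean_errors,
                 correlations = correlations,
                 table = tab),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> reference: %s\n", x$reference_label))
  cat("mean signed errors (%):\n")
  print(round(x$mean_errors, 2))
  invisible(x)
}

#' Write a comparison report as CSV
#'
#' Writes the long per-wound table and returns the summary data frame
#' (method, mean_error_pct, n).
#'
#' @param report a [compare_methods()] result.
#' @param path output CSV path for the per-wound table; the summary is
#'   written next to it as `<path base>_summary.csv`.
#' @return The summary data frame, invisibly.
#' @export
write_comparison <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  utils::write.csv(report$table, path, row.names = FALSE)
  summ <- data.frame(method = names(report$mean_errors),
                     mean_error_pct = unname(report$mean_errors),
                     n = colSums(!is.na(report$per_wound_errors)))
  utils::write.csv(summ,
                   sub("(\\.[^.]+)?$", "_summary.csv",
                       sub("\\.csv$", "", path)),
                   row.names = FALSE)
  invisible(summ)
}

#' Bundled per-wound method-error dataset
#'
#' A small example dataset of signed percentage errors of four wound-area
#' measurement approaches (two planimetry programs and two bedside
#' Kundin-coefficient readings) against a planimetry reference, for eight
#' chronic wounds labelled A--H. Used in examples and to exercise the
#' method-comparison summaries.
#'
#' @return A data frame with a `wound` column and one numeric column per
#'   method.
#' @export
method_errors_example <- function() {
  path <- system.file("extdata", "method_errors.csv", package = "planimetr",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
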