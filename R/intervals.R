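#' Nonparametric reference interval
#'
#' The central 95% reference interval of a sample: median and 2.5th/97.5th
#' percentiles by the rank r = p(n+1) rule ([rank_quantile()]), computed
#' on the original measurement scale. Requires n >= 39 so that the 2.5th
#' percentile rank reaches the first order statistic; n below 120 (the
#' guideline minimum for a nonparametric reference interval) is allowed
#' with a warning.
#'
#' @param values Numeric vector of finite values.
#' @param analyte,group_label Optional identifiers carried into the result.
#' @return Object of class `reference_interval`: list with `analyte`,
#'   `group_label`, `n`, `median`, `lower`, `upper`.
#' @examples
#' nonparametric_ri(1:39)  # lower 1, median 20, upper 39
#' @export
nonparametric_ri <- function(values, analyte = NA_character_,
                             group_label = NA_character_) {
  values <- values[!is.na(values)]
  if (any(!is.finite(values))) stop("non-finite values")
  n <- length(values)
  if (n < 39L) {
    stop("n = ", n, " is below the minimum of 39 for nonparametric ",
         "2.5th/97.5th percentiles")
  }
  if (n < 120L) {
    warning("n = ", n, " is below the guideline minimum of 120 for a ",
            "nonparametric reference interval")
  }
  q <- rank_quantile(values, c(0.025, 0.5, 0.975))
  out <- list(analyte = analyte, group_label = group_label, n = n,
              median = q[2], lower = q[1], upper = q[3])
  class(out) <- "reference_interval"
  out
}

#' Format a reference interval cell
#'
#' Renders `median (lower-upper)` with the panel's display precision:
#' 2 decimals for percentages and ratios, whole numbers for counts.
#'
#' @param median,lower,upper Interval values.
#' @param kind `"percentage"`, `"ratio"` or `"count"`.
#' @return A character scalar, e.g. `"80.59 (52.26-89.74)"`.
#' @export
format_ri_cell <- function(median, lower, upper, kind = "percentage") {
  digits <- if (kind == "count") 0L else 2L
  fmt <- paste0("%.", digits, "f")
  sprintf(paste0(fmt, " (", fmt, "-", fmt, ")"), median, lower, upper)
}

#' @export
print.reference_interval <- function(x, ...) {
  cat(sprintf("Reference interval%s%s (n = %d): %s\n",
              if (!is.na(x$analyte)) paste0(" ", x$analyte) else "",
              if (!is.na(x$group_label)) paste0(" [", x$group_label, "]") else "",
              x$n, format_ri_cell(x$median, x$lower, x$upper, "percentage")))
  invisible(x)
}

#' Build the reference-interval table
#'
#' Computes one nonparametric reference interval per analyte per final
#' merged group and lays the results out with one row per analyte and one
#' column per initial age bin, merged bins repeating their shared interval
#' across member columns (the usual published convention). Cells whose
#' final group falls below the minimum sample size are marked unavailable
#' and the run continues.
#'
#' @param cohort Outlier-filtered cohort data.frame.
#' @param merge_histories Named list (by analyte) of [merge_adjacent_age_groups()]
#'   results.
#' @param scheme,panel Age scheme and analyte panel.
#' @return Object of class `ri_table`: list with `long` (data.frame:
#'   `analyte`, `group`, `members`, `n`, `median`, `lower`, `upper`),
#'   `wide` (formatted character matrix, analyte x initial bin) and `scheme`.
#' @export
build_ri_table <- function(cohort, merge_histories,
                           scheme = age_group_scheme(),
                           panel = analyte_panel()) {
  grp <- age_to_group(cohort$age_value, cohort$age_unit, scheme)
  analytes <- names(merge_histories)
  long <- NULL
  wide <- matrix(NA_character_, nrow = length(analytes),
                 ncol = nrow(scheme),
                 dimnames = list(analytes, scheme$label))
  for (a in analytes) {
    hist <- merge_histories[[a]]
    kind <- panel$kind[match(a, panel$name)]
    if (is.na(kind)) kind <- "ratio"
    for (j in seq_along(hist$final_bins)) {
      members <- hist$final_bins[[j]]
      vals <- cohort[[a]][grp %in% members]
      vals <- vals[!is.na(vals)]
      ri <- tryCatch(
        suppressWarnings(nonparametric_ri(vals, a, hist$final_labels[j])),
        error = function(e) NULL)
      if (is.null(ri)) {
        warning("analyte ", a, ", group ", hist$final_labels[j],
                ": n = ", length(vals), " too small; cell unavailable")
        wide[a, members] <- "n/a"
        long <- rbind(long, data.frame(
          analyte = a, group = hist$final_labels[j],
          members = paste(members, collapse = ";"), n = length(vals),
          median = NA_real_, lower = NA_real_, upper = NA_real_,
          stringsAsFactors = FALSE))
      } else {
        wide[a, members] <- format_ri_cell(ri$median, ri$lower, ri$upper, kind)
        long <- rbind(long, data.frame(
          analyte = a, group = hist$final_labels[j],
          members = paste(members, collapse = ";"), n = ri$n,
          median = ri$median, lower = ri$lower, upper = ri$upper,
          stringsAsFactors = FALSE))
      }
    }
  }
  out <- list(long = long, wide = wide, scheme = scheme)
  class(out) <- "ri_table"
  out
}

#' @export
print.ri_table <- function(x, ...) {
  cat("Reference intervals, median (2.5th-97.5th percentile):\n\n")
  print(as.data.frame(x$wide), right = FALSE)
  invisible(x)
}

#' Write a reference-interval table
#'
#' Writes the long-form table as CSV and the formatted analyte-by-age-bin
#' matrix as a text table.
#'
#' @param ri An `ri_table`.
#' @param csv_path,txt_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_ri_table <- function(ri, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(ri$long, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    utils::capture.output(print(ri), file = con)
  }
  invisible(c(csv_path, txt_path))
}
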