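#' Tukey fences
#'
#' Computes the Tukey outlier fences of a sample: the lower fence
#' Q1 - 1.5 IQR and upper fence Q3 + 1.5 IQR, with quartiles taken by the
#' package-wide rank r = p(n+1) rule ([rank_quantile()]). Values strictly
#' outside the fences are flagged; values exactly on a fence are kept.
#'
#' @param values Numeric vector, n >= 4.
#' @return Object of class `tukey_fences`: list with `q1`, `q3`, `iqr`,
#'   `lower`, `upper`, logical `outlier_mask` (aligned with `values`) and
#'   `n_removed`.
#' @examples
#' tukey_fences(c(1:100, 1000))$n_removed  # 1
#' @export
tukey_fences <- function(values) {
  if (length(values) < 4L) {
    stop("insufficient sample: need n >= 4, got ", length(values))
  }
  if (any(!is.finite(values))) stop("non-finite values")
  q <- rank_quantile(values, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[2] + 1.5 * iqr
  mask <- values < lower | values > upper
  out <- list(q1 = q[1], q3 = q[2], iqr = iqr, lower = lower, upper = upper,
              outlier_mask = mask, n_removed = sum(mask))
  class(out) <- "tukey_fences"
  out
}

#' @export
print.tukey_fences <- function(x, ...) {
  cat(sprintf("Tukey fences: [%.4g, %.4g] (Q1 = %.4g, Q3 = %.4g); %d outlier(s)\n",
              x$lower, x$upper, x$q1, x$q3, x$n_removed))
  invisible(x)
}

#' Tukey outlier elimination across a cohort
#'
#' Applies Tukey fences per analyte within each age-group (by default
#' age-by-sex) cell. For an analyte that fails the skewness/kurtosis
#' normality screen the fences are computed on its Box-Cox-transformed
#' values (the transform is fitted once per analyte on the full cohort);
#' the screen/transform precedes outlier elimination in the workflow, and
#' monotonicity means the flagged subjects are well defined either way.
#' Flagged values are blanked (per-analyte removal, the default) or the
#' whole subject row is dropped, and every removal is recorded in a
#' ledger.
#'
#' @param cohort Cohort data.frame (see [load_cohort()]).
#' @param panel,scheme Analyte panel and age scheme.
#' @param by_sex Compute cells as age-by-sex (default) or age only.
#' @param removal `"per_analyte"` (blank the offending value, keep the
#'   subject for other analytes) or `"whole_subject"`.
#' @param passes Number of elimination passes (default 1, the single-pass
#'   convention; set higher to iterate).
#' @return The filtered cohort, with the removal ledger (columns `analyte`,
#'   `group`, `subject_id`, `value`, `fence`, `limit` on the raw scale) in
#'   `attr(, "ledger")` and the per-analyte normality/lambda summary in
#'   `attr(, "prep")`.
#' @export
filter_cohort <- function(cohort, panel = analyte_panel(),
                          scheme = age_group_scheme(), by_sex = TRUE,
                          removal = c("per_analyte", "whole_subject"),
                          passes = 1L) {
  removal <- match.arg(removal)
  df <- as.data.frame(cohort)
  analytes <- intersect(panel$name, names(df))
  if (!length(analytes)) stop("no panel analytes in cohort")
  ledger <- data.frame(analyte = character(0), group = character(0),
                       subject_id = character(0), value = numeric(0),
                       fence = character(0), limit = numeric(0),
                       stringsAsFactors = FALSE)
  prep <- data.frame(analyte = character(0), n = integer(0),
                     is_normal = logical(0), lambda = numeric(0),
                     shift = numeric(0), stringsAsFactors = FALSE)
  age_grp <- age_to_group(df$age_value, df$age_unit, scheme)
  cell <- if (by_sex) paste(age_grp, df$sex, sep = "/") else age_grp

  for (pass in seq_len(passes)) {
    for (a in analytes) {
      v <- df[[a]]
      ok <- !is.na(v)
      if (sum(ok) < 8L) next
      nm <- assess_normality(v[ok])
      lambda <- NA_real_; shift <- 0
      analysis <- v
      if (!nm$is_normal) {
        bc <- boxcox_transform(v[ok])
        lambda <- bc$lambda; shift <- bc$shift
        analysis[ok] <- bc$transformed
      }
      if (pass == 1L) {
        prep <- rbind(prep, data.frame(analyte = a, n = sum(ok),
                                       is_normal = nm$is_normal,
                                       lambda = lambda, shift = shift,
                                       stringsAsFactors = FALSE))
      }
      for (g in unique(cell)) {
        idx <- which(cell == g & ok)
        if (length(idx) < 4L) {
          warning("group ", g, " too small for analyte ", a, "; skipped")
          next
        }
        tf <- tukey_fences(analysis[idx])
        if (!tf$n_removed) next
        flagged <- idx[tf$outlier_mask]
        side <- ifelse(analysis[flagged] < tf$lower, "lower", "upper")
        lim <- ifelse(side == "lower", tf$lower, tf$upper)
        if (!is.na(lambda)) lim <- bc_inverse(lim, lambda, shift)
        ledger <- rbind(ledger, data.frame(
          analyte = a, group = g, subject_id = df$subject_id[flagged],
          value = v[flagged], fence = side, limit = lim,
          stringsAsFactors = FALSE))
        df[flagged, a] <- NA_real_
      }
    }
  }
  if (removal == "whole_subject" && nrow(ledger)) {
    df <- df[!df$subject_id %in% unique(ledger$subject_id), , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "ledger") <- ledger
  attr(df, "prep") <- prep
  attr(df, "analytes") <- analytes
  class(df) <- c("ri_cohort", "data.frame")
  df
}
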