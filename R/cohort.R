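#' Load and validate a cohort table
#'
#' Reads a tidy per-subject table (CSV path or data.frame) with columns
#' `subject_id`, `sex` (`M`/`F`), `age_value`, `age_unit`
#' (`days`/`months`/`years`) and one column per analyte in the panel.
#' Rows violating the domain invariants (unknown sex or unit, age outside
#' 0-227 completed months, percentage outside 0-100, negative count or
#' ratio, non-numeric analyte cell) are rejected and returned as row-level
#' diagnostics rather than silently dropped. The CD4+/CD8+ ratio column is
#' derived as `cnt_CD4 / cnt_CD8` when absent but both counts are present.
#'
#' @param table A file path to a CSV or a data.frame.
#' @param panel Analyte definitions, see [analyte_panel()].
#' @param scheme Age-group scheme used for the age-range check.
#' @return A data.frame of class `ri_cohort` containing only valid rows,
#'   with the rejected rows (and a `reason` column) in
#'   `attr(, "rejected")`.
#' @export
load_cohort <- function(table, panel = analyte_panel(),
                        scheme = age_group_scheme()) {
  df <- if (is.character(table)) {
    utils::read.csv(table, stringsAsFactors = FALSE)
  } else {
    as.data.frame(table, stringsAsFactors = FALSE)
  }
  required <- c("subject_id", "sex", "age_value", "age_unit")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  analytes <- intersect(panel$name, names(df))
  if (!"ratio_CD4_CD8" %in% analytes &&
      all(c("cnt_CD4", "cnt_CD8") %in% analytes)) {
    df$ratio_CD4_CD8 <- df$cnt_CD4 / df$cnt_CD8
    analytes <- intersect(panel$name, c(analytes, "ratio_CD4_CD8"))
  }
  if (!length(analytes)) {
    stop("cohort table contains no recognised analyte columns")
  }
  if (nrow(df) == 0L) {
    warning("empty cohort table")
    out <- df[, c(required, analytes), drop = FALSE]
    attr(out, "rejected") <- cbind(df[0L, , drop = FALSE],
                                   reason = character(0))
    attr(out, "analytes") <- analytes
    class(out) <- c("ri_cohort", "data.frame")
    return(out)
  }

  reason <- rep(NA_character_, nrow(df))
  note <- function(idx, msg) {
    reason[idx & is.na(reason)] <<- msg
  }
  df$subject_id <- as.character(df$subject_id)
  note(is.na(df$subject_id) | df$subject_id == "", "missing subject_id")
  note(duplicated(df$subject_id), "duplicate subject_id")
  note(!df$sex %in% c("M", "F"), "sex must be 'M' or 'F'")
  note(!df$age_unit %in% c("days", "months", "years"), "invalid age_unit")
  av <- suppressWarnings(as.numeric(df$age_value))
  note(!is.finite(av) | av < 0, "age_value not a non-negative number")
  ok_age <- !is.na(reason)  # rows already bad; compute months only for rest
  m <- rep(NA_integer_, nrow(df))
  good <- is.na(reason)
  if (any(good)) {
    m[good] <- age_to_months(av[good], df$age_unit[good])
    out_of_range <- good & (m < min(scheme$min_months) |
                              m > max(scheme$max_months))
    note(out_of_range, "age outside the 0-227 completed-month range")
  }
  for (a in analytes) {
    v <- suppressWarnings(as.numeric(df[[a]]))
    kind <- panel$kind[match(a, panel$name)]
    if (is.na(kind)) kind <- "ratio"
    note(!is.finite(v), paste0("non-numeric value in column ", a))
    if (identical(kind, "percentage")) {
      note(is.finite(v) & (v < 0 | v > 100),
           paste0("percentage out of [0, 100] in column ", a))
    } else {
      note(is.finite(v) & v < 0, paste0("negative value in column ", a))
    }
    df[[a]] <- v
  }

  keep <- is.na(reason)
  col_order <- c(required, analytes,
                 setdiff(names(df), c(required, analytes)))
  rejected <- df[!keep, col_order, drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- reason[!keep]
    warning(nrow(rejected), " row(s) rejected during cohort validation; ",
            "see attr(, 'rejected')")
  }
  out <- df[keep, c(required, analytes), drop = FALSE]
  out$age_value <- av[keep]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  attr(out, "analytes") <- analytes
  class(out) <- c("ri_cohort", "data.frame")
  out
}

#' Write a cohort table to CSV
#'
#' Inverse of [load_cohort()]: `load_cohort(write_cohort(x, f))` is the
#' identity on the validated records.
#'
#' @param cohort A cohort data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @export
print.ri_cohort <- function(x, ...) {
  analytes <- attr(x, "analytes")
  cat("Cohort of", nrow(x), "subjects,", length(analytes), "analytes\n")
  if (nrow(x)) {
    grp <- table(age_to_group(x$age_value, x$age_unit))
    cat("  sex:", paste(names(table(x$sex)), table(x$sex),
                        sep = "=", collapse = ", "), "\n")
    cat("  age groups:", paste(names(grp), grp, sep = "=", collapse = ", "),
        "\n")
  }
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej)) {
    cat("  rejected rows:", nrow(rej), "\n")
  }
  invisible(x)
}
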