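#' Built-in lymphocyte-subset analyte panel
#'
#' The 16-analyte immunophenotyping panel the package works with by default:
#' percentages (of total lymphocytes) for the seven subsets T (CD3+),
#' helper T (CD3+CD4+), cytotoxic T (CD3+CD8+), double-negative T
#' (CD3+CD4-CD8-), B (CD3-CD19+), NK (CD3-CD56+) and NKT-like (CD3+CD56+)
#' cells; absolute counts (cells/ul, single-platform bead counting) for the
#' same seven subsets plus total lymphocytes; and the CD4+/CD8+ ratio.
#'
#' @return A data.frame with one row per analyte and columns `name`, `kind`
#'   (`"percentage"`, `"count"` or `"ratio"`), `phenotype` and `units`.
#' @examples
#' analyte_panel()
#' @export
analyte_panel <- function() {
  pct <- c(pct_T = "CD3+", pct_CD4 = "CD3+CD4+", pct_CD8 = "CD3+CD8+",
           pct_DNT = "CD3+CD4-CD8-", pct_B = "CD3-CD19+",
           pct_NK = "CD3-CD56+", pct_NKT = "CD3+CD56+")
  cnt <- c(cnt_lymph = "lymphocytes", cnt_T = "CD3+", cnt_CD4 = "CD3+CD4+",
           cnt_CD8 = "CD3+CD8+", cnt_DNT = "CD3+CD4-CD8-",
           cnt_B = "CD3-CD19+", cnt_NK = "CD3-CD56+", cnt_NKT = "CD3+CD56+")
  data.frame(
    name = c(names(pct), "ratio_CD4_CD8", names(cnt)),
    kind = c(rep("percentage", 7L), "ratio", rep("count", 8L)),
    phenotype = c(unname(pct), "CD4+/CD8+", unname(cnt)),
    units = c(rep("%", 7L), "", rep("cells/ul", 8L)),
    stringsAsFactors = FALSE
  )
}

#' Pediatric age-group scheme
#'
#' Age bins used for partitioning, expressed in completed months. The default
#' is the five developmental strata: neonatal (0-1 month), infancy
#' (2-12 months), early childhood (1-3 years), preschool (4-6 years) and
#' school age (7-18 years). Boundary semantics: a child belongs to the bin
#' whose inclusive `[min_months, max_months]` range contains their completed
#' age in months, so the bins are contiguous and exhaustive on 0-227 months.
#'
#' @param labels,min_months,max_months Optional replacement bins; the three
#'   vectors must have equal length and describe ordered, contiguous,
#'   non-overlapping bins.
#' @return A data.frame of class `age_scheme` with columns `label`,
#'   `min_months`, `max_months`.
#' @export
age_group_scheme <- function(labels = c("0-1 month", "2-12 months",
                                        "1-3 years", "4-6 years",
                                        "7-18 years"),
                             min_months = c(0L, 2L, 13L, 48L, 84L),
                             max_months = c(1L, 12L, 47L, 83L, 227L)) {
  if (length(labels) != length(min_months) ||
      length(labels) != length(max_months)) {
    stop("labels, min_months and max_months must have equal length")
  }
  scheme <- data.frame(label = as.character(labels),
                       min_months = as.integer(min_months),
                       max_months = as.integer(max_months),
                       stringsAsFactors = FALSE)
  if (any(scheme$max_months < scheme$min_months)) {
    stop("each bin needs min_months <= max_months")
  }
  if (nrow(scheme) > 1L) {
    gaps <- scheme$min_months[-1L] - scheme$max_months[-nrow(scheme)]
    if (any(gaps != 1L)) {
      stop("bins must be ordered, contiguous and non-overlapping")
    }
  }
  if (anyDuplicated(scheme$label)) stop("bin labels must be unique")
  class(scheme) <- c("age_scheme", "data.frame")
  scheme
}

#' Convert an age to completed months
#'
#' Days are converted with the mean month length (floor(days / 30.44)),
#' months are floored to completed months, years are taken as 12 months per
#' year (integer ages assumed; fractional years are floored after
#' conversion).
#'
#' @param age_value Non-negative numeric vector.
#' @param age_unit Character vector (recycled): `"days"`, `"months"` or
#'   `"years"`.
#' @return Integer vector of completed months.
#' @examples
#' age_to_months(15, "days")   # 0
#' age_to_months(5, "years")   # 60
#' @export
age_to_months <- function(age_value, age_unit) {
  if (any(!is.finite(age_value)) || any(age_value < 0)) {
    stop("age_value must be finite and non-negative")
  }
  age_unit <- rep_len(as.character(age_unit), length(age_value))
  bad <- !age_unit %in% c("days", "months", "years")
  if (any(bad)) {
    stop("invalid age_unit: ", paste(unique(age_unit[bad]), collapse = ", "))
  }
  months <- numeric(length(age_value))
  months[age_unit == "days"] <- floor(age_value[age_unit == "days"] / 30.44)
  months[age_unit == "months"] <- floor(age_value[age_unit == "months"])
  months[age_unit == "years"] <-
    floor(age_value[age_unit == "years"] * 12 + 1e-9)
  as.integer(months)
}

#' Assign subjects to age groups
#'
#' @inheritParams age_to_months
#' @param scheme An [age_group_scheme()].
#' @return Character vector of bin labels, one per input age.
#' @examples
#' age_to_group(15, "days")    # "0-1 month"
#' age_to_group(13, "months")  # "1-3 years"
#' @export
age_to_group <- function(age_value, age_unit, scheme = age_group_scheme()) {
  m <- age_to_months(age_value, age_unit)
  out <- rep(NA_character_, length(m))
  for (i in seq_len(nrow(scheme))) {
    hit <- m >= scheme$min_months[i] & m <= scheme$max_months[i]
    out[hit] <- scheme$label[i]
  }
  if (anyNA(out)) {
    stop("age outside the scheme's range [", min(scheme$min_months), ", ",
         max(scheme$max_months), "] completed months: ",
         paste(utils::head(m[is.na(out)], 5L), collapse = ", "))
  }
  out
}
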