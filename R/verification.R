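#' Verify a reference interval on an independent sample
#'
#' Counts how many of the verification samples fall strictly outside the
#' interval (values exactly on an endpoint count as inside) and applies
#' the acceptance rule. The protocol calls for 40 subjects per group; any
#' other n is allowed with a protocol-deviation note. Under the default
#' rule the interval passes when at most 5% of samples are outside
#' (so 2/40 outside, i.e. 95% within, still passes); the strict
#' fewer-than-5% reading is available via `rule`.
#'
#' @param ri A `reference_interval` (or any list with `lower`/`upper`).
#' @param samples Numeric vector of verification measurements.
#' @param rule `"le_5pct"` (pass iff outside fraction <= 5%) or
#'   `"strict_lt_5pct"` (pass iff outside fraction < 5%).
#' @return Object of class `verification_result`: list with `analyte`,
#'   `group_label`, `n`, `n_outside`, `pct_within`, `passed`, `note`.
#' @examples
#' ri <- list(lower = 0, upper = 10)
#' verify_ri(ri, c(1:9, 50, rep(5, 30)))
#' @export
verify_ri <- function(ri, samples, rule = c("le_5pct", "strict_lt_5pct")) {
  rule <- match.arg(rule)
  samples <- samples[!is.na(samples)]
  if (!length(samples)) stop("empty verification sample")
  if (any(!is.finite(samples))) stop("non-finite values")
  n <- length(samples)
  n_outside <- sum(samples < ri$lower | samples > ri$upper)
  pct_within <- 100 * (n - n_outside) / n
  outside_frac <- n_outside / n
  passed <- if (rule == "le_5pct") outside_frac <= 0.05 else outside_frac < 0.05
  out <- list(analyte = if (!is.null(ri$analyte)) ri$analyte else NA_character_,
              group_label = if (!is.null(ri$group_label)) ri$group_label else NA_character_,
              n = n, n_outside = n_outside, pct_within = pct_within,
              passed = passed,
              note = if (n != 40L) sprintf("protocol deviation: n = %d (expected 40)", n) else NA_character_)
  class(out) <- "verification_result"
  out
}

#' @export
print.verification_result <- function(x, ...) {
  cat(sprintf("Verification: %d/%d outside -> %.1f%% within -> %s\n",
              x$n_outside, x$n, x$pct_within,
              if (x$passed) "PASS" else "FAIL"))
  if (!is.na(x$note)) cat("  ", x$note, "\n")
  invisible(x)
}

#' Verification report across analytes and age groups
#'
#' Applies [verify_ri()] per analyte per initial age bin, using the study
#' reference intervals (merged bins contribute their shared interval to
#' each member column) and optionally a second, alternative interval
#' table side by side, mirroring the usual two-column published layout.
#'
#' @param ri_table An `ri_table` from [build_ri_table()].
#' @param cohorts Named list (by initial bin label) of verification
#'   cohorts; each is a data.frame with the analyte columns (typically 40
#'   subjects per group).
#' @param alt_ri Optional second `ri_table` (or its `long` data.frame with
#'   columns `analyte`, `members`, `lower`, `upper`) to verify against as
#'   well.
#' @param rule Pass rule, see [verify_ri()].
#' @return Object of class `verification_table`: data.frame with columns
#'   `analyte`, `group`, `n`, `pct_within`, `passed` (plus `pct_within_alt`,
#'   `passed_alt` when `alt_ri` is given); overall pass in
#'   `attr(, "all_passed")`.
#' @export
verification_table <- function(ri_table, cohorts, alt_ri = NULL,
                               rule = c("le_5pct", "strict_lt_5pct")) {
  rule <- match.arg(rule)
  lookup <- function(long, analyte, bin) {
    i <- which(long$analyte == analyte &
                 vapply(strsplit(long$members, ";"),
                        function(mm) bin %in% mm, logical(1)))
    if (length(i) != 1L) return(NULL)
    long[i, , drop = FALSE]
  }
  alt_long <- if (is.null(alt_ri)) NULL else if (inherits(alt_ri, "ri_table")) alt_ri$long else alt_ri
  analytes <- unique(ri_table$long$analyte)
  bins <- colnames(ri_table$wide)
  rows <- NULL
  for (a in analytes) {
    for (b in bins) {
      if (!b %in% names(cohorts)) {
        rows <- rbind(rows, data.frame(analyte = a, group = b, n = NA_integer_,
                                       pct_within = NA_real_, passed = NA,
                                       stringsAsFactors = FALSE))
        next
      }
      samp <- cohorts[[b]][[a]]
      ref <- lookup(ri_table$long, a, b)
      if (is.null(ref) || is.na(ref$lower) || is.null(samp)) {
        rows <- rbind(rows, data.frame(analyte = a, group = b, n = NA_integer_,
                                       pct_within = NA_real_, passed = NA,
                                       stringsAsFactors = FALSE))
        next
      }
      vr <- verify_ri(list(lower = ref$lower, upper = ref$upper), samp, rule)
      row <- data.frame(analyte = a, group = b, n = vr$n,
                        pct_within = vr$pct_within, passed = vr$passed,
                        stringsAsFactors = FALSE)
      if (!is.null(alt_long)) {
        aref <- lookup(alt_long, a, b)
        if (is.null(aref) || is.na(aref$lower)) {
          row$pct_within_alt <- NA_real_; row$passed_alt <- NA
        } else {
          av <- verify_ri(list(lower = aref$lower, upper = aref$upper), samp, rule)
          row$pct_within_alt <- av$pct_within; row$passed_alt <- av$passed
        }
      }
      rows <- rbind(rows, row)
    }
  }
  attr(rows, "all_passed") <- all(rows$passed[!is.na(rows$passed)])
  attr(rows, "rule") <- rule
  class(rows) <- c("verification_table", "data.frame")
  rows
}

#' @export
print.verification_table <- function(x, ...) {
  cat("Reference-interval verification (rule:", attr(x, "rule"), ")\n")
  print.data.frame(x)
  cat(if (isTRUE(attr(x, "all_passed"))) "All cells passed.\n"
      else "Some cells FAILED (or were unavailable).\n")
  invisible(x)
}
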