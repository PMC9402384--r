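#' Harris-Boyd critical value z*
#'
#' The sample-size-scaled critical value for the partitioning z-test:
#' z* = 3 sqrt(n_average / 120) = 3 sqrt((n1 + n2) / 240). Two subgroups
#' warrant separate reference intervals only when their z statistic
#' exceeds this bound (and the omnibus test is significant), so the bar
#' rises with sample size and trivial differences in large cohorts do not
#' force a split.
#'
#' @param n1,n2 Positive group sizes.
#' @return The critical value, a positive number.
#' @examples
#' z_star(120, 120)  # 3
#' @export
z_star <- function(n1, n2) {
  if (!is.finite(n1) || !is.finite(n2) || n1 < 1 || n2 < 1) {
    stop("group sizes must be >= 1")
  }
  3 * sqrt((n1 + n2) / 240)
}

#' Summary statistics of one partition group
#'
#' @param values Numeric vector (analysis scale), n >= 2.
#' @param label Group label.
#' @return List with `label`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(values, label = "") {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need n >= 2 per group")
  list(label = label, n = length(values), mean = mean(values),
       sd = stats::sd(values))
}

#' Harris-Boyd two-sample z statistic
#'
#' z = |mean1 - mean2| / sqrt(sd1^2/n1 + sd2^2/n2), computed on the
#' analysis scale (Box-Cox transformed when the analyte required it).
#'
#' @param a,b Group summaries from [group_summary()].
#' @return The non-negative z statistic.
#' @export
harris_boyd_z <- function(a, b) {
  if (a$sd == 0 && b$sd == 0) {
    stop("undefined statistic: both group standard deviations are zero")
  }
  abs(a$mean - b$mean) / sqrt(a$sd^2 / a$n + b$sd^2 / b$n)
}

#' Omnibus location test across groups
#'
#' One-way ANOVA (on the analysis scale) or the Kruskal-Wallis H test
#' (rank-based, applied to raw values) across two or more groups.
#'
#' @param values Numeric vector.
#' @param group_labels Group factor, same length as `values`.
#' @param method `"anova"` or `"kruskal_wallis"`.
#' @return The p-value.
#' @export
omnibus_test <- function(values, group_labels,
                         method = c("anova", "kruskal_wallis")) {
  method <- match.arg(method)
  keep <- !is.na(values)
  values <- values[keep]
  g <- factor(group_labels[keep])
  tab <- table(g)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  if (stats::var(values) == 0) stop("degenerate data: zero variance")
  if (method == "anova") {
    fit <- stats::aov(values ~ g)
    summary(fit)[[1]][["Pr(>F)"]][1]
  } else {
    stats::kruskal.test(values, g)$p.value
  }
}

#' Partition split/merge decision
#'
#' Two subgroups keep separate reference intervals only when the omnibus
#' p-value is below `alpha` AND the Harris-Boyd z exceeds z*; otherwise
#' they are merged.
#'
#' @param p Omnibus p-value.
#' @param z Harris-Boyd z statistic.
#' @param z_star Critical value from [z_star()].
#' @param alpha Significance level (default 0.05).
#' @return `"split"` or `"merge"`.
#' @export
decide_merge <- function(p, z, z_star, alpha = 0.05) {
  if (!is.finite(p) || p < 0 || p > 1) stop("invalid p-value")
  if (p < alpha && z > z_star) "split" else "merge"
}

# Test one pair of groups: omnibus p on the appropriate scale, HB z on the
# analysis scale, z* from the actual ns.
test_pair <- function(raw_a, raw_b, ana_a, ana_b, method, alpha) {
  p <- if (method == "kruskal_wallis") {
    omnibus_test(c(raw_a, raw_b), rep(c("a", "b"), c(length(raw_a), length(raw_b))),
                 method = "kruskal_wallis")
  } else {
    omnibus_test(c(ana_a, ana_b), rep(c("a", "b"), c(length(ana_a), length(ana_b))),
                 method = "anova")
  }
  sa <- group_summary(ana_a, "a")
  sb <- group_summary(ana_b, "b")
  z <- harris_boyd_z(sa, sb)
  zs <- z_star(sa$n, sb$n)
  list(p = p, z = z, z_star = zs,
       decision = decide_merge(p, z, zs, alpha))
}

# Shared analysis-scale preparation: Box-Cox transform iff the pooled
# values fail the normality screen.
analysis_scale <- function(values) {
  nm <- assess_normality(values)
  if (nm$is_normal) {
    list(values = values, lambda = NA_real_, is_normal = TRUE)
  } else {
    bc <- boxcox_transform(values)
    list(values = bc$transformed, lambda = bc$lambda, is_normal = FALSE)
  }
}

#' Sex partition test for one analyte
#'
#' Tests male vs female on the full cohort (before any age merging): the
#' omnibus test plus the Harris-Boyd z against z* computed from the actual
#' male/female counts.
#'
#' @param cohort Cohort data.frame.
#' @param analyte Analyte column name.
#' @param method Omnibus method, see [omnibus_test()].
#' @param alpha Significance level.
#' @return Object of class `partition_test`: list with `pair`,
#'   `p_omnibus`, `z`, `z_star`, `decision`.
#' @export
test_sex_partition <- function(cohort, analyte,
                               method = c("anova", "kruskal_wallis"),
                               alpha = 0.05) {
  method <- match.arg(method)
  v <- cohort[[analyte]]
  keep <- !is.na(v)
  v <- v[keep]; sex <- cohort$sex[keep]
  if (length(unique(sex)) < 2L) {
    warning("single-sex cohort; sex partition test skipped for ", analyte)
    return(NULL)
  }
  ana <- analysis_scale(v)$values
  res <- test_pair(v[sex == "M"], v[sex == "F"],
                   ana[sex == "M"], ana[sex == "F"], method, alpha)
  out <- list(pair = c("M", "F"), p_omnibus = res$p, z = res$z,
              z_star = res$z_star, decision = res$decision,
              analyte = analyte)
  class(out) <- "partition_test"
  out
}

#' @export
print.partition_test <- function(x, ...) {
  cat(sprintf("Partition test %s vs %s%s: p = %.3g, z = %.2f, z* = %.2f -> %s\n",
              x$pair[1], x$pair[2],
              if (!is.null(x$analyte)) paste0(" (", x$analyte, ")") else "",
              x$p_omnibus, x$z, x$z_star, toupper(x$decision)))
  invisible(x)
}

#' Merge adjacent age groups for one analyte
#'
#' Starting from the initial age bins, repeatedly tests every adjacent
#' pair of current bins (omnibus p, Harris-Boyd z on the analysis scale,
#' z* from the pair's ns); among the pairs satisfying the merge rule the
#' one with the largest p is merged first, statistics are recomputed, and
#' the procedure stops when every adjacent pair splits. Only adjacent bins
#' ever merge, and bin order is preserved, so the final partition is a set
#' of contiguous unions of the initial bins.
#'
#' @param cohort Cohort data.frame (ideally already outlier-filtered).
#' @param analyte Analyte column name.
#' @param scheme Age scheme.
#' @param method,alpha Omnibus method and significance level.
#' @return Object of class `merge_history`: list with `analyte`,
#'   `initial_bins`, `events` (data.frame of every pair test in order:
#'   `left`, `right`, `p`, `z`, `z_star`, `decision`, `merged`),
#'   `final_bins` (list of member initial-bin labels) and `final_labels`.
#' @export
merge_adjacent_age_groups <- function(cohort, analyte,
                                      scheme = age_group_scheme(),
                                      method = c("anova", "kruskal_wallis"),
                                      alpha = 0.05) {
  method <- match.arg(method)
  v <- cohort[[analyte]]
  keep <- !is.na(v)
  grp <- age_to_group(cohort$age_value[keep], cohort$age_unit[keep], scheme)
  v <- v[keep]
  present <- scheme$label[scheme$label %in% unique(grp)]
  if (length(present) < 2L) stop("need >= 2 populated age bins")
  small <- present[vapply(present, function(b) sum(grp == b) < 20L, logical(1))]
  if (length(small)) {
    warning("small sample (n < 20) in bin(s): ", paste(small, collapse = ", "))
  }
  ana <- analysis_scale(v)$values

  bins <- lapply(present, function(b) b)  # each bin: member initial labels
  events <- data.frame(left = character(0), right = character(0),
                       p = numeric(0), z = numeric(0), z_star = numeric(0),
                       decision = character(0), merged = logical(0),
                       stringsAsFactors = FALSE)
  bin_lab <- function(members) paste(members, collapse = " + ")
  repeat {
    if (length(bins) < 2L) break
    tests <- vector("list", length(bins) - 1L)
    for (i in seq_len(length(bins) - 1L)) {
      ia <- grp %in% bins[[i]]
      ib <- grp %in% bins[[i + 1L]]
      tests[[i]] <- test_pair(v[ia], v[ib], ana[ia], ana[ib], method, alpha)
    }
    ps <- vapply(tests, `[[`, numeric(1), "p")
    mergeable <- vapply(tests, function(t) t$decision == "merge", logical(1))
    pick <- if (any(mergeable)) which(mergeable)[which.max(ps[mergeable])] else NA_integer_
    for (i in seq_along(tests)) {
      events <- rbind(events, data.frame(
        left = bin_lab(bins[[i]]), right = bin_lab(bins[[i + 1L]]),
        p = tests[[i]]$p, z = tests[[i]]$z, z_star = tests[[i]]$z_star,
        decision = tests[[i]]$decision,
        merged = identical(i, as.integer(pick)),
        stringsAsFactors = FALSE))
    }
    if (is.na(pick)) break
    bins[[pick]] <- c(bins[[pick]], bins[[pick + 1L]])
    bins[[pick + 1L]] <- NULL
  }
  out <- list(analyte = analyte, initial_bins = present, events = events,
              final_bins = bins,
              final_labels = vapply(bins, bin_lab, character(1)),
              small_sample_bins = small)
  class(out) <- "merge_history"
  out
}

#' @export
print.merge_history <- function(x, ...) {
  cat("Age-group merge history for", x$analyte, "\n")
  cat("  initial:", paste(x$initial_bins, collapse = " | "), "\n")
  cat("  final:  ", paste(x$final_labels, collapse = " | "), "\n")
  cat("  ", nrow(x$events), "pair tests,",
      sum(x$events$merged), "merge(s)\n")
  invisible(x)
}
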