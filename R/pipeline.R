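#' Pipeline run configuration
#'
#' Collects every tunable choice of the establishment pipeline. The
#' defaults reenact the published workflow: ANOVA omnibus on the analysis
#' scale, a single Tukey pass on age-by-sex cells with per-analyte
#' removal, sex tested before age on the full cohort, alpha = 0.05 with
#' no multiple-testing correction, and the at-most-5%-outside
#' verification rule.
#'
#' @param omnibus `"anova"` or `"kruskal_wallis"`.
#' @param outlier_passes Number of Tukey passes (1 = single-pass).
#' @param removal `"per_analyte"` or `"whole_subject"`.
#' @param pass_rule Verification rule, see [verify_ri()].
#' @param alpha Significance level for partition decisions.
#' @param by_sex_cells Compute Tukey fences on age-by-sex cells (default)
#'   or age-only cells.
#' @param scheme,panel Age scheme and analyte panel.
#' @return Object of class `run_config`.
#' @export
run_config <- function(omnibus = c("anova", "kruskal_wallis"),
                       outlier_passes = 1L,
                       removal = c("per_analyte", "whole_subject"),
                       pass_rule = c("le_5pct", "strict_lt_5pct"),
                       alpha = 0.05, by_sex_cells = TRUE,
                       scheme = age_group_scheme(),
                       panel = analyte_panel()) {
  out <- list(omnibus = match.arg(omnibus),
              outlier_passes = as.integer(outlier_passes),
              removal = match.arg(removal),
              pass_rule = match.arg(pass_rule),
              alpha = alpha, by_sex_cells = isTRUE(by_sex_cells),
              scheme = scheme, panel = panel)
  class(out) <- "run_config"
  out
}

#' Establish reference intervals from a cohort
#'
#' Runs the full establishment workflow in order: (1) per-analyte
#' normality screen and Box-Cox transform of non-normal analytes;
#' (2) Tukey-fence outlier elimination per analyte within age(-by-sex)
#' cells; (3) sex partition test per analyte on the filtered cohort;
#' (4) adjacent age-group merging per analyte (within each sex when the
#' sex test split); (5) nonparametric median and 2.5th/97.5th percentile
#' reference intervals per final group on the original scale. The run is
#' deterministic given the cohort and configuration.
#'
#' @param cohort Cohort data.frame (see [load_cohort()] or
#'   [generate_cohort()]).
#' @param config A [run_config()].
#' @return Object of class `ri_run`: list with `prep` (normality/lambda
#'   table), `outlier_ledger`, `sex_tests`, `merge_histories`, `ri`
#'   (an `ri_table`; for sex-split analytes the long table carries a
#'   `sex` column entry per sex), `config` and `n_subjects`.
#' @export
establish_ri <- function(cohort, config = run_config()) {
  analytes <- intersect(config$panel$name, names(cohort))
  if (!length(analytes)) stop("stage cohort: no panel analytes present")

  filtered <- tryCatch(
    filter_cohort(cohort, panel = config$panel, scheme = config$scheme,
                  by_sex = config$by_sex_cells, removal = config$removal,
                  passes = config$outlier_passes),
    error = function(e) stop("stage outlier_filter: ", conditionMessage(e)))

  sex_tests <- list()
  merge_histories <- list()
  split_sex <- character(0)
  for (a in analytes) {
    st <- tryCatch(
      test_sex_partition(filtered, a, method = config$omnibus,
                         alpha = config$alpha),
      error = function(e) stop("stage partitioning (sex, ", a, "): ",
                               conditionMessage(e)))
    sex_tests[[a]] <- st
    if (!is.null(st) && st$decision == "split") split_sex <- c(split_sex, a)
  }

  long_extra <- NULL
  for (a in analytes) {
    if (a %in% split_sex) {
      for (s in c("M", "F")) {
        sub <- filtered[filtered$sex == s, , drop = FALSE]
        h <- merge_adjacent_age_groups(sub, a, scheme = config$scheme,
                                       method = config$omnibus,
                                       alpha = config$alpha)
        merge_histories[[paste(a, s, sep = ".")]] <- h
      }
    } else {
      merge_histories[[a]] <- tryCatch(
        merge_adjacent_age_groups(filtered, a, scheme = config$scheme,
                                  method = config$omnibus,
                                  alpha = config$alpha),
        error = function(e) stop("stage partitioning (age, ", a, "): ",
                                 conditionMessage(e)))
    }
  }

  combined <- merge_histories[setdiff(names(merge_histories),
                                      paste(rep(split_sex, each = 2),
                                            c("M", "F"), sep = "."))]
  ri <- tryCatch(
    build_ri_table(filtered, combined, scheme = config$scheme,
                   panel = config$panel),
    error = function(e) stop("stage interval_estimation: ",
                             conditionMessage(e)))
  if (length(split_sex)) {
    for (a in split_sex) {
      for (s in c("M", "F")) {
        sub <- filtered[filtered$sex == s, , drop = FALSE]
        hx <- merge_histories[[paste(a, s, sep = ".")]]
        tab <- build_ri_table(sub, stats::setNames(list(hx), a),
                              scheme = config$scheme, panel = config$panel)
        tab$long$sex <- s
        long_extra <- rbind(long_extra, tab$long)
      }
    }
    ri$sex_split_long <- long_extra
  }

  out <- list(prep = attr(filtered, "prep"),
              outlier_ledger = attr(filtered, "ledger"),
              sex_tests = sex_tests,
              sex_split_analytes = split_sex,
              merge_histories = merge_histories,
              ri = ri,
              config = config,
              n_subjects = nrow(cohort))
  class(out) <- "ri_run"
  out
}

#' @export
print.ri_run <- function(x, ...) {
  cat("Reference-interval establishment run\n")
  cat("  subjects:", x$n_subjects, "; analytes:", nrow(x$prep), "\n")
  cat("  non-normal analytes (Box-Cox applied):",
      sum(!x$prep$is_normal), "of", nrow(x$prep), "\n")
  cat("  outlier removals:", nrow(x$outlier_ledger), "\n")
  cat("  sex split for:",
      if (length(x$sex_split_analytes)) paste(x$sex_split_analytes, collapse = ", ")
      else "none (sexes merged for every analyte)", "\n\n")
  print(x$ri)
  invisible(x)
}

#' Verify a run's reference intervals on fresh cohorts
#'
#' Thin wrapper pairing [establish_ri()] output with [verification_table()].
#'
#' @param run An `ri_run` (or an `ri_table`).
#' @param cohorts Named list of per-age-group verification cohorts.
#' @param alt_ri Optional alternative interval table.
#' @param config Run configuration (supplies the pass rule).
#' @return A `verification_table`.
#' @export
verify_run <- function(run, cohorts, alt_ri = NULL, config = run_config()) {
  ri <- if (inherits(run, "ri_run")) run$ri else run
  verification_table(ri, cohorts, alt_ri = alt_ri, rule = config$pass_rule)
}

#' Write the artifacts of a run to a directory
#'
#' Writes the reference intervals (CSV + formatted text), the outlier
#' removal ledger (CSV), the per-analyte preparation summary (CSV), the
#' sex decisions and age merge histories (JSON), and a plain-text run log.
#'
#' @param run An `ri_run`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_run_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ri_csv = file.path(dir, "reference_intervals.csv"),
             ri_txt = file.path(dir, "reference_intervals.txt"),
             ledger = file.path(dir, "outlier_ledger.csv"),
             prep = file.path(dir, "distribution_prep.csv"),
             merges = file.path(dir, "merge_history.json"),
             log = file.path(dir, "run_log.txt"))
  write_ri_table(run$ri, paths[["ri_csv"]], paths[["ri_txt"]])
  utils::write.csv(run$outlier_ledger, paths[["ledger"]], row.names = FALSE)
  utils::write.csv(run$prep, paths[["prep"]], row.names = FALSE)
  merges <- list(
    sex = lapply(run$sex_tests, function(s) if (is.null(s)) NULL else
      list(pair = s$pair, p = s$p_omnibus, z = s$z, z_star = s$z_star,
           decision = s$decision)),
    age = lapply(run$merge_histories, function(h)
      list(analyte = h$analyte, initial = h$initial_bins,
           final = h$final_labels, events = h$events)))
  jsonlite::write_json(merges, paths[["merges"]], auto_unbox = TRUE,
                       digits = NA)
  con <- file(paths[["log"]], "w")
  utils::capture.output(print(run), file = con)
  close(con)
  invisible(paths)
}
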