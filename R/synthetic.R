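#' Fit a split-lognormal to a median and two percentiles
#'
#' The two-piece (split) lognormal is the minimal strictly positive,
#' right-skew-capable family that reproduces a printed
#' median (2.5th-97.5th) triplet exactly: on the log scale the
#' distribution is a half-normal below the median with spread
#' `sigma_low` and a half-normal above it with spread `sigma_high`, each
#' side drawn with probability 1/2. Given the triplet,
#' mu = ln(median), sigma_low = (ln median - ln p2.5)/z(0.975) and
#' sigma_high = (ln p97.5 - ln median)/z(0.975).
#'
#' @param median,p_low,p_high The triplet, 0 < p_low < median < p_high.
#' @return Object of class `split_lognormal`: list with `mu`, `sigma_low`,
#'   `sigma_high`.
#' @examples
#' fit_split_lognormal(100, 25, 400)  # symmetric on the log scale
#' @export
fit_split_lognormal <- function(median, p_low, p_high) {
  if (!(is.finite(median) && is.finite(p_low) && is.finite(p_high)) ||
      !(0 < p_low && p_low < median && median < p_high)) {
    stop("need 0 < p_low < median < p_high")
  }
  z <- stats::qnorm(0.975)
  out <- list(mu = log(median),
              sigma_low = (log(median) - log(p_low)) / z,
              sigma_high = (log(p_high) - log(median)) / z)
  class(out) <- "split_lognormal"
  out
}

#' Split-lognormal random draws
#'
#' @param n Number of draws.
#' @param params A `split_lognormal` from [fit_split_lognormal()].
#' @return Strictly positive numeric vector of length `n`.
#' @export
rsplit_lognormal <- function(n, params) {
  lower <- stats::runif(n) < 0.5
  z <- abs(stats::rnorm(n))
  exp(params$mu + ifelse(lower, -z * params$sigma_low, z * params$sigma_high))
}

#' Split-lognormal quantile function
#'
#' @param p Probabilities.
#' @param params A `split_lognormal`.
#' @return Quantiles; by construction `q(0.025)`, `q(0.5)` and `q(0.975)`
#'   reproduce the fitted triplet exactly.
#' @export
qsplit_lognormal <- function(p, params) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  ifelse(p < 0.5,
         exp(params$mu - params$sigma_low * stats::qnorm(1 - p)),
         exp(params$mu + params$sigma_high * stats::qnorm(p)))
}

#' Split-lognormal distribution function
#'
#' @param q Quantiles.
#' @param params A `split_lognormal`.
#' @return `P(X <= q)`.
#' @export
psplit_lognormal <- function(q, params) {
  out <- numeric(length(q))
  below <- q <= 0
  lowside <- !below & q < exp(params$mu)
  out[below] <- 0
  out[lowside] <- 1 - stats::pnorm((params$mu - log(q[lowside])) / params$sigma_low)
  hi <- !below & !lowside
  out[hi] <- stats::pnorm((log(q[hi]) - params$mu) / params$sigma_high)
  out
}

#' @export
print.split_lognormal <- function(x, ...) {
  cat(sprintf("Split lognormal: median = %.4g, sigma_low = %.4f, sigma_high = %.4f\n",
              exp(x$mu), x$sigma_low, x$sigma_high))
  invisible(x)
}

#' Packaged per-analyte, per-age-group distribution parameters
#'
#' Loads the packaged parameter table transcribing the published pediatric
#' lymphocyte-subset median (2.5th-97.5th percentile) triplets for all 16
#' panel analytes in each of the five age groups (age groups the source
#' merged repeat their shared triplet). These triplets drive the synthetic
#' cohort generator.
#'
#' @return Data.frame with columns `analyte`, `group`, `median`, `p2.5`,
#'   `p97.5` (80 rows).
#' @export
table1_parameters <- function() {
  path <- system.file("extdata", "table1_reference_params.csv",
                      package = "lymphri", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Synthetic cohort specification
#'
#' Bundles everything [generate_cohort()] needs: the age scheme, the
#' per-bin group sizes, the male:female ratio, the per-analyte per-bin
#' split-lognormal triplets, and optional gross-outlier contamination
#' (each value independently multiplied by `outlier_scale` with
#' probability `outlier_rate`). Defaults reproduce the study conditions:
#' group sizes 187/154/197/155/120 (total 813) and a 476:337
#' male:female ratio, with no sex effect on any analyte.
#'
#' @param params Triplet table as from [table1_parameters()].
#' @param sizes Per-bin subject counts (same order as `scheme`).
#' @param sex_ratio Named vector `c(male =, female =)` proportions/counts.
#' @param outlier_rate,outlier_scale Contamination rate in \[0, 1\] and
#'   multiplicative scale (> 1).
#' @param scheme Age scheme.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(params = table1_parameters(),
                        sizes = c(187L, 154L, 197L, 155L, 120L),
                        sex_ratio = c(male = 476, female = 337),
                        outlier_rate = 0, outlier_scale = 10,
                        scheme = age_group_scheme()) {
  if (length(sizes) != nrow(scheme)) {
    stop("sizes must have one entry per age bin")
  }
  if (any(sizes < 0)) stop("group sizes must be >= 0")
  if (outlier_rate < 0 || outlier_rate > 1) stop("outlier_rate in [0, 1]")
  if (outlier_scale <= 1) stop("outlier_scale must exceed 1")
  analytes <- unique(params$analyte)
  for (a in analytes) {
    have <- params$group[params$analyte == a]
    gap <- setdiff(scheme$label, have)
    if (length(gap)) {
      stop("analyte ", a, " lacks parameters for bin(s): ",
           paste(gap, collapse = ", "))
    }
  }
  out <- list(params = params, sizes = as.integer(sizes),
              sex_ratio = sex_ratio / sum(sex_ratio),
              outlier_rate = outlier_rate, outlier_scale = outlier_scale,
              scheme = scheme, analytes = analytes)
  class(out) <- "cohort_spec"
  out
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", sum(x$sizes), "subjects in",
      length(x$sizes), "age bins;", length(x$analytes), "analytes;",
      sprintf("outlier rate %.3g\n", x$outlier_rate))
  invisible(x)
}

# Deterministic per-(analyte, bin) substream seed so adding an analyte or
# reordering the panel does not perturb the draws of the others.
stream_seed <- function(root, analyte, bin, salt = 0L) {
  codes <- utf8ToInt(paste(analyte, bin, sep = "\r"))
  h <- (root %% 2147483647)
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer((h + salt) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [cohort_spec()]: ages uniform over the completed
#' months of each bin, sex assigned at the specified ratio, each analyte
#' value drawn independently from its bin's split-lognormal (from its own
#' deterministic substream of `seed`), and, when contamination is
#' requested, a recorded fraction of values multiplied by the outlier
#' scale. The same seed always yields the identical table.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer root seed.
#' @return A cohort data.frame (class `ri_cohort`) in the standard schema
#'   (`subject_id`, `sex`, `age_value`, `age_unit`, analyte columns), with
#'   the contamination record (columns `subject_id`, `analyte`, `clean`,
#'   `injected`) in `attr(, "injections")`.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  total <- sum(spec$sizes)
  scheme <- spec$scheme
  analytes <- spec$analytes
  if (total == 0L) {
    df <- data.frame(subject_id = character(0), sex = character(0),
                     age_value = numeric(0), age_unit = character(0),
                     stringsAsFactors = FALSE)
    for (a in analytes) df[[a]] <- numeric(0)
    attr(df, "injections") <- data.frame(subject_id = character(0),
                                         analyte = character(0),
                                         clean = numeric(0),
                                         injected = numeric(0))
    attr(df, "analytes") <- analytes
    class(df) <- c("ri_cohort", "data.frame")
    return(df)
  }
  set.seed(stream_seed(seed, "demography", "root"))
  bin_of <- rep(seq_len(nrow(scheme)), spec$sizes)
  ages <- integer(total)
  sex <- character(total)
  p_male <- spec$sex_ratio[["male"]]
  for (i in seq_len(nrow(scheme))) {
    idx <- which(bin_of == i)
    ages[idx] <- sample(scheme$min_months[i]:scheme$max_months[i],
                        length(idx), replace = TRUE)
    n_male <- round(length(idx) * p_male)
    sex[idx] <- sample(rep(c("M", "F"), c(n_male, length(idx) - n_male)))
  }
  df <- data.frame(subject_id = sprintf("S%04d", seq_len(total)),
                   sex = sex, age_value = as.numeric(ages),
                   age_unit = "months", stringsAsFactors = FALSE)
  injections <- NULL
  for (a in analytes) {
    col <- numeric(total)
    for (i in seq_len(nrow(scheme))) {
      idx <- which(bin_of == i)
      if (!length(idx)) next
      row <- spec$params[spec$params$analyte == a &
                           spec$params$group == scheme$label[i], ]
      pars <- fit_split_lognormal(row$median, row$`p2.5`, row$`p97.5`)
      set.seed(stream_seed(seed, a, scheme$label[i]))
      vals <- rsplit_lognormal(length(idx), pars)
      if (spec$outlier_rate > 0) {
        hit <- stats::runif(length(idx)) < spec$outlier_rate
        if (any(hit)) {
          injections <- rbind(injections, data.frame(
            subject_id = df$subject_id[idx[hit]], analyte = a,
            clean = vals[hit], injected = vals[hit] * spec$outlier_scale,
            stringsAsFactors = FALSE))
          vals[hit] <- vals[hit] * spec$outlier_scale
        }
      }
      col[idx] <- vals
    }
    df[[a]] <- col
  }
  if (is.null(injections)) {
    injections <- data.frame(subject_id = character(0),
                             analyte = character(0), clean = numeric(0),
                             injected = numeric(0))
  }
  attr(df, "injections") <- injections
  attr(df, "analytes") <- analytes
  class(df) <- c("ri_cohort", "data.frame")
  df
}
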