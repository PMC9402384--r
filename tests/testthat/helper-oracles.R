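# Independent brute-force oracle for the rank r = p(n+1) quantile rule:
# scalar, loop-free of the package's vectorised code path.
brute_quantile <- function(x, p) {
  n <- length(x)
  sx <- sort(x)
  r <- p * (n + 1)
  if (r < 1) r <- 1
  if (r > n) r <- n
  k <- as.integer(floor(r))
  if (k == r) return(sx[k])
  frac <- r - k
  (1 - frac) * sx[k] + frac * sx[k + 1]
}

# Brute-force Tukey fences built on the brute oracle.
brute_fences <- function(x) {
  q1 <- brute_quantile(x, 0.25)
  q3 <- brute_quantile(x, 0.75)
  iqr <- q3 - q1
  list(lower = q1 - 1.5 * iqr, upper = q3 + 1.5 * iqr,
       mask = x < q1 - 1.5 * iqr | x > q3 + 1.5 * iqr)
}

# Exact quantiles of a size-weighted mixture of split-lognormals:
# the generating distribution of a merged age group.
mixture_quantile <- function(param_rows, weights, p) {
  prs <- lapply(seq_len(nrow(param_rows)), function(i)
    fit_split_lognormal(param_rows$median[i], param_rows$`p2.5`[i],
                        param_rows$`p97.5`[i]))
  w <- weights / sum(weights)
  cdf <- function(x) sum(w * vapply(prs, function(pp)
    psplit_lognormal(x, pp), numeric(1)))
  lo <- min(vapply(prs, function(pp) qsplit_lognormal(1e-7, pp), numeric(1)))
  hi <- max(vapply(prs, function(pp) qsplit_lognormal(1 - 1e-7, pp),
                   numeric(1)))
  vapply(p, function(pi)
    stats::uniroot(function(x) cdf(x) - pi, c(lo, hi), tol = 1e-9)$root,
    numeric(1))
}

# Small well-formed cohort table for loader tests.
toy_cohort_table <- function(n = 6) {
  data.frame(
    subject_id = sprintf("C%02d", seq_len(n)),
    sex = rep(c("M", "F"), length.out = n),
    age_value = 1 + seq_len(n),
    age_unit = rep("years", n),
    pct_T = seq(60, 70, length.out = n),
    cnt_CD4 = seq(900, 1400, length.out = n),
    cnt_CD8 = seq(500, 700, length.out = n),
    stringsAsFactors = FALSE
  )
}

# Cohort with one analyte drawn from an arbitrary per-bin sampler; used by
# partitioning tests. `samplers` is a list of functions keyed by bin label.
one_analyte_cohort <- function(samplers, sizes, scheme = age_group_scheme()) {
  bins <- rep(seq_len(nrow(scheme)), sizes)
  ages <- unlist(lapply(seq_len(nrow(scheme)), function(i)
    sample(scheme$min_months[i]:scheme$max_months[i], sizes[i],
           replace = TRUE)))
  n <- length(ages)
  df <- data.frame(
    subject_id = sprintf("P%05d", seq_len(n)),
    sex = sample(rep(c("M", "F"), length.out = n)),
    age_value = as.numeric(ages), age_unit = "months",
    stringsAsFactors = FALSE)
  df$y <- unlist(lapply(seq_len(nrow(scheme)), function(i)
    samplers[[scheme$label[i]]](sizes[i])))
  df
}
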