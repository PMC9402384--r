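test_that("Tukey fences match hand-computed cases", {
  tf <- tukey_fences(rep(5, 5))
  expect_equal(tf$iqr, 0)
  expect_equal(c(tf$lower, tf$upper), c(5, 5))
  expect_equal(tf$n_removed, 0L)

  tf2 <- tukey_fences(c(1:100, 1000))
  expect_equal(which(tf2$outlier_mask), 101L)   # only the gross value
  expect_equal(tf2$q1, 25.5)                     # rank 0.25 * 102
  expect_equal(tf2$q3, 76.5)

  # boundary values are kept (strict exceedance): zero-IQR data put the
  # fences exactly on the modal value, which must not be flagged
  x <- c(2, 2, 2, 2, 2, 2, 2, 7)
  tf3 <- tukey_fences(x)
  expect_equal(c(tf3$lower, tf3$upper), c(2, 2))
  expect_equal(tf3$outlier_mask, x != 2)

  expect_error(tukey_fences(1:3), "n >= 4")
})

test_that("fences equal an independent brute-force oracle on random vectors", {
  set.seed(77)
  for (i in 1:250) {
    n <- sample(4:60, 1)
    x <- switch(sample(3, 1),
                rnorm(n), rlnorm(n), sample(1:20, n, replace = TRUE))
    tf <- tukey_fences(x)
    or <- brute_fences(x)
    expect_equal(tf$lower, or$lower, tolerance = 1e-12)
    expect_equal(tf$upper, or$upper, tolerance = 1e-12)
    expect_equal(tf$outlier_mask, or$mask)
  }
})

test_that("fences are translation- and scale-equivariant and keep the median", {
  set.seed(5)
  for (i in 1:50) {
    x <- rlnorm(sample(10:80, 1))
    a <- runif(1, 0.5, 4); b <- runif(1, -10, 10)
    t1 <- tukey_fences(x)
    t2 <- tukey_fences(a * x + b)
    expect_equal(t2$lower, a * t1$lower + b, tolerance = 1e-10)
    expect_equal(t2$upper, a * t1$upper + b, tolerance = 1e-10)
    # the group median is never flagged
    med <- rank_quantile(x, 0.5)
    expect_true(med >= t1$lower && med <= t1$upper)
  }
})

test_that("cohort filtering flags injected gross outliers and little else", {
  spec_clean <- cohort_spec(outlier_rate = 0)
  clean <- generate_cohort(spec_clean, seed = 4)
  f_clean <- filter_cohort(clean)
  led_clean <- attr(f_clean, "ledger")
  # clean heavy-tailed data: small removal fraction per analyte (<= 5%)
  frac <- table(factor(led_clean$analyte, levels = analyte_panel()$name)) /
    nrow(clean)
  expect_true(all(frac <= 0.05))

  spec_dirty <- cohort_spec(outlier_rate = 0.05, outlier_scale = 10)
  dirty <- generate_cohort(spec_dirty, seed = 4)
  inj <- attr(dirty, "injections")
  expect_gt(nrow(inj), 0)
  recovery <- function(filtered) {
    led <- attr(filtered, "ledger")
    mean(paste(inj$subject_id, inj$analyte) %in%
           paste(led$subject_id, led$analyte))
  }
  # a single pass detects most injections but 5% contamination drags the
  # Box-Cox fit toward the injected tail; iterating restores sensitivity
  expect_gte(recovery(filter_cohort(dirty)), 0.65)
  expect_gte(recovery(filter_cohort(dirty, passes = 2)), 0.8)
  expect_gt(nrow(attr(filter_cohort(dirty), "ledger")), nrow(led_clean))
})

test_that("a tight-support cohort yields an empty removal ledger", {
  set.seed(3)
  n <- 400
  coh <- data.frame(subject_id = sprintf("T%03d", 1:n),
                    sex = rep(c("M", "F"), n / 2),
                    age_value = sample(24:227, n, replace = TRUE),
                    age_unit = "months",
                    pct_T = runif(n, 60, 70),
                    stringsAsFactors = FALSE)
  f <- filter_cohort(coh)
  expect_equal(nrow(attr(f, "ledger")), 0L)
  expect_equal(f$pct_T, coh$pct_T)   # idempotent on clean data
})

test_that("single pass is the default; iteration removes at most more", {
  spec <- cohort_spec(outlier_rate = 0.02)
  coh <- generate_cohort(spec, seed = 9)
  f1 <- filter_cohort(coh, passes = 1)
  f2 <- filter_cohort(coh, passes = 2)
  expect_gte(nrow(attr(f2, "ledger")), nrow(attr(f1, "ledger")))
})

test_that("whole-subject removal drops the entire record", {
  spec <- cohort_spec(outlier_rate = 0.02)
  coh <- generate_cohort(spec, seed = 12)
  f <- filter_cohort(coh, removal = "whole_subject")
  led <- attr(f, "ledger")
  expect_false(any(led$subject_id %in% f$subject_id))
  expect_lt(nrow(f), nrow(coh))
})
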