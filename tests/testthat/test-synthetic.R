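test_that("split-lognormal fitting matches the closed form", {
  f <- fit_split_lognormal(100, 25, 400)
  expect_equal(f$sigma_low, f$sigma_high, tolerance = 1e-12)
  expect_equal(f$sigma_low, log(4) / qnorm(0.975), tolerance = 1e-12)
  expect_equal(f$sigma_low, 0.7073, tolerance = 1e-4)

  g <- fit_split_lognormal(80.59, 52.26, 89.74)
  expect_equal(g$sigma_low, 0.2211, tolerance = 1e-3)
  expect_equal(g$sigma_high, 0.0549, tolerance = 1e-3)

  expect_error(fit_split_lognormal(10, 12, 20), "p_low < median")
  expect_error(fit_split_lognormal(10, 2, 8), "median < p_high")
})

test_that("quantile/distribution functions invert each other and the fit", {
  pars <- fit_split_lognormal(62, 23, 170)
  expect_equal(qsplit_lognormal(c(0.025, 0.5, 0.975), pars),
               c(23, 62, 170), tolerance = 1e-10)
  p <- c(0.01, 0.2, 0.5, 0.8, 0.99)
  expect_equal(psplit_lognormal(qsplit_lognormal(p, pars), pars), p,
               tolerance = 1e-10)
})

test_that("draws reproduce the fitted triplet and the 95% band", {
  pars <- fit_split_lognormal(62, 23, 170)
  set.seed(61)
  x <- rsplit_lognormal(1e5, pars)
  expect_true(all(x > 0))
  q <- rank_quantile(x, c(0.025, 0.5, 0.975))
  expect_equal(q / c(23, 62, 170), c(1, 1, 1), tolerance = 0.02)
  inside <- mean(x >= 23 & x <= 170)
  expect_equal(100 * inside, 95, tolerance = 1 / 95)   # 95% +/- 1
})

test_that("the packaged parameter table is complete and matches the source", {
  params <- table1_parameters()
  scheme <- age_group_scheme()
  expect_equal(nrow(params), 16L * 5L)
  expect_setequal(unique(params$analyte), analyte_panel()$name)
  for (a in unique(params$analyte)) {
    expect_setequal(params$group[params$analyte == a], scheme$label)
  }
  expect_true(all(params$`p2.5` < params$median &
                    params$median < params$`p97.5`))
  pick <- function(a, g, col)
    params[params$analyte == a & params$group == g, col]
  expect_equal(pick("pct_CD4", "0-1 month", "median"), 56.06)
  expect_equal(pick("pct_CD4", "0-1 month", "p2.5"), 28.37)
  expect_equal(pick("pct_CD4", "0-1 month", "p97.5"), 66.26)
  expect_equal(unlist(pick("cnt_NKT", "7-18 years",
                           c("median", "p2.5", "p97.5")), use.names = FALSE),
               c(35, 9, 119))
})

test_that("cohort generation is deterministic and obeys the spec sizes", {
  spec <- cohort_spec()
  expect_equal(sum(spec$sizes), 813L)
  a <- generate_cohort(spec, seed = 7)
  b <- generate_cohort(spec, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 813L)
  grp <- table(age_to_group(a$age_value, a$age_unit))
  expect_equal(as.integer(grp[age_group_scheme()$label]),
               c(187L, 154L, 197L, 155L, 120L))
  # sex ratio close to 476:337
  expect_lt(abs(sum(a$sex == "M") - 476), 4)

  empty <- generate_cohort(cohort_spec(sizes = rep(0L, 5)), seed = 1)
  expect_equal(nrow(empty), 0L)

  bad_params <- table1_parameters()
  bad_params <- bad_params[!(bad_params$analyte == "pct_T" &
                               bad_params$group == "1-3 years"), ]
  expect_error(cohort_spec(params = bad_params), "lacks parameters")
})

test_that("per-analyte substreams are independent of panel composition", {
  spec <- cohort_spec()
  full <- generate_cohort(spec, seed = 9)
  sub <- spec
  sub$params <- spec$params[spec$params$analyte != "pct_NKT", ]
  sub$analytes <- setdiff(spec$analytes, "pct_NKT")
  reduced <- generate_cohort(sub, seed = 9)
  for (a in sub$analytes) expect_identical(reduced[[a]], full[[a]])
})

test_that("empirical group medians track the generating medians", {
  spec <- cohort_spec()
  coh <- generate_cohort(spec, seed = 1)
  grp <- age_to_group(coh$age_value, coh$age_unit)
  params <- table1_parameters()
  sizes <- setNames(spec$sizes, age_group_scheme()$label)
  rel <- numeric(0)
  for (k in seq_len(nrow(params))) {
    a <- params$analyte[k]; g <- params$group[k]
    est <- rank_quantile(coh[[a]][grp == g], 0.5)
    m <- params$median[k]
    pars <- fit_split_lognormal(m, params$`p2.5`[k], params$`p97.5`[k])
    # asymptotic relative SE of the sample median of a split lognormal
    dens_m <- dnorm(0) * (1 / pars$sigma_low + 1 / pars$sigma_high) / 2
    se_rel <- 1 / (2 * sqrt(sizes[[g]]) * dens_m)
    err <- abs(est - m) / m
    rel <- c(rel, err)
    expect_lt(err, max(0.05, 4 * se_rel))
  }
  expect_lt(median(rel), 0.05)
})

test_that("the generated DNT percentage preserves its age trend", {
  spec <- cohort_spec()
  scheme <- age_group_scheme()
  set.seed(71)
  ok <- vapply(1:20, function(i) {
    coh <- generate_cohort(spec, seed = 400 + i)
    grp <- age_to_group(coh$age_value, coh$age_unit)
    meds <- vapply(scheme$label, function(g)
      rank_quantile(coh$pct_DNT[grp == g], 0.5), numeric(1))
    all(diff(meds) >= 0) || all(diff(meds[1:4]) > 0)  # bins 4 and 5 share params
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("contamination is recorded exactly where it was applied", {
  spec <- cohort_spec(outlier_rate = 0.05, outlier_scale = 10)
  coh <- generate_cohort(spec, seed = 13)
  inj <- attr(coh, "injections")
  expect_gt(nrow(inj), 0)
  for (k in sample(nrow(inj), min(25, nrow(inj)))) {
    expect_equal(coh[[inj$analyte[k]]][coh$subject_id == inj$subject_id[k]],
                 inj$injected[k])
    expect_equal(inj$injected[k], 10 * inj$clean[k])
  }
  # overall injected fraction near the nominal rate
  expect_lt(abs(nrow(inj) / (813 * 16) - 0.05), 0.01)
})
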