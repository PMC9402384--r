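test_that("z* formula reproduces the published values", {
  expect_equal(round(3 * sqrt(938 / 240), 1), 5.9)     # combined enrolment
  expect_equal(z_star(476, 462), 3 * sqrt(938 / 240))
  expect_equal(z_star(120, 120), 3)
  expect_equal(z_star(476, 337), 5.52, tolerance = 0.005)
  expect_error(z_star(0, 10), ">= 1")
})

test_that("z* grows with combined n and matches its equal-n form", {
  ns <- seq(40, 2000, by = 40)
  zs <- vapply(ns, function(n) z_star(n, 500), numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_equal(z_star(300, 300), 3 * sqrt(300 / 120))
})

test_that("Harris-Boyd z matches hand calculation and is symmetric", {
  a <- list(label = "a", n = 64, mean = 10, sd = 4)
  b <- list(label = "b", n = 64, mean = 12, sd = 4)
  expect_equal(harris_boyd_z(a, a), 0)
  expect_equal(harris_boyd_z(a, b), 2 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(harris_boyd_z(a, b), harris_boyd_z(b, a))
  z0 <- list(label = "z", n = 10, mean = 1, sd = 0)
  expect_error(harris_boyd_z(z0, z0), "undefined")
})

test_that("under the null the z statistic stays below z*", {
  set.seed(88)
  hits <- vapply(1:500, function(i) {
    x <- rnorm(406); y <- rnorm(407)
    harris_boyd_z(group_summary(x), group_summary(y)) < z_star(406, 407)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("omnibus test holds its type-I error and has power", {
  set.seed(21)
  rej <- vapply(1:1000, function(i) {
    v <- rnorm(120)
    g <- rep(letters[1:4], each = 30)
    omnibus_test(v, g) < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)

  set.seed(22)
  v <- c(rnorm(100), rnorm(100, 3))
  g <- rep(c("a", "b"), each = 100)
  expect_lt(omnibus_test(v, g), 0.001)
  expect_lt(omnibus_test(v, g, method = "kruskal_wallis"), 0.001)

  expect_error(omnibus_test(rep(1, 20), rep(c("a", "b"), 10)), "zero variance")
  expect_error(omnibus_test(rnorm(3), c("a", "a", "b")), ">= 2 groups")
})

test_that("merge decision applies the two-condition rule symmetrically", {
  expect_equal(decide_merge(0.40, 7.0, 5.9), "merge")   # p alone suffices
  expect_equal(decide_merge(0.01, 6.5, 5.9), "split")
  expect_equal(decide_merge(0.01, 4.0, 5.9), "merge")   # z under z*
  expect_error(decide_merge(1.2, 1, 1), "invalid p")
  # invariant to relabeling: z and p are label-symmetric by construction
  a <- list(label = "x", n = 50, mean = 4, sd = 1)
  b <- list(label = "y", n = 70, mean = 5, sd = 2)
  expect_equal(decide_merge(0.01, harris_boyd_z(a, b), z_star(50, 70)),
               decide_merge(0.01, harris_boyd_z(b, a), z_star(70, 50)))
})

test_that("age merging collapses null bins and isolates a shifted bin", {
  scheme <- age_group_scheme()
  sizes <- c(187, 154, 197, 155, 120)
  null_sampler <- function(n) rnorm(n, 50, 5)

  set.seed(31)
  full_merges <- vapply(1:20, function(i) {
    samplers <- setNames(rep(list(null_sampler), 5), scheme$label)
    coh <- one_analyte_cohort(samplers, sizes)
    h <- merge_adjacent_age_groups(coh, "y")
    length(h$final_bins)
  }, numeric(1))
  expect_gte(mean(full_merges == 1), 0.9)

  set.seed(32)
  for (i in 1:5) {
    samplers <- setNames(c(list(function(n) rnorm(n, 75, 5)),
                           rep(list(null_sampler), 4)), scheme$label)
    coh <- one_analyte_cohort(samplers, sizes)
    h <- merge_adjacent_age_groups(coh, "y")
    expect_equal(h$final_labels[1], scheme$label[1])
    expect_equal(length(h$final_bins), 2L)
    expect_equal(h$final_bins[[2]], scheme$label[2:5])
  }
})

test_that("final bins are contiguous unions of adjacent initial bins", {
  scheme <- age_group_scheme()
  sizes <- c(60, 60, 60, 60, 60)
  set.seed(44)
  for (i in 1:10) {
    mus <- cumsum(runif(5, 0, 3))  # arbitrary ordered effects
    samplers <- setNames(lapply(mus, function(m)
      function(n) rnorm(n, 10 + m, 1)), scheme$label)
    coh <- one_analyte_cohort(samplers, sizes)
    h <- suppressWarnings(merge_adjacent_age_groups(coh, "y"))
    flat <- unlist(h$final_bins)
    expect_equal(flat, scheme$label)       # order preserved, each bin once
  }
})

test_that("the neonatal separation of the total-T percentage is recovered", {
  # generating medians: 80.59 in the first bin vs 69.10 in bins 2-5
  spec <- cohort_spec()
  set.seed(55)
  seps <- vapply(1:5, function(i) {
    coh <- generate_cohort(spec, seed = 100 + i)
    h <- merge_adjacent_age_groups(coh, "pct_T")
    identical(h$final_labels,
              c("0-1 month", paste(age_group_scheme()$label[2:5],
                                   collapse = " + ")))
  }, logical(1))
  expect_gte(mean(seps), 0.8)
})

test_that("sex partitioning merges identical sexes and splits scaled ones", {
  spec <- cohort_spec()
  set.seed(66)
  merges <- vapply(1:10, function(i) {
    coh <- generate_cohort(spec, seed = 200 + i)
    st <- test_sex_partition(coh, "cnt_T")
    st$decision == "merge"
  }, logical(1))
  expect_gte(mean(merges), 0.9)

  coh <- generate_cohort(spec, seed = 300)
  coh$cnt_T[coh$sex == "M"] <- coh$cnt_T[coh$sex == "M"] * 1.5
  st <- test_sex_partition(coh, "cnt_T")
  expect_equal(st$decision, "split")
  # z* is wired to the actual male/female counts
  expect_equal(st$z_star, z_star(sum(coh$sex == "M"), sum(coh$sex == "F")))

  single <- coh[coh$sex == "M", ]
  expect_warning(expect_null(test_sex_partition(single, "cnt_T")),
                 "single-sex")
})
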