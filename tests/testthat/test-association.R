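test_that("odds_ratio matches the cross-product with Woolf interval", {
  or <- odds_ratio(two_by_two(34, 53, 70, 51))
  expect_equal(or$or_estimate, 34 * 51 / (53 * 70))
  # calibration of z = 1.959964: interval frozen from the closed form
  expect_equal(or$ci_low, 0.2664838, tolerance = 1e-6)
  expect_equal(or$ci_high, 0.8197465, tolerance = 1e-6)
  expect_true(or$ci_low <= or$or_estimate && or$or_estimate <= or$ci_high)

  unit <- odds_ratio(two_by_two(7, 7, 7, 7))
  expect_equal(unit$or_estimate, 1)
  expect_equal(log(unit$ci_low), -log(unit$ci_high))

  inest <- odds_ratio(two_by_two(2, 0, 32, 53))
  expect_false(inest$estimable)
  expect_true(inest$zero_cell)
  expect_identical(inest$or_estimate, Inf)
  expect_identical(odds_ratio(two_by_two(0, 5, 3, 4))$or_estimate, 0)
})

test_that("odds_ratio satisfies cross-product reciprocity", {
  set.seed(11)
  for (i in 1:25) {
    cells <- rpois(4, 20) + 1
    t1 <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    t2 <- two_by_two(cells[3], cells[4], cells[1], cells[2])
    expect_equal(odds_ratio(t1)$or_estimate * odds_ratio(t2)$or_estimate, 1)
  }
})

test_that("pearson_chi2 equals the 2x2 closed form, without continuity correction", {
  r1 <- pearson_chi2(two_by_two(69, 50, 32, 53))
  expect_equal(r1$statistic, 8.2, tolerance = 0.001)
  expect_equal(r1$df, 1)
  r2 <- pearson_chi2(two_by_two(38, 14, 15, 36))
  expect_equal(r2$statistic, 19.65, tolerance = 0.001)

  flat <- pearson_chi2(two_by_two(10, 20, 10, 20))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  set.seed(12)
  for (i in 1:25) {
    x <- rpois(4, 15) + 1
    a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]; n <- sum(x)
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(pearson_chi2(two_by_two(a, b, c, d))$statistic, closed)
  }

  expect_error(pearson_chi2(two_by_two(0, 0, 3, 4)), "degenerate")
})

test_that("fisher_exact follows the probability-mass rule and its enumeration oracle", {
  expect_equal(fisher_exact(two_by_two(2, 0, 32, 53))$p_value, 0.15,
               tolerance = 0.001)
  expect_equal(fisher_exact(two_by_two(3, 0, 51, 66))$p_value, 0.0883,
               tolerance = 0.001)
  expect_equal(fisher_exact(two_by_two(1, 1, 1, 1))$p_value, 1)

  set.seed(13)
  for (i in 1:30) {
    x <- c(rpois(2, 12), rpois(2, 30))[sample(4)]
    if (sum(x) > 200 || sum(x) == 0) next
    expect_equal(fisher_exact(two_by_two(x[1], x[2], x[3], x[4]))$p_value,
                 fisher_enum_oracle(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-7,
                 info = paste(x, collapse = ","))
  }
})

test_that("assoc_test falls back to the exact test on zero or small expected cells", {
  expect_equal(assoc_test(two_by_two(2, 0, 32, 53))$method, "fisher")
  expect_equal(assoc_test(two_by_two(2, 3, 4, 3))$method, "fisher")
  expect_equal(assoc_test(two_by_two(34, 53, 70, 51))$method, "pearson")
})

test_that("summary-statistics t-test reproduces the demographic comparison", {
  r <- t_test_summary(43.8, 15.1, 104, 44.99, 15.57, 104)
  expect_equal(r$p_value, 0.576, tolerance = 0.001)

  same <- t_test_summary(5, 2, 30, 5, 2, 30)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # independent tail-integration oracle for the t distribution
  r2 <- t_test_summary(0, 1, 10, 5, 1, 10)
  tail <- integrate(function(x) dt(x, r2$df), abs(r2$statistic), Inf)$value
  expect_equal(r2$p_value, 2 * tail, tolerance = 1e-8)

  expect_error(t_test_summary(1, 0, 10, 2, 1, 10))
  expect_error(t_test_summary(1, 1, 1, 2, 1, 10))
})

test_that("Hardy-Weinberg GOF test matches the study and is allele-label invariant", {
  ctrl <- hwe_test(c(66, 33, 5))
  expect_equal(ctrl$p_value, 0.7399, tolerance = 0.001)
  expect_equal(ctrl$allele_freq, 165 / 208)
  expect_equal(sum(ctrl$expected), 104)

  case <- hwe_test(c(54, 38, 12))
  expect_equal(case$p_value, 0.1959, tolerance = 0.001)

  exact <- hwe_test(c(25, 50, 25))
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p_value, 1)

  mono <- hwe_test(c(40, 0, 0))
  expect_true(mono$degenerate)
  expect_equal(mono$p_value, 1)

  set.seed(14)
  for (i in 1:20) {
    n <- rmultinom(1, 80, c(0.5, 0.35, 0.15))[, 1]
    expect_equal(hwe_test(n)$chi2, hwe_test(rev(n))$chi2)
  }
})

test_that("genetic model collapse orients the 2x2 as specified", {
  gp <- genotype_count_table("gstp1", c(54, 38, 12), c(66, 33, 5),
                             c("AA", "AG", "GG"))
  rec <- odds_ratio(genetic_model_table(gp, "recessive"))
  expect_equal(rec$or_estimate, 0.3872, tolerance = 1e-4)
  dom <- odds_ratio(genetic_model_table(gp, "dominant"))
  expect_equal(dom$or_estimate, 0.6218, tolerance = 1e-4)
  # variant orientation is the reciprocal
  recv <- odds_ratio(genetic_model_table(gp, "recessive",
                                         "variant_as_exposure"))
  expect_equal(rec$or_estimate * recv$or_estimate, 1)

  gm <- genotype_count_table("gstm1", c(34, 70), c(53, 51),
                             c("present", "null"))
  expect_equal(odds_ratio(genetic_model_table(gm, "recessive"))$or_estimate,
               0.4674, tolerance = 1e-4)

  empty_gg <- genotype_count_table("gstp1", c(50, 54, 0), c(60, 44, 0),
                                   c("AA", "AG", "GG"))
  expect_false(odds_ratio(genetic_model_table(empty_gg, "recessive"))$estimable)

  expect_error(genetic_model_table(gp, "additive"), "per_allele_logistic")
})

test_that("allele_table collapses genotypes to 2N allele counts", {
  gp <- genotype_count_table("gstp1", c(54, 38, 12), c(66, 33, 5),
                             c("AA", "AG", "GG"))
  al <- allele_table(gp)
  expect_equal(c(al$a, al$b, al$c, al$d), c(146, 165, 62, 43))
  expect_equal(odds_ratio(al)$or_estimate, 0.6137, tolerance = 1e-4)

  allAA <- allele_table(genotype_count_table("gstp1", c(10, 0, 0),
                                             c(10, 0, 0), c("AA", "AG", "GG")))
  expect_equal(allAA$c + allAA$d, 0)

  sym <- allele_table(genotype_count_table("gstp1", c(1, 1, 1), c(1, 1, 1),
                                           c("AA", "AG", "GG")))
  expect_equal(odds_ratio(sym)$or_estimate, 1)
})

test_that("per-allele logistic MLE matches the study fit and a grid-search oracle", {
  gp <- genotype_count_table("gstp1", c(54, 38, 12), c(66, 33, 5),
                             c("AA", "AG", "GG"))
  fit <- per_allele_logistic(gp)
  expect_equal(fit$or_estimate, 1.569, tolerance = 0.001)
  expect_equal(fit$ci_low, 1.016, tolerance = 0.001)
  expect_equal(fit$ci_high, 2.423, tolerance = 0.001)
  expect_true(fit$estimable)

  null <- per_allele_logistic(genotype_count_table(
    "gstp1", c(40, 20, 10), c(40, 20, 10), c("AA", "AG", "GG")))
  expect_equal(null$or_estimate, 1, tolerance = 1e-8)

  set.seed(15)
  for (i in 1:5) {
    cases <- rpois(3, 25) + 2
    controls <- rpois(3, 25) + 2
    fit_i <- per_allele_logistic(genotype_count_table(
      "gstp1", cases, controls, c("AA", "AG", "GG")))
    oracle <- logistic_grid_oracle(cases, controls)
    expect_equal(fit_i$log_or, unname(oracle["beta"]), tolerance = 1e-4)
  }
})

test_that("per-allele fit with an empty het class reduces to the hom-hom cross-product", {
  gp <- genotype_count_table("gstp1", c(30, 0, 12), c(45, 0, 6),
                             c("AA", "AG", "GG"))
  fit <- per_allele_logistic(gp)
  expect_equal(exp(2 * fit$log_or), (12 * 45) / (6 * 30), tolerance = 1e-6)
})
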