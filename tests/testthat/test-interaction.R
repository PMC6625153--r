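m1_null <- exposure_is("gstm1", "null")
smoker <- exposure_is("smoking", "smoker")
p1_var <- exposure_is("gstp1", c("AG", "GG"))
t1_null <- exposure_is("gstt1", "null")

test_that("joint_strata reproduces the published two-factor cells", {
  js <- joint_strata(generate_fixture("gstm1_smoking"), m1_null, smoker)
  expect_equal(unname(js$cells["exposed", "exposed", ]), c(38, 14))
  expect_equal(unname(js$cells["exposed", "unexposed", ]), c(32, 37))
  expect_equal(unname(js$cells["unexposed", "exposed", ]), c(19, 17))
  expect_equal(unname(js$cells["unexposed", "unexposed", ]), c(15, 36))
  expect_equal(js$n_excluded, 0)

  js2 <- joint_strata(generate_fixture("gstm1_gstp1"), m1_null, p1_var)
  expect_equal(unname(js2$cells["exposed", "exposed", ]), c(43, 19))
  expect_equal(unname(js2$cells["unexposed", "exposed", ]), c(7, 19))

  never <- function(d) rep(FALSE, nrow(d))
  js3 <- joint_strata(generate_fixture("gstm1_smoking"), m1_null, never)
  expect_true(all(js3$cells[, "exposed", ] == 0))
})

test_that("stratum odds ratios are taken against the doubly unexposed reference", {
  st <- stratum_odds_ratios(joint_strata(generate_fixture("gstm1_smoking"),
                                         m1_null, smoker))
  expect_equal(st$or11$or_estimate, 6.5143, tolerance = 1e-4)
  expect_equal(st$or10$or_estimate, 2.0757, tolerance = 1e-4)
  expect_equal(st$or01$or_estimate, 2.6824, tolerance = 1e-4)
  expect_close(st$or11$ci_high, 15.38, 0.011)

  st2 <- stratum_odds_ratios(joint_strata(generate_fixture("gstm1_gstp1"),
                                          m1_null, p1_var))
  expect_equal(st2$or11$or_estimate, 2.85, tolerance = 0.011)
  expect_equal(st2$or10$or_estimate, 1.06, tolerance = 0.011)
  expect_equal(st2$or01$or_estimate, 0.46, tolerance = 0.011)

  same <- joint_strata_counts(c(15, 36), c(10, 10), c(5, 5), c(15, 36))
  expect_equal(stratum_odds_ratios(same)$or11$or_estimate, 1)
})

test_that("additive interaction measures follow RERI/AP/SI from unrounded ORs", {
  st <- stratum_odds_ratios(joint_strata_counts(c(38, 14), c(32, 37),
                                                c(19, 17), c(15, 36)))
  it <- additive_interaction(st$or11, st$or10, st$or01)
  expect_equal(it$reri, 2.756, tolerance = 0.001)
  expect_equal(it$ap, 0.423, tolerance = 0.001)
  expect_equal(it$si, 1.999, tolerance = 0.001)
  expect_false(any(it$convention_applied))

  ones <- odds_ratio(two_by_two(5, 5, 5, 5))
  null_it <- additive_interaction(ones, ones, ones)
  expect_equal(null_it$reri, 0)
  expect_equal(null_it$ap, 0)
  expect_true(is.na(null_it$si))
})

test_that("inestimable strata contribute zero, reproducing all published interaction rows", {
  # GSTT1 x GSTP1: OR11 raw 0 and OR10 raw Inf both mapped to 0
  it_tp <- additive_interaction(joint_strata_counts(
    c(0, 1), c(3, 0), c(50, 37), c(51, 66)))
  expect_equal(it_tp$reri, -0.7488, tolerance = 0.001)
  expect_true(it_tp$convention_applied[["or11"]])
  expect_true(it_tp$convention_applied[["or10"]])
  expect_true(is.na(it_tp$ap))  # OR11 inestimable

  # GSTM1 x GSTT1: OR01 inestimable
  it_mt <- additive_interaction(joint_strata_counts(
    c(1, 1), c(69, 50), c(2, 0), c(32, 53)))
  expect_equal(it_mt$reri, 0.37, tolerance = 0.005)

  # GSTT1 x smoking: OR10 inestimable; AP and SI still reproduce
  it_ts <- additive_interaction(joint_strata_counts(
    c(2, 1), c(1, 0), c(55, 30), c(46, 73)))
  expect_close(it_ts$reri, 1.26, 0.005)
  expect_close(it_ts$ap, 0.398, 0.001)
  expect_close(it_ts$si, 2.39, 0.005)

  # GSTM1 x GSTP1 (all estimable, regression anchor)
  it_mp <- additive_interaction(joint_strata_counts(
    c(43, 19), c(27, 32), c(7, 19), c(27, 34)))
  expect_equal(it_mp$reri, 2.3235, tolerance = 0.001)
})

test_that("interaction identities hold on random estimable strata", {
  set.seed(16)
  for (i in 1:25) {
    cells <- matrix(rpois(8, 25) + 1, nrow = 4)
    st <- stratum_odds_ratios(joint_strata_counts(cells[1, ], cells[2, ],
                                                  cells[3, ], cells[4, ]))
    it <- additive_interaction(st$or11, st$or10, st$or01)
    o11 <- st$or11$or_estimate; o10 <- st$or10$or_estimate
    o01 <- st$or01$or_estimate
    expect_equal(it$reri + o10 + o01 - o11, 1)
    expect_equal(it$ap * o11, it$reri)
    denom <- (o10 - 1) + (o01 - 1)
    if (denom > 0) expect_equal(it$si > 1, it$reri > 0)
  }
})

test_that("bootstrap intervals are deterministic, contain the point estimate, and gate n_boot", {
  fx <- generate_fixture("gstm1_smoking")
  expect_error(interaction_ci_bootstrap(fx, m1_null, smoker, n_boot = 50),
               "at least 100")

  b1 <- interaction_ci_bootstrap(fx, m1_null, smoker, n_boot = 200, seed = 1)
  b2 <- interaction_ci_bootstrap(fx, m1_null, smoker, n_boot = 200, seed = 1)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci["reri", 1] <= b1$point$reri &&
                b1$point$reri <= b1$ci["reri", 2])
  expect_true(b1$ci["si", 1] <= b1$point$si &&
                b1$point$si <= b1$ci["si", 2])
})

test_that("degenerate resamples are counted and handled by the zero convention", {
  fx <- generate_fixture("gstt1_smoking")  # near-empty GSTT1-null strata
  bt <- interaction_ci_bootstrap(fx, t1_null, smoker, n_boot = 150, seed = 2)
  expect_gt(bt$n_degenerate, 0)
  expect_true(all(is.finite(bt$ci["reri", ])))
})
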