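test_that("every fixture block round-trips to its source table exactly", {
  tabs <- study_table_counts()
  for (locus in c("gstm1", "gstt1", "gstp1")) {
    gc <- genotype_counts(generate_fixture(locus), locus)
    expect_equal(unname(gc$counts["case", ]), tabs$genotypes[[locus]]$case,
                 info = locus)
    expect_equal(unname(gc$counts["control", ]),
                 tabs$genotypes[[locus]]$control, info = locus)
  }
  pred <- list(gstm1 = exposure_is("gstm1", "null"),
               gstt1 = exposure_is("gstt1", "null"),
               gstp1 = exposure_is("gstp1", c("AG", "GG")),
               smoking = exposure_is("smoking", "smoker"))
  for (block in c(names(tabs$gene_gene), names(tabs$gene_env))) {
    s <- c(tabs$gene_gene, tabs$gene_env)[[block]]
    parts <- strsplit(block, "_")[[1]]
    js <- joint_strata(generate_fixture(block), pred[[parts[1]]],
                       pred[[parts[2]]])
    expect_equal(unname(js$cells["exposed", "exposed", ]), s$s11, info = block)
    expect_equal(unname(js$cells["exposed", "unexposed", ]), s$s10,
                 info = block)
    expect_equal(unname(js$cells["unexposed", "exposed", ]), s$s01,
                 info = block)
    expect_equal(unname(js$cells["unexposed", "unexposed", ]), s$s00,
                 info = block)
  }
  for (locus in c("gstm1", "gstp1")) {
    fx <- generate_fixture(paste0("response_", locus))
    for (ep in c("mcyr_3m", "ccyr_6m", "bcrabl_3m", "bcrabl_6m")) {
      rt <- response_table(fx, locus, ep)
      want <- do.call(rbind, tabs$response[[locus]][[ep]])
      expect_equal(unname(rt$counts), unname(want),
                   info = paste(locus, ep))
    }
  }
})

test_that("the all-blocks fixture carries a manifest of per-table record sets", {
  all_fx <- generate_fixture("all")
  expect_true(all(c("gstm1", "gstm1_smoking", "response_gstp1") %in%
                    names(all_fx)))
  mf <- attr(all_fx, "manifest")
  expect_equal(mf$mode, "per-table fixtures")
  expect_true(all(vapply(all_fx, inherits, logical(1), "gst_cohort")))
})

test_that("inconsistent fixture counts are rejected", {
  bad <- study_table_counts()$genotypes$gstm1
  bad$case <- c(35, 70)  # sums to 105 against group size 104
  expect_error(generate_fixture("gstm1", counts = bad), "105")
})

test_that("a null simulation yields odds ratios near 1 and is seed-deterministic", {
  cfg <- simulation_config(
    n_cases = 20000, n_controls = 20000,
    effect_ors = list(gstm1_null = 1, gstt1_null = 1, gstp1_per_g = 1,
                      smoking = 1, gstm1_null_x_smoking = 1))
  co <- generate_cohort(cfg, seed = 31)
  for (pred in list(exposure_is("gstm1", "null"),
                    exposure_is("smoking", "smoker"))) {
    or <- odds_ratio(aggregate_2x2(co, pred))
    expect_lt(abs(or$log_or), 0.1)
  }
  co2 <- generate_cohort(cfg, seed = 31)
  expect_identical(as.data.frame(co), as.data.frame(co2))
  expect_false(identical(as.data.frame(generate_cohort(cfg, seed = 32)),
                         as.data.frame(co)))
})

test_that("the simulator recovers configured joint effects", {
  cfg <- simulation_config(n_cases = 20000, n_controls = 20000)
  co <- generate_cohort(cfg, seed = 7)
  ia <- interaction_analysis(co, exposure_is("gstm1", "null"),
                             exposure_is("smoking", "smoker"))
  target <- with(cfg$effect_ors,
                 gstm1_null * smoking * gstm1_null_x_smoking)
  expect_lt(abs(log(ia$or11$or_estimate / target)), log(1.10))
  expect_lt(abs(log(ia$or10$or_estimate / cfg$effect_ors$gstm1_null)),
            log(1.10))
})

test_that("attach_survival honors hazards, thresholds and determinism", {
  cfg0 <- simulation_config(survival = list(mmr_hazard = c(null = 0,
                                                           present = 0),
                                            efs_hazard = c(null = 0,
                                                           present = 0)))
  co <- attach_survival(generate_cohort(cfg0, seed = 8), cfg0, seed = 9)
  mm <- mmr_events(co)
  expect_true(all(!mm$event))
  expect_true(all(co$mcyr_3m[co$group == "case"] == "no"))

  cfg1 <- simulation_config(n_cases = 400, n_controls = 10)
  co1 <- attach_survival(generate_cohort(cfg1, seed = 10), cfg1, seed = 11)
  cases <- co1[co1$group == "case", ]
  # 3-month threshold consistency between latent time and binary endpoints
  ev <- mmr_events(co1)
  achieved_by3 <- ev$subject_id[ev$event & ev$time <= 3]
  expect_true(all(cases$mcyr_3m[cases$subject_id %in% achieved_by3] == "yes"))
  expect_identical(cases$bcrabl_3m == "le10pct", cases$mcyr_3m == "yes")

  co1b <- attach_survival(generate_cohort(cfg1, seed = 10), cfg1, seed = 11)
  expect_identical(as.data.frame(co1), as.data.frame(co1b))
})

test_that("ordered hazards produce ordered KM medians", {
  cfg <- simulation_config(
    n_cases = 200, n_controls = 10,
    survival = list(mmr_hazard = c(null = 0.03, present = 0.09),
                    horizon = 72))
  km_median <- function(km) km$time[which(km$surv <= 0.5)[1]]
  set.seed(41)
  ok <- 0L; reps <- 100L
  for (r in seq_len(reps)) {
    co <- attach_survival(generate_cohort(cfg), cfg)
    ev <- mmr_events(co)
    g <- co$gstm1[match(ev$subject_id, co$subject_id)]
    m_null <- km_median(km_estimate(ev$time[g == "null"],
                                    ev$event[g == "null"]))
    m_pres <- km_median(km_estimate(ev$time[g == "present"],
                                    ev$event[g == "present"]))
    if (!is.na(m_null) && !is.na(m_pres) && m_null > m_pres) ok <- ok + 1L
  }
  expect_gte(ok / reps, 0.95)
})
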