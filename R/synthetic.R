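#' Built-in reference study counts
#'
#' The marginal count tables of a published 104-case / 104-control study of
#' GST polymorphisms, smoking and CML in an Iranian population, used by the
#' fixture mode of the generator and by [replicate_study()]. Blocks:
#' demographics (sex, age summaries, smoking), per-locus genotype counts,
#' gene-gene and gene-environment joint strata in the fixed order
#' (1,1), (1,0), (0,1), (0,0) with each entry `c(cases, controls)`, and
#' treatment-response tables among cases. `published` carries the study's
#' printed odds ratios and interaction measures for side-by-side reporting.
#'
#' @return A nested list of count blocks.
#' @export
study_table_counts <- function() {
  list(
    n_cases = 104L, n_controls = 104L,
    demographics = list(
      sex = list(male = c(case = 55, control = 57),
                 female = c(case = 49, control = 47)),
      age = list(case = c(mean = 43.8, sd = 15.1),
                 control = c(mean = 44.99, sd = 15.57)),
      smoking = list(smoker = c(case = 57, control = 31),
                     nonsmoker = c(case = 47, control = 73))),
    genotypes = list(
      gstm1 = list(classes = c("present", "null"),
                   case = c(34, 70), control = c(53, 51)),
      gstt1 = list(classes = c("present", "null"),
                   case = c(101, 3), control = c(103, 1)),
      gstp1 = list(classes = c("AA", "AG", "GG"),
                   case = c(54, 38, 12), control = c(66, 33, 5))),
    gene_gene = list(
      gstm1_gstt1 = list(factors = c("gstm1 null", "gstt1 null"),
                         s11 = c(1, 1), s10 = c(69, 50),
                         s01 = c(2, 0), s00 = c(32, 53)),
      gstm1_gstp1 = list(factors = c("gstm1 null", "gstp1 AG/GG"),
                         s11 = c(43, 19), s10 = c(27, 32),
                         s01 = c(7, 19), s00 = c(27, 34)),
      gstt1_gstp1 = list(factors = c("gstt1 null", "gstp1 AG/GG"),
                         s11 = c(0, 1), s10 = c(3, 0),
                         s01 = c(50, 37), s00 = c(51, 66))),
    gene_env = list(
      gstm1_smoking = list(factors = c("gstm1 null", "smoker"),
                           s11 = c(38, 14), s10 = c(32, 37),
                           s01 = c(19, 17), s00 = c(15, 36)),
      gstt1_smoking = list(factors = c("gstt1 null", "smoker"),
                           s11 = c(2, 1), s10 = c(1, 0),
                           s01 = c(55, 30), s00 = c(46, 73)),
      gstp1_smoking = list(factors = c("gstp1 AG/GG", "smoker"),
                           s11 = c(27, 12), s10 = c(23, 26),
                           s01 = c(30, 19), s00 = c(24, 47))),
    # responders/non-responders among cases: rows (null, present) for GSTM1,
    # (AA, AG/GG) for GSTP1
    response = list(
      gstm1 = list(n = c(null = 70, present = 34),
                   mcyr_3m = list(null = c(10, 60), present = c(14, 20)),
                   ccyr_6m = list(null = c(17, 53), present = c(23, 11)),
                   bcrabl_3m = list(null = c(2, 68), present = c(10, 24)),
                   bcrabl_6m = list(null = c(6, 64), present = c(18, 16))),
      gstp1 = list(n = c(AA = 54, `AG/GG` = 50),
                   mcyr_3m = list(AA = c(15, 39), `AG/GG` = c(7, 43)),
                   ccyr_6m = list(AA = c(25, 29), `AG/GG` = c(13, 37)),
                   bcrabl_3m = list(AA = c(20, 34), `AG/GG` = c(10, 40)),
                   bcrabl_6m = list(AA = c(25, 29), `AG/GG` = c(11, 39)))),
    published = list(
      gstm1 = list(or = 0.46, ci = c(0.26, 0.82), p = 0.008),
      gstt1 = list(or = 0.32, ci = c(0.03, 3.19), p = 0.31),
      gstp1 = list(recessive = 0.38, dominant = 0.62, additive = 1.569,
                   additive_ci = c(1.016, 2.423), allele = 0.61,
                   hwe_p = c(case = 0.19, control = 0.73)),
      gene_gene = list(gstm1_gstt1 = list(or10 = 2.28, reri = 0.37),
                       gstm1_gstp1 = list(or11 = 2.85, reri = 2.32),
                       gstt1_gstp1 = list(or01 = 1.75, reri = -0.749)),
      gene_env = list(
        gstm1_smoking = list(or11 = 6.51, or10 = 2.07, or01 = 2.68,
                             reri = 2.756, ap = 0.423, si = 1.99),
        gstt1_smoking = list(or11 = 3.17, or01 = 2.91,
                             reri = 1.26, ap = 0.39, si = 2.39),
        gstp1_smoking = list(or11 = 4.40, or10 = 1.73, or01 = 3.09,
                             reri = 0.58, ap = 0.13, si = 1.20)))
  )
}

fixture_block_names <- c("demographics", "gstm1", "gstt1", "gstp1",
                         "gstm1_gstt1", "gstm1_gstp1", "gstt1_gstp1",
                         "gstm1_smoking", "gstt1_smoking", "gstp1_smoking",
                         "response_gstm1", "response_gstp1")

# deterministic age vector with exact sample mean and SD
exact_age_vector <- function(n, mean, sd) {
  s <- rep(c(1, -1), length.out = n)
  s <- (s - mean(s)) / stats::sd(s)
  mean + sd * s
}

new_fixture_cohort <- function(prefix, group, ...) {
  n <- length(group)
  cohort(subject_id = sprintf("%s-%03d", prefix, seq_len(n)),
         group = group, ...)
}

#' Reconstruct subject-level records from a marginal count table
#'
#' Fixture mode of the synthetic generator: builds a record set whose
#' aggregation reproduces one block of the reference study tables cell for
#' cell. Fields not constrained by that block are left missing, because the
#' study tables fix only marginal counts. `"all"` returns every block as a
#' named list with a manifest attribute — the cross-table joint distribution
#' is under-determined, so exactness is guaranteed per table, not jointly.
#'
#' @param block One of `"demographics"`, `"gstm1"`, `"gstt1"`, `"gstp1"`
#'   (genotype tables), `"gstm1_gstt1"`, `"gstm1_gstp1"`, `"gstt1_gstp1"`
#'   (gene-gene strata), `"gstm1_smoking"`, `"gstt1_smoking"`,
#'   `"gstp1_smoking"` (gene-environment strata), `"response_gstm1"`,
#'   `"response_gstp1"` (treatment response among cases), or `"all"`.
#' @param counts Optional replacement counts for the block, in the same
#'   shape as the corresponding entry of [study_table_counts()]; cells must
#'   sum to the group sizes.
#' @return A `gst_cohort` data frame, or for `"all"` a named list of them
#'   with attribute `manifest`.
#' @examples
#' fx <- generate_fixture("gstm1")
#' as.matrix(aggregate_2x2(fx, exposure_is("gstm1", "present")))
#' @export
generate_fixture <- function(block = "all", counts = NULL) {
  tabs <- study_table_counts()
  if (identical(block, "all")) {
    out <- lapply(fixture_block_names, generate_fixture)
    names(out) <- fixture_block_names
    attr(out, "manifest") <- list(
      mode = "per-table fixtures",
      blocks = fixture_block_names,
      note = paste("each record set reproduces its own table exactly;",
                   "a joint assignment consistent with all tables at once",
                   "is under-determined by the published margins"))
    return(out)
  }
  block <- match.arg(block, fixture_block_names)
  n_cases <- tabs$n_cases; n_controls <- tabs$n_controls
  group <- rep(c("case", "control"), c(n_cases, n_controls))

  fill_by_group <- function(case_counts, control_counts, levels) {
    if (sum(case_counts) != n_cases || sum(control_counts) != n_controls) {
      stop(sprintf("fixture counts for '%s' sum to %d cases / %d controls, expected %d / %d",
                   block, sum(case_counts), sum(control_counts),
                   n_cases, n_controls))
    }
    c(rep(levels, case_counts), rep(levels, control_counts))
  }

  if (block == "demographics") {
    d <- if (is.null(counts)) tabs$demographics else counts
    sex <- fill_by_group(c(d$sex$male["case"], d$sex$female["case"]),
                         c(d$sex$male["control"], d$sex$female["control"]),
                         c("male", "female"))
    smoking <- fill_by_group(
      c(d$smoking$smoker["case"], d$smoking$nonsmoker["case"]),
      c(d$smoking$smoker["control"], d$smoking$nonsmoker["control"]),
      c("smoker", "nonsmoker"))
    age <- c(exact_age_vector(n_cases, d$age$case["mean"], d$age$case["sd"]),
             exact_age_vector(n_controls, d$age$control["mean"],
                              d$age$control["sd"]))
    return(new_fixture_cohort("DEMO", group, sex = sex, smoking = smoking,
                              age = age))
  }

  if (block %in% c("gstm1", "gstt1", "gstp1")) {
    g <- if (is.null(counts)) tabs$genotypes[[block]] else counts
    geno <- fill_by_group(g$case, g$control, g$classes)
    args <- list(group = group)
    args[[block]] <- geno
    return(do.call(new_fixture_cohort,
                   c(list(prefix = toupper(block)), args)))
  }

  if (block %in% names(tabs$gene_gene) || block %in% names(tabs$gene_env)) {
    s <- if (!is.null(counts)) counts
         else if (block %in% names(tabs$gene_gene)) tabs$gene_gene[[block]]
         else tabs$gene_env[[block]]
    strata <- rbind(s$s11, s$s10, s$s01, s$s00)
    if (any(colSums(strata) != c(n_cases, n_controls))) {
      stop(sprintf("fixture counts for '%s' sum to %d cases / %d controls, expected %d / %d",
                   block, sum(strata[, 1]), sum(strata[, 2]),
                   n_cases, n_controls))
    }
    # stratum order (1,1),(1,0),(0,1),(0,0); cases then controls
    f1 <- c(rep(c(TRUE, TRUE, FALSE, FALSE), strata[, 1]),
            rep(c(TRUE, TRUE, FALSE, FALSE), strata[, 2]))
    f2 <- c(rep(c(TRUE, FALSE, TRUE, FALSE), strata[, 1]),
            rep(c(TRUE, FALSE, TRUE, FALSE), strata[, 2]))
    parts <- strsplit(block, "_")[[1]]
    as_field <- function(name, exposed) {
      switch(name,
             gstm1 = ifelse(exposed, "null", "present"),
             gstt1 = ifelse(exposed, "null", "present"),
             gstp1 = ifelse(exposed, "AG", "AA"),
             smoking = ifelse(exposed, "smoker", "nonsmoker"))
    }
    args <- list(group = group)
    args[[parts[1]]] <- as_field(parts[1], f1)
    args[[parts[2]]] <- as_field(parts[2], f2)
    return(do.call(new_fixture_cohort,
                   c(list(prefix = toupper(gsub("_", "-", block))), args)))
  }

  # response blocks: cases only
  locus <- sub("response_", "", block)
  r <- if (is.null(counts)) tabs$response[[locus]] else counts
  n_by_geno <- r$n
  if (sum(n_by_geno) != n_cases) {
    stop(sprintf("fixture counts for '%s' sum to %d cases, expected %d",
                 block, sum(n_by_geno), n_cases))
  }
  geno_levels <- if (locus == "gstm1") c("null", "present") else c("AA", "AG")
  geno <- rep(geno_levels, n_by_geno)
  endpoint_col <- function(ep) {
    yes <- endpoint_responder_level[[ep]]
    no <- setdiff(cohort_schema[[ep]], c(yes, "missing"))
    unlist(lapply(seq_along(n_by_geno), function(i) {
      cnt <- r[[ep]][[i]]
      if (sum(cnt) != n_by_geno[i]) {
        stop(sprintf("fixture counts for '%s' endpoint '%s' do not sum to the genotype group size",
                     block, ep))
      }
      rep(c(yes, no), cnt)
    }))
  }
  args <- list(group = rep("case", n_cases))
  args[[locus]] <- geno
  for (ep in names(endpoint_responder_level)) args[[ep]] <- endpoint_col(ep)
  do.call(new_fixture_cohort, c(list(prefix = toupper(block)), args))
}

#' Simulation configuration for the cohort generator
#'
#' Collects the parameters of the retrospective case-control sampling model.
#' Defaults are the reference study's conditions: control exposure
#' frequencies from its control arm (GSTM1 null 51/104, GSTT1 null 1/104,
#' GSTP1 G allele 43/208 under HWE, smoking 31/104) and odds-ratio effects
#' equal to its estimated stratum effects (GSTM1-null 2.076 and smoking
#' 2.682 main effects with joint multiplier giving OR 6.514, GSTP1 per-G
#' 1.569, GSTT1 null 1).
#'
#' @param n_cases,n_controls Arm sizes.
#' @param gstm1_null_freq,gstt1_null_freq Control null-genotype frequencies.
#' @param gstp1_g_freq Control G-allele frequency; genotypes drawn under HWE.
#' @param smoking_prev Control smoking prevalence.
#' @param effect_ors Named list of odds-scale multipliers: `gstm1_null`,
#'   `gstt1_null`, `gstp1_per_g` (per dosage unit), `smoking`, and the
#'   pairwise interaction multiplier `gstm1_null_x_smoking`.
#' @param survival List: `mmr_hazard` and `efs_hazard` (per-month
#'   exponential event hazards named by GSTM1 genotype) and `horizon`
#'   (months of uniform censoring).
#' @param seed Optional integer seed recorded in the config.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_cases = 104, n_controls = 104,
                              gstm1_null_freq = 51 / 104,
                              gstt1_null_freq = 1 / 104,
                              gstp1_g_freq = 43 / 208,
                              smoking_prev = 31 / 104,
                              effect_ors = list(),
                              survival = list(),
                              seed = NULL) {
  eff <- utils::modifyList(
    list(gstm1_null = 2.0757, gstt1_null = 1, gstp1_per_g = 1.569,
         smoking = 2.6824,
         gstm1_null_x_smoking = 6.5143 / (2.0757 * 2.6824)),
    effect_ors)
  surv <- utils::modifyList(
    list(mmr_hazard = c(null = 0.010, present = 0.035),
         efs_hazard = c(null = 0.004, present = 0.004),
         horizon = 72),
    survival)
  probs <- c(gstm1_null_freq, gstt1_null_freq, gstp1_g_freq, smoking_prev)
  stopifnot(n_cases >= 1, n_controls >= 1,
            all(probs >= 0 & probs <= 1),
            all(unlist(eff) > 0),
            all(unlist(surv[c("mmr_hazard", "efs_hazard")]) >= 0),
            surv$horizon > 0)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 gstm1_null_freq = gstm1_null_freq,
                 gstt1_null_freq = gstt1_null_freq,
                 gstp1_g_freq = gstp1_g_freq, smoking_prev = smoking_prev,
                 effect_ors = eff, survival = surv, seed = seed),
            class = "simulation_config")
}

# enumerate the 24 exposure profiles with control probabilities and
# odds-scale tilts
profile_table <- function(config) {
  pr <- expand.grid(m1 = c(TRUE, FALSE), t1 = c(TRUE, FALSE), dose = 0:2,
                    smoke = c(TRUE, FALSE))
  q <- config$gstp1_g_freq
  hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  eff <- config$effect_ors
  pr$p_control <-
    ifelse(pr$m1, config$gstm1_null_freq, 1 - config$gstm1_null_freq) *
    ifelse(pr$t1, config$gstt1_null_freq, 1 - config$gstt1_null_freq) *
    hwe[pr$dose + 1] *
    ifelse(pr$smoke, config$smoking_prev, 1 - config$smoking_prev)
  tilt <- eff$gstm1_null^pr$m1 * eff$gstt1_null^pr$t1 *
    eff$gstp1_per_g^pr$dose * eff$smoking^pr$smoke *
    eff$gstm1_null_x_smoking^(pr$m1 & pr$smoke)
  pr$p_case <- pr$p_control * tilt
  pr$p_case <- pr$p_case / sum(pr$p_case)
  pr
}

#' Simulate a case-control cohort
#'
#' Model mode of the generator: a retrospective sampling scheme in which
#' control exposure profiles (GSTM1, GSTT1, GSTP1 genotype, smoking) follow
#' the configured frequencies (GSTP1 under HWE) and case profiles follow the
#' tilted distribution `P(profile | case) proportional to
#' P(profile | control) * OR(profile)`, with `OR(profile)` the product of
#' the configured main-effect and interaction multipliers. With this scheme
#' the configured odds ratios are exactly the estimands of the downstream
#' analysis. Sex and age are filled from independent per-group distributions
#' matching the reference demographics; they feed no effect.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (overrides `config$seed`); fixed seed gives an
#'   identical cohort.
#' @return A `gst_cohort` data frame with attribute `manifest` recording the
#'   seed and config.
#' @export
generate_cohort <- function(config = simulation_config(), seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  pr <- profile_table(config)
  n <- config$n_cases + config$n_controls
  group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  idx <- c(sample(nrow(pr), config$n_cases, replace = TRUE, prob = pr$p_case),
           sample(nrow(pr), config$n_controls, replace = TRUE,
                  prob = pr$p_control))
  male_p <- ifelse(group == "case", 55 / 104, 57 / 104)
  age_mean <- ifelse(group == "case", 43.8, 44.99)
  age_sd <- ifelse(group == "case", 15.1, 15.57)
  out <- cohort(
    subject_id = sprintf("SIM-%05d", seq_len(n)),
    group = group,
    gstm1 = ifelse(pr$m1[idx], "null", "present"),
    gstt1 = ifelse(pr$t1[idx], "null", "present"),
    gstp1 = c("AA", "AG", "GG")[pr$dose[idx] + 1],
    smoking = ifelse(pr$smoke[idx], "smoker", "nonsmoker"),
    sex = ifelse(stats::runif(n) < male_p, "male", "female"),
    age = pmax(0, stats::rnorm(n, age_mean, age_sd)))
  attr(out, "manifest") <- list(mode = "model", seed = seed, config = config)
  out
}

#' Attach simulated response and survival fields
#'
#' Draws, for each case record, a latent time to molecular response and a
#' time to the composite EFS event from per-GSTM1-genotype exponential
#' hazards, censors both with independent uniform censoring on the follow-up
#' horizon, and derives the binary ELN-style endpoints by thresholding the
#' latent response time at 3 and 6 months (response achieved by month 3:
#' MCyR yes and BCR-ABL <=10%; by month 6: CCyR yes and BCR-ABL <1%).
#'
#' @param records A `gst_cohort` data frame.
#' @param config A [simulation_config()]; only `$survival` is used.
#' @param seed Optional integer seed.
#' @return The records with response/survival fields filled for cases.
#' @export
attach_survival <- function(records, config = simulation_config(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  surv <- config$survival
  is_case <- records$group == "case"
  n <- sum(is_case)
  if (n == 0) return(records)
  haz_for <- function(h) {
    g <- records$gstm1[is_case]
    ifelse(g == "null", h[["null"]],
           ifelse(g == "present", h[["present"]], mean(h)))
  }
  draw_times <- function(rate) {
    t <- rep(Inf, n)
    pos <- rate > 0
    t[pos] <- stats::rexp(sum(pos), rate[pos])
    t
  }
  t_mmr <- draw_times(haz_for(surv$mmr_hazard))
  c_mmr <- stats::runif(n, 0, surv$horizon)
  t_efs <- draw_times(haz_for(surv$efs_hazard))
  c_efs <- stats::runif(n, 0, surv$horizon)
  records$mmr_time[is_case] <- pmin(t_mmr, c_mmr)
  records$mmr_event[is_case] <- ifelse(t_mmr <= c_mmr, "yes", "no")
  records$efs_time[is_case] <- pmin(t_efs, c_efs)
  records$efs_event[is_case] <- ifelse(t_efs <= c_efs, "yes", "no")
  records$mcyr_3m[is_case] <- ifelse(t_mmr <= 3, "yes", "no")
  records$bcrabl_3m[is_case] <- ifelse(t_mmr <= 3, "le10pct", "gt10pct")
  records$ccyr_6m[is_case] <- ifelse(t_mmr <= 6, "yes", "no")
  records$bcrabl_6m[is_case] <- ifelse(t_mmr <= 6, "lt1pct", "ge1pct")
  validate_cohort(records)
}
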