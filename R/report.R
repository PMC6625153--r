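single_locus_block <- function(gc, alpha = 0.05) {
  out <- list(locus = gc$locus, counts = gc$counts, missing = gc$missing)
  rec <- genetic_model_table(gc, "recessive")
  out$recessive <- list(or = odds_ratio(rec, alpha), test = assoc_test(rec))
  if (length(gc$classes) == 3) {
    dom <- genetic_model_table(gc, "dominant")
    out$dominant <- list(or = odds_ratio(dom, alpha), test = assoc_test(dom))
    al <- allele_table(gc)
    out$allele <- list(or = odds_ratio(al, alpha), test = assoc_test(al))
    out$additive <- per_allele_logistic(gc, alpha = alpha)
    out$hwe <- list(case = hwe_test(gc, "case"),
                    control = hwe_test(gc, "control"))
  }
  out
}

interaction_block <- function(js, alpha = 0.05, expected_threshold = 5) {
  st <- stratum_odds_ratios(js, alpha)
  ref <- js$cells["unexposed", "unexposed", ]
  stratum_test <- function(i, j) {
    s <- js$cells[i, j, ]
    assoc_test(two_by_two(s["case"], s["control"], ref["case"],
                          ref["control"]), expected_threshold)
  }
  list(strata = js,
       interaction = additive_interaction(st$or11, st$or10, st$or01),
       tests = list(s11 = stratum_test("exposed", "exposed"),
                    s10 = stratum_test("exposed", "unexposed"),
                    s01 = stratum_test("unexposed", "exposed")))
}

#' Analyze a subject-level cohort end to end
#'
#' Runs the full analysis sequence on one cohort: demographic comparisons,
#' per-locus genetic-model associations with HWE, gene-gene and
#' gene-environment additive interactions, treatment-response tables, and
#' (when survival fields are present) Kaplan-Meier curves with a log-rank
#' comparison by GSTM1 genotype.
#'
#' @param records A `gst_cohort` data frame.
#' @param alpha Level for all confidence intervals.
#' @param expected_threshold Small-cell threshold for [assoc_test()].
#' @return A list of class `replication_report`.
#' @export
analyze_cohort <- function(records, alpha = 0.05, expected_threshold = 5) {
  smry <- cohort_summary(records)
  demo <- list(summary = smry)
  sex_m <- rbind(male = smry$sex$male, female = smry$sex$female)
  if (all(rowSums(sex_m) > 0)) demo$sex_test <- assoc_test(sex_m)
  smk_m <- rbind(smoker = smry$smoking$smoker,
                 nonsmoker = smry$smoking$nonsmoker)
  if (all(rowSums(smk_m) > 0)) demo$smoking_test <- assoc_test(smk_m)
  if (smry$age$case$n_missing < smry$n_cases &&
      smry$age$control$n_missing < smry$n_controls) {
    demo$age_test <- t_test_summary(
      smry$age$case$mean, smry$age$case$sd,
      smry$n_cases - smry$age$case$n_missing,
      smry$age$control$mean, smry$age$control$sd,
      smry$n_controls - smry$age$control$n_missing)
  }

  preds <- list(gstm1 = exposure_is("gstm1", "null"),
                gstt1 = exposure_is("gstt1", "null"),
                gstp1 = exposure_is("gstp1", c("AG", "GG")),
                smoking = exposure_is("smoking", "smoker"))
  labels <- c(gstm1 = "gstm1 null", gstt1 = "gstt1 null",
              gstp1 = "gstp1 AG/GG", smoking = "smoker")
  has_field <- function(f) any(records[[f]] != "missing")

  single <- list()
  for (locus in c("gstm1", "gstt1", "gstp1")) {
    if (has_field(locus)) {
      single[[locus]] <- single_locus_block(genotype_counts(records, locus),
                                            alpha)
    }
  }

  pair_block <- function(f1, f2) {
    if (!has_field(f1) || !has_field(f2)) return(NULL)
    js <- joint_strata(records, preds[[f1]], preds[[f2]],
                       labels[[f1]], labels[[f2]])
    interaction_block(js, alpha, expected_threshold)
  }
  gene_gene <- Filter(Negate(is.null), list(
    gstm1_gstt1 = pair_block("gstm1", "gstt1"),
    gstm1_gstp1 = pair_block("gstm1", "gstp1"),
    gstt1_gstp1 = pair_block("gstt1", "gstp1")))
  gene_env <- Filter(Negate(is.null), list(
    gstm1_smoking = pair_block("gstm1", "smoking"),
    gstt1_smoking = pair_block("gstt1", "smoking"),
    gstp1_smoking = pair_block("gstp1", "smoking")))

  response <- list()
  for (locus in c("gstm1", "gstp1")) {
    if (!has_field(locus)) next
    for (ep in names(endpoint_responder_level)) {
      cases <- records[records$group == "case", , drop = FALSE]
      if (any(cases[[ep]] != "missing")) {
        response[[paste(locus, ep, sep = "_")]] <-
          response_table(records, locus, ep, expected_threshold)
      }
    }
  }

  surv <- NULL
  mmr <- tryCatch(mmr_events(records), error = function(e) NULL)
  if (!is.null(mmr) && nrow(mmr) > 0 && has_field("gstm1")) {
    cases <- records[records$group == "case", , drop = FALSE]
    g <- cases$gstm1[match(mmr$subject_id, cases$subject_id)]
    keep <- g != "missing"
    surv <- list(mmr_km = km_estimate(mmr$time, mmr$event))
    if (length(unique(g[keep])) == 2) {
      surv$mmr_logrank <- logrank_test(g[keep], mmr$time[keep],
                                       mmr$event[keep])
    }
    efs <- tryCatch(efs_events(records), error = function(e) NULL)
    if (!is.null(efs) && nrow(efs) > 0) {
      ge <- cases$gstm1[match(efs$subject_id, cases$subject_id)]
      keepe <- ge != "missing"
      surv$efs_km <- km_estimate(efs$time, efs$event)
      if (length(unique(ge[keepe])) == 2) {
        surv$efs_logrank <- logrank_test(ge[keepe], efs$time[keepe],
                                         efs$event[keepe])
      }
    }
  }

  structure(list(demographics = demo, single_locus = single,
                 gene_gene = gene_gene, gene_env = gene_env,
                 response = response, survival = surv,
                 alpha = alpha, n_records = nrow(records)),
            class = "replication_report")
}

#' Replicate the reference study from its built-in tables
#'
#' Reconstructs each published table block with [generate_fixture()], runs
#' the corresponding analysis on it, and reports the computed values side by
#' side with the published ones. Per-table fixtures are used because the
#' published margins under-determine a joint subject-level dataset.
#'
#' @param alpha Level for confidence intervals.
#' @return A list of class `replication_report` with an extra `published`
#'   element carrying the printed values for comparison.
#' @examples
#' rep <- replicate_study()
#' rep$gene_env$gstm1_smoking$interaction$reri  # 2.756
#' @export
replicate_study <- function(alpha = 0.05) {
  tabs <- study_table_counts()
  demo_fx <- generate_fixture("demographics")
  report <- analyze_cohort(demo_fx, alpha)
  for (locus in c("gstm1", "gstt1", "gstp1")) {
    gc <- genotype_counts(generate_fixture(locus), locus)
    report$single_locus[[locus]] <- single_locus_block(gc, alpha)
  }
  pair_pred <- function(name) {
    switch(name,
           gstm1 = exposure_is("gstm1", "null"),
           gstt1 = exposure_is("gstt1", "null"),
           gstp1 = exposure_is("gstp1", c("AG", "GG")),
           smoking = exposure_is("smoking", "smoker"))
  }
  for (kind in c("gene_gene", "gene_env")) {
    for (block in names(tabs[[kind]])) {
      parts <- strsplit(block, "_")[[1]]
      fx <- generate_fixture(block)
      js <- joint_strata(fx, pair_pred(parts[1]), pair_pred(parts[2]),
                         parts[1], parts[2])
      report[[kind]][[block]] <- interaction_block(js, alpha)
    }
  }
  report$response <- list()
  for (locus in c("gstm1", "gstp1")) {
    fx <- generate_fixture(paste0("response_", locus))
    for (ep in names(endpoint_responder_level)) {
      report$response[[paste(locus, ep, sep = "_")]] <-
        response_table(fx, locus, ep)
    }
  }
  report$published <- tabs$published
  report$mode <- "study fixture replication"
  report
}

#' Run the full pipeline from a config
#'
#' Orchestrates input acquisition and [analyze_cohort()] /
#' [replicate_study()], optionally rendering the report to disk. Exactly one
#' input source must be given: a cohort file path, an in-memory cohort, a
#' [simulation_config()] (a cohort is simulated), or `replicate = TRUE` for
#' the built-in study tables.
#'
#' @param input Path to a cohort file, a `gst_cohort` data frame, or a
#'   `simulation_config`.
#' @param replicate If `TRUE`, ignore `input` and run [replicate_study()].
#' @param alpha Level for confidence intervals; must lie in (0, 1).
#' @param expected_threshold Small-cell threshold for [assoc_test()].
#' @param seed Seed forwarded to the simulator.
#' @param output_dir If non-NULL, `render_report()` writes `report.txt` and
#'   `report.json` there.
#' @param sep Field separator when `input` is a path.
#' @return A `replication_report`.
#' @export
run_pipeline <- function(input = NULL, replicate = FALSE, alpha = 0.05,
                         expected_threshold = 5, seed = NULL,
                         output_dir = NULL, sep = ",") {
  stopifnot(alpha > 0, alpha < 1)
  if (replicate) {
    report <- replicate_study(alpha)
  } else if (is.null(input)) {
    stop("no input: give a cohort file path, a cohort, a simulation_config, ",
         "or replicate = TRUE")
  } else if (inherits(input, "simulation_config")) {
    records <- generate_cohort(input, seed = if (is.null(seed)) input$seed
                                             else seed)
    records <- attach_survival(records, input)
    report <- analyze_cohort(records, alpha, expected_threshold)
  } else if (is.data.frame(input)) {
    report <- analyze_cohort(validate_cohort(input), alpha,
                             expected_threshold)
  } else if (is.character(input) && length(input) == 1) {
    report <- analyze_cohort(read_cohort(input, sep = sep), alpha,
                             expected_threshold)
  } else {
    stop("unrecognized input")
  }
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) {
      dir.create(output_dir, recursive = TRUE)
    }
    render_report(report, "text", file.path(output_dir, "report.txt"))
    render_report(report, "json", file.path(output_dir, "report.json"))
  }
  report
}

fmt_p <- function(p) {
  if (is.na(p)) "NA" else if (p < 0.001) "<0.001" else sprintf("%.3f", p)
}
fmt_or <- function(o) {
  if (!isTRUE(o$estimable)) return("-- (inestimable)")
  sprintf("%.2f (%.2f-%.2f)", o$or_estimate, o$ci_low, o$ci_high)
}
fmt_num <- function(x, digits = 2) {
  if (is.na(x)) "undefined" else sprintf(paste0("%.", digits, "f"), x)
}

report_text_lines <- function(report) {
  lines <- c("GST case-control replication report",
             sprintf("records analyzed: %d", report$n_records))
  d <- report$demographics
  if (!is.null(d)) {
    lines <- c(lines, "", "[demographics]")
    if (!is.null(d$sex_test)) {
      lines <- c(lines, sprintf("sex: %s p = %s", d$sex_test$method,
                                fmt_p(d$sex_test$p_value)))
    }
    if (!is.null(d$age_test)) {
      lines <- c(lines, sprintf("age t-test: p = %s", fmt_p(d$age_test$p_value)))
    }
    if (!is.null(d$smoking_test)) {
      lines <- c(lines, sprintf("smoking: %s p = %s", d$smoking_test$method,
                                fmt_p(d$smoking_test$p_value)))
    }
  }
  for (locus in names(report$single_locus)) {
    b <- report$single_locus[[locus]]
    lines <- c(lines, "", sprintf("[single locus: %s]", locus),
               sprintf("recessive OR %s, %s p = %s", fmt_or(b$recessive$or),
                       b$recessive$test$method, fmt_p(b$recessive$test$p_value)))
    if (!is.null(b$dominant)) {
      lines <- c(lines,
                 sprintf("dominant OR %s, %s p = %s", fmt_or(b$dominant$or),
                         b$dominant$test$method, fmt_p(b$dominant$test$p_value)),
                 sprintf("allele OR %s, %s p = %s", fmt_or(b$allele$or),
                         b$allele$test$method, fmt_p(b$allele$test$p_value)),
                 sprintf("additive OR %s, Wald p = %s", fmt_or(b$additive),
                         fmt_p(b$additive$p_value)),
                 sprintf("HWE p: cases %s, controls %s",
                         fmt_p(b$hwe$case$p_value),
                         fmt_p(b$hwe$control$p_value)))
    }
  }
  for (kind in c("gene_gene", "gene_env")) {
    for (nm in names(report[[kind]])) {
      b <- report[[kind]][[nm]]
      it <- b$interaction
      lines <- c(lines, "", sprintf("[%s: %s]", kind, nm),
                 sprintf("OR11 %s [%s p = %s]", fmt_or(it$or11),
                         b$tests$s11$method, fmt_p(b$tests$s11$p_value)),
                 sprintf("OR10 %s [%s p = %s]", fmt_or(it$or10),
                         b$tests$s10$method, fmt_p(b$tests$s10$p_value)),
                 sprintf("OR01 %s [%s p = %s]", fmt_or(it$or01),
                         b$tests$s01$method, fmt_p(b$tests$s01$p_value)),
                 sprintf("RERI %s  AP %s  SI %s", fmt_num(it$reri, 3),
                         fmt_num(it$ap, 3), fmt_num(it$si, 2)))
      if (any(it$convention_applied)) {
        lines <- c(lines, sprintf("warning: zero-cell convention applied to %s",
                                  paste(names(which(it$convention_applied)),
                                        collapse = ", ")))
      }
    }
  }
  for (nm in names(report$response)) {
    b <- report$response[[nm]]
    lines <- c(lines, "", sprintf("[response: %s]", nm),
               sprintf("counts %s", paste(t(b$counts), collapse = "/")),
               sprintf("%s p = %s", b$test$method, fmt_p(b$test$p_value)))
  }
  if (!is.null(report$survival)) {
    lines <- c(lines, "", "[survival]")
    if (!is.null(report$survival$mmr_logrank)) {
      lr <- report$survival$mmr_logrank
      lines <- c(lines, sprintf("MMR log-rank chi2 %.3f p = %s",
                                lr$statistic, fmt_p(lr$p_value)))
    }
    if (!is.null(report$survival$efs_logrank)) {
      lr <- report$survival$efs_logrank
      lines <- c(lines, sprintf("EFS log-rank chi2 %.3f p = %s",
                                lr$statistic, fmt_p(lr$p_value)))
    }
  }
  lines
}

# strip closures/fits so the structured render is plain data
report_as_data <- function(x) {
  if (inherits(x, "km_curve")) return(as.data.frame(x))
  if (is.function(x)) return(NULL)
  if (inherits(x, "glm")) return(NULL)
  if (is.list(x)) {
    out <- lapply(unclass(x), report_as_data)
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(names(out))) out <- out[order(names(out))]
    return(out)
  }
  x
}

#' Render a report to text or JSON
#'
#' Text rendering uses fixed formatting (ORs, RERI and SI to 2-3 decimals,
#' AP to 3, p-values to 3 or `<0.001`); the JSON rendering keeps full
#' precision with keys sorted, so identical reports render byte-identically
#' and parse back with [jsonlite::fromJSON()].
#'
#' @param report A `replication_report`.
#' @param format `"text"` or `"json"`.
#' @param path Output file; when NULL the rendering is returned invisibly.
#' @return The rendered lines (text) or JSON string, invisibly.
#' @export
render_report <- function(report, format = c("text", "json"), path = NULL) {
  format <- match.arg(format)
  out <- if (format == "text") {
    report_text_lines(report)
  } else {
    jsonlite::toJSON(report_as_data(report), auto_unbox = TRUE, digits = NA,
                     na = "null", pretty = TRUE)
  }
  if (!is.null(path)) {
    writeLines(as.character(out), path)
  }
  invisible(out)
}

#' @export
print.replication_report <- function(x, ...) {
  writeLines(report_text_lines(x))
  invisible(x)
}
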