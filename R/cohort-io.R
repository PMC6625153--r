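#' @keywords internal
"_PACKAGE"

# Schema for subject-level cohort tables. Categorical fields are restricted to
# these tokens (lower case); empty cells and "NA" map to "missing".
cohort_schema <- list(
  group     = c("case", "control"),
  gstm1     = c("present", "null", "missing"),
  gstt1     = c("present", "null", "missing"),
  gstp1     = c("AA", "AG", "GG", "missing"),
  smoking   = c("smoker", "nonsmoker", "missing"),
  sex       = c("male", "female", "missing"),
  mcyr_3m   = c("yes", "no", "missing"),
  ccyr_6m   = c("yes", "no", "missing"),
  bcrabl_3m = c("le10pct", "gt10pct", "missing"),
  bcrabl_6m = c("lt1pct", "ge1pct", "missing"),
  mmr_event = c("yes", "no", "missing"),
  efs_event = c("yes", "no", "missing")
)

cohort_numeric_fields <- c("age", "mmr_time", "efs_time")

cohort_fields <- c("subject_id", "group", "gstm1", "gstt1", "gstp1", "smoking",
                   "sex", "age", "mcyr_3m", "ccyr_6m", "bcrabl_3m", "bcrabl_6m",
                   "mmr_time", "mmr_event", "efs_time", "efs_event")

#' Construct a subject-level cohort table
#'
#' Builds a validated cohort data frame, one row per subject. Only
#' `subject_id` and `group` are required; every other schema field defaults to
#' `"missing"` (categorical) or `NA` (numeric). Extra columns are kept as
#' opaque extras.
#'
#' @param ... Vectors named after schema fields (`subject_id`, `group`,
#'   `gstm1`, `gstt1`, `gstp1`, `smoking`, `sex`, `age`, `mcyr_3m`, `ccyr_6m`,
#'   `bcrabl_3m`, `bcrabl_6m`, `mmr_time`, `mmr_event`, `efs_time`,
#'   `efs_event`) plus any extra columns, recycled to a common length.
#' @return A `gst_cohort` data frame.
#' @examples
#' cohort(subject_id = c("s1", "s2"), group = c("case", "control"),
#'        gstm1 = c("null", "present"))
#' @export
cohort <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(d))) {
    stop("a cohort needs at least 'subject_id' and 'group' columns")
  }
  for (f in setdiff(names(cohort_schema), names(d))) {
    d[[f]] <- rep("missing", nrow(d))
  }
  for (f in setdiff(cohort_numeric_fields, names(d))) {
    d[[f]] <- rep(NA_real_, nrow(d))
  }
  d <- d[, c(cohort_fields, setdiff(names(d), cohort_fields)), drop = FALSE]
  validate_cohort(d)
}

#' Validate a cohort table
#'
#' Checks the subject-level invariants: unique subject ids, categorical fields
#' restricted to their schema tokens, nonnegative ages and times, and event
#' flags implying an event time.
#'
#' @param records A data frame with the cohort schema columns.
#' @return The validated records, classed as `gst_cohort`.
#' @export
validate_cohort <- function(records) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(records$subject_id[duplicated(records$subject_id)]),
               collapse = ", "))
  }
  for (f in names(cohort_schema)) {
    bad <- which(!(records[[f]] %in% cohort_schema[[f]]))
    if (length(bad)) {
      stop(sprintf("row %d, column '%s': unknown category token '%s'",
                   bad[1], f, records[[f]][bad[1]]))
    }
  }
  for (f in cohort_numeric_fields) {
    v <- records[[f]]
    if (!is.numeric(v)) stop("column '", f, "' must be numeric")
    if (any(v < 0, na.rm = TRUE)) stop("column '", f, "' has negative values")
  }
  if (any(records$mmr_event == "yes" & is.na(records$mmr_time))) {
    stop("mmr_event = yes requires mmr_time")
  }
  if (any(records$efs_event == "yes" & is.na(records$efs_time))) {
    stop("efs_event = yes requires efs_time")
  }
  class(records) <- unique(c("gst_cohort", class(records)))
  records
}

#' Read a cohort file
#'
#' Reads a delimited subject-level cohort table (comma by default, any single
#' separator accepted). The header must name at least `subject_id` and
#' `group`; schema columns absent from the file are filled with the missing
#' category, unknown columns are preserved. Empty cells and `NA` map to
#' missing. Category tokens outside the schema raise an error naming the row,
#' column and token.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field separator, `","` by default (use `"\t"` for TSV).
#' @return A `gst_cohort` data frame; the number of data rows read is
#'   available as `attr(x, "n_rows")`.
#' @seealso [write_cohort()], [cohort()]
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         colClasses = "character", na.strings = character(),
                         check.names = FALSE, quote = "\"",
                         stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(d))) {
    stop("cohort header must include 'subject_id' and 'group'")
  }
  if (nrow(d) == 0) {
    warning("cohort file '", basename(path), "' has a header but no records")
  }
  for (f in names(cohort_schema)) {
    if (!f %in% names(d)) d[[f]] <- rep("missing", nrow(d))
    v <- trimws(d[[f]])
    v[v == "" | v == "NA"] <- "missing"
    d[[f]] <- v
  }
  for (f in cohort_numeric_fields) {
    if (!f %in% names(d)) { d[[f]] <- rep(NA_real_, nrow(d)); next }
    v <- trimws(d[[f]])
    v[v == "" | v == "NA"] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop(sprintf("row %d, column '%s': unknown numeric token '%s'",
                   bad[1], f, v[bad[1]]))
    }
    d[[f]] <- num
  }
  d <- d[, c(cohort_fields, setdiff(names(d), cohort_fields)), drop = FALSE]
  out <- validate_cohort(d)
  attr(out, "n_rows") <- nrow(out)
  out
}

#' Write a cohort file
#'
#' Writes a cohort table in the delimited format read by [read_cohort()].
#' Missing categories and `NA` times are written as empty cells, so a
#' write/read round trip reproduces the records field for field.
#'
#' @param records A `gst_cohort` data frame.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, sep = ",") {
  d <- as.data.frame(records)
  for (f in names(cohort_schema)) d[[f]][d[[f]] == "missing"] <- ""
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Build an exposure/outcome predicate from field levels
#'
#' Returns a predicate function mapping a cohort table to a logical vector:
#' `TRUE` when the field is in `levels`, `FALSE` for any other non-missing
#' level, `NA` when missing. Predicates feed [aggregate_2x2()] and
#' [joint_strata()], which exclude `NA` rows complete-case.
#'
#' @param field A schema field name, e.g. `"gstm1"`.
#' @param levels Character vector of levels counted as exposed, e.g. `"null"`
#'   or `c("AG", "GG")`.
#' @return A function of a cohort data frame returning a logical vector.
#' @examples
#' gstm1_null <- exposure_is("gstm1", "null")
#' variant_carrier <- exposure_is("gstp1", c("AG", "GG"))
#' @export
exposure_is <- function(field, levels) {
  stopifnot(field %in% names(cohort_schema))
  force(levels)
  function(records) {
    v <- records[[field]]
    ifelse(v == "missing", NA, v %in% levels)
  }
}

#' Aggregate records into a labeled 2x2 table
#'
#' Cross-classifies subjects by an exposure predicate and an outcome predicate
#' (case status by default) into the 2x2 count table that underlies every
#' odds-ratio and contingency test. Records for which either predicate is
#' missing are excluded complete-case; the exclusion count is recorded.
#'
#' @param records A `gst_cohort` data frame.
#' @param exposure Predicate function (see [exposure_is()]).
#' @param outcome Predicate function; defaults to `group == "case"`.
#' @param exposure_label,outcome_label Labels carried on the table.
#' @return A [two_by_two()] object with cells `a` (exposed cases), `b`
#'   (exposed controls), `c` (unexposed cases), `d` (unexposed controls) and
#'   attribute `n_excluded`.
#' @export
aggregate_2x2 <- function(records, exposure,
                          outcome = exposure_is("group", "case"),
                          exposure_label = "exposed", outcome_label = "case") {
  e <- exposure(records)
  o <- outcome(records)
  keep <- !is.na(e) & !is.na(o)
  tab <- two_by_two(a = sum(e[keep] & o[keep]),
                    b = sum(e[keep] & !o[keep]),
                    c = sum(!e[keep] & o[keep]),
                    d = sum(!e[keep] & !o[keep]),
                    exposure_label = exposure_label,
                    outcome_label = outcome_label)
  tab$n_excluded <- sum(!keep)
  tab
}

#' Labeled 2x2 count table
#'
#' @param a,b,c,d Nonnegative integer counts: exposed cases, exposed controls,
#'   unexposed cases, unexposed controls.
#' @param exposure_label,outcome_label Labels for display.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d, exposure_label = "exposed",
                       outcome_label = "case") {
  a <- unname(a); b <- unname(b); c <- unname(c); d <- unname(d)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("2x2 cells must be nonnegative integers")
  }
  structure(list(a = a, b = b, c = c, d = d, n_excluded = 0L,
                 exposure_label = exposure_label,
                 outcome_label = outcome_label),
            class = "two_by_two")
}

#' @export
as.matrix.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
              dimnames = list(exposure = c("exposed", "unexposed"),
                              outcome = c(x$outcome_label, "other")))
  m
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("2x2 table: %s x %s (excluded %d)\n",
              x$exposure_label, x$outcome_label, x$n_excluded))
  print(as.matrix(x))
  invisible(x)
}

#' Per-locus genotype counts by group
#'
#' Tabulates genotype class counts for one locus in cases and controls.
#' GSTM1/GSTT1 use classes present/null (the deletion assay cannot separate
#' heterozygotes from homozygous present); GSTP1 uses AA/AG/GG. Missing
#' genotypes are excluded and counted separately.
#'
#' @param records A `gst_cohort` data frame.
#' @param locus One of `"gstm1"`, `"gstt1"`, `"gstp1"`.
#' @return A `genotype_counts` object: count matrix (rows case/control,
#'   columns genotype classes), per-group missing counts, and the locus name.
#' @export
genotype_counts <- function(records, locus = c("gstm1", "gstt1", "gstp1")) {
  locus <- match.arg(locus)
  classes <- setdiff(cohort_schema[[locus]], "missing")
  g <- records[[locus]]
  grp <- records$group
  counts <- sapply(classes, function(cl) {
    c(case = sum(grp == "case" & g == cl),
      control = sum(grp == "control" & g == cl))
  })
  counts <- matrix(counts, nrow = 2,
                   dimnames = list(group = c("case", "control"),
                                   genotype = classes))
  missing <- c(case = sum(grp == "case" & g == "missing"),
               control = sum(grp == "control" & g == "missing"))
  structure(list(locus = locus, classes = classes, counts = counts,
                 missing = missing),
            class = "genotype_counts")
}

#' Manually specified genotype counts
#'
#' Builds the same object as [genotype_counts()] from raw per-class counts,
#' for use with published marginal tables.
#'
#' @param locus Locus name.
#' @param cases,controls Named or ordered count vectors, one entry per class.
#' @param classes Genotype class labels.
#' @return A `genotype_counts` object.
#' @examples
#' genotype_count_table("gstp1", cases = c(54, 38, 12),
#'                      controls = c(66, 33, 5), classes = c("AA", "AG", "GG"))
#' @export
genotype_count_table <- function(locus, cases, controls, classes) {
  stopifnot(length(cases) == length(classes),
            length(controls) == length(classes),
            all(c(cases, controls) >= 0))
  counts <- rbind(case = cases, control = controls)
  colnames(counts) <- classes
  names(dimnames(counts)) <- c("group", "genotype")
  structure(list(locus = locus, classes = classes, counts = counts,
                 missing = c(case = 0L, control = 0L)),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("Genotype counts for %s (missing: case %d, control %d)\n",
              x$locus, x$missing["case"], x$missing["control"]))
  print(x$counts)
  invisible(x)
}

#' Demographic summary of a cohort
#'
#' Group sizes, sex and smoking counts per group, and age mean/SD per group
#' (missing tracked separately), mirroring the usual first table of a
#' case-control report.
#'
#' @param records A `gst_cohort` data frame.
#' @return A list of class `cohort_summary`.
#' @export
cohort_summary <- function(records) {
  grp <- records$group
  by_group <- function(f, lv) {
    sapply(c("case", "control"), function(g) sum(grp == g & records[[f]] == lv))
  }
  age_stats <- lapply(c(case = "case", control = "control"), function(g) {
    a <- records$age[grp == g]
    list(mean = mean(a, na.rm = TRUE), sd = stats::sd(a, na.rm = TRUE),
         n_missing = sum(is.na(a)))
  })
  structure(list(
    n_cases = sum(grp == "case"), n_controls = sum(grp == "control"),
    sex = list(male = by_group("sex", "male"),
               female = by_group("sex", "female"),
               missing = by_group("sex", "missing")),
    smoking = list(smoker = by_group("smoking", "smoker"),
                   nonsmoker = by_group("smoking", "nonsmoker"),
                   missing = by_group("smoking", "missing")),
    age = age_stats), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d cases, %d controls\n", x$n_cases, x$n_controls))
  cat(sprintf("  males %d/%d, smokers %d/%d (case/control)\n",
              x$sex$male["case"], x$sex$male["control"],
              x$smoking$smoker["case"], x$smoking$smoker["control"]))
  cat(sprintf("  age: case %.1f +/- %.1f, control %.1f +/- %.1f\n",
              x$age$case$mean, x$age$case$sd,
              x$age$control$mean, x$age$control$sd))
  invisible(x)
}
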