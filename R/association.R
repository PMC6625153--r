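#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio `OR = ad/(bc)` from a 2x2 table with the Woolf
#' (log-normal) confidence interval, `exp(log OR +/- z * SE)` where
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. A table with any zero cell is flagged
#' inestimable: the raw cross-product (0, `Inf`, or `NaN` for 0/0) is
#' recorded but no interval is produced.
#'
#' @param table A [two_by_two()] object.
#' @param alpha Two-sided level for the interval (default 0.05).
#' @return An object of class `odds_ratio`: `or_estimate`, `log_or`,
#'   `se_log_or`, `ci_low`, `ci_high`, `alpha`, `estimable`, `zero_cell`.
#' @examples
#' odds_ratio(two_by_two(34, 53, 70, 51))  # GSTM1 present vs null, OR 0.467
#' @export
odds_ratio <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "two_by_two"), alpha > 0, alpha < 1)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  zero <- any(c(a, b, c, d) == 0)
  raw <- (a * d) / (b * c)  # 0, Inf or NaN when a cell is zero
  if (zero) {
    res <- list(or_estimate = raw, log_or = NA_real_, se_log_or = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, alpha = alpha,
                estimable = FALSE, zero_cell = TRUE)
  } else {
    lo <- log(raw)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    z <- stats::qnorm(1 - alpha / 2)
    res <- list(or_estimate = raw, log_or = lo, se_log_or = se,
                ci_low = exp(lo - z * se), ci_high = exp(lo + z * se),
                alpha = alpha, estimable = TRUE, zero_cell = FALSE)
  }
  res$table <- table
  structure(res, class = "odds_ratio")
}

#' @export
print.odds_ratio <- function(x, ...) {
  if (x$estimable) {
    cat(sprintf("OR %.3f (%.0f%% CI %.3f-%.3f)\n", x$or_estimate,
                100 * (1 - x$alpha), x$ci_low, x$ci_high))
  } else {
    cat(sprintf("OR inestimable (zero cell; raw cross-product %s)\n",
                format(x$or_estimate)))
  }
  invisible(x)
}

as_count_matrix <- function(x) {
  if (inherits(x, "two_by_two")) as.matrix(x)
  else if (is.matrix(x)) x
  else stop("expected a two_by_two table or a count matrix")
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square on an r x c count table, without continuity correction,
#' with `df = (r-1)(c-1)`.
#'
#' @param table A [two_by_two()] object or a count matrix.
#' @return A `chi_square_test`: `statistic`, `df`, `p_value`,
#'   `method = "pearson"`.
#' @export
pearson_chi2 <- function(table) {
  m <- as_count_matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate margin: a row or column of the table is all zero")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), method = "pearson"),
            class = "chi_square_test")
}

#' Fisher exact test (two-sided)
#'
#' Two-sided exact test on a 2x2 table by the probability-mass rule: the sum
#' of hypergeometric probabilities, over tables with the observed margins, no
#' larger than that of the observed table.
#'
#' @param table A [two_by_two()] object or 2x2 count matrix.
#' @return A `chi_square_test` with `p_value` and `method = "fisher"`
#'   (no statistic).
#' @export
fisher_exact <- function(table) {
  m <- as_count_matrix(table)
  p <- stats::fisher.test(m)$p.value
  structure(list(statistic = NA_real_, df = 1L, p_value = min(p, 1),
                 method = "fisher"), class = "chi_square_test")
}

#' Contingency test with small-cell fallback
#'
#' The package's decision rule for 2x2 tables: Pearson chi-square without
#' continuity correction, replaced by the Fisher exact test when any cell is
#' zero or any expected count falls below `expected_threshold`.
#'
#' @param table A [two_by_two()] object or 2x2 count matrix.
#' @param expected_threshold Minimum expected count for the chi-square path
#'   (default 5).
#' @return A `chi_square_test`; `method` records which test ran.
#' @export
assoc_test <- function(table, expected_threshold = 5) {
  m <- as_count_matrix(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(m == 0) || any(expected < expected_threshold)) fisher_exact(m)
  else pearson_chi2(m)
}

#' @export
print.chi_square_test <- function(x, ...) {
  if (is.na(x$statistic)) {
    cat(sprintf("%s test: p = %.4g\n", x$method, x$p_value))
  } else {
    cat(sprintf("%s test: chi2 = %.4g, df = %d, p = %.4g\n",
                x$method, x$statistic, x$df, x$p_value))
  }
  invisible(x)
}

#' Two-sample t-test from summary statistics
#'
#' Welch two-sided t-test computed from group means, standard deviations and
#' sizes only, for comparing published summary rows (e.g. mean age of cases
#' vs controls) without subject-level data.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A list: `statistic` (t), `df` (Welch-Satterthwaite), `p_value`.
#' @examples
#' t_test_summary(43.8, 15.1, 104, 44.99, 15.57, 104)$p_value  # ~0.58
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Hardy-Weinberg goodness-of-fit test
#'
#' Chi-square goodness-of-fit comparing observed AA/AG/GG counts with the
#' expectations `p^2 N`, `2p(1-p) N`, `(1-p)^2 N` under the allele-frequency
#' MLE `p = (2 n_AA + n_AG) / 2N`, on 1 degree of freedom. A monomorphic
#' sample (`p` of 0 or 1) is flagged degenerate with p-value 1.
#'
#' @param counts Either a numeric vector of three genotype counts in the
#'   order hom-reference, het, hom-variant, or a `genotype_counts` object for
#'   a three-class locus together with `group`.
#' @param group When `counts` is a `genotype_counts` object: `"case"` or
#'   `"control"`.
#' @return An `hwe_test`: `allele_freq` (reference allele), `expected`,
#'   `chi2`, `df`, `p_value`, `degenerate`.
#' @examples
#' hwe_test(c(66, 33, 5))$p_value  # GSTP1 controls, ~0.74
#' @export
hwe_test <- function(counts, group = NULL) {
  if (inherits(counts, "genotype_counts")) {
    stopifnot(length(counts$classes) == 3, !is.null(group))
    counts <- counts$counts[group, ]
  }
  stopifnot(length(counts) == 3, all(counts >= 0), sum(counts) > 0)
  n <- sum(counts)
  p <- (2 * counts[[1]] + counts[[2]]) / (2 * n)
  if (p == 0 || p == 1) {
    return(structure(list(allele_freq = p, expected = counts, chi2 = 0,
                          df = 1L, p_value = 1, degenerate = TRUE),
                     class = "hwe_test"))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  structure(list(allele_freq = p, expected = expected, chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 degenerate = FALSE),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("HWE GOF: allele freq %.3f, chi2 = %.3f, df = 1, p = %.3f\n",
              x$allele_freq, x$chi2, x$p_value))
  invisible(x)
}

#' Collapse genotype counts under a genetic model
#'
#' Builds the 2x2 table for a recessive or dominant penetrance model. For a
#' three-class locus (GSTP1), recessive collapses hom-variant (GG) against
#' AA+AG and dominant collapses variant carriers (AG+GG, the M* group)
#' against AA. For the two-class deletion loci the null genotype (homozygous
#' deletion) plays the hom-variant role, so both models reduce to null vs
#' present. `exposure_orientation` chooses which collapsed category sits in
#' the exposed row; the additive model is fitted by [per_allele_logistic()]
#' and rejected here.
#'
#' @param counts A `genotype_counts` object.
#' @param model `"recessive"` or `"dominant"`.
#' @param exposure_orientation `"wildtype_as_exposure"` (default; reproduces
#'   the protective-direction ORs of single-locus tables) or
#'   `"variant_as_exposure"`.
#' @return A [two_by_two()] object.
#' @export
genetic_model_table <- function(counts,
                                model = c("recessive", "dominant"),
                                exposure_orientation = c("wildtype_as_exposure",
                                                         "variant_as_exposure")) {
  if (identical(model, "additive")) {
    stop("the additive model is a per-allele logistic fit; ",
         "use per_allele_logistic()")
  }
  model <- match.arg(model)
  exposure_orientation <- match.arg(exposure_orientation)
  m <- counts$counts
  if (length(counts$classes) == 2) {
    # deletion locus: present / null
    variant <- m[, "null"]; rest <- m[, "present"]
    label <- paste(counts$locus, "null")
  } else {
    if (model == "recessive") {
      variant <- m[, "GG"]; rest <- m[, "AA"] + m[, "AG"]
      label <- paste(counts$locus, "GG")
    } else {
      variant <- m[, "AG"] + m[, "GG"]; rest <- m[, "AA"]
      label <- paste(counts$locus, "AG/GG")
    }
  }
  if (exposure_orientation == "variant_as_exposure") {
    two_by_two(variant["case"], variant["control"], rest["case"],
               rest["control"], exposure_label = label)
  } else {
    two_by_two(rest["case"], rest["control"], variant["case"],
               variant["control"],
               exposure_label = paste("not", label))
  }
}

#' Allele count table for a SNP locus
#'
#' Collapses AA/AG/GG genotype counts to per-allele counts (two alleles per
#' subject): reference allele count `2 n_AA + n_AG`, variant
#' `2 n_GG + n_AG`, per group.
#'
#' @param counts A `genotype_counts` object with three classes.
#' @return A [two_by_two()] with the reference allele as exposure.
#' @export
allele_table <- function(counts) {
  stopifnot(length(counts$classes) == 3)
  m <- counts$counts
  refA <- 2 * m[, "AA"] + m[, "AG"]
  varG <- 2 * m[, "GG"] + m[, "AG"]
  two_by_two(refA["case"], refA["control"], varG["case"], varG["control"],
             exposure_label = paste(counts$locus, "A allele"))
}

#' Per-allele (additive model) logistic regression
#'
#' Maximum-likelihood logistic regression of case status on risk-allele
#' dosage (0/1/2) fitted to the grouped genotype counts; the grouped binomial
#' fit has the same MLE as the expanded subject-level fit. Returns the
#' per-allele odds ratio `exp(beta)` with its Wald confidence interval and
#' p-value. Perfect separation (an empty case or control margin, or a
#' diverging estimate) is flagged inestimable.
#'
#' @param counts A `genotype_counts` object with classes AA/AG/GG.
#' @param risk_allele Which allele carries the dosage (default `"G"`, so
#'   AA/AG/GG score 0/1/2).
#' @param alpha Level for the Wald interval.
#' @return An object of classes `per_allele_fit` and `odds_ratio`:
#'   `or_estimate = exp(beta)`, `log_or`, `se_log_or`, `ci_low`, `ci_high`,
#'   `p_value` (Wald), `estimable`, `converged`.
#' @examples
#' gc <- genotype_count_table("gstp1", c(54, 38, 12), c(66, 33, 5),
#'                            c("AA", "AG", "GG"))
#' per_allele_logistic(gc)  # OR 1.569 (1.016-2.423)
#' @export
per_allele_logistic <- function(counts, risk_allele = c("G", "A"),
                                alpha = 0.05) {
  stopifnot(length(counts$classes) == 3)
  risk_allele <- match.arg(risk_allele)
  dose <- if (risk_allele == "G") 0:2 else 2:0
  cases <- counts$counts["case", ]
  controls <- counts$counts["control", ]
  fit <- stats::glm(cbind(cases, controls) ~ dose, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  beta <- stats::coef(fit)[["dose"]]
  se <- sqrt(stats::vcov(fit)["dose", "dose"])
  separated <- !fit$converged || abs(beta) > 15 || se > 100
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(
    or_estimate = exp(beta), log_or = beta, se_log_or = se,
    ci_low = if (separated) NA_real_ else exp(beta - z * se),
    ci_high = if (separated) NA_real_ else exp(beta + z * se),
    p_value = if (separated) NA_real_ else 2 * stats::pnorm(-abs(beta / se)),
    alpha = alpha, estimable = !separated, converged = fit$converged,
    zero_cell = FALSE, risk_allele = risk_allele),
    class = c("per_allele_fit", "odds_ratio"))
}
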