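#' Joint two-factor stratification of a case-control cohort
#'
#' Cross-classifies subjects by two binary exposure predicates and case
#' status into the eight cells feeding additive-interaction analysis. Rows
#' missing either factor or group are excluded complete-case. The doubly
#' unexposed stratum (0,0) is the reference.
#'
#' @param records A `gst_cohort` data frame.
#' @param factor1,factor2 Predicate functions (see [exposure_is()]).
#' @param factor1_label,factor2_label Labels for reporting.
#' @return A `joint_strata` object: a `2 x 2 x 2` count array indexed by
#'   factor1 (exposed/unexposed), factor2 (exposed/unexposed) and group
#'   (case/control), plus `n_excluded`.
#' @export
joint_strata <- function(records, factor1, factor2,
                         factor1_label = "factor1",
                         factor2_label = "factor2") {
  f1 <- factor1(records)
  f2 <- factor2(records)
  case <- ifelse(records$group == "missing", NA, records$group == "case")
  keep <- !is.na(f1) & !is.na(f2) & !is.na(case)
  cells <- array(0L, dim = c(2, 2, 2),
                 dimnames = list(factor1 = c("exposed", "unexposed"),
                                 factor2 = c("exposed", "unexposed"),
                                 group = c("case", "control")))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    cells[i, j, k] <- sum(keep & (f1 == (i == 1)) & (f2 == (j == 1)) &
                            (case == (k == 1)))
  }
  structure(list(cells = cells, factor1_label = factor1_label,
                 factor2_label = factor2_label,
                 n_excluded = sum(!keep)),
            class = "joint_strata")
}

#' Joint strata from published counts
#'
#' Builds a [joint_strata()] object directly from the eight cell counts of a
#' published two-factor table, in the fixed stratum order (1,1), (1,0),
#' (0,1), (0,0), each as `c(cases, controls)`.
#'
#' @param s11,s10,s01,s00 Length-2 vectors `c(cases, controls)` for the four
#'   exposure strata; `s00` is the doubly unexposed reference.
#' @param factor1_label,factor2_label Labels.
#' @return A `joint_strata` object.
#' @export
joint_strata_counts <- function(s11, s10, s01, s00,
                                factor1_label = "factor1",
                                factor2_label = "factor2") {
  cells <- array(0L, dim = c(2, 2, 2),
                 dimnames = list(factor1 = c("exposed", "unexposed"),
                                 factor2 = c("exposed", "unexposed"),
                                 group = c("case", "control")))
  cells["exposed", "exposed", ] <- s11
  cells["exposed", "unexposed", ] <- s10
  cells["unexposed", "exposed", ] <- s01
  cells["unexposed", "unexposed", ] <- s00
  structure(list(cells = cells, factor1_label = factor1_label,
                 factor2_label = factor2_label, n_excluded = 0L),
            class = "joint_strata")
}

#' @export
print.joint_strata <- function(x, ...) {
  cat(sprintf("Joint strata: %s x %s (excluded %d)\n",
              x$factor1_label, x$factor2_label, x$n_excluded))
  m <- rbind(`(1,1)` = x$cells["exposed", "exposed", ],
             `(1,0)` = x$cells["exposed", "unexposed", ],
             `(0,1)` = x$cells["unexposed", "exposed", ],
             `(0,0) ref` = x$cells["unexposed", "unexposed", ])
  print(m)
  invisible(x)
}

#' Stratum odds ratios against the doubly unexposed reference
#'
#' Computes OR11, OR10 and OR01: the odds of disease in each exposed stratum
#' relative to the (0,0) reference stratum (whose OR is 1 by construction),
#' each by [odds_ratio()] with a Woolf interval. Zero-cell strata are
#' returned flagged inestimable.
#'
#' @param table A `joint_strata` object.
#' @param alpha Level for the Woolf intervals.
#' @return A list with `odds_ratio` elements `or11`, `or10`, `or01`, in the
#'   fixed stratum order (1,1), (1,0), (0,1).
#' @export
stratum_odds_ratios <- function(table, alpha = 0.05) {
  ref <- table$cells["unexposed", "unexposed", ]
  one <- function(i, j, lab) {
    s <- table$cells[i, j, ]
    odds_ratio(two_by_two(s["case"], s["control"], ref["case"], ref["control"],
                          exposure_label = lab), alpha = alpha)
  }
  list(or11 = one("exposed", "exposed", "both exposed"),
       or10 = one("exposed", "unexposed", paste(table$factor1_label, "only")),
       or01 = one("unexposed", "exposed", paste(table$factor2_label, "only")))
}

# Value a stratum OR contributes to the additive-interaction formulas:
# the unrounded estimate when estimable, 0 under the zero-cell convention.
convention_value <- function(or) {
  if (isTRUE(or$estimable)) or$or_estimate else 0
}

#' Additive-scale interaction: RERI, AP and SI
#'
#' Measures departure from additivity of odds ratios for two joint
#' exposures: the relative excess risk due to interaction
#' `RERI = OR11 - OR10 - OR01 + 1`, the attributable proportion due to
#' interaction `AP = RERI / OR11`, and the synergy index
#' `SI = (OR11 - 1) / ((OR10 - 1) + (OR01 - 1))`, all from unrounded stratum
#' estimates.
#'
#' Any stratum OR rendered zero or inestimable by a zero cell contributes the
#' value 0 to the formulas; the affected strata are flagged in
#' `convention_applied` and the choice is deliberately loud because it is
#' statistically aggressive (see the package vignette). `AP` is undefined
#' (NA) when OR11 is inestimable; `SI` is undefined when its denominator is
#' zero.
#'
#' @param or11,or10,or01 `odds_ratio` results for the (1,1), (1,0) and (0,1)
#'   strata (e.g. from [stratum_odds_ratios()]). Alternatively `or11` may be
#'   a `joint_strata` object, in which case the stratum ORs are computed
#'   internally.
#' @param alpha Level used when `or11` is a `joint_strata` object.
#' @return An `additive_interaction` object: `or11`, `or10`, `or01`, `reri`,
#'   `ap`, `si`, `convention_applied` (named logical vector).
#' @examples
#' st <- stratum_odds_ratios(joint_strata_counts(
#'   c(38, 14), c(32, 37), c(19, 17), c(15, 36)))
#' additive_interaction(st$or11, st$or10, st$or01)  # RERI 2.756
#' @export
additive_interaction <- function(or11, or10 = NULL, or01 = NULL,
                                 alpha = 0.05) {
  if (inherits(or11, "joint_strata")) {
    st <- stratum_odds_ratios(or11, alpha = alpha)
    or11 <- st$or11; or10 <- st$or10; or01 <- st$or01
  }
  stopifnot(inherits(or11, "odds_ratio"), inherits(or10, "odds_ratio"),
            inherits(or01, "odds_ratio"))
  v11 <- convention_value(or11)
  v10 <- convention_value(or10)
  v01 <- convention_value(or01)
  reri <- v11 - v10 - v01 + 1
  ap <- if (or11$estimable) reri / v11 else NA_real_
  denom <- (v10 - 1) + (v01 - 1)
  si <- if (denom == 0) NA_real_ else (v11 - 1) / denom
  structure(list(or11 = or11, or10 = or10, or01 = or01,
                 reri = reri, ap = ap, si = si,
                 convention_applied = c(or11 = !or11$estimable,
                                        or10 = !or10$estimable,
                                        or01 = !or01$estimable)),
            class = "additive_interaction")
}

#' @export
print.additive_interaction <- function(x, ...) {
  fmt_or <- function(o) {
    if (o$estimable) sprintf("%.2f", o$or_estimate) else "-- (zero cell -> 0)"
  }
  cat(sprintf("OR11 %s, OR10 %s, OR01 %s (OR00 = 1 ref)\n",
              fmt_or(x$or11), fmt_or(x$or10), fmt_or(x$or01)))
  cat(sprintf("RERI %.3f, AP %s, SI %s\n", x$reri,
              if (is.na(x$ap)) "undefined" else sprintf("%.3f", x$ap),
              if (is.na(x$si)) "undefined" else sprintf("%.2f", x$si)))
  if (any(x$convention_applied)) {
    cat("note: zero-cell convention applied to",
        paste(names(which(x$convention_applied)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full interaction analysis of two factors
#'
#' Convenience wrapper: [joint_strata()], [stratum_odds_ratios()] and
#' [additive_interaction()] in one call.
#'
#' @inheritParams joint_strata
#' @param alpha Level for the Woolf intervals.
#' @return An `additive_interaction` object with the `joint_strata` table
#'   attached as `$strata`.
#' @export
interaction_analysis <- function(records, factor1, factor2,
                                 factor1_label = "factor1",
                                 factor2_label = "factor2", alpha = 0.05) {
  js <- joint_strata(records, factor1, factor2, factor1_label, factor2_label)
  res <- additive_interaction(js, alpha = alpha)
  res$strata <- js
  res
}

#' Percentile bootstrap intervals for RERI, AP and SI
#'
#' Resamples subjects with replacement within the case and control groups
#' separately (preserving the case-control design), recomputes the additive
#' interaction measures on each resample under the same zero-cell
#' convention, and returns percentile intervals. The convention breaks the
#' smoothness that a delta-method interval would need, which is why the
#' bootstrap is used.
#'
#' @inheritParams joint_strata
#' @param n_boot Number of resamples, at least 100.
#' @param seed Integer seed; fixed seed gives identical intervals.
#' @param alpha Level: `1 - alpha` percentile intervals.
#' @return A list of class `interaction_bootstrap`: `point` (the
#'   full-sample `additive_interaction`), `ci` (matrix with rows reri/ap/si),
#'   `n_boot`, `n_degenerate` (resamples where the convention fired or a
#'   measure was undefined, counted per measure as NA-dropped), `seed`.
#' @export
interaction_ci_bootstrap <- function(records, factor1, factor2,
                                     n_boot = 1000, seed = NULL,
                                     alpha = 0.05) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  point <- interaction_analysis(records, factor1, factor2)
  idx_case <- which(records$group == "case")
  idx_ctrl <- which(records$group == "control")
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 3,
                  dimnames = list(NULL, c("reri", "ap", "si")))
  n_degenerate <- 0L
  for (b in seq_len(n_boot)) {
    rows <- c(sample(idx_case, replace = TRUE),
              sample(idx_ctrl, replace = TRUE))
    res <- interaction_analysis(records[rows, , drop = FALSE],
                                factor1, factor2)
    if (any(res$convention_applied)) n_degenerate <- n_degenerate + 1L
    draws[b, ] <- c(res$reri, res$ap, res$si)
  }
  probs <- c(alpha / 2, 1 - alpha / 2)
  ci <- t(apply(draws, 2, stats::quantile, probs = probs, na.rm = TRUE))
  structure(list(point = point, ci = ci, draws = draws, n_boot = n_boot,
                 n_degenerate = n_degenerate, seed = seed, alpha = alpha),
            class = "interaction_bootstrap")
}

#' @export
print.interaction_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap (%d resamples, %d with zero-cell convention):\n",
              x$n_boot, x$n_degenerate))
  cat(sprintf("  RERI %.3f (%.3f, %.3f)\n", x$point$reri,
              x$ci["reri", 1], x$ci["reri", 2]))
  if (!is.na(x$point$ap)) {
    cat(sprintf("  AP   %.3f (%.3f, %.3f)\n", x$point$ap,
                x$ci["ap", 1], x$ci["ap", 2]))
  }
  if (!is.na(x$point$si)) {
    cat(sprintf("  SI   %.3f (%.3f, %.3f)\n", x$point$si,
                x$ci["si", 1], x$ci["si", 2]))
  }
  invisible(x)
}
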