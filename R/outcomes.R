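endpoint_responder_level <- c(mcyr_3m = "yes", ccyr_6m = "yes",
                              bcrabl_3m = "le10pct", bcrabl_6m = "lt1pct")

#' Response table by genotype grouping
#'
#' Cross-tabulates an ELN-style binary response endpoint against a genotype
#' grouping among case records only: GSTM1 null vs present, or GSTP1 AA vs
#' AG/GG. Cases with the endpoint missing are excluded and counted; the
#' contingency test follows the package decision rule ([assoc_test()]).
#'
#' @param records A `gst_cohort` data frame (controls are ignored).
#' @param grouping `"gstm1"` (rows null, present) or `"gstp1"` (rows AA,
#'   AG/GG).
#' @param endpoint One of `"mcyr_3m"`, `"ccyr_6m"`, `"bcrabl_3m"`,
#'   `"bcrabl_6m"`. Responders are `yes`, `yes`, `le10pct`, `lt1pct`
#'   respectively.
#' @param expected_threshold Passed to [assoc_test()].
#' @return A `response_table`: `counts` (2x2, rows genotype groups, columns
#'   responder/non-responder), `test`, `n_excluded`, labels.
#' @export
response_table <- function(records, grouping = c("gstm1", "gstp1"),
                           endpoint = names(endpoint_responder_level),
                           expected_threshold = 5) {
  grouping <- match.arg(grouping)
  endpoint <- match.arg(endpoint)
  d <- records[records$group == "case", , drop = FALSE]
  resp <- d[[endpoint]]
  if (all(resp == "missing")) {
    stop("endpoint '", endpoint, "' is entirely missing among cases")
  }
  if (grouping == "gstm1") {
    glev <- d$gstm1
    rows <- c("null", "present")
  } else {
    glev <- ifelse(d$gstp1 %in% c("AG", "GG"), "AG/GG", d$gstp1)
    rows <- c("AA", "AG/GG")
  }
  keep <- resp != "missing" & glev != "missing"
  yes <- endpoint_responder_level[[endpoint]]
  counts <- t(sapply(rows, function(r) {
    c(responder = sum(keep & glev == r & resp == yes),
      non_responder = sum(keep & glev == r & resp != yes))
  }))
  structure(list(grouping = grouping, endpoint = endpoint, counts = counts,
                 test = assoc_test(counts, expected_threshold),
                 n_excluded = sum(!keep)),
            class = "response_table")
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("Response %s by %s (excluded %d):\n",
              x$endpoint, x$grouping, x$n_excluded))
  print(x$counts)
  print(x$test)
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival estimate `S(t) = prod(1 - d_i / n_i)` over event
#' times up to `t`, with events at a tied time processed before censorings at
#' the same time. Greenwood standard errors and log-transformed confidence
#' bands are carried along from the underlying [survival::survfit()] fit.
#'
#' @param times Nonnegative times in months.
#' @param events Logical (or 0/1) event indicators; `FALSE` is censoring.
#' @param conf_level Level for the Greenwood log-scale band.
#' @return A `km_curve`: `time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   `lower`, `upper`, `n_events`, `n_censored`, `n`.
#' @export
km_estimate <- function(times, events, conf_level = 0.95) {
  if (length(times) == 0) stop("no observations")
  stopifnot(length(times) == length(events), all(times >= 0), !anyNA(times),
            !anyNA(events))
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log", conf.int = conf_level)
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, surv = fit$surv,
                 lower = fit$lower, upper = fit$upper,
                 n_events = sum(events), n_censored = sum(!events),
                 n = length(times)),
            class = "km_curve")
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, n_at_risk = x$n_risk, survival = x$surv,
             events = x$n_event, censored = x$n_censor,
             lower = x$lower, upper = x$upper)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, censored = %d\n",
              x$n, x$n_events, x$n_censored))
  print(utils::head(as.data.frame(x), 10))
  if (length(x$time) > 10) cat("...\n")
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank chi-square on 1 degree of freedom comparing
#' two survival curves, from observed-minus-expected event counts over the
#' pooled event times.
#'
#' @param groups Group labels; exactly two distinct values, each nonempty.
#' @param times Nonnegative times in months.
#' @param events Logical event indicators.
#' @return A `logrank_test`: `statistic`, `df`, `p_value`, `observed` and
#'   `expected` event counts per group.
#' @export
logrank_test <- function(groups, times, events) {
  stopifnot(length(groups) == length(times), length(times) == length(events))
  groups <- as.character(groups)
  if (length(unique(groups)) != 2) {
    stop("logrank_test needs exactly two nonempty groups")
  }
  sd <- survival::survdiff(
    survival::Surv(times, as.logical(events)) ~ groups)
  structure(list(statistic = unname(sd$chisq), df = 1L,
                 p_value = stats::pchisq(sd$chisq, 1, lower.tail = FALSE),
                 observed = sd$obs, expected = sd$exp,
                 method = "logrank"),
            class = c("logrank_test", "chi_square_test"))
}

#' Extract event-free survival observations
#'
#' Validates and extracts (time, event) pairs for the composite EFS endpoint
#' (loss of response, progression to accelerated/blast phase, or death) from
#' case records. The composite event is consumed pre-coded — deriving it
#' would require visit-level response schedules the cohort format does not
#' carry. Records with the event flag missing are dropped; an event flag
#' without a time is an error.
#'
#' @param records A `gst_cohort` data frame.
#' @return A data frame with columns `subject_id`, `time`, `event` (logical).
#' @export
efs_events <- function(records) {
  d <- records[records$group == "case" & records$efs_event != "missing", ,
               drop = FALSE]
  if (any(d$efs_event == "yes" & is.na(d$efs_time))) {
    stop("efs_event = yes without efs_time")
  }
  d <- d[!is.na(d$efs_time), , drop = FALSE]
  data.frame(subject_id = d$subject_id, time = d$efs_time,
             event = d$efs_event == "yes", stringsAsFactors = FALSE)
}

#' Extract time-to-MMR observations
#'
#' Same contract as [efs_events()] for the major-molecular-response endpoint:
#' the event is MMR achievement, censoring is end of follow-up without MMR.
#'
#' @param records A `gst_cohort` data frame.
#' @return A data frame with columns `subject_id`, `time`, `event`.
#' @export
mmr_events <- function(records) {
  d <- records[records$group == "case" & records$mmr_event != "missing", ,
               drop = FALSE]
  if (any(d$mmr_event == "yes" & is.na(d$mmr_time))) {
    stop("mmr_event = yes without mmr_time")
  }
  d <- d[!is.na(d$mmr_time), , drop = FALSE]
  data.frame(subject_id = d$subject_id, time = d$mmr_time,
             event = d$mmr_event == "yes", stringsAsFactors = FALSE)
}
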