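# Windowed case-control comorbidity screen: which conditions occur in the
# 60 days before a query index event more often than before a control
# index event? Enrichment is summarized by the incidence ratio
# (a/n1)/(b/n2) -- the statistic printed for published case-control rows,
# numerically a risk ratio, not the cross-product odds ratio -- with a
# two-sided Fisher exact test on the 2x2 table, and the screen is run
# against each control cohort and intersected.

#' Incidence ratio between case and control cohorts
#'
#' `(a/n1) / (b/n2)`, with the sentinel -1 whenever the control count `b`
#' is zero (infinite enrichment is unprintable; the sentinel mirrors
#' standard reporting).
#'
#' @param a case patients with the condition in-window.
#' @param n1 case cohort size.
#' @param b control patients with the condition in-window.
#' @param n2 control cohort size.
#' @return numeric vector of ratios (or -1 sentinels).
#' @export
incidence_ratio <- function(a, n1, b, n2) {
  stopifnot(all(a >= 0 & a <= n1), all(b >= 0 & b <= n2))
  ifelse(b == 0, -1, (a / n1) / (b / n2))
}

#' Fisher exact p-value for a case-control condition count
#'
#' Two-sided Fisher exact test on the table `[a, n1-a; b, n2-b]`.
#'
#' @inheritParams incidence_ratio
#' @return numeric vector of p-values.
#' @export
comorbidity_test <- function(a, n1, b, n2) {
  mapply(function(a, n1, b, n2)
    stats::fisher.test(matrix(c(a, n1 - a, b, n2 - b), nrow = 2,
                              byrow = TRUE))$p.value,
    a, n1, b, n2)
}

#' Build case and control cohorts with index dates
#'
#' The index event is each patient's *first* occurrence of the
#' cohort-defining code. Patients appearing in both the case cohort and a
#' control cohort are removed from the control.
#'
#' @param events data frame with `patient_id`, `code`, `date`.
#' @param query query (case-defining) code.
#' @param controls character vector of control codes (>= 1), disjoint from
#'   `query`.
#' @return list with `case` (data frame `patient_id`, `index_date`) and
#'   `controls` (named list of such data frames).
#' @export
build_cohorts <- function(events, query, controls) {
  stopifnot(length(controls) >= 1, !query %in% controls)
  events$date <- as.Date(events$date)
  index_of <- function(code) {
    ev <- events[events$code == code, c("patient_id", "date")]
    if (nrow(ev) == 0) stop("no events with code '", code, "'")
    first <- tapply(ev$date, ev$patient_id, min)
    data.frame(patient_id = names(first),
               index_date = as.Date(first, origin = "1970-01-01"),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  case <- index_of(query)
  ctrl <- lapply(controls, function(cc) {
    co <- index_of(cc)
    co[!co$patient_id %in% case$patient_id, , drop = FALSE]
  })
  names(ctrl) <- controls
  if (any(vapply(ctrl, nrow, integer(1)) == 0))
    stop("a control cohort is empty after excluding case patients")
  list(case = case, controls = ctrl)
}

#' Screen conditions enriched before the index event
#'
#' For every candidate condition code (all codes except the query and
#' control codes), counts distinct case and control patients with at least
#' one event of that code in the half-open window
#' `[index - window, index)` -- events on the index day itself are
#' excluded as plausibly consequent rather than antecedent. Rows carry the
#' incidence ratio, Fisher exact p, and BH q, sorted by p.
#'
#' @param events data frame with `patient_id`, `code`, `date`.
#' @param case,control cohort data frames (`patient_id`, `index_date`)
#'   from [build_cohorts()].
#' @param exclude codes never reported as conditions (the query and
#'   control codes).
#' @param window look-back window in days (default 60).
#' @return data frame with columns `condition`, `a`, `n1`, `inc_case`,
#'   `b`, `n2`, `inc_ctrl`, `ratio`, `p`, `q`.
#' @export
screen <- function(events, case, control, exclude = character(0),
                   window = 60) {
  stopifnot(nrow(case) > 0, nrow(control) > 0, window > 0)
  events$date <- as.Date(events$date)
  in_window_counts <- function(cohort) {
    ev <- events[events$patient_id %in% cohort$patient_id &
                   !events$code %in% exclude, ]
    idx <- cohort$index_date[match(ev$patient_id, cohort$patient_id)]
    ok <- ev$date >= idx - window & ev$date < idx
    ev <- ev[ok, c("patient_id", "code")]
    ev <- ev[!duplicated(ev), , drop = FALSE]
    table(ev$code)
  }
  ta <- in_window_counts(case)
  tb <- in_window_counts(control)
  conditions <- sort(union(names(ta), names(tb)))
  if (length(conditions) == 0)
    return(data.frame(condition = character(0), a = integer(0),
                      n1 = integer(0), inc_case = numeric(0),
                      b = integer(0), n2 = integer(0),
                      inc_ctrl = numeric(0), ratio = numeric(0),
                      p = numeric(0), q = numeric(0)))
  a <- as.integer(ifelse(is.na(ta[conditions]), 0, ta[conditions]))
  b <- as.integer(ifelse(is.na(tb[conditions]), 0, tb[conditions]))
  n1 <- nrow(case); n2 <- nrow(control)
  out <- data.frame(
    condition = conditions, a = a, n1 = n1, inc_case = a / n1,
    b = b, n2 = n2, inc_ctrl = b / n2,
    ratio = incidence_ratio(a, n1, b, n2),
    p = comorbidity_test(a, n1, b, n2), stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect screen results across control cohorts
#'
#' Keeps only conditions significant (raw p below `p_threshold`) against
#' *every* control; the reported statistics are those of the first-listed
#' (or `report`-selected) control.
#'
#' @param results named list (>= 2) of screen result data frames, one per
#'   control.
#' @param p_threshold significance threshold applied per control.
#' @param report index or name of the control whose statistics are
#'   reported (default the first).
#' @return data frame in the [screen()] layout, restricted to the
#'   intersection; empty (with a warning) when no condition survives.
#' @export
intersect_controls <- function(results, p_threshold = 0.05, report = 1) {
  stopifnot(length(results) >= 2)
  sig <- lapply(results, function(r) r$condition[r$p < p_threshold])
  common <- Reduce(intersect, sig)
  out <- results[[report]]
  out <- out[out$condition %in% common, , drop = FALSE]
  if (nrow(out) == 0)
    warning("no condition is significant against every control")
  rownames(out) <- NULL
  out
}

#' Run the full comorbidity screen
#'
#' Builds cohorts, screens against each control, and intersects.
#'
#' @inheritParams build_cohorts
#' @inheritParams screen
#' @param p_threshold per-control significance threshold for the
#'   intersection.
#' @return list with `per_control` (list of full screen tables) and
#'   `intersection` (the final table).
#' @export
comorbidity_screen <- function(events, query, controls, window = 60,
                               p_threshold = 0.05) {
  cohorts <- build_cohorts(events, query, controls)
  exclude <- c(query, controls)
  per <- lapply(cohorts$controls, function(ctrl)
    screen(events, cohorts$case, ctrl, exclude = exclude, window = window))
  final <- if (length(per) >= 2)
    intersect_controls(per, p_threshold = p_threshold)
  else per[[1]][per[[1]]$p < p_threshold, , drop = FALSE]
  rownames(final) <- NULL
  list(per_control = per, intersection = final)
}
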