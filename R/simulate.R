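# Synthetic EHR generator. Emulates the structure that makes seasonality
# detection in hospital data hard: a multi-year secular growth in total
# events, a shared ~6-month oscillation in total visits (spring/fall
# peaks), per-code planted periodic signals, chronic codes that are a
# fixed proportion of total visits (the de-totaling confound), and
# Poisson count noise. Counts are sampled first and events materialized
# from them, so the truth table is exact by construction.

#' Simulation configuration
#'
#' @param n_codes number of diagnosis codes.
#' @param months calendar span in months (default 156 = the 13 years
#'   1997-2009).
#' @param start first month, `"YYYY-MM"` (default `"1997-01"`).
#' @param baseline_rates per-code mean monthly count at time 0; scalar or
#'   length-`n_codes` vector, all > 0.
#' @param growth_rate multiplicative secular trend slope per year:
#'   `growth(t) = 1 + growth_rate * t_years`. The default `1/12` doubles
#'   the rates over 12 years, the visual character of hospital-volume
#'   growth over a comparable span.
#' @param total_season_amplitude unitless fraction in `[0, 1)` modulating
#'   every non-chronic code: `1 + A * cos(2*pi*(t - phase)/period)`.
#'   Default 0.05 -- a 5% swing in total visits, a realistic magnitude for
#'   the shared spring/fall pattern.
#' @param total_season_period months (default 6, spring + fall peaks).
#' @param total_season_phase months; the default 3 puts peaks in April and
#'   October.
#' @param planted_signals data frame with columns `code` (1-based index),
#'   `period` (months, >= 2), `phase` (months) and `amplitude`
#'   (`[0, 1)`): per-code periodic signals to plant.
#' @param chronic_fraction data frame with columns `code` (1-based index)
#'   and `fraction` (> 0): codes whose mean is `fraction` times the summed
#'   mean of all non-chronic codes at each month, i.e. a fixed proportion
#'   of the total. Indices must be disjoint from `planted_signals$code`.
#' @param extra_visit_prob probability that a simulated patient makes a
#'   second visit with the same code in the same month (exercises
#'   unique-patient counting without breaking the count round-trip).
#' @param seed RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_codes, months = 156, start = "1997-01",
                       baseline_rates = 100, growth_rate = 1 / 12,
                       total_season_amplitude = 0.05,
                       total_season_period = 6, total_season_phase = 3,
                       planted_signals = NULL, chronic_fraction = NULL,
                       extra_visit_prob = 0, seed = 1) {
  stopifnot(n_codes >= 1, months >= 1)
  baseline_rates <- rep_len(baseline_rates, n_codes)
  if (any(baseline_rates <= 0)) stop("baseline_rates must be > 0")
  if (total_season_amplitude < 0 || total_season_amplitude >= 1)
    stop("total_season_amplitude must be in [0, 1)")
  if (total_season_period < 2) stop("total_season_period must be >= 2")
  if (!is.null(planted_signals)) {
    stopifnot(all(c("code", "period", "phase", "amplitude") %in%
                    names(planted_signals)))
    if (any(planted_signals$amplitude < 0 | planted_signals$amplitude >= 1))
      stop("planted amplitudes must be in [0, 1)")
    if (any(planted_signals$period < 2))
      stop("planted periods must be >= 2 months")
    if (any(planted_signals$code < 1 | planted_signals$code > n_codes))
      stop("planted code index out of range")
  }
  if (!is.null(chronic_fraction)) {
    stopifnot(all(c("code", "fraction") %in% names(chronic_fraction)))
    if (any(chronic_fraction$fraction <= 0))
      stop("chronic fractions must be > 0")
    if (any(chronic_fraction$code < 1 | chronic_fraction$code > n_codes))
      stop("chronic code index out of range")
    if (!is.null(planted_signals) &&
        length(intersect(chronic_fraction$code, planted_signals$code)))
      stop("chronic and planted code indices must be disjoint")
  }
  structure(
    list(n_codes = n_codes, months = months, start = start,
         baseline_rates = baseline_rates, growth_rate = growth_rate,
         total_season_amplitude = total_season_amplitude,
         total_season_period = total_season_period,
         total_season_phase = total_season_phase,
         planted_signals = planted_signals,
         chronic_fraction = chronic_fraction,
         extra_visit_prob = extra_visit_prob, seed = seed),
    class = "sim_config")
}

# deterministic mean matrix (codes x months) implied by a sim_config
sim_means <- function(config) {
  t <- seq_len(config$months) - 1  # month index
  growth <- 1 + config$growth_rate * t / 12
  shared <- 1 + config$total_season_amplitude *
    cos(2 * pi * (t - config$total_season_phase) / config$total_season_period)
  mu <- outer(config$baseline_rates, growth * shared)
  if (!is.null(config$planted_signals)) {
    ps <- config$planted_signals
    for (i in seq_len(nrow(ps))) {
      own <- 1 + ps$amplitude[i] *
        cos(2 * pi * (t - ps$phase[i]) / ps$period[i])
      mu[ps$code[i], ] <- mu[ps$code[i], ] * own
    }
  }
  if (!is.null(config$chronic_fraction)) {
    cf <- config$chronic_fraction
    others <- colSums(mu[-cf$code, , drop = FALSE])
    for (i in seq_len(nrow(cf)))
      mu[cf$code[i], ] <- cf$fraction[i] * others
  }
  if (any(mu < 0)) stop("implied mean counts are negative: amplitude too large")
  mu
}

#' Simulate monthly diagnosis counts and the events behind them
#'
#' Draws the code x month count matrix from Poisson distributions around
#' the configured means, then (optionally) materializes one event per
#' count with a fresh patient identifier -- so aggregating the events
#' reproduces the counts exactly, and the planted truth is exact.
#'
#' @param config a [sim_config()].
#' @param events materialize the event table (`TRUE`)? Disable for large
#'   simulations where only the counts matrix is needed.
#' @return An object of class `sim_output`: list with `events` (data
#'   frame `patient_id`, `code`, `date`, or `NULL`), `truth` (per-code
#'   planted period/phase/amplitude or `NA`, plus a `chronic` flag) and
#'   `counts` (a [monthly_counts] object).
#' @export
simulate_counts <- function(config, events = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mu <- sim_means(config)
  n <- config$n_codes
  codes <- sprintf("S%03d", seq_len(n))
  values <- matrix(stats::rpois(length(mu), mu), nrow = n)
  start <- parse_month(config$start)
  mon <- first_of_month(month_index(start) + seq_len(config$months) - 1L)
  counts <- monthly_counts(values, codes, mon)

  truth <- data.frame(code = codes, period = NA_real_, phase = NA_real_,
                      amplitude = NA_real_, chronic = FALSE,
                      stringsAsFactors = FALSE)
  if (!is.null(config$planted_signals)) {
    ps <- config$planted_signals
    truth$period[ps$code] <- ps$period
    truth$phase[ps$code] <- ps$phase
    truth$amplitude[ps$code] <- ps$amplitude
  }
  if (!is.null(config$chronic_fraction))
    truth$chronic[config$chronic_fraction$code] <- TRUE

  ev <- NULL
  if (events) {
    cell <- which(values > 0, arr.ind = TRUE)
    kk <- values[cell]
    ci <- rep(cell[, 1], kk)
    mi <- rep(cell[, 2], kk)
    within <- sequence(kk)
    pid <- sprintf("P%03d.%03d.%04d", ci, mi, within)
    day <- sample(0:27, length(ci), replace = TRUE)
    ev <- data.frame(patient_id = pid, code = codes[ci],
                     date = mon[mi] + day, stringsAsFactors = FALSE)
    if (config$extra_visit_prob > 0) {
      dup <- stats::runif(nrow(ev)) < config$extra_visit_prob
      if (any(dup)) {
        extra <- ev[dup, , drop = FALSE]
        extra$date <- mon[mi[dup]] + sample(0:27, sum(dup), replace = TRUE)
        ev <- rbind(ev, extra)  # same patient/code/month: unique count unchanged
      }
    }
    ev <- ev[order(ev$date, ev$code, ev$patient_id), , drop = FALSE]
    rownames(ev) <- NULL
  }
  structure(list(events = ev, truth = truth, counts = counts),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("sim_output: %d codes x %d months, %s events\n",
              length(x$counts$codes), length(x$counts$months),
              if (is.null(x$events)) "no" else format(nrow(x$events))))
  invisible(x)
}

#' Simulate a case-control cohort for the comorbidity screen
#'
#' Emits one index event per patient (`query_code` for cases,
#' `control_code` for controls) and, per candidate condition, co-occurring
#' events placed uniformly within the look-back window before the index
#' date, with the stated per-arm probabilities.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param conditions character vector of condition codes.
#' @param case_incidence,control_incidence per-condition probabilities in
#'   `[0, 1]` (recycled to `length(conditions)`).
#' @param window_days look-back window; condition events land 1 ..
#'   `window_days` days before the index date.
#' @param query_code,control_code index-event codes.
#' @param exact when `TRUE`, exactly `round(p * n)` patients per arm get
#'   the condition (deterministic assignment); otherwise Bernoulli.
#' @param seed RNG seed.
#' @return event data frame (`patient_id`, `code`, `date`) with the
#'   per-condition planted counts in attribute `"truth"`.
#' @export
simulate_comorbidity_cohort <- function(n_cases, n_controls, conditions,
                                        case_incidence, control_incidence,
                                        window_days = 60,
                                        query_code = "Q",
                                        control_code = "CTRL",
                                        exact = FALSE, seed = 1) {
  case_incidence <- rep_len(case_incidence, length(conditions))
  control_incidence <- rep_len(control_incidence, length(conditions))
  if (any(c(case_incidence, control_incidence) < 0 |
            c(case_incidence, control_incidence) > 1))
    stop("incidences must be in [0, 1]")
  set.seed(seed)
  base <- as.Date("2005-01-01")
  arm <- function(n, prefix, code, p_vec) {
    pid <- sprintf("%s%05d", prefix, seq_len(n))
    index <- base + sample(0:3650, n, replace = TRUE)
    ev <- data.frame(patient_id = pid, code = code, date = index,
                     stringsAsFactors = FALSE)
    truth <- integer(length(conditions))
    for (j in seq_along(conditions)) {
      has <- if (exact) seq_len(n) <= round(p_vec[j] * n)
             else stats::runif(n) < p_vec[j]
      truth[j] <- sum(has)
      if (any(has)) {
        off <- sample(seq_len(window_days), sum(has), replace = TRUE)
        ev <- rbind(ev, data.frame(patient_id = pid[has],
                                   code = conditions[j],
                                   date = index[has] - off,
                                   stringsAsFactors = FALSE))
      }
    }
    list(events = ev, truth = truth)
  }
  ca <- arm(n_cases, "case", query_code, case_incidence)
  co <- arm(n_controls, "ctrl", control_code, control_incidence)
  ev <- rbind(ca$events, co$events)
  rownames(ev) <- NULL
  attr(ev, "truth") <- data.frame(condition = conditions,
                                  a = ca$truth, n1 = n_cases,
                                  b = co$truth, n2 = n_controls,
                                  stringsAsFactors = FALSE)
  ev
}

#' Write simulated events and truth as delimited text
#'
#' @param sim a `sim_output` from [simulate_counts()] (with events).
#' @param dir output directory (created if needed).
#' @param delim field delimiter.
#' @return paths of the written files, invisibly.
#' @export
write_simulation <- function(sim, dir, delim = ",") {
  stopifnot(inherits(sim, "sim_output"))
  if (is.null(sim$events)) stop("simulation has no event table")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(dir, "events.csv")
  tp <- file.path(dir, "truth.csv")
  utils::write.table(sim$events, ep, sep = delim, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(sim$truth, tp, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(c(events = ep, truth = tp))
}
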