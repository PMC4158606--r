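# Lomb-Scargle periodogram scan with exponential false-alarm null,
# 18-month period admissibility cutoff and Benjamini-Hochberg control.
#
# The classical normalized form (Press et al.):
#   P(w) = 1/(2 s^2) * [ (sum (y-ybar) cos w(t-tau))^2 / sum cos^2 w(t-tau)
#                      + (sum (y-ybar) sin w(t-tau))^2 / sum sin^2 w(t-tau) ]
# with tan(2 w tau) = sum sin(2wt) / sum cos(2wt) and s^2 the (N-1)-
# denominator sample variance. Under Gaussian white noise P at a fixed
# frequency is Exp(1); the false-alarm probability of the maximum over M
# independent frequencies is 1 - (1 - e^-z)^M.

#' Frequency grid for the periodicity scan
#'
#' Frequencies in cycles/month spanning periods `min_period`..`max_period`,
#' spaced `1/(ofac * span)` so adjacent grid points differ by `1/ofac`
#' cycles over the observation span.
#'
#' @param n_months observation span in months.
#' @param min_period,max_period period range, months.
#' @param ofac oversampling factor.
#' @return list with `frequencies` (cycles/month), `periods` (months) and
#'   `n_indep`, the effective number of independent frequencies
#'   `length(frequencies)/ofac` used for the false-alarm probability.
#' @export
ls_grid <- function(n_months, min_period = 2, max_period = 60, ofac = 4) {
  stopifnot(min_period >= 2, max_period > min_period, ofac >= 1)
  df <- 1 / (ofac * n_months)
  f <- seq(1 / max_period, 1 / min_period, by = df)
  list(frequencies = f, periods = 1 / f, n_indep = length(f) / ofac)
}

#' Lomb-Scargle periodogram
#'
#' Normalized Lomb-Scargle power on an arbitrary frequency grid. Invariant
#' to adding a constant to `values` and to shifting the time origin. For
#' evenly spaced data it coincides with the classical (Schuster)
#' periodogram normalized by the sample variance at Fourier frequencies.
#'
#' @param values numeric series (at least 24 points, non-constant).
#' @param time numeric sampling times; `frequencies` are in cycles per unit
#'   of `time`.
#' @param frequencies positive frequencies at which to evaluate the power.
#' @return numeric vector of powers `P(omega) >= 0`, one per frequency.
#' @export
lomb_scargle <- function(values, time, frequencies) {
  if (length(values) != length(time)) stop("values/time length mismatch")
  if (length(values) < 24) stop("need >= 24 points")
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  s2 <- stats::var(values)
  if (s2 == 0) stop("constant series: variance is zero")
  d <- ls_design(time, frequencies)
  ls_power(d, values, s2)
}

# Precomputes the per-frequency phase-shifted design; reused across codes
# that share a time axis.
ls_design <- function(time, frequencies) {
  omega <- 2 * pi * frequencies
  tw <- outer(time, omega)                       # n x nf
  tau_w <- atan2(colSums(sin(2 * tw)), colSums(cos(2 * tw))) / 2  # omega*tau
  arg <- sweep(tw, 2, tau_w, "-")                # omega*(t - tau)
  C <- cos(arg); S <- sin(arg)
  list(C = C, S = S, cc = colSums(C^2), ss = colSums(S^2))
}

ls_power <- function(d, values, s2 = stats::var(values)) {
  yc <- values - mean(values)
  pc <- as.vector(crossprod(d$C, yc))^2
  ps <- as.vector(crossprod(d$S, yc))^2
  # a vanishing denominator (e.g. sin terms at the Nyquist frequency on
  # integer times) comes with a vanishing numerator: contribute 0
  pc <- ifelse(d$cc > 1e-12, pc / pmax(d$cc, 1e-300), 0)
  ps <- ifelse(d$ss > 1e-12, ps / pmax(d$ss, 1e-300), 0)
  (pc + ps) / (2 * s2)
}

#' False-alarm probability of a periodogram peak
#'
#' Probability that the maximum of `n_indep` independent Exp(1) powers
#' exceeds `best_power`: `1 - (1 - exp(-z))^M`, evaluated through
#' `expm1`/`log1p` so that small probabilities (~ `M exp(-z)`) do not lose
#' precision.
#'
#' @param best_power maximum normalized power (>= 0).
#' @param n_indep effective number of independent frequencies M (>= 1).
#' @return p-value in [0, 1].
#' @export
false_alarm_p <- function(best_power, n_indep) {
  stopifnot(all(best_power >= 0), n_indep >= 1)
  p <- -expm1(n_indep * log1p(-exp(-best_power)))
  pmin(p, 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment with monotonization, order-preserving.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Scan all adjusted series for periodic signal
#'
#' For each code, computes the Lomb-Scargle periodogram of the chosen
#' adjusted series over periods 2-60 months (oversampled grid), takes the
#' best (highest-power) period anywhere on the grid, and converts the peak
#' to a false-alarm p-value -- unless the best period exceeds
#' `max_admissible_period` (default 18 months = 1.5 years), in which case
#' the p-value is set to 1: long periods are poorly supported by a
#' decade-scale window and are reported non-significant regardless of
#' power. BH q-values are computed across codes.
#'
#' @param adjusted list of `adjusted_series` (see [adjust_all()]).
#' @param use which series to scan: `"detotaled"` (default; falls back to
#'   detrended with a warning when absent), `"detrended"`, or `"raw"`.
#' @param min_period,max_period,ofac grid settings, months; see [ls_grid()].
#' @param max_admissible_period periods above this (months) are reported
#'   non-significant.
#' @param p_threshold significance threshold on the raw false-alarm p.
#' @return An object of class `scan_result`: data frame with columns
#'   `code`, `best_period`, `best_power`, `p_value`, `bh_q`, `significant`.
#' @export
scan_all <- function(adjusted, use = c("detotaled", "detrended", "raw"),
                     min_period = 2, max_period = 60, ofac = 4,
                     max_admissible_period = 18, p_threshold = 0.01) {
  use <- match.arg(use)
  if (length(adjusted) < 1) stop("no series to scan")
  designs <- list()  # cache per distinct time axis
  res <- lapply(adjusted, function(a) {
    y <- switch(use,
      detotaled = if (is.null(a$detotaled)) {
        warning("code '", a$code, "': no detotaled series, using detrended")
        a$detrended
      } else a$detotaled,
      detrended = a$detrended,
      raw = a$raw)
    tm <- (a$time - a$time[1]) * 12  # months since first retained month
    grid <- ls_grid(diff(range(tm)), min_period, max_period, ofac)
    key <- paste0(length(tm), ":", tm[length(tm)])
    if (is.null(designs[[key]]))
      designs[[key]] <<- ls_design(tm, grid$frequencies)
    pw <- ls_power(designs[[key]], y)
    i <- which.max(pw)
    best_period <- grid$periods[i]
    p <- if (best_period > max_admissible_period) 1
         else false_alarm_p(pw[i], grid$n_indep)
    data.frame(code = a$code, best_period = best_period,
               best_power = pw[i], p_value = p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$bh_q <- bh_adjust(out$p_value)
  out$significant <- out$p_value < p_threshold &
    out$best_period <= max_admissible_period
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Write a scan result as delimited text
#'
#' @param scan a `scan_result` from [scan_all()].
#' @param path file path.
#' @param delim field delimiter.
#' @param header_comment optional `#` comment line written first.
#' @export
write_scan <- function(scan, path, delim = ",", header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(as.data.frame(scan), con, sep = delim,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
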