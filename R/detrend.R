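# Trend and shared-seasonal correction of monthly count series.
#
# De-trending: subtract a Gaussian-kernel (Nadaraya-Watson) smooth of the
# series, with the bandwidth chosen by Silverman's normal-reference rule on
# the count-weighted month values -- the estimator implied by evaluating an
# automatic-bandwidth weighted KDE of event times at every month and
# rescaling to counts. Months within two bandwidths of either end are
# trimmed: the kernel estimate there leans on data outside the observation
# window and is unreliable.
#
# De-totaling: subtract, from each code's detrended series, the detrended
# total over all codes scaled by mean(code)/mean(total) -- the counts the
# code would show if it were always a fixed proportion of all hospital
# visits. This removes the shared seasonal oscillation in total visits
# that otherwise masquerades as per-code seasonality.

#' Kernel-smooth a monthly count series
#'
#' Nadaraya-Watson regression with a Gaussian kernel on the month axis.
#' When `bandwidth` is `NULL` it is set by Silverman's rule applied to the
#' count-weighted month values, and floored at `bw_floor` so the smoother
#' captures only secular trend and passes seasonal (<= 18 month)
#' frequencies essentially unattenuated (a cosine of period T survives
#' smoothing with factor `exp(-(2*pi*h/T)^2/2)`).
#'
#' @param counts non-negative numeric vector, one value per month.
#' @param bandwidth kernel bandwidth in months, or `NULL` for automatic.
#' @param bw_floor lower bound on the automatic bandwidth, months.
#' @return list with `trend` (same length as `counts`) and `bandwidth`
#'   (months; `NA` for an all-zero series, whose trend is identically 0).
#' @export
smooth_series <- function(counts, bandwidth = NULL, bw_floor = 9) {
  n <- length(counts)
  if (n < 24) stop("series too short to smooth (need >= 24 months)")
  if (any(counts < 0)) stop("counts must be non-negative")
  t <- seq_len(n) - 1  # month index
  if (all(counts == 0))
    return(list(trend = rep(0, n), bandwidth = NA_real_))
  if (is.null(bandwidth)) {
    bandwidth <- max(silverman_bw(t, counts), bw_floor)
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  k <- stats::dnorm(outer(t, t, "-") / bandwidth)
  trend <- as.vector(k %*% counts) / rowSums(k)
  list(trend = trend, bandwidth = bandwidth)
}

# Silverman's normal-reference bandwidth for a weighted sample:
# 0.9 * min(sd, IQR/1.34) * n^(-1/5), with n the total count mass.
silverman_bw <- function(t, w) {
  n <- sum(w)
  mu <- sum(w * t) / n
  sdev <- sqrt(sum(w * (t - mu)^2) / n)
  iqr <- weighted_quantile(t, w, 0.75) - weighted_quantile(t, w, 0.25)
  sigma <- min(sdev, iqr / 1.34)
  if (sigma <= 0) sigma <- sdev
  0.9 * sigma * n^(-1 / 5)
}

weighted_quantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= p)[1]]
}

#' De-trend one code's monthly series
#'
#' Subtracts the kernel-smoothed trend and trims `ceil(2 * bandwidth)`
#' months from each end of the series, where the kernel estimate is
#' unreliable.
#'
#' @param counts non-negative numeric vector of monthly counts.
#' @param time_axis numeric time per month in decimal years (mid-month), as
#'   produced by [aggregate_monthly()].
#' @param code code label carried through to the result.
#' @inheritParams smooth_series
#' @return An object of class `adjusted_series`: list with `code`, `time`,
#'   `raw`, `trend`, `detrended`, `detotaled` (`NULL` until
#'   [detotal_series()]), `bandwidth` (months) and `trim` (months removed
#'   per end).
#' @export
detrend_series <- function(counts, time_axis, code = "",
                           bandwidth = NULL, bw_floor = 9) {
  if (length(counts) != length(time_axis))
    stop("counts and time_axis lengths differ")
  counts <- unname(counts)
  time_axis <- unname(time_axis)
  sm <- smooth_series(counts, bandwidth = bandwidth, bw_floor = bw_floor)
  bw <- if (is.na(sm$bandwidth)) bw_floor else sm$bandwidth
  trim <- ceiling(2 * bw)
  n <- length(counts)
  if (n - 2 * trim < 24)
    stop("trimming 2 bandwidths (", trim, " months/end) leaves < 24 months")
  idx <- (trim + 1):(n - trim)
  structure(
    list(code = code, time = time_axis[idx], raw = counts[idx],
         trend = sm$trend[idx], detrended = counts[idx] - sm$trend[idx],
         detotaled = NULL, bandwidth = sm$bandwidth, trim = trim),
    class = "adjusted_series")
}

#' @export
print.adjusted_series <- function(x, ...) {
  cat(sprintf(
    "adjusted_series '%s': %d months, bandwidth %.2f mo, trim %d mo/end%s\n",
    x$code, length(x$time), x$bandwidth, x$trim,
    if (is.null(x$detotaled)) " (not detotaled)" else ""))
  invisible(x)
}

#' Build the shared seasonal component of total hospital visits
#'
#' Sums counts over all codes per month, de-trends the total with the same
#' smoother, and records per-code scale factors
#' `mean(code counts) / mean(total counts)` on the trimmed axis. The total
#' includes every code (self-inclusion is negligible with many codes).
#'
#' @param counts a [monthly_counts] object with at least 2 codes.
#' @inheritParams smooth_series
#' @return An object of class `shared_seasonal`: list with `time`,
#'   `total_detrended`, `scale` (named per-code vector), `bandwidth`,
#'   `trim`.
#' @export
build_shared_seasonal <- function(counts, bandwidth = NULL, bw_floor = 9) {
  stopifnot(inherits(counts, "monthly_counts"))
  if (length(counts$codes) < 2)
    stop("de-totaling needs >= 2 codes")
  total <- colSums(counts$values)
  adj <- detrend_series(total, counts$time_axis, code = ".total",
                        bandwidth = bandwidth, bw_floor = bw_floor)
  idx <- match_times(adj$time, counts$time_axis)
  mean_total <- mean(total[idx])
  scale <- rowMeans(counts$values[, idx, drop = FALSE]) / mean_total
  names(scale) <- counts$codes
  structure(
    list(time = adj$time, total_detrended = adj$detrended,
         scale = scale, bandwidth = adj$bandwidth, trim = adj$trim),
    class = "shared_seasonal")
}

match_times <- function(sub, full, tol = 1e-6) {
  idx <- vapply(sub, function(t) {
    j <- which(abs(full - t) < tol)
    if (length(j) != 1) NA_integer_ else j
  }, integer(1))
  if (anyNA(idx)) stop("time axes do not align")
  idx
}

#' Remove the shared seasonal hospitalization trend from a detrended series
#'
#' Subtracts `scale_c * total_detrended` from the code's detrended values:
#' the code's expected counts were it a fixed proportion of total visits.
#' The series' months must all be present in the shared component's axis
#' (an axis mismatch is an error).
#'
#' @param adj an `adjusted_series` from [detrend_series()].
#' @param shared a `shared_seasonal` from [build_shared_seasonal()].
#' @return `adj` with `detotaled` populated.
#' @export
detotal_series <- function(adj, shared) {
  stopifnot(inherits(adj, "adjusted_series"),
            inherits(shared, "shared_seasonal"))
  sc <- shared$scale[adj$code]
  if (is.na(sc)) stop("code '", adj$code, "' absent from shared seasonal")
  idx <- match_times(adj$time, shared$time)
  adj$detotaled <- adj$detrended - sc * shared$total_detrended[idx]
  adj
}

#' De-trend and de-total every code in a counts matrix
#'
#' Runs [detrend_series()] per code, builds the shared seasonal component,
#' aligns each code to the common (intersection) trimmed axis, and applies
#' [detotal_series()]. Per-code bandwidths may differ; each code keeps its
#' own trim, further restricted to the shared component's axis.
#'
#' @param counts a [monthly_counts] object.
#' @param detotal apply de-totaling (`TRUE`) or stop after de-trending.
#' @inheritParams smooth_series
#' @return list of `adjusted_series`, one per code, with the
#'   `shared_seasonal` object (or `NULL`) in attribute `"shared"`.
#' @export
adjust_all <- function(counts, bandwidth = NULL, bw_floor = 9,
                       detotal = TRUE) {
  stopifnot(inherits(counts, "monthly_counts"))
  shared <- if (detotal)
    build_shared_seasonal(counts, bandwidth = bandwidth, bw_floor = bw_floor)
  adjusted <- lapply(seq_along(counts$codes), function(i) {
    adj <- detrend_series(counts$values[i, ], counts$time_axis,
                          code = counts$codes[i],
                          bandwidth = bandwidth, bw_floor = bw_floor)
    if (detotal) {
      # restrict to months the shared axis also covers, then subtract
      keep <- !is.na(vapply(adj$time, function(t) {
        j <- which(abs(shared$time - t) < 1e-6)
        if (length(j) == 1) j else NA_integer_
      }, integer(1)))
      if (!all(keep)) {
        for (f in c("time", "raw", "trend", "detrended"))
          adj[[f]] <- adj[[f]][keep]
        if (length(adj$time) < 24)
          stop("code '", adj$code,
               "': aligning with shared axis leaves < 24 months")
      }
      adj <- detotal_series(adj, shared)
    }
    adj
  })
  names(adjusted) <- counts$codes
  attr(adjusted, "shared") <- shared
  adjusted
}

#' Write adjusted series as a long delimited table
#'
#' Columns: code, month (decimal years), raw, trend, detrended, detotaled.
#'
#' @param adjusted list of `adjusted_series` (from [adjust_all()]).
#' @param path file path.
#' @param delim field delimiter.
#' @param header_comment optional `#` comment line written first.
#' @export
write_adjusted <- function(adjusted, path, delim = ",",
                           header_comment = NULL) {
  rows <- do.call(rbind, lapply(adjusted, function(a) {
    data.frame(code = a$code, month = a$time, raw = a$raw, trend = a$trend,
               detrended = a$detrended,
               detotaled = if (is.null(a$detotaled)) NA_real_ else a$detotaled)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(rows, con, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}
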