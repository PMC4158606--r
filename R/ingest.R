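# Event-table ingestion: monthly unique-patient counts per diagnosis code.

#' Construct a monthly counts matrix
#'
#' Container for a code x month matrix of unique-patient counts on a
#' contiguous calendar-month axis.
#'
#' @param values integer matrix, rows = codes, columns = months.
#' @param codes character vector of code labels (row names).
#' @param months `Date` vector, first day of each month, strictly increasing
#'   with no gaps.
#' @return An object of class `monthly_counts`: a list with elements
#'   `codes`, `months`, `values` and `time_axis` (decimal years at
#'   mid-month, e.g. Jan 1997 -> 1997.0417).
#' @export
monthly_counts <- function(values, codes, months) {
  values <- as.matrix(values)
  if (nrow(values) != length(codes))
    stop("nrow(values) must equal length(codes)")
  if (ncol(values) != length(months))
    stop("ncol(values) must equal length(months)")
  if (any(values < 0) || any(values != round(values)))
    stop("counts must be non-negative integers")
  months <- as.Date(months)
  if (length(months) > 1) {
    step <- month_index(months[-1]) - month_index(months[-length(months)])
    if (any(step != 1L))
      stop("months must be contiguous and strictly increasing")
  }
  dimnames(values) <- list(codes, format(months, "%Y-%m"))
  structure(
    list(codes = as.character(codes), months = months,
         values = values, time_axis = mid_month_years(months)),
    class = "monthly_counts")
}

#' @export
print.monthly_counts <- function(x, ...) {
  cat(sprintf("monthly_counts: %d codes x %d months (%s .. %s)\n",
              length(x$codes), length(x$months),
              format(x$months[1], "%Y-%m"),
              format(x$months[length(x$months)], "%Y-%m")))
  invisible(x)
}

# serial month number (year*12 + month-1); differences of 1 = consecutive
month_index <- function(d) {
  lt <- as.POSIXlt(d)
  (lt$year + 1900L) * 12L + lt$mon
}

# decimal years at the month midpoint: Jan -> year + 0.5/12
mid_month_years <- function(d) {
  lt <- as.POSIXlt(d)
  (lt$year + 1900) + (lt$mon + 0.5) / 12
}

first_of_month <- function(idx) {
  as.Date(sprintf("%04d-%02d-01", idx %/% 12L, idx %% 12L + 1L))
}

#' Aggregate diagnosis events into monthly unique-patient counts
#'
#' Each cell (code, month) counts the number of *distinct* patients having
#' at least one event of that code in that month; repeat visits by the same
#' patient within a month do not inflate the count. Months inside the
#' requested range with no events appear as zero columns.
#'
#' @param events data frame with columns `patient_id`, `code`, `date`
#'   (`Date` or ISO-8601 strings).
#' @param start,end optional month bounds (`Date` or "YYYY-MM" strings);
#'   events outside are dropped. Defaults to the data range.
#' @return A [monthly_counts] object.
#' @export
aggregate_monthly <- function(events, start = NULL, end = NULL) {
  req <- c("patient_id", "code", "date")
  if (!all(req %in% names(events)))
    stop("events must have columns patient_id, code, date")
  dates <- suppressWarnings(as.Date(as.character(events$date),
                                    optional = TRUE))
  bad <- which(is.na(dates) & !is.na(events$date))
  if (length(bad))
    stop("unparseable dates at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (any(is.na(dates))) stop("missing dates in events")
  if (any(is.na(events$code) | !nzchar(as.character(events$code))))
    stop("empty diagnosis codes in events")

  midx <- month_index(dates)
  if (length(midx) == 0) {
    warning("no events: returning empty matrix")
    return(monthly_counts(matrix(0L, 0, 0), character(0), as.Date(character(0))))
  }
  lo <- if (is.null(start)) min(midx) else month_index(parse_month(start))
  hi <- if (is.null(end)) max(midx) else month_index(parse_month(end))
  if (lo > hi) stop("start month is after end month")
  keep <- midx >= lo & midx <= hi
  if (!any(keep)) {
    warning("no events inside the requested period: returning empty matrix")
    return(monthly_counts(matrix(0L, 0, 0), character(0), as.Date(character(0))))
  }
  ev <- data.frame(patient = as.character(events$patient_id)[keep],
                   code = as.character(events$code)[keep],
                   m = midx[keep])
  # distinct (patient, code, month) triples, then count patients per cell
  ev <- ev[!duplicated(ev), , drop = FALSE]
  codes <- sort(unique(ev$code))
  mon_levels <- lo:hi
  tab <- table(factor(ev$code, levels = codes),
               factor(ev$m, levels = mon_levels))
  values <- matrix(as.integer(tab), nrow = length(codes),
                   dimnames = NULL)
  monthly_counts(values, codes, first_of_month(mon_levels))
}

parse_month <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  if (grepl("^\\d{4}-\\d{2}$", x)) x <- paste0(x, "-01")
  d <- as.Date(x)
  if (is.na(d)) stop("cannot parse month: ", x)
  d
}

#' Drop rare codes
#'
#' Keeps codes whose total unique-patient count across the whole period is
#' strictly greater than `min_cases` ("more than `min_cases` cases").
#'
#' @param counts a [monthly_counts] object.
#' @param min_cases threshold; the default 500 matches the common-code
#'   filter used for hospital-scale extracts.
#' @return A [monthly_counts] object with the retained rows, order kept.
#' @export
filter_codes <- function(counts, min_cases = 500) {
  stopifnot(inherits(counts, "monthly_counts"), min_cases >= 0)
  keep <- rowSums(counts$values) > min_cases
  monthly_counts(counts$values[keep, , drop = FALSE],
                 counts$codes[keep], counts$months)
}

#' Restrict the counts matrix to a span of calendar years
#'
#' @param counts a [monthly_counts] object.
#' @param start_year,end_year inclusive year bounds; columns are limited to
#'   Jan `start_year` .. Dec `end_year`.
#' @return A [monthly_counts] object.
#' @export
restrict_period <- function(counts, start_year = 1997, end_year = 2009) {
  stopifnot(inherits(counts, "monthly_counts"), start_year <= end_year)
  yr <- as.POSIXlt(counts$months)$year + 1900L
  keep <- yr >= start_year & yr <= end_year
  if (!any(keep))
    stop("no months fall inside ", start_year, "-", end_year)
  monthly_counts(counts$values[, keep, drop = FALSE],
                 counts$codes, counts$months[keep])
}

#' Read a diagnosis event table from delimited text
#'
#' Expects a header with columns `patient_id`, `code`, `date` (ISO-8601).
#'
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @return data frame of events with `date` parsed to `Date`.
#' @export
read_events <- function(path, delim = ",") {
  ev <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", comment.char = "#",
                          quote = "\"", stringsAsFactors = FALSE)
  req <- c("patient_id", "code", "date")
  if (!all(req %in% names(ev)))
    stop(path, " must have header columns patient_id, code, date")
  ev$date <- as.Date(ev$date)
  ev
}

#' Write / read a monthly counts matrix as delimited text
#'
#' Layout: a `code` column plus one column per month with `YYYY-MM`
#' headers. Lines beginning with `#` are treated as comments.
#'
#' @param counts a [monthly_counts] object.
#' @param path file path.
#' @param delim field delimiter.
#' @param header_comment optional comment line(s) written before the table.
#' @rdname counts_io
#' @export
write_counts <- function(counts, path, delim = ",", header_comment = NULL) {
  stopifnot(inherits(counts, "monthly_counts"))
  df <- data.frame(code = counts$codes, counts$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname counts_io
#' @export
read_counts <- function(path, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "code") stop(path, ": first column must be 'code'")
  months <- as.Date(paste0(names(df)[-1], "-01"))
  if (any(is.na(months))) stop(path, ": month headers must be YYYY-MM")
  monthly_counts(as.matrix(df[, -1, drop = FALSE]), df$code, months)
}
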