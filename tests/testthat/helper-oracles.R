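# Independent oracles and shared fixtures.

# Brute-force unique-patient monthly aggregation: nested loops, no shared
# code with aggregate_monthly().
brute_force_aggregate <- function(events, codes, months) {
  out <- matrix(0L, length(codes), length(months),
                dimnames = list(codes, format(months, "%Y-%m")))
  ev_mon <- format(as.Date(events$date), "%Y-%m")
  for (i in seq_along(codes)) {
    for (j in seq_along(months)) {
      sel <- events$code == codes[i] & ev_mon == format(months[j], "%Y-%m")
      out[i, j] <- length(unique(events$patient_id[sel]))
    }
  }
  out
}

# Independently coded Gaussian Nadaraya-Watson smoother (plain loops).
nw_oracle <- function(y, h) {
  n <- length(y)
  out <- numeric(n)
  for (j in seq_len(n)) {
    w <- exp(-((seq_len(n) - j) / h)^2 / 2)
    out[j] <- sum(w * y) / sum(w)
  }
  out
}

# Published case-control comorbidity table (counts, printed ratio and p);
# case cohort 204 patients, control cohort 2582.
load_table1 <- function() {
  tb <- utils::read.delim(test_path("table1.tsv"), stringsAsFactors = FALSE)
  tb$n1 <- 204L
  tb$n2 <- 2582L
  tb
}

# decimal places of a printed number, for printed-precision comparisons
printed_decimals <- function(x) {
  vapply(strsplit(as.character(x), ".", fixed = TRUE),
         function(p) if (length(p) > 1) nchar(p[2]) else 0L, integer(1))
}

month_seq <- function(from, n) seq(as.Date(from), by = "month", length.out = n)
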