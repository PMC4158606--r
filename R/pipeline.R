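# End-to-end driver: counts -> adjust -> scan -> cluster, with a resolved
# config written next to the outputs for reproducibility. The command-line
# wrapper in inst/cli/lspdetrend.R is a thin shell over these functions.

#' Default pipeline configuration
#'
#' @return named list of every tunable with its default: input paths
#'   (`events`, `counts`), date range (`start_year`, `end_year`),
#'   `min_cases` filter, smoother settings (`bandwidth`, `bw_floor`,
#'   `detotal`), periodogram grid (`min_period`, `max_period`, `ofac`,
#'   `max_admissible_period`), `p_threshold`, `cluster_k`, `delim`,
#'   `seed`, `out_dir`.
#' @export
default_config <- function() {
  list(events = NULL, counts = NULL,
       start_year = 1997, end_year = 2009, min_cases = 500,
       bandwidth = NULL, bw_floor = 9, detotal = TRUE,
       min_period = 2, max_period = 60, ofac = 4,
       max_admissible_period = 18, p_threshold = 0.01,
       cluster_k = 2, delim = ",", seed = 1, out_dir = "lspdetrend_out")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return config list as in [default_config()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defs <- default_config()
  unknown <- setdiff(names(cfg), names(defs))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defs[names(cfg)] <- cfg
  if (!is.null(defs$bandwidth) && identical(defs$bandwidth, "auto"))
    defs$bandwidth <- NULL
  defs
}

#' Run the full seasonality pipeline
#'
#' Aggregates events (or loads a counts matrix), restricts the calendar
#' window, filters rare codes, de-trends and de-totals, scans for periodic
#' signal, clusters the significant codes, and writes every stage to
#' `out_dir` as delimited text. Each output carries a `#` header with the
#' package version and the MD5 of the resolved config.
#'
#' @param config a config list (see [default_config()]) or path to a YAML
#'   file; exactly one of `events` / `counts` must be set.
#' @return invisibly, a list with `counts`, `adjusted`, `scan`, `clusters`
#'   (or `NULL`) and the output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  defs <- default_config()
  defs[names(config)] <- config
  cfg <- defs
  if (is.null(cfg$events) == is.null(cfg$counts))
    stop("set exactly one of config$events or config$counts")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], cfg_path)
  stamp <- sprintf("lspdetrend %s config_md5=%s",
                   as.character(utils::packageVersion("lspdetrend")),
                   unname(tools::md5sum(cfg_path)))

  counts <- if (!is.null(cfg$events)) {
    if (!file.exists(cfg$events)) stop("events file not found: ", cfg$events)
    aggregate_monthly(read_events(cfg$events, delim = cfg$delim))
  } else {
    if (!file.exists(cfg$counts)) stop("counts file not found: ", cfg$counts)
    read_counts(cfg$counts, delim = cfg$delim)
  }
  counts <- restrict_period(counts, cfg$start_year, cfg$end_year)
  counts <- filter_codes(counts, min_cases = cfg$min_cases)
  if (length(counts$codes) == 0)
    stop("no codes left after the min_cases filter")
  counts_path <- file.path(cfg$out_dir, "counts.csv")
  write_counts(counts, counts_path, delim = cfg$delim,
               header_comment = stamp)

  adjusted <- adjust_all(counts, bandwidth = cfg$bandwidth,
                         bw_floor = cfg$bw_floor, detotal = cfg$detotal)
  adj_path <- file.path(cfg$out_dir, "adjusted.csv")
  write_adjusted(adjusted, adj_path, delim = cfg$delim,
                 header_comment = stamp)

  scan <- scan_all(adjusted,
                   use = if (cfg$detotal) "detotaled" else "detrended",
                   min_period = cfg$min_period, max_period = cfg$max_period,
                   ofac = cfg$ofac,
                   max_admissible_period = cfg$max_admissible_period,
                   p_threshold = cfg$p_threshold)
  scan_path <- file.path(cfg$out_dir, "scan.csv")
  write_scan(scan, scan_path, delim = cfg$delim, header_comment = stamp)

  clusters <- NULL
  paths <- c(config = cfg_path, counts = counts_path,
             adjusted = adj_path, scan = scan_path)
  if (sum(scan$significant) >= 2) {
    mat <- cluster_input(scan, adjusted,
                         use = if (cfg$detotal) "detotaled" else "detrended")
    clusters <- cluster_codes(mat, k = min(cfg$cluster_k, nrow(mat)))
    cl_path <- file.path(cfg$out_dir, "clusters.csv")
    con <- file(cl_path, "w")
    writeLines(paste0("# ", stamp), con)
    utils::write.table(
      data.frame(code = names(clusters$clusters),
                 cluster = unname(clusters$clusters)),
      con, sep = cfg$delim, row.names = FALSE, quote = FALSE)
    close(con)
    paths["clusters"] <- cl_path
  }
  invisible(list(counts = counts, adjusted = adjusted, scan = scan,
                 clusters = clusters, paths = paths))
}
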