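# Hierarchical clustering of seasonal codes on row-normalized monthly
# incidence, to expose groups with shared period and phase (e.g. the
# summer- vs winter-peaking split).

#' Row-normalize a codes x months matrix
#'
#' Z-scores each row (mean 0, unit variance). Zero-variance rows cannot be
#' normalized and are dropped with a warning.
#'
#' @param mat numeric matrix, rows = codes, columns = months; row names are
#'   code labels.
#' @return the normalized matrix.
#' @export
row_normalize <- function(mat) {
  mat <- as.matrix(mat)
  sds <- apply(mat, 1, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop)) {
    warning(sum(drop), " zero-variance row(s) dropped: ",
            paste(utils::head(rownames(mat)[drop], 5), collapse = ", "))
    mat <- mat[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  (mat - rowMeans(mat)) / sds
}

#' Assemble the clustering input from a scan result and adjusted series
#'
#' Takes the codes flagged significant in `scan`, stacks their chosen
#' adjusted series on the common months, and row-normalizes.
#'
#' @param scan a `scan_result` from [scan_all()].
#' @param adjusted list of `adjusted_series`.
#' @param use which series to stack (default `"detotaled"`).
#' @return numeric matrix (significant codes x months), row-normalized.
#' @export
cluster_input <- function(scan, adjusted, use = "detotaled") {
  sig <- scan$code[scan$significant]
  if (length(sig) < 2) stop("need >= 2 significant codes to cluster")
  series <- lapply(adjusted[sig], function(a) {
    y <- a[[use]]
    if (is.null(y)) stop("code '", a$code, "' has no '", use, "' series")
    y
  })
  len <- unique(vapply(series, length, integer(1)))
  if (length(len) != 1)
    stop("significant codes are on differing time axes; re-run adjust_all")
  mat <- do.call(rbind, series)
  rownames(mat) <- sig
  row_normalize(mat)
}

#' Hierarchically cluster codes by their seasonal profiles
#'
#' Agglomerative clustering with, by default, distance = 1 - Pearson
#' correlation between rows and average linkage. Correlation distance makes
#' the tree invariant to row scaling, so codes group by period and phase
#' rather than amplitude.
#'
#' @param mat row-normalized matrix from [cluster_input()] or
#'   [row_normalize()] (>= 2 rows).
#' @param distance `"correlation"` (1 - Pearson r) or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @param k optional number of flat clusters to cut.
#' @return An object of class `code_clusters`: list with `hclust` (the
#'   merge tree), `order` (leaf order), `labels`, and `clusters` (named
#'   integer vector when `k` is given, else `NULL`).
#' @export
cluster_codes <- function(mat, distance = c("correlation", "euclidean"),
                          linkage = "average", k = NULL) {
  distance <- match.arg(distance)
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need >= 2 rows to cluster")
  d <- switch(distance,
    correlation = stats::as.dist(1 - stats::cor(t(mat))),
    euclidean = stats::dist(mat))
  hc <- stats::hclust(d, method = linkage)
  structure(
    list(hclust = hc, order = hc$order, labels = rownames(mat),
         clusters = if (!is.null(k)) stats::cutree(hc, k = k)),
    class = "code_clusters")
}

#' @export
print.code_clusters <- function(x, ...) {
  cat(sprintf("code_clusters: %d codes%s\n", length(x$labels),
              if (is.null(x$clusters)) ""
              else sprintf(", %d flat clusters", max(x$clusters))))
  invisible(x)
}

#' Heatmap of clustered seasonal profiles
#'
#' Rows ordered by the dendrogram leaf order, diverging color scale
#' (elevated vs depressed incidence). Requires the pheatmap package.
#'
#' @param mat the row-normalized matrix that was clustered.
#' @param clusters a `code_clusters` object for `mat`.
#' @param file optional path; when given the plot is written there.
#' @return the pheatmap object, invisibly.
#' @export
plot_cluster_heatmap <- function(mat, clusters, file = NA) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_cluster_heatmap needs the 'pheatmap' package")
  ph <- pheatmap::pheatmap(
    mat, cluster_rows = clusters$hclust, cluster_cols = FALSE,
    show_colnames = FALSE, filename = file,
    color = grDevices::colorRampPalette(c("green3", "black", "red2"))(101))
  invisible(ph)
}
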