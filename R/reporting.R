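# Comparison artifacts: Pearson correlations between score sets,
# log-rescaled hierarchically clustered matrices for heatmaps, and PCA
# projections.

#' Pearson correlation between two paired score vectors
#'
#' Standard product-moment coefficient on untransformed scores; pairs with
#' a missing value in either vector are dropped listwise. Zero variance in
#' either vector makes the coefficient undefined, which is reported as
#' such rather than silently returned as `NA`.
#'
#' @param x,y numeric vectors of equal length, paired by (tissue, animal)
#'   or (tissue) keys.
#' @return A `correlation_result` list with `r`, `n` (pairs used), and
#'   `defined`.
#' @export
score_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("score vectors must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs, got ", n)
  defined <- stats::sd(x) > 0 && stats::sd(y) > 0
  r <- if (defined) stats::cor(x, y) else NA_real_
  structure(list(r = r, n = n, defined = defined),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("Pearson R = %.4f (n = %d pairs)\n", x$r, x$n))
  } else {
    cat(sprintf("Pearson R undefined (zero variance; n = %d pairs)\n", x$n))
  }
  invisible(x)
}

#' Log-rescaled, hierarchically clustered score matrix
#'
#' Prepares a score matrix for heatmap display: optional natural-log
#' rescaling (zeros mapped via `ln(max(x, eps))` with `eps` half the
#' smallest positive entry, keeping the transform monotone) and
#' unsupervised agglomerative clustering of rows and columns. Defaults are
#' euclidean distance with complete linkage. An all-constant matrix cannot
#' be clustered; input order is retained with a notice.
#'
#' @param scores numeric matrix or `score_matrix` (its `mean`/`values` are
#'   used).
#' @param log_transform natural-log rescale positive values (default
#'   `TRUE`).
#' @param method linkage for [stats::hclust()] (default `"complete"`).
#' @param metric distance for [stats::dist()] (default `"euclidean"`).
#' @return A `clustered_matrix` list: transformed `values`, `row_order`
#'   and `col_order` (permutations of the input indices), `method`,
#'   `metric`, `clustered`.
#' @export
cluster_matrix <- function(scores, log_transform = TRUE,
                           method = "complete", metric = "euclidean") {
  if (inherits(scores, "score_matrix")) {
    scores <- scores$mean %||% scores$values
  }
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L || ncol(scores) < 2L) {
    stop("need at least 2 rows and 2 columns to cluster")
  }
  v <- scores
  if (log_transform) {
    pos <- v[is.finite(v) & v > 0]
    if (!length(pos)) stop("no positive entries to log-rescale")
    eps <- min(pos) / 2
    v <- log(pmax(v, eps))
  }
  if (all(v == v[[1L]], na.rm = TRUE)) {
    message("matrix is constant; clustering skipped, input order retained")
    return(structure(list(values = v,
                          row_order = seq_len(nrow(v)),
                          col_order = seq_len(ncol(v)),
                          method = method, metric = metric,
                          clustered = FALSE),
                     class = "clustered_matrix"))
  }
  row_hc <- stats::hclust(stats::dist(v, method = metric), method = method)
  col_hc <- stats::hclust(stats::dist(t(v), method = metric), method = method)
  structure(list(values = v,
                 row_order = row_hc$order, col_order = col_hc$order,
                 row_hclust = row_hc, col_hclust = col_hc,
                 method = method, metric = metric, clustered = TRUE),
            class = "clustered_matrix")
}

#' @export
print.clustered_matrix <- function(x, ...) {
  cat(sprintf("Clustered matrix %d x %d (%s linkage, %s distance)%s\n",
              nrow(x$values), ncol(x$values), x$method, x$metric,
              if (!x$clustered) " [constant input, not clustered]" else ""))
  invisible(x)
}

#' PCA projection of score observations
#'
#' Column-centered (not variance-scaled by default, matching
#' [stats::prcomp()] defaults) principal components. Each component is
#' oriented so that its largest-magnitude loading is positive, making
#' outputs comparable across runs and implementations.
#'
#' @param x observations x features numeric matrix.
#' @param scale. also scale columns to unit variance.
#' @return List with `coordinates` (scores), `rotation` (loadings),
#'   `var_explained` (fractions summing to 1), and `sdev`.
#' @export
pca_project <- function(x, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 observations and 2 features")
  }
  if (all(apply(x, 2L, stats::sd) == 0)) stop("matrix has rank 0")
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[[which.max(abs(v))]])
  }, 0)
  flip[flip == 0] <- 1
  rotation <- sweep(p$rotation, 2L, flip, `*`)
  coordinates <- sweep(p$x, 2L, flip, `*`)
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(coordinates = coordinates, rotation = rotation,
       var_explained = ve, sdev = p$sdev)
}
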