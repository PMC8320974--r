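#' Principal coordinate analysis (classical metric MDS)
#'
#' Gower double-centring of `-0.5 * d^2` followed by eigendecomposition.
#' Coordinates are returned for positive eigenvalues only (scaled by the
#' square root of the eigenvalue); negative eigenvalues, which arise for
#' non-Euclidean dissimilarities, are reported unchanged and excluded from
#' the percent-variance denominator.
#'
#' @param d symmetric distance matrix
#' @param n_axes maximum number of coordinate axes to return (default: all
#'   positive-eigenvalue axes)
#' @return object of class `pcoa_result`: `eigenvalues` (descending),
#'   `coordinates` (individuals x axes), `percent` (percent variance per
#'   returned axis, relative to the positive-eigenvalue sum)
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("distance matrix contains NA/NaN or infinite values")
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  if (is.null(n_axes)) n_axes <- length(pos)
  axes <- pos[seq_len(min(n_axes, length(pos)))]
  coords <- e$vectors[, axes, drop = FALSE] %*% diag(sqrt(ev[axes]), length(axes))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_along(axes))
  structure(list(eigenvalues = ev,
                 coordinates = coords,
                 percent = 100 * ev[axes] / sum(ev[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(3L, length(x$percent))
  cat("<pcoa_result> ", nrow(x$coordinates), " points, ",
      ncol(x$coordinates), " axes; first ", k, " axes explain ",
      paste(sprintf("%.2f%%", x$percent[seq_len(k)]), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
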