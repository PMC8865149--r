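# Standardization + PCA of the weekly passive summary statistics.

#' Standardize features and fit a principal component analysis
#'
#' Z-scores each feature by its training mean/SD, then fits PCA on the
#' standardized rows. Features that are constant in training are dropped
#' with a warning (they carry no information and would break the scaling).
#' Component signs are fixed so that the loading of the anchor feature
#' (weekend distance traveled by default — the most interpretable
#' high-variance mobility feature) is nonnegative in every component,
#' making loadings reproducible across fits.
#'
#' @param x data.frame or matrix of feature rows (training fold only;
#'   rows with any `NA` are dropped).
#' @param anchor feature name used to fix component signs.
#' @return Object of class `"passive_pca"`: `center`, `scale`, `loadings`
#'   (features x components), `explained` (variance fractions, nonincreasing,
#'   summing to 1), `features` (those retained), `n` (training rows used).
#' @export
standardize_and_pca <- function(x, anchor = "weekend_distance_m") {
  x <- as.matrix(as.data.frame(x))
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 complete rows for PCA")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  const <- scl == 0 | !is.finite(scl)
  if (any(const)) {
    warning(sprintf("dropping constant feature(s) from PCA: %s",
                    paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
    ctr <- ctr[!const]; scl <- scl[!const]
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  load <- pc$rotation
  a <- if (anchor %in% rownames(load)) anchor else rownames(load)[1]
  flip <- load[a, ] < 0
  load[, flip] <- -load[, flip]
  structure(list(center = ctr, scale = scl, loadings = load,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 features = colnames(x), n = nrow(x)),
            class = "passive_pca")
}

#' Project new feature rows onto fitted components
#'
#' Applies the training standardizer and loadings to new rows. Rows with a
#' missing value in any retained feature get `NA` scores.
#'
#' @param object a `"passive_pca"`.
#' @param newdata data.frame/matrix containing the retained features.
#' @param ... unused.
#' @return Matrix of component scores (`PC1`, `PC2`, ...).
#' @export
predict.passive_pca <- function(object, newdata, ...) {
  m <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  z <- sweep(sweep(m, 2, object$center), 2, object$scale, "/")
  z %*% object$loadings
}

#' @export
print.passive_pca <- function(x, ...) {
  cat(sprintf("Passive-feature PCA: %d features, %d training rows\n",
              length(x$features), x$n))
  cat(sprintf("  PC1 explains %.1f%% of variance; PC2 %.1f%%\n",
              100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}
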