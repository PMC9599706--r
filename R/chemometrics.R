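#' Principal component analysis of a spectral window
#'
#' Covariance PCA: spectra are column-mean-centered (no unit-variance
#' scaling, so loadings retain band-intensity structure) and decomposed by
#' singular value decomposition. The sign of each component is fixed so that
#' its largest-magnitude loading coefficient is positive, making scores and
#' loadings reproducible across runs and linear-algebra backends. A `scale`
#' flag is provided for users who want correlation PCA.
#'
#' @param set an `ftir_spectra_set` (typically area-normalized and, following
#'   the pipeline, baseline-corrected per window).
#' @param q number of components to retain (`<= min(n, p)`).
#' @param window optional `c(lo, hi)` wavenumber window (half-closed
#'   `[lo, hi)`) to analyze; `NULL` for the full grid.
#' @param scale if `TRUE`, scale columns to unit variance after centering.
#' @return An object of class `ftir_pca`: list with `center` (mean spectrum),
#'   `scores` (n x q), `loadings` (q x p, orthonormal rows), `singular_values`
#'   (all `min(n,p)` values), `explained_variance_fraction` (first q),
#'   `wavenumber`, `metadata`, `window`.
#' @export
run_pca <- function(set, q = 3, window = NULL, scale = FALSE) {
  stopifnot(inherits(set, "ftir_spectra_set"))
  if (!is.null(window)) set <- extract_region_set(set, window[1], window[2])
  X <- set$absorbance
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("PCA needs at least two spectra", call. = FALSE)
  if (q < 1L || q > min(n, p)) stop("q must be in [1, min(n, p)]", call. = FALSE)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  if (scale) {
    s <- apply(Xc, 2L, sd)
    s[s == 0] <- 1
    Xc <- sweep(Xc, 2L, s, `/`)
  }
  sv <- svd(Xc)
  d <- sv$d
  V <- sv$v[, seq_len(q), drop = FALSE]
  U <- sv$u[, seq_len(q), drop = FALSE]
  # sign convention: largest-|loading| coefficient of each PC positive
  for (i in seq_len(q)) {
    j <- which.max(abs(V[, i]))
    if (V[j, i] < 0) {
      V[, i] <- -V[, i]
      U[, i] <- -U[, i]
    }
  }
  scores <- U %*% diag(d[seq_len(q)], nrow = q)
  rownames(scores) <- set$metadata$spectrum_id
  colnames(scores) <- paste0("PC", seq_len(q))
  loadings <- t(V)
  rownames(loadings) <- paste0("PC", seq_len(q))
  colnames(loadings) <- format(set$wavenumber, trim = TRUE)
  structure(
    list(center = center, scores = scores, loadings = loadings,
         singular_values = d,
         explained_variance_fraction = (d^2 / sum(d^2))[seq_len(q)],
         wavenumber = set$wavenumber, metadata = set$metadata,
         window = if (is.null(window)) range(set$wavenumber) else window,
         scaled = scale),
    class = "ftir_pca"
  )
}

#' Per-wavenumber squared correlation of the leading components
#'
#' For each wavenumber column j and component i `<= k`, the incremental R^2
#' is the sum of squares explained by component i at column j divided by the
#' total centered sum of squares at column j. Components are orthogonal, so
#' the cumulative R^2 over all components is 1 at every column with nonzero
#' variance.
#'
#' @param pca an `ftir_pca`.
#' @param set the `ftir_spectra_set` the PCA was run on (same window applied).
#' @param k number of leading components to report (`<= q`).
#' @return Matrix k x p of R^2 values (`NA` at zero-variance columns), with a
#'   `"cumulative"` attribute holding the column sums over the k components.
#' @export
per_wavenumber_r2 <- function(pca, set, k = nrow(pca$loadings)) {
  stopifnot(inherits(pca, "ftir_pca"))
  if (k < 1L || k > nrow(pca$loadings)) stop("k must be in [1, q]", call. = FALSE)
  cols <- match(pca$wavenumber, set$wavenumber)
  if (anyNA(cols)) stop("set does not contain the PCA window grid", call. = FALSE)
  Xc <- sweep(set$absorbance[, cols, drop = FALSE], 2L, pca$center)
  if (isTRUE(pca$scaled)) {
    s <- apply(Xc, 2L, sd); s[s == 0] <- 1
    Xc <- sweep(Xc, 2L, s, `/`)
  }
  ss_total <- colSums(Xc^2)
  out <- matrix(NA_real_, nrow = k, ncol = ncol(Xc),
                dimnames = list(paste0("PC", seq_len(k)), colnames(pca$loadings)))
  nz <- ss_total > 0
  for (i in seq_len(k)) {
    ss_i <- sum(pca$scores[, i]^2) * pca$loadings[i, ]^2
    out[i, nz] <- ss_i[nz] / ss_total[nz]
  }
  structure(out, cumulative = colSums(out))
}

#' Ward hierarchical clustering in score space
#'
#' Agglomerative clustering of the spectra by Ward's minimum-variance
#' criterion on Euclidean distances between their q-dimensional PC score
#' rows (clustering operates in score space, not on raw spectra). Linkage
#' heights are Ward distances (`ward.D2` convention: the squared merge height
#' equals twice the increase in total within-cluster sum of squares).
#'
#' @param pca an `ftir_pca`.
#' @return An object of classes `ftir_dendrogram` and `hclust` (so
#'   [stats::cutree()] and plotting work directly), with `method = "ward"`
#'   and `metric = "euclidean"` recorded.
#' @export
hca_ward <- function(pca) {
  stopifnot(inherits(pca, "ftir_pca"))
  if (nrow(pca$scores) < 2L) stop("clustering needs at least two spectra", call. = FALSE)
  hc <- hclust(dist(pca$scores, method = "euclidean"), method = "ward.D2")
  hc$labels <- rownames(pca$scores)
  hc$method <- "ward"
  hc$dist.method <- "euclidean"
  class(hc) <- c("ftir_dendrogram", "hclust")
  hc
}

#' Serialize a dendrogram merge list
#'
#' @param dend an `ftir_dendrogram`.
#' @return data.frame with one row per merge: child node codes (negative =
#'   leaf index, positive = earlier merge) and linkage height.
#' @export
dendrogram_table <- function(dend) {
  data.frame(node_a = dend$merge[, 1], node_b = dend$merge[, 2],
             height = dend$height)
}

#' Per-condition score centroids
#'
#' Mean PC-score row per condition label; the condition-level representative
#' points used for the class dendrogram and biplot associations. Unlabeled
#' spectra (missing/empty condition) are excluded with a warning.
#'
#' @param pca an `ftir_pca` (carries the metadata of the set it was fit on).
#' @return Matrix (conditions x q) of score centroids.
#' @export
class_representatives <- function(pca) {
  stopifnot(inherits(pca, "ftir_pca"))
  cond <- pca$metadata$condition
  keep <- !is.na(cond) & cond != ""
  if (!all(keep)) {
    warning(sum(!keep), " unlabeled spectra excluded from class representatives")
  }
  if (!any(keep)) stop("no labeled spectra", call. = FALSE)
  ag <- aggregate(pca$scores[keep, , drop = FALSE], by = list(condition = cond[keep]), FUN = mean)
  out <- as.matrix(ag[, -1, drop = FALSE])
  rownames(out) <- ag$condition
  out
}

#' Condition-level dendrogram of class representatives
#'
#' Ward clustering of the per-condition score centroids; with three
#' conditions this reproduces the three-leaf condition-level tree. A Newick
#' string is attached for export when the `ape` package is available.
#'
#' @param pca an `ftir_pca`.
#' @return An `ftir_dendrogram` over the condition centroids, with attribute
#'   `newick` (or `NA` if `ape` is unavailable).
#' @export
representatives_dendrogram <- function(pca) {
  reps <- class_representatives(pca)
  hc <- hclust(dist(reps, method = "euclidean"), method = "ward.D2")
  hc$labels <- rownames(reps)
  class(hc) <- c("ftir_dendrogram", "hclust")
  nwk <- NA_character_
  if (requireNamespace("ape", quietly = TRUE)) {
    nwk <- ape::write.tree(ape::as.phylo(stats::as.hclust(structure(hc, class = "hclust"))))
  }
  attr(hc, "newick") <- nwk
  hc
}

#' Biplot association table
#'
#' Associates every wavenumber in the PCA window with the condition whose
#' score centroid (in the PC1-PC2 plane) makes the smallest angle with that
#' wavenumber's loading vector. Loading vectors with norm below
#' `none_threshold` times the maximum norm, and exact ties, are labeled
#' `"none"`. The angular rule and threshold are configurable conventions, not
#' fitted quantities.
#'
#' @param pca an `ftir_pca` with `q >= 2`.
#' @param none_threshold relative loading-norm floor below which no
#'   association is assigned.
#' @return data.frame (`wavenumber`, `pc1`, `pc2`, `association`) with the
#'   per-spectrum PC1/PC2 score coordinates attached as attribute `scores`.
#' @export
biplot_table <- function(pca, none_threshold = 0.05) {
  stopifnot(inherits(pca, "ftir_pca"))
  if (nrow(pca$loadings) < 2L) stop("biplot needs at least two components", call. = FALSE)
  reps <- class_representatives(pca)[, 1:2, drop = FALSE]
  if (nrow(reps) < 2L) stop("biplot association needs >= 2 conditions", call. = FALSE)
  L <- t(pca$loadings[1:2, , drop = FALSE])     # p x 2
  lnorm <- sqrt(rowSums(L^2))
  rnorm_ <- sqrt(rowSums(reps^2))
  cosines <- (L %*% t(reps)) / outer(pmax(lnorm, .Machine$double.eps),
                                     pmax(rnorm_, .Machine$double.eps))
  assoc <- apply(cosines, 1L, function(cs) {
    top <- max(cs)
    hits <- which(cs >= top - 1e-12)
    if (length(hits) != 1L) "none" else rownames(reps)[hits]
  })
  assoc[lnorm < none_threshold * max(lnorm)] <- "none"
  out <- data.frame(wavenumber = pca$wavenumber,
                    pc1 = L[, 1], pc2 = L[, 2],
                    association = assoc, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "scores") <- data.frame(spectrum_id = rownames(pca$scores),
                                    condition = pca$metadata$condition,
                                    pc1 = pca$scores[, 1], pc2 = pca$scores[, 2],
                                    stringsAsFactors = FALSE)
  out
}

#' @export
print.ftir_pca <- function(x, ...) {
  cat(sprintf("<ftir_pca> %d spectra x %d wavenumbers, window %.0f-%.0f cm-1\n",
              nrow(x$scores), length(x$center), x$window[2], x$window[1]))
  cat("explained variance:",
      paste(sprintf("PC%d=%.1f%%", seq_along(x$explained_variance_fraction),
                    100 * x$explained_variance_fraction), collapse = ", "), "\n")
  invisible(x)
}
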