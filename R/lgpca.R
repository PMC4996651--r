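#' Lineage-guided principal components analysis
#'
#' Diagonalizes the lineage-weighted covariance of an expression matrix. With
#' samples-by-genes data X (column-centered, optionally column-scaled) and the
#' symmetrized lineage proximity \eqn{W_s = (W + W^T)/2}, the axes are the
#' eigenvectors of \eqn{H = X^T W_s X / n}, ordered by signed eigenvalue,
#' descending. Each eigenvalue factorizes as \eqn{\lambda_k =
#' \mathrm{var}(y_k)\, I(y_k)} where \eqn{y_k = X u_k} are the sample scores,
#' \eqn{\mathrm{var}(y) = \sum y^2 / n} and \eqn{I(y) = y^T W_s y / y^T y} is
#' Moran's I under the lineage weighting. Axes with positive eigenvalues carry
#' "global" structure (related samples score similarly); negative eigenvalues
#' mark "local" structure (related samples diverge).
#'
#' Because the number of genes far exceeds the number of samples, the
#' eigensystem is computed in the row space of X via its singular value
#' decomposition; on small instances this matches the direct gene-by-gene
#' eigendecomposition to numerical precision. The sign of each axis is
#' arbitrary; it is fixed by making the largest-magnitude gene loading
#' positive.
#'
#' @param x numeric matrix of normalized expression, genes in rows, samples in
#'   columns. Column names must match the proximity labels.
#' @param prox square lineage proximity matrix indexed by sample (see
#'   \code{\link{abouheif_proximity}}); a \code{lineage_tree} is also accepted
#'   and converted.
#' @param scale. scale every gene to unit variance after centering (default
#'   TRUE). Genes constant across samples are set to zero with a warning.
#' @param rank_tol axes with \eqn{|\lambda|} below \code{rank_tol} times the
#'   largest \eqn{|\lambda|} are dropped (default 1e-9).
#' @return an object of class \code{"lgpca"} with components
#'   \item{eigenvalues}{signed eigenvalues, descending;}
#'   \item{scores}{samples-by-axes score matrix;}
#'   \item{loadings}{genes-by-axes loading matrix, columns unit-norm;}
#'   \item{moran, var_scores}{Moran's I and variance of each score vector;}
#'   \item{center, scale}{the per-gene centering/scaling vectors applied.}
#' @seealso \code{\link{partition_axes}}, \code{\link{extreme_genes}},
#'   \code{\link{loading_gene_set_test}}
#' @export
lgpca <- function(x, prox, scale. = TRUE, rank_tol = 1e-9) {
  cl <- match.call()
  if (inherits(prox, "phylo")) prox <- abouheif_proximity(prox)
  samples <- colnames(x)
  if (is.null(samples)) stop("`x` must have sample column names")
  if (ncol(x) < 3L) stop("need at least 3 samples")
  if (!setequal(samples, rownames(prox))) {
    only_x <- setdiff(samples, rownames(prox))
    only_w <- setdiff(rownames(prox), samples)
    stop("sample/leaf label mismatch; only in expression: {",
         paste(only_x, collapse = ", "), "}; only in proximity: {",
         paste(only_w, collapse = ", "), "}")
  }
  W <- prox[samples, samples]
  Ws <- (W + t(W)) / 2
  X <- t(x)                              # samples x genes
  n <- nrow(X)
  ctr <- colMeans(X)
  X <- sweep(X, 2, ctr)
  scl <- NULL
  if (scale.) {
    scl <- sqrt(colMeans(X^2))           # population sd
    const <- scl <= 0
    if (any(const)) {
      warning(sum(const), " constant gene(s) set to zero under scaling")
      scl[const] <- 1
    }
    X <- sweep(X, 2, scl, "/")
    X[, const] <- 0
  }
  s <- svd(X)
  keep <- s$d > max(s$d) * 1e-12
  U <- s$u[, keep, drop = FALSE]
  d <- s$d[keep]
  V <- s$v[, keep, drop = FALSE]
  K <- crossprod(U, Ws %*% U)
  M <- (K + t(K)) / 2 * tcrossprod(d) / n
  eig <- eigen(M, symmetric = TRUE)      # eigenvalues descending
  lambda <- eig$values
  ax <- abs(lambda) > rank_tol * max(abs(lambda))
  lambda <- lambda[ax]
  Q <- eig$vectors[, ax, drop = FALSE]
  loadings <- V %*% Q
  scores <- U %*% (d * Q)
  # canonical sign: largest-|loading| gene positive on every axis
  flip <- vapply(seq_len(ncol(loadings)), function(k) {
    loadings[which.max(abs(loadings[, k])), k] < 0
  }, logical(1))
  loadings[, flip] <- -loadings[, flip, drop = FALSE]
  scores[, flip] <- -scores[, flip, drop = FALSE]
  axes <- paste0("PC", seq_along(lambda))
  dimnames(scores) <- list(samples, axes)
  dimnames(loadings) <- list(rownames(x), axes)
  var_scores <- colMeans(scores^2)
  moran <- colSums(scores * (Ws %*% scores)) / colSums(scores^2)
  structure(list(eigenvalues = stats::setNames(lambda, axes),
                 scores = scores, loadings = loadings,
                 var_scores = var_scores, moran = moran,
                 center = ctr, scale = scl, scaled = scale.,
                 n = n, rank_tol = rank_tol, call = cl),
            class = "lgpca")
}

#' @export
print.lgpca <- function(x, ...) {
  cat("Lineage-guided PCA\n")
  cat("  samples:", x$n, " genes:", nrow(x$loadings),
      " retained axes:", length(x$eigenvalues), "\n")
  cat("  global candidates (lambda > 0):", sum(x$eigenvalues > 0), "\n")
  cat("  eigenvalue range: [", format(min(x$eigenvalues), digits = 4), ", ",
      format(max(x$eigenvalues), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
summary.lgpca <- function(object, ...) {
  tab <- data.frame(axis = names(object$eigenvalues),
                    eigenvalue = object$eigenvalues,
                    var = object$var_scores,
                    moran_I = object$moran,
                    structure = ifelse(object$eigenvalues > 0,
                                       "global", "local"),
                    row.names = NULL)
  class(tab) <- c("summary.lgpca", "data.frame")
  tab
}

#' @export
print.summary.lgpca <- function(x, ...) {
  cat("LgPCA axis decomposition (lambda = var x Moran's I):\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Plot an LgPCA eigenvalue decomposition
#'
#' Variance against Moran's I for every retained axis; iso-eigenvalue
#' position separates lineage-coherent (I > 0) from heterogeneity axes.
#'
#' @param x an \code{lgpca} fit.
#' @param ... passed to \code{plot}.
#' @export
plot.lgpca <- function(x, ...) {
  plot(x$var_scores, x$moran, xlab = "var(score)",
       ylab = "Moran's I", pch = 19,
       main = "LgPCA decomposition", ...)
  graphics::abline(h = 0, lty = 2)
  graphics::text(x$var_scores, x$moran, names(x$eigenvalues),
                 pos = 3, cex = 0.7)
  invisible(x)
}

#' @export
screeplot.lgpca <- function(x, ...) {
  graphics::barplot(x$eigenvalues, las = 2,
                    ylab = "signed eigenvalue", ...)
  invisible(x)
}

#' Project new samples onto fitted LgPCA axes
#'
#' @param object an \code{lgpca} fit.
#' @param newdata genes-by-samples matrix on the same genes (by name) as the
#'   training matrix.
#' @param ... unused.
#' @return samples-by-axes score matrix.
#' @export
predict.lgpca <- function(object, newdata, ...) {
  genes <- rownames(object$loadings)
  if (!all(genes %in% rownames(newdata)))
    stop("newdata is missing ", sum(!genes %in% rownames(newdata)),
         " training genes")
  Xn <- t(newdata[genes, , drop = FALSE])
  Xn <- sweep(Xn, 2, object$center)
  if (object$scaled) Xn <- sweep(Xn, 2, object$scale, "/")
  Xn %*% object$loadings
}

#' Partition LgPCA axes into global and local sets
#'
#' The first \code{n_global} axes (signed-eigenvalue order) are labeled
#' global, the rest local. The sign-based suggestion (number of axes with
#' positive eigenvalue) is reported alongside.
#'
#' @param object an \code{lgpca} fit.
#' @param n_global how many leading axes to call global (e.g. 15 of 31).
#' @return list with \code{global}, \code{local} (axis names) and
#'   \code{suggested_n_global}.
#' @export
partition_axes <- function(object, n_global) {
  k <- length(object$eigenvalues)
  if (n_global < 0 || n_global > k)
    stop("n_global must be between 0 and ", k)
  axes <- names(object$eigenvalues)
  list(global = axes[seq_len(n_global)],
       local = if (n_global < k) axes[(n_global + 1L):k] else character(),
       suggested_n_global = sum(object$eigenvalues > 0))
}

#' Extreme-loading genes of an axis
#'
#' The k genes with the largest (high pole) and the k with the most negative
#' (low pole) loadings on one axis. Ties are broken by gene ID,
#' lexicographically; the two sets are disjoint.
#'
#' @param object an \code{lgpca} fit.
#' @param axis axis index or name (e.g. \code{"PC1"}).
#' @param k genes per pole (default 1000); must not exceed half the gene count.
#' @return list with character vectors \code{high} and \code{low}.
#' @export
extreme_genes <- function(object, axis, k = 1000) {
  l <- .axis_loadings(object, axis)
  ids <- names(l)
  if (k > length(l) / 2)
    stop("k = ", k, " exceeds half the gene count (", length(l), ")")
  high <- ids[order(-l, ids)][seq_len(k)]
  low <- ids[order(l, ids)][seq_len(k)]
  list(high = high, low = low)
}

.axis_loadings <- function(object, axis) {
  if (is.character(axis)) {
    if (!axis %in% colnames(object$loadings))
      stop("no such axis: ", axis)
  } else if (axis < 1 || axis > ncol(object$loadings)) {
    stop("axis index out of range: ", axis)
  }
  object$loadings[, axis]
}

#' Rank-sum test of a gene set against an axis' loadings
#'
#' Two-sided Wilcoxon rank-sum test of the loadings of genes in the set
#' against all remaining genes on one axis, with the rank-biserial correlation
#' as effect size and the enriched pole as direction. Sets of
#' \code{min_size} or fewer genes are skipped (strict inequality).
#'
#' @param object an \code{lgpca} fit.
#' @param axis axis index or name.
#' @param gene_set character vector of gene IDs; IDs absent from the fit are
#'   dropped with a warning.
#' @param min_size minimum set size, exclusive (default 10: a 10-gene set is
#'   skipped).
#' @return list with \code{status} ("ok" or "skipped"), \code{p_value},
#'   \code{direction} ("high"/"low"), \code{rank_biserial}, \code{n_set},
#'   \code{n_background}.
#' @export
loading_gene_set_test <- function(object, axis, gene_set, min_size = 10) {
  l <- .axis_loadings(object, axis)
  absent <- setdiff(gene_set, names(l))
  if (length(absent)) {
    warning(length(absent), " gene(s) in set absent from fit; dropped")
    gene_set <- setdiff(gene_set, absent)
  }
  if (length(gene_set) <= min_size) {
    return(list(status = "skipped",
                reason = sprintf("set size %d <= min_size %d",
                                 length(gene_set), min_size),
                p_value = NA_real_, direction = NA_character_,
                rank_biserial = NA_real_,
                n_set = length(gene_set),
                n_background = length(l) - length(gene_set)))
  }
  inset <- names(l) %in% gene_set
  wt <- stats::wilcox.test(l[inset], l[!inset], exact = FALSE)
  n1 <- sum(inset); n2 <- sum(!inset)
  rb <- 2 * unname(wt$statistic) / (n1 * n2) - 1
  list(status = "ok", p_value = wt$p.value,
       direction = if (rb >= 0) "high" else "low",
       rank_biserial = rb, n_set = n1, n_background = n2)
}
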