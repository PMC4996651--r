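#' Read a gene-by-sample count matrix from TSV
#'
#' First column is the gene identifier, header row holds sample identifiers.
#'
#' @param path TSV file path.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_counts(m)
  m
}

#' Write an expression matrix as TSV
#' @param x matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param id_col name of the identifier column, default \code{"gene_id"}.
#' @export
write_expression <- function(x, path, id_col = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet mapping samples to tissues
#'
#' Expects columns \code{sample} and \code{tissue} (an optional \code{batch}
#' column is carried through).
#'
#' @param path TSV path.
#' @return data.frame with at least columns \code{sample}, \code{tissue}.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("sample", "tissue") %in% names(df)))
    stop("sample sheet needs columns `sample` and `tissue`")
  if (anyDuplicated(df$sample))
    stop("duplicate sample IDs in sample sheet")
  df
}

validate_counts <- function(m) {
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("gene IDs must be present and unique")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("sample IDs must be present and unique")
  if (any(m < 0)) stop("count matrix has negative entries")
  invisible(m)
}

#' Quantile-normalize an expression matrix across samples
#'
#' Each column is forced onto a common reference distribution: the reference
#' value for rank r is the mean over samples of every sample's r-th order
#' statistic. Entries are replaced by the reference value of their
#' within-column rank; tied entries receive the mean of the reference values
#' over their tied ranks.
#'
#' @param counts genes-by-samples numeric matrix (at least 2 columns).
#' @return matrix of the same shape and dimnames. In the absence of ties every
#'   column holds an identical multiset of values.
#' @examples
#' m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' quantile_normalize(m)  # both columns become 2.5, 3.5, 4.5
#' @export
quantile_normalize <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) < 1L)
    stop("`counts` must be a matrix with at least one gene")
  if (ncol(counts) < 2L) stop("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(counts, 2, sort))
  out <- apply(counts, 2, function(x) {
    v <- numeric(length(x))
    v[order(x)] <- ref
    # average the reference values over groups of tied input values
    stats::ave(v, match(x, x), FUN = mean)
  })
  dimnames(out) <- dimnames(counts)
  out
}

#' Tissue-specificity index Tau
#'
#' Tau is computed on per-tissue mean expression: replicate columns of each
#' tissue are averaged first, then for each gene
#' \deqn{\tau = \sum_i (1 - x_i / x_{max}) / (N - 1)}
#' over the N tissues. Tau is 0 for uniform expression and 1 for expression
#' confined to a single tissue. Genes whose tissue means are all zero have an
#' undefined Tau and are returned as \code{NA}.
#'
#' @param norm genes-by-samples matrix of normalized (non-negative) expression.
#' @param tissue_map named character vector mapping sample ID to tissue, or a
#'   sample-sheet data.frame with columns \code{sample}, \code{tissue}.
#' @param log2_transform apply \code{log2(x + 1)} to the matrix before
#'   averaging (off by default: Tau is taken on linear-scale means).
#' @return named numeric vector of per-gene Tau in [0, 1] (NA where undefined).
#' @examples
#' m <- rbind(g1 = c(8, 8, 8, 8), g2 = c(8, 0, 0, 0))
#' tau(m, stats::setNames(paste0("t", 1:4), colnames(m)))
#' @export
tau <- function(norm, tissue_map, log2_transform = FALSE) {
  if (is.data.frame(tissue_map))
    tissue_map <- stats::setNames(tissue_map$tissue, tissue_map$sample)
  if (is.null(colnames(norm))) colnames(norm) <- names(tissue_map)
  missing <- setdiff(colnames(norm), names(tissue_map))
  if (length(missing))
    stop("samples without tissue assignment: ", paste(missing, collapse = ", "))
  if (any(norm < 0)) stop("Tau requires non-negative expression values")
  if (log2_transform) norm <- log2(norm + 1)
  tis <- tissue_map[colnames(norm)]
  tissues <- unique(tis)
  if (length(tissues) < 2L)
    stop("Tau is undefined for a single tissue (N - 1 = 0)")
  means <- matrix(vapply(tissues, function(t)
    rowMeans(norm[, tis == t, drop = FALSE]), numeric(nrow(norm))),
    nrow = nrow(norm))
  xmax <- apply(means, 1, max)
  res <- rowSums(1 - means / xmax) / (length(tissues) - 1)
  res[xmax == 0] <- NA_real_
  stats::setNames(res, rownames(norm))
}

#' Prefilter a count matrix for metagene extraction
#'
#' Drops genes named in \code{excluded_genes} (e.g. Y-linked genes and XIST,
#' supplied by the caller so the operation stays annotation-free) and genes
#' whose total count across all samples is below \code{min_total}. A gene with
#' total exactly \code{min_total} is retained.
#'
#' @param counts genes-by-samples count matrix.
#' @param excluded_genes character vector of gene IDs to drop unconditionally.
#' @param min_total minimum total read count across samples (default 100).
#' @return the filtered matrix; columns unchanged.
#' @export
prefilter_counts <- function(counts, excluded_genes = character(),
                             min_total = 100) {
  keep <- !(rownames(counts) %in% excluded_genes) &
    rowSums(counts) >= min_total
  if (!any(keep)) warning("prefilter removed every gene")
  counts[keep, , drop = FALSE]
}
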