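#' Abouheif topological proximity between tree leaves
#'
#' Computes the tip-by-tip proximity matrix used to weight the lineage-guided
#' PCA. For leaves i and j the raw proximity is the reciprocal of the product
#' of direct-descendant counts of every internal node on the path connecting
#' them; the diagonal is zero. Branch lengths play no role. With the default
#' variant each row is then divided by its sum, so rows sum to exactly 1.
#'
#' @param tree a \code{lineage_tree} (see \code{\link{read_lineage_tree}}).
#' @param variant \code{"Abouheif"} (row-normalized, zero diagonal; the form
#'   the lineage-guided PCA consumes) or \code{"raw"} (unnormalized symmetric
#'   path products, zero diagonal).
#' @return a square numeric matrix indexed by leaf labels.
#' @examples
#' tr <- read_lineage_tree("((A,B),(C,D));")
#' abouheif_proximity(tr)["A", ]  # B: 2/3, C and D: 1/6 each
#' @export
abouheif_proximity <- function(tree, variant = c("Abouheif", "raw")) {
  variant <- match.arg(variant)
  if (!inherits(tree, "phylo")) stop("`tree` must be a lineage tree")
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 2L) stop("tree must have at least 2 leaves")
  ntot <- n + tree$Nnode
  # direct-descendant count of every node (0 for tips)
  dd <- tabulate(tree$edge[, 1], nbins = ntot)
  parent <- integer(ntot)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  # ancestor chains from each tip to the root
  chain <- lapply(seq_len(n), function(tip) {
    path <- tip
    v <- tip
    while (v != root) {
      v <- parent[v]
      path <- c(path, v)
    }
    path
  })
  A <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ci <- chain[[i]]
      cj <- chain[[j]]
      # path i -> j = both chains up to (and including) the MRCA
      mrca <- ci[min(which(ci %in% cj))]
      nodes <- c(ci[seq_len(which(ci == mrca))], cj[seq_len(which(cj == mrca))])
      nodes <- setdiff(unique(nodes), c(i, j))
      A[i, j] <- A[j, i] <- 1 / prod(dd[nodes])
    }
  }
  if (variant == "Abouheif") A <- A / rowSums(A)
  A
}

#' Write / read a proximity matrix as TSV
#'
#' Plain-text exchange format: leaf labels as both header and first column.
#'
#' @param prox square proximity matrix with dimnames.
#' @param path output file path.
#' @return \code{write_proximity}: the path, invisibly.
#'   \code{read_proximity}: the matrix.
#' @export
write_proximity <- function(prox, path) {
  df <- data.frame(leaf = rownames(prox), prox, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proximity
#' @export
read_proximity <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
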