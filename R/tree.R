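#' Parse a developmental-lineage tree from newick text
#'
#' Reads a rooted guide tree whose leaves are RNA-seq samples. Branch lengths,
#' if present, are silently dropped: lineage weighting uses topology only.
#' Internal nodes with a single child are collapsed at parse time (they carry
#' no topological information and would violate the multifurcation invariant).
#'
#' @param text a newick string, e.g. \code{"((A,B),(C,D));"}. Exactly one of
#'   \code{text}/\code{file} must be given.
#' @param file path to a newick file.
#' @return an object of class \code{lineage_tree}: an \code{ape} \code{phylo}
#'   tree (topology only) with attribute checks applied. Leaf labels are the
#'   sample identifiers.
#' @examples
#' tr <- read_lineage_tree("((A,B),(C,D));")
#' leaf_labels(tr)
#' @export
read_lineage_tree <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  .check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("newick parse error: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("newick parse error: string could not be parsed")
  phy <- ape::collapse.singles(phy)
  phy$edge.length <- NULL
  validate_lineage_tree(phy)
  class(phy) <- c("lineage_tree", "phylo")
  phy
}

# minimal syntactic pre-scan so malformed strings fail with the offending
# character position (ape's own messages do not locate the error)
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unbalanced ')' at position ", i,
             call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("newick parse error: ", depth, " unclosed '(' at end of string ",
         "(position ", nchar(text), ")", call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop("newick parse error: missing terminal ';' at position ",
         nchar(text), call. = FALSE)
  invisible(TRUE)
}

#' Validate lineage-tree invariants
#'
#' Checks that the tree is rooted, has at least 3 leaves, unique leaf labels,
#' and that every internal node has at least two children.
#'
#' @param phy a \code{phylo} object.
#' @return the tree, invisibly, if valid; otherwise an error.
#' @export
validate_lineage_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a phylo tree")
  n <- length(phy$tip.label)
  if (n < 3L) stop("lineage tree must have at least 3 leaves, got ", n)
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  # every parsed newick has a structural root node; a basal polytomy (star
  # tree) is treated as rooted there, which is all lineage weighting needs
  deg <- tabulate(phy$edge[, 1], nbins = n + phy$Nnode)
  internal <- (n + 1L):(n + phy$Nnode)
  bad <- internal[deg[internal] < 2L]
  if (length(bad))
    stop("internal node(s) with fewer than 2 children: ",
         paste(bad, collapse = ", "))
  invisible(phy)
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("Developmental-lineage tree (topology only)\n")
  cat("  leaves: ", length(x$tip.label), "; internal nodes: ", x$Nnode,
      "\n", sep = "")
  cat("  samples:", paste(utils::head(x$tip.label, 8), collapse = ", "),
      if (length(x$tip.label) > 8) "...", "\n")
  invisible(x)
}

#' Leaf (sample) labels of a lineage tree
#' @param tree a \code{lineage_tree}.
#' @return character vector of sample identifiers.
#' @export
leaf_labels <- function(tree) tree$tip.label

#' Tips descended from a named clade
#'
#' Resolves a clade either by an internal node label present in the tree or by
#' a set of tip labels whose most recent common ancestor defines the clade.
#'
#' @param tree a \code{lineage_tree}.
#' @param node an internal node label (character scalar) or a character vector
#'   of two or more tip labels.
#' @return character vector of tip labels under the clade.
#' @export
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (length(node) == 1L && !is.null(tree$node.label) &&
      node %in% tree$node.label) {
    idx <- ntip + match(node, tree$node.label)
  } else if (all(node %in% tree$tip.label)) {
    if (length(node) == 1L) return(node)
    idx <- ape::getMRCA(tree, node)
  } else {
    stop("clade node not in tree: ", paste(node, collapse = ", "))
  }
  desc <- .descendant_tips(tree, idx)
  tree$tip.label[desc]
}

.descendant_tips <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, .descendant_tips, phy = phy))
}
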