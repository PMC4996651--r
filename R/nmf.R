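# run code with a private, seeded RNG stream, leaving the caller's untouched
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# fold derived seeds into the 32-bit integer range
.derive_seed <- function(...) {
  v <- as.numeric(c(...))
  as.integer(sum(v * 7919 ^ (seq_along(v) - 1)) %% 2147483629)
}

#' Non-negative matrix factorization with Brunet multiplicative updates
#'
#' Factors a non-negative genes-by-samples matrix V into basis W (genes x r)
#' and coefficients H (r x samples) by minimizing the generalized
#' Kullback-Leibler divergence D(V || WH) with the Brunet variant of the
#' multiplicative update rules. Initialization is random uniform on
#' (0, max(V)/r) under the given seed, so runs are reproducible bit for bit.
#' Iteration stops at \code{max_iter} or once the sample connectivity matrix
#' (co-clustering by argmax coefficient) has been unchanged for
#' \code{stall_checks} consecutive checks taken every \code{check_every}
#' iterations.
#'
#' @param V non-negative matrix, no all-zero row or column.
#' @param r factorization rank, below \code{min(dim(V))}.
#' @param max_iter iteration cap (default 2000).
#' @param seed RNG seed (mandatory; reproducibility contract).
#' @param check_every,stall_checks connectivity stall-stopping controls; set
#'   \code{stall_checks = Inf} to always run to \code{max_iter}.
#' @param eps small constant guarding divisions (default machine epsilon).
#' @return object of class \code{"nmf_brunet"}: \code{W}, \code{H},
#'   \code{rank}, \code{kl_trace} (divergence per recorded iteration),
#'   \code{iterations}, \code{seed}.
#' @export
nmf_brunet <- function(V, r, max_iter = 2000, seed,
                       check_every = 10, stall_checks = 40,
                       eps = .Machine$double.eps) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (any(V < 0)) stop("V must be non-negative")
  if (r >= min(dim(V))) stop("rank r = ", r, " must be < min(dim(V)) = ",
                             min(dim(V)))
  zr <- which(rowSums(V) == 0); zc <- which(colSums(V) == 0)
  if (length(zr)) stop("all-zero row(s): ",
                       paste(utils::head(rownames(V)[zr], 5), collapse = ", "))
  if (length(zc)) stop("all-zero column(s): ",
                       paste(utils::head(colnames(V)[zc], 5), collapse = ", "))
  n <- nrow(V); m <- ncol(V)
  with_seed(seed, {
    W <- matrix(stats::runif(n * r, 0, max(V) / r), n, r)
    H <- matrix(stats::runif(r * m, 0, max(V) / r), r, m)
  })
  kl <- function(WH) {
    P <- V > 0
    sum(V[P] * log(V[P] / WH[P])) - sum(V) + sum(WH)
  }
  trace <- numeric(0)
  last_conn <- NULL
  stable <- 0L
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    WH <- W %*% H
    H <- H * (crossprod(W, V / (WH + eps))) / (colSums(W) + eps)
    WH <- W %*% H
    W <- W * ((V / (WH + eps)) %*% t(H)) / rep(rowSums(H) + eps, each = n)
    trace[it] <- kl(W %*% H + eps)
    if (it %% check_every == 0L && is.finite(stall_checks)) {
      cl <- max.col(t(H))
      conn <- outer(cl, cl, "==")
      if (!is.null(last_conn) && identical(conn, last_conn)) {
        stable <- stable + 1L
        if (stable >= stall_checks) break
      } else stable <- 0L
      last_conn <- conn
    }
  }
  dimnames(W) <- list(rownames(V), paste0("metagene", seq_len(r)))
  dimnames(H) <- list(paste0("metagene", seq_len(r)), colnames(V))
  structure(list(W = W, H = H, rank = r, kl_trace = trace,
                 iterations = it, seed = seed),
            class = "nmf_brunet")
}

#' @export
print.nmf_brunet <- function(x, ...) {
  cat("NMF (Brunet KL updates)\n")
  cat("  rank:", x$rank, " dims:", nrow(x$W), "x", ncol(x$H),
      " iterations:", x$iterations, "\n")
  cat("  final KL divergence:",
      format(utils::tail(x$kl_trace, 1), digits = 6), "\n")
  invisible(x)
}

#' @export
fitted.nmf_brunet <- function(object, ...) object$W %*% object$H

#' Consensus clustering over NMF ranks with cophenetic rank selection
#'
#' For each candidate rank, runs the factorization \code{runs} times under
#' derived seeds; each run assigns every sample to its argmax metagene, the
#' run's connectivity matrices are averaged into a consensus matrix, and the
#' cophenetic coefficient is the correlation between the consensus distance
#' (1 - consensus) and the cophenetic distances of its average-linkage
#' dendrogram. The chosen rank maximizes the coefficient.
#'
#' @param V non-negative matrix as for \code{\link{nmf_brunet}}.
#' @param ranks candidate ranks (default 11:18).
#' @param runs factorization runs per rank (default 50; at least 2).
#' @param seed base seed from which per-run seeds are derived.
#' @param ... passed to \code{\link{nmf_brunet}} (e.g. \code{max_iter}).
#' @return object of class \code{"nmf_consensus"}: list of per-rank
#'   \code{consensus} matrices, named \code{cophenetic} vector,
#'   \code{best_rank} (NA with \code{stable = FALSE} when the coefficient is
#'   undefined at every rank, e.g. a single degenerate block), \code{runs}.
#' @export
consensus_select_rank <- function(V, ranks = 11:18, runs = 50, seed = 1, ...) {
  if (runs < 2) stop("need at least 2 runs")
  ranks <- as.integer(ranks)
  m <- ncol(V)
  # a matrix without any between-sample structure (every gene flat across
  # samples) cannot support rank selection
  degenerate <- all(apply(V, 1, max) == apply(V, 1, min))
  if (degenerate)
    warning("no between-sample structure: rank selection is degenerate")
  consensus <- list()
  coph <- stats::setNames(rep(NA_real_, length(ranks)), as.character(ranks))
  for (r in ranks) {
    C <- matrix(0, m, m)
    for (run in seq_len(runs)) {
      fit <- nmf_brunet(V, r, seed = .derive_seed(seed, r, run), ...)
      cl <- max.col(t(fit$H))
      C <- C + outer(cl, cl, function(a, b) as.numeric(a == b))
    }
    C <- C / runs
    dimnames(C) <- list(colnames(V), colnames(V))
    consensus[[as.character(r)]] <- C
    d <- stats::as.dist(1 - C)
    if (stats::sd(d) > 0) {
      hc <- stats::hclust(d, method = "average")
      coph[as.character(r)] <- stats::cor(d, stats::cophenetic(hc))
    } else if (all(d == 0)) {
      # all runs agree on a single cluster: consensus is degenerate
      coph[as.character(r)] <- NA_real_
    }
  }
  stable <- any(!is.na(coph)) && !degenerate
  best <- if (any(!is.na(coph))) ranks[which.max(coph)] else NA_integer_
  structure(list(consensus = consensus, cophenetic = coph,
                 best_rank = best, stable = stable,
                 ranks = ranks, runs = runs, seed = seed),
            class = "nmf_consensus")
}

#' @export
print.nmf_consensus <- function(x, ...) {
  cat("NMF consensus rank selection (", x$runs, " runs per rank)\n", sep = "")
  print(round(x$cophenetic, 4))
  cat("  chosen rank:", x$best_rank,
      if (!x$stable) "(unstable: cophenetic undefined at every rank)", "\n")
  invisible(x)
}

#' Tissue-specific gene sets from an NMF basis
#'
#' A gene is assigned to metagene k when its row-normalized basis weight
#' (basis contribution) exceeds \code{threshold}; with any threshold above
#' 0.5 the resulting sets are necessarily disjoint. Genes clearing the
#' threshold for no metagene, and genes with an all-zero basis row, are left
#' unassigned.
#'
#' @param model an \code{nmf_brunet} fit.
#' @param threshold strict lower bound on the basis contribution (default 0.8).
#' @return named list of gene-ID character vectors, one per metagene.
#' @export
metagene_genes <- function(model, threshold = 0.8) {
  W <- model$W
  tot <- rowSums(W)
  contrib <- W / ifelse(tot > 0, tot, Inf)   # zero rows -> contribution 0
  out <- lapply(seq_len(ncol(W)), function(k)
    rownames(W)[contrib[, k] > threshold])
  stats::setNames(out, colnames(W))
}

#' Score external samples against metagene gene sets
#'
#' For each metagene gene set and each external sample, the score is the mean
#' \code{log2(x + 1)} expression of the set's genes, z-scored across metagenes
#' within the sample. A sample resembling one metagene's tissue ranks that
#' metagene first.
#'
#' @param gene_sets named list of gene-ID vectors (see
#'   \code{\link{metagene_genes}}).
#' @param external_expr genes-by-samples matrix of normalized expression.
#' @return metagenes-by-samples score matrix; a set with no genes present in
#'   the matrix yields NA scores with a warning.
#' @export
metagene_score <- function(gene_sets, external_expr) {
  lx <- log2(external_expr + 1)
  raw <- t(vapply(gene_sets, function(g) {
    g <- intersect(g, rownames(lx))
    if (!length(g)) return(rep(NA_real_, ncol(lx)))
    colMeans(lx[g, , drop = FALSE])
  }, numeric(ncol(lx))))
  if (anyNA(raw))
    warning("metagene set(s) with no genes in the expression matrix: ",
            paste(names(gene_sets)[rowSums(is.na(raw)) > 0], collapse = ", "))
  colnames(raw) <- colnames(external_expr)
  apply(raw, 2, function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) return(v * 0)
    (v - mean(v, na.rm = TRUE)) / s
  })
}
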