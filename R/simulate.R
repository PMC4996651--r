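#' Default developmental-lineage guide tree for the synthetic atlas
#'
#' A 32-leaf topology mirroring the shape of a multi-organ embryonic atlas:
#' 15 organ/tissue groups plus a pluripotent-stem-cell (PSC) pair, two
#' replicates each, arranged under germ-layer clades with a foregut-endoderm
#' subclade. Internal nodes are labelled so planted modules can target clades
#' by name.
#'
#' @return a \code{lineage_tree} with 32 leaves.
#' @export
default_lineage_tree <- function() {
  txt <- paste0(
    "((PSC_1,PSC_2)psc,",
    "(((brain_1,brain_2),(RPE_1,RPE_2),(palate_1,palate_2),",
    "(skin_1,skin_2))ectoderm,",
    "((heart_1,heart_2),(limb_1,limb_2),(adrenal_1,adrenal_2),",
    "(kidney_1,kidney_2),(gonad_1,gonad_2))mesoderm,",
    "((((liver_1,liver_2),(lung_1,lung_2),(pancreas_1,pancreas_2),",
    "(stomach_1,stomach_2),(thyroid_1,thyroid_2))foregut,",
    "(tongue_1,tongue_2))endoderm))embryo)root;")
  read_lineage_tree(txt)
}

#' Simulation settings for tree-structured count data
#'
#' Bundles every knob of the generative model: per-gene baseline log2 means,
#' Brownian evolution of the log-mean along tree edges, clade-restricted
#' expression modules, negative-binomial count noise and log-normal library
#' size factors.
#'
#' @param tree a \code{lineage_tree}; leaves become samples.
#' @param n_genes number of genes (default 5000).
#' @param base_logmean_mean,base_logmean_sd distribution of baseline log2
#'   mean counts across genes (defaults 4 and 1.5: typical bulk depth).
#' @param brownian_sd standard deviation of the Gaussian log2-mean step per
#'   tree edge (default 0.3).
#' @param modules list of planted modules, each
#'   \code{list(clade = <node label or tip set>, n_genes, log2_effect)}.
#' @param dispersion negative-binomial dispersion (1/size; default 0.05).
#' @param libsize_sdlog log-sd of the per-sample library factor (default 0.1).
#' @param seed mandatory RNG seed.
#' @return a \code{simulation_spec} list.
#' @export
simulation_spec <- function(tree = default_lineage_tree(), n_genes = 5000,
                            base_logmean_mean = 4, base_logmean_sd = 1.5,
                            brownian_sd = 0.3, modules = list(),
                            dispersion = 0.05, libsize_sdlog = 0.1, seed) {
  if (missing(seed)) stop("`seed` is mandatory (reproducibility contract)")
  if (dispersion <= 0) stop("dispersion must be > 0")
  for (m in modules) {
    if (!all(c("clade", "n_genes", "log2_effect") %in% names(m)))
      stop("each module needs clade, n_genes, log2_effect")
    if (!is.finite(m$log2_effect)) stop("module effects must be finite")
  }
  structure(list(tree = tree, n_genes = n_genes,
                 base_logmean_mean = base_logmean_mean,
                 base_logmean_sd = base_logmean_sd,
                 brownian_sd = brownian_sd, modules = modules,
                 dispersion = dispersion, libsize_sdlog = libsize_sdlog,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a tree-structured count matrix with planted clade modules
#'
#' Each gene's log2 mean starts at a baseline drawn once per gene and evolves
#' by independent Gaussian steps along every edge from the root to each leaf,
#' giving counts a tree-structured covariance. Module genes additionally gain
#' their log2 effect on every leaf under the module's clade. Counts are drawn
#' negative-binomially around the per-sample library-scaled means.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list with \code{counts} (genes x samples integer matrix),
#'   \code{truth} (data.frame: gene, module index, clade label) and
#'   \code{tissue_map} (sample to tissue, from leaf labels of the form
#'   \code{tissue_replicate}).
#' @export
simulate_lineage_counts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  tree <- spec$tree
  leaves <- leaf_labels(tree)
  n <- length(leaves)
  g <- spec$n_genes
  module_tips <- lapply(spec$modules, function(m) clade_tips(tree, m$clade))
  with_seed(spec$seed, {
    base <- stats::rnorm(g, spec$base_logmean_mean, spec$base_logmean_sd)
    ntot <- n + tree$Nnode
    # accumulate Brownian steps down the tree, per gene
    logmu_node <- matrix(0, g, ntot)
    root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
    logmu_node[, root] <- base
    # edges in preorder: parents always precede children in ape's edge
    # matrix after reorder
    edges <- stats::reorder(tree, "cladewise")$edge
    for (k in seq_len(nrow(edges))) {
      par <- edges[k, 1]; child <- edges[k, 2]
      logmu_node[, child] <- logmu_node[, par] +
        stats::rnorm(g, 0, spec$brownian_sd)
    }
    logmu <- logmu_node[, seq_len(n), drop = FALSE]
    colnames(logmu) <- leaves
    gene_ids <- sprintf("gene%05d", seq_len(g))
    truth <- NULL
    pool <- seq_len(g)
    for (mi in seq_along(spec$modules)) {
      m <- spec$modules[[mi]]
      pick <- pool[seq_len(m$n_genes)]
      pool <- pool[-seq_len(m$n_genes)]
      tips <- module_tips[[mi]]
      logmu[pick, tips] <- logmu[pick, tips] + m$log2_effect
      truth <- rbind(truth, data.frame(gene = gene_ids[pick], module = mi,
                                       clade = paste(m$clade,
                                                     collapse = "+")))
    }
    lib <- stats::rlnorm(n, 0, spec$libsize_sdlog)
    mu <- sweep(2^logmu, 2, lib, "*")
    counts <- matrix(stats::rnbinom(g * n, mu = mu, size = 1 / spec$dispersion),
                     g, n, dimnames = list(gene_ids, leaves))
  })
  tissue <- sub("_[0-9]+$", "", leaves)
  list(counts = counts, truth = truth,
       tissue_map = stats::setNames(tissue, leaves))
}

#' Simulate a block-structured count matrix for NMF ground truth
#'
#' Disjoint gene blocks are elevated in disjoint sample blocks over a low
#' uniform background; with \code{background_noise = 0} counts are exact and
#' the consensus structure at the true rank is perfect.
#'
#' @param n_blocks number of blocks (default 3).
#' @param samples_per_block,genes_per_block block dimensions (defaults 4, 40).
#' @param background_noise negative-binomial dispersion of the count noise;
#'   0 gives deterministic counts (default 0.05).
#' @param background_mean,block_mean mean counts off/on block (defaults 5,
#'   100).
#' @param seed mandatory RNG seed.
#' @return list with \code{counts} and \code{truth} (data.frame: gene/sample
#'   block memberships in \code{gene_block}, \code{sample_block}).
#' @export
simulate_block_counts <- function(n_blocks = 3, samples_per_block = 4,
                                  genes_per_block = 40,
                                  background_noise = 0.05,
                                  background_mean = 5, block_mean = 100,
                                  seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  g <- n_blocks * genes_per_block
  m <- n_blocks * samples_per_block
  gene_block <- rep(seq_len(n_blocks), each = genes_per_block)
  sample_block <- rep(seq_len(n_blocks), each = samples_per_block)
  mu <- matrix(background_mean, g, m)
  for (b in seq_len(n_blocks))
    mu[gene_block == b, sample_block == b] <- block_mean
  counts <- if (background_noise == 0) mu else with_seed(seed, {
    matrix(stats::rnbinom(g * m, mu = mu, size = 1 / background_noise), g, m)
  })
  dimnames(counts) <- list(sprintf("bgene%03d", seq_len(g)),
                           sprintf("bsample%02d", seq_len(m)))
  list(counts = counts,
       truth = list(gene_block = stats::setNames(gene_block,
                                                 rownames(counts)),
                    sample_block = stats::setNames(sample_block,
                                                   colnames(counts))))
}

#' Deterministic toy annotation covering every transcript class
#'
#' Writes a miniature reference GTF, a novel-transcript GTF, a coding-score
#' TSV and a hand-built truth table into \code{dir}. The fixture contains at
#' least one instance of every classification outcome (discards j/e/p; the
#' 2 kb run-on boundary; retained o/x/i/u; BI at and just beyond the 1 kb
#' boundary; a TUCP; a sub-200 bp transcript; same-strand and antisense
#' overlap loci for the dedup step), with the expected class and name of every
#' novel transcript recorded in the truth table. Output is byte-identical
#' across calls.
#'
#' @param dir output directory (created if needed).
#' @param seed accepted for interface symmetry with the other generators; the
#'   fixture is fully deterministic.
#' @return list of paths (\code{ref_gtf}, \code{novel_gtf}, \code{scores_tsv},
#'   \code{truth_tsv}) plus the \code{truth} data.frame.
#' @export
make_toy_annotation <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- list(
    # gene, tx, chrom, strand, exon starts, exon ends
    list("GENEA", "GENEA.1", "chr7", "+", c(10000, 15000, 19000),
         c(11000, 16000, 20000)),
    list("GENEB", "GENEB.1", "chr7", "-", c(50000, 58000), c(52000, 60000)),
    list("GENEC", "GENEC.1", "chr7", "+", 100000, 101000),
    list("GENED", "GENED.1", "chr7", "-", 80000, 81000),
    list("GENEE", "GENEE.1", "chr7", "-", 90000, 91000))
  ref_lines <- unlist(lapply(ref, function(g)
    sprintf(paste0("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t",
                   'gene_id "%s"; transcript_id "%s"; gene_name "%s";'),
            g[[3]], g[[5]], g[[6]], g[[4]], g[[1]], g[[2]], g[[1]])))

  nov <- list(
    # id, chrom, strand, starts, ends
    list("NOV_J",     "chr7", "+", c(9500, 15000), c(11000, 15500)),
    list("NOV_E",     "chr7", "+", 10500, 12000),
    list("NOV_P",     "chr7", "+", 21000, 21800),
    list("NOV_PB",    "chr7", "+", 22001, 22500),
    list("NOV_O",     "chr7", "+", 19500, 20500),
    list("NOV_X",     "chr7", "-", 15200, 15800),
    list("NOV_I",     "chr7", "+", 12000, 12800),
    list("NOV_U1",    "chr7", "+", c(200000, 201000), c(200400, 201400)),
    list("NOV_BI",    "chr7", "+", 60500, 61200),
    list("NOV_BIB",   "chr7", "+", 82000, 82600),
    list("NOV_NB",    "chr7", "+", 92001, 92700),
    list("NOV_T",     "chr7", "+", 300000, 300900),
    list("NOV_SHORT", "chr7", "+", 400000, 400150),
    list("NOV_D1",    "chr7", "+", 500000, 500300),
    list("NOV_D2",    "chr7", "+", 500200, 501100),
    list("NOV_D3",    "chr7", "-", 500250, 500800),
    list("NOV_C1",    "chr1", "+", 5000, 5400))
  nov_lines <- unlist(lapply(nov, function(g)
    sprintf(paste0("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t",
                   'gene_id "%s"; transcript_id "%s";'),
            g[[2]], g[[4]], g[[5]], g[[3]], g[[1]], g[[1]])))

  scores <- data.frame(
    transcript_id = vapply(nov, `[[`, character(1), 1),
    score = 0.05)
  scores$score[scores$transcript_id == "NOV_T"] <- 0.6
  scores$score[scores$transcript_id == "NOV_O"] <- 0.3   # dual OT + TUCP

  truth <- data.frame(
    transcript_id = c("NOV_J", "NOV_E", "NOV_P", "NOV_PB", "NOV_O", "NOV_X",
                      "NOV_I", "NOV_U1", "NOV_BI", "NOV_BIB", "NOV_NB",
                      "NOV_T", "NOV_SHORT", "NOV_D1", "NOV_D2", "NOV_D3",
                      "NOV_C1"),
    class_code = c("j", "e", "p", "u", "o", "x", "i", "u", "u", "u", "u",
                   "u", "u", "u", "u", "u", "u"),
    discarded = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE),
    positional_class = c(NA, NA, NA, "LINC", "OT", "AS", "LINC", "LINC",
                         "BI", "BI", "LINC", "TUCP", "LINC", "LINC", "LINC",
                         "LINC", "LINC"),
    tucp = c(NA, NA, NA, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
             FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    name = c(NA, NA, NA, "HE-LINC-C7T2", "HE-OT-GENEA", "HE-AS-GENEA",
             "HE-LINC-C7T1", "HE-LINC-C7T4", "HE-BI-GENEB", "HE-BI-GENED",
             "HE-LINC-C7T3", "HE-TUCP-C7T5", "HE-LINC-C7T6", "HE-LINC-C7T7",
             "HE-LINC-C7T8", "HE-LINC-C7T9", "HE-LINC-C1T1"),
    in_final_set = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                     TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
                     TRUE))

  paths <- list(ref_gtf = file.path(dir, "toy_reference.gtf"),
                novel_gtf = file.path(dir, "toy_novel.gtf"),
                scores_tsv = file.path(dir, "toy_coding_scores.tsv"),
                truth_tsv = file.path(dir, "toy_truth.tsv"))
  writeLines(ref_lines, paths$ref_gtf)
  writeLines(nov_lines, paths$novel_gtf)
  utils::write.table(scores, paths$scores_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, paths$truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(paths, list(truth = truth))
}
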