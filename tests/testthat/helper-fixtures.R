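# shared fixture builders; everything is generated in code under fixed seeds

star_newick <- function(labels) {
  paste0("(", paste(labels, collapse = ","), ");")
}

rand_expr <- function(n_genes, n_samples, seed,
                      samples = paste0("s", seq_len(n_samples))) {
  set.seed(seed)
  matrix(stats::rlnorm(n_genes * n_samples, 3, 1), n_genes, n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)), samples))
}

# small planted-module atlas reused across LgPCA tests
planted_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- simulation_spec(
        n_genes = 2000,
        modules = list(list(clade = "foregut", n_genes = 100,
                            log2_effect = 2)),
        seed = 101)
      sim <- simulate_lineage_counts(spec)
      cache <<- list(spec = spec, sim = sim,
                     tree = spec$tree,
                     prox = abouheif_proximity(spec$tree))
    }
    cache
  }
})

# planted distant-correlate scenario: uncorrelated near genes, a shared
# tissue profile 700 kb away, and genes at both sides of the 1 Mb boundary
neighbor_fixture <- function() {
  ref_ex <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(2010000, 2100000, 2700000, 3000000, 3000001),
                     c(2011000, 2101000, 2701000, 3001000, 3001800)),
    strand = "+",
    gene_id = c("GN1", "GN2", "GFAR", "GEDGE", "GOUT"),
    transcript_id = paste0("t", 1:5),
    gene_name = c("GN1", "GN2", "GFAR", "GEDGE", "GOUT"))
  ref <- genome_annotation(ref_ex)
  nov_ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2e6, 2000600),
                                   strand = "+", transcript_id = "NOVT")
  nov <- transcript_models(nov_ex)
  prof <- c(1, 5, 20, 3, 1, 2, 8, 1)
  en <- matrix(prof, 1, 8, dimnames = list("NOVT", paste0("s", 1:8)))
  set.seed(77)
  eg <- rbind(GN1 = rep(4, 8), GN2 = stats::runif(8, 0, 10),
              GFAR = prof, GEDGE = stats::runif(8, 0, 10),
              GOUT = 100 * prof)
  colnames(eg) <- paste0("s", 1:8)
  list(ref = ref, nov = nov, expr_novel = en, expr_genes = eg, profile = prof)
}
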