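toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "toy_annotation")
      paths <- make_toy_annotation(d)
      ref <- read_genome_annotation(paths$ref_gtf)
      nov <- read_transcript_models(paths$novel_gtf,
                                    scores = paths$scores_tsv)
      cls <- suppressWarnings(classify_transcripts(nov, ref))
      named <- assign_names(retained_transcripts(cls), ref)
      final <- dedupe_and_filter(named)
      cache <<- list(paths = paths, truth = paths$truth, ref = ref,
                     nov = nov, cls = cls, named = named, final = final)
    }
    cache
  }
})

test_that("class codes match the hand-built truth table exactly", {
  t <- toy()
  got <- stats::setNames(t$cls$tx$class_code, t$cls$tx$tx_id)
  exp <- stats::setNames(t$truth$class_code, t$truth$transcript_id)
  expect_identical(got[names(exp)], exp)
  # every discard class is exercised at least once
  expect_true(all(c("e", "j", "p") %in% exp))
})

test_that("discarded classes never reach the named output", {
  t <- toy()
  expect_false(any(t$named$tx$tx_id %in%
                     t$truth$transcript_id[t$truth$discarded]))
  expect_true(all(t$named$tx$positional_class %in%
                    c("BI", "AS", "OT", "LINC", "TUCP")))
})

test_that("positional classes, TUCP flags and systematic names match the truth table", {
  t <- toy()
  keep <- !t$truth$discarded
  exp <- t$truth[keep, ]
  got <- t$named$tx[match(exp$transcript_id, t$named$tx$tx_id), ]
  expect_identical(got$positional_class, exp$positional_class)
  expect_identical(got$tucp, exp$tucp)
  expect_identical(got$name, exp$name)
})

test_that("the final set applies longest-per-locus and the length filter", {
  t <- toy()
  expect_setequal(t$final$models$tx$tx_id,
                  t$truth$transcript_id[t$truth$in_final_set])
  expect_true(all(t$final$models$tx$length > 200))
  expect_identical(t$final$n_loci, 13L)
  # antisense overlap forms its own locus: both NOV_D2 (+) and NOV_D3 (-)
  # survive although their exons overlap
  expect_true(all(c("NOV_D2", "NOV_D3") %in% t$final$models$tx$tx_id))
  expect_false("NOV_D1" %in% t$final$models$tx$tx_id)   # shorter, same locus
})

test_that("naming is stable under input order", {
  t <- toy()
  ex <- t$nov$exons
  set.seed(1)
  shuffled <- transcript_models(ex[sample(length(ex))])
  shuffled$tx$coding_score <-
    t$nov$tx$coding_score[match(shuffled$tx$tx_id, t$nov$tx$tx_id)]
  cls2 <- suppressWarnings(classify_transcripts(shuffled, t$ref))
  named2 <- assign_names(retained_transcripts(cls2), t$ref)
  m <- match(t$named$tx$tx_id, named2$tx$tx_id)
  expect_identical(named2$tx$name[m], t$named$tx$name)
})

test_that("the final GTF round-trips coordinates, strands and names", {
  t <- toy()
  p <- withr::local_tempfile(fileext = ".gtf")
  write_transcripts_gtf(t$final, p)
  rt <- read_transcript_models(p)
  orig <- t$final$models$tx
  m <- match(orig$name, rt$tx$tx_id)
  expect_false(anyNA(m))
  expect_identical(rt$tx$chrom[m], orig$chrom)
  expect_identical(rt$tx$strand[m], orig$strand)
  expect_identical(rt$tx$start[m], orig$start)
  expect_identical(rt$tx$end[m], orig$end)
  expect_identical(rt$tx$n_exons[m], orig$n_exons)
})

test_that("run-on and bidirectional boundaries are inclusive at the stated windows", {
  t <- toy()
  tx <- t$cls$tx
  # NOV_P starts 1000 bp past the reference end -> run-on; NOV_PB at
  # 2001 bp escapes the 2 kb window
  expect_identical(tx$class_code[tx$tx_id == "NOV_P"], "p")
  expect_identical(tx$class_code[tx$tx_id == "NOV_PB"], "u")
  named <- t$named$tx
  # NOV_BIB TSS is exactly 1000 bp from GENED's TSS -> BI;
  # NOV_NB at 1001 bp is not
  expect_identical(named$positional_class[named$tx_id == "NOV_BIB"], "BI")
  expect_identical(named$positional_class[named$tx_id == "NOV_NB"], "LINC")
})

test_that("coding scores are validated and required for naming", {
  t <- toy()
  bare <- transcript_models(t$nov$exons)
  cls <- suppressWarnings(classify_transcripts(bare, t$ref))
  expect_error(assign_names(retained_transcripts(cls), t$ref),
               "coding scores")
  expect_error(
    add_coding_scores(bare, data.frame(transcript_id = "NOV_J", score = 0.1)),
    "missing coding scores")
})

test_that("neighborhood correlation recovers a distant co-expressed gene", {
  fx <- neighbor_fixture()
  nc <- neighborhood_correlation(fx$nov, fx$ref, fx$expr_novel,
                                 fx$expr_genes)
  s <- nc$summary
  expect_identical(s$best_gene, "GFAR")
  expect_identical(s$best_distance, 700000L)
  expect_identical(s$nearest_gene, "GN1")
  expect_identical(s$nearest_distance, 10000L)
  # exact profile copy: r = 1
  expect_equal(s$best_r, 1)
  # 1 Mb window is inclusive at 1,000,000 and exclusive at 1,000,001
  expect_true("GEDGE" %in% nc$neighbors$gene)
  expect_false("GOUT" %in% nc$neighbors$gene)
  expect_equal(s$mean_window_distance,
               mean(c(10000, 100000, 700000, 1000000)))
})

test_that("transcripts without neighbors are flagged, not dropped", {
  fx <- neighbor_fixture()
  lone_ex <- GenomicRanges::GRanges("chr9",
                                    IRanges::IRanges(100, 700),
                                    strand = "+", transcript_id = "LONE")
  lone <- transcript_models(lone_ex)
  en <- matrix(1:8, 1, 8, dimnames = list("LONE", paste0("s", 1:8)))
  nc <- neighborhood_correlation(lone, fx$ref, en, fx$expr_genes)
  expect_identical(nc$summary$n_neighbors, 0L)
  expect_true(is.na(nc$summary$best_gene))
})

test_that("expression matrices must share sample columns", {
  fx <- neighbor_fixture()
  expect_error(neighborhood_correlation(fx$nov, fx$ref, fx$expr_novel,
                                        fx$expr_genes[, 1:4]),
               "identical sample columns")
})
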