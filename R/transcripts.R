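#' Transcript models from an exon GRanges
#'
#' Internal container for assembled transcript models: the exon ranges
#' (1-based closed, the native convention of the Bioconductor interval stack;
#' GTF conversion happens at the I/O boundary) plus a per-transcript table
#' with strand-aware TSS, exonic length and exon count.
#'
#' @param exons a \code{GRanges} with a \code{transcript_id} metadata column;
#'   strand must be + or -.
#' @return object of class \code{"transcript_models"}: list with \code{exons}
#'   (sorted GRanges) and \code{tx} (data.frame, one row per transcript).
#' @export
transcript_models <- function(exons) {
  if (!"transcript_id" %in% names(S4Vectors::mcols(exons)))
    stop("exons need a transcript_id metadata column")
  if (any(BiocGenerics::strand(exons) == "*"))
    stop("transcript exons must be stranded (+/-)")
  exons <- BiocGenerics::sort(exons)
  grl <- S4Vectors::split(exons, exons$transcript_id)
  if (any(vapply(grl, function(g)
    length(unique(as.character(BiocGenerics::strand(g)))) > 1 ||
      length(unique(as.character(GenomicRanges::seqnames(g)))) > 1,
    logical(1))))
    stop("a transcript spans multiple strands or chromosomes")
  red <- vapply(grl, function(g)
    length(GenomicRanges::reduce(g)) < length(g), logical(1))
  if (any(red))
    stop("overlapping exons within transcript(s): ",
         paste(utils::head(names(grl)[red], 5), collapse = ", "))
  spans <- unlist(range(grl))
  strand <- as.character(BiocGenerics::strand(unlist(grl))[
    match(names(grl), unlist(grl)$transcript_id)])
  tx <- data.frame(
    tx_id = names(grl),
    chrom = as.character(GenomicRanges::seqnames(spans)),
    strand = strand,
    start = BiocGenerics::start(spans),
    end = BiocGenerics::end(spans),
    n_exons = vapply(grl, length, integer(1)),
    length = vapply(grl, function(g) sum(BiocGenerics::width(g)), numeric(1)),
    row.names = NULL)
  tx$tss <- ifelse(tx$strand == "+", tx$start, tx$end)
  structure(list(exons = exons, tx = tx), class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("Transcript models:", nrow(x$tx), "transcripts,",
      length(x$exons), "exons\n")
  extra <- intersect(c("coding_score", "class_code", "positional_class",
                       "name"), names(x$tx))
  if (length(extra)) cat("  annotated with:", paste(extra, collapse = ", "),
                         "\n")
  invisible(x)
}

#' Read assembled transcript models from GTF
#'
#' @param path GTF file; exon features are used.
#' @param scores optional path to a coding-score TSV (columns
#'   \code{transcript_id}, \code{score}) merged onto the models.
#' @return a \code{\link{transcript_models}} object.
#' @export
read_transcript_models <- function(path, scores = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  mod <- transcript_models(gr)
  if (!is.null(scores)) mod <- add_coding_scores(mod, read_coding_scores(scores))
  mod
}

#' Read per-transcript coding-potential scores
#' @param path TSV with columns \code{transcript_id} and \code{score} in [0,1].
#' @return data.frame.
#' @export
read_coding_scores <- function(path) {
  df <- utils::read.delim(path)
  if (!all(c("transcript_id", "score") %in% names(df)))
    stop("coding-score TSV needs columns transcript_id, score")
  if (any(df$score < 0 | df$score > 1)) stop("coding scores must lie in [0,1]")
  df
}

#' Attach coding scores to transcript models
#' @param models a \code{transcript_models} object.
#' @param scores data.frame from \code{\link{read_coding_scores}}.
#' @return the models with a \code{coding_score} column.
#' @export
add_coding_scores <- function(models, scores) {
  i <- match(models$tx$tx_id, scores$transcript_id)
  if (anyNA(i))
    stop("missing coding scores for: ",
         paste(utils::head(models$tx$tx_id[is.na(i)], 5), collapse = ", "))
  models$tx$coding_score <- scores$score[i]
  models
}

#' Reference genome annotation from GTF
#'
#' Builds the reference structures the classifier interrogates: per-transcript
#' exon sets, introns, transcript spans and a per-gene table of TSS/TTS.
#'
#' @param path reference GTF (exon features with \code{gene_id},
#'   \code{transcript_id} and optionally \code{gene_name} attributes).
#' @return object of class \code{"genome_annotation"}.
#' @export
read_genome_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  genome_annotation(gr)
}

#' @rdname read_genome_annotation
#' @param exons a GRanges of reference exons with \code{gene_id},
#'   \code{transcript_id} and optional \code{gene_name} metadata.
#' @export
genome_annotation <- function(exons) {
  if (is.null(exons$gene_id) || is.null(exons$transcript_id))
    stop("reference exons need gene_id and transcript_id")
  if (is.null(exons$gene_name)) exons$gene_name <- exons$gene_id
  exons <- BiocGenerics::sort(exons)
  grl <- S4Vectors::split(exons, exons$transcript_id)
  spans <- unlist(range(grl))
  spans$transcript_id <- names(grl)
  introns <- GenomicRanges::psetdiff(unlist(range(grl)), grl)
  intr <- unlist(introns)
  if (length(intr)) intr$transcript_id <- rep(names(introns),
                                              lengths(introns))
  first <- !duplicated(exons$gene_id)
  gspans <- unlist(range(S4Vectors::split(exons, exons$gene_id)))
  g <- data.frame(gene_id = names(gspans),
                  chrom = as.character(GenomicRanges::seqnames(gspans)),
                  start = BiocGenerics::start(gspans),
                  end = BiocGenerics::end(gspans), row.names = NULL)
  g$symbol <- exons$gene_name[first][match(g$gene_id, exons$gene_id[first])]
  g$strand <- as.character(BiocGenerics::strand(exons)[first])[
    match(g$gene_id, exons$gene_id[first])]
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g$tts <- ifelse(g$strand == "+", g$end, g$start)
  structure(list(exons = exons, introns = intr, tx_spans = spans,
                 genes = g), class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("Genome annotation:", nrow(x$genes), "genes,",
      length(x$tx_spans), "transcripts,", length(x$exons), "exons\n")
  invisible(x)
}

#' Classify novel transcript models against a reference annotation
#'
#' Simplified single-letter class codes, assigned in the fixed priority order
#' j > e > p > o > x > i > u:
#' \describe{
#'   \item{j}{an intron exactly matches a reference intron, same strand
#'     (novel isoform spliced to known exons; discarded downstream);}
#'   \item{e}{unspliced, contained in a same-strand reference transcript span
#'     and overlapping both exon and intron (pre-mRNA-like; discarded);}
#'   \item{p}{same strand, entirely downstream of a reference transcript end,
#'     within 2,000 bp (3' run-on; discarded);}
#'   \item{o}{exonic overlap with a reference exon on the same strand;}
#'   \item{x}{exonic overlap on the opposite strand (antisense);}
#'   \item{i}{wholly inside a reference intron;}
#'   \item{u}{none of the above (intergenic/unknown).}
#' }
#' Transcripts on chromosomes absent from the reference are classified
#' \code{u} with a warning.
#'
#' @param novel a \code{\link{transcript_models}} object.
#' @param ref a \code{\link{genome_annotation}}.
#' @param runon_window maximum run-on distance in bp (default 2000,
#'   inclusive).
#' @return the models with a \code{class_code} column added to \code{tx}.
#' @export
classify_transcripts <- function(novel, ref, runon_window = 2000) {
  tx <- novel$tx
  exons <- novel$exons
  grl <- S4Vectors::split(exons, exons$transcript_id)[tx$tx_id]
  spans <- GenomicRanges::GRanges(tx$chrom,
                                  IRanges::IRanges(tx$start, tx$end),
                                  strand = tx$strand)
  novel_introns <- GenomicRanges::psetdiff(spans, grl)

  unknown_chr <- !(tx$chrom %in% ref$genes$chrom)
  if (any(unknown_chr))
    warning("transcript(s) on chromosome(s) absent from the reference, ",
            "classified 'u': ",
            paste(utils::head(tx$tx_id[unknown_chr], 5), collapse = ", "))

  # j: exact same-strand intron match
  ni <- unlist(novel_introns)
  is_j <- rep(FALSE, nrow(tx))
  if (length(ni) && length(ref$introns)) {
    ni_tx <- rep(names(novel_introns), lengths(novel_introns))
    hit <- GenomicRanges::findOverlaps(ni, ref$introns, type = "equal")
    is_j[tx$tx_id %in% ni_tx[S4Vectors::queryHits(hit)]] <- TRUE
  }

  # e: unspliced, within a same-strand reference span, touching exon + intron
  is_e <- rep(FALSE, nrow(tx))
  cand <- which(tx$n_exons == 1L)
  if (length(cand)) {
    within <- GenomicRanges::findOverlaps(spans[cand], ref$tx_spans,
                                          type = "within")
    for (h in seq_along(within)) {
      qi <- cand[S4Vectors::queryHits(within)[h]]
      rtx <- ref$tx_spans$transcript_id[S4Vectors::subjectHits(within)[h]]
      rex <- ref$exons[ref$exons$transcript_id == rtx]
      rin <- ref$introns[ref$introns$transcript_id == rtx]
      if (length(GenomicRanges::findOverlaps(spans[qi], rex)) &&
          length(GenomicRanges::findOverlaps(spans[qi], rin,
                                             ignore.strand = TRUE)))
        is_e[qi] <- TRUE
    }
  }

  # p: same-strand run-on within the window downstream of a reference end
  is_p <- rep(FALSE, nrow(tx))
  for (i in seq_len(nrow(tx))) {
    g <- ref$genes[ref$genes$chrom == tx$chrom[i] &
                     ref$genes$strand == tx$strand[i], , drop = FALSE]
    if (!nrow(g)) next
    gap <- if (tx$strand[i] == "+") tx$start[i] - g$tts
           else g$tts - tx$end[i]
    if (any(gap >= 1 & gap <= runon_window)) is_p[i] <- TRUE
  }

  # o / x: exonic overlap by strand
  ov <- GenomicRanges::findOverlaps(exons, ref$exons, ignore.strand = TRUE)
  same <- as.character(BiocGenerics::strand(exons))[
    S4Vectors::queryHits(ov)] ==
    as.character(BiocGenerics::strand(ref$exons))[S4Vectors::subjectHits(ov)]
  o_tx <- unique(exons$transcript_id[S4Vectors::queryHits(ov)[same]])
  x_tx <- unique(exons$transcript_id[S4Vectors::queryHits(ov)[!same]])
  is_o <- tx$tx_id %in% o_tx
  is_x <- tx$tx_id %in% x_tx

  # i: whole span inside a reference intron (either strand)
  is_i <- rep(FALSE, nrow(tx))
  if (length(ref$introns)) {
    wi <- GenomicRanges::findOverlaps(spans, ref$introns, type = "within",
                                      ignore.strand = TRUE)
    is_i[unique(S4Vectors::queryHits(wi))] <- TRUE
  }

  code <- rep("u", nrow(tx))
  code[is_i] <- "i"
  code[is_x] <- "x"
  code[is_o] <- "o"
  code[is_p] <- "p"
  code[is_e] <- "e"
  code[is_j] <- "j"
  code[unknown_chr] <- "u"
  novel$tx$class_code <- code
  novel
}

#' Subset classified models to the retained classes
#'
#' Drops the discard classes e (pre-mRNA-like), j (known-junction isoforms)
#' and p (3' run-ons), keeping i/u/o/x.
#'
#' @param models classified \code{transcript_models}.
#' @return the retained subset.
#' @export
retained_transcripts <- function(models) {
  if (is.null(models$tx$class_code)) stop("classify_transcripts first")
  keep <- models$tx$class_code %in% c("i", "u", "o", "x")
  subset_transcripts(models, models$tx$tx_id[keep])
}

subset_transcripts <- function(models, ids) {
  models$tx <- models$tx[match(ids, models$tx$tx_id), , drop = FALSE]
  rownames(models$tx) <- NULL
  models$exons <- models$exons[models$exons$transcript_id %in% ids]
  models
}

#' Positional classification and systematic naming of retained transcripts
#'
#' Retained transcripts are assigned a positional class: BI (bidirectional)
#' when the TSS lies within \code{bi_window} bp of an annotated TSS on the
#' opposite strand; otherwise AS for antisense-exonic ('x'), OT for
#' same-strand overlap ('o'), and LINC for the rest. A coding score above
#' \code{tucp_threshold} sets the TUCP flag; purely intergenic TUCPs are
#' classed TUCP in place of LINC, while BI/AS/OT keep their positional class
#' with the flag as a dual label. LINC and TUCP transcripts share one
#' sequential T number per chromosome, ordered by TSS coordinate
#' (\code{HE-LINC-C7T121} is the 121st LINC/TUCP start on chromosome 7);
#' gene-associated classes are named by the associated gene symbol
#' (\code{HE-BI-<symbol>}), with \code{-2}, \code{-3} suffixes when several
#' transcripts associate with one gene.
#'
#' @param models retained, classified \code{transcript_models} with coding
#'   scores (discard classes present are dropped with a message).
#' @param ref a \code{\link{genome_annotation}}.
#' @param bi_window BI distance in bp, inclusive (default 1000).
#' @param tucp_threshold strict coding-score threshold for TUCP (default 0.2).
#' @return the models with \code{positional_class}, \code{tucp},
#'   \code{associated_gene} and \code{name} columns.
#' @export
assign_names <- function(models, ref, bi_window = 1000,
                         tucp_threshold = 0.2) {
  if (is.null(models$tx$class_code)) stop("classify_transcripts first")
  if (is.null(models$tx$coding_score))
    stop("coding scores must be attached before naming")
  if (any(models$tx$class_code %in% c("e", "j", "p"))) {
    message("dropping discard-class transcripts before naming")
    models <- retained_transcripts(models)
  }
  tx <- models$tx

  # BI: nearest opposite-strand annotated TSS within the window
  assoc <- rep(NA_character_, nrow(tx))
  pos <- character(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    g <- ref$genes[ref$genes$chrom == tx$chrom[i] &
                     ref$genes$strand != tx$strand[i], , drop = FALSE]
    d <- abs(g$tss - tx$tss[i])
    hit <- which(d <= bi_window)
    if (length(hit)) {
      hit <- hit[order(d[hit], g$symbol[hit])][1]
      pos[i] <- "BI"
      assoc[i] <- g$symbol[hit]
    }
  }
  as_ot <- pos == "" & tx$class_code %in% c("x", "o")
  if (any(as_ot)) {
    ga <- .overlap_gene(models, ref)
    pos[as_ot] <- ifelse(tx$class_code[as_ot] == "x", "AS", "OT")
    assoc[as_ot] <- ga[as_ot]
  }
  pos[pos == ""] <- "LINC"
  tucp <- tx$coding_score > tucp_threshold
  pos[pos == "LINC" & tucp] <- "TUCP"

  name <- character(nrow(tx))
  chrom_label <- sub("^chr", "", tx$chrom)
  numbered <- pos %in% c("LINC", "TUCP")
  for (ch in unique(chrom_label[numbered])) {
    idx <- which(numbered & chrom_label == ch)
    idx <- idx[order(tx$tss[idx], tx$tx_id[idx])]
    name[idx] <- sprintf("HE-%s-C%sT%d", pos[idx], ch, seq_along(idx))
  }
  gene_assoc <- which(!numbered)
  if (length(gene_assoc)) {
    base <- sprintf("HE-%s-%s", pos[gene_assoc], assoc[gene_assoc])
    ord <- gene_assoc[order(base, tx$tss[gene_assoc], tx$tx_id[gene_assoc])]
    base_o <- sprintf("HE-%s-%s", pos[ord], assoc[ord])
    reps <- stats::ave(seq_along(base_o), base_o, FUN = seq_along)
    name[ord] <- ifelse(reps == 1, base_o, paste0(base_o, "-", reps))
  }
  models$tx$positional_class <- pos
  models$tx$tucp <- tucp
  models$tx$associated_gene <- assoc
  models$tx$name <- name
  models
}

# gene with the largest exonic overlap (ignoring strand; classes o and x),
# ties broken by symbol
.overlap_gene <- function(models, ref) {
  tx <- models$tx
  ov <- GenomicRanges::findOverlaps(models$exons, ref$exons,
                                    ignore.strand = TRUE)
  if (!length(ov)) return(rep(NA_character_, nrow(tx)))
  w <- BiocGenerics::width(IRanges::pintersect(
    IRanges::ranges(models$exons)[S4Vectors::queryHits(ov)],
    IRanges::ranges(ref$exons)[S4Vectors::subjectHits(ov)]))
  df <- data.frame(tx = models$exons$transcript_id[S4Vectors::queryHits(ov)],
                   sym = ref$exons$gene_name[S4Vectors::subjectHits(ov)],
                   w = w)
  agg <- stats::aggregate(w ~ tx + sym, df, sum)
  out <- rep(NA_character_, nrow(tx))
  for (id in unique(agg$tx)) {
    a <- agg[agg$tx == id, ]
    a <- a[order(-a$w, a$sym), ]
    out[tx$tx_id == id] <- a$sym[1]
  }
  out
}

#' Collapse named transcripts to one per locus and apply the length filter
#'
#' Loci are single-linkage clusters of same-strand exonic overlap (antisense
#' overlaps stay separate loci). Within each locus the longest transcript by
#' exonic length is kept (ties: more exons, then lexicographically smaller
#' ID); transcripts of length at or below \code{min_len} are then dropped.
#'
#' @param models named \code{transcript_models}.
#' @param min_len strict minimum exonic length in bp (default 200: a 200 bp
#'   transcript is removed).
#' @return list of class \code{"final_transcript_set"}: \code{models} (the
#'   final set), \code{n_loci}, \code{class_tally} (per positional class).
#' @export
dedupe_and_filter <- function(models, min_len = 200) {
  tx <- models$tx
  n <- nrow(tx)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  red <- GenomicRanges::reduce(models$exons, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(models$exons, red)
  txi <- match(models$exons$transcript_id, tx$tx_id)
  for (r in unique(S4Vectors::subjectHits(hits))) {
    members <- unique(txi[S4Vectors::queryHits(hits)[
      S4Vectors::subjectHits(hits) == r]])
    if (length(members) > 1)
      for (m in members[-1]) union2(members[1], m)
  }
  locus <- vapply(seq_len(n), find, integer(1))
  keep <- unlist(lapply(split(seq_len(n), locus), function(idx) {
    o <- order(-tx$length[idx], -tx$n_exons[idx], tx$tx_id[idx])
    idx[o][1]
  }))
  keep <- keep[tx$length[keep] > min_len]
  final <- subset_transcripts(models, tx$tx_id[sort(keep)])
  tally <- table(final$tx$positional_class)
  structure(list(models = final, n_loci = length(unique(locus)),
                 class_tally = tally),
            class = "final_transcript_set")
}

#' @export
print.final_transcript_set <- function(x, ...) {
  cat("Final transcript set:", nrow(x$models$tx), "transcripts from",
      x$n_loci, "loci\n")
  print(x$class_tally)
  invisible(x)
}

#' Correlate novel transcripts with annotated genes in a genomic window
#'
#' For every final transcript, annotated genes whose TSS lies within
#' \code{window} bp of the transcript TSS (inclusive; either strand) are
#' collected; the Pearson correlation of \code{log2(x + 1)} expression is
#' computed against each. Reported per transcript: the nearest gene and its
#' distance, the best-correlated gene (largest |r|) and its distance, and the
#' mean distance over the window as the random expectation.
#'
#' @param final a \code{final_transcript_set} or named
#'   \code{transcript_models}.
#' @param ref a \code{\link{genome_annotation}}.
#' @param expr_novel transcripts-by-samples expression (rows named by
#'   transcript name or ID).
#' @param expr_genes genes-by-samples expression (rows named by gene symbol or
#'   ID); columns must match \code{expr_novel}.
#' @param window TSS-to-TSS distance cutoff in bp (default 1e6, inclusive: a
#'   gene at 1,000,001 bp is excluded).
#' @return list with \code{neighbors} (long data.frame: transcript, gene,
#'   distance, r) and \code{summary} (one row per transcript; transcripts with
#'   no neighbor in the window are flagged with \code{n_neighbors = 0}).
#' @export
neighborhood_correlation <- function(final, ref, expr_novel, expr_genes,
                                     window = 1e6) {
  models <- if (inherits(final, "final_transcript_set")) final$models
            else final
  tx <- models$tx
  if (!identical(colnames(expr_novel), colnames(expr_genes)))
    stop("expression matrices must share identical sample columns")
  ln <- log2(expr_novel + 1)
  lg <- log2(expr_genes + 1)
  key <- if (!is.null(tx$name) && all(tx$name %in% rownames(ln))) tx$name
         else tx$tx_id
  nb <- list(); sm <- list()
  for (i in seq_len(nrow(tx))) {
    g <- ref$genes[ref$genes$chrom == tx$chrom[i], , drop = FALSE]
    d <- abs(g$tss - tx$tss[i])
    g <- g[d <= window, , drop = FALSE]
    d <- d[d <= window]
    if (!nrow(g)) {
      sm[[i]] <- data.frame(transcript = key[i], n_neighbors = 0L,
                            nearest_gene = NA, nearest_distance = NA,
                            best_gene = NA, best_r = NA, best_distance = NA,
                            mean_window_distance = NA)
      next
    }
    gk <- ifelse(g$symbol %in% rownames(lg), g$symbol, g$gene_id)
    r <- vapply(gk, function(s) {
      if (!s %in% rownames(lg)) return(NA_real_)
      suppressWarnings(stats::cor(ln[key[i], ], lg[s, ]))
    }, numeric(1))
    nb[[i]] <- data.frame(transcript = key[i], gene = g$symbol,
                          distance = d, r = unname(r))
    best <- which.max(abs(r))
    nearest <- which.min(d)
    sm[[i]] <- data.frame(transcript = key[i], n_neighbors = nrow(g),
                          nearest_gene = g$symbol[nearest],
                          nearest_distance = d[nearest],
                          best_gene = if (length(best)) g$symbol[best] else NA,
                          best_r = if (length(best)) unname(r[best]) else NA,
                          best_distance = if (length(best)) d[best] else NA,
                          mean_window_distance = mean(d))
  }
  list(neighbors = do.call(rbind, nb), summary = do.call(rbind, sm))
}

#' Write transcript models to GTF
#'
#' One exon row per exon; \code{transcript_id} carries the systematic name
#' when present (original IDs kept in \code{orig_id}), along with class code,
#' positional class and TUCP flag attributes. 1-based inclusive coordinates
#' on disk.
#'
#' @param models a \code{transcript_models} object (or
#'   \code{final_transcript_set}).
#' @param path output GTF path.
#' @param source source field (default \code{"lgpca"}).
#' @return the path, invisibly.
#' @export
write_transcripts_gtf <- function(models, path, source = "lgpca") {
  if (inherits(models, "final_transcript_set")) models <- models$models
  tx <- models$tx
  use_name <- !is.null(tx$name)
  lines <- character(0)
  ord <- order(tx$chrom, tx$start, tx$tx_id)
  for (i in ord) {
    ex <- models$exons[models$exons$transcript_id == tx$tx_id[i]]
    id <- if (use_name) tx$name[i] else tx$tx_id[i]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', id, id)
    if (use_name)
      attrs <- paste0(attrs, sprintf(' orig_id "%s"; class_code "%s";',
                                     tx$tx_id[i], tx$class_code[i]),
                      sprintf(' positional_class "%s"; tucp "%s";',
                              tx$positional_class[i],
                              tolower(tx$tucp[i])))
    lines <- c(lines, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                              tx$chrom[i], source,
                              BiocGenerics::start(ex), BiocGenerics::end(ex),
                              tx$strand[i], attrs))
  }
  writeLines(lines, path)
  invisible(path)
}
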