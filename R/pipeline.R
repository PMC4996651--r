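#' Pipeline configuration
#'
#' Assembles and validates the full parameter set of the analysis pipeline.
#' Defaults follow the atlas analysis settings: extreme-gene sets of 1000 per
#' pole, NMF over ranks 11-18 with 50 consensus runs (200 confirmation runs),
#' basis-contribution threshold 0.8, bidirectional window 1 kb, TUCP
#' threshold 0.2, neighborhood window 1 Mb, minimum transcript length 200 bp
#' and minimum gene total 100 reads.
#'
#' @param counts,sample_sheet,newick paths for the expression branch (counts
#'   TSV, sample sheet TSV, guide-tree newick); all three or none.
#' @param ref_gtf,novel_gtf,scores_tsv paths for the annotation branch.
#' @param novel_counts,gene_counts optional expression TSVs enabling the
#'   neighborhood-correlation stage.
#' @param scale,n_global,k_extreme LgPCA controls.
#' @param run_nmf run the metagene branch (default TRUE when counts given).
#' @param nmf_ranks,nmf_runs,nmf_confirm_runs,nmf_max_iter,basis_threshold
#'   metagene controls.
#' @param excluded_genes genes removed before NMF (e.g. Y-linked and XIST).
#' @param min_total,bi_window,tucp_threshold,window,min_len filter windows.
#' @param seed pipeline seed.
#' @return validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(counts = NULL, sample_sheet = NULL, newick = NULL,
                            ref_gtf = NULL, novel_gtf = NULL,
                            scores_tsv = NULL, novel_counts = NULL,
                            gene_counts = NULL,
                            scale = TRUE, n_global = 15, k_extreme = 1000,
                            run_nmf = !is.null(counts), nmf_ranks = 11:18,
                            nmf_runs = 50, nmf_confirm_runs = 200,
                            nmf_max_iter = 2000, basis_threshold = 0.8,
                            excluded_genes = character(), min_total = 100,
                            bi_window = 1000, tucp_threshold = 0.2,
                            window = 1e6, min_len = 200, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' Read a pipeline configuration from a flat YAML file
#' @param path YAML file of \code{pipeline_config} keys.
#' @return validated \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param cfg a configuration list.
#' @export
validate_pipeline_config <- function(cfg) {
  chk_file <- function(p, what) {
    if (!is.null(p) && !file.exists(p))
      stop("missing ", what, " file: ", p)
  }
  has_expr <- !is.null(cfg$counts)
  if (has_expr && (is.null(cfg$sample_sheet) || is.null(cfg$newick)))
    stop("expression branch needs counts, sample_sheet and newick together")
  has_annot <- !is.null(cfg$novel_gtf)
  if (has_annot && (is.null(cfg$ref_gtf) || is.null(cfg$scores_tsv)))
    stop("annotation branch needs novel_gtf, ref_gtf and scores_tsv together")
  if (!has_expr && !has_annot)
    stop("configuration enables no stage")
  for (k in c("counts", "sample_sheet", "newick", "ref_gtf", "novel_gtf",
              "scores_tsv", "novel_counts", "gene_counts"))
    chk_file(cfg[[k]], k)
  stopifnot(cfg$n_global >= 0, cfg$k_extreme >= 1,
            all(cfg$nmf_ranks >= 2), cfg$nmf_runs >= 2,
            cfg$basis_threshold > 0.5, cfg$basis_threshold <= 1,
            cfg$min_total >= 0, cfg$bi_window >= 0,
            cfg$tucp_threshold >= 0, cfg$tucp_threshold <= 1,
            cfg$window > 0, cfg$min_len >= 0)
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Executes the configured stages in dependency order (normalize, LgPCA and
#' extreme-gene extraction; the normalization-free NMF branch; the annotation
#' branch with classification, naming, filtering and optional neighborhood
#' correlation), writing every stage's outputs plus a machine-readable
#' manifest (versions, seed, parameters, input checksums, stages run) into
#' \code{outdir}. Any stage error aborts with the stage name. Re-running with
#' an identical configuration and seed reproduces numerically identical
#' outputs.
#'
#' @param config a \code{\link{pipeline_config}} (or path to its YAML).
#' @param outdir output directory.
#' @return invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$counts)) {
    stages <- c(stages, "normalize")
    norm <- stage("normalize", {
      counts <- read_counts(config$counts)
      sheet <- read_sample_sheet(config$sample_sheet)
      nm <- quantile_normalize(counts)
      write_expression(nm, file.path(outdir, "normalized.tsv"))
      tv <- tau(nm, sheet)
      utils::write.table(
        data.frame(gene_id = names(tv), tau = tv),
        file.path(outdir, "tau.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      list(counts = counts, norm = nm, sheet = sheet, tau = tv)
    })
    res$normalize <- norm

    stages <- c(stages, "lgpca")
    res$lgpca <- stage("lgpca", {
      tree <- read_lineage_tree(file = config$newick)
      prox <- abouheif_proximity(tree)
      write_proximity(prox, file.path(outdir, "proximity.tsv"))
      fit <- lgpca(norm$norm, prox, scale. = config$scale)
      write_expression(fit$scores, file.path(outdir, "scores.tsv"),
                       id_col = "sample")
      write_expression(fit$loadings, file.path(outdir, "loadings.tsv"))
      utils::write.table(summary(fit), file.path(outdir, "eigen_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      fit
    })

    stages <- c(stages, "extremes")
    res$extremes <- stage("extremes", {
      fit <- res$lgpca
      n_global <- min(config$n_global, length(fit$eigenvalues))
      part <- partition_axes(fit, n_global)
      k <- min(config$k_extreme, floor(nrow(fit$loadings) / 2))
      ex <- lapply(part$global, function(ax) extreme_genes(fit, ax, k))
      names(ex) <- part$global
      for (ax in part$global) {
        writeLines(ex[[ax]]$high,
                   file.path(outdir, sprintf("extreme_%s_high.txt", ax)))
        writeLines(ex[[ax]]$low,
                   file.path(outdir, sprintf("extreme_%s_low.txt", ax)))
      }
      list(partition = part, extreme = ex, k = k)
    })

    if (isTRUE(config$run_nmf)) {
      stages <- c(stages, "metagenes")
      res$metagenes <- stage("metagenes", {
        filt <- prefilter_counts(norm$counts, config$excluded_genes,
                                 config$min_total)
        cons <- consensus_select_rank(filt, ranks = config$nmf_ranks,
                                      runs = config$nmf_runs,
                                      seed = config$seed,
                                      max_iter = config$nmf_max_iter)
        utils::write.table(
          data.frame(rank = names(cons$cophenetic),
                     cophenetic = cons$cophenetic),
          file.path(outdir, "cophenetic.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        fit <- nmf_brunet(filt, cons$best_rank, seed = config$seed,
                          max_iter = config$nmf_max_iter)
        write_expression(fit$W, file.path(outdir, "nmf_basis.tsv"))
        write_expression(fit$H, file.path(outdir, "nmf_coef.tsv"),
                         id_col = "metagene")
        sets <- metagene_genes(fit, config$basis_threshold)
        for (k in names(sets))
          writeLines(sets[[k]],
                     file.path(outdir, sprintf("metagene_%s_genes.txt", k)))
        list(consensus = cons, fit = fit, gene_sets = sets)
      })
    }
  }

  if (!is.null(config$novel_gtf)) {
    stages <- c(stages, "classify")
    res$classify <- stage("classify", {
      ref <- read_genome_annotation(config$ref_gtf)
      nov <- read_transcript_models(config$novel_gtf,
                                    scores = config$scores_tsv)
      cls <- classify_transcripts(nov, ref)
      named <- assign_names(retained_transcripts(cls), ref,
                            bi_window = config$bi_window,
                            tucp_threshold = config$tucp_threshold)
      final <- dedupe_and_filter(named, min_len = config$min_len)
      write_transcripts_gtf(final, file.path(outdir, "novel_final.gtf"))
      utils::write.table(
        as.data.frame(final$class_tally),
        file.path(outdir, "class_tally.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      list(ref = ref, classified = cls, named = named, final = final)
    })

    if (!is.null(config$novel_counts) && !is.null(config$gene_counts)) {
      stages <- c(stages, "correlate")
      res$correlate <- stage("correlate", {
        en <- read_counts(config$novel_counts)
        eg <- read_counts(config$gene_counts)
        nc <- neighborhood_correlation(res$classify$final, res$classify$ref,
                                       en, eg, window = config$window)
        utils::write.table(nc$summary,
                           file.path(outdir, "neighborhood_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(nc$neighbors,
                           file.path(outdir, "neighborhood_pairs.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        nc
      })
    }
  }

  inputs <- Filter(Negate(is.null),
                   config[c("counts", "sample_sheet", "newick", "ref_gtf",
                            "novel_gtf", "scores_tsv", "novel_counts",
                            "gene_counts")])
  manifest <- list(
    package = "lgpca",
    version = as.character(utils::packageVersion("lgpca")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    parameters = config[setdiff(names(config), names(inputs))],
    input_checksums = as.list(vapply(inputs, function(p)
      unname(tools::md5sum(p)), character(1))),
    stages = stages)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  res$manifest <- manifest
  invisible(res)
}
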