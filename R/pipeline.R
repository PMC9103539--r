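## End-to-end orchestration: simulate -> screen -> co-express -> stats,
## each command a thin wrapper over the module functions, writing standard
## files plus a machine-readable JSON run manifest. A single global seed
## fans out to per-module seeds by fixed offsets, giving one knob and
## independent streams.

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset * 10007) %% 2147483647)
}

run_manifest <- function(config, inputs, outputs, extra = list()) {
  c(list(tool = "ernascreen",
         version = as.character(utils::packageVersion("ernascreen")),
         config = config,
         input_md5 = as.list(tools::md5sum(inputs)),
         outputs = as.list(outputs)),
    extra)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a synthetic fixture directory
#'
#' Writes the full set of pipeline inputs (locus FASTA, reads FASTQ,
#' peaks/repeats BED, transcripts GTF, read-origin TSV, ground-truth
#' JSON) for a seeded configuration. Identical configurations produce
#' byte-identical directories.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of written paths.
#' @export
cmd_simulate <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_locus(config)
  rd <- simulate_reads(sim$sequence, sim$truth, config)
  p <- function(f) file.path(out_dir, f)
  write_fasta(sim$sequence, p("locus.fa"))
  write_fastq(rd$reads, p("reads.fastq"))
  write_bed(sim$peaks, p("peaks.bed"))
  reps <- sim$repeats; names(reps)[names(reps) == "repeat_class"] <- "name"
  write_bed(reps, p("repeats.bed"))
  write_gtf_transcripts(sim$transcripts, p("transcripts.gtf"))
  utils::write.table(rd$origins, p("read_origins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE,
                       force = TRUE)
  paths <- list(fasta = p("locus.fa"), fastq = p("reads.fastq"),
                peaks = p("peaks.bed"), repeats = p("repeats.bed"),
                gtf = p("transcripts.gtf"),
                origins = p("read_origins.tsv"), truth = p("truth.json"))
  write_manifest(run_manifest(unclass(config), character(0),
                              unlist(paths)),
                 p("manifest.json"))
  invisible(paths)
}

#' Run the screening funnel on a fixture or real inputs
#'
#' Maps reads internally (FASTQ) or accepts precomputed ungapped
#' alignments (SAM) via `sam`, then runs [run_screen()] and writes a BED
#' of surviving regions per stage, a funnel TSV, a SAM of the alignments
#' used, and a JSON manifest (configuration, input hashes, funnel).
#'
#' @param fasta,fastq,peaks,repeats,gtf Input paths (a fixture directory's
#'   files, or real data in the same formats).
#' @param sam Optional SAM path; when given, internal mapping is skipped.
#' @param out_dir Output directory.
#' @param locus Optional [locus_spec()]; defaults to the full FASTA
#'   sequence at offset 0.
#' @param flank,mapper,dense,repeat_filter,merge_touching Screen
#'   parameters (see [run_screen()]).
#' @return The `screen_result`, invisibly, with `$paths` attached.
#' @export
cmd_screen <- function(fasta, fastq = NULL, peaks, repeats, gtf,
                       sam = NULL, out_dir, locus = NULL,
                       flank = 3000L, mapper = mapper_config(),
                       dense = dense_params(),
                       repeat_filter = repeat_filter_params(),
                       merge_touching = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- read_fasta(fasta)
  if (is.null(locus))
    locus <- locus_spec(names(seqs)[1], 0L, nchar(seqs[[1]]), "as_given")
  peaks_df <- read_bed(peaks)
  reps_df <- read_bed(repeats)
  if ("name" %in% names(reps_df))
    names(reps_df)[names(reps_df) == "name"] <- "repeat_class"
  tx <- read_gtf_transcripts(gtf)
  alignments <- NULL; reads <- NULL
  if (!is.null(sam)) alignments <- read_sam(sam)
  else if (!is.null(fastq)) reads <- read_fastq(fastq)
  else stop("need either a FASTQ of reads or a SAM of alignments")
  res <- run_screen(peaks_df, locus, locus_sequence = seqs[[1]],
                    reads = reads, alignments = alignments,
                    repeats = reps_df, transcripts = tx, flank = flank,
                    mapper = mapper, dense = dense,
                    repeat_filter = repeat_filter,
                    merge_touching = merge_touching)
  p <- function(f) file.path(out_dir, f)
  stage_files <- character(0)
  for (nm in names(res$regions)) {
    df <- res$regions[[nm]]
    out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                      name = df$region_id, stringsAsFactors = FALSE)
    f <- p(sprintf("regions_%s.bed", nm))
    write_bed(out, f)
    stage_files <- c(stage_files, f)
  }
  funnel_tsv <- p("funnel.tsv")
  utils::write.table(
    data.frame(stage = res$funnel$stage, count = res$funnel$count,
               region_ids = vapply(res$funnel$region_ids, paste,
                                   "", collapse = ",")),
    funnel_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  cand_tsv <- p("candidates.tsv")
  utils::write.table(res$candidates, cand_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sam_out <- p("alignments.sam")
  write_sam(res$alignments, locus, sam_out,
            reads = if (!is.null(reads)) reads)
  inputs <- c(fasta, fastq, peaks, repeats, gtf, sam)
  cfg <- list(flank = flank, mapper = unclass(mapper),
              dense = unclass(dense),
              repeat_filter = unclass(repeat_filter),
              merge_touching = merge_touching)
  outputs <- c(stage_files, funnel_tsv, cand_tsv, sam_out)
  write_manifest(run_manifest(cfg, inputs, outputs, extra = list(
    funnel = stats::setNames(as.list(res$funnel$count), res$funnel$stage))),
    p("manifest.json"))
  res$paths <- c(outputs, p("manifest.json"))
  invisible(res)
}

#' Run the co-expression screen from a TSV matrix
#'
#' @param matrix_tsv Expression matrix TSV (see [read_expression_tsv()]).
#' @param target_gene Target transcript identifier.
#' @param out_dir Output directory.
#' @param orientation Matrix orientation in the TSV.
#' @param config A [coexpression_config()].
#' @return The ranked results data.frame, invisibly.
#' @export
cmd_coexpress <- function(matrix_tsv, target_gene, out_dir,
                          orientation = "genes_x_samples",
                          config = coexpression_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- read_expression_tsv(matrix_tsv, orientation)
  res <- coexpression_screen(m, target_gene, config)
  p <- function(f) file.path(out_dir, f)
  export_gene_list(res, config$top_k, p("top_genes.tsv"))
  write_manifest(run_manifest(unclass(config), matrix_tsv,
                              p("top_genes.tsv"),
                              extra = list(n_tested = nrow(res),
                                           n_skipped =
                                             attr(res, "n_skipped"))),
                 p("manifest.json"))
  invisible(res)
}

#' Relative-expression and viability statistics from TSV tables
#'
#' Computes delta-delta-Ct fold changes from a Ct table (plus a Wilcoxon
#' signed-rank test of the treated fold changes against 1), and/or
#' normalized viability fractions from a viability table (plus a pooled
#' Student's t-test per concentration between arms). Results with
#' `p < alpha` are flagged significant.
#'
#' @param ct_tsv Optional Ct table TSV (`sample`, `condition`, `gene`,
#'   `ct`).
#' @param viability_tsv Optional viability TSV (`cell_line`, `arm`,
#'   `concentration`, `value`).
#' @param target_gene,reference_gene Genes for the ddCt analysis.
#' @param out_dir Output directory.
#' @param alpha Significance level (default 0.05).
#' @param efficiency Amplification factor `E`.
#' @return Invisibly, a list with `fold_changes`, `wilcoxon`,
#'   `viability`, `t_tests` (those requested).
#' @export
cmd_stats <- function(ct_tsv = NULL, viability_tsv = NULL,
                      target_gene = "eRNA1", reference_gene = "GAPDH",
                      out_dir, alpha = 0.05, efficiency = 2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  out <- list()
  outputs <- character(0); inputs <- character(0)
  if (!is.null(ct_tsv)) {
    ct <- utils::read.delim(ct_tsv, stringsAsFactors = FALSE)
    fc <- ddct_fold_change(ct, target_gene, reference_gene, efficiency)
    wt <- wilcoxon_test(fc$fold_change[fc$condition == "treated"], 1,
                        mode = "signed_rank")
    utils::write.table(fc, p("fold_changes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res <- data.frame(test = "wilcoxon_signed_rank_vs_1",
                      statistic = wt$statistic, p_value = wt$p_value,
                      n = wt$n_effective, n_dropped = wt$n_dropped,
                      significant = !is.na(wt$p_value) &
                        wt$p_value < alpha)
    utils::write.table(res, p("ct_tests.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$fold_changes <- fc; out$wilcoxon <- wt
    inputs <- c(inputs, ct_tsv)
    outputs <- c(outputs, p("fold_changes.tsv"), p("ct_tests.tsv"))
  }
  if (!is.null(viability_tsv)) {
    v <- utils::read.delim(viability_tsv, stringsAsFactors = FALSE)
    nv <- normalize_viability(v)
    tests <- list()
    for (cl in unique(nv$cell_line)) {
      for (conc in setdiff(unique(nv$concentration[nv$cell_line == cl]),
                           0)) {
        ta <- nv$normalized[nv$cell_line == cl & nv$concentration == conc &
                              nv$arm == "targeting"]
        sc <- nv$normalized[nv$cell_line == cl & nv$concentration == conc &
                              nv$arm == "scrambled"]
        if (length(ta) >= 2L && length(sc) >= 2L) {
          tt <- students_t_test(ta, sc)
          tests[[length(tests) + 1L]] <- data.frame(
            cell_line = cl, concentration = conc,
            statistic = tt$statistic, p_value = tt$p_value, df = tt$df,
            significant = tt$p_value < alpha, stringsAsFactors = FALSE)
        }
      }
    }
    tdf <- do.call(rbind, tests)
    utils::write.table(nv, p("viability_normalized.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(tdf))
      utils::write.table(tdf, p("viability_tests.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    out$viability <- nv; out$t_tests <- tdf
    inputs <- c(inputs, viability_tsv)
    outputs <- c(outputs, p("viability_normalized.tsv"))
  }
  write_manifest(run_manifest(list(alpha = alpha,
                                   efficiency = efficiency,
                                   target_gene = target_gene,
                                   reference_gene = reference_gene),
                              inputs, outputs),
                 p("manifest.json"))
  invisible(out)
}
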