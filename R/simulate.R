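## Seeded generators for every input the pipeline consumes, with ground
## truth recorded. The locus generator is structural-by-construction: the
## number of covered, merged, repeat-masked and annotated groups is fixed
## by the configuration, while positions and sequence are seeded-random.
## The expected screening funnel is therefore recomputable from the
## recorded ground truth alone, independent of the pipeline.

#' Simulation configuration
#'
#' Defaults emulate the screen's study conditions: a ~100 kb enhancer-rich
#' locus, twelve enhancer peaks of which five are transcribed (one
#' overlapping pair among them, so covered windows merge 5 -> 4), 20x mean
#' coverage of transcribed intervals with 50 bp reads and a 1% per-base
#' substitution error, interspersed repeats of the four filtered classes
#' with two covered groups fully repeat-masked, and one surviving group
#' carrying an annotated lncRNA.
#'
#' @param seed Integer seed; every output is a pure function of the
#'   configuration (identical seeds give byte-identical files).
#' @param locus_length Locus length in bp (default 100000).
#' @param n_peaks Number of enhancer peaks (default 12).
#' @param n_transcribed Number of peak windows containing a transcribed
#'   interval (default 5; must be <= n_peaks and >= 2 for a merged pair).
#' @param transcript_len Length of each planted transcribed interval in bp
#'   (default 1000).
#' @param depth Mean read coverage of transcribed intervals (default 20).
#' @param read_len Read length in bp (default 50).
#' @param error_rate Per-base substitution probability (default 0.01).
#' @param flank Candidate-window half-width in bp (default 3000).
#' @param n_repeats Total planted repeats (default 6; the first `n_masked`
#'   fully cover masked transcribed intervals, the rest fall between
#'   windows).
#' @param repeat_classes Classes drawn for planted repeats (default the
#'   four interspersed classes).
#' @param n_masked Covered groups whose transcribed intervals are fully
#'   repeat-masked (default 2).
#' @param plant_annotated Plant one lncRNA over one surviving transcribed
#'   interval (default `TRUE`).
#' @param chrom Chromosome label for all emitted records.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 42L, locus_length = 100000L, n_peaks = 12L,
                       n_transcribed = 5L, transcript_len = 1000L,
                       depth = 20, read_len = 50L, error_rate = 0.01,
                       flank = 3000L, n_repeats = 6L,
                       repeat_classes = c("SINE", "LINE", "LTR", "DNA"),
                       n_masked = 2L, plant_annotated = TRUE,
                       chrom = "chrSim") {
  stopifnot(n_transcribed <= n_peaks, n_transcribed >= 2L,
            transcript_len >= read_len, transcript_len <= 2L * flank,
            n_repeats >= n_masked, error_rate >= 0, error_rate < 1,
            depth > 0)
  ## one overlapping pair merges two windows into one (never masked,
  ## never annotated); masking and annotation apply to single groups
  if (n_masked > n_transcribed - 2L - as.integer(plant_annotated))
    stop("n_masked leaves no single transcribed group for the ",
         "annotated/novel candidates")
  structure(list(seed = as.integer(seed),
                 locus_length = as.integer(locus_length),
                 n_peaks = as.integer(n_peaks),
                 n_transcribed = as.integer(n_transcribed),
                 transcript_len = as.integer(transcript_len),
                 depth = depth, read_len = as.integer(read_len),
                 error_rate = error_rate, flank = as.integer(flank),
                 n_repeats = as.integer(n_repeats),
                 repeat_classes = repeat_classes,
                 n_masked = as.integer(n_masked),
                 plant_annotated = isTRUE(plant_annotated),
                 chrom = chrom),
            class = "sim_config")
}

#' Simulate the locus: sequence, peaks, repeats and annotation
#'
#' Lays out `n_peaks - 1` non-overlapping blocks along the locus (the
#' overlapping peak pair shares one block) separated by seeded-random
#' gaps, then plants transcribed intervals, masking repeats, decoy
#' repeats and (optionally) a two-exon lncRNA over one surviving
#' interval. Infeasible packing (blocks + minimum gaps exceed the locus)
#' is an error suggesting a larger locus.
#'
#' @param config A [sim_config()].
#' @return List with `sequence` (named character), `peaks`, `repeats`
#'   (data.frames), `transcripts` (list, possibly empty), `locus`
#'   (a [locus_spec()]) and `truth` (ground truth: per-group windows,
#'   summits, transcribed intervals, masked/annotated flags, per-repeat
#'   intervals and classes, lncRNA exons).
#' @export
simulate_locus <- function(config = sim_config()) {
  cfg <- config
  withr::with_seed(cfg$seed, {
    w <- 2L * cfg$flank
    n_single_tr <- cfg$n_transcribed - 2L        # transcribed single blocks
    n_decoy <- cfg$n_peaks - cfg$n_transcribed   # untranscribed blocks
    spacing <- sample(seq(cfg$transcript_len + 500L, w - 500L), 1L)
    widths <- c(spacing + w, rep(w, n_single_tr + n_decoy))
    types <- c("pair", rep("single", n_single_tr), rep("decoy", n_decoy))
    ord <- sample(length(widths))
    widths <- widths[ord]; types <- types[ord]
    nb <- length(widths)
    min_gap <- 10L
    slack <- cfg$locus_length - sum(widths) - min_gap * (nb + 1L)
    if (slack < 0L)
      stop("infeasible packing: peaks do not fit; increase locus_length")
    ## random composition of the slack into nb + 1 gaps of >= min_gap
    cutpts <- sort(sample.int(slack + 1L, nb, replace = TRUE) - 1L)
    gaps <- min_gap + diff(c(0L, cutpts, slack))
    starts <- cumsum(gaps[seq_len(nb)]) + cumsum(c(0L, widths[-nb]))

    groups <- list(); peak_rows <- list()
    for (i in seq_len(nb)) {
      b <- starts[i]
      if (types[i] == "pair") {
        summits <- c(b + cfg$flank, b + cfg$flank + spacing)
      } else {
        summits <- b + cfg$flank
      }
      windows <- data.frame(start = summits - cfg$flank,
                            end = summits + cfg$flank)
      tr <- NULL
      if (types[i] != "decoy") {
        half <- cfg$transcript_len %/% 2L
        tr <- data.frame(start = summits - half,
                         end = summits - half + cfg$transcript_len)
      }
      groups[[i]] <- list(type = types[i], summits = summits,
                          windows = windows, transcribed = tr,
                          masked = FALSE, annotated = FALSE)
      peak_rows[[i]] <- summits
    }
    ## masking / annotation over the single transcribed groups: the pair
    ## group is never masked (it is the "novel, unannotated" survivor)
    singles <- which(types == "single")
    masked_groups <- utils::tail(singles, cfg$n_masked)
    for (g in masked_groups) groups[[g]]$masked <- TRUE
    ann_group <- NA_integer_
    if (cfg$plant_annotated) {
      unmasked_singles <- setdiff(singles, masked_groups)
      ann_group <- unmasked_singles[1]
      groups[[ann_group]]$annotated <- TRUE
    }

    ## sequence
    sequence <- paste(sample(c("A", "C", "G", "T"), cfg$locus_length,
                             replace = TRUE), collapse = "")

    ## peaks BED (100 bp intervals whose midpoint is the summit)
    all_summits <- sort(unlist(peak_rows))
    peaks <- data.frame(chrom = cfg$chrom,
                        start = all_summits - 50L, end = all_summits + 50L,
                        name = sprintf("peak_%02d", seq_along(all_summits)),
                        stringsAsFactors = FALSE)

    ## repeats: masking repeats cover masked transcribed intervals exactly;
    ## decoys land in inter-block gaps
    rep_rows <- list()
    ri <- 0L
    for (g in masked_groups) {
      tr <- groups[[g]]$transcribed
      ri <- ri + 1L
      rep_rows[[ri]] <- data.frame(
        chrom = cfg$chrom, start = tr$start[1], end = tr$end[1],
        repeat_class = cfg$repeat_classes[(ri - 1L) %%
                                            length(cfg$repeat_classes) + 1L],
        stringsAsFactors = FALSE)
    }
    n_extra <- cfg$n_repeats - cfg$n_masked
    if (n_extra > 0L) {
      gap_starts <- c(0L, starts + widths)
      gap_ends <- c(starts, cfg$locus_length)
      gw <- gap_ends - gap_starts
      ok <- which(gw >= 320L)
      for (j in seq_len(n_extra)) {
        gsel <- ok[(j - 1L) %% length(ok) + 1L]
        rlen <- sample(150:300, 1L)
        rstart <- gap_starts[gsel] +
          sample.int(gw[gsel] - rlen, 1L) - 1L
        ri <- ri + 1L
        rep_rows[[ri]] <- data.frame(
          chrom = cfg$chrom, start = rstart, end = rstart + rlen,
          repeat_class = sample(cfg$repeat_classes, 1L),
          stringsAsFactors = FALSE)
      }
    }
    repeats <- do.call(rbind, rep_rows)
    if (is.null(repeats))
      repeats <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0), repeat_class = character(0),
                            stringsAsFactors = FALSE)

    ## annotated lncRNA: two exons over the annotated transcribed interval
    transcripts <- list()
    if (cfg$plant_annotated) {
      tr <- groups[[ann_group]]$transcribed
      len <- tr$end[1] - tr$start[1]
      e1 <- c(tr$start[1], tr$start[1] + round(0.4 * len))
      e2 <- c(tr$start[1] + round(0.55 * len), tr$end[1])
      transcripts <- list(list(
        transcript_id = "SYNLNC-201", gene_name = "SYNLNC",
        biotype = "lncRNA",
        exons = data.frame(chrom = cfg$chrom,
                           start = c(e1[1], e2[1]), end = c(e1[2], e2[2]),
                           stringsAsFactors = FALSE)))
    }

    locus <- locus_spec(cfg$chrom, 0L, cfg$locus_length, "synthetic")
    truth <- list(config = cfg, groups = groups, repeats = repeats,
                  transcripts = transcripts,
                  masked_groups = masked_groups, annotated_group = ann_group)
    list(sequence = stats::setNames(sequence, cfg$chrom), peaks = peaks,
         repeats = repeats, transcripts = transcripts, locus = locus,
         truth = truth)
  })
}

#' Simulate RNA-seq reads over the planted transcribed intervals
#'
#' Read starts are uniform within each transcribed interval (reads lie
#' fully inside it); the read count per interval is
#' `round(depth * interval_length / read_len)`. Each base is substituted
#' independently with probability `error_rate` to a uniformly chosen
#' different base; about half the reads come from the minus strand.
#'
#' @param sequence Locus sequence (character, or the named vector from
#'   [simulate_locus()]).
#' @param truth Ground truth from [simulate_locus()].
#' @param config The same [sim_config()].
#' @return List with `reads` (`read_id`, `sequence`) and `origins`
#'   (`read_id`, `start`, `end`, `strand`, `group`, `n_errors`).
#' @export
simulate_reads <- function(sequence, truth, config) {
  cfg <- config
  seqchr <- if (!is.null(names(sequence))) sequence[[1]] else sequence
  withr::with_seed(cfg$seed + 1L, {
    rows <- list(); k <- 0L; rid <- 0L
    for (gi in seq_along(truth$groups)) {
      g <- truth$groups[[gi]]
      if (is.null(g$transcribed)) next
      for (ti in seq_len(nrow(g$transcribed))) {
        s <- g$transcribed$start[ti]; e <- g$transcribed$end[ti]
        len <- e - s
        if (cfg$read_len > len)
          stop("read_len exceeds transcribed interval length")
        n_reads <- round(cfg$depth * len / cfg$read_len)
        starts <- s + sample.int(len - cfg$read_len + 1L, n_reads,
                                 replace = TRUE) - 1L
        for (p in starts) {
          rid <- rid + 1L
          base <- substr(seqchr, p + 1L, p + cfg$read_len)
          ch <- strsplit(base, "", fixed = TRUE)[[1]]
          err <- which(stats::runif(cfg$read_len) < cfg$error_rate)
          for (ei in err) {
            ch[ei] <- sample(setdiff(c("A", "C", "G", "T"), ch[ei]), 1L)
          }
          rseq <- paste(ch, collapse = "")
          strand <- sample(c("+", "-"), 1L)
          if (strand == "-") rseq <- revcomp(rseq)
          k <- k + 1L
          rows[[k]] <- data.frame(
            read_id = sprintf("read_%05d", rid), sequence = rseq,
            start = p, end = p + cfg$read_len, strand = strand,
            group = gi, n_errors = length(err),
            stringsAsFactors = FALSE)
        }
      }
    }
    origins <- do.call(rbind, rows)
    if (is.null(origins))
      return(list(reads = data.frame(read_id = character(0),
                                     sequence = character(0)),
                  origins = data.frame()))
    list(reads = origins[, c("read_id", "sequence")],
         origins = origins[, c("read_id", "start", "end", "strand",
                               "group", "n_errors")])
  })
}

#' Simulate an expression matrix with a planted co-expression module
#'
#' The target transcript is log-normal; `n_correlated` genes are noisy
#' monotone transforms of the target generated from a shared latent
#' Gaussian (latent correlation `effect`, so `effect = 1` gives Spearman
#' rho exactly 1 and `effect = 0` gives independence); the remaining
#' genes are independent log-normal noise.
#'
#' @param n_samples Number of samples (default 200).
#' @param n_genes Total genes including the target (default 50).
#' @param n_correlated Planted co-expressed genes (default 10).
#' @param effect Latent correlation strength in `[0, 1]` (default 0.8).
#' @param seed Integer seed.
#' @param target_gene Name of the target transcript row.
#' @return List with `matrix` (genes x samples) and `truth` (character
#'   vector of planted gene names).
#' @export
simulate_expression_matrix <- function(n_samples = 200L, n_genes = 50L,
                                       n_correlated = 10L, effect = 0.8,
                                       seed = 42L,
                                       target_gene = "target_lnc") {
  stopifnot(n_correlated < n_genes, effect >= 0, effect <= 1)
  withr::with_seed(seed, {
    z <- stats::rnorm(n_samples)
    target <- exp(1 + 0.5 * z)
    others <- sprintf("G%04d", seq_len(n_genes - 1L))
    planted <- sort(sample(others, n_correlated))
    m <- matrix(0, nrow = n_genes, ncol = n_samples,
                dimnames = list(c(target_gene, others),
                                sprintf("S%03d", seq_len(n_samples))))
    m[target_gene, ] <- target
    for (g in others) {
      if (g %in% planted) {
        zi <- effect * z + sqrt(1 - effect^2) * stats::rnorm(n_samples)
      } else {
        zi <- stats::rnorm(n_samples)
      }
      m[g, ] <- exp(1 + 0.5 * zi)
    }
    list(matrix = m, truth = planted)
  })
}

#' Simulate a paired knockdown qPCR Ct table
#'
#' Each experiment contributes a control (scrambled siRNA) and a treated
#' (targeting siRNA) sample, measured for the target gene and the
#' reference gene in `n_replicates` technical replicates. The treated
#' delta-Ct is shifted by `-log_E(true_fold)` relative to the control
#' baseline, so a `true_fold` of 0.5 at `E = 2` is a one-cycle shift.
#'
#' @param n_experiments Independent experiments (default 8).
#' @param true_fold True knockdown fold change (default 0.5, the
#'   approximately two-fold reduction regime).
#' @param ct_noise_sd SD of Gaussian technical noise per Ct measurement,
#'   in cycles (default 0.3).
#' @param seed Integer seed.
#' @param efficiency Amplification factor `E` (default 2).
#' @param n_replicates Technical replicates per measurement (default 3).
#' @param target_gene,reference_gene Gene labels in the emitted table.
#' @return data.frame with columns `sample`, `condition`, `gene`, `ct`.
#' @export
simulate_knockdown_ct <- function(n_experiments = 8L, true_fold = 0.5,
                                  ct_noise_sd = 0.3, seed = 42L,
                                  efficiency = 2, n_replicates = 3L,
                                  target_gene = "eRNA1",
                                  reference_gene = "GAPDH") {
  stopifnot(true_fold > 0, ct_noise_sd >= 0)
  shift <- -log(true_fold) / log(efficiency)
  base_ref <- 15; base_dct <- 5
  withr::with_seed(seed, {
    rows <- list(); k <- 0L
    for (i in seq_len(n_experiments)) {
      for (cond in c("control", "treated")) {
        dct <- base_dct + if (cond == "treated") shift else 0
        sid <- sprintf("exp%02d_%s", i, cond)
        for (r in seq_len(n_replicates)) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            sample = sid, condition = cond,
            gene = c(reference_gene, target_gene),
            ct = c(base_ref + stats::rnorm(1, sd = ct_noise_sd),
                   base_ref + dct + stats::rnorm(1, sd = ct_noise_sd)),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
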