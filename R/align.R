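## Ungapped seed-and-verify read mapping.
##
## The mapping contract is "at most k substitutions, no indels": a read is
## placed wherever its Hamming distance to the locus substring is <= k.
## Placements are found by the pigeonhole principle — split the read into
## k+1 contiguous blocks; any placement with <= k mismatches must contain
## at least one block matching exactly — seeding candidate offsets by exact
## block matching and verifying each candidate by full Hamming comparison.
## An N (in read or locus) matches nothing and always counts as a mismatch,
## so N-rich reads cannot inflate coverage.

#' Mapper configuration
#'
#' @param max_mismatch Maximum substitutions allowed per placement
#'   (default 1, the screen's one-mismatch contract).
#' @param report_policy `"all_hits"` (default; every placement with
#'   `mismatches <= k`, multi-mappers flagged) or `"best_only"` (only
#'   minimum-mismatch placements).
#' @param search_both_strands Also align the reverse complement
#'   (default `TRUE`).
#' @return A `mapper_config` list.
#' @export
mapper_config <- function(max_mismatch = 1L,
                          report_policy = c("all_hits", "best_only"),
                          search_both_strands = TRUE) {
  stopifnot(max_mismatch >= 0L)
  structure(list(max_mismatch = as.integer(max_mismatch),
                 report_policy = match.arg(report_policy),
                 search_both_strands = isTRUE(search_both_strands)),
            class = "mapper_config")
}

#' Reverse complement of DNA strings
#' @param seq Character vector over `{A,C,G,T,N}`.
#' @return Reverse-complemented string(s) (N maps to N).
#' @export
revcomp <- function(seq) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

## Prepared locus: DNAString for exact block seeding, raw vector for fast
## Hamming verification. Built once per locus sequence.
prepare_locus_index <- function(sequence) {
  sequence <- toupper(sequence)
  raw <- charToRaw(sequence)
  structure(list(dna = Biostrings::DNAString(sequence),
                 raw = raw,
                 valid = raw %in% charToRaw("ACGT"),
                 n = nchar(sequence)),
            class = "locus_index")
}

## pigeonhole block boundaries: k+1 near-equal contiguous blocks
split_blocks <- function(len, k) {
  nb <- k + 1L
  sizes <- rep(len %/% nb, nb)
  extra <- len %% nb
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  starts <- cumsum(c(1L, sizes[-nb]))
  data.frame(start = starts, end = starts + sizes - 1L)
}

## mismatch counts of an oriented read at 1-based candidate offsets
hamming_at <- function(idx, qraw, qvalid, offsets) {
  L <- length(qraw)
  vapply(offsets, function(p) {
    span <- p:(p + L - 1L)
    sum(idx$raw[span] != qraw | !idx$valid[span] | !qvalid)
  }, numeric(1))
}

## verified hits (named int vector: names = 1-based offsets, values = mm)
verify_candidates <- function(idx, qseq, cand, k) {
  L <- nchar(qseq)
  cand <- sort(unique(cand[cand >= 1L & cand + L - 1L <= idx$n]))
  if (!length(cand)) return(integer(0))
  qraw <- charToRaw(qseq)
  qvalid <- qraw %in% charToRaw("ACGT")
  mm <- hamming_at(idx, qraw, qvalid, cand)
  keep <- mm <= k
  stats::setNames(as.integer(mm[keep]), cand[keep])
}

align_oriented <- function(idx, qseq, k) {
  L <- nchar(qseq)
  if (L > idx$n) return(integer(0))
  if (grepl("[^ACGTN]", qseq)) stop("read contains non-ACGTN characters")
  blocks <- split_blocks(L, k)
  cand <- integer(0)
  for (b in seq_len(nrow(blocks))) {
    bs <- substr(qseq, blocks$start[b], blocks$end[b])
    m <- Biostrings::matchPattern(bs, idx$dna, fixed = TRUE)
    cand <- c(cand, BiocGenerics::start(m) - blocks$start[b] + 1L)
  }
  verify_candidates(idx, qseq, cand, k)
}

#' Align one read to the locus (ungapped, at most k mismatches)
#'
#' @param read One-row data.frame (or list) with `read_id` and `sequence`.
#' @param locus_sequence Locus DNA string, or a prepared index when
#'   aligning many reads.
#' @param config A [mapper_config()].
#' @return data.frame of placements: `read_id`, `pos` (0-based start on the
#'   locus), `strand`, `mismatches`, `read_len`, `is_multi`; ordered by
#'   position then strand. Reads shorter than `2 * (k + 1)` are rejected
#'   with a warning (the pigeonhole split would degenerate).
#' @examples
#' align_read(list(read_id = "r1", sequence = "GTAC"), "ACGTACGTAC",
#'            mapper_config(max_mismatch = 1, search_both_strands = FALSE))
#' @export
align_read <- function(read, locus_sequence, config = mapper_config()) {
  idx <- if (inherits(locus_sequence, "locus_index")) locus_sequence
         else prepare_locus_index(locus_sequence)
  seq <- toupper(read$sequence[[1]])
  if (!nzchar(seq)) stop("empty read sequence for read ", read$read_id[[1]])
  k <- config$max_mismatch
  if (nchar(seq) < 2L * (k + 1L)) {
    warning(sprintf("read %s shorter than 2*(k+1)=%d bp; rejected",
                    read$read_id[[1]], 2L * (k + 1L)))
    return(empty_alignments())
  }
  hits <- list(`+` = align_oriented(idx, seq, k))
  if (config$search_both_strands)
    hits[["-"]] <- align_oriented(idx, revcomp(seq), k)
  assemble_read_hits(read$read_id[[1]], nchar(seq), hits,
                     config$report_policy)
}

assemble_read_hits <- function(read_id, read_len, hits, report_policy) {
  df <- do.call(rbind, lapply(names(hits), function(s) {
    h <- hits[[s]]
    if (!length(h)) return(NULL)
    data.frame(read_id = read_id,
               pos = as.integer(names(h)) - 1L, strand = s,
               mismatches = as.integer(h), stringsAsFactors = FALSE)
  }))
  if (is.null(df)) return(empty_alignments())
  if (report_policy == "best_only")
    df <- df[df$mismatches == min(df$mismatches), , drop = FALSE]
  df <- df[order(df$pos, df$strand), , drop = FALSE]
  df$read_len <- read_len
  df$is_multi <- nrow(df) > 1L
  rownames(df) <- NULL
  df
}

empty_alignments <- function() {
  data.frame(read_id = character(0), pos = integer(0), strand = character(0),
             mismatches = integer(0), read_len = integer(0),
             is_multi = logical(0), stringsAsFactors = FALSE)
}

#' Align a batch of reads
#'
#' Equivalent to [align_read()] applied read by read (results
#' concatenated in read order, positions ascending within a read), but
#' seeded in bulk: all same-width blocks are exact-matched against the
#' locus in one dictionary pass (`matchPDict`), then every candidate is
#' verified by full Hamming comparison. Reads containing N fall back to
#' the per-read path. A bad read (too short, empty, non-ACGTN) produces
#' a warning, never aborts the batch.
#'
#' @param reads data.frame with `read_id`, `sequence`.
#' @param locus_sequence Locus DNA string or prepared index.
#' @param config A [mapper_config()].
#' @return Alignment data.frame as in [align_read()].
#' @export
align_all <- function(reads, locus_sequence, config = mapper_config()) {
  idx <- if (inherits(locus_sequence, "locus_index")) locus_sequence
         else prepare_locus_index(locus_sequence)
  n <- nrow(reads)
  if (n == 0L) return(empty_alignments())
  seqs <- toupper(reads$sequence)
  k <- config$max_mismatch
  lens <- nchar(seqs)
  empty <- lens == 0L
  short <- !empty & lens < 2L * (k + 1L)
  badchar <- !empty & grepl("[^ACGTN]", seqs)
  if (any(empty))
    warning(sprintf("%d read(s) with empty sequence skipped", sum(empty)))
  if (any(short))
    warning(sprintf("%d read(s) shorter than 2*(k+1)=%d bp rejected",
                    sum(short), 2L * (k + 1L)))
  if (any(badchar))
    warning(sprintf("%d read(s) with non-ACGTN characters skipped",
                    sum(badchar)))
  has_n <- grepl("N", seqs, fixed = TRUE)
  ok <- !(empty | short | badchar)
  batch <- ok & !has_n

  strands <- if (config$search_both_strands) c("+", "-") else "+"
  oriented <- list(`+` = seqs)
  if (config$search_both_strands) {
    rc <- seqs
    rc[ok] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[ok])))
    oriented[["-"]] <- rc
  }

  ## candidate offsets per read and strand, from bulk block seeding
  cand <- vector("list", n)
  for (s in strands) {
    oseqs <- oriented[[s]]
    for (L in unique(lens[batch])) {
      rows <- which(batch & lens == L)
      blocks <- split_blocks(L, k)
      for (b in seq_len(nrow(blocks))) {
        bs <- substr(oseqs[rows], blocks$start[b], blocks$end[b])
        pd <- Biostrings::PDict(bs)
        m <- Biostrings::matchPDict(pd, idx$dna)
        st <- Biostrings::startIndex(m)  # plain list, one element per read
        for (j in seq_along(rows)) {
          off <- st[[j]]
          if (length(off))
            cand[[rows[j]]] <- c(cand[[rows[j]]],
                                 stats::setNames(
                                   list(off - blocks$start[b] + 1L), s))
        }
      }
    }
  }

  out <- vector("list", n)
  for (i in which(ok)) {
    if (!batch[i]) {
      out[[i]] <- tryCatch(
        align_read(list(read_id = reads$read_id[i], sequence = seqs[i]),
                   idx, config),
        error = function(e) {
          warning(sprintf("read %s skipped: %s", reads$read_id[i],
                          conditionMessage(e)))
          empty_alignments()
        })
      next
    }
    ci <- cand[[i]]
    hits <- lapply(stats::setNames(strands, strands), function(s) {
      offs <- unlist(ci[names(ci) == s], use.names = FALSE)
      if (is.null(offs)) return(integer(0))
      verify_candidates(idx, oriented[[s]][i], offs, k)
    })
    out[[i]] <- assemble_read_hits(reads$read_id[i], lens[i], hits,
                                   config$report_policy)
  }
  df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(df)) return(empty_alignments())
  rownames(df) <- NULL
  df
}
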