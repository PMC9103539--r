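## Text SAM exchange for the ungapped alignment model. Only fully-matching
## CIGARs (<len>M) are representable; imported records with indels or
## clipping are skipped with a counted warning so that externally produced
## spliced/gapped alignments cannot silently enter the ungapped screen.

#' Write ungapped alignments as SAM
#'
#' Emits a valid header (`@SQ` for the locus) and one line per placement.
#' `POS` is 1-based per the SAM standard (internal coordinates are
#' 0-based); the `NM` tag carries the mismatch count. Secondary placements
#' of a multi-mapping read get the secondary-alignment flag.
#'
#' @param alignments Alignment data.frame from [align_all()].
#' @param locus A [locus_spec()]; `@SQ` uses `locus$chrom` and the locus
#'   length.
#' @param path Output path.
#' @param reads Optional data.frame (`read_id`, `sequence`) used to fill
#'   the SEQ column (reverse-complemented for minus-strand placements, per
#'   the standard); `SEQ` is `*` when omitted.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, locus, path, reads = NULL) {
  seqs <- if (!is.null(reads))
    stats::setNames(toupper(reads$sequence), reads$read_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", locus$chrom, locus_length(locus)),
               "@PG\tID:ernascreen\tPN:ernascreen"), con)
  if (nrow(alignments)) {
    primary <- !duplicated(alignments$read_id)
    flag <- ifelse(alignments$strand == "-", 16L, 0L) +
      ifelse(primary, 0L, 256L)
    seqcol <- rep("*", nrow(alignments))
    if (!is.null(reads)) {
      seqcol <- seqs[alignments$read_id]
      minus <- alignments$strand == "-"
      if (any(minus)) seqcol[minus] <- revcomp(seqcol[minus])
      seqcol[is.na(seqcol)] <- "*"
    }
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       alignments$read_id, flag, locus$chrom,
                       alignments$pos + 1L, alignments$read_len,
                       seqcol, alignments$mismatches), con)
  }
  invisible(path)
}

#' Read ungapped alignments from SAM
#'
#' Inverts [write_sam()] on the alignment fields, and also accepts
#' externally produced SAM so a real-data run can bypass the internal
#' mapper. Records that are unmapped or whose CIGAR contains anything but
#' a single match run (indels, clips, splices) are skipped; the skip count
#' is reported in one warning.
#'
#' @param path Path to a SAM text file.
#' @return Alignment data.frame (`read_id`, `pos` 0-based, `strand`,
#'   `mismatches`, `read_len`, `is_multi`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop(sprintf("malformed SAM line %d: fewer than 11 fields",
                 which(nf < 11L)[1]))
  flag <- as.integer(vapply(fields, `[`, "", 2L))
  cigar <- vapply(fields, `[`, "", 6L)
  unmapped <- bitwAnd(flag, 4L) > 0L
  gapped <- !grepl("^[0-9]+M$", cigar) & !unmapped
  keep <- !unmapped & !gapped
  if (any(gapped))
    warning(sprintf("%d SAM record(s) with non-ungapped CIGAR skipped",
                    sum(gapped)))
  if (!any(keep)) return(empty_alignments())
  fields <- fields[keep]
  flag <- flag[keep]
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  if (anyNA(nm)) {
    warning(sprintf("%d SAM record(s) without NM tag: mismatches set to 0",
                    sum(is.na(nm))))
    nm[is.na(nm)] <- 0L
  }
  df <- data.frame(
    read_id = vapply(fields, `[`, "", 1L),
    pos = as.integer(vapply(fields, `[`, "", 4L)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mismatches = nm,
    read_len = as.integer(sub("M$", "", vapply(fields, `[`, "", 6L))),
    stringsAsFactors = FALSE)
  df$is_multi <- df$read_id %in% df$read_id[duplicated(df$read_id)]
  df
}
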