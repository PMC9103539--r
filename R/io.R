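## Positional-format I/O. BED is 0-based half-open and is preserved
## bit-exact on round-trip; GTF is 1-based closed and is converted to the
## internal 0-based half-open convention on read (and back on write).
## FASTA/FASTQ go through Biostrings.

#' Read a minimal BED file
#'
#' Accepts the 3+ column dialect (chrom, start, end, then optional name,
#' score, strand). Column 4 carries the repeat class for repeat-annotation
#' BEDs and the region identifier for candidate-region BEDs.
#'
#' @param path Path to a tab-separated BED file.
#' @return data.frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`. Unknown strand symbols are treated
#'   as unstranded (`"*"`) with a warning.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                 which(nf < 3L)[1], path))
  starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                 bad[1], path))
  df <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                   start = starts, end = ends, stringsAsFactors = FALSE)
  ncol_max <- max(nf)
  if (ncol_max >= 4L) df$name <- vapply(fields, function(f)
    if (length(f) >= 4L) f[4] else NA_character_, "")
  if (ncol_max >= 5L) df$score <- vapply(fields, function(f)
    if (length(f) >= 5L) f[5] else NA_character_, "")
  if (ncol_max >= 6L) {
    s <- vapply(fields, function(f) if (length(f) >= 6L) f[6] else "*", "")
    unknown <- !(s %in% c("+", "-", "*", "."))
    if (any(unknown)) {
      warning(sprintf("%d BED record(s) with unknown strand symbol treated as unstranded",
                      sum(unknown)))
      s[unknown] <- "*"
    }
    s[s == "."] <- "*"
    df$strand <- s
  }
  validate_intervals(df, sprintf("BED record in %s", path))
  df
}

#' Write a minimal BED file
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns (written in that order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  # trailing optional columns only: cannot emit strand without name/score
  keep <- cols[seq_len(max(which(c("chrom", "start", "end", "name", "score",
                                   "strand") %in% cols)))]
  if (!all(keep %in% names(df)))
    stop("BED columns must be contiguous from the left: missing ",
         paste(setdiff(keep, names(df)), collapse = ", "))
  m <- do.call(cbind, lapply(keep, function(k) as.character(df[[k]])))
  writeLines(if (nrow(df)) apply(m, 1L, paste, collapse = "\t") else character(0),
             path)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Exon records are grouped by `transcript_id` and converted from GTF's
#' 1-based closed coordinates to the internal 0-based half-open convention.
#'
#' @param path Path to a GTF file with `exon` features carrying
#'   `transcript_id` attributes (plus optional `gene_name`,
#'   `gene_biotype`/`transcript_biotype`).
#' @return A list of transcript records; each has `transcript_id`,
#'   `gene_name`, `biotype` and an `exons` data.frame (sorted,
#'   non-overlapping, 0-based half-open).
#' @export
read_gtf_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) return(list())
  meta <- S4Vectors::mcols(gr)
  tid <- as.character(meta$transcript_id)
  if (anyNA(tid)) stop("GTF exon without transcript_id in ", path)
  gname <- if ("gene_name" %in% names(meta)) as.character(meta$gene_name)
           else rep(NA_character_, length(gr))
  btype <- if ("transcript_biotype" %in% names(meta))
             as.character(meta$transcript_biotype)
           else if ("gene_biotype" %in% names(meta))
             as.character(meta$gene_biotype)
           else rep(NA_character_, length(gr))
  out <- lapply(split(seq_along(gr), tid), function(idx) {
    ex <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[idx],
                     start = BiocGenerics::start(gr)[idx] - 1L,
                     end = BiocGenerics::end(gr)[idx],
                     stringsAsFactors = FALSE)
    ex <- ex[order(ex$start), , drop = FALSE]
    rownames(ex) <- NULL
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)]))
      stop("overlapping exons within transcript ", tid[idx[1]])
    list(transcript_id = tid[idx[1]],
         gene_name = gname[idx[1]],
         biotype = btype[idx[1]],
         exons = ex)
  })
  unname(out[order(names(out))])
}

#' Write transcript models as GTF
#'
#' The inverse of [read_gtf_transcripts()]: internal 0-based half-open
#' exons become 1-based closed GTF records.
#'
#' @param transcripts List of transcript records (see
#'   [read_gtf_transcripts()]).
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf_transcripts <- function(transcripts, path, source = "ernascreen") {
  lines <- unlist(lapply(transcripts, function(tx) {
    ex <- tx$exons
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "%s";',
      tx$transcript_id, tx$transcript_id,
      if (is.na(tx$gene_name)) tx$transcript_id else tx$gene_name,
      if (is.na(tx$biotype)) "lncRNA" else tx$biotype)
    sprintf("%s\t%s\texon\t%d\t%d\t.\t+\t.\t%s",
            ex$chrom, source, ex$start + 1L, ex$end, attrs)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#' @param path Path to an uncompressed or gzipped FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read reads from a FASTQ file
#'
#' Quality strings are parsed (the record structure is validated) but not
#' used by the ungapped mapper.
#'
#' @param path Path to a FASTQ file.
#' @return data.frame with columns `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = unname(toupper(as.character(x))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to a FASTQ file (constant placeholder qualities)
#' @param reads data.frame with `read_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(paste0("@", reads$read_id[i]), reads$sequence[i], "+",
                 strrep("I", nchar(reads$sequence[i]))), con)
  }
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV with row identifiers in the first column.
#' @param orientation `"genes_x_samples"` (default) or
#'   `"samples_x_genes"`; the matrix is returned genes-by-samples either way.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_tsv <- function(path, orientation = c("genes_x_samples",
                                                      "samples_x_genes")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (orientation == "samples_x_genes") m <- t(m)
  m
}

#' Write an expression matrix as TSV (genes in rows)
#' @param m Numeric matrix, genes in rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
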