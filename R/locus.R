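#' Define the genomic locus under study
#'
#' All pipeline coordinates are 0-based, half-open and must fall inside
#' `[start, end)`. The default corresponds to a ~2 Mb immunoglobulin
#' heavy-chain (IGH) locus on chromosome 14, the kind of single-locus
#' universe this screen is designed for.
#'
#' @param chrom Chromosome name, e.g. `"chr14"`.
#' @param start,end Locus bounds in bp (0-based, half-open).
#' @param genome_build Assembly label, e.g. `"hg38"`.
#' @return An object of class `locus_spec`.
#' @examples
#' locus_spec("chr14", 105000000, 107000000, "hg38")
#' @export
locus_spec <- function(chrom, start, end, genome_build = "unknown") {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start < end)) stop("locus start must be < end")
  structure(
    list(chrom = chrom, start = start, end = end,
         genome_build = genome_build),
    class = "locus_spec"
  )
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("<locus_spec> %s:%s-%s (%s), length %s bp\n",
              x$chrom, format(x$start, big.mark = ","),
              format(x$end, big.mark = ","), x$genome_build,
              format(x$end - x$start, big.mark = ",")))
  invisible(x)
}

#' Length of a locus in bp
#' @param locus A [locus_spec()].
#' @return Integer length `end - start`.
#' @export
locus_length <- function(locus) as.integer(locus$end - locus$start)

## ---- internal interval helpers -------------------------------------------
## Intervals travel as data.frames with columns chrom, start, end (0-based,
## half-open) plus whatever metadata a stage adds. Conversion to the 1-based
## closed convention of IRanges happens only here.

intervals_to_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

iranges_to_intervals <- function(ir, chrom) {
  data.frame(chrom = rep(chrom, length(ir)),
             start = BiocGenerics::start(ir) - 1L,
             end = BiocGenerics::end(ir),
             stringsAsFactors = FALSE)
}

validate_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!(df$start < df$end))
  if (length(bad))
    stop(sprintf("%s %d has start >= end (%s:%s-%s)", what, bad[1],
                 df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  invisible(df)
}

#' Fraction of one interval covered by another
#'
#' @param a,b Intervals given as `c(start, end)` (0-based half-open) or
#'   1-row data.frames with `start`/`end` columns, assumed to lie on the
#'   same chromosome.
#' @return Fraction in `[0, 1]` of `a`'s bases covered by `b`. Zero when
#'   disjoint, one when `a` is contained in `b`; not symmetric in general.
#' @examples
#' overlap_fraction(c(0, 10), c(5, 15))  # 0.5
#' @export
overlap_fraction <- function(a, b) {
  a <- as_se(a); b <- as_se(b)
  ov <- min(a[2], b[2]) - max(a[1], b[1])
  if (ov <= 0) return(0)
  ov / (a[2] - a[1])
}

as_se <- function(x) {
  if (is.data.frame(x)) x <- c(x$start[1], x$end[1])
  x <- as.numeric(x)
  if (length(x) != 2L || !(x[1] < x[2])) stop("need a valid (start, end) pair")
  x
}
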