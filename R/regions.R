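## Candidate regions travel as data.frames with columns:
##   region_id, chrom, start, end, stage, parent_ids (list column),
##   read_count. Stages move forward only:
REGION_STAGES <- c("constructed", "covered", "merged", "dense_subregion",
                   "repeat_free", "annotated")

new_regions <- function(chrom, start, end, stage, region_id = NULL,
                        parent_ids = NULL, read_count = NA_integer_) {
  n <- length(start)
  if (is.null(region_id)) region_id <- sprintf("R%03d", seq_len(n))
  if (is.null(parent_ids)) parent_ids <- replicate(n, character(0),
                                                   simplify = FALSE)
  df <- data.frame(region_id = region_id,
                   chrom = rep_len(chrom, n),
                   start = as.integer(start), end = as.integer(end),
                   stage = rep_len(stage, n),
                   read_count = rep_len(as.integer(read_count), n),
                   stringsAsFactors = FALSE)
  df$parent_ids <- parent_ids
  validate_intervals(df, "region")
  df
}

advance_stage <- function(regions, stage) {
  stopifnot(stage %in% REGION_STAGES)
  if (nrow(regions)) {
    from <- match(regions$stage, REGION_STAGES)
    if (any(from > match(stage, REGION_STAGES)))
      stop("region stage transitions must move forward, not back to ", stage)
  }
  regions$stage <- rep_len(stage, nrow(regions))
  regions
}

#' Expand enhancer peaks into fixed-width candidate eRNA regions
#'
#' Each peak summit is expanded to `[summit - flank, summit + flank)` —
#' 6000 bp at the default flank of 3000 bp, the window width used for
#' enhancer-RNA regions around a ChIP-seq peak — then clipped to the locus.
#' Peaks supplied as intervals (columns `start`/`end`) use the midpoint,
#' rounded down, as the summit.
#'
#' @param peaks data.frame with either a `summit` column (bp) or
#'   `start`/`end` columns (0-based half-open interval); optional
#'   `source_label`.
#' @param flank Half-width of the candidate window in bp (default 3000).
#' @param locus A [locus_spec()].
#' @return Candidate-region data.frame at stage `"constructed"`, one row
#'   per usable peak. Peaks whose summit falls outside the locus are
#'   skipped with a warning, not an error.
#' @examples
#' loc <- locus_spec("chr14", 105000000, 107000000, "hg38")
#' build_candidate_regions(data.frame(summit = 105500000), 3000, loc)
#' @export
build_candidate_regions <- function(peaks, flank = 3000L, locus) {
  stopifnot(flank > 0)
  if (nrow(peaks) == 0L)
    return(new_regions(locus$chrom, integer(0), integer(0), "constructed"))
  summit <- if ("summit" %in% names(peaks)) {
    as.numeric(peaks$summit)
  } else {
    floor((as.numeric(peaks$start) + as.numeric(peaks$end)) / 2)
  }
  inside <- summit >= locus$start & summit < locus$end
  if (any(!inside))
    warning(sprintf("%d peak(s) with summit outside %s:%s-%s skipped",
                    sum(!inside), locus$chrom, locus$start, locus$end))
  summit <- summit[inside]
  start <- pmax(summit - flank, locus$start)
  end <- pmin(summit + flank, locus$end)
  regs <- new_regions(locus$chrom, start, end, "constructed")
  regs$parent_ids <- as.list(regs$region_id)
  regs
}

#' Merge overlapping candidate regions
#'
#' Combines overlapping (and, by default, bookended) regions into their
#' union hull, mirroring the screen step in which overlapping read-covered
#' regions are combined into one. Parent region identifiers are carried
#' through so the funnel can be traced back.
#'
#' @param regions Candidate-region data.frame (single chromosome).
#' @param merge_touching Combine regions that touch end-to-start without
#'   overlapping (default `TRUE`).
#' @return Merged regions at stage `"merged"`, pairwise disjoint and sorted
#'   by start; `parent_ids` lists the input `region_id`s of each hull and
#'   `read_count` sums the parents' counts (recomputed downstream when
#'   alignments are at hand).
#' @export
merge_regions <- function(regions, merge_touching = TRUE) {
  if (nrow(regions) == 0L) return(advance_stage(regions, "merged"))
  if (length(unique(regions$chrom)) > 1L) {
    off <- regions$region_id[regions$chrom != regions$chrom[1]][1]
    stop("merge_regions requires one chromosome; offending region: ", off)
  }
  ir <- intervals_to_iranges(regions)
  red <- IRanges::reduce(ir, min.gapwidth = if (merge_touching) 1L else 0L,
                         with.revmap = TRUE)
  out <- iranges_to_intervals(red, regions$chrom[1])
  revmap <- S4Vectors::mcols(red)$revmap
  parents <- lapply(seq_along(red), function(i)
    sort(unique(unlist(c(regions$parent_ids[revmap[[i]]],
                         regions$region_id[revmap[[i]]])))))
  counts <- vapply(seq_along(red), function(i) {
    v <- regions$read_count[revmap[[i]]]
    if (all(is.na(v))) NA_integer_ else as.integer(sum(v, na.rm = TRUE))
  }, integer(1))
  new_regions(out$chrom, out$start, out$end, "merged",
              region_id = sprintf("M%03d", seq_len(nrow(out))),
              parent_ids = parents, read_count = counts)
}
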