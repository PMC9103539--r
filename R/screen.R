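## The screening funnel: coverage construction, zero-read elimination,
## merging, dense sub-region delineation, repeat filtering, uniqueness
## verdict and lncRNA annotation, with a per-stage funnel report.

#' Dense sub-region parameters
#'
#' "Densely covered" is formalized as a run-bridging rule on per-base
#' depth: maximal runs with depth >= `min_cov`, in which below-threshold
#' runs no longer than `max_gap` bp are bridged, trimmed so both ends sit
#' at depth >= `min_cov`, and kept only at final length >= `min_len`.
#'
#' @param min_cov Minimum per-base read depth (default 5).
#' @param min_len Minimum sub-region length in bp (default 100).
#' @param max_gap Longest below-threshold run tolerated inside a
#'   sub-region, in bp (default 50, i.e. one read length).
#' @return A `dense_params` list.
#' @export
dense_params <- function(min_cov = 5L, min_len = 100L, max_gap = 50L) {
  stopifnot(min_cov >= 1L, min_len >= 1L, max_gap >= 0L)
  structure(list(min_cov = as.integer(min_cov), min_len = as.integer(min_len),
                 max_gap = as.integer(max_gap)), class = "dense_params")
}

#' Repeat-filter parameters
#'
#' @param max_overlap_frac Largest fraction of a sub-region allowed to
#'   overlap repeats of the filtered classes (default 0: any overlap with
#'   an interspersed repeat disqualifies the sub-region).
#' @param classes Repeat classes to filter on (default all four
#'   interspersed classes). Repeats of other classes never trigger
#'   filtering.
#' @return A `repeat_filter_params` list.
#' @export
repeat_filter_params <- function(max_overlap_frac = 0,
                                 classes = c("SINE", "LINE", "LTR", "DNA")) {
  stopifnot(max_overlap_frac >= 0, max_overlap_frac <= 1)
  structure(list(max_overlap_frac = max_overlap_frac,
                 classes = classes), class = "repeat_filter_params")
}

#' Per-base read coverage over the locus
#'
#' @param alignments Alignment data.frame ([align_all()] or [read_sam()]).
#' @param locus A [locus_spec()].
#' @return A `coverage_track`: integer depth vector of length
#'   `locus_length(locus)` (index 1 = locus base 0) plus the locus.
#'   `sum(depth)` equals the summed lengths of the contributing
#'   alignments. An alignment extending past the locus end is an error —
#'   the internal mapper cannot produce one.
#' @export
compute_coverage <- function(alignments, locus) {
  n <- locus_length(locus)
  if (nrow(alignments) == 0L) {
    depth <- integer(n)
  } else {
    if (any(alignments$pos < 0L | alignments$pos + alignments$read_len > n))
      stop("alignment extends outside the locus")
    ir <- IRanges::IRanges(start = alignments$pos + 1L,
                           width = alignments$read_len)
    depth <- as.integer(IRanges::coverage(ir, width = n))
  }
  structure(list(locus = locus, depth = depth), class = "coverage_track")
}

#' Eliminate candidate regions with zero aligned reads
#'
#' A region survives iff at least one alignment overlaps it by >= 1 bp
#' (region coordinates are locus-relative bp, alignments locus-relative
#' too). The overlapping-read count is recorded on each survivor.
#'
#' @param regions Candidate regions at stage `"constructed"`.
#' @param alignments Alignment data.frame.
#' @return Surviving regions at stage `"covered"`, `read_count` filled.
#' @export
drop_zero_read_regions <- function(regions, alignments) {
  if (nrow(regions) == 0L) return(advance_stage(regions, "covered"))
  counts <- integer(nrow(regions))
  if (nrow(alignments)) {
    ra <- IRanges::IRanges(start = alignments$pos + 1L,
                           width = alignments$read_len)
    hits <- IRanges::countOverlaps(intervals_to_iranges(regions), ra,
                                   minoverlap = 1L)
    counts <- as.integer(hits)
  }
  regions$read_count <- counts
  advance_stage(regions[counts > 0L, , drop = FALSE], "covered")
}

#' Delineate densely covered sub-regions within a candidate region
#'
#' Applies the (`min_cov`, `min_len`, `max_gap`) run-bridging rule of
#' [dense_params()] to the depth signal restricted to the region. The
#' returned sub-regions are disjoint, sorted, contained in the region, and
#' begin and end on bases at or above the depth threshold.
#'
#' @param track A `coverage_track` from [compute_coverage()].
#' @param region One-row candidate-region data.frame.
#' @param params A [dense_params()].
#' @return Sub-regions at stage `"dense_subregion"` (possibly zero rows);
#'   `parent_ids` names the enclosing region.
#' @export
detect_dense_subregions <- function(track, region, params = dense_params()) {
  loc <- track$locus
  if (region$start < loc$start || region$end > loc$end)
    stop("region lies outside the locus")
  i0 <- region$start - loc$start  # 0-based offset into depth
  seg <- track$depth[(i0 + 1):(region$end - loc$start)]
  above <- seg >= params$min_cov
  runs <- rle(above)
  if (length(runs$values) > 1L) {
    internal <- seq_along(runs$values) != 1L &
      seq_along(runs$values) != length(runs$values)
    bridge <- !runs$values & internal & runs$lengths <= params$max_gap
    runs$values[bridge] <- TRUE
    above <- inverse.rle(runs)
    runs <- rle(above)
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= params$min_len
  if (!any(keep))
    return(new_regions(region$chrom, integer(0), integer(0),
                       "dense_subregion"))
  sub <- new_regions(region$chrom,
                     region$start + starts[keep] - 1L,
                     region$start + ends[keep],
                     "dense_subregion",
                     region_id = sprintf("%s.d%d", region$region_id,
                                         seq_len(sum(keep))),
                     parent_ids = replicate(sum(keep),
                                            region$region_id,
                                            simplify = FALSE))
  sub
}

#' Remove sub-regions overlapping interspersed repeats
#'
#' A sub-region survives iff the fraction of its bases covered by the
#' union of repeats belonging to the filtered classes is at most
#' `max_overlap_frac` (0 by default: strict absence of repeats). Repeat
#' classes outside `params$classes` — including the `"other"` catch-all —
#' never disqualify anything.
#'
#' @param subregions Sub-regions at stage `"dense_subregion"`.
#' @param repeats data.frame with `chrom`, `start`, `end`, `repeat_class`
#'   (a BED name column parses into `repeat_class`; see [read_bed()]).
#' @param params A [repeat_filter_params()].
#' @return Surviving sub-regions at stage `"repeat_free"`, with the
#'   measured `repeat_overlap_frac` attached.
#' @export
filter_repeats <- function(subregions, repeats,
                           params = repeat_filter_params()) {
  if (nrow(subregions) == 0L)
    return(advance_stage(subregions, "repeat_free"))
  cls <- repeats[["repeat_class"]]
  if (is.null(cls)) cls <- repeats[["name"]]
  if (is.null(cls) && nrow(repeats) > 0L)
    stop("repeat records must carry a parsed repeat_class (or name) column")
  rep_use <- repeats[cls %in% params$classes, , drop = FALSE]
  frac <- numeric(nrow(subregions))
  if (nrow(rep_use)) {
    runion <- IRanges::reduce(intervals_to_iranges(rep_use))
    sir <- intervals_to_iranges(subregions)
    for (i in seq_len(nrow(subregions))) {
      ov <- IRanges::intersect(sir[i], runion)
      frac[i] <- sum(BiocGenerics::width(ov)) /
        (subregions$end[i] - subregions$start[i])
    }
  }
  out <- subregions[frac <= params$max_overlap_frac, , drop = FALSE]
  out$repeat_overlap_frac <- frac[frac <= params$max_overlap_frac]
  advance_stage(out, "repeat_free")
}

#' Uniqueness verdict on merged regions
#'
#' A merged region survives — i.e. retains reads aligned to unique,
#' repeat-free sequence — iff at least one of its dense sub-regions
#' survived the repeat filter.
#'
#' @param regions Merged regions.
#' @param surviving_subregions Output of [filter_repeats()] (sub-regions
#'   carry their parent region id).
#' @return The surviving subset of `regions` at stage `"repeat_free"`.
#' @export
region_uniqueness_verdict <- function(regions, surviving_subregions) {
  parents <- unique(unlist(surviving_subregions$parent_ids))
  advance_stage(regions[regions$region_id %in% parents, , drop = FALSE],
                "repeat_free")
}

#' Intersect surviving sub-regions with lncRNA annotation
#'
#' A match is >= 1 bp overlap between a sub-region and an annotated exon
#' (intron-only overlap does not count: exonic reads are the evidence for
#' a spliced eRNA). Unmatched survivors are reported as novel.
#'
#' @param subregions Surviving sub-regions (stage `"repeat_free"`).
#' @param transcripts List of transcript records
#'   ([read_gtf_transcripts()]).
#' @return data.frame with one row per sub-region: `region_id`,
#'   `parent_region`, `transcripts` (comma-joined matching transcript ids,
#'   `""` if none) and `annotated` flag.
#' @export
annotate_candidates <- function(subregions, transcripts) {
  if (nrow(subregions) == 0L)
    return(data.frame(region_id = character(0), parent_region = character(0),
                      transcripts = character(0), annotated = logical(0),
                      stringsAsFactors = FALSE))
  exons <- do.call(rbind, lapply(transcripts, function(tx) {
    cbind(tx$exons, transcript_id = tx$transcript_id,
          stringsAsFactors = FALSE)
  }))
  matches <- character(nrow(subregions))
  if (!is.null(exons) && nrow(exons)) {
    sir <- intervals_to_iranges(subregions)
    eir <- intervals_to_iranges(exons)
    hits <- IRanges::findOverlaps(sir, eir, minoverlap = 1L)
    for (i in seq_len(nrow(subregions))) {
      tx <- unique(exons$transcript_id[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]])
      matches[i] <- paste(sort(tx), collapse = ",")
    }
  }
  data.frame(region_id = subregions$region_id,
             parent_region = vapply(subregions$parent_ids, `[`, "", 1L),
             transcripts = matches,
             annotated = nzchar(matches),
             stringsAsFactors = FALSE)
}

#' Run the full eRNA screening funnel
#'
#' Executes the stages in order: construct candidate windows from peaks,
#' eliminate windows with zero aligned reads, merge overlapping covered
#' windows, delineate densely covered sub-regions, filter sub-regions
#' against interspersed repeats, apply the region-level uniqueness
#' verdict, and intersect the survivors with lncRNA annotation. The
#' funnel report records the surviving count and identifiers after every
#' stage (counts never increase).
#'
#' @param peaks Peak data.frame (see [build_candidate_regions()]).
#' @param locus A [locus_spec()].
#' @param locus_sequence Locus DNA string (needed when `reads` are given).
#' @param reads data.frame of reads to map internally, or `NULL` when
#'   `alignments` are supplied.
#' @param alignments Precomputed ungapped alignments ([read_sam()]),
#'   bypassing the internal mapper.
#' @param repeats Repeat annotation data.frame with `repeat_class`.
#' @param transcripts Transcript list ([read_gtf_transcripts()]).
#' @param flank Candidate half-width in bp (default 3000).
#' @param mapper A [mapper_config()].
#' @param dense A [dense_params()].
#' @param repeat_filter A [repeat_filter_params()].
#' @param merge_touching Passed to [merge_regions()].
#' @return A list of class `screen_result`: `funnel` (stage, count,
#'   region ids), `candidates` (annotation table for surviving
#'   sub-regions), `regions` (per-stage region tables), `coverage`,
#'   `alignments`.
#' @export
run_screen <- function(peaks, locus, locus_sequence = NULL, reads = NULL,
                       alignments = NULL, repeats, transcripts,
                       flank = 3000L, mapper = mapper_config(),
                       dense = dense_params(),
                       repeat_filter = repeat_filter_params(),
                       merge_touching = TRUE) {
  stage_err <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("screen stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }
  constructed <- stage_err("construct",
                           build_candidate_regions(peaks, flank, locus))
  if (is.null(alignments)) {
    if (is.null(reads) || is.null(locus_sequence))
      stop("screen stage 'align' failed: need reads + locus_sequence, or alignments")
    ridx <- prepare_locus_index(locus_sequence)
    alignments <- stage_err("align", align_all(reads, ridx, mapper))
  }
  ## alignments are locus-relative bp; regions are absolute bp. Shift.
  aln_abs <- alignments
  aln_abs$pos <- aln_abs$pos + locus$start

  covered <- stage_err("zero_read_drop",
                       drop_zero_read_regions(constructed, aln_abs))
  merged <- stage_err("merge", merge_regions(covered, merge_touching))
  ## recompute read counts on the merged hulls
  merged <- stage_err("merge", {
    m <- drop_zero_read_regions_counts(merged, aln_abs); m
  })
  track <- stage_err("coverage", compute_coverage(alignments, locus))
  subs <- if (nrow(merged) == 0L) {
    new_regions(locus$chrom, integer(0), integer(0), "dense_subregion")
  } else {
    stage_err("dense_subregions", do.call(rbind, c(
      lapply(seq_len(nrow(merged)), function(i)
        detect_dense_subregions(track, merged[i, , drop = FALSE], dense)),
      list(make.row.names = FALSE))))
  }
  with_dense <- merged[merged$region_id %in%
                         unlist(subs$parent_ids), , drop = FALSE]
  surv_subs <- stage_err("repeat_filter",
                         filter_repeats(subs, repeats, repeat_filter))
  unique_regions <- stage_err("uniqueness",
                              region_uniqueness_verdict(with_dense,
                                                        surv_subs))
  cand <- stage_err("annotate", annotate_candidates(surv_subs, transcripts))
  annotated_regions <- unique(cand$parent_region[cand$annotated])

  funnel <- data.frame(
    stage = c("constructed", "covered", "merged", "with_dense_subregion",
              "repeat_free", "annotated"),
    count = c(nrow(constructed), nrow(covered), nrow(merged),
              nrow(with_dense), nrow(unique_regions),
              length(annotated_regions)),
    stringsAsFactors = FALSE)
  funnel$region_ids <- list(constructed$region_id, covered$region_id,
                            merged$region_id, with_dense$region_id,
                            unique_regions$region_id, annotated_regions)
  structure(list(funnel = funnel, candidates = cand,
                 regions = list(constructed = constructed, covered = covered,
                                merged = merged, with_dense = with_dense,
                                subregions = subs,
                                surviving_subregions = surv_subs,
                                repeat_free = unique_regions),
                 coverage = track, alignments = alignments),
            class = "screen_result")
}

## read counts for already-merged hulls (no stage change)
drop_zero_read_regions_counts <- function(regions, alignments) {
  if (nrow(regions) == 0L || nrow(alignments) == 0L) return(regions)
  ra <- IRanges::IRanges(start = alignments$pos + 1L,
                         width = alignments$read_len)
  regions$read_count <- as.integer(
    IRanges::countOverlaps(intervals_to_iranges(regions), ra,
                           minoverlap = 1L))
  regions
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> funnel:\n")
  for (i in seq_len(nrow(x$funnel)))
    cat(sprintf("  %-22s %d\n", x$funnel$stage[i], x$funnel$count[i]))
  ann <- x$candidates[x$candidates$annotated, , drop = FALSE]
  if (nrow(ann))
    cat("annotated candidate(s):",
        paste(sprintf("%s (%s)", ann$region_id, ann$transcripts),
              collapse = ", "), "\n")
  invisible(x)
}
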