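## Independent oracles: deliberately naive per-base / brute-force
## implementations, kept free of the package's code paths.

## all placements of a read with Hamming distance <= k, by scanning every
## offset of both strands
oracle_hamming_hits <- function(read_seq, locus_seq, k,
                                both_strands = TRUE) {
  lc <- strsplit(toupper(locus_seq), "")[[1]]
  lvalid <- lc %in% c("A", "C", "G", "T")
  scan <- function(q, strand) {
    qc <- strsplit(q, "")[[1]]
    qvalid <- qc %in% c("A", "C", "G", "T")
    L <- length(qc)
    n <- length(lc)
    if (L > n) return(NULL)
    hits <- list()
    for (p in seq_len(n - L + 1L)) {
      seg <- lc[p:(p + L - 1L)]
      mm <- sum(seg != qc | !lvalid[p:(p + L - 1L)] | !qvalid)
      if (mm <= k)
        hits[[length(hits) + 1L]] <- data.frame(
          pos = p - 1L, strand = strand, mismatches = mm)
    }
    do.call(rbind, hits)
  }
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  out <- scan(toupper(read_seq), "+")
  if (both_strands) out <- rbind(out, scan(rc(toupper(read_seq)), "-"))
  if (is.null(out)) return(data.frame(pos = integer(0),
                                      strand = character(0),
                                      mismatches = integer(0)))
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## same exhaustive scan, vectorized over offsets (shift-and-compare sums)
## for ACGT-only reads and loci; used where many reads are checked
oracle_hamming_hits_fast <- function(read_seq, locus_chars, k,
                                     both_strands = TRUE) {
  n <- length(locus_chars)
  scan <- function(q, strand) {
    qc <- strsplit(q, "")[[1]]
    L <- length(qc)
    if (L > n) return(NULL)
    mm <- integer(n - L + 1L)
    for (j in seq_len(L))
      mm <- mm + (locus_chars[j:(n - L + j)] != qc[j])
    hit <- which(mm <= k)
    if (!length(hit)) return(NULL)
    data.frame(pos = hit - 1L, strand = strand, mismatches = mm[hit])
  }
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  out <- scan(toupper(read_seq), "+")
  if (both_strands) out <- rbind(out, scan(rc(toupper(read_seq)), "-"))
  if (is.null(out)) return(data.frame(pos = integer(0),
                                      strand = character(0),
                                      mismatches = integer(0)))
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## interval Jaccard |a intersect b| / |a union b|
jaccard_interval <- function(a_start, a_end, b_start, b_end) {
  inter <- max(0, min(a_end, b_end) - max(a_start, b_start))
  union <- (a_end - a_start) + (b_end - b_start) - inter
  inter / union
}

## union of intervals via a boolean per-base occupancy array
oracle_merge <- function(starts, ends, universe_len) {
  occ <- logical(universe_len)
  for (i in seq_along(starts)) occ[(starts[i] + 1L):ends[i]] <- TRUE
  r <- rle(occ)
  cum <- cumsum(r$lengths)
  st <- cum - r$lengths
  data.frame(start = st[r$values], end = cum[r$values])
}

## fraction of [a1,a2) covered by [b1,b2), by counting bases
oracle_overlap_fraction <- function(a, b) {
  abases <- seq.int(a[1], a[2] - 1L)
  mean(abases >= b[1] & abases < b[2])
}

## dense sub-regions by clustering above-threshold positions: positions
## with depth >= c, split where the below-threshold gap exceeds g, kept
## at span >= L (spans start/end on above-threshold bases by construction)
oracle_dense <- function(depth, c, L, g) {
  pos <- which(depth >= c)
  if (!length(pos)) return(data.frame(start = integer(0), end = integer(0)))
  brk <- which(diff(pos) - 1L > g)
  grp <- cumsum(c(0L, seq_along(pos)[-1] %in% (brk + 1L)))
  out <- do.call(rbind, lapply(split(pos, grp), function(p)
    data.frame(start = min(p) - 1L, end = max(p))))
  out <- out[out$end - out$start >= L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## per-base fraction of [s,e) covered by class-filtered repeats
oracle_repeat_frac <- function(s, e, rep_start, rep_end, rep_class,
                               classes) {
  bases <- seq.int(s, e - 1L)
  covered <- rep(FALSE, length(bases))
  for (i in seq_along(rep_start)) {
    if (!(rep_class[i] %in% classes)) next
    covered <- covered | (bases >= rep_start[i] & bases < rep_end[i])
  }
  mean(covered)
}

## expected screening funnel recomputed from generator ground truth alone:
## windows covered by true read origins, per-base coverage from origins,
## dense spans by the naive clustering rule, repeat fractions per base,
## annotation by exon overlap
oracle_funnel_from_truth <- function(truth, origins,
                                     c = 5L, L = 100L, g = 50L,
                                     classes = c("SINE", "LINE", "LTR",
                                                 "DNA"),
                                     max_frac = 0) {
  cfg <- truth$config
  windows <- do.call(rbind, lapply(truth$groups, function(gr) gr$windows))
  constructed <- nrow(windows)
  covered_w <- vapply(seq_len(nrow(windows)), function(i)
    any(origins$start < windows$end[i] & origins$end > windows$start[i]),
    logical(1))
  covered <- sum(covered_w)
  merged <- oracle_merge(windows$start[covered_w], windows$end[covered_w],
                         cfg$locus_length)
  depth <- integer(cfg$locus_length)
  for (i in seq_len(nrow(origins))) {
    span <- (origins$start[i] + 1L):origins$end[i]
    depth[span] <- depth[span] + 1L
  }
  reps <- truth$repeats
  n_dense <- 0L; n_unique <- 0L; n_annot <- 0L
  exons <- if (length(truth$transcripts))
    truth$transcripts[[1]]$exons else NULL
  for (m in seq_len(nrow(merged))) {
    seg <- depth[(merged$start[m] + 1L):merged$end[m]]
    dense <- oracle_dense(seg, c, L, g)
    if (!nrow(dense)) next
    n_dense <- n_dense + 1L
    dense$start <- dense$start + merged$start[m]
    dense$end <- dense$end + merged$start[m]
    surv <- vapply(seq_len(nrow(dense)), function(i)
      oracle_repeat_frac(dense$start[i], dense$end[i], reps$start,
                         reps$end, reps$repeat_class,
                         classes) <= max_frac, logical(1))
    if (!any(surv)) next
    n_unique <- n_unique + 1L
    if (!is.null(exons)) {
      ds <- dense[surv, , drop = FALSE]
      hit <- any(vapply(seq_len(nrow(ds)), function(i)
        any(exons$start < ds$end[i] & exons$end > ds$start[i]),
        logical(1)))
      if (hit) n_annot <- n_annot + 1L
    }
  }
  c(constructed = constructed, covered = covered, merged = nrow(merged),
    with_dense_subregion = n_dense, repeat_free = n_unique,
    annotated = n_annot)
}

## exact signed-rank p by looping over all sign bitmasks
oracle_wilcoxon_signed_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  count <- 0L
  for (mask in 0:(2^n - 1L)) {
    bits <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0
    if (abs(sum(r[bits]) - mu) >= abs(W - mu) - 1e-9) count <- count + 1L
  }
  count / 2^n
}

## exact rank-sum p by looping over all group assignments
oracle_wilcoxon_ranksum_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  sets <- utils::combn(n, n1)
  count <- 0L
  for (j in seq_len(ncol(sets))) {
    if (abs(sum(r[sets[, j]]) - mu) >= abs(W - mu) - 1e-9)
      count <- count + 1L
  }
  count / ncol(sets)
}

## naive tie-aware Spearman rho: Pearson formula on midranks computed by
## counting
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) vapply(v, function(vi)
    sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## exact permutation p for Spearman by recursive enumeration
oracle_spearman_perm_p <- function(x, y) {
  rho_obs <- abs(oracle_spearman_rho(x, y))
  n <- length(y)
  count <- 0L; total <- 0L
  recurse <- function(remaining, chosen) {
    if (!length(remaining)) {
      total <<- total + 1L
      if (abs(oracle_spearman_rho(x, y[chosen])) >= rho_obs - 1e-12)
        count <<- count + 1L
      return(invisible())
    }
    for (i in seq_along(remaining))
      recurse(remaining[-i], c(chosen, remaining[i]))
  }
  recurse(seq_len(n), integer(0))
  count / total
}

empty_alignments_for_test <- function() {
  data.frame(read_id = character(0), pos = integer(0),
             strand = character(0), mismatches = integer(0),
             read_len = integer(0), is_multi = logical(0),
             stringsAsFactors = FALSE)
}

## region table in the package's candidate-region shape, from bare intervals
new_regions_for_test <- function(iv, loc, stage = "covered") {
  df <- data.frame(region_id = sprintf("T%03d", seq_len(nrow(iv))),
                   chrom = loc$chrom, start = iv$start, end = iv$end,
                   stage = stage, read_count = NA_integer_,
                   stringsAsFactors = FALSE)
  df$parent_ids <- as.list(df$region_id)
  df
}

## random non-degenerate interval set on [0, universe)
random_intervals <- function(n, universe = 1000L) {
  s <- sample.int(universe - 2L, n, replace = TRUE) - 1L
  w <- sample.int(50L, n, replace = TRUE)
  data.frame(start = s, end = pmin(s + w, universe))
}

## shared small fixture: seeded default simulation (built once per run)
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42L)
      sim <- simulate_locus(cfg)
      rd <- simulate_reads(sim$sequence, sim$truth, cfg)
      cache <<- list(cfg = cfg, sim = sim, rd = rd)
    }
    cache
  }
})
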