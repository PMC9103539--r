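make_aln <- function(pos, read_len = 10L) {
  data.frame(read_id = sprintf("r%03d", seq_along(pos)), pos = as.integer(pos),
             strand = "+", mismatches = 0L,
             read_len = as.integer(rep_len(read_len, length(pos))),
             is_multi = FALSE, stringsAsFactors = FALSE)
}

test_that("coverage is exact per base and conserves aligned bases", {
  loc <- locus_spec("chrT", 0, 100)
  t1 <- compute_coverage(make_aln(0), loc)
  expect_equal(t1$depth[1:10], rep(1L, 10))
  expect_equal(sum(t1$depth), 10L)
  t2 <- compute_coverage(make_aln(c(5, 5)), loc)
  expect_equal(t2$depth[6:15], rep(2L, 10))
  expect_equal(sum(t2$depth), 20L)
  withr::with_seed(51, {
    for (rep in 1:5) {
      pos <- sample(0:90, 100, replace = TRUE)
      trk <- compute_coverage(make_aln(pos), loc)
      expect_equal(sum(trk$depth), 100L * 10L)  # conservation
    }
  })
  expect_error(compute_coverage(make_aln(95), loc), "outside")
})

test_that("zero-read elimination keeps exactly the overlapped regions", {
  loc <- locus_spec("chrT", 0, 1000)
  regs <- new_regions_for_test(
    data.frame(start = c(0, 100, 200), end = c(50, 150, 250)), loc,
    stage = "constructed")
  # single-base overlap retains; none removes
  aln <- make_aln(c(49, 300))  # read 49-59 clips region1 by 1 base
  out <- drop_zero_read_regions(regs, aln)
  expect_equal(out$region_id, "T001")
  expect_equal(out$read_count, 1L)
  expect_equal(out$stage, "covered")

  withr::with_seed(52, {
    for (rep in 1:10) {
      iv <- random_intervals(20)
      regs <- new_regions_for_test(iv, loc, stage = "constructed")
      pos <- sample(0:990, 30, replace = TRUE)
      aln <- make_aln(pos)
      out <- drop_zero_read_regions(regs, aln)
      brute <- vapply(seq_len(nrow(iv)), function(i)
        sum(pos < iv$end[i] & pos + 10 > iv$start[i]), integer(1))
      expect_equal(out$region_id, regs$region_id[brute > 0])
      expect_equal(out$read_count, brute[brute > 0])
    }
  })
})

test_that("dense sub-region delineation follows the (c, L, g) bridging rule", {
  loc <- locus_spec("chrT", 0, 1000)
  mk_track <- function(depth) {
    structure(list(locus = loc,
                   depth = c(depth, integer(1000 - length(depth)))),
              class = "coverage_track")
  }
  reg <- new_regions_for_test(data.frame(start = 0, end = 250), loc,
                              stage = "merged")

  # constant depth c over 200 bp -> the full run
  sub <- detect_dense_subregions(mk_track(rep(5L, 200)), reg[1, ],
                                 dense_params(5, 100, 0))
  expect_equal(sub$start, 0L)
  expect_equal(sub$end, 200L)

  # [c x 120, 0 x 10, c x 120]: bridged at g = 50, split at g = 5
  depth <- c(rep(5L, 120), rep(0L, 10), rep(5L, 120))
  b1 <- detect_dense_subregions(mk_track(depth), reg[1, ],
                                dense_params(5, 100, 50))
  expect_equal(b1$start, 0L)
  expect_equal(b1$end, 250L)
  b2 <- detect_dense_subregions(mk_track(depth), reg[1, ],
                                dense_params(5, 100, 5))
  expect_equal(b2$start, c(0L, 130L))
  expect_equal(b2$end, c(120L, 250L))

  # all-zero depth -> nothing
  expect_equal(nrow(detect_dense_subregions(mk_track(integer(200)),
                                            reg[1, ], dense_params())), 0L)

  # ends always sit at depth >= c (trimming), random vs oracle
  withr::with_seed(53, {
    for (rep in 1:10) {
      depth <- as.integer(rpois(400, 4))
      reg4 <- new_regions_for_test(data.frame(start = 0, end = 400), loc,
                                   stage = "merged")
      prm <- dense_params(5, 20, 8)
      sub <- detect_dense_subregions(mk_track(depth), reg4[1, ], prm)
      o <- oracle_dense(depth, 5L, 20L, 8L)
      expect_equal(sub$start, o$start)
      expect_equal(sub$end, o$end)
      if (nrow(sub)) {
        expect_true(all(depth[sub$start + 1L] >= 5))
        expect_true(all(depth[sub$end] >= 5))
      }
    }
  })
})

test_that("repeat filtering follows class policy and the overlap fraction", {
  loc <- locus_spec("chrT", 0, 1000)
  subs <- new_regions_for_test(
    data.frame(start = c(100, 300, 500), end = c(200, 400, 600)), loc,
    stage = "dense_subregion")
  reps <- data.frame(chrom = "chrT",
                     start = c(90, 350), end = c(210, 360),
                     repeat_class = c("SINE", "other"),
                     stringsAsFactors = FALSE)
  out <- filter_repeats(subs, reps, repeat_filter_params(0))
  # sub1 inside a SINE -> removed; sub2 overlaps only "other" -> kept
  expect_equal(out$region_id, c("T002", "T003"))
  expect_equal(out$stage, c("repeat_free", "repeat_free"))

  withr::with_seed(54, {
    for (rep in 1:5) {
      iv <- random_intervals(15)
      subs <- new_regions_for_test(iv, loc, stage = "dense_subregion")
      nrep <- 10
      rp <- random_intervals(nrep)
      reps <- data.frame(chrom = "chrT", start = rp$start, end = rp$end,
                         repeat_class = sample(c("SINE", "LINE", "LTR",
                                                 "DNA", "other"),
                                               nrep, TRUE),
                         stringsAsFactors = FALSE)
      fr <- vapply(seq_len(nrow(iv)), function(i)
        oracle_repeat_frac(iv$start[i], iv$end[i], reps$start, reps$end,
                           reps$repeat_class,
                           c("SINE", "LINE", "LTR", "DNA")), numeric(1))
      prev <- -1L
      for (mx in c(0, 0.25, 0.5, 1)) {
        out <- filter_repeats(subs, reps, repeat_filter_params(mx))
        expect_equal(out$region_id, subs$region_id[fr <= mx])
        expect_gte(nrow(out), prev)  # monotone in max_overlap_frac
        prev <- nrow(out)
      }
    }
  })
})

test_that("uniqueness verdict keeps regions with a surviving sub-region", {
  loc <- locus_spec("chrT", 0, 1000)
  regions <- new_regions_for_test(
    data.frame(start = c(0, 500), end = c(400, 900)), loc, stage = "merged")
  subs <- new_regions_for_test(
    data.frame(start = c(10, 600), end = c(200, 700)), loc,
    stage = "repeat_free")
  subs$parent_ids <- list("T001", "T002")
  expect_equal(region_uniqueness_verdict(regions, subs)$region_id,
               c("T001", "T002"))
  # region whose only sub-region was masked drops out
  expect_equal(region_uniqueness_verdict(regions,
                                         subs[2, , drop = FALSE])$region_id,
               "T002")
})

test_that("annotation requires exon overlap, not transcript-span overlap", {
  loc <- locus_spec("chrT", 0, 10000)
  subs <- new_regions_for_test(
    data.frame(start = c(1000, 2500), end = c(1100, 2600)), loc,
    stage = "repeat_free")
  tx <- list(list(transcript_id = "tx1", gene_name = "G", biotype = "lncRNA",
                  exons = data.frame(chrom = "chrT",
                                     start = c(900, 3000),
                                     end = c(1200, 3200))))
  ann <- annotate_candidates(subs, tx)
  expect_true(ann$annotated[1])           # inside exon 1
  expect_equal(ann$transcripts[1], "tx1")
  expect_false(ann$annotated[2])          # intronic only -> novel
})

test_that("the full screen handles degenerate inputs and read shuffling", {
  fx <- default_fixture()
  # no reads: funnel collapses to zero after the zero-read stage
  res0 <- run_screen(fx$sim$peaks, fx$sim$locus,
                     locus_sequence = fx$sim$sequence[[1]],
                     alignments = empty_alignments_for_test(),
                     repeats = fx$sim$repeats,
                     transcripts = fx$sim$transcripts)
  expect_equal(res0$funnel$count, c(12L, 0L, 0L, 0L, 0L, 0L))

  # repeats covering the whole locus remove every sub-region
  all_rep <- data.frame(chrom = fx$sim$locus$chrom, start = 0,
                        end = locus_length(fx$sim$locus),
                        repeat_class = "LINE", stringsAsFactors = FALSE)
  res1 <- run_screen(fx$sim$peaks, fx$sim$locus,
                     locus_sequence = fx$sim$sequence[[1]],
                     reads = fx$rd$reads, repeats = all_rep,
                     transcripts = fx$sim$transcripts)
  expect_equal(res1$funnel$count[5:6], c(0L, 0L))

  # shuffling read order leaves funnel and candidate set unchanged
  withr::with_seed(55, {
    shuffled <- fx$rd$reads[sample(nrow(fx$rd$reads)), , drop = FALSE]
  })
  res2 <- run_screen(fx$sim$peaks, fx$sim$locus,
                     locus_sequence = fx$sim$sequence[[1]],
                     reads = shuffled, repeats = fx$sim$repeats,
                     transcripts = fx$sim$transcripts)
  res_ref <- run_screen(fx$sim$peaks, fx$sim$locus,
                        locus_sequence = fx$sim$sequence[[1]],
                        reads = fx$rd$reads, repeats = fx$sim$repeats,
                        transcripts = fx$sim$transcripts)
  expect_equal(res2$funnel$count, res_ref$funnel$count)
  expect_equal(sort(res2$candidates$region_id),
               sort(res_ref$candidates$region_id))
})
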