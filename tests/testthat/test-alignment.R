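test_that("worked examples: exact and one-mismatch placements", {
  cfg <- mapper_config(max_mismatch = 1, search_both_strands = FALSE)
  a <- align_read(list(read_id = "r", sequence = "GTAC"), "ACGTACGTAC", cfg)
  expect_equal(a$pos, c(2L, 6L))
  expect_equal(a$mismatches, c(0L, 0L))
  expect_true(all(a$is_multi))

  b <- align_read(list(read_id = "r", sequence = "GTCC"), "ACGTACGTAC", cfg)
  expect_equal(b$pos, c(2L, 6L))
  expect_equal(b$mismatches, c(1L, 1L))

  # best_only keeps only minimum-mismatch placements
  c0 <- align_read(list(read_id = "r", sequence = "GTAC"), "ACGTACGTCC",
                   mapper_config(1, "best_only", FALSE))
  expect_equal(c0$pos, 2L)
  expect_equal(c0$mismatches, 0L)
})

test_that("pigeonhole mapper equals the exhaustive Hamming oracle", {
  withr::with_seed(31, {
    locus <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE),
                   collapse = "")
    n_reads <- 60
    reads <- data.frame(
      read_id = sprintf("r%03d", seq_len(n_reads)),
      sequence = vapply(seq_len(n_reads), function(i) {
        if (i <= 40) {  # planted with 0-2 substitutions
          p <- sample(10000 - 36, 1)
          s <- strsplit(substr(locus, p + 1, p + 36), "")[[1]]
          for (j in sample(36, sample(0:2, 1)))
            s[j] <- sample(setdiff(c("A", "C", "G", "T"), s[j]), 1)
          if (runif(1) < 0.5)
            s <- rev(chartr("ACGT", "TGCA", s))
          paste(s, collapse = "")
        } else {
          paste(sample(c("A", "C", "G", "T"), 36, TRUE), collapse = "")
        }
      }, ""), stringsAsFactors = FALSE)
    for (k in 0:1) {
      cfg <- mapper_config(max_mismatch = k)
      got <- align_all(reads, locus, cfg)
      want <- do.call(rbind, lapply(seq_len(n_reads), function(i) {
        h <- oracle_hamming_hits(reads$sequence[i], locus, k)
        if (nrow(h)) cbind(read_id = reads$read_id[i], h)
      }))
      expect_equal(got[c("read_id", "pos", "strand", "mismatches")],
                   want[c("read_id", "pos", "strand", "mismatches")],
                   ignore_attr = TRUE)
    }
  })
})

test_that("hit set at k = 0 is a subset of the hit set at k = 1", {
  withr::with_seed(32, {
    locus <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    reads <- data.frame(read_id = sprintf("r%d", 1:20),
                        sequence = vapply(1:20, function(i) {
                          p <- sample(1970, 1)
                          substr(locus, p, p + 19)
                        }, ""))
    a0 <- align_all(reads, locus, mapper_config(max_mismatch = 0))
    a1 <- align_all(reads, locus, mapper_config(max_mismatch = 1))
    key <- function(df) paste(df$read_id, df$pos, df$strand)
    expect_true(all(key(a0) %in% key(a1)))
  })
})

test_that("reverse-complement symmetry mirrors strands", {
  withr::with_seed(33, {
    locus <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
    p <- sample(2950, 1)
    fwd <- substr(locus, p + 1, p + 30)
    a_f <- align_read(list(read_id = "f", sequence = fwd), locus,
                      mapper_config())
    a_r <- align_read(list(read_id = "r", sequence = revcomp(fwd)), locus,
                      mapper_config())
    expect_equal(a_f$pos, a_r$pos)
    expect_equal(sort(a_f$strand), sort(chartr("+-", "-+", a_r$strand)))
  })
})

test_that("batch alignment equals the per-read path, including N reads", {
  withr::with_seed(34, {
    locus <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
    reads <- data.frame(read_id = sprintf("r%d", 1:15),
                        sequence = vapply(1:15, function(i) {
                          p <- sample(2960, 1)
                          s <- substr(locus, p, p + 29)
                          if (i %% 5 == 0) substr(s, 3, 3) <- "N"
                          s
                        }, ""), stringsAsFactors = FALSE)
    cfg <- mapper_config()
    batch <- align_all(reads, locus, cfg)
    single <- do.call(rbind, lapply(seq_len(nrow(reads)), function(i)
      align_read(reads[i, ], locus, cfg)))
    rownames(single) <- NULL
    expect_identical(batch, single)
    # an N counts as a mismatch at its own position
    n_reads <- batch[grepl("N", reads$sequence[match(batch$read_id,
                                                     reads$read_id)]), ]
    expect_true(all(n_reads$mismatches >= 1L))
  })
})

test_that("degenerate reads warn and are skipped, never abort the batch", {
  locus <- "ACGTACGTACGTACGT"
  expect_warning(
    a <- align_read(list(read_id = "tiny", sequence = "ACG"), locus,
                    mapper_config(max_mismatch = 1)),
    "rejected")
  expect_equal(nrow(a), 0L)
  expect_error(align_read(list(read_id = "none", sequence = ""), locus),
               "empty")
  reads <- data.frame(read_id = c("good", "bad", "weird"),
                      sequence = c("ACGTACGT", "", "ACGTXCGT"),
                      stringsAsFactors = FALSE)
  warns <- testthat::capture_warnings(out <- align_all(reads, locus))
  expect_match(warns, "empty sequence", all = FALSE)
  expect_match(warns, "non-ACGTN", all = FALSE)
  expect_true("good" %in% out$read_id)
  expect_false(any(c("bad", "weird") %in% out$read_id))
})
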