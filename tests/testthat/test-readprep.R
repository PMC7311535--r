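mk_pairs <- function(seq1, seq2, qual1 = NULL, qual2 = NULL) {
  data.frame(
    id = sprintf("r%03d", seq_along(seq1)),
    seq1 = seq1, seq2 = seq2,
    qual1 = if (is.null(qual1)) strrep("I", nchar(seq1)) else qual1,
    qual2 = if (is.null(qual2)) strrep("I", nchar(seq2)) else qual2,
    stringsAsFactors = FALSE
  )
}

test_that("clone filter keys on both UMIs plus both remaining sequences", {
  layout <- read_layout()
  # byte-identical pairs collapse to one
  p <- mk_pairs(rep("ACGTTGCAGAAACCC", 2), rep("TTTTAATTCGGGAAA", 2))
  res <- clone_filter(p, layout)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$n_duplicates, 1L)
  expect_equal(res$pairs$umi1, "ACGT")
  expect_equal(res$pairs$seq1, "TGCAGAAACCC")  # UMI trimmed

  # same insert, different UMI at either end: both retained
  p <- mk_pairs(c("ACGTTGCAGAAACCC", "GGGGTGCAGAAACCC"),
                c("TTTTAATTCGGGAAA", "TTTTAATTCGGGAAA"))
  expect_equal(clone_filter(p, layout)$n_duplicates, 0L)
  p <- mk_pairs(rep("ACGTTGCAGAAACCC", 2),
                c("TTTTAATTCGGGAAA", "CCCCAATTCGGGAAA"))
  expect_equal(clone_filter(p, layout)$n_duplicates, 0L)

  # empty input, idempotence, and count conservation
  empty <- clone_filter(p[0, ], layout)
  expect_equal(nrow(empty$pairs), 0L)
  expect_equal(empty$n_duplicates, 0L)
  big <- mk_pairs(rep(c("ACGTTGCAGAAACCC", "ACCTTGCAGAAACCC"), 4),
                  rep("TTTTAATTCGGGAAA", 8))
  r1 <- clone_filter(big, layout)
  expect_equal(nrow(r1$pairs) + r1$n_duplicates + nrow(r1$discarded), 8L)
  # idempotence: a second pass over the retained molecules removes nothing
  again <- r1$pairs
  again$seq1 <- paste0(again$umi1, again$seq1)
  again$seq2 <- paste0(again$umi2, again$seq2)
  again$qual1 <- strrep("I", nchar(again$seq1))
  again$qual2 <- strrep("I", nchar(again$seq2))
  r2 <- clone_filter(again[, c("id", "seq1", "seq2", "qual1", "qual2")], layout)
  expect_equal(r2$n_duplicates, 0L)

  # reads shorter than the UMI are discarded with a reason
  short <- mk_pairs("AC", "TTTTAATTCGGG")
  rs <- clone_filter(short, layout)
  expect_equal(nrow(rs$pairs), 0L)
  expect_equal(rs$discarded$reason, "shorter_than_umi")
})

test_that("demultiplexing assigns within the mismatch radius and partitions input", {
  layout <- read_layout()
  map <- data.frame(sample = c("S1", "S2"),
                    bc1 = c("AAACCC", "GGGTTT"),
                    bc2 = c("ACACAC", "GTGTGT"))
  insert <- "TGCAGAAAACCCGGG"
  p <- mk_pairs(
    c(paste0("AAACCC", insert),   # exact S1
      paste0("AAACCG", insert),   # 1 mismatch from S1
      paste0("AAGCGC", insert),   # 3 mismatches: unassigned
      paste0("GGGTTT", insert)),  # exact S2
    c(paste0("ACACAC", insert), paste0("ACACAC", insert),
      paste0("ACACAC", insert), paste0("GTGTGT", insert))
  )
  res <- demultiplex(p, map, layout, max_mismatch = 1)
  expect_equal(res$pairs$sample, c("S1", "S1", NA, "S2"))
  expect_equal(res$pairs$seq1[1], insert)  # barcode trimmed
  expect_equal(sum(res$summary[c("assigned", "unassigned")]),
               unname(res$summary["input"]))

  # at mismatch 0 the near-miss read is unassigned
  res0 <- demultiplex(p, map, layout, max_mismatch = 0)
  expect_equal(res0$pairs$sample, c("S1", NA, NA, "S2"))

  # barcode maps closer than 2*max_mismatch+1 are a configuration error
  close_map <- data.frame(sample = c("S1", "S2"),
                          bc1 = c("AAACCC", "AAACCG"),
                          bc2 = c("ACACAC", "GTGTGT"))
  expect_error(demultiplex(p, close_map, layout, max_mismatch = 1),
               "ambiguous")
  expect_silent(demultiplex(p, close_map, layout, max_mismatch = 0))
})

test_that("RAD-tag verification is IUPAC-aware and accepts mirrored orientation", {
  layout <- read_layout()  # TGCAG / AATTY
  ok <- mk_pairs("TGCAGAAAA", "AATTCGGGG")      # AATTC matches AATTY
  expect_equal(radtag_check(ok, layout)$n_rejected, 0L)
  ok2 <- mk_pairs("TGCAGAAAA", "AATTTGGGG")     # AATTT matches AATTY too
  expect_equal(radtag_check(ok2, layout)$n_rejected, 0L)

  both_pst <- mk_pairs("TGCAGAAAA", "TGCAGGGGG")
  expect_equal(radtag_check(both_pst, layout)$n_rejected, 1L)

  mirrored <- mk_pairs("AATTCAAAA", "TGCAGGGGG")
  expect_equal(radtag_check(mirrored, layout)$n_rejected, 0L)
  expect_equal(radtag_check(mirrored, layout,
                            allow_mirror = FALSE)$n_rejected, 1L)

  # tags stay on the read: they are genomic sequence
  expect_equal(radtag_check(ok, layout)$pairs$seq1, "TGCAGAAAA")
})

test_that("quality filter drops pairs with a low mean-quality window", {
  q40 <- strrep("I", 40)
  p <- mk_pairs("ACGT", "ACGT", strrep("I", 4), strrep("I", 4))
  expect_equal(quality_filter(p)$n_rejected, 0L)

  # contiguous Q2 (#) stretch longer than the window fails; oracle: all
  # windows brute force
  bad_qual <- paste0(strrep("I", 10), strrep("#", 12), strrep("I", 18))
  scores <- as.integer(charToRaw(bad_qual)) - 33L
  w <- floor(0.15 * 40)
  worst <- min(vapply(seq_len(40 - w + 1), function(i)
    mean(scores[i:(i + w - 1)]), numeric(1)))
  expect_lt(worst, 10)
  p <- mk_pairs(strrep("A", 40), strrep("A", 40), bad_qual, q40)
  expect_equal(quality_filter(p)$n_rejected, 1L)
  # either mate can fail the pair
  p2 <- mk_pairs(strrep("A", 40), strrep("A", 40), q40, bad_qual)
  expect_equal(quality_filter(p2)$n_rejected, 1L)

  # threshold 0 passes everything
  expect_equal(quality_filter(p, phred_threshold = 0)$n_rejected, 0L)
})

test_that("simulated reads round-trip exactly through the pipeline", {
  pos <- seq(300, 11500, by = 800)
  plan <- data.frame(enzyme = rep(c("PstI", "ApoI"), length.out = length(pos)),
                     pos = pos)
  gen <- make_genome(12000, sites = plan, seed = 130)
  frags <- gen$fragments[gen$fragments$length >= 200, ]
  map <- data.frame(sample = c("S1", "S2"),
                    bc1 = c("AAACCC", "GGGTTT"),
                    bc2 = c("ACACAC", "GTGTGT"))
  sim <- simulate_reads(frags, gen$genome, map, n_pairs = 400,
                        duplication_rate = 0.5, read_length = 80, seed = 131)
  truth_dups <- sum(sim$truth$duplicate)
  expect_gt(truth_dups, 0)

  res <- readprep_pipeline(sim$pairs, map, max_mismatch = 0)
  expect_equal(unname(res$summary["duplicates"]), truth_dups)
  expect_equal(unname(res$summary["unassigned"]), 0L)
  expect_equal(unname(res$summary["tag_failed"]), 0L)
  expect_equal(unname(res$summary["quality_failed"]), 0L)
  expect_equal(nrow(res$pairs), 400L)

  # 100% assignment accuracy vs truth at mismatch 0 with error-free reads
  truth <- sim$truth[match(res$pairs$id, sim$truth$id), ]
  expect_equal(res$pairs$sample, truth$sample)

  # duplication_rate 0 removes nothing
  sim0 <- simulate_reads(frags, gen$genome, map, n_pairs = 100,
                         duplication_rate = 0, read_length = 80, seed = 132)
  expect_equal(clone_filter(sim0$pairs)$n_duplicates, 0L)
})

test_that("paired FASTQ files round-trip through Phred+33 encoding", {
  p <- mk_pairs(c("ACGTACGTAA", "TTTTGGGGCC"), c("GGGGCCCCAA", "AAAATTTTGG"))
  p$qual1 <- c("IIIIIIIIII", "IIII#IIIII")
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_pairs(p, r1, r2)
  back <- read_fastq_pairs(r1, r2)
  expect_equal(back, p)
})
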