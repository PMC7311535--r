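#' Read preprocessing for UMI + inner-barcode libraries
#'
#' Each mate of a read pair carries, in order: a random UMI, a sample
#' (inner) barcode, the residual restriction-site tag left by the cut, and
#' genomic insert. Preprocessing removes PCR clones by UMI + sequence
#' identity, demultiplexes on the inner barcode pair, verifies the residual
#' tags, and drops low-quality pairs — in that order, all pre-alignment.
#'
#' @name readprep
NULL

#' Describe the read layout
#'
#' Defaults match a PstI/ApoI double-digest library: 4 bp UMIs on both
#' mates, 6 bp inner barcodes, and residual tags `TGCAG` (what PstI
#' `CTGCA^G` leaves at a fragment end) and `AATTY` (ApoI `R^AATTY`).
#'
#' @param umi_length UMI length in bp (default 4).
#' @param barcode_length inner-barcode length in bp (default 6).
#' @param expected_tag_r1,expected_tag_r2 IUPAC residual-tag sequences
#'   expected at the insert start of each mate.
#' @return object of class `"read_layout"`.
#' @export
read_layout <- function(umi_length = 4L, barcode_length = 6L,
                        expected_tag_r1 = "TGCAG",
                        expected_tag_r2 = "AATTY") {
  stopifnot(umi_length >= 0L, barcode_length >= 0L)
  for (tag in c(expected_tag_r1, expected_tag_r2)) {
    bad <- setdiff(strsplit(toupper(tag), "")[[1]], names(IUPAC_CODES))
    if (length(bad)) stop("invalid IUPAC code in residual tag: ",
                          paste(bad, collapse = ", "))
  }
  structure(
    list(umi_length = as.integer(umi_length),
         barcode_length = as.integer(barcode_length),
         expected_tag_r1 = toupper(expected_tag_r1),
         expected_tag_r2 = toupper(expected_tag_r2)),
    class = "read_layout"
  )
}

validate_pairs <- function(pairs) {
  needed <- c("id", "seq1", "seq2", "qual1", "qual2")
  if (!is.data.frame(pairs) || !all(needed %in% names(pairs))) {
    stop("read pairs must be a data.frame with columns ",
         paste(needed, collapse = ", "))
  }
  if (nrow(pairs) &&
      (any(nchar(pairs$seq1) != nchar(pairs$qual1)) ||
       any(nchar(pairs$seq2) != nchar(pairs$qual2)))) {
    stop("sequence and quality strings must have equal length per mate")
  }
  pairs
}

empty_pairs <- function() {
  data.frame(id = character(), seq1 = character(), seq2 = character(),
             qual1 = character(), qual2 = character(),
             stringsAsFactors = FALSE)
}

#' Remove PCR clones by UMI and sequence identity
#'
#' A clone key is the pair's two UMIs plus both remaining mate sequences;
#' the first occurrence of each key is kept and later occurrences are
#' counted as PCR duplicates. Retained reads have their UMIs trimmed (from
#' sequence and quality). Matching is exact: UMIs are not error-corrected.
#' Pairs with a mate shorter than the UMI are discarded with a logged
#' reason.
#'
#' @param pairs read-pair data.frame (`id`, `seq1`, `seq2`, `qual1`,
#'   `qual2`).
#' @param layout a [read_layout()].
#' @return list with `pairs` (retained, UMI-trimmed, plus columns `umi1`,
#'   `umi2`), `n_duplicates`, and `discarded` (too-short pairs with
#'   reasons).
#' @export
clone_filter <- function(pairs, layout = read_layout()) {
  validate_pairs(pairs)
  u <- layout$umi_length
  too_short <- nchar(pairs$seq1) < u | nchar(pairs$seq2) < u
  discarded <- pairs[too_short, , drop = FALSE]
  if (nrow(discarded)) discarded$reason <- "shorter_than_umi"
  pairs <- pairs[!too_short, , drop = FALSE]
  umi1 <- substr(pairs$seq1, 1L, u)
  umi2 <- substr(pairs$seq2, 1L, u)
  rest1 <- substr(pairs$seq1, u + 1L, nchar(pairs$seq1))
  rest2 <- substr(pairs$seq2, u + 1L, nchar(pairs$seq2))
  key <- paste(umi1, umi2, rest1, rest2, sep = "\r")
  dup <- duplicated(key)
  out <- data.frame(
    id = pairs$id[!dup],
    seq1 = rest1[!dup], seq2 = rest2[!dup],
    qual1 = substr(pairs$qual1[!dup], u + 1L, nchar(pairs$qual1[!dup])),
    qual2 = substr(pairs$qual2[!dup], u + 1L, nchar(pairs$qual2[!dup])),
    umi1 = umi1[!dup], umi2 = umi2[!dup],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  list(pairs = out, n_duplicates = sum(dup), discarded = discarded)
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Demultiplex read pairs on inner barcodes
#'
#' Assigns a pair to a sample when both mates' barcodes match that sample's
#' barcode pair within `max_mismatch` substitutions and no other sample
#' matches as well; ambiguous or unmatched pairs go to `unassigned`.
#' Barcodes are trimmed from assigned and unassigned reads alike. A
#' barcode map whose entries are closer than `2 * max_mismatch + 1` on
#' either side cannot guarantee unique assignment and is rejected.
#'
#' @param pairs read-pair data.frame (UMIs already removed, barcodes at the
#'   front of each mate).
#' @param barcode_map data.frame with columns `sample`, `bc1`, `bc2`.
#' @param layout a [read_layout()].
#' @param max_mismatch allowed substitutions per barcode (default 1).
#' @return list with `pairs` (all input pairs, barcode-trimmed, plus a
#'   `sample` column; `NA` = unassigned), `per_sample` (split list of
#'   assigned pairs), `unassigned`, and `summary` counts.
#' @export
demultiplex <- function(pairs, barcode_map, layout = read_layout(),
                        max_mismatch = 1L) {
  validate_pairs(pairs)
  stopifnot(all(c("sample", "bc1", "bc2") %in% names(barcode_map)),
            !anyDuplicated(barcode_map$sample))
  b <- layout$barcode_length
  barcode_map$bc1 <- toupper(barcode_map$bc1)
  barcode_map$bc2 <- toupper(barcode_map$bc2)
  if (any(nchar(c(barcode_map$bc1, barcode_map$bc2)) != b)) {
    stop("barcodes in the map must all have length ", b)
  }
  for (side in c("bc1", "bc2")) {
    bcs <- unique(barcode_map[[side]])
    if (length(bcs) > 1L) {
      for (i in seq_len(length(bcs) - 1L)) {
        for (j in seq(i + 1L, length(bcs))) {
          if (hamming(bcs[i], bcs[j]) < 2L * max_mismatch + 1L) {
            stop("barcodes ", bcs[i], " and ", bcs[j], " are closer than ",
                 2L * max_mismatch + 1L,
                 " substitutions; assignment at max_mismatch = ",
                 max_mismatch, " would be ambiguous")
          }
        }
      }
    }
  }
  obs1 <- substr(pairs$seq1, 1L, b)
  obs2 <- substr(pairs$seq2, 1L, b)
  assign_one <- function(o1, o2) {
    if (nchar(o1) != b || nchar(o2) != b) return(NA_character_)
    d1 <- vapply(barcode_map$bc1, hamming, numeric(1), a = o1)
    d2 <- vapply(barcode_map$bc2, hamming, numeric(1), a = o2)
    hit <- which(d1 <= max_mismatch & d2 <= max_mismatch)
    if (length(hit) == 1L) barcode_map$sample[hit] else NA_character_
  }
  sample <- if (nrow(pairs)) {
    mapply(assign_one, obs1, obs2, USE.NAMES = FALSE)
  } else character()
  out <- data.frame(
    id = pairs$id,
    seq1 = substr(pairs$seq1, b + 1L, nchar(pairs$seq1)),
    seq2 = substr(pairs$seq2, b + 1L, nchar(pairs$seq2)),
    qual1 = substr(pairs$qual1, b + 1L, nchar(pairs$qual1)),
    qual2 = substr(pairs$qual2, b + 1L, nchar(pairs$qual2)),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(pairs), names(out))
  for (col in extra) out[[col]] <- pairs[[col]]
  out$sample <- sample
  assigned <- out[!is.na(out$sample), , drop = FALSE]
  list(
    pairs = out,
    per_sample = split(assigned, assigned$sample),
    unassigned = out[is.na(out$sample), , drop = FALSE],
    summary = c(input = nrow(out), assigned = nrow(assigned),
                unassigned = sum(is.na(out$sample)))
  )
}

# does each string start with the IUPAC prefix? vectorized over x
iupac_startswith <- function(x, prefix) {
  if (!nchar(prefix)) return(rep(TRUE, length(x)))
  pat <- strsplit(prefix, "")[[1]]
  ok <- nchar(x) >= length(pat)
  for (k in seq_along(pat)) {
    base <- substr(x, k, k)
    valid <- base %in% rownames(iupac_match_table)
    ok <- ok & valid & ifelse(valid,
                              iupac_match_table[cbind(base, pat[k])], FALSE)
  }
  ok
}

#' Verify residual restriction-site tags
#'
#' After barcode trimming, mate 1 must begin with the tag left by the first
#' enzyme and mate 2 with the tag of the second — or the mirrored
#' assignment, since a fragment ligates to the sequencing adapters in
#' either orientation. Matching is IUPAC-aware. Tags are genomic sequence
#' and are retained on the reads.
#'
#' @param pairs read-pair data.frame (barcodes already trimmed).
#' @param layout a [read_layout()].
#' @param allow_mirror accept tags swapped between mates (default `TRUE`).
#' @return list with `pairs` (passing), `rejected` (failing pairs) and
#'   `n_rejected`.
#' @export
radtag_check <- function(pairs, layout = read_layout(),
                         allow_mirror = TRUE) {
  validate_pairs(pairs)
  direct <- iupac_startswith(toupper(pairs$seq1), layout$expected_tag_r1) &
    iupac_startswith(toupper(pairs$seq2), layout$expected_tag_r2)
  ok <- direct
  if (allow_mirror) {
    mirror <- iupac_startswith(toupper(pairs$seq1), layout$expected_tag_r2) &
      iupac_startswith(toupper(pairs$seq2), layout$expected_tag_r1)
    ok <- ok | mirror
  }
  pass <- pairs[ok, , drop = FALSE]
  rownames(pass) <- NULL
  list(pairs = pass, rejected = pairs[!ok, , drop = FALSE],
       n_rejected = sum(!ok))
}

phred_scores <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}

#' Drop read pairs with a low-quality window
#'
#' Slides a window of `window_fraction * read_length` bases (at least 1)
#' along each mate; a pair is discarded if any window's mean Phred score
#' falls below `phred_threshold` in either mate. Defaults follow common
#' RAD-processing practice (15% window, Q10).
#'
#' @param pairs read-pair data.frame with Phred+33 quality strings.
#' @param window_fraction window length as a fraction of read length
#'   (default 0.15).
#' @param phred_threshold minimum acceptable window-mean Phred score
#'   (default 10).
#' @return list with `pairs` (passing) and `n_rejected`.
#' @export
quality_filter <- function(pairs, window_fraction = 0.15,
                           phred_threshold = 10) {
  validate_pairs(pairs)
  mate_ok <- function(qual) {
    q <- phred_scores(qual)
    w <- max(1L, floor(window_fraction * length(q)))
    if (length(q) < w) return(TRUE)
    means <- stats::filter(q, rep(1 / w, w), sides = 1)
    all(means[!is.na(means)] >= phred_threshold)
  }
  ok <- if (nrow(pairs)) {
    vapply(seq_len(nrow(pairs)), function(i) {
      mate_ok(pairs$qual1[i]) && mate_ok(pairs$qual2[i])
    }, logical(1))
  } else logical()
  pass <- pairs[ok, , drop = FALSE]
  rownames(pass) <- NULL
  list(pairs = pass, n_rejected = sum(!ok))
}

#' Read paired FASTQ files into a read-pair data.frame
#' @param r1,r2 FASTQ paths (gzip allowed), Phred+33.
#' @return read-pair data.frame (`id`, `seq1`, `seq2`, `qual1`, `qual2`).
#' @export
read_fastq_pairs <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq",
                                     with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(s1) != length(s2)) stop("mate files differ in read count")
  data.frame(
    id = sub("\\s.*$", "", names(s1)),
    seq1 = as.character(s1), seq2 = as.character(s2),
    qual1 = as.character(S4Vectors::mcols(s1)$qualities),
    qual2 = as.character(S4Vectors::mcols(s2)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a read-pair data.frame as two FASTQ files
#' @param pairs read-pair data.frame.
#' @param r1,r2 output FASTQ paths.
#' @return `c(r1, r2)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, r1, r2) {
  validate_pairs(pairs)
  write_mate <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::PhredQuality(Biostrings::BStringSet(quals))
    qx <- Biostrings::QualityScaledDNAStringSet(x, q)
    Biostrings::writeQualityScaledXStringSet(qx, path)
  }
  write_mate(pairs$seq1, pairs$qual1, pairs$id, r1)
  write_mate(pairs$seq2, pairs$qual2, pairs$id, r2)
  invisible(c(r1, r2))
}

#' Run the full preprocessing chain
#'
#' Clone removal, demultiplexing, RAD-tag verification and quality
#' filtering in pipeline order, with a per-step summary.
#'
#' @param pairs read-pair data.frame.
#' @param barcode_map data.frame with columns `sample`, `bc1`, `bc2`.
#' @param layout a [read_layout()].
#' @param max_mismatch barcode mismatch tolerance (default 1).
#' @param window_fraction,phred_threshold see [quality_filter()].
#' @return list with `pairs` (surviving pairs with `sample` column) and
#'   `summary` (named counts per step).
#' @export
readprep_pipeline <- function(pairs, barcode_map, layout = read_layout(),
                              max_mismatch = 1L, window_fraction = 0.15,
                              phred_threshold = 10) {
  n_input <- nrow(pairs)
  cf <- clone_filter(pairs, layout)
  dm <- demultiplex(cf$pairs, barcode_map, layout, max_mismatch)
  assigned <- dm$pairs[!is.na(dm$pairs$sample), , drop = FALSE]
  rt <- radtag_check(assigned, layout)
  qf <- quality_filter(rt$pairs, window_fraction, phred_threshold)
  list(
    pairs = qf$pairs,
    summary = c(
      input = n_input,
      too_short = nrow(cf$discarded),
      duplicates = cf$n_duplicates,
      unassigned = unname(dm$summary["unassigned"]),
      tag_failed = rt$n_rejected,
      quality_failed = qf$n_rejected,
      retained = nrow(qf$pairs)
    )
  )
}
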