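#' Synthetic data generators
#'
#' Generators for genomes with restriction sites planted at known
#' positions, somatic SNV sets drawn from known signature-exposure
#' mixtures, and read pairs in the UMI + inner-barcode + residual-tag
#' layout. Every generator takes a mandatory seed and returns a truth
#' table, so downstream modules can be tested against exact expectations.
#'
#' @name synthdata
NULL

random_dna <- function(n, gc = 0.4) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# one concrete A/C/G/T realization of an IUPAC string (random over choices)
realize_iupac <- function(recognition) {
  paste(vapply(strsplit(toupper(recognition), "")[[1]], function(code) {
    opts <- IUPAC_CODES[[code]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Generate a genome with planted restriction sites
#'
#' Builds a random background sequence, plants one concrete recognition
#' site per requested (enzyme, position), and rejection-samples the
#' background until the planted enzymes match nowhere else — so the truth
#' tables of sites, cut points and fragments are exact, not probabilistic.
#' Re-randomization is capped at 1000 rounds, after which the plan is
#' reported as infeasible.
#'
#' @param length genome length in bp.
#' @param sites data.frame with columns `enzyme` (catalog name or
#'   [enzyme()]) and `pos` (0-based start of the recognition site); planted
#'   sites must not overlap. `NULL` plants nothing.
#' @param gc GC fraction of the background (default 0.4).
#' @param seed mandatory integer seed.
#' @param contig contig name (default `"chr1"`).
#' @return list with `genome` (a one-contig `DNAStringSet`), `sites`
#'   (enzyme, pos, cut — the 0-based cut coordinate) and `fragments` (the
#'   expected fragment set between adjacent cuts, as in
#'   [digest_genome()]).
#' @export
make_genome <- function(length, sites = NULL, gc = 0.4, seed,
                        contig = "chr1") {
  stopifnot(length >= 1L, !missing(seed))
  catalog <- enzyme_catalog()
  if (is.null(sites) || nrow(sites) == 0L) {
    sites <- data.frame(enzyme = character(), pos = integer(),
                        stringsAsFactors = FALSE)
  }
  enzymes <- lapply(sites$enzyme, as_enzyme, catalog = catalog)
  widths <- vapply(enzymes, function(e) nchar(e$recognition), integer(1))
  if (nrow(sites)) {
    if (any(sites$pos != floor(sites$pos))) {
      stop("planted site positions must be whole numbers")
    }
    sites$pos <- as.integer(sites$pos)
    stopifnot(all(sites$pos >= 0L), all(sites$pos + widths <= length))
    ord <- order(sites$pos)
    if (any(diff(sites$pos[ord]) < widths[ord][-length(widths)])) {
      stop("planted sites overlap")
    }
  }
  scan_enzymes <- unique(vapply(enzymes, `[[`, character(1), "name"))
  if (!nrow(sites)) {
    # with nothing planted, still keep the two default screening enzymes out
    scan_enzymes <- c("PstI", "ApoI")
  }
  scan_enzymes <- lapply(scan_enzymes, as_enzyme, catalog = catalog)

  res <- with_seed(seed, {
    chars <- strsplit(random_dna(length, gc), "")[[1]]
    planted_at <- integer(0)
    planted_w <- integer(0)
    if (nrow(sites)) {
      for (i in seq_len(nrow(sites))) {
        concrete <- realize_iupac(enzymes[[i]]$recognition)
        span <- (sites$pos[i] + 1L):(sites$pos[i] + widths[i])
        chars[span] <- strsplit(concrete, "")[[1]]
      }
      planted_at <- sites$pos
      planted_w <- widths
    }
    key <- paste(sites$enzyme, sites$pos)
    for (round in seq_len(1000L)) {
      seq_str <- paste(chars, collapse = "")
      extra <- do.call(rbind, lapply(scan_enzymes, function(e)
        find_sites(seq_str, e, contig = contig)))
      if (!is.null(extra) && nrow(extra)) {
        # cut position -> match start for comparison with the plan
        offs <- vapply(scan_enzymes, `[[`, integer(1), "cut_offset")
        names(offs) <- vapply(scan_enzymes, `[[`, character(1), "name")
        extra$start <- extra$position - offs[extra$enzyme]
        extra <- extra[!paste(extra$enzyme, extra$start) %in% key, ,
                       drop = FALSE]
      }
      if (is.null(extra) || nrow(extra) == 0L) break
      if (round == 1000L) {
        stop("could not build a background free of accidental sites in ",
             "1000 rounds; the site plan is too dense")
      }
      for (i in seq_len(nrow(extra))) {
        w <- nchar(as_enzyme(extra$enzyme[i], catalog)$recognition)
        span <- (extra$start[i] + 1L):(extra$start[i] + w)
        # never disturb a planted site
        in_plant <- if (nrow(sites)) {
          outer(span - 1L, planted_at, ">=") &
            outer(span - 1L, planted_at + planted_w, "<")
        } else matrix(FALSE, nrow = length(span), ncol = 0)
        free <- span[rowSums(in_plant) == 0L]
        chars[free] <- sample(DNA_BASES, length(free), replace = TRUE,
                              prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                       (1 - gc) / 2))
      }
    }
    paste(chars, collapse = "")
  })

  genome <- Biostrings::DNAStringSet(setNames(res, contig))
  truth_sites <- data.frame(
    enzyme = as.character(sites$enzyme),
    pos = as.integer(sites$pos),
    cut = as.integer(sites$pos +
                       vapply(enzymes, `[[`, integer(1), "cut_offset")),
    stringsAsFactors = FALSE
  )
  truth_sites <- truth_sites[order(truth_sites$cut), , drop = FALSE]
  rownames(truth_sites) <- NULL
  nf <- nrow(truth_sites)
  fragments <- if (nf >= 2L) {
    data.frame(
      contig = contig,
      start = truth_sites$cut[-nf],
      end = truth_sites$cut[-1L],
      left_enzyme = truth_sites$enzyme[-nf],
      right_enzyme = truth_sites$enzyme[-1L],
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(contig = character(), start = integer(), end = integer(),
               left_enzyme = character(), right_enzyme = character(),
               stringsAsFactors = FALSE)
  }
  fragments$length <- fragments$end - fragments$start
  list(genome = genome, sites = truth_sites, fragments = fragments)
}

# pyrimidine-strand trinucleotide key of every internal genome position
# returns data.frame(contig, pos, key)
genome_context_table <- function(genome) {
  g <- as_genome(genome)
  out <- lapply(names(g), function(ctg) {
    s <- toupper(as.character(g[[ctg]]))
    L <- nchar(s)
    if (L < 3L) return(NULL)
    ctx <- substring(s, 1:(L - 2L), 3:L)
    pos <- 1:(L - 2L)  # 0-based center positions
    keep <- !grepl("[^ACGT]", ctx)
    ctx <- ctx[keep]
    pos <- pos[keep]
    center <- substr(ctx, 2L, 2L)
    flip <- center %in% c("A", "G")
    if (any(flip)) {
      ctx[flip] <- vapply(strsplit(ctx[flip], ""), function(b)
        paste(rev(unname(BASE_COMPLEMENT[b])), collapse = ""), character(1))
    }
    data.frame(contig = ctg, pos = pos, key = ctx, flipped = flip,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sample somatic SNVs from a signature mixture
#'
#' Draws each mutation's channel from the mixture distribution
#' `exposures %*% sigs` (multinomial over the 96 channels), places it on a
#' uniformly chosen genome position whose pyrimidine-strand trinucleotide
#' matches the channel context, and emits ref/alt on the genome strand
#' (reverse-complemented where the genome shows the purine context).
#' Positions are distinct across the whole draw, matching somatic-SNV
#' semantics.
#'
#' @param genome genome sequences.
#' @param sigs a [signature_matrix()].
#' @param exposures non-negative weights over the signatures, summing to 1.
#' @param n number of mutations.
#' @param seed mandatory integer seed.
#' @param sample sample label (default `"S1"`).
#' @return SNV data.frame (`contig`, `pos`, `ref`, `alt`, `sample`) with
#'   attributes `exposures` (the truth vector) and `channels` (the drawn
#'   channel per row).
#' @export
sample_mutations <- function(genome, sigs, exposures, n, seed,
                             sample = "S1") {
  stopifnot(inherits(sigs, "signature_matrix"), !missing(seed), n >= 0)
  exposures <- as.numeric(exposures)
  if (length(exposures) != nrow(sigs) || any(exposures < 0) ||
      abs(sum(exposures) - 1) > 1e-6) {
    stop("exposures must be non-negative over the signatures and sum to 1")
  }
  p <- as.numeric(crossprod(unclass(sigs), exposures))
  ctx_table <- genome_context_table(genome)
  labs <- sbs96_channels()
  chan_key <- paste0(substr(labs, 1, 1), substr(labs, 3, 3),
                     substr(labs, 7, 7))
  chan_alt <- substr(labs, 5, 5)

  out <- with_seed(seed, {
    counts <- if (n > 0) as.integer(rmultinom(1L, n, p)) else integer(96)
    by_key <- split(seq_len(nrow(ctx_table)), ctx_table$key)
    need <- tapply(counts, chan_key, sum)
    short <- names(need)[vapply(names(need), function(k)
      need[[k]] > length(by_key[[k]]), logical(1))]
    if (length(short)) {
      stop("genome lacks enough positions for context(s): ",
           paste(short, collapse = ", "))
    }
    rows <- integer(0)
    channel <- integer(0)
    for (key in unique(chan_key)) {
      chans <- which(chan_key == key)
      total <- sum(counts[chans])
      if (total == 0L) next
      pick <- by_key[[key]][sample.int(length(by_key[[key]]), total)]
      rows <- c(rows, pick)
      channel <- c(channel, rep(chans, counts[chans]))
    }
    list(rows = rows, channel = channel)
  })

  tab <- ctx_table[out$rows, , drop = FALSE]
  alt_pyr <- chan_alt[out$channel]
  ref_pyr <- substr(tab$key, 2L, 2L)
  ref <- ifelse(tab$flipped, unname(BASE_COMPLEMENT[ref_pyr]), ref_pyr)
  alt <- ifelse(tab$flipped, unname(BASE_COMPLEMENT[alt_pyr]), alt_pyr)
  snvs <- data.frame(
    contig = tab$contig, pos = tab$pos, ref = ref, alt = alt,
    sample = rep(sample, nrow(tab)), stringsAsFactors = FALSE
  )
  ord <- order(snvs$contig, snvs$pos)
  snvs <- snvs[ord, , drop = FALSE]
  rownames(snvs) <- NULL
  structure(snvs, exposures = exposures, channels = out$channel[ord])
}

#' Simulate read pairs in the UMI + barcode + residual-tag layout
#'
#' Each original molecule draws a fragment, a sample from the barcode map,
#' and fresh random UMIs for both mates; mate 1 carries
#' `[UMI][bc1][tag1][fragment 5' sequence]` and mate 2
#' `[UMI][bc2][tag2][reverse-complemented fragment 3' sequence]`. PCR
#' duplicates are created by re-emitting a pair verbatim with probability
#' `duplication_rate`. UMI pairs are drawn to be unique per distinct
#' molecule so the truth duplicate count is exact. Reads are error-free at
#' Q40.
#'
#' @param fragments fragment data.frame (from [digest_genome()] or a truth
#'   table).
#' @param genome genome sequences the fragments index into.
#' @param barcode_map data.frame with columns `sample`, `bc1`, `bc2`.
#' @param n_pairs number of original (non-duplicate) molecules.
#' @param duplication_rate probability that a molecule is re-emitted once
#'   (default 0).
#' @param layout a [read_layout()].
#' @param read_length total read length per mate (default 100).
#' @param seed mandatory integer seed.
#' @return list with `pairs` (read-pair data.frame) and `truth`
#'   (data.frame: `id`, `sample`, `fragment` row index, `duplicate` flag).
#' @export
simulate_reads <- function(fragments, genome, barcode_map, n_pairs,
                           duplication_rate = 0, layout = read_layout(),
                           read_length = 100L, seed) {
  stopifnot(nrow(fragments) >= 1L, n_pairs >= 1L, !missing(seed),
            duplication_rate >= 0, duplication_rate <= 1,
            all(c("sample", "bc1", "bc2") %in% names(barcode_map)))
  g <- as_genome(genome)
  u <- layout$umi_length
  b <- layout$barcode_length
  prefix <- u + b + max(nchar(layout$expected_tag_r1),
                        nchar(layout$expected_tag_r2))
  insert_len <- read_length - prefix
  stopifnot(insert_len >= 1L)
  if (any(fragments$length < insert_len)) {
    stop("all fragments must be at least ", insert_len,
         " bp to fill the configured read length")
  }
  with_seed(seed, {
    frag_i <- sample.int(nrow(fragments), n_pairs, replace = TRUE)
    samp_i <- sample.int(nrow(barcode_map), n_pairs, replace = TRUE)
    tag1 <- vapply(seq_len(n_pairs), function(i)
      realize_iupac(layout$expected_tag_r1), character(1))
    tag2 <- vapply(seq_len(n_pairs), function(i)
      realize_iupac(layout$expected_tag_r2), character(1))
    seen <- new.env(hash = TRUE)
    umi1 <- character(n_pairs)
    umi2 <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      repeat {
        u1 <- random_dna(u, gc = 0.5)
        u2 <- random_dna(u, gc = 0.5)
        k <- paste(frag_i[i], samp_i[i], u1, u2)
        if (is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          umi1[i] <- u1
          umi2[i] <- u2
          break
        }
      }
    }
    frag_seq <- vapply(seq_len(n_pairs), function(i) {
      f <- fragments[frag_i[i], ]
      as.character(Biostrings::Views(g[[f$contig]], start = f$start + 1L,
                                     end = f$end)[[1L]])
    }, character(1))
    left <- substr(frag_seq, 1L, insert_len)
    right_full <- vapply(frag_seq, function(s) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }, character(1), USE.NAMES = FALSE)
    right <- substr(right_full, 1L, insert_len)
    seq1 <- paste0(umi1, barcode_map$bc1[samp_i], tag1, left)
    seq2 <- paste0(umi2, barcode_map$bc2[samp_i], tag2, right)
    ids <- sprintf("read%06d", seq_len(n_pairs))
    dup <- runif(n_pairs) < duplication_rate
    ord_rows <- c(seq_len(n_pairs), which(dup))
    is_dup <- c(rep(FALSE, n_pairs), rep(TRUE, sum(dup)))
    shuffle <- sample.int(length(ord_rows))
    ord_rows <- ord_rows[shuffle]
    is_dup <- is_dup[shuffle]
    pairs <- data.frame(
      id = ifelse(is_dup, paste0(ids[ord_rows], "_dup"), ids[ord_rows]),
      seq1 = seq1[ord_rows], seq2 = seq2[ord_rows],
      qual1 = strrep("I", nchar(seq1[ord_rows])),
      qual2 = strrep("I", nchar(seq2[ord_rows])),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      id = pairs$id,
      sample = barcode_map$sample[samp_i[ord_rows]],
      fragment = frag_i[ord_rows],
      duplicate = is_dup,
      stringsAsFactors = FALSE
    )
    list(pairs = pairs, truth = truth)
  })
}
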