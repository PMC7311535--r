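#' 96-channel single-base-substitution spectra
#'
#' SNVs are classified by the pyrimidine-strand substitution (C>A, C>G,
#' C>T, T>A, T>C, T>G) and the two flanking bases, giving the canonical
#' 96 trinucleotide channels used by COSMIC-style signature matrices.
#'
#' @name spectrum
NULL

SBS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DNA_BASES <- c("A", "C", "G", "T")
BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Canonical channel labels of the 96-channel SBS spectrum
#'
#' Substitution-major order (C>A, C>G, C>T, T>A, T>C, T>G), then the 5'
#' flanking base and the 3' flanking base, each alphabetical. Signature
#' matrices and spectra in this package always use this order; tabular
#' inputs carrying channel labels are harmonized to it by label.
#'
#' @return character vector of 96 labels like `"A[C>A]A"`.
#' @examples
#' head(sbs96_channels())
#' @export
sbs96_channels <- function() {
  labs <- character(96)
  i <- 0L
  for (sub in SBS_SUBSTITUTIONS) {
    for (five in DNA_BASES) {
      for (three in DNA_BASES) {
        i <- i + 1L
        labs[i] <- paste0(five, "[", sub, "]", three)
      }
    }
  }
  labs
}

# run expr with a private RNG state; NULL seed = use current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

validate_snvs <- function(snvs) {
  needed <- c("contig", "pos", "ref", "alt")
  if (!is.data.frame(snvs) || !all(needed %in% names(snvs))) {
    stop("SNVs must be a data.frame with columns contig, pos, ref, alt")
  }
  if (nrow(snvs) && any(toupper(snvs$ref) == toupper(snvs$alt))) {
    stop("SNVs must have ref != alt")
  }
  snvs
}

#' Map SNVs to their trinucleotide channels
#'
#' Looks up each SNV's trinucleotide context in the genome, strandizes
#' purine-reference substitutions to the pyrimidine strand by reverse
#' complement, and returns the canonical channel index. SNVs whose context
#' cannot be determined (missing flank at a contig end, or an `N` in the
#' context) get `NA` and are reported in the `skipped` attribute; a
#' reference allele that contradicts the genome is an error.
#'
#' @param snvs data.frame with columns `contig`, `pos` (0-based), `ref`,
#'   `alt`.
#' @param genome genome sequences (see [find_sites()] for accepted forms).
#' @return integer vector of channel indices in `1..96` (`NA` = excluded),
#'   with attribute `skipped`: a data.frame of excluded rows and reasons.
#' @export
snv_channels <- function(snvs, genome) {
  validate_snvs(snvs)
  g <- as_genome(genome)
  n <- nrow(snvs)
  idx <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)
  if (n) {
    ref <- toupper(snvs$ref)
    alt <- toupper(snvs$alt)
    ctx <- rep(NA_character_, n)
    for (ctg in unique(snvs$contig)) {
      rows <- which(snvs$contig == ctg)
      if (!ctg %in% names(g)) {
        reason[rows] <- "unknown_contig"
        next
      }
      len <- length(g[[ctg]])
      pos <- snvs$pos[rows]
      ok <- pos >= 1L & pos + 2L <= len
      reason[rows[!ok]] <- "missing_flank"
      if (any(ok)) {
        v <- Biostrings::Views(g[[ctg]], start = pos[ok], width = 3L)
        ctx[rows[ok]] <- as.character(v)
      }
    }
    has_n <- !is.na(ctx) & grepl("[^ACGT]", ctx)
    reason[has_n] <- "context_with_N"
    ctx[has_n] <- NA_character_
    usable <- !is.na(ctx)
    if (any(usable)) {
      center <- substr(ctx[usable], 2L, 2L)
      if (any(center != ref[usable])) {
        bad <- which(usable)[center != ref[usable]][1L]
        stop("SNV ref allele disagrees with the genome at ",
             snvs$contig[bad], ":", snvs$pos[bad], " (genome ",
             substr(ctx[bad], 2L, 2L), ", ref ", ref[bad], ")")
      }
      five <- substr(ctx[usable], 1L, 1L)
      three <- substr(ctx[usable], 3L, 3L)
      r <- ref[usable]
      a <- alt[usable]
      flip <- r %in% c("A", "G")
      r2 <- ifelse(flip, unname(BASE_COMPLEMENT[r]), r)
      a2 <- ifelse(flip, unname(BASE_COMPLEMENT[a]), a)
      f2 <- ifelse(flip, unname(BASE_COMPLEMENT[three]), five)
      t2 <- ifelse(flip, unname(BASE_COMPLEMENT[five]), three)
      sub_i <- match(paste0(r2, ">", a2), SBS_SUBSTITUTIONS)
      idx[usable] <- as.integer(
        (sub_i - 1L) * 16L + (match(f2, DNA_BASES) - 1L) * 4L +
          match(t2, DNA_BASES)
      )
    }
  }
  skipped <- snvs[!is.na(reason), c("contig", "pos", "ref", "alt"),
                  drop = FALSE]
  skipped$reason <- reason[!is.na(reason)]
  rownames(skipped) <- NULL
  structure(idx, skipped = skipped)
}

#' Trinucleotide channel of a single SNV
#'
#' Convenience wrapper around [snv_channels()] for one variant.
#'
#' @param contig,pos,ref,alt the SNV (`pos` 0-based).
#' @param genome genome sequences.
#' @return a length-1 integer channel index (`1..96`), named with the
#'   channel label; `NA` if the context is undeterminable.
#' @examples
#' trinucleotide_channel("chr1", 1, "C", "T", c(chr1 = "ACAT"))
#' @export
trinucleotide_channel <- function(contig, pos, ref, alt, genome) {
  idx <- snv_channels(
    data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    genome
  )
  out <- as.integer(idx[1L])
  names(out) <- if (is.na(out)) NA_character_ else sbs96_channels()[out]
  out
}

#' Build a 96-channel mutational spectrum
#'
#' Counts SNVs per trinucleotide channel, optionally restricted to a set of
#' genomic regions (e.g. size-selected fragments): with `regions`, only
#' SNVs whose position falls inside a half-open region interval contribute.
#' The spectrum total equals the number of contributing SNVs exactly.
#'
#' @param snvs data.frame with columns `contig`, `pos` (0-based), `ref`,
#'   `alt` (one sample).
#' @param genome genome sequences.
#' @param regions optional fragment data.frame, BED path, or `GRanges`.
#' @return object of class `"mutational_spectrum"`: a named numeric vector
#'   of 96 counts with attributes `total` (contributing SNVs), `n_excluded`
#'   (context-undeterminable SNVs) and `n_outside` (region-filtered SNVs).
#' @export
build_spectrum <- function(snvs, genome, regions = NULL) {
  validate_snvs(snvs)
  n_outside <- 0L
  if (!is.null(regions) && nrow(snvs)) {
    gr <- as_region_granges(regions)
    pts <- GenomicRanges::GRanges(
      seqnames = snvs$contig,
      ranges = IRanges::IRanges(start = snvs$pos + 1L, width = 1L)
    )
    inside <- IRanges::overlapsAny(pts, gr)
    n_outside <- sum(!inside)
    snvs <- snvs[inside, , drop = FALSE]
  }
  idx <- snv_channels(snvs, genome)
  counts <- tabulate(idx, nbins = 96L)
  structure(
    setNames(as.numeric(counts), sbs96_channels()),
    total = sum(counts),
    n_excluded = sum(is.na(idx)),
    n_outside = n_outside,
    skipped = attr(idx, "skipped"),
    class = "mutational_spectrum"
  )
}

#' @export
print.mutational_spectrum <- function(x, ...) {
  cat(sprintf(
    "<mutational_spectrum> 96 channels, %d mutations (%d excluded, %d outside regions)\n",
    attr(x, "total"), attr(x, "n_excluded"), attr(x, "n_outside")))
  top <- sort(unclass(x), decreasing = TRUE)
  top <- top[top > 0]
  if (length(top)) {
    show <- head(top, 5L)
    cat("  top channels:",
        paste(sprintf("%s=%g", names(show), show), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subsample SNVs without replacement
#'
#' Draws a uniform random subset of `n` SNVs, reproducibly under `seed`.
#' When `n` is at least the number of available SNVs all are returned;
#' callers deciding whether a sample has enough mutations to contribute to
#' a subset size do so themselves.
#'
#' @param snvs SNV data.frame.
#' @param n subset size (`>= 0`).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return a row subset of `snvs`.
#' @export
subsample_snvs <- function(snvs, n, seed = NULL) {
  stopifnot(n >= 0)
  if (n >= nrow(snvs)) return(snvs)
  keep <- with_seed(seed, sample.int(nrow(snvs), size = n))
  out <- snvs[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read SNVs from a VCF file
#'
#' Multi-allelic records are split into one row per alternate allele and
#' only single-base ref/alt substitutions are kept. The FILTER column is
#' ignored by default (filtering is a separate, explicit step; see
#' [apply_filters()]). Positions are converted to 0-based coordinates.
#'
#' @param path VCF (4.x) file path.
#' @param sample sample label to attach; defaults to the file's base name.
#' @return data.frame with columns `contig`, `pos` (0-based), `ref`, `alt`,
#'   `sample`.
#' @export
read_snv_vcf <- function(path, sample = NULL) {
  if (is.null(sample)) {
    sample <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sample = character(), stringsAsFactors = FALSE))
  }
  alt_split <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  rep_i <- rep(seq_len(nrow(fix)), lengths(alt_split))
  out <- data.frame(
    contig = fix[rep_i, "CHROM"],
    pos = as.integer(fix[rep_i, "POS"]) - 1L,
    ref = toupper(fix[rep_i, "REF"]),
    alt = toupper(unlist(alt_split)),
    sample = sample,
    stringsAsFactors = FALSE
  )
  out <- out[nchar(out$ref) == 1L & nchar(out$alt) == 1L &
             out$ref %in% DNA_BASES & out$alt %in% DNA_BASES, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write SNVs as a minimal VCF
#'
#' Serializes `contig`/`pos`/`ref`/`alt` rows as a plain-text VCF 4.2 file
#' (site-only, no genotypes).
#'
#' @param snvs SNV data.frame (`pos` 0-based).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, path) {
  validate_snvs(snvs)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mutread",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  ord <- order(snvs$contig, snvs$pos)
  body <- if (nrow(snvs)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
            snvs$contig[ord], snvs$pos[ord] + 1L,
            toupper(snvs$ref[ord]), toupper(snvs$alt[ord]))
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a spectrum as a two-column TSV (channel, count)
#' @param spectrum a `"mutational_spectrum"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  write.table(
    data.frame(channel = names(spectrum), count = as.numeric(spectrum)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a spectrum TSV written by [write_spectrum_tsv()]
#'
#' Channels are harmonized to the canonical order by label.
#'
#' @param path TSV path with columns `channel`, `count`.
#' @return a `"mutational_spectrum"`.
#' @export
read_spectrum_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("channel", "count") %in% names(tab)))
  labs <- sbs96_channels()
  if (!setequal(tab$channel, labs) || nrow(tab) != 96L) {
    stop("spectrum TSV must contain each of the 96 channel labels exactly once")
  }
  counts <- setNames(as.numeric(tab$count[match(labs, tab$channel)]), labs)
  structure(counts, total = sum(counts), n_excluded = 0L, n_outside = 0L,
            class = "mutational_spectrum")
}
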