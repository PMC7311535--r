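#' In-silico digestion and size selection
#'
#' The double-digest simulation cuts a genome with two restriction enzymes,
#' forms fragments between adjacent cut points, and retains fragments inside
#' a size window with one end from each enzyme — the set of loci an RR-seq
#' library is expected to sample. All coordinates are 0-based half-open.
#'
#' @name digestion
NULL

# coerce genome input (named character vector, DNAStringSet, or FASTA path)
# to a named DNAStringSet
as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    g <- genome
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome) && is.null(names(genome))) {
    g <- Biostrings::readDNAStringSet(genome)
    # FASTA headers may carry descriptions; keep the first word as contig name
    names(g) <- sub("\\s.*$", "", names(g))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) {
      names(genome) <- if (length(genome) == 1L) "seq1"
                       else paste0("seq", seq_along(genome))
    }
    g <- Biostrings::DNAStringSet(toupper(genome))
  } else {
    stop("genome must be a DNAStringSet, a named character vector, ",
         "or a FASTA path")
  }
  if (length(g) && (is.null(names(g)) || anyDuplicated(names(g)))) {
    stop("genome contigs must have unique names")
  }
  g
}

#' Find restriction cut sites on the top strand
#'
#' Scans a nucleotide sequence for every IUPAC-compatible occurrence of an
#' enzyme's recognition sequence and reports the top-strand cut point of
#' each (match start + cut offset). Matching is case-insensitive,
#' overlapping matches are all reported, and matches spanning an `N` are
#' rejected so that assembly gaps never spawn sites. For palindromic
#' recognitions (all catalog enzymes) a top-strand scan is exhaustive.
#'
#' @param sequence a single nucleotide string over `A,C,G,T,N`
#'   (case-insensitive), or a `DNAString`.
#' @param enzyme an [enzyme()] or catalog enzyme name.
#' @param contig contig label attached to the returned sites.
#' @return data.frame with columns `contig`, `position` (0-based cut
#'   coordinate), `enzyme`, sorted by position.
#' @examples
#' find_sites("AAACTGCAGAAA", enzyme("PstI", "CTGCAG", 5))
#' @export
find_sites <- function(sequence, enzyme, contig = "seq1") {
  enzyme <- as_enzyme(enzyme)
  subject <- if (is(sequence, "DNAString")) sequence
             else Biostrings::DNAString(toupper(as.character(sequence)))
  if (length(subject) < nchar(enzyme$recognition)) {
    return(data.frame(contig = character(), position = integer(),
                      enzyme = character(), stringsAsFactors = FALSE))
  }
  hits <- Biostrings::matchPattern(enzyme$recognition, subject,
                                   fixed = FALSE)
  starts <- BiocGenerics::start(hits)
  if (length(starts)) {
    # fixed = FALSE lets subject Ns satisfy any pattern code; drop those
    matched <- as.character(hits)
    starts <- starts[!grepl("N", matched, fixed = TRUE)]
  }
  data.frame(
    contig = rep(contig, length(starts)),
    position = as.integer(starts - 1L + enzyme$cut_offset),
    enzyme = rep(enzyme$name, length(starts)),
    stringsAsFactors = FALSE
  )
}

#' Double-digest a genome into fragments
#'
#' Pools the cut sites of both enzymes per contig, sorts them, and emits one
#' fragment per pair of adjacent cut points, labelled with the enzymes that
#' produced its two ends. Contig ends do not generate fragments: terminal
#' half-fragments have no defined restriction end and cannot ligate an
#' enzyme-specific adapter.
#'
#' @param genome named sequences (see [find_sites()] for accepted forms).
#' @param enzyme_a,enzyme_b the two enzymes ([enzyme()] or catalog names);
#'   must differ by recognition sequence.
#' @return data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open), `left_enzyme`, `right_enzyme`, `length`, sorted by
#'   (contig, start).
#' @examples
#' g <- c(chr1 = paste0(strrep("A", 100), "CTGCAG", strrep("T", 200),
#'                      "GAATTC", strrep("A", 100)))
#' digest_genome(g, "PstI", "ApoI")
#' @export
digest_genome <- function(genome, enzyme_a, enzyme_b) {
  catalog <- NULL
  if (is.character(enzyme_a) || is.character(enzyme_b)) {
    catalog <- enzyme_catalog()
  }
  enzyme_a <- as_enzyme(enzyme_a, catalog)
  enzyme_b <- as_enzyme(enzyme_b, catalog)
  if (identical(enzyme_a$recognition, enzyme_b$recognition)) {
    stop("double digestion requires two enzymes with distinct recognition ",
         "sequences")
  }
  g <- as_genome(genome)
  per_contig <- lapply(names(g), function(ctg) {
    sites <- rbind(find_sites(g[[ctg]], enzyme_a, contig = ctg),
                   find_sites(g[[ctg]], enzyme_b, contig = ctg))
    if (nrow(sites) < 2L) return(NULL)
    sites <- sites[order(sites$position, sites$enzyme), , drop = FALSE]
    n <- nrow(sites)
    data.frame(
      contig = ctg,
      start = sites$position[-n],
      end = sites$position[-1L],
      left_enzyme = sites$enzyme[-n],
      right_enzyme = sites$enzyme[-1L],
      stringsAsFactors = FALSE
    )
  })
  frags <- do.call(rbind, per_contig)
  if (is.null(frags)) {
    frags <- data.frame(contig = character(), start = integer(),
                        end = integer(), left_enzyme = character(),
                        right_enzyme = character(), stringsAsFactors = FALSE)
  }
  # adjacent cuts at the same coordinate (overlapping degenerate matches)
  # would give zero-length intervals; they carry no sequence
  frags <- frags[frags$end > frags$start, , drop = FALSE]
  frags$length <- frags$end - frags$start
  rownames(frags) <- NULL
  frags[order(frags$contig, frags$start), , drop = FALSE]
}

#' Size-select fragments
#'
#' Retains fragments whose length lies in `[min_len, max_len]` (both
#' boundaries inclusive) and, by default, whose two ends come from different
#' enzymes. The mixed-ends rule reflects enzyme-specific Y-adapters: a
#' fragment with two identical ends receives the same adapter twice and is
#' not amplified. Toggle `require_mixed_ends = FALSE` for other designs.
#'
#' @param fragments data.frame from [digest_genome()].
#' @param min_len,max_len inclusive fragment-length window in bp.
#' @param require_mixed_ends keep only fragments with `left_enzyme !=
#'   right_enzyme` (default `TRUE`).
#' @return the retained subset of `fragments`, row-renumbered.
#' @export
size_select <- function(fragments, min_len = 350L, max_len = 450L,
                        require_mixed_ends = TRUE) {
  stopifnot(min_len <= max_len)
  len <- fragments$end - fragments$start
  keep <- len >= min_len & len <= max_len
  if (require_mixed_ends) {
    keep <- keep & fragments$left_enzyme != fragments$right_enzyme
  }
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write fragments as a 6-column BED file
#'
#' Records are 0-based half-open, named `leftEnzyme-rightEnzyme`, and sorted
#' by (contig, start).
#'
#' @param fragments data.frame from [digest_genome()] / [size_select()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  ord <- order(fragments$contig, fragments$start)
  bed <- data.frame(
    chrom = fragments$contig[ord],
    start = fragments$start[ord],
    end = fragments$end[ord],
    name = paste0(fragments$left_enzyme[ord], "-",
                  fragments$right_enzyme[ord]),
    score = rep(0L, length(ord)),
    strand = rep("+", length(ord)),
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genomic regions from a BED file
#'
#' Accepts 3+ column BED; extra columns beyond the first four are ignored.
#'
#' @param path BED file path.
#' @return data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open) and `name` when present.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(fields))
  if (ncol < 3L) stop("BED file must have at least 3 columns: ", path)
  out <- data.frame(
    contig = vapply(fields, `[[`, character(1), 1L),
    start = as.integer(vapply(fields, `[[`, character(1), 2L)),
    end = as.integer(vapply(fields, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
  if (ncol >= 4L) out$name <- vapply(fields, `[[`, character(1), 4L)
  out
}

# regions (fragments df, BED path, or GRanges) -> GRanges, 1-based internal
as_region_granges <- function(regions) {
  if (is(regions, "GRanges")) return(regions)
  if (is.character(regions) && length(regions) == 1L) {
    regions <- read_regions_bed(regions)
  }
  stopifnot(is.data.frame(regions),
            all(c("contig", "start", "end") %in% names(regions)))
  GenomicRanges::GRanges(
    seqnames = regions$contig,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}
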