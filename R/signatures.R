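#' Signature matrices and exposure refitting
#'
#' A signature matrix holds k mutational signatures as probability
#' distributions over the 96 SBS channels. Refitting estimates the
#' non-negative contribution (exposure) of each signature to an observed
#' spectrum by non-negative least squares, then scales the coefficients to
#' sum to one. Profiles are compared with the cosine similarity.
#'
#' @name signatures
NULL

#' Construct a signature matrix
#'
#' @param mat numeric k x 96 matrix, rows = signatures, columns in the
#'   canonical channel order ([sbs96_channels()]); rows are renormalized to
#'   sum to 1 (tolerance `1e-6` on input after renormalization is exact).
#' @param names optional signature labels (defaults to rownames).
#' @return object of class `"signature_matrix"`: the renormalized matrix
#'   with signature rownames and channel colnames.
#' @export
signature_matrix <- function(mat, names = NULL) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 96L) stop("signature matrix must have 96 columns")
  if (is.null(names)) names <- rownames(mat)
  if (is.null(names)) names <- paste0("Signature", seq_len(nrow(mat)))
  if (anyDuplicated(names)) stop("duplicate signature names")
  if (nrow(mat) < 1L) stop("signature matrix needs at least one signature")
  if (any(mat < 0)) stop("signature matrix must be non-negative")
  rs <- rowSums(mat)
  if (any(rs <= 0)) {
    stop("signature row(s) sum to zero: ",
         paste(names[rs <= 0], collapse = ", "))
  }
  mat <- mat / rs
  dimnames(mat) <- list(names, sbs96_channels())
  structure(mat, class = c("signature_matrix", "matrix"))
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d signatures x 96 channels: %s\n",
              nrow(x), paste(rownames(x), collapse = ", ")))
  invisible(x)
}

#' Load a signature matrix from a TSV file
#'
#' Accepts the common tabular layouts: 96 rows x k signature columns with
#' either a combined channel-label column (`A[C>T]G` style; column named
#' `Type`, `MutationType`, `channel` or the first character column) or the
#' split COSMIC pair `Type` (`C>T`) + `Subtype` (`ACG`). Channel order is
#' harmonized to canonical by label, never trusted positionally. Rows are
#' renormalized to sum to one.
#'
#' @param path TSV file path.
#' @return a [signature_matrix()].
#' @export
load_signatures <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) != 96L) {
    stop("signature table must have 96 rows (one per channel), got ",
         nrow(tab))
  }
  cols <- names(tab)
  labels <- NULL
  if (all(c("Type", "Subtype") %in% cols)) {
    sub <- tab[["Type"]]
    ctx <- toupper(tab[["Subtype"]])
    if (all(grepl("^[ACGT]>[ACGT]$", sub)) && all(nchar(ctx) == 3L)) {
      labels <- paste0(substr(ctx, 1, 1), "[", sub, "]", substr(ctx, 3, 3))
      tab <- tab[, setdiff(cols, c("Type", "Subtype")), drop = FALSE]
    }
  }
  if (is.null(labels)) {
    is_chr <- vapply(tab, is.character, logical(1))
    combined <- which(is_chr & vapply(tab, function(x) {
      all(grepl("^[ACGT]\\[[ACGT]>[ACGT]\\][ACGT]$", x))
    }, logical(1)))
    if (!length(combined)) {
      stop("no channel-label column found (expected combined 'A[C>T]G' ",
           "labels or a Type/Subtype pair)")
    }
    labels <- tab[[combined[1L]]]
    tab <- tab[, -combined[1L], drop = FALSE]
  }
  if (!setequal(labels, sbs96_channels()) || anyDuplicated(labels)) {
    missing <- setdiff(sbs96_channels(), labels)
    extra <- setdiff(labels, sbs96_channels())
    stop("channel labels do not form the 96-channel set",
         if (length(missing)) paste0("; missing: ",
                                     paste(head(missing, 3), collapse = ", "),
                                     if (length(missing) > 3) ", ..."),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(head(extra, 3), collapse = ", ")))
  }
  num <- vapply(tab, is.numeric, logical(1))
  if (!any(num)) stop("no numeric signature columns found")
  mat <- t(as.matrix(tab[match(sbs96_channels(), labels), num, drop = FALSE]))
  if (any(mat < 0)) stop("signature values must be non-negative")
  signature_matrix(mat, names = names(tab)[num])
}

#' Write a signature matrix as a TSV (combined channel labels)
#' @param sigs a [signature_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signatures_tsv <- function(sigs, path) {
  stopifnot(inherits(sigs, "signature_matrix"))
  out <- data.frame(Type = colnames(sigs), t(unclass(sigs)),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Refit signature exposures by non-negative least squares
#'
#' Normalizes the observed spectrum to channel frequencies, solves
#' `min ||S' x - p||_2, x >= 0` where the rows of `S` are the signatures,
#' and scales the coefficients to sum to one. Because NNLS is linear in the
#' overall scale of `p`, fitting frequencies and fitting raw counts give
#' the same exposures after this final normalization.
#'
#' @param spectrum a `"mutational_spectrum"` or a non-negative vector of 96
#'   channel counts with total > 0.
#' @param sigs a [signature_matrix()].
#' @return object of class `"exposure_profile"`: named numeric weights
#'   summing to 1, with attributes `residual_norm` (residual of the
#'   frequency-scale fit) and `n_mutations`.
#' @export
fit_exposures <- function(spectrum, sigs) {
  stopifnot(inherits(sigs, "signature_matrix"))
  counts <- as.numeric(spectrum)
  if (length(counts) != 96L) stop("spectrum must have 96 channels")
  if (any(counts < 0)) stop("spectrum counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) {
    stop("cannot fit exposures to an all-zero spectrum")
  }
  p <- counts / total
  fit <- nnls_fit(t(unclass(sigs)), p)
  if (all(fit$x <= 0)) {
    stop("degenerate fit: all exposures zero; the profile is undefined")
  }
  weights <- fit$x / sum(fit$x)
  structure(
    setNames(weights, rownames(sigs)),
    residual_norm = fit$residual,
    n_mutations = if (inherits(spectrum, "mutational_spectrum"))
      attr(spectrum, "total") else total,
    class = "exposure_profile"
  )
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat(sprintf("<exposure_profile> %d signatures, %g mutations, residual %.4g\n",
              length(x), attr(x, "n_mutations"), attr(x, "residual_norm")))
  print(round(setNames(as.numeric(x), names(x)), 4))
  invisible(x)
}

#' Cosine similarity of two profiles
#'
#' `sum(P * Q) / (||P|| * ||Q||)`, the inner product of the two vectors
#' normalized by their Euclidean norms. Identical profiles score 1;
#' profiles with disjoint support (independent mutational processes) score
#' 0. Both arguments must be non-zero; the value lies in `[0, 1]` for
#' non-negative inputs such as exposures or spectra.
#'
#' @param p,q exposure profiles, spectra, or plain numeric vectors of equal
#'   length.
#' @return the cosine similarity, a single number.
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' @export
cosine_similarity <- function(p, q) {
  p <- as.numeric(p)
  q <- as.numeric(q)
  if (length(p) != length(q)) stop("profiles must have equal length")
  np <- sqrt(sum(p^2))
  nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0) {
    stop("cosine similarity is undefined for zero vectors")
  }
  # guard against floating-point overshoot just past +/-1
  max(-1, min(1, sum(p * q) / (np * nq)))
}

#' Write an exposure profile as a TSV (signature, weight)
#' @param exposures an `"exposure_profile"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exposures_tsv <- function(exposures, path) {
  write.table(
    data.frame(signature = names(exposures),
               weight = as.numeric(exposures)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read an exposure profile TSV written by [write_exposures_tsv()]
#' @param path TSV path with columns `signature`, `weight`.
#' @return named numeric vector of weights.
#' @export
read_exposures_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("signature", "weight") %in% names(tab)))
  setNames(as.numeric(tab$weight), tab$signature)
}

#' Deterministic six-signature synthetic reference set
#'
#' A stand-in signature matrix for experiments that need a handful of
#' well-separated mutational processes: six signatures, each concentrating
#' most of its mass on one block of 16 channels with a smooth triangular
#' shape plus a small uniform floor, giving pairwise cosine similarity
#' below 0.3. These are synthetic constructions, not estimates of any
#' published signature set.
#'
#' @param floor mass spread uniformly over all 96 channels (default 0.1).
#' @return a [signature_matrix()] with six signatures.
#' @export
synthetic_signatures <- function(floor = 0.1) {
  stopifnot(floor >= 0, floor < 1)
  mat <- matrix(floor / 96, nrow = 6L, ncol = 96L)
  shape <- c(1:8, 8:1)
  shape <- shape / sum(shape)
  for (i in 1:6) {
    block <- ((i - 1L) * 16L + 1L):(i * 16L)
    mat[i, block] <- mat[i, block] + (1 - floor) * shape
  }
  signature_matrix(mat, names = paste0("SynthSig", 1:6))
}
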