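# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force sliding-window IUPAC scanning,
# exhaustive simplex grid search for NNLS, and literal interval scans.

IUPAC_SET <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# all-offsets sliding-window scan; subject N never matches. One logical
# vector per pattern position keeps the scan exhaustive yet affordable.
oracle_find_sites <- function(sequence, recognition, cut_offset) {
  s <- strsplit(toupper(sequence), "")[[1]]
  p <- strsplit(toupper(recognition), "")[[1]]
  m <- length(p)
  L <- length(s)
  if (L < m) return(integer(0))
  ok <- rep(TRUE, L - m + 1)
  for (k in seq_len(m)) {
    ok <- ok & s[k:(L - m + k)] %in% IUPAC_SET[[p[k]]]
  }
  which(ok) - 1L + cut_offset
}

# pair adjacent cuts of the pooled sorted cut list
oracle_digest <- function(sequence, enzA, enzB) {
  a <- oracle_find_sites(sequence, enzA$recognition, enzA$cut_offset)
  b <- oracle_find_sites(sequence, enzB$recognition, enzB$cut_offset)
  cuts <- data.frame(pos = c(a, b),
                     enz = c(rep(enzA$name, length(a)),
                             rep(enzB$name, length(b))))
  cuts <- cuts[order(cuts$pos, cuts$enz), , drop = FALSE]
  if (nrow(cuts) < 2) {
    return(data.frame(start = integer(), end = integer(),
                      left = character(), right = character()))
  }
  n <- nrow(cuts)
  out <- data.frame(start = cuts$pos[-n], end = cuts$pos[-1],
                    left = cuts$enz[-n], right = cuts$enz[-1])
  out[out$end > out$start, , drop = FALSE]
}

# all points of the k-simplex at the given step, as a matrix (reusable
# across oracle invocations: the k = 3 grid has ~5e5 rows at step 1e-3)
simplex_grid <- local({
  cache <- list()
  function(k, step) {
    key <- paste(k, step)
    if (!is.null(cache[[key]])) return(cache[[key]])
    grid1 <- seq(0, 1, by = step)
    W <- if (k == 2) {
      cbind(grid1, 1 - grid1)
    } else if (k == 3) {
      ab <- as.matrix(expand.grid(a = grid1, b = grid1))
      ab <- ab[ab[, 1] + ab[, 2] <= 1 + 1e-12, , drop = FALSE]
      cbind(ab, pmax(0, 1 - ab[, 1] - ab[, 2]))
    } else {
      stop("grid oracle supports k in {2, 3}")
    }
    dimnames(W) <- NULL
    cache[[key]] <<- W
    W
  }
})

# exhaustive search over the k-simplex at the given step; returns the best
# grid point for min ||t(S) %*% x - p||
oracle_grid_nnls <- function(S, p, step = 1e-3) {
  k <- nrow(S)
  W <- simplex_grid(k, step)
  # residual^2 = x'Gx - 2 f'x + p'p with G = S S', f = S p
  Gm <- S %*% t(S)
  f <- as.numeric(S %*% p)
  r2 <- rowSums((W %*% Gm) * W) - 2 * as.numeric(W %*% f) + sum(p^2)
  W[which.min(r2), ]
}

random_sequence <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small cohort of signature-mixture SNV sets on a shared synthetic genome
make_cohort <- function(n_samples, n_mutations, seed, genome_length = 60000) {
  sigs <- synthetic_signatures()
  gen <- make_genome(genome_length, seed = seed)
  set.seed(seed + 1)
  snv_sets <- lapply(seq_len(n_samples), function(i) {
    e <- rexp(6)
    e <- e / sum(e)
    sample_mutations(gen$genome, sigs, e, n_mutations, seed = seed + i,
                     sample = paste0("S", i))
  })
  names(snv_sets) <- paste0("S", seq_len(n_samples))
  list(genome = gen$genome, sigs = sigs, snv_sets = snv_sets)
}

clean_metrics <- function(n = 1) {
  data.frame(
    VariantAlleleCount = rep(10, n),
    VariantAlleleCountControl = 0,
    ReadCountControl = 30,
    VariantAlleleFrequency = 0.25,
    VariantMapQualMedian = 60,
    MapQualDiffMedian = 0,
    LowMapQual = 0.01,
    VariantBaseQualMedian = 35,
    VariantStrandBias = 0.5,
    ReferenceStrandBias = 0.5
  )
}
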