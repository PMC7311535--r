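#' Simulation experiments for RR-seq design
#'
#' Two in-silico experiments drive enzyme-pair selection: (1) profile
#' stability under random mutation subsets of increasing size, which shows
#' how many mutations a reduced library must recover; and (2) ranking of
#' enzyme combinations by the cosine similarity between signature profiles
#' refitted from fragment-restricted mutations and the full-set profiles.
#'
#' @name screening
NULL

# full-set reference profile + per-SNV channels for one sample
sample_reference <- function(snvs, genome, sigs) {
  ch <- snv_channels(snvs, genome)
  ch <- ch[!is.na(ch)]
  profile <- if (length(ch)) {
    fit_exposures(tabulate(ch, nbins = 96L), sigs)
  } else NULL
  list(channels = as.integer(ch), profile = profile)
}

#' Profile stability under random mutation subsets
#'
#' For each sample, refits the signature profile from random subsets of its
#' mutations (without replacement) at each subset size, and records the
#' cosine similarity to the profile refitted from the full mutation set. A
#' sample contributes to a given size only if it has at least that many
#' usable mutations.
#'
#' @param snv_sets named list of per-sample SNV data.frames.
#' @param genome genome sequences.
#' @param sigs a [signature_matrix()].
#' @param sizes increasing vector of subset sizes.
#' @param replicates subsamples per (sample, size); default 10.
#' @param seed integer seed making the whole experiment reproducible.
#' @return object of class `"stability_curve"`: a data.frame with columns
#'   `sample`, `size`, `replicate`, `cosine`, plus attribute
#'   `contributing` — a sample x size logical matrix of who had enough
#'   mutations.
#' @export
stability_experiment <- function(snv_sets, genome, sigs, sizes,
                                 replicates = 10L, seed = NULL) {
  stopifnot(length(snv_sets) >= 1L, !is.null(names(snv_sets)),
            all(diff(as.numeric(sizes)) >= 0))
  refs <- lapply(snv_sets, sample_reference, genome = genome, sigs = sigs)
  contributing <- matrix(
    FALSE, nrow = length(snv_sets), ncol = length(sizes),
    dimnames = list(names(snv_sets), as.character(sizes))
  )
  rows <- with_seed(seed, {
    out <- vector("list", length(snv_sets) * length(sizes))
    k <- 0L
    for (s in names(snv_sets)) {
      ch <- refs[[s]]$channels
      ref <- refs[[s]]$profile
      if (is.null(ref)) next
      for (j in seq_along(sizes)) {
        n <- sizes[j]
        if (length(ch) < n) next  # not enough mutations: excluded
        contributing[s, j] <- TRUE
        cosims <- vapply(seq_len(replicates), function(r) {
          sub <- if (n == length(ch)) ch else ch[sample.int(length(ch), n)]
          cosine_similarity(fit_exposures(tabulate(sub, nbins = 96L), sigs),
                            ref)
        }, numeric(1))
        k <- k + 1L
        out[[k]] <- data.frame(
          sample = s, size = n, replicate = seq_len(replicates),
          cosine = cosims, stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out[seq_len(k)])
  })
  if (is.null(rows)) {
    rows <- data.frame(sample = character(), size = numeric(),
                       replicate = integer(), cosine = numeric(),
                       stringsAsFactors = FALSE)
  }
  structure(rows, contributing = contributing, class = c("stability_curve",
                                                         "data.frame"))
}

#' Per-size summary of a stability curve
#' @param object a `"stability_curve"`.
#' @param ... unused.
#' @return data.frame with per-size mean/sd cosine and contributing-sample
#'   count.
#' @export
summary.stability_curve <- function(object, ...) {
  df <- as.data.frame(object)
  sizes <- sort(unique(df$size))
  data.frame(
    size = sizes,
    mean_cosine = vapply(sizes, function(n) mean(df$cosine[df$size == n]),
                         numeric(1)),
    sd_cosine = vapply(sizes, function(n) stats::sd(df$cosine[df$size == n]),
                       numeric(1)),
    n_samples = vapply(sizes, function(n)
      length(unique(df$sample[df$size == n])), integer(1))
  )
}

#' Plot a stability curve
#'
#' Simple mean +/- sd display of cosine similarity against subset size.
#'
#' @param curve a `"stability_curve"`.
#' @return a ggplot object.
#' @export
plot_stability_curve <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_stability_curve requires ggplot2")
  }
  s <- summary(curve)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$size, y = .data$mean_cosine)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$mean_cosine - .data$sd_cosine),
      ymax = pmin(1, .data$mean_cosine + .data$sd_cosine))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mutations in subset",
                  y = "cosine similarity to full-set profile")
}

as_enzyme_pairs <- function(enzyme_pairs) {
  if (is.data.frame(enzyme_pairs)) {
    stopifnot(all(c("enzyme_a", "enzyme_b") %in% names(enzyme_pairs)))
    enzyme_pairs <- Map(c, enzyme_pairs$enzyme_a, enzyme_pairs$enzyme_b)
  }
  if (!is.list(enzyme_pairs)) enzyme_pairs <- list(enzyme_pairs)
  lapply(enzyme_pairs, function(p) {
    stopifnot(length(p) == 2L)
    p
  })
}

#' Screen enzyme combinations for signature recovery
#'
#' For each enzyme pair: digest the genome, size-select, restrict each
#' sample's mutations to the retained fragments, refit the signature
#' profile, and compare to the full-set profile by cosine similarity.
#' Pairs retaining no fragments are reported with zero yield and flagged
#' (`flagged = TRUE`, similarity `NA`), never averaged; likewise samples
#' whose restricted spectrum is empty are excluded from that pair's mean
#' and counted in `n_samples_flagged`.
#'
#' @param genome genome sequences.
#' @param snv_sets named list of per-sample SNV data.frames.
#' @param sigs a [signature_matrix()].
#' @param enzyme_pairs list of 2-vectors of enzyme names/objects, or a
#'   data.frame with columns `enzyme_a`, `enzyme_b`.
#' @param min_len,max_len size-selection window in bp (default 350–450).
#' @return data.frame, one row per pair: `enzyme_a`, `enzyme_b`,
#'   `n_fragments`, `covered_bp`, `mean_cosine`, `sd_cosine`,
#'   `mean_mutations`, `n_samples_used`, `n_samples_flagged`, `flagged`.
#' @export
screen_combinations <- function(genome, snv_sets, sigs, enzyme_pairs,
                                min_len = 350L, max_len = 450L) {
  pairs <- as_enzyme_pairs(enzyme_pairs)
  stopifnot(length(pairs) >= 1L)
  g <- as_genome(genome)
  refs <- lapply(snv_sets, sample_reference, genome = g, sigs = sigs)
  catalog <- enzyme_catalog()
  rows <- lapply(pairs, function(pair) {
    ea <- as_enzyme(pair[[1]], catalog)
    eb <- as_enzyme(pair[[2]], catalog)
    frags <- size_select(digest_genome(g, ea, eb),
                         min_len = min_len, max_len = max_len)
    base <- data.frame(
      enzyme_a = ea$name, enzyme_b = eb$name,
      n_fragments = nrow(frags),
      covered_bp = sum(frags$length),
      stringsAsFactors = FALSE
    )
    if (nrow(frags) == 0L) {
      return(cbind(base, mean_cosine = NA_real_, sd_cosine = NA_real_,
                   mean_mutations = 0, n_samples_used = 0L,
                   n_samples_flagged = length(snv_sets), flagged = TRUE))
    }
    per_sample <- lapply(names(snv_sets), function(s) {
      if (is.null(refs[[s]]$profile)) return(c(NA_real_, 0))
      spec <- build_spectrum(snv_sets[[s]], g, regions = frags)
      if (attr(spec, "total") == 0L) return(c(NA_real_, 0))
      c(cosine_similarity(fit_exposures(spec, sigs), refs[[s]]$profile),
        attr(spec, "total"))
    })
    cosims <- vapply(per_sample, `[[`, numeric(1), 1L)
    yields <- vapply(per_sample, `[[`, numeric(1), 2L)
    used <- !is.na(cosims)
    cbind(base,
          mean_cosine = if (any(used)) mean(cosims[used]) else NA_real_,
          sd_cosine = if (sum(used) > 1L) stats::sd(cosims[used]) else NA_real_,
          mean_mutations = mean(yields),
          n_samples_used = sum(used),
          n_samples_flagged = sum(!used),
          flagged = !any(used))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Target-region restriction experiment
#'
#' Generic version of the enzyme screen for fixed target regions (e.g.
#' exome capture designs supplied as BED): restricts each sample's
#' mutations to the regions, refits, and reports the per-sample cosine
#' similarity to the full-set profile. Samples whose restricted spectrum is
#' empty are flagged with `NA` similarity.
#'
#' @param snv_sets named list of per-sample SNV data.frames.
#' @param regions fragment data.frame, BED path, or `GRanges`.
#' @param genome genome sequences.
#' @param sigs a [signature_matrix()].
#' @return data.frame with columns `sample`, `n_mutations`, `cosine`,
#'   `flagged`.
#' @export
region_restrict_experiment <- function(snv_sets, regions, genome, sigs) {
  g <- as_genome(genome)
  gr <- as_region_granges(regions)
  rows <- lapply(names(snv_sets), function(s) {
    ref <- sample_reference(snv_sets[[s]], g, sigs)
    spec <- build_spectrum(snv_sets[[s]], g, regions = gr)
    if (is.null(ref$profile) || attr(spec, "total") == 0L) {
      return(data.frame(sample = s, n_mutations = attr(spec, "total"),
                        cosine = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    data.frame(
      sample = s,
      n_mutations = attr(spec, "total"),
      cosine = cosine_similarity(fit_exposures(spec, sigs), ref$profile),
      flagged = FALSE, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
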