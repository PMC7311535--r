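#' Somatic-variant filtering
#'
#' Post-calling filter for somatic SNVs. Each rule below is a REJECTION
#' trigger — a record is removed as soon as any rule fires — applied to
#' per-variant quality metrics computed upstream by the caller:
#'
#' * `VariantAlleleCountControl > 1` (germline leakage / contamination)
#' * `VariantMapQualMedian < 40` (poorly mapped variant reads)
#' * `MapQualDiffMedian < -5` or `> 5` (mapping-quality imbalance
#'   between variant and reference reads)
#' * `LowMapQual > 0.05` (excess ambiguously mapped reads at the locus)
#' * `VariantBaseQualMedian < 30` (low base quality on the variant allele)
#' * `VariantAlleleCount >= 7 & VariantStrandBias < 0.05 &
#'   ReferenceStrandBias >= 0.2` (well-supported call whose variant reads
#'   are nonetheless confined to one strand while reference reads are not)
#' * `ReadCountControl < min_control_depth` (not enough normal coverage to
#'   establish somatic status)
#' * `VariantAlleleCount < min_variant_reads`
#' * `VariantAlleleFrequency < min_vaf`
#'
#' Inequalities are strict or inclusive exactly as written. The last three
#' thresholds are cohort-specific and carried by a [filter_profile()].
#'
#' @name variant_filter
NULL

VARIANT_METRICS <- c(
  "VariantAlleleCount", "VariantAlleleCountControl", "ReadCountControl",
  "VariantAlleleFrequency", "VariantMapQualMedian", "MapQualDiffMedian",
  "LowMapQual", "VariantBaseQualMedian", "VariantStrandBias",
  "ReferenceStrandBias"
)

FILTER_PRESETS <- list(
  mutread_ff   = c(min_variant_reads = 5,  min_vaf = 0.03),
  wes          = c(min_variant_reads = 7,  min_vaf = 0.01),
  swgs10x      = c(min_variant_reads = 5,  min_vaf = 0.11),
  mutread_ffpe = c(min_variant_reads = 10, min_vaf = 0.13),
  strelka_ff   = c(min_variant_reads = 20, min_vaf = 0.11),
  strelka_ffpe = c(min_variant_reads = 11, min_vaf = 0.03)
)

#' Cohort-specific filter thresholds
#'
#' Named presets bundle the minimum variant-supporting read count and
#' minimum VAF tuned per library type and caller: `mutread_ff` (5, 0.03),
#' `wes` (7, 0.01), `swgs10x` (5, 0.11), `mutread_ffpe` (10, 0.13),
#' `strelka_ff` (20, 0.11), `strelka_ffpe` (11, 0.03). The control-depth
#' requirement is a cohort-level setting — 20 for matched fresh-frozen/FFPE
#' trios, 10 for lower-coverage FFPE-only cohorts — and defaults to 20.
#'
#' @param preset one of the preset names above, or `NULL` to set thresholds
#'   directly.
#' @param min_variant_reads,min_vaf,min_control_depth explicit thresholds;
#'   override the preset values when given.
#' @return object of class `"filter_profile"`.
#' @examples
#' filter_profile("mutread_ffpe")
#' filter_profile("mutread_ffpe", min_control_depth = 10)
#' @export
filter_profile <- function(preset = NULL, min_variant_reads = NULL,
                           min_vaf = NULL, min_control_depth = NULL) {
  if (!is.null(preset)) {
    if (!preset %in% names(FILTER_PRESETS)) {
      stop("unknown filter preset '", preset, "'; available: ",
           paste(names(FILTER_PRESETS), collapse = ", "))
    }
    vals <- FILTER_PRESETS[[preset]]
    if (is.null(min_variant_reads)) min_variant_reads <- vals[["min_variant_reads"]]
    if (is.null(min_vaf)) min_vaf <- vals[["min_vaf"]]
  }
  if (is.null(min_variant_reads) || is.null(min_vaf)) {
    stop("supply a preset or both min_variant_reads and min_vaf")
  }
  if (is.null(min_control_depth)) min_control_depth <- 20
  structure(
    list(preset = if (is.null(preset)) NA_character_ else preset,
         min_variant_reads = as.numeric(min_variant_reads),
         min_vaf = as.numeric(min_vaf),
         min_control_depth = as.numeric(min_control_depth)),
    class = "filter_profile"
  )
}

#' @export
print.filter_profile <- function(x, ...) {
  cat(sprintf(
    "<filter_profile> %s: >=%g variant reads, VAF >= %g, control depth >= %g\n",
    ifelse(is.na(x$preset), "custom", x$preset),
    x$min_variant_reads, x$min_vaf, x$min_control_depth))
  invisible(x)
}

# each rule: fires(record) -> TRUE means REJECT; NA metrics handled upstream
filter_rules <- function(profile) {
  list(
    VariantAlleleCountControl = function(m)
      m[["VariantAlleleCountControl"]] > 1,
    VariantMapQualMedian = function(m) m[["VariantMapQualMedian"]] < 40.0,
    MapQualDiffMedian = function(m)
      m[["MapQualDiffMedian"]] < -5.0 | m[["MapQualDiffMedian"]] > 5.0,
    LowMapQual = function(m) m[["LowMapQual"]] > 0.05,
    VariantBaseQualMedian = function(m) m[["VariantBaseQualMedian"]] < 30.0,
    StrandBias = function(m)
      m[["VariantAlleleCount"]] >= 7 & m[["VariantStrandBias"]] < 0.05 &
        m[["ReferenceStrandBias"]] >= 0.2,
    ReadCountControl = function(m)
      m[["ReadCountControl"]] < profile$min_control_depth,
    MinVariantReads = function(m)
      m[["VariantAlleleCount"]] < profile$min_variant_reads,
    MinVAF = function(m)
      m[["VariantAlleleFrequency"]] < profile$min_vaf
  )
}

#' Apply the somatic filter ledger to one variant record
#'
#' Evaluates every rejection rule (see [variant_filter]) and returns the
#' verdict with the names of all rules that fired. A metric referenced by a
#' rule but missing (`NA` or absent) fails the record conservatively with
#' rule `"missing_metric"`.
#'
#' @param record a one-row data.frame or named list/vector carrying the
#'   metric fields (`VariantAlleleCount`, `VariantAlleleCountControl`,
#'   `ReadCountControl`, `VariantAlleleFrequency`, `VariantMapQualMedian`,
#'   `MapQualDiffMedian`, `LowMapQual`, `VariantBaseQualMedian`,
#'   `VariantStrandBias`, `ReferenceStrandBias`).
#' @param profile a [filter_profile()] or preset name.
#' @return list with `pass` (logical) and `fired` (character vector of rule
#'   names, empty when passing).
#' @export
apply_filters <- function(record, profile) {
  if (is.character(profile)) profile <- filter_profile(profile)
  stopifnot(inherits(profile, "filter_profile"))
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  m <- lapply(setNames(VARIANT_METRICS, VARIANT_METRICS), function(f) {
    v <- record[[f]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  })
  fired <- character()
  if (anyNA(unlist(m))) fired <- "missing_metric"
  for (rule in names(rules <- filter_rules(profile))) {
    hit <- rules[[rule]](m)
    if (isTRUE(hit)) fired <- c(fired, rule)
  }
  list(pass = length(fired) == 0L, fired = fired)
}

#' Filter a table of variant records
#'
#' Vectorized application of [apply_filters()] to a record table, with an
#' optional column mapping for inputs whose metric columns are named
#' differently. Input order is preserved; a record failing several rules is
#' removed once but counted in each rule's tally.
#'
#' @param records data.frame of variant records (typically `contig`, `pos`,
#'   `ref`, `alt` plus the metric columns).
#' @param profile a [filter_profile()] or preset name.
#' @param metric_map optional named character vector mapping metric names
#'   to column names in `records`, e.g. `c(VariantAlleleCount = "t_alt_count")`.
#' @return list with `pass` (passing records), `fail` (rejected records
#'   with a `fired_rules` column), `verdict` (logical per input row) and
#'   `rule_counts` (named integer vector).
#' @export
filter_variants <- function(records, profile, metric_map = NULL) {
  if (is.character(profile)) profile <- filter_profile(profile)
  stopifnot(is.data.frame(records))
  work <- records
  if (!is.null(metric_map)) {
    for (metric in names(metric_map)) {
      col <- metric_map[[metric]]
      if (!col %in% names(records)) {
        stop("metric_map points '", metric, "' at missing column '", col, "'")
      }
      work[[metric]] <- records[[col]]
    }
  }
  rules <- filter_rules(profile)
  all_rules <- c("missing_metric", names(rules))
  rule_counts <- setNames(integer(length(all_rules)), all_rules)
  n <- nrow(records)
  verdict <- logical(n)
  fired_rules <- character(n)
  if (n) {
    m <- lapply(setNames(VARIANT_METRICS, VARIANT_METRICS), function(f) {
      if (f %in% names(work)) as.numeric(work[[f]]) else rep(NA_real_, n)
    })
    missing <- Reduce(`|`, lapply(m, is.na))
    fired <- matrix(FALSE, nrow = n, ncol = length(rules),
                    dimnames = list(NULL, names(rules)))
    for (rule in names(rules)) {
      hit <- rules[[rule]](m)
      fired[, rule] <- !is.na(hit) & hit
    }
    fired <- cbind(missing_metric = missing, fired)
    rule_counts <- colSums(fired)
    verdict <- rowSums(fired) == 0L
    fired_rules <- apply(fired, 1L, function(row)
      paste(colnames(fired)[row], collapse = ";"))
  }
  fail <- records[!verdict, , drop = FALSE]
  if (nrow(fail)) fail$fired_rules <- fired_rules[!verdict]
  list(
    pass = records[verdict, , drop = FALSE],
    fail = fail,
    verdict = verdict,
    rule_counts = rule_counts
  )
}

#' Filter a VCF file on INFO-encoded metrics
#'
#' Reads a VCF whose INFO field carries the filter metrics (under the
#' metric names themselves or via `metric_map`), applies
#' [filter_variants()], and writes a VCF in which the FILTER column of
#' rejected records lists the fired rule names (`PASS` otherwise).
#'
#' @param path input VCF path.
#' @param profile a [filter_profile()] or preset name.
#' @param out output VCF path, or `NULL` to skip writing.
#' @param metric_map optional named character vector mapping metric names
#'   to INFO keys.
#' @return the [filter_variants()] result, with the parsed records attached
#'   as attribute `"records"`.
#' @export
filter_vcf <- function(path, profile, out = NULL, metric_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  records <- data.frame(
    contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]) - 1L,
    ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )[seq_len(n), , drop = FALSE]
  keys <- setNames(VARIANT_METRICS, VARIANT_METRICS)
  if (!is.null(metric_map)) keys[names(metric_map)] <- metric_map
  info <- if (n) fix[, "INFO"] else character()
  for (metric in names(keys)) {
    pat <- paste0("(?:^|;)", keys[[metric]], "=([^;]+)")
    hit <- regmatches(info, regexec(pat, info))
    records[[metric]] <- vapply(hit, function(h)
      if (length(h) == 2L) as.numeric(h[2L]) else NA_real_, numeric(1))
  }
  res <- filter_variants(records, profile)
  if (!is.null(out)) {
    fired_full <- character(n)
    if (any(!res$verdict)) fired_full[!res$verdict] <- res$fail$fired_rules
    filt <- ifelse(res$verdict, "PASS", gsub(";", ",", fired_full))
    meta <- v@meta
    if (!any(grepl("^##fileformat", meta))) {
      meta <- c("##fileformat=VCFv4.2", meta)
    }
    body <- if (n) {
      paste(fix[, "CHROM"], fix[, "POS"],
            ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
            fix[, "REF"], fix[, "ALT"],
            ifelse(is.na(fix[, "QUAL"]), ".", fix[, "QUAL"]),
            filt, fix[, "INFO"], sep = "\t")
    } else character()
    writeLines(c(meta, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", body),
               out)
  }
  attr(res, "records") <- records
  res
}
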