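test_that("presets carry the published thresholds", {
  expect_equal(filter_profile("mutread_ff")$min_variant_reads, 5)
  expect_equal(filter_profile("mutread_ff")$min_vaf, 0.03)
  expect_equal(filter_profile("wes")$min_variant_reads, 7)
  expect_equal(filter_profile("wes")$min_vaf, 0.01)
  expect_equal(filter_profile("swgs10x")$min_variant_reads, 5)
  expect_equal(filter_profile("swgs10x")$min_vaf, 0.11)
  expect_equal(filter_profile("mutread_ffpe")$min_variant_reads, 10)
  expect_equal(filter_profile("mutread_ffpe")$min_vaf, 0.13)
  expect_equal(filter_profile("strelka_ff")$min_variant_reads, 20)
  expect_equal(filter_profile("strelka_ff")$min_vaf, 0.11)
  expect_equal(filter_profile("strelka_ffpe")$min_variant_reads, 11)
  expect_equal(filter_profile("strelka_ffpe")$min_vaf, 0.03)
  expect_equal(filter_profile("mutread_ff")$min_control_depth, 20)
  expect_equal(filter_profile("mutread_ffpe",
                              min_control_depth = 10)$min_control_depth, 10)
  expect_error(filter_profile("nope"), "unknown filter preset")
})

test_that("every rejection rule fires at its boundary exactly as written", {
  # generous profile so only the rule under test can fire
  prof <- filter_profile(min_variant_reads = 0, min_vaf = 0,
                         min_control_depth = 0)
  check <- function(field, value, should_fire, rule = field) {
    m <- clean_metrics()
    m[[field]] <- value
    res <- apply_filters(m, prof)
    if (should_fire) {
      expect_true(rule %in% res$fired,
                  label = paste0(field, "=", value, " fires ", rule))
      expect_false(res$pass)
    } else {
      expect_false(rule %in% res$fired,
                   label = paste0(field, "=", value, " does not fire ", rule))
    }
  }
  # VariantAlleleCountControl > 1 (strict)
  check("VariantAlleleCountControl", 1, FALSE)
  check("VariantAlleleCountControl", 2, TRUE)
  # VariantMapQualMedian < 40 (strict)
  check("VariantMapQualMedian", 40, FALSE)
  check("VariantMapQualMedian", 39.9, TRUE)
  # MapQualDiffMedian < -5 or > 5 (strict both sides)
  check("MapQualDiffMedian", -5, FALSE)
  check("MapQualDiffMedian", -5.1, TRUE)
  check("MapQualDiffMedian", 5, FALSE)
  check("MapQualDiffMedian", 5.1, TRUE)
  # LowMapQual > 0.05 (strict)
  check("LowMapQual", 0.05, FALSE)
  check("LowMapQual", 0.051, TRUE)
  # VariantBaseQualMedian < 30 (strict)
  check("VariantBaseQualMedian", 30, FALSE)
  check("VariantBaseQualMedian", 29.9, TRUE)
})

test_that("the strand-bias compound needs all three clauses", {
  prof <- filter_profile(min_variant_reads = 0, min_vaf = 0,
                         min_control_depth = 0)
  at <- function(vac, vsb, rsb) {
    m <- clean_metrics()
    m$VariantAlleleCount <- vac
    m$VariantStrandBias <- vsb
    m$ReferenceStrandBias <- rsb
    "StrandBias" %in% apply_filters(m, prof)$fired
  }
  expect_true(at(7, 0.04, 0.2))    # >= 7, < 0.05, >= 0.2: fires
  expect_false(at(6, 0.04, 0.2))   # count below 7
  expect_false(at(7, 0.05, 0.2))   # strand bias not strictly below 0.05
  expect_false(at(7, 0.04, 0.19))  # reference strand bias below 0.2
  expect_true(at(100, 0.0, 0.9))
})

test_that("profile thresholds reject at their boundaries for every preset", {
  presets <- list(
    mutread_ff = c(5, 0.03), wes = c(7, 0.01), swgs10x = c(5, 0.11),
    mutread_ffpe = c(10, 0.13), strelka_ff = c(20, 0.11),
    strelka_ffpe = c(11, 0.03)
  )
  for (nm in names(presets)) {
    reads <- presets[[nm]][1]
    vaf <- presets[[nm]][2]
    prof <- filter_profile(nm)
    m <- clean_metrics()
    m$VariantAlleleCount <- reads
    m$VariantAlleleFrequency <- vaf
    expect_true(apply_filters(m, prof)$pass, label = paste(nm, "at boundary"))
    m$VariantAlleleCount <- reads - 1
    expect_true("MinVariantReads" %in% apply_filters(m, prof)$fired,
                label = paste(nm, "one read short"))
    m$VariantAlleleCount <- reads
    m$VariantAlleleFrequency <- vaf - 0.001
    expect_true("MinVAF" %in% apply_filters(m, prof)$fired,
                label = paste(nm, "VAF below threshold"))
    # control depth boundary
    m <- clean_metrics()
    m$VariantAlleleCount <- max(reads, 10)
    m$VariantAlleleFrequency <- max(vaf, 0.2)
    m$ReadCountControl <- 20
    expect_true(apply_filters(m, prof)$pass)
    m$ReadCountControl <- 19
    expect_true("ReadCountControl" %in% apply_filters(m, prof)$fired)
    expect_false("ReadCountControl" %in% apply_filters(
      m, filter_profile(nm, min_control_depth = 10))$fired)
  }
})

test_that("missing metrics fail conservatively", {
  m <- clean_metrics()
  m$LowMapQual <- NULL
  res <- apply_filters(m, "mutread_ff")
  expect_false(res$pass)
  expect_true("missing_metric" %in% res$fired)
})

test_that("filtering is stateless, order-preserving, and counts fired rules", {
  set.seed(200)
  n <- 60
  rec <- clean_metrics(n)
  rec$contig <- "chr1"
  rec$pos <- seq_len(n)
  # plant three artifact classes beyond thresholds
  germline <- 1:10
  strand <- 11:20
  lowq <- 21:30
  rec$VariantAlleleCountControl[germline] <- 5
  rec$VariantStrandBias[strand] <- 0.01
  rec$ReferenceStrandBias[strand] <- 0.5
  rec$VariantBaseQualMedian[lowq] <- 20
  res <- filter_variants(rec, "mutread_ff")
  expect_equal(which(!res$verdict), 1:30)
  expect_equal(nrow(res$pass), 30L)
  expect_equal(unname(res$rule_counts["VariantAlleleCountControl"]), 10)
  expect_equal(unname(res$rule_counts["StrandBias"]), 10)
  expect_equal(unname(res$rule_counts["VariantBaseQualMedian"]), 10)
  # per-record results agree with the vectorized path
  for (i in c(1, 11, 21, 31)) {
    expect_equal(apply_filters(rec[i, ], filter_profile("mutread_ff"))$pass,
                 res$verdict[i])
  }
  # a record failing two rules is removed once, counted twice
  rec2 <- clean_metrics(1)
  rec2$VariantAlleleCountControl <- 3
  rec2$VariantBaseQualMedian <- 10
  res2 <- filter_variants(rec2, "mutread_ff")
  expect_equal(nrow(res2$fail), 1L)
  expect_equal(sum(res2$rule_counts), 2)
  expect_match(res2$fail$fired_rules, "VariantAlleleCountControl")
  expect_match(res2$fail$fired_rules, "VariantBaseQualMedian")
})

test_that("tightening any threshold never admits more records", {
  set.seed(201)
  n <- 1000
  rec <- data.frame(
    VariantAlleleCount = rpois(n, 12),
    VariantAlleleCountControl = rpois(n, 0.7),
    ReadCountControl = rpois(n, 30),
    VariantAlleleFrequency = runif(n),
    VariantMapQualMedian = runif(n, 20, 60),
    MapQualDiffMedian = rnorm(n, 0, 4),
    LowMapQual = runif(n, 0, 0.1),
    VariantBaseQualMedian = runif(n, 20, 40),
    VariantStrandBias = runif(n),
    ReferenceStrandBias = runif(n)
  )
  base <- filter_profile(min_variant_reads = 5, min_vaf = 0.03,
                         min_control_depth = 20)
  n_base <- nrow(filter_variants(rec, base)$pass)
  for (tighter in list(
    filter_profile(min_variant_reads = 8, min_vaf = 0.03, min_control_depth = 20),
    filter_profile(min_variant_reads = 5, min_vaf = 0.11, min_control_depth = 20),
    filter_profile(min_variant_reads = 5, min_vaf = 0.03, min_control_depth = 35)
  )) {
    expect_lte(nrow(filter_variants(rec, tighter)$pass), n_base)
  }
})

test_that("metric mapping and VCF filtering annotate fired rules", {
  rec <- clean_metrics(2)
  names(rec)[names(rec) == "VariantAlleleCount"] <- "t_alt_count"
  rec$t_alt_count[2] <- 1
  res <- filter_variants(rec, "mutread_ff",
                         metric_map = c(VariantAlleleCount = "t_alt_count"))
  expect_equal(res$verdict, c(TRUE, FALSE))
  expect_error(
    filter_variants(rec, "mutread_ff",
                    metric_map = c(VariantAlleleCount = "no_such")),
    "missing column"
  )

  # VCF with INFO-encoded metrics
  m <- clean_metrics(1)
  info_ok <- paste(paste0(names(m), "=", unlist(m)), collapse = ";")
  m_bad <- m
  m_bad$VariantAlleleCountControl <- 4
  info_bad <- paste(paste0(names(m_bad), "=", unlist(m_bad)), collapse = ";")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chr1\t100\t.\tC\tT\t.\t.\t", info_ok),
    paste0("chr1\t200\t.\tG\tA\t.\t.\t", info_bad)
  ), path)
  out <- withr::local_tempfile(fileext = ".vcf")
  res <- filter_vcf(path, "mutread_ff", out = out)
  expect_equal(res$verdict, c(TRUE, FALSE))
  lines <- readLines(out)
  body <- lines[!startsWith(lines, "#")]
  expect_match(body[1], "\tPASS\t")
  expect_match(body[2], "VariantAlleleCountControl")
})
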