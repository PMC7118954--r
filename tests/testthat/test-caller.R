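caller_scene <- function(seed = 81, end = 3000L) {
  regions <- tibble::tibble(chrom = "chr1", start = 1000L, end = end)
  set.seed(seed)
  ref <- random_reference(c(chr1 = end + 300L))
  list(regions = regions, ref = ref)
}

test_that("an error-free sample yields zero candidates and zero calls", {
  sc <- caller_scene(81)
  cfg <- sim_config(seed = 81, regions = sc$regions, reference = sc$ref,
                    templates_per_site = 150, error_rate = 0)
  sim <- simulate_sample(cfg)
  res <- call_sample(sim$fragments, sc$regions, sc$ref)
  expect_equal(nrow(res$calls), 0L)
  aud <- res$audit
  expect_equal(aud$n_candidates[aud$stage == "virtual_barcode"], 0L)
  # audit counts never increase along the filter chain
  chain <- aud$n_candidates[aud$stage != "raw_pileup"]
  expect_true(all(diff(chain) <= 0))
})

test_that("a clean 5% spike is called exactly, with a faithful VCF", {
  sc <- caller_scene(82)
  spos <- 1999L
  alt <- setdiff(BASES, ref_base(sc$ref, "chr1", spos))[1]
  cfg <- sim_config(seed = 82, regions = sc$regions, reference = sc$ref,
                    templates_per_site = 300, error_rate = 0,
                    spiked = tibble::tibble(chrom = "chr1", pos = spos,
                                            alt = alt, af = 0.05))
  sim <- simulate_sample(cfg)
  res <- call_sample(sim$fragments, sc$regions, sc$ref,
                     sample_name = "spike5")
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$pos, spos)
  expect_equal(res$calls$alt, alt)
  expect_lt(abs(res$calls$af - 0.05), 0.03)
  ev <- truth_evaluate(res, sim)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$fp, 0L)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(res, vcf, reference = sc$ref)
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 1L)
  f <- strsplit(body, "\t")[[1]]
  expect_equal(as.integer(f[2]), spos + 1L)  # 1-based POS
  expect_equal(f[4], ref_base(sc$ref, "chr1", spos))
  expect_equal(f[5], alt)
  expect_equal(f[7], "PASS")
  skip_if_not_installed("VariantAnnotation")
  v <- VariantAnnotation::readVcf(vcf)
  expect_equal(BiocGenerics::start(SummarizedExperiment::rowRanges(v)),
               spos + 1L)
  expect_equal(unname(unlist(VariantAnnotation::info(v)$NF)),
               res$calls$n_families)
  expect_equal(unname(unlist(VariantAnnotation::info(v)$NS)),
               res$calls$n_singletons)
  expect_equal(as.numeric(unlist(VariantAnnotation::info(v)$AF)),
               res$calls$af, tolerance = 1e-5)
})

test_that("a stereotypical-only sample is cleared at the polishing stage", {
  sc <- caller_scene(83)
  pos <- c(1500L, 2200L)
  alt <- vapply(pos, function(p) {
    setdiff(BASES, ref_base(sc$ref, "chr1", p))[1]
  }, "")
  stereo <- tibble::tibble(chrom = "chr1", pos = pos, alt = alt,
                           presence = 1, meanlog = log(0.03), sdlog = 0.25)
  base_cfg <- sim_config(seed = 8300, regions = sc$regions,
                         reference = sc$ref, templates_per_site = 400,
                         error_rate = 0, stereotypical = stereo)
  cohort <- simulate_background_cohort(base_cfg, 10)
  pups <- lapply(cohort, function(s) {
    build_pileups(s$fragments, sc$ref, sc$regions)
  })
  db <- suppressWarnings(build_background_db(pups))
  expect_equal(sort(db$sites$pos), sort(pos))

  test_cfg <- sim_config(seed = 8399, regions = sc$regions,
                         reference = sc$ref, templates_per_site = 400,
                         error_rate = 0, stereotypical = stereo)
  sim <- simulate_sample(test_cfg)
  res <- call_sample(sim$fragments, sc$regions, sc$ref, db = db)
  expect_equal(nrow(res$calls), 0L)
  aud <- res$audit
  expect_gte(aud$n_candidates[aud$stage == "blacklist"], 2L)
  expect_equal(aud$n_candidates[aud$stage == "polishing"], 0L)
})

test_that("blacklisted candidates are removed before polishing", {
  sc <- caller_scene(84)
  spos <- 1500L
  alt <- setdiff(BASES, ref_base(sc$ref, "chr1", spos))[1]
  cfg <- sim_config(seed = 84, regions = sc$regions, reference = sc$ref,
                    templates_per_site = 300, error_rate = 0,
                    spiked = tibble::tibble(chrom = "chr1", pos = spos,
                                            alt = alt, af = 0.05))
  sim <- simulate_sample(cfg)
  bl <- tibble::tibble(chrom = "chr1", start = 1400L, end = 1501L)
  res <- call_sample(sim$fragments, sc$regions, sc$ref, blacklist = bl)
  expect_equal(nrow(res$calls), 0L)
  # half-open: a blacklist ending exactly at the site leaves it alone
  bl2 <- tibble::tibble(chrom = "chr1", start = 1400L, end = 1500L)
  res2 <- call_sample(sim$fragments, sc$regions, sc$ref, blacklist = bl2)
  expect_equal(nrow(res2$calls), 1L)
})

test_that("calling is bit-identical across reruns", {
  sc <- caller_scene(85)
  spos <- 1700L
  alt <- setdiff(BASES, ref_base(sc$ref, "chr1", spos))[1]
  cfg <- sim_config(seed = 85, regions = sc$regions, reference = sc$ref,
                    templates_per_site = 250, error_rate = 0.002,
                    spiked = tibble::tibble(chrom = "chr1", pos = spos,
                                            alt = alt, af = 0.05))
  sim <- simulate_sample(cfg)
  r1 <- call_sample(sim$fragments, sc$regions, sc$ref)
  r2 <- call_sample(sim$fragments, sc$regions, sc$ref)
  expect_identical(r1$calls, r2$calls)
  expect_identical(r1$audit, r2$audit)
  expect_identical(r1$stats, r2$stats)
})

test_that("a panel/database chromosome mismatch is rejected", {
  sc <- caller_scene(86)
  db <- structure(list(panel = "p", n_background_samples = 10L,
                       candidates = candidate_distributions(),
                       confidence = 0.99, min_occurrence = 6L,
                       background_template_rate = 1e-5,
                       sites = tibble::tibble(
                         chrom = "chr9", pos = 1L, ref = "C", alt = "T",
                         occurrence = 6L, n_af = 6L, dist_name = "empirical",
                         params = list(numeric()), af_cutoff = 0.01)),
                  class = "vb_background_db")
  cfg <- sim_config(seed = 86, regions = sc$regions, reference = sc$ref,
                    templates_per_site = 50, error_rate = 0)
  sim <- simulate_sample(cfg)
  expect_error(call_sample(sim$fragments, sc$regions, sc$ref, db = db),
               "mismatch")
})

test_that("unsorted calls are refused by the VCF writer; empty VCF is valid", {
  calls <- tibble::tibble(chrom = "chr1", pos = c(200L, 100L),
                          ref = "A", alt = "T", af = 0.1,
                          n_families = 3L, n_singletons = 1L,
                          total_templates = 100L, depth = 500L, ffr = 0,
                          singleton_ratio = 0.3, k_min = 2L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  expect_error(write_vcf(calls, vcf), "sorted")
  empty <- calls[0, ]
  write_vcf(empty, vcf)
  lines <- readLines(vcf)
  expect_true(all(startsWith(lines, "#")))
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
})

test_that("tidy, glance and autoplot expose the result surface", {
  sc <- caller_scene(87)
  cfg <- sim_config(seed = 87, regions = sc$regions, reference = sc$ref,
                    templates_per_site = 100, error_rate = 0)
  sim <- simulate_sample(cfg)
  res <- call_sample(sim$fragments, sc$regions, sc$ref, sample_name = "s1")
  expect_identical(tidy(res), res$calls)
  g <- glance(res)
  expect_equal(g$sample, "s1")
  expect_equal(g$n_calls, 0L)
  expect_true(all(c("family_degree", "panel_singleton_ratio") %in% names(g)))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
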