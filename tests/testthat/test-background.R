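# build a minimal pileup-like object for background tests: one row per
# (pos, alt) with full-f family support and fixed denominators
fake_pileup <- function(sites, total_families = 1000L,
                        total_singletons = 200L, fam_cov_sum = 1e6,
                        n_positions = 1000L) {
  p <- tibble::tibble(
    chrom = "chr1", pos = sites$pos, ref = sites$ref, alt = sites$alt,
    n_fam_full = sites$n_fam_full,
    n_fam_sub = 0L, n_singleton = 0L,
    n_qualified_singleton = 0L,
    total_families = total_families, total_singletons = total_singletons,
    depth = 5000L,
    af = (sites$n_fam_full) / (total_families + total_singletons)
  )
  attr(p, "stats") <- list(n_positions = n_positions,
                           panel_mean_depth = 5000,
                           raw_error_positions = nrow(sites),
                           family_error_positions = nrow(sites),
                           n_families = total_families,
                           n_singletons = total_singletons,
                           family_sizes = rep(2L, total_families),
                           fam_cov_sum = fam_cov_sum,
                           singleton_cov_sum = fam_cov_sum / 5,
                           depth_sum = 5e6, f_threshold = 1)
  class(p) <- c("vb_pileup", class(p))
  p
}

site_tbl <- function(pos, alt, n = 2L, ref = "C") {
  tibble::tibble(pos = pos, ref = ref, alt = alt, n_fam_full = n)
}

test_that("observations carry family-level AFs per sample-site-alt", {
  p1 <- fake_pileup(site_tbl(100L, "T", n = 2L))
  obs <- collect_observations(list(S1 = p1))
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$af, 2 / 1200)
  # only f < 1.0 support -> no observation
  p2 <- fake_pileup(site_tbl(100L, "T", n = 0L))
  p2$n_fam_sub <- 1L
  expect_equal(nrow(collect_observations(list(S1 = p2))), 0L)
})

test_that("classification boundary sits exactly at 6 background samples", {
  mk_obs <- function(pos, alt, samples) {
    tibble::tibble(sample_id = samples, chrom = "chr1", pos = pos,
                   ref = "C", alt = alt, af = 0.01)
  }
  obs <- dplyr::bind_rows(
    mk_obs(100L, "T", paste0("S", 1:6)),   # stereotypical
    mk_obs(200L, "T", paste0("S", 1:5)),   # stochastic
    mk_obs(300L, "T", paste0("S", 1:7)),   # stereotypical
    mk_obs(300L, "G", "S1")                # same pos, other alt: stochastic
  )
  cls <- classify_sites(obs, min_occurrence = 6L)
  expect_equal(sort(cls$stereotypical$pos), c(100L, 300L))
  expect_equal(cls$stereotypical$alt[order(cls$stereotypical$pos)],
               c("T", "T"))
  expect_true(any(cls$stochastic$pos == 300L & cls$stochastic$alt == "G"))
  expect_true(any(cls$stochastic$pos == 200L))
  expect_error(classify_sites(obs, min_occurrence = 0L), "min_occurrence")
})

test_that("a cohort smaller than the occurrence threshold is refused", {
  p <- fake_pileup(site_tbl(100L, "T"))
  expect_error(build_background_db(list(S1 = p)), "cannot reach")
})

test_that("DB construction fits recurrent sites and stores the rate", {
  set.seed(51)
  afs <- stats::rlnorm(10, log(0.02), 0.3)
  pileups <- lapply(seq_len(10), function(i) {
    n_full <- max(1L, round(afs[i] * 1200))
    fake_pileup(dplyr::bind_rows(
      site_tbl(100L, "T", n = n_full),
      if (i <= 3) site_tbl(200L, "G", n = 1L, ref = "A")  # occurrence 3
    ))
  })
  names(pileups) <- paste0("BG", 1:10)
  db <- suppressWarnings(
    build_background_db(pileups, min_occurrence = 6L, confidence = 0.99))
  expect_s3_class(db, "vb_background_db")
  expect_equal(nrow(db$sites), 1L)
  expect_equal(db$sites$pos, 100L)
  expect_equal(db$sites$occurrence, 10L)
  expect_true(db$sites$dist_name %in% c(candidate_distributions(),
                                        "empirical"))
  expect_gt(db$sites$af_cutoff, max(afs[1:10] * 1200 / 1200) * 0.8)
  # cutoff is floored at the largest observed background AF
  expect_gte(db$sites$af_cutoff, max(round(afs * 1200)) / 1200 - 1e-12)
  expect_gt(db$background_template_rate, 0)

  # polishing verdicts around the cutoff
  cut <- db$sites$af_cutoff
  expect_equal(polish("chr1", 100L, "T", cut * 0.5, db), "POLISHED")
  expect_equal(polish("chr1", 100L, "T", cut * 1.5, db), "PASS")
  expect_equal(polish("chr1", 100L, "G", cut * 0.5, db), "PASS") # other alt
  expect_equal(polish("chr1", 999L, "T", 0.001, db), "PASS")     # not in DB
  # monotone in AF
  afseq <- seq(0.0005, 0.2, length.out = 50)
  v <- polish(rep("chr1", 50), rep(100L, 50), rep("T", 50), afseq, db)
  expect_true(all(diff(v == "PASS") >= 0))
})

test_that("database JSON round-trip is lossless and versioned", {
  set.seed(52)
  pileups <- lapply(1:8, function(i) {
    fake_pileup(site_tbl(c(100L, 150L), c("T", "G"),
                         n = 1L + (i %% 3), ref = c("C", "A")))
  })
  names(pileups) <- paste0("BG", 1:8)
  db <- suppressWarnings(build_background_db(pileups, min_occurrence = 6L))
  expect_equal(nrow(db$sites), 2L)
  path <- withr::local_tempfile(fileext = ".json")
  save_db(db, path)
  db2 <- load_db(path)
  expect_equal(db2$sites$af_cutoff, db$sites$af_cutoff)
  expect_equal(db2$sites$params, db$sites$params)
  expect_equal(db2$sites$dist_name, db$sites$dist_name)
  expect_equal(db2$background_template_rate, db$background_template_rate)
  expect_equal(db2$n_background_samples, db$n_background_samples)
  # truncated file fails to parse
  txt <- readLines(path)
  writeLines(substr(paste(txt, collapse = ""), 1, 50), path)
  expect_error(load_db(path))
  # wrong schema is rejected
  jsonlite::write_json(list(schema = "other", version = 1), path,
                       auto_unbox = TRUE)
  expect_error(load_db(path), "not a vbcall")
})

test_that("substitution spectrum covers all 12 types and normalizes", {
  sites <- tibble::tibble(ref = c("C", "C", "G", "A"),
                          alt = c("T", "T", "A", "G"))
  spec <- substitution_spectrum(sites)
  expect_equal(nrow(spec), 12L)
  expect_equal(sum(spec$fraction), 1)
  expect_equal(spec$fraction[spec$substitution == "C>T"], 0.5)
  expect_equal(spec$fraction[spec$substitution == "T>A"], 0)
  all_ct <- tibble::tibble(ref = "C", alt = "T")
  s2 <- substitution_spectrum(all_ct)
  expect_equal(s2$fraction[s2$substitution == "C>T"], 1)
  expect_error(substitution_spectrum(sites[0, ]), "empty")
})

test_that("simulated substitution spectrum recovers the generator weights", {
  regions <- tibble::tibble(chrom = "chr1", start = 500L, end = 3500L)
  set.seed(53)
  ref <- random_reference(c(chr1 = 3800L))
  cfg <- sim_config(seed = 53, regions = regions, reference = ref,
                    templates_per_site = 300, error_rate = 0.01)
  sim <- simulate_sample(cfg)
  mm <- attr(sim$fragments, "mismatches")
  err <- sim$truth$errors
  rb <- ref_base(ref, "chr1", err$pos)
  obs <- substitution_spectrum(tibble::tibble(ref = rb, alt = err$base))
  spec <- vbcall:::default_error_spectrum()
  base_freq <- table(factor(strsplit(rawToChar(ref$seq$chr1), "")[[1]],
                            levels = c("A", "C", "G", "T")))
  base_freq <- as.numeric(base_freq / sum(base_freq))
  names(base_freq) <- c("A", "C", "G", "T")
  for (sub in c("C>T", "G>A", "A>G")) {
    from <- substr(sub, 1, 1); to <- substr(sub, 3, 3)
    expected <- base_freq[from] * spec[from, to] /
      sum(vapply(c("A", "C", "G", "T"), function(b) {
        base_freq[b] * sum(spec[b, ])
      }, 0))
    got <- obs$fraction[obs$substitution == sub]
    expect_lt(abs(got - expected), 0.03)
  }
})
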