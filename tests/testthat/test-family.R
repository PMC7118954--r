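test_that("fragments sharing a virtual barcode form one family", {
  rows <- dplyr::bind_rows(
    lay_fragment(120L, 100L, "+", qname = "a"),
    lay_fragment(120L, 100L, "+", qname = "b"),
    lay_fragment(120L, 100L, "+", qname = "c"),
    lay_fragment(120L, 99L, "+", qname = "d"),   # different length
    lay_fragment(120L, 100L, "-", qname = "e")   # different strand
  )
  cl <- cluster_families(mk_fragments(rows))
  expect_equal(nrow(cl$families), 1L)
  expect_equal(cl$families$size, 3L)
  expect_equal(nrow(cl$singletons), 2L)
})

test_that("clustering is an exact partition matching a group-by oracle", {
  for (seed in 1:20) {
    fr <- random_fragments(n = 300L, seed = seed)
    cl <- cluster_families(fr)
    oracle <- partition_oracle(
      fr$frag_id, paste(fr$chrom, fr$start, fr$tlen, fr$strand))
    expect_identical(partition_signature(cl$members), oracle)
    # partition property: sizes sum to input count
    expect_equal(sum(cl$families$size) + nrow(cl$singletons), nrow(fr))
  }
})

test_that("real (UMI) families split virtual families on barcode collisions", {
  rows <- dplyr::bind_rows(
    lay_fragment(100L, 80L, "+", qname = "u1", umi = "AAT"),
    lay_fragment(100L, 80L, "+", qname = "u2", umi = "AAT"),
    lay_fragment(100L, 80L, "+", qname = "u3", umi = "CCG"),
    lay_fragment(200L, 80L, "+", qname = "u4", umi = "GTA")
  )
  fr <- mk_fragments(rows)
  cmp <- compare_real_virtual(fr)
  expect_equal(cmp$n_virtual, 2L)
  expect_equal(cmp$n_real, 3L)
  expect_false(cmp$identical)
  # the mis-merged virtual family contains exactly 2 real families
  expect_equal(cmp$mismerged_composition$nr, 2L)
  # only the collision-free real family is recovered intact
  expect_equal(cmp$recovery_rate, 1 / 3)
})

test_that("with unique endpoints the virtual and real partitions coincide", {
  rows <- purrr::map_dfr(1:30, function(i) {
    lay_fragment(100L + 3L * i, 80L, "+", qname = paste0("q", i),
                 umi = rep(c("AAT", "CCG"), 15)[i])
  })
  rows <- dplyr::bind_rows(rows, rows)  # two reads per template
  rows$qname <- paste0(rows$qname, rep(c(".1", ".2"), each = 30))
  fr <- mk_fragments(rows)
  cmp <- compare_real_virtual(fr)
  expect_true(cmp$identical)
  expect_equal(cmp$recovery_rate, 1)
})

test_that("missing UMIs make real-family clustering fail", {
  fr <- mk_fragments(lay_fragment(100L, 80L, "+"))
  expect_error(cluster_families(fr, by_umi = TRUE), "UMI")
})

test_that("mate consolidation votes: agree, disagree, single-coverage", {
  ref <- flat_reference()
  # span [100, 200), 60bp reads: double zone [140, 160)
  base_rows <- lay_fragment(100L, 100L, "+")
  # both mates carry T at 150 -> single vote T
  fr <- mk_fragments(base_rows, mm_rows(1L, 150L, "T", mates = c(1L, 2L)))
  expect_equal(consolidate_mates(fr, 150L, ref), "T")
  # mates disagree at 150 -> ABSTAIN
  fr <- mk_fragments(base_rows, mm_rows(1L, 150L, c("T", "G"), mates = c(1L, 2L)))
  expect_equal(consolidate_mates(fr, 150L, ref), "ABSTAIN")
  # mate1-only coverage at 110, error there -> that base
  fr <- mk_fragments(base_rows, mm_rows(1L, 110L, "G", mates = 1L))
  expect_equal(consolidate_mates(fr, 110L, ref), "G")
  # one mate mismatch inside double zone, other mate reference -> ABSTAIN
  fr <- mk_fragments(base_rows, mm_rows(1L, 150L, "T", mates = 1L))
  expect_equal(consolidate_mates(fr, 150L, ref), "ABSTAIN")
  # no mismatch anywhere -> reference vote
  fr <- mk_fragments(base_rows)
  expect_equal(consolidate_mates(fr, 150L, ref), "A")
  expect_error(consolidate_mates(fr, 99L, ref), "span")
})

test_that("family f values and consensus follow the vote arithmetic", {
  ref <- flat_reference()
  rows <- dplyr::bind_rows(lapply(1:5, function(i) {
    lay_fragment(100L, 100L, "+", qname = paste0("m", i))
  }))
  # all 5 members carry T at 150 -> f = 1, consensus T
  mm <- dplyr::bind_rows(lapply(1:5, function(i) mm_rows(i, 150L, "T")))
  fr <- mk_fragments(rows, mm)
  cl <- cluster_families(fr)
  fs <- family_f(cl, cl$members$key_id[1], 150L, ref)
  expect_equal(fs$f, 1.0)
  expect_equal(fs$consensus, "T")
  # 1 of 5 carries T -> f = 0.2
  fr <- mk_fragments(rows, mm_rows(1L, 150L, "T"))
  fs <- family_f(cluster_families(fr), 1L, 150L, ref)
  expect_equal(fs$f, 0.2)
  # 2 T + 2 G + 1 abstaining member: f = 1 over the 4 votes, consensus tie
  mm <- dplyr::bind_rows(
    mm_rows(1L, 150L, "T"), mm_rows(2L, 150L, "T"),
    mm_rows(3L, 150L, "G"), mm_rows(4L, 150L, "G"),
    mm_rows(5L, 150L, c("T", "G"), mates = c(1L, 2L))
  )
  fs <- family_f(cluster_families(mk_fragments(rows, mm)), 1L, 150L, ref)
  expect_equal(fs$n_abstain, 1L)
  expect_equal(fs$f, 1.0)
  expect_true(is.na(fs$consensus))
})

test_that("pileups count full families, sub-threshold families, singletons", {
  ref <- flat_reference()
  regions <- small_panel()
  rows <- dplyr::bind_rows(
    # family FA: 3 members, unanimous T at 150
    lay_fragment(100L, 100L, "+", qname = "fa1"),
    lay_fragment(100L, 100L, "+", qname = "fa2"),
    lay_fragment(100L, 100L, "+", qname = "fa3"),
    # family FB: 2 members, one T one ref at 150 -> f = 0.5
    lay_fragment(110L, 100L, "+", qname = "fb1"),
    lay_fragment(110L, 100L, "+", qname = "fb2"),
    # singletons: two vote T at 150, one votes G at 150
    lay_fragment(120L, 100L, "+", qname = "s1"),
    lay_fragment(121L, 100L, "+", qname = "s2"),
    lay_fragment(122L, 100L, "+", qname = "s3")
  )
  mm <- dplyr::bind_rows(
    mm_rows(1L, 150L, "T"), mm_rows(2L, 150L, "T"), mm_rows(3L, 150L, "T"),
    mm_rows(4L, 150L, "T"),
    mm_rows(6L, 150L, "T"), mm_rows(7L, 150L, "T"), mm_rows(8L, 150L, "G")
  )
  p <- build_pileups(mk_fragments(rows, mm), ref, regions)
  pT <- p[p$alt == "T", ]
  expect_equal(pT$n_fam_full, 1L)
  expect_equal(pT$n_fam_sub, 1L)
  expect_equal(pT$n_singleton, 2L)
  expect_equal(pT$n_qualified_singleton, 2L)  # an f=1.0 T family exists
  pG <- p[p$alt == "G", ]
  expect_equal(pG$n_fam_full, 0L)
  expect_equal(pG$n_qualified_singleton, 0L)  # no G family: not qualified
  # denominators: 2 families and 3 singletons cover position 150
  expect_equal(unique(p$total_families), 2L)
  expect_equal(unique(p$total_singletons), 3L)
  expect_equal(pT$af, (1 + 2) / (2 + 3))
  st <- pileup_stats(p)
  expect_equal(st$family_error_positions, 1L)
  expect_equal(st$raw_error_positions, 1L)
})

test_that("an error-free sample yields an empty pileup", {
  rows <- dplyr::bind_rows(lay_fragment(100L, 100L, "+"),
                           lay_fragment(100L, 100L, "+", qname = "x"))
  p <- build_pileups(mk_fragments(rows), flat_reference(), small_panel())
  expect_equal(nrow(p), 0L)
  expect_equal(error_position_fractions(p)$raw, 0)
  expect_equal(error_position_fractions(p)$family, 0)
})

test_that("mate-overlap confirmation is recorded in the support table", {
  ref <- flat_reference()
  rows <- dplyr::bind_rows(
    lay_fragment(100L, 100L, "+", qname = "a"),
    lay_fragment(100L, 100L, "+", qname = "b")
  )
  # unanimous T at 110: covered by the left mate only (double zone [140,160))
  mm <- dplyr::bind_rows(mm_rows(1L, 110L, "T", mates = 1L),
                         mm_rows(2L, 110L, "T", mates = 1L))
  p <- build_pileups(mk_fragments(rows, mm), ref, small_panel())
  sup <- pileup_support(p)
  expect_equal(nrow(sup), 1L)
  expect_false(sup$mate_confirmed)
  # unanimous T at 150 (both mates cover): confirmed
  mm2 <- dplyr::bind_rows(mm_rows(1L, 150L, "T"), mm_rows(2L, 150L, "T"))
  p2 <- build_pileups(mk_fragments(rows, mm2), ref, small_panel())
  expect_true(pileup_support(p2)$mate_confirmed)
})
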