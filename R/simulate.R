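# Synthetic cfDNA read-pair generator with a ground-truth ledger.
#
# Emits pre-aligned paired-end fragments directly (all-match CIGARs,
# correct flags/TLEN), so the pipeline can be exercised end to end without
# an external aligner. All randomness is driven by the config seed and the
# global RNG state is restored on exit.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

default_error_spectrum <- function() {
  # rows: template base; columns: erroneous base read out. The skew mirrors
  # the C>T/G>A-dominated substitution profile of PCR/DNA-damage errors.
  m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  m["A", c("C", "G", "T")] <- c(0.25, 0.50, 0.25)
  m["C", c("A", "G", "T")] <- c(0.25, 0.15, 0.60)
  m["G", c("A", "C", "T")] <- c(0.60, 0.15, 0.25)
  m["T", c("A", "C", "G")] <- c(0.25, 0.50, 0.25)
  m
}

#' Simulation configuration
#'
#' Generative parameters for a synthetic hybrid-capture cfDNA sample. The
#' defaults describe a deeply sequenced 10 kb panel: ~3000 templates
#' covering each position, fragment lengths peaked at 166 bp, 150 bp
#' paired reads, a 20% singleton fraction with geometric family sizes, and
#' a post-filter per-base read error rate of 0.1%.
#'
#' @param seed Mandatory RNG seed.
#' @param regions Panel tibble; default one 10 kb region on `chr1`.
#' @param reference Optional `vb_reference`; generated at random (with a
#'   margin beyond the panel for fragment overhang) when `NULL`.
#' @param templates_per_site Expected number of templates covering a
#'   panel position (ignored when `n_templates` is given).
#' @param n_templates Total template count; computed from
#'   `templates_per_site` when `NULL`.
#' @param frag_len_mean,frag_len_sd,frag_len_min,frag_len_max Fragment
#'   length distribution (rounded normal, bounded).
#' @param read_len Read length of each mate.
#' @param singleton_fraction Probability that a template is sequenced
#'   exactly once.
#' @param family_geom_prob Non-singleton family size is
#'   `2 + rgeom(family_geom_prob)`.
#' @param family_size_sampler Optional function `n -> integer sizes`
#'   overriding the singleton/geometric scheme (e.g. a constant size for
#'   error-suppression experiments).
#' @param error_rate Per-base sequencing error probability.
#' @param error_spectrum 4x4 substitution weight matrix (template base by
#'   read base).
#' @param umi Emit a random UMI per template.
#' @param umi_len UMI length in bases.
#' @param spiked Tibble of true variants: `chrom`, `pos` (0-based), `alt`,
#'   `af`. Each covering template carries the variant with probability
#'   `af`.
#' @param stereotypical Tibble of recurrent artifact sites: `chrom`,
#'   `pos`, `alt`, `presence` (per-sample probability the artifact is
#'   active), `meanlog`, `sdlog` (per-sample AF drawn from a log-normal,
#'   truncated to (0, 0.4]).
#' @return A `vb_sim_config` list.
#' @export
sim_config <- function(seed,
                       regions = tibble::tibble(chrom = "chr1",
                                                start = 1000L,
                                                end = 11000L),
                       reference = NULL,
                       templates_per_site = 3000,
                       n_templates = NULL,
                       frag_len_mean = 166, frag_len_sd = 25,
                       frag_len_min = 100, frag_len_max = 300,
                       read_len = 150L,
                       singleton_fraction = 0.2,
                       family_geom_prob = 0.55,
                       family_size_sampler = NULL,
                       error_rate = 0.001,
                       error_spectrum = default_error_spectrum(),
                       umi = FALSE, umi_len = 8L,
                       spiked = NULL, stereotypical = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(n_templates)) {
    n_templates <- as.integer(round(templates_per_site *
                                      region_width(regions) / frag_len_mean))
  }
  stopifnot(singleton_fraction >= 0, singleton_fraction <= 1,
            error_rate >= 0, error_rate < 1,
            frag_len_min <= frag_len_mean, frag_len_mean <= frag_len_max)
  if (!is.null(spiked) && nrow(spiked) &&
      any(spiked$af <= 0 | spiked$af >= 1)) {
    stop("spiked AFs must lie in (0, 1)")
  }
  structure(list(seed = as.integer(seed), regions = regions,
                 reference = reference,
                 n_templates = n_templates,
                 frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
                 frag_len_min = frag_len_min, frag_len_max = frag_len_max,
                 read_len = as.integer(read_len),
                 singleton_fraction = singleton_fraction,
                 family_geom_prob = family_geom_prob,
                 family_size_sampler = family_size_sampler,
                 error_rate = error_rate, error_spectrum = error_spectrum,
                 umi = umi, umi_len = as.integer(umi_len),
                 spiked = spiked, stereotypical = stereotypical),
            class = "vb_sim_config")
}

#' Simulate one cfDNA sample
#'
#' Draws templates (position, length, strand, family size, optional UMI),
#' assigns true variant alleles to covering templates per spiked-site AF,
#' activates stereotypical artifact sites with their per-sample AF draws,
#' expands templates into read pairs, and injects i.i.d. per-base read
#' errors with the configured substitution spectrum. Returns the fragments
#' in the package's internal representation plus a complete truth ledger;
#' use [write_sam()] to materialize a SAM file.
#'
#' @param config A `vb_sim_config`.
#' @return List of class `vb_simulation` with elements `fragments`
#'   (`vb_fragments`), `reference` (`vb_reference`), `regions`, and
#'   `truth` (list: `templates`, `template_variants`, `errors`,
#'   `spiked`, `stereotypical`, `warnings`, `seed`).
#' @export
simulate_sample <- function(config) {
  with_seed(config$seed, simulate_sample_impl(config))
}

simulate_sample_impl <- function(config) {
  regions <- config$regions
  margin <- config$frag_len_max
  reference <- config$reference
  if (is.null(reference)) {
    lens <- vapply(split(regions$end, regions$chrom), max, 0)
    reference <- random_reference(stats::setNames(as.integer(lens + margin),
                                                  names(lens)))
  }
  n <- config$n_templates
  # fragment lengths and placement (uniform coverage across each region)
  len <- as.integer(pmin(pmax(round(stats::rnorm(n, config$frag_len_mean,
                                                 config$frag_len_sd)),
                              config$frag_len_min), config$frag_len_max))
  w <- regions$end - regions$start
  ridx <- sample.int(nrow(regions), n, replace = TRUE, prob = w)
  lo <- pmax(regions$start[ridx] - len + 1L, 0L)
  hi <- regions$end[ridx] - 1L
  start <- lo + floor(stats::runif(n) * (hi - lo + 1L))
  start <- as.integer(start)
  chrom <- regions$chrom[ridx]
  end <- start + len
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  size <- if (is.null(config$family_size_sampler)) {
    ifelse(stats::runif(n) < config$singleton_fraction, 1L,
           2L + stats::rgeom(n, config$family_geom_prob))
  } else {
    as.integer(config$family_size_sampler(n))
  }
  umi <- if (config$umi) {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), config$umi_len, replace = TRUE),
            collapse = "")
    }, "")
  } else NA_character_

  templates <- tibble::tibble(template_id = seq_len(n), chrom = chrom,
                              start = start, end = end, tlen = len,
                              strand = strand, size = size, umi = umi)

  warnings <- character(0)
  tv <- list()
  spiked <- config$spiked
  for (tab in list(spiked, config$stereotypical)) {
    if (!is.null(tab) && nrow(tab)) {
      rb <- ref_base(reference, tab$chrom, tab$pos)
      bad <- which(rb == tab$alt)
      if (length(bad)) {
        stop("variant/artifact alt allele equals the reference base at ",
             paste0(tab$chrom[bad], ":", tab$pos[bad], collapse = ", "))
      }
    }
  }
  if (!is.null(spiked) && nrow(spiked)) {
    for (i in seq_len(nrow(spiked))) {
      covering <- which(chrom == spiked$chrom[i] & start <= spiked$pos[i] &
                          end > spiked$pos[i])
      if (spiked$af[i] * length(covering) < 1) {
        warnings <- c(warnings, sprintf(
          "spiked site %s:%d expects < 1 mutant template", spiked$chrom[i],
          spiked$pos[i]))
      }
      carriers <- covering[stats::runif(length(covering)) < spiked$af[i]]
      if (length(carriers)) {
        tv[[length(tv) + 1L]] <- tibble::tibble(
          template_id = carriers, chrom = spiked$chrom[i],
          pos = spiked$pos[i], alt = spiked$alt[i], origin = "spiked")
      }
    }
  }
  stereo_out <- NULL
  stereo <- config$stereotypical
  if (!is.null(stereo) && nrow(stereo)) {
    present <- stats::runif(nrow(stereo)) < stereo$presence
    af_drawn <- rep(NA_real_, nrow(stereo))
    for (i in which(present)) {
      af_i <- min(stats::rlnorm(1, stereo$meanlog[i], stereo$sdlog[i]), 0.4)
      af_drawn[i] <- af_i
      covering <- which(chrom == stereo$chrom[i] & start <= stereo$pos[i] &
                          end > stereo$pos[i])
      carriers <- covering[stats::runif(length(covering)) < af_i]
      if (length(carriers)) {
        tv[[length(tv) + 1L]] <- tibble::tibble(
          template_id = carriers, chrom = stereo$chrom[i],
          pos = stereo$pos[i], alt = stereo$alt[i], origin = "stereotypical")
      }
    }
    stereo_out <- tibble::tibble(chrom = stereo$chrom, pos = stereo$pos,
                                 alt = stereo$alt, present = present,
                                 af_drawn = af_drawn)
  }
  template_variants <- if (length(tv)) dplyr::bind_rows(tv) else
    tibble::tibble(template_id = integer(), chrom = character(),
                   pos = integer(), alt = character(), origin = character())

  # expand templates into read pairs
  tid <- rep.int(templates$template_id, templates$size)
  nf <- length(tid)
  t_start <- templates$start[tid]
  t_end <- templates$end[tid]
  t_len <- templates$tlen[tid]
  t_chrom <- templates$chrom[tid]
  t_strand <- templates$strand[tid]
  rl <- pmin(config$read_len, t_len)
  left_pos <- t_start
  right_pos <- t_end - rl
  # strand "+": read1 is the forward (leftmost) read
  r1_pos <- ifelse(t_strand == "+", left_pos, right_pos)
  r2_pos <- ifelse(t_strand == "+", right_pos, left_pos)
  dup_idx <- stats::ave(tid, tid, FUN = seq_along)
  frags <- tibble::tibble(
    frag_id = seq_len(nf),
    qname = paste0("T", tid, ".", dup_idx),
    chrom = t_chrom, start = t_start, end = t_end, tlen = t_len,
    strand = t_strand,
    r1_pos = as.integer(r1_pos), r1_len = as.integer(rl),
    r2_pos = as.integer(r2_pos), r2_len = as.integer(rl),
    umi = templates$umi[tid],
    template_id = tid
  )

  # template-variant bases carried into every covering mate
  mm_var <- list()
  if (nrow(template_variants)) {
    fv <- dplyr::inner_join(frags, template_variants,
                            by = c("template_id", "chrom"),
                            relationship = "many-to-many")
    for (m in 1:2) {
      mp <- fv[[paste0("r", m, "_pos")]]
      ml <- fv[[paste0("r", m, "_len")]]
      cov <- fv$pos >= mp & fv$pos < mp + ml
      if (any(cov)) {
        mm_var[[m]] <- tibble::tibble(frag_id = fv$frag_id[cov], mate = m,
                                      pos = fv$pos[cov], base = fv$alt[cov])
      }
    }
  }
  mm_var <- if (length(mm_var)) dplyr::bind_rows(mm_var) else empty_mismatches()

  # i.i.d. per-base read errors with the configured substitution spectrum
  mm_err <- simulate_read_errors(frags, mm_var, reference, config)

  vk <- paste(mm_var$frag_id, mm_var$mate, mm_var$pos)
  ek <- paste(mm_err$at$frag_id, mm_err$at$mate, mm_err$at$pos)
  mm <- dplyr::bind_rows(mm_var[!(vk %in% ek), ], mm_err$mm)
  fragments <- new_fragments(
    dplyr::select(frags, -"template_id"), mm)
  truth <- list(templates = templates,
                template_variants = template_variants,
                errors = mm_err$at,
                spiked = spiked, stereotypical = stereo_out,
                warnings = warnings, seed = config$seed)
  structure(list(fragments = fragments, reference = reference,
                 regions = regions, truth = truth),
            class = "vb_simulation")
}

# Draw per-base errors. Returns list(at = tibble of error events
# (frag_id, mate, pos, base_read), mm = error rows expressed as
# reference-mismatch rows (template-carried alt bases taken into account;
# errors that recreate the reference base yield no mismatch row)).
simulate_read_errors <- function(frags, mm_var, reference, config) {
  e <- config$error_rate
  empty <- list(at = tibble::tibble(frag_id = integer(), mate = integer(),
                                    pos = integer(), base = character()),
                mm = empty_mismatches())
  if (e <= 0) return(empty)
  lens <- c(frags$r1_len, frags$r2_len)
  n_reads <- nrow(frags)
  B <- sum(lens)
  K <- stats::rbinom(1L, B, e)
  if (K == 0L) return(empty)
  flat <- sort(sample.int(B, K))
  cum <- cumsum(lens)
  row <- findInterval(flat - 1L, cum) + 1L
  offset <- flat - c(0L, cum)[row] - 1L
  mate <- ifelse(row > n_reads, 2L, 1L)
  fr <- ifelse(row > n_reads, row - n_reads, row)
  pos <- ifelse(mate == 1L, frags$r1_pos[fr], frags$r2_pos[fr]) + offset
  chrom <- frags$chrom[fr]
  refb <- character(K)
  for (cn in unique(chrom)) {
    i <- chrom == cn
    refb[i] <- ref_base(reference, cn, pos[i])
  }
  # template base: reference unless this template carries a variant here
  tbase <- refb
  if (nrow(mm_var)) {
    key <- paste(frags$frag_id[fr], mate, pos)
    vkey <- paste(mm_var$frag_id, mm_var$mate, mm_var$pos)
    hit <- match(key, vkey)
    tbase[!is.na(hit)] <- mm_var$base[hit[!is.na(hit)]]
  }
  spec <- config$error_spectrum
  bases <- c("A", "C", "G", "T")
  newb <- character(K)
  for (b in bases) {
    i <- which(tbase == b)
    if (!length(i)) next
    wts <- spec[b, ]
    wts[b] <- 0
    newb[i] <- sample(bases, length(i), replace = TRUE, prob = wts)
  }
  at <- tibble::tibble(frag_id = frags$frag_id[fr], mate = mate,
                       pos = pos, base = newb)
  mmrows <- at[at$base != refb, ]
  list(at = at, mm = mmrows)
}

#' Write a simulated sample to a coordinate-sorted SAM file
#'
#' Materializes full read sequences from the reference plus the sparse
#' mismatch ledger, with exact all-match CIGARs, proper-pair flags and
#' signed TLEN, and an optional `RX` UMI tag.
#'
#' @param sim A `vb_simulation` (or a `vb_fragments` with mismatches,
#'   plus `reference`).
#' @param path Output SAM path.
#' @param reference Required when `sim` is a bare `vb_fragments`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, path, reference = NULL) {
  if (inherits(sim, "vb_simulation")) {
    fragments <- sim$fragments
    reference <- sim$reference
  } else {
    fragments <- sim
    if (is.null(reference)) stop("reference required")
  }
  mm <- frag_mm(fragments)
  # two read records per fragment (orphans not emitted by the simulator)
  mk_reads <- function(m) {
    other <- if (m == 1L) 2L else 1L
    pos <- fragments[[paste0("r", m, "_pos")]]
    mpos <- fragments[[paste0("r", other, "_pos")]]
    tibble::tibble(
      frag_id = fragments$frag_id,
      qname = fragments$qname,
      chrom = fragments$chrom,
      pos = pos,
      len = fragments[[paste0("r", m, "_len")]],
      mpos = mpos,
      mate = m,
      # FR orientation: read1 carries the fragment strand, read2 the
      # opposite; with fully-overlapping mates position cannot decide
      is_rev = if (m == 1L) fragments$strand == "-"
               else fragments$strand == "+",
      tlen = fragments$tlen,
      umi = fragments$umi
    )
  }
  reads <- dplyr::bind_rows(mk_reads(1L), mk_reads(2L))
  reads$flag <- 1L + 2L +
    ifelse(reads$is_rev, 16L, 0L) + ifelse(reads$is_rev, 0L, 32L) +
    ifelse(reads$mate == 1L, 64L, 128L)
  reads$tlen_signed <- ifelse(reads$is_rev, -reads$tlen, reads$tlen)
  # sequences: reference substring with mismatches applied
  seqs <- character(nrow(reads))
  for (cn in unique(reads$chrom)) {
    i <- which(reads$chrom == cn)
    refstr <- rawToChar(ref_raw(reference, cn))
    seqs[i] <- substring(refstr, reads$pos[i] + 1L, reads$pos[i] + reads$len[i])
  }
  if (nrow(mm)) {
    rk <- paste(reads$frag_id, reads$mate)
    mk <- paste(mm$frag_id, mm$mate)
    ri <- match(mk, rk)
    off <- mm$pos - reads$pos[ri] + 1L
    for (j in seq_along(ri)) {
      substr(seqs[ri[j]], off[j], off[j]) <- mm$base[j]
    }
  }
  o <- order(reads$chrom, reads$pos, reads$qname, reads$mate)
  reads <- reads[o, ]
  seqs <- seqs[o]
  chroms <- names(reference$seq)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                   vapply(reference$seq, length, 1L)))
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
                 reads$qname, reads$flag, reads$chrom, reads$pos + 1L,
                 reads$len, reads$mpos + 1L, reads$tlen_signed, seqs,
                 strrep("I", reads$len))
  has_umi <- !is.na(reads$umi)
  rec[has_umi] <- paste0(rec[has_umi], "\tRX:Z:", reads$umi[has_umi])
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Simulate a background cohort
#'
#' Generates `n_samples` independent samples from a shared configuration;
#' per-sample seeds are derived as `seed + i`, stereotypical artifact
#' sites are activated independently per sample, and template numbers can
#' vary across samples (e.g. to contrast low-template controls with
#' high-template reference standards).
#'
#' @param config A `vb_sim_config` (the cohort base configuration).
#' @param n_samples Number of samples.
#' @param templates_per_site Optional vector (recycled) overriding the
#'   per-sample template level.
#' @return Named list of `vb_simulation` objects (`BG1`, `BG2`, ...).
#' @export
simulate_background_cohort <- function(config, n_samples,
                                       templates_per_site = NULL) {
  stopifnot(n_samples >= 1)
  if (!is.null(templates_per_site)) {
    templates_per_site <- rep_len(templates_per_site, n_samples)
  }
  out <- lapply(seq_len(n_samples), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    if (!is.null(templates_per_site)) {
      cfg$n_templates <- as.integer(round(
        templates_per_site[i] * region_width(cfg$regions) / cfg$frag_len_mean))
    }
    simulate_sample(cfg)
  })
  names(out) <- paste0("BG", seq_len(n_samples))
  out
}

#' Evaluate calls against the simulation truth
#'
#' @param result A `vb_result` (or calls tibble).
#' @param truth Truth ledger from [simulate_sample()] (`$truth`), or a
#'   `vb_simulation`.
#' @param n_positions Panel size in bp (taken from the simulation when a
#'   `vb_simulation` is given).
#' @return One-row tibble: `tp`, `fp`, `fn`, `sensitivity`, `ppv`, `f1`,
#'   `fpr` (per genomic position). `ppv`/`f1` are `NA` when no calls were
#'   made.
#' @export
truth_evaluate <- function(result, truth, n_positions = NULL) {
  if (inherits(truth, "vb_simulation")) {
    if (is.null(n_positions)) n_positions <- region_width(truth$regions)
    truth <- truth$truth
  }
  if (is.null(n_positions)) stop("n_positions required")
  calls <- if (inherits(result, "vb_result")) result$calls else result
  spiked <- truth$spiked
  if (is.null(spiked)) {
    spiked <- tibble::tibble(chrom = character(), pos = integer(),
                             alt = character())
  }
  ckey <- paste(calls$chrom, calls$pos, calls$alt)
  skey <- paste(spiked$chrom, spiked$pos, spiked$alt)
  tp <- sum(ckey %in% skey)
  fp <- sum(!ckey %in% skey)
  fn <- sum(!skey %in% ckey)
  sens <- if (nrow(spiked)) tp / nrow(spiked) else NA_real_
  ppv <- if (nrow(calls)) tp / nrow(calls) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  fpr <- fp / (n_positions - nrow(spiked))
  tibble::tibble(tp = tp, fp = fp, fn = fn, sensitivity = sens,
                 ppv = ppv, f1 = f1, fpr = fpr)
}
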