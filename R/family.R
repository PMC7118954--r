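#' Cluster fragments into virtual families
#'
#' The virtual barcode is the triple (fragment start, template length,
#' strand of read 1) within a chromosome; every group of fragments sharing
#' a barcode is one virtual family when it has at least two members, and a
#' singleton otherwise. With `by_umi = TRUE` the grouping key is instead
#' (UMI, start, template length) — the "real" family used to validate the
#' virtual barcode against exogenous molecular tags.
#'
#' @param fragments A `vb_fragments` tibble.
#' @param by_umi Cluster by (UMI, start, template length) instead of the
#'   virtual barcode. Requires a non-missing `umi` on every fragment.
#' @return A list of class `vb_clustering`:
#'   * `members`: the input fragments with `key_id` and `fam_size` columns;
#'   * `families`: one row per family (size >= 2) with key fields and `size`;
#'   * `singletons`: one row per singleton key.
#' @export
cluster_families <- function(fragments, by_umi = FALSE) {
  df <- tibble::as_tibble(fragments)
  if (by_umi) {
    if (nrow(df) > 0L && anyNA(df$umi)) {
      stop("UMI tag missing on some fragments; cannot cluster real families")
    }
    keycols <- c("chrom", "start", "tlen", "umi")
  } else {
    keycols <- c("chrom", "start", "tlen", "strand")
  }
  if (nrow(df) == 0L) {
    keys <- tibble::tibble(key_id = integer(), chrom = character(),
                           start = integer(), end = integer(),
                           tlen = integer(), strand = character(),
                           umi = character(), size = integer())
    return(structure(list(members = fragments, families = keys,
                          singletons = keys),
                     class = "vb_clustering"))
  }
  key_str <- do.call(paste, c(unname(as.list(df[keycols])), sep = "\r"))
  key_id <- match(key_str, unique(key_str))
  df$key_id <- key_id
  df$fam_size <- tabulate(key_id)[key_id]
  first <- !duplicated(key_id)
  keys <- tibble::tibble(
    key_id = key_id[first],
    chrom = df$chrom[first],
    start = df$start[first],
    end = df$end[first],
    tlen = df$tlen[first],
    strand = df$strand[first],
    umi = df$umi[first],
    size = df$fam_size[first]
  )
  keys <- dplyr::arrange(keys, .data$key_id)
  out <- list(
    members = new_fragments(df, frag_mm(fragments)),
    families = keys[keys$size >= 2L, ],
    singletons = keys[keys$size == 1L, ]
  )
  structure(out, class = "vb_clustering")
}

#' @export
print.vb_clustering <- function(x, ...) {
  cat("<vb_clustering> ", nrow(x$families), " families (median size ",
      if (nrow(x$families)) stats::median(x$families$size) else NA, "), ",
      nrow(x$singletons), " singletons\n", sep = "")
  invisible(x)
}

#' Compare the virtual-barcode partition with the UMI ("real") partition
#'
#' Used to validate the endogenous barcode against exogenous molecular
#' tags: distinct templates occasionally share fragment endpoints, so a
#' virtual family can merge several real families. A real family is
#' "recovered intact" when its member set is exactly the member set of one
#' virtual family.
#'
#' @param fragments A `vb_fragments` tibble with UMIs.
#' @return A list with `recovery_rate`, `n_real`, `n_virtual`,
#'   `identical` (TRUE when the two partitions coincide) and
#'   `mismerged_composition`, a tibble counting mis-merged virtual
#'   families by how many real families they contain.
#' @export
compare_real_virtual <- function(fragments) {
  virt <- cluster_families(fragments, by_umi = FALSE)$members
  real <- cluster_families(fragments, by_umi = TRUE)$members
  ov <- order(virt$frag_id)
  or <- order(real$frag_id)
  tab <- tibble::tibble(v = virt$key_id[ov], r = real$key_id[or])
  by_r <- dplyr::summarise(dplyr::group_by(tab, .data$r),
                           nv = dplyr::n_distinct(.data$v),
                           v1 = .data$v[1], .groups = "drop")
  by_v <- dplyr::summarise(dplyr::group_by(tab, .data$v),
                           nr = dplyr::n_distinct(.data$r), .groups = "drop")
  pure_v <- by_v$v[by_v$nr == 1L]
  intact <- by_r$nv == 1L & by_r$v1 %in% pure_v
  mism <- by_v[by_v$nr > 1L, ]
  comp <- dplyr::count(mism, .data$nr, name = "n_virtual_families")
  list(
    recovery_rate = mean(intact),
    n_real = nrow(by_r),
    n_virtual = nrow(by_v),
    identical = all(intact) && nrow(by_r) == nrow(by_v),
    mismerged_composition = comp
  )
}

#' Consolidate mate votes for one fragment at one position
#'
#' If both mates cover the position their bases must agree to contribute a
#' single vote; disagreeing mates abstain. A position covered by one mate
#' contributes that mate's base.
#'
#' @param fragment One-row `vb_fragments` tibble (with mismatches attached).
#' @param position 0-based reference position, inside the fragment span.
#' @param reference A `vb_reference`.
#' @return The voted base as a single character, or `"ABSTAIN"`.
#' @export
consolidate_mates <- function(fragment, position, reference) {
  stopifnot(nrow(fragment) == 1L)
  if (position < fragment$start || position >= fragment$end) {
    stop("position outside fragment span")
  }
  mm <- frag_mm(fragment)
  refb <- ref_base(reference, fragment$chrom, position)
  base_of <- function(mate, pos0, len) {
    if (is.na(pos0) || position < pos0 || position >= pos0 + len) {
      return(NA_character_)
    }
    hit <- mm[mm$frag_id == fragment$frag_id & mm$mate == mate &
                mm$pos == position, ]
    if (nrow(hit)) hit$base[1] else refb
  }
  b1 <- base_of(1L, fragment$r1_pos, fragment$r1_len)
  b2 <- base_of(2L, fragment$r2_pos, fragment$r2_len)
  if (!is.na(b1) && !is.na(b2)) {
    if (b1 == b2) b1 else "ABSTAIN"
  } else if (!is.na(b1)) {
    b1
  } else if (!is.na(b2)) {
    b2
  } else {
    stop("position not covered by either mate")
  }
}

# ---- internal vectorized vote/pileup machinery ------------------------------

# Member-level consolidated votes at all positions where a member carries at
# least one non-reference base. Returns (frag_id, key_id, fam_size, chrom,
# pos, vote) with vote an alt base or "ABSTAIN"; implicit reference votes are
# never materialized.
member_votes <- function(members, mm, reference) {
  if (nrow(mm) == 0L) {
    return(tibble::tibble(frag_id = integer(), key_id = integer(),
                          fam_size = integer(), chrom = character(),
                          pos = integer(), vote = character()))
  }
  geo <- members[, c("frag_id", "key_id", "fam_size", "chrom",
                     "r1_pos", "r1_len", "r2_pos", "r2_len")]
  mmw <- tidyr::pivot_wider(mm, id_cols = c("frag_id", "pos"),
                            names_from = "mate", values_from = "base",
                            names_prefix = "b", values_fn = dplyr::first)
  if (!"b1" %in% names(mmw)) mmw$b1 <- NA_character_
  if (!"b2" %in% names(mmw)) mmw$b2 <- NA_character_
  v <- dplyr::inner_join(mmw, geo, by = "frag_id")
  cov1 <- !is.na(v$r1_pos) & v$pos >= v$r1_pos & v$pos < v$r1_pos + v$r1_len
  cov2 <- !is.na(v$r2_pos) & v$pos >= v$r2_pos & v$pos < v$r2_pos + v$r2_len
  refb <- character(nrow(v))
  for (cn in unique(v$chrom)) {
    i <- v$chrom == cn
    refb[i] <- ref_base(reference, cn, v$pos[i])
  }
  b1 <- ifelse(cov1, ifelse(is.na(v$b1), refb, v$b1), NA_character_)
  b2 <- ifelse(cov2, ifelse(is.na(v$b2), refb, v$b2), NA_character_)
  vote <- ifelse(
    !is.na(b1) & !is.na(b2),
    ifelse(b1 == b2, b1, "ABSTAIN"),
    ifelse(!is.na(b1), b1, b2)
  )
  out <- tibble::tibble(frag_id = v$frag_id, key_id = v$key_id,
                        fam_size = v$fam_size, chrom = v$chrom,
                        pos = v$pos, vote = vote, ref = refb)
  out <- out[!is.na(out$vote) & out$vote != out$ref, ]
  out$ref <- NULL
  out
}

# Aggregate member votes to per-(family, position) f values.
# Returns one row per voted (key_id, pos) for families (size >= 2):
# n_cov (members covering), n_abstain, n_nonref, n_votes, f, consensus_alt
# (unique plurality alternate allele, NA on tie or reference majority),
# plus span fields.
summarize_family_votes <- function(fam_votes, members) {
  if (nrow(fam_votes) == 0L) {
    return(tibble::tibble(key_id = integer(), chrom = character(),
                          pos = integer(), n_cov = integer(),
                          n_abstain = integer(), n_nonref = integer(),
                          n_votes = integer(), f = double(),
                          consensus_alt = character(), start = integer(),
                          end = integer(), fam_size = integer()))
  }
  counts <- dplyr::count(fam_votes, .data$key_id, .data$chrom, .data$pos,
                         .data$vote, name = "n")
  agg <- dplyr::summarise(
    dplyr::group_by(counts, .data$key_id, .data$chrom, .data$pos),
    n_abstain = sum(.data$n[.data$vote == "ABSTAIN"]),
    n_nonref = sum(.data$n[.data$vote != "ABSTAIN"]),
    alt_top = {
      alt <- .data$vote != "ABSTAIN"
      if (!any(alt)) NA_character_ else {
        nn <- .data$n[alt]; vv <- .data$vote[alt]
        top <- which(nn == max(nn))
        if (length(top) == 1L) vv[top] else NA_character_
      }
    },
    alt_top_n = {
      alt <- .data$vote != "ABSTAIN"
      if (any(alt)) max(.data$n[alt]) else 0L
    },
    .groups = "drop"
  )
  # exact member-coverage count for the affected (key, pos) pairs only
  aff <- dplyr::distinct(agg, .data$key_id, .data$pos)
  geo <- members[, c("key_id", "r1_pos", "r1_len", "r2_pos", "r2_len")]
  J <- dplyr::inner_join(aff, geo, by = "key_id",
                         relationship = "many-to-many")
  cv <- (!is.na(J$r1_pos) & J$pos >= J$r1_pos & J$pos < J$r1_pos + J$r1_len) |
        (!is.na(J$r2_pos) & J$pos >= J$r2_pos & J$pos < J$r2_pos + J$r2_len)
  ncov <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(key_id = J$key_id, pos = J$pos, cv = cv),
                    .data$key_id, .data$pos),
    n_cov = sum(.data$cv), .groups = "drop")
  pf <- dplyr::left_join(agg, ncov, by = c("key_id", "pos"))
  pf$n_votes <- pf$n_cov - pf$n_abstain
  pf$f <- ifelse(pf$n_votes > 0, pf$n_nonref / pf$n_votes, NA_real_)
  n_ref <- pf$n_votes - pf$n_nonref
  # consensus: unique plurality among all votes; reference plurality or any
  # tie involving the top alternate disqualifies the family from alt support
  pf$consensus_alt <- ifelse(!is.na(pf$alt_top) & pf$alt_top_n > n_ref,
                             pf$alt_top, NA_character_)
  spans <- members[!duplicated(members$key_id),
                   c("key_id", "start", "end", "fam_size")]
  pf <- dplyr::left_join(pf, spans, by = "key_id")
  pf$alt_top <- NULL
  pf$alt_top_n <- NULL
  pf
}

#' Per-family non-reference fraction at one position
#'
#' Computes the f value — the fraction of a family's consolidated member
#' votes that are non-reference — together with the consensus alternate
#' allele (`NA` on a tie or when reference bases hold the plurality).
#'
#' @param clustering A `vb_clustering` (from [cluster_families()]).
#' @param key_id Family key id.
#' @param position 0-based position within the family span.
#' @param reference A `vb_reference`.
#' @return One-row tibble with `n_votes`, `n_nonref`, `n_abstain`, `f`,
#'   `consensus`.
#' @export
family_f <- function(clustering, key_id, position, reference) {
  mem <- clustering$members[clustering$members$key_id == key_id, ]
  if (nrow(mem) == 0L) stop("unknown key_id")
  votes <- vapply(seq_len(nrow(mem)), function(i) {
    fr <- new_fragments(mem[i, ], frag_mm(clustering$members))
    consolidate_mates(fr, position, reference)
  }, "")
  refb <- ref_base(reference, mem$chrom[1], position)
  n_abstain <- sum(votes == "ABSTAIN")
  eff <- votes[votes != "ABSTAIN"]
  n_nonref <- sum(eff != refb)
  f <- if (length(eff)) n_nonref / length(eff) else NA_real_
  cons <- NA_character_
  alt <- eff[eff != refb]
  if (length(alt)) {
    tb <- sort(table(alt), decreasing = TRUE)
    unique_top <- length(tb) == 1L || tb[1] > tb[2]
    if (unique_top && tb[1] > sum(eff == refb)) cons <- names(tb)[1]
  }
  tibble::tibble(n_votes = length(eff), n_nonref = n_nonref,
                 n_abstain = n_abstain, f = f, consensus = cons)
}

# per-key reduced read-union coverage, counted once per key
key_coverage <- function(keys_members, chrom_lengths) {
  reads <- dplyr::bind_rows(
    tibble::tibble(key_id = keys_members$key_id, chrom = keys_members$chrom,
                   pos = keys_members$r1_pos, len = keys_members$r1_len),
    tibble::tibble(key_id = keys_members$key_id, chrom = keys_members$chrom,
                   pos = keys_members$r2_pos, len = keys_members$r2_len)
  )
  reads <- reads[!is.na(reads$pos), ]
  out <- list()
  for (cn in unique(reads$chrom)) {
    rr <- reads[reads$chrom == cn, ]
    ir <- IRanges::IRanges(start = rr$pos + 1L, width = rr$len)
    red <- IRanges::reduce(S4Vectors::split(ir, rr$key_id))
    out[[cn]] <- IRanges::coverage(unlist(red, use.names = FALSE),
                                   width = chrom_lengths[[cn]])
  }
  out
}

read_coverage <- function(members, chrom_lengths) {
  reads <- dplyr::bind_rows(
    tibble::tibble(chrom = members$chrom, pos = members$r1_pos,
                   len = members$r1_len),
    tibble::tibble(chrom = members$chrom, pos = members$r2_pos,
                   len = members$r2_len)
  )
  reads <- reads[!is.na(reads$pos), ]
  out <- list()
  for (cn in unique(reads$chrom)) {
    rr <- reads[reads$chrom == cn, ]
    out[[cn]] <- IRanges::coverage(
      IRanges::IRanges(start = rr$pos + 1L, width = rr$len),
      width = chrom_lengths[[cn]])
  }
  out
}

cov_at <- function(covlist, chrom, pos) {
  out <- integer(length(pos))
  for (cn in unique(chrom)) {
    i <- chrom == cn
    cv <- covlist[[cn]]
    out[i] <- if (is.null(cv)) 0L else as.integer(cv[pos[i] + 1L])
  }
  out
}

cov_panel_sum <- function(covlist, regions) {
  tot <- 0
  for (i in seq_len(nrow(regions))) {
    cv <- covlist[[regions$chrom[i]]]
    if (is.null(cv)) next
    w <- IRanges::Views(cv, start = regions$start[i] + 1L,
                        end = regions$end[i])
    tot <- tot + sum(IRanges::viewSums(w))
  }
  tot
}

#' Build family-resolution pileups over the panel
#'
#' The central summarization step: fragments are clustered into virtual
#' families, mate bases are consolidated, per-family f values are computed
#' at every position carrying non-reference evidence, and per-position
#' per-allele counts are tallied. Reference-only positions produce no rows;
#' panel-wide denominators are carried in the `stats` attribute.
#'
#' A variant singleton is flagged "qualified" only when at least one family
#' with f >= `f_threshold` supports the same alternate allele at that
#' position.
#'
#' @param fragments A `vb_fragments` tibble.
#' @param reference A `vb_reference`.
#' @param regions Panel tibble (merged).
#' @param f_threshold Minimum f for a family to count as a full mutant
#'   family (default 1.0, i.e. unanimity).
#' @return A `vb_pileup` tibble with one row per (position, alternate
#'   allele) carrying evidence: `chrom`, `pos`, `ref`, `alt`, `n_fam_full`,
#'   `n_fam_sub`, `n_singleton`, `n_qualified_singleton`, `total_families`,
#'   `total_singletons`, `depth`, `af`. Attributes: `support` (supporting
#'   family/singleton spans, for the fragment-end filter) and `stats`
#'   (panel-wide denominators for [sample_stats()]).
#' @export
build_pileups <- function(fragments, reference, regions, f_threshold = 1.0) {
  if (region_width(regions) == 0L) stop("empty panel")
  fragments <- fragment_mismatches(fragments, reference)
  cl <- cluster_families(fragments)
  members <- cl$members
  mm <- frag_mm(fragments)
  if (nrow(mm)) {
    mm_chrom <- members$chrom[match(mm$frag_id, members$frag_id)]
    keep <- positions_in_regions(mm_chrom, mm$pos, regions)
    mm <- mm[keep, ]
    mm_chrom <- mm_chrom[keep]
  } else {
    mm_chrom <- character()
  }

  chrom_lengths <- lapply(reference$seq, length)

  votes <- member_votes(members, mm, reference)
  fam_votes <- votes[votes$fam_size >= 2L, ]
  sing_votes <- votes[votes$fam_size == 1L & votes$vote != "ABSTAIN", ]
  pf <- summarize_family_votes(fam_votes, members)

  fam_members <- members[members$fam_size >= 2L, ]
  sing_members <- members[members$fam_size == 1L, ]
  fam_cov <- key_coverage(fam_members, chrom_lengths)
  sing_cov <- key_coverage(sing_members, chrom_lengths)
  read_cov <- read_coverage(members, chrom_lengths)

  sites <- assemble_sites(pf, sing_votes, members, reference,
                          fam_cov, sing_cov, read_cov, f_threshold)

  n_pos <- region_width(regions)
  raw_err_pos <- dplyr::n_distinct(paste(mm_chrom, mm$pos))
  has_f1 <- !is.na(pf$f) & pf$f >= f_threshold & pf$n_nonref > 0
  fam_err_pos <- dplyr::n_distinct(paste(pf$chrom, pf$pos)[has_f1])
  depth_sum <- cov_panel_sum(read_cov, regions)
  stats <- list(
    n_positions = n_pos,
    panel_mean_depth = depth_sum / n_pos,
    raw_error_positions = raw_err_pos,
    family_error_positions = fam_err_pos,
    n_families = nrow(cl$families),
    n_singletons = nrow(cl$singletons),
    family_sizes = cl$families$size,
    fam_cov_sum = cov_panel_sum(fam_cov, regions),
    singleton_cov_sum = cov_panel_sum(sing_cov, regions),
    depth_sum = depth_sum,
    f_threshold = f_threshold
  )
  attr(sites, "stats") <- stats
  class(sites) <- c("vb_pileup", class(sites))
  sites
}

# assemble the per-(pos, alt) site table plus the support-span table
assemble_sites <- function(pf, sing_votes, members, reference,
                           fam_cov, sing_cov, read_cov, f_threshold) {
  supp_fam <- pf[!is.na(pf$f) & pf$f >= f_threshold &
                   !is.na(pf$consensus_alt), ]
  fam_alt <- dplyr::count(supp_fam, .data$chrom, .data$pos,
                          alt = .data$consensus_alt, name = "n_fam_full")
  sub <- dplyr::summarise(
    dplyr::group_by(pf[!is.na(pf$f) & pf$n_nonref > 0, ],
                    .data$chrom, .data$pos),
    n_fam_sub = sum(.data$f < f_threshold), .groups = "drop")
  sing_alt <- dplyr::count(sing_votes, .data$chrom, .data$pos,
                           alt = .data$vote, name = "n_singleton")

  sites <- dplyr::full_join(fam_alt, sing_alt, by = c("chrom", "pos", "alt"))
  sites <- dplyr::left_join(sites, sub, by = c("chrom", "pos"))
  for (col in c("n_fam_full", "n_singleton", "n_fam_sub")) {
    sites[[col]][is.na(sites[[col]])] <- 0L
  }
  if (nrow(sites) == 0L) {
    sites <- tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            n_fam_full = integer(), n_fam_sub = integer(),
                            n_singleton = integer(),
                            n_qualified_singleton = integer(),
                            total_families = integer(),
                            total_singletons = integer(),
                            depth = integer(), af = double())
    attr(sites, "support") <- empty_support()
    return(sites)
  }
  sites$ref <- ref_base(reference, sites$chrom, sites$pos)
  sites$n_qualified_singleton <- ifelse(sites$n_fam_full > 0L,
                                        sites$n_singleton, 0L)
  sites$total_families <- cov_at(fam_cov, sites$chrom, sites$pos)
  sites$total_singletons <- cov_at(sing_cov, sites$chrom, sites$pos)
  sites$depth <- cov_at(read_cov, sites$chrom, sites$pos)
  denom <- sites$total_families + sites$total_singletons
  sites$af <- ifelse(denom > 0,
                     (sites$n_fam_full + sites$n_qualified_singleton) / denom,
                     NA_real_)
  sites <- dplyr::arrange(sites, .data$chrom, .data$pos, .data$alt)
  sites <- dplyr::select(
    sites, "chrom", "pos", "ref", "alt", "n_fam_full", "n_fam_sub",
    "n_singleton", "n_qualified_singleton", "total_families",
    "total_singletons", "depth", "af")

  # representative member geometry per key: all members of a proper-pair
  # family share read placement, so one member suffices to decide whether a
  # position is covered by both mates (mate-confirmed)
  rep_geo <- members[!duplicated(members$key_id),
                     c("key_id", "r1_pos", "r1_len", "r2_pos", "r2_len")]
  mate_conf <- function(df) {
    g <- rep_geo[match(df$key_id, rep_geo$key_id), ]
    !is.na(g$r1_pos) & !is.na(g$r2_pos) &
      df$pos >= g$r1_pos & df$pos < g$r1_pos + g$r1_len &
      df$pos >= g$r2_pos & df$pos < g$r2_pos + g$r2_len
  }
  fam_support <- tibble::tibble(
    chrom = supp_fam$chrom, pos = supp_fam$pos, alt = supp_fam$consensus_alt,
    key_id = supp_fam$key_id, start = supp_fam$start, end = supp_fam$end,
    size = supp_fam$fam_size, is_singleton = FALSE, f = supp_fam$f,
    mate_confirmed = mate_conf(supp_fam))
  smem <- members[members$fam_size == 1L, c("key_id", "start", "end")]
  ssup <- dplyr::inner_join(sing_votes, smem, by = "key_id")
  sing_support <- tibble::tibble(
    chrom = ssup$chrom, pos = ssup$pos, alt = ssup$vote,
    key_id = ssup$key_id, start = ssup$start, end = ssup$end,
    size = 1L, is_singleton = TRUE, f = 1.0,
    mate_confirmed = mate_conf(ssup))
  support <- dplyr::bind_rows(fam_support, sing_support)
  support <- dplyr::semi_join(support, sites, by = c("chrom", "pos", "alt"))
  attr(sites, "support") <- support
  sites
}

empty_support <- function() {
  tibble::tibble(chrom = character(), pos = integer(), alt = character(),
                 key_id = integer(), start = integer(), end = integer(),
                 size = integer(), is_singleton = logical(), f = double(),
                 mate_confirmed = logical())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Access the support-span table of a pileup
#' @param pileup A `vb_pileup`.
#' @return Tibble of supporting family/singleton spans per (position, alt).
#' @export
pileup_support <- function(pileup) attr(pileup, "support")

#' Access the panel-wide statistics of a pileup
#' @param pileup A `vb_pileup`.
#' @return Named list of panel-wide denominators.
#' @export
pileup_stats <- function(pileup) attr(pileup, "stats")
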