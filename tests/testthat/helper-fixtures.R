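# Shared fixtures: tiny references, hand-laid fragments and small
# simulation scenarios. Everything is generated in code at test time.

BASES <- c("A", "C", "G", "T")

# reference of all-'A' (plus a short panel), so any other base is ALT
flat_reference <- function(len = 400L, chrom = "chr1") {
  reference_from_strings(stats::setNames(list(strrep("A", len)), chrom))
}

# lay out a proper FR pair for a fragment [start, start+tlen)
lay_fragment <- function(start, tlen, strand = "+", read_len = 60L,
                         chrom = "chr1", qname = NULL, umi = NA_character_) {
  rl <- min(read_len, tlen)
  left <- start
  right <- start + tlen - rl
  tibble::tibble(
    qname = if (is.null(qname)) paste0("q", start, "_", tlen) else qname,
    chrom = chrom, start = start, end = start + tlen, tlen = tlen,
    strand = strand,
    r1_pos = if (strand == "+") left else right, r1_len = rl,
    r2_pos = if (strand == "+") right else left, r2_len = rl,
    umi = umi
  )
}

# build a vb_fragments object from stacked lay_fragment() rows and an
# optional mismatch table (frag_id, mate, pos, base)
mk_fragments <- function(rows, mm = NULL) {
  rows$frag_id <- seq_len(nrow(rows))
  if (is.null(mm)) {
    mm <- tibble::tibble(frag_id = integer(), mate = integer(),
                         pos = integer(), base = character())
  }
  vbcall:::new_fragments(rows, mm)
}

# mismatch rows for one fragment at one position on the given mates
mm_rows <- function(frag_id, pos, base, mates = c(1L, 2L)) {
  tibble::tibble(frag_id = frag_id, mate = mates, pos = pos, base = base)
}

small_panel <- function(start = 100L, end = 300L, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = start, end = end)
}

# random fragment set with engineered key collisions (for clustering tests)
random_fragments <- function(n, seed, with_umi = FALSE, read_len = 50L) {
  vbcall:::with_seed(seed, {
    start <- sample(100:160, n, replace = TRUE)
    tlen <- sample(c(80L, 81L, 82L, 90L), n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rl <- pmin(read_len, tlen)
    left <- start
    right <- start + tlen - rl
    rows <- tibble::tibble(
      qname = paste0("r", seq_len(n)),
      chrom = "chr1", start = start, end = start + tlen, tlen = tlen,
      strand = strand,
      r1_pos = ifelse(strand == "+", left, right), r1_len = rl,
      r2_pos = ifelse(strand == "+", right, left), r2_len = rl,
      umi = if (with_umi) sample(c("AAT", "CCG", "GTA", "TTC"), n,
                                 replace = TRUE) else NA_character_
    )
    mk_fragments(rows)
  })
}

# independent group-by partition oracle on explicit key strings: returns a
# canonical signature of the partition (sorted member lists per group)
partition_oracle <- function(ids, keys) {
  unname(sort(vapply(split(ids, keys),
                     function(g) paste(sort(g), collapse = ","), "")))
}

# canonical signature of a clustering result's partition
partition_signature <- function(members) {
  partition_oracle(members$frag_id, members$key_id)
}
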