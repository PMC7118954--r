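#' Fragment records
#'
#' A `vb_fragments` object is a tibble with one row per sequenced cfDNA
#' fragment (read pair), carrying the virtual-barcode key fields
#' (`chrom`, `start`, `tlen`, `strand`) plus read placement. Non-reference
#' bases are held sparsely in the `mismatches` attribute — a tibble of
#' `(frag_id, mate, pos, base)` — rather than as full read sequences, since
#' at realistic error rates almost every base matches the reference.
#'
#' @param df Tibble with columns `frag_id`, `qname`, `chrom`, `start`,
#'   `end`, `tlen`, `strand`, `r1_pos`, `r1_len`, `r2_pos`, `r2_len`, `umi`.
#' @param mismatches Sparse non-reference base tibble (see above), or `NULL`
#'   if not yet computed (sequences must then be present as `r1_seq`/`r2_seq`).
#' @return A `vb_fragments` tibble.
#' @keywords internal
new_fragments <- function(df, mismatches = NULL) {
  df <- tibble::as_tibble(df)
  attr(df, "mismatches") <- mismatches
  class(df) <- c("vb_fragments", class(df))
  df
}

frag_mm <- function(fragments) attr(fragments, "mismatches")

empty_mismatches <- function() {
  tibble::tibble(frag_id = integer(), mate = integer(),
                 pos = integer(), base = character())
}

#' Read fragment records from a coordinate-sorted SAM/BAM file
#'
#' Parses paired-end alignments, applies flag and quality filters
#' (unmapped, secondary, supplementary and QC-fail reads are dropped;
#' `mapq < min_mapq` is dropped), pairs mates by query name, and keeps
#' fragments overlapping the panel. A mate whose partner was filtered out
#' is kept as an "orphan" fragment with `r2_*` absent, with its template
#' length taken from the TLEN field.
#'
#' Only simple all-match CIGARs (`<n>M`) are supported; reads with indels,
#' clipping or splices are dropped with a message (the caller considers
#' SNVs only and performs no realignment).
#'
#' @param path SAM or BAM file, coordinate-sorted.
#' @param regions Optional panel tibble from [read_bed()]; fragments not
#'   overlapping it are dropped.
#' @param min_mapq Minimum mapping quality (default 30; paralogous regions
#'   produce multi-mapping reads with low MAPQ).
#' @param max_tlen Maximum absolute template length for a proper fragment
#'   (default 1000 bp; cfDNA fragments are short and larger TLEN indicates
#'   an artifactual pair). Pairs with TLEN 0 are treated as discordant.
#' @param umi_tag Optional SAM tag holding a molecular barcode
#'   (default `"RX"`).
#' @return A `vb_fragments` tibble with read sequences attached
#'   (`r1_seq`, `r2_seq`); call [fragment_mismatches()] with a reference to
#'   convert these to the sparse mismatch representation.
#' @export
read_fragments <- function(path, regions = NULL, min_mapq = 30L,
                           max_tlen = 1000L, umi_tag = "RX") {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isNotPassingQualityControls = FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "isize", "seq"),
    tag = umi_tag
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  umi <- res$tag[[umi_tag]]
  rd <- tibble::tibble(
    qname = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    pos = res$pos - 1L,           # 0-based
    mapq = res$mapq,
    cigar = res$cigar,
    tlen = res$isize,
    seq = as.character(res$seq),
    umi = if (is.null(umi)) NA_character_ else as.character(umi)
  )
  # coordinate order check (per chromosome, as scanBam preserves file order)
  for (cn in unique(rd$chrom)) {
    p <- rd$pos[rd$chrom == cn]
    if (is.unsorted(p)) stop("input alignments are not coordinate-sorted")
  }
  simple <- grepl("^[0-9]+M$", rd$cigar)
  if (any(!simple)) {
    message(sum(!simple), " read(s) with non all-match CIGAR dropped")
    rd <- rd[simple, ]
  }
  rd <- rd[!is.na(rd$mapq) & rd$mapq >= min_mapq, ]
  if (nrow(rd) == 0L) {
    return(new_fragments(empty_fragment_df(), empty_mismatches()))
  }
  rd$len <- as.integer(sub("M$", "", rd$cigar))
  rd$is_r1 <- bitwAnd(rd$flag, 64L) > 0L
  rd$is_rev <- bitwAnd(rd$flag, 16L) > 0L

  r1 <- rd[rd$is_r1, ]
  r2 <- rd[!rd$is_r1, ]
  j <- match(r1$qname, r2$qname)
  paired <- !is.na(j)
  r2m <- r2[j[paired], , drop = FALSE]
  r1p <- r1[paired, , drop = FALSE]

  frag_paired <- tibble::tibble(
    qname = r1p$qname,
    chrom = r1p$chrom,
    start = pmin(r1p$pos, r2m$pos),
    tlen = abs(r1p$tlen),
    strand = as.character(ifelse(r1p$is_rev, "-", "+")),
    r1_pos = r1p$pos, r1_len = r1p$len, r1_seq = r1p$seq,
    r2_pos = r2m$pos, r2_len = r2m$len, r2_seq = r2m$seq,
    umi = r1p$umi
  )
  # orphans: R1 without surviving mate, and R2 without surviving R1
  orph1 <- r1[!paired, , drop = FALSE]
  orph2 <- r2[!(r2$qname %in% r1$qname), , drop = FALSE]
  orph <- dplyr::bind_rows(orph1, orph2)
  frags <- frag_paired
  if (nrow(orph)) {
    frag_orphan <- tibble::tibble(
      qname = orph$qname,
      chrom = orph$chrom,
      start = as.integer(ifelse(orph$tlen >= 0L, orph$pos,
                                orph$pos + orph$len - abs(orph$tlen))),
      tlen = abs(orph$tlen),
      strand = as.character(ifelse(xor(orph$is_rev, !orph$is_r1), "-", "+")),
      r1_pos = orph$pos, r1_len = orph$len, r1_seq = orph$seq,
      r2_pos = NA_integer_, r2_len = NA_integer_, r2_seq = NA_character_,
      umi = orph$umi
    )
    frags <- dplyr::bind_rows(frag_paired, frag_orphan)
  }
  frags <- frags[frags$tlen > 0L & frags$tlen <= max_tlen, ]
  frags$end <- frags$start + frags$tlen
  if (!is.null(regions) && nrow(frags) > 0L) {
    frags <- frags[overlaps_regions(frags$chrom, frags$start, frags$end, regions), ]
  }
  frags <- dplyr::arrange(frags, .data$chrom, .data$start, .data$tlen, .data$qname)
  frags$frag_id <- seq_len(nrow(frags))
  frags <- dplyr::select(
    frags, "frag_id", "qname", "chrom", "start", "end", "tlen", "strand",
    "r1_pos", "r1_len", "r1_seq", "r2_pos", "r2_len", "r2_seq", "umi"
  )
  new_fragments(frags, NULL)
}

empty_fragment_df <- function() {
  tibble::tibble(
    frag_id = integer(), qname = character(), chrom = character(),
    start = integer(), end = integer(), tlen = integer(), strand = character(),
    r1_pos = integer(), r1_len = integer(), r2_pos = integer(),
    r2_len = integer(), umi = character()
  )
}

#' Extract sparse non-reference bases from fragment read sequences
#'
#' Compares each read against the reference and stores only differing
#' bases in the `mismatches` attribute, after which the (bulky) sequence
#' columns are dropped. Fragments produced by the simulator already carry
#' their mismatch table and pass through unchanged.
#'
#' @param fragments A `vb_fragments` tibble.
#' @param reference A `vb_reference`.
#' @param chunk_size Reads compared per chunk (memory/speed trade-off).
#' @return The fragments with the `mismatches` attribute populated.
#' @export
fragment_mismatches <- function(fragments, reference, chunk_size = 200000L) {
  if (!is.null(frag_mm(fragments))) return(fragments)
  reads <- dplyr::bind_rows(
    tibble::tibble(frag_id = fragments$frag_id, mate = 1L,
                   chrom = fragments$chrom, pos = fragments$r1_pos,
                   len = fragments$r1_len, seq = fragments$r1_seq),
    tibble::tibble(frag_id = fragments$frag_id, mate = 2L,
                   chrom = fragments$chrom, pos = fragments$r2_pos,
                   len = fragments$r2_len, seq = fragments$r2_seq)
  )
  reads <- reads[!is.na(reads$pos), ]
  out <- vector("list", 0L)
  for (cn in unique(reads$chrom)) {
    rr <- reads[reads$chrom == cn, ]
    refb <- ref_raw(reference, cn)
    n <- nrow(rr)
    for (lo in seq(1L, n, by = chunk_size)) {
      hi <- min(lo + chunk_size - 1L, n)
      ch <- rr[lo:hi, ]
      readb <- charToRaw(paste(toupper(ch$seq), collapse = ""))
      idx <- sequence(ch$len, from = ch$pos + 1L)
      if (length(readb) != length(idx)) {
        stop("read length does not match CIGAR-implied length")
      }
      diffs <- which(readb != refb[idx])
      if (length(diffs)) {
        cum <- cumsum(ch$len)
        row <- findInterval(diffs - 1L, cum) + 1L
        offset <- diffs - c(0L, cum)[row] - 1L
        out[[length(out) + 1L]] <- tibble::tibble(
          frag_id = ch$frag_id[row],
          mate = ch$mate[row],
          pos = ch$pos[row] + offset,
          base = strsplit(rawToChar(readb[diffs]), "")[[1]]
        )
      }
    }
  }
  mm <- if (length(out)) dplyr::bind_rows(out) else empty_mismatches()
  mm <- mm[mm$base %in% c("A", "C", "G", "T"), ]
  fragments$r1_seq <- NULL
  fragments$r2_seq <- NULL
  new_fragments(fragments, mm)
}
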