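#' Read a BED file of panel (or blacklist) regions
#'
#' Regions are 0-based, half-open, as in BED. After parsing, regions are
#' sorted and overlapping/abutting regions on the same chromosome are merged,
#' so downstream code can assume a disjoint sorted panel.
#'
#' @param path Path to a BED file (first three columns used).
#' @return A tibble with columns `chrom`, `start` (0-based, inclusive) and
#'   `end` (exclusive), sorted and merged.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    stop("malformed BED line ", bad[1], " in '", path, "': fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad)) {
    stop("malformed BED line ", bad[1], ": start must be < end (0-based half-open)")
  }
  merge_regions(tibble::tibble(chrom = chrom, start = start, end = end))
}

#' Sort and merge genomic regions
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return Tibble of disjoint sorted regions; abutting regions are merged.
#' @export
merge_regions <- function(regions) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (nrow(regions) == 0L) return(tibble::as_tibble(regions))
  gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr)
  )
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Write regions to a BED file
#' @param regions Tibble with `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  writeLines(sprintf("%s\t%d\t%d", regions$chrom, regions$start, regions$end), path)
  invisible(path)
}

#' Total size of a region set in bp
#' @param regions Tibble of merged regions.
#' @return Integer number of positions covered.
#' @export
region_width <- function(regions) sum(regions$end - regions$start)

# TRUE for each (chrom, pos) lying inside any region; pos 0-based.
positions_in_regions <- function(chrom, pos, regions) {
  if (nrow(regions) == 0L) return(rep(FALSE, length(pos)))
  inside <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(regions))) {
    inside <- inside |
      (chrom == regions$chrom[i] & pos >= regions$start[i] & pos < regions$end[i])
  }
  inside
}

# TRUE for fragments [start,end) overlapping any region on chrom.
overlaps_regions <- function(chrom, start, end, regions) {
  hit <- rep(FALSE, length(start))
  for (i in seq_len(nrow(regions))) {
    hit <- hit |
      (chrom == regions$chrom[i] & start < regions$end[i] & end > regions$start[i])
  }
  hit
}
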