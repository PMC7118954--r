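#' Load a reference genome from FASTA
#'
#' @param path Path to a FASTA file (an `.fai` index is not required; the
#'   whole sequence set is read into memory, which is appropriate for
#'   panel-scale references).
#' @return An object of class `vb_reference` supporting [ref_base()].
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  new_reference(seqs)
}

new_reference <- function(seqs) {
  # store per-chromosome raw byte vectors of the uppercase sequence for
  # O(1) vectorized base lookup
  raw <- lapply(seq_along(seqs), function(i) {
    charToRaw(toupper(as.character(seqs[[i]])))
  })
  names(raw) <- names(seqs)
  structure(list(seq = raw), class = "vb_reference")
}

#' Construct a reference from named character strings
#' @param ... Named chromosome sequences, e.g. `chr1 = "ACGT..."`.
#' @return A `vb_reference`.
#' @export
reference_from_strings <- function(...) {
  x <- list(...)
  if (length(x) == 1L && is.list(x[[1]])) x <- x[[1]]
  raw <- lapply(x, function(s) charToRaw(toupper(s)))
  structure(list(seq = raw), class = "vb_reference")
}

#' @export
print.vb_reference <- function(x, ...) {
  cat("<vb_reference> ", length(x$seq), " sequence(s): ",
      paste0(names(x$seq), " (", vapply(x$seq, length, 1L), " bp)",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Reference base lookup
#'
#' @param reference A `vb_reference`.
#' @param chrom Chromosome name(s), recycled against `pos`.
#' @param pos 0-based position(s).
#' @return Uppercase base character vector.
#' @export
ref_base <- function(reference, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  out <- character(n)
  for (cn in unique(chrom)) {
    if (!cn %in% names(reference$seq)) {
      stop("chromosome '", cn, "' absent from reference")
    }
    idx <- which(chrom == cn)
    p <- pos[idx]
    if (any(p < 0L | p >= length(reference$seq[[cn]]))) {
      stop("position out of range on chromosome '", cn, "'")
    }
    out[idx] <- strsplit(rawToChar(reference$seq[[cn]][p + 1L]), "")[[1]]
  }
  out
}

# raw bytes of chrom sequence (internal fast path)
ref_raw <- function(reference, chrom) {
  r <- reference$seq[[chrom]]
  if (is.null(r)) stop("chromosome '", chrom, "' absent from reference")
  r
}

ref_length <- function(reference, chrom) length(ref_raw(reference, chrom))

#' Write a reference to FASTA
#' @param reference A `vb_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cn in names(reference$seq)) {
    writeLines(paste0(">", cn), con)
    s <- rawToChar(reference$seq[[cn]])
    # wrap at 70 columns
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

#' Generate a random reference sequence
#'
#' Used by the simulator when no reference is supplied. Deterministic given
#' the current RNG state.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return A `vb_reference`.
#' @export
random_reference <- function(chrom_lengths) {
  raw <- lapply(chrom_lengths, function(n) {
    charToRaw(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
  })
  names(raw) <- names(chrom_lengths)
  structure(list(seq = raw), class = "vb_reference")
}
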