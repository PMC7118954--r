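#' Remove candidates falling inside blacklist regions
#'
#' Low-complexity and short-tandem-repeat regions produce recurrent
#' alignment artifacts; candidates inside them are removed outright.
#'
#' @param candidates Tibble with `chrom` and `pos` (0-based).
#' @param blacklist Merged region tibble, or `NULL`/empty for a no-op.
#' @return The surviving candidate rows.
#' @export
apply_blacklist <- function(candidates, blacklist = NULL) {
  if (is.null(blacklist) || nrow(blacklist) == 0L || nrow(candidates) == 0L) {
    return(candidates)
  }
  keep <- !positions_in_regions(candidates$chrom, candidates$pos, blacklist)
  candidates[keep, ]
}

#' Call SNVs in one sample
#'
#' Runs the full pipeline in fixed stage order: family-resolution pileup,
#' full-f candidate selection, blacklist, background polishing, Ds /
#' false-family-ratio filter, sample-level singleton-ratio filter, and the
#' minimum-template threshold. Deterministic given inputs and
#' configuration.
#'
#' @param x A `vb_fragments` tibble (e.g. from [simulate_sample()]) or a
#'   path to a coordinate-sorted SAM/BAM file.
#' @param regions Panel tibble from [read_bed()].
#' @param reference A `vb_reference`.
#' @param db Optional `vb_background_db`. Without it no polishing is done
#'   and the background template rate is taken as 0.
#' @param blacklist Optional blacklist region tibble.
#' @param config A `vb_filter_config`.
#' @param f_threshold Family f threshold (default 1.0).
#' @param sample_name Sample label for reporting/VCF.
#' @param min_mapq,max_tlen,umi_tag Passed to [read_fragments()] when `x`
#'   is a file path.
#' @return A `vb_result` list: `calls` (tibble of surviving variants with
#'   per-stage filter trail), `audit` (per-stage candidate counts),
#'   `stats` (one-row [sample_stats()] tibble), `sample_name`, `config`.
#' @export
call_sample <- function(x, regions, reference, db = NULL, blacklist = NULL,
                        config = filter_config(), f_threshold = 1.0,
                        sample_name = "sample", min_mapq = 30L,
                        max_tlen = 1000L, umi_tag = "RX") {
  fragments <- x
  if (is.character(x)) {
    fragments <- read_fragments(x, regions, min_mapq = min_mapq,
                                max_tlen = max_tlen, umi_tag = umi_tag)
  }
  if (!is.null(db) && nrow(db$sites) > 0L) {
    db_chroms <- unique(db$sites$chrom)
    if (!all(db_chroms %in% regions$chrom)) {
      stop("background database refers to chromosomes outside the panel; ",
           "panel/database mismatch")
    }
  }
  pileup <- build_pileups(fragments, reference, regions, f_threshold)
  stats <- sample_stats(pileup)
  support <- pileup_support(pileup)

  audit <- tibble::tibble(stage = character(), n_candidates = integer())
  note <- function(stage, n) {
    audit <<- dplyr::bind_rows(audit,
                               tibble::tibble(stage = stage,
                                              n_candidates = as.integer(n)))
  }
  note("raw_pileup", pileup_stats(pileup)$raw_error_positions)

  cand <- pileup[pileup$n_fam_full > 0L, ]
  cand <- tibble::as_tibble(cand)
  note("virtual_barcode", nrow(cand))

  cand <- apply_blacklist(cand, blacklist)
  note("blacklist", nrow(cand))

  if (!is.null(db)) {
    verdict <- polish(cand$chrom, cand$pos, cand$alt, cand$af, db)
    cand <- cand[verdict == "PASS", ]
  }
  note("polishing", nrow(cand))

  # Ds / FFR filter, with pruning of false templates
  if (nrow(cand)) {
    skey <- paste(support$chrom, support$pos, support$alt)
    res <- purrr::map(seq_len(nrow(cand)), function(i) {
      sup <- support[skey == paste(cand$chrom[i], cand$pos[i], cand$alt[i]), ]
      ffr_filter(sup, config)
    })
    cand$ffr <- vapply(res, `[[`, 0, "ffr")
    cand$updated_families <- vapply(res, `[[`, 0L, "updated_families")
    cand$updated_singletons <- vapply(res, `[[`, 0L, "updated_singletons")
    cand$updated_template_count <- vapply(res, `[[`, 0L,
                                          "updated_template_count")
    ffr_pass <- vapply(res, `[[`, "", "verdict") == "PASS" &
      cand$updated_families > 0L
    cand <- cand[ffr_pass, ]
  } else {
    cand$ffr <- double()
    cand$updated_families <- integer()
    cand$updated_singletons <- integer()
    cand$updated_template_count <- integer()
  }
  note("ds_ffr", nrow(cand))

  sr_in <- tibble::tibble(n_families = cand$updated_families,
                          n_singletons = cand$updated_singletons,
                          af = cand$af)
  sr <- singleton_ratio_filter(sr_in, stats$panel_singleton_ratio, config)
  cand$singleton_ratio <- sr$singleton_ratio
  cand$singleton_padj <- sr$singleton_padj
  cand <- cand[sr$singleton_verdict == "PASS", ]
  note("singleton_ratio", nrow(cand))

  rate <- if (is.null(db)) 0 else db$background_template_rate
  if (nrow(cand)) {
    cand$k_min <- vapply(cand$total_families + cand$total_singletons,
                         template_threshold, 0L,
                         background_template_rate = rate,
                         confidence = config$confidence)
  } else {
    cand$k_min <- integer()
  }
  cand <- cand[template_filter(cand$updated_template_count, cand$k_min) ==
                 "PASS", ]
  note("template_threshold", nrow(cand))

  denom <- cand$total_families + cand$total_singletons
  calls <- tibble::tibble(
    chrom = cand$chrom, pos = cand$pos, ref = cand$ref, alt = cand$alt,
    af = ifelse(denom > 0,
                (cand$updated_families + cand$updated_singletons) / denom,
                NA_real_),
    n_families = cand$updated_families,
    n_singletons = cand$updated_singletons,
    total_templates = denom,
    depth = cand$depth,
    ffr = cand$ffr,
    singleton_ratio = cand$singleton_ratio,
    k_min = cand$k_min
  )
  structure(list(calls = calls, audit = audit, stats = stats,
                 sample_name = sample_name, config = config),
            class = "vb_result")
}

#' @export
print.vb_result <- function(x, ...) {
  cat("<vb_result> sample '", x$sample_name, "': ", nrow(x$calls),
      " call(s)\n", sep = "")
  if (nrow(x$calls)) {
    print(x$calls, n = 10)
  }
  cat("audit: ", paste0(x$audit$stage, "=", x$audit$n_candidates,
                        collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Write calls to a VCF 4.2 file
#'
#' Positions are converted to 1-based VCF coordinates. Supporting full-f
#' family count (NF), qualified singleton count (NS) and family-level AF
#' are written as INFO fields.
#'
#' @param result A `vb_result` (or a calls tibble).
#' @param path Output path.
#' @param reference Optional `vb_reference` for contig header lines.
#' @param sample_name Sample label (defaults to the result's).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(result, path, reference = NULL, sample_name = NULL) {
  calls <- if (inherits(result, "vb_result")) result$calls else result
  if (is.null(sample_name)) {
    sample_name <- if (inherits(result, "vb_result")) result$sample_name
                   else "sample"
  }
  if (nrow(calls) > 1L) {
    o <- order(calls$chrom, calls$pos)
    if (!identical(o, seq_len(nrow(calls)))) {
      stop("calls must be sorted by (chrom, pos)")
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=vbcall",
    sprintf("##INFO=<ID=%s,Number=%s,Type=%s,Description=\"%s\">",
            c("NF", "NS", "AF", "DP"),
            c("1", "1", "1", "1"),
            c("Integer", "Integer", "Float", "Integer"),
            c("Supporting f=1.0 virtual family count",
              "Qualified variant singleton count",
              "Family-level allelic fraction",
              "Read depth at position"))
  )
  if (!is.null(reference)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(reference$seq),
                          vapply(reference$seq, length, 1L)))
  }
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  body <- character(0)
  if (nrow(calls)) {
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tNF=%d;NS=%d;AF=%.6g;DP=%d",
                    calls$chrom, calls$pos + 1L, calls$ref, calls$alt,
                    calls$n_families, calls$n_singletons, calls$af,
                    calls$depth)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
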