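#' Panel-wide sample noise statistics
#'
#' Summarizes the noise profile of one sample from its family-resolution
#' pileup: the fraction of panel positions carrying read-level errors, the
#' (much smaller) fraction carrying mutant-family-level errors, the family
#' degree, the panel-wide singleton ratio and the median virtual family
#' size.
#'
#' @param pileup A `vb_pileup` from [build_pileups()].
#' @return A one-row tibble with columns `panel_mean_depth`, `n_positions`,
#'   `error_position_fraction_raw`, `error_position_fraction_family`,
#'   `family_degree`, `panel_singleton_ratio`, `median_family_size`.
#' @export
sample_stats <- function(pileup) {
  st <- pileup_stats(pileup)
  if (is.null(st)) stop("pileup carries no stats attribute")
  ef <- error_position_fractions(pileup)
  tibble::tibble(
    panel_mean_depth = st$panel_mean_depth,
    n_positions = st$n_positions,
    error_position_fraction_raw = ef$raw,
    error_position_fraction_family = ef$family,
    family_degree = family_degree(pileup),
    panel_singleton_ratio = panel_singleton_ratio(pileup),
    median_family_size = median_family_size(pileup)
  )
}

#' Error-position fractions at read and mutant-family level
#'
#' `raw` is the fraction of panel positions with at least one non-reference
#' read base; `family` is the fraction with at least one family whose f
#' value reaches the pileup's threshold (mutant-family-level noise). The
#' clustering step can only remove evidence, so `family <= raw` always.
#'
#' @param pileup A `vb_pileup`.
#' @return List with elements `raw` and `family`.
#' @export
error_position_fractions <- function(pileup) {
  st <- pileup_stats(pileup)
  if (st$n_positions == 0) stop("empty panel")
  list(raw = st$raw_error_positions / st$n_positions,
       family = st$family_error_positions / st$n_positions)
}

#' Family degree: panel-wide family numbers normalized by coverage
#'
#' Defined as the position-summed virtual family count divided by the
#' position-summed read depth over the panel; for homogeneous family size
#' s (and no singletons) this is 1/s, so its reciprocal tracks the median
#' family size.
#'
#' @param pileup A `vb_pileup`.
#' @return Dimensionless ratio in (0, 0.5] for family-only samples.
#' @export
family_degree <- function(pileup) {
  st <- pileup_stats(pileup)
  if (st$depth_sum == 0) stop("zero read depth over the panel")
  st$fam_cov_sum / st$depth_sum
}

#' Panel-wide singleton ratio
#'
#' Total singleton count divided by total virtual family count.
#'
#' @param pileup A `vb_pileup`.
#' @return Ratio >= 0.
#' @export
panel_singleton_ratio <- function(pileup) {
  st <- pileup_stats(pileup)
  if (st$n_families == 0) stop("no virtual families in sample")
  st$n_singletons / st$n_families
}

#' Median virtual family size
#' @param pileup A `vb_pileup`.
#' @return Median of member counts over families (>= 2 when families exist).
#' @export
median_family_size <- function(pileup) {
  st <- pileup_stats(pileup)
  if (st$n_families == 0) stop("no virtual families in sample")
  stats::median(st$family_sizes)
}
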