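#' Filter configuration
#'
#' Thresholds for the three fine-tuning filters against stochastic
#' mutant-family-level noise.
#'
#' @param ds_low A supporting template whose variant lies within `ds_low`
#'   bp of a fragment end is a false family (default 2).
#' @param ds_high ... or at least `ds_high` bp from the near end
#'   (default 149; with 150 bp reads this marks variants at or beyond the
#'   far read end of the template span). Panel/read-length dependent.
#' @param high_af_threshold AF at or above which a site is used to
#'   estimate the sample's expected singleton proportion (default 0.05).
#' @param singleton_fdr Benjamini-Hochberg level for the sample-level
#'   singleton-ratio outlier removal (default 0.01).
#' @param panel_ratio_cutoff Variant-singleton ratio below which a site
#'   always passes the singleton filter (default 2.0, the panel-wide bound
#'   observed across background cohorts).
#' @param confidence Confidence level of the minimum-template threshold
#'   (default 0.99).
#' @param min_high_af_sites Minimum number of high-AF sites before their
#'   pooled counts replace the panel-wide singleton proportion (default 3).
#' @param require_mate_overlap Additionally treat a supporting template as
#'   false when its variant is not covered by both mates (default `TRUE`).
#'   Where only one mate covers a position, mate consolidation cannot veto
#'   a read error, so unanimous-error families arise exclusively in those
#'   single-covered end zones; the Ds cutoffs are a data-derived proxy for
#'   the same geometry.
#' @return A `vb_filter_config` list.
#' @export
filter_config <- function(ds_low = 2L, ds_high = 149L,
                          high_af_threshold = 0.05, singleton_fdr = 0.01,
                          panel_ratio_cutoff = 2.0, confidence = 0.99,
                          min_high_af_sites = 3L,
                          require_mate_overlap = TRUE) {
  stopifnot(ds_low >= 0, ds_low < ds_high,
            high_af_threshold > 0, high_af_threshold < 1,
            singleton_fdr > 0, singleton_fdr < 1)
  if (confidence < 0.8 || confidence > 0.995) {
    stop("confidence must lie in [0.8, 0.995]")
  }
  structure(list(ds_low = ds_low, ds_high = ds_high,
                 high_af_threshold = high_af_threshold,
                 singleton_fdr = singleton_fdr,
                 panel_ratio_cutoff = panel_ratio_cutoff,
                 confidence = confidence,
                 min_high_af_sites = min_high_af_sites,
                 require_mate_overlap = require_mate_overlap),
            class = "vb_filter_config")
}

#' Minimum distance from a variant to its template's ends
#'
#' The Ds value of a supporting template is the smaller of the distances
#' from the variant position to the first and last base of the template
#' span `[start, end)`.
#'
#' @param start,end Template span, 0-based half-open (vectorized).
#' @param position Variant position, 0-based.
#' @return Integer Ds values.
#' @export
ds_value <- function(start, end, position) {
  if (any(position < start | position >= end)) {
    stop("variant position outside template span")
  }
  pmin(position - start, (end - 1L) - position)
}

#' Is a supporting template a false family?
#'
#' Stochastic artifact templates carry their variant at characteristic
#' extreme positions: `ds <= ds_low` or `ds >= ds_high`.
#'
#' @param ds Ds value(s) from [ds_value()].
#' @param config A `vb_filter_config`.
#' @return Logical vector.
#' @export
is_false_family <- function(ds, config = filter_config()) {
  stopifnot(all(ds >= 0))
  ds <= config$ds_low | ds >= config$ds_high
}

#' False-family-ratio filter for one site
#'
#' Computes Ds for every supporting template (full-f families and variant
#' singletons both have spans), flags false families, and fails the site
#' only when every supporting family is false (FFR = 1.0). False families
#' and false singletons are pruned from the updated template count either
#' way.
#'
#' @param support Tibble of supporting templates for one (position, alt):
#'   columns `pos`, `start`, `end`, `is_singleton`, and (when
#'   `require_mate_overlap` is set) `mate_confirmed`.
#' @param config A `vb_filter_config`.
#' @return List: `verdict` (`"PASS"`/`"FAIL_FFR"`), `ffr`,
#'   `n_false_families`, `updated_families`, `updated_singletons`,
#'   `updated_template_count`, and the pruned `support` table.
#' @export
ffr_filter <- function(support, config = filter_config()) {
  fam <- support[!support$is_singleton, ]
  if (nrow(fam) == 0L) stop("site has no supporting family")
  ds <- ds_value(support$start, support$end, support$pos)
  false <- is_false_family(ds, config)
  if (isTRUE(config$require_mate_overlap) &&
      "mate_confirmed" %in% names(support)) {
    false <- false | !support$mate_confirmed
  }
  ffr <- mean(false[!support$is_singleton])
  surviving <- support[!false, ]
  list(
    verdict = if (ffr >= 1.0) "FAIL_FFR" else "PASS",
    ffr = ffr,
    n_false_families = sum(false & !support$is_singleton),
    updated_families = sum(!surviving$is_singleton),
    updated_singletons = sum(surviving$is_singleton),
    updated_template_count = nrow(surviving),
    support = surviving
  )
}

#' Variant-singleton ratio of a site
#'
#' Qualified variant singleton count over full-f variant family count.
#'
#' @param n_singletons,n_families Counts for the site.
#' @return Ratio.
#' @export
variant_singleton_ratio <- function(n_singletons, n_families) {
  if (any(n_families == 0)) stop("site requires at least one full-f family")
  n_singletons / n_families
}

#' Sample-level singleton-ratio filter
#'
#' Two-stage removal of sites whose variant singletons are implausibly
#' abundant. Stage 1: any site whose variant-singleton ratio is at most
#' `panel_ratio_cutoff` passes. Stage 2: the expected singleton proportion
#' `p_hat` is estimated from pooled (singleton, family) counts of high-AF
#' sites (falling back to the panel-wide singleton proportion when fewer
#' than `min_high_af_sites` exist); each remaining site gets a binomial
#' exceedance p-value for its singleton count given its supporting
#' templates, Benjamini-Hochberg correction is applied across them, and a
#' site fails iff its adjusted p-value is at most `singleton_fdr`.
#' Samples whose panel-wide singleton ratio exceeds `panel_ratio_cutoff`
#' (singleton-dominated libraries) skip stage 2 entirely.
#'
#' @param sites Tibble with one row per candidate site: columns
#'   `n_families` (full-f, post-Ds), `n_singletons` (qualified, post-Ds)
#'   and `af`.
#' @param panel_singleton_ratio The sample's panel-wide singleton ratio.
#' @param config A `vb_filter_config`.
#' @return The input tibble plus `singleton_ratio`, `singleton_p`,
#'   `singleton_padj` and `singleton_verdict`
#'   (`"PASS"`/`"FAIL_SINGLETON"`).
#' @export
singleton_ratio_filter <- function(sites, panel_singleton_ratio,
                                   config = filter_config()) {
  out <- tibble::as_tibble(sites)
  n <- nrow(out)
  out$singleton_ratio <- ifelse(out$n_families > 0,
                                out$n_singletons / out$n_families, Inf)
  out$singleton_p <- NA_real_
  out$singleton_padj <- NA_real_
  out$singleton_verdict <- "PASS"
  if (n == 0L) return(out)
  stage2 <- out$singleton_ratio > config$panel_ratio_cutoff
  if (!any(stage2) || panel_singleton_ratio > config$panel_ratio_cutoff) {
    return(out)
  }
  high <- out[out$af >= config$high_af_threshold, ]
  if (nrow(high) >= config$min_high_af_sites) {
    p_hat <- sum(high$n_singletons) /
      sum(high$n_singletons + high$n_families)
  } else {
    p_hat <- panel_singleton_ratio / (1 + panel_singleton_ratio)
  }
  p_hat <- min(max(p_hat, 1e-12), 1 - 1e-12)
  idx <- which(stage2)
  s <- out$n_singletons[idx]
  t <- out$n_singletons[idx] + out$n_families[idx]
  pv <- stats::pbinom(s - 1L, t, p_hat, lower.tail = FALSE)
  padj <- stats::p.adjust(pv, method = "BH")
  out$singleton_p[idx] <- pv
  out$singleton_padj[idx] <- padj
  out$singleton_verdict[idx] <- ifelse(padj <= config$singleton_fdr,
                                       "FAIL_SINGLETON", "PASS")
  out
}

#' Minimum supporting-template threshold
#'
#' The smallest k such that, under independent background trials at
#' `background_template_rate` among `total_templates` templates, the
#' probability of observing at least k background-supporting templates is
#' at most `1 - confidence`.
#'
#' @param total_templates Templates (families + singletons) at the site.
#' @param background_template_rate Per-template background support rate,
#'   from the background database.
#' @param confidence Confidence level in \[0.8, 0.995\].
#' @return Integer `k_min >= 1`.
#' @export
template_threshold <- function(total_templates, background_template_rate,
                               confidence = 0.99) {
  if (confidence < 0.8 || confidence > 0.995) {
    stop("confidence must lie in [0.8, 0.995]")
  }
  stopifnot(total_templates >= 1,
            background_template_rate >= 0, background_template_rate < 1)
  if (background_template_rate == 0) return(1L)
  alpha <- 1 - confidence
  k <- 1L
  while (stats::pbinom(k - 1L, total_templates, background_template_rate,
                       lower.tail = FALSE) > alpha) {
    k <- k + 1L
    if (k > total_templates) break
  }
  k
}

#' Apply the minimum-template filter
#'
#' @param updated_template_count Surviving full-f families plus surviving
#'   qualified singletons after Ds pruning.
#' @param k_min From [template_threshold()].
#' @return `"PASS"` or `"FAIL_TEMPLATE"` (vectorized).
#' @export
template_filter <- function(updated_template_count, k_min) {
  ifelse(updated_template_count >= k_min, "PASS", "FAIL_TEMPLATE")
}
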