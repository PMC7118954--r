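#' Collect mutant-family-level background observations from BG pileups
#'
#' One observation per (sample, position, alternate allele) with at least
#' one full-f mutant family; the AF is the family-level allelic fraction
#' (full-f families plus qualified variant singletons over all families
#' plus singletons covering the position).
#'
#' @param bg_pileups Named list of `vb_pileup` objects, one per background
#'   sample (names become sample ids).
#' @return Tibble with `sample_id`, `chrom`, `pos`, `ref`, `alt`, `af`.
#' @export
collect_observations <- function(bg_pileups) {
  if (is.null(names(bg_pileups)) || any(!nzchar(names(bg_pileups)))) {
    names(bg_pileups) <- paste0("BG", seq_along(bg_pileups))
  }
  purrr::map_dfr(names(bg_pileups), function(id) {
    p <- bg_pileups[[id]]
    obs <- p[p$n_fam_full > 0L, c("chrom", "pos", "ref", "alt", "af")]
    if (nrow(obs) == 0L) return(NULL)
    tibble::tibble(sample_id = id, obs)
  })
}

#' Classify background site-alts as stereotypical or stochastic
#'
#' A (position, alternate allele) is stereotypical when it carries a
#' full-f mutant-family observation in at least `min_occurrence`
#' background samples; all others are stochastic. Classification is per
#' allele: a different substitution at the same position is unaffected.
#'
#' @param observations Tibble from [collect_observations()].
#' @param min_occurrence Minimum number of BG samples (default 6).
#' @return List with `stereotypical` and `stochastic` tibbles
#'   (`chrom`, `pos`, `ref`, `alt`, `occurrence`).
#' @export
classify_sites <- function(observations, min_occurrence = 6L) {
  if (min_occurrence < 1L) stop("min_occurrence must be >= 1")
  occ <- dplyr::summarise(
    dplyr::group_by(observations, .data$chrom, .data$pos, .data$ref, .data$alt),
    occurrence = dplyr::n_distinct(.data$sample_id), .groups = "drop")
  list(stereotypical = occ[occ$occurrence >= min_occurrence, ],
       stochastic = occ[occ$occurrence < min_occurrence, ])
}

#' Build the polishing background database
#'
#' Classifies recurrent (stereotypical) mutant-family-level noise across a
#' background cohort, fits each stereotypical site's AF distribution from
#' the candidate family, derives the per-site AF cutoff at the requested
#' confidence, and records the cohort-level background template rate used
#' by the minimum-template filter.
#'
#' Sites with fewer than `min_fit_n` AF values (or a degenerate,
#' zero-variance AF sample) fall back to the empirical `confidence`
#' quantile of their observed AFs, flagged with `dist_name = "empirical"`.
#'
#' With `calibrate = TRUE` (the default) each site's cutoff confidence is
#' adjusted by a seeded parametric bootstrap so that the probability that
#' a *future* background AF draw exceeds the cutoff is close to
#' `1 - confidence` despite parameter-estimation noise at small cohort
#' sizes; the plugin quantile of a distribution fitted to few samples
#' under-covers otherwise.
#'
#' @param bg_pileups Named list of `vb_pileup` objects for the BG cohort.
#' @param extra_observations Optional tibble of additional AF observations
#'   (same shape as [collect_observations()] output) pooled into the
#'   per-site fits — not into occurrence classification.
#' @param min_occurrence Stereotypical threshold (default 6 BG samples).
#' @param confidence Cutoff confidence level (default 0.99).
#' @param candidates Candidate distribution names.
#' @param min_fit_n Minimum pooled AF count for a parametric fit.
#' @param calibrate Bootstrap-calibrate cutoff coverage (default `TRUE`).
#' @param seed Seed for the calibration bootstrap (fits themselves are
#'   deterministic); the global RNG state is untouched.
#' @param panel Optional panel identifier string stored in the DB.
#' @return A `vb_background_db` list: `panel`, `n_background_samples`,
#'   `candidates`, `confidence`, `min_occurrence`,
#'   `background_template_rate`, and `sites` (tibble with fitted
#'   distribution and `af_cutoff` per stereotypical site-alt).
#' @export
build_background_db <- function(bg_pileups, extra_observations = NULL,
                                min_occurrence = 6L, confidence = 0.99,
                                candidates = candidate_distributions(),
                                min_fit_n = 8L, calibrate = TRUE,
                                seed = 1L, panel = "panel") {
  n_bg <- length(bg_pileups)
  if (n_bg < min_occurrence) {
    stop("background cohort of ", n_bg, " sample(s) cannot reach the ",
         "stereotypical occurrence threshold of ", min_occurrence)
  }
  obs <- collect_observations(bg_pileups)
  cls <- classify_sites(obs, min_occurrence)
  stereo <- cls$stereotypical
  pooled <- obs
  if (!is.null(extra_observations) && nrow(extra_observations)) {
    pooled <- dplyr::bind_rows(obs, extra_observations)
  }
  sites <- purrr::pmap_dfr(
    stereo, function(chrom, pos, ref, alt, occurrence) {
      af <- pooled$af[pooled$chrom == chrom & pooled$pos == pos &
                        pooled$alt == alt]
      af <- af[af > 0 & af < 1]
      if (length(af) >= min_fit_n) {
        fit <- fit_site_distribution(af, candidates, min_fit_n)
      } else {
        fit <- list(degenerate = TRUE)
      }
      if (isTRUE(fit$degenerate)) {
        cutoff <- as.numeric(stats::quantile(af, confidence, type = 7))
        tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       occurrence = occurrence, n_af = length(af),
                       dist_name = "empirical",
                       params = list(numeric()), af_cutoff = cutoff)
      } else {
        conf_used <- confidence
        if (calibrate) {
          conf_used <- with_seed(
            seed + pos,
            calibrate_confidence(fit$dist_name, fit$params, length(af),
                                 confidence))
        }
        cutoff <- af_cutoff_clamped(fit$dist_name, fit$params, conf_used)
        # never call below the background AF range actually observed here
        cutoff <- max(cutoff, max(af))
        tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       occurrence = occurrence, n_af = length(af),
                       dist_name = fit$dist_name, params = list(fit$params),
                       af_cutoff = cutoff)
      }
    })
  if (nrow(sites) == 0L) {
    sites <- tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            occurrence = integer(), n_af = integer(),
                            dist_name = character(), params = list(),
                            af_cutoff = double())
  }
  rate <- background_template_rate(bg_pileups)
  structure(list(panel = panel, n_background_samples = n_bg,
                 candidates = candidates, confidence = confidence,
                 min_occurrence = min_occurrence,
                 background_template_rate = rate,
                 sites = sites),
            class = "vb_background_db")
}

# quantile-based cutoff without the user-facing confidence range check
# (bootstrap calibration may push the working confidence above 0.995)
af_cutoff_clamped <- function(dist_name, params, confidence) {
  q <- dist_quantile(dist_name, confidence, params)
  min(max(q, 1e-12), 1 - 1e-12)
}

# Parametric-bootstrap search for the working confidence level whose plugin
# quantile attains ~ (1 - confidence) predictive exceedance at sample size n.
calibrate_confidence <- function(dist_name, params, n, confidence,
                                 B = 120L, m = 25L) {
  reg <- vb_dist_registry()[[dist_name]]
  alpha <- 1 - confidence
  grid <- sort(unique(pmin(1 - alpha * c(1, 0.7, 0.5, 0.35, 0.25, 0.18,
                                         0.12, 0.08, 0.05),
                           1 - 1e-5)))
  hits <- integer(length(grid))
  total <- 0L
  for (b in seq_len(B)) {
    xb <- reg$r(n, params)
    xb <- xb[is.finite(xb)]
    if (length(xb) < n) next
    fb <- tryCatch(fit_one_dist(xb, dist_name), error = function(e) NULL)
    if (is.null(fb)) next
    qb <- tryCatch(reg$q(grid, fb$par), error = function(e) NULL)
    if (is.null(qb) || any(!is.finite(qb))) next
    yb <- reg$r(m, params)
    hits <- hits + vapply(qb, function(ct) sum(yb > ct), 0L)
    total <- total + m
  }
  if (total == 0L) return(confidence)
  exceed <- hits / total
  ok <- which(exceed <= alpha)
  if (!length(ok)) return(max(grid))
  grid[ok[1]]
}

#' Cohort background template rate
#'
#' Position-summed full-f mutant family count over the position-summed
#' family count, across the whole BG cohort; the per-template probability
#' that background noise produces a supporting mutant family, used by
#' [template_threshold()].
#'
#' @param bg_pileups List of `vb_pileup` objects.
#' @return Rate in \[0, 1).
#' @export
background_template_rate <- function(bg_pileups) {
  num <- sum(vapply(bg_pileups, function(p) sum(p$n_fam_full), 0))
  den <- sum(vapply(bg_pileups, function(p) pileup_stats(p)$fam_cov_sum, 0))
  if (den == 0) return(0)
  num / den
}

#' @export
print.vb_background_db <- function(x, ...) {
  cat("<vb_background_db> panel '", x$panel, "': ", nrow(x$sites),
      " stereotypical site(s) from ", x$n_background_samples,
      " BG sample(s); confidence ", x$confidence,
      "; background template rate ",
      signif(x$background_template_rate, 3), "\n", sep = "")
  invisible(x)
}

#' Polish a candidate call against the background database
#'
#' A call at a stereotypical site-alt whose AF does not exceed the site's
#' fitted cutoff is an artifact (`"POLISHED"`); a call above the cutoff —
#' a real mutation of the same type at a noisy site — passes, as does any
#' call at a site absent from the database.
#'
#' @param chrom,pos,alt Call coordinates (vectorized), `pos` 0-based.
#' @param af Call allelic fraction(s).
#' @param db A `vb_background_db`.
#' @return Character vector `"PASS"`/`"POLISHED"`.
#' @export
polish <- function(chrom, pos, alt, af, db) {
  key <- paste(chrom, pos, alt)
  dbkey <- paste(db$sites$chrom, db$sites$pos, db$sites$alt)
  idx <- match(key, dbkey)
  cutoff <- rep(NA_real_, length(key))
  cutoff[!is.na(idx)] <- db$sites$af_cutoff[idx[!is.na(idx)]]
  ifelse(!is.na(cutoff) & af <= cutoff, "POLISHED", "PASS")
}

#' Save / load the background database
#'
#' Versioned JSON with full per-site fitted parameters; the round trip is
#' lossless.
#'
#' @param db A `vb_background_db`.
#' @param path File path.
#' @return `save_db` returns `path` invisibly; `load_db` the database.
#' @export
save_db <- function(db, path) {
  sites <- db$sites
  payload <- list(
    schema = "vbcall-background-db",
    version = 1L,
    panel = db$panel,
    n_background_samples = db$n_background_samples,
    candidates = db$candidates,
    confidence = db$confidence,
    min_occurrence = db$min_occurrence,
    background_template_rate = db$background_template_rate,
    sites = lapply(seq_len(nrow(sites)), function(i) {
      list(chrom = sites$chrom[i], pos = sites$pos[i], ref = sites$ref[i],
           alt = sites$alt[i], occurrence = sites$occurrence[i],
           n_af = sites$n_af[i], dist_name = sites$dist_name[i],
           params = as.list(sites$params[[i]]),
           af_cutoff = sites$af_cutoff[i])
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_db
#' @export
load_db <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e) stop("cannot parse database file '",
                                               path, "': ", conditionMessage(e)))
  if (!identical(payload$schema, "vbcall-background-db")) {
    stop("not a vbcall background database file")
  }
  if (!identical(as.integer(payload$version), 1L)) {
    stop("unsupported database schema version: ", payload$version)
  }
  sites <- purrr::map_dfr(payload$sites, function(s) {
    tibble::tibble(chrom = s$chrom, pos = as.integer(s$pos), ref = s$ref,
                   alt = s$alt, occurrence = as.integer(s$occurrence),
                   n_af = as.integer(s$n_af), dist_name = s$dist_name,
                   params = list(unlist(s$params)),
                   af_cutoff = as.numeric(s$af_cutoff))
  })
  if (nrow(sites) == 0L) {
    sites <- tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            occurrence = integer(), n_af = integer(),
                            dist_name = character(), params = list(),
                            af_cutoff = double())
  }
  structure(list(panel = payload$panel,
                 n_background_samples = as.integer(payload$n_background_samples),
                 candidates = unlist(payload$candidates),
                 confidence = as.numeric(payload$confidence),
                 min_occurrence = as.integer(payload$min_occurrence),
                 background_template_rate = as.numeric(payload$background_template_rate),
                 sites = sites),
            class = "vb_background_db")
}

#' Substitution spectrum of a site set
#'
#' Fractions of the 12 substitution types (ref>alt) among a set of sites,
#' normalized to sum to 1; absent types are reported as 0.
#'
#' @param sites Tibble with `ref` and `alt` columns.
#' @return Tibble with `substitution` and `fraction` for all 12 types.
#' @export
substitution_spectrum <- function(sites) {
  if (nrow(sites) == 0L) stop("empty site list")
  bases <- c("A", "C", "G", "T")
  types <- unlist(lapply(bases, function(r) paste0(r, ">", setdiff(bases, r))))
  obs <- paste0(sites$ref, ">", sites$alt)
  counts <- vapply(types, function(t) sum(obs == t), 0)
  tibble::tibble(substitution = types,
                 fraction = unname(counts) / sum(counts))
}
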