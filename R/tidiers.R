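#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a call result
#'
#' @param x A `vb_result`.
#' @param ... Unused.
#' @return The calls tibble, one row per emitted variant.
#' @method tidy vb_result
#' @export
tidy.vb_result <- function(x, ...) x$calls

#' One-row summary of a call result
#'
#' @param x A `vb_result`.
#' @param ... Unused.
#' @return One-row tibble combining call counts with the sample's
#'   panel-wide noise statistics.
#' @method glance vb_result
#' @export
glance.vb_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(sample = x$sample_name, n_calls = nrow(x$calls)),
    x$stats
  )
}

#' Tidy a background database
#'
#' @param x A `vb_background_db`.
#' @param ... Unused.
#' @return The stereotypical site tibble (without the parameter
#'   list-column).
#' @method tidy vb_background_db
#' @export
tidy.vb_background_db <- function(x, ...) {
  dplyr::select(x$sites, -"params")
}

#' One-row summary of a background database
#' @param x A `vb_background_db`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance vb_background_db
#' @export
glance.vb_background_db <- function(x, ...) {
  tibble::tibble(panel = x$panel, n_sites = nrow(x$sites),
                 n_background_samples = x$n_background_samples,
                 confidence = x$confidence,
                 background_template_rate = x$background_template_rate)
}

#' Audit funnel plot for a call result
#'
#' Candidate counts entering/surviving each pipeline stage.
#'
#' @param object A `vb_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vb_result
#' @export
autoplot.vb_result <- function(object, ...) {
  aud <- object$audit
  aud$stage <- factor(aud$stage, levels = aud$stage)
  ggplot2::ggplot(aud, ggplot2::aes(x = .data$stage,
                                    y = .data$n_candidates)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "candidate sites (log scale)",
                  title = paste0("Filter cascade - ", object$sample_name)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Substitution-spectrum plot for a background database
#'
#' @param object A `vb_background_db`.
#' @param ... Unused.
#' @return A ggplot of the 12 substitution-type fractions among the
#'   polishing sites.
#' @method autoplot vb_background_db
#' @export
autoplot.vb_background_db <- function(object, ...) {
  if (nrow(object$sites) == 0L) stop("database has no sites to plot")
  spec <- substitution_spectrum(object$sites)
  ggplot2::ggplot(spec, ggplot2::aes(x = .data$substitution,
                                     y = .data$fraction)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "substitution type", y = "fraction of polishing sites") +
    ggplot2::theme_minimal()
}

#' Per-site AF distribution plot
#'
#' Observed background AFs for one polishing site with its fitted density
#' and AF cutoff.
#'
#' @param db A `vb_background_db`.
#' @param observations Tibble from [collect_observations()].
#' @param site_index Row of `db$sites` to plot.
#' @return A ggplot.
#' @export
plot_site_distribution <- function(db, observations, site_index = 1L) {
  s <- db$sites[site_index, ]
  af <- observations$af[observations$chrom == s$chrom &
                          observations$pos == s$pos &
                          observations$alt == s$alt]
  p <- ggplot2::ggplot(tibble::tibble(af = af), ggplot2::aes(x = .data$af)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = s$af_cutoff, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(title = sprintf("%s:%d %s>%s (%s)", s$chrom, s$pos + 1L,
                                  s$ref, s$alt, s$dist_name),
                  x = "family-level AF", y = "density") +
    ggplot2::theme_minimal()
  if (s$dist_name != "empirical") {
    xs <- seq(max(min(af) / 2, 1e-6), max(af) * 1.5, length.out = 200)
    dens <- dist_pdf(s$dist_name, xs, s$params[[1]])
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(x = xs, y = dens),
      ggplot2::aes(x = .data$x, y = .data$y), colour = "steelblue")
  }
  p
}

#' @importFrom rlang .data
NULL
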