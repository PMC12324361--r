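#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for comparison and aggregation results
#'
#' Broom-style methods: `tidy()` returns the per-component table of a result
#' object, `glance()` a one-row summary.
#'
#' @param x A result object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name hicsig_tidiers
NULL

#' @rdname hicsig_tidiers
#' @export
tidy.intensity_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method, n_ref = x$n_ref, n_treated = x$n_treated,
                 median_ref = x$median_ref, median_treated = x$median_treated,
                 median_ratio = x$median_ratio)
}

#' @rdname hicsig_tidiers
#' @export
glance.intensity_comparison <- function(x, ...) tidy.intensity_comparison(x)

#' @rdname hicsig_tidiers
#' @export
tidy.saddle_result <- function(x, ...) x$corners

#' @rdname hicsig_tidiers
#' @export
glance.saddle_result <- function(x, ...) x$strength

#' @rdname hicsig_tidiers
#' @export
tidy.loop_pileup <- function(x, ...) {
  w <- x$w_bins
  off <- (-w):w
  tibble::tibble(offset1_bin = rep(off, times = 2 * w + 1),
                 offset2_bin = rep(off, each = 2 * w + 1),
                 value = as.vector(x$pileup))
}

#' @rdname hicsig_tidiers
#' @export
tidy.boundary_pileup <- function(x, ...) {
  f <- (ncol(x$pileup) - 1) / 2
  off <- (-f):f
  tibble::tibble(offset1_bin = rep(off, times = 2 * f + 1),
                 offset2_bin = rep(off, each = 2 * f + 1),
                 value = as.vector(x$pileup))
}

#' @rdname hicsig_tidiers
#' @export
glance.hic_report <- function(x, ...) {
  w <- x$params$w_bins
  tibble::tibble(
    reference = x$reference, treated = x$treated,
    n_conditions = length(x$balanced),
    n_tads = nrow(x$tads),
    intensity_median_ratio = x$wilcoxon$median_ratio,
    wilcoxon_p = x$wilcoxon$p_value,
    cohesin_fraction = if (!is.null(x$attribution))
      x$attribution$cohesin_fraction else NA_real_,
    loopline_centre_ratio = if (!is.null(x$loops))
      x$loops$ratio$ratio[w + 1] else NA_real_,
    saddle_combined_ref = if (!is.null(x$compartments))
      x$compartments$saddles[[x$reference]]$strength$combined else NA_real_,
    saddle_combined_treated = if (!is.null(x$compartments))
      x$compartments$saddles[[x$treated]]$strength$combined else NA_real_)
}
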