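#' Intra-TAD interaction intensity
#'
#' For each TAD, takes the square O/E block over its interior bins, removes
#' the diagonal plus `k` additional diagonals and trims `k` rows/columns
#' from each edge of the block, where `k = max(1, floor(mask_scale * m))`
#' for a TAD of `m` bins (so the masking scales with TAD size). The
#' intensity is the mean of the remaining defined entries; a constant O/E
#' field therefore yields the constant for every `mask_scale`. TADs with no
#' remaining entries are skipped and counted.
#'
#' Supply `expected` produced by [oe_vs_reference()] upstream when comparing
#' absolute contact levels across conditions; see that help page.
#'
#' @param oe An `oe_matrix`.
#' @param tads A `tad_set` (non-overlapping; overlapping input is rejected).
#' @param mask_scale Fraction of the TAD size removed from the diagonal and
#'   each edge (default 0.1).
#' @param condition Optional condition label stored alongside each value.
#' @return A tibble of class `intensity_table` with columns `tad_id`,
#'   `start`, `end`, `n_bins`, `k`, `intensity`, `n_entries`, `condition`;
#'   attribute `"n_skipped"` counts degenerate TADs.
#' @export
intra_tad_intensity <- function(oe, tads, mask_scale = 0.1, condition = NA_character_) {
  stopifnot(inherits(oe, "oe_matrix"), inherits(tads, "tad_set"))
  if (nrow(tads) > 1) {
    o <- order(tads$start_bin)
    if (any(tads$start_bin[o][-1] <= tads$end_bin[o][-nrow(tads)]))
      stop("overlapping TADs rejected")
  }
  rows <- purrr::pmap(tads, function(tad_id, start, end, start_bin, end_bin, ...) {
    m <- end_bin - start_bin + 1L
    k <- max(1L, as.integer(floor(mask_scale * m)))
    lo <- start_bin + k; hi <- end_bin - k
    if (hi - lo < k + 1L)   # no entries with |i - j| > k left after trimming
      return(NULL)
    idx <- (lo:hi) + 1L
    blk <- oe$oe[idx, idx, drop = FALSE]
    off <- abs(outer(seq_along(idx), seq_along(idx), "-"))
    vals <- blk[off > k & !is.na(blk)]
    if (length(vals) == 0) return(NULL)
    tibble::tibble(tad_id = tad_id, start = start, end = end, n_bins = m,
                   k = k, intensity = mean(vals), n_entries = length(vals))
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble::tibble(tad_id = integer(), start = numeric(), end = numeric(),
                          n_bins = integer(), k = integer(),
                          intensity = numeric(), n_entries = integer())
  out$condition <- condition
  if (skipped > 0)
    message(sprintf("%d TAD(s) too small for mask_scale = %.2f; skipped", skipped, mask_scale))
  attr(out, "n_skipped") <- skipped
  attr(out, "mask_scale") <- mask_scale
  class(out) <- c("intensity_table", class(out))
  out
}

#' Interquartile-range outlier filter
#'
#' Flags values above `Q3 + 1.5 IQR` (upper outliers) or below
#' `Q1 - 1.5 IQR` (lower outliers), with quartiles computed by the
#' linear-interpolation convention (R quantile type 7). With fewer than 4
#' values nothing is flagged and a warning is raised.
#'
#' @param x A numeric vector or an `intensity_table`.
#' @return For a vector, a tibble (`value`, `outlier`); for an
#'   `intensity_table`, the table with an `outlier` column added.
#' @export
iqr_filter <- function(x) {
  flag <- function(v) {
    if (sum(!is.na(v)) < 4) {
      warning("fewer than 4 values; IQR outlier filtering not applied")
      return(rep(FALSE, length(v)))
    }
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, type = 7)
    iqr <- q[2] - q[1]
    !is.na(v) & (v > q[2] + 1.5 * iqr | v < q[1] - 1.5 * iqr)
  }
  if (inherits(x, "intensity_table")) {
    x$outlier <- flag(x$intensity)
    x
  } else {
    tibble::tibble(value = x, outlier = flag(x))
  }
}

#' Compare intra-TAD intensities between two conditions
#'
#' Two-sided Wilcoxon rank-sum test on the retained (non-outlier) intensity
#' values of two conditions, plus the ratio of medians (treated over
#' reference). The exact null distribution is used when both groups have at
#' most 25 values and no cross-group ties; otherwise the normal
#' approximation with tie correction. The method used is recorded.
#'
#' @param table_ref,table_treated `intensity_table`s (run [iqr_filter()]
#'   first; rows flagged `outlier` are excluded) or plain numeric vectors.
#' @return An object of class `intensity_comparison`; see [tidy()] /
#'   [glance()] methods.
#' @export
compare_intensity <- function(table_ref, table_treated) {
  pull_vals <- function(x) {
    if (inherits(x, "intensity_table")) {
      if ("outlier" %in% names(x)) x$intensity[!x$outlier] else x$intensity
    } else as.numeric(x)
  }
  a <- pull_vals(table_ref); b <- pull_vals(table_treated)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty group in comparison")
  exact <- length(a) <= 25 && length(b) <= 25 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(b, a, exact = exact, correct = !exact))
  structure(list(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (exact) "exact" else "normal_approx_tie_corrected",
    n_ref = length(a), n_treated = length(b),
    median_ref = stats::median(a), median_treated = stats::median(b),
    median_ratio = stats::median(b) / stats::median(a)),
    class = "intensity_comparison")
}

#' @export
print.intensity_comparison <- function(x, ...) {
  cat(sprintf(
    "<intensity_comparison> n=%d vs %d | median ratio %.3f | W=%.1f, p=%.3g (%s)\n",
    x$n_ref, x$n_treated, x$median_ratio, x$statistic, x$p_value, x$method))
  invisible(x)
}

#' Cohesin-attributable fraction of a treatment effect
#'
#' Decomposes a treatment-induced decrease in intra-TAD intensity measured
#' with and without cohesin (on the same reference TAD set): the
#' cohesin-independent share is `delta_without / delta_with`, and the
#' cohesin-attributable fraction is `1 - delta_without / delta_with`. Both
#' deltas are `control - treated` median intensities. When `delta_with <= 0`
#' the treatment did not reduce intensity in cohesin-intact cells and no
#' fraction is emitted (flagged non-attributable).
#'
#' @param delta_with Intensity decrease with cohesin present.
#' @param delta_without Intensity decrease with cohesin depleted.
#' @return A one-row tibble with `delta_with`, `delta_without`,
#'   `background_fraction`, `cohesin_fraction`, `attributable`.
#' @export
cohesin_attribution <- function(delta_with, delta_without) {
  if (delta_with <= 0) {
    return(tibble::tibble(delta_with = delta_with, delta_without = delta_without,
                          background_fraction = NA_real_,
                          cohesin_fraction = NA_real_, attributable = FALSE))
  }
  bg <- delta_without / delta_with
  tibble::tibble(delta_with = delta_with, delta_without = delta_without,
                 background_fraction = bg, cohesin_fraction = 1 - bg,
                 attributable = TRUE)
}
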