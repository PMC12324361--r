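#' Loop size classes
#'
#' Assigns each loop size (distance between anchor midpoints, bp) to the
#' strata `100kb-500kb` (`[1e5, 5e5)`), `500kb-1Mb` (`[5e5, 1e6)`) and
#' `>1Mb` (`[1e6, Inf)`); sizes below 100 kb get `NA` (excluded from
#' stratified analyses). Boundaries are half-open, so a loop of exactly
#' 500 kb falls in the second class.
#'
#' @param size_bp Numeric vector of loop sizes in bp.
#' @return A character vector of class labels.
#' @export
loop_size_class <- function(size_bp) {
  cls <- rep(NA_character_, length(size_bp))
  cls[size_bp >= 1e5 & size_bp < 5e5] <- "100kb-500kb"
  cls[size_bp >= 5e5 & size_bp < 1e6] <- "500kb-1Mb"
  cls[size_bp >= 1e6] <- ">1Mb"
  cls
}

#' Validate and annotate a loop list
#'
#' Takes BEDPE-style anchors (0-based half-open), computes each loop's size
#' as the distance between anchor midpoints, and assigns size classes.
#'
#' @param x A tibble with `chrom1`, `start1`, `end1`, `chrom2`, `start2`,
#'   `end2` and optional extra columns (e.g. a covariate).
#' @return A tibble of class `loop_set` with `size` and `size_class` added.
#' @export
loop_set <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  stopifnot(all(req %in% names(x)))
  mid1 <- (x$start1 + x$end1) / 2
  mid2 <- (x$start2 + x$end2) / 2
  if (any(mid1 >= mid2))
    stop("first anchor must lie upstream of the second (size > 0)")
  x$size <- mid2 - mid1
  x$size_class <- loop_size_class(x$size)
  class(x) <- c("loop_set", class(x))
  x
}

#' Map loop anchors to matrix bins
#'
#' Anchor midpoints are assigned by floor division; a midpoint exactly on a
#' bin edge is resolved toward the lower bin.
#'
#' @param loops A `loop_set`.
#' @param bin_size Bin width in bp.
#' @return The loop set with integer columns `bin1`, `bin2` added.
#' @export
loops_to_bins <- function(loops, bin_size) {
  stopifnot(inherits(loops, "loop_set"))
  to_bin <- function(mid) {
    b <- floor(mid / bin_size)
    on_edge <- mid %% bin_size == 0
    as.integer(b - on_edge)  # ties toward the lower bin
  }
  loops$bin1 <- to_bin((loops$start1 + loops$end1) / 2)
  loops$bin2 <- to_bin((loops$start2 + loops$end2) / 2)
  loops
}

#' Aggregate O/E windows at loop anchors (loop pileup / APA)
#'
#' Stacks `(2w + 1)` x `(2w + 1)` O/E windows centred on each loop pixel
#' `(bin1, bin2)` and averages them pixel-wise (NA-aware). Windows
#' extending past the matrix, or whose loop-pixel row or column is masked,
#' are dropped and counted; masked pixels elsewhere in a window simply do
#' not contribute to the mean.
#'
#' @param oe An `oe_matrix` (20-kb binned data in the canonical analysis).
#' @param loops A `loop_set` (bins computed via [loops_to_bins()] if absent).
#' @param w_bins Window half-width in bins (default 10).
#' @return A list of class `loop_pileup`: `pileup`, `n_loops`, `n_dropped`,
#'   `w_bins`, `bin_size`.
#' @export
loop_pileup <- function(oe, loops, w_bins = 10) {
  stopifnot(inherits(oe, "oe_matrix"), inherits(loops, "loop_set"))
  if (!all(c("bin1", "bin2") %in% names(loops)))
    loops <- loops_to_bins(loops, oe$bin_size)
  w <- as.integer(w_bins)
  n <- oe$n_bins
  side <- 2L * w + 1L
  acc <- matrix(0, side, side)
  cnt <- matrix(0, side, side)
  used <- 0L
  for (k in seq_len(nrow(loops))) {
    b1 <- loops$bin1[k]; b2 <- loops$bin2[k]
    if (b1 - w < 0L || b2 - w < 0L || b1 + w > n - 1L || b2 + w > n - 1L) next
    if (oe$mask[b1 + 1L] || oe$mask[b2 + 1L]) next
    ri <- (b1 - w):(b1 + w) + 1L
    ci <- (b2 - w):(b2 + w) + 1L
    wdw <- oe$oe[ri, ci]
    ok <- !is.na(wdw)
    acc[ok] <- acc[ok] + wdw[ok]
    cnt <- cnt + ok
    used <- used + 1L
  }
  if (used == 0L) stop("zero retained loop windows")
  structure(list(pileup = ifelse(cnt > 0, acc / cnt, NA_real_),
                 n_loops = used, n_dropped = nrow(loops) - used,
                 w_bins = w, bin_size = oe$bin_size),
            class = "loop_pileup")
}

#' @export
print.loop_pileup <- function(x, ...) {
  cat(sprintf("<loop_pileup> %dx%d window (+/-%d bins), %d loops (%d dropped), centre %.3f\n",
              2 * x$w_bins + 1, 2 * x$w_bins + 1, x$w_bins, x$n_loops,
              x$n_dropped, x$pileup[x$w_bins + 1, x$w_bins + 1]))
  invisible(x)
}

#' Loop-line: the diagonal profile through the loop pixel
#'
#' Extracts `pileup[centre + k, centre + k]` for offsets `k` in
#' `[-w, +w]` - the diagonal running from the bottom-left to the top-right
#' corner of the loop aggregation heatmap, under the convention that rows
#' and columns index the genomic offset around the first and second anchor.
#' The centre entry (`k = 0`) is the loop-pixel mean.
#'
#' @param pileup A `loop_pileup`.
#' @return A tibble of class `loop_line` with columns `offset_bin`,
#'   `offset_bp`, `value`.
#' @export
loop_line <- function(pileup) {
  stopifnot(inherits(pileup, "loop_pileup"))
  w <- pileup$w_bins
  out <- tibble::tibble(offset_bin = (-w):w,
                        offset_bp = ((-w):w) * pileup$bin_size,
                        value = diag(pileup$pileup))
  class(out) <- c("loop_line", class(out))
  out
}

#' Ratio and difference of loop-lines
#'
#' Elementwise comparison of two loop-lines on the same window. The ratio
#' is masked where the reference line falls below `epsilon_frac` of its
#' maximum.
#'
#' @param line_treated,line_ref `loop_line` tibbles of equal length.
#' @param epsilon_frac Masking threshold for the ratio (default 0.05).
#' @return A tibble with `offset_bin`, `offset_bp`, and `ratio` or `diff`.
#' @export
loopline_ratio <- function(line_treated, line_ref, epsilon_frac = 0.05) {
  check_lines(line_treated, line_ref)
  eps <- epsilon_frac * max(line_ref$value, na.rm = TRUE)
  tibble::tibble(offset_bin = line_ref$offset_bin,
                 offset_bp = line_ref$offset_bp,
                 ratio = ifelse(!is.na(line_ref$value) & line_ref$value >= eps,
                                line_treated$value / line_ref$value, NA_real_))
}

#' @rdname loopline_ratio
#' @export
loopline_difference <- function(line_treated, line_ref) {
  check_lines(line_treated, line_ref)
  tibble::tibble(offset_bin = line_ref$offset_bin,
                 offset_bp = line_ref$offset_bp,
                 diff = line_treated$value - line_ref$value)
}

check_lines <- function(a, b) {
  stopifnot(inherits(a, "loop_line"), inherits(b, "loop_line"))
  if (nrow(a) != nrow(b)) stop("loop-line length mismatch")
  invisible(TRUE)
}

#' Stratify loops by size class
#'
#' Partitions a loop set into the three size strata; loops below 100 kb are
#' excluded and counted in the `"n_excluded"` attribute. Class counts plus
#' exclusions always total the input.
#'
#' @param loops A `loop_set`.
#' @return The loop set restricted to classified loops, ordered by class;
#'   attributes `"n_excluded"` and `"class_counts"`.
#' @export
stratify_by_size <- function(loops) {
  stopifnot(inherits(loops, "loop_set"))
  excluded <- sum(is.na(loops$size_class))
  out <- loops[!is.na(loops$size_class), ]
  out$size_class <- factor(out$size_class,
                           levels = c("100kb-500kb", "500kb-1Mb", ">1Mb"))
  out <- out[order(out$size_class, out$size), ]
  attr(out, "n_excluded") <- excluded
  attr(out, "class_counts") <- table(out$size_class)
  out
}

#' Covariate-ranked loop-line comparison
#'
#' Ranks loops by a per-loop covariate (e.g. the combined anchor
#' acetylation change), splits them into `n_groups` quantile groups, and
#' compares treated-versus-reference loop signal within each group. The
#' trend test is the Spearman rank correlation between the covariate and
#' each loop's centre-pixel O/E ratio (treated / reference); a correlation
#' near zero means the treatment effect does not scale with the covariate.
#'
#' @param oe_treated,oe_ref `oe_matrix` objects for the two conditions.
#' @param loops A `loop_set` with a covariate column.
#' @param covariate Name of the covariate column (default `"covariate"`).
#' @param n_groups Number of quantile groups (default 5; 1 reduces to a
#'   plain comparison).
#' @param w_bins Pileup half-window in bins.
#' @return A list of class `loop_covariate_ranking`: `per_loop` tibble
#'   (loops with centre values, ratio, group), `groups` tibble (per-group
#'   centre ratios and loop-lines), `trend` tibble (rho, p), `n_dropped`
#'   (loops with missing covariate or unusable windows).
#' @export
rank_loops_by_covariate <- function(oe_treated, oe_ref, loops,
                                    covariate = "covariate", n_groups = 5,
                                    w_bins = 10) {
  stopifnot(inherits(oe_treated, "oe_matrix"), inherits(oe_ref, "oe_matrix"),
            inherits(loops, "loop_set"), covariate %in% names(loops))
  if (!all(c("bin1", "bin2") %in% names(loops)))
    loops <- loops_to_bins(loops, oe_ref$bin_size)
  cov <- loops[[covariate]]
  keep <- !is.na(cov)
  n_missing <- sum(!keep)
  lp <- loops[keep, ]
  ctr_t <- oe_treated$oe[cbind(lp$bin1 + 1L, lp$bin2 + 1L)]
  ctr_r <- oe_ref$oe[cbind(lp$bin1 + 1L, lp$bin2 + 1L)]
  usable <- !is.na(ctr_t) & !is.na(ctr_r) & ctr_r > 0
  lp <- lp[usable, ]
  per_loop <- dplyr::mutate(
    lp,
    centre_treated = ctr_t[usable], centre_ref = ctr_r[usable],
    centre_ratio = ctr_t[usable] / ctr_r[usable],
    group = if (n_groups > 1)
      dplyr::ntile(dplyr::desc(.data[[covariate]]), n_groups) else 1L)
  groups <- per_loop |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      covariate_mean = mean(.data[[covariate]]),
      centre_ratio = mean(.data$centre_ratio),
      .groups = "drop")
  group_lines <- lapply(split(per_loop, per_loop$group), function(g) {
    gl <- g; class(gl) <- c("loop_set", class(tibble::tibble()))
    pr <- loop_pileup(oe_ref, gl, w_bins = w_bins)
    pt <- loop_pileup(oe_treated, gl, w_bins = w_bins)
    list(line_ref = loop_line(pr), line_treated = loop_line(pt))
  })
  trend <- if (nrow(per_loop) >= 3) {
    ct <- suppressWarnings(
      stats::cor.test(per_loop[[covariate]], per_loop$centre_ratio,
                      method = "spearman"))
    tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value)
  } else tibble::tibble(rho = NA_real_, p_value = NA_real_)
  structure(list(per_loop = per_loop, groups = groups,
                 group_lines = group_lines, trend = trend,
                 n_dropped = n_missing + sum(!usable)),
            class = "loop_covariate_ranking")
}

#' Mean track signal at loop anchors
#'
#' Averages a per-bin track within `anchor +/- flank` for both anchors of
#' each loop, and summarizes per size class. Loops whose flanked anchors
#' fall outside the track are dropped and counted.
#'
#' @param track Numeric per-bin vector (e.g. an occupancy proxy).
#' @param loops A `loop_set` with `bin1`/`bin2` (or computable via
#'   `bin_size`).
#' @param flank_bp Flank on each side in bp.
#' @param bin_size Bin width of the track in bp.
#' @return A list with `per_loop` and `by_class` tibbles and `n_dropped`.
#' @export
anchor_signal_summary <- function(track, loops, flank_bp, bin_size) {
  stopifnot(inherits(loops, "loop_set"))
  if (!all(c("bin1", "bin2") %in% names(loops)))
    loops <- loops_to_bins(loops, bin_size)
  f <- as.integer(round(flank_bp / bin_size))
  n <- length(track)
  win_mean <- function(b) {
    if (b - f < 0L || b + f > n - 1L) return(NA_real_)
    mean(track[(b - f):(b + f) + 1L], na.rm = TRUE)
  }
  m1 <- vapply(loops$bin1, win_mean, numeric(1))
  m2 <- vapply(loops$bin2, win_mean, numeric(1))
  ok <- !is.na(m1) & !is.na(m2)
  per_loop <- tibble::tibble(size = loops$size[ok],
                             size_class = loops$size_class[ok],
                             anchor1_mean = m1[ok], anchor2_mean = m2[ok],
                             anchor_mean = (m1[ok] + m2[ok]) / 2)
  by_class <- per_loop |>
    dplyr::filter(!is.na(.data$size_class)) |>
    dplyr::group_by(.data$size_class) |>
    dplyr::summarise(n = dplyr::n(), mean_signal = mean(.data$anchor_mean),
                     .groups = "drop")
  list(per_loop = per_loop, by_class = by_class, n_dropped = sum(!ok))
}
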