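#' Simulate a multi-condition experiment
#'
#' Generates contact maps for up to four conditions from one base
#' configuration: a control (`dmso`), a hyperacetylation treatment (`tsa`),
#' and their cohesin-depleted counterparts (`dmso_nocohesin`,
#' `tsa_nocohesin`). All conditions share the base structure (decay,
#' compartments, TADs, loops); each condition applies its perturbation and
#' is sampled with its own seed offset so replicates are independent.
#'
#' @param base_config A `sim_config` with `perturbation = "none"`.
#' @param conditions Subset of the four canonical condition labels.
#' @param chrom Chromosome label.
#' @return A list with `matrices` (named `contact_matrix` list),
#'   `ground_truth`, and `configs`.
#' @export
simulate_experiment <- function(base_config,
                                conditions = c("dmso", "tsa",
                                               "dmso_nocohesin", "tsa_nocohesin"),
                                chrom = "chrS") {
  stopifnot(inherits(base_config, "sim_config"),
            base_config$perturbation == "none")
  pert_of <- c(dmso = "none", tsa = "tsa",
               dmso_nocohesin = "cohesin_depleted",
               tsa_nocohesin = "tsa_and_depleted")
  conditions <- match.arg(conditions, names(pert_of), several.ok = TRUE)
  configs <- list(); mats <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    cfg <- base_config
    cfg$perturbation <- pert_of[[cond]]
    cfg$seed <- base_config$seed + (i - 1L) * 1009L
    configs[[cond]] <- cfg
    mats[[cond]] <- simulate_map(cfg, chrom = chrom)
  }
  list(matrices = mats, ground_truth = emit_ground_truth(base_config, chrom = chrom),
       configs = configs)
}

#' Balance a raw contact matrix (filter + ICE)
#'
#' Convenience wrapper chaining [madmax_filter()], [apply_mask()] and
#' [ice_balance()].
#'
#' @param mat A `contact_matrix`.
#' @param madmax MAD-max constant.
#' @param ignore_diags,tol,max_iter Passed to [ice_balance()].
#' @return A balanced `contact_matrix`.
#' @export
balance_matrix <- function(mat, madmax = 5, ignore_diags = 2L, tol = 1e-5,
                           max_iter = 200) {
  mat |>
    apply_mask(madmax_filter(mat, madmax = madmax)) |>
    ice_balance(ignore_diags = ignore_diags, tol = tol, max_iter = max_iter)
}

#' End-to-end comparison of treatment conditions
#'
#' Orchestrates the full comparative analysis on two to four conditions.
#' Every reference-anchored choice (E1 ranking for saddles, TAD boundaries,
#' the expected profile and long-range anchoring for intensity comparisons,
#' loop-line denominators) resolves to the declared `reference` condition.
#' With all four conditions present, the P(s) differential decomposition
#' and the cohesin-attribution fraction are computed as well.
#'
#' @param mats Named list of `contact_matrix` objects (raw counts or already
#'   balanced), including `reference` and `treated`.
#' @param reference,treated Labels of the cohesin-intact control and treated
#'   conditions.
#' @param reference_depleted,treated_depleted Labels of the cohesin-depleted
#'   pair (optional; `NULL` to skip the four-condition analyses).
#' @param loops Optional `loop_set` for the loop analyses.
#' @param e1_covariate Optional per-bin orientation covariate at the
#'   compartment resolution (e.g. gene density); required for compartment
#'   analyses.
#' @param compartment_factor Coarsening factor from the input resolution to
#'   the compartment resolution (default 10, i.e. 10 kb to 100 kb); set to
#'   `NULL` to skip compartment analyses.
#' @param insulation_window Insulation window in bp.
#' @param boundary_flank Boundary pileup flank in bp.
#' @param mask_scale Intra-TAD masking fraction.
#' @param w_bins Loop pileup half-window in bins.
#' @param ps_s_ref P(s) normalization anchor in bp; defaults to a
#'   separation beyond the short-range treatment effect (5 Mb).
#' @param anchor_bp Long-range anchoring window for cross-condition O/E;
#'   default `NULL` uses separations beyond 4 Mb (or half the chromosome
#'   span, whichever is smaller).
#' @param saddle_groups,saddle_corner Saddle binning.
#' @param iqr_per_condition Apply the IQR outlier filter within each
#'   condition (default) rather than jointly.
#' @return A list of class `hic_report`; see [glance()] for the headline
#'   numbers.
#' @export
hic_compare <- function(mats, reference = "dmso", treated = "tsa",
                        reference_depleted = NULL, treated_depleted = NULL,
                        loops = NULL, e1_covariate = NULL,
                        compartment_factor = 10,
                        insulation_window = 1e5, boundary_flank = 6e5,
                        mask_scale = 0.1, w_bins = 10, ps_s_ref = 5e6,
                        anchor_bp = NULL, saddle_groups = 50,
                        saddle_corner = 10, iqr_per_condition = TRUE) {
  if (!reference %in% names(mats))
    stop(sprintf("reference condition '%s' missing from `mats`", reference))
  if (!treated %in% names(mats))
    stop(sprintf("treated condition '%s' missing from `mats`", treated))
  four <- !is.null(reference_depleted) && !is.null(treated_depleted)
  if (four && !all(c(reference_depleted, treated_depleted) %in% names(mats)))
    stop("cohesin-depleted conditions missing from `mats`")

  if (is.null(anchor_bp)) {
    span <- mats[[reference]]$n_bins * mats[[reference]]$bin_size
    anchor_bp <- c(min(4e6, span / 2), Inf)
  }
  bal <- lapply(mats, function(m) if (is.null(m$weights)) balance_matrix(m) else m)
  expected <- lapply(bal, expected_cis)
  oe_own <- lapply(bal, oe_transform)

  ## -- P(s) scaling -------------------------------------------------------
  ps <- lapply(bal, ps_curve, normalize = "ref", s_ref = ps_s_ref)
  deriv <- lapply(ps, ps_derivative)
  dratio <- if (four)
    delta_ratio(ps[[reference]], ps[[treated]],
                ps[[reference_depleted]], ps[[treated_depleted]])
  else NULL

  ## -- compartments -------------------------------------------------------
  compartments <- NULL
  if (!is.null(compartment_factor) && !is.null(e1_covariate)) {
    coarse <- lapply(mats, function(m)
      balance_matrix(coarsen_matrix(if (is.null(m$weights)) m else m,
                                    compartment_factor)))
    oe_coarse <- lapply(coarse, oe_transform)
    e1 <- lapply(oe_coarse, compute_e1, covariate = e1_covariate)
    ref_track <- e1[[reference]]
    compartments <- list(
      e1 = e1,
      summaries = lapply(e1, e1_summary),
      boundaries = lapply(e1, call_compartment_boundaries),
      saddles = lapply(oe_coarse, saddle_strength, reference_track = ref_track,
                       n_groups = saddle_groups, corner = saddle_corner))
  }

  ## -- insulation, TADs, intensity ---------------------------------------
  ins <- lapply(bal, insulation, window_bp = insulation_window)
  ref_boundaries <- call_boundaries(ins[[reference]])
  tads <- tads_from_boundaries(ref_boundaries)
  pileups_boundary <- lapply(oe_own, boundary_pileup, boundaries = ref_boundaries,
                             flank_bp = boundary_flank)
  oe_shared <- lapply(names(bal), function(nm) {
    if (nm == reference) oe_transform(bal[[nm]])
    else oe_vs_reference(bal[[nm]], expected[[reference]], anchor_bp = anchor_bp)
  })
  names(oe_shared) <- names(bal)
  intensities <- lapply(names(bal), function(nm)
    intra_tad_intensity(oe_shared[[nm]], tads, mask_scale = mask_scale,
                        condition = nm))
  names(intensities) <- names(bal)
  if (iqr_per_condition) {
    intensities <- lapply(intensities, iqr_filter)
  } else {
    pooled <- iqr_filter(unlist(lapply(intensities, `[[`, "intensity")))
    off <- 0L
    for (nm in names(intensities)) {
      k <- nrow(intensities[[nm]])
      intensities[[nm]]$outlier <- pooled$outlier[off + seq_len(k)]
      off <- off + k
    }
  }
  wilcoxon <- compare_intensity(intensities[[reference]], intensities[[treated]])
  attribution <- NULL
  if (four) {
    med <- function(nm) stats::median(
      intensities[[nm]]$intensity[!intensities[[nm]]$outlier])
    attribution <- cohesin_attribution(
      delta_with = med(reference) - med(treated),
      delta_without = med(reference_depleted) - med(treated_depleted))
  }

  ## -- loops --------------------------------------------------------------
  loops_out <- NULL
  if (!is.null(loops)) {
    loops <- loops_to_bins(loops, bal[[reference]]$bin_size)
    pile <- lapply(oe_own, loop_pileup, loops = loops, w_bins = w_bins)
    lines <- lapply(pile, loop_line)
    ratio <- loopline_ratio(lines[[treated]], lines[[reference]])
    difference <- loopline_difference(lines[[treated]], lines[[reference]])
    strat <- stratify_by_size(loops)
    by_class <- lapply(split(strat, strat$size_class), function(g) {
      if (nrow(g) == 0) return(NULL)
      class(g) <- c("loop_set", "tbl_df", "tbl", "data.frame")
      pr <- loop_pileup(oe_own[[reference]], g, w_bins = w_bins)
      pt <- loop_pileup(oe_own[[treated]], g, w_bins = w_bins)
      list(n = nrow(g), line_ref = loop_line(pr), line_treated = loop_line(pt),
           ratio = loopline_ratio(loop_line(pt), loop_line(pr)))
    })
    ranking <- if ("covariate" %in% names(loops))
      rank_loops_by_covariate(oe_own[[treated]], oe_own[[reference]], loops,
                              w_bins = w_bins)
    else NULL
    loops_out <- list(pileups = pile, lines = lines, ratio = ratio,
                      difference = difference, by_class = by_class,
                      ranking = ranking,
                      n_excluded_small = attr(strat, "n_excluded"))
  }

  structure(list(
    reference = reference, treated = treated,
    reference_depleted = if (four) reference_depleted else NULL,
    treated_depleted = if (four) treated_depleted else NULL,
    balanced = bal, expected = expected,
    ps = ps, derivatives = deriv, delta_ratio = dratio,
    compartments = compartments,
    insulation = ins, boundaries = ref_boundaries, tads = tads,
    boundary_pileups = pileups_boundary,
    intensities = intensities, wilcoxon = wilcoxon, attribution = attribution,
    loops = loops_out,
    params = list(insulation_window = insulation_window,
                  boundary_flank = boundary_flank, mask_scale = mask_scale,
                  w_bins = w_bins, ps_s_ref = ps_s_ref, anchor_bp = anchor_bp,
                  saddle_groups = saddle_groups, saddle_corner = saddle_corner,
                  iqr_per_condition = iqr_per_condition)),
    class = "hic_report")
}

#' @export
print.hic_report <- function(x, ...) {
  cat(sprintf("<hic_report> %s vs %s (%d conditions)\n",
              x$reference, x$treated, length(x$balanced)))
  cat(sprintf("  TADs from reference boundaries: %d | intensity median ratio %.3f, Wilcoxon p = %.3g\n",
              nrow(x$tads), x$wilcoxon$median_ratio, x$wilcoxon$p_value))
  if (!is.null(x$attribution) && isTRUE(x$attribution$attributable))
    cat(sprintf("  cohesin-attributable fraction of the effect: %.2f\n",
                x$attribution$cohesin_fraction))
  if (!is.null(x$loops)) {
    w <- x$params$w_bins
    cat(sprintf("  loop-line centre ratio (%s/%s): %.3f over %d loops\n",
                x$treated, x$reference, x$loops$ratio$ratio[w + 1],
                x$loops$pileups[[x$reference]]$n_loops))
  }
  invisible(x)
}
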