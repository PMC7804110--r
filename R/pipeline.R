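# End-to-end per-layer analysis and ground-truth recovery assessment.

#' Run the full location-specific analysis for one layer
#'
#' Chains the whole pipeline on an orientation-normalised, exclusion-filtered
#' dataset: covariate screening decides the grouping (age cohorts, sex, or
#' whole cohort); candidate cluster patterns are generated and merged to
#' d-prime separability; each candidate is evaluated (age-regression fit or
#' coefficient of variation); and the best candidate is selected. For
#' sex-grouped layers the per-cluster Mann-Whitney sex comparison is
#' attached.
#'
#' @param ds A `grid_dataset` (any orientation; normalisation and exclusions
#'   are applied internally).
#' @param seed Integer seed for the k-means restarts.
#' @param alpha Significance level used throughout (default 0.05).
#' @param threshold d-prime merge threshold (default 2).
#' @return A `layer_analysis` object: `screen`, `candidates`,
#'   `evaluations`, `final` (the selected `pattern_evaluation`),
#'   `exclusions`, and `sex_comparison` when applicable.
#' @export
analyze_layer <- function(ds, seed = 1L, alpha = 0.05, threshold = 2) {
  stopifnot(inherits(ds, "grid_dataset"))
  ds <- normalize_orientation(ds)
  excl <- apply_exclusions(ds)
  ds <- excl$data
  screen <- screen_covariates(ds, alpha = alpha)
  grouping <- screen$grouping_decision
  candidates <- candidate_patterns(ds, grouping, seed = seed,
                                   threshold = threshold)
  evaluations <- purrr::map(candidates, ~ evaluate_pattern(ds, .x, alpha = alpha))
  final <- select_final_pattern(evaluations)
  sex_cmp <- if (grouping == "sex") sex_cluster_comparison(ds, final$pattern)
  structure(
    list(layer = attr(ds, "layer"), data = ds, screen = screen,
         candidates = candidates, evaluations = evaluations, final = final,
         exclusions = excl$excluded, sex_comparison = sex_cmp),
    class = "layer_analysis"
  )
}

#' @export
print.layer_analysis <- function(x, ...) {
  cat(sprintf("<layer_analysis> %s: grouped by %s, %d candidate pattern(s)\n",
              x$layer, x$screen$grouping_decision, length(x$candidates)))
  print(x$final)
  invisible(x)
}

#' @rdname analyze_layer
#' @param x A `layer_analysis`.
#' @param ... Unused.
#' @method tidy layer_analysis
#' @export
tidy.layer_analysis <- function(x, ...) tidy(x$final)

#' @rdname analyze_layer
#' @method glance layer_analysis
#' @export
glance.layer_analysis <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(layer = x$layer), glance(x$final))
}

# --- parameter recovery ----------------------------------------------------

#' Assess recovery of a simulated layer's ground truth
#'
#' Compares a [analyze_layer()] result against the generator's ground truth:
#' adjusted Rand index between the final assignment and the true pattern;
#' absolute error of the pooled post-vertex slope versus the mean true
#' slope; and, per true cluster, the absolute vertex-age error of the
#' best-overlapping estimated cluster.
#'
#' @param analysis A `layer_analysis` from a simulated dataset.
#' @param truth The `ground_truth` returned by [simulate_cohort()].
#' @return A one-row tibble: `layer`, `k_true`, `k_est`, `ari`,
#'   `pooled_slope_est`, `pooled_slope_true`, `pooled_slope_abs_err`,
#'   `vertex_mae` (NA for layers without an age model).
#' @export
assess_recovery <- function(analysis, truth) {
  stopifnot(inherits(analysis, "layer_analysis"),
            inherits(truth, "ground_truth"))
  spec <- truth$layers[[analysis$layer]]
  if (is.null(spec)) stop("no ground truth for layer ", analysis$layer, call. = FALSE)
  est <- analysis$final$pattern$assignment
  true_assign <- spec$assignment[names(est)]
  ari <- mclust::adjustedRandIndex(est, true_assign)
  if (spec$grouping == "age" && analysis$final$grouping == "age") {
    slope_true <- mean(spec$clusters$post_vertex_slope)
    slope_est <- analysis$final$pooled_slope
    models <- analysis$final$models
    vertex_err <- purrr::map_dbl(seq_len(nrow(spec$clusters)), function(cl) {
      members <- names(spec$assignment)[spec$assignment == cl]
      members <- intersect(members, names(est))
      overlap <- table(est[members])
      match_cl <- as.integer(names(overlap)[which.max(overlap)])
      v_est <- models$vertex_age[models$cluster == match_cl]
      abs(v_est - spec$clusters$vertex_age[cl])
    })
    vertex_mae <- mean(vertex_err)
  } else {
    slope_true <- NA_real_
    slope_est <- NA_real_
    vertex_mae <- NA_real_
  }
  tibble::tibble(
    layer = analysis$layer,
    k_true = nrow(spec$clusters), k_est = analysis$final$pattern$k,
    ari = ari,
    pooled_slope_est = slope_est, pooled_slope_true = slope_true,
    pooled_slope_abs_err = abs(slope_est - slope_true),
    vertex_mae = vertex_mae
  )
}
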