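# Pattern evaluation and final-pattern selection.

#' Evaluate a candidate cluster pattern
#'
#' For an age-grouped pattern, fits the per-cluster age models and computes
#' the pattern-level goodness-of-fit summaries used for selection (mean R^2,
#' mean residual sum-of-squares, mean SD-of-residuals) plus the slope
#' homogeneity test and pooled slope. For sex- or whole-cohort patterns,
#' where age regression does not apply, computes the mean coefficient of
#' variation of per-eye cluster thicknesses across clusters and groups.
#'
#' @param ds A `grid_dataset` after [apply_exclusions()].
#' @param pattern A finalised `cluster_pattern`.
#' @param alpha Significance level used in the component tests.
#' @return A `pattern_evaluation` object.
#' @export
evaluate_pattern <- function(ds, pattern, alpha = 0.05) {
  stopifnot(inherits(pattern, "cluster_pattern"))
  if (pattern$grouping == "age") {
    cohorts <- cohort_spec(ds$age, pattern$width)
    models <- cluster_age_models(ds, pattern, cohorts, alpha = alpha)
    pool <- slope_homogeneity_and_pool(models, alpha = alpha)
    out <- list(pattern = pattern, grouping = "age", cohorts = cohorts,
                models = models,
                mean_r_squared = mean(models$r_squared),
                mean_ss = mean(models$ss_resid),
                mean_sd_resid = mean(models$sd_resid),
                slope_p = pool$p_value, pooled_slope = pool$pooled_slope,
                poolable = pool$poolable, cov = NA_real_)
  } else {
    eyes <- cluster_eye_thickness(ds, pattern)
    eyes$group <- if (pattern$grouping == "sex") eyes$sex else "all"
    covs <- eyes |>
      dplyr::group_by(.data$cluster, .data$group) |>
      dplyr::summarise(
        cov = coefficient_of_variation(mean(.data$thickness_um),
                                       sd0(.data$thickness_um)),
        .groups = "drop")
    out <- list(pattern = pattern, grouping = pattern$grouping, cohorts = NULL,
                models = NULL, mean_r_squared = NA_real_, mean_ss = NA_real_,
                mean_sd_resid = NA_real_, slope_p = NA_real_,
                pooled_slope = NA_real_, poolable = NA,
                cov = mean(covs$cov), cov_table = covs)
  }
  structure(out, class = "pattern_evaluation")
}

#' @export
print.pattern_evaluation <- function(x, ...) {
  cat(sprintf("<pattern_evaluation> %s/%s, %d cluster(s)\n",
              x$pattern$method, x$pattern$grouping, x$pattern$k))
  if (x$grouping == "age") {
    cat(sprintf("  mean R^2 %.4f, mean SS %.4g, mean SD-resid %.4g\n",
                x$mean_r_squared, x$mean_ss, x$mean_sd_resid))
    cat(sprintf("  slope homogeneity p = %.3g; pooled slope %.4g um/yr\n",
                x$slope_p, x$pooled_slope))
  } else {
    cat(sprintf("  mean coefficient of variation %.4f\n", x$cov))
  }
  invisible(x)
}

#' @rdname evaluate_pattern
#' @param x A `pattern_evaluation`.
#' @param ... Unused.
#' @method tidy pattern_evaluation
#' @export
tidy.pattern_evaluation <- function(x, ...) {
  if (x$grouping != "age") {
    return(x$cov_table)
  }
  dplyr::select(x$models, "cluster", "form", "r_squared", "ss_resid",
                "sd_resid", "vertex_age", "beyond_cohort",
                "post_vertex_slope", "zero_slope_p", "peak_um")
}

#' @rdname evaluate_pattern
#' @method glance pattern_evaluation
#' @export
glance.pattern_evaluation <- function(x, ...) {
  tibble::tibble(
    method = x$pattern$method, grouping = x$grouping,
    width = x$pattern$width, k = x$pattern$k,
    mean_r_squared = x$mean_r_squared, mean_ss = x$mean_ss,
    mean_sd_resid = x$mean_sd_resid, slope_p = x$slope_p,
    pooled_slope = x$pooled_slope, cov = x$cov
  )
}

# Lexicographic sort keys; smaller is better on every key.
evaluation_sort_keys <- function(evals) {
  age <- vapply(evals, function(e) e$grouping == "age", logical(1))
  if (!all(age) && any(age)) {
    stop("cannot rank age-grouped against non-age patterns", call. = FALSE)
  }
  tibble::tibble(
    idx = seq_along(evals),
    key1 = vapply(evals, function(e) if (e$grouping == "age") -e$mean_r_squared else e$cov, numeric(1)),
    key2 = vapply(evals, function(e) if (e$grouping == "age") e$mean_ss else 0, numeric(1)),
    key3 = vapply(evals, function(e) if (e$grouping == "age") e$mean_sd_resid else 0, numeric(1)),
    k = vapply(evals, function(e) e$pattern$k, numeric(1)),
    method = vapply(evals, function(e) e$pattern$method, character(1))
  )
}

#' Select the final cluster pattern
#'
#' Ranks candidate evaluations lexicographically: for age-grouped layers by
#' highest mean R^2, then lowest mean residual sum-of-squares, then lowest
#' SD-of-residuals; for other layers by lowest mean coefficient of
#' variation. Remaining ties break deterministically towards fewer clusters,
#' then alphabetical method name.
#'
#' @param evaluations A list of [evaluate_pattern()] results (all
#'   age-grouped or all not).
#' @return The winning `pattern_evaluation`, with the full ranking attached
#'   as attribute `"ranking"`.
#' @export
select_final_pattern <- function(evaluations) {
  stopifnot(length(evaluations) >= 1L)
  keys <- evaluation_sort_keys(evaluations)
  ord <- order(keys$key1, keys$key2, keys$key3, keys$k, keys$method)
  best <- evaluations[[keys$idx[ord[1]]]]
  attr(best, "ranking") <- keys[ord, ]
  best
}
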