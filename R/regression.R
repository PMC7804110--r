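# Per-cluster age-trend modelling: linear vs quadratic fits on cohort means,
# vertex ages, post-vertex slopes, zero-slope tests and age correction.

new_layer_fit <- function(form, coefs, points, extra = list()) {
  x <- points$age
  y <- points$thickness_um
  yhat <- predict_fit_raw(form, coefs, x)
  res <- y - yhat
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    c(list(form = form, coef = coefs, n = length(x),
           r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
           ss_resid = ss_res, sd_resid = sd0(res)),
      extra),
    class = "layer_fit"
  )
}

predict_fit_raw <- function(form, coefs, x) {
  if (form == "quadratic") {
    coefs[["a"]] * x^2 + coefs[["b"]] * x + coefs[["c"]]
  } else {
    coefs[["m"]] * x + coefs[["c"]]
  }
}

#' Evaluate a fitted age-trend model
#'
#' @param fit A `layer_fit` from [fit_models()] or [choose_form()].
#' @param age Ages (years) at which to evaluate the fitted curve.
#' @return Fitted thickness (um).
#' @export
predict_fit <- function(fit, age) {
  stopifnot(inherits(fit, "layer_fit"))
  predict_fit_raw(fit$form, fit$coef, age)
}

#' @export
print.layer_fit <- function(x, ...) {
  eq <- if (x$form == "quadratic") {
    sprintf("y = %.6g x^2 + %.6g x + %.6g", x$coef[["a"]], x$coef[["b"]], x$coef[["c"]])
  } else {
    sprintf("y = %.6g x + %.6g", x$coef[["m"]], x$coef[["c"]])
  }
  cat(sprintf("<layer_fit> %s: %s (R^2 %.3f, n %d)\n", x$form, eq,
              x$r_squared, x$n))
  invisible(x)
}

#' Fit linear and quadratic age-trend models to cohort means
#'
#' Ordinary least squares of cohort mean thickness on representative cohort
#' age, unweighted by cohort size. Both model forms are returned; use
#' [choose_form()] to pick one.
#'
#' @param points A tibble with columns `age` (representative cohort age,
#'   years) and `thickness_um` (cohort mean thickness).
#' @param weights Optional per-point weights (e.g. cohort sizes); default
#'   unweighted.
#' @return A list with elements `linear` and `quadratic`, each a
#'   `layer_fit` carrying the coefficients (`m`, `c` or `a`, `b`, `c`) and
#'   fit statistics (R^2, residual sum-of-squares, SD of residuals).
#' @export
fit_models <- function(points, weights = NULL) {
  stopifnot(all(c("age", "thickness_um") %in% names(points)))
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 points for a quadratic fit", call. = FALSE)
  if (length(unique(points$age)) < 3L) {
    stop("need at least 3 distinct ages", call. = FALSE)
  }
  w <- weights %||% rep(1, n)
  lin <- lm(thickness_um ~ age, data = points, weights = w)
  quad <- lm(thickness_um ~ age + I(age^2), data = points, weights = w)
  list(
    linear = new_layer_fit("linear",
                           c(m = unname(coef(lin)[2]), c = unname(coef(lin)[1])),
                           points),
    quadratic = new_layer_fit("quadratic",
                              c(a = unname(coef(quad)[3]), b = unname(coef(quad)[2]),
                                c = unname(coef(quad)[1])),
                              points)
  )
}

#' Choose between the linear and quadratic fit
#'
#' The extra-sum-of-squares F-test comparing the nested models is computed
#' and reported, but the quadratic form is retained whether or not the
#' improvement is significant -- a deliberately conservative preference for
#' the curvature that retinal ageing data show -- except when the fitted
#' curvature is negligible (`|a| < linearity_tol`), in which case the
#' quadratic has degenerated to a line and the linear fit is returned.
#'
#' @param fits The list returned by [fit_models()].
#' @param points The points the models were fitted to.
#' @param linearity_tol Curvature magnitude (um/year^2) below which a
#'   quadratic is treated as linear (default 1e-4).
#' @param alpha Significance level recorded with the F-test (default 0.05).
#' @return The chosen `layer_fit`, augmented with `f_statistic`, `f_p_value`
#'   and (for quadratics) an `upward` flag when `a >= 0` (a rising fit,
#'   flagged because ageing decline is modelled as downward).
#' @export
choose_form <- function(fits, points, linearity_tol = 1e-4, alpha = 0.05) {
  stopifnot(is.list(fits), inherits(fits$linear, "layer_fit"),
            inherits(fits$quadratic, "layer_fit"))
  n <- nrow(points)
  ss_lin <- fits$linear$ss_resid
  ss_quad <- fits$quadratic$ss_resid
  df2 <- n - 3
  f_stat <- if (df2 > 0 && ss_quad > 0) (ss_lin - ss_quad) / (ss_quad / df2) else Inf
  f_p <- if (is.finite(f_stat)) pf(f_stat, 1, df2, lower.tail = FALSE) else 0
  chosen <- if (abs(fits$quadratic$coef[["a"]]) < linearity_tol) {
    fits$linear
  } else {
    fits$quadratic
  }
  chosen$f_statistic <- f_stat
  chosen$f_p_value <- f_p
  if (chosen$form == "quadratic") {
    chosen$upward <- chosen$coef[["a"]] >= 0
  }
  chosen
}

#' Vertex age of a quadratic age-trend model
#'
#' The age at which the fitted quadratic peaks: `-b / (2a)`. Flagged
#' `beyond_cohort` when it falls outside the range of representative cohort
#' ages, i.e. decline is estimated to begin outside the sampled ages.
#'
#' @param fit A quadratic `layer_fit`.
#' @param age_range Numeric length-2 range of representative cohort ages.
#' @return A list with `age` (years) and `beyond_cohort` (logical).
#' @export
vertex_age <- function(fit, age_range) {
  stopifnot(inherits(fit, "layer_fit"))
  if (fit$form != "quadratic") stop("vertex age requires a quadratic fit", call. = FALSE)
  a <- fit$coef[["a"]]
  if (a == 0) stop("a = 0: degenerate quadratic should have been classed linear",
                   call. = FALSE)
  v <- -fit$coef[["b"]] / (2 * a)
  list(age = v, beyond_cohort = v < min(age_range) || v > max(age_range))
}

#' Post-vertex slope of thickness decline
#'
#' The OLS slope (um/year) over the cohort-mean points at ages at or beyond
#' the vertex. When fewer than `min_points` such points exist (including a
#' vertex beyond the oldest cohort), the nearest younger points are added
#' until `min_points` are available, to stabilise the estimate. For a linear
#' model the slope is simply its coefficient `m`.
#'
#' @param fit The chosen `layer_fit`.
#' @param points Cohort-mean points (`age`, `thickness_um`).
#' @param min_points Minimum number of points for the slope (default 3).
#' @return A list with `slope` (um/year), `ages_used`, and `n_extended`
#'   (how many younger points were pulled in).
#' @export
post_vertex_slope <- function(fit, points, min_points = 3L) {
  stopifnot(inherits(fit, "layer_fit"))
  if (nrow(points) < min_points) {
    stop("need at least ", min_points, " points", call. = FALSE)
  }
  if (fit$form == "linear") {
    return(list(slope = fit$coef[["m"]], ages_used = sort(points$age),
                n_extended = 0L))
  }
  v <- -fit$coef[["b"]] / (2 * fit$coef[["a"]])
  pts <- dplyr::arrange(points, .data$age)
  sel <- pts$age >= v
  n_ext <- max(0L, min_points - sum(sel))
  if (n_ext > 0) {
    younger <- utils::tail(which(!sel), n_ext)
    sel[younger] <- TRUE
  }
  sub <- pts[sel, ]
  slope <- unname(coef(lm(thickness_um ~ age, data = sub))[2])
  list(slope = slope, ages_used = sub$age, n_extended = n_ext)
}

#' F-test of a zero slope
#'
#' Tests slope = 0 in a simple OLS regression of thickness on age
#' (equivalent to the squared-t test on the slope coefficient). Used both
#' for post-vertex decline and for checking pre-vertex flatness.
#'
#' @param points A tibble with `age` and `thickness_um`, at least 3 rows.
#' @return The two-sided p-value.
#' @export
test_zero_slope <- function(points) {
  if (nrow(points) < 3L) stop("need at least 3 points", call. = FALSE)
  if (length(unique(points$age)) < 2L) {
    stop("degenerate ages: slope is undefined", call. = FALSE)
  }
  fit <- lm(thickness_um ~ age, data = points)
  unname(anova(fit)[["Pr(>F)"]][1])
}

#' Age-correct an observed thickness
#'
#' Shifts an observed thickness along the fitted ageing curve from the
#' subject's age to a reference age: `corrected = thickness +
#' (f(reference_age) - f(age))`. The default reference age is the curve's
#' peak: the vertex for a quadratic, age zero (the intercept) for a linear
#' fit. Correcting and then un-correcting returns the original value.
#'
#' @param thickness_um Observed thickness (um); vectorised.
#' @param age Subject age (years); vectorised.
#' @param fit The cluster's `layer_fit`.
#' @param reference_age Age to correct to (default: curve peak).
#' @return Corrected thickness (um). Ages outside [20, 85] trigger an
#'   extrapolation warning.
#' @export
age_correct <- function(thickness_um, age, fit, reference_age = NULL) {
  stopifnot(inherits(fit, "layer_fit"))
  if (is.null(reference_age)) {
    reference_age <- if (fit$form == "quadratic") {
      -fit$coef[["b"]] / (2 * fit$coef[["a"]])
    } else {
      0
    }
  }
  if (any(age < 20 | age > 85)) {
    warning("age outside [20, 85]: correction is an extrapolation", call. = FALSE)
  }
  thickness_um + (predict_fit(fit, reference_age) - predict_fit(fit, age))
}

# --- cohort means and per-cluster models ----------------------------------

# Per-eye cluster thickness: mean over the cluster's member cells present.
cluster_eye_thickness <- function(ds, pattern) {
  stopifnot(inherits(ds, "grid_dataset"), inherits(pattern, "cluster_pattern"))
  assignment <- tibble::tibble(cell = names(pattern$assignment),
                               cluster = unname(pattern$assignment))
  grid_long(ds) |>
    dplyr::inner_join(assignment, by = "cell") |>
    dplyr::group_by(.data$subject_id, .data$age, .data$sex, .data$cluster) |>
    dplyr::summarise(thickness_um = mean(.data$thickness_um), .groups = "drop")
}

#' Cluster-by-cohort thickness summaries
#'
#' For each eye, cluster thickness is the mean over the cluster's present
#' member cells; for each cluster x age-interval cohort, the mean, SD and
#' eye count of those per-eye values.
#'
#' @param ds A `grid_dataset` after [apply_exclusions()].
#' @param pattern A finalised `cluster_pattern`.
#' @param cohorts A [cohort_spec()].
#' @return A tibble with `cluster`, `cohort`, `rep_age`, `mean_um`, `sd_um`,
#'   `n`. Errors on an empty cohort.
#' @export
cluster_cohort_means <- function(ds, pattern, cohorts) {
  stopifnot(inherits(cohorts, "cohort_spec"))
  if (any(cohorts$n == 0)) {
    stop("empty cohort(s): ",
         paste(cohorts$cohort[cohorts$n == 0], collapse = ", "), call. = FALSE)
  }
  eyes <- cluster_eye_thickness(ds, pattern)
  eyes$cohort <- assign_cohort(eyes$age, cohorts)
  eyes |>
    dplyr::group_by(.data$cluster, .data$cohort) |>
    dplyr::summarise(mean_um = mean(.data$thickness_um),
                     sd_um = sd0(.data$thickness_um),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(cohorts[, c("cohort", "rep_age")], by = "cohort") |>
    dplyr::arrange(.data$cluster, .data$rep_age) |>
    dplyr::relocate("cluster", "cohort", "rep_age")
}

#' Fit age-trend models for every cluster of a pattern
#'
#' Runs the whole per-cluster modelling chain on cluster-by-cohort means:
#' linear and quadratic fits, form choice, vertex age, post-vertex slope
#' and the zero-slope test on the post-vertex points.
#'
#' @inheritParams cluster_cohort_means
#' @param linearity_tol,alpha Passed to [choose_form()].
#' @return A tibble with one row per cluster: the chosen fit (list column
#'   `fit`), its coefficients and statistics, `vertex_age`, `beyond_cohort`,
#'   `post_vertex_slope`, `zero_slope_p`, `peak_um`, and the post-vertex
#'   points used (list column `post_points`).
#' @export
cluster_age_models <- function(ds, pattern, cohorts, linearity_tol = 1e-4,
                               alpha = 0.05) {
  means <- cluster_cohort_means(ds, pattern, cohorts)
  age_range <- range(cohorts$rep_age)
  means |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_map(function(pts, key) {
      points <- tibble::tibble(age = pts$rep_age, thickness_um = pts$mean_um)
      fits <- fit_models(points)
      chosen <- choose_form(fits, points, linearity_tol, alpha)
      if (chosen$form == "quadratic") {
        vx <- vertex_age(chosen, age_range)
        peak <- if (vx$beyond_cohort) chosen$coef[["c"]]
                else predict_fit(chosen, vx$age)
      } else {
        vx <- list(age = NA_real_, beyond_cohort = TRUE)
        peak <- chosen$coef[["c"]]
      }
      pvs <- post_vertex_slope(chosen, points)
      post <- points[points$age %in% pvs$ages_used, ]
      tibble::tibble(
        cluster = key$cluster,
        form = chosen$form,
        fit = list(chosen),
        r_squared = chosen$r_squared,
        ss_resid = chosen$ss_resid,
        sd_resid = chosen$sd_resid,
        vertex_age = vx$age,
        beyond_cohort = vx$beyond_cohort,
        post_vertex_slope = pvs$slope,
        zero_slope_p = test_zero_slope(post),
        peak_um = peak,
        points = list(points),
        post_points = list(post)
      )
    }) |>
    dplyr::bind_rows()
}

#' Test slope homogeneity across clusters and pool
#'
#' ANCOVA-equivalent comparison of post-vertex decline across clusters: the
#' F-test on the cluster x age interaction in a linear model over the
#' clusters' post-vertex cohort-mean points. The pooled slope is the common
#' age coefficient from the no-interaction model; by construction it lies
#' within the range of the per-cluster slopes. Pooling is conventionally
#' reported only when the homogeneity p-value is >= `alpha`.
#'
#' @param models The tibble from [cluster_age_models()].
#' @param alpha Significance level for the homogeneity decision.
#' @return A list with `p_value` (NA for a single cluster), `pooled_slope`
#'   (um/year) and `poolable` (logical).
#' @export
slope_homogeneity_and_pool <- function(models, alpha = 0.05) {
  pts <- models |>
    dplyr::select("cluster", "post_points") |>
    tidyr::unnest("post_points")
  if (dplyr::n_distinct(pts$cluster) < 2L) {
    return(list(p_value = NA_real_,
                pooled_slope = models$post_vertex_slope[1], poolable = NA))
  }
  pts$cluster <- factor(pts$cluster)
  full <- lm(thickness_um ~ age * cluster, data = pts)
  add <- lm(thickness_um ~ age + cluster, data = pts)
  p <- stats::anova(add, full)[["Pr(>F)"]][2]
  list(p_value = p, pooled_slope = unname(coef(add)[["age"]]),
       poolable = !is.na(p) && p >= alpha)
}

# --- per-cluster sex comparison -------------------------------------------

#' Compare cluster thicknesses between sexes
#'
#' Two-sided Mann-Whitney U-test of per-eye cluster thickness between
#' females and males, one test per cluster, with Bonferroni adjustment
#' (p multiplied by the cluster count, capped at 1).
#'
#' @param ds A `grid_dataset` after [apply_exclusions()].
#' @param pattern A finalised `cluster_pattern`.
#' @return A tibble with `cluster`, `n_f`, `n_m`, `median_f`, `median_m`,
#'   `u_statistic`, `p_value`, `p_adjusted`.
#' @export
sex_cluster_comparison <- function(ds, pattern) {
  eyes <- cluster_eye_thickness(ds, pattern)
  if (length(unique(eyes$sex)) < 2L) {
    stop("both sexes must be present", call. = FALSE)
  }
  k <- pattern$k
  eyes |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_map(function(df, key) {
      f <- df$thickness_um[df$sex == "F"]
      m <- df$thickness_um[df$sex == "M"]
      wt <- stats::wilcox.test(f, m, exact = FALSE, correct = FALSE)
      tibble::tibble(cluster = key$cluster, n_f = length(f), n_m = length(m),
                     median_f = stats::median(f), median_m = stats::median(m),
                     u_statistic = unname(wt$statistic),
                     p_value = wt$p.value,
                     p_adjusted = min(1, wt$p.value * k))
    }) |>
    dplyr::bind_rows()
}
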