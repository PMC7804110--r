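# ETDRS sector geometry over the 8x8 grid, sector summaries, and the
# cluster-versus-sector coefficient-of-variation comparison.

#' Map grid cells to ETDRS sectors
#'
#' Assigns each 8x8 cell to an ETDRS sector by its centre point: ring by
#' distance from the fovea (central circle radius 500 um, inner ring to
#' 1500 um, outer ring to 3000 um; centres beyond 3000 um are unassigned
#' since the 6880 um grid overhangs the 6 mm circle), quadrant by the +-45
#' degree diagonals with boundary angles going to the horizontal (nasal /
#' temporal) sectors. No cell centre falls inside the 500 um central circle,
#' so the four innermost cells stand in for it: by default they form the
#' `central` sector; with `central_as_ring = TRUE` they join their
#' inner-ring quadrants instead.
#'
#' @param central_as_ring Place the four innermost cells in their inner-ring
#'   quadrants rather than a separate central sector (default `FALSE`).
#' @param pitch_um Grid cell pitch in micrometres (default 860).
#' @return A `sector_map` tibble: `cell`, `row`, `col`, `x_um`, `y_um`,
#'   `dist_um`, `ring`, `quadrant`, `sector`.
#' @export
etdrs_sector_map <- function(central_as_ring = FALSE, pitch_um = 860) {
  cells <- grid_cells(pitch_um)
  cells <- dplyr::mutate(cells,
    ring = dplyr::case_when(
      .data$dist_um > 3000 ~ "unassigned",
      .data$dist_um > 1500 ~ "outer",
      .data$dist_um > 500 ~ "inner",
      TRUE ~ "central"
    ),
    quadrant = dplyr::case_when(
      abs(.data$x_um) >= abs(.data$y_um) & .data$x_um > 0 ~ "nasal",
      abs(.data$x_um) >= abs(.data$y_um) ~ "temporal",
      .data$y_um > 0 ~ "superior",
      TRUE ~ "inferior"
    )
  )
  central <- cells$row %in% 4:5 & cells$col %in% 4:5
  cells$sector <- dplyr::case_when(
    cells$ring == "unassigned" ~ "unassigned",
    central & !central_as_ring ~ "central",
    TRUE ~ paste(cells$ring, cells$quadrant, sep = "_")
  )
  structure(cells, class = c("sector_map", class(tibble::tibble())))
}

#' Coefficient of variation
#'
#' `sd / mean`: the dimensionless dispersion used to compare the variability
#' of sector-based versus cluster-based thickness summaries. Full precision
#' is kept internally; round only at the reporting layer.
#'
#' @param mean_um Mean thickness (um), strictly positive; vectorised.
#' @param sd_um Standard deviation (um), non-negative; vectorised.
#' @return `sd_um / mean_um`.
#' @export
#' @examples
#' round(coefficient_of_variation(38.79, 2.46), 2) # 0.06
coefficient_of_variation <- function(mean_um, sd_um) {
  if (any(mean_um <= 0)) stop("mean must be strictly positive", call. = FALSE)
  if (any(sd_um < 0)) stop("sd must be non-negative", call. = FALSE)
  sd_um / mean_um
}

#' Sector thickness summaries by age cohort
#'
#' For each eye, sector thickness is the mean over the sector's member cells
#' present; per cohort the mean, sample SD, coefficient of variation and eye
#' count of those per-eye values are reported.
#'
#' @param ds A `grid_dataset` after [apply_exclusions()].
#' @param sector Sector label from [etdrs_sector_map()], e.g.
#'   `"outer_nasal"`.
#' @param cohorts A [cohort_spec()].
#' @param map A `sector_map` (default [etdrs_sector_map()]).
#' @return A tibble with `cohort`, `rep_age`, `mean_um`, `sd_um`, `cov`,
#'   `n`.
#' @export
sector_cohort_summary <- function(ds, sector, cohorts,
                                  map = etdrs_sector_map()) {
  stopifnot(inherits(cohorts, "cohort_spec"))
  member <- map$cell[map$sector == sector]
  member <- intersect(member, analysable_cells(attr(ds, "layer")))
  if (length(member) == 0L) {
    stop("sector has no analysable cells: ", sector, call. = FALSE)
  }
  eyes <- grid_long(ds) |>
    dplyr::filter(.data$cell %in% member) |>
    dplyr::group_by(.data$subject_id, .data$age) |>
    dplyr::summarise(thickness_um = mean(.data$thickness_um), .groups = "drop")
  eyes$cohort <- assign_cohort(eyes$age, cohorts)
  eyes |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(mean_um = mean(.data$thickness_um),
                     sd_um = sd0(.data$thickness_um),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(cov = coefficient_of_variation(.data$mean_um, .data$sd_um),
                  .before = "n") |>
    dplyr::left_join(cohorts[, c("cohort", "rep_age")], by = "cohort") |>
    dplyr::arrange(.data$rep_age) |>
    dplyr::relocate("cohort", "rep_age")
}

#' Cluster thickness coefficients of variation by age cohort
#'
#' The cluster-side counterpart of [sector_cohort_summary()]: per cluster
#' and cohort, the coefficient of variation of per-eye cluster thicknesses.
#'
#' @param ds A `grid_dataset` after [apply_exclusions()].
#' @param pattern A finalised `cluster_pattern`.
#' @param cohorts A [cohort_spec()].
#' @param clusters Optional subset of cluster labels (default all).
#' @return A tibble with `cluster`, `cohort`, `rep_age`, `mean_um`, `sd_um`,
#'   `cov`, `n`.
#' @export
cluster_cohort_cov <- function(ds, pattern, cohorts, clusters = NULL) {
  means <- cluster_cohort_means(ds, pattern, cohorts)
  if (!is.null(clusters)) means <- means[means$cluster %in% clusters, ]
  means$cov <- coefficient_of_variation(means$mean_um, means$sd_um)
  means
}

#' Compare two collections of coefficients of variation
#'
#' Summarises each collection as mean +- sample SD and compares them with a
#' two-sided Mann-Whitney U test (mid-ranks for ties). Used to contrast the
#' variability of ETDRS sector summaries against grid-wise cluster
#' summaries.
#'
#' @param sector_covs Numeric CoV values for the ETDRS sector.
#' @param cluster_covs Numeric CoV values for the grid-wise clusters.
#' @return A `cov_comparison` list: `sector_mean`, `sector_sd`,
#'   `cluster_mean`, `cluster_sd`, `u_statistic`, `p_value`.
#' @export
compare_cov_sets <- function(sector_covs, cluster_covs) {
  stopifnot(length(sector_covs) > 0, length(cluster_covs) > 0)
  wt <- stats::wilcox.test(sector_covs, cluster_covs, exact = FALSE,
                           correct = FALSE)
  structure(
    list(sector_mean = mean(sector_covs), sector_sd = sd0(sector_covs),
         cluster_mean = mean(cluster_covs), cluster_sd = sd0(cluster_covs),
         u_statistic = unname(wt$statistic), p_value = wt$p.value,
         n_sector = length(sector_covs), n_cluster = length(cluster_covs)),
    class = "cov_comparison"
  )
}

#' @export
print.cov_comparison <- function(x, ...) {
  cat(sprintf("<cov_comparison> sector %.2f +- %.2f (n %d) vs clusters %.2f +- %.2f (n %d); Mann-Whitney p = %.3g\n",
              x$sector_mean, x$sector_sd, x$n_sector,
              x$cluster_mean, x$cluster_sd, x$n_cluster, x$p_value))
  invisible(x)
}

#' @rdname compare_cov_sets
#' @param x A `cov_comparison`.
#' @param ... Unused.
#' @method glance cov_comparison
#' @export
glance.cov_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
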