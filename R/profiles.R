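# Per-location feature profiles: the inputs to spatial clustering.

#' Build per-location thickness profiles by grouping variable
#'
#' Each analysable grid location becomes one observation whose features are
#' its mean thickness within each group of eyes: age-interval cohorts when
#' thickness is age-associated, female/male when sex-associated, or a single
#' whole-cohort column otherwise. Group means use only the eyes with that
#' cell present; a location missing an entire group is an error.
#'
#' @param ds A `grid_dataset` after [apply_exclusions()].
#' @param grouping `"age"`, `"sex"` or `"whole"`.
#' @param width Cohort bin width in years (5 or 10), used when
#'   `grouping = "age"`.
#' @return A `feature_profiles` object: matrices `mean`, `sd` and `n`
#'   (locations x groups), the grouping tag, and the [cohort_spec()] when
#'   age-grouped.
#' @export
build_feature_profiles <- function(ds, grouping = c("age", "sex", "whole"),
                                   width = 10) {
  grouping <- match.arg(grouping)
  layer <- attr(ds, "layer")
  cells <- analysable_cells(layer)
  long <- grid_long(ds)
  cohorts <- NULL
  if (grouping == "age") {
    cohorts <- cohort_spec(ds$age, width)
    long$group <- assign_cohort(long$age, cohorts)
    group_levels <- cohorts$cohort[cohorts$n > 0]
    if (length(group_levels) < nrow(cohorts)) {
      stop("empty age cohort(s): ",
           paste(setdiff(cohorts$cohort, group_levels), collapse = ", "),
           call. = FALSE)
    }
  } else if (grouping == "sex") {
    if (length(unique(long$sex)) < 2L) {
      stop("both sexes must be present for sex grouping", call. = FALSE)
    }
    long$group <- factor(long$sex, levels = c("F", "M"))
    group_levels <- c("F", "M")
  } else {
    long$group <- factor("all")
    group_levels <- "all"
  }
  summ <- long |>
    dplyr::group_by(.data$cell, .data$group) |>
    dplyr::summarise(mean_um = mean(.data$thickness_um),
                     sd_um = sd0(.data$thickness_um),
                     n = dplyr::n(), .groups = "drop")
  full <- tidyr::expand_grid(cell = cells, group = factor(group_levels, group_levels))
  summ <- dplyr::left_join(full, summ, by = c("cell", "group"))
  if (anyNA(summ$mean_um)) {
    miss <- summ[is.na(summ$mean_um), ]
    stop("no eyes with data for location x group: ",
         paste(sprintf("%s x %s", miss$cell, miss$group), collapse = ", "),
         call. = FALSE)
  }
  to_mat <- function(col) {
    m <- matrix(summ[[col]], nrow = length(cells), byrow = TRUE,
                dimnames = list(cells, group_levels))
    m
  }
  structure(
    list(mean = to_mat("mean_um"), sd = to_mat("sd_um"), n = to_mat("n"),
         grouping = grouping, width = if (grouping == "age") attr(cohorts, "width") else NA,
         cohorts = cohorts, layer = layer),
    class = "feature_profiles"
  )
}

#' @export
print.feature_profiles <- function(x, ...) {
  cat(sprintf("<feature_profiles> layer %s, %d locations x %d group(s) [%s]\n",
              x$layer, nrow(x$mean), ncol(x$mean), x$grouping))
  invisible(x)
}

#' @rdname build_feature_profiles
#' @param x A `feature_profiles` object.
#' @param ... Unused.
#' @method tidy feature_profiles
#' @export
tidy.feature_profiles <- function(x, ...) {
  tibble::as_tibble(as.table(x$mean), .name_repair = "minimal") |>
    rlang::set_names(c("cell", "group", "mean_um")) |>
    dplyr::mutate(sd_um = as.vector(x$sd), n = as.vector(x$n))
}
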