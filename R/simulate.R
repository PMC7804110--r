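# Synthetic cohort generator with known ground truth.
#
# Emulates the demographic structure of the study cohort (253 eyes in six
# decade bins with fixed sex and ethnicity counts) and the spatial/ageing
# structure the analysis assumes: per-layer concentric (or, for the RNFL,
# nasally anchored radial) baseline fields constant within each true
# cluster, a per-cluster downward-quadratic ageing trajectory parameterised
# by vertex age and post-vertex slope, a female sex effect on the RNFL, and
# independent Gaussian cell noise.

# Decade-bin demographic defaults (counts, sex and ethnicity splits,
# refraction and BCVA moments). One White count is raised by 1 in the 50-59
# bin so the ethnicity split sums to the bin size.
default_demographics <- function() {
  tibble::tibble(
    lower = c(20, 30, 40, 50, 60, 70),
    upper = c(30, 40, 50, 60, 70, 85),
    n = c(29L, 26L, 69L, 66L, 40L, 23L),
    n_male = c(11L, 9L, 25L, 30L, 19L, 14L),
    n_white = c(13L, 9L, 39L, 43L, 32L, 19L),
    n_asian = c(16L, 17L, 28L, 20L, 8L, 4L),
    n_other = c(0L, 0L, 2L, 3L, 0L, 0L),
    se_mean = c(-1.45, -1.42, -0.73, -0.16, -0.03, 0.83),
    se_sd = c(1.71, 1.72, 1.54, 1.43, 2.07, 1.20),
    bcva_mean = c(-0.04, -0.02, -0.01, 0.00, 0.04, 0.10),
    bcva_sd = c(0.06, 0.10, 0.08, 0.07, 0.17, 0.10)
  )
}

# Concentric distance bands over the 64 cells (cell units from the fovea).
concentric_assignment <- function(breaks, cells = grid_cells(pitch_um = 1)) {
  d <- sqrt(((4.5 - cells$col))^2 + ((4.5 - cells$row))^2)
  findInterval(d, breaks) + 1L
}

# Radial bands from an anchor just beyond the nasal edge, displaced slightly
# inferiorly so inferior cells land in thicker bands than superior ones.
radial_nasal_assignment <- function(breaks = c(4, 6, 8),
                                    anchor = c(x = 5.5, y = -1)) {
  cells <- grid_cells(pitch_um = 1)
  cx <- 4.5 - cells$col
  cy <- 4.5 - cells$row
  d <- sqrt((cx - anchor[["x"]])^2 + (cy - anchor[["y"]])^2)
  findInterval(d, breaks) + 1L
}

# Curvature of the downward quadratic a (x - v)^2 whose OLS slope over the
# post-vertex decade representative ages equals the requested post-vertex
# slope. rep_ages are the nominal decade representatives (top bin ~77.5).
quadratic_curvature <- function(vertex, slope,
                                rep_ages = c(25, 35, 45, 55, 65, 77.5)) {
  post <- rep_ages[rep_ages >= vertex]
  if (length(post) < 3L) post <- utils::tail(rep_ages, 3L)
  slope / (2 * (mean(post) - vertex))
}

layer_spec <- function(layer, grouping, assignment, baseline_um, noise_sd,
                       vertex_age = NULL, post_vertex_slope = NULL,
                       sex_effect_um = 0) {
  cells <- grid_cell_names()
  info <- layer_info(layer)
  assignment <- as.integer(assignment)
  stopifnot(length(assignment) == 64L)
  names(assignment) <- cells
  if (info$foveal_exclusion) assignment[foveal_cell_names()] <- 0L
  k <- length(unique(assignment[assignment > 0]))
  stopifnot(length(baseline_um) == k)
  clusters <- tibble::tibble(
    cluster = seq_len(k),
    baseline_um = as.numeric(baseline_um),
    vertex_age = if (grouping == "age") as.numeric(vertex_age) else NA_real_,
    post_vertex_slope = if (grouping == "age") as.numeric(post_vertex_slope) else NA_real_
  )
  if (grouping == "age") {
    stopifnot(length(vertex_age) == k, length(post_vertex_slope) == k)
    clusters$curvature <- purrr::map2_dbl(clusters$vertex_age,
                                          clusters$post_vertex_slope,
                                          quadratic_curvature)
  } else {
    clusters$curvature <- NA_real_
  }
  list(layer = layer, grouping = grouping, assignment = assignment,
       clusters = clusters, noise_sd = noise_sd, sex_effect_um = sex_effect_um)
}

# Default per-layer ground truths. Baselines are free parameters chosen as
# realistic um values; cluster counts, groupings, vertex ages and slopes
# follow the study's qualitative structure (concentric patterns except a
# radial RNFL; decline starting in the late 4th decade; pooled slopes of
# about -0.04 to -0.11 um/year).
default_layer_specs <- function() {
  ring5 <- concentric_assignment(c(1, 2.2, 3.2, 4.0))    # 4/12/16/20/12 cells
  ring4 <- concentric_assignment(c(2.2, 3.2, 4.0))       # 16/16/20/12
  ring3 <- concentric_assignment(c(2.2, 3.6))            # 16/28/20
  list(
    RNFL = layer_spec("RNFL", "sex", radial_nasal_assignment(),
                      baseline_um = c(38, 30, 24, 19), noise_sd = 2.5,
                      sex_effect_um = 1.82),
    GCL = layer_spec("GCL", "age", ring5,
                     baseline_um = c(30, 50, 43, 36, 24), noise_sd = 3,
                     vertex_age = c(40.8, 37.7, 38.5, 39.5, 40.2),
                     post_vertex_slope = c(-0.12, -0.11, -0.11, -0.10, -0.11)),
    IPL = layer_spec("IPL", "age", ring4,
                     baseline_um = c(42, 38, 33, 28), noise_sd = 2,
                     vertex_age = c(36.5, 45, 50, 55),
                     post_vertex_slope = c(-0.10, -0.10, -0.10, -0.10)),
    INL = layer_spec("INL", "age", ring4,
                     baseline_um = c(41, 37, 33, 29), noise_sd = 1.5,
                     vertex_age = c(25.2, 35, 40, 44.6),
                     post_vertex_slope = c(-0.05, -0.05, -0.05, -0.05)),
    OPL = layer_spec("OPL", "whole", ring3,
                     baseline_um = c(22, 19.5, 17), noise_sd = 1.5),
    ONL_HFL = layer_spec("ONL_HFL", "age", ring5,
                         baseline_um = c(78, 68, 60, 53, 47), noise_sd = 4,
                         vertex_age = c(40.6, 25.8, 45, 50, 52),
                         post_vertex_slope = c(-0.06, -0.06, -0.06, -0.06, -0.06)),
    ISOS = layer_spec("ISOS", "age", ring3,
                      baseline_um = c(36.5, 33, 29.5), noise_sd = 1.2,
                      vertex_age = c(45, 48, 50),
                      post_vertex_slope = c(-0.04, -0.04, -0.04)),
    RPE = layer_spec("RPE", "whole", ring4,
                     baseline_um = c(17, 15.5, 14, 12.5), noise_sd = 1)
  )
}

#' Simulation configuration
#'
#' Assembles the study conditions for [simulate_cohort()]: decade-bin
#' demographics, per-layer ground-truth cluster patterns and ageing models,
#' noise levels and the cell missingness rate. The defaults encode the
#' cohort the package's analyses are calibrated against (253 eyes across
#' six decade bins); per-layer defaults are described in the package
#' vignette.
#'
#' @param demographics Decade-bin demographic tibble (see
#'   `default_demographics()` internals); must keep its column set.
#' @param layers Named list of layer specifications (default all eight
#'   layers).
#' @param missing_rate Probability that an individual analysable cell is
#'   missing (default 0.02).
#' @param age_model `"quadratic"` (default: thickness follows a downward
#'   quadratic in age, flat at the vertex) or `"hinge"` (exactly flat before
#'   the vertex, linear decline after; a stress-test mode).
#' @param seed Default integer seed used by [simulate_cohort()] when none is
#'   passed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(demographics = default_demographics(),
                       layers = default_layer_specs(),
                       missing_rate = 0.02,
                       age_model = c("quadratic", "hinge"),
                       seed = 1L) {
  age_model <- match.arg(age_model)
  stopifnot(is.numeric(missing_rate), missing_rate >= 0, missing_rate <= 1,
            all(demographics$n >= 0))
  cfg <- structure(
    list(demographics = demographics, layers = layers,
         missing_rate = missing_rate, age_model = age_model, seed = seed),
    class = "sim_config"
  )
  for (spec in layers) validate_layer_separability(spec, age_model)
  cfg
}

# Ground-truth separability check: at zero noise the true clusters must be
# pairwise d-prime separable (>= 2) on the theoretical feature profiles.
validate_layer_separability <- function(spec, age_model,
                                        rep_ages = c(25, 35, 45, 55, 65, 77.5)) {
  assignment <- spec$assignment[spec$assignment > 0]
  groups <- switch(spec$grouping,
    age = rep_ages, sex = c(F_ = 1, M_ = 0), whole = 1)
  profile <- matrix(0, nrow = length(assignment), ncol = length(groups))
  for (i in seq_along(assignment)) {
    cl <- spec$clusters[assignment[i], ]
    profile[i, ] <- switch(spec$grouping,
      age = cl$baseline_um + age_effect(rep_ages, cl, age_model),
      sex = cl$baseline_um + spec$sex_effect_um * c(1, 0),
      whole = cl$baseline_um)
  }
  stats <- cluster_feature_stats(unname(assignment), profile)
  pd <- pairwise_dprime(stats)
  if (nrow(pd) && min(pd$dprime) < 2) {
    stop("ground-truth pattern for ", spec$layer,
         " is not d-prime separable at zero noise (min d' = ",
         signif(min(pd$dprime), 3), ")", call. = FALSE)
  }
  invisible(spec)
}

age_effect <- function(age, cluster_row, age_model) {
  if (is.na(cluster_row$vertex_age)) return(rep(0, length(age)))
  v <- cluster_row$vertex_age
  if (age_model == "hinge") {
    cluster_row$post_vertex_slope * pmax(age - v, 0)
  } else {
    cluster_row$curvature * (age - v)^2
  }
}

simulate_demographics <- function(demographics) {
  purrr::pmap_dfr(demographics, function(lower, upper, n, n_male, n_white,
                                         n_asian, n_other, se_mean, se_sd,
                                         bcva_mean, bcva_sd) {
    if (n == 0L) return(NULL)
    sex <- sample(c(rep("M", n_male), rep("F", n - n_male)))
    eth <- sample(c(rep("White", n_white), rep("Asian", n_asian),
                    rep("Other", n_other)))
    age <- stats::runif(n, lower, upper)
    bcva_cap <- ifelse(age < 60, 0.1, 0.2)
    tibble::tibble(
      eye = sample(c("OD", "OS"), n, replace = TRUE),
      age = age, sex = sex, ethnicity = eth,
      se_refraction = pmin(pmax(stats::rnorm(n, se_mean, se_sd), -6), 3),
      bcva = pmin(pmax(stats::rnorm(n, bcva_mean, bcva_sd), -0.3), bcva_cap - 1e-3)
    )
  })
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Draws a cohort with the configured decade-bin demographics, then for each
#' layer builds per-eye grids as `baseline(cell) + age_effect(cluster, age)
#' + sex_effect * [sex == F] + noise`, masks cells at the configured
#' missingness rate, and mirrors the grids of left eyes into their native
#' (as-scanned) orientation so the datasets exercise orientation
#' normalisation. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param layers Character vector of layer names to simulate (default: all
#'   in the config).
#' @param seed Integer seed (default: the config's).
#' @return A list with `datasets` (named list of `grid_dataset`, native
#'   orientation) and `truth` (a `ground_truth` object; see
#'   [assess_recovery()]).
#' @export
simulate_cohort <- function(config = sim_config(), layers = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  layers <- layers %||% names(config$layers)
  stopifnot(all(layers %in% names(config$layers)))
  withr::with_seed(seed, {
    demo <- simulate_demographics(config$demographics)
    demo$subject_id <- sprintf("S%03d", seq_len(nrow(demo)))
    cells <- grid_cell_names()
    datasets <- purrr::map(config$layers[layers], function(spec) {
      n <- nrow(demo)
      grid <- matrix(NA_real_, n, 64, dimnames = list(NULL, cells))
      active <- spec$assignment > 0
      for (j in which(active)) {
        row_cl <- spec$clusters[spec$assignment[j], ]
        grid[, j] <- row_cl$baseline_um +
          age_effect(demo$age, row_cl, config$age_model) +
          spec$sex_effect_um * (demo$sex == "F") +
          stats::rnorm(n, 0, spec$noise_sd)
      }
      if (config$missing_rate > 0) {
        mask <- matrix(stats::runif(n * 64) < config$missing_rate, n, 64)
        mask[, !active] <- FALSE
        grid[mask] <- NA_real_
      }
      df <- dplyr::bind_cols(
        demo[, c("subject_id", "eye", "age", "sex", "ethnicity",
                 "se_refraction", "bcva")],
        tibble::as_tibble(grid)
      )
      df$layer <- spec$layer
      ds <- new_grid_dataset(df, spec$layer, orientation = "right_eye")
      # store in native orientation: mirror the OS grids back
      attr(ds, "orientation") <- "native"
      mirrored <- as.vector(t(outer(1:8, 8:1, function(r, c) sprintf("r%dc%d", r, c))))
      os <- ds$eye == "OS"
      if (any(os)) {
        m <- as.matrix(ds[, cells])
        m[os, ] <- m[os, mirrored, drop = FALSE]
        ds[, cells] <- tibble::as_tibble(m)
      }
      ds
    })
    truth <- structure(
      list(layers = config$layers[layers], age_model = config$age_model,
           seed = seed),
      class = "ground_truth"
    )
    list(datasets = datasets, truth = truth)
  })
}

#' Mask grid cells at random
#'
#' Independently masks each analysable cell with probability `rate`;
#' deterministic given `seed`. Used to exercise the missing-data exclusion
#' rules.
#'
#' @param ds A `grid_dataset`.
#' @param rate Masking probability in [0, 1].
#' @param seed Integer seed.
#' @return The dataset with additional cells set to missing.
#' @export
inject_missingness <- function(ds, rate, seed = 1L) {
  stopifnot(inherits(ds, "grid_dataset"), rate >= 0, rate <= 1)
  cells <- analysable_cells(attr(ds, "layer"))
  withr::with_seed(seed, {
    m <- as.matrix(ds[, cells])
    mask <- matrix(stats::runif(length(m)) < rate, nrow(m), ncol(m))
    m[mask] <- NA_real_
    ds[, cells] <- tibble::as_tibble(m)
  })
  ds
}
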