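# Spatial clustering of grid locations: within-groups hierarchical linkage,
# k-means assignment, and d-prime merging.

# --- within-groups agglomeration ------------------------------------------
#
# Agglomerative clustering under squared Euclidean distance where the cost of
# merging two clusters is the mean pairwise squared distance *within* the
# merged cluster (SPSS-style "within-groups linkage", as opposed to UPGMA's
# between-cluster average). Implemented directly: base hclust() offers no
# such linkage. Pairwise sums are maintained incrementally so each of the
# n - 1 merges costs O(n).
hclust_within_groups <- function(mat) {
  n <- nrow(mat)
  stopifnot(n >= 1)
  partitions <- vector("list", n)
  partitions[[n]] <- seq_len(n)
  if (n == 1L) {
    return(list(heights = numeric(0), partitions = partitions))
  }
  d2 <- as.matrix(stats::dist(mat))^2
  between <- d2            # between[i, j] = sum of cross-pair d2 (singletons)
  within <- numeric(n)     # sum of pairwise d2 inside each cluster
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  assignment <- seq_len(n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    ids <- which(active)
    pairs <- utils::combn(ids, 2)
    np <- (size[pairs[1, ]] + size[pairs[2, ]])
    crit <- (within[pairs[1, ]] + within[pairs[2, ]] +
             between[cbind(pairs[1, ], pairs[2, ])]) / (np * (np - 1) / 2)
    best <- which.min(crit)
    i <- pairs[1, best]; j <- pairs[2, best]
    heights[step] <- crit[best]
    within[i] <- within[i] + within[j] + between[i, j]
    size[i] <- size[i] + size[j]
    others <- setdiff(ids, c(i, j))
    between[i, others] <- between[i, others] + between[j, others]
    between[others, i] <- between[i, others]
    active[j] <- FALSE
    assignment[assignment == j] <- i
    k <- n - step
    partitions[[k]] <- match(assignment, sort(unique(assignment)))
  }
  list(heights = heights, partitions = partitions)
}

#' Candidate cluster count from within-groups hierarchical clustering
#'
#' Agglomerates the location profiles under squared Euclidean distance with
#' within-groups linkage and picks the cluster count, bounded to `[1,
#' max_k]`, at the largest relative jump in the agglomeration-height
#' schedule: for each candidate `k` in `2..max_k` the jump is the ratio of
#' the height of the merge that would reduce `k` clusters to `k - 1` over
#' the preceding merge height. Identical profiles (an all-zero schedule)
#' give `k = 1`.
#'
#' @param profiles A [build_feature_profiles()] result.
#' @param max_k Upper bound on the returned cluster count (default 10).
#' @return An integer cluster count.
#' @export
hierarchical_candidate_k <- function(profiles, max_k = 10) {
  stopifnot(inherits(profiles, "feature_profiles"))
  tree <- hclust_within_groups(profiles$mean)
  h <- tree$heights
  n <- nrow(profiles$mean)
  if (n < 2L || all(h <= .Machine$double.eps)) return(1L)
  if (n == 2L) return(2L)
  ks <- seq(2L, min(max_k, n - 1L))
  gap <- vapply(ks, function(k) {
    i <- n - k + 1L                     # merge that collapses k -> k - 1 clusters
    if (i < 2L) return(NA_real_)
    h[i] / max(h[i - 1L], .Machine$double.eps)
  }, numeric(1))
  if (all(is.na(gap))) return(1L)
  as.integer(ks[which.max(gap)])
}

# --- cluster patterns ------------------------------------------------------

new_cluster_pattern <- function(assignment, profiles, method, merge_audit = NULL,
                                k_init = NULL) {
  cells <- rownames(profiles$mean)
  stopifnot(length(assignment) == length(cells))
  assignment <- relabel_by_thickness(assignment, profiles$mean)
  names(assignment) <- cells
  stats <- cluster_feature_stats(assignment, profiles$mean)
  structure(
    list(layer = profiles$layer, assignment = assignment, k = nrow(stats),
         stats = stats, method = method, grouping = profiles$grouping,
         width = profiles$width, k_init = k_init %||% nrow(stats),
         merge_audit = merge_audit %||%
           tibble::tibble(step = integer(), cluster_a = integer(),
                          cluster_b = integer(), dprime = numeric())),
    class = "cluster_pattern"
  )
}

# Canonical labels: 1..k in order of decreasing mean member thickness, so
# cluster 1 is always the thickest. Deterministic under relabelled input.
relabel_by_thickness <- function(assignment, profile_matrix) {
  stats <- cluster_feature_stats(assignment, profile_matrix)
  ord <- order(-stats$mean_um, stats$cluster)
  match(assignment, stats$cluster[ord])
}

#' @export
print.cluster_pattern <- function(x, ...) {
  cat(sprintf("<cluster_pattern> layer %s, %d cluster(s), method %s, grouping %s%s\n",
              x$layer, x$k, x$method, x$grouping,
              if (!is.na(x$width)) sprintf(" (%d-year cohorts)", x$width) else ""))
  print(x$stats)
  invisible(x)
}

#' Tidy a cluster pattern into one row per grid cell
#'
#' @param x A `cluster_pattern`.
#' @param ... Unused.
#' @return A tibble with columns `cell`, `row`, `col`, `cluster`.
#' @method tidy cluster_pattern
#' @export
tidy.cluster_pattern <- function(x, ...) {
  dplyr::inner_join(
    grid_cells()[, c("cell", "row", "col")],
    tibble::tibble(cell = names(x$assignment), cluster = unname(x$assignment)),
    by = "cell"
  )
}

#' Cluster assignment as an 8x8 integer matrix
#'
#' @param pattern A `cluster_pattern`.
#' @return An 8x8 integer matrix; excluded (foveal) cells are 0.
#' @export
pattern_matrix <- function(pattern) {
  m <- matrix(0L, 8, 8, dimnames = list(paste0("r", 1:8), paste0("c", 1:8)))
  td <- tidy(pattern)
  m[cbind(td$row, td$col)] <- td$cluster
  m
}

#' Write a cluster pattern to JSON
#'
#' Serialises the assignment (as an 8x8 matrix with 0 for excluded cells),
#' per-cluster statistics and the merge audit trail.
#'
#' @param pattern A `cluster_pattern`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_pattern <- function(pattern, path) {
  jsonlite::write_json(
    list(layer = pattern$layer, method = pattern$method,
         grouping = pattern$grouping, k = pattern$k,
         assignment = pattern_matrix(pattern),
         stats = pattern$stats, merge_audit = pattern$merge_audit),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}

#' k-means assignment of grid locations
#'
#' Runs k-means (squared-Euclidean objective, multiple restarts, best
#' objective kept) on the location profiles. Deterministic given `seed`.
#'
#' @param profiles A [build_feature_profiles()] result.
#' @param k Number of clusters, between 1 and the number of distinct
#'   profiles.
#' @param seed Integer seed for the restarts.
#' @param nstart Number of random restarts (default 50).
#' @return An unmerged `cluster_pattern`; follow with
#'   [merge_until_separable()].
#' @export
kmeans_assign <- function(profiles, k, seed = 1L, nstart = 50L) {
  stopifnot(inherits(profiles, "feature_profiles"))
  mat <- profiles$mean
  n_distinct <- nrow(unique(mat))
  if (k < 1 || k > nrow(mat)) stop("k must be in [1, n locations]", call. = FALSE)
  if (k > n_distinct) {
    stop("k exceeds the number of distinct profiles (", n_distinct, ")",
         call. = FALSE)
  }
  if (k == nrow(mat)) {
    # all-singleton partition: the exact optimum (zero within-cluster SS)
    return(new_cluster_pattern(seq_len(nrow(mat)), profiles, method = "kmeans"))
  }
  fit <- withr::with_seed(seed, {
    stats::kmeans(mat, centers = k, nstart = nstart, iter.max = 100L)
  })
  new_cluster_pattern(fit$cluster, profiles, method = "kmeans")
}

#' Hierarchical-cut assignment of grid locations
#'
#' Cuts the within-groups agglomeration tree at `k` clusters.
#'
#' @inheritParams kmeans_assign
#' @return An unmerged `cluster_pattern`.
#' @export
hierarchical_assign <- function(profiles, k) {
  stopifnot(inherits(profiles, "feature_profiles"))
  if (k < 1 || k > nrow(profiles$mean)) {
    stop("k must be in [1, n locations]", call. = FALSE)
  }
  tree <- hclust_within_groups(profiles$mean)
  new_cluster_pattern(tree$partitions[[k]], profiles, method = "hierarchical")
}

#' Merge clusters until all pairs are d-prime separable
#'
#' While any cluster pair has `dprime < threshold`, the pair with the
#' smallest d-prime is merged (its member feature values pooled and the
#' mean/SD recomputed) and the merge appended to the audit trail. The
#' cluster count strictly decreases, so the procedure terminates; the worst
#' case is a single cluster.
#'
#' @param pattern A `cluster_pattern`.
#' @param profiles The `feature_profiles` the pattern was computed from.
#' @param threshold Minimum required pairwise separability (default 2:
#'   cluster means at least two pooled SDs apart).
#' @return A `cluster_pattern` whose pairwise d-prime values are all
#'   `>= threshold`, with the merge audit recorded.
#' @export
merge_until_separable <- function(pattern, profiles, threshold = 2) {
  stopifnot(inherits(pattern, "cluster_pattern"),
            inherits(profiles, "feature_profiles"))
  assignment <- unname(pattern$assignment)
  audit <- pattern$merge_audit
  step <- nrow(audit)
  repeat {
    stats <- cluster_feature_stats(assignment, profiles$mean)
    pd <- pairwise_dprime(stats)
    if (nrow(pd) == 0L || min(pd$dprime) >= threshold) break
    worst <- dplyr::arrange(pd, .data$dprime, .data$cluster_a, .data$cluster_b)[1, ]
    step <- step + 1L
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      step = step, cluster_a = worst$cluster_a, cluster_b = worst$cluster_b,
      dprime = worst$dprime))
    assignment[assignment == worst$cluster_b] <- worst$cluster_a
    assignment <- relabel_by_thickness(assignment, profiles$mean)
  }
  new_cluster_pattern(assignment, profiles, method = pattern$method,
                      merge_audit = audit, k_init = pattern$k_init)
}

#' Generate the candidate cluster patterns for a layer
#'
#' For an age-grouped layer, four candidates: within-groups hierarchical cut
#' and k-means, each under 5- and 10-year age-interval cohorts. For a sex- or
#' whole-cohort-grouped layer, two candidates (hierarchical cut and k-means).
#' Every candidate's cluster count comes from [hierarchical_candidate_k()]
#' and every candidate is merged to pairwise d-prime >= `threshold`.
#'
#' @param ds A `grid_dataset` after [apply_exclusions()].
#' @param grouping `"age"`, `"sex"` or `"whole"` (normally the
#'   `grouping_decision` of [screen_covariates()]).
#' @param seed Integer seed for the k-means restarts.
#' @param threshold d-prime merge threshold (default 2).
#' @param widths Cohort bin widths tried for age grouping (default 10 and 5).
#' @return A list of `cluster_pattern` objects.
#' @export
candidate_patterns <- function(ds, grouping, seed = 1L, threshold = 2,
                               widths = c(10, 5)) {
  grouping <- match.arg(grouping, c("age", "sex", "whole"))
  profile_sets <- if (grouping == "age") {
    purrr::map(widths, ~ build_feature_profiles(ds, "age", width = .x))
  } else {
    list(build_feature_profiles(ds, grouping))
  }
  purrr::flatten(purrr::map(profile_sets, function(pf) {
    k <- hierarchical_candidate_k(pf)
    list(
      merge_until_separable(hierarchical_assign(pf, k), pf, threshold),
      merge_until_separable(kmeans_assign(pf, k, seed = seed), pf, threshold)
    )
  }))
}
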