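test_that("d-prime matches its definition and symmetries", {
  expect_equal(dprime(10, 1, 12, 1), 2)
  expect_equal(dprime(0, 2, 4, 2), 2)
  expect_equal(dprime(7, 1.3, 7, 1.3), 0)
  # symmetry and scale equivariance
  set.seed(4)
  for (i in 1:20) {
    m1 <- runif(1, 10, 50); m2 <- runif(1, 10, 50)
    s1 <- runif(1, 0, 5); s2 <- runif(1, 0, 5); k <- runif(1, 0.1, 10)
    expect_equal(dprime(m1, s1, m2, s2), dprime(m2, s2, m1, s1))
    expect_equal(dprime(k * m1, k * s1, k * m2, k * s2),
                 dprime(m1, s1, m2, s2), tolerance = 1e-12)
  }
  # degenerate SDs
  expect_identical(dprime(5, 0, 9, 0), Inf)
  expect_identical(dprime(5, 0, 5, 0), 0)
  expect_error(dprime(1, -0.1, 2, 1), "non-negative")
})

test_that("within-groups linkage matches a direct re-implementation", {
  brute_within_groups <- function(mat) {
    clusters <- as.list(seq_len(nrow(mat)))
    d2 <- as.matrix(dist(mat))^2
    heights <- numeric(0)
    partitions <- list()
    while (length(clusters) > 1) {
      best <- NULL; best_crit <- Inf
      for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
        u <- c(clusters[[i]], clusters[[j]])
        pairs <- combn(u, 2)
        crit <- mean(d2[cbind(pairs[1, ], pairs[2, ])])
        if (crit < best_crit) { best_crit <- crit; best <- c(j, i) }
      }
      merged <- c(clusters[[best[1]]], clusters[[best[2]]])
      clusters[[best[2]]] <- NULL
      clusters[[best[1]]] <- merged
      heights <- c(heights, best_crit)
      assign <- integer(nrow(mat))
      for (ci in seq_along(clusters)) assign[clusters[[ci]]] <- ci
      partitions[[length(clusters)]] <- assign
    }
    list(heights = heights, partitions = partitions)
  }
  set.seed(5)
  for (rep in 1:5) {
    mat <- matrix(rnorm(8 * 3), 8, 3)
    ours <- retgrid:::hclust_within_groups(mat)
    ref <- brute_within_groups(mat)
    expect_equal(ours$heights, ref$heights, tolerance = 1e-12)
    for (k in 1:7) {
      expect_equal(mclust::adjustedRandIndex(ours$partitions[[k]],
                                             ref$partitions[[k]]), 1)
    }
  }
})

test_that("the height-gap rule finds the blob count", {
  expect_equal(hierarchical_candidate_k(make_profiles(matrix(5, 12, 2))), 1L)
  set.seed(6)
  blob <- function(center, n) sweep(matrix(rnorm(n * 2, 0, 0.1), n, 2), 2,
                                    center, `+`)
  three <- rbind(blob(c(0, 0), 20), blob(c(10, 0), 22), blob(c(0, 10), 22))
  expect_equal(hierarchical_candidate_k(make_profiles(three)), 3L)
  two <- rbind(blob(c(0, 0), 30), blob(c(12, 3), 34))
  expect_equal(hierarchical_candidate_k(make_profiles(two)), 2L)
  # invariant to location order
  perm <- sample(nrow(two))
  expect_equal(hierarchical_candidate_k(make_profiles(two[perm, ])), 2L)
})

test_that("k-means honours its contracts and finds exact blob partitions", {
  set.seed(7)
  mat <- matrix(rnorm(12 * 2), 12, 2)
  profiles <- make_profiles(mat)
  p1 <- kmeans_assign(profiles, 1, seed = 1)
  expect_equal(p1$k, 1L)
  expect_equal(unname(p1$assignment), rep(1L, 12))
  pn <- kmeans_assign(profiles, 12, seed = 1)
  expect_equal(pn$k, 12L)
  expect_error(kmeans_assign(make_profiles(matrix(5, 6, 2)), 3), "distinct")

  blob <- function(center, n) sweep(matrix(rnorm(n * 2, 0, 0.1), n, 2), 2,
                                    center, `+`)
  three <- rbind(blob(c(0, 0), 4), blob(c(10, 0), 4), blob(c(0, 10), 4))
  pat <- kmeans_assign(make_profiles(three), 3, seed = 2)
  expect_equal(mclust::adjustedRandIndex(unname(pat$assignment),
                                         rep(1:3, each = 4)), 1)
})

test_that("k-means best-of-restarts equals the exhaustive optimum", {
  wss <- function(mat, assign) {
    sum(vapply(unique(assign), function(l) {
      sub <- mat[assign == l, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
  }
  set.seed(8)
  mat <- matrix(rnorm(9 * 2), 9, 2)
  pat <- kmeans_assign(make_profiles(mat), 3, seed = 3)
  ours <- wss(mat, unname(pat$assignment))
  # enumerate all 3^9 labelings
  best <- Inf
  grid <- as.matrix(expand.grid(rep(list(1:3), 9)))
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    if (length(unique(a)) == 3) best <- min(best, wss(mat, a))
  }
  expect_equal(ours, best, tolerance = 1e-9)
})

test_that("merging stops exactly at the separability threshold", {
  # Three clusters on one feature column; exactly one pair below threshold.
  x <- 1.5 * sqrt(2)
  vals <- matrix(c(-1, 1, x - 1, x + 1, 99, 101), ncol = 1)
  profiles <- make_profiles(vals)
  pat <- retgrid:::new_cluster_pattern(c(1, 1, 2, 2, 3, 3), profiles, "kmeans")
  pd <- retgrid:::pairwise_dprime(pat$stats)
  expect_equal(min(pd$dprime), 1.5, tolerance = 1e-12)

  merged <- merge_until_separable(pat, profiles)
  expect_equal(merged$k, 2L)
  expect_equal(nrow(merged$merge_audit), 1L)
  expect_equal(merged$merge_audit$dprime, 1.5, tolerance = 1e-12)
  expect_gte(min_pairwise_dprime(merged, profiles), 2)

  # already separable -> unchanged with empty audit
  ok <- merge_until_separable(merged, profiles)
  expect_equal(unname(ok$assignment), unname(merged$assignment))
  expect_equal(nrow(ok$merge_audit), nrow(merged$merge_audit))

  # identical means merge all the way down
  same <- make_profiles(matrix(c(10, 10, 10, 10), ncol = 1))
  pat2 <- retgrid:::new_cluster_pattern(c(1, 1, 2, 2), same, "kmeans")
  expect_equal(merge_until_separable(pat2, same)$k, 1L)
})

test_that("every produced pattern satisfies the d-prime invariant", {
  set.seed(9)
  for (rep in 1:50) {
    n <- sample(6:16, 1)
    g <- sample(1:3, 1)
    mat <- matrix(rnorm(n * g, mean = 30, sd = 3), n, g)
    profiles <- make_profiles(mat)
    k <- sample(seq_len(min(n, 5)), 1)
    pat <- kmeans_assign(profiles, k, seed = rep)
    merged <- merge_until_separable(pat, profiles)
    expect_gte(min_pairwise_dprime(merged, profiles), 2)
    expect_lte(merged$k, pat$k)
    # labels contiguous from 1
    expect_setequal(unique(unname(merged$assignment)), seq_len(merged$k))
  }
})

test_that("the merge audit replays to the final pattern", {
  set.seed(10)
  mat <- matrix(rnorm(10, mean = 30, sd = 1), ncol = 1)
  profiles <- make_profiles(mat)
  pat <- kmeans_assign(profiles, 5, seed = 1)
  merged <- merge_until_separable(pat, profiles)
  # replay: apply the recorded merges to the starting assignment
  assign <- unname(pat$assignment)
  for (s in seq_len(nrow(merged$merge_audit))) {
    row <- merged$merge_audit[s, ]
    assign[assign == row$cluster_b] <- row$cluster_a
    assign <- retgrid:::relabel_by_thickness(assign, profiles$mean)
  }
  expect_equal(assign, unname(merged$assignment))
})

test_that("candidate counts follow the grouping decision", {
  cfg <- sim_config(demographics = small_demographics(10), missing_rate = 0)
  sim <- simulate_cohort(cfg, layers = c("GCL", "OPL"), seed = 12)
  gcl <- apply_exclusions(normalize_orientation(sim$datasets$GCL))$data
  opl <- apply_exclusions(normalize_orientation(sim$datasets$OPL))$data
  cands_age <- candidate_patterns(gcl, "age", seed = 12)
  expect_length(cands_age, 4)
  cands_whole <- candidate_patterns(opl, "whole", seed = 12)
  expect_length(cands_whole, 2)
  for (p in c(cands_age, cands_whole)) {
    pf <- build_feature_profiles(
      if (p$layer == "GCL") gcl else opl,
      grouping = p$grouping,
      width = if (!is.na(p$width)) p$width else 10
    )
    expect_gte(min_pairwise_dprime(p, pf), 2)
  }
})

test_that("patterns are invariant to eye order", {
  cfg <- sim_config(demographics = small_demographics(10), missing_rate = 0)
  sim <- simulate_cohort(cfg, layers = "GCL", seed = 13)
  ds <- apply_exclusions(normalize_orientation(sim$datasets$GCL))$data
  profiles1 <- build_feature_profiles(ds, "age", width = 10)
  perm <- withr::with_seed(1, sample(nrow(ds)))
  ds2 <- retgrid:::restore_grid_attrs(ds[perm, ], ds)
  profiles2 <- build_feature_profiles(ds2, "age", width = 10)
  expect_equal(profiles1$mean, profiles2$mean)
  p1 <- kmeans_assign(profiles1, 5, seed = 2)
  p2 <- kmeans_assign(profiles2, 5, seed = 2)
  expect_identical(p1$assignment, p2$assignment)
})

test_that("feature profiles average per location and group", {
  ds <- constant_grid_dataset(6)
  pf <- build_feature_profiles(ds, "whole")
  expect_true(all(pf$mean == 30))

  # two sexes with location-specific separation
  thickness <- matrix(20, 4, 64)
  thickness[3:4, ] <- 40 # males
  ds2 <- make_grid_dataset(thickness, sex = c("F", "F", "M", "M"))
  pf2 <- build_feature_profiles(ds2, "sex")
  expect_equal(unname(pf2$mean["r1c1", ]), c(20, 40))

  # duplication of every eye leaves group means unchanged
  ds3 <- retgrid:::restore_grid_attrs(dplyr::bind_rows(ds2, dplyr::mutate(
    tibble::as_tibble(ds2), subject_id = paste0(subject_id, "b"))), ds2)
  pf3 <- build_feature_profiles(ds3, "sex")
  expect_equal(pf3$mean, pf2$mean)
})
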