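quad_points <- function(a, b, c, ages = c(25, 35, 45, 55, 65, 77.5)) {
  tibble::tibble(age = ages, thickness_um = a * ages^2 + b * ages + c)
}

test_that("cohort specs partition ages with increasing representatives", {
  ages <- c(25, 34, 47, 52, 66, 71, 78, 84)
  for (w in c(10, 5)) {
    spec <- cohort_spec(ages, width = w)
    expect_equal(sum(spec$n), length(ages))
    expect_true(all(diff(spec$rep_age) > 0))
    expect_equal(spec$rep_age[nrow(spec)], mean(ages[ages >= 70]))
  }
  spec10 <- cohort_spec(ages, 10)
  expect_equal(spec10$rep_age[1:5], c(25, 35, 45, 55, 65))
  expect_equal(as.character(assign_cohort(c(29.9, 30, 70), spec10)),
               c("20-29", "30-39", "70+"))
})

test_that("exact polynomial data are interpolated to numerical precision", {
  pts <- quad_points(-0.01, 0.8, 20)
  fits <- fit_models(pts)
  expect_equal(unname(fits$quadratic$coef), c(-0.01, 0.8, 20), tolerance = 1e-9)
  expect_equal(fits$quadratic$r_squared, 1, tolerance = 1e-12)

  lin_pts <- tibble::tibble(age = c(25, 35, 45, 55),
                            thickness_um = -0.1 * c(25, 35, 45, 55) + 40)
  lfits <- fit_models(lin_pts)
  expect_equal(lfits$linear$coef[["m"]], -0.1, tolerance = 1e-12)
  expect_lt(abs(lfits$quadratic$coef[["a"]]), 1e-12)
  expect_error(fit_models(lin_pts[1:2, ]), "at least 3")
})

test_that("noisy OLS equals the closed-form normal-equations solution", {
  set.seed(14)
  for (rep in 1:10) {
    pts <- tibble::tibble(age = c(25, 35, 45, 55, 65, 77.5),
                          thickness_um = rnorm(6, 40, 3))
    fits <- fit_models(pts)
    X <- cbind(1, pts$age, pts$age^2)
    beta <- solve(t(X) %*% X, t(X) %*% pts$thickness_um)
    expect_equal(unname(fits$quadratic$coef[c("c", "b", "a")]),
                 as.vector(beta), tolerance = 1e-8)
    rss <- sum((pts$thickness_um - X %*% beta)^2)
    expect_equal(fits$quadratic$ss_resid, rss, tolerance = 1e-8)
  }
})

test_that("form choice applies the near-linearity rule on both sides", {
  curved <- quad_points(-0.01, 0.8, 20)
  expect_equal(choose_form(fit_models(curved), curved)$form, "quadratic")
  almost_linear <- quad_points(-0.00005, 0.1, 35)
  expect_equal(choose_form(fit_models(almost_linear), almost_linear)$form,
               "linear")
  exactly_linear <- quad_points(0, -0.1, 40)
  expect_equal(choose_form(fit_models(exactly_linear), exactly_linear)$form,
               "linear")
  just_curved <- quad_points(-0.01, 0.6, 30)
  expect_equal(choose_form(fit_models(just_curved), just_curved)$form,
               "quadratic")
})

test_that("vertex age is -b/2a with the beyond-cohort flag", {
  rng <- c(25, 77.5)
  mk <- function(a, b, c) {
    choose_form(fit_models(quad_points(a, b, c)), quad_points(a, b, c))
  }
  expect_equal(vertex_age(mk(-0.005, 0.4, 20), rng)$age, 40)
  expect_false(vertex_age(mk(-0.005, 0.4, 20), rng)$beyond_cohort)
  v2 <- vertex_age(mk(-0.001, 0.2, 30), rng)
  expect_equal(v2$age, 100)
  expect_true(v2$beyond_cohort)
  fit_a1 <- retgrid:::new_layer_fit("quadratic", c(a = -1, b = 2, c = 0),
                                    quad_points(-1, 2, 0, ages = c(0, 1, 3)))
  expect_equal(vertex_age(fit_a1, c(0, 3))$age, 1)
  # derivative vanishes at the vertex for any fitted quadratic
  set.seed(15)
  for (rep in 1:20) {
    pts <- tibble::tibble(age = c(25, 35, 45, 55, 65, 77.5),
                          thickness_um = 40 - 0.002 * (c(25, 35, 45, 55, 65, 77.5) - 40)^2 +
                            rnorm(6, 0, 0.5))
    fit <- fit_models(pts)$quadratic
    v <- vertex_age(fit, c(25, 77.5))$age
    expect_lt(abs(2 * fit$coef[["a"]] * v + fit$coef[["b"]]), 1e-12)
  }
})

test_that("post-vertex slope uses the three-point extension rule", {
  # exact line after vertex 40
  pts <- tibble::tibble(age = c(40, 50, 60, 70),
                        thickness_um = c(100, 99, 98, 97))
  fit <- retgrid:::new_layer_fit("quadratic", c(a = -0.001, b = 0.08, c = 99),
                                 pts)
  expect_equal(post_vertex_slope(fit, pts)$slope, -0.1, tolerance = 1e-12)

  # vertex at 62: only ages 65 and 75 beyond, extended with 55
  set.seed(16)
  pts2 <- tibble::tibble(age = c(25, 35, 45, 55, 65, 75),
                         thickness_um = rnorm(6, 40, 2))
  fit2 <- retgrid:::new_layer_fit("quadratic",
                                  c(a = -0.005, b = 0.62, c = 20), pts2)
  expect_equal(-fit2$coef[["b"]] / (2 * fit2$coef[["a"]]), 62)
  res <- post_vertex_slope(fit2, pts2)
  expect_equal(res$ages_used, c(55, 65, 75))
  expect_equal(res$n_extended, 1L)
  sub <- pts2[pts2$age >= 55, ]
  X <- cbind(1, sub$age)
  beta <- solve(t(X) %*% X, t(X) %*% sub$thickness_um)
  expect_equal(res$slope, beta[2], tolerance = 1e-10)

  # flat post-vertex data give zero slope; linear fits return m directly
  flat <- tibble::tibble(age = c(45, 55, 65, 75), thickness_um = rep(33, 4))
  fit3 <- retgrid:::new_layer_fit("quadratic", c(a = -0.01, b = 0.9, c = 15),
                                  flat)
  expect_equal(post_vertex_slope(fit3, flat)$slope, 0)
  lin <- retgrid:::new_layer_fit("linear", c(m = -0.07, c = 40), flat)
  expect_equal(post_vertex_slope(lin, flat)$slope, -0.07)
})

test_that("the zero-slope F-test matches the squared-t and calibrates", {
  exact <- tibble::tibble(age = c(30, 40, 50, 60, 70, 80),
                          thickness_um = 50 - 0.2 * c(30, 40, 50, 60, 70, 80))
  expect_lt(suppressWarnings(test_zero_slope(exact)), 1e-12) # zero-residual fit
  set.seed(17)
  for (rep in 1:10) {
    pts <- tibble::tibble(age = c(25, 35, 45, 55, 65),
                          thickness_um = rnorm(5, 40, 1))
    f_p <- test_zero_slope(pts)
    tt <- summary(lm(thickness_um ~ age, data = pts))$coefficients["age", ]
    expect_equal(f_p, unname(2 * pt(-abs(tt["t value"]), df = 3)),
                 tolerance = 1e-12)
  }
  expect_error(test_zero_slope(tibble::tibble(age = c(40, 40, 40),
                                              thickness_um = 1:3)),
               "degenerate")
})

test_that("slope homogeneity pools only compatible clusters", {
  mk_models <- function(slopes, noise_sd = 0.05, seed = 18) {
    set.seed(seed)
    purrr::map_dfr(seq_along(slopes), function(i) {
      ages <- c(45, 55, 65, 75)
      pts <- tibble::tibble(age = ages,
                            thickness_um = 40 - 5 * i + slopes[i] * (ages - 45) +
                              rnorm(4, 0, noise_sd))
      tibble::tibble(cluster = i,
                     post_vertex_slope = coef(lm(thickness_um ~ age, pts))[[2]],
                     post_points = list(pts))
    })
  }
  same <- mk_models(c(-0.1, -0.1, -0.1))
  res_same <- slope_homogeneity_and_pool(same)
  expect_gt(res_same$p_value, 0.05)
  expect_true(res_same$poolable)
  expect_gte(res_same$pooled_slope, min(same$post_vertex_slope))
  expect_lte(res_same$pooled_slope, max(same$post_vertex_slope))

  diff_slopes <- mk_models(c(-0.1, -0.5), seed = 19)
  res_diff <- slope_homogeneity_and_pool(diff_slopes)
  expect_lt(res_diff$p_value, 0.05)
  expect_false(res_diff$poolable)

  single <- mk_models(-0.1)[1, ]
  res_single <- slope_homogeneity_and_pool(single)
  expect_true(is.na(res_single$p_value))
  expect_equal(res_single$pooled_slope, single$post_vertex_slope)
})

test_that("age correction shifts along the fitted curve and inverts", {
  pts <- tibble::tibble(age = c(30, 45, 60), thickness_um = c(37, 35.5, 34))
  lin <- retgrid:::new_layer_fit("linear", c(m = -0.1, c = 40), pts)
  expect_equal(age_correct(30, 60, lin, reference_age = 40), 32)
  expect_equal(age_correct(28, 50, lin, reference_age = 50), 28)
  corrected <- age_correct(31.2, 72, lin, reference_age = 40)
  uncorrected <- corrected + (predict_fit(lin, 72) - predict_fit(lin, 40))
  expect_equal(uncorrected, 31.2)
  quad <- retgrid:::new_layer_fit("quadratic", c(a = -0.002, b = 0.16, c = 30),
                                  pts)
  # default reference is the vertex (peak thickness)
  expect_equal(age_correct(predict_fit(quad, 55), 55, quad),
               predict_fit(quad, 40))
  expect_warning(age_correct(30, 90, lin, reference_age = 40), "extrapolation")
})

test_that("final-pattern selection is a deterministic total order", {
  mk_eval <- function(r2, ss, sdres, k, method) {
    structure(list(pattern = list(k = k, method = method, width = 10),
                   grouping = "age", mean_r_squared = r2, mean_ss = ss,
                   mean_sd_resid = sdres, cov = NA_real_),
              class = "pattern_evaluation")
  }
  a <- mk_eval(0.9, 5, 1, 5, "kmeans")
  b <- mk_eval(0.7, 2, 1, 5, "kmeans")
  expect_equal(select_final_pattern(list(a, b)),
               select_final_pattern(list(b, a)), ignore_attr = TRUE)
  expect_equal(select_final_pattern(list(a, b))$mean_r_squared, 0.9)
  # R^2 tie broken by lower sum-of-squares
  c1 <- mk_eval(0.9, 2, 3, 5, "kmeans")
  expect_equal(select_final_pattern(list(a, c1))$mean_ss, 2)
  # full tie broken by fewer clusters then method name
  d1 <- mk_eval(0.9, 5, 1, 4, "kmeans")
  expect_equal(select_final_pattern(list(a, d1))$pattern$k, 4)
  e1 <- mk_eval(0.9, 5, 1, 5, "hierarchical")
  expect_equal(select_final_pattern(list(a, e1))$pattern$method, "hierarchical")

  # selection agrees with a brute-force sort under any permutation
  set.seed(20)
  evals <- purrr::map(1:8, ~ mk_eval(sample(c(0.7, 0.8, 0.9), 1),
                                     sample(1:3, 1), sample(1:3, 1),
                                     sample(3:6, 1),
                                     sample(c("kmeans", "hierarchical"), 1)))
  keys <- purrr::map_dfr(evals, ~ tibble::tibble(
    r2 = .x$mean_r_squared, ss = .x$mean_ss, sdres = .x$mean_sd_resid,
    k = .x$pattern$k, method = .x$pattern$method))
  best_idx <- order(-keys$r2, keys$ss, keys$sdres, keys$k, keys$method)[1]
  for (i in 1:5) {
    perm <- sample(length(evals))
    expect_identical(select_final_pattern(evals[perm]), evals[[best_idx]],
                     ignore_attr = TRUE)
  }
})

test_that("sex comparison matches exhaustive pair counting and Bonferroni", {
  # 5 vs 5 toy: U = number of (female, male) pairs won by the female value
  thickness <- matrix(30, 10, 64)
  f_vals <- c(31, 29, 35, 33, 30)
  m_vals <- c(28, 32, 27, 30, 26)
  thickness[1:5, ] <- f_vals
  thickness[6:10, ] <- m_vals
  ds <- make_grid_dataset(thickness, sex = rep(c("F", "M"), each = 5),
                          age = rep(50, 10))
  profiles <- build_feature_profiles(ds, "sex")
  pat <- kmeans_assign(profiles, 1, seed = 1)
  res <- sex_cluster_comparison(ds, pat)
  u_brute <- sum(outer(f_vals, m_vals, ">")) + 0.5 * sum(outer(f_vals, m_vals, "=="))
  expect_equal(res$u_statistic, u_brute)
  expect_gte(res$p_adjusted, res$p_value)

  # a +5 um shift at n = 50/50 and low noise is detected after adjustment
  set.seed(21)
  thickness2 <- matrix(rnorm(100 * 64, 30, 1.5), 100, 64)
  thickness2[1:50, ] <- thickness2[1:50, ] + 5
  ds2 <- make_grid_dataset(thickness2, sex = rep(c("F", "M"), each = 50),
                           age = rep(50, 100))
  pat2 <- kmeans_assign(build_feature_profiles(ds2, "sex"), 1, seed = 1)
  expect_lt(sex_cluster_comparison(ds2, pat2)$p_adjusted, 0.05)
})

test_that("rank-based and variance-robust group tests match hand arithmetic", {
  # Kruskal-Wallis H on 3 groups of 4, no ties: H = 12/(N(N+1)) sum n R^2 - 3(N+1)
  vals <- c(12, 15, 11, 19, 22, 25, 27, 21, 31, 35, 29, 33)
  grp <- rep(c("a", "b", "c"), each = 4)
  res <- kruskal_dunn_test(vals, grp)
  r <- rank(vals)
  rbar <- tapply(r, grp, mean)
  h_hand <- 12 / (12 * 13) * sum(4 * rbar^2) - 3 * 13
  expect_equal(res$kruskal$statistic, h_hand, tolerance = 1e-12)
  expect_equal(nrow(res$dunn), 3)
  expect_true(all(res$dunn$p_adjusted >= res$dunn$p_value))

  # identical group distributions: Brown-Forsythe sees nothing
  set.seed(22)
  base <- rnorm(15, 0, 1)
  bf_same <- brown_forsythe_test(rep(base, 3), rep(1:3, each = 15))
  expect_gt(bf_same$p_value, 0.9)
  # a 3-pooled-SD shift is found
  shifted <- c(base, base, base + 3)
  expect_lt(brown_forsythe_test(shifted, rep(1:3, each = 15))$p_value, 0.05)

  # cross-layer wrapper wires Brown-Forsythe + Dunnett together
  sets <- list(GCL = base - 0.1, IPL = base - 0.1 + rnorm(15, 0, 0.01),
               ISOS = base + 2)
  out <- cross_layer_slope_test(sets, reference = "GCL")
  expect_lt(out$brown_forsythe$p_value, 0.05)
  expect_equal(nrow(out$dunnett), 2)
  p_isos <- out$dunnett$p_adjusted[grepl("ISOS", out$dunnett$comparison)]
  expect_lt(p_isos, 0.05)
})
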