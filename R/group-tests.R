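# Group-comparison tests used across clusters, cohorts and layers:
# Brown-Forsythe with Dunnett follow-ups, Kruskal-Wallis with Dunn
# follow-ups.

#' Brown-Forsythe test for equality of group means
#'
#' Heteroscedasticity-robust one-way comparison of group means: the F*
#' statistic weights between-group variation by `(1 - n_i/N) s_i^2` and uses
#' Satterthwaite denominator degrees of freedom, so unequal group variances
#' do not inflate the test.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor).
#' @return A tibble with `statistic`, `df1`, `df2`, `p_value`.
#' @export
brown_forsythe_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  n_i <- tapply(values, groups, length)
  if (any(n_i < 2L)) stop("every group needs at least 2 observations", call. = FALSE)
  m_i <- tapply(values, groups, mean)
  v_i <- tapply(values, groups, stats::var)
  n <- length(values)
  grand <- mean(values)
  num <- sum(n_i * (m_i - grand)^2)
  c_i <- (1 - n_i / n) * v_i
  den <- sum(c_i)
  f_star <- num / den
  g_i <- c_i / den
  df2 <- 1 / sum(g_i^2 / (n_i - 1))
  k <- nlevels(groups)
  tibble::tibble(statistic = f_star, df1 = k - 1, df2 = df2,
                 p_value = pf(f_star, k - 1, df2, lower.tail = FALSE))
}

#' Dunnett comparisons against a reference group
#'
#' Standard two-sided Dunnett multiple comparisons of group means versus a
#' designated reference group, via `multcomp`.
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @param reference The reference group label (default: first factor level).
#' @return A tibble with `comparison`, `estimate`, `p_adjusted`.
#' @export
dunnett_test <- function(values, groups, reference = NULL) {
  groups <- factor(groups)
  if (!is.null(reference)) groups <- stats::relevel(groups, ref = reference)
  df <- data.frame(v = values, g = groups)
  fit <- stats::aov(v ~ g, data = df)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl)
  tibble::tibble(comparison = names(sm$test$coefficients),
                 estimate = unname(sm$test$coefficients),
                 p_adjusted = unname(sm$test$pvalues))
}

#' Kruskal-Wallis test with post-hoc Dunn comparisons
#'
#' Non-parametric one-way comparison across groups, followed by Dunn's
#' rank-based pairwise z-tests (with the usual tie correction) and
#' Bonferroni adjustment over all pairs.
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @return A list with `kruskal` (tibble: `statistic`, `df`, `p_value`) and
#'   `dunn` (tibble: `group_a`, `group_b`, `z`, `p_value`, `p_adjusted`).
#' @export
kruskal_dunn_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  kw <- stats::kruskal.test(values, groups)
  r <- rank(values)
  n <- length(values)
  n_i <- tapply(r, groups, length)
  rbar_i <- tapply(r, groups, mean)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_corr
  pairs <- utils::combn(levels(groups), 2)
  dunn <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(s2 * (1 / n_i[[a]] + 1 / n_i[[b]]))
    z <- (rbar_i[[a]] - rbar_i[[b]]) / se
    tibble::tibble(group_a = a, group_b = b, z = z,
                   p_value = 2 * stats::pnorm(-abs(z)))
  })
  dunn$p_adjusted <- pmin(1, dunn$p_value * nrow(dunn))
  list(kruskal = tibble::tibble(statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p_value = kw$p.value),
       dunn = dunn)
}

#' Compare post-vertex slopes between retinal layers
#'
#' Brown-Forsythe comparison of the per-cluster post-vertex slope
#' collections across layers, with Dunnett follow-ups against a designated
#' reference layer.
#'
#' @param slope_sets A named list: one numeric vector of per-cluster slopes
#'   (um/year) per layer.
#' @param reference Name of the reference layer (default: first element).
#' @return A list with `brown_forsythe` and `dunnett` tibbles.
#' @export
cross_layer_slope_test <- function(slope_sets, reference = NULL) {
  stopifnot(is.list(slope_sets), length(slope_sets) >= 2L,
            !is.null(names(slope_sets)))
  values <- unlist(slope_sets, use.names = FALSE)
  groups <- factor(rep(names(slope_sets), lengths(slope_sets)),
                   levels = names(slope_sets))
  reference <- reference %||% names(slope_sets)[1]
  list(brown_forsythe = brown_forsythe_test(values, groups),
       dunnett = dunnett_test(values, groups, reference = reference))
}
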