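# d-prime separability of cluster thickness distributions.

#' d-prime separability index
#'
#' Separation of two cluster means in units of their pooled standard
#' deviation: `|m1 - m2| / sqrt(0.5 * (s1^2 + s2^2))`. A value of 2 means the
#' cluster means are two pooled SDs apart, the threshold below which clusters
#' are considered statistically inseparable and are merged.
#'
#' Both SDs zero with equal means gives 0; both zero with unequal means gives
#' `Inf` (perfectly separable point masses). The statistic is symmetric in
#' its arguments and invariant under a common positive rescaling of all four.
#'
#' @param mean1,sd1 Mean and SD of the first cluster's member values (um).
#' @param mean2,sd2 Mean and SD of the second cluster's member values (um).
#' @return Dimensionless separability (vectorised over its arguments).
#' @export
#' @examples
#' dprime(10, 1, 12, 1) # 2
#' dprime(0, 2, 4, 2)   # 2
dprime <- function(mean1, sd1, mean2, sd2) {
  if (any(sd1 < 0, na.rm = TRUE) || any(sd2 < 0, na.rm = TRUE)) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  num <- abs(mean1 - mean2)
  den <- sqrt(0.5 * (sd1^2 + sd2^2))
  out <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  as.numeric(out)
}

# SD that treats a single observation as exactly located (zero spread).
sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

# Per-cluster mean/SD of member feature values (profile rows flattened
# across grouping columns), given an assignment vector over profile rows.
cluster_feature_stats <- function(assignment, profile_matrix) {
  labels <- sort(unique(assignment))
  purrr::map_dfr(labels, function(lab) {
    vals <- as.vector(profile_matrix[assignment == lab, , drop = FALSE])
    tibble::tibble(cluster = lab, n_cells = sum(assignment == lab),
                   mean_um = mean(vals), sd_um = sd0(vals))
  })
}

# All pairwise d-prime values for a cluster stats table.
pairwise_dprime <- function(stats) {
  k <- nrow(stats)
  if (k < 2L) {
    return(tibble::tibble(cluster_a = integer(), cluster_b = integer(),
                          dprime = numeric()))
  }
  pairs <- utils::combn(seq_len(k), 2)
  tibble::tibble(
    cluster_a = stats$cluster[pairs[1, ]],
    cluster_b = stats$cluster[pairs[2, ]],
    dprime = dprime(stats$mean_um[pairs[1, ]], stats$sd_um[pairs[1, ]],
                    stats$mean_um[pairs[2, ]], stats$sd_um[pairs[2, ]])
  )
}
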