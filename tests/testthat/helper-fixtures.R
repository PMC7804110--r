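# Shared fixtures: small grid datasets and profile objects built in code.

grid_cols <- retgrid:::grid_cell_names()

# A grid dataset with explicit thickness matrix (n x 64) and demographics.
make_grid_dataset <- function(thickness, layer = "GCL",
                              eye = rep("OD", nrow(thickness)),
                              age = seq(25, length.out = nrow(thickness), by = 5),
                              sex = rep(c("F", "M"), length.out = nrow(thickness)),
                              orientation = "right_eye") {
  n <- nrow(thickness)
  colnames(thickness) <- grid_cols
  df <- tibble::tibble(
    subject_id = sprintf("T%03d", seq_len(n)), eye = eye, age = age, sex = sex,
    ethnicity = rep(c("White", "Asian"), length.out = n),
    se_refraction = rep(-1, n), bcva = rep(0, n), layer = layer
  )
  df <- dplyr::bind_cols(df, tibble::as_tibble(thickness))
  retgrid:::new_grid_dataset(df, layer, orientation = orientation)
}

constant_grid_dataset <- function(n = 4, value = 30, layer = "GCL", ...) {
  make_grid_dataset(matrix(value, n, 64), layer = layer, ...)
}

# Hand-built feature profiles for clustering unit tests.
make_profiles <- function(mean_mat, layer = "GCL", grouping = "whole") {
  n <- nrow(mean_mat)
  rownames(mean_mat) <- grid_cols[seq_len(n)]
  if (is.null(colnames(mean_mat))) {
    colnames(mean_mat) <- paste0("g", seq_len(ncol(mean_mat)))
  }
  structure(
    list(mean = mean_mat, sd = mean_mat * 0, n = mean_mat * 0 + 1,
         grouping = grouping, width = NA, cohorts = NULL, layer = layer),
    class = "feature_profiles"
  )
}

# Small simulation: same structure as the default cohort, fewer eyes per bin.
small_demographics <- function(n_per_bin = 8L) {
  demo <- retgrid:::default_demographics()
  demo$n <- rep(n_per_bin, 6)
  demo$n_male <- rep(n_per_bin %/% 2L, 6)
  demo$n_white <- rep(n_per_bin %/% 2L, 6)
  demo$n_other <- c(0L, 0L, 1L, 1L, 0L, 0L)
  demo$n_asian <- demo$n - demo$n_white - demo$n_other
  demo
}

# Brute-force pairwise d-prime check straight from definition.
min_pairwise_dprime <- function(pattern, profiles) {
  labs <- sort(unique(pattern$assignment))
  if (length(labs) < 2) return(Inf)
  vals <- lapply(labs, function(l) {
    as.vector(profiles$mean[pattern$assignment == l, , drop = FALSE])
  })
  mn <- Inf
  for (i in seq_along(labs)) for (j in seq_len(i - 1)) {
    x <- vals[[i]]; y <- vals[[j]]
    sdx <- if (length(x) > 1) sd(x) else 0
    sdy <- if (length(y) > 1) sd(y) else 0
    den <- sqrt(0.5 * (sdx^2 + sdy^2))
    d <- if (den == 0) {
      if (abs(mean(x) - mean(y)) == 0) 0 else Inf
    } else {
      abs(mean(x) - mean(y)) / den
    }
    mn <- min(mn, d)
  }
  mn
}

# 4-connected contiguity of a cell set on the 8x8 grid.
cells_contiguous <- function(cells) {
  pos <- retgrid::grid_cells()[retgrid::grid_cells()$cell %in% cells,
                               c("row", "col")]
  n <- nrow(pos)
  if (n <= 1) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(!seen & abs(pos$row - pos$row[i]) + abs(pos$col - pos$col[i]) == 1)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}
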