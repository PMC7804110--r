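# Grid dataset container and CSV I/O.
#
# A grid dataset is a tibble with one row per eye: demographic columns,
# a `layer` column, and 64 thickness columns r1c1..r8c8 (row-major, in
# micrometres, NA = missing). One eye per subject is enforced at load.

demographic_cols <- c("subject_id", "eye", "age", "sex", "ethnicity",
                      "se_refraction", "bcva")

grid_schema_cols <- function() c(demographic_cols, "layer", grid_cell_names())

new_grid_dataset <- function(df, layer, orientation = c("right_eye", "native")) {
  orientation <- match.arg(orientation)
  df <- tibble::as_tibble(df)[, grid_schema_cols()]
  structure(df,
    class = c("grid_dataset", class(tibble::tibble())),
    layer = layer,
    orientation = orientation
  )
}

# Tibble subsetting drops custom attributes; re-attach.
restore_grid_attrs <- function(df, template) {
  new_grid_dataset(df, attr(template, "layer"), attr(template, "orientation"))
}

#' @export
print.grid_dataset <- function(x, ...) {
  cat(sprintf("<grid_dataset> layer %s, %d eyes, orientation: %s\n",
              attr(x, "layer"), nrow(x), attr(x, "orientation")))
  NextMethod()
}

validate_grid_rows <- function(df) {
  problems <- character()
  bad_row <- function(i, msg) sprintf("row %d: %s", i, msg)
  thick <- as.matrix(df[, grid_cell_names()])
  for (i in seq_len(nrow(df))) {
    v <- thick[i, ]
    bad <- which(!is.na(v) & (!is.finite(v) | v <= 0))
    if (length(bad)) {
      problems <- c(problems, bad_row(
        i, paste0("non-positive or non-finite thickness in ",
                  paste(grid_cell_names()[bad], collapse = ", "))))
    }
    if (is.na(df$eye[i]) || !df$eye[i] %in% c("OD", "OS")) {
      problems <- c(problems, bad_row(i, "eye must be OD or OS"))
    }
    if (is.na(df$age[i]) || df$age[i] < 18 || df$age[i] > 100) {
      problems <- c(problems, bad_row(i, "age missing or outside [18, 100]"))
    }
    if (!is.na(df$sex[i]) && !df$sex[i] %in% c("F", "M")) {
      problems <- c(problems, bad_row(i, "sex must be F or M"))
    }
  }
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate subject_id (one eye per subject): ",
                                   paste(dup, collapse = ", ")))
  }
  problems
}

#' Read a grid thickness dataset from CSV
#'
#' Reads the wide per-eye schema: `subject_id, eye, age, sex, ethnicity,
#' se_refraction, bcva, layer, r1c1, ..., r8c8` (64 thickness columns in
#' micrometres, row-major; empty fields are missing cells). The header must
#' match the schema exactly; rows failing validation (non-positive thickness,
#' invalid demographics, duplicated subjects) abort with row-numbered
#' messages.
#'
#' @param path Path to a CSV file.
#' @param layer Layer name the file holds; rows with a different `layer`
#'   value are a validation error.
#' @param orientation Orientation of the grids as stored: `"native"`
#'   (as scanned, left eyes unmirrored) or `"right_eye"`.
#' @return A `grid_dataset` tibble.
#' @seealso [write_grid_dataset()], [normalize_orientation()]
#' @export
load_grid_dataset <- function(path, layer, orientation = c("native", "right_eye")) {
  orientation <- match.arg(orientation)
  layer_info(layer) # validates the name
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  expected <- grid_schema_cols()
  extra <- setdiff(header, expected)
  missing <- setdiff(expected, header)
  if (length(extra) || length(missing)) {
    stop("schema error in ", path,
         if (length(extra)) paste0("; unexpected column(s): ", paste(extra, collapse = ", ")),
         if (length(missing)) paste0("; missing column(s): ", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  spec <- readr::cols(
    subject_id = readr::col_character(), eye = readr::col_character(),
    age = readr::col_double(), sex = readr::col_character(),
    ethnicity = readr::col_character(), se_refraction = readr::col_double(),
    bcva = readr::col_double(), layer = readr::col_character(),
    .default = readr::col_double()
  )
  df <- readr::read_csv(path, col_types = spec, na = "", show_col_types = FALSE)
  parse_problems <- readr::problems(df)
  if (nrow(parse_problems)) {
    stop("row error(s) in ", path, ": ",
         paste(sprintf("row %d col %s: %s", parse_problems$row,
                       parse_problems$col, parse_problems$expected),
               collapse = "; "),
         call. = FALSE)
  }
  wrong_layer <- which(df$layer != layer)
  problems <- validate_grid_rows(df)
  if (length(wrong_layer)) {
    problems <- c(problems, sprintf("row %d: layer is %s, expected %s",
                                    wrong_layer, df$layer[wrong_layer], layer))
  }
  if (length(problems)) {
    stop("row error(s) in ", path, ":\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  new_grid_dataset(df, layer, orientation)
}

#' Write a grid dataset to CSV
#'
#' Writes the canonical wide schema with empty fields for missing cells, so
#' that [load_grid_dataset()] round-trips values and missingness exactly.
#'
#' @param ds A `grid_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_dataset <- function(ds, path) {
  readr::write_csv(tibble::as_tibble(ds)[, grid_schema_cols()], path, na = "")
  invisible(path)
}

#' Mirror left-eye grids into right-eye format
#'
#' Left-eye (OS) grids are mirrored about the vertical axis (column `c`
#' becomes column `9 - c`) so that nasal/temporal positions align across
#' eyes; right-eye (OD) grids are unchanged. The operation is idempotent:
#' a dataset already in right-eye orientation is returned as is.
#'
#' @param ds A `grid_dataset`.
#' @return The dataset with orientation `"right_eye"`.
#' @export
normalize_orientation <- function(ds) {
  stopifnot(inherits(ds, "grid_dataset"))
  if (attr(ds, "orientation") == "right_eye") return(ds)
  if (anyNA(ds$eye) || !all(ds$eye %in% c("OD", "OS"))) {
    stop("unknown eye laterality; cannot normalize orientation", call. = FALSE)
  }
  cells <- grid_cell_names()
  mirrored <- as.vector(t(outer(1:8, 8:1, function(r, c) sprintf("r%dc%d", r, c))))
  os <- ds$eye == "OS"
  if (any(os)) {
    mat <- as.matrix(ds[, cells])
    mat[os, ] <- mat[os, mirrored, drop = FALSE]
    ds[, cells] <- tibble::as_tibble(mat)
  }
  attr(ds, "orientation") <- "right_eye"
  ds
}

#' Apply the missing-data exclusion rules
#'
#' For layers with foveal exclusion (IPL, INL, OPL) the central four cells
#' are masked first; the missing fraction is then evaluated over the layer's
#' analysable cells (60 or 64) and eyes with strictly more than `max_missing`
#' missing are dropped.
#'
#' @param ds A `grid_dataset` in right-eye orientation.
#' @param max_missing Maximum tolerated missing fraction (default 0.10;
#'   the rule is strict, i.e. a fraction exactly equal to `max_missing`
#'   is retained).
#' @return A list with elements `data` (the retained `grid_dataset`) and
#'   `excluded` (a tibble of `subject_id`, `reason`, `missing_fraction`).
#'   Errors if no analysable eyes remain.
#' @seealso [write_exclusion_report()]
#' @export
apply_exclusions <- function(ds, max_missing = 0.10) {
  stopifnot(inherits(ds, "grid_dataset"))
  if (attr(ds, "orientation") != "right_eye") {
    stop("dataset must be orientation-normalized first; see normalize_orientation()",
         call. = FALSE)
  }
  layer <- attr(ds, "layer")
  info <- layer_info(layer)
  if (info$foveal_exclusion) {
    ds[, foveal_cell_names()] <- NA_real_
  }
  cells <- analysable_cells(layer)
  frac <- rowMeans(is.na(as.matrix(ds[, cells])))
  drop <- frac > max_missing
  excluded <- tibble::tibble(
    subject_id = ds$subject_id[drop],
    reason = rep("missing_gt_10pct", sum(drop)),
    missing_fraction = frac[drop]
  )
  kept <- restore_grid_attrs(ds[!drop, ], ds)
  if (nrow(kept) == 0L) {
    stop("no analysable eyes remain after exclusion", call. = FALSE)
  }
  list(data = kept, excluded = excluded)
}

#' Write an exclusion report as JSON
#'
#' @param excluded The `excluded` tibble from [apply_exclusions()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(excluded, path) {
  jsonlite::write_json(excluded, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Per-eye mean layer thickness
#'
#' Unweighted mean over the present analysable cells of each eye; used as the
#' response variable for covariate screening.
#'
#' @param ds A `grid_dataset` (after exclusions).
#' @return A tibble with columns `subject_id` and `mean_um`.
#' @export
layer_mean_thickness <- function(ds) {
  stopifnot(inherits(ds, "grid_dataset"))
  cells <- analysable_cells(attr(ds, "layer"))
  mat <- as.matrix(ds[, cells])
  n_present <- rowSums(!is.na(mat))
  if (any(n_present == 0L)) {
    stop("eye(s) with zero present analysable cells: ",
         paste(ds$subject_id[n_present == 0L], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(subject_id = ds$subject_id, mean_um = rowMeans(mat, na.rm = TRUE))
}

# Long (tidy) view of the analysable grid cells: one row per eye x cell.
grid_long <- function(ds, drop_missing = TRUE) {
  cells <- analysable_cells(attr(ds, "layer"))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(ds)[, c(demographic_cols, cells)],
    cols = dplyr::all_of(cells), names_to = "cell", values_to = "thickness_um"
  )
  if (drop_missing) long <- dplyr::filter(long, !is.na(.data$thickness_um))
  long
}
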