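# Retinal layer metadata for the 8x8 macular thickness grid.
#
# The central 2x2 block of the fovea-centred grid systematically
# under-represents true thickness in the synaptic/nuclear layers listed with
# foveal_exclusion = TRUE, so those four cells are masked before analysis and
# the layer's analysable cell count drops from 64 to 60.

#' Retinal layer metadata
#'
#' Metadata for the eight retinal layers measured on the fovea-centred 8x8
#' macular grid: whether the central four (foveal) cells are excluded from
#' analysis, and the resulting number of analysable grid cells (60 or 64).
#'
#' @return A tibble with columns `layer`, `analysable_cells` and
#'   `foveal_exclusion`.
#' @export
#' @examples
#' oct_layers()
oct_layers <- function() {
  tibble::tibble(
    layer = c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL_HFL", "ISOS", "RPE"),
    foveal_exclusion = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    analysable_cells = ifelse(c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 60L, 64L)
  )
}

#' Look up metadata for a single layer
#'
#' @param layer Layer name, one of `"RNFL"`, `"GCL"`, `"IPL"`, `"INL"`,
#'   `"OPL"`, `"ONL_HFL"`, `"ISOS"`, `"RPE"`.
#' @return A one-row tibble (see [oct_layers()]).
#' @export
layer_info <- function(layer) {
  layers <- oct_layers()
  if (!is.character(layer) || length(layer) != 1L || !layer %in% layers$layer) {
    stop("unknown layer: ", paste(layer, collapse = ", "),
         " (expected one of ", paste(layers$layer, collapse = ", "), ")",
         call. = FALSE)
  }
  layers[layers$layer == layer, ]
}

# Cell naming: r<row>c<col>, rows 1-8 superior -> inferior, columns 1-8
# nasal -> temporal in right-eye format (fixed package convention).
grid_cell_names <- function() {
  as.vector(t(outer(1:8, 1:8, function(r, c) sprintf("r%dc%d", r, c))))
}

#' Grid cell geometry
#'
#' Coordinates of the 64 grid cell centres. Rows run superior to inferior and
#' columns nasal to temporal (right-eye format); the grid is centred on the
#' fovea with an 860 micrometre cell pitch. `x_um` is positive towards nasal,
#' `y_um` positive towards superior.
#'
#' @param pitch_um Cell pitch in micrometres (default 860).
#' @return A tibble with columns `cell`, `row`, `col`, `x_um`, `y_um`,
#'   `dist_um` (distance of the cell centre from the fovea).
#' @export
grid_cells <- function(pitch_um = 860) {
  cells <- tidyr::expand_grid(row = 1:8, col = 1:8)
  dplyr::mutate(cells,
    cell = sprintf("r%dc%d", .data$row, .data$col),
    x_um = (4.5 - .data$col) * pitch_um,
    y_um = (4.5 - .data$row) * pitch_um,
    dist_um = sqrt(.data$x_um^2 + .data$y_um^2),
    .before = 1
  )
}

# Central 2x2 block masked in foveal-exclusion layers.
foveal_cell_names <- function() c("r4c4", "r4c5", "r5c4", "r5c5")

# Cells that enter analysis for a layer (60 or 64 of the 64).
analysable_cells <- function(layer) {
  info <- layer_info(layer)
  cells <- grid_cell_names()
  if (info$foveal_exclusion) cells <- setdiff(cells, foveal_cell_names())
  cells
}
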