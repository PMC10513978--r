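#' Voxel grid with fixed patient-based axis convention
#'
#' A `voxel_grid` describes a regular 3D sampling lattice. Array axes map to
#' patient axes as: axis 1 = x, patient left (+) / right (-); axis 2 = y,
#' anterior (+) / posterior (-); axis 3 = z, superior (+) / inferior (-).
#' Voxel centers are placed symmetrically about the world origin, and each
#' voxel owns the half-open cell `[center - h/2, center + h/2)` along every
#' axis, so a world coordinate maps to exactly one voxel.
#'
#' @param shape integer vector of length 3 (nx, ny, nz); values >= 1.
#' @param spacing_mm positive voxel edge lengths in mm, length 1 or 3.
#'   The default 3.3 mm isotropic spacing on a 128^3 matrix matches a typical
#'   reconstructed lung SPECT geometry.
#' @return an object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(64, 64, 64), 3.3)
#' range(grid_axis_coords(g, 3))
#' @export
voxel_grid <- function(shape = c(128L, 128L, 128L), spacing_mm = 3.3) {
  shape <- as.integer(rep_len(shape, 3L))
  spacing <- as.numeric(rep_len(spacing_mm, 3L))
  if (any(is.na(shape)) || any(shape < 1L))
    stop("all grid shape entries must be integers >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all voxel spacings must be positive")
  structure(list(shape = shape, spacing_mm = spacing), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  invisible(x)
}

#' World coordinates of voxel centers along one axis
#'
#' @param grid a [voxel_grid()].
#' @param axis axis index, 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of voxel-center coordinates in mm, centered on 0.
#' @export
grid_axis_coords <- function(grid, axis) {
  stopifnot(inherits(grid, "voxel_grid"), axis %in% 1:3)
  n <- grid$shape[axis]
  (seq_len(n) - (n + 1) / 2) * grid$spacing_mm[axis]
}

#' Map world coordinates (mm) to voxel indices
#'
#' Cells are half-open, so every in-range coordinate maps to exactly one voxel.
#'
#' @param grid a [voxel_grid()].
#' @param xyz numeric length-3 world coordinate, or an n x 3 matrix.
#' @return integer voxel indices (1-based), same shape as the input rows;
#'   coordinates outside the grid return NA.
#' @export
world_to_index <- function(grid, xyz) {
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3)
  out <- matrix(NA_integer_, nrow(m), 3)
  for (a in 1:3) {
    h <- grid$spacing_mm[a]
    n <- grid$shape[a]
    lower_edge <- (1 - (n + 1) / 2) * h - h / 2
    i <- as.integer(floor((m[, a] - lower_edge) / h)) + 1L
    i[i < 1L | i > n] <- NA_integer_
    out[, a] <- i
  }
  if (is.matrix(xyz)) out else out[1, ]
}

# Number of voxels in the grid
grid_nvox <- function(grid) prod(grid$shape)

# Voxel volume in mm^3
grid_voxel_volume <- function(grid) prod(grid$spacing_mm)
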