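#' Planar image container
#'
#' 2D count image indexed (x, z) — patient left-right by superior-inferior —
#' produced by forward projection along the anteroposterior (y) axis.
#' Anterior and posterior views of the same volume share shape and spacing
#' and the same (x, z) index convention (the posterior view is not mirrored).
#'
#' @param pixels nonnegative numeric matrix (nx x nz).
#' @param view "anterior" or "posterior".
#' @param spacing_mm pixel spacing (x, z) in mm.
#' @param attenuated logical; whether attenuation was applied.
#' @return object of class `planar_image`.
#' @export
planar_image <- function(pixels, view = c("anterior", "posterior"),
                         spacing_mm = c(3.3, 3.3), attenuated = FALSE) {
  view <- match.arg(view)
  if (any(pixels < 0)) stop("planar pixels must be nonnegative")
  structure(list(pixels = pixels, view = view,
                 spacing_mm = rep_len(as.numeric(spacing_mm), 2L),
                 attenuated = attenuated),
            class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("<planar_image> %s view, %d x %d px, total counts %.4g%s\n",
              x$view, nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              if (x$attenuated) ", attenuated" else ""))
  invisible(x)
}

# Attenuation factor volume for a view: factor = exp(-dy * S) where S is the
# integral of mu from (and including half of) the emitting voxel to the
# detector-side boundary along y. Computed with a triangular cumulative-sum
# matrix so the whole volume is handled in one pass.
attenuation_volume <- function(mu_map, view) {
  mu <- mu_map$mu
  d <- dim(mu)
  dy <- mu_map$grid$spacing_mm[2]
  ny <- d[2]
  # inclusive suffix (anterior, detector at +y) or prefix (posterior) sums:
  # t(Tm)[j, r] = 1 selects the voxels r on the detector side of emitter j
  Tm <- matrix(0, ny, ny)
  if (view == "anterior") Tm[row(Tm) >= col(Tm)] <- 1 else Tm[row(Tm) <= col(Tm)] <- 1
  v <- aperm(mu, c(2, 1, 3))
  m <- matrix(v, ny, d[1] * d[3])
  S <- t(Tm) %*% m - m / 2  # strictly-between integral plus half self-term
  A <- exp(-dy * S)
  dim(A) <- c(ny, d[1], d[3])
  aperm(A, c(2, 1, 3))
}

#' Attenuation factor along the ray from one voxel to the detector
#'
#' Returns `exp(-sum(mu_j * dy))` where the sum runs over the voxels strictly
#' between the emitting voxel and the detector-side boundary along y
#' (anterior view: increasing y; posterior: decreasing y), plus half the
#' emitting voxel's own `mu * dy` (half-voxel self-attenuation convention,
#' second-order accurate for an emitter at the voxel center).
#'
#' @param mu_map a [hu_to_mu()] result with a grid.
#' @param voxel_index integer (i, j, k) voxel index.
#' @param view "anterior" or "posterior".
#' @return attenuation factor in \[0, 1\].
#' @export
path_attenuation <- function(mu_map, voxel_index,
                             view = c("anterior", "posterior")) {
  view <- match.arg(view)
  d <- dim(mu_map$mu)
  i <- voxel_index[1]; j <- voxel_index[2]; k <- voxel_index[3]
  stopifnot(i >= 1, i <= d[1], j >= 1, j <= d[2], k >= 1, k <= d[3])
  dy <- mu_map$grid$spacing_mm[2]
  ray <- mu_map$mu[i, , k]
  between <- if (view == "anterior") {
    if (j < d[2]) sum(ray[(j + 1):d[2]]) else 0
  } else {
    if (j > 1) sum(ray[1:(j - 1)]) else 0
  }
  exp(-dy * (between + ray[j] / 2))
}

#' Forward-project a SPECT volume into a planar view
#'
#' Synthesizes an anterior or posterior planar scintigraphy image by
#' parallel-beam ray sums along the anteroposterior axis, with optional
#' exponential attenuation through a mu-map:
#' `pixel(x, z) = sum_y counts(x, y, z) * path_attenuation(x, y, z, view)`.
#' With `mu_map = NULL`, the plain ray sum conserves total counts exactly.
#'
#' @param spect a `spect_volume`.
#' @param mu_map a `mu_map` on the same grid, or NULL for no attenuation.
#' @param view "anterior" or "posterior".
#' @return a [planar_image()].
#' @export
project_planar <- function(spect, mu_map = NULL,
                           view = c("anterior", "posterior")) {
  view <- match.arg(view)
  counts <- spect$counts
  d <- dim(counts)
  if (!is.null(mu_map)) {
    if (!identical(dim(mu_map$mu), d))
      stop("mu-map and SPECT grids differ (", paste(dim(mu_map$mu), collapse = "x"),
           " vs ", paste(d, collapse = "x"),
           "); resample one onto the other first (see resample_block)")
    if (is.null(mu_map$grid)) mu_map$grid <- spect$grid
    counts <- counts * attenuation_volume(mu_map, view)
  }
  v <- aperm(counts, c(2, 1, 3))
  pix <- colSums(matrix(v, d[2], d[1] * d[3]))
  dim(pix) <- c(d[1], d[3])
  planar_image(pix, view = view,
               spacing_mm = spect$grid$spacing_mm[c(1, 3)],
               attenuated = !is.null(mu_map))
}

#' Project both planar views
#' @inheritParams project_planar
#' @return list with elements `anterior` and `posterior`.
#' @export
project_planar_views <- function(spect, mu_map = NULL) {
  list(anterior = project_planar(spect, mu_map, "anterior"),
       posterior = project_planar(spect, mu_map, "posterior"))
}

#' Project a label map into a 2D binary lung mask
#'
#' A pixel is true iff any voxel of the selected lung's labels lies along
#' its anteroposterior ray. Serves as the lung delineation for the planar
#' template method.
#'
#' @param labels integer lobe label array.
#' @param lung "left", "right" or "both".
#' @param codes optional explicit label codes to project instead.
#' @return logical (nx x nz) matrix.
#' @export
project_mask <- function(labels, lung = c("both", "left", "right"),
                         codes = NULL) {
  lung <- match.arg(lung)
  if (is.null(codes))
    codes <- switch(lung, both = 1:5, right = right_lobe_codes,
                    left = left_lobe_codes)
  d <- dim(labels)
  sel <- array(labels %in% codes, dim = d)
  v <- aperm(sel, c(2, 1, 3))
  hit <- colSums(matrix(v, d[2], d[1] * d[3])) > 0
  dim(hit) <- c(d[1], d[3])
  hit
}

#' Project an arbitrary logical volume into a 2D mask
#' @param mask logical 3D array.
#' @return logical (nx x nz) matrix, true where any voxel along y is true.
#' @export
project_volume_mask <- function(mask) {
  d <- dim(mask)
  v <- aperm(mask, c(2, 1, 3))
  hit <- colSums(matrix(v, d[2], d[1] * d[3])) > 0
  dim(hit) <- c(d[1], d[3])
  hit
}
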