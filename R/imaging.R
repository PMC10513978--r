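#' Convert Hounsfield units to 140 keV linear attenuation coefficients
#'
#' Standard bilinear CT-to-mu conversion evaluated at the 99mTc photon
#' energy: for HU <= 0, `mu = mu_water * (1 + HU/1000)` floored at 0 (air at
#' -1000 HU maps to exactly 0); for HU > 0, the slope is reduced by
#' `bone_slope` to account for the higher effective Z of mineralized tissue,
#' `mu = mu_water * (1 + bone_slope * HU/1000)`. The mapping is monotone
#' nondecreasing and continuous at HU = 0.
#'
#' @param hu numeric array of Hounsfield units.
#' @param mu_water water attenuation coefficient at 140 keV, per mm
#'   (default 0.0151 mm^-1).
#' @param bone_slope slope factor above 0 HU (default 0.5).
#' @param grid optional [voxel_grid()] carried along for downstream checks.
#' @return object of class `mu_map` with elements `mu`, `grid`, `mu_water`,
#'   `bone_slope`.
#' @export
hu_to_mu <- function(hu, mu_water = 0.0151, bone_slope = 0.5, grid = NULL) {
  if (any(!is.finite(hu))) stop("HU volume contains non-finite values")
  if (mu_water <= 0) stop("mu_water must be > 0")
  # branch-free bilinear map: negative and positive HU parts contribute
  # separately; identical to the piecewise definition
  neg <- pmin(hu, 0)
  pos <- pmax(hu, 0)
  mu <- pmax(0, mu_water * (1 + neg / 1000)) +
    mu_water * bone_slope * pos / 1000
  if (!is.null(dim(hu))) dim(mu) <- dim(hu)
  structure(list(mu = mu, grid = grid, mu_water = mu_water,
                 bone_slope = bone_slope), class = "mu_map")
}

#' Attenuation map of a phantom
#' @param phantom a phantom.
#' @param ... passed to [hu_to_mu()].
#' @return a `mu_map` on the phantom grid.
#' @export
mu_map_from_phantom <- function(phantom, ...) {
  hu_to_mu(phantom$hu, ..., grid = phantom$grid)
}

# 1D Gaussian smoothing matrix (n x n), truncated at 4 sigma and
# column-normalized: column s gives the fractions of source voxel s
# distributed to destinations, so matrix application conserves the total
# exactly, including at the volume edges.
gaussian_smoothing_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- ceiling(4 * sigma_vox)
  offs <- (-half):half
  w <- exp(-offs^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- s + offs
    ok <- d >= 1L & d <= n
    K[d[ok], s] <- w[ok] / sum(w[ok])
  }
  K
}

apply_matrix_along_axis <- function(vol, K, axis) {
  d <- dim(vol)
  if (axis == 1) {
    out <- K %*% matrix(vol, d[1], d[2] * d[3])
    dim(out) <- d
    out
  } else if (axis == 2) {
    v <- aperm(vol, c(2, 1, 3))
    out <- K %*% matrix(v, d[2], d[1] * d[3])
    dim(out) <- c(d[2], d[1], d[3])
    aperm(out, c(2, 1, 3))
  } else {
    out <- matrix(vol, d[1] * d[2], d[3]) %*% t(K)
    dim(out) <- d
    out
  }
}

#' Separable isotropic Gaussian blur of a volume
#'
#' Kernel truncated at 4 sigma with per-position renormalization, so total
#' counts are conserved to machine precision.
#'
#' @param vol numeric 3D array.
#' @param grid [voxel_grid()] giving voxel spacing.
#' @param fwhm_mm full width at half maximum of the point-spread function.
#' @return blurred array of the same shape.
#' @export
blur_gaussian <- function(vol, grid, fwhm_mm) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (a in 1:3) {
    K <- gaussian_smoothing_matrix(grid$shape[a], sigma_mm / grid$spacing_mm[a])
    vol <- apply_matrix_along_axis(vol, K, a)
  }
  vol
}

#' Simulate a reconstructed SPECT-like count volume
#'
#' Models the product of the acquisition + reconstruction chain directly:
#' the activity volume is scaled so its total equals `total_counts`,
#' convolved with an isotropic Gaussian point-spread function
#' (sigma = FWHM / 2.3548, truncated at 4 sigma, renormalized), and, with
#' noise enabled, each voxel is replaced by a Poisson draw with that mean.
#' Deterministic given the seed.
#'
#' @param x a phantom, or a nonnegative 3D activity array.
#' @param ... further arguments to methods.
#' @return object of class `spect_volume` with elements `grid`, `counts`,
#'   and `meta` (tracer, psf_fwhm_mm, total_counts, noise, seed).
#' @export
simulate_spect <- function(x, ...) UseMethod("simulate_spect")

#' @rdname simulate_spect
#' @param grid a [voxel_grid()] matching the activity array.
#' @param fwhm_mm Gaussian post-filter FWHM in mm (default 5, the usual
#'   reconstruction post-filter for lung SPECT).
#' @param total_counts expected total counts in the volume (default 5e6).
#' @param noise logical; Poisson counting noise on/off.
#' @param seed integer RNG seed (used only when noise is on).
#' @param tracer tag carried in metadata ("V" or "Q").
#' @export
simulate_spect.default <- function(x, grid, fwhm_mm = 5, total_counts = 5e6,
                                   noise = TRUE, seed = 1L, tracer = "V", ...) {
  if (any(x < 0)) stop("activity must be nonnegative")
  tot <- sum(x)
  if (tot <= 0) stop("activity volume sums to zero")
  if (total_counts <= 0) stop("total_counts must be > 0")
  mean_img <- blur_gaussian(x * (total_counts / tot), grid, fwhm_mm)
  counts <- if (noise) {
    withr::with_seed(as.integer(seed), {
      out <- stats::rpois(length(mean_img), lambda = as.vector(mean_img))
      array(as.numeric(out), dim = dim(mean_img))
    })
  } else mean_img
  structure(list(grid = grid, counts = counts,
                 meta = list(tracer = tracer, psf_fwhm_mm = fwhm_mm,
                             total_counts = total_counts, noise = noise,
                             seed = as.integer(seed))),
            class = "spect_volume")
}

#' @rdname simulate_spect
#' @export
simulate_spect.phantom <- function(x, tracer = c("V", "Q"), ...) {
  tracer <- match.arg(tracer)
  simulate_spect(x$activity[[tracer]], grid = x$grid, tracer = tracer, ...)
}

#' @export
print.spect_volume <- function(x, ...) {
  cat(sprintf("<spect_volume> tracer=%s fwhm=%.1f mm total=%.3g noise=%s\n",
              x$meta$tracer, x$meta$psf_fwhm_mm, sum(x$counts),
              x$meta$noise))
  invisible(x)
}

#' Block-resample a volume by an integer factor
#'
#' Bridges CT-resolution and SPECT-resolution grids. Scalar volumes are
#' reduced by the block mean; label volumes by the per-block modal label,
#' ties broken by the smallest label code.
#'
#' @param vol 3D array.
#' @param factor integer downsampling factor, scalar or per-axis triple.
#' @param mode "mean" for scalar volumes, "majority" for label volumes.
#' @return the downsampled array.
#' @export
resample_block <- function(vol, factor, mode = c("mean", "majority")) {
  mode <- match.arg(mode)
  f <- as.integer(rep_len(factor, 3L))
  if (any(f < 1L)) stop("factor must be >= 1 per axis")
  d <- dim(vol)
  if (any(d %% f != 0L))
    stop("volume shape (", paste(d, collapse = "x"),
         ") is not divisible by factor (", paste(f, collapse = "x"),
         "); pad the volume first")
  nd <- d %/% f
  # reorder so the within-block axes come first
  v <- array(vol, dim = c(f[1], nd[1], f[2], nd[2], f[3], nd[3]))
  v <- aperm(v, c(1, 3, 5, 2, 4, 6))
  m <- matrix(v, nrow = prod(f), ncol = prod(nd))
  if (mode == "mean") {
    out <- colMeans(m)
  } else {
    codes <- sort(unique(as.vector(vol)))
    hits <- vapply(codes, function(cd) colSums(m == cd), numeric(ncol(m)))
    if (!is.matrix(hits)) hits <- matrix(hits, nrow = 1)
    out <- codes[max.col(hits, ties.method = "first")]
  }
  array(out, dim = nd)
}
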