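# Synthetic 3D nucleus images with planted diffraction-limited foci.
# The point-spread function is modeled as a Gaussian, isotropic in xy and
# elongated along z (standard widefield approximation); per-voxel expected
# photon counts use exact Gaussian integrals over voxel extents, so a
# focus's voxel sum equals its planted integrated intensity up to
# truncation at the grid boundary.

#' Image3D container
#'
#' @param data 3D numeric array indexed `[x, y, z]` of nonnegative voxel
#'   intensities.
#' @param voxel_size Length-3 vector (x, y, z) in um per voxel.
#' @param center Nucleus center in um (image coordinates, origin at the
#'   corner of voxel (1,1,1)).
#' @param radius Nucleus radius in um.
#' @return An object of class `Image3D`.
#' @export
image3d <- function(data, voxel_size, center, radius) {
  stopifnot(length(dim(data)) == 3, all(voxel_size > 0), radius > 0)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 center = as.numeric(center), radius = radius),
            class = "Image3D")
}

#' @export
print.Image3D <- function(x, ...) {
  cat(sprintf("Image3D: %s voxels @ %s um, nucleus r=%.2f um\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"), x$radius))
  invisible(x)
}

# voxel-center coordinate vectors (um) along each axis
voxel_axes <- function(dims, voxel_size) {
  lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * voxel_size[a])
}

nucleus_mask <- function(dims, voxel_size, center, radius) {
  ax <- voxel_axes(dims, voxel_size)
  dx2 <- (ax[[1]] - center[1])^2
  dy2 <- (ax[[2]] - center[2])^2
  dz2 <- (ax[[3]] - center[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
}

#' Render a synthetic nucleus image with planted foci
#'
#' @param foci Data.frame with columns `x, y, z` (um), `intensity`
#'   (integrated photons) and optionally `sigma_xy`, `sigma_z` (um);
#'   may have zero rows.
#' @param dims Integer grid dimensions (nx, ny, nz).
#' @param voxel_size Length-3 voxel size in um.
#' @param center,radius Nucleus sphere in um; defaults to the grid center.
#' @param background Mean background photons per voxel inside the nucleus.
#' @param sigma_xy,sigma_z Default PSF widths (um) for foci lacking them.
#' @param read_noise Gaussian read-noise SD (camera counts).
#' @param noise Apply Poisson shot noise and read noise?
#' @param seed Integer seed; the image is deterministic given the seed.
#' @return An `Image3D` with attribute `planted` (the foci table).
#' @export
render_nucleus_image <- function(foci,
                                 dims = c(48L, 48L, 16L),
                                 voxel_size = c(0.065, 0.065, 0.2),
                                 center = dims * voxel_size / 2,
                                 radius = 1.0,
                                 background = 100,
                                 sigma_xy = 0.13, sigma_z = 0.35,
                                 read_noise = 2,
                                 noise = TRUE,
                                 seed = 1L) {
  if (background < 0) stop("background must be nonnegative")
  foci <- as.data.frame(foci)
  if (nrow(foci)) {
    if (is.null(foci$sigma_xy)) foci$sigma_xy <- sigma_xy
    if (is.null(foci$sigma_z)) foci$sigma_z <- sigma_z
    if (any(foci$intensity <= 0)) stop("focus intensities must be > 0")
    d2 <- (foci$x - center[1])^2 + (foci$y - center[2])^2 +
      (foci$z - center[3])^2
    if (any(d2 > radius^2)) stop("planted foci must lie inside the nucleus")
    if (any(foci$sigma_xy < voxel_size[1] / 2) ||
        any(foci$sigma_z < voxel_size[3] / 2)) {
      warning("focus sigma below half a voxel: undersampled rendering")
    }
  }
  img <- array(0, dims)
  edges <- lapply(1:3, function(a) (0:dims[a]) * voxel_size[a])
  for (k in seq_len(nrow(foci))) {
    wx <- diff(stats::pnorm(edges[[1]], foci$x[k], foci$sigma_xy[k]))
    wy <- diff(stats::pnorm(edges[[2]], foci$y[k], foci$sigma_xy[k]))
    wz <- diff(stats::pnorm(edges[[3]], foci$z[k], foci$sigma_z[k]))
    img <- img + foci$intensity[k] * outer(outer(wx, wy), wz)
  }
  mask <- nucleus_mask(dims, voxel_size, center, radius)
  img <- img + background * mask
  if (noise) {
    img <- with_seed(seed, {
      shot <- stats::rpois(length(img), img)
      pmax(shot + stats::rnorm(length(img), 0, read_noise), 0)
    })
    img <- array(img, dims)
  }
  out <- image3d(img, voxel_size, center, radius)
  attr(out, "planted") <- foci
  out
}

#' Sample a planted-foci specification for one nucleus
#'
#' Draws focus centers uniformly inside a concentric ball of
#' `placement_fraction * radius` (so foci are not truncated by the nuclear
#' boundary) subject to a minimum pairwise separation expressed in PSF
#' sigmas under the anisotropic metric
#' `sqrt((dx^2 + dy^2) / sigma_xy^2 + dz^2 / sigma_z^2)`.
#'
#' @param n_foci Number of foci.
#' @param center,radius Nucleus sphere in um.
#' @param intensity Integrated intensity (photons) per focus; recycled.
#' @param sigma_xy,sigma_z PSF widths in um.
#' @param min_sep_sigma Minimum pairwise separation in PSF sigmas.
#' @param placement_fraction Fraction of the nuclear radius available for
#'   focus centers.
#' @param seed Integer seed.
#' @return Data.frame `x, y, z, intensity, sigma_xy, sigma_z`.
#' @export
sample_foci_spec <- function(n_foci, center, radius, intensity = 4e4,
                             sigma_xy = 0.13, sigma_z = 0.35,
                             min_sep_sigma = 4, placement_fraction = 0.6,
                             seed = 1L) {
  with_seed(seed, {
    pts <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(pts) < n_foci && tries < 10000L) {
      tries <- tries + 1L
      p <- runif_ball(1, placement_fraction * radius, center)[1, ]
      ok <- TRUE
      if (nrow(pts)) {
        d <- sqrt(((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) / sigma_xy^2 +
                    (pts[, 3] - p[3])^2 / sigma_z^2)
        ok <- all(d >= min_sep_sigma)
      }
      if (ok) pts <- rbind(pts, p)
    }
    if (nrow(pts) < n_foci) {
      stop("could not place ", n_foci, " foci at the requested separation")
    }
    data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
               intensity = rep_len(intensity, n_foci),
               sigma_xy = sigma_xy, sigma_z = sigma_z)
  })
}

#' Write / read a 3D image stack as multi-plane TIFF
#'
#' Intensities are stored as 32-bit floats after division by `scale` (TIFF
#' float storage is defined on `[0, 1]`); pass the same `scale` to the
#' reader to recover absolute photon counts. z-planes become TIFF
#' directories.
#'
#' @param img An `Image3D`.
#' @param path TIFF file path.
#' @param scale Divisor applied before writing; the default uses the image
#'   maximum (returned invisibly).
#' @return The scale used, invisibly.
#' @export
write_image_tiff <- function(img, path, scale = NULL) {
  if (is.null(scale)) scale <- max(img$data, 1)
  planes <- lapply(seq_len(dim(img$data)[3]), function(z) {
    # tiff expects row-major y/x planes
    t(img$data[, , z]) / scale
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(scale)
}

#' @rdname write_image_tiff
#' @param voxel_size,center,radius Geometry to attach to the loaded image.
#' @export
read_image_tiff <- function(path, voxel_size, center = NULL, radius = NULL,
                            scale = 1) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  nx <- ncol(planes[[1]]); ny <- nrow(planes[[1]]); nz <- length(planes)
  a <- array(0, c(nx, ny, nz))
  for (z in seq_len(nz)) a[, , z] <- t(planes[[z]]) * scale
  if (is.null(center)) center <- c(nx, ny, nz) * voxel_size / 2
  if (is.null(radius)) radius <- min(c(nx, ny) * voxel_size[1:2]) / 2
  image3d(a, voxel_size, center, radius)
}
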