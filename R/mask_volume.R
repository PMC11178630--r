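# Binary mask volumes: the common currency of the whole package. A mask
# volume is a 3D {0,1} voxel grid plus the metadata needed to place it in
# world (patient) space. World coordinates in mm are defined at voxel
# centres: world = origin + (index - 1) * spacing, with 1-based indices.
# The needle axis is the third array dimension throughout the package.

#' Construct a binary mask volume
#'
#' The basic spatial container used for prostate gland masks, lesion masks
#' and needle trajectory masks. Voxels are stored as an integer 3D array of
#' 0/1; `spacing` gives the voxel size in mm along each axis and `origin`
#' the world coordinate (mm) of the centre of voxel `[1,1,1]`.
#'
#' @param voxels 3D array with values in `{0,1}` (logical arrays accepted).
#' @param spacing numeric length-3, voxel spacing in mm; all components > 0.
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre.
#' @return An object of class `mask_volume` with fields `voxels`, `spacing`,
#'   `origin`.
#' @examples
#' m <- mask_volume(array(0L, dim = c(8, 8, 4)))
#' dim(m$voxels)
#' @export
mask_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (is.logical(voxels)) voxels <- array(as.integer(voxels), dim = dim(voxels))
  storage.mode(voxels) <- "integer"
  rng <- range(voxels)
  if (rng[1] < 0L || rng[2] > 1L) stop("voxel values must be in {0,1}")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (mm)")
  }
  if (length(origin) != 3L) stop("origin must have 3 components (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "mask_volume")
}

is_mask_volume <- function(x) inherits(x, "mask_volume")

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("mask_volume %dx%dx%d, spacing (%g, %g, %g) mm, %d foreground voxels\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$voxels)))
  invisible(x)
}

# Shared-geometry check used by every voxelwise operation.
check_same_geometry <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels))) stop("mask shapes differ")
  if (max(abs(a$spacing - b$spacing)) > 1e-9) stop("mask spacings differ")
  invisible(TRUE)
}

#' Number of foreground voxels in a mask
#' @param mask a `mask_volume`.
#' @return integer count.
#' @export
mask_count <- function(mask) sum(mask$voxels)

#' Foreground volume of a mask in cubic millimetres
#' @param mask a `mask_volume`.
#' @return numeric volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask) sum(mask$voxels) * prod(mask$spacing)

#' Foreground centroid of a mask in world mm
#'
#' Voxel-count-weighted mean of the foreground voxel centres, the
#' definition used to place the template grid and to anchor the expert
#' sampling policies on the lesion.
#'
#' @param mask a nonempty `mask_volume`.
#' @return numeric length-3 world coordinate (mm).
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask$voxels == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  mean_idx <- unname(colMeans(idx))
  mask$origin + (mean_idx - 1) * mask$spacing
}

# World-space bounding range (voxel centres) of the foreground along one
# axis (1, 2 or 3).
mask_extent_mm <- function(mask, axis) {
  marg <- mask_axis_counts(mask, axis)
  nz <- which(marg > 0)
  if (length(nz) == 0L) stop("mask is empty")
  mask$origin[axis] + (c(min(nz), max(nz)) - 1) * mask$spacing[axis]
}

# Foreground voxel counts collapsed onto one axis (C-level reductions;
# these run on every environment step via the observation encoder).
mask_axis_counts <- function(mask, axis) {
  v <- mask$voxels
  d <- dim(v)
  if (axis == 1L) return(.rowSums(v, d[1], d[2] * d[3]))
  cs <- .colSums(v, d[1], d[2] * d[3])  # collapses x -> (y, z) matrix
  if (axis == 2L) .rowSums(cs, d[2], d[3]) else .colSums(cs, d[2], d[3])
}

# All three axis marginals of a mask in two passes.
mask_marginals <- function(mask) {
  v <- mask$voxels
  d <- dim(v)
  cs <- matrix(.colSums(v, d[1], d[2] * d[3]), d[2], d[3])
  list(x = .rowSums(v, d[1], d[2] * d[3]),
       y = .rowSums(cs, d[2], d[3]),
       z = .colSums(cs, d[2], d[3]))
}

#' Translate a mask rigidly by a world-space vector
#'
#' The translation is rounded to the nearest whole number of voxels along
#' each axis (voxels shifted past the image border are dropped; vacated
#' voxels become background). Used to apply simulated rigid registration
#' error to the observed anatomy.
#'
#' @param mask a `mask_volume`.
#' @param t_mm numeric length-3 translation in mm.
#' @return the translated `mask_volume`.
#' @export
translate_mask <- function(mask, t_mm) {
  stop_if_not_finite(t_mm, "translation")
  shift <- round_half_away(t_mm / mask$spacing)
  if (all(shift == 0L)) return(mask)
  d <- dim(mask$voxels)
  out <- array(0L, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- shift[ax]
    if (s >= d[ax] || -s >= d[ax]) return(mask_volume(out, mask$spacing, mask$origin))
    if (s >= 0) { src[[ax]] <- 1:(d[ax] - s); dst[[ax]] <- (1 + s):d[ax] }
    else        { src[[ax]] <- (1 - s):d[ax]; dst[[ax]] <- 1:(d[ax] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask$voxels[src[[1]], src[[2]], src[[3]]]
  mask_volume(out, mask$spacing, mask$origin)
}

#' Resample a mask to a new voxel grid shape
#'
#' Nearest-neighbour resampling over the same world extent, used to bring
#' observation channels to the fixed shape consumed by policy networks.
#' Binary values are preserved exactly.
#'
#' @param mask a `mask_volume`.
#' @param shape integer length-3 target shape.
#' @return resampled `mask_volume` (spacing rescaled to preserve extent).
#' @export
resample_mask <- function(mask, shape) {
  d <- dim(mask$voxels)
  shape <- as.integer(shape)
  if (identical(shape, d)) return(mask)
  idx <- lapply(1:3, function(ax) {
    clamp(round((seq_len(shape[ax]) - 0.5) / shape[ax] * d[ax] + 0.5), 1L, d[ax])
  })
  mask_volume(mask$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
              spacing = mask$spacing * d / shape,
              origin = mask$origin)
}

#' Read a binary mask from a NIfTI file
#'
#' Values are thresholded at 0.5; a warning is emitted when the file holds
#' anything other than exact 0/1 (tolerant ingestion of interpolated
#' masks). Spacing and origin are taken from the stored transform.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a `mask_volume`.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) != 3L) stop("expected a 3D volume: ", path)
  u <- unique(as.vector(vox))
  if (!all(u %in% c(0, 1))) {
    warning("non-binary voxel values in ", path, "; thresholding at 0.5")
  }
  vox <- array(as.integer(vox >= 0.5), dim = dim(vox))
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (any(spacing <= 0)) spacing <- RNifti::pixdim(img)[1:3]
  origin <- as.numeric(xf[1:3, 4])
  mask_volume(vox, spacing = spacing, origin = origin)
}

#' Write a binary mask to a NIfTI file
#'
#' Stores voxels with the volume's spacing and origin in an axis-aligned
#' sform so that `read_mask()` round-trips voxels, spacing and origin.
#'
#' @param mask a `mask_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(mask$voxels)
  RNifti::pixdim(img) <- mask$spacing
  m <- diag(4)
  diag(m)[1:3] <- mask$spacing
  m[1:3, 4] <- mask$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
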