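# Intra-procedure spatial mismatch. Two mechanisms are simulated:
#
# * rigid target registration error (TRE): isotropic Gaussian translations
#   applied to the anatomy the agent OBSERVES, while rewards and metrics
#   are computed against the unperturbed anatomy — a registration error
#   between plan and truth;
# * free-form deformation (FFD): displacements at a 10x10x10 equidistant
#   control-point grid over the image, smoothed into a dense field with
#   Gaussian splines. Deformation alters the TRUE anatomy each step and
#   the observation reflects the currently deformed anatomy.

#' Target registration error configuration
#'
#' @param level_mm expected displacement magnitude in mm
#'   (root-mean-square of the translation norm); typical evaluation levels
#'   are 0, 3, 6 and 10 mm.
#' @param per_structure draw independent translations for gland and lesion
#'   (default) or one shared translation.
#' @return a list of class `tre_config`.
#' @export
tre_config <- function(level_mm = 0, per_structure = TRUE) {
  if (level_mm < 0) stop("TRE level must be >= 0")
  structure(list(level_mm = level_mm, per_structure = per_structure),
            class = "tre_config")
}

#' Sample rigid TRE translations
#'
#' Each translation is an isotropic 3D Gaussian draw with per-axis sigma
#' `level_mm / sqrt(3)`, so the root-mean-square translation magnitude
#' equals `level_mm`. Level 0 yields exact zero vectors.
#'
#' @param config a `tre_config` (or a bare nonnegative level in mm).
#' @param n number of translations to draw.
#' @param seed optional integer; when given the draw is deterministic and
#'   does not disturb the caller's RNG stream.
#' @return an `n x 3` matrix of translations in mm.
#' @export
sample_tre <- function(config, n = 1L, seed = NULL) {
  level <- if (inherits(config, "tre_config")) config$level_mm else as.numeric(config)
  if (level < 0) stop("TRE level must be >= 0")
  if (level == 0) return(matrix(0, nrow = n, ncol = 3))
  draw <- function() matrix(stats::rnorm(3 * n, 0, level / sqrt(3)), ncol = 3)
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Sample a free-form deformation field
#'
#' Selects `ceiling(rate * 1000)` of the 10x10x10 control points uniformly
#' at random and assigns each displaced point a displacement with
#' components drawn uniformly in `[-scale, +scale]` mm; remaining control
#' points stay at zero.
#'
#' @param rate fraction of control points displaced, in `[0, 1]`.
#' @param scale maximum displacement magnitude per component, mm (>= 0).
#' @param image_extent_mm numeric length-3 world extent spanned by the
#'   control grid (first to last voxel centre).
#' @param kernel_sigma_mm Gaussian spline width; defaults to the
#'   control-point spacing (`extent / 9`), giving overlapping basis
#'   functions.
#' @param control_shape control lattice dimensions (10 x 10 x 10).
#' @param origin_mm world position of the first control point.
#' @param seed optional integer for a deterministic, stream-isolated draw.
#' @return an object of class `deformation_field` with the control-point
#'   displacement array (`control_shape x 3`, mm) and kernel metadata.
#' @export
sample_deformation <- function(rate, scale, image_extent_mm,
                               kernel_sigma_mm = NULL,
                               control_shape = c(10L, 10L, 10L),
                               origin_mm = c(0, 0, 0),
                               seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (scale < 0) stop("scale must be >= 0")
  control_shape <- as.integer(control_shape)
  n_ctrl <- prod(control_shape)
  n_sel <- as.integer(ceiling(rate * n_ctrl))
  draw <- function() {
    disp <- array(0, dim = c(control_shape, 3))
    if (n_sel > 0 && scale > 0) {
      sel <- sample.int(n_ctrl, n_sel)
      for (comp in 1:3) {
        flat <- rep(0, n_ctrl)
        flat[sel] <- stats::runif(n_sel, -scale, scale)
        disp[, , , comp] <- array(flat, dim = control_shape)
      }
    }
    disp
  }
  disp <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  if (is.null(kernel_sigma_mm)) {
    kernel_sigma_mm <- mean(image_extent_mm / (control_shape - 1))
  }
  structure(list(displacements = disp, control_shape = control_shape,
                 rate = rate, scale = scale,
                 image_extent_mm = as.numeric(image_extent_mm),
                 kernel_sigma_mm = kernel_sigma_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "deformation_field")
}

# Mode-d tensor-times-matrix product for a 3D array T and matrix M
# (new_dim x old_dim_d): contracts dimension d of T against M.
ttm3 <- function(T, M, d) {
  dm <- dim(T)
  perm <- c(d, setdiff(1:3, d))
  Tp <- aperm(T, perm)
  out <- M %*% matrix(Tp, nrow = dm[d])
  out <- array(out, dim = c(nrow(M), dm[setdiff(1:3, d)]))
  aperm(out, order(perm))
}

#' Evaluate a deformation field densely at every voxel
#'
#' The dense displacement is the sum over control points of their
#' displacement vectors weighted by a separable Gaussian kernel
#' `exp(-d^2 / (2 sigma^2))` normalised to unit peak, so `scale` remains an
#' interpretable per-point displacement bound; the dense magnitude can
#' exceed a single control displacement only through superposition of
#' neighbouring points (bounded by the kernel row sums).
#'
#' @param field a `deformation_field`.
#' @param target_shape integer length-3 voxel grid shape.
#' @param spacing voxel spacing in mm.
#' @param origin world coordinate of the first voxel centre.
#' @return a 4D array `target_shape x 3` of displacements in mm.
#' @export
densify <- function(field, target_shape, spacing = c(1, 1, 1),
                    origin = c(0, 0, 0)) {
  target_shape <- as.integer(target_shape)
  sig <- field$kernel_sigma_mm
  kmats <- lapply(1:3, function(ax) {
    vox <- origin[ax] + (seq_len(target_shape[ax]) - 1) * spacing[ax]
    ctrl <- field$origin_mm[ax] +
      seq(0, field$image_extent_mm[ax], length.out = field$control_shape[ax])
    exp(-outer(vox, ctrl, `-`)^2 / (2 * sig^2))
  })
  out <- array(0, dim = c(target_shape, 3))
  for (comp in 1:3) {
    T <- field$displacements[, , , comp]
    T <- ttm3(T, kmats[[1]], 1)
    T <- ttm3(T, kmats[[2]], 2)
    T <- ttm3(T, kmats[[3]], 3)
    out[, , , comp] <- T
  }
  out
}

#' Warp a binary mask with a dense displacement field
#'
#' Backward-warp resampling: the output at voxel position `x` samples the
#' input at `x - u(x)` (so content is pushed along `+u`) with trilinear
#' interpolation, then thresholds at 0.5 to restore a binary mask.
#' Positions sampled outside the image are background.
#'
#' @param mask a `mask_volume`.
#' @param dense_field 4D array `dim(mask) x 3` of displacements in mm, as
#'   produced by [densify()].
#' @return the warped binary `mask_volume`.
#' @export
warp_mask <- function(mask, dense_field) {
  d <- dim(mask$voxels)
  if (!identical(dim(dense_field), c(d, 3L)) &&
      !identical(dim(dense_field), c(d, 3))) {
    stop("dense field shape does not match the mask")
  }
  if (!all(is.finite(dense_field))) stop("dense field has non-finite values")
  n <- prod(d)
  # sample coordinates in (0-based) index space
  gi <- rep(seq_len(d[1]) - 1, times = d[2] * d[3])
  gj <- rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  gk <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  sx <- gi - as.vector(dense_field[, , , 1]) / mask$spacing[1]
  sy <- gj - as.vector(dense_field[, , , 2]) / mask$spacing[2]
  sz <- gk - as.vector(dense_field[, , , 3]) / mask$spacing[3]
  fx <- floor(sx); fy <- floor(sy); fz <- floor(sz)
  wx <- sx - fx; wy <- sy - fy; wz <- sz - fz
  vox <- mask$voxels
  val_at <- function(ii, jj, kk) {
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
    v <- numeric(n)
    idx <- (ii[ok]) + d[1] * (jj[ok] + d[2] * kk[ok]) + 1
    v[ok] <- vox[idx]
    v
  }
  acc <- val_at(fx,     fy,     fz)     * (1 - wx) * (1 - wy) * (1 - wz) +
         val_at(fx + 1, fy,     fz)     * wx       * (1 - wy) * (1 - wz) +
         val_at(fx,     fy + 1, fz)     * (1 - wx) * wy       * (1 - wz) +
         val_at(fx + 1, fy + 1, fz)     * wx       * wy       * (1 - wz) +
         val_at(fx,     fy,     fz + 1) * (1 - wx) * (1 - wy) * wz +
         val_at(fx + 1, fy,     fz + 1) * wx       * (1 - wy) * wz +
         val_at(fx,     fy + 1, fz + 1) * (1 - wx) * wy       * wz +
         val_at(fx + 1, fy + 1, fz + 1) * wx       * wy       * wz
  mask_volume(array(as.integer(acc >= 0.5), dim = d), mask$spacing, mask$origin)
}

#' Write a deformation field's dense displacements as 4D NIfTI
#'
#' @param field a `deformation_field`.
#' @param target_shape,spacing,origin passed to [densify()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_deformation <- function(field, target_shape, path,
                              spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dense <- densify(field, target_shape, spacing, origin)
  img <- RNifti::asNifti(dense)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
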