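# Template-grid geometry. A transperineal brachytherapy template offers a
# 13x13 lattice of needle holes at 5 mm pitch in a para-transverse plane;
# needles travel along the third image axis (z). Grid nodes are indexed
# (i, j) with i, j in 1..13 and node (7, 7) at the grid centre, which is
# anchored at the in-plane projection of the gland centroid.

#' Build the 13x13 template grid for a case
#'
#' The grid is centred on the in-plane (x, y) projection of the true gland
#' centroid, mirroring how the physical template is positioned over the
#' perineum. Node `(i, j)` sits at `centre + ((i-7)*pitch, (j-7)*pitch)`.
#'
#' @param case a `patient_case` (or a gland `mask_volume`).
#' @param pitch_mm grid pitch in mm (5 mm for the standard template).
#' @param n_rows,n_cols grid dimensions (13 x 13 standard).
#' @return an object of class `template_grid`.
#' @export
build_template_grid <- function(case, pitch_mm = 5, n_rows = 13L, n_cols = 13L) {
  gland <- if (inherits(case, "patient_case")) case$gland else case
  centre <- mask_centroid(gland)[1:2]
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pitch_mm = pitch_mm, centre_mm = centre,
                 axis = 3L),
            class = "template_grid")
}

#' World coordinates of template grid nodes
#'
#' @param grid a `template_grid`.
#' @param i,j node indices in `1..13` (vectorised).
#' @return matrix with columns `x`, `y` (mm).
#' @export
grid_node_xy <- function(grid, i, j) {
  ci <- (grid$n_rows + 1) / 2
  cj <- (grid$n_cols + 1) / 2
  cbind(x = grid$centre_mm[1] + (i - ci) * grid$pitch_mm,
        y = grid$centre_mm[2] + (j - cj) * grid$pitch_mm)
}

#' All grid nodes as a data frame
#' @param grid a `template_grid`.
#' @return data.frame with columns `i`, `j`, `x`, `y`.
#' @export
grid_nodes <- function(grid) {
  nodes <- expand.grid(i = seq_len(grid$n_rows), j = seq_len(grid$n_cols))
  xy <- grid_node_xy(grid, nodes$i, nodes$j)
  cbind(nodes, as.data.frame(xy))
}

#' Construct an action
#'
#' Actions are continuous: `dx`, `dy` move the template position by up to
#' ten grid holes in one step (converted to 5 mm intervals by
#' quantization), allowing movement of multiple grid positions at a time;
#' `dz`, nominally in `[-1, 1]`, selects between not firing and firing at
#' one of two depths (near the gland apex or base).
#'
#' @param dx,dy continuous in-plane displacement in grid steps, `(-10, 10)`.
#' @param dz continuous firing channel: `dz < -1/3` do not fire;
#'   `-1/3 <= dz < 1/3` fire at the apex depth; `dz >= 1/3` fire at the
#'   base depth.
#' @return numeric length-3 vector of class `biopsy_action`.
#' @export
biopsy_action <- function(dx, dy, dz) {
  a <- c(dx = dx, dy = dy, dz = dz)
  stop_if_not_finite(a, "action components")
  structure(a, class = "biopsy_action")
}

# dz encodings used when emitting demonstration actions.
DZ_NO_FIRE <- -2 / 3
DZ_APEX <- 0
DZ_BASE <- 2 / 3

#' Quantize a continuous action at a grid node
#'
#' In-plane components are rounded half-away-from-zero to whole grid
#' steps, then the destination node is clamped into the 13x13 grid. The
#' firing channel is thresholded into no-fire / fire-apex / fire-base.
#'
#' @param action numeric length-3 `(dx, dy, dz)`.
#' @param node integer length-2 current node `(i, j)`.
#' @param grid a `template_grid`.
#' @return list with `node` (new `(i, j)`), `fired` (logical) and
#'   `depth_label` (`"apex"`, `"base"` or `NA` when not fired).
#' @export
quantize_action <- function(action, node, grid) {
  a <- as.numeric(action)
  stop_if_not_finite(a, "action components")
  di <- round_half_away(a[1])
  dj <- round_half_away(a[2])
  new_node <- c(clamp(node[1] + di, 1L, grid$n_rows),
                clamp(node[2] + dj, 1L, grid$n_cols))
  if (a[3] < -1 / 3) {
    list(node = new_node, fired = FALSE, depth_label = NA_character_)
  } else {
    list(node = new_node, fired = TRUE,
         depth_label = if (a[3] < 1 / 3) "apex" else "base")
  }
}

#' Apex and base firing depth planes for a gland
#'
#' Needles are fired at one of two depths, near the apex and near the base
#' of the gland: the planes at 25% and 75% of the gland's world-space
#' extent along the needle axis.
#'
#' @param case a `patient_case` or gland `mask_volume`.
#' @return named numeric `c(apex =, base =)` world z in mm.
#' @export
depth_planes <- function(case) {
  gland <- if (inherits(case, "patient_case")) case$gland else case
  ext <- mask_extent_mm(gland, 3L)
  if (diff(ext) < gland$spacing[3]) stop("gland degenerate along the needle axis")
  c(apex = ext[1] + 0.25 * diff(ext), base = ext[1] + 0.75 * diff(ext))
}

# Internal: needle column voxel indices for a node and depth. Returns NULL
# when the clipped core is empty, otherwise list(ix, iy, k0, k1).
needle_column <- function(node, depth_label, core_length_mm, grid, ref_mask,
                          planes) {
  xy <- grid_node_xy(grid, node[1], node[2])
  d <- dim(ref_mask$voxels)
  ix <- round_half_away((xy[1] - ref_mask$origin[1]) / ref_mask$spacing[1]) + 1L
  iy <- round_half_away((xy[2] - ref_mask$origin[2]) / ref_mask$spacing[2]) + 1L
  if (ix < 1L || ix > d[1] || iy < 1L || iy > d[2]) {
    stop("grid node outside the image field of view")
  }
  zc <- planes[[depth_label]]
  sz <- ref_mask$spacing[3]
  # voxel k covered when its centre lies in [zc - L/2, zc + L/2)
  zlo <- zc - core_length_mm / 2
  zhi <- zc + core_length_mm / 2
  k0 <- max(1L, as.integer(ceiling((zlo - ref_mask$origin[3]) / sz + 1 - 1e-9)))
  k1 <- min(d[3], as.integer(floor((zhi - ref_mask$origin[3]) / sz + 1 - 1e-9)))
  if (k0 > k1) return(NULL)
  list(ix = ix, iy = iy, k0 = k0, k1 = k1)
}

#' Rasterize a needle trajectory as a binary mask
#'
#' The needle is modelled as a straight, axis-aligned core of
#' `core_length_mm` centred on the chosen depth plane: a one-voxel-thick
#' column at the node's (x, y), clipped to the image bounds.
#'
#' @param node integer `(i, j)` grid node.
#' @param depth_label `"apex"` or `"base"`.
#' @param case a `patient_case` providing geometry and the gland for depth
#'   planes.
#' @param grid a `template_grid`; defaults to [build_template_grid()] on
#'   the case.
#' @param core_length_mm sampled core length in mm (default 20, a standard
#'   biopsy core throw).
#' @return a `mask_volume` of the trajectory.
#' @export
rasterize_needle <- function(node, depth_label, case,
                             grid = build_template_grid(case),
                             core_length_mm = 20) {
  stopifnot(core_length_mm > 0, depth_label %in% c("apex", "base"))
  ref <- case$gland
  col <- needle_column(node, depth_label, core_length_mm, grid, ref,
                       as.list(depth_planes(case)))
  vox <- array(0L, dim = dim(ref$voxels))
  if (!is.null(col)) vox[col$ix, col$iy, col$k0:col$k1] <- 1L
  mask_volume(vox, ref$spacing, ref$origin)
}

#' Intersection length of a needle trajectory with a mask
#'
#' The cancer core length primitive: the count of voxels shared by the
#' trajectory and the target mask, times the voxel size along the needle
#' axis.
#'
#' @param trajectory,mask `mask_volume`s on identical grids.
#' @return length in mm (>= 0).
#' @export
intersection_length <- function(trajectory, mask) {
  check_same_geometry(trajectory, mask)
  sum(trajectory$voxels & mask$voxels) * mask$spacing[3]
}

# Fast path used by the environment: CCL of a needle column against a mask
# without materializing the trajectory volume.
column_intersection_mm <- function(col, mask) {
  if (is.null(col)) return(0)
  sum(mask$voxels[col$ix, col$iy, col$k0:col$k1]) * mask$spacing[3]
}

#' Longest needle-axis chord through a mask
#'
#' The maximum, over in-plane voxel columns, of the foreground length along
#' the needle axis; the per-needle ceiling on attainable core length used
#' to normalise CCL.
#'
#' @param mask a `mask_volume`.
#' @return chord length in mm.
#' @export
max_axis_chord_mm <- function(mask) {
  cols <- apply(mask$voxels, c(1, 2), sum)
  max(cols) * mask$spacing[3]
}

#' Projected area of a mask on the transverse plane
#'
#' Area of the union of foreground voxel columns projected along the
#' needle axis, in mm^2 (the lesion-area denominator of the needle
#' coverage metric).
#'
#' @param mask a `mask_volume`.
#' @return area in mm^2.
#' @export
projected_area_mm2 <- function(mask) {
  proj <- apply(mask$voxels, c(1, 2), max)
  sum(proj) * mask$spacing[1] * mask$spacing[2]
}
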