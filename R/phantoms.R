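# Synthetic phantom cohorts. Real gland/lesion segmentations from targeted
# biopsy cohorts are not redistributable, so the package generates
# ellipsoidal gland phantoms with embedded spherical/ellipsoidal lesions
# that reproduce the structural assumptions the simulator relies on: one
# gland per case, one target lesion per case fully inside the gland, lesion
# diameters from about one to several template-grid cells, and patient-level
# dataset splits (a patient with several lesions contributes several cases,
# all landing in the same split).

#' Construct a patient case
#'
#' The unit of simulation: one gland mask plus one target lesion mask on a
#' shared voxel grid. Patients with multiple lesions are represented as
#' multiple cases sharing `patient_id`.
#'
#' @param patient_id character scalar.
#' @param gland,lesion `mask_volume` objects on identical grids; the lesion
#'   must be a voxelwise subset of the gland and both must be nonempty.
#' @param lesion_id character scalar distinguishing lesions of one patient.
#' @return an object of class `patient_case`.
#' @export
patient_case <- function(patient_id, gland, lesion, lesion_id = "L1") {
  stopifnot(is_mask_volume(gland), is_mask_volume(lesion))
  check_same_geometry(gland, lesion)
  if (mask_count(gland) == 0L) stop("gland mask is empty")
  if (mask_count(lesion) == 0L) stop("lesion mask is empty")
  if (any(lesion$voxels > gland$voxels)) {
    stop("lesion mask is not contained in the gland mask")
  }
  structure(list(patient_id = as.character(patient_id),
                 lesion_id = as.character(lesion_id),
                 gland = gland, lesion = lesion),
            class = "patient_case")
}

case_id <- function(case) paste(case$patient_id, case$lesion_id, sep = "_")

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("patient_case %s: gland %d voxels, lesion %d voxels\n",
              case_id(x), mask_count(x$gland), mask_count(x$lesion)))
  invisible(x)
}

# Rasterize an axis-aligned ellipsoid into {0,1} voxels: a voxel is
# foreground when its centre lies inside the ellipsoid.
rasterize_ellipsoid <- function(centre_mm, radii_mm, shape, spacing, origin) {
  ax <- lapply(1:3, function(d) {
    ((origin[d] + (seq_len(shape[d]) - 1) * spacing[d]) - centre_mm[d]) / radii_mm[d]
  })
  q <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  mask_volume(array(as.integer(q <= 1), dim = shape), spacing, origin)
}

# Sufficient (slightly conservative) condition for a sphere of radius r at
# offset o from the gland centre to lie inside an axis-aligned ellipsoid
# with semi-axes R.
lesion_fits_inside <- function(offset_mm, lesion_radii_mm, gland_radii_mm) {
  sum(((abs(offset_mm) + lesion_radii_mm) / gland_radii_mm)^2) <= 1
}

#' Generate one synthetic patient phantom
#'
#' Builds an ellipsoidal gland mask centred in the volume with an embedded
#' ellipsoidal (spherical when `lesion_radius_mm` is scalar) lesion at a
#' given offset from the gland centre. Optional multiplicative jitter on
#' radii and additive jitter on the offset is drawn deterministically from
#' `seed`. Raises an error if the requested lesion would protrude outside
#' the gland.
#'
#' @param seed integer seed controlling the jitter.
#' @param gland_radii_mm length-3 gland semi-axes in mm.
#' @param lesion_radius_mm lesion semi-axis/es in mm (scalar or length 3).
#' @param lesion_offset_mm length-3 offset of the lesion centre from the
#'   gland centre, mm.
#' @param shape integer length-3 voxel grid shape.
#' @param spacing voxel spacing in mm.
#' @param jitter fractional standard deviation of radius jitter and, times
#'   the lesion radius, of offset jitter; 0 disables jitter.
#' @param patient_id,lesion_id identifiers stored on the case.
#' @return a `patient_case`.
#' @examples
#' ph <- generate_phantom(1, lesion_radius_mm = 5)
#' mask_count(ph$lesion)
#' @export
generate_phantom <- function(seed = 1L,
                             gland_radii_mm = c(25, 20, 25),
                             lesion_radius_mm = 6,
                             lesion_offset_mm = c(0, 0, 0),
                             shape = c(96, 96, 64),
                             spacing = c(1, 1, 1),
                             jitter = 0,
                             patient_id = "P001",
                             lesion_id = "L1") {
  stopifnot(all(gland_radii_mm > 0), all(lesion_radius_mm > 0))
  shape <- as.integer(shape)
  lesion_radii <- rep(as.numeric(lesion_radius_mm), length.out = 3)
  gland_radii <- as.numeric(gland_radii_mm)
  offset <- as.numeric(lesion_offset_mm)
  if (jitter > 0) {
    with_local_seed(seed, {
      gland_radii <- gland_radii * exp(stats::rnorm(3, 0, jitter))
      lesion_radii <- lesion_radii * exp(stats::rnorm(3, 0, jitter))
      offset <- offset + stats::rnorm(3, 0, jitter * mean(lesion_radii))
    })
  }
  if (!lesion_fits_inside(offset, lesion_radii, gland_radii)) {
    stop("requested lesion would protrude outside the gland")
  }
  origin <- c(0, 0, 0)
  centre <- origin + (shape - 1) * spacing / 2
  gland <- rasterize_ellipsoid(centre, gland_radii, shape, spacing, origin)
  lesion <- rasterize_ellipsoid(centre + offset, lesion_radii, shape, spacing, origin)
  # guard against raster boundary effects; containment is analytic already
  lesion$voxels <- lesion$voxels * gland$voxels
  patient_case(patient_id, gland, lesion, lesion_id)
}

#' Default parameter ranges for synthetic cohorts
#'
#' Gland semi-axes of 20-28 x 16-22 x 20-28 mm match typical prostate
#' dimensions; lesion radii of 4-10 mm give diameters spanning roughly one
#' to four template-grid cells (5 mm pitch).
#'
#' @return a list with components `gland_radii_mm` (2x3 lo/hi matrix),
#'   `lesion_radius_mm` (lo, hi), `lesion_offset_frac` maximal offset as a
#'   fraction of the feasible room, `shape` and `spacing`.
#' @export
default_cohort_ranges <- function() {
  list(gland_radii_mm = rbind(lo = c(20, 16, 20), hi = c(28, 22, 28)),
       lesion_radius_mm = c(4, 10),
       lesion_offset_frac = 0.8,
       shape = c(96, 96, 64),
       spacing = c(1, 1, 1))
}

#' Generate a cohort of synthetic patient cases
#'
#' Draws per-patient gland geometry and per-lesion size/placement from
#' `param_ranges`. Cases of one patient share `patient_id` and gland
#' geometry but differ in lesion placement. Lesion offsets are
#' rejection-sampled until the lesion fits inside the gland.
#'
#' @param n_patients number of patients (>= 1).
#' @param lesions_per_patient lesions (cases) per patient.
#' @param seed integer seed; the cohort is a deterministic function of
#'   `(n_patients, lesions_per_patient, seed, param_ranges)`.
#' @param param_ranges see [default_cohort_ranges()].
#' @return list of `patient_case` objects, length
#'   `n_patients * lesions_per_patient`.
#' @export
generate_cohort <- function(n_patients, lesions_per_patient = 1L, seed = 1L,
                            param_ranges = default_cohort_ranges()) {
  stopifnot(n_patients >= 1, lesions_per_patient >= 1)
  pr <- utils::modifyList(default_cohort_ranges(), param_ranges)
  lo <- pr$gland_radii_mm[1, ]; hi <- pr$gland_radii_mm[2, ]
  if (any(hi < lo) || pr$lesion_radius_mm[2] < pr$lesion_radius_mm[1]) {
    stop("infeasible parameter ranges")
  }
  cases <- vector("list", n_patients * lesions_per_patient)
  k <- 0L
  with_local_seed(seed, {
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%04d", p)
      gland_radii <- stats::runif(3, lo, hi)
      for (l in seq_len(lesions_per_patient)) {
        r <- stats::runif(1, pr$lesion_radius_mm[1], pr$lesion_radius_mm[2])
        offset <- NULL
        for (try in 1:200) {
          cand <- stats::runif(3, -1, 1) * pr$lesion_offset_frac *
            pmax(gland_radii - r, 0)
          if (lesion_fits_inside(cand, rep(r, 3), gland_radii)) {
            offset <- cand
            break
          }
        }
        if (is.null(offset)) stop("infeasible parameter ranges: no admissible lesion placement")
        k <- k + 1L
        cases[[k]] <- generate_phantom(seed = derive_seed(seed, k),
                                       gland_radii_mm = gland_radii,
                                       lesion_radius_mm = r,
                                       lesion_offset_mm = offset,
                                       shape = pr$shape,
                                       spacing = pr$spacing,
                                       jitter = 0,
                                       patient_id = pid,
                                       lesion_id = sprintf("L%d", l))
      }
    }
  })
  cases
}

#' Split cases into train/validation/test at the patient level
#'
#' All cases of one patient are assigned to the same split, preventing
#' leakage of patient anatomy between training and evaluation. `ratios` may
#' be absolute patient counts (summing to the number of distinct patients,
#' e.g. `c(396, 58, 113)` for 567 patients) or proportions.
#'
#' @param cases list of `patient_case`.
#' @param ratios length-3 numeric, counts or proportions for
#'   (train, validation, test).
#' @param seed integer; patients are shuffled deterministically under the
#'   seed (after sorting by id, so input order is irrelevant).
#' @return a list of class `dataset_split` with components `train`, `val`,
#'   `test` (lists of cases) and `assignment` (data.frame patient_id,
#'   split).
#' @export
split_dataset <- function(cases, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios >= 0))
  pids <- sort(unique(vapply(cases, function(c) c$patient_id, "")))
  n <- length(pids)
  if (abs(sum(ratios) - n) < 1e-9 && all(abs(ratios - round(ratios)) < 1e-9)) {
    counts <- as.integer(round(ratios))
  } else {
    prop <- ratios / sum(ratios)
    counts <- floor(prop * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      frac_order <- order(prop * n - counts, decreasing = TRUE)
      counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1L
    }
  }
  if (any(counts == 0L)) stop("a split would be empty with these ratios")
  perm <- with_local_seed(seed, sample.int(n))
  shuffled <- pids[perm]
  lab <- rep(c("train", "val", "test"), counts)
  assignment <- data.frame(patient_id = shuffled, split = lab,
                           stringsAsFactors = FALSE)
  assignment <- assignment[order(assignment$patient_id), , drop = FALSE]
  rownames(assignment) <- NULL
  by_split <- split(assignment$patient_id, assignment$split)
  pick <- function(ids) Filter(function(c) c$patient_id %in% ids, cases)
  structure(list(train = pick(by_split$train),
                 val = pick(by_split$val),
                 test = pick(by_split$test),
                 assignment = assignment),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split: %d/%d/%d cases (train/val/test), %d patients\n",
              length(x$train), length(x$val), length(x$test),
              nrow(x$assignment)))
  invisible(x)
}
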