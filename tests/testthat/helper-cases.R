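# Fixture builders shared across test files. All fixtures are generated in
# code; volumes are kept small so the whole suite stays fast.

# A case whose gland is an ellipsoid with z-extent 40 mm (the apex core
# reaches the gland centre) and a central spherical lesion.
sphere_case <- function(lesion_radius = 8, offset = c(0, 0, 0),
                        gland_radii = c(24, 20, 20), shape = c(64, 64, 48),
                        seed = 1) {
  generate_phantom(seed, gland_radii_mm = gland_radii,
                   lesion_radius_mm = lesion_radius,
                   lesion_offset_mm = offset, shape = shape)
}

# Toy task in which every fired needle inside the gland hits: the lesion
# mask equals the gland mask.
full_gland_case <- function(shape = c(64, 64, 40),
                            gland_radii = c(22, 18, 16)) {
  ph <- generate_phantom(3, gland_radii_mm = gland_radii,
                         lesion_radius_mm = 5, shape = shape)
  patient_case("T001", ph$gland, ph$gland, "L1")
}

# Small training cohort used by imitation/PPO tests: lesions large enough
# to be reachable from the two firing depths.
small_cohort <- function(n, seed = 42, shape = c(64, 64, 48)) {
  generate_cohort(n, 1, seed = seed, param_ranges = list(
    shape = shape,
    gland_radii_mm = rbind(lo = c(20, 16, 18), hi = c(26, 20, 23)),
    lesion_radius_mm = c(6, 9)))
}

# Minimal valid cases for split tests: shared tiny masks, distinct ids.
tiny_cases <- function(patient_ids, lesions_per_patient = 1L) {
  vox <- array(0L, dim = c(4, 4, 4))
  vox[2:3, 2:3, 2:3] <- 1L
  g <- mask_volume(vox)
  out <- list()
  for (pid in patient_ids) {
    for (l in seq_len(lesions_per_patient)) {
      out[[length(out) + 1L]] <- patient_case(pid, g, g, sprintf("L%d", l))
    }
  }
  out
}

expect_plan_equal <- function(plan, expected_ij) {
  expect_equal(unname(as.matrix(plan[, c("i", "j")])), unname(expected_ij))
}
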