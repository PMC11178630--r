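test_that("the reward table yields the exact integer for every outcome", {
  spec <- reward_spec()
  rf <- biopsyplan:::reward_for
  # exhaustive over (fired, hit, inside_gland); hit implies inside for a
  # lesion contained in the gland but the precedence is still defined
  expect_equal(rf(FALSE, FALSE, FALSE, spec), -1)
  expect_equal(rf(FALSE, FALSE, TRUE, spec), -1)
  expect_equal(rf(FALSE, TRUE, TRUE, spec), -1)   # not fired dominates
  expect_equal(rf(FALSE, TRUE, FALSE, spec), -1)
  expect_equal(rf(TRUE, FALSE, FALSE, spec), -5)
  expect_equal(rf(TRUE, TRUE, FALSE, spec), -5)   # outside-gland dominates
  expect_equal(rf(TRUE, FALSE, TRUE, spec), -2)
  expect_equal(rf(TRUE, TRUE, TRUE, spec), 10)
})

test_that("the environment realises each reward case end to end", {
  ph <- sphere_case(lesion_radius = 8)
  e <- biopsy_env(ph)
  env_reset(e, 1)
  # fire at the centre node, apex depth: hits the central lesion
  expect_equal(env_step(e, c(0, 0, 0))$reward, 10)
  # no-fire move
  expect_equal(env_step(e, c(1, 0, -1))$reward, -1)
  # fired far from the lesion but inside the gland: miss
  env_reset(e, 1)
  expect_equal(env_step(e, c(-4, 0, 0))$reward, -2)
  # fired at the grid corner, outside the gland entirely
  env_reset(e, 1)
  expect_equal(env_step(e, c(-10, -10, 0))$reward, -5)
})

test_that("observations start clean and the needle history shifts exactly", {
  ph <- sphere_case()
  e <- biopsy_env(ph)
  obs <- env_reset(e, 1)
  expect_named(obs$channels, c("P", "L", "N_t", "N_t1", "N_t2"))
  expect_equal(obs$node, c(7L, 7L))
  expect_equal(mask_count(obs$channels$N_t), 0)
  expect_equal(mask_count(obs$channels$N_t1), 0)
  expect_equal(mask_count(obs$channels$N_t2), 0)
  # with no mismatch the observation equals the true anatomy
  expect_identical(obs$channels$P$voxels, ph$gland$voxels)
  expect_identical(obs$channels$L$voxels, ph$lesion$voxels)
  o1 <- env_step(e, c(0, 0, 0))$observation
  n1 <- o1$channels$N_t
  expect_gt(mask_count(n1), 0)
  o2 <- env_step(e, c(1, 1, 0))$observation
  expect_identical(o2$channels$N_t1$voxels, n1$voxels)
  o3 <- env_step(e, c(0, 0, -1))$observation
  expect_identical(o3$channels$N_t2$voxels, n1$voxels)
  expect_equal(mask_count(o3$channels$N_t), 0)  # no-fire adds an empty channel
})

test_that("episodes terminate at five hits or twenty steps with bounded rewards", {
  toy <- full_gland_case()
  res <- run_episode(function(obs) c(0, 0, 0), toy)
  expect_equal(nrow(res$records), 5)
  expect_equal(res$reason, "five_hits")
  expect_equal(res$total_reward, 50)
  res2 <- run_episode(never_fire_policy(), toy)
  expect_equal(nrow(res2$records), 20)
  expect_equal(res2$reason, "max_steps")
  expect_equal(res2$total_reward, -20)
  # per-step rewards always come from the four-integer table; total <= 50
  set.seed(2)
  for (k in 1:5) {
    r <- run_episode(random_policy(), toy, seed = k)
    expect_true(all(r$rewards %in% c(10, -2, -1, -5)))
    expect_lte(r$total_reward, 50)
  }
})

test_that("stepping a finished episode errors and reset makes episodes reproducible", {
  toy <- full_gland_case()
  e <- biopsy_env(toy)
  env_reset(e, 1)
  for (k in 1:5) out <- env_step(e, c(0, 0, 0))
  expect_true(out$done)
  expect_error(env_step(e, c(0, 0, 0)), "finished")
  r1 <- run_episode(expert_agent("centre"), toy, seed = 3)
  r2 <- run_episode(expert_agent("centre"), toy, seed = 3)
  expect_identical(r1$records, r2$records)
})

test_that("TRE shifts only the observation while rewards use the true anatomy", {
  ph <- sphere_case(lesion_radius = 8)
  cfg <- env_config(tre = tre_config(10))
  e <- biopsy_env(ph, cfg)
  obs <- env_reset(e, 7)
  expect_false(identical(obs$channels$L$voxels, ph$lesion$voxels))
  # firing at the true lesion centre still hits: truth is unperturbed
  expect_equal(env_step(e, c(0, 0, 0))$reward, 10)
})

test_that("per-step deformation reshapes the anatomy seen and scored", {
  ph <- sphere_case(lesion_radius = 8, shape = c(48, 48, 40),
                    gland_radii = c(18, 16, 16))
  cfg <- env_config(deform = list(rate = 0.5, scale = 3))
  e <- biopsy_env(ph, cfg)
  env_reset(e, 5)
  out <- env_step(e, c(0, 0, 0))
  obs <- out$observation
  # observation reflects the deformed lesion, not the base mask
  expect_false(identical(obs$channels$L$voxels, ph$lesion$voxels))
  expect_true(all(obs$channels$L$voxels %in% c(0L, 1L)))
  # determinism under the episode seed
  e2 <- biopsy_env(ph, cfg)
  env_reset(e2, 5)
  out2 <- env_step(e2, c(0, 0, 0))
  expect_identical(out$observation$channels$L$voxels, obs$channels$L$voxels)
  expect_equal(out$reward, out2$reward)
})

test_that("episode JSON round-trips the per-step records", {
  ph <- sphere_case()
  res <- run_episode(expert_agent("centre"), ph, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  episode_to_json(res, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$case_id, res$case_id)
  expect_equal(nrow(back$steps), nrow(res$records))
  expect_equal(back$steps$ccl_mm, res$records$ccl_mm)
  expect_equal(sum(back$steps$reward), res$total_reward)
})
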