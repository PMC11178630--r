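# The biopsy MDP. States are five aligned mask channels
# s_t = (P_t, L_t, N_t, N_{t-1}, N_{t-2}): the observed prostate and
# lesion masks plus the current and two previous needle-trajectory masks.
# Actions are continuous (dx, dy, dz) template moves with a thresholded
# firing channel. Rewards are the integer clinical shaping:
#   +10 fired and intersecting the target lesion
#    -2 fired inside the gland but missing the lesion
#    -1 not fired
#    -5 fired with the trajectory entirely outside the gland
# Episodes run for at most 20 steps and terminate early once five fired
# needles have intersected the lesion.
#
# Mismatch semantics: TRE translates the OBSERVED masks only (rewards use
# the true anatomy); free-form deformation re-shapes the TRUE anatomy each
# step (resampled fresh from the base masks by default) and the
# observation shows the deformed anatomy.

#' Reward specification for the biopsy MDP
#'
#' @param hit,miss,no_fire,outside_gland integer rewards (defaults +10,
#'   -2, -1, -5).
#' @return a list of class `reward_spec`.
#' @export
reward_spec <- function(hit = 10, miss = -2, no_fire = -1, outside_gland = -5) {
  structure(list(hit = hit, miss = miss, no_fire = no_fire,
                 outside_gland = outside_gland),
            class = "reward_spec")
}

# The reward table as a pure function of the step outcome; precedence for
# fired needles is outside-gland, then hit, then miss.
reward_for <- function(fired, hit, inside_gland, spec = reward_spec()) {
  if (!fired) return(spec$no_fire)
  if (!inside_gland) return(spec$outside_gland)
  if (hit) return(spec$hit)
  spec$miss
}

#' Environment configuration
#'
#' @param reward a [reward_spec()].
#' @param core_length_mm needle core length in mm.
#' @param max_steps episode cap (20).
#' @param target_hits early-termination hit count (5).
#' @param tre a [tre_config()] or NULL for no registration error.
#' @param deform NULL, or a list with `rate`, `scale` and optionally
#'   `kernel_sigma_mm` and `accumulate` (default FALSE: each step's field
#'   is resampled fresh and applied to the base anatomy; TRUE composes the
#'   control displacements across steps).
#' @param obs_shape observation channel shape for network input (default
#'   64 x 64 x 32); `NULL` keeps the native resolution. Rewards and
#'   metrics always use full resolution.
#' @return a list of class `env_config`.
#' @export
env_config <- function(reward = reward_spec(), core_length_mm = 20,
                       max_steps = 20L, target_hits = 5L,
                       tre = NULL, deform = NULL,
                       obs_shape = c(64L, 64L, 32L)) {
  structure(list(reward = reward, core_length_mm = core_length_mm,
                 max_steps = as.integer(max_steps),
                 target_hits = as.integer(target_hits),
                 tre = tre, deform = deform, obs_shape = obs_shape),
            class = "env_config")
}

#' Create a biopsy environment for one patient case
#'
#' The returned object follows the standard episodic-control contract:
#' [env_reset()] then repeated [env_step()] until `done`.
#'
#' @param case a `patient_case`.
#' @param config an [env_config()].
#' @return an object of class `biopsy_env` (an R environment).
#' @export
biopsy_env <- function(case, config = env_config()) {
  e <- new.env(parent = emptyenv())
  e$case <- case
  e$config <- config
  e$grid <- build_template_grid(case)
  e$planes <- as.list(depth_planes(case))
  e$zero_mask <- mask_volume(array(0L, dim = dim(case$gland$voxels)),
                             case$gland$spacing, case$gland$origin)
  e$done <- TRUE
  class(e) <- "biopsy_env"
  e
}

#' @export
print.biopsy_env <- function(x, ...) {
  cat(sprintf("biopsy_env for %s (step %s, done=%s)\n", case_id(x$case),
              if (is.null(x$step_count)) "-" else x$step_count, x$done))
  invisible(x)
}

build_observation <- function(e) {
  chans <- list(P = e$obs_gland, L = e$obs_lesion,
                N_t = e$needles[[1]], N_t1 = e$needles[[2]],
                N_t2 = e$needles[[3]])
  margs <- list(P = e$marg_gland, L = e$marg_lesion,
                N_t = e$needle_margs[[1]], N_t1 = e$needle_margs[[2]],
                N_t2 = e$needle_margs[[3]])
  structure(list(
    channels = chans,
    marginals = margs,
    node = e$node,
    step = e$step_count,
    hits = e$hits,
    max_steps = e$config$max_steps,
    target_hits = e$config$target_hits,
    grid = e$grid,
    planes = e$planes,
    obs_shape = e$config$obs_shape %||% dim(e$case$gland$voxels)
  ), class = "biopsy_observation")
}

# Refresh true (possibly deformed) anatomy and the observed (possibly
# TRE-shifted) anatomy for the current step.
refresh_anatomy <- function(e) {
  cfg <- e$config
  if (!is.null(cfg$deform) && (cfg$deform$rate %||% 0) > 0 &&
      (cfg$deform$scale %||% 0) > 0) {
    d <- dim(e$case$gland$voxels)
    extent <- (d - 1) * e$case$gland$spacing
    fld <- sample_deformation(cfg$deform$rate, cfg$deform$scale,
                              image_extent_mm = extent,
                              kernel_sigma_mm = cfg$deform$kernel_sigma_mm,
                              origin_mm = e$case$gland$origin,
                              seed = derive_seed(e$episode_seed, 7L + e$step_count))
    if (isTRUE(cfg$deform$accumulate) && !is.null(e$accum_field)) {
      fld$displacements <- fld$displacements + e$accum_field$displacements
    }
    if (isTRUE(cfg$deform$accumulate)) e$accum_field <- fld
    dense <- densify(fld, d, e$case$gland$spacing, e$case$gland$origin)
    e$true_gland <- warp_mask(e$case$gland, dense)
    e$true_lesion <- warp_mask(e$case$lesion, dense)
  } else {
    e$true_gland <- e$case$gland
    e$true_lesion <- e$case$lesion
  }
  if (!is.null(cfg$tre) && cfg$tre$level_mm > 0) {
    tr <- sample_tre(cfg$tre, n = 2L,
                     seed = derive_seed(e$episode_seed, 3L))
    if (!cfg$tre$per_structure) tr[2, ] <- tr[1, ]
    e$obs_gland <- translate_mask(e$true_gland, tr[1, ])
    e$obs_lesion <- translate_mask(e$true_lesion, tr[2, ])
  } else {
    e$obs_gland <- e$true_gland
    e$obs_lesion <- e$true_lesion
  }
  e$marg_gland <- mask_marginals(e$obs_gland)
  e$marg_lesion <- mask_marginals(e$obs_lesion)
  invisible(e)
}

#' Reset a biopsy environment
#'
#' Places the template cursor at the grid centre, clears the needle
#' history channels and initialises the episode's mismatch state from
#' `seed`.
#'
#' @param e a `biopsy_env`.
#' @param seed integer episode seed (drives TRE and deformation draws).
#' @return the initial observation (class `biopsy_observation`).
#' @export
env_reset <- function(e, seed = 1L) {
  e$episode_seed <- as.integer(seed)
  e$node <- c((e$grid$n_rows + 1L) %/% 2L, (e$grid$n_cols + 1L) %/% 2L)
  e$step_count <- 0L
  e$hits <- 0L
  e$done <- FALSE
  e$reason <- NA_character_
  e$records <- list()
  e$rewards <- numeric(0)
  e$accum_field <- NULL
  e$needles <- list(e$zero_mask, e$zero_mask, e$zero_mask)
  d <- dim(e$zero_mask$voxels)
  e$zero_marg <- list(x = numeric(d[1]), y = numeric(d[2]), z = numeric(d[3]))
  e$needle_margs <- list(e$zero_marg, e$zero_marg, e$zero_marg)
  refresh_anatomy(e)
  build_observation(e)
}

#' Advance a biopsy environment by one action
#'
#' Quantizes the action, moves the template cursor, optionally fires a
#' needle, scores it against the current true anatomy and shifts the
#' needle history channels.
#'
#' @param e a `biopsy_env` that has been reset and is not done.
#' @param action numeric `(dx, dy, dz)`.
#' @return list with `observation`, `reward`, `done` and `info` (the
#'   needle record for this step).
#' @export
env_step <- function(e, action) {
  if (e$done) stop("episode is finished; call env_reset()")
  cfg <- e$config
  e$step_count <- e$step_count + 1L
  q <- quantize_action(action, e$node, e$grid)
  e$node <- q$node
  # deformation evolves the true anatomy before the needle is scored
  if (!is.null(cfg$deform)) refresh_anatomy(e)
  fired <- q$fired
  hit <- FALSE
  inside <- FALSE
  ccl <- 0
  new_chan <- e$zero_mask
  new_marg <- e$zero_marg
  if (fired) {
    col <- needle_column(q$node, q$depth_label, cfg$core_length_mm, e$grid,
                         e$case$gland, e$planes)
    inside <- column_intersection_mm(col, e$true_gland) > 0
    ccl <- column_intersection_mm(col, e$true_lesion)
    hit <- ccl > 0
    if (!is.null(col)) {
      vox <- e$zero_mask$voxels
      vox[col$ix, col$iy, col$k0:col$k1] <- 1L
      new_chan <- mask_volume(vox, e$zero_mask$spacing, e$zero_mask$origin)
      len <- col$k1 - col$k0 + 1L
      new_marg <- e$zero_marg
      new_marg$x[col$ix] <- len
      new_marg$y[col$iy] <- len
      new_marg$z[col$k0:col$k1] <- 1
    }
  }
  reward <- reward_for(fired, hit, inside, cfg$reward)
  if (hit) e$hits <- e$hits + 1L
  e$needles <- list(new_chan, e$needles[[1]], e$needles[[2]])
  e$needle_margs <- list(new_marg, e$needle_margs[[1]], e$needle_margs[[2]])
  xy <- grid_node_xy(e$grid, q$node[1], q$node[2])
  rec <- list(step = e$step_count, i = q$node[1], j = q$node[2],
              x_mm = unname(xy[1, 1]), y_mm = unname(xy[1, 2]),
              depth_label = if (fired) q$depth_label else NA_character_,
              fired = fired, hit = hit, inside_gland = inside,
              ccl_mm = ccl, reward = reward)
  e$records[[length(e$records) + 1L]] <- rec
  e$rewards <- c(e$rewards, reward)
  if (e$hits >= cfg$target_hits) {
    e$done <- TRUE
    e$reason <- "five_hits"
  } else if (e$step_count >= cfg$max_steps) {
    e$done <- TRUE
    e$reason <- "max_steps"
  }
  list(observation = build_observation(e), reward = reward, done = e$done,
       info = rec)
}

records_df <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(step = r$step, i = r$i, j = r$j, x_mm = r$x_mm, y_mm = r$y_mm,
               depth_label = r$depth_label, fired = r$fired, hit = r$hit,
               inside_gland = r$inside_gland, ccl_mm = r$ccl_mm,
               reward = r$reward, stringsAsFactors = FALSE)
  }))
}

#' Run one full episode of a policy in an environment
#'
#' @param policy a policy: either a function `observation -> action` or a
#'   policy object (see [as_policy()]).
#' @param case a `patient_case`.
#' @param config an [env_config()].
#' @param seed integer episode seed.
#' @param env optionally a prebuilt `biopsy_env` for `case` (reused across
#'   episodes to avoid rebuilding geometry).
#' @return an `episode_result`: list with `records` (data.frame),
#'   `rewards`, `total_reward`, `reason`, `case_id`, `seed`.
#' @export
run_episode <- function(policy, case, config = env_config(), seed = 1L,
                        env = NULL) {
  e <- env %||% biopsy_env(case, config)
  pol <- as_policy(policy)
  obs <- env_reset(e, seed)
  pol$reset()
  repeat {
    a <- pol$act(obs)
    out <- env_step(e, a)
    obs <- out$observation
    if (out$done) break
  }
  structure(list(records = records_df(e$records), rewards = e$rewards,
                 total_reward = sum(e$rewards), reason = e$reason,
                 case_id = case_id(case), seed = seed,
                 lesion_voxels = mask_count(case$lesion),
                 lesion_area_mm2 = projected_area_mm2(case$lesion),
                 lesion_chord_mm = max_axis_chord_mm(case$lesion)),
            class = "episode_result")
}

#' @export
print.episode_result <- function(x, ...) {
  cat(sprintf("episode %s: %d steps, %d fired, %d hit, total reward %g (%s)\n",
              x$case_id, nrow(x$records), sum(x$records$fired),
              sum(x$records$hit), x$total_reward, x$reason))
  invisible(x)
}

#' Export an episode as JSON
#'
#' Per-step action outcomes (node, depth, fired, hit, CCL, reward) plus
#' episode metadata, the raw material for independent metric
#' recomputation.
#'
#' @param result an `episode_result`.
#' @param path output path; `NULL` returns the JSON string.
#' @return the path (or JSON string), invisibly when written.
#' @export
episode_to_json <- function(result, path = NULL) {
  payload <- list(case_id = result$case_id, seed = result$seed,
                  reason = result$reason, total_reward = result$total_reward,
                  lesion_voxels = result$lesion_voxels,
                  lesion_area_mm2 = result$lesion_area_mm2,
                  lesion_chord_mm = result$lesion_chord_mm,
                  steps = result$records)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
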