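test_that("centre policy equals brute-force 5-nearest with the stated tie-break on 50 phantoms", {
  cases <- generate_cohort(50, 1, seed = 11, param_ranges = list(
    shape = c(48, 48, 36),
    gland_radii_mm = rbind(lo = c(14, 12, 11), hi = c(18, 16, 14)),
    lesion_radius_mm = c(3, 6)))
  for (cs in cases) {
    grid <- build_template_grid(cs)
    plan <- centre_policy(cs, grid)
    # independent brute force: explicit loops over every node
    cen <- mask_centroid(cs$lesion)
    recs <- list()
    for (i in 1:13) for (j in 1:13) {
      xy <- grid_node_xy(grid, i, j)
      recs[[length(recs) + 1L]] <-
        c(d = sqrt((xy[1] - cen[1])^2 + (xy[2] - cen[2])^2), i = i, j = j)
    }
    m <- do.call(rbind, recs)
    m <- m[order(m[, "d"], m[, "i"], m[, "j"]), ]
    expect_plan_equal(plan, m[1:5, c("i", "j")])
  }
})

test_that("a lesion centred on a node makes its orthogonal neighbours the other four targets", {
  # odd volume: lesion centroid exactly on the grid centre node
  ph <- sphere_case(lesion_radius = 6, gland_radii = c(24, 20, 20),
                    shape = c(65, 65, 49))
  plan <- centre_policy(ph)
  expect_equal(unname(unlist(plan[1, c("i", "j")])), c(7, 7))
  neigh <- plan[2:5, c("i", "j")]
  expected <- rbind(c(6, 7), c(7, 6), c(7, 8), c(8, 7))  # (dist, i, j) order
  expect_plan_equal(neigh, expected)
})

test_that("centre policy minimises summed node-centroid distance among 5-subsets on a small grid", {
  ph <- sphere_case(lesion_radius = 6, shape = c(65, 65, 49),
                    gland_radii = c(24, 20, 20))
  grid <- build_template_grid(ph)
  grid$n_rows <- 5L; grid$n_cols <- 5L  # shrink for exhaustive search
  plan <- centre_policy(ph, grid)
  cen <- mask_centroid(ph$lesion)
  nodes <- grid_nodes(grid)
  d <- sqrt((nodes$x - cen[1])^2 + (nodes$y - cen[2])^2)
  best <- min(combn(d, 5, sum))
  got <- sum(d[match(paste(plan$i, plan$j),
                     paste(nodes$i, nodes$j))])
  expect_equal(got, best, tolerance = 1e-9)
})

test_that("translating the lesion by one grid pitch shifts the whole centre plan", {
  ph <- sphere_case(lesion_radius = 6, shape = c(65, 65, 49),
                    gland_radii = c(24, 20, 20))
  grid <- build_template_grid(ph)
  plan0 <- centre_policy(ph, grid)
  shifted <- translate_mask(ph$lesion, c(5, 0, 0))
  plan1 <- centre_policy(ph, grid, lesion_mask = shifted)
  expect_equal(plan1$i, plan0$i + 1L)
  expect_equal(plan1$j, plan0$j)
})

test_that("edge policy targets the centre plus boundary nodes two pitches out for a 10 mm lesion", {
  ph <- sphere_case(lesion_radius = 10, gland_radii = c(26, 24, 20),
                    shape = c(65, 65, 49))
  plan <- edge_policy(ph)
  expect_equal(unname(unlist(plan[1, c("i", "j")])), c(7, 7))
  expect_plan_equal(plan[2:5, ],
                    rbind(c(9, 7), c(5, 7), c(7, 9), c(7, 5)))
  # first node agrees with the centre policy's first node
  cp <- centre_policy(ph)
  expect_equal(unname(unlist(plan[1, c("i", "j")])),
               unname(unlist(cp[1, c("i", "j")])))
})

test_that("edge policy de-duplicates nodes for sub-grid-cell lesions", {
  ph <- sphere_case(lesion_radius = 2, gland_radii = c(24, 20, 20),
                    shape = c(65, 65, 49))
  plan <- edge_policy(ph)
  expect_equal(nrow(plan), 5)
  expect_equal(nrow(unique(plan[, c("i", "j")])), 5)
  # outward-step rule: the four extra nodes are the orthogonal neighbours
  expect_plan_equal(plan[2:5, ],
                    rbind(c(8, 7), c(6, 7), c(7, 8), c(7, 6)))
})

test_that("edge policy spreads needles at least as widely as the centre policy on large lesions", {
  cases <- generate_cohort(10, 1, seed = 21, param_ranges = list(
    shape = c(64, 64, 48),
    gland_radii_mm = rbind(lo = c(20, 18, 18), hi = c(26, 22, 22)),
    lesion_radius_mm = c(7, 10)))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  spread <- function(plan, grid) {
    xy <- grid_node_xy(grid, plan$i, plan$j)
    pop_sd(xy[, 1]) * pop_sd(xy[, 2])
  }
  for (cs in cases) {
    grid <- build_template_grid(cs)
    expect_gte(spread(edge_policy(cs, grid), grid) + 1e-9,
               spread(centre_policy(cs, grid), grid))
  }
})

test_that("plans convert to demo actions that replay to the exact planned nodes", {
  ph <- sphere_case(lesion_radius = 8)
  plan <- centre_policy(ph)
  demos <- plan_to_demos(plan, ph)
  expect_length(demos$observations, nrow(demos$actions))
  # all five needles hit the large central lesion: total reward 50
  res <- run_episode(expert_agent("centre"), ph)
  expect_equal(res$total_reward, 50)
  # an action sequence requiring > 10 node displacement is split
  far_plan <- structure(data.frame(i = c(13L, 1L), j = c(13L, 1L),
                                   depth_label = "apex"),
                        class = c("needle_plan", "data.frame"))
  acts <- plan_to_actions(far_plan, start_node = c(1L, 1L))
  expect_gt(nrow(acts), 2)
  expect_true(all(abs(acts$dx) <= 10 & abs(acts$dy) <= 10))
  # replay: quantization round-trip lands on the planned nodes
  cur <- c(1L, 1L); fired_nodes <- NULL
  grid <- build_template_grid(ph)
  for (r in seq_len(nrow(acts))) {
    q <- quantize_action(as.numeric(acts[r, ]), cur, grid)
    cur <- q$node
    if (q$fired) fired_nodes <- rbind(fired_nodes, cur)
  }
  expect_equal(unname(fired_nodes), unname(as.matrix(far_plan[, c("i", "j")])))
})

test_that("demonstrations must come from a zero-mismatch environment", {
  ph <- sphere_case()
  plan <- centre_policy(ph)
  expect_error(plan_to_demos(plan, ph, env_config(tre = tre_config(5))),
               "zero-mismatch")
})
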