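# Clinically motivated demonstration policies.
#
# The centre strategy samples the five template holes closest to the
# lesion centre; the edge strategy samples the hole at the lesion centre
# followed by four holes at the boundary of the lesion's transverse-plane
# projection along +x, -x, +y, -y — the classical alternatives for
# targeted sampling, the first risking under-grading of heterogeneous
# tumours, the second trading hit rate for spatial coverage.

#' Five-needle plan targeting nodes closest to the lesion centre
#'
#' The five grid nodes with smallest in-plane Euclidean distance to the
#' lesion centroid, ties broken by `(distance, i, j)` lexicographic order.
#' Each needle fires at the depth plane (apex or base) nearer the lesion
#' centroid along the needle axis.
#'
#' @param case a `patient_case`; the lesion of `lesion_mask` (observed
#'   anatomy) may be supplied to plan against what the clinician sees.
#' @param grid a `template_grid`.
#' @param lesion_mask optional `mask_volume` overriding `case$lesion`.
#' @param planes optional named depth planes, defaults to
#'   [depth_planes()] of the case.
#' @param n_needles number of needles (5 standard).
#' @return a `needle_plan`: data.frame with columns `i`, `j`,
#'   `depth_label`.
#' @export
centre_policy <- function(case, grid = build_template_grid(case),
                          lesion_mask = NULL,
                          planes = depth_planes(case), n_needles = 5L) {
  lesion <- lesion_mask %||% case$lesion
  if (mask_count(lesion) == 0L) stop("lesion mask is empty")
  cen <- mask_centroid(lesion)
  nodes <- grid_nodes(grid)
  dist <- sqrt((nodes$x - cen[1])^2 + (nodes$y - cen[2])^2)
  ord <- order(dist, nodes$i, nodes$j)
  sel <- nodes[ord[seq_len(n_needles)], c("i", "j")]
  depth <- if (abs(cen[3] - planes[["apex"]]) <= abs(cen[3] - planes[["base"]]))
    "apex" else "base"
  plan <- data.frame(i = sel$i, j = sel$j, depth_label = depth,
                     stringsAsFactors = FALSE)
  rownames(plan) <- NULL
  structure(plan, class = c("needle_plan", "data.frame"))
}

# Nearest grid node (single) to a world (x, y) point, ties by (dist, i, j).
nearest_node <- function(grid, x, y) {
  nodes <- grid_nodes(grid)
  dist <- sqrt((nodes$x - x)^2 + (nodes$y - y)^2)
  ord <- order(dist, nodes$i, nodes$j)
  c(nodes$i[ord[1]], nodes$j[ord[1]])
}

#' Five-needle plan targeting the lesion centre and its edges
#'
#' Needle 1 targets the node nearest the lesion centroid; needles 2-5
#' target the nodes nearest the four boundary points of the lesion's
#' transverse-plane projection along +x, -x, +y and -y from the centroid.
#' When an edge node duplicates an already-selected node it steps outward
#' (away from the centroid along its axis) to the next unused node.
#'
#' @inheritParams centre_policy
#' @return a `needle_plan`.
#' @export
edge_policy <- function(case, grid = build_template_grid(case),
                        lesion_mask = NULL,
                        planes = depth_planes(case)) {
  lesion <- lesion_mask %||% case$lesion
  if (mask_count(lesion) == 0L) stop("lesion mask is empty")
  cen <- mask_centroid(lesion)
  proj <- apply(lesion$voxels, c(1, 2), max)
  # boundary of the projection along each in-plane axis, through the
  # raster row/column nearest the centroid
  ci <- clamp(round_half_away((cen[1] - lesion$origin[1]) / lesion$spacing[1]) + 1L,
              1L, dim(lesion$voxels)[1])
  cj <- clamp(round_half_away((cen[2] - lesion$origin[2]) / lesion$spacing[2]) + 1L,
              1L, dim(lesion$voxels)[2])
  xs <- which(proj[, cj] > 0)
  ys <- which(proj[ci, ] > 0)
  if (length(xs) == 0L) xs <- ci
  if (length(ys) == 0L) ys <- cj
  wx <- function(i) lesion$origin[1] + (i - 1) * lesion$spacing[1]
  wy <- function(j) lesion$origin[2] + (j - 1) * lesion$spacing[2]
  edge_pts <- list(c(wx(max(xs)), cen[2]),  # +x
                   c(wx(min(xs)), cen[2]),  # -x
                   c(cen[1], wy(max(ys))),  # +y
                   c(cen[1], wy(min(ys))))  # -y
  step_dir <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  sel <- list(nearest_node(grid, cen[1], cen[2]))
  for (k in 1:4) {
    nd <- nearest_node(grid, edge_pts[[k]][1], edge_pts[[k]][2])
    while (any(vapply(sel, function(s) all(s == nd), TRUE))) {
      nd <- c(clamp(nd[1] + step_dir[[k]][1], 1L, grid$n_rows),
              clamp(nd[2] + step_dir[[k]][2], 1L, grid$n_cols))
      if ((step_dir[[k]][1] != 0 && (nd[1] == 1L || nd[1] == grid$n_rows)) ||
          (step_dir[[k]][2] != 0 && (nd[2] == 1L || nd[2] == grid$n_cols))) {
        # ran off the grid edge; accept the clamped node even if duplicate
        if (!any(vapply(sel, function(s) all(s == nd), TRUE))) break
        # step inward instead
        step_dir[[k]] <- -step_dir[[k]]
      }
    }
    sel[[k + 1]] <- nd
  }
  depth <- if (abs(cen[3] - planes[["apex"]]) <= abs(cen[3] - planes[["base"]]))
    "apex" else "base"
  plan <- data.frame(i = vapply(sel, `[`, 1L, 1),
                     j = vapply(sel, `[`, 1L, 2),
                     depth_label = depth, stringsAsFactors = FALSE)
  structure(plan, class = c("needle_plan", "data.frame"))
}

#' Convert a needle plan into environment actions
#'
#' Each planned needle becomes an action encoding the relative grid
#' displacement from the current node plus the firing depth
#' (`dz = 0` apex, `dz = 2/3` base). A displacement beyond 10 nodes (not
#' expressible in one action) is split into a no-fire move followed by a
#' fire step. Quantization round-trips exactly: replaying the actions in
#' a zero-mismatch environment reproduces the plan's nodes.
#'
#' @param plan a `needle_plan`.
#' @param start_node starting node, the grid centre by default.
#' @return data.frame of actions with columns `dx`, `dy`, `dz`.
#' @export
plan_to_actions <- function(plan, start_node = c(7L, 7L)) {
  cur <- as.integer(start_node)
  out <- list()
  for (r in seq_len(nrow(plan))) {
    target <- c(plan$i[r], plan$j[r])
    repeat {
      d <- target - cur
      if (max(abs(d)) > 10L) {
        mv <- clamp(d, -10L, 10L)
        out[[length(out) + 1L]] <- c(dx = mv[1], dy = mv[2], dz = DZ_NO_FIRE)
        cur <- cur + mv
      } else {
        dz <- if (plan$depth_label[r] == "apex") DZ_APEX else DZ_BASE
        out[[length(out) + 1L]] <- c(dx = d[1], dy = d[2], dz = dz)
        cur <- target
        break
      }
    }
  }
  as.data.frame(do.call(rbind, out))
}

#' Roll a needle plan through an environment to build demonstrations
#'
#' Executes the plan in a zero-mismatch environment, recording the
#' (observation, action) pairs an imitation learner trains on.
#'
#' @param plan a `needle_plan`.
#' @param case the `patient_case` the plan was made for.
#' @param config an [env_config()]; must have no mismatch.
#' @param seed episode seed.
#' @return a `demo_dataset`: list with `observations` (list), `actions`
#'   (matrix n x 3), `case_id`, `plan`.
#' @export
plan_to_demos <- function(plan, case, config = env_config(), seed = 1L) {
  if (!is.null(config$tre) && config$tre$level_mm > 0) {
    stop("demonstrations must be generated in a zero-mismatch environment")
  }
  if (!is.null(config$deform)) {
    stop("demonstrations must be generated in a zero-mismatch environment")
  }
  e <- biopsy_env(case, config)
  obs <- env_reset(e, seed)
  actions <- plan_to_actions(plan, start_node = obs$node)
  observations <- vector("list", nrow(actions))
  visited <- matrix(NA_integer_, nrow(actions), 2)
  for (r in seq_len(nrow(actions))) {
    observations[[r]] <- obs
    out <- env_step(e, as.numeric(actions[r, ]))
    visited[r, ] <- out$info[c("i", "j")] |> unlist()
    obs <- out$observation
  }
  fired_nodes <- visited[actions$dz > -1 / 3, , drop = FALSE]
  planned <- as.matrix(plan[, c("i", "j")])
  if (!isTRUE(all.equal(unname(fired_nodes), unname(planned)))) {
    stop("internal error: demo replay did not reproduce the plan")
  }
  structure(list(observations = observations,
                 actions = as.matrix(actions),
                 case_id = case_id(case), plan = plan),
            class = "demo_dataset")
}

#' Combine demonstration datasets from several cases
#' @param demos list of `demo_dataset` objects.
#' @return a single `demo_dataset` with pairs concatenated.
#' @export
merge_demos <- function(demos) {
  structure(list(
    observations = do.call(c, lapply(demos, `[[`, "observations")),
    actions = do.call(rbind, lapply(demos, `[[`, "actions")),
    case_id = vapply(demos, `[[`, "", "case_id"),
    plan = lapply(demos, `[[`, "plan")),
    class = "demo_dataset")
}

#' Policy objects
#'
#' A policy is a list with `reset()` and `act(observation)`; bare
#' functions `observation -> action` are wrapped. Expert agents plan once
#' from the first observation they see (pre-procedure planning from the
#' observed anatomy) and then replay the plan.
#'
#' @param x a function or policy object.
#' @return a policy object.
#' @export
as_policy <- function(x) {
  if (is.list(x) && is.function(x$act)) {
    if (is.null(x$reset)) x$reset <- function() invisible(NULL)
    return(x)
  }
  if (is.function(x)) {
    return(list(reset = function() invisible(NULL), act = x))
  }
  stop("not a policy: need a function(observation) or a list with $act")
}

#' Expert agent replaying a centre or edge plan
#'
#' On the first observation of an episode the agent computes the expert
#' plan from the observed lesion mask (so simulated registration error
#' misleads it, as it would mislead a clinician planning on mis-registered
#' imaging), converts it to actions and replays them; after the plan is
#' exhausted it stops firing.
#'
#' @param kind `"centre"` or `"edge"`.
#' @return a policy object for [run_episode()].
#' @export
expert_agent <- function(kind = c("centre", "edge")) {
  kind <- match.arg(kind)
  state <- new.env(parent = emptyenv())
  state$queue <- NULL
  list(
    reset = function() {
      state$queue <- NULL
      invisible(NULL)
    },
    act = function(obs) {
      if (is.null(state$queue)) {
        plan_fun <- if (kind == "centre") centre_policy else edge_policy
        lesion <- obs$channels$L
        plan <- plan_fun(case = NULL, grid = obs$grid, lesion_mask = lesion,
                         planes = unlist(obs$planes))
        state$queue <- plan_to_actions(plan, start_node = obs$node)
      }
      if (nrow(state$queue) == 0L) {
        return(c(0, 0, DZ_NO_FIRE))
      }
      a <- as.numeric(state$queue[1, ])
      state$queue <- state$queue[-1, , drop = FALSE]
      a
    })
}

#' A policy that never fires and never moves
#' @return a policy object.
#' @export
never_fire_policy <- function() {
  list(reset = function() invisible(NULL),
       act = function(obs) c(0, 0, DZ_NO_FIRE))
}

#' A uniform random policy over the action space
#'
#' Draws `dx`, `dy` uniformly in `(-10, 10)` and `dz` uniformly in
#' `[-1, 1]`; the baseline policy for reinforcement-learning comparisons.
#'
#' @return a policy object.
#' @export
random_policy <- function() {
  list(reset = function() invisible(NULL),
       act = function(obs) c(stats::runif(2, -10, 10), stats::runif(1, -1, 1)))
}
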