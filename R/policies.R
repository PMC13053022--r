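#' Fixate-MAP action rule
#'
#' The resource-rational search rule: terminate (action `0`) when the maximum
#' target posterior exceeds `theta`, otherwise fixate the non-phantom object
#' with maximal posterior (ties broken toward the lowest index).
#'
#' @param p posterior vector over objects.
#' @param theta termination threshold in (0, 1).
#' @param phantom_mask logical phantom flags (phantoms are never fixated).
#' @return an action: object index, or `0` to terminate.
#' @export
fixate_map_action <- function(p, theta,
                              phantom_mask = rep(FALSE, length(p))) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1)
    stop("theta must lie in (0, 1)")
  live <- which(!phantom_mask)
  best <- live[which.max(p[live])]
  if (p[best] > theta) 0L else best
}

#' Fixate-MAP policy
#'
#' @param theta termination threshold; if `NULL`, `params$theta` is used at
#'   decision time.
#' @return a policy function `(belief, scene, params) -> action` for
#'   [run_episode()].
#' @export
fixate_map_policy <- function(theta = NULL) {
  if (!is.null(theta) &&
      (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1))
    stop("theta must lie in (0, 1)")
  function(belief, scene, params) {
    fixate_map_action(belief$p, theta %||% params$theta, belief$phantom_mask)
  }
}

#' Uniform-random baseline policy
#'
#' Fixates a uniformly random non-phantom object, terminating by the same
#' threshold rule as Fixate-MAP.
#'
#' @inheritParams fixate_map_policy
#' @return a policy function.
#' @export
random_policy <- function(theta = NULL) {
  function(belief, scene, params) {
    th <- theta %||% params$theta
    live <- which(!belief$phantom_mask)
    if (max(belief$p[live]) > th) return(0L)
    live[sample.int(length(live), 1L)]
  }
}

#' Omniscient oracle baseline policy
#'
#' Always fixates the true target (an upper bound on information per
#' fixation), terminating by the same threshold rule.
#'
#' @inheritParams fixate_map_policy
#' @return a policy function.
#' @export
greedy_oracle_policy <- function(theta = NULL) {
  function(belief, scene, params) {
    th <- theta %||% params$theta
    live <- which(!belief$phantom_mask)
    if (max(belief$p[live]) > th) return(0L)
    scene$target_index
  }
}

#' Simulate Fixate-MAP (or any policy) over a scene ensemble
#'
#' Runs `reps` episodes per scene with deterministic per-episode child seeds
#' and returns the traces in scene-major order.
#'
#' @param scenes list of `scene` objects.
#' @param policy a policy function.
#' @param params a [meta_mdp_params()].
#' @param reps episodes per scene.
#' @param seed integer base seed.
#' @return list of `episode_trace`, with attributes `scene_index` and `rep`.
#' @export
simulate_policy <- function(scenes, policy, params, reps = 1L, seed = 1L) {
  idx <- expand.grid(rep = seq_len(reps), scene = seq_along(scenes))
  traces <- lapply(seq_len(nrow(idx)), function(i) {
    run_episode(scenes[[idx$scene[i]]], policy, params,
                seed = child_seed(seed, paste0("ep", idx$scene[i], "_", idx$rep[i])))
  })
  attr(traces, "scene_index") <- idx$scene
  attr(traces, "rep") <- idx$rep
  traces
}

#' Logit-spaced threshold grid over (0.5, 0.999)
#'
#' @param grid_size number of grid points.
#' @return numeric vector of thresholds, equally spaced in logit space (so
#'   spacing shrinks near 1).
#' @export
threshold_grid <- function(grid_size = 25L) {
  stopifnot(is_count(grid_size))
  stats::plogis(seq(stats::qlogis(0.5), stats::qlogis(0.999),
                    length.out = grid_size))
}

#' Optimize the termination threshold by grid search
#'
#' Evaluates the mean Fixate-MAP return at each point of a logit-spaced grid
#' over (0.5, 0.999) and returns the argmax. Common random numbers are used
#' across grid points (each grid point replays the same per-episode seeds),
#' which removes simulation noise from the comparison between thresholds.
#'
#' @param scenes non-empty list of `scene` objects.
#' @param params a [meta_mdp_params()]; its `theta` is ignored.
#' @param n_sims total simulated episodes per grid point (cycled over
#'   scenes). The experiment-scale figure is 10000; 1000 is a practical
#'   reduced default.
#' @param grid_size number of grid points (or pass `grid` directly).
#' @param seed integer seed.
#' @param grid optional explicit threshold vector.
#' @return list (class `threshold_opt`) with `theta`, `grid`, `mean_return`,
#'   `n_sims`, `seed`.
#' @export
optimize_threshold <- function(scenes, params, n_sims = 1000L,
                               grid_size = 25L, seed = 1L, grid = NULL) {
  if (length(scenes) == 0L) stop("scene ensemble is empty")
  if (!is_count(n_sims)) stop("n_sims must be a positive integer")
  grid <- grid %||% threshold_grid(grid_size)
  scene_of <- (seq_len(n_sims) - 1L) %% length(scenes) + 1L
  ep_seeds <- vapply(seq_len(n_sims),
                     function(i) child_seed(seed, paste0("opt", i)), integer(1))
  mean_return <- vapply(grid, function(th) {
    pol <- fixate_map_policy(th)
    mean(vapply(seq_len(n_sims), function(i) {
      run_episode(scenes[[scene_of[i]]], pol, params, seed = ep_seeds[i])$return
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(mean_return)
  structure(
    list(theta = grid[best], grid = grid, mean_return = mean_return,
         n_sims = as.integer(n_sims), seed = as.integer(seed)),
    class = "threshold_opt"
  )
}

#' @export
print.threshold_opt <- function(x, ...) {
  cat(sprintf(
    "<threshold_opt> theta* = %.5f (mean return %.4f over %d sims, %d grid points)\n",
    x$theta, max(x$mean_return), x$n_sims, length(x$grid)
  ))
  invisible(x)
}

# Standardize score columns across the table; constant (zero-information)
# columns stay centered at zero rather than blowing up.
standardize_scores <- function(scores) {
  Z <- as.matrix(scores)
  Z <- sweep(Z, 2, colMeans(Z))
  sds <- apply(Z, 2, stats::sd)
  Z[, sds > 0] <- sweep(Z[, sds > 0, drop = FALSE], 2, sds[sds > 0], "/")
  Z
}

# Scene skeletons: which table rows appear, which is the target, and where
# everything sits. Shared across PC counts so that varying the
# representation is a paired comparison on identical scenes.
sample_scene_skeletons <- function(n_rows, n_scenes, n_objects,
                                   cap_half_angle = pi / 3, seed = 1L) {
  if (n_objects > n_rows) stop("n_objects exceeds the table size")
  lapply(seq_len(n_scenes), function(i) {
    with_seed_maybe(child_seed(seed, paste0("fscene", i)), {
      list(rows = sample.int(n_rows, n_objects),
           target = sample.int(n_objects, 1L),
           locations = sample_cap_locations(n_objects, cap_half_angle))
    })
  })
}

scene_from_skeleton <- function(skel, Z, k, object_ids, deadline_s = 8) {
  scene(
    object_ids = object_ids[skel$rows],
    locations = skel$locations,
    features = Z[skel$rows, seq_len(k), drop = FALSE],
    target_index = skel$target,
    deadline_s = deadline_s
  )
}

#' Build a scene ensemble from a feature-score table
#'
#' Each scene samples `n_objects` distinct table rows (features = the first
#' `k` score columns, standardized across the table), a uniformly chosen
#' target, and cap-uniform locations.
#'
#' @param scores numeric score matrix (objects x components).
#' @param k number of leading score columns to use.
#' @param n_scenes,n_objects ensemble shape.
#' @param cap_half_angle,deadline_s scene geometry and deadline.
#' @param seed integer seed.
#' @return list of `scene` objects.
#' @export
scenes_from_scores <- function(scores, k, n_scenes, n_objects,
                               cap_half_angle = pi / 3, deadline_s = 8,
                               seed = 1L) {
  scores <- as.matrix(scores)
  if (k > ncol(scores)) stop("k exceeds the available score columns")
  Z <- standardize_scores(scores)
  ids <- rownames(scores) %||% sprintf("obj%03d", seq_len(nrow(scores)))
  skels <- sample_scene_skeletons(nrow(Z), n_scenes, n_objects,
                                  cap_half_angle, seed)
  lapply(skels, scene_from_skeleton, Z = Z, k = k, object_ids = ids,
         deadline_s = deadline_s)
}

#' Feature-space x principal-components ablation
#'
#' For each requested (feature space, number of PCs) cell: builds a scene
#' ensemble from the first `k` score columns of that space's table, optimizes
#' the termination threshold, then simulates `n_agents` independent
#' Fixate-MAP agents (one episode per scene each) and records the mean and sd
#' of the per-agent mean return and mean fixation count.
#'
#' @param feature_tables named list of score matrices (objects x components),
#'   one per feature space; scores are re-standardized per column before use.
#' @param pcs integer vector of principal-component counts to ablate.
#' @param params a [meta_mdp_params()] (its `theta` is replaced per cell).
#' @param n_agents independent simulated agents per cell (default 20).
#' @param n_scenes scenes per ensemble.
#' @param n_objects objects per scene.
#' @param n_sims_opt episodes for the per-cell threshold optimization.
#' @param grid_size threshold grid size.
#' @param seed integer seed.
#' @return data.frame with columns `space`, `n_pcs`, `theta`, `mean_return`,
#'   `sd_return`, `mean_fixations`, `sd_fixations`, `n_agents`, `seed`.
#' @export
ablate <- function(feature_tables, pcs, params, n_agents = 20L,
                   n_scenes = 20L, n_objects = 16L, n_sims_opt = 200L,
                   grid_size = 15L, seed = 1L) {
  if (is.null(names(feature_tables)) || any(names(feature_tables) == ""))
    stop("feature_tables must be a named list of score matrices")
  cells <- expand.grid(space = names(feature_tables), n_pcs = pcs,
                       stringsAsFactors = FALSE)
  # scene skeletons are shared across PC counts within a space, so varying
  # k is a paired comparison on identical scenes
  skeletons <- lapply(names(feature_tables), function(space) {
    sample_scene_skeletons(nrow(feature_tables[[space]]), n_scenes, n_objects,
                           seed = child_seed(seed, paste0("scenes_", space)))
  })
  names(skeletons) <- names(feature_tables)
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    space <- cells$space[ci]
    k <- cells$n_pcs[ci]
    tab <- feature_tables[[space]]
    if (is.null(tab)) stop("missing feature table for cell (", space, ", ", k, ")")
    if (k > ncol(tab))
      stop("cell (", space, ", ", k, "): table has only ", ncol(tab), " components")
    cell_seed <- child_seed(seed, paste0("cell_", space, "_", k))
    Z <- standardize_scores(tab)
    ids <- rownames(tab) %||% sprintf("obj%03d", seq_len(nrow(tab)))
    scenes <- lapply(skeletons[[space]], scene_from_skeleton, Z = Z, k = k,
                     object_ids = ids)
    opt <- optimize_threshold(scenes, params, n_sims = n_sims_opt,
                              grid_size = grid_size, seed = cell_seed)
    pol <- fixate_map_policy(opt$theta)
    per_agent <- vapply(seq_len(n_agents), function(a) {
      traces <- lapply(seq_along(scenes), function(si) {
        run_episode(scenes[[si]], pol, params,
                    seed = child_seed(cell_seed, paste0("agent", a, "_s", si)))
      })
      c(mean(vapply(traces, `[[`, numeric(1), "return")),
        mean(vapply(traces, `[[`, numeric(1), "n_fixations")))
    }, numeric(2))
    data.frame(
      space = space, n_pcs = k, theta = opt$theta,
      mean_return = mean(per_agent[1, ]), sd_return = stats::sd(per_agent[1, ]),
      mean_fixations = mean(per_agent[2, ]),
      sd_fixations = stats::sd(per_agent[2, ]),
      n_agents = as.integer(n_agents), seed = as.integer(seed)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ablation_result", class(out))
  out
}
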