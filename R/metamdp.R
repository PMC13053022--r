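#' Meta-MDP parameters
#'
#' Free parameters of the belief-MDP. Defaults are the values used to simulate
#' the search experiment: a broad, effectively uninformative Gaussian prior
#' over features (mean jitter sd 0.01, precision 0.01, i.e. prior variance
#' 100), a foveal von Mises-Fisher kernel of scale 3 and sharpness 200, and a
#' per-fixation computation cost of 0.01. The termination threshold `theta`
#' has no package default semantics beyond validation: it is either supplied
#' (the experiment preset is 0.998) or produced by [optimize_threshold()].
#'
#' @param theta termination threshold in (0, 1); search stops when the
#'   maximum target posterior exceeds it.
#' @param cost cost `c` charged per fixation.
#' @param mask_scale foveal kernel scale (peak measurement precision).
#' @param mask_sharpness foveal kernel sharpness `k`: precision decays as
#'   `exp((cos(angle) - 1) * k)` with angular misalignment.
#' @param prior_mean_sd sd of the initial mean-belief jitter.
#' @param prior_precision initial belief precision `J0`.
#' @param fixation_budget maximum number of fixations per episode (emulates
#'   the search deadline; the default 22 is `round(8 s / 0.367 s per fixation)`).
#' @param precision_floor measurement precisions below this are treated as
#'   "no sample" (zero information) rather than drawn with near-infinite
#'   variance.
#' @param charge_terminate if `TRUE`, the terminal action is charged `cost`
#'   like any other computation; by default it is free (MAP fixation rankings
#'   are unaffected either way).
#' @return an object of class `meta_mdp_params`.
#' @export
meta_mdp_params <- function(theta, cost = 0.01, mask_scale = 3,
                            mask_sharpness = 200, prior_mean_sd = 0.01,
                            prior_precision = 0.01, fixation_budget = 22L,
                            precision_floor = 1e-12,
                            charge_terminate = FALSE) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1)
    stop("theta must lie in (0, 1)")
  vals <- c(cost = cost, mask_scale = mask_scale, mask_sharpness = mask_sharpness,
            prior_mean_sd = prior_mean_sd, prior_precision = prior_precision,
            precision_floor = precision_floor)
  if (any(!is.finite(vals)) || any(vals[c("mask_scale", "mask_sharpness",
                                          "prior_mean_sd", "prior_precision")] <= 0))
    stop("kernel and prior parameters must be positive and finite")
  if (cost < 0) stop("cost must be non-negative")
  if (!is_count(fixation_budget)) stop("fixation_budget must be a positive integer")
  structure(
    list(theta = theta, cost = cost, mask_scale = mask_scale,
         mask_sharpness = mask_sharpness, prior_mean_sd = prior_mean_sd,
         prior_precision = prior_precision,
         fixation_budget = as.integer(fixation_budget),
         precision_floor = precision_floor,
         charge_terminate = isTRUE(charge_terminate)),
    class = "meta_mdp_params"
  )
}

#' @export
print.meta_mdp_params <- function(x, ...) {
  cat(sprintf(
    paste0("<meta_mdp_params> theta=%g cost=%g mask scale=%g sharpness=%g ",
           "J0=%g budget=%d\n"),
    x$theta, x$cost, x$mask_scale, x$mask_sharpness, x$prior_precision,
    x$fixation_budget
  ))
  invisible(x)
}

new_belief_state <- function(F, J, f_target, phantom_mask, p = NULL) {
  b <- structure(
    list(F = F, J = J, f_target = f_target, phantom_mask = phantom_mask,
         p = p),
    class = "belief_state"
  )
  if (is.null(p)) b$p <- target_posterior(b)
  b
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf(
    "<belief_state> %d objects x %d features; max p = %.4f (object %d)\n",
    nrow(x$F), ncol(x$F), max(x$p), which.max(x$p)
  ))
  invisible(x)
}

#' Initialize beliefs for a scene
#'
#' Mean beliefs start as i.i.d. `N(0, prior_mean_sd^2)` jitter and every
#' precision equals `prior_precision` (so the initial belief variance is
#' `1 / prior_precision = 100` at the default), an effectively uninformative
#' prior. The target feature vector is copied from the target's row of the
#' true feature matrix, and the target posterior is computed immediately with
#' phantom entries zeroed.
#'
#' @param s a `scene`.
#' @param params a [meta_mdp_params()].
#' @param seed integer seed for the mean-belief jitter, or `NULL`.
#' @return a `belief_state` with fields `F`, `J`, `f_target`, `phantom_mask`,
#'   `p`.
#' @export
init_beliefs <- function(s, params, seed = NULL) {
  validate_scene(s)
  n <- nrow(s$features)
  nf <- ncol(s$features)
  with_seed_maybe(seed, {
    F0 <- matrix(stats::rnorm(n * nf, sd = params$prior_mean_sd), n, nf)
    J0 <- matrix(params$prior_precision, n, nf)
    new_belief_state(F0, J0, s$features[s$target_index, ], s$phantom_mask)
  })
}

#' Foveal attention mask
#'
#' Multiplicative precision profile of a fixation: a von Mises-Fisher kernel
#' `g_o = scale * exp((x_o . mu - 1) * k)` scoring how aligned each object's
#' gaze direction is with the fixated object's direction `mu`. The fixated
#' object receives the full scale; misaligned objects decay exponentially
#' (and may underflow to exactly 0, never NaN).
#'
#' @param locations n x 3 matrix of unit gaze directions.
#' @param fixated_index index of the fixated object.
#' @param params a [meta_mdp_params()].
#' @return numeric vector `g` of per-object measurement precisions.
#' @export
attention_mask <- function(locations, fixated_index, params) {
  locations <- as.matrix(locations)
  norms <- sqrt(rowSums(locations^2))
  if (any(abs(norms - 1) > 1e-9))
    stop("attention_mask requires unit-norm locations")
  mu <- locations[fixated_index, ]
  align <- as.vector(locations %*% mu)
  pmax(0, params$mask_scale * exp((pmin(align, 1) - 1) * params$mask_sharpness))
}

#' Sample a foveated measurement of the latent scene
#'
#' Every object-feature cell is measured independently around its true value
#' with precision `g_o` (constant across features within an object):
#' `X[o, f] ~ N(A[o, f], 1 / g_o)`. Cells whose precision falls below
#' `params$precision_floor` carry no information: they are emitted with
#' `J_meas = 0` and `X = 0`, and the Bayesian update ignores them.
#'
#' @param s a `scene`.
#' @param g per-object precision vector from [attention_mask()].
#' @param params a [meta_mdp_params()].
#' @return a list with matrices `X` and `J_meas` (class `measurement`).
#' @export
sample_measurement <- function(s, g, params) {
  if (any(g < 0)) stop("measurement precisions must be non-negative")
  n <- nrow(s$features)
  nf <- ncol(s$features)
  live <- g >= params$precision_floor
  J_meas <- matrix(ifelse(live, g, 0), n, nf)
  X <- matrix(0, n, nf)
  if (any(live)) {
    sd_live <- 1 / sqrt(g[live])
    k <- sum(live)
    X[live, ] <- s$features[live, , drop = FALSE] +
      matrix(stats::rnorm(k * nf), k, nf) * sd_live
  }
  structure(list(X = X, J_meas = J_meas), class = "measurement")
}

#' Bayesian cue-combination update
#'
#' Conjugate Gaussian update of the belief by a measurement:
#' `F <- (F * J + X * J_meas) / (J + J_meas)` elementwise, and
#' `J <- J + J_meas`. Zero-precision cells leave the belief unchanged. The
#' target posterior is recomputed after the update.
#'
#' @param belief a `belief_state`.
#' @param measurement a `measurement` from [sample_measurement()].
#' @return the updated `belief_state`.
#' @export
update_beliefs <- function(belief, measurement) {
  X <- measurement$X
  Jm <- measurement$J_meas
  if (!all(dim(X) == dim(belief$F)) || !all(dim(Jm) == dim(belief$F)))
    stop("measurement shape does not match the belief")
  if (any(Jm < 0)) stop("measurement precisions must be non-negative")
  Jnew <- belief$J + Jm
  Fnew <- (belief$F * belief$J + X * Jm) / Jnew
  new_belief_state(Fnew, Jnew, belief$f_target, belief$phantom_mask)
}

#' Posterior probability that each object is the target
#'
#' Under the generative assumption that true feature values are mutually
#' independent standard normal, the posterior that object `o` is the target
#' given Gaussian beliefs `(F, J)` is
#' `p_o ∝ exp{ 1/2 * sum_f [ log(1 + J_of) + J_of/(1 + J_of) * F_of^2`
#' ` - J_of * (F_of - f_target_f)^2 ] }`,
#' computed in log space with max-subtraction for stability. Phantom entries
#' are set to exactly 0 and the rest renormalized.
#'
#' @param belief a `belief_state`.
#' @return probability vector over objects, summing to 1 over non-phantoms.
#' @export
target_posterior <- function(belief) {
  F <- belief$F
  J <- belief$J
  ft <- matrix(belief$f_target, nrow(F), ncol(F), byrow = TRUE)
  log_score <- 0.5 * rowSums(log1p(J) + J / (1 + J) * F^2 - J * (F - ft)^2)
  live <- !belief$phantom_mask
  if (!any(live)) stop("target posterior undefined: all objects are phantoms")
  p <- numeric(length(log_score))
  ls <- log_score[live]
  w <- exp(ls - max(ls))
  p[live] <- w / sum(w)
  p
}

#' Advance the meta-MDP by one action
#'
#' A fixation action masks, measures, and updates the belief at cost
#' `-params$cost`. The terminal action `0` ends search: the agent reports the
#' non-phantom object with maximal posterior (ties broken toward the lowest
#' index) and earns reward 1 if the report is the target, 0 otherwise. By
#' default the terminal action itself is free.
#'
#' @param s a `scene`.
#' @param belief current `belief_state`.
#' @param action object index to fixate, or `0` to terminate.
#' @param params a [meta_mdp_params()].
#' @return list `(belief, reward, done, info)`; on termination `info` holds
#'   `report` and `correct`.
#' @export
metamdp_step <- function(s, belief, action, params) {
  n <- nrow(belief$F)
  if (length(action) != 1L || is.na(action) || action != round(action) ||
      action < 0 || action > n)
    stop("action must be an object index in 1..N_o or 0 (terminate)")
  if (action == 0) {
    live <- which(!belief$phantom_mask)
    report <- live[which.max(belief$p[live])]
    correct <- report == s$target_index
    reward <- as.numeric(correct) - if (params$charge_terminate) params$cost else 0
    return(list(belief = belief, reward = reward, done = TRUE,
                info = list(report = report, correct = correct)))
  }
  if (belief$phantom_mask[action])
    stop("cannot fixate a phantom object (index ", action, ")")
  g <- attention_mask(s$locations, action, params)
  m <- sample_measurement(s, g, params)
  list(belief = update_beliefs(belief, m), reward = -params$cost,
       done = FALSE, info = list())
}

#' Run one search episode under a policy
#'
#' Steps the policy from freshly initialized beliefs until it terminates or
#' the fixation budget is exhausted. The budget counts fixations only: the
#' terminal report is instantaneous (a click at the deadline), so the policy
#' is offered one final chance to terminate after its last permitted
#' fixation. An episode whose policy still wants to fixate at that point
#' forfeits: termination reason `"budget"`, no report, final reward 0.
#' Terminal stops record reason `"threshold"` with the reported object.
#' Reproducible under a fixed seed.
#'
#' @param s a `scene`.
#' @param policy a function `(belief, scene, params) -> action` where the
#'   action is an object index or `0` (terminate).
#' @param params a [meta_mdp_params()].
#' @param seed integer seed, or `NULL`.
#' @return an `episode_trace` with fields `fixations`, `posteriors` (one row
#'   per step, after the update), `rewards`, `termination`, `report`,
#'   `reward_final`, `return`, `n_fixations`.
#' @export
run_episode <- function(s, policy, params, seed = NULL) {
  validate_scene(s)
  with_seed_maybe(seed, {
    belief <- init_beliefs(s, params)
    n <- nrow(belief$F)
    budget <- params$fixation_budget
    fixations <- integer(0)
    rewards <- numeric(0)
    posteriors <- matrix(NA_real_, budget, n)
    termination <- "budget"
    report <- NA_integer_
    reward_final <- 0
    for (t in seq_len(budget + 1L)) {
      a <- policy(belief, s, params)
      if (length(a) != 1L || is.na(a) || a < 0 || a > n || a != round(a))
        stop("policy returned an invalid action: ", deparse(a))
      if (a != 0 && t > budget) break  # fixation budget exhausted: forfeit
      out <- metamdp_step(s, belief, a, params)
      if (out$done) {
        termination <- "threshold"
        report <- out$info$report
        reward_final <- as.numeric(out$info$correct)
        rewards <- c(rewards, out$reward)
        break
      }
      belief <- out$belief
      fixations <- c(fixations, as.integer(a))
      rewards <- c(rewards, out$reward)
      posteriors[t, ] <- belief$p
    }
    structure(
      list(
        fixations = fixations,
        posteriors = posteriors[seq_along(fixations), , drop = FALSE],
        rewards = rewards,
        termination = termination,
        report = report,
        reward_final = reward_final,
        return = sum(rewards),
        n_fixations = length(fixations)
      ),
      class = "episode_trace"
    )
  })
}

#' @export
print.episode_trace <- function(x, ...) {
  cat(sprintf(
    "<episode_trace> %d fixations, terminated by %s%s, return %.3f\n",
    x$n_fixations, x$termination,
    if (!is.na(x$report)) sprintf(" (report #%d, R=%g)", x$report, x$reward_final)
    else "",
    x$return
  ))
  invisible(x)
}

#' Write episode traces as JSONL
#'
#' One episode per line: scene id, seed, fixations, per-step rewards,
#' termination reason, report and return. Object indices are written 0-based
#' (the on-disk convention); the terminal report of a timeout is `null`.
#'
#' @param traces list of `episode_trace` objects.
#' @param path output path.
#' @param scene_ids optional character vector of scene identifiers.
#' @param seeds optional integer vector of per-episode seeds.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, scene_ids = NULL, seeds = NULL) {
  lines <- vapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    jsonlite::toJSON(list(
      scene_id = scene_ids[i] %||% NA_character_,
      seed = seeds[i] %||% NA_integer_,
      fixations = tr$fixations - 1L,
      rewards = tr$rewards,
      termination = tr$termination,
      report = if (is.na(tr$report)) NULL else tr$report - 1L,
      reward_final = tr$reward_final,
      return = tr$return
    ), auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read episode traces from JSONL
#'
#' @param path file written by [write_traces()].
#' @return list of `episode_trace` objects (with `scene_id`/`seed` fields).
#' @export
read_traces <- function(path) {
  lapply(readLines(path), function(line) {
    obj <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    structure(
      list(
        scene_id = obj$scene_id,
        seed = obj$seed,
        fixations = as.integer(obj$fixations) + 1L,
        posteriors = NULL,
        rewards = as.numeric(obj$rewards),
        termination = obj$termination,
        report = if (is.null(obj$report)) NA_integer_ else as.integer(obj$report) + 1L,
        reward_final = obj$reward_final,
        return = obj$return,
        n_fixations = length(obj$fixations)
      ),
      class = "episode_trace"
    )
  })
}
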