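#' Rank-ordered policy-state encoding
#'
#' Encodes a belief state for the policy network: objects are reordered by
#' posterior rank (stable sort, ties by index) so that row 1 / action 1
#' always corresponds to the current posterior-argmax object, the same
#' permutation is applied to the action mapping, and 3-D gaze directions are
#' projected to normalized 2-D screen coordinates in `[-1, 1]^2`. Phantom
#' rows keep posterior exactly 0 and sit at the screen center `(0, 0)`.
#'
#' @param belief a `belief_state`.
#' @param s the `scene` (for object locations).
#' @param cap_half_angle half-angle used by the screen projection.
#' @return list (class `policy_state`) with rank-ordered `F`, `J`,
#'   `f_target`, `x` (n x 2 screen coordinates), `p`, `phantom_mask`, and
#'   `perm` (rank -> original object index).
#' @export
encode_state <- function(belief, s, cap_half_angle = pi / 3) {
  perm <- order(-belief$p, seq_along(belief$p))
  x <- project_to_screen(s$locations, cap_half_angle)
  x[s$phantom_mask, ] <- 0
  structure(
    list(F = belief$F[perm, , drop = FALSE],
         J = belief$J[perm, , drop = FALSE],
         f_target = belief$f_target,
         x = x[perm, , drop = FALSE],
         p = belief$p[perm],
         phantom_mask = belief$phantom_mask[perm],
         perm = perm),
    class = "policy_state"
  )
}

#' Map an encoded action back to the raw action space
#'
#' Action `r` in the encoded space fixates the rank-`r` object; action
#' `n + 1` terminates (raw action `0`).
#'
#' @param state a `policy_state` from [encode_state()].
#' @param action encoded action index in `1..(n+1)`.
#' @return the raw action (object index or `0`).
#' @export
decode_action <- function(state, action) {
  n <- length(state$perm)
  if (action < 1L || action > n + 1L) stop("encoded action out of range")
  if (action == n + 1L) 0L else state$perm[action]
}

#' Training configuration for the reduced-scale agent
#'
#' Mirrors the full-scale architecture (each input tensor through one dense
#' layer, concatenated, then 3 dense layers whose width equals the object
#' count) at a size where convergence is demonstrable on one CPU.
#'
#' @param n_objects objects per scene (default 8).
#' @param n_features feature dimensions (default 2).
#' @param episodes total training episodes.
#' @param batch_episodes episodes collected per policy update.
#' @param hidden_width width of the dense layers (default `n_objects`).
#' @param lr initial Adam learning rate.
#' @param lr_decay exponential decay factor applied per 1000 updates.
#' @param clip PPO clipping parameter.
#' @param entropy_coef entropy-bonus coefficient.
#' @param value_coef critic-loss coefficient.
#' @param epochs gradient passes over each collected batch.
#' @param fixation_budget per-episode fixation budget.
#' @param seed integer seed.
#' @return an object of class `training_config`.
#' @export
training_config <- function(n_objects = 8L, n_features = 2L,
                            episodes = 30000L, batch_episodes = 64L,
                            hidden_width = n_objects, lr = 0.003,
                            lr_decay = 0.99, clip = 0.2,
                            entropy_coef = 0.01, value_coef = 0.5,
                            epochs = 4L, fixation_budget = 12L, seed = 1L) {
  stopifnot(is_count(episodes), is_count(batch_episodes), is_count(epochs),
            is_count(n_objects), is_count(n_features),
            is_count(fixation_budget))
  structure(
    list(n_objects = as.integer(n_objects), n_features = as.integer(n_features),
         episodes = as.integer(episodes),
         batch_episodes = as.integer(batch_episodes),
         hidden_width = as.integer(hidden_width), lr = lr, lr_decay = lr_decay,
         clip = clip, entropy_coef = entropy_coef, value_coef = value_coef,
         epochs = as.integer(epochs),
         fixation_budget = as.integer(fixation_budget),
         seed = as.integer(seed)),
    class = "training_config"
  )
}

# Flatten a policy_state into the network input vector. J enters through
# log1p, a monotone reparameterization that keeps accumulated precisions in
# a range the tanh layers resolve.
rl_featurize <- function(es) {
  c(as.vector(es$F), log1p(as.vector(es$J)), es$f_target, as.vector(es$x),
    es$p)
}

rl_block_dims <- function(n, f) c(F = n * f, J = n * f, f_target = f,
                                  x = 2L * n, p = n)

rl_init_weights <- function(cfg) {
  n <- cfg$n_objects
  f <- cfg$n_features
  h <- cfg$hidden_width
  dims <- rl_block_dims(n, f)
  glorot <- function(din, dout) {
    matrix(stats::rnorm(din * dout, sd = sqrt(2 / (din + dout))), din, dout)
  }
  w <- list(
    pre_W = lapply(dims, function(d) glorot(d, h)),
    pre_b = lapply(dims, function(d) numeric(h)),
    W1 = glorot(5L * h, h), b1 = numeric(h),
    W2 = glorot(h, h), b2 = numeric(h),
    W3 = glorot(h, h), b3 = numeric(h),
    Wa = glorot(h, n + 1L) * 0.1, ba = numeric(n + 1L),
    Wv = glorot(h, 1L), bv = 0
  )
  w
}

# Forward pass on a batch of featurized states (rows of S). Returns logits,
# values and the activations needed for backprop.
rl_forward <- function(w, S, dims) {
  B <- nrow(S)
  h <- length(w$b1)
  Z0 <- matrix(0, B, 5L * h)
  off_in <- 0L
  for (k in seq_along(dims)) {
    cols_in <- off_in + seq_len(dims[k])
    Z0[, (k - 1L) * h + seq_len(h)] <-
      S[, cols_in, drop = FALSE] %*% w$pre_W[[k]] +
      matrix(w$pre_b[[k]], B, h, byrow = TRUE)
    off_in <- off_in + dims[k]
  }
  H0 <- tanh(Z0)
  H1 <- tanh(H0 %*% w$W1 + matrix(w$b1, B, h, byrow = TRUE))
  H2 <- tanh(H1 %*% w$W2 + matrix(w$b2, B, h, byrow = TRUE))
  H3 <- tanh(H2 %*% w$W3 + matrix(w$b3, B, h, byrow = TRUE))
  logits <- H3 %*% w$Wa + matrix(w$ba, B, ncol(w$Wa), byrow = TRUE)
  value <- as.vector(H3 %*% w$Wv) + w$bv
  list(logits = logits, value = value,
       cache = list(S = S, H0 = H0, H1 = H1, H2 = H2, H3 = H3))
}

rl_backward <- function(w, cache, dlogits, dvalue, dims) {
  h <- length(w$b1)
  g <- list()
  g$Wa <- t(cache$H3) %*% dlogits
  g$ba <- colSums(dlogits)
  g$Wv <- t(cache$H3) %*% matrix(dvalue, ncol = 1)
  g$bv <- sum(dvalue)
  dH3 <- dlogits %*% t(w$Wa) + outer(dvalue, as.vector(w$Wv))
  dZ3 <- dH3 * (1 - cache$H3^2)
  g$W3 <- t(cache$H2) %*% dZ3; g$b3 <- colSums(dZ3)
  dZ2 <- (dZ3 %*% t(w$W3)) * (1 - cache$H2^2)
  g$W2 <- t(cache$H1) %*% dZ2; g$b2 <- colSums(dZ2)
  dZ1 <- (dZ2 %*% t(w$W2)) * (1 - cache$H1^2)
  g$W1 <- t(cache$H0) %*% dZ1; g$b1 <- colSums(dZ1)
  dZ0 <- (dZ1 %*% t(w$W1)) * (1 - cache$H0^2)
  g$pre_W <- vector("list", length(dims))
  g$pre_b <- vector("list", length(dims))
  off_in <- 0L
  for (k in seq_along(dims)) {
    cols_in <- off_in + seq_len(dims[k])
    blk <- dZ0[, (k - 1L) * h + seq_len(h), drop = FALSE]
    g$pre_W[[k]] <- t(cache$S[, cols_in, drop = FALSE]) %*% blk
    g$pre_b[[k]] <- colSums(blk)
    off_in <- off_in + dims[k]
  }
  g
}

rl_softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Adam on the nested weight list.
rl_adam_init <- function(w) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  list(m = zero_like(w), v = zero_like(w), t = 0L)
}

rl_adam_step <- function(w, g, opt, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  opt$t <- opt$t + 1L
  g <- g[names(w)]
  upd <- function(wk, gk, mk, vk) {
    if (is.list(wk)) {
      out <- Map(upd, wk, gk, mk, vk)
      return(list(w = lapply(out, `[[`, "w"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    mk <- beta1 * mk + (1 - beta1) * gk
    vk <- beta2 * vk + (1 - beta2) * gk^2
    mhat <- mk / (1 - beta1^opt$t)
    vhat <- vk / (1 - beta2^opt$t)
    list(w = wk - lr * mhat / (sqrt(vhat) + eps), m = mk, v = vk)
  }
  out <- Map(upd, w, g, opt$m, opt$v)
  list(w = lapply(out, `[[`, "w"),
       opt = list(m = lapply(out, `[[`, "m"), v = lapply(out, `[[`, "v"),
                  t = opt$t))
}

# Run one episode with the current network, collecting transitions.
rl_rollout_episode <- function(w, s, params, cfg, dims) {
  belief <- init_beliefs(s, params)
  n <- cfg$n_objects
  A <- n + 1L
  states <- matrix(0, cfg$fixation_budget + 1L, sum(dims))
  actions <- integer(0)
  logps <- numeric(0)
  rewards <- numeric(0)
  n_fix <- 0L
  t <- 0L
  repeat {
    t <- t + 1L
    es <- encode_state(belief, s)
    sv <- rl_featurize(es)
    fwd <- rl_forward(w, matrix(sv, 1), dims)
    logits <- fwd$logits[1, ]
    logits[c(es$phantom_mask, FALSE)] <- -1e9
    pr <- exp(logits - max(logits))
    pr <- pr / sum(pr)
    a <- sample.int(A, 1L, prob = pr)
    states[t, ] <- sv
    actions <- c(actions, a)
    logps <- c(logps, log(pr[a]))
    if (a < A && n_fix >= cfg$fixation_budget) {
      # wants another fixation with the budget spent: forfeit (reward 0)
      rewards <- c(rewards, 0)
      break
    }
    raw <- decode_action(es, a)
    out <- metamdp_step(s, belief, raw, params)
    rewards <- c(rewards, out$reward)
    belief <- out$belief
    if (out$done) break
    n_fix <- n_fix + 1L
  }
  list(states = states[seq_len(t), , drop = FALSE], actions = actions,
       logps = logps, rewards = rewards,
       returns = rev(cumsum(rev(rewards))),
       episode_return = sum(rewards))
}

#' Train a reduced-scale actor-critic agent on the meta-MDP
#'
#' Shared preprocessing (each of the five state tensors through its own
#' dense layer, concatenated) feeding a 3-layer tanh trunk with an actor
#' head (softmax over fixation actions plus terminate) and a critic head.
#' Training uses the clipped-surrogate policy-gradient objective with an
#' entropy bonus, undiscounted returns-to-go with the critic as baseline,
#' Adam with exponential learning-rate decay, and is fully seeded.
#'
#' @param config a [training_config()].
#' @param scenes ensemble of `scene` objects matching the config's object
#'   and feature counts.
#' @param params a [meta_mdp_params()] supplying cost, kernel and prior
#'   values (`theta` is unused: the agent learns its own stopping rule).
#' @return list (class `trained_agent`) with `weights`, `config`, and
#'   `curve` (a data.frame of per-update mean episode returns).
#' @export
train_agent <- function(config, scenes, params) {
  stopifnot(inherits(config, "training_config"))
  if (length(scenes) == 0L) stop("scene ensemble is empty")
  for (s in scenes) {
    if (nrow(s$features) != config$n_objects ||
        ncol(s$features) != config$n_features)
      stop("scene dimensions do not match the training config")
  }
  params <- meta_mdp_params(
    theta = 0.5, cost = params$cost, mask_scale = params$mask_scale,
    mask_sharpness = params$mask_sharpness,
    prior_mean_sd = params$prior_mean_sd,
    prior_precision = params$prior_precision,
    fixation_budget = config$fixation_budget,
    precision_floor = params$precision_floor
  )
  dims <- rl_block_dims(config$n_objects, config$n_features)
  withr::with_seed(config$seed, {
    w <- rl_init_weights(config)
    opt <- rl_adam_init(w)
    n_updates <- ceiling(config$episodes / config$batch_episodes)
    curve <- data.frame(update = integer(n_updates),
                        episodes = integer(n_updates),
                        mean_return = numeric(n_updates))
    ep_total <- 0L
    for (it in seq_len(n_updates)) {
      rolls <- lapply(seq_len(config$batch_episodes), function(e) {
        rl_rollout_episode(w, scenes[[sample.int(length(scenes), 1L)]],
                           params, config, dims)
      })
      ep_total <- ep_total + config$batch_episodes
      S <- do.call(rbind, lapply(rolls, `[[`, "states"))
      act <- unlist(lapply(rolls, `[[`, "actions"))
      logp_old <- unlist(lapply(rolls, `[[`, "logps"))
      G <- unlist(lapply(rolls, `[[`, "returns"))
      B <- nrow(S)
      Aidx <- cbind(seq_len(B), act)
      base <- rl_forward(w, S, dims)$value
      adv <- G - base
      adv <- (adv - mean(adv)) / (stats::sd(adv) + 1e-8)
      lr <- config$lr * config$lr_decay^(it / 1000)
      for (ep in seq_len(config$epochs)) {
        fwd <- rl_forward(w, S, dims)
        if (any(!is.finite(fwd$logits)))
          stop("training diverged: non-finite logits at update ", it)
        pr <- rl_softmax(fwd$logits)
        logp <- log(pmax(pr[Aidx], 1e-12))
        ratio <- exp(logp - logp_old)
        flow <- ifelse(adv >= 0, ratio < 1 + config$clip,
                       ratio > 1 - config$clip)
        coef <- ifelse(flow, adv * ratio, 0) / B
        dlogits <- -coef * (-pr)
        dlogits[Aidx] <- dlogits[Aidx] - coef
        logpr <- log(pmax(pr, 1e-12))
        ent <- -rowSums(pr * logpr)
        dlogits <- dlogits + config$entropy_coef / B * pr * (logpr + ent)
        dvalue <- config$value_coef * 2 * (fwd$value - G) / B
        g <- rl_backward(w, fwd$cache, dlogits, dvalue, dims)
        step <- rl_adam_step(w, g, opt, lr)
        w <- step$w
        opt <- step$opt
      }
      curve$update[it] <- it
      curve$episodes[it] <- ep_total
      curve$mean_return[it] <- mean(vapply(rolls, `[[`, numeric(1),
                                           "episode_return"))
    }
    structure(list(weights = w, config = config, curve = curve,
                   params = params),
              class = "trained_agent")
  })
}

#' @export
print.trained_agent <- function(x, ...) {
  k <- nrow(x$curve)
  tail_mean <- mean(utils::tail(x$curve$mean_return, max(1L, k %/% 10L)))
  cat(sprintf(
    "<trained_agent> %d objects x %d features; %d episodes; final mean return %.3f\n",
    x$config$n_objects, x$config$n_features, max(x$curve$episodes), tail_mean))
  invisible(x)
}

#' Turn a trained agent into an episode policy
#'
#' @param agent a `trained_agent`.
#' @param greedy if `TRUE` (default) take the argmax action, otherwise sample
#'   from the action distribution.
#' @return a policy function `(belief, scene, params) -> action` usable with
#'   [run_episode()].
#' @export
agent_policy <- function(agent, greedy = TRUE) {
  dims <- rl_block_dims(agent$config$n_objects, agent$config$n_features)
  function(belief, scene, params) {
    es <- encode_state(belief, scene)
    fwd <- rl_forward(agent$weights, matrix(rl_featurize(es), 1), dims)
    logits <- fwd$logits[1, ]
    logits[c(es$phantom_mask, FALSE)] <- -1e9
    a <- if (greedy) which.max(logits) else {
      pr <- exp(logits - max(logits))
      sample.int(length(logits), 1L, prob = pr / sum(pr))
    }
    decode_action(es, a)
  }
}

#' Save / load a trained agent as JSON
#'
#' Portable text serialization of the weights together with the config and
#' learning curve.
#'
#' @param agent a `trained_agent`.
#' @param path file path.
#' @return `path` (save) or the restored `trained_agent` (load).
#' @export
save_agent <- function(agent, path) {
  jsonlite::write_json(
    list(config = unclass(agent$config), curve = agent$curve,
         weights = agent$weights),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_agent
#' @export
load_agent <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(training_config, obj$config)
  h <- cfg$hidden_width
  dims <- rl_block_dims(cfg$n_objects, cfg$n_features)
  as_mat <- function(x, nr, nc) {
    if (is.matrix(x)) {
      storage.mode(x) <- "double"
      return(x)
    }
    matrix(as.numeric(unlist(x)), nr, nc, byrow = TRUE)
  }
  w <- obj$weights
  w$pre_W <- lapply(seq_along(dims), function(k) as_mat(w$pre_W[[k]], dims[k], h))
  w$pre_b <- lapply(w$pre_b, as.numeric)
  w$W1 <- as_mat(w$W1, 5L * h, h); w$W2 <- as_mat(w$W2, h, h)
  w$W3 <- as_mat(w$W3, h, h)
  w$Wa <- as_mat(w$Wa, h, cfg$n_objects + 1L)
  w$Wv <- as_mat(w$Wv, h, 1L)
  w$b1 <- as.numeric(w$b1); w$b2 <- as.numeric(w$b2); w$b3 <- as.numeric(w$b3)
  w$ba <- as.numeric(w$ba); w$bv <- as.numeric(w$bv)
  structure(list(weights = w, config = cfg, curve = as.data.frame(obj$curve)),
            class = "trained_agent")
}

#' Behavioral diagnostics of a search policy
#'
#' Runs seeded episodes and summarizes (1) the probability of terminating as
#' a function of the number of fixations already taken, (2) the frequency of
#' the chosen action's posterior rank at each timepoint (rank 1 = the MAP
#' object), and (3) the agreement with Fixate-MAP: the fraction of
#' non-terminal decisions whose chosen action is the rank-1 (MAP) object.
#'
#' @param policy a policy function or a `trained_agent`.
#' @param scenes scene ensemble.
#' @param params a [meta_mdp_params()].
#' @param n_episodes number of episodes.
#' @param seed integer seed.
#' @param greedy for a `trained_agent`, use the argmax action.
#' @return list (class `policy_diagnostics`) with `termination_prob`,
#'   `rank_freq` (timepoint x rank, row-normalized), `agreement`,
#'   `mean_return`, `sd_return`.
#' @export
policy_diagnostics <- function(policy, scenes, params, n_episodes = 200L,
                               seed = 1L, greedy = TRUE) {
  if (inherits(policy, "trained_agent")) policy <- agent_policy(policy, greedy)
  budget <- params$fixation_budget
  n_max <- max(vapply(scenes, function(s) nrow(s$features), integer(1)))
  reached <- numeric(budget + 1L)
  terminated <- numeric(budget + 1L)
  rank_counts <- matrix(0, budget + 1L, n_max)
  n_fix_decisions <- 0
  n_map_decisions <- 0
  returns <- numeric(n_episodes)
  for (e in seq_len(n_episodes)) {
    s <- scenes[[(e - 1L) %% length(scenes) + 1L]]
    ep_seed <- child_seed(seed, paste0("diag", e))
    returns[e] <- withr::with_seed(ep_seed, {
      belief <- init_beliefs(s, params)
      total <- 0
      t <- 0L
      repeat {
        reached[t + 1L] <- reached[t + 1L] + 1
        a <- policy(belief, s, params)
        if (a == 0L) {
          terminated[t + 1L] <- terminated[t + 1L] + 1
          out <- metamdp_step(s, belief, 0L, params)
          total <- total + out$reward
          break
        }
        rk <- which(order(-belief$p, seq_along(belief$p)) == a)
        rank_counts[t + 1L, rk] <- rank_counts[t + 1L, rk] + 1
        n_fix_decisions <- n_fix_decisions + 1
        if (rk == 1L) n_map_decisions <- n_map_decisions + 1
        if (t >= budget) break  # budget spent: forfeit
        out <- metamdp_step(s, belief, a, params)
        belief <- out$belief
        total <- total + out$reward
        t <- t + 1L
      }
      total
    })
  }
  rf <- rank_counts
  rs <- rowSums(rf)
  rf[rs > 0, ] <- rf[rs > 0, , drop = FALSE] / rs[rs > 0]
  structure(
    list(termination_prob = ifelse(reached > 0, terminated / reached,
                                   NA_real_),
         rank_freq = rf,
         agreement = if (n_fix_decisions > 0) n_map_decisions / n_fix_decisions
         else NA_real_,
         mean_return = mean(returns), sd_return = stats::sd(returns)),
    class = "policy_diagnostics"
  )
}
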