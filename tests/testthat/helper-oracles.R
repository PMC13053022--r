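# Independent oracles used to check the analytic implementations.

# Generative target posterior by numerical quadrature: for each object,
# p(data | A_o = f_target) / integral p(data | a) N(a; 0, 1) da, where the
# accumulated evidence for a cell is summarized by the Gaussian likelihood
# exp(-J/2 (a - F)^2). Built independently of target_posterior().
quad_target_posterior <- function(F, J, f_target,
                                  phantom_mask = rep(FALSE, nrow(F))) {
  n <- nrow(F)
  nf <- ncol(F)
  score <- numeric(n)
  for (o in seq_len(n)) {
    val <- 1
    for (f in seq_len(nf)) {
      lik <- function(a) exp(-J[o, f] / 2 * (a - F[o, f])^2)
      num <- lik(f_target[f])
      den <- stats::integrate(function(a) lik(a) * stats::dnorm(a),
                              -Inf, Inf, rel.tol = 1e-12)$value
      val <- val * num / den
    }
    score[o] <- val
  }
  score[phantom_mask] <- 0
  score / sum(score)
}

# Closed-form conjugate combination of a set of measurements (precision sum,
# precision-weighted mean), used against sequential update_beliefs().
merge_measurements <- function(F0, J0, Xs, Js) {
  Jsum <- Reduce(`+`, Js)
  num <- F0 * J0
  for (i in seq_along(Xs)) num <- num + Xs[[i]] * Js[[i]]
  list(F = num / (J0 + Jsum), J = J0 + Jsum)
}

# Monte-Carlo value of an open-loop fixation-sequence policy on a fixed
# scene: the fixation ORDER is predetermined, while stopping follows the
# same rule as Fixate-MAP (report the posterior argmax once max p exceeds
# theta; forfeit if the sequence ends without crossing). Beliefs evolve by
# closed-form conjugate combination, vectorized over replicates --
# independent of run_episode()/metamdp_step()/update_beliefs().
open_loop_value <- function(s, fix_seq, params, n_rep, seed) {
  n <- nrow(s$features)
  stopifnot(ncol(s$features) == 1L)
  A <- s$features[, 1]
  ft <- A[s$target_index]
  withr::with_seed(seed, {
    Fm <- matrix(stats::rnorm(n_rep * n, sd = params$prior_mean_sd), n_rep, n)
    Jm <- matrix(params$prior_precision, n_rep, n)
    active <- rep(TRUE, n_rep)
    ret <- rep(-params$cost * length(fix_seq), n_rep)  # forfeit outcome
    for (t in seq_along(fix_seq)) {
      g <- attention_mask(s$locations, fix_seq[t], params)
      gl <- ifelse(g >= params$precision_floor, g, 0)
      X <- matrix(A, n_rep, n, byrow = TRUE)
      if (any(gl > 0)) {
        noise <- matrix(stats::rnorm(n_rep * sum(gl > 0)), n_rep)
        X[, gl > 0] <- X[, gl > 0, drop = FALSE] +
          sweep(noise, 2, 1 / sqrt(gl[gl > 0]), "*")
      }
      G <- matrix(gl, n_rep, n, byrow = TRUE)
      Fm <- (Fm * Jm + X * G) / (Jm + G)
      Jm <- Jm + G
      logsc <- 0.5 * (log1p(Jm) + Jm / (1 + Jm) * Fm^2 - Jm * (Fm - ft)^2)
      m <- apply(logsc, 1, max)
      w <- exp(logsc - m)
      pm <- 1 / rowSums(w)  # max-posterior probability per replicate
      amax <- max.col(logsc, ties.method = "first")
      stop_now <- active & (pm > params$theta)
      if (any(stop_now))
        ret[stop_now] <- as.numeric(amax[stop_now] == s$target_index) -
          params$cost * t
      active <- active & !stop_now
    }
    list(mean = mean(ret), se = stats::sd(ret) / sqrt(n_rep))
  })
}

# All open-loop fixation sequences of length 1..budget over n objects.
enumerate_open_loop <- function(n, budget) {
  out <- list()
  for (L in seq_len(budget)) {
    grids <- do.call(expand.grid, rep(list(seq_len(n)), L))
    out <- c(out, lapply(seq_len(nrow(grids)), function(i)
      as.integer(grids[i, ])))
  }
  out
}
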