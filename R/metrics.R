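#' Relative looking-time distribution
#'
#' The proportion of fixation samples each object received in a scene.
#' Model traces and recorded fixation streams share this code path: the
#' input is either a list of `episode_trace` objects (their fixation
#' sequences are pooled) or an integer vector of fixated object indices.
#'
#' @param fixations list of `episode_trace` objects, or an integer vector of
#'   1-based object indices.
#' @param n_objects number of objects in the scene.
#' @return probability vector of length `n_objects` summing to 1.
#' @export
looking_time_distribution <- function(fixations, n_objects) {
  if (is.list(fixations))
    fixations <- unlist(lapply(fixations, `[[`, "fixations"))
  fixations <- as.integer(fixations)
  if (length(fixations) == 0L)
    stop("fixation records are empty: looking times are undefined")
  if (any(fixations < 1L | fixations > n_objects))
    stop("fixation indices outside 1..n_objects")
  counts <- tabulate(fixations, nbins = n_objects)
  counts / sum(counts)
}

#' Cross-entropy between model and empirical looking times
#'
#' The model distribution is lapse-smoothed as
#' `(1 - epsilon) * p + epsilon * uniform` before computing
#' `CE = -sum(q * log p_smoothed)` against the empirical distribution `q`.
#' Any positive lapse keeps the score finite when the model assigns zero
#' probability to an object the data support.
#'
#' @param model_dist model probability vector.
#' @param empirical_dist empirical probability vector (same objects).
#' @param epsilon lapse rate in `[0, 1]`.
#' @return the cross-entropy (nats).
#' @export
cross_entropy_score <- function(model_dist, empirical_dist, epsilon = 0) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 || epsilon > 1)
    stop("epsilon must lie in [0, 1]")
  if (length(model_dist) != length(empirical_dist))
    stop("distributions must cover the same objects")
  n <- length(model_dist)
  p <- (1 - epsilon) * model_dist + epsilon / n
  terms <- ifelse(empirical_dist > 0, -empirical_dist * log(p), 0)
  sum(terms)
}

#' Cross-entropy improvement over the uniform baseline
#'
#' `CE_uniform - CE_model`, where the baseline assumes uniform relative
#' looking times across the scene's objects. The higher the difference, the
#' better the model matches which objects were fixated.
#'
#' @inheritParams cross_entropy_score
#' @return `CE(uniform) - CE(model)`.
#' @export
baseline_difference <- function(model_dist, empirical_dist, epsilon = 0) {
  n <- length(model_dist)
  ce_unif <- cross_entropy_score(rep(1 / n, n), empirical_dist, 0)
  ce_unif - cross_entropy_score(model_dist, empirical_dist, epsilon)
}

#' Fit a lapse rate by 1-D minimization of summed cross-entropy
#'
#' Minimizes the total cross-entropy over the scenes of one participant with
#' respect to the lapse `epsilon` in `[0, 1]` (golden-section search via
#' [stats::optimize()], refined against the endpoints).
#'
#' @param model_dists list of model probability vectors (one per scene).
#' @param empirical_dists list of matching empirical probability vectors.
#' @return the fitted lapse rate.
#' @export
fit_lapse_rate <- function(model_dists, empirical_dists) {
  if (length(model_dists) == 0L || length(model_dists) != length(empirical_dists))
    stop("need matching, non-empty lists of model and empirical distributions")
  total_ce <- function(eps) {
    sum(vapply(seq_along(model_dists), function(i)
      cross_entropy_score(model_dists[[i]], empirical_dists[[i]], eps),
      numeric(1)))
  }
  opt <- stats::optimize(total_ce, interval = c(0, 1), tol = 1e-6)
  cands <- c(0, opt$minimum, 1)
  cands[which.min(vapply(cands, total_ce, numeric(1)))]
}

#' Fixation transition matrix of a scene
#'
#' Counts consecutive fixation pairs within each trace (self-transitions
#' included by default), row-normalizes each trace's count matrix, and
#' averages the per-trace matrices. Traces with fewer than two fixations do
#' not contribute.
#'
#' @param traces list of `episode_trace` objects or of integer fixation
#'   vectors.
#' @param n_objects number of objects in the scene.
#' @param count_self include self-transitions (a model agent may refixate
#'   the MAP object; dwell-encoded human streams may warrant dropping them).
#' @return list (class `transition_matrix`) with `P` (n x n row-stochastic
#'   on rows with outgoing transitions, zero rows otherwise) and `n_traces`.
#' @export
transition_matrix <- function(traces, n_objects, count_self = TRUE) {
  seqs <- lapply(traces, function(tr)
    if (inherits(tr, "episode_trace")) tr$fixations else as.integer(tr))
  seqs <- Filter(function(x) length(x) >= 2L, seqs)
  mats <- lapply(seqs, function(fx) {
    from <- fx[-length(fx)]
    to <- fx[-1]
    if (!count_self) {
      keep <- from != to
      from <- from[keep]; to <- to[keep]
    }
    M <- matrix(0, n_objects, n_objects)
    for (i in seq_along(from)) M[from[i], to[i]] <- M[from[i], to[i]] + 1
    rs <- rowSums(M)
    M[rs > 0, ] <- M[rs > 0, , drop = FALSE] / rs[rs > 0]
    M
  })
  if (length(mats) == 0L)
    stop("no usable trace: transition matrices need at least two fixations")
  structure(list(P = Reduce(`+`, mats) / length(mats),
                 n_traces = length(mats)),
            class = "transition_matrix")
}

# Object-by-object distance matrix from a transition matrix: entry (i, j) is
# the Euclidean distance between the transition profiles of objects i and j
# (row, or row concatenated with the matching column).
transition_distance_matrix <- function(tm, profile = c("row_column", "row")) {
  profile <- match.arg(profile)
  P <- if (inherits(tm, "transition_matrix")) tm$P else as.matrix(tm)
  prof <- if (profile == "row_column") cbind(P, t(P)) else P
  as.matrix(stats::dist(prof))
}

#' Mantel comparison of simulated and empirical transition structure
#'
#' Converts each transition matrix into an object-by-object distance matrix
#' (Euclidean distance between transition profiles), then tests the
#' association of the two distance matrices: the Mantel `r` is the Pearson
#' correlation of their off-diagonal upper triangles, and the one-sided `p`
#' comes from permuting the object labels of one matrix,
#' `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`.
#'
#' @param simulated a `transition_matrix` (or plain matrix) from the model.
#' @param empirical the matching empirical `transition_matrix`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed, or `NULL`.
#' @param profile transition-profile strategy: `"row_column"` (in- and
#'   out-transitions, the default) or `"row"` (out-transitions only).
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_compare <- function(simulated, empirical, n_perm = 999L, seed = NULL,
                           profile = c("row_column", "row")) {
  profile <- match.arg(profile)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  D1 <- transition_distance_matrix(simulated, profile)
  D2 <- transition_distance_matrix(empirical, profile)
  if (!all(dim(D1) == dim(D2)))
    stop("transition matrices must cover the same object set")
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  if (stats::sd(v1) == 0 || stats::sd(D2[ut]) == 0)
    stop("constant distance matrix: the Mantel correlation is undefined")
  r_obs <- stats::cor(v1, D2[ut])
  n <- nrow(D1)
  with_seed_maybe(seed, {
    r_perm <- vapply(seq_len(n_perm), function(i) {
      pm <- sample.int(n)
      stats::cor(v1, D2[pm, pm][ut])
    }, numeric(1))
    list(r = r_obs, p = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
         n_perm = as.integer(n_perm))
  })
}

#' Seconds-per-fixation constant and reaction-time mapping
#'
#' The model's fixation counts map linearly to reaction times through
#' `tau = m / f`, the ratio of the empirical mean RT to the model's mean
#' fixation count; a trial's RT is then `tau * n_fixations`.
#'
#' @param mean_rt_s empirical mean reaction time in seconds.
#' @param mean_fixations model mean fixation count.
#' @return `tau` in seconds per fixation.
#' @export
fit_tau <- function(mean_rt_s, mean_fixations) {
  if (!is.numeric(mean_rt_s) || mean_rt_s <= 0 ||
      !is.numeric(mean_fixations) || mean_fixations <= 0)
    stop("fit_tau requires positive mean RT and mean fixation count")
  mean_rt_s / mean_fixations
}

#' @rdname fit_tau
#' @param n_fix fixation count(s).
#' @param tau seconds per fixation.
#' @export
rt_from_fixations <- function(n_fix, tau) {
  if (any(n_fix < 0) || tau <= 0)
    stop("rt_from_fixations requires non-negative counts and positive tau")
  tau * n_fix
}

#' Performance breakdown of simulated searches
#'
#' Splits traces into correct reports, wrong-target reports, and timeouts,
#' and maps fixation counts to reaction-time quantiles via
#' [rt_from_fixations()].
#'
#' @param traces list of `episode_trace` objects.
#' @param tau seconds per fixation for the RT mapping.
#' @param probs RT quantile probabilities.
#' @return list with `fractions` (correct / wrong_target / timeout, summing
#'   to 1), `rt_quantiles_s` (over correct trials), `mean_fixations`,
#'   `mean_return`.
#' @export
performance_summary <- function(traces, tau = NULL,
                                probs = c(0.25, 0.5, 0.75)) {
  if (length(traces) == 0L) stop("no traces supplied")
  term <- vapply(traces, `[[`, character(1), "termination")
  rfin <- vapply(traces, `[[`, numeric(1), "reward_final")
  nfix <- vapply(traces, `[[`, numeric(1), "n_fixations")
  correct <- term == "threshold" & rfin == 1
  wrong <- term == "threshold" & rfin == 0
  timeout <- term == "budget"
  fractions <- c(correct = mean(correct), wrong_target = mean(wrong),
                 timeout = mean(timeout))
  rt_q <- if (!is.null(tau) && any(correct)) {
    stats::quantile(rt_from_fixations(nfix[correct], tau), probs = probs,
                    names = TRUE)
  } else NULL
  list(fractions = fractions, rt_quantiles_s = rt_q,
       mean_fixations = mean(nfix),
       mean_return = mean(vapply(traces, `[[`, numeric(1), "return")))
}

#' Read recorded fixation streams
#'
#' Accepts CSV or JSONL with fields `participant_id`, `scene_id`, `ordinal`,
#' `object_id` (0-based object indices on disk).
#'
#' @param path file path (`.csv` or `.jsonl`).
#' @return data.frame ordered by participant, scene, ordinal, with a 1-based
#'   `object` column.
#' @export
read_fixation_records <- function(path) {
  df <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    do.call(rbind, lapply(readLines(path), function(l)
      as.data.frame(jsonlite::fromJSON(l, simplifyVector = TRUE))))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("participant_id", "scene_id", "ordinal", "object_id")
  if (!all(need %in% names(df)))
    stop("fixation records need columns: ", paste(need, collapse = ", "))
  df <- df[order(df$participant_id, df$scene_id, df$ordinal), ]
  df$object <- as.integer(df$object_id) + 1L
  df
}
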