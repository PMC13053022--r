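#' Latent search scenes
#'
#' A scene is the latent environment the searcher faces: a set of labelled
#' objects at gaze-direction locations on the viewing sphere, a true feature
#' matrix `A` (objects x features), the index of the unique target, and a
#' search deadline. Phantom objects are zero-feature placeholder rows used to
#' pad every scene to a common maximum object count; they sit at the canonical
#' screen-center direction and can never be the target.
#'
#' @param object_ids character vector of object labels.
#' @param locations numeric matrix, one row per object, of 3-D unit
#'   gaze-direction vectors. Phantom rows must equal the screen-center
#'   direction `c(0, 0, 1)`.
#' @param features numeric matrix `A` of true feature values
#'   (objects x features). Phantom rows must be exactly zero.
#' @param target_index 1-based index of the target object.
#' @param phantom_mask logical vector flagging phantom rows.
#' @param deadline_s positive search deadline in seconds.
#' @return an object of class `scene`.
#' @export
scene <- function(object_ids, locations, features, target_index,
                  phantom_mask = rep(FALSE, length(object_ids)),
                  deadline_s = 8) {
  locations <- as.matrix(locations)
  features <- as.matrix(features)
  dimnames(locations) <- NULL
  dimnames(features) <- NULL
  s <- structure(
    list(
      object_ids = as.character(object_ids),
      locations = locations,
      features = features,
      target_index = as.integer(target_index),
      phantom_mask = as.logical(phantom_mask),
      deadline_s = as.numeric(deadline_s)
    ),
    class = "scene"
  )
  validate_scene(s)
}

# Canonical screen-center gaze direction (the cap's central axis).
screen_center_direction <- function() c(0, 0, 1)

#' Validate a scene's invariants
#'
#' Checks unit-norm locations, the single non-phantom target, zero features
#' and screen-center locations on phantom rows, and shape consistency.
#'
#' @param s a `scene`.
#' @param max_objects optional upper bound on the object count.
#' @return `s`, invisibly valid.
#' @export
validate_scene <- function(s, max_objects = NULL) {
  n <- length(s$object_ids)
  if (n < 1L) stop("scene must contain at least one object")
  if (!is.matrix(s$locations) || nrow(s$locations) != n || ncol(s$locations) != 3L)
    stop("locations must be an n x 3 matrix aligned with object_ids")
  if (!is.matrix(s$features) || nrow(s$features) != n)
    stop("features must have one row per object")
  if (any(!is.finite(s$features))) stop("features must be finite")
  if (length(s$phantom_mask) != n) stop("phantom_mask must have one entry per object")
  if (length(s$target_index) != 1L || is.na(s$target_index) ||
      s$target_index < 1L || s$target_index > n)
    stop("target_index out of range: scenes have exactly one target in 1..N_o")
  if (s$phantom_mask[s$target_index]) stop("the target must not be a phantom object")
  norms <- sqrt(rowSums(s$locations^2))
  if (any(abs(norms[!s$phantom_mask] - 1) > 1e-9))
    stop("non-phantom locations must be unit vectors (|norm - 1| <= 1e-9)")
  if (any(s$phantom_mask)) {
    ctr <- screen_center_direction()
    ph <- which(s$phantom_mask)
    if (any(abs(s$locations[ph, , drop = FALSE] -
                matrix(ctr, length(ph), 3, byrow = TRUE)) > 1e-9))
      stop("phantom locations must be the canonical screen-center direction")
    if (any(s$features[ph, , drop = FALSE] != 0))
      stop("phantom feature rows must be exactly zero")
  }
  if (!is.null(max_objects) && n > max_objects)
    stop("scene has more objects than the configured maximum (", max_objects, ")")
  if (!is.numeric(s$deadline_s) || s$deadline_s <= 0)
    stop("deadline_s must be a positive number of seconds")
  invisible(s)
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(
    "<scene> %d objects (%d phantom), %d features, target '%s' (#%d), deadline %.1f s\n",
    length(x$object_ids), sum(x$phantom_mask), ncol(x$features),
    x$object_ids[x$target_index], x$target_index, x$deadline_s
  ))
  invisible(x)
}

#' Scene generator configuration
#'
#' The generator emulates the statistical structure the belief model assumes:
#' true features i.i.d. standard normal across non-phantom objects, locations
#' uniform in a spherical cap of the viewing sphere (a head-fixed field of
#' regard), one unique target among 55--112 distractors, and an 8-second
#' deadline. `distractor_similarity` mixes distractor feature rows toward the
#' target row (then rescales so marginal variance stays 1), making the target
#' harder to discriminate.
#'
#' @param n_objects integer range `c(min, max)` of total objects
#'   (target included), or a single count.
#' @param n_features number of latent feature dimensions.
#' @param distractor_similarity mixing weight in `[0, 1)`.
#' @param cap_half_angle half-angle (radians) of the spherical cap the
#'   locations are drawn from; default 60 degrees.
#' @param deadline_s search deadline in seconds.
#' @param max_objects maximum object count scenes may be padded to.
#' @param allow_single allow degenerate single-object scenes (target only).
#' @return an object of class `scene_generator_config`.
#' @export
scene_generator_config <- function(n_objects = c(56L, 113L), n_features = 6L,
                                   distractor_similarity = 0,
                                   cap_half_angle = pi / 3,
                                   deadline_s = 8, max_objects = 113L,
                                   allow_single = FALSE) {
  if (length(n_objects) == 1L) n_objects <- rep(n_objects, 2L)
  n_objects <- as.integer(n_objects)
  if (length(n_objects) != 2L || any(is.na(n_objects)) || n_objects[1] > n_objects[2])
    stop("n_objects must be a non-empty integer range c(min, max)")
  if (n_objects[1] < 2L && !allow_single)
    stop("n_objects < 2: search is undefined with a lone target ",
         "(set allow_single = TRUE to permit it)")
  if (n_objects[1] < 1L) stop("n_objects must be >= 1")
  if (!is_count(n_features)) stop("n_features must be a positive integer")
  if (!is.numeric(distractor_similarity) || distractor_similarity < 0 ||
      distractor_similarity >= 1)
    stop("distractor_similarity must lie in [0, 1): distractors are never ",
         "identical to the target")
  if (cap_half_angle <= 0 || cap_half_angle > pi)
    stop("cap_half_angle must be in (0, pi]")
  if (n_objects[2] > max_objects)
    stop("n_objects range exceeds max_objects")
  structure(
    list(
      n_objects = n_objects, n_features = as.integer(n_features),
      distractor_similarity = distractor_similarity,
      cap_half_angle = cap_half_angle, deadline_s = deadline_s,
      max_objects = as.integer(max_objects)
    ),
    class = "scene_generator_config"
  )
}

# Uniform sample of n unit vectors in the spherical cap of half-angle `alpha`
# around the +z axis (area-uniform: cos(theta) ~ U[cos(alpha), 1]).
sample_cap_locations <- function(n, alpha) {
  z <- stats::runif(n, min = cos(alpha), max = 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate a synthetic scene
#'
#' Draws the object count uniformly from the configured range, samples true
#' features i.i.d. standard normal, optionally mixes distractor rows toward
#' the target row by `distractor_similarity` (rescaled so the marginal
#' variance remains 1), places objects uniformly in the configured spherical
#' cap, and picks the target uniformly. Bit-reproducible under a fixed seed.
#'
#' @param config a [scene_generator_config()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a `scene`.
#' @export
generate_scene <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scene_generator_config"))
  with_seed_maybe(seed, {
    n <- if (config$n_objects[1] == config$n_objects[2]) config$n_objects[1] else
      sample(seq(config$n_objects[1], config$n_objects[2]), 1L)
    nf <- config$n_features
    A <- matrix(stats::rnorm(n * nf), n, nf)
    target <- sample.int(n, 1L)
    s <- config$distractor_similarity
    if (s > 0 && n > 1L) {
      d <- setdiff(seq_len(n), target)
      tgt <- matrix(A[target, ], length(d), nf, byrow = TRUE)
      A[d, ] <- ((1 - s) * A[d, , drop = FALSE] + s * tgt) / sqrt((1 - s)^2 + s^2)
    }
    locs <- sample_cap_locations(n, config$cap_half_angle)
    scene(
      object_ids = sprintf("obj%03d", seq_len(n)),
      locations = locs, features = A, target_index = target,
      deadline_s = config$deadline_s
    )
  })
}

#' Generate an ensemble of scenes
#'
#' @param config a [scene_generator_config()].
#' @param n_scenes number of scenes.
#' @param seed integer seed; scene `i` uses the deterministic child seed
#'   `child_seed(seed, paste0("scene", i))`.
#' @return a list of `scene` objects.
#' @export
generate_scenes <- function(config, n_scenes, seed) {
  stopifnot(is_count(n_scenes))
  lapply(seq_len(n_scenes), function(i) {
    generate_scene(config, seed = child_seed(seed, paste0("scene", i)))
  })
}

#' Pad a scene with phantom objects
#'
#' Appends zero-feature phantom rows at the screen-center direction until the
#' scene has exactly `max_objects` rows, so scenes of different sizes share a
#' fixed belief-state layout. Padding never alters existing rows and is
#' idempotent.
#'
#' @param s a `scene`.
#' @param max_objects target object count.
#' @return the padded `scene`.
#' @export
pad_with_phantoms <- function(s, max_objects = 113L) {
  validate_scene(s)
  n <- length(s$object_ids)
  if (n > max_objects)
    stop("scene has ", n, " objects, more than max_objects = ", max_objects)
  if (n == max_objects) return(s)
  k <- max_objects - n
  scene(
    object_ids = c(s$object_ids, sprintf("phantom%03d", seq_len(k))),
    locations = rbind(s$locations,
                      matrix(screen_center_direction(), k, 3, byrow = TRUE)),
    features = rbind(s$features, matrix(0, k, ncol(s$features))),
    target_index = s$target_index,
    phantom_mask = c(s$phantom_mask, rep(TRUE, k)),
    deadline_s = s$deadline_s
  )
}

#' Project gaze directions to normalized 2-D screen coordinates
#'
#' Deterministic equirectangular projection of unit gaze directions to
#' `[-1, 1]^2`: longitude `atan2(x, z)` and latitude `asin(y)`, each divided
#' by the cap half-angle. Reconciles the 3-D unit-vector convention used by
#' the foveal kernel (which needs bounded dot products) with the 2-D screen
#' coordinates the policy network consumes.
#'
#' @param locations n x 3 matrix of unit vectors.
#' @param cap_half_angle normalizing half-angle in radians.
#' @return n x 2 matrix of screen coordinates.
#' @export
project_to_screen <- function(locations, cap_half_angle = pi / 3) {
  locations <- as.matrix(locations)
  stopifnot(ncol(locations) == 3L)
  lon <- atan2(locations[, 1], locations[, 3])
  lat <- asin(pmin(1, pmax(-1, locations[, 2])))
  out <- cbind(lon, lat) / cap_half_angle
  out[] <- pmin(1, pmax(-1, out))
  out
}

SCENE_SCHEMA_VERSION <- "1.0"

#' Write a scene to JSON
#'
#' Serializes with a versioned schema and 0-based `target_index` (the on-disk
#' convention; in R the index is 1-based).
#'
#' @param s a `scene`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(s, path) {
  validate_scene(s)
  obj <- list(
    schema_version = SCENE_SCHEMA_VERSION,
    object_ids = s$object_ids,
    locations = unname(apply(s$locations, 1, as.numeric, simplify = FALSE)),
    features = unname(apply(s$features, 1, as.numeric, simplify = FALSE)),
    target_index = s$target_index - 1L,
    phantom_mask = s$phantom_mask,
    deadline_s = s$deadline_s
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene from JSON
#'
#' @param path file written by [write_scene()].
#' @return a validated `scene`.
#' @export
read_scene <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("schema_version", "object_ids", "locations", "features",
                "target_index", "phantom_mask", "deadline_s")
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop("scene file is missing required fields: ", paste(missing, collapse = ", "))
  if (!identical(as.character(obj$schema_version), SCENE_SCHEMA_VERSION))
    stop("unsupported scene schema_version: ", obj$schema_version)
  ti <- obj$target_index
  if (length(ti) != 1L || !is.numeric(ti) || ti < 0 || ti >= length(obj$object_ids))
    stop("target_index out of range: scenes have exactly one target in 0..N_o-1")
  scene(
    object_ids = obj$object_ids,
    locations = matrix(unlist(obj$locations), ncol = 3, byrow = !is.matrix(obj$locations)),
    features = if (is.matrix(obj$features)) obj$features else
      matrix(unlist(obj$features), nrow = length(obj$object_ids), byrow = TRUE),
    target_index = as.integer(ti) + 1L,
    phantom_mask = as.logical(obj$phantom_mask),
    deadline_s = obj$deadline_s
  )
}
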