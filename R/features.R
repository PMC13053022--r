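#' Feature tables
#'
#' A feature table holds one object representation: a numeric matrix with one
#' row per object, tagged with the space it came from (`"shape"`, `"color"`,
#' `"shape_color"`, or `"embedding"`).
#'
#' @param object_ids character labels, one per row.
#' @param values numeric matrix (objects x raw dimensions), no missing values.
#' @param space name of the feature space.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(object_ids, values,
                          space = c("shape", "color", "shape_color", "embedding")) {
  space <- match.arg(space)
  values <- as.matrix(values)
  if (nrow(values) != length(object_ids))
    stop("values must have one row per object_id")
  if (any(!is.finite(values))) stop("feature tables must not contain missing values")
  rownames(values) <- object_ids
  structure(list(object_ids = as.character(object_ids), values = values,
                 space = space),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> space '%s': %d objects x %d dimensions\n",
              x$space, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read an object-embedding table from CSV/TSV
#'
#' Expects an `object_id` column plus numeric columns.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.tsv` = tab, otherwise comma).
#' @param space feature-space label for the resulting table.
#' @return a `feature_table`.
#' @export
read_embedding_table <- function(path, space = "embedding") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"object_id" %in% names(df))
    stop("embedding table must contain an 'object_id' column")
  vals <- as.matrix(df[setdiff(names(df), "object_id")])
  if (!is.numeric(vals)) stop("embedding table columns must be numeric")
  feature_table(df$object_id, vals, space = space)
}

# ---------------------------------------------------------------------------
# Triangle meshes

new_triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (ncol(vertices) != 3L) stop("mesh vertices must be n x 3")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("mesh face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a triangle mesh from an OFF file
#'
#' Triangles only; faces with more than three vertices are rejected.
#'
#' @param path file path.
#' @return a `triangle_mesh`.
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!identical(toupper(lines[1]), "OFF")) stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtx <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(l, "\\s+")[[1]][1:3])))
  faces <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    f <- as.integer(strsplit(l, "\\s+")[[1]])
    if (f[1] != 3L) stop("only triangle faces are supported (found ", f[1],
                         "-gon)")
    f[2:4] + 1L
  }))
  new_triangle_mesh(vtx, faces)
}

#' Read a triangle mesh from a Wavefront OBJ file
#'
#' Triangles only; `f` entries may use the `v`, `v/vt` or `v/vt/vn` forms.
#'
#' @param path file path.
#' @return a `triangle_mesh`.
#' @export
read_obj <- function(path) {
  lines <- trimws(readLines(path))
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl) || !length(fl)) stop("no vertices or faces found in ", path)
  vtx <- do.call(rbind, lapply(vl, function(l)
    as.numeric(strsplit(l, "\\s+")[[1]][2:4])))
  faces <- do.call(rbind, lapply(fl, function(l) {
    parts <- strsplit(l, "\\s+")[[1]][-1]
    if (length(parts) != 3L)
      stop("only triangle faces are supported (found ", length(parts), "-gon)")
    as.integer(vapply(strsplit(parts, "/"), `[[`, character(1), 1L))
  }))
  new_triangle_mesh(vtx, faces)
}

#' Icosphere approximation of the unit sphere
#'
#' Subdivides an icosahedron and projects vertices onto the unit sphere; a
#' convenient analytic test mesh (subdivision 4 gives 5120 triangles).
#'
#' @param subdivisions number of 4-way subdivision passes.
#' @return a `triangle_mesh`.
#' @export
unit_sphere_mesh <- function(subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      midpoint_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, 0, 3)
    for (fi in seq_len(nrow(f))) {
      a <- f[fi, 1]; b <- f[fi, 2]; c3 <- f[fi, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                    c(ab, bc, ca))
    }
    v <- verts
    f <- newf
  }
  new_triangle_mesh(v, f)
}

triangle_areas <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a
  w <- c3 - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Sample points uniformly by area on a mesh surface
#'
#' Triangles are chosen proportional to area, points barycentric-uniform
#' within each triangle.
#'
#' @param mesh a `triangle_mesh`.
#' @param n number of points.
#' @param seed integer seed, or `NULL`.
#' @return n x 3 matrix of surface points.
#' @export
sample_mesh_points <- function(mesh, n, seed = NULL) {
  areas <- triangle_areas(mesh)
  if (sum(areas) <= 0) stop("degenerate mesh: total surface area is zero")
  with_seed_maybe(seed, {
    tri <- sample.int(length(areas), n, replace = TRUE, prob = areas)
    u <- stats::runif(n)
    v <- stats::runif(n)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]
    v[flip] <- 1 - v[flip]
    a <- mesh$vertices[mesh$faces[tri, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[tri, 2], , drop = FALSE]
    c3 <- mesh$vertices[mesh$faces[tri, 3], , drop = FALSE]
    a + u * (b - a) + v * (c3 - a)
  })
}

# Maximum pairwise vertex distance; for a triangulated surface the farthest
# surface points are vertices, so this is the mesh diameter.
mesh_diameter <- function(mesh) {
  v <- mesh$vertices
  n <- nrow(v)
  best <- 0
  chunk <- 512L
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(n, i0 + chunk - 1L)
    block <- v[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(v^2), `+`) - 2 * block %*% t(v)
    best <- max(best, max(d2))
  }
  sqrt(max(0, best))
}

#' D2 shape distribution of a mesh
#'
#' The classic rigid-motion-invariant global shape descriptor: the histogram
#' of Euclidean distances between random point pairs sampled uniformly by
#' area on the mesh surface. Bins span `[0, mesh diameter]` with the last bin
#' right-closed, and the histogram is normalized to sum to 1. The bin support
#' is stored with the histogram so descriptors of differently scaled meshes
#' remain comparable.
#'
#' @param mesh a `triangle_mesh` with at least one positive-area triangle.
#' @param n_pairs number of point pairs (default 500000).
#' @param n_bins number of histogram bins (default 100).
#' @param seed integer seed, or `NULL`.
#' @return list (class `d2_histogram`) with `density` (bin probabilities),
#'   `breaks`, and `support` (the mesh diameter).
#' @export
d2_shape_distribution <- function(mesh, n_pairs = 500000L, n_bins = 100L,
                                  seed = NULL) {
  if (!is_count(n_pairs) || !is_count(n_bins))
    stop("n_pairs and n_bins must be positive integers")
  pts <- sample_mesh_points(mesh, 2L * n_pairs, seed = seed)
  p1 <- pts[seq_len(n_pairs), , drop = FALSE]
  p2 <- pts[n_pairs + seq_len(n_pairs), , drop = FALSE]
  d <- sqrt(rowSums((p1 - p2)^2))
  support <- mesh_diameter(mesh)
  width <- support / n_bins
  idx <- pmin(n_bins, floor(d / width) + 1L)
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(density = counts / n_pairs,
         breaks = seq(0, support, length.out = n_bins + 1L),
         support = support),
    class = "d2_histogram"
  )
}

# ---------------------------------------------------------------------------
# Color

#' CIE L*a*b* color features of a texture image
#'
#' Resizes the texture to 500 x 500 pixels (bilinear), converts sRGB to CIE
#' L*a*b* under the D65 white point, and concatenates the flattened a* then
#' b* channels -- a length-500000 vector preserving spatial color layout (no
#' histogramming).
#'
#' @param image an RGB array (height x width x 3, values in `[0, 1]`) or a
#'   path to a PNG/JPEG file.
#' @param size output side length in pixels.
#' @return numeric vector of length `2 * size^2`.
#' @export
color_features <- function(image, size = 500L) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("color_features requires the EBImage package")
  if (is.character(image)) image <- EBImage::readImage(image)
  if (inherits(image, "Image")) {
    img <- image
    if (EBImage::colorMode(img) != EBImage::Color || dim(img)[3] < 3L)
      stop("color_features requires an RGB image")
    img <- img[, , 1:3]
  } else {
    arr <- unclass(image)
    if (length(dim(arr)) != 3L || dim(arr)[3] != 3L)
      stop("color_features requires an RGB image (height x width x 3)")
    img <- EBImage::Image(aperm(arr, c(2, 1, 3)), colormode = "Color")
  }
  img <- EBImage::resize(img, w = size, h = size)
  rgb <- matrix(as.numeric(EBImage::imageData(img)), ncol = 3)
  rgb[] <- pmin(1, pmax(0, rgb))
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  c(lab[, 2], lab[, 3])
}

# ---------------------------------------------------------------------------
# Embedding pooling

#' Pool a spatial activation tensor into an embedding
#'
#' Averages a `H x W x C` activation tensor over the channel axis and
#' flattens the resulting spatial map row-major: a `7 x 7 x 512` pooling
#' layer becomes a 49-dimensional embedding.
#'
#' @param activation 3-axis numeric array.
#' @return numeric vector of length `H * W`.
#' @export
pool_embedding <- function(activation) {
  d <- dim(activation)
  if (is.null(d) || length(d) != 3L)
    stop("activation must be a 3-axis array (H x W x C)")
  m <- rowMeans(matrix(activation, d[1] * d[2], d[3]))
  as.vector(t(matrix(m, d[1], d[2])))
}

# ---------------------------------------------------------------------------
# PCA

#' Fit a centered PCA to a feature table
#'
#' When `variance_target` is given, the retained component count is the
#' smallest number whose cumulative explained-variance ratio reaches the
#' target (the convention used here is a 95% target).
#'
#' @param table a `feature_table` or numeric matrix (objects x dimensions).
#' @param variance_target cumulative explained-variance target in (0, 1].
#' @param n_components explicit component count (alternative to
#'   `variance_target`).
#' @return list (class `pca_model`) with `rotation`, `center`, `sdev`,
#'   `explained_variance_ratio`, `n_components`.
#' @export
fit_pca <- function(table, variance_target = NULL, n_components = NULL) {
  X <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  if (nrow(X) < 2L) stop("PCA requires at least two objects")
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evr <- fit$sdev^2 / sum(fit$sdev^2)
  k <- if (!is.null(variance_target)) {
    stopifnot(variance_target > 0, variance_target <= 1)
    which(cumsum(evr) >= variance_target - 1e-12)[1]
  } else if (!is.null(n_components)) {
    if (n_components > length(fit$sdev))
      stop("n_components exceeds the available components")
    as.integer(n_components)
  } else {
    length(fit$sdev)
  }
  structure(
    list(rotation = fit$rotation, center = fit$center, sdev = fit$sdev,
         explained_variance_ratio = evr, n_components = as.integer(k)),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components retained (%.1f%% variance)\n",
              x$n_components,
              100 * sum(x$explained_variance_ratio[seq_len(x$n_components)])))
  invisible(x)
}

#' Project a feature table onto principal components
#'
#' By default the projected scores are standardized to zero mean and unit
#' variance per component, so that any feature space is consistent with the
#' belief model's standard-normal prior on true feature values. Set
#' `standardize = FALSE` for raw scores (which preserve pairwise Euclidean
#' distances of the centered data when all components are kept).
#'
#' @param table a `feature_table` or numeric matrix.
#' @param model a fitted `pca_model`.
#' @param k number of leading components (default `model$n_components`).
#' @param standardize standardize scores per component.
#' @return numeric score matrix (objects x k), carrying the input rownames.
#' @export
project_features <- function(table, model, k = model$n_components,
                             standardize = TRUE) {
  X <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  if (k > ncol(model$rotation))
    stop("k exceeds the available components (", ncol(model$rotation), ")")
  scores <- sweep(X, 2, model$center) %*% model$rotation[, seq_len(k), drop = FALSE]
  if (standardize) {
    sd_k <- model$sdev[seq_len(k)]
    if (any(sd_k <= 0)) stop("cannot standardize zero-variance components")
    scores <- sweep(scores, 2, sd_k, "/")
  }
  scores
}

# ---------------------------------------------------------------------------
# Gaze-distance diagnostics

pairwise_feature_distance <- function(a, b, method) {
  if (method == "euclidean") return(sqrt(sum((a - b)^2)))
  rho <- suppressWarnings(stats::cor(a, b, method = "spearman"))
  if (is.na(rho)) rho <- 0
  1 - rho^2
}

#' Distance-to-target diagnostics of fixation records
#'
#' Two model-agnostic contrasts per scene, computed in the scene's feature
#' space: (1) per fixation, the distance from the fixated object to the
#' target versus to the average feature vector of all distractors; (2) per
#' object (target excluded), the mean distance to the target of objects that
#' were fixated at least once versus objects never fixated. Distances are
#' Euclidean, or the Spearman dissimilarity `1 - rho^2` typically used for
#' embedding spaces.
#'
#' @param scenes list of `scene` objects (their `features` define the space).
#' @param fixations data.frame with columns `scene` (index into `scenes`) and
#'   `object` (1-based object index within the scene).
#' @param method `"euclidean"` or `"spearman"`.
#' @return data.frame with one row per scene that has fixations: columns
#'   `scene`, `fixated_to_target`, `fixated_to_distractor_avg`,
#'   `target_dist_fixated`, `target_dist_nonfixated`.
#' @export
distance_diagnostics <- function(scenes, fixations,
                                 method = c("euclidean", "spearman")) {
  method <- match.arg(method)
  if (is.null(fixations) || nrow(fixations) == 0L)
    stop("fixation records are empty")
  if (!all(c("scene", "object") %in% names(fixations)))
    stop("fixations must have columns 'scene' and 'object'")
  rows <- lapply(sort(unique(fixations$scene)), function(si) {
    s <- scenes[[si]]
    fx <- fixations$object[fixations$scene == si]
    if (any(fx < 1 | fx > nrow(s$features)))
      stop("fixation records reference objects outside scene ", si)
    feats <- s$features
    tgt <- feats[s$target_index, ]
    live <- which(!s$phantom_mask)
    distractors <- setdiff(live, s$target_index)
    dist_avg <- colMeans(feats[distractors, , drop = FALSE])
    d_ft <- mean(vapply(fx, function(o)
      pairwise_feature_distance(feats[o, ], tgt, method), numeric(1)))
    d_fd <- mean(vapply(fx, function(o)
      pairwise_feature_distance(feats[o, ], dist_avg, method), numeric(1)))
    others <- setdiff(live, s$target_index)
    fixated <- intersect(others, unique(fx))
    nonfixated <- setdiff(others, unique(fx))
    d_to_t <- function(set) {
      if (!length(set)) return(NA_real_)
      mean(vapply(set, function(o)
        pairwise_feature_distance(feats[o, ], tgt, method), numeric(1)))
    }
    data.frame(scene = si,
               fixated_to_target = d_ft,
               fixated_to_distractor_avg = d_fd,
               target_dist_fixated = d_to_t(fixated),
               target_dist_nonfixated = d_to_t(nonfixated))
  })
  do.call(rbind, rows)
}
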