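test_that("the sphere D2 histogram matches the analytic chord-length law", {
  mesh <- unit_sphere_mesh(4L)
  h <- d2_shape_distribution(mesh, n_pairs = 100000L, n_bins = 100L, seed = 1)
  expect_equal(sum(h$density), 1)
  expect_equal(h$support, 2, tolerance = 1e-3)
  # analytic bin mass for f(d) = d/2 on [0, 2]
  expected <- diff(h$breaks^2) / 4
  expect_lt(max(abs(h$density - expected)), 0.01)
})

test_that("D2 is rigid-motion invariant and scale equivariant", {
  mesh <- unit_sphere_mesh(2L)
  # an arbitrary rotation + translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- mesh
  moved$vertices <- sweep(mesh$vertices %*% t(R), 2, c(3, -1, 2), "+")
  h1 <- d2_shape_distribution(mesh, n_pairs = 20000L, seed = 5)
  h2 <- d2_shape_distribution(moved, n_pairs = 20000L, seed = 5)
  expect_equal(h1$support, h2$support, tolerance = 1e-9)
  expect_equal(h1$density, h2$density, tolerance = 1e-12)
  # uniform scaling stretches the support, not the normalized histogram
  scaled <- mesh
  scaled$vertices <- 2 * mesh$vertices
  h3 <- d2_shape_distribution(scaled, n_pairs = 20000L, seed = 5)
  expect_equal(h3$support, 2 * h1$support, tolerance = 1e-9)
  expect_equal(h3$density, h1$density, tolerance = 1e-12)
})

test_that("degenerate meshes and bad arguments are rejected", {
  flat <- structure(
    list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
         faces = matrix(c(1L, 2L, 3L), 1)),
    class = "triangle_mesh")
  expect_error(d2_shape_distribution(flat, 100L), "degenerate")
  expect_error(d2_shape_distribution(unit_sphere_mesh(1L), 0L),
               "positive integers")
})

test_that("OFF and OBJ meshes read back with triangles intact", {
  # a regular tetrahedron
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f0 <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3))
  off <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "4 4 0",
               apply(v, 1, paste, collapse = " "),
               apply(f0 - 1L, 1, function(r) paste(c(3, r), collapse = " "))),
             off)
  m1 <- read_off(off)
  expect_equal(m1$vertices, v)
  expect_equal(m1$faces, f0)
  obj <- withr::local_tempfile(fileext = ".obj")
  writeLines(c(paste("v", apply(v, 1, paste, collapse = " ")),
               paste("f", apply(f0, 1, function(r)
                 paste(sprintf("%d/1/1", r), collapse = " ")))), obj)
  m2 <- read_obj(obj)
  expect_equal(m2$vertices, v)
  expect_equal(m2$faces, f0)
  # same D2 statistics from both encodings
  h1 <- d2_shape_distribution(m1, 5000L, 20L, seed = 2)
  h2 <- d2_shape_distribution(m2, 5000L, 20L, seed = 2)
  expect_equal(h1$density, h2$density)
  # quads are rejected
  bad <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "4 1 0", apply(v, 1, paste, collapse = " "),
               "4 0 1 2 3"), bad)
  expect_error(read_off(bad), "triangle")
})

test_that("color features live in CIE L*a*b* with the expected layout", {
  skip_if_not_installed("EBImage")
  gray <- array(0.5, dim = c(20, 20, 3))
  cf <- color_features(gray, size = 50L)
  expect_length(cf, 2L * 50L^2)
  expect_lt(max(abs(cf)), 1)
  red <- array(rep(c(1, 0, 0), each = 400), dim = c(20, 20, 3))
  cfr <- color_features(red, size = 50L)
  a_star <- cfr[1:2500]
  b_star <- cfr[2501:5000]
  # reference conversion of saturated sRGB red
  ref <- grDevices::convertColor(matrix(c(1, 0, 0), 1), "sRGB", "Lab")
  expect_gt(mean(a_star), 0)
  expect_equal(mean(a_star), unname(ref[1, 2]), tolerance = 0.5)
  expect_equal(mean(b_star), unname(ref[1, 3]), tolerance = 0.5)
  expect_error(color_features(array(0.5, c(4, 4, 2))), "RGB")
  # default size matches the pixel-level convention
  expect_length(color_features(gray), 500000L)
})

test_that("embedding pooling averages channels and flattens row-major", {
  ones <- array(1, c(7, 7, 512))
  expect_equal(pool_embedding(ones), rep(1, 49))
  expect_length(pool_embedding(array(rnorm(7 * 7 * 512), c(7, 7, 512))), 49L)
  # channel-constant input collapses to the mean of the channel constants
  cc <- array(rep(1:8, each = 6), c(2, 3, 8))
  expect_equal(pool_embedding(cc), rep(mean(1:8), 6))
  # invariance to channel permutation
  x <- array(rnorm(2 * 3 * 5), c(2, 3, 5))
  expect_equal(pool_embedding(x), pool_embedding(x[, , sample(5)]))
  # row-major layout: entry 2 is row 1, column 2
  m <- array(0, c(2, 2, 1))
  m[1, 2, 1] <- 4
  expect_equal(pool_embedding(m), c(0, 4, 0, 0))
  expect_error(pool_embedding(matrix(1, 2, 2)), "3-axis")
})

test_that("PCA reduction honors rank, spectra, and reconstruction", {
  withr::with_seed(29, {
    # data on an exact 2-D plane in 10-D
    basis <- qr.Q(qr(matrix(rnorm(100), 10)))[, 1:2]
    X <- matrix(rnorm(60), 30) %*% t(basis)
    m <- fit_pca(X, variance_target = 1)
    expect_identical(m$n_components, 2L)
    expect_equal(sum(m$explained_variance_ratio[1:2]), 1, tolerance = 1e-9)
    # geometric spectrum 0.5^j: the 95% count has a closed form
    n <- 200; d <- 8
    U <- qr.Q(qr(cbind(1, matrix(rnorm(n * d), n))))[, 2:(d + 1)]
    Xg <- U %*% diag(sqrt(0.5^(0:(d - 1))))
    mg <- fit_pca(Xg, variance_target = 0.95)
    evr_exact <- 0.5^(0:(d - 1)) / sum(0.5^(0:(d - 1)))
    k_exact <- which(cumsum(evr_exact) >= 0.95)[1]
    expect_identical(mg$n_components, as.integer(k_exact))
    expect_equal(mg$explained_variance_ratio, evr_exact, tolerance = 1e-9)
    # full projection reconstructs and preserves pairwise distances
    Y <- matrix(rnorm(20 * 6), 20)
    mf <- fit_pca(Y)
    sc <- project_features(Y, mf, k = 6, standardize = FALSE)
    recon <- sweep(sc %*% t(mf$rotation), 2, mf$center, "+")
    expect_equal(recon, Y, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(as.matrix(dist(sc)), as.matrix(dist(Y)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # standardized scores have unit variance per component
    scs <- project_features(Y, mf, k = 3)
    expect_equal(unname(apply(scs, 2, sd)), rep(1, 3), tolerance = 1e-9)
    expect_error(project_features(Y, mf, k = 9), "exceeds")
    expect_error(fit_pca(Y[1, , drop = FALSE]), "two objects")
  })
})

test_that("distance diagnostics match a brute-force recomputation", {
  withr::with_seed(31, {
    feats <- matrix(rnorm(5 * 3), 5)
    s <- manual_scene(feats, target_index = 2L)
    fx <- data.frame(scene = 1L, object = c(1L, 3L, 3L, 2L))
    d <- distance_diagnostics(list(s), fx)
    eu <- function(a, b) sqrt(sum((a - b)^2))
    tgt <- feats[2, ]
    davg <- colMeans(feats[-2, ])
    expect_equal(d$fixated_to_target,
                 mean(sapply(c(1, 3, 3, 2), function(o) eu(feats[o, ], tgt))))
    expect_equal(d$fixated_to_distractor_avg,
                 mean(sapply(c(1, 3, 3, 2), function(o) eu(feats[o, ], davg))))
    expect_equal(d$target_dist_fixated, mean(c(eu(feats[1, ], tgt),
                                               eu(feats[3, ], tgt))))
    expect_equal(d$target_dist_nonfixated, mean(c(eu(feats[4, ], tgt),
                                                  eu(feats[5, ], tgt))))
    # fixations landing only on the target give zero self-distance
    d0 <- distance_diagnostics(list(s), data.frame(scene = 1L, object = 2L))
    expect_equal(d0$fixated_to_target, 0)
    # identical vectors are at Spearman distance zero
    s2 <- manual_scene(rbind(feats[1, ], feats[1, ], feats[3, ]))
    ds <- distance_diagnostics(list(s2),
                               data.frame(scene = 1L, object = 2L),
                               method = "spearman")
    expect_equal(ds$fixated_to_target, 0)
    expect_error(distance_diagnostics(list(s), fx[0, ]), "empty")
  })
})

test_that("feature tables validate alignment and read from delimited files", {
  expect_error(feature_table(c("a", "b"), matrix(1, 3, 2)), "one row per")
  expect_error(feature_table("a", matrix(NA_real_, 1, 1)), "missing values")
  tab <- data.frame(object_id = c("a", "b"), e1 = c(1, 2), e2 = c(3, 4))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  ft <- read_embedding_table(f)
  expect_identical(ft$object_ids, c("a", "b"))
  expect_equal(unname(ft$values), cbind(c(1, 2), c(3, 4)))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, f2, sep = "\t", row.names = FALSE)
  expect_equal(read_embedding_table(f2)$values, ft$values)
})
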