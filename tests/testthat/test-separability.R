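test_that("class distances reproduce hand-computed geometry", {
  # two coincident class-0 points; centroids at (0,0) and (3,4)
  coords <- rbind(c(0, 0), c(0, 0), c(3, 4))
  d <- class_distances(coords, c(0, 0, 1))
  expect_equal(unname(d["intra_class_0"]), 0)
  expect_equal(unname(d["inter_class_center_distance"]), 5)

  # three-point class with centroid (1, 1)
  pts <- rbind(c(0, 0), c(2, 0), c(1, 3))
  hand <- mean(c(sqrt(2), sqrt(2), 2))
  d2 <- class_distances(rbind(pts, c(10, 10)), c(0, 0, 0, 1))
  expect_equal(unname(d2["intra_class_0"]), hand)
})

test_that("distances are translation invariant and scale equivariant", {
  set.seed(60)
  coords <- matrix(rnorm(40), 20, 2)
  labels <- rep(0:1, 10)
  base <- class_distances(coords, labels)
  shifted <- class_distances(sweep(coords, 2, c(13.7, -2.2), `+`), labels)
  expect_equal(shifted, base, tolerance = 1e-12)
  scaled <- class_distances(coords * 3.5, labels)
  expect_equal(scaled, base * 3.5, tolerance = 1e-12)
  expect_error(class_distances(coords, rep(0, 20)), "both classes")

  pw <- class_distances(coords, labels, method = "pairwise")
  expect_equal(unname(pw["inter_class_center_distance"]),
               unname(base["inter_class_center_distance"]))
})

test_that("t-SNE enforces its size precondition and is seed-stable", {
  set.seed(61)
  x <- matrix(rnorm(60), 20, 3)
  expect_error(tsne_embed(x, perplexity = 10), "at least")
  e1 <- tsne_embed(x, perplexity = 5, n_iter = 50, seed = 4)
  e2 <- tsne_embed(x, perplexity = 5, n_iter = 50, seed = 4)
  expect_identical(e1$coords, e2$coords)
})

test_that("t-SNE preserves the structure of separated Gaussian blobs", {
  set.seed(62)
  n <- 30
  blob1 <- matrix(rnorm(n * 5, mean = 0), n, 5)
  blob2 <- matrix(rnorm(n * 5, mean = 8), n, 5)
  x <- rbind(blob1, blob2)
  labels <- rep(0:1, each = n)
  emb <- tsne_embed(x, perplexity = 8, n_iter = 300, seed = 1)
  # pairwise-distance rank correlation with the input is positive
  rc <- cor(as.vector(dist(x)), as.vector(dist(emb$coords)),
            method = "spearman")
  expect_gt(rc, 0.5)
  # the two blobs stay separated relative to their spread
  d <- class_distances(emb, labels)
  expect_gt(unname(d["inter_class_center_distance"]),
            max(d["intra_class_0"], d["intra_class_1"]))
})

test_that("separation statistics grow with true blob separation", {
  set.seed(63)
  gaps <- c(1, 4, 12)
  inter <- vapply(gaps, function(g) {
    n <- 24
    x <- rbind(matrix(rnorm(n * 4), n, 4),
               matrix(rnorm(n * 4, mean = g), n, 4))
    emb <- tsne_embed(x, perplexity = 6, n_iter = 250, seed = 2)
    unname(class_distances(emb, rep(0:1, each = n))["inter_class_center_distance"])
  }, numeric(1))
  expect_true(inter[1] < inter[3])
})

test_that("extracted features are deterministic with dropout off", {
  m <- build_model(model_from_id(2, input_shape = c(16L, 24L)), seed = 5)
  x <- matrix(rnorm(16 * 24), 16, 24)
  f1 <- extract_features(m, list(x = list(x, x)))
  expect_identical(f1[1, ], f1[2, ])
  d3 <- pcgcbam:::stage_dims(m$cfg)[[3]]
  expect_equal(ncol(f1), d3[1] * d3[2] * 128)
  # zero-weight network maps any input to the zero feature vector
  m0 <- m
  m0$params <- pcgcbam:::tree_map(function(x, ...) x * 0, m0$params)
  f0 <- extract_features(m0, list(x = list(x)))
  expect_true(all(f0 == 0))
})
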