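# Feature assembly, K-means stratification, anchored labels, PCA, and
# one-vs-rest enrichment.

test_that("feature assembly z-scores, drops incomplete samples, and
           flags constants", {
  set.seed(51)
  ab <- matrix(runif(20 * 5), 20, 5,
               dimnames = list(sprintf("S%02d", 1:20), letters[1:5]))
  ab[1:3, 2] <- NA                       # three samples missing a panel
  sc <- setNames(rnorm(20), rownames(ab))
  f <- build_features(ab, sc)
  expect_equal(nrow(f), 17)
  expect_lt(max(abs(colMeans(f))), 1e-9)
  expect_lt(max(abs(apply(f, 2, sd) - 1)), 1e-9)
  ab2 <- cbind(ab[, -2], k = 0.5)
  expect_warning(build_features(ab2, sc), "zero-variance")
})

test_that("K-means recovers planted sample blobs and reports honest
           inertia", {
  set.seed(52)
  ctr <- matrix(c(0, 0, 8, 0, 0, 8), 3, 2, byrow = TRUE)
  truth <- rep(1:3, each = 15)
  x <- ctr[truth, ] + matrix(rnorm(90), 45, 2)
  rownames(x) <- sprintf("S%02d", 1:45)
  km <- kmeans_stratify(x, K = 3, restarts = 10, seed = 9)
  expect_equal(adjusted_rand_index(km$cluster, truth), 1.0)
  km2 <- kmeans_stratify(x, K = 3, restarts = 10, seed = 9)
  expect_identical(km, km2)
  ## K = 1: inertia equals total SS around the grand centroid
  km1 <- kmeans_stratify(x, K = 1, restarts = 2, seed = 9)
  expect_equal(km1$inertia, sum(scale(x, scale = FALSE)^2),
               tolerance = 1e-8)
  expect_error(kmeans_stratify(x[1:2, ], K = 3), "exceeds")
})

test_that("anchoring follows control fraction, IFN score, and the
           granzyme-B tie-break", {
  ids <- sprintf("S%02d", 1:30)
  raw <- setNames(rep(1:3, each = 10), ids)
  ctrl <- setNames(ids %in% ids[11:18], ids)     # controls in cluster 2
  ifn <- setNames(c(rep(5, 10), rep(0, 10), rep(1, 10)), ids)
  gz <- setNames(c(rep(0, 10), rep(0, 10), rep(3, 10)), ids)
  a <- anchor_group_labels(raw, ctrl, ifn, gz)
  expect_equal(unique(a$group[a$cluster == 2]), "G0")
  expect_equal(unique(a$group[a$cluster == 1]), "G1")  # highest IFN
  expect_equal(unique(a$group[a$cluster == 3]), "G2")
  ## swapping the planted IFN pattern swaps G1/G2
  ifn_sw <- setNames(c(rep(1, 10), rep(0, 10), rep(5, 10)), ids)
  a2 <- anchor_group_labels(raw, ctrl, ifn_sw, gz)
  expect_equal(unique(a2$group[a2$cluster == 3]), "G1")
  expect_equal(unique(a2$group[a2$cluster == 1]), "G2")
  ## IFN tie: granzyme-B signature sends the richer cluster to G2
  ifn_tie <- setNames(c(rep(2, 10), rep(0, 10), rep(2, 10)), ids)
  a3 <- anchor_group_labels(raw, ctrl, ifn_tie, gz)
  expect_equal(unique(a3$group[a3$cluster == 3]), "G2")
  ## exact control-fraction tie is ambiguous
  ctrl_tie <- setNames(c(rep(c(TRUE, FALSE), 5), rep(c(TRUE, FALSE), 5),
                         rep(FALSE, 10)), ids)
  expect_error(anchor_group_labels(raw, ctrl_tie, ifn, gz), "ambiguous")
})

test_that("PCA embedding fixes signs and orders variance", {
  set.seed(53)
  x <- matrix(rnorm(200), 20, 10)
  rownames(x) <- sprintf("S%02d", 1:20)
  p <- pca_embed(x)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  for (j in 1:2) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  ## rank-1 input: first PC carries everything
  u <- rnorm(20); v <- rnorm(6)
  r1 <- pca_embed(outer(u, v))
  expect_equal(r1$var_explained[1], 1, tolerance = 1e-12)
})

test_that("one-vs-rest enrichment flags planted expansions with the
           right sign", {
  set.seed(54)
  n <- 60
  grp <- rep(c("G0", "G1", "G2"), each = n / 3)
  ids <- sprintf("S%02d", 1:n)
  ab <- matrix(rnorm(n * 4, 0.2, 0.03), n, 4,
               dimnames = list(ids, c("gz1", "gz2", "x1", "x2")))
  ab[grp == "G2", c("gz1", "gz2")] <- ab[grp == "G2", c("gz1", "gz2")] + 0.1
  assign <- data.frame(sample_id = ids, cluster = 1, group = grp)
  enr <- group_enrichment(ab, assign, mode = "per-subset")
  g2 <- enr[enr$group == "G2", ]
  expect_true(all(g2$estimate[g2$subset %in% c("gz1", "gz2")] > 0))
  expect_true(all(g2$q[g2$subset %in% c("gz1", "gz2")] < 0.05))
  expect_true(all(g2$q[g2$subset %in% c("x1", "x2")] > 0.05))
  ## groups below 3 samples are skipped, with a message
  assign2 <- assign[c(1:2, 21:60), ]
  expect_message(group_enrichment(ab[c(1:2, 21:60), ], assign2,
                                  mode = "per-subset"), "skipping G0")
})
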