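# Transform, QC rules, batch correction, and graph clustering.

test_that("arcsinh transform matches closed forms and inverts exactly", {
  expect_equal(arcsinh_transform(matrix(0), cofactor = 5)[1], 0)
  expect_equal(arcsinh_transform(matrix(5), cofactor = 5)[1], asinh(1),
               tolerance = 1e-12)
  set.seed(1)
  x <- matrix(rexp(2000, 1 / 50), 100)
  expect_lt(max(abs(inverse_arcsinh(arcsinh_transform(x, 5), 5) - x)), 1e-9)
  ## negative values survive the sign-aware formula
  xn <- matrix(c(-3, -0.1, 0.1, 7), 2)
  expect_equal(arcsinh_transform(xn, 5), asinh(xn / 5), tolerance = 1e-12)
  expect_error(arcsinh_transform(x, 0), "cofactor")
  es <- structure(list(values = x, sample = factor(rep("a", 100)),
                       scale = "raw"), class = "event_set")
  tr <- arcsinh_transform(es, 5)
  expect_error(arcsinh_transform(tr, 5), "already transformed")
})

test_that("QC removes exactly the constructed violations with reasons", {
  ids <- sprintf("S%02d", 1:10)
  via <- setNames(rep(0.9, 10), ids)
  via["S01"] <- 0.49                      # viability rule
  via["S04"] <- 0.50                      # boundary: kept (strict <)
  labels <- do.call(rbind, lapply(ids, function(s)
    data.frame(sample_id = s, cluster = rep(c("L1", "L2", "L3"),
                                            c(40, 40, 20)),
               lineage = rep(c("T", "B", "myeloid"), c(40, 40, 20)))))
  labels$lineage[labels$sample_id == "S02" & labels$lineage == "B"] <- "T"
  labels$cluster[labels$sample_id == "S03"] <-
    rep(c("L1", "L2"), c(95, 5))          # 95% occupancy
  labels$cluster[labels$sample_id == "S05"] <-
    rep(c("L1", "L2"), c(90, 10))         # boundary: kept (strict >)
  qc <- qc_filter(ids, via, labels)
  expect_setequal(qc$kept, setdiff(ids, c("S01", "S02", "S03")))
  r <- qc$report
  expect_match(r$reasons[r$sample_id == "S01"], "viability")
  expect_match(r$reasons[r$sample_id == "S02"], "0 B cells")
  expect_match(r$reasons[r$sample_id == "S03"], "90%")
  ## missing viability is a removal, not a silent keep
  via["S06"] <- NA
  qc2 <- qc_filter(ids, via, labels)
  expect_false("S06" %in% qc2$kept)
  expect_match(qc2$report$reasons[qc2$report$sample_id == "S06"],
               "unmeasured")
})

test_that("batch correction removes planted shifts and is an identity on
           a single batch", {
  set.seed(21)
  n <- 4000
  x <- rbind(matrix(rnorm(n * 6), ncol = 6),
             matrix(rnorm(n * 6, 3), ncol = 6))
  x <- x[sample(nrow(x)), ]
  shift <- c(0.8, -0.5, 0.3, 0, 0.6, -0.7)
  batch <- rep(c("b1", "b2"), each = n)
  xb <- x
  xb[batch == "b2", ] <- sweep(xb[batch == "b2", ], 2, shift, "+")
  corr <- correct_batches(xb, batch, n_anchors = 10, max_iter = 5, seed = 1)
  d <- colMeans(corr[batch == "b1", ]) - colMeans(corr[batch == "b2", ])
  expect_lt(max(abs(d) / apply(corr, 2, sd)), 0.05)
  expect_identical(dim(corr), dim(xb))
  ## single batch: untouched
  expect_identical(correct_batches(xb, rep("b1", nrow(xb)), seed = 1), xb)
  ## batch renaming leaves corrected values unchanged
  relab <- ifelse(batch == "b1", "z9", "a0")
  corr2 <- correct_batches(xb, relab, n_anchors = 10, max_iter = 5, seed = 1)
  expect_equal(corr, corr2, tolerance = 1e-10)
})

test_that("a batch smaller than the anchor count falls back gracefully", {
  set.seed(22)
  x <- matrix(rnorm(600), ncol = 3)
  batch <- rep(c("big", "tiny"), c(190, 10))
  expect_message(correct_batches(x, batch, n_anchors = 20, seed = 1),
                 "falling back")
})

test_that("planted lineages and subsets are recovered from the graph", {
  fx <- make_lineage_fixture(n_per = 400, sep = 6)
  cl <- cluster_cells(fx$values, fx$sample, k_neighbors = 15, seed = 5,
                      level = "lineage", max_graph_cells = 1600)
  expect_gte(adjusted_rand_index(cl$labels$cluster, fx$lineage), 0.95)
  ## canonical-marker labels agree with the planted lineages
  expect_gt(mean(cl$labels$lineage == fx$lineage), 0.95)
  expect_gt(cl$modularity, 0)   # beats the trivial one-cluster partition
  ## determinism
  cl2 <- cluster_cells(fx$values, fx$sample, k_neighbors = 15, seed = 5,
                       level = "lineage", max_graph_cells = 1600)
  expect_identical(cl$labels, cl2$labels)
  expect_error(cluster_cells(fx$values[1:10, ], fx$sample[1:10],
                             k_neighbors = 30), "fewer cells")
})

test_that("within-lineage subclustering resolves a planted 3-subset mix", {
  set.seed(23)
  k <- 3; n <- 500; p <- 10
  ctr <- matrix(0, k, p); ctr[cbind(1:k, 1:k)] <- 4
  sub <- sample(k, k * n, TRUE)
  x <- ctr[sub, ] + matrix(rnorm(k * n * p), ncol = p)
  colnames(x) <- sprintf("m%02d", 1:p)
  cl <- cluster_cells(x, rep_len(sprintf("S%d", 1:8), k * n),
                      k_neighbors = 15, seed = 6, level = "subset",
                      max_graph_cells = 1500)
  expect_gte(adjusted_rand_index(cl$labels$cluster, sub), 0.90)
  ## the PCA-space search may refine clusters but must not mix planted
  ## subsets: every discovered cluster stays pure
  cl2 <- cluster_cells(x, rep_len(sprintf("S%d", 1:8), k * n),
                       k_neighbors = 15, seed = 6, level = "subset",
                       max_graph_cells = 1500, pca_dims = 4)
  tab <- table(cl2$labels$cluster, sub)
  expect_gte(sum(apply(tab, 1, max)) / sum(tab), 0.95)
})
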