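# Abundance matrices, IFN-I score machinery, simplified gating, and the
# co-abundance correlation map.

test_that("subset proportions are per-lineage fractions with honest
           missingness", {
  labels <- rbind(
    data.frame(sample_id = "S1", subset = rep(c("B3", "B0"), c(30, 70)),
               lineage = "B"),
    data.frame(sample_id = "S1", subset = "T0", lineage = "T"),
    data.frame(sample_id = "S2", subset = rep(c("B0", "M0"), c(10, 5)),
               lineage = rep(c("B", "myeloid"), c(10, 5))))
  ab <- subset_proportions(labels, c("S1", "S2", "S3"))
  expect_equal(ab["S1", "B3"], 0.30)
  expect_equal(ab["S1", "T0"], 1)            # one-subset lineage closes
  expect_true(is.na(ab["S1", "M0"]))         # zero myeloid cells: missing
  expect_true(all(is.na(ab["S3", ])))        # absent sample: missing row
  expect_equal(ab["S2", "B0"], 1)
})

test_that("IFN reference stores control moments and the mean+3SD
           threshold", {
  x <- cbind(MX1 = c(1, 3), ISG15 = c(2, 4), SIGLEC1 = c(0, 2))
  ref <- fit_ifn_reference(x)
  expect_equal(unname(ref$mean), c(2, 3, 1))
  expect_equal(unname(ref$sd), c(1, 1, 1))   # population SD
  ## direct recomputation oracle on random controls
  set.seed(31)
  y <- matrix(rnorm(120), 40, 3,
              dimnames = list(NULL, c("MX1", "ISG15", "SIGLEC1")))
  ref2 <- fit_ifn_reference(y)
  mu <- colMeans(y); sdv <- apply(y, 2, sd) * sqrt(39 / 40)
  sc <- rowSums(sweep(sweep(y, 2, mu), 2, sdv, "/"))
  expect_equal(ref2$threshold, mean(sc) + 3 * sd(sc) * sqrt(39 / 40),
               tolerance = 1e-12)
  expect_error(fit_ifn_reference(x[c(1, 1), ]), "zero variance")
})

test_that("IFN score is a sum of control-standardized summaries", {
  set.seed(32)
  ctrl <- matrix(rnorm(90, 2), 30, 3,
                 dimnames = list(NULL, c("MX1", "ISG15", "SIGLEC1")))
  ref <- fit_ifn_reference(ctrl)
  at_mean <- matrix(ref$mean, 1, dimnames = list("a", names(ref$mean)))
  expect_equal(unname(ifn_score(at_mean, ref)), 0)
  plus1 <- at_mean + matrix(ref$sd, 1)
  expect_equal(unname(ifn_score(plus1, ref)), 3)
  hole <- at_mean; hole[1, 2] <- NA
  expect_true(is.na(ifn_score(hole, ref)))
  ## elevation is a strict threshold and propagates missingness
  expect_false(ifn_elevated(ref$threshold, ref))
  expect_true(ifn_elevated(ref$threshold + 1e-9, ref))
  expect_true(is.na(ifn_elevated(NA_real_, ref)))
  ## affine invariance: rescaling raw units consistently leaves scores
  a <- 2.7; b <- 0.4
  ref_r <- fit_ifn_reference(a * ctrl + b)
  expect_equal(ifn_score(a * plus1 + b, ref_r), ifn_score(plus1, ref),
               tolerance = 1e-10)
})

test_that("simplified gating matches hand counts and the exact negation", {
  mk_set <- function(vals, lineage, panel) {
    es <- structure(list(values = vals,
                         sample = factor(rep("S1", nrow(vals))),
                         scale = "transformed", panel = panel),
                    class = "event_set")
    list(events = es,
         labels = data.frame(sample_id = "S1", lineage = lineage))
  }
  gates <- c(Ki67 = 1, GranzymeB = 1, CD21 = 1, CD14 = 1, CD16 = 1,
             CD11b = 1, CD15 = 1)
  ## 200 T cells: 10 granzyme-B+ Ki67-, none Ki67+
  tv <- matrix(0, 200, 3, dimnames = list(NULL, c("Ki67", "GranzymeB",
                                                  "CD21")))
  tv[1:10, "GranzymeB"] <- 2
  t_fx <- mk_set(tv, rep("T", 200), "T")
  bv <- matrix(0, 50, 3, dimnames = list(NULL, c("Ki67", "GranzymeB",
                                                 "CD21")))
  bv[, "CD21"] <- 2.5
  b_fx <- mk_set(bv, rep("B", 50), "B")
  mv <- matrix(0, 40, 7, dimnames = list(NULL, names(gates)))
  mv[1:4, c("CD16", "CD11b", "CD15")] <- 2    # 4 low-density neutrophils
  m_fx <- mk_set(mv, rep("myeloid", 40), "myeloid")
  sig <- simplified_signatures(
    list(T = t_fx$events, B = b_fx$events, myeloid = m_fx$events),
    list(T = t_fx$labels, B = b_fx$labels, myeloid = m_fx$labels), gates)
  expect_equal(sig$pct_gzmB_nonprolif_T, 5.0)
  expect_equal(sig$pct_proliferative_TB, 0)    # every cell below Ki67 gate
  expect_equal(sig$median_CD21_nonprolif_B, 2.5)
  expect_equal(sig$neg_median_CD21_nonprolif_B,
               -sig$median_CD21_nonprolif_B)
  expect_equal(sig$pct_low_density_neutrophils, 10)
  expect_error(simplified_signatures(list(T = t_fx$events),
                                     list(T = t_fx$labels),
                                     gates[-1]), "gates must define")
})

test_that("correlation map recovers planted rank correlation and stays
           calibrated under the null", {
  set.seed(33)
  n <- 115
  z <- rnorm(n)
  ## Gaussian copula with Pearson r chosen to give Spearman rho 0.8
  r <- 2 * sin(pi * 0.8 / 6)
  x1 <- z; x2 <- r * z + sqrt(1 - r^2) * rnorm(n)
  feats <- cbind(a = x1, b = x2, c = rnorm(n))
  cm <- subset_correlation_map(feats)
  expect_equal(cm$rho["a", "a"], 1)
  expect_lt(abs(cm$rho["a", "b"] - 0.8), 0.1)
  expect_true(cm$significant["a", "b"])
  ## constant features yield missing correlations, not crashes
  cm2 <- subset_correlation_map(cbind(feats, k = rep(1, n)))
  expect_true(all(is.na(cm2$rho["k", ])))
  ## null calibration of the shared Spearman core: two independent
  ## features, many replicates
  set.seed(34)
  hits <- mean(replicate(400, {
    spearman_screen(matrix(rnorm(100), dimnames = list(NULL, "f")),
                    rnorm(100))$q < 0.05
  }))
  expect_lt(hits, 0.075)
  expect_error(subset_correlation_map(feats[1:5, ]), "at least 10")
})
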