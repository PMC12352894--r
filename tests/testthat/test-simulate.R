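# Synthetic-cohort generator: compositional model, planted effects,
# determinism, and the coupled clinical table.

test_that("no planted effects leaves group compositions symmetric", {
  eff <- default_group_effects(ifn_shift_sd = 0, expansion_logfc = 0)
  eff$G1$proportion_logfc[] <- 0
  eff$G2$proportion_logfc[] <- 0
  eff$G2$marker_shift <- eff$G1$marker_shift <- list()
  d <- cohort_design(n_controls = 2, n_per_group = c(2, 20, 20),
                     cells_per_sample = 50, seed = 301)
  co <- simulate_cohort(d, effects = eff)
  fr <- co$truth$subset_fractions
  g <- co$truth$sample_group[rownames(fr)]
  for (s in colnames(fr)) {
    a <- fr[g == "G1", s]; b <- fr[g == "G2", s]
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    expect_lt(abs(mean(a) - mean(b)), 3 * se + 1e-12)
  }
})

test_that("a planted logFC matches the brute-force renormalization oracle", {
  lfc <- log(2)
  eff <- default_group_effects(ifn_shift_sd = 0, expansion_logfc = 0)
  eff$G1$proportion_logfc <- c(B3_naive_CD21lo = lfc)
  eff$G2$proportion_logfc <- numeric(0)
  eff$G2$marker_shift <- eff$G1$marker_shift <- list()
  d <- cohort_design(n_controls = 2, n_per_group = c(2, 120, 2),
                     cells_per_sample = 30, seed = 302)
  co <- simulate_cohort(d, effects = eff)
  tmpl <- co$templates
  b_idx <- vapply(tmpl, function(t) t$lineage == "B", TRUE)
  base <- vapply(tmpl[b_idx], `[[`, 0, "baseline_fraction")
  names(base) <- vapply(tmpl[b_idx], `[[`, "", "subset_name")
  lfc_vec <- ifelse(names(base) == "B3_naive_CD21lo", lfc, 0)
  set.seed(99)
  expect_mean <- oracle_logisticnormal_mean(base, lfc_vec, d$alr_sd)
  g1 <- co$truth$sample_group == "G1"
  obs <- co$truth$subset_fractions[g1, "B3_naive_CD21lo"]
  i <- which(names(base) == "B3_naive_CD21lo")
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expect_mean[i]), 3 * se + 0.003)
})

test_that("identical design and seed reproduce the cohort bit for bit", {
  d <- tiny_design(seed = 303)
  a <- simulate_cohort(d)
  b <- simulate_cohort(d)
  expect_identical(a$events, b$events)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(tiny_design(seed = 304))
  expect_false(identical(a$events$T$values, c2$events$T$values))
})

test_that("within-lineage fractions close to 1 and respond monotonically", {
  d <- tiny_design(seed = 305)
  co <- simulate_cohort(d)
  lin <- co$truth$subset_lineage
  for (l in unique(lin)) {
    rs <- rowSums(co$truth$subset_fractions[, names(lin)[lin == l],
                                            drop = FALSE])
    expect_true(all(abs(rs - 1) < 1e-9))
  }
  ## monotone response of the expected fraction over a logFC grid
  means <- vapply(c(0, 0.4, 0.8, 1.3), function(lfc) {
    eff <- default_group_effects(ifn_shift_sd = 0, expansion_logfc = 0)
    eff$G1$proportion_logfc <- c(M3_LDN = lfc)
    eff$G2$proportion_logfc <- numeric(0)
    eff$G1$marker_shift <- eff$G2$marker_shift <- list()
    dd <- cohort_design(n_controls = 2, n_per_group = c(2, 80, 2),
                        cells_per_sample = 30, seed = 306)
    coo <- simulate_cohort(dd, effects = eff)
    mean(coo$truth$subset_fractions[coo$truth$sample_group == "G1",
                                    "M3_LDN"])
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("changing the seed moves realizations but not expectations", {
  d <- cohort_design(n_controls = 2, n_per_group = c(2, 50, 2),
                     cells_per_sample = 30, seed = 307)
  a <- simulate_cohort(d)
  d$seed <- 308L
  b <- simulate_cohort(d)
  xa <- a$truth$subset_fractions[a$truth$sample_group == "G1", "T0_naive_CD4"]
  xb <- b$truth$subset_fractions[b$truth$sample_group == "G1", "T0_naive_CD4"]
  expect_gt(t.test(xa, xb)$p.value, 0.01)
})

test_that("malformed designs and effects are rejected", {
  eff <- default_group_effects()
  eff$G2$proportion_logfc <- c(no_such_subset = 1)
  expect_error(simulate_cohort(tiny_design(), effects = eff),
               "unknown subset")
  eff <- default_group_effects()
  eff$G1$marker_shift <- list(list(subsets = NULL, marker = "XYZ",
                                   sd_units = 1))
  expect_error(simulate_cohort(tiny_design(), effects = eff),
               "unknown marker")
  expect_error(simulate_cohort(cohort_design(cells_per_sample = 4)),
               "smaller than the number of subsets")
})

test_that("raw events are nonnegative and the round trip is exact", {
  co <- simulate_cohort(tiny_design(seed = 309))
  v <- co$events$B$values
  expect_true(all(v >= 0))
  tr <- arcsinh_transform(v, cofactor = co$design$cofactor)
  back <- inverse_arcsinh(tr, cofactor = co$design$cofactor)
  expect_lt(max(abs(back - v)), 1e-9 * max(1, max(v)))
})

test_that("clinical generator couples outcomes to groups as planted", {
  grp <- setNames(sample(rep(c("G0", "G1", "G2"), c(400, 800, 800))),
                  sprintf("S%04d", 1:2000))
  cl <- simulate_clinical(grp, seed = 310)
  ## empirical complete-response log-odds for G2 vs rest near ln(8.5)
  ev <- cl$response %in% c("complete", "partial", "none")
  g2 <- cl$group[ev] == "G2"
  comp <- cl$response[ev] == "complete"
  lo <- log(mean(comp[g2]) / (1 - mean(comp[g2]))) -
    log(mean(comp[!g2]) / (1 - mean(comp[!g2])))
  expect_lt(abs(lo - log(8.5)) / log(8.5), 0.20)
  ## evaluable fraction tracks the configured UPCR >= 1 rate
  expect_lt(abs(mean(cl$upcr_baseline >= 1, na.rm = TRUE) - 0.75), 0.04)
  ## planted orderings
  act <- tapply(cl$activity_index, cl$group, mean, na.rm = TRUE)
  expect_true(act["G2"] > act["G1"] && act["G1"] > act["G0"])
  chr <- tapply(cl$chronicity_index, cl$group, mean, na.rm = TRUE)
  expect_true(chr["G0"] > max(chr["G1"], chr["G2"]))
  ## week-52 fields are drawn inside the drawn category's rule region
  back <- classify_renal_response(cl$upcr_baseline, cl$upcr_wk52,
                                  cl$creatinine_baseline, cl$creatinine_wk52,
                                  cl$prednisone_wk52)
  expect_identical(back$response[ev], cl$response[ev])
})

test_that("zero clinical effects give symmetric response rates", {
  grp <- setNames(rep(c("G1", "G2"), each = 400), sprintf("S%04d", 1:800))
  cl <- simulate_clinical(grp, clinical_params = list(g2_complete_logor = 0),
                          seed = 311)
  ev <- cl$response %in% c("complete", "partial", "none")
  p1 <- mean(cl$response[ev & cl$group == "G1"] == "complete")
  p2 <- mean(cl$response[ev & cl$group == "G2"] == "complete")
  n1 <- sum(ev & cl$group == "G1"); n2 <- sum(ev & cl$group == "G2")
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  expect_lt(abs(p1 - p2), 3 * se + 1e-9)
  expect_error(simulate_clinical(setNames(c("G1", NA), c("a", "b"))),
               "group label")
})

test_that("the reduced mixture generator plants expansions as requested", {
  mix <- simulate_subset_mixture(n_per_arm = 15, cells_per_sample = 500,
                                 expanded_subset = 5, seed = 312)
  tab <- prop.table(table(mix$sample, mix$subset), 1)
  pos <- mix$phenotype == 1
  expect_gt(mean(tab[pos, 5]), mean(tab[!pos, 5]) * 1.4)
  expect_equal(sum(duplicated(rbind(mix$values[1:5, ], mix$values[1:5, ]))),
               5)
})
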