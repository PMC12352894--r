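# Clinical association stages: response rules, group tests, screens,
# multivariable models, elastic net, and longitudinal mixed models.

test_that("renal-response rules match direct enumeration on every branch", {
  cases <- expand.grid(b = c(0.8, 1, 2), w = c(0.3, 0.5, 0.9, 1.6),
                       cb = c(1.0, 1.4), cw = c(1.0, 1.5, 1.9),
                       p = c(5, 10, 12, 15, 20))
  got <- classify_renal_response(cases$b, cases$w, cases$cb, cases$cw,
                                 cases$p)
  want <- mapply(oracle_response, cases$b, cases$w, cases$cb, cases$cw,
                 cases$p)
  expect_identical(got$response, unname(want))
  ## spec-level examples
  expect_equal(classify_renal_response(2, 0.4, 1, 1, 5)$response,
               "complete")
  expect_equal(classify_renal_response(2, 0.9, 1, 1, 12)$response,
               "partial")
  expect_equal(classify_renal_response(0.8, 0.1, 1, 1, 0)$response,
               "not_evaluable")
  miss <- classify_renal_response(2, NA, 1, 1, 5)
  expect_equal(miss$response, "not_evaluable")
  expect_equal(miss$trace, "missing")
  expect_error(classify_renal_response(-1, 0.4, 1, 1, 5), "negative")
  ## the creatinine branch taken is recorded in the trace
  tr <- classify_renal_response(2, 0.4, 1.4, 1.6, 5)$trace
  expect_match(tr, "125%")
})

test_that("Kruskal-Wallis and Dunn agree with a hand-ranked oracle", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- compare_groups(v, g)
  expect_equal(res$kw_statistic, oracle_kw_stat(v, g), tolerance = 1e-12)
  expect_equal(res$kw_p, kruskal.test(v, factor(g))$p.value)
  ## identical groups: Dunn pairwise p near 1
  set.seed(61)
  v2 <- rep(rnorm(6), 2)
  g2 <- rep(c("a", "b"), each = 6)
  res2 <- compare_groups(v2, g2)
  expect_gt(res2$pairwise$p[1], 0.95)
  expect_message(compare_groups(rep(1, 8), rep(c("a", "b"), 4)), "tied")
  ## null calibration of the omnibus test
  set.seed(62)
  hits <- mean(replicate(600, {
    compare_groups(rnorm(24), rep(c("a", "b", "c"), 8))$kw_p < 0.05
  }))
  expect_gt(hits, 0.03); expect_lt(hits, 0.07)
})

test_that("Spearman screen is monotone-invariant and BH-flags like the
           step-up oracle", {
  set.seed(63)
  x <- rnorm(40); y <- 0.7 * x + rnorm(40)
  s1 <- spearman_screen(cbind(f = x), y)
  s2 <- spearman_screen(cbind(f = exp(x)), y)
  expect_equal(s1$rho, s2$rho, tolerance = 1e-12)
  expect_equal(spearman_screen(cbind(f = 1:10), -(1:10))$rho, -1)
  feats <- matrix(rnorm(40 * 6), 40, 6,
                  dimnames = list(NULL, letters[1:6]))
  feats[, 1] <- y + rnorm(40, sd = 0.1)
  scr <- spearman_screen(feats, cbind(t1 = y, t2 = rnorm(40)))
  expect_identical(scr$significant, oracle_bh_pass(scr$p, 0.05))
})

test_that("multivariable models report exact fits, coverage, and
           separation", {
  y <- rnorm(30)
  fit <- suppressWarnings(fit_multivariable(y, y, family = "linear"))
  expect_equal(fit$estimate, 1, tolerance = 1e-10)
  ## null-covariate coverage at the nominal rate
  set.seed(64)
  cover <- mean(replicate(60, {
    f <- fit_multivariable(rnorm(50), rbinom(50, 1, 0.5),
                           covariates = data.frame(a = rnorm(50)),
                           family = "linear")
    f$conf_low <= 0 && f$conf_high >= 0
  }))
  expect_gte(cover, 0.85)
  ## separation is flagged
  x <- c(rep(0, 20), rep(1, 20))
  expect_warning(fs <- fit_multivariable(x, x, family = "logistic"),
                 "separation")
  expect_true(fs$separation)
  ## CI always contains the point estimate
  set.seed(65)
  f2 <- fit_multivariable(rbinom(80, 1, 0.4), rbinom(80, 1, 0.5),
                          family = "logistic")
  expect_true(f2$conf_low <= f2$estimate && f2$estimate <= f2$conf_high)
})

test_that("elastic net finds a planted predictor and shrinks pure noise", {
  set.seed(66)
  found <- replicate(8, {
    x <- matrix(rnorm(150 * 21), 150, 21,
                dimnames = list(NULL, c("hit", paste0("n", 1:20))))
    y <- x[, "hit"] + rnorm(150)
    att <- elastic_net_attribution(x, y, seed = sample.int(1e6, 1))
    att$predictor[which.max(abs(att$mean_coefficient))] == "hit" &&
      att$sign[att$predictor == "hit"] > 0
  })
  expect_gte(sum(found), 7)
  ## pure noise: selection is rare and coefficients shrink toward zero
  set.seed(67)
  x0 <- matrix(rnorm(120 * 15), 120, 15)
  att0 <- elastic_net_attribution(x0, rnorm(120), repeats = 10, seed = 3)
  expect_lt(median(att0$selection_frequency), 0.35)
  expect_lt(max(abs(att0$mean_coefficient)), 0.3)
  set.seed(68)
  y1 <- rnorm(120)
  a1 <- elastic_net_attribution(x0, y1, repeats = 5, seed = 11)
  a2 <- elastic_net_attribution(x0, y1, repeats = 5, seed = 11)
  expect_identical(a1, a2)
  expect_error(elastic_net_attribution(x0[1:8, ], rnorm(8)), "folds")
})

test_that("mixed longitudinal model recovers planted slopes and falls
           back without replication", {
  gen <- function(seed, slope_resp = -0.5) {
    set.seed(seed)
    pat <- sprintf("P%02d", 1:30)
    grp <- rep(c("responder", "nonresponder"), each = 15)
    d <- expand.grid(patient = pat, time = 0:2)
    d$group <- grp[match(d$patient, pat)]
    u <- setNames(rnorm(30, sd = 1), pat)
    d$y <- u[d$patient] + ifelse(d$group == "responder",
                                 slope_resp * d$time, 0) +
      rnorm(nrow(d), sd = 0.5)
    d
  }
  hits <- sapply(1:12, function(s) {
    d <- gen(s)
    m <- mixed_longitudinal(d$y, d$time, d$group, d$patient)
    i <- grep("time:group", m$fixed$term)
    m$fixed$p[i] < 0.05 &&
      (m$slopes["responder"] - m$slopes["nonresponder"]) *
        sign(m$fixed$estimate[i]) != 0 &&
      m$slopes["responder"] < m$slopes["nonresponder"]
  })
  expect_gte(mean(hits), 0.8)
  ## no replication: OLS fallback equals lm exactly
  d0 <- gen(99)
  d1 <- d0[order(d0$patient), ]
  d1 <- d1[seq_len(nrow(d1)) %% 3 == match(d1$patient,
                                           unique(d1$patient)) %% 3, ]
  d1 <- d1[!duplicated(d1$patient), ]    # one visit, staggered times
  expect_gt(sd(d1$time), 0)
  expect_warning(m1 <- mixed_longitudinal(d1$y, d1$time, d1$group,
                                          d1$patient), "replication")
  ref <- lm(y ~ time * group, data = transform(d1, group = factor(group)))
  expect_equal(m1$fixed$estimate, unname(coef(ref)), tolerance = 1e-10)
  expect_equal(m1$model, "ols")
  ## balanced null: interaction p roughly uniform
  set.seed(69)
  ps <- replicate(120, {
    d <- gen(sample.int(1e6, 1), slope_resp = 0)
    m <- suppressWarnings(suppressMessages(
      mixed_longitudinal(d$y, d$time, d$group, d$patient)))
    m$fixed$p[grep("time:group", m$fixed$term)]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
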