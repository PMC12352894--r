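## Clinical association stages: the rule-based renal-response classifier,
## group comparisons (Kruskal-Wallis + Dunn), Spearman screens with BH
## control, multivariable models, repeated cross-validated elastic-net
## attribution, and longitudinal mixed-effects trends.

#' Rule-based renal-response classification at week 52
#'
#' Patients with baseline UPCR below 1 are not evaluable. Complete
#' response: week-52 UPCR < 0.5, normal serum creatinine (<= 1.3 mg/dL)
#' or, if abnormal, week-52 creatinine < 125 percent of baseline, and
#' prednisone < 10 mg/d. Partial response: > 50 percent reduction in UPCR
#' without meeting the complete-response UPCR criterion, normal creatinine
#' or week-52 creatinine <= 125 percent of baseline, and prednisone
#' <= 15 mg/d. Otherwise none. All five inputs must be present, else the
#' call is `not_evaluable` with reason `"missing"`. Each call carries a
#' rule trace naming the criterion that decided it.
#'
#' @param upcr_baseline,upcr_wk52 urine protein-to-creatinine ratios (g/g).
#' @param creatinine_baseline,creatinine_wk52 serum creatinine (mg/dL).
#' @param prednisone_wk52 prednisone dose (mg/d).
#' @return data.frame with `response` (complete/partial/none/
#'   not_evaluable) and `trace`.
#' @export
classify_renal_response <- function(upcr_baseline, upcr_wk52,
                                    creatinine_baseline, creatinine_wk52,
                                    prednisone_wk52) {
  n <- length(upcr_baseline)
  args <- list(upcr_baseline, upcr_wk52, creatinine_baseline,
               creatinine_wk52, prednisone_wk52)
  stopifnot(all(lengths(args) == n))
  if (any(vapply(args, function(a) any(a < 0, na.rm = TRUE), TRUE)))
    stop("negative clinical inputs")
  one <- function(b, w, cb, cw, p) {
    if (anyNA(c(b, w, cb, cw, p)))
      return(c("not_evaluable", "missing"))
    if (b < 1)
      return(c("not_evaluable", "baseline UPCR < 1"))
    creat_norm <- cw <= 1.3
    if (w < 0.5 && (creat_norm || cw < 1.25 * cb) && p < 10)
      return(c("complete", paste0(
        "UPCR<0.5; ", if (creat_norm) "creatinine<=1.3"
        else "creatinine<125% baseline", "; prednisone<10")))
    if (w <= 0.5 * b && (creat_norm || cw <= 1.25 * cb) && p <= 15)
      return(c("partial", paste0(
        ">50% UPCR reduction; ", if (creat_norm) "creatinine<=1.3"
        else "creatinine<=125% baseline", "; prednisone<=15")))
    c("none", "criteria not met")
  }
  out <- t(mapply(one, upcr_baseline, upcr_wk52, creatinine_baseline,
                  creatinine_wk52, prednisone_wk52))
  data.frame(response = out[, 1], trace = out[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Kruskal-Wallis omnibus test with Dunn post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis statistic via `stats::kruskal.test`,
#' followed by Dunn z-tests on mean ranks for every pair of groups with
#' Benjamini-Hochberg adjustment of the pairwise p-values.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return list: `kw_p`, `kw_statistic`, `pairwise` data.frame (group1,
#'   group2, z, p, q).
#' @export
compare_groups <- function(values, groups) {
  g <- factor(groups)
  ok <- !is.na(values) & !is.na(g)
  values <- values[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("need at least 2 groups with at least 2 samples")
  if (stats::sd(values) == 0) {
    message("all values tied; p = 1")
    pw <- t(utils::combn(levels(g), 2))
    return(list(kw_p = 1, kw_statistic = 0,
                pairwise = data.frame(group1 = pw[, 1], group2 = pw[, 2],
                                      z = 0, p = 1, q = 1)))
  }
  kw <- stats::kruskal.test(values, g)
  n <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, g, mean)
  n_g <- table(g)
  ## tie correction for the Dunn standard error
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- t(utils::combn(levels(g), 2))
  z <- p <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[a] + 1 / n_g[b]))
    z[i] <- (mean_rank[a] - mean_rank[b]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  list(kw_p = kw$p.value, kw_statistic = unname(kw$statistic),
       pairwise = data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                             z = z, p = p,
                             q = stats::p.adjust(p, method = "BH"),
                             stringsAsFactors = FALSE))
}

#' Spearman correlation screen with BH control
#'
#' Spearman rho and p for every feature-target pair (pairwise-complete
#' observations), with Benjamini-Hochberg adjustment over all pairs.
#'
#' @param features samples x features matrix.
#' @param targets samples x targets matrix (or vector).
#' @param q FDR level for the `significant` flag (default 0.05).
#' @return data.frame: feature, target, rho, p, q, significant.
#' @export
spearman_screen <- function(features, targets, q = 0.05) {
  f <- as.matrix(features)
  t_ <- as.matrix(targets)
  if (is.null(colnames(t_))) colnames(t_) <- paste0("target",
                                                    seq_len(ncol(t_)))
  rows <- expand.grid(feature = colnames(f), target = colnames(t_),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    x <- f[, rows$feature[i]]; y <- t_[, rows$target[i]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                           method = "spearman",
                                           exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  })
  res <- do.call(rbind, res)
  out <- cbind(rows, rho = res[, 1], p = res[, 2])
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$q) & out$q < q
  out
}

#' Multivariable one-vs-rest group association model
#'
#' Maximum-likelihood linear or logistic fit of an outcome on a
#' one-vs-rest group indicator plus covariates; Wald 95 percent CI.
#' Logistic fits report the odds-ratio scale and are checked for
#' separation (flagged; optionally refit with a small ridge penalty).
#'
#' @param outcome numeric (linear) or 0/1 (logistic) per sample.
#' @param exposure one-vs-rest indicator (0/1) per sample.
#' @param covariates optional data.frame.
#' @param family `"linear"` or `"logistic"`.
#' @param penalize_on_separation refit with ridge-penalized logistic
#'   regression when separation is detected (default TRUE).
#' @return data.frame row: estimate (beta or OR), conf_low, conf_high, p,
#'   separation flag; attribute `fit` carries the model object.
#' @export
fit_multivariable <- function(outcome, exposure, covariates = NULL,
                              family = c("linear", "logistic"),
                              penalize_on_separation = TRUE) {
  family <- match.arg(family)
  dat <- data.frame(y = outcome, exposure = exposure)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  mm <- stats::model.matrix(~ ., data = dat[, -1, drop = FALSE])
  if (qr(mm)$rank < ncol(mm)) stop("design matrix is rank deficient")
  separation <- FALSE
  if (family == "linear") {
    fit <- stats::lm(y ~ ., data = dat)
    co <- summary(fit)$coefficients["exposure", ]
    est <- co[1]; se <- co[2]; p <- co[4]
    ci <- est + c(-1, 1) * stats::qnorm(0.975) * se
  } else {
    fit <- suppressWarnings(stats::glm(y ~ ., data = dat,
                                       family = stats::binomial()))
    co <- summary(fit)$coefficients["exposure", ]
    separation <- !fit$converged || abs(co[1]) > 15 || co[2] > 15
    if (separation) {
      warning("possible separation in logistic fit",
              if (penalize_on_separation) "; refitting with ridge penalty")
      if (penalize_on_separation) {
        x <- stats::model.matrix(~ ., data = dat[, -1,
                                                 drop = FALSE])[, -1,
                                                                drop = FALSE]
        if (ncol(x) < 2L) x <- cbind(x, `.pad` = 0)  # glmnet needs >= 2
        rf <- glmnet::glmnet(x, dat$y, family = "binomial", alpha = 0,
                             lambda = 1e-3)
        co[1] <- stats::coef(rf)["exposure", 1]
      }
    }
    est <- exp(co[1])
    ci <- exp(co[1] + c(-1, 1) * stats::qnorm(0.975) * co[2])
    p <- co[4]
  }
  out <- data.frame(estimate = unname(est), conf_low = ci[1],
                    conf_high = ci[2], p = unname(p),
                    separation = separation,
                    family = family, row.names = NULL)
  attr(out, "fit") <- fit
  out
}

#' Elastic-net attribution of clinical factors to an immune signature
#'
#' Linear elastic-net regression of a signature on standardized clinical
#' predictors, with the penalty chosen by minimum mean cross-validation
#' error inside each of `repeats` random `folds`-fold splits; coefficients
#' are averaged over repeats and reported with their selection frequency.
#'
#' @param predictors samples x predictors data.frame or matrix
#'   (factors are expanded; all columns standardized).
#' @param response numeric signature per sample.
#' @param l1_ratio elastic-net mixing parameter alpha (default 0.5).
#' @param lambda_grid penalty grid (default log-spaced 1e-3 to 1e1).
#' @param repeats,folds cross-validation design (default 10 x 10).
#' @param seed integer seed; identical seed gives identical fold splits
#'   and averaged coefficients.
#' @return data.frame: predictor, mean_coefficient (standardized),
#'   selection_frequency, sign.
#' @export
elastic_net_attribution <- function(predictors, response, l1_ratio = 0.5,
                                    lambda_grid = 10^seq(1, -3,
                                                         length.out = 50),
                                    repeats = 10, folds = 10, seed = 1L) {
  x <- stats::model.matrix(~ ., data = as.data.frame(predictors))[, -1,
                                                                  drop = FALSE]
  ok <- stats::complete.cases(x) & !is.na(response)
  x <- x[ok, , drop = FALSE]; y <- response[ok]
  n <- nrow(x)
  if (n < folds) stop("fewer samples than folds")
  if (n < 3 * folds) stop("need at least 3 x folds samples")
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0
  set.seed(as.integer(seed))
  coefs <- matrix(0, ncol(x), repeats,
                  dimnames = list(colnames(x), NULL))
  for (r in seq_len(repeats)) {
    foldid <- sample(rep_len(seq_len(folds), n))
    cv <- glmnet::cv.glmnet(x, y, alpha = l1_ratio, lambda = lambda_grid,
                            foldid = foldid, standardize = FALSE)
    coefs[, r] <- as.vector(stats::coef(cv, s = "lambda.min"))[-1]
  }
  mean_co <- rowMeans(coefs)
  data.frame(predictor = rownames(coefs), mean_coefficient = mean_co,
             selection_frequency = rowMeans(coefs != 0),
             sign = sign(mean_co), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Longitudinal mixed-effects trend model
#'
#' Linear mixed model of a signature on time, response group and their
#' interaction, with a random intercept per patient (REML via lme4;
#' Wald/Satterthwaite p-values via lmerTest). Without within-patient
#' replication the random effect is degenerate and the model falls back to
#' ordinary least squares with a warning.
#'
#' @param value numeric signature per sample.
#' @param timepoint numeric time per sample.
#' @param group response group per sample (factor; first level is the
#'   reference).
#' @param patient patient id per sample.
#' @return list: `fixed` coefficient table (estimate, se, p),
#'   `slopes` per-group time slope, `model` ("mixed" or "ols"), `fit`.
#' @export
mixed_longitudinal <- function(value, timepoint, group, patient) {
  dat <- data.frame(y = value, time = timepoint, group = factor(group),
                    patient = factor(patient))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  replicated <- any(table(dat$patient) > 1L)
  if (replicated) {
    fit <- suppressMessages(lmerTest::lmer(
      y ~ time * group + (1 | patient), data = dat))
    co <- stats::coef(summary(fit))
    fixed <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                        se = co[, "Std. Error"], p = co[, "Pr(>|t|)"],
                        row.names = NULL)
    model <- "mixed"
  } else {
    warning("no within-patient replication; falling back to OLS")
    fit <- stats::lm(y ~ time * group, data = dat)
    co <- summary(fit)$coefficients
    fixed <- data.frame(term = rownames(co), estimate = co[, 1],
                        se = co[, 2], p = co[, 4], row.names = NULL)
    model <- "ols"
  }
  levs <- levels(dat$group)
  base_slope <- fixed$estimate[fixed$term == "time"]
  if (!length(base_slope)) base_slope <- NA_real_  # time not estimable
  slopes <- stats::setNames(rep(base_slope, length(levs)), levs)
  for (g in levs[-1]) {
    term <- paste0("time:group", g)
    if (term %in% fixed$term)
      slopes[g] <- base_slope + fixed$estimate[fixed$term == term]
  }
  list(fixed = fixed, slopes = slopes, model = model, fit = fit)
}
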