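## Sample-level features: subset abundance matrices, the cytometric IFN-I
## score with its elevation call, the simplified 5-parameter gating
## signature, and the co-abundance correlation map.

#' Within-lineage subset proportions per sample
#'
#' proportion(subset s, sample i) = cells of sample i in s divided by cells
#' of sample i in the lineage of s. Lineages with zero cells in a sample
#' give missing values for all their subsets, never zeros.
#'
#' @param labels data.frame with `sample_id`, `subset`, `lineage` per cell.
#' @param sample_ids samples to report (rows); samples absent from
#'   `labels` give all-missing rows.
#' @return `abundance_matrix`: samples x subsets matrix with a
#'   `subset_lineage` attribute recording each column's denominator
#'   lineage.
#' @export
subset_proportions <- function(labels, sample_ids = NULL) {
  stopifnot(all(c("sample_id", "subset", "lineage") %in% names(labels)))
  sample_ids <- sample_ids %||% sort(unique(labels$sample_id))
  subsets <- sort(unique(labels$subset))
  sub_lin <- vapply(subsets, function(s)
    labels$lineage[match(s, labels$subset)], "")
  cnt <- table(factor(labels$sample_id, levels = sample_ids),
               factor(labels$subset, levels = subsets))
  lin_tot <- table(factor(labels$sample_id, levels = sample_ids),
                   factor(labels$lineage))
  prop <- matrix(NA_real_, length(sample_ids), length(subsets),
                 dimnames = list(sample_ids, subsets))
  for (j in seq_along(subsets)) {
    denom <- lin_tot[, sub_lin[j]]
    ok <- denom > 0
    prop[ok, j] <- cnt[ok, j] / denom[ok]
  }
  structure(prop, subset_lineage = sub_lin, class = c("abundance_matrix",
                                                      "matrix", "array"))
}

#' Per-sample marker summaries feeding the IFN-I score
#'
#' Medians of MX1 and ISG-15 over all cells of the panel carrying each
#' marker, and of Siglec-1 over myeloid-lineage cells of the myeloid
#' panel, computed on transformed (batch-corrected) intensities.
#'
#' @param events named list of transformed `event_set`s (panels T, B,
#'   myeloid at least).
#' @param lineage_labels per-panel data.frame(sample_id, lineage), needed
#'   for the Siglec-1 summary.
#' @param markers named character: summary marker per panel
#'   (default MX1/T, ISG15/B, Siglec-1/myeloid).
#' @return samples x 3 matrix of summaries (columns MX1, ISG15, SIGLEC1).
#' @export
ifn_marker_summaries <- function(events, lineage_labels,
                                 markers = c(T = "MX1", B = "ISG15",
                                             myeloid = "Siglec-1")) {
  all_ids <- sort(unique(unlist(lapply(events[names(markers)], function(e)
    levels(droplevels(e$sample))))))
  out <- matrix(NA_real_, length(all_ids), 3,
                dimnames = list(all_ids, c("MX1", "ISG15", "SIGLEC1")))
  for (j in seq_along(markers)) {
    pn <- names(markers)[j]
    e <- events[[pn]]
    if (is.null(e)) next
    if (!identical(e$scale, "transformed"))
      stop("summaries require transformed events")
    v <- e$values[, markers[[j]]]
    s <- as.character(e$sample)
    if (pn == "myeloid") {
      keep <- lineage_labels[[pn]]$lineage == "myeloid"
      v <- v[keep]; s <- s[keep]
    }
    med <- tapply(v, s, stats::median)
    out[names(med), j] <- med
  }
  out
}

#' Fit the control reference for the IFN-I score
#'
#' Stores per-marker control means and SDs of the sample-level summaries
#' (population SD by default), and the elevation threshold defined as
#' mean + 3 SD of the control samples' own scores.
#'
#' @param control_summaries controls x markers matrix of sample-level
#'   summaries (as from [ifn_marker_summaries()]).
#' @param sd_type `"population"` (divide by n, the default) or `"sample"`.
#' @return object of class `ifn_reference`.
#' @export
fit_ifn_reference <- function(control_summaries,
                              sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- as.matrix(control_summaries)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 complete control samples")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  if (sd_type == "population") sdv <- sdv * sqrt((n - 1) / n)
  if (any(sdv <= 0))
    stop("zero variance in control summaries for: ",
         paste(colnames(x)[sdv <= 0], collapse = ", "))
  scores <- rowSums(sweep(sweep(x, 2, mu), 2, sdv, "/"))
  thr_sd <- stats::sd(scores)
  if (sd_type == "population") thr_sd <- thr_sd * sqrt((n - 1) / n)
  ref <- list(mean = mu, sd = sdv, n_controls = n,
              control_scores = scores,
              threshold = mean(scores) + 3 * thr_sd, sd_type = sd_type)
  class(ref) <- "ifn_reference"
  ref
}

#' @export
print.ifn_reference <- function(x, ...) {
  cat(sprintf(
    "IFN-I reference: %d controls; elevation threshold (mean+3SD) = %.3f\n",
    x$n_controls, x$threshold))
  print(round(rbind(mean = x$mean, sd = x$sd), 3))
  invisible(x)
}

#' Cytometric IFN-I score
#'
#' Sum over the three score markers of the control-standardized
#' sample-level summaries: `sum_m (x_m - mu_m) / sd_m`. A sample missing
#' any marker summary (e.g., a panel that failed QC) gets a missing score.
#'
#' @param summaries samples x markers matrix ([ifn_marker_summaries()]).
#' @param ref fitted [fit_ifn_reference()].
#' @return named numeric vector of scores (NA where incomplete).
#' @export
ifn_score <- function(summaries, ref) {
  if (!inherits(ref, "ifn_reference")) stop("ref must be an ifn_reference")
  x <- as.matrix(summaries)[, names(ref$mean), drop = FALSE]
  z <- sweep(sweep(x, 2, ref$mean), 2, ref$sd, "/")
  out <- rowSums(z)           # NA propagates when any marker is missing
  stats::setNames(out, rownames(x))
}

#' IFN-I elevation call
#'
#' TRUE iff the score strictly exceeds the reference threshold
#' (control mean + 3 SD of control scores); missing scores stay missing.
#'
#' @param score numeric score(s) from [ifn_score()].
#' @param ref fitted [fit_ifn_reference()].
#' @return logical vector with NA where the score is missing.
#' @export
ifn_elevated <- function(score, ref) {
  if (!inherits(ref, "ifn_reference")) stop("ref must be an ifn_reference")
  score > ref$threshold
}

#' Simplified five-parameter gating signature
#'
#' Rectangular gating on transformed intensities reproducing the pipeline's
#' five key cellular features with a handful of canonical markers:
#' the IFN-I score; the Ki67+ fraction of T and B cells
#' (`pct_proliferative_TB`, percent); the granzyme-B+ Ki67- fraction of
#' T cells (`pct_gzmB_nonprolif_T`, percent); the median CD21 of Ki67-
#' B cells (`median_CD21_nonprolif_B`, reported alongside its exact
#' negation); and the CD14- CD16+ CD11b+ CD15-high fraction of
#' myeloid-panel events (`pct_low_density_neutrophils`, percent).
#'
#' @param events named list of transformed `event_set`s (T, B, myeloid).
#' @param lineage_labels per-panel data.frame(sample_id, lineage).
#' @param gates named per-marker positivity thresholds on the transformed
#'   scale; must cover Ki67, GranzymeB, CD21, CD14, CD16, CD11b, CD15.
#'   See [default_gates()].
#' @param ref optional [fit_ifn_reference()]; when given (together with
#'   panel summaries computable from `events`) the `ifn_score` column is
#'   filled in.
#' @return data.frame, one row per sample, columns as above.
#' @export
simplified_signatures <- function(events, lineage_labels, gates,
                                  ref = NULL) {
  need <- c("Ki67", "GranzymeB", "CD21", "CD14", "CD16", "CD11b", "CD15")
  if (!all(need %in% names(gates)))
    stop("gates must define: ", paste(setdiff(need, names(gates)),
                                      collapse = ", "))
  for (m in need) {
    carried <- any(vapply(events, function(e) m %in% colnames(e$values),
                          TRUE))
    if (!carried) stop("gated marker absent from every panel: ", m)
  }
  ids <- sort(unique(unlist(lapply(events, function(e)
    unique(as.character(e$sample))))))
  out <- data.frame(sample_id = ids, ifn_score = NA_real_,
                    pct_proliferative_TB = NA_real_,
                    pct_gzmB_nonprolif_T = NA_real_,
                    median_CD21_nonprolif_B = NA_real_,
                    neg_median_CD21_nonprolif_B = NA_real_,
                    pct_low_density_neutrophils = NA_real_)
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)

  ## proliferative T-B: Ki67+ share of T+B cells, averaged over the T and
  ## B panels' own lineage events
  tb_num <- tb_den <- stats::setNames(numeric(length(ids)), ids)
  for (pn in intersect(c("T", "B"), names(events))) {
    e <- events[[pn]]
    if (!identical(e$scale, "transformed")) stop("transformed events required")
    lin <- lineage_labels[[pn]]$lineage
    keep <- lin %in% c("T", "B")
    s <- as.character(e$sample)[keep]
    ki <- e$values[keep, "Ki67"] > gates["Ki67"]
    tb_num <- tb_num + tapply_fill(ki & TRUE, s, sum, ids)
    tb_den <- tb_den + tapply_fill(ki | TRUE, s, sum, ids)
  }
  out$pct_proliferative_TB <- pct(tb_num[ids], tb_den[ids])

  if ("T" %in% names(events)) {
    e <- events$T
    keep <- lineage_labels$T$lineage == "T"
    s <- as.character(e$sample)[keep]
    gz <- e$values[keep, "GranzymeB"] > gates["GranzymeB"]
    ki <- e$values[keep, "Ki67"] > gates["Ki67"]
    num <- tapply_fill(gz & !ki, s, sum, ids)
    den <- tapply_fill(rep(TRUE, length(s)), s, sum, ids)
    out$pct_gzmB_nonprolif_T <- pct(num[ids], den[ids])
  }
  if ("B" %in% names(events)) {
    e <- events$B
    keep <- lineage_labels$B$lineage == "B" &
      e$values[, "Ki67"] <= gates["Ki67"]
    s <- as.character(e$sample)[keep]
    med <- tapply(e$values[keep, "CD21"], s, stats::median)
    out$median_CD21_nonprolif_B <- unname(med[ids])
    out$neg_median_CD21_nonprolif_B <- -out$median_CD21_nonprolif_B
  }
  if ("myeloid" %in% names(events)) {
    e <- events$myeloid
    v <- e$values
    ldn <- v[, "CD14"] <= gates["CD14"] & v[, "CD16"] > gates["CD16"] &
      v[, "CD11b"] > gates["CD11b"] & v[, "CD15"] > gates["CD15"]
    s <- as.character(e$sample)
    num <- tapply_fill(ldn, s, sum, ids)
    den <- tapply_fill(rep(TRUE, length(s)), s, sum, ids)
    out$pct_low_density_neutrophils <- pct(num[ids], den[ids])
  }
  if (!is.null(ref)) {
    summ <- ifn_marker_summaries(events, lineage_labels)
    sc <- ifn_score(summ, ref)
    out$ifn_score <- unname(sc[ids])
  }
  out
}

tapply_fill <- function(x, g, f, levels) {
  r <- tapply(x, factor(g, levels = levels), f)
  r[is.na(r)] <- 0
  r
}

#' Default positivity gates from pooled control cells
#'
#' The per-marker positivity threshold defaults to the given quantile
#' (99th percentile) of pooled control-sample cells, computed per panel and
#' averaged over the panels carrying the marker. CD14/CD16/CD11b/CD15 use
#' the myeloid panel only (where the gate is applied).
#'
#' @param events named list of transformed `event_set`s.
#' @param control_ids character vector of control sample ids.
#' @param markers markers to gate.
#' @param probs quantile (default 0.99).
#' @return named numeric vector of thresholds.
#' @export
default_gates <- function(events, control_ids,
                          markers = c("Ki67", "GranzymeB", "CD21", "CD14",
                                      "CD16", "CD11b", "CD15"),
                          probs = 0.99) {
  myeloid_only <- c("CD14", "CD16", "CD11b", "CD15")
  out <- stats::setNames(rep(NA_real_, length(markers)), markers)
  for (m in markers) {
    pans <- if (m %in% myeloid_only) "myeloid" else names(events)
    qs <- c()
    for (pn in pans) {
      e <- events[[pn]]
      if (is.null(e) || !m %in% colnames(e$values)) next
      keep <- as.character(e$sample) %in% control_ids
      qs <- c(qs, stats::quantile(e$values[keep, m], probs, names = FALSE))
    }
    if (!length(qs)) stop("gated marker absent from every panel: ", m)
    out[m] <- mean(qs)
  }
  out
}

#' Co-abundance correlation map
#'
#' Pairwise Spearman correlations (pairwise-complete observations) across
#' sample-level features (subset proportions plus the IFN-I score), with
#' Benjamini-Hochberg control over all unordered pairs and an
#' average-linkage hierarchical ordering on the distance 1 - rho.
#'
#' @param features samples x features numeric matrix.
#' @param fdr_q FDR level for the significance mask (default 0.05).
#' @return list: `rho` (correlations, NA for constant features),
#'   `p` (raw), `q` (BH-adjusted), `significant` (mask at `fdr_q`,
#'   diagonal FALSE), `order` (hierarchical ordering of features).
#' @export
subset_correlation_map <- function(features, fdr_q = 0.05) {
  x <- as.matrix(features)
  if (nrow(x) < 10L) stop("need at least 10 samples")
  p <- ncol(x)
  const <- apply(x, 2, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                   all(is.na(v)))
  rho <- suppressWarnings(stats::cor(x, method = "spearman",
                                     use = "pairwise.complete.obs"))
  rho[const, ] <- NA; rho[, const] <- NA
  diag(rho) <- ifelse(const, NA, 1)
  pm <- matrix(NA_real_, p, p, dimnames = dimnames(rho))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (const[i] || const[j]) next
    ok <- stats::complete.cases(x[, c(i, j)])
    if (sum(ok) < 3) next
    pm[i, j] <- pm[j, i] <- suppressWarnings(
      stats::cor.test(x[ok, i], x[ok, j], method = "spearman",
                      exact = FALSE)$p.value)
  }
  up <- upper.tri(pm)
  qv <- pm
  qv[up] <- stats::p.adjust(pm[up], method = "BH")
  qv[lower.tri(qv)] <- t(qv)[lower.tri(qv)]
  sig <- !is.na(qv) & qv < fdr_q
  d <- stats::as.dist(1 - ifelse(is.na(rho), 0, rho))
  ord <- stats::hclust(d, method = "average")$order
  list(rho = rho, p = pm, q = qv, significant = sig, order = ord,
       fdr_q = fdr_q)
}
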