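## Sample stratification: feature assembly, K-means with k-means++
## restarts, anchored G0/G1/G2 labeling, PCA loadings, and one-vs-rest
## subset enrichment.

#' Assemble the stratification feature matrix
#'
#' Binds subset proportions and the IFN-I score, drops samples missing any
#' panel (default) or mean-imputes them, and z-scores every feature over
#' the retained samples. Zero-variance features are dropped with a
#' warning.
#'
#' @param abundance samples x subsets matrix ([subset_proportions()]).
#' @param ifn_scores named per-sample scores ([ifn_score()]).
#' @param impute mean-impute missing entries instead of dropping samples.
#' @return `feature_matrix`: z-scored samples x features matrix with
#'   attributes `retained` and `dropped_samples`.
#' @export
build_features <- function(abundance, ifn_scores, impute = FALSE) {
  ids <- intersect(rownames(abundance), names(ifn_scores))
  x <- cbind(abundance[ids, , drop = FALSE],
             ifn_score = unname(ifn_scores[ids]))
  if (impute) {
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      x[miss, j] <- mean(x[, j], na.rm = TRUE)
    }
    dropped <- character(0)
  } else {
    complete <- stats::complete.cases(x)
    dropped <- ids[!complete]
    x <- x[complete, , drop = FALSE]
  }
  if (nrow(x) < 4L) stop("fewer than K + 1 = 4 retained samples")
  z <- zscore_columns(x)
  structure(z, retained = rownames(z), dropped_samples = dropped,
            class = c("feature_matrix", "matrix", "array"))
}

#' K-means sample stratification
#'
#' k-means++ initialisation with `restarts` independent restarts (Lloyd
#' iterations via `stats::kmeans`), returning the lowest-inertia solution;
#' deterministic given the seed.
#'
#' @param features samples x features matrix ([build_features()]).
#' @param K number of clusters (default 3).
#' @param restarts independent restarts (default 50).
#' @param seed integer seed.
#' @return list: `cluster` (named integer vector), `inertia` (total
#'   within-cluster sum of squares), `centers`.
#' @export
kmeans_stratify <- function(features, K = 3, restarts = 50, seed = 1L) {
  x <- unclass(features)
  if (K > nrow(x)) stop("K exceeds the number of samples")
  if (any(!is.finite(x))) stop("features must be finite")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(x, K)
    km <- suppressWarnings(stats::kmeans(x, centers = centers,
                                         iter.max = 100,
                                         algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  list(cluster = stats::setNames(best$cluster, rownames(x)),
       inertia = best$tot.withinss, centers = best$centers)
}

#' Anchor raw K-means clusters to semantic G0/G1/G2 labels
#'
#' G0 is the cluster with the maximal control fraction; of the remaining
#' two, G1 is the one with the higher mean IFN-I score and G2 the other.
#' An exact tie on the IFN score is broken toward G2 by the higher mean
#' granzyme-B signature; an exact tie on control fraction is rejected as
#' ambiguous.
#'
#' @param raw_labels named cluster vector from [kmeans_stratify()] (K=3).
#' @param control_mask named logical: TRUE for control samples.
#' @param ifn_scores named per-sample IFN-I scores.
#' @param gzmb_signature named per-sample granzyme-B signature (sum of
#'   granzyme-B+ subset proportions).
#' @return `group_assignment` data.frame (sample_id, cluster, group) with
#'   an `anchoring` attribute recording per-cluster control fractions and
#'   mean scores.
#' @export
anchor_group_labels <- function(raw_labels, control_mask, ifn_scores,
                                gzmb_signature = NULL) {
  ids <- names(raw_labels)
  k <- sort(unique(raw_labels))
  if (length(k) != 3L) stop("anchoring requires exactly 3 clusters")
  if (!any(control_mask[ids])) stop("no control samples present")
  ctrl_frac <- vapply(k, function(j)
    mean(control_mask[ids][raw_labels == j]), 0)
  mean_ifn <- vapply(k, function(j)
    mean(ifn_scores[ids][raw_labels == j], na.rm = TRUE), 0)
  mean_gzmb <- if (is.null(gzmb_signature)) rep(NA_real_, 3) else
    vapply(k, function(j)
      mean(gzmb_signature[ids][raw_labels == j], na.rm = TRUE), 0)
  o <- order(ctrl_frac, decreasing = TRUE)
  if (ctrl_frac[o[1]] == ctrl_frac[o[2]])
    stop("ambiguous anchoring: two clusters tie on control fraction")
  g0 <- k[o[1]]
  rest <- setdiff(k, g0)
  if (mean_ifn[match(rest[1], k)] == mean_ifn[match(rest[2], k)] &&
      !all(is.na(mean_gzmb))) {
    ## tie on IFN: the higher granzyme-B cluster becomes G2
    g2 <- rest[which.max(mean_gzmb[match(rest, k)])]
    g1 <- setdiff(rest, g2)
  } else {
    g1 <- rest[which.max(mean_ifn[match(rest, k)])]
    g2 <- setdiff(rest, g1)
  }
  map <- stats::setNames(c("G0", "G1", "G2"), c(g0, g1, g2))
  out <- data.frame(sample_id = ids, cluster = unname(raw_labels),
                    group = unname(map[as.character(raw_labels)]),
                    stringsAsFactors = FALSE)
  attr(out, "anchoring") <- data.frame(
    cluster = k, control_fraction = ctrl_frac, mean_ifn = mean_ifn,
    mean_gzmb = mean_gzmb, group = unname(map[as.character(k)]))
  class(out) <- c("group_assignment", class(out))
  out
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Anchored sample groups:\n")
  print(table(x$group))
  cat("\nAnchoring provenance:\n")
  print(attr(x, "anchoring"), row.names = FALSE)
  invisible(x)
}

#' PCA embedding of the stratification features
#'
#' Centered PCA with per-feature loadings for the first two components.
#' The sign convention fixes each component so its largest-|loading|
#' feature has a positive loading.
#'
#' @param features samples x features matrix ([build_features()]).
#' @return list: `scores` (samples x 2), `loadings` (features x 2),
#'   `var_explained` (all PCs).
#' @export
pca_embed <- function(features) {
  x <- unclass(features)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = load, var_explained = ve)
}

#' One-vs-rest group enrichment of subsets
#'
#' For each anchored group, tests every subset's abundance against a
#' one-vs-rest group indicator. `mode = "per-subset"` fits a
#' covariate-adjusted linear model per subset with BH FDR across subsets;
#' `mode = "neighborhood"` feeds the indicator to [nda_associate()] on a
#' supplied NAM.
#'
#' @param abundance samples x subsets matrix.
#' @param assignment [anchor_group_labels()] output.
#' @param covariates optional per-sample data.frame (rownames = sample
#'   ids).
#' @param mode `"per-subset"` or `"neighborhood"`.
#' @param nam,... NAM and further arguments for the neighborhood mode.
#' @return per-subset mode: data.frame (group, subset, estimate, p, q);
#'   neighborhood mode: named list of `nda_result` per group.
#' @export
group_enrichment <- function(abundance, assignment, covariates = NULL,
                             mode = c("per-subset", "neighborhood"),
                             nam = NULL, ...) {
  mode <- match.arg(mode)
  grp <- stats::setNames(assignment$group, assignment$sample_id)
  ids <- intersect(rownames(abundance), names(grp))
  res <- list()
  for (g in c("G0", "G1", "G2")) {
    ind <- as.numeric(grp[ids] == g)
    if (sum(ind) < 3L) {
      message("skipping ", g, ": fewer than 3 samples")
      next
    }
    if (mode == "neighborhood") {
      res[[g]] <- nda_associate(nam[ids, , drop = FALSE], ind,
                                covariates = covariates[ids, , drop = FALSE],
                                ...)
    } else {
      rows <- lapply(colnames(abundance), function(s) {
        y <- abundance[ids, s]
        dat <- data.frame(y = y, g = ind)
        if (!is.null(covariates)) dat <- cbind(dat,
                                               covariates[ids, , drop = FALSE])
        fit <- stats::lm(y ~ ., data = dat)
        co <- summary(fit)$coefficients
        data.frame(group = g, subset = s, estimate = co["g", 1],
                   p = co["g", 4], stringsAsFactors = FALSE)
      })
      res[[g]] <- do.call(rbind, rows)
      res[[g]]$q <- stats::p.adjust(res[[g]]$p, method = "BH")
    }
  }
  if (mode == "per-subset") do.call(rbind, res) else res
}
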