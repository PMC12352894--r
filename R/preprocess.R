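## Event-level preprocessing: arcsinh transform, sample quality control,
## anchor-based batch correction, and two-level graph-based clustering.

#' Arcsinh transform of raw mass-cytometry intensities
#'
#' Applies `asinh(x / cofactor)` columnwise. For an `event_set` the scale
#' flag is checked (raw in, transformed out) so the transform cannot be
#' applied twice; plain matrices are transformed as-is.
#'
#' @param events an `event_set` (from [simulate_cohort()] or
#'   [read_events()]) or a numeric matrix of raw intensities.
#' @param cofactor positive scaling cofactor (default 5).
#' @return same shape as the input, transformed; `event_set` inputs get
#'   `scale = "transformed"`.
#' @export
arcsinh_transform <- function(events, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("cofactor must be a positive number")
  if (inherits(events, "event_set")) {
    if (!identical(events$scale, "raw"))
      stop("events are already transformed")
    events$values <- cpp_asinh(events$values, cofactor)
    events$scale <- "transformed"
    events$cofactor <- cofactor
    return(events)
  }
  if (is.matrix(events)) cpp_asinh(events, cofactor)
  else asinh(events / cofactor)
}

#' Invert the arcsinh transform
#' @param events transformed `event_set` or matrix.
#' @param cofactor cofactor used for the forward transform.
#' @return raw-scale values.
#' @export
inverse_arcsinh <- function(events, cofactor = 5) {
  if (inherits(events, "event_set")) {
    if (!identical(events$scale, "transformed"))
      stop("events are not on the transformed scale")
    events$values <- cofactor * sinh(events$values)
    events$scale <- "raw"
    return(events)
  }
  cofactor * sinh(events)
}

#' Sample-level quality control
#'
#' Removes a sample iff its viability is below 0.50 (strict), it has zero
#' B cells, or more than 90 percent (strict) of its events sit in a single
#' cluster of the provisional lineage-level clustering. Samples with
#' missing viability are removed with reason `"unmeasured"`, never silently
#' kept.
#'
#' @param sample_ids character vector of samples under QC.
#' @param viability named per-sample viability fractions.
#' @param labels data.frame with columns `sample_id`, `cluster` and
#'   `lineage` from a provisional lineage-level clustering of the pooled
#'   cohort.
#' @return list with `kept` (character vector) and `report` (a `qc_report`
#'   data.frame with per-sample metrics, pass flag and all violated rules).
#' @export
qc_filter <- function(sample_ids, viability, labels) {
  stopifnot(all(c("sample_id", "cluster", "lineage") %in% names(labels)))
  b_counts <- table(factor(labels$sample_id[labels$lineage == "B"],
                           levels = sample_ids))
  tab <- table(factor(labels$sample_id, levels = sample_ids),
               labels$cluster)
  tot <- rowSums(tab)
  occ <- ifelse(tot > 0, apply(tab, 1, max) / tot, NA_real_)[sample_ids]
  via <- viability[sample_ids]
  reasons <- lapply(seq_along(sample_ids), function(i) {
    r <- character(0)
    if (is.na(via[i])) r <- c(r, "unmeasured")
    else if (via[i] < 0.50) r <- c(r, "viability<50%")
    if (b_counts[i] == 0) r <- c(r, "0 B cells")
    if (!is.na(occ[i]) && occ[i] > 0.90) r <- c(r, ">90% in one cluster")
    r
  })
  pass <- lengths(reasons) == 0L
  report <- data.frame(sample_id = sample_ids, viability = unname(via),
                       b_cells = as.integer(b_counts),
                       max_occupancy = unname(occ), pass = pass,
                       reasons = vapply(reasons, paste, "", collapse = "; "),
                       stringsAsFactors = FALSE)
  class(report) <- c("qc_report", class(report))
  list(kept = sample_ids[pass], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d of %d samples pass\n", sum(x$pass), nrow(x)))
  fail <- x[!x$pass, c("sample_id", "reasons")]
  if (nrow(fail)) print.data.frame(fail, row.names = FALSE)
  invisible(x)
}

## k-means++ seeding (Arthur & Vassilvitskii); base R provides none
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  if (k > 1L) for (j in 2:k) {
    idx <- sample.int(n, 1L, prob = pmax(d2, 1e-300))
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

## squared Euclidean distances of rows of x to rows of c, via the Gram trick
dist2_to_centers <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  d2
}

#' Anchor-based batch correction
#'
#' Iteratively removes per-batch location offsets estimated within soft
#' clusters ("anchors") of the pooled corrected data, in the spirit of
#' soft-clustering mixture-model integration: cells are softly assigned to
#' `n_anchors` cohort-wide centroids, per-anchor per-batch marker-mean
#' offsets are estimated and subtracted (each cell weighted by its anchor
#' responsibilities), and centroids are refreshed, until the offsets' norm
#' falls below `tol` or `max_iter` is reached. Cell and sample counts are
#' never altered, only marker values.
#'
#' A batch with fewer cells than `n_anchors` triggers a fall-back to global
#' (anchor-free) location matching for all batches, with a message.
#'
#' @param events transformed `event_set`, or numeric matrix.
#' @param batch per-cell batch labels (or per-sample named vector when
#'   `events` is an `event_set`).
#' @param n_anchors number of anchor centroids (default 20).
#' @param max_iter maximum sweeps (default 10).
#' @param tol convergence threshold on the root-mean-square offset.
#' @param scale also match per-batch per-marker residual scale globally
#'   before the location sweeps (default FALSE).
#' @param seed integer seed controlling anchor initialisation.
#' @return corrected object of the same class as `events`.
#' @export
correct_batches <- function(events, batch, n_anchors = 20, max_iter = 10,
                            tol = 1e-3, scale = FALSE, seed = 1L) {
  is_set <- inherits(events, "event_set")
  x <- if (is_set) events$values else events
  if (is_set) {
    if (!identical(events$scale, "transformed"))
      stop("batch correction expects transformed events")
    if (!is.null(names(batch)))
      batch <- unname(batch[as.character(events$sample)])
  }
  batch <- as.factor(batch)
  stopifnot(length(batch) == nrow(x))
  if (nlevels(batch) < 2L) {
    return(events)            # single batch: identity
  }
  if (any(table(batch) < 1L)) stop("empty batch")
  set.seed(as.integer(seed))

  if (scale) {
    gm <- colMeans(x)
    for (b in levels(batch)) {
      rows <- which(batch == b)
      sb <- apply(x[rows, , drop = FALSE], 2, stats::sd)
      sall <- apply(x, 2, stats::sd)
      ratio <- ifelse(sb > 0, sall / sb, 1)
      x[rows, ] <- sweep(sweep(sweep(x[rows, , drop = FALSE], 2, gm),
                               2, ratio, "*"), 2, gm, "+")
    }
  }

  if (any(table(batch) < n_anchors)) {
    message("batch smaller than n_anchors: falling back to global ",
            "location matching")
    gm <- colMeans(x)
    for (b in levels(batch)) {
      rows <- which(batch == b)
      off <- colMeans(x[rows, , drop = FALSE]) - gm
      x[rows, ] <- sweep(x[rows, , drop = FALSE], 2, off)
    }
  } else {
    init_idx <- sample.int(nrow(x), min(nrow(x), 10000L))
    centers <- kmeanspp_centers(x[init_idx, , drop = FALSE], n_anchors)
    x <- x + 0        # private copy: the compiled sweep works in place
    cpp_correct_batches(x, centers, as.integer(batch), nlevels(batch),
                        as.integer(max_iter), tol)
  }
  if (is_set) {
    events$values <- x
    events
  } else x
}

#' Graph-based clustering of single-cell events
#'
#' Builds a k-nearest-neighbor graph (Euclidean distance on z-scored
#' markers) on a seeded subsample of at most `max_graph_cells` events,
#' partitions it by Leiden modularity optimisation, assigns every event to
#' the nearest cluster centroid, and merges clusters smaller than
#' `min_size` into their nearest (centroid distance) cluster. At
#' `level = "lineage"` clusters are additionally labeled T/B/myeloid/NK by
#' the maximal mean z-scored expression of each lineage's canonical
#' markers; a cluster whose top-two canonical means are closer than
#' `tau` is labeled `"unassigned"`.
#'
#' @param values numeric matrix of transformed (and typically
#'   batch-corrected) intensities, cells x markers.
#' @param sample_ids per-cell sample identifiers.
#' @param markers which columns to cluster on (default all; for lineage
#'   level pass the shared `lineage_markers`).
#' @param k_neighbors kNN parameter (default 30).
#' @param resolution Leiden resolution (default 1).
#' @param seed integer seed; identical seed gives identical labels.
#' @param level `"lineage"` or `"subset"` (controls labeling only).
#' @param min_size minimum cohort-wide cluster size (default 50).
#' @param max_graph_cells subsample size for graph construction.
#' @param tau margin below which a lineage-level cluster is "unassigned".
#' @param canonical named list of canonical markers per lineage.
#' @param eps approximation bound for the kd-tree neighbor search
#'   (0 = exact; default 1, i.e., returned neighbors are within 2x the
#'   true neighbor distance, the usual speed/quality trade for graph
#'   construction).
#' @param pca_dims when set and smaller than the marker count, the
#'   neighbor search and centroid assignment run in this many principal
#'   components (fitted on the graph subsample); cluster labeling and
#'   profiles still use the full marker space.
#' @param compute_profiles compute per-cluster marker-median profiles on a
#'   subsample of at most 20000 cells (default TRUE).
#' @return `cluster_labels` list: `labels` data.frame (sample_id, cluster,
#'   and lineage at lineage level), `centroids` (z-scored space),
#'   `profiles` (per-cluster marker medians on the input scale),
#'   `modularity`.
#' @export
cluster_cells <- function(values, sample_ids, markers = colnames(values),
                          k_neighbors = 30, resolution = 1, seed = 1L,
                          level = c("subset", "lineage"), min_size = 50,
                          max_graph_cells = 20000, tau = 0.1,
                          canonical = CANONICAL_MARKERS, eps = 1,
                          pca_dims = NULL, compute_profiles = TRUE) {
  level <- match.arg(level)
  stopifnot(nrow(values) == length(sample_ids))
  if (level == "lineage" && !is.null(pca_dims))
    stop("pca_dims is not supported at lineage level (canonical-marker ",
         "labeling needs marker-space centroids)")
  if (nrow(values) < k_neighbors + 1L)
    stop("fewer cells than k_neighbors + 1")
  x <- values[, markers, drop = FALSE]
  n <- nrow(x)
  mu <- colMeans(x)
  sdv <- sqrt(pmax(colMeans(x * x) - mu^2, 0) * n / max(1, n - 1))
  sdv[sdv == 0] <- 1
  z <- x
  for (j in seq_len(ncol(z))) z[, j] <- (z[, j] - mu[j]) / sdv[j]

  set.seed(as.integer(seed))
  sub <- if (n > max_graph_cells) sort(sample.int(n, max_graph_cells))
         else seq_len(n)
  zs <- z[sub, , drop = FALSE]
  if (!is.null(pca_dims) && ncol(z) > pca_dims) {
    ## neighbor search and centroid assignment in PCA space (fitted on
    ## the graph subsample), the standard reduction for dense panels
    rot <- stats::prcomp(zs, center = FALSE, rank. = pca_dims)$rotation
    z <- z %*% rot
    zs <- z[sub, , drop = FALSE]
  }
  nn <- RANN::nn2(zs, k = min(k_neighbors + 1L, nrow(zs)),
                  eps = eps)$nn.idx[, -1L, drop = FALSE]
  edges <- cbind(rep(seq_len(nrow(zs)), ncol(nn)), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  memb <- igraph::membership(comm)
  mod <- igraph::modularity(g, memb)

  centroids <- rowsum_mean(zs, memb)
  ## assign every cell to the nearest centroid
  lab <- cpp_assign_nearest(z, centroids)
  ## merge clusters below min_size into the nearest retained centroid
  repeat {
    cnt <- tabulate(lab, nbins = nrow(centroids))
    small <- which(cnt > 0 & cnt < min_size)
    keep <- which(cnt >= min_size)
    if (!length(small) || !length(keep)) break
    d <- dist2_to_centers(centroids[small, , drop = FALSE],
                          centroids[keep, , drop = FALSE])
    remap <- seq_len(nrow(centroids))
    remap[small] <- keep[max.col(-d, "first")]
    lab <- remap[lab]
    lab <- match(lab, sort(unique(lab)))
    centroids <- rowsum_mean(z, lab)
  }
  lab <- match(lab, sort(unique(lab)))
  centroids <- rowsum_mean(z, lab)
  k_final <- nrow(centroids)
  cluster_name <- sprintf("%s%02d", if (level == "lineage") "L" else "S",
                          seq_len(k_final))

  labels <- data.frame(sample_id = as.character(sample_ids),
                       cluster = cluster_name[lab],
                       stringsAsFactors = FALSE)
  lineage <- NULL
  if (level == "lineage") {
    lin_score <- vapply(names(canonical), function(lin)
      rowMeans(centroids[, canonical[[lin]], drop = FALSE]),
      numeric(k_final))
    if (k_final == 1L) lin_score <- matrix(lin_score, 1L,
                                           dimnames = list(NULL,
                                                           names(canonical)))
    top <- apply(lin_score, 1, function(s) {
      o <- order(s, decreasing = TRUE)
      if (s[o[1]] - s[o[2]] < tau) "unassigned" else names(canonical)[o[1]]
    })
    labels$lineage <- top[lab]
    lineage <- top
  }
  profiles <- NULL
  if (compute_profiles) {
    prof_idx <- if (n > 20000L) sort(sample.int(n, 20000L)) else seq_len(n)
    profiles <- do.call(rbind, lapply(seq_len(k_final), function(j) {
      rows <- prof_idx[lab[prof_idx] == j]
      if (!length(rows)) rows <- which(lab == j)[1L]
      apply(values[rows, , drop = FALSE], 2, stats::median)
    }))
    rownames(profiles) <- cluster_name
  }
  structure(list(labels = labels, centroids = centroids,
                 cluster_lineage = lineage, profiles = profiles,
                 modularity = mod, markers = markers, level = level),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("%s-level clustering: %d clusters, %d cells, modularity %.3f\n",
              x$level, nrow(x$centroids), nrow(x$labels), x$modularity))
  print(utils::head(sort(table(x$labels$cluster), decreasing = TRUE), 10))
  invisible(x)
}
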