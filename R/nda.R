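## Covarying-neighborhood differential abundance: random-walk-smoothed
## per-sample neighborhood abundances on a cell kNN graph, tested against
## sample-level phenotypes with covariate adjustment, a permutation global
## test, and a permutation-derived per-cell FDR mask.

#' Build a cell k-nearest-neighbor graph
#'
#' Directed kNN edges (Euclidean distance) are symmetrized and returned as
#' a sparse row-normalizable weight matrix with no self-loops.
#'
#' @param values cells x markers matrix on the transformed (and typically
#'   batch-corrected) scale.
#' @param k number of neighbors (default 30).
#' @param eps kd-tree approximation bound (0 = exact; default 1).
#' @return `knn_graph` list: `w` (sparse symmetric adjacency), `k`, `n`.
#' @export
knn_graph <- function(values, k = 30, eps = 1) {
  n <- nrow(values)
  if (n < k + 1L) stop("fewer cells than k + 1")
  nn <- RANN::nn2(values, k = k + 1L, eps = eps)$nn.idx
  ## drop the self column defensively (ties can displace it)
  from <- rep(seq_len(n), k + 1L)
  to <- as.vector(nn)
  keep <- from != to
  a <- Matrix::sparseMatrix(i = from[keep], j = to[keep], x = 1,
                            dims = c(n, n))
  a@x[] <- 1                      # collapse duplicate entries
  w <- (a + Matrix::t(a)) / 2     # symmetrize; no self-loops by construction
  structure(list(w = w, k = k, n = n), class = "knn_graph")
}

#' Neighborhood abundance matrix (NAM)
#'
#' Row i starts as the uniform distribution over sample i's cells and is
#' multiplied `n_steps` times by the symmetrized, row-normalized graph
#' transition matrix; each row is a probability distribution over cells
#' (sums to 1).
#'
#' @param graph a [knn_graph()].
#' @param sample_of_cell per-cell sample labels (factor or character).
#' @param n_steps number of random-walk steps (default 3).
#' @return samples x cells dense matrix with samples as rownames.
#' @export
build_nam <- function(graph, sample_of_cell, n_steps = 3) {
  stopifnot(inherits(graph, "knn_graph"))
  if (n_steps < 0) stop("n_steps must be >= 0")
  s <- factor(sample_of_cell)
  if (length(s) != graph$n) stop("sample labels must cover every cell")
  cnt <- table(s)
  if (any(cnt == 0)) stop("empty sample: ",
                          paste(names(cnt)[cnt == 0], collapse = ", "))
  ## row-normalized transition matrix; the walk is iterated on the
  ## transposed system (sparse x skinny-dense) for speed
  deg <- Matrix::rowSums(graph$w)
  deg[deg == 0] <- 1
  trans_t <- Matrix::t(graph$w / deg)
  namt <- matrix(0, graph$n, nlevels(s))
  namt[cbind(seq_len(graph$n), as.integer(s))] <-
    1 / as.vector(cnt)[as.integer(s)]
  for (step in seq_len(n_steps)) namt <- as.matrix(trans_t %*% namt)
  nam <- t(namt)
  rownames(nam) <- levels(s)
  nam
}

## residualize the columns of y on covariates x (OLS with intercept)
residualize <- function(y, x = NULL) {
  n <- NROW(y)
  xm <- if (is.null(x) || ncol(as.matrix(x)) == 0) {
    matrix(1, n, 1)
  } else {
    stats::model.matrix(~ ., data = as.data.frame(x))
  }
  qr_x <- qr(xm)
  y - qr.fitted(qr_x, as.matrix(y))
}

#' Covarying-neighborhood association test
#'
#' Residualizes the phenotype and every NAM column on the covariates
#' (ordinary least squares with intercept), extracts principal components
#' of the residualized NAM, and tests the squared multiple correlation of
#' the phenotype with the top `n_pcs` PCs against a permutation null
#' (phenotype residuals permuted across samples, add-one rule). Per-cell
#' association coefficients are correlations of the residualized phenotype
#' with residualized NAM columns; the FDR threshold is the smallest
#' |coefficient| cutoff at which the mean permuted exceedance count over
#' the observed exceedance count drops to `fdr_q`.
#'
#' @param nam samples x cells matrix from [build_nam()].
#' @param phenotype per-sample numeric (binary phenotypes are coded 0/1
#'   and treated numerically).
#' @param covariates optional per-sample data.frame.
#' @param n_pcs number of NAM PCs, or `"auto"` (smallest number explaining
#'   at least 50 percent of residual variance, capped at
#'   `min(10, n_samples - 2)`).
#' @param n_perms number of permutations (default 1000).
#' @param seed integer seed.
#' @param fdr_q FDR level for the per-cell mask (default 0.05).
#' @param fdr compute the per-cell FDR threshold and mask (default TRUE);
#'   the permutation null of the FDR curve uses at most 200 of the
#'   permutation draws, which stabilises the mean exceedance count without
#'   scanning every draw.
#' @return `nda_result`: global p-value, per-cell coefficients, FDR
#'   threshold, passing mask, number of PCs, permutation settings.
#' @export
nda_associate <- function(nam, phenotype, covariates = NULL, n_pcs = "auto",
                          n_perms = 1000, seed = 1L, fdr_q = 0.05,
                          fdr = TRUE) {
  n <- nrow(nam)
  if (n < 8L) stop("need at least 8 samples")
  if (stats::sd(phenotype) == 0) stop("constant phenotype")
  if (length(phenotype) != n) stop("phenotype must match NAM rows")
  if (!is.null(covariates)) {
    cc <- stats::complete.cases(covariates)
    if (!all(cc)) {
      message("dropping ", sum(!cc), " sample(s) with missing covariates")
      nam <- nam[cc, , drop = FALSE]
      phenotype <- phenotype[cc]
      covariates <- covariates[cc, , drop = FALSE]
      n <- nrow(nam)
    }
  }
  set.seed(as.integer(seed))
  y <- as.numeric(residualize(phenotype, covariates))
  if (stats::sd(y) < 1e-10 * max(1, stats::sd(phenotype))) {
    ## phenotype fully explained by covariates: nothing left to test
    warning("phenotype is collinear with the covariates; returning a ",
            "degenerate result (p = 1)")
    return(structure(list(global_p = 1,
                          coefficients = rep(0, ncol(nam)),
                          fdr_threshold = Inf,
                          passing_mask = rep(FALSE, ncol(nam)),
                          n_pcs = 0L, n_perms = n_perms,
                          seed = as.integer(seed), fdr_q = fdr_q,
                          obs_r2 = 0), class = "nda_result"))
  }
  m <- residualize(nam, covariates)
  ## PCA of the residualized NAM (centered)
  m_c <- sweep(m, 2, colMeans(m))
  sv <- svd(m_c, nu = min(n, 30L), nv = 0)
  ev <- sv$d^2
  pos <- ev > max(ev) * 1e-12
  var_frac <- cumsum(ev[pos]) / sum(ev[pos])
  cap <- max(1L, min(10L, n - 2L))
  k <- if (identical(n_pcs, "auto")) {
    min(which(var_frac >= 0.5), cap)
  } else {
    if (n_pcs >= n) stop("n_pcs must be smaller than the number of samples")
    min(as.integer(n_pcs), sum(pos))
  }
  u <- sv$u[, seq_len(k), drop = FALSE]        # orthonormal sample scores
  yc <- y - mean(y)
  obs_r2 <- sum(crossprod(u, yc)^2) / sum(yc^2)
  perms <- matrix(0L, n, n_perms)
  for (b in seq_len(n_perms)) perms[, b] <- sample.int(n)
  yp_all <- matrix(y[perms], n)
  yp_all <- sweep(yp_all, 2, colMeans(yp_all))
  perm_r2 <- colSums(crossprod(u, yp_all)^2) / colSums(yp_all^2)
  global_p <- (1 + sum(perm_r2 >= obs_r2)) / (1 + n_perms)

  ## per-cell coefficients: correlation of residualized phenotype with
  ## residualized NAM columns
  corr_with <- function(v) {
    vc <- v - mean(v)
    mc <- m_c                                   # already column-centered
    num <- as.vector(crossprod(mc, vc))
    den <- sqrt(colSums(mc^2) * sum(vc^2))
    out <- num / den
    out[den == 0] <- 0
    out
  }
  coefs <- corr_with(y)

  ## permutation null for the FDR curve, chunked to bound memory
  fdr_threshold <- NA_real_
  mask <- rep(NA, length(coefs))
  if (isTRUE(fdr)) {
    qs <- sort(unique(stats::quantile(abs(coefs),
                                      seq(0, 0.999, length = 200),
                                      names = FALSE)))
    ## exceedance counts per threshold via interval binning + suffix sums
    bin_exceed <- function(v) {
      cnt <- cpp_bin_counts(v, qs)
      rev(cumsum(rev(cnt)))[-1L]
    }
    exceed_obs <- bin_exceed(abs(coefs))
    n_fdr <- min(n_perms, 200L)
    exceed_perm <- numeric(length(qs))
    col_ss <- colSums(m_c^2)
    chunk <- 100L
    for (start in seq(1L, n_fdr, by = chunk)) {
      idxs <- start:min(start + chunk - 1L, n_fdr)
      yp <- matrix(y[perms[, idxs, drop = FALSE]], n)
      yp <- sweep(yp, 2, colMeans(yp))
      num <- crossprod(m_c, yp)                   # cells x chunk
      den <- outer(sqrt(col_ss), sqrt(colSums(yp^2)))
      pc <- abs(num / den)
      pc[den == 0] <- 0
      exceed_perm <- exceed_perm + bin_exceed(pc)
    }
    exceed_perm <- exceed_perm / n_fdr
    fdr_curve <- ifelse(exceed_obs > 0, exceed_perm / exceed_obs, 0)
    ok <- which(fdr_curve <= fdr_q)
    fdr_threshold <- if (length(ok)) qs[min(ok)] else Inf
    mask <- abs(coefs) > fdr_threshold |
      (is.finite(fdr_threshold) & abs(coefs) == fdr_threshold)
  }

  structure(list(global_p = global_p, coefficients = coefs,
                 fdr_threshold = fdr_threshold, passing_mask = mask,
                 n_pcs = k, n_perms = n_perms, seed = as.integer(seed),
                 fdr_q = fdr_q, obs_r2 = obs_r2),
            class = "nda_result")
}

#' @export
print.nda_result <- function(x, ...) {
  cat(sprintf(
    "Neighborhood DA: global p = %.4g (R2 = %.3f, %d PCs, %d perms)\n",
    x$global_p, x$obs_r2, x$n_pcs, x$n_perms))
  if (!anyNA(x$passing_mask))
    cat(sprintf("  %d of %d cells pass FDR < %g (|coef| threshold %.3g)\n",
                sum(x$passing_mask), length(x$coefficients), x$fdr_q,
                x$fdr_threshold))
  invisible(x)
}
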