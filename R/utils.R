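## Small shared helpers: seed derivation, partition agreement, z-scoring.

#' Derive per-stage seeds from a master seed
#'
#' All randomness in the package flows from a single master seed. Each
#' stochastic stage receives its own 31-bit seed, drawn once from an RNG
#' stream initialised with the master seed, so that adding or removing a
#' stage never perturbs the seeds of the others.
#'
#' @param master integer master seed.
#' @param n number of stage seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master %% 2147483647L))
  sample.int(2147483645L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used throughout to score recovery of planted cell subsets and patient
#' groups.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar; 1 for identical partitions, ~0 for independent.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

## Column z-scoring that tolerates (and reports) zero-variance columns.
zscore_columns <- function(x, drop_constant = TRUE) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    if (!drop_constant) stop("constant feature(s): ",
                             paste(colnames(x)[!keep], collapse = ", "))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  }
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  z
}

## Weighted column means per group without forming model matrices.
rowsum_mean <- function(x, g) {
  s <- rowsum(x, g)
  n <- as.vector(table(g)[rownames(s)])
  sweep(s, 1, n, "/")
}
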