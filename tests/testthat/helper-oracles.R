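# Independent oracles used across tests; deliberately brute-force and
# unrelated to the package's own implementation paths.

# Monte-Carlo oracle for the logistic-normal composition model: perturb the
# baseline fraction vector, renormalize, average.
oracle_logisticnormal_mean <- function(baseline, logfc, sd, n_draws = 2e5) {
  k <- length(baseline)
  draws <- matrix(rnorm(n_draws * k, 0, sd), n_draws, k)
  z <- sweep(draws, 2, log(baseline) + logfc, "+")
  e <- exp(z)
  colMeans(e / rowSums(e))
}

# Brute-force Kruskal-Wallis statistic from first principles (tie-corrected)
oracle_kw_stat <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) -
                                                       (n + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# BH step-up by hand
oracle_bh_pass <- function(p, q) {
  m <- length(p)
  o <- order(p)
  passed <- rep(FALSE, m)
  thr <- which(p[o] <= q * seq_len(m) / m)
  if (length(thr)) passed[o[seq_len(max(thr))]] <- TRUE
  passed
}

# Direct enumeration of the renal-response rules
oracle_response <- function(b, w, cb, cw, p) {
  if (anyNA(c(b, w, cb, cw, p))) return("not_evaluable")
  if (b < 1) return("not_evaluable")
  if (w < 0.5 && (cw <= 1.3 || cw < 1.25 * cb) && p < 10) return("complete")
  if (w <= 0.5 * b && (cw <= 1.3 || cw <= 1.25 * cb) && p <= 15)
    return("partial")
  "none"
}

# A small planted-lineage event matrix with canonical marker structure
make_lineage_fixture <- function(n_per = 400, sep = 6, seed = 42) {
  set.seed(seed)
  mk <- c("CD3", "CD4", "CD8a", "CD19", "CD20", "CD14", "CD16", "CD56",
          "CD11b", "CD11c", "CD15", "HLA-DR")
  hi <- list(T = "CD3", B = c("CD19", "CD20"), myeloid = c("CD14", "CD11b"),
             NK = "CD56")
  lin <- rep(names(hi), each = n_per)
  x <- matrix(rnorm(length(lin) * length(mk)), ncol = length(mk),
              dimnames = list(NULL, mk))
  for (l in names(hi)) x[lin == l, hi[[l]]] <- x[lin == l, hi[[l]]] + sep
  idx <- sample(length(lin))
  list(values = x[idx, ], lineage = lin[idx],
       sample = rep_len(sprintf("S%02d", 1:10), length(lin)))
}

tiny_design <- function(...) {
  cohort_design(n_controls = 6, n_per_group = c(4, 6, 6),
                cells_per_sample = 400, n_batches = 2, ...)
}
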