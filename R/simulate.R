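## Synthetic multi-panel mass-cytometry cohort generator with full ground
## truth: planted cell subsets, patient groups, batch effects, and clinical
## outcomes statistically coupled to group membership.

#' Cohort design for the synthetic generator
#'
#' @param n_controls number of healthy-control samples (default 40).
#' @param n_per_group LN samples per planted group; a single count or a
#'   length-3 vector for (G0-like, G1-like, G2-like). The default 24/48/48
#'   gives a 20/40/40 percent split with the control-like group smallest,
#'   as seen in real LN cohorts, and totals 120 LN samples.
#' @param cells_per_sample events simulated per sample per panel.
#' @param n_batches number of acquisition batches (balanced assignment).
#' @param batch_shift_sd SD of the per-batch per-marker additive location
#'   shift, arcsinh scale.
#' @param batch_scale_sd SD of the per-batch per-marker multiplicative gain
#'   around 1 (default 0.1).
#' @param panel_dropout_prob probability that a sample lacks a given panel.
#' @param timepoints visit weeks at which each LN patient is sampled
#'   (controls are baseline only). Default baseline only.
#' @param alr_sd between-sample SD of within-lineage subset log-abundances
#'   (logistic-normal noise, default 0.3).
#' @param lineage_alr_sd between-sample SD of major-lineage log-abundances.
#' @param sample_effect_sd between-sample SD of per-marker intensity offsets
#'   (arcsinh scale); this is what makes control marker medians vary across
#'   samples and therefore sets the scale of the IFN reference SDs.
#' @param cofactor arcsinh cofactor used for the inverse transform to the
#'   raw scale (default 5, the mass-cytometry convention).
#' @param lineage_fractions named baseline fractions of the four lineages.
#' @param seed integer seed; identical design + seed gives a bit-identical
#'   cohort.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_controls = 40, n_per_group = c(24, 48, 48),
                          cells_per_sample = 5000, n_batches = 4,
                          batch_shift_sd = 0.25, batch_scale_sd = 0.1,
                          panel_dropout_prob = 0, timepoints = 0,
                          alr_sd = 0.3, lineage_alr_sd = 0.2,
                          sample_effect_sd = 0.2, cofactor = 5,
                          lineage_fractions = c(T = 0.55, B = 0.15,
                                                myeloid = 0.22, NK = 0.08),
                          seed = 1L) {
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 3L)
  stopifnot(length(n_per_group) == 3L, all(n_per_group >= 1),
            n_controls >= 1, cells_per_sample >= 1, n_batches >= 1,
            panel_dropout_prob >= 0, panel_dropout_prob <= 1,
            cofactor > 0, abs(sum(lineage_fractions) - 1) < 1e-9)
  out <- list(n_controls = n_controls,
              n_per_group = stats::setNames(n_per_group, c("G0", "G1", "G2")),
              cells_per_sample = cells_per_sample, n_batches = n_batches,
              batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
              panel_dropout_prob = panel_dropout_prob,
              timepoints = timepoints, alr_sd = alr_sd,
              lineage_alr_sd = lineage_alr_sd,
              sample_effect_sd = sample_effect_sd, cofactor = cofactor,
              lineage_fractions = lineage_fractions,
              seed = as.integer(seed))
  class(out) <- "cohort_design"
  out
}

## logistic-normal draw: softmax of log-baseline + planted logFC + noise
rlogisticnormal <- function(baseline, logfc, sd) {
  z <- log(baseline) + logfc + stats::rnorm(length(baseline), 0, sd)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Simulate a multi-panel mass-cytometry cohort
#'
#' Draws a cohort according to `design`: per-sample within-lineage subset
#' fractions follow a logistic-normal model centred at each template's
#' baseline fraction and shifted by the planted group log fold changes;
#' per-cell marker intensities are Gaussian on the arcsinh scale around the
#' template profile plus planted group marker shifts, per-sample offsets and
#' per-batch location/gain effects, left-censored at zero, and
#' inverse-transformed (`cofactor * sinh`) to the raw scale so the
#' pipeline's own transform is exercised.
#'
#' @param design a [cohort_design()].
#' @param templates subset templates ([default_subset_templates()]).
#' @param effects group effect profiles ([default_group_effects()]).
#' @param panels panel configuration ([default_panels()]).
#' @return list with `events` (per panel: `values` cells x markers raw-scale
#'   matrix, `sample` factor, `scale` flag), `metadata` (one row per
#'   sample), `truth` (per-cell subset/lineage labels per panel, per-sample
#'   planted group, batch and realised subset fractions), and the design,
#'   templates, effects and panels used.
#' @export
simulate_cohort <- function(design = cohort_design(),
                            templates = default_subset_templates(),
                            effects = default_group_effects(),
                            panels = default_panels()) {
  stopifnot(inherits(design, "cohort_design"))
  subset_names <- vapply(templates, `[[`, "", "subset_name")
  lineages <- vapply(templates, `[[`, "", "lineage")
  if (!setequal(unique(lineages), c("T", "B", "myeloid", "NK")))
    stop("templates must cover all four lineages")
  if (anyDuplicated(subset_names)) stop("duplicate subset names")
  for (lin in unique(lineages)) {
    fr <- vapply(templates[lineages == lin], `[[`, 0, "baseline_fraction")
    if (abs(sum(fr) - 1) > 1e-9)
      stop("baseline fractions of lineage ", lin, " do not sum to 1")
    if (design$cells_per_sample < sum(lineages == lin))
      stop("cells_per_sample smaller than the number of subsets in ", lin)
  }
  if (!setequal(names(effects), c("G0", "G1", "G2")))
    stop("effects must cover groups G0, G1, G2")
  universe <- names(templates[[1]]$mean_profile)
  for (ef in effects) {
    bad <- setdiff(names(ef$proportion_logfc), subset_names)
    if (length(bad)) stop("unknown subset in effects: ",
                          paste(bad, collapse = ", "))
    for (ms in ef$marker_shift) {
      if (!ms$marker %in% universe)
        stop("unknown marker in effects: ", ms$marker)
      bad <- setdiff(ms$subsets, subset_names)
      if (length(bad)) stop("unknown subset in effects: ",
                            paste(bad, collapse = ", "))
    }
  }
  if (length(effects$G0$proportion_logfc) || length(effects$G0$marker_shift))
    stopifnot("G0 effect profile must be all-zero" = all(
      effects$G0$proportion_logfc == 0))

  set.seed(design$seed)

  ## ---- sample sheet ---------------------------------------------------
  groups <- c(rep("control", design$n_controls),
              rep(names(design$n_per_group), design$n_per_group))
  n_pat <- length(groups)
  patient_id <- sprintf("P%03d", seq_len(n_pat))
  tps <- design$timepoints
  meta <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
    tp <- if (groups[i] == "control") tps[1] else tps
    data.frame(patient_id = patient_id[i], timepoint = tp,
               group = groups[i], stringsAsFactors = FALSE)
  }))
  meta$sample_id <- sprintf("%s_wk%02d", meta$patient_id, meta$timepoint)
  meta$disease <- ifelse(meta$group == "control", "control", "LN")
  n_samp <- nrow(meta)
  meta$batch <- sprintf("batch%02d", (seq_len(n_samp) - 1L) %%
                          design$n_batches + 1L)
  meta$viability <- stats::rbeta(n_samp, 60, 5)
  ## panel dropout
  panel_names <- names(panels)
  present <- matrix(stats::runif(n_samp * length(panel_names)) >=
                      design$panel_dropout_prob,
                    n_samp, length(panel_names),
                    dimnames = list(meta$sample_id, panel_names))
  meta$panels <- apply(present, 1, function(z)
    paste(panel_names[z], collapse = ";"))

  ## ---- planted per-sample composition --------------------------------
  lin_names <- names(design$lineage_fractions)
  lineage_frac <- t(vapply(seq_len(n_samp), function(i)
    rlogisticnormal(design$lineage_fractions, 0, design$lineage_alr_sd),
    numeric(length(lin_names))))
  colnames(lineage_frac) <- lin_names

  group_lfc <- function(g) {
    lfc <- stats::setNames(rep(0, length(subset_names)), subset_names)
    if (g %in% names(effects)) {
      e <- effects[[g]]$proportion_logfc
      lfc[names(e)] <- e
    }
    lfc
  }
  lfc_by_group <- vapply(c("control", "G0", "G1", "G2"),
                         function(g) group_lfc(if (g == "control") "G0" else g),
                         numeric(length(subset_names)))
  subset_frac <- matrix(0, n_samp, length(subset_names),
                        dimnames = list(meta$sample_id, subset_names))
  for (lin in lin_names) {
    idx <- which(lineages == lin)
    base <- vapply(templates[idx], `[[`, 0, "baseline_fraction")
    for (i in seq_len(n_samp)) {
      subset_frac[i, idx] <- rlogisticnormal(
        base, lfc_by_group[idx, meta$group[i]], design$alr_sd)
    }
  }

  ## per-sample per-marker biological offsets, shared across panels
  sample_offset <- matrix(stats::rnorm(n_samp * length(universe), 0,
                                       design$sample_effect_sd),
                          n_samp, length(universe),
                          dimnames = list(meta$sample_id, universe))
  ## batch location and gain, per marker
  batches <- sort(unique(meta$batch))
  batch_loc <- matrix(stats::rnorm(length(batches) * length(universe), 0,
                                   design$batch_shift_sd),
                      length(batches), length(universe),
                      dimnames = list(batches, universe))
  batch_scale <- matrix(pmax(0.2, stats::rnorm(
    length(batches) * length(universe), 1, design$batch_scale_sd)),
    length(batches), length(universe), dimnames = list(batches, universe))

  ## per (group, subset) mean profiles over the marker universe
  prof <- t(vapply(templates, `[[`, numeric(length(universe)),
                   "mean_profile"))
  disp <- t(vapply(templates, `[[`, numeric(length(universe)), "dispersion"))
  rownames(prof) <- rownames(disp) <- subset_names
  group_prof <- function(g) {
    p <- prof
    eff <- if (g == "control") "G0" else g
    for (ms in effects[[eff]]$marker_shift) {
      rows <- if (is.null(ms$subsets)) subset_names else ms$subsets
      p[rows, ms$marker] <- p[rows, ms$marker] +
        ms$sd_units * disp[rows, ms$marker]
    }
    p
  }
  prof_by_group <- lapply(stats::setNames(nm = c("control", "G0", "G1", "G2")),
                          group_prof)

  ## ---- event generation, panel by panel ------------------------------
  events <- list()
  truth_cells <- list()
  for (pn in panel_names) {
    pm <- panels[[pn]]$markers
    keep <- which(present[, pn])
    ## per-sample cell counts by subset
    counts <- matrix(0L, length(keep), length(subset_names))
    for (j in seq_along(keep)) {
      i <- keep[j]
      lc <- stats::rmultinom(1, design$cells_per_sample,
                             lineage_frac[i, ])[, 1]
      for (lin in lin_names) {
        idx <- which(lineages == lin)
        if (lc[lin] > 0)
          counts[j, idx] <- stats::rmultinom(1, lc[lin],
                                             subset_frac[i, idx])[, 1]
      }
    }
    ## fused generation (compiled): one (group, subset) mean row per cell,
    ## plus per-sample additive offsets (biological + batch location) and
    ## per-sample batch gains; left-censored at 0 (ion counts cannot be
    ## negative) and inverse-transformed to the raw scale
    cell_sample <- rep.int(keep, rowSums(counts))
    cell_subset <- unlist(lapply(seq_along(keep), function(j)
      rep.int(seq_along(subset_names), counts[j, ])), use.names = FALSE)
    total <- length(cell_sample)
    grp_of <- match(meta$group[cell_sample], names(prof_by_group))
    combo <- (grp_of - 1L) * length(subset_names) + cell_subset
    prof_all <- do.call(rbind, lapply(prof_by_group, function(p)
      p[, pm, drop = FALSE]))
    addoff <- sample_offset[, pm, drop = FALSE] +
      batch_loc[meta$batch, pm, drop = FALSE]
    gain <- batch_scale[meta$batch, pm, drop = FALSE]
    vals <- cpp_synth_events(prof_all, combo, disp[, pm, drop = FALSE],
                             cell_subset, addoff, gain, cell_sample,
                             stats::rnorm(total * length(pm)),
                             design$cofactor)
    dimnames(vals) <- list(NULL, pm)
    events[[pn]] <- structure(
      list(values = vals,
           sample = factor(meta$sample_id[cell_sample],
                           levels = meta$sample_id),
           panel = pn, scale = "raw", cofactor_used = design$cofactor),
      class = "event_set")
    truth_cells[[pn]] <- data.frame(
      sample_id = meta$sample_id[cell_sample],
      subset = subset_names[cell_subset],
      lineage = lineages[cell_subset], stringsAsFactors = FALSE)
  }

  truth <- list(cells = truth_cells,
                sample_group = stats::setNames(meta$group, meta$sample_id),
                sample_batch = stats::setNames(meta$batch, meta$sample_id),
                subset_fractions = subset_frac,
                lineage_fractions = lineage_frac,
                subset_lineage = stats::setNames(lineages, subset_names))
  list(events = events, metadata = meta, truth = truth, design = design,
       templates = templates, effects = effects, panels = panels)
}

## solve the baseline complete-response logit so the marginal rate matches
## the requested value under the planted G2 log-odds offset
solve_base_logit <- function(p_marginal, w_g2, logor) {
  f <- function(l0) w_g2 * stats::plogis(l0 + logor) +
    (1 - w_g2) * stats::plogis(l0) - p_marginal
  stats::uniroot(f, c(-20, 20))$root
}

#' Default clinical effect parameters
#'
#' Effect sizes coupling the simulated clinical table to planted group
#' membership: the activity index is ordered G2 > G1 > G0 in expectation,
#' chronicity is highest in G0, the complete-response log-odds offset for
#' G2 defaults to `log(8.5)`, and the marginal complete/partial/none rates
#' default to 28/24/48 percent among evaluable patients.
#'
#' @return named list of parameters, all overridable.
#' @export
default_clinical_params <- function() {
  list(
    response_marginal = c(complete = 0.28, partial = 0.24, none = 0.48),
    g2_complete_logor = log(8.5),
    upcr_ge1_fraction = 0.75,
    upcr_sdlog = 0.8,
    activity_base = 3.5,
    activity_offsets = c(G0 = 0, G1 = 2.2, G2 = 4.4),
    activity_sd = 2.5,
    chronicity_base = 2.0,
    chronicity_offsets = c(G0 = 1.8, G1 = 0, G2 = 0),
    chronicity_sd = 1.2,
    proliferative_prob = c(G0 = 0.35, G1 = 0.65, G2 = 0.85))
}

#' Simulate a clinical table coupled to planted group membership
#'
#' Generates per-patient demographics, baseline renal measures, NIH
#' activity/chronicity indices, histologic class, and week-52 outcome
#' fields. The week-52 renal response category is drawn first (with the
#' planted G2 complete-response log-odds offset) and the week-52 UPCR,
#' creatinine and prednisone values are then drawn inside the region of the
#' week-52 response rules corresponding to that category, so the
#' rule-based classifier recovers the drawn category exactly. Patients with
#' baseline UPCR below 1 are non-evaluable by design.
#'
#' @param truth either the `truth` element of [simulate_cohort()] output or
#'   a named character vector of per-sample groups
#'   (`control`/`G0`/`G1`/`G2`).
#' @param clinical_params see [default_clinical_params()]; partial lists
#'   are merged over the defaults.
#' @param seed integer seed.
#' @return data.frame with one row per patient (baseline sample).
#' @export
simulate_clinical <- function(truth, clinical_params = list(), seed = 1L) {
  grp <- if (is.list(truth)) truth$sample_group else truth
  if (is.null(grp) || anyNA(grp) || is.null(names(grp)))
    stop("every sample needs a group label")
  cp <- utils::modifyList(default_clinical_params(), clinical_params)
  stopifnot(abs(sum(cp$response_marginal) - 1) < 1e-9)
  set.seed(as.integer(seed))

  ## one clinical row per patient: keep baseline samples only
  ids <- names(grp)
  base <- !duplicated(sub("_wk.*$", "", ids))
  ids <- ids[base]; grp <- grp[base]
  n <- length(ids)
  ln <- grp != "control"
  out <- data.frame(patient_id = sub("_wk.*$", "", ids),
                    sample_id = ids, group = unname(grp),
                    stringsAsFactors = FALSE)
  out$age <- round(ifelse(ln, stats::rnorm(n, 35, 10),
                          stats::rnorm(n, 45, 12)))
  out$age <- pmax(out$age, 16)
  out$sex <- ifelse(stats::runif(n) < ifelse(ln, 0.87, 0.70), "F", "M")
  out$ethnicity <- ifelse(stats::runif(n) < ifelse(ln, 0.31, 0.10),
                          "Hispanic", "NonHispanic")
  out$race <- ifelse(stats::runif(n) < ifelse(ln, 0.52, 0.25), "Black",
                     ifelse(stats::runif(n) < 0.75, "White", "Other"))
  out$previous_biopsy <- ln & stats::runif(n) < 0.69
  out$mmf_use <- ln & stats::runif(n) < 0.57

  ## renal measures exist for LN patients only
  out$upcr_baseline <- NA_real_
  mu_upcr <- cp$upcr_sdlog * stats::qnorm(cp$upcr_ge1_fraction)
  out$upcr_baseline[ln] <- stats::rlnorm(sum(ln), mu_upcr, cp$upcr_sdlog)
  out$creatinine_baseline <- NA_real_
  out$creatinine_baseline[ln] <- stats::rlnorm(sum(ln), log(0.9), 0.25)
  out$prednisone_baseline <- NA_real_
  out$prednisone_baseline[ln] <- round(stats::rlnorm(sum(ln), log(10), 0.6) *
                                         ifelse(grp[ln] == "G2", 1.4, 1), 1)

  clamp_round <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))
  out$activity_index <- NA_real_
  out$activity_index[ln] <- clamp_round(
    cp$activity_base + cp$activity_offsets[grp[ln]] +
      stats::rnorm(sum(ln), 0, cp$activity_sd), 0, 24)
  out$activity_interstitial <- NA_real_
  out$activity_interstitial[ln] <- clamp_round(
    out$activity_index[ln] * stats::runif(sum(ln), 0.1, 0.3), 0, 3)
  out$activity_glomerular <- out$activity_index - out$activity_interstitial
  out$chronicity_index <- NA_real_
  out$chronicity_index[ln] <- clamp_round(
    cp$chronicity_base + cp$chronicity_offsets[grp[ln]] +
      stats::rnorm(sum(ln), 0, cp$chronicity_sd), 0, 12)
  out$histologic_class <- NA_character_
  out$histologic_class[ln] <- ifelse(
    stats::runif(sum(ln)) < cp$proliferative_prob[grp[ln]],
    "proliferative", "membranous")

  ## week-52 response, drawn then realised through the response rules
  out$response <- NA_character_
  evaluable <- ln & out$upcr_baseline >= 1
  w_g2 <- if (any(evaluable)) mean(grp[evaluable] == "G2") else 0
  l0 <- solve_base_logit(cp$response_marginal["complete"], w_g2,
                         cp$g2_complete_logor)
  p_complete <- stats::plogis(l0 + ifelse(grp == "G2",
                                          cp$g2_complete_logor, 0))
  p_partial_given_not <- cp$response_marginal["partial"] /
    (cp$response_marginal["partial"] + cp$response_marginal["none"])
  u1 <- stats::runif(n); u2 <- stats::runif(n)
  out$response[evaluable] <- ifelse(
    u1[evaluable] < p_complete[evaluable], "complete",
    ifelse(u2[evaluable] < p_partial_given_not, "partial", "none"))
  out$response[ln & !evaluable] <- "not_evaluable"

  out$upcr_wk52 <- NA_real_
  out$creatinine_wk52 <- NA_real_
  out$prednisone_wk52 <- NA_real_
  draw_wk52 <- function(i) {
    b <- out$upcr_baseline[i]
    switch(out$response[i],
      complete = c(stats::runif(1, 0.05, 0.45),
                   stats::runif(1, 0.6, 1.25),
                   round(stats::runif(1, 0, 9.5), 1)),
      partial = c(stats::runif(1, 0.5, max(0.5, 0.5 * b)),
                  stats::runif(1, 0.6, 1.25),
                  round(stats::runif(1, 0, 15), 1)),
      none = c(stats::runif(1, max(0.6, 0.55 * b), max(1, 1.2 * b)),
               stats::runif(1, 0.8, 1.6),
               round(stats::runif(1, 5, 40), 1)),
      c(stats::runif(1, 0.1, 1) * b, stats::runif(1, 0.6, 1.3),
        round(stats::runif(1, 0, 20), 1)))
  }
  for (i in which(ln)) {
    w <- draw_wk52(i)
    out$upcr_wk52[i] <- w[1]
    out$creatinine_wk52[i] <- w[2]
    out$prednisone_wk52[i] <- w[3]
  }
  rownames(out) <- NULL
  out
}

#' Simulate a reduced single-panel cell mixture
#'
#' A light-weight generator used to calibrate the neighborhood
#' differential-abundance machinery: `k` Gaussian cell subsets on
#' orthogonal axes in `n_markers` dimensions, a per-sample logistic-normal
#' composition, and an optional planted expansion of one subset in
#' phenotype-positive samples. Values are returned on the transformed
#' (analysis) scale.
#'
#' @param n_per_arm samples per phenotype arm.
#' @param cells_per_sample cells per sample.
#' @param baseline_props baseline subset proportions (defines `k`).
#' @param n_markers dimensionality (default `max(5, k)`).
#' @param separation distance of each subset centroid from the origin in
#'   per-marker SD units (default 4, a clearly separated mixture as is
#'   typical of lineage-resolved cytometry subsets).
#' @param expanded_subset index of the subset expanded in the positive arm,
#'   or `NULL` for a null draw.
#' @param expansion_logfc planted log fold change (default `log(2)`).
#' @param alr_sd between-sample compositional noise SD.
#' @param seed integer seed.
#' @return list with `values`, `sample`, `phenotype` (0/1 per sample),
#'   `subset` (true per-cell subset index).
#' @export
simulate_subset_mixture <- function(n_per_arm = 20, cells_per_sample = 1000,
                                    baseline_props = c(0.35, 0.3, 0.2, 0.1,
                                                       0.05),
                                    n_markers = NULL, separation = 4,
                                    expanded_subset = NULL,
                                    expansion_logfc = log(2),
                                    alr_sd = 0.2, seed = 1L) {
  set.seed(as.integer(seed))
  k <- length(baseline_props)
  p <- n_markers %||% max(5L, k)
  stopifnot(p >= k, abs(sum(baseline_props) - 1) < 1e-9)
  centroids <- matrix(0, k, p)
  centroids[cbind(seq_len(k), seq_len(k))] <- separation
  n_samp <- 2L * n_per_arm
  phenotype <- rep(c(0L, 1L), each = n_per_arm)
  sample_id <- sprintf("S%03d", seq_len(n_samp))
  vals <- matrix(0, n_samp * cells_per_sample, p)
  colnames(vals) <- sprintf("m%02d", seq_len(p))
  subset <- integer(nrow(vals))
  cell_sample <- integer(nrow(vals))
  for (i in seq_len(n_samp)) {
    lfc <- rep(0, k)
    if (!is.null(expanded_subset) && phenotype[i] == 1L)
      lfc[expanded_subset] <- expansion_logfc
    pr <- rlogisticnormal(baseline_props, lfc, alr_sd)
    cnt <- stats::rmultinom(1, cells_per_sample, pr)[, 1]
    sub <- rep.int(seq_len(k), cnt)
    rows <- (i - 1L) * cells_per_sample + seq_len(cells_per_sample)
    vals[rows, ] <- centroids[sub, , drop = FALSE] +
      matrix(stats::rnorm(cells_per_sample * p), cells_per_sample, p)
    subset[rows] <- sub
    cell_sample[rows] <- i
  }
  list(values = vals,
       sample = factor(sample_id[cell_sample], levels = sample_id),
       phenotype = stats::setNames(phenotype, sample_id), subset = subset)
}
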