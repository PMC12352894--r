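## Run configuration and the end-to-end orchestrated analysis:
## simulate -> transform -> QC -> batch correction -> two-level clustering
## -> signatures -> (optional neighborhood DA) -> stratification ->
## clinical associations, with a reproducibility manifest.

#' Build a run configuration
#'
#' All module parameters in one serializable object. Every stochastic
#' stage draws its own seed, derived deterministically from the master
#' seed (see [derive_seeds()]), and all seeds are recorded in the run
#' manifest.
#'
#' @param seed master seed.
#' @param design a [cohort_design()] (or list of its arguments) for the
#'   simulate stage.
#' @param cofactor arcsinh cofactor.
#' @param n_anchors,batch_iter batch-correction parameters.
#' @param k_neighbors,lineage_resolution,subset_resolution,min_size,
#'   lineage_graph_cells,subset_graph_cells,subset_pca_dims clustering
#'   parameters.
#' @param gate_quantile control quantile defining positivity gates.
#' @param K,restarts stratification parameters.
#' @param run_nda run the neighborhood differential-abundance stage
#'   (disease vs control, per panel) on `nda_cells` subsampled cells.
#' @param nda_cells,n_steps,n_perms,fdr_q neighborhood-DA parameters.
#' @param run_clinical simulate and analyse the clinical table.
#' @param out_dir optional output directory for stage CSVs + manifest.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, design = cohort_design(seed = 1L),
                       cofactor = 5, n_anchors = 20, batch_iter = 2,
                       k_neighbors = 30, lineage_resolution = 1,
                       subset_resolution = 1, min_size = 50,
                       lineage_graph_cells = 8000,
                       subset_graph_cells = 10000, subset_pca_dims = 15,
                       gate_quantile = 0.99, K = 3, restarts = 50,
                       run_nda = FALSE, nda_cells = 20000, n_steps = 3,
                       n_perms = 1000, fdr_q = 0.05,
                       run_clinical = TRUE, out_dir = NULL) {
  if (!inherits(design, "cohort_design"))
    design <- do.call(cohort_design, design)
  cfg <- list(seed = as.integer(seed), design = design, cofactor = cofactor,
              n_anchors = n_anchors, batch_iter = batch_iter,
              k_neighbors = k_neighbors,
              lineage_resolution = lineage_resolution,
              subset_resolution = subset_resolution, min_size = min_size,
              lineage_graph_cells = lineage_graph_cells,
              subset_graph_cells = subset_graph_cells,
              subset_pca_dims = subset_pca_dims,
              gate_quantile = gate_quantile, K = K, restarts = restarts,
              run_nda = run_nda, nda_cells = nda_cells, n_steps = n_steps,
              n_perms = n_perms, fdr_q = fdr_q,
              run_clinical = run_clinical, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' The write-read-write round trip is byte-identical.
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns the `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$design <- unclass(x$design)
  x$design$n_per_group <- as.list(x$design$n_per_group)
  x$design$lineage_fractions <- as.list(x$design$lineage_fractions)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$design$n_per_group <- unlist(x$design$n_per_group)
  x$design$lineage_fractions <- unlist(x$design$lineage_fractions)
  design <- do.call(cohort_design, x$design)
  do.call(run_config, c(list(design = design),
                        x[setdiff(names(x), "design")]))
}

## subset an event_set to a set of samples
filter_event_set <- function(e, keep_ids) {
  keep <- as.character(e$sample) %in% keep_ids
  e$values <- e$values[keep, , drop = FALSE]
  e$sample <- factor(as.character(e$sample)[keep], levels = keep_ids)
  e
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (simulate, transform, QC, batch
#' correction, lineage and subset clustering, signatures, optional
#' neighborhood DA, stratification, clinical associations) and returns a
#' `cytostrat_run` with all stage outputs plus a manifest (settings,
#' derived seeds, file hashes when `out_dir` is set) that allows an exact
#' re-run.
#'
#' @param config a [run_config()].
#' @param cohort optionally, a pre-simulated [simulate_cohort()] output to
#'   analyse instead of simulating inside the run.
#' @return object of class `cytostrat_run`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 8L)
  names(seeds) <- c("simulate", "batch", "lineage_prov", "lineage",
                    "subset", "nda", "kmeans", "clinical")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## -- simulate ---------------------------------------------------------
  if (is.null(cohort)) {
    design <- config$design
    design$seed <- seeds[["simulate"]]
    cohort <- stage("simulate", simulate_cohort(design))
  }
  meta <- cohort$metadata
  panels <- cohort$panels

  ## -- transform + provisional lineage clustering + QC ------------------
  ## (panel by panel, releasing the raw-scale copy as we go)
  events <- list()
  for (pn in names(cohort$events)) {
    events[[pn]] <- arcsinh_transform(cohort$events[[pn]],
                                      cofactor = config$cofactor)
    cohort$events[pn] <- list(NULL)
  }
  prov <- list(); reports <- list()
  kept <- meta$sample_id
  for (pn in names(events)) {
    e <- events[[pn]]
    cl <- stage("qc-clustering", cluster_cells(
      e$values, e$sample, markers = panels[[pn]]$lineage_markers,
      k_neighbors = config$k_neighbors,
      resolution = config$lineage_resolution,
      seed = seeds[["lineage_prov"]], level = "lineage",
      min_size = config$min_size,
      max_graph_cells = min(4000L, config$lineage_graph_cells),
      compute_profiles = FALSE))
    prov[[pn]] <- cl
    ids <- intersect(meta$sample_id, unique(cl$labels$sample_id))
    qc <- stage("qc", qc_filter(
      ids, stats::setNames(meta$viability, meta$sample_id), cl$labels))
    qc$report$panel <- pn
    reports[[pn]] <- qc$report
    kept <- setdiff(kept, setdiff(ids, qc$kept))
  }
  qc_report <- do.call(rbind, reports)
  events <- lapply(events, filter_event_set, keep_ids = kept)
  meta_kept <- meta[meta$sample_id %in% kept, , drop = FALSE]

  ## -- batch correction -------------------------------------------------
  batch_map <- stats::setNames(meta$batch, meta$sample_id)
  events <- lapply(names(events), function(pn) stage("batch",
    correct_batches(events[[pn]], batch_map, n_anchors = config$n_anchors,
                    max_iter = config$batch_iter,
                    seed = seeds[["batch"]])))
  names(events) <- names(cohort$events)

  ## -- final two-level clustering --------------------------------------
  lineage_labels <- list(); subset_labels <- list()
  for (pn in names(events)) {
    e <- events[[pn]]
    lin <- stage("lineage-clustering", cluster_cells(
      e$values, e$sample, markers = panels[[pn]]$lineage_markers,
      k_neighbors = config$k_neighbors,
      resolution = config$lineage_resolution, seed = seeds[["lineage"]],
      level = "lineage", min_size = config$min_size,
      max_graph_cells = config$lineage_graph_cells,
      compute_profiles = FALSE))
    lineage_labels[[pn]] <- lin$labels
    ## subsets are resolved within each panel's focus lineage
    focus <- pn
    rows <- which(lin$labels$lineage == focus)
    sub <- stage("subset-clustering", cluster_cells(
      e$values[rows, , drop = FALSE], e$sample[rows],
      k_neighbors = config$k_neighbors,
      resolution = config$subset_resolution, seed = seeds[["subset"]],
      level = "subset", min_size = config$min_size,
      max_graph_cells = config$subset_graph_cells,
      pca_dims = config$subset_pca_dims))
    subset_labels[[pn]] <- data.frame(
      sample_id = sub$labels$sample_id,
      subset = paste(pn, sub$labels$cluster, sep = "."),
      lineage = focus, stringsAsFactors = FALSE)
    attr(subset_labels[[pn]], "profiles") <- sub$profiles
  }

  ## -- signatures -------------------------------------------------------
  all_subset_labels <- do.call(rbind, subset_labels)
  abundance <- stage("abundance",
                     subset_proportions(all_subset_labels, kept))
  summaries <- stage("ifn-summaries",
                     ifn_marker_summaries(events, lineage_labels))
  control_ids <- meta_kept$sample_id[meta_kept$group == "control"]
  ref <- stage("ifn-reference",
               fit_ifn_reference(summaries[control_ids, , drop = FALSE]))
  scores <- ifn_score(summaries, ref)
  elevated <- ifn_elevated(scores, ref)
  gates <- stage("gates", default_gates(events, control_ids,
                                        probs = config$gate_quantile))
  signatures <- stage("signatures",
                      simplified_signatures(events, lineage_labels, gates,
                                            ref = ref))

  ## granzyme-B signature: total abundance of subsets whose median
  ## granzyme B exceeds the gate (anchoring tie-break + recovery tests)
  gz_cols <- unlist(lapply(names(subset_labels), function(pn) {
    pr <- attr(subset_labels[[pn]], "profiles")
    if (!"GranzymeB" %in% colnames(pr)) return(character(0))
    paste(pn, rownames(pr)[pr[, "GranzymeB"] > gates["GranzymeB"]],
          sep = ".")
  }))
  gz_cols <- intersect(gz_cols, colnames(abundance))
  gzmb_sig <- if (length(gz_cols))
    rowSums(abundance[, gz_cols, drop = FALSE]) else
    stats::setNames(rep(0, nrow(abundance)), rownames(abundance))

  ## -- optional neighborhood DA ----------------------------------------
  nda <- NULL
  if (isTRUE(config$run_nda)) {
    nda <- list()
    disease <- stats::setNames(as.numeric(meta_kept$disease == "LN"),
                               meta_kept$sample_id)
    for (pn in names(events)) {
      e <- events[[pn]]
      set.seed(seeds[["nda"]])
      idx <- sort(sample.int(nrow(e$values),
                             min(config$nda_cells, nrow(e$values))))
      g <- knn_graph(e$values[idx, , drop = FALSE],
                     k = config$k_neighbors)
      nam <- build_nam(g, e$sample[idx], n_steps = config$n_steps)
      nda[[pn]] <- stage("nda", nda_associate(
        nam, disease[rownames(nam)], n_perms = config$n_perms,
        seed = seeds[["nda"]], fdr_q = config$fdr_q))
    }
  }

  ## -- stratification ---------------------------------------------------
  features <- stage("features", build_features(abundance, scores))
  km <- stage("kmeans", kmeans_stratify(features, K = config$K,
                                        restarts = config$restarts,
                                        seed = seeds[["kmeans"]]))
  control_mask <- stats::setNames(meta$group == "control", meta$sample_id)
  assignment <- stage("anchoring",
                      anchor_group_labels(km$cluster, control_mask, scores,
                                          gzmb_sig))
  pca <- stage("pca", pca_embed(features))

  ## -- clinical ---------------------------------------------------------
  clinical <- NULL; clinical_tests <- NULL
  if (isTRUE(config$run_clinical)) {
    clinical <- stage("clinical", simulate_clinical(
      cohort$truth, seed = seeds[["clinical"]]))
    m <- merge(clinical, assignment, by = "sample_id")
    ln_rows <- !is.na(m$activity_index)
    clinical_tests <- list(
      activity = compare_groups(m$activity_index[ln_rows],
                                m$group.y[ln_rows]),
      chronicity = compare_groups(m$chronicity_index[ln_rows],
                                  m$group.y[ln_rows]))
  }

  run <- structure(list(
    config = config, seeds = seeds, metadata = meta,
    qc_report = qc_report, kept = kept, abundance = abundance,
    ifn = list(summaries = summaries, reference = ref, scores = scores,
               elevated = elevated),
    gates = gates, signatures = signatures, gzmb_signature = gzmb_sig,
    lineage_labels = lineage_labels, subset_labels = all_subset_labels,
    nda = nda, features = features, kmeans = km, assignment = assignment,
    pca = pca, clinical = clinical, clinical_tests = clinical_tests,
    truth = cohort$truth), class = "cytostrat_run")
  if (!is.null(config$out_dir)) run$manifest <- write_run(run,
                                                          config$out_dir)
  run
}

## write stage outputs as CSV and return the manifest
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(x, f, row.names = FALSE)
    f
  }
  ab <- data.frame(sample_id = rownames(run$abundance),
                   as.data.frame(unclass(run$abundance),
                                 check.names = FALSE))
  files <- c(
    w(run$qc_report, "qc_report.csv"),
    w(ab, "abundance.csv"),
    w(data.frame(sample_id = names(run$ifn$scores),
                 ifn_score = unname(run$ifn$scores),
                 elevated = unname(run$ifn$elevated)), "ifn_scores.csv"),
    w(run$signatures, "signatures.csv"),
    w(as.data.frame(run$assignment), "assignment.csv"),
    w(data.frame(sample_id = rownames(run$pca$scores),
                 run$pca$scores), "pca_scores.csv"),
    w(data.frame(feature = rownames(run$pca$loadings),
                 run$pca$loadings), "pca_loadings.csv"))
  if (!is.null(run$clinical)) files <- c(files,
                                         w(run$clinical, "clinical.csv"))
  manifest <- list(
    package = "cytostrat",
    version = as.character(utils::packageVersion("cytostrat")),
    seed = run$config$seed, seeds = as.list(run$seeds),
    settings = lapply(unclass(run$config)[
      setdiff(names(unclass(run$config)), c("design", "out_dir"))],
      identity),
    design = lapply(unclass(run$config$design), function(v)
      if (is.numeric(v)) unname(v) else v),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' @export
print.cytostrat_run <- function(x, ...) {
  cat("cytostrat pipeline run\n")
  cat(sprintf("  samples: %d kept of %d (QC)\n", length(x$kept),
              nrow(x$metadata)))
  cat(sprintf("  subsets: %d across %d panels\n", ncol(x$abundance),
              length(x$lineage_labels)))
  cat(sprintf("  IFN-I elevation threshold: %.3f; %d%% of LN samples elevated\n",
              x$ifn$reference$threshold,
              round(100 * mean(x$ifn$elevated[
                x$metadata$sample_id[x$metadata$disease == "LN"]],
                na.rm = TRUE))))
  print(table(anchored = x$assignment$group))
  invisible(x)
}

#' @export
summary.cytostrat_run <- function(object, ...) {
  x <- object
  truth_grp <- x$truth$sample_group[x$assignment$sample_id]
  planted <- ifelse(truth_grp == "control", "G0", truth_grp)
  cat("Anchored vs planted groups:\n")
  print(table(anchored = x$assignment$group, planted = planted))
  cat(sprintf("ARI = %.3f\n",
              adjusted_rand_index(x$assignment$group, planted)))
  if (!is.null(x$clinical_tests)) {
    cat(sprintf("Kruskal-Wallis activity p = %.3g, chronicity p = %.3g\n",
                x$clinical_tests$activity$kw_p,
                x$clinical_tests$chronicity$kw_p))
  }
  invisible(x)
}
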