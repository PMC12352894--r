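## Default marker panels, cell-subset templates, and patient-group effect
## profiles for the synthetic lupus-nephritis cohort.
##
## Four overlapping 48-marker staining panels (T, B, myeloid, NK) share a
## core of phenotyping markers used for major-lineage separation; each panel
## adds lineage-specific markers and carries at most one of the three
## IFN-I score markers (MX1 on the T panel, ISG15 on the B panel,
## Siglec-1 on the myeloid panel).

CORE_MARKERS <- c("CD45", "CD3", "CD4", "CD8a", "CD19", "CD20", "CD14",
                  "CD16", "CD56", "CD11b", "CD11c", "CD15", "HLA-DR",
                  "CD38", "CD27", "Ki67")

## markers shared across panels that drive lineage-level clustering
LINEAGE_MARKERS <- c("CD3", "CD4", "CD8a", "CD19", "CD20", "CD14", "CD16",
                     "CD56", "CD11b", "CD11c", "CD15", "HLA-DR")

## canonical markers used to give lineage-level clusters a semantic label
CANONICAL_MARKERS <- list(
  T = "CD3", B = c("CD19", "CD20"), myeloid = c("CD14", "CD11b"), NK = "CD56")

#' Default panel configuration
#'
#' Returns the four-panel design used by the synthetic cohort. Each panel
#' is a list with `panel_name`, `markers` (48 names), `lineage_markers`
#' (shared phenotyping core) and `score_markers` (which of MX1/ISG15/SIGLEC1
#' the panel carries). Jointly the panels carry all three score markers.
#'
#' @return named list of panel configurations.
#' @export
default_panels <- function() {
  t_extra <- c("CD45RA", "CD45RO", "CCR7", "CD25", "CD127", "PD-1", "ICOS",
               "CXCR5", "TCF1", "GranzymeB", "Perforin", "CD57", "CD28",
               "CD95", "TIGIT", "CD226", "OX40", "CD161", "CCR6", "CXCR3",
               "CCR4", "CD69", "CD103", "FoxP3", "T-bet", "Eomes", "MX1",
               "CD5", "CD7", "CD2", "GITR", "LAG-3")
  b_extra <- c("CD21", "IgD", "IgM", "IgA", "IgG", "CD10", "CD23", "CD24",
               "CD1c", "CD5", "CD9", "CD22", "CD40", "CD72", "CD79b",
               "CD86", "CXCR4", "CXCR5", "CCR6", "CD62L", "T-bet", "TACI",
               "BAFF-R", "CD95", "FcRL4", "FcRL5", "CD32", "ISG15", "CD43",
               "CD71", "CD138", "CD31")
  m_extra <- c("Siglec-1", "CD86", "CD163", "CD123", "IRF8", "CD64", "CD36",
               "CD33", "CD1c", "CD141", "CD206", "CD209", "CX3CR1", "CCR2",
               "CD115", "CD66b", "CD10", "CD62L", "CD101", "CD24", "CD45RA",
               "CD172a", "CD88", "CD89", "CD40", "CD80", "PD-L1", "TREM2",
               "MerTK", "CD93", "FceRI", "CD32")
  nk_extra <- c("CD57", "NKG2D", "NKG2A", "NKG2C", "NKp30", "NKp44",
                "NKp46", "KIR2DL1", "KIR3DL1", "GranzymeB", "GranzymeK",
                "Perforin", "CD69", "CD94", "CD62L", "CX3CR1", "CD2", "CD7",
                "DNAM-1", "TIGIT", "T-bet", "Eomes", "CD122", "CD127",
                "CD25", "CD45RA", "FasL", "TRAIL", "CD160", "2B4",
                "Siglec-7", "KLRG1")
  mk <- function(name, extra, score) {
    markers <- c(CORE_MARKERS, extra)
    stopifnot(!anyDuplicated(markers), length(markers) == 48L)
    list(panel_name = name, markers = markers,
         lineage_markers = LINEAGE_MARKERS, score_markers = score)
  }
  list(T = mk("T", t_extra, "MX1"),
       B = mk("B", b_extra, "ISG15"),
       myeloid = mk("myeloid", m_extra, "Siglec-1"),
       NK = mk("NK", nk_extra, character(0)))
}

## intensity anchors on the arcsinh scale
.HI <- 3.0
.MID <- 1.5
.LO <- 0.3
## score / gating markers are kept away from the zero-censoring boundary
.LO_SCORE <- 1.0

#' Default cell-subset templates
#'
#' A catalog of 23 cell subsets across the four major lineages, each with a
#' mean marker profile on the arcsinh scale, a common per-marker dispersion,
#' and a baseline within-lineage fraction (fractions sum to 1 per lineage).
#' The catalog is deliberately smaller than a real 55-subset CyTOF analysis
#' but carries every population the pipeline's signatures depend on:
#' MX1-high naive T cells, granzyme B+ (Ki67- and Ki67+) T cells, Tph cells,
#' CD21-low naive B cells, transitional B cells, plasmablasts, Siglec-1-high
#' monocytes, low-density neutrophils, and proliferating NK cells.
#'
#' @param dispersion per-marker SD on the arcsinh scale (default 0.5).
#' @return list of subset templates (`subset_name`, `lineage`,
#'   `mean_profile` named vector over the full marker universe,
#'   `dispersion`, `baseline_fraction`).
#' @export
default_subset_templates <- function(dispersion = 0.5) {
  panels <- default_panels()
  universe <- unique(unlist(lapply(panels, `[[`, "markers")))
  base <- stats::setNames(rep(.LO, length(universe)), universe)
  base[c("MX1", "ISG15", "Siglec-1")] <- .LO_SCORE
  base["CD21"] <- .LO_SCORE  # gated median must sit above the censor point
  base["CD45"] <- .HI
  tmpl <- function(name, lineage, frac, hi = character(0), mid = character(0),
                   lo = character(0), set = NULL) {
    p <- base
    p[hi] <- .HI; p[mid] <- .MID; p[lo] <- .LO
    if (!is.null(set)) p[names(set)] <- set
    list(subset_name = name, lineage = lineage, mean_profile = p,
         dispersion = stats::setNames(rep(dispersion, length(universe)),
                                      universe),
         baseline_fraction = frac)
  }
  list(
    ## --- T lineage -----------------------------------------------------
    tmpl("T0_naive_CD4", "T", 0.30,
         hi = c("CD3", "CD4", "CD45RA", "CCR7", "TCF1", "CD5", "CD7", "CD2",
                "CD28", "CD127")),
    tmpl("T2_naive_CD4_MX1hi", "T", 0.06,
         hi = c("CD3", "CD4", "CD45RA", "CCR7", "CD5", "CD7", "CD2", "CD28",
                "CD127"),
         mid = "TCF1", set = c(MX1 = 2.5)),
    tmpl("T1_mem_CD4", "T", 0.25,
         hi = c("CD3", "CD4", "CD45RO", "CD5", "CD7", "CD2", "CD28",
                "CD127"), mid = c("CCR6", "CXCR3")),
    tmpl("T11_Tph", "T", 0.04,
         hi = c("CD3", "CD4", "CD45RO", "PD-1", "ICOS", "Ki67", "CD5",
                "CD7", "CD2"), lo = "CXCR5"),
    tmpl("T3_naive_CD8", "T", 0.12,
         hi = c("CD3", "CD8a", "CD45RA", "CCR7", "TCF1", "CD5", "CD7",
                "CD2")),
    tmpl("T5_mem_CD8", "T", 0.13,
         hi = c("CD3", "CD8a", "CD45RO", "CD5", "CD7", "CD2"),
         mid = "CXCR3"),
    tmpl("T4_gzmB_CD8", "T", 0.07,
         hi = c("CD3", "CD8a", "GranzymeB", "Perforin", "CD57", "CD45RA",
                "CD7", "CD2"), mid = "T-bet"),
    tmpl("T13_gzmB_Ki67", "T", 0.03,
         hi = c("CD3", "CD8a", "GranzymeB", "Ki67", "CD38", "CD7", "CD2"),
         mid = "Perforin"),
    ## --- B lineage -----------------------------------------------------
    tmpl("B0_naive", "B", 0.55,
         hi = c("CD19", "CD20", "IgD", "IgM", "CD23", "HLA-DR", "CD24",
                "CD79b", "CD22", "CD32"), set = c(CD21 = 3.0)),
    tmpl("B3_naive_CD21lo", "B", 0.08,
         hi = c("CD19", "CD20", "IgD", "IgM", "CD79b", "CD22"),
         mid = c("CD38", "HLA-DR"), set = c(CD21 = 1.0, CD23 = 0.3)),
    tmpl("B2_memory", "B", 0.20,
         hi = c("CD19", "CD20", "CD27", "CD79b", "CD22", "HLA-DR"),
         mid = "IgG", set = c(CD21 = 3.0)),
    tmpl("B6_transitional", "B", 0.07,
         hi = c("CD19", "CD20", "CD24", "CD38", "CD10", "IgM", "HLA-DR"),
         mid = "IgD", set = c(CD21 = 1.5)),
    tmpl("B8_plasmablast_Ki67", "B", 0.04,
         hi = c("CD27", "CD38", "Ki67", "CD71", "CD138"),
         mid = c("CD19", "HLA-DR"), lo = "CD20"),
    tmpl("B5_CD11c", "B", 0.06,
         hi = c("CD19", "CD20", "CD11c", "T-bet", "FcRL5", "HLA-DR"),
         lo = "CD23", set = c(CD21 = 0.5)),
    ## --- myeloid lineage ----------------------------------------------
    tmpl("M0_CD14_mono", "myeloid", 0.55,
         hi = c("CD14", "CD11b", "CD33", "CD64", "CD36", "HLA-DR", "CD86",
                "CCR2", "CD93")),
    tmpl("M2_CD16_mono", "myeloid", 0.12,
         hi = c("CD16", "CD11b", "CX3CR1", "HLA-DR", "CD86"),
         mid = c("CD14", "CD33")),
    tmpl("M1_Siglec1_mono", "myeloid", 0.10,
         hi = c("CD14", "CD11b", "CD33", "CD64", "HLA-DR", "CD86"),
         set = c("Siglec-1" = 2.5)),
    tmpl("M4_cDC", "myeloid", 0.08,
         hi = c("CD1c", "CD11c", "HLA-DR", "CD86", "FceRI"),
         lo = "CD14"),
    tmpl("M6_pDC", "myeloid", 0.07,
         hi = c("CD123", "IRF8", "HLA-DR"), lo = c("CD14", "CD11c")),
    tmpl("M3_LDN", "myeloid", 0.08,
         hi = c("CD15", "CD16", "CD11b", "CD66b", "CD10"),
         lo = c("CD14", "HLA-DR")),
    ## --- NK lineage ----------------------------------------------------
    tmpl("NK0_CD56dim", "NK", 0.70,
         hi = c("CD16", "CD57", "GranzymeB", "Perforin", "NKp46", "CD7",
                "CD2", "2B4"), mid = "CD56"),
    tmpl("NK1_CD56bright", "NK", 0.18,
         hi = c("CD56", "CD94", "NKG2A", "CD62L", "NKp46", "CD7", "CD127"),
         lo = "CD16"),
    tmpl("NK4_Ki67", "NK", 0.12,
         hi = c("Ki67", "NKG2D", "NKp46", "CD7", "CD38"), mid = "CD56")
  )
}

#' Default patient-group effect profiles
#'
#' Planted effects for the three synthetic patient groups. `G0` carries no
#' effects (control-like by construction). `G1` (IFN-high) shifts the three
#' IFN-induced score markers up by `ifn_shift_sd` cell-level SDs in every
#' subset and expands IFN-co-regulated subsets. `G2` (cytotoxic-enriched)
#' expands granzyme B+ T subsets, CD21-low naive B cells and low-density
#' neutrophils, shifts CD21 down in naive B cells, and shows an intermediate
#' IFN shift. Both active groups expand the Ki67+ proliferating T-B subsets.
#'
#' Effect sizes are expressed as within-lineage log fold changes
#' (`proportion_logfc`) and additive marker shifts in units of the subset's
#' per-marker SD (`marker_shift`, entries `list(subsets, marker, sd_units)`;
#' `subsets = NULL` means all subsets whose panel carries the marker).
#'
#' @param ifn_shift_sd score-marker shift for G1 in cell-SD units
#'   (default 2); G2 receives half of it.
#' @param expansion_logfc log fold change for expanded subsets
#'   (default `log(2)`).
#' @return named list of effect profiles for groups `G0`, `G1`, `G2`.
#' @export
default_group_effects <- function(ifn_shift_sd = 2, expansion_logfc = log(2)) {
  lfc <- expansion_logfc
  list(
    G0 = list(group = "G0", proportion_logfc = numeric(0),
              marker_shift = list()),
    G1 = list(
      group = "G1",
      proportion_logfc = c(T2_naive_CD4_MX1hi = lfc, B6_transitional = lfc,
                           NK4_Ki67 = lfc, M1_Siglec1_mono = lfc,
                           T11_Tph = lfc, B8_plasmablast_Ki67 = lfc,
                           T13_gzmB_Ki67 = 0.5 * lfc),
      marker_shift = list(
        list(subsets = NULL, marker = "MX1", sd_units = ifn_shift_sd),
        list(subsets = NULL, marker = "ISG15", sd_units = ifn_shift_sd),
        list(subsets = NULL, marker = "Siglec-1", sd_units = ifn_shift_sd))),
    G2 = list(
      group = "G2",
      proportion_logfc = c(T4_gzmB_CD8 = lfc, T13_gzmB_Ki67 = lfc,
                           B3_naive_CD21lo = lfc, M3_LDN = lfc,
                           T11_Tph = lfc, B8_plasmablast_Ki67 = lfc),
      marker_shift = list(
        list(subsets = c("B0_naive", "B3_naive_CD21lo"), marker = "CD21",
             sd_units = -2),
        list(subsets = NULL, marker = "MX1", sd_units = ifn_shift_sd / 2),
        list(subsets = NULL, marker = "ISG15", sd_units = ifn_shift_sd / 2),
        list(subsets = NULL, marker = "Siglec-1",
             sd_units = ifn_shift_sd / 2)))
  )
}

## granzyme B+ subsets used for the G1/G2 anchoring tie-break and for
## recovery tests
GZMB_SUBSETS <- c("T4_gzmB_CD8", "T13_gzmB_Ki67")
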