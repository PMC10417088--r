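#' Cell types covered by the liver-tumor reference signature
#'
#' The reference covers one tumor cell type (an HCC cell line) plus sixteen
#' immune cell types, including polarized macrophage forms (M1 induced by
#' IFN-gamma, IFN-gamma + TNF, or LPS; M2 induced by IL4 + dexamethasone;
#' M2a; M2c), dendritic cells, NK cells, B-cell and CD8/CD4 T-cell subsets.
#'
#' @return Character vector of the 17 cell-type labels. The tumor label is
#'   `"HCC"`; the remaining 16 labels are immune cell types.
#' @export
#' @examples
#' hcc_cell_types()
hcc_cell_types <- function() {
  c("HCC",
    "M1_IFNg", "M1_IFNg_TNF", "M1_LPS",
    "M2_IL4_Dex", "M2a", "M2c",
    "DC", "NK",
    "B_memory", "B_naive",
    "CD8_Tmem", "CD8_Tnaive",
    "CD4_Tnaive", "Treg", "Th1", "Th2")
}

#' Label used for the tumor (HCC cell line) component
#' @return The string `"HCC"`.
#' @export
hcc_tumor_label <- function() "HCC"

#' Cell-type groups used for signature gene selection
#'
#' Differential-expression ranking is run within seven groups: the group of
#' all 17 cell types, plus six groups of closely related immune subsets whose
#' expression profiles are highly correlated (macrophage M1 forms, macrophage
#' M2 forms, B cells, CD8 T cells, CD4 T-helper lineage, and NK/dendritic
#' cells). Ranking genes within each correlated subset recovers markers that
#' a single 17-way comparison would miss, and counters multicollinearity in
#' the downstream regression.
#'
#' @return Named list mapping group id to a character vector of member cell
#'   types. The first element (`all`) contains all 17 types; each immune type
#'   additionally belongs to exactly one of the six subset groups.
#' @export
#' @examples
#' names(hcc_cell_groups())
hcc_cell_groups <- function() {
  list(
    all = hcc_cell_types(),
    M1  = c("M1_IFNg", "M1_IFNg_TNF", "M1_LPS"),
    M2  = c("M2_IL4_Dex", "M2a", "M2c"),
    B   = c("B_memory", "B_naive"),
    CD8 = c("CD8_Tmem", "CD8_Tnaive"),
    CD4 = c("CD4_Tnaive", "Treg", "Th1", "Th2"),
    innate = c("NK", "DC")
  )
}

#' Default replicate counts per reference cell type
#'
#' Number of replicate profiles per cell type used by the synthetic reference
#' generator (204 samples in total: 19 tumor plus 185 immune).
#'
#' @return Named integer vector (cell type -> replicate count).
#' @export
hcc_replicate_counts <- function() {
  c(HCC = 19L,
    M1_IFNg = 9L, M1_IFNg_TNF = 4L, M1_LPS = 6L,
    M2_IL4_Dex = 15L, M2a = 12L, M2c = 8L,
    DC = 13L, NK = 12L,
    B_memory = 18L, B_naive = 25L,
    CD8_Tmem = 12L, CD8_Tnaive = 15L,
    CD4_Tnaive = 10L, Treg = 10L, Th1 = 7L, Th2 = 9L)
}

#' Default fine-to-coarse cell-type aggregation mapping
#'
#' Benchmark datasets typically report fractions only for parent populations
#' (e.g., total CD8 T cells, total monocytes/macrophages), so predicted
#' subtype fractions are summed onto those parents before scoring. This is
#' the default mapping: macrophage polarization forms map to a single
#' monocyte/macrophage lineage, CD8 subsets to CD8 T, the CD4 helper lineage
#' (naive CD4, Treg, Th1, Th2) to CD4 T, and B-cell subsets to B cells.
#'
#' @return Named character vector (fine label -> coarse label). The special
#'   coarse label `"DROP"` marks fractions discarded from scoring.
#' @export
hcc_default_mapping <- function() {
  c(HCC = "HCC",
    M1_IFNg = "Mono_Mac", M1_IFNg_TNF = "Mono_Mac", M1_LPS = "Mono_Mac",
    M2_IL4_Dex = "Mono_Mac", M2a = "Mono_Mac", M2c = "Mono_Mac",
    DC = "DC", NK = "NK",
    B_memory = "B", B_naive = "B",
    CD8_Tmem = "CD8_T", CD8_Tnaive = "CD8_T",
    CD4_Tnaive = "CD4_T", Treg = "CD4_T", Th1 = "CD4_T", Th2 = "CD4_T")
}
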