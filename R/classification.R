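#' Feature-class configuration
#'
#' Numeric definitions of the candidate histopathologic features, following
#' the conventional literature definitions: a tumor bud is a detached
#' pan-CK-positive cluster of at most `bud_max_nuclei` tumor cells, a poorly
#' differentiated cluster (PDC) one of at least `pdc_min_nuclei`; an
#' intravascular cluster with fewer than `lvi_min_nuclei_full` tumor cells
#' is "minimal" lymphatic vessel invasion, otherwise full LVI.  An
#' epithelial object counts as intravascular when at least
#' `vessel_overlap_fraction` of its pixels lie within a vessel region
#' (ring + lumen), so vessels merely brushing a gland are not counted.
#'
#' @param bud_max_nuclei maximum nuclei in a tumor bud (default 4).
#' @param pdc_min_nuclei minimum nuclei in a PDC (default 5).
#' @param lvi_min_nuclei_full minimum intravascular nuclei for full LVI
#'   (default 5; below it the event is minimal LVI).
#' @param vessel_overlap_fraction required overlap of an epithelial object
#'   with a vessel region to call it intravascular (default 0.5).
#' @return a named list of class `feature_class_config`.
#' @export
feature_class_config <- function(bud_max_nuclei = 4L, pdc_min_nuclei = 5L,
                                 lvi_min_nuclei_full = 5L,
                                 vessel_overlap_fraction = 0.5) {
  stopifnot(bud_max_nuclei >= 1, pdc_min_nuclei > bud_max_nuclei,
            lvi_min_nuclei_full >= 1,
            vessel_overlap_fraction > 0, vessel_overlap_fraction <= 1)
  structure(list(bud_max_nuclei = as.integer(bud_max_nuclei),
                 pdc_min_nuclei = as.integer(pdc_min_nuclei),
                 lvi_min_nuclei_full = as.integer(lvi_min_nuclei_full),
                 vessel_overlap_fraction = vessel_overlap_fraction),
            class = "feature_class_config")
}

#' Classify segmented objects into histopathologic features
#'
#' Sub-classifies the epithelial objects of a segmentation hierarchy into
#' tumor buds, poorly differentiated clusters and (minimal) lymphatic vessel
#' invasion events, and computes the per-field scalar summaries: bud / PDC /
#' LVI / minimal-LVI / vessel counts, summed PDC area, lymphatic vessel
#' density and tumor:stroma ratio.  Detached objects with no assigned
#' nucleus (cytokeratin debris) are classed `unresolved` and excluded from
#' the counts.
#'
#' @param h a `SegmentationHierarchy`.
#' @param cfg a [feature_class_config()].
#' @return list of class `ClassifiedField`: `objects` data frame with a
#'   `class` column, the scalar summaries (`n_buds`, `n_pdc`, `n_lvi`,
#'   `n_minimal_lvi`, `n_vessels`, `area_pdc_um2`, `lvd_per_mm2`,
#'   `tumor_stroma_pct`), and `tissue_area_mm2`.
#' @export
classify_objects <- function(h, cfg = feature_class_config()) {
  stopifnot(inherits(h, "SegmentationHierarchy"))
  obj <- h$objects
  px2 <- h$pixel_size_um^2
  obj$class <- NA_character_
  is_epi <- obj$layer == "epithelial_object"
  obj$class[obj$layer == "vessel"] <- "vessel"

  if (any(is_epi)) {
    ves_any <- h$vessel_labels > 0L
    epi_idx <- which(h$epi_labels > 0L)
    li <- as.integer(h$epi_labels[epi_idx])
    inside <- rowsum(as.numeric(ves_any[epi_idx]), li)
    tot <- tabulate(li)
    frac <- numeric(max(li)); frac[as.integer(rownames(inside))] <-
      inside[, 1] / tot[as.integer(rownames(inside))]
    for (i in which(is_epi)) {
      id <- obj$id[i]; k <- obj$nucleus_count[i]
      if (k == 0L) { obj$class[i] <- "unresolved"; next }
      if (frac[id] >= cfg$vessel_overlap_fraction) {
        obj$class[i] <- if (k < cfg$lvi_min_nuclei_full) "minimal_lvi" else "lvi"
      } else if (k <= cfg$bud_max_nuclei) {
        obj$class[i] <- "tumor_bud"
      } else if (k >= cfg$pdc_min_nuclei) {
        obj$class[i] <- "pdc"
      } else {
        obj$class[i] <- "unresolved"   # unreachable under default config
      }
    }
    n_unres <- sum(obj$class == "unresolved", na.rm = TRUE)
    if (n_unres > 0)
      message("classify_objects: ", n_unres,
              " epithelial object(s) with no assigned nucleus excluded")
  }

  roi <- h$roi
  tissue_px <- sum(unclass(roi) != ROI_LEVELS[["no_tissue"]])
  tissue_area_mm2 <- tissue_px * px2 / 1e6
  n_vessels <- sum(obj$class == "vessel", na.rm = TRUE)
  cf <- structure(list(
    objects = obj,
    n_buds = sum(obj$class == "tumor_bud", na.rm = TRUE),
    n_pdc = sum(obj$class == "pdc", na.rm = TRUE),
    n_lvi = sum(obj$class == "lvi", na.rm = TRUE),
    n_minimal_lvi = sum(obj$class == "minimal_lvi", na.rm = TRUE),
    n_vessels = n_vessels,
    area_pdc_um2 = sum(obj$area_um2[obj$class == "pdc"], na.rm = TRUE),
    lvd_per_mm2 = if (tissue_area_mm2 > 0) n_vessels / tissue_area_mm2 else NA_real_,
    tumor_stroma_pct = if (tissue_px > 0) tumor_stroma_ratio(roi) else NA_real_,
    tissue_area_mm2 = tissue_area_mm2), class = "ClassifiedField")
  cf
}

#' Summed area of poorly differentiated clusters
#'
#' The sum of the areas of all PDC-class objects in a classified field, in
#' square micrometres; 0 when the field has no PDCs.  At patient level
#' (after collation over fields) this is the AreaPDC parameter.
#'
#' @param cf a `ClassifiedField`.
#' @return numeric scalar, square micrometres.
#' @export
area_pdc <- function(cf) {
  stopifnot(inherits(cf, "ClassifiedField"))
  sum(cf$objects$area_um2[cf$objects$class == "pdc"], na.rm = TRUE)
}

#' Lymphatic vessel density
#'
#' Vessel count per square millimetre of analyzed tissue.
#'
#' @param cf a `ClassifiedField`.
#' @param tissue_area_mm2 analyzed tissue area; defaults to the field's own.
#' @return vessels per mm^2.
#' @export
compute_lvd <- function(cf, tissue_area_mm2 = cf$tissue_area_mm2) {
  stopifnot(inherits(cf, "ClassifiedField"))
  if (!is.finite(tissue_area_mm2) || tissue_area_mm2 <= 0)
    stop("tissue_area_mm2 must be positive")
  cf$n_vessels / tissue_area_mm2
}

#' Tumor:stroma ratio
#'
#' Tumor area as a percentage of the total tissue area
#' (tumor + stroma + lumen/necrosis).
#'
#' @param roi a `RoiMap`.
#' @return percentage in `[0, 100]`.
#' @export
tumor_stroma_ratio <- function(roi) {
  stopifnot(inherits(roi, "RoiMap"))
  m <- unclass(roi)
  tumor <- sum(m == ROI_LEVELS[["tumor"]])
  tissue <- sum(m != ROI_LEVELS[["no_tissue"]])
  if (tissue == 0) stop("no tissue pixels in RoiMap")
  100 * tumor / tissue
}
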