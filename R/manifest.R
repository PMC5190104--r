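#' The default multi-parametric feature manifest (123 parameters)
#'
#' Declares the feature-set extracted per field and collated per patient:
#' name, hierarchy level (roi / object / nucleus / field), source class,
#' measurement family, and the collation rule used to reduce the per-field
#' values to one data point per patient.  Extensive quantities (counts,
#' summed areas) are summed over the fields of a section; intensive ones
#' (means, ratios, intensities, texture) are averaged.
#'
#' The manifest is built from the hierarchy classes crossed with the
#' measurement families (count, area, shape, density, spatial distance,
#' intensity, texture) and has exactly 123 entries in a stable order.  The
#' headline histopathologic parameters (`n_buds`, `n_pdc`, `n_lvi`,
#' `n_minimal_lvi`, `n_vessels`, `area_pdc_um2`, `lvd_per_mm2`,
#' `tumor_stroma_pct`) lead the manifest under their canonical names.
#'
#' @return data frame of class `FeatureManifest` with columns `name`,
#'   `level`, `class`, `family`, `collation`.
#' @export
manifest_default <- function() {
  rows <- list()
  add <- function(name, level, class, family, collation)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, level = level, class = class,
      family = family, collation = collation)

  ## headline scalars (8)
  add("n_buds", "object", "tumor_bud", "count", "sum")
  add("n_pdc", "object", "pdc", "count", "sum")
  add("n_lvi", "object", "lvi", "count", "sum")
  add("n_minimal_lvi", "object", "minimal_lvi", "count", "sum")
  add("n_vessels", "object", "vessel", "count", "sum")
  add("area_pdc_um2", "object", "pdc", "sum_area", "sum")
  add("lvd_per_mm2", "field", "vessel", "density", "mean")
  add("tumor_stroma_pct", "roi", "tumor", "density", "mean")

  roi_classes <- c("tumor", "stroma", "lumen_necrosis")
  channels <- c("dapi", "panck", "d240")
  ## ROI-level morphometry + intensity + pan-CK texture (3 + 9 + 9 + 9 = 30)
  for (cl in roi_classes)
    add(sprintf("roi_%s_area_um2", cl), "roi", cl, "sum_area", "sum")
  for (cl in roi_classes) for (ch in channels)
    add(sprintf("roi_%s_mean_%s", cl, ch), "roi", cl, "intensity", "mean")
  for (cl in roi_classes) for (ch in channels)
    add(sprintf("roi_%s_sd_%s", cl, ch), "roi", cl, "intensity", "mean")
  for (cl in roi_classes) for (tx in c("contrast", "entropy", "correlation"))
    add(sprintf("roi_%s_texture_%s_panck", cl, tx), "roi", cl, "texture", "mean")

  obj_classes <- c("tumor_bud", "pdc", "lvi", "minimal_lvi", "vessel")
  ## object-level morphometry (5 * 5 + 4 + 2 + 2 = 33)
  for (cl in obj_classes)
    add(sprintf("obj_%s_sum_area_um2", cl), "object", cl, "sum_area", "sum")
  for (cl in obj_classes)
    add(sprintf("obj_%s_mean_area_um2", cl), "object", cl, "mean_area", "mean")
  for (cl in obj_classes)
    add(sprintf("obj_%s_sd_area_um2", cl), "object", cl, "sd_area", "mean")
  for (cl in obj_classes)
    add(sprintf("obj_%s_mean_roundness", cl), "object", cl, "shape", "mean")
  for (cl in obj_classes)
    add(sprintf("obj_%s_mean_elongation", cl), "object", cl, "shape", "mean")
  for (cl in setdiff(obj_classes, "vessel"))
    add(sprintf("obj_%s_mean_nuclei", cl), "object", cl, "count", "mean")
  for (cl in c("tumor_bud", "pdc")) {
    add(sprintf("obj_%s_mean_dist_tumor_um", cl), "object", cl,
        "spatial_distance", "mean")
    add(sprintf("obj_%s_sd_dist_tumor_um", cl), "object", cl,
        "spatial_distance", "mean")
  }

  nuc_classes <- c("tumor", "stroma", "tumor_bud", "pdc", "intravascular")
  ## nucleus-level (6 * 5 = 30)
  for (cl in nuc_classes)
    add(sprintf("nuc_%s_count", cl), "nucleus", cl, "count", "sum")
  for (cl in nuc_classes)
    add(sprintf("nuc_%s_mean_area_um2", cl), "nucleus", cl, "mean_area", "mean")
  for (cl in nuc_classes)
    add(sprintf("nuc_%s_sd_area_um2", cl), "nucleus", cl, "sd_area", "mean")
  for (cl in nuc_classes)
    add(sprintf("nuc_%s_mean_dapi", cl), "nucleus", cl, "intensity", "mean")
  for (cl in nuc_classes)
    add(sprintf("nuc_%s_mean_panck", cl), "nucleus", cl, "intensity", "mean")
  for (cl in nuc_classes)
    add(sprintf("nuc_%s_mean_roundness", cl), "nucleus", cl, "shape", "mean")

  ## densities, spatial statistics, DAPI texture, composition (22)
  for (cl in obj_classes)
    add(sprintf("density_%s_per_mm2", cl), "object", cl, "density", "mean")
  for (cl in c("tumor_bud", "pdc", "vessel"))
    add(sprintf("nn_dist_%s_um", cl), "object", cl, "spatial_distance", "mean")
  for (cl in roi_classes) for (tx in c("contrast", "entropy", "correlation"))
    add(sprintf("roi_%s_texture_%s_dapi", cl, tx), "roi", cl, "texture", "mean")
  for (cl in roi_classes)
    add(sprintf("roi_%s_fraction_tissue", cl), "roi", cl, "density", "mean")
  add("tissue_area_mm2", "roi", "tissue", "sum_area", "sum")
  add("n_nuclei_total", "nucleus", "all", "count", "sum")

  m <- do.call(rbind, rows)
  stopifnot(nrow(m) == 123L, !anyDuplicated(m$name),
            all(m$collation %in% c("sum", "mean")))
  class(m) <- c("FeatureManifest", "data.frame")
  m
}
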