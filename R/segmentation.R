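#' Segmentation configuration
#'
#' Threshold-and-morphology rules implementing the three-level segmentation
#' hierarchy.  The four-class region partition (tumor / stroma /
#' lumen-necrosis / no-tissue) is the contract consumed downstream; the
#' rules here are tuned to the immunofluorescence contrast model of the
#' synthetic generator and are all exposed for retuning on other material.
#'
#' @param panck_threshold,dapi_threshold,d240_threshold intensity thresholds
#'   (rasters are scaled to `[0,1]`) for epithelium, nuclei and lymphatic
#'   endothelium; defaults sit at half-amplitude between slide background
#'   and the stain plateau, which keeps blurred object boundaries unbiased.
#' @param tissue_threshold intensity above which a pixel counts as tissue
#'   (diffuse stromal signal sits above it, slide background below).
#' @param tissue_brush diameter (px) of the closing brush used to
#'   consolidate the tissue mask.
#' @param main_mass_min_um2 pan-CK components at least this large form the
#'   tumor region; smaller stromal components become detached objects.
#' @param min_object_px minimum object size in pixels (small enough to keep
#'   single-cell buds).
#' @param min_lumen_px minimum enclosed pan-CK-negative hole (px) labelled
#'   lumen/necrosis rather than absorbed into tumor.
#' @param nucleus_min_px minimum nucleus size in pixels.
#' @param watershed_tolerance,watershed_ext declumping parameters of the
#'   distance-transform watershed used to split touching nuclei.
#' @return a named list of class `seg_config`.
#' @export
seg_config <- function(panck_threshold = 0.375, dapi_threshold = 0.40,
                       d240_threshold = 0.39, tissue_threshold = 0.08,
                       tissue_brush = 15L, main_mass_min_um2 = 10000,
                       min_object_px = 20L, min_lumen_px = 60L,
                       nucleus_min_px = 12L,
                       watershed_tolerance = 1, watershed_ext = 1) {
  structure(list(panck_threshold = panck_threshold,
                 dapi_threshold = dapi_threshold,
                 d240_threshold = d240_threshold,
                 tissue_threshold = tissue_threshold,
                 tissue_brush = as.integer(tissue_brush),
                 main_mass_min_um2 = main_mass_min_um2,
                 min_object_px = as.integer(min_object_px),
                 min_lumen_px = as.integer(min_lumen_px),
                 nucleus_min_px = as.integer(nucleus_min_px),
                 watershed_tolerance = watershed_tolerance,
                 watershed_ext = watershed_ext), class = "seg_config")
}

ROI_LEVELS <- c(no_tissue = 0L, tumor = 1L, stroma = 2L, lumen_necrosis = 3L)

as_ebimage <- function(m) EBImage::Image(m)

label_areas <- function(lab) {
  lab <- as.integer(lab)
  tabulate(lab[lab > 0L])
}

#' Segment a field into the four tissue regions
#'
#' Top level of the hierarchy: partitions every pixel into tumor, stroma,
#' lumen/necrosis or no-tissue.  The tumor region is the union of pan-CK
#' connected components above `main_mass_min_um2`; pan-CK-negative holes
#' enclosed by tumor become lumen/necrosis; remaining tissue is stroma and
#' background is no-tissue.
#'
#' @param field a `FieldImage`.
#' @param cfg a [seg_config()].
#' @return `RoiMap`: integer matrix with codes 0 no_tissue, 1 tumor,
#'   2 stroma, 3 lumen_necrosis; attributes `pixel_size_um` and `levels`.
#' @export
segment_rois <- function(field, cfg = seg_config()) {
  stopifnot(inherits(field, "FieldImage"))
  px2 <- field$pixel_size_um^2
  H <- nrow(field$panck); W <- ncol(field$panck)
  empty <- max(field$panck, field$dapi, field$d240) <= cfg$tissue_threshold
  if (empty) {
    message("segment_rois: empty field (all background); returning no_tissue")
    roi <- matrix(ROI_LEVELS[["no_tissue"]], H, W)
    return(structure(roi, pixel_size_um = field$pixel_size_um,
                     levels = ROI_LEVELS, empty_field = TRUE, class = "RoiMap"))
  }
  brush <- EBImage::makeBrush(cfg$tissue_brush, "disc")
  raw_tissue <- field$panck > cfg$tissue_threshold |
    field$dapi > cfg$dapi_threshold | field$d240 > cfg$d240_threshold
  tissue <- EBImage::closing(as_ebimage(raw_tissue), brush)
  tissue <- as.matrix(EBImage::fillHull(tissue)) > 0

  panck_mask <- field$panck > cfg$panck_threshold
  lab <- as.matrix(EBImage::bwlabel(as_ebimage(panck_mask)))
  areas <- label_areas(lab)
  big <- which(areas * px2 >= cfg$main_mass_min_um2)
  tumor_core <- matrix(lab %in% big, nrow(lab), ncol(lab))
  tumor_filled <- as.matrix(EBImage::fillHull(as_ebimage(tumor_core))) > 0
  holes <- tumor_filled & !tumor_core
  hol_lab <- as.matrix(EBImage::bwlabel(as_ebimage(holes)))
  hol_areas <- label_areas(hol_lab)
  lumen <- matrix(hol_lab %in% which(hol_areas >= cfg$min_lumen_px),
                  nrow(hol_lab), ncol(hol_lab))

  roi <- matrix(ROI_LEVELS[["no_tissue"]], H, W)
  roi[tissue] <- ROI_LEVELS[["stroma"]]
  roi[tumor_filled] <- ROI_LEVELS[["tumor"]]
  roi[lumen] <- ROI_LEVELS[["lumen_necrosis"]]
  structure(roi, pixel_size_um = field$pixel_size_um, levels = ROI_LEVELS,
            empty_field = FALSE, class = "RoiMap")
}

object_table <- function(lab, px2, layer, parent_roi) {
  ids <- sort(unique(as.integer(lab[lab > 0L])))
  if (!length(ids))
    return(data.frame(id = integer(), layer = character(),
                      area_px = integer(), area_um2 = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      parent_roi = character()))
  idx <- which(lab > 0L)
  li <- as.integer(lab[idx])
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  a <- tabulate(li)[ids]
  cr <- rowsum(as.numeric(rows), li)[, 1] / a
  cc <- rowsum(as.numeric(cols), li)[, 1] / a
  data.frame(id = ids, layer = layer, area_px = a, area_um2 = a * px2,
             centroid_row = cr, centroid_col = cc, parent_roi = parent_roi)
}

#' Detect stromal pan-CK objects and lymphatic vessels
#'
#' Object level of the hierarchy: connected components of thresholded pan-CK
#' signal restricted to the stroma region (detached epithelial objects), and
#' D2-40-positive components reconstructed as ring-plus-lumen vessel regions.
#' Components below `min_object_px` are discarded.
#'
#' @param field a `FieldImage`.
#' @param roi the matching `RoiMap`.
#' @param cfg a [seg_config()].
#' @return list of class `SegmentedObjects`: `epi_labels` and
#'   `vessel_labels` label rasters (vessel labels cover ring + lumen) and an
#'   `objects` data frame (`id`, `layer`, areas, centroid, `parent_roi`);
#'   epithelial and vessel ids are numbered independently.
#' @export
detect_objects <- function(field, roi, cfg = seg_config()) {
  px2 <- field$pixel_size_um^2
  stroma <- roi == ROI_LEVELS[["stroma"]]
  epi_mask <- field$panck > cfg$panck_threshold & stroma
  epi_lab <- as.matrix(EBImage::bwlabel(as_ebimage(epi_mask)))
  epi_lab <- drop_small(epi_lab, cfg$min_object_px)

  ves_mask <- field$d240 > cfg$d240_threshold
  ves_lab <- as.matrix(EBImage::bwlabel(as_ebimage(ves_mask)))
  ves_lab <- drop_small(ves_lab, cfg$min_object_px)
  # reconstruct each ring as ring + enclosed lumen
  if (max(ves_lab) > 0L) {
    filled_all <- as.matrix(EBImage::fillHull(as_ebimage(ves_lab > 0L))) > 0
    # propagate ring labels into their enclosed lumens via bwlabel on filled
    fl <- as.matrix(EBImage::bwlabel(as_ebimage(filled_all)))
    map <- integer(max(fl))
    sel <- fl > 0L & ves_lab > 0L
    map[fl[sel]] <- ves_lab[sel]
    out <- matrix(0L, nrow(fl), ncol(fl))
    out[fl > 0L] <- map[fl[fl > 0L]]
    ves_lab <- out
    ves_lab <- relabel_consecutive(ves_lab)
  }
  objects <- rbind(
    object_table(epi_lab, px2, "epithelial_object", "stroma"),
    object_table(ves_lab, px2, "vessel", "stroma"))
  structure(list(epi_labels = epi_lab, vessel_labels = ves_lab,
                 objects = objects, pixel_size_um = field$pixel_size_um),
            class = "SegmentedObjects")
}

drop_small <- function(lab, min_px) {
  if (max(lab) == 0L) return(lab)
  areas <- label_areas(lab)
  keep <- which(areas >= min_px)
  out <- matrix(0L, nrow(lab), ncol(lab))
  sel <- lab > 0L & lab %in% keep
  out[sel] <- lab[sel]
  relabel_consecutive(out)
}

relabel_consecutive <- function(lab) {
  ids <- sort(unique(as.integer(lab[lab > 0L])))
  if (!length(ids)) return(lab)
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

#' Segment nuclei from the DAPI channel
#'
#' Final level of the hierarchy.  Thresholded DAPI blobs are declumped by a
#' distance-transform watershed, so touching nuclei whose centres are
#' separated by at least ~1.5 nuclear radii are split; per-nucleus pixel
#' sets are disjoint by construction.
#'
#' @param field a `FieldImage`.
#' @param cfg a [seg_config()].
#' @return list of class `SegmentedNuclei`: `labels` raster and `nuclei`
#'   data frame (`id`, `area_px`, `centroid_row`, `centroid_col`).
#' @export
segment_nuclei <- function(field, cfg = seg_config()) {
  mask <- field$dapi > cfg$dapi_threshold
  if (!any(mask)) {
    return(structure(list(labels = matrix(0L, nrow(field$dapi), ncol(field$dapi)),
                          nuclei = data.frame(id = integer(), area_px = integer(),
                                              centroid_row = numeric(),
                                              centroid_col = numeric())),
                     class = "SegmentedNuclei"))
  }
  dm <- EBImage::distmap(as_ebimage(mask))
  lab <- as.matrix(EBImage::watershed(dm, tolerance = cfg$watershed_tolerance,
                                      ext = cfg$watershed_ext))
  lab <- drop_small(lab, cfg$nucleus_min_px)
  tab <- object_table(lab, 1, "nucleus", NA_character_)
  structure(list(labels = lab,
                 nuclei = data.frame(id = tab$id, area_px = tab$area_px,
                                     centroid_row = tab$centroid_row,
                                     centroid_col = tab$centroid_col)),
            class = "SegmentedNuclei")
}

#' Assemble the segmentation hierarchy with exclusive nucleus assignment
#'
#' Each nucleus is assigned to exactly one parent: the epithelial object
#' containing its centroid if any, else the vessel region containing it,
#' else its centroid's region class.  Epithelial objects record their
#' nucleus counts.  Nuclei landing on no-tissue are tallied for QC.
#'
#' @param roi `RoiMap`.
#' @param objects `SegmentedObjects` from the same field.
#' @param nuclei `SegmentedNuclei` from the same field.
#' @return list of class `SegmentationHierarchy`: `roi`, `objects` (with
#'   `nucleus_count`), `nuclei` (with `parent_type`, `parent_id`), label
#'   rasters, and `qc` (count of no-tissue nuclei).
#' @export
assign_hierarchy <- function(roi, objects, nuclei) {
  nuc <- nuclei$nuclei
  n <- nrow(nuc)
  parent_type <- character(n); parent_id <- rep(NA_integer_, n)
  if (n > 0) {
    pr <- pmin(pmax(round(nuc$centroid_row), 1L), nrow(roi))
    pc <- pmin(pmax(round(nuc$centroid_col), 1L), ncol(roi))
    at <- cbind(pr, pc)
    epi <- objects$epi_labels[at]
    ves <- objects$vessel_labels[at]
    rois <- unclass(roi)[at]
    lvl <- names(ROI_LEVELS)[match(rois, ROI_LEVELS)]
    parent_type <- ifelse(epi > 0L, "epithelial_object",
                          ifelse(ves > 0L, "vessel", lvl))
    parent_id[epi > 0L] <- epi[epi > 0L]
    parent_id[epi == 0L & ves > 0L] <- ves[epi == 0L & ves > 0L]
  }
  nuc$parent_type <- parent_type
  nuc$parent_id <- parent_id
  obj <- objects$objects
  cnt_epi <- table(factor(parent_id[parent_type == "epithelial_object"],
                          levels = obj$id[obj$layer == "epithelial_object"]))
  obj$nucleus_count <- 0L
  sel <- obj$layer == "epithelial_object"
  obj$nucleus_count[sel] <- as.integer(cnt_epi[as.character(obj$id[sel])])
  structure(list(roi = roi, objects = obj, nuclei = nuc,
                 epi_labels = objects$epi_labels,
                 vessel_labels = objects$vessel_labels,
                 nuclei_labels = nuclei$labels,
                 pixel_size_um = attr(roi, "pixel_size_um"),
                 qc = list(n_no_tissue_nuclei = sum(parent_type == "no_tissue"))),
            class = "SegmentationHierarchy")
}

#' Run the full segmentation chain on one field
#'
#' Convenience wrapper: [segment_rois()], [detect_objects()],
#' [segment_nuclei()], [assign_hierarchy()].
#'
#' @param field a `FieldImage`.
#' @param cfg a [seg_config()].
#' @return a `SegmentationHierarchy`.
#' @export
segment_field <- function(field, cfg = seg_config()) {
  roi <- segment_rois(field, cfg)
  obj <- detect_objects(field, roi, cfg)
  nuc <- segment_nuclei(field, cfg)
  assign_hierarchy(roi, obj, nuc)
}
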