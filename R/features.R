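## Multi-parametric feature extraction across the segmentation hierarchy.
## Empty-class policy: extensive features (counts, summed areas) are 0 when
## the class is absent from a field; intensive features (means, shape,
## texture, distances) are NA and are ignored by the collation step.

glcm_stats <- function(mask, channel) {
  if (!any(mask)) return(c(contrast = NA_real_, entropy = NA_real_,
                           correlation = NA_real_))
  lab <- matrix(0L, nrow(mask), ncol(mask)); lab[mask] <- 1L
  h <- EBImage::computeFeatures.haralick(lab, EBImage::Image(channel),
                                         haralick.nbins = 32,
                                         haralick.scales = 1)
  c(contrast = unname(h[1, "h.con.s1"]), entropy = unname(h[1, "h.ent.s1"]),
    correlation = unname(h[1, "h.cor.s1"]))
}

roundness_from_shape <- function(sh) {
  # 4*pi*A / P^2, capped at 1 (rasterization can push slightly above)
  pmin(4 * pi * sh[, "s.area"] / pmax(sh[, "s.perimeter"], 1e-9)^2, 1)
}

elongation_from_moment <- function(mo) {
  ecc <- pmin(mo[, "m.eccentricity"], 0.999999)
  1 / sqrt(1 - ecc^2)   # major / minor axis ratio
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
sd_or_na <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_

#' Extract the per-field feature values for a manifest
#'
#' Computes one value per manifest entry from a segmented, classified field:
#' per-class counts and areas, shape descriptors (roundness `4*pi*A/P^2`,
#' elongation = major/minor axis), distances from detached-cluster
#' centroids to the tumor margin, per-region channel intensities, and
#' grey-level co-occurrence texture summaries (contrast, entropy,
#' correlation; 32 grey levels, distance 1, direction-averaged).
#'
#' @param h a `SegmentationHierarchy`.
#' @param cf the matching `ClassifiedField`.
#' @param field the `FieldImage` the hierarchy was computed from (intensity
#'   and texture features need the rasters).
#' @param manifest a `FeatureManifest`; defaults to [manifest_default()].
#' @return named numeric vector aligned with the manifest; `NA` marks
#'   intensive features of classes absent from this field.
#' @export
extract_field_features <- function(h, cf, field, manifest = manifest_default()) {
  stopifnot(inherits(h, "SegmentationHierarchy"),
            inherits(cf, "ClassifiedField"), inherits(field, "FieldImage"))
  px <- h$pixel_size_um; px2 <- px^2
  roi <- unclass(h$roi)
  v <- stats::setNames(rep(NA_real_, nrow(manifest)), manifest$name)

  v["n_buds"] <- cf$n_buds; v["n_pdc"] <- cf$n_pdc
  v["n_lvi"] <- cf$n_lvi; v["n_minimal_lvi"] <- cf$n_minimal_lvi
  v["n_vessels"] <- cf$n_vessels
  v["area_pdc_um2"] <- cf$area_pdc_um2
  v["lvd_per_mm2"] <- cf$lvd_per_mm2
  v["tumor_stroma_pct"] <- cf$tumor_stroma_pct
  v["tissue_area_mm2"] <- cf$tissue_area_mm2
  v["n_nuclei_total"] <- nrow(h$nuclei)

  ## ---- ROI level ----
  roi_classes <- c("tumor", "stroma", "lumen_necrosis")
  tissue_px <- sum(roi != ROI_LEVELS[["no_tissue"]])
  chans <- list(dapi = field$dapi, panck = field$panck, d240 = field$d240)
  for (cl in roi_classes) {
    mask <- roi == ROI_LEVELS[[cl]]
    npx <- sum(mask)
    v[sprintf("roi_%s_area_um2", cl)] <- npx * px2
    v[sprintf("roi_%s_fraction_tissue", cl)] <-
      if (tissue_px > 0) npx / tissue_px else NA_real_
    for (ch in names(chans)) {
      xs <- chans[[ch]][mask]
      v[sprintf("roi_%s_mean_%s", cl, ch)] <- mean_or_na(xs)
      v[sprintf("roi_%s_sd_%s", cl, ch)] <- sd_or_na(xs)
    }
    for (ch in c("panck", "dapi")) {
      tx <- glcm_stats(mask, chans[[ch]])
      v[sprintf("roi_%s_texture_contrast_%s", cl, ch)] <- tx["contrast"]
      v[sprintf("roi_%s_texture_entropy_%s", cl, ch)] <- tx["entropy"]
      v[sprintf("roi_%s_texture_correlation_%s", cl, ch)] <- tx["correlation"]
    }
  }

  ## ---- object level ----
  obj <- cf$objects
  obj_classes <- c("tumor_bud", "pdc", "lvi", "minimal_lvi", "vessel")
  shp_by_layer <- list()
  for (layer in c("epithelial_object", "vessel")) {
    lab <- if (layer == "vessel") h$vessel_labels else h$epi_labels
    if (max(lab) > 0L) {
      sh <- EBImage::computeFeatures.shape(lab)
      mo <- EBImage::computeFeatures.moment(lab, EBImage::Image(field$panck))
      shp_by_layer[[layer]] <- data.frame(
        id = seq_len(nrow(sh)), roundness = roundness_from_shape(sh),
        elongation = elongation_from_moment(mo))
    }
  }
  tumor_any <- any(roi == ROI_LEVELS[["tumor"]])
  dist_tumor <- NULL
  if (tumor_any) {
    dm <- as.matrix(EBImage::distmap(
      EBImage::Image(roi != ROI_LEVELS[["tumor"]])))
    dist_tumor <- function(rows, cols)
      dm[cbind(pmin(pmax(round(rows), 1L), nrow(dm)),
               pmin(pmax(round(cols), 1L), ncol(dm)))] * px
  }
  for (cl in obj_classes) {
    sel <- obj$class %in% cl
    areas <- obj$area_um2[sel]
    v[sprintf("obj_%s_sum_area_um2", cl)] <- sum(areas)
    v[sprintf("obj_%s_mean_area_um2", cl)] <- mean_or_na(areas)
    v[sprintf("obj_%s_sd_area_um2", cl)] <- sd_or_na(areas)
    layer <- if (cl == "vessel") "vessel" else "epithelial_object"
    sh <- shp_by_layer[[layer]]
    if (!is.null(sh) && any(sel)) {
      ids <- obj$id[sel]
      v[sprintf("obj_%s_mean_roundness", cl)] <-
        mean_or_na(sh$roundness[match(ids, sh$id)])
      v[sprintf("obj_%s_mean_elongation", cl)] <-
        mean_or_na(sh$elongation[match(ids, sh$id)])
    }
    if (cl != "vessel")
      v[sprintf("obj_%s_mean_nuclei", cl)] <-
        mean_or_na(obj$nucleus_count[sel])
    if (cl %in% c("tumor_bud", "pdc") && any(sel) && !is.null(dist_tumor)) {
      d <- dist_tumor(obj$centroid_row[sel], obj$centroid_col[sel])
      v[sprintf("obj_%s_mean_dist_tumor_um", cl)] <- mean_or_na(d)
      v[sprintf("obj_%s_sd_dist_tumor_um", cl)] <- sd_or_na(d)
    }
    v[sprintf("density_%s_per_mm2", cl)] <-
      if (cf$tissue_area_mm2 > 0) sum(sel) / cf$tissue_area_mm2 else NA_real_
  }
  for (cl in c("tumor_bud", "pdc", "vessel")) {
    sel <- obj$class %in% cl
    if (sum(sel) >= 2) {
      pts <- cbind(obj$centroid_row[sel], obj$centroid_col[sel])
      dd <- as.matrix(stats::dist(pts)); diag(dd) <- Inf
      v[sprintf("nn_dist_%s_um", cl)] <- mean(apply(dd, 1, min)) * px
    }
  }

  ## ---- nucleus level ----
  nuc <- h$nuclei
  if (nrow(nuc)) {
    epi_ids <- obj$id[obj$layer == "epithelial_object"]
    epi_cls <- obj$class[obj$layer == "epithelial_object"]
    ncls <- ifelse(nuc$parent_type == "epithelial_object",
                   epi_cls[match(nuc$parent_id, epi_ids)], nuc$parent_type)
    ncls[ncls %in% c("lvi", "minimal_lvi")] <- "intravascular"
    lab <- h$nuclei_labels
    idx <- which(lab > 0L)
    li <- as.integer(lab[idx])
    mdapi <- rowsum(as.numeric(field$dapi[idx]), li)
    mpanck <- rowsum(as.numeric(field$panck[idx]), li)
    npix <- tabulate(li)
    ord <- as.integer(rownames(mdapi))
    nuc_dapi <- stats::setNames(mdapi[, 1] / npix[ord], ord)
    nuc_panck <- stats::setNames(mpanck[, 1] / npix[ord], ord)
    sh <- EBImage::computeFeatures.shape(lab)
    nuc_round <- roundness_from_shape(sh)
    for (cl in c("tumor", "stroma", "tumor_bud", "pdc", "intravascular")) {
      sel <- which(ncls == cl)
      v[sprintf("nuc_%s_count", cl)] <- length(sel)
      ids <- nuc$id[sel]
      v[sprintf("nuc_%s_mean_area_um2", cl)] <- mean_or_na(nuc$area_px[sel] * px2)
      v[sprintf("nuc_%s_sd_area_um2", cl)] <- sd_or_na(nuc$area_px[sel] * px2)
      v[sprintf("nuc_%s_mean_dapi", cl)] <- mean_or_na(nuc_dapi[as.character(ids)])
      v[sprintf("nuc_%s_mean_panck", cl)] <- mean_or_na(nuc_panck[as.character(ids)])
      v[sprintf("nuc_%s_mean_roundness", cl)] <- mean_or_na(nuc_round[ids])
    }
  } else {
    for (cl in c("tumor", "stroma", "tumor_bud", "pdc", "intravascular"))
      v[sprintf("nuc_%s_count", cl)] <- 0
  }
  v
}

#' Collate per-field feature vectors into one patient vector
#'
#' Reduces the feature values of a section's fields to one data point per
#' parameter per patient: extensive features are summed over fields,
#' intensive features averaged, per the manifest's collation column.  Fields
#' where an intensive feature is missing (class absent) are ignored by the
#' average; a feature missing in every field collates to 0 and is listed in
#' the `"qc_all_missing"` attribute.
#'
#' @param field_vectors list of named vectors from
#'   [extract_field_features()] (or a matrix with fields in rows).
#' @param manifest the `FeatureManifest` the vectors follow.
#' @return named numeric vector of class `FeatureVector`, one entry per
#'   manifest row, no missing values.
#' @export
collate_patient <- function(field_vectors, manifest = manifest_default()) {
  if (is.list(field_vectors)) {
    len <- vapply(field_vectors, length, 0L)
    if (length(unique(len)) != 1L)
      stop("field vectors have unequal lengths: ",
           paste(unique(len), collapse = ", "))
    M <- do.call(rbind, field_vectors)
  } else M <- as.matrix(field_vectors)
  if (ncol(M) != nrow(manifest))
    stop("field vectors (", ncol(M), ") do not match manifest length (",
         nrow(manifest), ")")
  out <- stats::setNames(numeric(nrow(manifest)), manifest$name)
  for (j in seq_len(nrow(manifest))) {
    x <- M[, j]
    out[j] <- if (manifest$collation[j] == "sum") sum(x, na.rm = TRUE)
              else mean(x, na.rm = TRUE)
  }
  all_missing <- manifest$name[colSums(!is.na(M)) == 0L]
  out[is.nan(out)] <- 0
  structure(out, qc_all_missing = all_missing, class = "FeatureVector")
}
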