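#' Specify a synthetic immunofluorescence field
#'
#' Defines one field of view of a synthetic three-channel immunofluorescence
#' image of a colorectal tumor invasive front: a pan-cytokeratin-positive
#' tumor mass with enclosed lumen/necrosis holes, a stromal compartment
#' carrying detached epithelial clusters (tumor buds of 1--4 nuclei, poorly
#' differentiated clusters of >= 5 nuclei), and D2-40-positive lymphatic
#' vessels optionally invaded by intravascular tumor cells.
#'
#' Object footprints are placed pairwise non-overlapping; generation fails
#' with an explicit error if the requested objects cannot be placed.
#'
#' @param image_size_px integer pair, raster height and width in pixels.
#' @param pixel_size_um physical pixel edge in micrometres; all areas are
#'   reported in square micrometres via `pixel_size_um^2`.
#' @param n_buds,bud_nucleus_counts number of tumor buds and nuclei per bud
#'   (each in 1--4).  Default counts cycle 1,2,3,4.
#' @param n_pdc,pdc_nucleus_counts number of poorly differentiated clusters
#'   and nuclei per cluster (each >= 5).  Default counts cycle 5,7,9,6.
#' @param n_vessels number of lymphatic vessels.
#' @param lvi_events list of `c(vessel, n)` pairs: vessel index invaded by
#'   `n` intravascular tumor nuclei.
#' @param tumor_fraction fraction of the field occupied by the tumor mass.
#' @param lumen_fraction fraction of the field carved out of the tumor mass
#'   as enclosed lumen/necrosis holes.
#' @param noise_sd standard deviation of Gaussian read noise per channel.
#' @param n_stromal_nuclei,n_tumor_nuclei background (non-object) nuclei
#'   scattered over stroma and tumor mass; placed by dart throwing, so the
#'   realised number can fall short in crowded fields.
#' @param nucleus_radius_px nucleus disc radius.
#' @param cluster_margin_px cytoplasmic pan-CK margin around cluster nuclei.
#' @param seed integer seed; fields are bit-reproducible given the spec.
#' @return An object of class `FieldSpec`.
#' @seealso [generate_field()], [generate_section()]
#' @export
field_spec <- function(image_size_px = c(512L, 512L),
                       pixel_size_um = 0.5,
                       n_buds = 3L, bud_nucleus_counts = NULL,
                       n_pdc = 2L, pdc_nucleus_counts = NULL,
                       n_vessels = 2L, lvi_events = list(),
                       tumor_fraction = 0.4, lumen_fraction = 0.02,
                       noise_sd = 0.02,
                       n_stromal_nuclei = 60L, n_tumor_nuclei = 120L,
                       nucleus_radius_px = 6L, cluster_margin_px = 3L,
                       seed = 1L) {
  n_buds <- as.integer(n_buds); n_pdc <- as.integer(n_pdc)
  n_vessels <- as.integer(n_vessels)
  if (is.null(bud_nucleus_counts))
    bud_nucleus_counts <- if (n_buds) ((seq_len(n_buds) - 1L) %% 4L) + 1L else integer()
  if (is.null(pdc_nucleus_counts))
    pdc_nucleus_counts <- if (n_pdc) c(5L, 7L, 9L, 6L)[((seq_len(n_pdc) - 1L) %% 4L) + 1L] else integer()
  spec <- structure(list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    n_buds = n_buds, bud_nucleus_counts = as.integer(bud_nucleus_counts),
    n_pdc = n_pdc, pdc_nucleus_counts = as.integer(pdc_nucleus_counts),
    n_vessels = n_vessels, lvi_events = lvi_events,
    tumor_fraction = tumor_fraction, lumen_fraction = lumen_fraction,
    noise_sd = noise_sd,
    n_stromal_nuclei = as.integer(n_stromal_nuclei),
    n_tumor_nuclei = as.integer(n_tumor_nuclei),
    nucleus_radius_px = as.integer(nucleus_radius_px),
    cluster_margin_px = as.integer(cluster_margin_px),
    seed = as.integer(seed)), class = "FieldSpec")
  validate_field_spec(spec)
  spec
}

validate_field_spec <- function(spec) {
  stopifnot(
    length(spec$image_size_px) == 2L, all(spec$image_size_px >= 64L),
    spec$pixel_size_um > 0,
    spec$n_buds >= 0L, spec$n_pdc >= 0L, spec$n_vessels >= 0L,
    length(spec$bud_nucleus_counts) == spec$n_buds,
    length(spec$pdc_nucleus_counts) == spec$n_pdc,
    spec$tumor_fraction >= 0, spec$tumor_fraction <= 1,
    spec$lumen_fraction >= 0, spec$lumen_fraction <= 1,
    spec$noise_sd >= 0)
  if (spec$n_buds && any(spec$bud_nucleus_counts < 1L | spec$bud_nucleus_counts > 4L))
    stop("bud_nucleus_counts must each be in 1..4")
  if (spec$n_pdc && any(spec$pdc_nucleus_counts < 5L))
    stop("pdc_nucleus_counts must each be >= 5")
  for (ev in spec$lvi_events) {
    if (length(ev) != 2L || ev[1] < 1 || ev[1] > spec$n_vessels || ev[2] < 1)
      stop("each lvi_event must be c(vessel_index <= n_vessels, n_nuclei >= 1)")
  }
  if (anyDuplicated(vapply(spec$lvi_events, `[`, numeric(1), 1L)))
    stop("at most one lvi_event per vessel")
  invisible(spec)
}

# Intensity model shared with the segmentation defaults: plateau levels well
# above / below the 0.35 detection thresholds after sigma-1 blur.
FIELD_LEVELS <- list(background = 0.03, stroma_diffuse = 0.12,
                     tumor_panck = 0.72, cluster_panck = 0.72,
                     nucleus_dapi = 0.78, vessel_d240 = 0.75)

#' Generate one synthetic immunofluorescence field with ground truth
#'
#' Renders the three channel rasters (DAPI nuclei, pan-CK epithelium, D2-40
#' lymphatic endothelium) described by a [field_spec()] and returns them
#' together with exact ground truth: per-layer label rasters, per-object
#' records and planted summary counts/areas.
#'
#' @param spec a `FieldSpec`.
#' @return A list with elements `image` (class `FieldImage`: `dapi`, `panck`,
#'   `d240` matrices in `[0,1]` plus `pixel_size_um`) and `truth` (class
#'   `GroundTruth`: `roi` label raster coded 0 no_tissue / 1 tumor /
#'   2 stroma / 3 lumen_necrosis, `epi_labels`, `vessel_labels`,
#'   `nuclei_labels`, an `objects` data frame and a `summary` list).
#' @export
generate_field <- function(spec) {
  validate_field_spec(spec)
  with_seed(spec$seed, generate_field_impl(spec))
}

generate_field_impl <- function(spec) {
  H <- spec$image_size_px[1]; W <- spec$image_size_px[2]
  px2 <- spec$pixel_size_um^2
  r_nuc <- spec$nucleus_radius_px
  r_cyt <- r_nuc + spec$cluster_margin_px

  ## ---- ROI scaffold: tumor mass with a sinuous invasive margin ----
  tumor0 <- matrix(FALSE, H, W)
  if (spec$tumor_fraction > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    b <- W * spec$tumor_fraction +
      0.05 * W * sin(2 * pi * 1.5 * seq_len(H) / H + phase)
    b <- pmin(pmax(b, 2), W - 2)
    tumor0 <- outer(b, seq_len(W), function(bi, j) j <= bi)
  }
  boundary_col <- if (spec$tumor_fraction > 0) b else rep(0, H)

  ## lumen/necrosis holes carved from the tumor mass
  lumen <- matrix(FALSE, H, W)
  if (spec$lumen_fraction > 0 && any(tumor0)) {
    a_l <- 14; b_l <- 10
    k <- max(1L, round(spec$lumen_fraction * H * W / (pi * a_l * b_l)))
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < k && tries < 500L) {
      tries <- tries + 1L
      cy <- sample.int(H, 1)
      cx <- sample.int(W, 1)
      if (cx > boundary_col[cy] - a_l - 12 || cx < a_l + 6 ||
          cy < a_l + 6 || cy > H - a_l - 6) next
      if (nrow(centers) &&
          min(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)) < 2 * a_l + 8) next
      centers <- rbind(centers, c(cy, cx))
      lumen <- lumen | ellipse_mask(H, W, cy, cx, a_l, b_l)
    }
  }

  ## ---- place stromal objects (buds, PDCs, vessels) without overlap ----
  placed <- matrix(numeric(0), 0, 2)   # centres
  placed_r <- numeric(0)               # effective footprint radii
  place_one <- function(r_eff, what) {
    for (try in 1:600) {
      cy <- sample(seq.int(ceiling(r_eff) + 12, H - ceiling(r_eff) - 12), 1)
      cx <- sample(seq.int(ceiling(r_eff) + 12, W - ceiling(r_eff) - 12), 1)
      if (cx < boundary_col[cy] + r_eff + 25) next    # keep clear of tumor mass
      if (nrow(placed) &&
          any(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2) <
              placed_r + r_eff + 10)) next
      placed <<- rbind(placed, c(cy, cx))
      placed_r <<- c(placed_r, r_eff)
      return(c(cy, cx))
    }
    stop("field too crowded: could not place ", what,
         " after bounded retries; reduce object counts or enlarge the field")
  }

  spacing <- 2 * r_nuc + 2.5   # nucleus centre separation within clusters
  objects <- list()
  nuc_rows <- numeric(0); nuc_cols <- numeric(0); nuc_obj <- integer(0)
  epi <- matrix(0L, H, W); vess <- matrix(0L, H, W)
  obj_id <- 0L

  add_cluster <- function(k, class) {
    rot <- stats::runif(1, 0, 2 * pi)
    lay <- cluster_layout(k, spacing, rot)
    r_eff <- layout_radius(lay) + r_cyt + 3
    ctr <- place_one(r_eff, class)
    rows <- round(ctr[1] + lay[, 1]); cols <- round(ctr[2] + lay[, 2])
    obj_id <<- obj_id + 1L
    mask <- disc_mask(H, W, rows, cols, r_cyt)
    epi[mask] <<- obj_id
    nuc_rows <<- c(nuc_rows, rows); nuc_cols <<- c(nuc_cols, cols)
    nuc_obj <<- c(nuc_obj, rep(obj_id, k))
    objects[[obj_id]] <<- list(id = obj_id, class = class, nucleus_count = k,
                               area_px = sum(mask),
                               centroid_row = mean(rows), centroid_col = mean(cols))
  }

  for (k in spec$bud_nucleus_counts) add_cluster(k, "tumor_bud")
  for (k in spec$pdc_nucleus_counts) add_cluster(k, "pdc")

  ## vessels: elliptical D2-40 rings; lumen sized to fit any invading cluster
  lvi_n <- integer(spec$n_vessels)
  for (ev in spec$lvi_events) lvi_n[ev[1]] <- as.integer(ev[2])
  vessel_centers <- vector("list", spec$n_vessels)
  vessel_lumen_r <- numeric(spec$n_vessels)
  if (spec$n_vessels > 0) for (vi in seq_len(spec$n_vessels)) {
    lay <- if (lvi_n[vi] > 0) cluster_layout(lvi_n[vi], spacing) else matrix(0, 1, 2)
    lumen_r <- max(12, layout_radius(lay) + r_cyt + 3)
    outer_r <- lumen_r + 4
    ctr <- place_one(outer_r + 3, "vessel")
    # invaded vessels stay circular so the planted cluster fits the lumen
    stretch <- if (lvi_n[vi] > 0) 1.0 else stats::runif(1, 1.0, 1.25)
    a <- outer_r * stretch; bb <- outer_r / stretch
    rmask <- ring_mask(H, W, ctr[1], ctr[2], a, bb, 4)
    filled <- ellipse_mask(H, W, ctr[1], ctr[2], a, bb)
    vess[filled] <- vi + 0L   # vessel label raster = full (ring + lumen) region
    attr(vess, "rings") <- c(attr(vess, "rings"), list(rmask))
    vessel_centers[[vi]] <- ctr
    vessel_lumen_r[vi] <- lumen_r
    obj_id <- obj_id + 1L
    objects[[obj_id]] <- list(id = obj_id, class = "vessel", nucleus_count = 0L,
                              area_px = sum(filled),
                              centroid_row = ctr[1], centroid_col = ctr[2])
    if (lvi_n[vi] > 0) {
      rot <- stats::runif(1, 0, 2 * pi)
      lay <- cluster_layout(lvi_n[vi], spacing, rot)
      rows <- round(ctr[1] + lay[, 1]); cols <- round(ctr[2] + lay[, 2])
      obj_id <- obj_id + 1L
      mask <- disc_mask(H, W, rows, cols, r_cyt)
      epi[mask] <- obj_id
      nuc_rows <- c(nuc_rows, rows); nuc_cols <- c(nuc_cols, cols)
      nuc_obj <- c(nuc_obj, rep(obj_id, lvi_n[vi]))
      cls <- if (lvi_n[vi] < 5L) "minimal_lvi" else "lvi"
      objects[[obj_id]] <- list(id = obj_id, class = cls,
                                nucleus_count = lvi_n[vi], area_px = sum(mask),
                                centroid_row = mean(rows), centroid_col = mean(cols))
    }
  }

  ## ---- background nuclei (dart throwing, min separation for declumping) ----
  epi_any <- epi > 0L; vess_any <- vess > 0L
  sep_bg <- 2 * r_nuc + 2
  throw_nuclei <- function(n_target, in_tumor) {
    rows <- integer(0); cols <- integer(0)
    tries <- 0L
    while (length(rows) < n_target && tries < n_target * 40L) {
      tries <- tries + 1L
      cy <- sample(seq.int(r_nuc + 3L, H - r_nuc - 3L), 1)
      cx <- sample(seq.int(r_nuc + 3L, W - r_nuc - 3L), 1)
      if (in_tumor) {
        if (cx > boundary_col[cy] - r_nuc - 4) next
        if (lumen[cy, cx]) next
      } else {
        if (cx < boundary_col[cy] + r_nuc + 6) next
        if (nrow(placed) &&
            any(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2) <
                placed_r + r_nuc + 4)) next
      }
      if (length(rows) &&
          min(sqrt((rows - cy)^2 + (cols - cx)^2)) < sep_bg) next
      rows <- c(rows, cy); cols <- c(cols, cx)
    }
    cbind(rows, cols)
  }
  tum_n <- if (spec$tumor_fraction > 0) throw_nuclei(spec$n_tumor_nuclei, TRUE)
           else cbind(integer(0), integer(0))
  str_n <- throw_nuclei(spec$n_stromal_nuclei, FALSE)

  all_rows <- c(nuc_rows, tum_n[, 1], str_n[, 1])
  all_cols <- c(nuc_cols, tum_n[, 2], str_n[, 2])
  all_parent <- c(nuc_obj, rep(NA_integer_, nrow(tum_n) + nrow(str_n)))

  nuc_lab <- matrix(0L, H, W)
  off <- disc_offsets(r_nuc)
  for (i in seq_along(all_rows)) {
    rr <- all_rows[i] + off[, 1]; cc <- all_cols[i] + off[, 2]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    nuc_lab[cbind(rr[ok], cc[ok])] <- i
  }

  ## ---- render channels ----
  lv <- FIELD_LEVELS
  dapi <- matrix(lv$background, H, W)
  dapi <- stamp_discs(dapi, all_rows, all_cols, r_nuc, lv$nucleus_dapi)

  panck <- matrix(lv$background, H, W)
  panck[!tumor0] <- lv$stroma_diffuse
  panck[tumor0 & !lumen] <- lv$tumor_panck
  panck[lumen] <- lv$background
  panck[epi > 0L] <- lv$cluster_panck

  d240 <- matrix(lv$background, H, W)
  for (rmask in attr(vess, "rings")) d240[rmask] <- lv$vessel_d240

  finish <- function(m) {
    m <- as.matrix(EBImage::gblur(EBImage::Image(m), sigma = 1))
    if (spec$noise_sd > 0) m <- m + stats::rnorm(length(m), 0, spec$noise_sd)
    pmin(pmax(m, 0), 1)
  }
  image <- structure(list(dapi = finish(dapi), panck = finish(panck),
                          d240 = finish(d240),
                          pixel_size_um = spec$pixel_size_um),
                     class = "FieldImage")

  ## ---- ground truth ----
  roi <- matrix(2L, H, W)            # stroma
  roi[tumor0 & !lumen] <- 1L         # tumor
  roi[lumen] <- 3L                   # lumen_necrosis
  attr(vess, "rings") <- NULL
  obj_df <- do.call(rbind, lapply(objects, function(o)
    data.frame(id = o$id, class = o$class, nucleus_count = o$nucleus_count,
               area_px = o$area_px, area_um2 = o$area_px * px2,
               centroid_row = o$centroid_row, centroid_col = o$centroid_col)))
  if (is.null(obj_df))
    obj_df <- data.frame(id = integer(), class = character(),
                         nucleus_count = integer(), area_px = integer(),
                         area_um2 = numeric(), centroid_row = numeric(),
                         centroid_col = numeric())
  counts <- list(
    bud = sum(obj_df$class == "tumor_bud"),
    pdc = sum(obj_df$class == "pdc"),
    vessel = sum(obj_df$class == "vessel"),
    lvi = sum(obj_df$class == "lvi"),
    minimal_lvi = sum(obj_df$class == "minimal_lvi"))
  summary <- list(
    counts = counts,
    area_pdc_um2 = sum(obj_df$area_um2[obj_df$class == "pdc"]),
    tumor_fraction_actual = mean(roi == 1L | roi == 3L),
    tissue_area_mm2 = H * W * px2 / 1e6,
    n_nuclei = length(all_rows))
  truth <- structure(list(
    roi = roi, epi_labels = epi, vessel_labels = vess,
    nuclei_labels = nuc_lab,
    objects = obj_df,
    nuclei = data.frame(id = seq_along(all_rows), row = all_rows,
                        col = all_cols, parent_object = all_parent),
    summary = summary, pixel_size_um = spec$pixel_size_um),
    class = "GroundTruth")
  list(image = image, truth = truth)
}

#' Generate a synthetic tissue section (a set of fields per patient)
#'
#' A section is the per-patient unit of analysis: by default 15 fields of
#' view sampled along the invasive front, mirroring standard practice of
#' capturing evenly spaced high-resolution fields per tissue section.
#'
#' @param section_spec optional list of `FieldSpec`s, one per field.  When
#'   omitted, `n_fields` variants of `base_spec` are generated with distinct
#'   sub-seeds drawn from `seed`.
#' @param base_spec template `FieldSpec` used when `section_spec` is `NULL`.
#' @param n_fields number of fields per section (default 15).
#' @param seed integer seed controlling the per-field sub-seeds.
#' @return list of `n_fields` elements, each as [generate_field()]; the
#'   attribute `"section_summary"` carries planted totals over fields.
#' @export
generate_section <- function(section_spec = NULL, base_spec = field_spec(),
                             n_fields = 15L, seed = 1L) {
  if (is.null(section_spec)) {
    sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_fields))
    section_spec <- lapply(sub, function(s) { b <- base_spec; b$seed <- s; b })
  }
  fields <- lapply(section_spec, generate_field)
  tot <- list(
    bud = sum(vapply(fields, function(f) f$truth$summary$counts$bud, 0)),
    pdc = sum(vapply(fields, function(f) f$truth$summary$counts$pdc, 0)),
    vessel = sum(vapply(fields, function(f) f$truth$summary$counts$vessel, 0)),
    lvi = sum(vapply(fields, function(f) f$truth$summary$counts$lvi, 0)),
    minimal_lvi = sum(vapply(fields, function(f) f$truth$summary$counts$minimal_lvi, 0)),
    area_pdc_um2 = sum(vapply(fields, function(f) f$truth$summary$area_pdc_um2, 0)))
  attr(fields, "section_summary") <- tot
  fields
}

#' Write a field to disk as three greyscale TIFFs plus a JSON sidecar
#'
#' Follows the three-greyscale-TIFF-per-field export convention:
#' `<patient>_<field>_dapi.tif`, `_cy3.tif` (pan-CK), `_cy5.tif` (D2-40),
#' with planted ground-truth records in `<patient>_<field>_truth.json`.
#'
#' @param field a `list(image, truth)` as returned by [generate_field()].
#' @param dir output directory (created if needed).
#' @param patient,field_id identifiers used in the file names.
#' @return invisibly, the paths written.
#' @export
write_field <- function(field, dir, patient, field_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, sprintf("%s_%s", patient, field_id))
  paths <- paste0(stem, c("_dapi.tif", "_cy3.tif", "_cy5.tif"))
  tiff::writeTIFF(field$image$dapi, paths[1], bits.per.sample = 16L)
  tiff::writeTIFF(field$image$panck, paths[2], bits.per.sample = 16L)
  tiff::writeTIFF(field$image$d240, paths[3], bits.per.sample = 16L)
  side <- paste0(stem, "_truth.json")
  jsonlite::write_json(list(
    pixel_size_um = field$image$pixel_size_um,
    objects = field$truth$objects,
    summary = field$truth$summary), side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, side))
}

#' Read a field written by [write_field()]
#'
#' @param dir directory holding the TIFF triplet.
#' @param patient,field_id identifiers in the file names.
#' @param pixel_size_um physical pixel size of the rasters.
#' @return a `FieldImage`.
#' @export
read_field <- function(dir, patient, field_id, pixel_size_um = 0.5) {
  stem <- file.path(dir, sprintf("%s_%s", patient, field_id))
  dapi <- tiff::readTIFF(paste0(stem, "_dapi.tif"))
  panck <- tiff::readTIFF(paste0(stem, "_cy3.tif"))
  d240 <- tiff::readTIFF(paste0(stem, "_cy5.tif"))
  if (!all(dim(dapi) == dim(panck)) || !all(dim(dapi) == dim(d240)))
    stop("channel rasters are not co-registered (shapes differ)")
  structure(list(dapi = dapi, panck = panck, d240 = d240,
                 pixel_size_um = pixel_size_um), class = "FieldImage")
}
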