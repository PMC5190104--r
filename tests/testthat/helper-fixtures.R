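# Shared fixtures, memoised so expensive field generation/segmentation runs
# once per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# standard rich field: buds + PDCs + one invaded and one clean vessel
rich_spec <- function(seed = 42L)
  field_spec(n_buds = 3L, n_pdc = 2L, n_vessels = 2L,
             lvi_events = list(c(1L, 6L), c(2L, 2L)), seed = seed)

rich_field <- function() memo("rich_field", generate_field(rich_spec()))

rich_hierarchy <- function()
  memo("rich_hierarchy", segment_field(rich_field()$image))

rich_classified <- function()
  memo("rich_classified",
       suppressMessages(classify_objects(rich_hierarchy())))

# bare FieldImage from channel matrices (for constructed edge cases)
make_field_image <- function(dapi, panck = NULL, d240 = NULL,
                             pixel_size_um = 0.5) {
  H <- nrow(dapi); W <- ncol(dapi)
  blank <- matrix(0.03, H, W)
  structure(list(dapi = dapi, panck = panck %||% blank,
                 d240 = d240 %||% blank, pixel_size_um = pixel_size_um),
            class = "FieldImage")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# render a noisy DAPI raster with nuclei at given centres
render_dapi <- function(H, W, rows, cols, r = 6, noise = 0.02, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  m <- matrix(0.03, H, W)
  m <- invasivefront:::stamp_discs(m, rows, cols, r, 0.78)
  m <- as.matrix(EBImage::gblur(EBImage::Image(m), 1))
  withr_seed(m <- m + rnorm(H * W, 0, noise))
  pmin(pmax(m, 0), 1)
}

# minimal hand-built SegmentationHierarchy for classification unit tests:
# one epithelial object per entry of `nuclei_per_object`, optionally inside
# a vessel region.
toy_hierarchy <- function(nuclei_per_object, in_vessel = logical(length(nuclei_per_object)),
                          pixel_size_um = 0.5) {
  n <- length(nuclei_per_object)
  H <- 40L; W <- 40L * n
  roi <- matrix(2L, H, W)   # all stroma
  attr(roi, "pixel_size_um") <- pixel_size_um
  attr(roi, "levels") <- c(no_tissue = 0L, tumor = 1L, stroma = 2L,
                           lumen_necrosis = 3L)
  class(roi) <- "RoiMap"
  epi <- matrix(0L, H, W); ves <- matrix(0L, H, W)
  objects <- NULL; vid <- 0L
  for (i in seq_len(n)) {
    cols <- (40L * (i - 1L) + 10L):(40L * (i - 1L) + 25L)
    epi[10:25, cols] <- i
    if (in_vessel[i]) {
      vid <- vid + 1L
      ves[5:30, (40L * (i - 1L) + 5L):(40L * (i - 1L) + 30L)] <- vid
    }
    objects <- rbind(objects, data.frame(
      id = i, layer = "epithelial_object", area_px = 16L * 16L,
      area_um2 = 256 * pixel_size_um^2, centroid_row = 17.5,
      centroid_col = 40 * (i - 1) + 17.5, parent_roi = "stroma",
      nucleus_count = nuclei_per_object[i]))
  }
  if (vid > 0L)
    for (v in seq_len(vid))
      objects <- rbind(objects, data.frame(
        id = v, layer = "vessel", area_px = sum(ves == v),
        area_um2 = sum(ves == v) * pixel_size_um^2,
        centroid_row = 17.5, centroid_col = 17.5, parent_roi = "stroma",
        nucleus_count = 0L))
  structure(list(roi = roi, objects = objects,
                 nuclei = data.frame(id = integer(), area_px = integer(),
                                     centroid_row = numeric(),
                                     centroid_col = numeric(),
                                     parent_type = character(),
                                     parent_id = integer()),
                 epi_labels = epi, vessel_labels = ves,
                 nuclei_labels = matrix(0L, H, W),
                 pixel_size_um = pixel_size_um,
                 qc = list(n_no_tissue_nuclei = 0L)),
            class = "SegmentationHierarchy")
}

# independent hand-coded Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force composite-index rule, enumerated independently of build_npi
npi_oracle <- function(area, pt, diff) {
  flags <- c(area > 35647, pt == "pT4", diff == "poor")
  list(score = sum(flags), group = if (sum(flags) >= 2) "high" else "low")
}
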