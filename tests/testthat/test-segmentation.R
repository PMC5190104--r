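test_that("region labels partition every pixel into the four classes", {
  for (s in c(1L, 2L, 3L)) {
    f <- generate_field(field_spec(seed = s))
    roi <- segment_rois(f$image)
    expect_identical(dim(unclass(roi)), dim(f$image$panck))
    expect_true(all(unclass(roi) %in% 0:3))
  }
})

test_that("an all-background field maps to 100% no_tissue with a log note", {
  blank <- make_field_image(matrix(0.0, 128, 128))
  expect_message(roi <- segment_rois(blank), "empty field")
  expect_true(all(unclass(roi) == 0L))
})

test_that("recovered tumor fraction tracks the planted fraction", {
  f <- generate_field(field_spec(n_buds = 0, n_pdc = 0, n_vessels = 0,
                                 tumor_fraction = 0.4, lumen_fraction = 0,
                                 seed = 17))
  roi <- segment_rois(f$image)
  frac <- mean(unclass(roi) == 1L)
  expect_lt(abs(frac - 0.40) / 0.40, 0.10)
})

test_that("planted lumen holes are recovered with high overlap", {
  f <- generate_field(field_spec(n_buds = 0, n_pdc = 0, n_vessels = 0,
                                 tumor_fraction = 0.5, lumen_fraction = 0.03,
                                 seed = 23))
  roi <- segment_rois(f$image)
  planted <- f$truth$roi == 3L
  found <- unclass(roi) == 3L
  jaccard <- sum(planted & found) / sum(planted | found)
  expect_gt(jaccard, 0.90)
})

test_that("detached epithelial objects are found exactly; no vessels means none", {
  f <- generate_field(field_spec(n_buds = 3, n_pdc = 2, n_vessels = 0,
                                 seed = 31))
  roi <- segment_rois(f$image)
  obj <- detect_objects(f$image, roi)
  expect_identical(sum(obj$objects$layer == "epithelial_object"), 5L)
  expect_identical(sum(obj$objects$layer == "vessel"), 0L)
})

test_that("nearby but distinct planted clusters stay separate objects", {
  # two 5-nucleus clusters rendered ~12 px apart edge to edge
  H <- 160L; W <- 160L
  panck <- matrix(0.12, H, W)
  lay <- invasivefront:::cluster_layout(5L, 14.5)
  for (ctr_col in c(55, 105)) {
    rows <- round(80 + lay[, 1]); cols <- round(ctr_col + lay[, 2])
    panck <- invasivefront:::stamp_discs(panck, rows, cols, 9, 0.72)
  }
  panck <- as.matrix(EBImage::gblur(EBImage::Image(panck), 1))
  fi <- make_field_image(matrix(0.03, H, W), panck = panck)
  roi <- segment_rois(fi)
  obj <- detect_objects(fi, roi)
  expect_identical(sum(obj$objects$layer == "epithelial_object"), 2L)
})

test_that("well-separated nuclei are counted exactly and a blank channel gives none", {
  H <- 128L; W <- 128L
  pts <- expand.grid(row = c(30, 64, 98), col = c(30, 64, 98))
  dapi <- render_dapi(H, W, pts$row, pts$col, seed = 4)
  nuc <- segment_nuclei(make_field_image(dapi))
  expect_identical(nrow(nuc$nuclei), 9L)
  blank <- segment_nuclei(make_field_image(matrix(0.0, 64, 64)))
  expect_identical(nrow(blank$nuclei), 0L)
})

test_that("touching nuclei at 1.6x radius separation are declumped", {
  r <- 6
  dapi <- render_dapi(96L, 96L, c(48, 48), c(40, 40 + 1.6 * r), r = r,
                      seed = 6)
  nuc <- segment_nuclei(make_field_image(dapi))
  expect_identical(nrow(nuc$nuclei), 2L)
})

test_that("nucleus pixel sets are disjoint and every nucleus has one parent", {
  h <- rich_hierarchy()
  lab <- h$nuclei_labels
  expect_identical(sort(unique(as.integer(lab[lab > 0]))),
                   seq_len(nrow(h$nuclei)))
  expect_true(all(h$nuclei$parent_type %in%
                    c("epithelial_object", "vessel", "tumor", "stroma",
                      "lumen_necrosis", "no_tissue")))
  expect_false(any(is.na(h$nuclei$parent_type)))
})

test_that("nucleus counts are conserved across parents", {
  for (s in c(5L, 6L)) {
    f <- generate_field(field_spec(seed = s))
    h <- segment_field(f$image)
    per_parent <- table(h$nuclei$parent_type)
    expect_identical(sum(per_parent), nrow(h$nuclei))
    n_epi <- sum(h$objects$nucleus_count[h$objects$layer == "epithelial_object"])
    expect_identical(n_epi,
                     sum(h$nuclei$parent_type == "epithelial_object"))
  }
})

test_that("segmented object areas are within 5% of planted areas", {
  f <- rich_field()
  h <- rich_hierarchy()
  truth <- f$truth$objects
  seg <- h$objects[h$objects$layer == "epithelial_object", ]
  # match planted clusters to segmented objects by centroid proximity
  for (i in which(truth$class %in% c("tumor_bud", "pdc"))) {
    d <- sqrt((seg$centroid_row - truth$centroid_row[i])^2 +
              (seg$centroid_col - truth$centroid_col[i])^2)
    j <- which.min(d)
    expect_lt(d[j], 5)
    expect_lt(abs(seg$area_um2[j] - truth$area_um2[i]) / truth$area_um2[i],
              0.05)
  }
})
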