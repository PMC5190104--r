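test_that("the default manifest declares 123 uniquely named parameters", {
  m <- manifest_default()
  expect_identical(nrow(m), 123L)
  expect_identical(anyDuplicated(m$name), 0L)
  expect_true(all(m$collation %in% c("sum", "mean")))
  # extensive families summed (per-object nucleus means excepted), intensive averaged
  idx <- which(m$family %in% c("count", "sum_area"))
  exc <- grepl("mean_nuclei", m$name[idx])
  expect_true(all(m$collation[idx][!exc] == "sum"))
  expect_true(all(m$collation[m$family %in%
                                c("intensity", "texture", "shape")] == "mean"))
})

test_that("empty classes give zero counts and missing intensive features", {
  f <- generate_field(field_spec(n_buds = 1, n_pdc = 0, n_vessels = 0,
                                 seed = 13))
  h <- segment_field(f$image)
  cf <- suppressMessages(classify_objects(h))
  v <- extract_field_features(h, cf, f$image)
  expect_identical(unname(v["n_pdc"]), 0)
  expect_identical(unname(v["obj_pdc_sum_area_um2"]), 0)
  expect_true(is.na(v["obj_pdc_mean_roundness"]))
  expect_true(is.na(v["obj_pdc_mean_area_um2"]))
  expect_true(is.na(v["nn_dist_vessel_um"]))
})

test_that("a rasterized disc scores near-unit roundness and low elongation", {
  H <- 128L; W <- 128L
  panck <- matrix(0.12, H, W)
  panck <- invasivefront:::stamp_discs(panck, 64, 64, 14, 0.72)
  panck <- as.matrix(EBImage::gblur(EBImage::Image(panck), 1))
  dapi <- render_dapi(H, W, 64, 64, r = 6, seed = 2)
  fi <- make_field_image(dapi, panck = panck)
  h <- segment_field(fi)
  cf <- classify_objects(h)
  v <- extract_field_features(h, cf, fi)
  expect_gte(unname(v["obj_tumor_bud_mean_roundness"]), 0.9)
  expect_lte(unname(v["obj_tumor_bud_mean_roundness"]), 1.0)
  expect_lt(unname(v["obj_tumor_bud_mean_elongation"]), 1.2)
})

test_that("per-class nucleus counts agree with the hierarchy tallies", {
  h <- rich_hierarchy()
  cf <- rich_classified()
  f <- rich_field()
  v <- extract_field_features(h, cf, f$image)
  epi <- h$objects[h$objects$layer == "epithelial_object", ]
  cls <- cf$objects$class[match(epi$id, cf$objects$id[
    cf$objects$layer == "epithelial_object"])]
  expect_equal(unname(v["nuc_tumor_bud_count"]),
               sum(epi$nucleus_count[cls == "tumor_bud"]))
  expect_equal(unname(v["nuc_pdc_count"]),
               sum(epi$nucleus_count[cls == "pdc"]))
  expect_equal(unname(v["nuc_intravascular_count"]),
               sum(epi$nucleus_count[cls %in% c("lvi", "minimal_lvi")]))
  expect_equal(unname(v["n_nuclei_total"]), nrow(h$nuclei))
  got <- sum(v[c("nuc_tumor_count", "nuc_stroma_count", "nuc_tumor_bud_count",
                 "nuc_pdc_count", "nuc_intravascular_count")])
  expect_lte(got, nrow(h$nuclei))
})

test_that("collation sums extensive and averages intensive features", {
  m <- manifest_default()
  v1 <- setNames(rep(NA_real_, 123), m$name)
  v1[] <- 0
  v2 <- v1; v3 <- v1
  v1["n_buds"] <- 1; v2["n_buds"] <- 2; v3["n_buds"] <- 0
  v1["tumor_stroma_pct"] <- 40; v2["tumor_stroma_pct"] <- 40
  v3["tumor_stroma_pct"] <- 40
  out <- collate_patient(list(v1, v2, v3), m)
  expect_identical(unname(out["n_buds"]), 3)
  expect_identical(unname(out["tumor_stroma_pct"]), 40)
})

test_that("collating a single field reproduces that field's vector", {
  f <- rich_field(); h <- rich_hierarchy(); cf <- rich_classified()
  v <- extract_field_features(h, cf, f$image)
  out <- collate_patient(list(v))
  ok <- !is.na(v)
  expect_equal(unname(unclass(out))[ok], unname(v)[ok])
})

test_that("mean features skip missing fields; all-missing collates to 0 with QC flag", {
  m <- manifest_default()
  v1 <- setNames(rep(0, 123), m$name)
  v2 <- v1
  v1["obj_pdc_mean_roundness"] <- NA_real_
  v2["obj_pdc_mean_roundness"] <- 0.8
  v1["nn_dist_vessel_um"] <- NA_real_
  v2["nn_dist_vessel_um"] <- NA_real_
  out <- collate_patient(list(v1, v2), m)
  expect_identical(unname(out["obj_pdc_mean_roundness"]), 0.8)
  expect_identical(unname(out["nn_dist_vessel_um"]), 0)
  expect_true("nn_dist_vessel_um" %in% attr(out, "qc_all_missing"))
  expect_false(anyNA(out))
})

test_that("unequal field vector lengths are rejected", {
  expect_error(collate_patient(list(c(a = 1), c(a = 1, b = 2))),
               "unequal")
})

test_that("patient AreaPDC equals the concatenated-section pixel oracle", {
  sec <- generate_section(base_spec = field_spec(n_buds = 1, n_pdc = 2,
                                                 n_vessels = 0, seed = 1),
                          n_fields = 3L, seed = 77)
  m <- manifest_default()
  vecs <- lapply(sec, function(fld) {
    h <- segment_field(fld$image)
    cf <- suppressMessages(classify_objects(h))
    extract_field_features(h, cf, fld$image, m)
  })
  pv <- collate_patient(vecs, m)
  oracle <- sum(vapply(sec, function(fld) {
    ids <- fld$truth$objects$id[fld$truth$objects$class == "pdc"]
    sum(fld$truth$epi_labels %in% ids) * 0.5^2
  }, 0))
  expect_lt(abs(pv["area_pdc_um2"] - oracle) / oracle, 0.05)
})
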