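test_that("planted counts equal the spec by construction", {
  f <- rich_field()
  counts <- f$truth$summary$counts
  expect_identical(counts$bud, 3L)
  expect_identical(counts$pdc, 2L)
  expect_identical(counts$vessel, 2L)
  expect_identical(counts$lvi, 1L)       # 6 intravascular nuclei
  expect_identical(counts$minimal_lvi, 1L)  # 2 intravascular nuclei
  expect_identical(nrow(f$truth$objects), 3L + 2L + 2L + 2L)
})

test_that("empty field spec yields only region classes and zero PDC area", {
  f <- generate_field(field_spec(n_buds = 0, n_pdc = 0, n_vessels = 0,
                                 tumor_fraction = 0.4, seed = 3))
  expect_identical(nrow(f$truth$objects), 0L)
  expect_identical(f$truth$summary$area_pdc_um2, 0)
  expect_setequal(unique(as.vector(f$truth$roi)), c(1L, 2L, 3L))
})

test_that("planted PDC area equals brute-force pixel counting on the label raster", {
  spec <- field_spec(n_buds = 0, n_pdc = 2, pdc_nucleus_counts = c(5L, 7L),
                     n_vessels = 0, pixel_size_um = 0.5, seed = 11)
  f <- generate_field(spec)
  pdc_ids <- f$truth$objects$id[f$truth$objects$class == "pdc"]
  # independent oracle: count label-raster pixels, multiply by 0.25 um^2/px
  oracle <- sum(f$truth$epi_labels %in% pdc_ids) * 0.5^2
  expect_equal(f$truth$summary$area_pdc_um2, oracle)
  expect_equal(sum(f$truth$objects$area_um2[f$truth$objects$class == "pdc"]),
               oracle)
})

test_that("generation is bit-reproducible for a fixed spec and leaves RNG alone", {
  spec <- rich_spec(seed = 99L)
  set.seed(1234); before <- runif(1)
  f1 <- generate_field(spec)
  f2 <- generate_field(spec)
  expect_identical(f1$image$dapi, f2$image$dapi)
  expect_identical(f1$image$panck, f2$image$panck)
  expect_identical(f1$truth$objects, f2$truth$objects)
  set.seed(1234)
  expect_identical(runif(1), before)
})

test_that("overcrowded fields abort with an explicit error", {
  expect_error(
    generate_field(field_spec(image_size_px = c(96L, 96L), n_buds = 30,
                              n_pdc = 10, tumor_fraction = 0.6, seed = 1)),
    "too crowded")
})

test_that("a section holds 15 fields by default and planted totals sum over fields", {
  sec <- generate_section(base_spec = field_spec(n_buds = 1, n_pdc = 1,
                                                 n_vessels = 1, seed = 1),
                          seed = 5)
  expect_length(sec, 15L)
  tot <- attr(sec, "section_summary")
  # summation oracle: recount over all per-field ground truths
  expect_identical(tot$bud,
                   sum(vapply(sec, function(f) f$truth$summary$counts$bud, 0)))
  expect_identical(tot$area_pdc_um2,
                   sum(vapply(sec, function(f) f$truth$summary$area_pdc_um2, 0)))
  expect_identical(tot$bud, 15)
  expect_identical(tot$pdc, 15)
})

test_that("identical field specs under different sub-seeds share counts, not pixels", {
  sec <- generate_section(base_spec = field_spec(seed = 1), n_fields = 2L,
                          seed = 8)
  c1 <- sec[[1]]$truth$summary$counts
  c2 <- sec[[2]]$truth$summary$counts
  expect_identical(c1, c2)
  expect_false(identical(sec[[1]]$image$dapi, sec[[2]]$image$dapi))
})

test_that("TIFF triplet + sidecar round-trips through write_field/read_field", {
  td <- withr::local_tempdir()
  f <- rich_field()
  paths <- write_field(f, td, "P001", "F01")
  expect_true(all(file.exists(paths)))
  expect_match(basename(paths[1:3]),
               "^P001_F01_(dapi|cy3|cy5)\\.tif$")
  img <- read_field(td, "P001", "F01")
  expect_s3_class(img, "FieldImage")
  # 16-bit quantization: agreement to 1/65535
  expect_lt(max(abs(img$dapi - f$image$dapi)), 1 / 65535 + 1e-9)
  side <- jsonlite::read_json(paths[4], simplifyVector = TRUE)
  expect_equal(side$summary$counts$bud, 3)
})
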