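# Coordinate transfer from per-area fullres frames into the group frame, and
# the lowres stitched image with its matching scale factor.

identity_tr <- function() affine2d(1, 0, 0, 1, 0, 0)

test_that("the reference area with identity transform maps to itself", {
  spots <- hex_spot_table(4L, 6L, col_pitch_px = 100)
  out <- apply_group_transform(spots, identity_tr(), h = 0.1, s = 1,
                               norm_scale_ref = 0.1)
  expect_equal(out, spots)
})

test_that("canvas translations rescale into group-fullres pixels", {
  spots <- hex_spot_table(3L, 4L, col_pitch_px = 100)
  tr <- affine2d(1, 0, 0, 1, 100, 50)
  out <- apply_group_transform(spots, tr, h = 0.1, s = 1, norm_scale_ref = 0.1)
  # t / norm_scale_ref = (1000, 500) group-fullres pixels; x is pxl_col
  expect_equal(out$pxl_col_in_fullres, spots$pxl_col_in_fullres + 1000)
  expect_equal(out$pxl_row_in_fullres, spots$pxl_row_in_fullres + 500)
  expect_identical(out$barcode, spots$barcode)
  expect_error(apply_group_transform(spots, NULL, 0.1, 1, 0.1), "transform")
})

test_that("rigid transforms scale all pairwise distances by d_ref/d_i", {
  set.seed(33)
  spots <- hex_spot_table(5L, 8L, col_pitch_px = 72.7)
  th <- -0.4
  tr <- affine2d(cos(th), sin(th), -sin(th), cos(th), 321, -55)
  d_ref <- 200; d_i <- 150; h_i <- 0.1
  # h_i * s_i = max(d h)/d_i with shared h: s_i = d_ref/d_i
  s_i <- d_ref / d_i
  norm_scale <- 0.1  # reference: h_ref * s_ref
  out <- apply_group_transform(spots, tr, h = h_i, s = s_i,
                               norm_scale_ref = norm_scale)
  before <- dist(cbind(spots$pxl_col_in_fullres, spots$pxl_row_in_fullres))
  after <- dist(cbind(out$pxl_col_in_fullres, out$pxl_row_in_fullres))
  expect_lt(max(abs(after - before * (d_ref / d_i)) / after), 1e-6)
})

test_that("frame composition for the reference area is the identity map", {
  set.seed(12)
  for (h in c(0.08, 0.2, 0.43)) {
    spots <- hex_spot_table(3L, 5L, col_pitch_px = runif(1, 50, 200))
    out <- apply_group_transform(spots, identity_tr(), h = h, s = 1,
                                 norm_scale_ref = h)
    expect_equal(out$pxl_col_in_fullres, spots$pxl_col_in_fullres, tolerance = 1e-12)
    expect_equal(out$pxl_row_in_fullres, spots$pxl_row_in_fullres, tolerance = 1e-12)
  }
})

test_that("stitched image resizes to the requested longest dimension", {
  canvas <- matrix(runif(120 * 90), nrow = 90)  # landscape 120 wide x 90 tall
  out <- resize_stitched_image(canvas, norm_scale_ref = 0.1, target_longest = 60L)
  expect_equal(dim(out$image), c(45L, 60L))
  expect_equal(out$tissue_lowres_scalef, (60 / 120) * 0.1)

  # already at target: dimensions unchanged
  same <- resize_stitched_image(canvas, norm_scale_ref = 0.1, target_longest = 120L)
  expect_equal(dim(same$image), dim(canvas))
  expect_equal(same$image, canvas)

  # default 1200-px target and the hand-computed lowres scale factor
  big <- matrix(0, nrow = 3000, ncol = 4000)
  res <- resize_stitched_image(big, norm_scale_ref = 0.1)
  expect_equal(dim(res$image), c(900L, 1200L))
  expect_equal(res$tissue_lowres_scalef, (1200 / 4000) * 0.1)

  expect_error(resize_stitched_image(matrix(numeric(), 0, 0), 0.1), "zero size")
})

test_that("group position tables concatenate areas with provenance columns", {
  sim <- small_sim()
  areas <- purrr::map2(sim$sample_info$spaceranger_dir, sim$sample_info$area_id,
                       read_capture_area)
  plan <- compute_rescale_factors(areas)
  transforms <- parse_fiji_xml(sim$sample_info$fiji_xml_path[[1L]])
  tab <- stitch_positions(areas, plan, transforms)
  expect_equal(nrow(tab), sum(purrr::map_int(areas, ~ nrow(.x$spots))))
  expect_true(all(c("capture_area", "barcode_original",
                    "array_row_original", "array_col_original") %in% names(tab)))
  expect_identical(unique(tab$capture_area), sim$sample_info$area_id)
  expect_false(anyDuplicated(tab$barcode) > 0)

  out <- withr::local_tempdir()
  paths <- write_group_positions(list(grp = tab), out)
  rt <- read_tissue_positions(file.path(out, "grp", "tissue_positions.csv"))
  expect_equal(nrow(rt), nrow(tab))
  expect_identical(rt$barcode, tab$barcode)
})

test_that("a single-area group with identity transform keeps its coordinates", {
  area <- small_area()
  plan <- compute_rescale_factors(list(area))
  tab <- stitch_positions(list(area), plan,
                          list("tiny_A1.png" = identity_tr()))
  expect_equal(tab$pxl_row_in_fullres, area$spots$pxl_row_in_fullres)
  expect_equal(tab$pxl_col_in_fullres, area$spots$pxl_col_in_fullres)
  expect_identical(tab$array_row, tab$array_row_original)
})

test_that("negative transformed coordinates warn instead of failing", {
  area <- small_area()
  plan <- compute_rescale_factors(list(area))
  shift_left <- affine2d(1, 0, 0, 1, -1e6, 0)
  expect_warning(
    stitch_positions(list(area), plan, list("tiny_A1.png" = shift_left)),
    "negative")
})

test_that("ground-truth coincident spot pairs land within 1 group-fullres pixel", {
  sim <- small_sim()
  g <- small_built()
  sp <- tidy(g)
  i <- match(sim$ground_truth$key_1, sp$barcode)
  j <- match(sim$ground_truth$key_2, sp$barcode)
  expect_false(anyNA(c(i, j)))
  d <- sqrt((sp$pxl_col_in_fullres[i] - sp$pxl_col_in_fullres[j])^2 +
              (sp$pxl_row_in_fullres[i] - sp$pxl_row_in_fullres[j])^2)
  expect_true(all(d <= 1))
})

test_that("transformed spot spacing converts back to 100 um within 0.5%", {
  g <- small_built()
  sp <- tidy(g)
  one_area <- sp[sp$capture_area == sp$capture_area[[1L]], ]
  xy <- cbind(one_area$pxl_col_in_fullres, one_area$pxl_row_in_fullres)
  nn <- vapply(seq_len(nrow(xy)), function(k) {
    d2 <- (xy[, 1L] - xy[k, 1L])^2 + (xy[, 2L] - xy[k, 2L])^2
    d2[[k]] <- Inf
    sqrt(min(d2))
  }, numeric(1L))
  med_um <- median(nn) * g$lattice$microns_per_pixel
  expect_lt(abs(med_um - 100) / 100, 0.005)
})
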