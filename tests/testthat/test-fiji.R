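# Uniform physical rescaling for stitching, and parsing of the per-image
# rigid affine transforms.

test_that("rescale factors equalise physical scale across capture areas", {
  # single area: identity
  one <- compute_rescale_factors(tibble::tibble(
    area_id = "A", spot_diameter_fullres = 200, tissue_hires_scalef = 0.1,
    width = 1000L, height = 800L))
  expect_equal(one$scale_factor, 1)
  expect_equal(one$new_width, 1000L)
  expect_equal(one$new_height, 800L)
  expect_identical(attr(one, "reference_id"), "A")

  # hand oracle: products d*h are 20 and 15, so s = (1, 20/15)
  two <- compute_rescale_factors(tibble::tibble(
    area_id = c("A", "B"),
    spot_diameter_fullres = c(200, 150), tissue_hires_scalef = c(0.1, 0.1),
    width = c(1000L, 1000L), height = c(800L, 800L)))
  expect_equal(two$scale_factor, c(1, 4 / 3))
  expect_identical(attr(two, "reference_id"), "A")
  expect_equal(attr(two, "norm_scale"), 0.1)

  # equal products: all s = 1, reference is lexicographically smallest id
  eq <- compute_rescale_factors(tibble::tibble(
    area_id = c("C", "B", "A"),
    spot_diameter_fullres = c(100, 200, 50),
    tissue_hires_scalef = c(0.2, 0.1, 0.4),
    width = 500L, height = 500L))
  expect_equal(eq$scale_factor, rep(1, 3))
  expect_identical(attr(eq, "reference_id"), "A")

  expect_error(compute_rescale_factors(tibble::tibble(
    area_id = character(), spot_diameter_fullres = double(),
    tissue_hires_scalef = double(), width = integer(), height = integer())),
    "empty")
})

test_that("d*h*s is constant across areas within 1e-9 relative", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(2:6, 1L)
    tab <- tibble::tibble(
      area_id = paste0("A", seq_len(n)),
      spot_diameter_fullres = runif(n, 50, 400),
      tissue_hires_scalef = runif(n, 0.05, 0.5),
      width = sample(200:2000, n), height = sample(200:2000, n))
    plan <- compute_rescale_factors(tab)
    prods <- plan$spot_diameter_fullres * plan$tissue_hires_scalef *
      plan$scale_factor
    expect_lt(max(abs(prods - max(prods))) / max(prods), 1e-9)
    expect_equal(min(plan$scale_factor), 1)
  }
})

test_that("images rescale to planned dimensions; s = 1 copies pixels", {
  # d*h products 30 and 20, so B upscales by exactly 1.5
  areas <- list(fake_area("A", d = 300, h = 0.1, width = 1000L, height = 800L),
                fake_area("B", d = 200, h = 0.1, width = 1000L, height = 800L))
  plan <- compute_rescale_factors(areas)
  expect_equal(plan$new_width[plan$area_id == "B"], 1500L)
  expect_equal(plan$new_height[plan$area_id == "B"], 1200L)
  out <- withr::local_tempdir()
  rescale_images(areas, plan, out)
  imgA <- read_raster(file.path(out, "A.png"))
  imgB <- read_raster(file.path(out, "B.png"))
  expect_equal(dim(imgA)[1:2], c(800L, 1000L))      # s = 1: unchanged
  # pixel-identical up to 8-bit PNG quantisation
  expect_lt(max(abs(imgA - areas[[1L]]$image)), 1 / 254)
  expect_equal(dim(imgB)[1:2], c(1200L, 1500L))
  meta <- jsonlite::read_json(file.path(out, "rescale_metadata.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$reference_id, "A")
  expect_equal(meta$norm_scale, 0.1)
})

test_that("rendered spot diameters agree across rescaled areas within 1 px", {
  # two areas with different fullres resolution (d) and hires scale (h);
  # each hires image carries a calibration disc of exactly one spot diameter
  dirs <- file.path(withr::local_tempdir(), c("cal_A", "cal_B"))
  simulate_capture_area(dirs[[1L]], n_rows = 6L, n_cols = 8L, d = 55, h = 0.5,
                        depth = 20, n_genes = 5L, seed = 21L)
  simulate_capture_area(dirs[[2L]], n_rows = 6L, n_cols = 8L, d = 80, h = 0.4,
                        depth = 20, n_genes = 5L, seed = 22L)
  areas <- lapply(dirs, read_capture_area)
  plan <- compute_rescale_factors(areas)
  out <- withr::local_tempdir()
  rescale_images(areas, plan, out)
  measure_disc <- function(path) {
    img <- read_raster(path)
    hits <- which(img > 0.9, arr.ind = TRUE)
    # calibration disc is the only near-white region
    max(hits[, 2L]) - min(hits[, 2L]) + 1L
  }
  d1 <- measure_disc(file.path(out, "cal_A.png"))
  d2 <- measure_disc(file.path(out, "cal_B.png"))
  expect_lte(abs(d1 - d2), 1L)
})

fiji_xml <- function(entries) {
  path <- tempfile(fileext = ".xml")
  writeLines(c("<trakem2><t2_layer_set>", entries, "</t2_layer_set></trakem2>"),
             path)
  path
}

test_that("Fiji XML transforms parse in both dialects", {
  path <- fiji_xml(c(
    '<t2_patch file_path="A1.png" transform="matrix(1,0,0,1,0,0)"/>',
    '<t2_patch file_path="D1.png" transform="matrix(0,1,-1,0,100,50)"/>'))
  trs <- parse_fiji_xml(path)
  expect_setequal(names(trs), c("A1.png", "D1.png"))
  expect_equal(trs[["A1.png"]]$matrix,
               matrix(c(1, 0, 0, 1, 0, 0), nrow = 2L,
                      dimnames = list(c("x", "y"), c("x", "y", "t"))))
  # 90-degree rotation plus translation: (0,0) -> (100,50), (1,0) -> (100,51)
  expect_equal(unname(apply_affine(trs[["D1.png"]], rbind(c(0, 0)))),
               rbind(c(100, 50)))
  expect_equal(unname(apply_affine(trs[["D1.png"]], rbind(c(1, 0)))),
               rbind(c(100, 51)))
  expect_true(is_rigid(trs[["D1.png"]]))

  # fallback dialect: explicit numeric attributes
  path2 <- fiji_xml('<patch image="C1.png" a="1" b="0" c="0" d="1" e="7" f="-2"/>')
  trs2 <- parse_fiji_xml(path2)
  expect_equal(unname(apply_affine(trs2[["C1.png"]], rbind(c(0, 0)))),
               rbind(c(7, -2)))
})

test_that("malformed or incomplete XML entries are hard errors", {
  expect_error(
    parse_fiji_xml(fiji_xml('<t2_patch file_path="A1.png" transform="matrix(1,0,0)"/>')),
    "malformed.*matrix\\(1,0,0\\)")
  expect_error(
    parse_fiji_xml(fiji_xml(c(
      '<t2_patch file_path="A1.png" transform="matrix(1,0,0,1,0,0)"/>',
      '<t2_patch file_path="A1.png" transform="matrix(1,0,0,1,5,5)"/>'))),
    "duplicate image name.*A1.png")
  expect_error(
    parse_fiji_xml(fiji_xml(c(
      '<t2_patch file_path="A1.png" transform="matrix(1,0,0,1,0,0)"/>',
      '<t2_patch file_path="B1.png"/>'))),
    "B1.png.*no transform")
})

test_that("non-rigid transforms warn by default and error when rigidity is required", {
  path <- fiji_xml('<t2_patch file_path="A1.png" transform="matrix(2,0,0,2,0,0)"/>')
  expect_warning(parse_fiji_xml(path), "not rigid")
  expect_error(parse_fiji_xml(path, require_rigid = TRUE), "not rigid")
})

test_that("parsed rigid transforms preserve pairwise distances within 1e-6", {
  th <- 0.7
  path <- fiji_xml(sprintf(
    '<t2_patch file_path="R.png" transform="matrix(%.12f,%.12f,%.12f,%.12f,12.5,-3)"/>',
    cos(th), sin(th), -sin(th), cos(th)))
  tr <- parse_fiji_xml(path)[["R.png"]]
  set.seed(7)
  pts <- matrix(runif(20, -500, 500), ncol = 2L)
  before <- dist(pts)
  after <- dist(apply_affine(tr, pts))
  expect_lt(max(abs(after - before) / before), 1e-6)
})
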