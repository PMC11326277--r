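# SpaceRanger-style file formats: scalefactors JSON, the two
# tissue_positions dialects, MatrixMarket counts, group spatial output.

test_that("scalefactors parse with field mapping, preserved extras, and errors", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0(
    '{"spot_diameter_fullres":200.0,"tissue_hires_scalef":0.1,',
    '"tissue_lowres_scalef":0.03}'), path)
  sf <- read_scalefactors(path)
  expect_s3_class(sf, "scalefactors")
  expect_equal(sf$spot_diameter_fullres, 200)
  expect_equal(sf$tissue_hires_scalef, 0.1)
  expect_equal(sf$tissue_lowres_scalef, 0.03)
  expect_null(sf$fiducial_diameter_fullres)

  # unknown keys survive a round trip
  writeLines(paste0(
    '{"spot_diameter_fullres":200.0,"tissue_hires_scalef":0.1,',
    '"tissue_lowres_scalef":0.03,"regist_target_img_scalef":0.5}'), path)
  sf2 <- read_scalefactors(path)
  expect_equal(sf2$spot_diameter_fullres, 200)
  expect_equal(sf2$extra$regist_target_img_scalef, 0.5)
  out <- withr::local_tempfile(fileext = ".json")
  write_scalefactors(sf2, out)
  back <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(back$regist_target_img_scalef, 0.5)
  rt <- read_scalefactors(out)
  expect_equal(rt[names(rt) != "extra"], sf2[names(sf2) != "extra"])

  writeLines('{"spot_diameter_fullres":200.0}', path)
  expect_error(read_scalefactors(path), "tissue_hires_scalef")
  writeLines('{"spot_diameter_fullres":-5,"tissue_hires_scalef":0.1}', path)
  expect_error(read_scalefactors(path), "positive")
})

test_that("unrealistic scale-factor orderings warn but do not fail", {
  expect_warning(scalefactors(100, 1.2), ">= 1")
  expect_warning(scalefactors(100, 0.1, tissue_lowres_scalef = 0.2), "lowres")
})

test_that("both tissue_positions dialects parse to identical records", {
  row <- "AAACAACGAATAGTTC-1,1,0,16,1000.5,2000.5"
  header <- "barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres"
  headered <- withr::local_tempfile(fileext = ".csv")
  headerless <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(header, row, "TTACAACGAATAGGGC-1,0,1,17,1100.5,2100.5"), headered)
  writeLines(c(row, "TTACAACGAATAGGGC-1,0,1,17,1100.5,2100.5"), headerless)

  a <- read_tissue_positions(headered)
  b <- read_tissue_positions(headerless)
  expect_identical(a, b)
  expect_identical(a$barcode[[1L]], "AAACAACGAATAGTTC-1")
  expect_true(a$in_tissue[[1L]])
  expect_false(a$in_tissue[[2L]])
  expect_identical(a$array_row, c(0L, 1L))
  expect_identical(a$array_col, c(16L, 17L))
  expect_equal(a$pxl_row_in_fullres, c(1000.5, 1100.5))
  expect_equal(a$pxl_col_in_fullres, c(2000.5, 2100.5))
})

test_that("tissue_positions rejects malformed rows with a line number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A-1,1,0,16,1000.5,2000.5", "B-1,1,0,16,1000.5"), path)
  expect_error(read_tissue_positions(path), "line 2")
  writeLines(c("A-1,1,0,16,1000.5,2000.5", "A-1,0,1,18,1.5,2.5"), path)
  expect_error(read_tissue_positions(path), "duplicate barcode")
})

test_that("gzipped positions files are read transparently", {
  path <- withr::local_tempfile(fileext = ".csv.gz")
  con <- gzfile(path, "w")
  writeLines("A-1,1,0,16,1000.5,2000.5", con)
  close(con)
  expect_equal(read_tissue_positions(path)$pxl_col_in_fullres, 2000.5)
})

test_that("positions round-trip bit-identically through write and read", {
  area <- small_area()
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_tissue_positions(area$spots, p1)
  rt <- read_tissue_positions(p1)
  expect_equal(rt, area$spots, tolerance = 1e-12)
  write_tissue_positions(rt, p2)
  expect_identical(readLines(p1), readLines(p2))
})

write_mtx_fixture <- function(dir, entries, n_genes, n_barcodes) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(
    "%%MatrixMarket matrix coordinate integer general",
    paste(n_genes, n_barcodes, nrow(entries)),
    apply(entries, 1L, paste, collapse = " ")
  ), file.path(dir, "matrix.mtx"))
  writeLines(paste0("BC", seq_len(n_barcodes), "-1"), file.path(dir, "barcodes.tsv"))
  writeLines(paste0("G", seq_len(n_genes), "\tSym", seq_len(n_genes),
                    "\tGene Expression"), file.path(dir, "features.tsv"))
  dir
}

test_that("MatrixMarket counts load with identifiers and stored-entry count", {
  dir <- withr::local_tempdir()
  # 3 genes x 2 barcodes, 4 nonzeros (independently counted in the text above)
  write_mtx_fixture(dir, rbind(c(1, 1, 5), c(2, 1, 1), c(3, 2, 7), c(1, 2, 2)),
                    n_genes = 3L, n_barcodes = 2L)
  m <- read_counts(dir)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(Matrix::nnzero(m), 4)
  expect_identical(rownames(m), c("G1", "G2", "G3"))
  expect_identical(colnames(m), c("BC1-1", "BC2-1"))
  expect_equal(attr(m, "features")$symbol, c("Sym1", "Sym2", "Sym3"))
  expect_equal(m["G3", "BC2-1"], 7)
})

test_that("empty count matrices are valid and dimension mismatches are not", {
  dir <- withr::local_tempdir()
  write_mtx_fixture(dir, matrix(numeric(), ncol = 3L), n_genes = 3L, n_barcodes = 2L)
  m <- read_counts(dir)
  expect_equal(Matrix::nnzero(m), 0)
  expect_equal(dim(m), c(3L, 2L))

  writeLines(paste0("BC", 1:3, "-1"), file.path(dir, "barcodes.tsv"))
  expect_error(read_counts(dir), "3 barcodes")
})

test_that("group spatial directory round-trips and georeferences the lowres image", {
  g <- small_built()
  dir <- file.path(withr::local_tempdir(), "spatial")
  write_group_spatial(dir, g$spots, g$image, g$scalefactors)
  expect_setequal(list.files(dir), c("tissue_positions.csv",
                                     "tissue_lowres_image.png",
                                     "scalefactors_json.json"))
  rt <- read_tissue_positions(file.path(dir, "tissue_positions.csv"))
  expect_equal(rt$barcode, g$spots$barcode)
  expect_equal(rt$pxl_row_in_fullres, g$spots$pxl_row_in_fullres, tolerance = 1e-9)
  img <- read_raster(file.path(dir, "tissue_lowres_image.png"))
  expect_equal(dim(img)[1:2], dim(g$image)[1:2])
  sf <- read_scalefactors(file.path(dir, "scalefactors_json.json"))
  # a group-fullres coordinate times the written factor lands on the raster
  expect_true(all(rt$pxl_row_in_fullres * sf$tissue_lowres_scalef <= dim(img)[1L]))
  expect_true(all(rt$pxl_col_in_fullres * sf$tissue_lowres_scalef <= dim(img)[2L]))
})

test_that("an empty spot table writes a header-only file", {
  dir <- file.path(withr::local_tempdir(), "spatial")
  header_only <- tempfile(fileext = ".csv")
  writeLines(
    "barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres",
    header_only)
  empty <- read_tissue_positions(header_only)
  g <- small_built()
  write_group_spatial(dir, empty, g$image, g$scalefactors)
  lines <- readLines(file.path(dir, "tissue_positions.csv"))
  expect_length(lines, 1L)
  expect_match(lines, "^barcode,")
  expect_equal(nrow(read_tissue_positions(file.path(dir, "tissue_positions.csv"))), 0L)
})
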