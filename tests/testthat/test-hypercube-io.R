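test_that("ENVI round trip is the identity for every interleave and dtype", {
  for (seed in 1:3) {
    cube <- rand_cube(3, 4, 5, seed = seed)
    for (il in c("bsq", "bil", "bip")) {
      for (dt in c("float32", "uint16")) {
        cb <- cube
        if (dt == "uint16") cb$data <- round(cb$data * 16)
        hdr <- tempfile(fileext = ".hdr")
        write_envi(cb, hdr, interleave = il, data_type = dt)
        back <- read_envi(hdr)
        expect_identical(back$data, cb$data,
                         label = paste("data", il, dt, seed))
        expect_equal(back$wavelengths, cb$wavelengths)
      }
    }
  }
})

test_that("the same voxels written as BIL and BIP read back identically", {
  cube <- rand_cube(4, 3, 6, seed = 9)
  h1 <- tempfile(fileext = ".hdr"); h2 <- tempfile(fileext = ".hdr")
  write_envi(cube, h1, interleave = "bil")
  write_envi(cube, h2, interleave = "bip")
  expect_identical(read_envi(h1)$data, read_envi(h2)$data)
})

test_that("header metadata is recorded and parsed faithfully", {
  # a 512-band VIS-NIR grid over 380-1030 nm survives the header
  cube <- hypercube(array(0.5, c(2, 2, 512)),
                    seq(380, 1030, length.out = 512), "reflectance")
  hdr <- tempfile(fileext = ".hdr")
  write_envi(cube, hdr)
  back <- read_envi(hdr, kind = "reflectance")
  expect_length(back$wavelengths, 512L)
  expect_equal(back$wavelengths, cube$wavelengths)

  # a 672-column frame declares samples = 672 and the interleave verbatim
  wide <- hypercube(array(1, c(2, 672, 3)), c(500, 600, 700))
  hdr2 <- tempfile(fileext = ".hdr")
  write_envi(wide, hdr2, interleave = "bil")
  txt <- readLines(hdr2)
  expect_true(any(grepl("^samples = 672$", txt)))
  expect_true(any(grepl("^interleave = bil$", txt)))
})

test_that("malformed ENVI inputs fail loudly and name the problem", {
  cube <- rand_cube(2, 2, 3)
  hdr <- tempfile(fileext = ".hdr")
  write_envi(cube, hdr)

  # missing key
  txt <- readLines(hdr)
  writeLines(txt[!grepl("^interleave", txt)], hdr)
  expect_error(read_envi(hdr), "interleave")

  # header/binary size mismatch
  hdr2 <- tempfile(fileext = ".hdr")
  write_envi(cube, hdr2)
  bin <- sub("\\.hdr$", ".dat", hdr2)
  writeBin(raw(10), bin)
  expect_error(read_envi(hdr2), "integrity")

  # unsupported data type
  hdr3 <- tempfile(fileext = ".hdr")
  write_envi(cube, hdr3)
  txt <- readLines(hdr3)
  writeLines(sub("^data type = 4$", "data type = 5", txt), hdr3)
  expect_error(read_envi(hdr3), "data type")
})

test_that("reflectance calibration follows (I0 - B) / (W - B)", {
  refs <- flat_refs(2, 2, 3)
  wl <- refs$white$wavelengths

  raw_w <- hypercube(refs$white$data, wl)
  expect_equal(calibrate_reflectance(raw_w, refs)$data,
               array(1, c(2, 2, 3)))
  raw_b <- hypercube(refs$black$data, wl)
  expect_equal(calibrate_reflectance(raw_b, refs)$data,
               array(0, c(2, 2, 3)))

  raw <- hypercube(array(0.6, c(2, 2, 3)), wl)
  cal <- calibrate_reflectance(raw, refs)
  expect_equal(cal$data, array(0.5, c(2, 2, 3)))  # (0.6-0.2)/(1-0.2)
  expect_s3_class(cal, "hypercube")
  expect_identical(cal$kind, "reflectance")
})

test_that("degenerate denominators yield 0 and are flagged in the mask", {
  wl <- c(500, 600)
  white <- array(1, c(2, 2, 2)); black <- array(0.2, c(2, 2, 2))
  white[1, 1, 1] <- 0.2                       # W == B at one voxel
  refs <- reference_pair(hypercube(white, wl), hypercube(black, wl))
  cal <- calibrate_reflectance(hypercube(array(0.6, c(2, 2, 2)), wl), refs)
  expect_identical(cal$data[1, 1, 1], 0)
  expect_true(cal$qc$degenerate[1, 1, 1])
  expect_identical(cal$qc$n_degenerate, 1L)
  expect_error(calibrate_reflectance(hypercube(array(1, c(2, 2, 2)), wl),
                                     refs, eps = -1), "eps")
})

test_that("calibration is invariant to a common positive intensity scale", {
  set.seed(4)
  wl <- seq(500, 700, length.out = 4)
  w <- array(runif(2 * 2 * 4, 0.8, 1), c(2, 2, 4))
  b <- array(runif(2 * 2 * 4, 0, 0.1), c(2, 2, 4))
  i0 <- b + (w - b) * array(runif(2 * 2 * 4), c(2, 2, 4))
  refs1 <- reference_pair(hypercube(w, wl), hypercube(b, wl))
  refs2 <- reference_pair(hypercube(3.7 * w, wl), hypercube(3.7 * b, wl))
  r1 <- calibrate_reflectance(hypercube(i0, wl), refs1)
  r2 <- calibrate_reflectance(hypercube(3.7 * i0, wl), refs2)
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
})

test_that("calibration rejects mismatched shapes", {
  refs <- flat_refs(2, 2, 3)
  raw <- hypercube(array(1, c(3, 3, 3)), refs$white$wavelengths)
  expect_error(calibrate_reflectance(raw, refs), "shape")
})

test_that("spectral cropping keeps the closed interval and is idempotent", {
  wl <- c(400, 500, 600, 900, 950)
  cube <- hypercube(array(seq_len(2 * 2 * 5), c(2, 2, 5)), wl)

  full <- crop_spectral(cube, 400, 950)
  expect_identical(full$data, cube$data)

  cr <- crop_spectral(cube, 500, 900)
  expect_identical(cr$wavelengths, c(500, 600, 900))
  expect_identical(dim(cr$data)[3L], 3L)
  expect_identical(crop_spectral(cr, 500, 900)$data, cr$data)

  expect_error(crop_spectral(cube, 700, 850), "no bands")
  expect_error(crop_spectral(cube, 900, 500), "lo")
})

test_that("ROI extraction is seeded, disjoint and bounded", {
  cube <- rand_cube(40, 40, 2)

  # whole image as the single ROI when side equals the image
  whole <- extract_rois(cube, side = 40, n = 1, seed = 3)
  expect_length(whole, 1L)
  expect_identical(whole[[1]]$cube$data, cube$data)

  r1 <- extract_rois(cube, side = 10, n = 5, seed = 7)
  r2 <- extract_rois(cube, side = 10, n = 5, seed = 7)
  expect_identical(lapply(r1, `[[`, "origin"), lapply(r2, `[[`, "origin"))

  # ROI pixels are a subset of the parent and the union has area n * side^2
  mask <- matrix(FALSE, 40, 40)
  for (rr in r1) {
    rows <- rr$origin[1]:(rr$origin[1] + rr$side - 1)
    cols <- rr$origin[2]:(rr$origin[2] + rr$side - 1)
    expect_identical(rr$cube$data, cube$data[rows, cols, , drop = FALSE])
    mask[rows, cols] <- TRUE
  }
  expect_identical(sum(mask), 5L * 100L)

  expect_error(extract_rois(cube, side = 30, n = 4, seed = 1),
               "maximum achieved")
})

test_that("ten disjoint 100x100 ROIs fit in a 1000x1000 frame", {
  big <- hypercube(array(0, c(1000, 1000, 1)), 550)
  rois <- extract_rois(big, side = 100, n = 10, seed = 1)
  expect_length(rois, 10L)
  origins <- do.call(rbind, lapply(rois, `[[`, "origin"))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_true(abs(origins[i, 1] - origins[j, 1]) >= 100 ||
                  abs(origins[i, 2] - origins[j, 2]) >= 100)
  }
})
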