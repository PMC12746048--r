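test_that("dose_image validates its invariants", {
  expect_s3_class(dose_image(matrix(1, 3, 3)), "dose_image")
  expect_error(dose_image(matrix(-1, 3, 3)), "non-negative")
  expect_error(dose_image(matrix(NA_real_, 3, 3)), "finite")
  expect_error(dose_image(matrix(1, 1, 5)), "at least 2 x 2")
  expect_error(dose_image(matrix(1, 3, 3), spacing = c(0, 1)), "spacing")
})

test_that("text-grid files round-trip and parse the documented header", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("spacing 1.0 1.0", "origin 0 0", "unit Gy",
               "1 1 1", "1 1 1", "1 1 1"), path)
  img <- read_dose_plane(path, "text-grid")
  expect_equal(img$values, matrix(1, 3, 3))
  expect_equal(img$spacing, c(1, 1))
  expect_equal(img$origin, c(0, 0))

  set.seed(11)
  img2 <- dose_image(matrix(runif(35, 0, 2.5), 5, 7),
                     spacing = c(0.7, 1.3), origin = c(-3.2, 4.5),
                     unit_label = "Gy")
  write_dose_plane(img2, path, "text-grid")
  back <- read_dose_plane(path)
  expect_equal(back$values, img2$values, tolerance = 1e-6)
  expect_equal(back$spacing, img2$spacing)
  expect_equal(back$origin, img2$origin)
  expect_equal(back$unit_label, "Gy")
})

test_that("DICOM RT Dose planes round-trip within 1e-6 of the maximum dose", {
  path <- withr::local_tempfile(fileext = ".dcm")
  ramp <- dose_image(matrix(0:99, 10, 10, byrow = TRUE),
                     spacing = c(2, 2), origin = c(-9, -9))
  write_dose_plane(ramp, path, "dicom-rtdose")
  back <- read_dose_plane(path) # format sniffed from the DICM magic
  expect_equal(back$values, ramp$values, tolerance = 1e-7)
  expect_equal(back$spacing, c(2, 2))
  expect_equal(back$origin, c(-9, -9))

  set.seed(12)
  img <- dose_image(matrix(runif(64, 0, 4), 8, 8))
  write_dose_plane(img, path, "dicom-rtdose")
  back <- read_dose_plane(path, "dicom-rtdose")
  expect_lt(max(abs(back$values - img$values)), 1e-6 * max(img$values))
})

test_that("reading a missing or malformed file fails cleanly", {
  expect_error(read_dose_plane(file.path(tempdir(), "nope.txt")), "no such file")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("notaheader 1 1", "origin 0 0", "unit Gy", "1 1", "1 1"), path)
  expect_error(read_dose_plane(path, "text-grid"), "spacing")
  writeLines(c("spacing 1 1", "origin 0 0", "unit Gy", "1 1 1", "1 1"), path)
  expect_error(read_dose_plane(path, "text-grid"), "unequal")
})

test_that("resample_to is exact on identity, constants and affine surfaces", {
  set.seed(3)
  img <- dose_image(matrix(runif(100, 1, 5), 10, 10))
  same <- resample_to(img, img)
  expect_equal(same$values, img$values)
  expect_true(all(attr(same, "valid")))

  const <- dose_image(matrix(7, 12, 12), origin = c(-2, -2))
  target <- dose_image(matrix(0, 5, 5), spacing = c(1.3, 1.7), origin = c(0.1, 0.2))
  out <- resample_to(const, target)
  expect_equal(out$values[attr(out, "valid")],
               rep(7, sum(attr(out, "valid"))))

  # planar dose surface: bilinear interpolation reproduces it exactly
  y <- 0:10; x <- 0:10
  plane <- outer(y, x, function(y, x) 2 + 0.3 * y + 0.7 * x)
  src <- dose_image(plane)
  fine <- dose_image(matrix(0, 19, 19), spacing = c(0.5, 0.5), origin = c(0.25, 0.25))
  out <- resample_to(src, fine)
  fy <- fine$origin[1] + (0:18) * 0.5
  fx <- fine$origin[2] + (0:18) * 0.5
  expected <- outer(fy, fx, function(y, x) 2 + 0.3 * y + 0.7 * x)
  expect_equal(out$values, expected, tolerance = 1e-12)
})

test_that("resample_to flags points outside the source extent", {
  img <- dose_image(matrix(5, 4, 4)) # extent [0, 3] x [0, 3]
  target <- dose_image(matrix(0, 4, 4), origin = c(2, 2)) # extent [2, 5]
  out <- resample_to(img, target)
  v <- attr(out, "valid")
  expect_true(v[1, 1])
  expect_false(v[4, 4])
  expect_equal(out$values[!v], rep(0, sum(!v)))
  far <- dose_image(matrix(1, 3, 3), origin = c(100, 100))
  expect_error(resample_to(img, far), "overlap")
})
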