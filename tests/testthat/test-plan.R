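test_that("plan models round-trip through DICOM on all modelled fields", {
  path <- withr::local_tempfile(fileext = ".dcm")
  plan <- demo_plan(n_pairs = 10, n_cp = 2, mu = 250)
  write_rtplan(plan, path)
  back <- read_rtplan(path)
  expect_equal(length(back$beams), 1)
  b0 <- plan$beams[[1]]; b1 <- back$beams[[1]]
  expect_equal(b1$mu, b0$mu)
  expect_equal(b1$collimator_angle_deg, b0$collimator_angle_deg)
  expect_equal(b1$leaf_boundaries_mm, b0$leaf_boundaries_mm)
  for (k in seq_along(b0$control_points)) {
    expect_equal(b1$control_points[[k]]$bank_A_positions_mm,
                 b0$control_points[[k]]$bank_A_positions_mm, tolerance = 1e-9)
    expect_equal(b1$control_points[[k]]$bank_B_positions_mm,
                 b0$control_points[[k]]$bank_B_positions_mm, tolerance = 1e-9)
    expect_equal(b1$control_points[[k]]$jaw_x_mm,
                 b0$control_points[[k]]$jaw_x_mm)
    expect_equal(b1$control_points[[k]]$jaw_y_mm,
                 b0$control_points[[k]]$jaw_y_mm)
  }
  # write(read(file)) preserves every modelled attribute again
  path2 <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(back, path2)
  again <- read_rtplan(path2)
  expect_equal(again$beams[[1]], b1)
})

test_that("perturbations follow the symmetric-split arithmetic", {
  plan <- demo_plan(mu = 100)
  p2 <- perturb_plan(plan, "mu_pct", 2)
  expect_equal(p2$beams[[1]]$mu, 102)

  # +1.5 mm gap on a pair at (-10, +10) -> (-10.75, +10.75)
  wide <- plan
  wide$beams[[1]]$control_points <- lapply(
    wide$beams[[1]]$control_points, function(cp) {
      cp$bank_A_positions_mm[] <- -10
      cp$bank_B_positions_mm[] <- 10
      cp
    })
  grown <- perturb_plan(wide, "mlc_gap_mm", 1.5)
  expect_equal(grown$beams[[1]]$control_points[[1]]$bank_A_positions_mm,
               rep(-10.75, 10))
  expect_equal(grown$beams[[1]]$control_points[[1]]$bank_B_positions_mm,
               rep(10.75, 10))

  # gap errors that never clamp are invertible
  undone <- perturb_plan(grown, "mlc_gap_mm", -1.5)
  expect_equal(undone$beams[[1]], wide$beams[[1]], tolerance = 1e-12)

  # independent errors commute
  a <- perturb_plan(perturb_plan(plan, "mu_pct", 2), "collimator_deg", 1)
  b <- perturb_plan(perturb_plan(plan, "collimator_deg", 1), "mu_pct", 2)
  expect_equal(a$beams, b$beams)

  # the central variant leaves the outer pairs alone
  central <- perturb_plan(wide, "mlc_gap_central_mm", 5)
  cp <- central$beams[[1]]$control_points[[1]]
  expect_equal(sum(cp$bank_A_positions_mm == -12.5), 3) # middle third of 10
  expect_equal(sum(cp$bank_A_positions_mm == -10), 7)
})

test_that("erosions clamp closed pairs and report degenerate plans", {
  plan <- demo_plan()
  expect_warning(perturb_plan(plan, "mlc_gap_mm", -45), "clamped")
  expect_error(suppressWarnings(perturb_plan(plan, "mlc_gap_mm", -200)),
               "closed every leaf pair")
})

test_that("perturb-write-read shows exactly the applied deltas", {
  path <- withr::local_tempfile(fileext = ".dcm")
  plan <- demo_plan(n_pairs = 8)
  write_rtplan(perturb_plan(plan, "mlc_gap_mm", 2), path)
  back <- read_rtplan(path)
  for (k in seq_along(plan$beams[[1]]$control_points)) {
    cp0 <- plan$beams[[1]]$control_points[[k]]
    cp1 <- back$beams[[1]]$control_points[[k]]
    open <- cp0$bank_B_positions_mm - cp0$bank_A_positions_mm > 0.5
    expect_equal(cp1$bank_A_positions_mm[open],
                 cp0$bank_A_positions_mm[open] - 1, tolerance = 1e-9)
    expect_equal(cp1$bank_B_positions_mm[open],
                 cp0$bank_B_positions_mm[open] + 1, tolerance = 1e-9)
    expect_equal(cp1$bank_A_positions_mm[!open],
                 cp0$bank_A_positions_mm[!open], tolerance = 1e-9)
  }
})

test_that("aperture projection reproduces analytic areas", {
  grid <- sim_grid(n = 100)
  plan <- demo_plan(n_pairs = 10)
  # retract the MLC: the aperture becomes the jaw rectangle
  ny <- perturb_plan(plan, "retract_mlc")
  mask <- project_aperture(ny$beams[[1]], grid)
  cp <- plan$beams[[1]]$control_points[[1]]
  jaw_area <- diff(cp$jaw_x_mm) * diff(cp$jaw_y_mm)
  rind <- 2 * (diff(cp$jaw_x_mm) + diff(cp$jaw_y_mm)) * 0.5
  expect_lt(abs(sum(mask) - jaw_area), rind / 2 + 1)

  # rotating a square aperture by 1 degree preserves its area within 0.5%
  sq <- plan
  sq$beams[[1]]$control_points <- lapply(sq$beams[[1]]$control_points,
                                         function(cp) {
    cp$bank_A_positions_mm[] <- -15; cp$bank_B_positions_mm[] <- 15
    cp$jaw_x_mm <- c(-15, 15); cp$jaw_y_mm <- c(-15, 15)
    cp
  })
  a0 <- sum(project_aperture(sq$beams[[1]], grid))
  rot <- perturb_plan(sq, "collimator_deg", 1)
  a1 <- sum(project_aperture(rot$beams[[1]], grid))
  expect_lt(abs(a1 - a0) / a0, 0.005)

  # a fully closed plan projects to an empty mask
  closed <- plan
  closed$beams[[1]]$control_points <- lapply(closed$beams[[1]]$control_points,
                                             function(cp) {
    cp$bank_A_positions_mm[] <- 0; cp$bank_B_positions_mm[] <- 0
    cp
  })
  expect_equal(sum(project_aperture(closed$beams[[1]], grid)), 0)
})

test_that("plans without an MLC sequence are rejected as malformed", {
  path <- withr::local_tempfile(fileext = ".dcm")
  plan <- demo_plan()
  ds <- transitgamma:::rtplan_skeleton(plan)
  ds <- transitgamma:::rtplan_update(ds, plan)
  beam <- ds[["300A,00B0"]]$value[[1]]
  beam[["300A,00B6"]] <- NULL # drop the device definitions
  cps <- beam[["300A,0111"]]$value
  for (k in seq_along(cps)) {
    pos <- cps[[k]][["300A,011A"]]$value
    pos <- Filter(function(it) !identical(it[["300A,00B8"]]$value, "MLCX"), pos)
    cps[[k]][["300A,011A"]]$value <- pos
  }
  beam[["300A,0111"]]$value <- cps
  ds[["300A,00B0"]]$value[[1]] <- beam
  transitgamma:::write_dicom_file(ds, path, transitgamma:::UID_RTPLAN, "2.25.2")
  expect_error(read_rtplan(path), "MLCX")
})
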