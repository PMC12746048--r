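# small grid keeps the forward-model unit tests fast
fs_grid <- sim_grid(n = 96, spacing_mm = 1)

open_beam <- function(grid, half = 30, sigma = 1, mu = 100, k = 1) {
  beam_model(grid, leaf_x1 = rep(-half, 12), leaf_x2 = rep(half, 12),
             leaf_edges = seq(-half, half, length.out = 13),
             jaw = c(-half, half, -half, half),
             mu = mu, output_per_mu = k, penumbra_sigma_mm = sigma)
}

slab_patient <- function(grid, t_mm, ptv_r = 10) {
  patient_model(grid,
                components = list(soft = matrix(t_mm, grid$n[1], grid$n[2])),
                densities = c(soft = 1),
                ptv_mask = ellipse_mask_for_test(grid, c(0, 0), c(ptv_r, ptv_r)))
}

ellipse_mask_for_test <- function(grid, center, semi) {
  transitgamma:::ellipse_mask(grid, center, semi)
}

test_that("the transit forward model obeys its closed forms", {
  beam <- open_beam(fs_grid, sigma = 0.6)
  # zero thickness: dose equals k * MU deep inside the aperture
  p0 <- slab_patient(fs_grid, 0)
  d0 <- transit_dose(p0, beam)
  center <- d0$values[44:52, 44:52]
  expect_true(all(abs(center - 100) < 1e-9))
  # uniform 200 mm slab at mu = 0.005/mm: interior dose = k MU e^-1
  p200 <- slab_patient(fs_grid, 200)
  d200 <- transit_dose(p200, beam)
  expect_equal(mean(d200$values[44:52, 44:52]), 100 * exp(-1), tolerance = 1e-9)
  # doubling MU doubles every pixel
  beam2 <- beam; beam2$mu <- beam$mu * 2
  expect_equal(transit_dose(p200, beam2)$values, 2 * d200$values)
})

test_that("the surrogate PTV mean dose is exact where it must be", {
  beam <- open_beam(fs_grid)
  pat <- slab_patient(fs_grid, 150)
  base <- surrogate_ptv_dmean(pat, beam)
  expect_gt(base, 0)
  expect_equal(base, surrogate_ptv_dmean(pat, beam)) # deterministic

  # MU x 1.02 shifts the surrogate by exactly +2%
  up <- apply_linac_error(beam, "mu_scale", 2)
  expect_equal(surrogate_ptv_dmean(pat, up) / base, 1.02, tolerance = 1e-12)

  # removing a bolus of thickness b multiplies the mid-depth surrogate by
  # exp(mu * b / 2)
  bol <- pat
  bol$components$bolus <- matrix(10, fs_grid$n[1], fs_grid$n[2])
  bol$densities <- c(bol$densities, bolus = 1)
  bol <- patient_model(fs_grid, bol$components, bol$densities, bol$ptv_mask)
  expect_equal(surrogate_ptv_dmean(pat, beam) / surrogate_ptv_dmean(bol, beam),
               exp(0.005 * 10 / 2), tolerance = 1e-12)

  # a beam that misses the PTV entirely is a degenerate scenario
  off <- ellipse_mask_for_test(fs_grid, c(44, 44), c(3, 3))
  missed <- patient_model(fs_grid, pat$components, pat$densities, off)
  expect_error(surrogate_ptv_dmean(missed, beam), "does not overlap")
})

test_that("MLC shifts grow the aperture by sub-pixel-weighted rinds", {
  beam <- open_beam(fs_grid, half = 20, sigma = 1)
  area0 <- sum(beam$aperture_mask)
  grown <- apply_linac_error(beam, "mlc_shift", 1.5)
  # each bank moves 0.75 mm over a 40 mm-tall stack of open leaves
  expect_equal(sum(grown$aperture_mask) - area0, 1.5 * 40, tolerance = 2)
  shrunk <- apply_linac_error(beam, "mlc_shift", -1.5)
  expect_equal(area0 - sum(shrunk$aperture_mask), 1.5 * 40, tolerance = 2)
  # central variant touches only the middle third of open leaves
  central <- apply_linac_error(beam, "mlc_shift_central", 5)
  moved_rows <- which(apply(abs(central$aperture_mask - beam$aperture_mask) > 0, 1, any))
  expect_true(all(moved_rows > 96 / 2 - 12 & moved_rows < 96 / 2 + 12))
  # closing everything is a degenerate scenario
  expect_error(apply_linac_error(beam, "mlc_shift", -100), "degenerate")
})

test_that("a fully retracted MLC floods the jaw aperture with dose", {
  pat <- hn_patient(sim_grid(n = 128))
  beam <- hn_beam(pat, seed = 7)
  ny <- apply_linac_error(beam, "mlc_retracted")
  ref <- transit_dose(pat, beam)
  ev <- transit_dose(pat, ny)
  expect_true(all(ev$values >= ref$values - 1e-9))
  g <- compute_gamma(ref, ev, gamma_criterion(10, 5, "global"))
  expect_lt(g$passing_rate_pct, 50)
})

test_that("breathing-phase errors move dose in the physically right direction", {
  grid <- sim_grid(n = 192)
  insp <- thorax_patient(grid, 0)
  exp_pat <- thorax_patient(grid, 25)
  beam_i <- transitgamma:::conformal_beam(insp)
  ref <- transit_dose(insp, beam_i)
  delivered <- apply_anatomy_error(insp, "breath_shift",
                                   list(displacement_mm = 25))
  ev <- transit_dose(delivered, beam_i)
  # delivering in expiration after planning in inspiration puts soft tissue
  # where lung was expected: more attenuation, lower transit dose
  changed <- abs(transitgamma:::effective_thickness(delivered) -
                 transitgamma:::effective_thickness(insp)) > 1
  infield <- changed & ref$values > 0.2 * max(ref$values)
  expect_lt(mean(ev$values[infield]), mean(ref$values[infield]))

  # and the converse delivery raises the transit dose
  beam_e <- transitgamma:::conformal_beam(exp_pat)
  ref_e <- transit_dose(exp_pat, beam_e)
  delivered_i <- apply_anatomy_error(exp_pat, "breath_shift",
                                     list(displacement_mm = 0))
  ev_i <- transit_dose(delivered_i, beam_e)
  changed_e <- abs(transitgamma:::effective_thickness(delivered_i) -
                   transitgamma:::effective_thickness(exp_pat)) > 1
  infield_e <- changed_e & ref_e$values > 0.2 * max(ref_e$values)
  expect_gt(mean(ev_i$values[infield_e]), mean(ref_e$values[infield_e]))

  # zero displacement is a no-op
  same <- apply_anatomy_error(insp, "breath_shift", list(displacement_mm = 0))
  expect_equal(transitgamma:::effective_thickness(same),
               transitgamma:::effective_thickness(insp))
})

test_that("bolus removal is an involution and raises the transit dose", {
  grid <- sim_grid(n = 128)
  pat <- breast_patient(grid, "A", seed = 3, bolus_mm = 10)
  removed <- apply_anatomy_error(pat, "bolus_removed")
  restored <- apply_anatomy_error(removed, "bolus_removed")
  expect_equal(restored$thickness_map, pat$thickness_map)
  beam <- transitgamma:::conformal_beam(pat)
  ref <- transit_dose(pat, beam)
  ev <- transit_dose(removed, beam)
  footprint <- pat$components$bolus > 0
  expect_true(all(ev$values[footprint] >= ref$values[footprint]))
})

test_that("fluid_change toggles the fluid region density both ways", {
  grid <- sim_grid(n = 128)
  wet <- wrongct_patient(grid, fluid_present = TRUE)
  dry <- apply_anatomy_error(wet, "fluid_change")
  expect_equal(dry$densities[["fluid"]], 0.25)
  expect_equal(apply_anatomy_error(dry, "fluid_change")$densities[["fluid"]], 1.0)
  # same geometric thickness, lower effective thickness without fluid
  expect_equal(dry$thickness_map, wet$thickness_map)
  expect_lt(mean(transitgamma:::effective_thickness(dry)),
            mean(transitgamma:::effective_thickness(wet)))
})

test_that("the generated suite is deterministic and correctly composed", {
  cfg <- suite_config(grid = sim_grid(n = 144))
  s1 <- generate_suite(cfg, seed = 9)
  s2 <- generate_suite(cfg, seed = 9)
  expect_identical(suite_manifest(s1), suite_manifest(s2))
  for (k in c(1, 11, 15, 22))
    expect_identical(s1[[k]]$evaluated$values, s2[[k]]$evaluated$values)
  m <- suite_manifest(s1)
  expect_equal(nrow(m), 22)
  expect_equal(as.vector(table(m$failure_mode)[c("linac_hardware", "breathing",
                                                 "patient_id", "wrong_ct",
                                                 "bolus")]),
               c(11, 6, 2, 2, 1))
  # MU +/-2% scenarios carry exactly +/-2% surrogate labels
  expect_equal(m$delta_dmean_pct[m$scenario_id == "linac_mu_+2_pct"], 2,
               tolerance = 1e-9)
  expect_equal(m$delta_dmean_pct[m$scenario_id == "linac_mu_-2_pct"], -2,
               tolerance = 1e-9)
  # a different seed changes the seeded modulation
  s3 <- generate_suite(cfg, seed = 10)
  expect_false(identical(s1[[1]]$reference$values, s3[[1]]$reference$values))
})
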