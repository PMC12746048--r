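test_that("identity comparison gives gamma 0 and a 100% passing rate", {
  set.seed(21)
  img <- dose_image(matrix(runif(400, 10, 90), 20, 20))
  for (cr in list(gamma_criterion(3, 3, "global"),
                  gamma_criterion(10, 1, "local"),
                  gamma_criterion(5, 5, "global", threshold_pct = 50))) {
    g <- compute_gamma(img, img, cr)
    expect_equal(g$passing_rate_pct, 100)
    expect_equal(max(g$gamma_map, na.rm = TRUE), 0)
  }
})

test_that("uniform fields reproduce the closed-form gamma", {
  p <- uniform_pair(100, 104)
  g <- compute_gamma(p$reference, p$evaluated, gamma_criterion(3, 3, "global"))
  expect_equal(unique(c(g$gamma_map)), 4 / 3, tolerance = 1e-9)
  expect_equal(g$passing_rate_pct, 0)
  expect_equal(g$normalization_dose, 100)

  # boundary case: gamma exactly 1 counts as a pass
  p3 <- uniform_pair(100, 103)
  g3 <- compute_gamma(p3$reference, p3$evaluated, gamma_criterion(3, 3, "global"))
  expect_equal(unique(c(g3$gamma_map)), 1, tolerance = 1e-9)
  expect_equal(g3$passing_rate_pct, 100)

  # local normalization identical here since D_ref = D_norm everywhere
  gl <- compute_gamma(p$reference, p$evaluated, gamma_criterion(3, 3, "local"))
  expect_equal(gl$gamma_map, g$gamma_map, tolerance = 1e-9)
})

test_that("a translated step edge passes within the DTA and fails beyond it", {
  step <- matrix(0, 21, 21)
  step[, 11:21] <- 100
  ref <- dose_image(step)
  shifted <- dose_image(step, origin = c(0, 2)) # edge moved +2 mm in x
  g3 <- compute_gamma(ref, shifted, gamma_criterion(1, 3, "global"))
  expect_equal(g3$passing_rate_pct, 100)
  expect_lt(max(g3$gamma_map, na.rm = TRUE), 1)
  g1 <- compute_gamma(ref, shifted, gamma_criterion(1, 1, "global"))
  expect_lt(g1$passing_rate_pct, 100)
  # the failures sit in the moved penumbra: the reference columns whose
  # evaluated dose dropped and whose nearest agreement is farther than 1 mm
  fails <- which(g1$gamma_map > 1, arr.ind = TRUE)
  expect_true(all(fails[, "col"] %in% 11:12))
  # brute-force oracle on a finely upsampled grid agrees
  b1 <- brute_force_gamma(ref, shifted, gamma_criterion(1, 1, "global"),
                          upsample_factor = 20)
  expect_equal(g1$passing_rate_pct, b1$passing_rate_pct, tolerance = 0.5)
})

test_that("gamma is invariant under joint rescaling of both images", {
  p <- smooth_pair(31)
  for (norm in c("global", "local")) {
    cr <- gamma_criterion(3, 3, norm)
    base <- compute_gamma(p$reference, p$evaluated, cr)
    for (k in c(0.25, 40)) {
      scaled <- compute_gamma(
        dose_image(p$reference$values * k, p$reference$spacing, p$reference$origin),
        dose_image(p$evaluated$values * k, p$evaluated$spacing, p$evaluated$origin),
        cr)
      expect_equal(scaled$gamma_map, base$gamma_map, tolerance = 1e-9)
      expect_equal(scaled$passing_rate_pct, base$passing_rate_pct)
    }
  }
})

test_that("local normalization is never more lenient than global", {
  for (s in 41:44) {
    p <- smooth_pair(s, perturb = 0.04)
    for (cfg in list(c(3, 3), c(10, 1))) {
      gg <- compute_gamma(p$reference, p$evaluated,
                          gamma_criterion(cfg[1], cfg[2], "global"))
      gl <- compute_gamma(p$reference, p$evaluated,
                          gamma_criterion(cfg[1], cfg[2], "local"))
      # ordering holds to the search's numerical accuracy (the refinement
      # of the two normalizations can polish along different paths)
      expect_true(all(gl$gamma_map >= gg$gamma_map - 1e-3, na.rm = TRUE))
      expect_lte(gl$passing_rate_pct, gg$passing_rate_pct + 1e-9)
    }
  }
})

test_that("passing rate is monotone in the dose and distance tolerances", {
  # checked against the exhaustive oracle so search truncation cannot fake
  # or break monotonicity
  p <- smooth_pair(55, n = 14, perturb = 0.06)
  rate <- function(dd, dta) {
    brute_force_gamma(p$reference, p$evaluated,
                      gamma_criterion(dd, dta, "global"),
                      upsample_factor = 16)$passing_rate_pct
  }
  by_dd <- vapply(c(1, 2, 3, 5, 10), rate, numeric(1), dta = 2)
  expect_true(all(diff(by_dd) >= 0))
  by_dta <- vapply(c(0.5, 1, 2, 3), function(d) rate(2, d), numeric(1))
  expect_true(all(diff(by_dta) >= 0))
})

test_that("compiled search matches the exhaustive oracle on smooth pairs", {
  crs <- list(gamma_criterion(3, 3, "global"), gamma_criterion(5, 3, "local"),
              gamma_criterion(10, 3, "global"))
  for (s in 1:6) {
    p <- smooth_pair(100 + s)
    cr <- crs[[(s %% 3) + 1]]
    a <- compute_gamma(p$reference, p$evaluated, cr)
    b <- brute_force_gamma(p$reference, p$evaluated, cr, upsample_factor = 32)
    expect_lt(max(abs(a$gamma_map - b$gamma_map), na.rm = TRUE), 0.02)
    expect_lt(abs(a$passing_rate_pct - b$passing_rate_pct), 0.5)
  }
})

test_that("degenerate inputs raise the documented errors", {
  zero <- dose_image(matrix(0, 4, 4))
  img <- dose_image(matrix(50, 4, 4))
  cr <- gamma_criterion(3, 3, "global")
  expect_error(compute_gamma(zero, img, cr), "no dose")
  # evaluated image physically elsewhere: nothing to search
  far <- dose_image(matrix(50, 4, 4), origin = c(500, 500))
  expect_error(compute_gamma(img, far, cr), "no evaluable points")
})

test_that("evaluate_criteria_set tabulates the 14 study metrics", {
  p <- uniform_pair(100, 104, n = 6)
  tab <- evaluate_criteria_set(p$reference, p$reference)
  expect_equal(nrow(tab), 14)
  expect_equal(unique(tab$passing_rate_pct), 100)
  expect_equal(sum(tab$normalization == "global"), 7)

  tab4 <- evaluate_criteria_set(p$reference, p$evaluated)
  # a 4% uniform offset passes every >= 5% criterion and fails every 3% one
  expect_true(all(tab4$passing_rate_pct[tab4$dose_diff_pct >= 5] == 100))
  expect_true(all(tab4$passing_rate_pct[tab4$dose_diff_pct == 3] == 0))

  # a failing criterion is recorded, not fatal
  far <- dose_image(matrix(50, 6, 6), origin = c(500, 500))
  mixed <- evaluate_criteria_set(p$reference, far,
                                 criteria = list(gamma_criterion(3, 3, "global")))
  expect_true(is.na(mixed$passing_rate_pct[1]))
  expect_match(mixed$error[1], "no evaluable")
})
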