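# Parameterized toy anatomies for the five failure modes. All geometry is
# deterministic given the seed; distances in mm on the image-plane grid.

# stable sub-seed from the master seed and a scenario/patient identifier
derive_seed <- function(seed, id) {
  h <- 0
  for (b in utf8ToInt(id)) h <- (h * 131 + b) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

#' Head-and-neck patient for the linac-error failure mode
#'
#' An elliptical-dome body (peak 140 mm water-equivalent) with a PTV formed
#' by a boost volume plus an elective nodal volume, mimicking a
#' head-and-neck target with lymph-node involvement.
#'
#' @param grid a [sim_grid()].
#' @return a [patient_model()].
#' @export
hn_patient <- function(grid = sim_grid()) {
  body <- dome_thickness(grid, c(0, 0), c(85, 70), 140)
  ptv <- ellipse_mask(grid, c(5, 12), c(24, 20)) |
    ellipse_mask(grid, c(-12, -22), c(28, 16))
  patient_model(grid, components = list(soft = body),
                densities = c(soft = 1), ptv_mask = ptv)
}

#' Modulated VMAT-like beam for the head-and-neck patient
#'
#' The beam holds several MLC segments (control-point apertures); the
#' fluence is their average. Each segment starts from a conformal fit to
#' the PTV plus margin and is modulated by pseudo-random per-leaf insets
#' from one side, so a fraction of the target area is blocked per segment
#' (as in a modulated arc). Retracting the MLC behind the jaws therefore
#' raises the open-field dose well above the base plan at the same MU.
#'
#' @param patient the [hn_patient()].
#' @param seed integer; fixes the modulation pattern.
#' @param n_segments number of MLC segments (default 8).
#' @param max_inset_frac deepest per-leaf modulation inset as a fraction of
#'   the conformal leaf gap (default 0.6).
#' @return a calibrated [beam_model()].
#' @export
hn_beam <- function(patient, seed = 1L, n_segments = 8L, max_inset_frac = 0.6) {
  fit <- fit_mlc_to_mask(patient$grid, patient$ptv_mask, margin_mm = 7)
  rng <- derive_seed(seed, "hn_beam_modulation")
  segments <- withr_seed(rng, {
    lapply(seq_len(n_segments), function(s) {
      gap <- fit$leaf_x2 - fit$leaf_x1
      open <- gap > 0.5
      inset <- stats::runif(length(gap), 0, max_inset_frac) * gap
      from_left <- stats::runif(length(gap)) < 0.5
      x1 <- fit$leaf_x1; x2 <- fit$leaf_x2
      x1[open & from_left] <- x1[open & from_left] + inset[open & from_left]
      x2[open & !from_left] <- x2[open & !from_left] - inset[open & !from_left]
      list(leaf_x1 = x1, leaf_x2 = x2)
    })
  })
  beam <- beam_model(patient$grid, fit$leaf_x1, fit$leaf_x2, fit$leaf_edges,
                     fit$jaw, segments = segments)
  calibrate_beam(beam, patient)
}

# run expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# default thorax geometry shared by all breathing scenarios
thorax_params <- function() {
  list(body_peak = 220, body_axes = c(110, 120),
       lung_cx = -45, lung_rx = 40, lung_chord = 150,
       diaphragm_y0 = -50, apex_y = 75,
       gtv_radius = 12.5, gtv_x = -45, gtv_y0 = -28,
       amplitude_mm = 25, rho_insp = 0.15, rho_exp = 0.45,
       ptv_margin = 5)
}

#' Breathing thorax patient at a given phase displacement
#'
#' A lung-SBRT-like anatomy: a thorax dome with an ipsilateral lung of
#' phase-dependent density and a GTV sphere riding on the diaphragm. The
#' phase is parameterized by the diaphragm/tumor displacement `d` in
#' `[0, amplitude]` mm: `d = 0` is full inspiration (diaphragm low, lung
#' density 0.15), `d = amplitude` full expiration (diaphragm 25 mm higher,
#' lung density 0.45). The PTV is the planned-phase GTV footprint plus a
#' 5 mm margin.
#'
#' @param grid a [sim_grid()].
#' @param displacement_mm delivered-phase displacement, mm.
#' @param planned_displacement_mm displacement of the planning phase (sets
#'   the PTV position); defaults to `displacement_mm`.
#' @param params geometry list, see `thorax_params()` internals.
#' @return a [patient_model()] carrying its parameters so that
#'   [apply_anatomy_error()] can rebuild other phases.
#' @export
thorax_patient <- function(grid = sim_grid(), displacement_mm = 0,
                           planned_displacement_mm = displacement_mm,
                           params = thorax_params()) {
  p <- params
  d <- displacement_mm
  co <- grid_coords(grid)
  body <- dome_thickness(grid, c(0, 0), p$body_axes, p$body_peak)
  y_d <- p$diaphragm_y0 + d
  in_lung <- abs(co$X - p$lung_cx) <= p$lung_rx & co$Y >= y_d & co$Y <= p$apex_y
  chord <- p$lung_chord * sqrt(pmax(0, 1 - ((co$X - p$lung_cx) / p$lung_rx)^2))
  lung_chord <- pmin(chord, 0.85 * body) * in_lung
  gtv_chord <- pmin(disc_chord(grid, c(p$gtv_y0 + d, p$gtv_x), p$gtv_radius),
                    lung_chord)
  rho <- p$rho_insp + (p$rho_exp - p$rho_insp) * d / p$amplitude_mm
  ptv <- ellipse_mask(grid, c(p$gtv_y0 + planned_displacement_mm, p$gtv_x),
                      rep(p$gtv_radius + p$ptv_margin, 2))
  out <- patient_model(grid,
                       components = list(soft = body - lung_chord,
                                         lung = lung_chord - gtv_chord,
                                         gtv = gtv_chord),
                       densities = c(soft = 1, lung = rho, gtv = 1),
                       ptv_mask = ptv)
  attr(out, "thorax_params") <- p
  attr(out, "planned_displacement") <- planned_displacement_mm
  out
}

# delivered anatomy averaged over breathing phases (average-CT surrogate):
# the effective thickness is the weighted mean of the per-phase effective
# thicknesses, folded into a single density-1 component
thorax_patient_average <- function(grid, displacements, weights,
                                   params = thorax_params(),
                                   planned_displacement = 0) {
  stopifnot(length(displacements) == length(weights), all(weights >= 0))
  w <- weights / sum(weights)
  t_eff <- matrix(0, grid$n[1], grid$n[2])
  for (k in seq_along(displacements)) {
    ph <- thorax_patient(grid, displacements[k],
                         planned_displacement_mm = planned_displacement,
                         params = params)
    t_eff <- t_eff + w[k] * effective_thickness(ph)
  }
  ref <- thorax_patient(grid, displacements[1],
                        planned_displacement_mm = planned_displacement,
                        params = params)
  out <- patient_model(grid, components = list(wet = t_eff),
                       densities = c(wet = 1), ptv_mask = ref$ptv_mask)
  attr(out, "thorax_params") <- params
  attr(out, "planned_displacement") <- planned_displacement
  out
}

# sinusoidal phase-to-displacement mapping; phase in [0, 1), 0 = inspiration
phase_displacement <- function(phase, amplitude_mm) {
  amplitude_mm * (1 - cos(2 * pi * phase)) / 2
}

#' Breast patient for the patient-swap and bolus failure modes
#'
#' A chest-wall dome plus a breast mound. The two swap patients are
#' structurally different (laterality, mound size and thickness differ by
#' construction) with small seeded jitter on top, so that delivering one
#' patient's plan on the other always produces both a geometric target
#' miss and a large attenuation change.
#'
#' @param grid a [sim_grid()].
#' @param which `"A"` (small, left-sided target) or `"B"` (large,
#'   right-sided).
#' @param seed integer; jitters the geometry by a few mm.
#' @param bolus_mm thickness of a bolus slab over the PTV footprint
#'   (default 0, i.e. none).
#' @return a [patient_model()].
#' @export
breast_patient <- function(grid = sim_grid(), which = c("A", "B"), seed = 1L,
                           bolus_mm = 0) {
  which <- match.arg(which)
  base <- if (which == "A")
    list(chest_peak = 80, mound_c = c(0, -30), mound_axes = c(55, 45),
         mound_peak = 55, ptv_c = c(0, -30))
  else
    list(chest_peak = 115, mound_c = c(0, -5), mound_axes = c(80, 65),
         mound_peak = 90, ptv_c = c(5, 25))
  jit <- withr_seed(derive_seed(seed, paste0("breast_", which)),
                    stats::runif(3, -4, 4))
  chest <- dome_thickness(grid, c(0, 0), c(105, 115), base$chest_peak)
  mound <- dome_thickness(grid, base$mound_c + jit[1:2], base$mound_axes,
                          base$mound_peak + jit[3])
  ptv <- ellipse_mask(grid, base$ptv_c + jit[1:2], c(16, 16))
  comps <- list(soft = chest + mound)
  dens <- c(soft = 1)
  if (bolus_mm > 0) {
    footprint <- ellipse_mask(grid, base$ptv_c + jit[1:2], c(26, 26))
    comps$bolus <- footprint * bolus_mm
    dens <- c(dens, bolus = 1)
  }
  patient_model(grid, comps, dens, ptv)
}

#' Palliative lung patient for the wrong-CT failure mode
#'
#' An ipsilateral lung with a pleural-fluid region in its lower half; the
#' two planning CTs differ only in whether that region holds fluid
#' (density 1) or aerated lung (density 0.25). The PTV sits inside the
#' fluid region's projection, where the attenuation change is largest.
#'
#' @param grid a [sim_grid()].
#' @param fluid_present logical; `TRUE` reproduces the original CT.
#' @return a [patient_model()].
#' @export
wrongct_patient <- function(grid = sim_grid(), fluid_present = TRUE) {
  co <- grid_coords(grid)
  body <- dome_thickness(grid, c(0, 0), c(105, 115), 200)
  lung_cx <- 45; lung_rx <- 30
  in_lung <- abs(co$X - lung_cx) <= lung_rx & co$Y >= -60 & co$Y <= 70
  chord <- 130 * sqrt(pmax(0, 1 - ((co$X - lung_cx) / lung_rx)^2))
  lung_chord <- pmin(chord, 0.85 * body) * in_lung
  fluid_mask <- ellipse_mask(grid, c(-30, 45), c(25, 28)) & in_lung
  ptv <- ellipse_mask(grid, c(-30, 45), c(15, 15))
  patient_model(grid,
                components = list(soft = body - lung_chord,
                                  lung = lung_chord * !fluid_mask,
                                  fluid = lung_chord * fluid_mask),
                densities = c(soft = 1, lung = 0.25,
                              fluid = if (fluid_present) 1.0 else 0.25),
                ptv_mask = ptv)
}

# conformal single-segment beam fitted to a patient's PTV, calibrated so
# the base transit maximum is 100
conformal_beam <- function(patient, margin_mm = 7) {
  fit <- fit_mlc_to_mask(patient$grid, patient$ptv_mask, margin_mm = margin_mm)
  beam <- beam_model(patient$grid, fit$leaf_x1, fit$leaf_x2, fit$leaf_edges,
                     fit$jaw)
  calibrate_beam(beam, patient)
}
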