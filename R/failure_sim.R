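# Synthetic transit-dosimetry study generator.
#
# A deliberately simple forward model stands in for the TPS transit-dose
# prediction: D(x,y) = k * MU * [aperture (x) Gaussian(sigma)](x,y)
#                        * exp(-mu * t_eff(x,y)),
# where t_eff is the density-weighted water-equivalent thickness of the
# patient along the beam axis and the blurred aperture plays the role of
# the in-air fluence. It captures the one physical effect transit dosimetry
# reacts to -- a change in beam attenuation or fluence -- not scatter,
# beam hardening or detector response.

# --- grids -----------------------------------------------------------------

#' Image-plane grid specification
#'
#' @param n pixels per side (grid is n x n), default 256.
#' @param spacing_mm isotropic pixel pitch, default 1 mm.
#' @return list with `n`, `spacing`, `origin` (grid centered on (0, 0)).
#' @export
sim_grid <- function(n = 256, spacing_mm = 1) {
  stopifnot(n >= 2, spacing_mm > 0)
  list(n = c(n, n), spacing = c(spacing_mm, spacing_mm),
       origin = -c((n - 1) / 2, (n - 1) / 2) * spacing_mm)
}

grid_y <- function(grid) grid$origin[1] + (seq_len(grid$n[1]) - 1) * grid$spacing[1]
grid_x <- function(grid) grid$origin[2] + (seq_len(grid$n[2]) - 1) * grid$spacing[2]

# physical coordinate matrices (Y varies along rows, X along columns)
grid_coords <- function(grid) {
  list(Y = matrix(grid_y(grid), grid$n[1], grid$n[2]),
       X = matrix(grid_x(grid), grid$n[1], grid$n[2], byrow = TRUE))
}

ellipse_mask <- function(grid, center, semi_axes) {
  co <- grid_coords(grid)
  ((co$Y - center[1]) / semi_axes[1])^2 + ((co$X - center[2]) / semi_axes[2])^2 <= 1
}

# dome-shaped thickness: peak * sqrt(1 - normalized radius^2), 0 outside
dome_thickness <- function(grid, center, semi_axes, peak) {
  co <- grid_coords(grid)
  r2 <- ((co$Y - center[1]) / semi_axes[1])^2 + ((co$X - center[2]) / semi_axes[2])^2
  peak * sqrt(pmax(0, 1 - r2))
}

disc_chord <- function(grid, center, radius) {
  # projected chord length of a sphere of given radius (max = diameter)
  co <- grid_coords(grid)
  d2 <- (co$Y - center[1])^2 + (co$X - center[2])^2
  2 * sqrt(pmax(0, radius^2 - d2))
}

# separable Gaussian blur with zero-padding boundary (no fluence outside)
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  blur_1d <- function(mat, kern, along_rows) {
    out <- matrix(0, nrow(mat), ncol(mat))
    n <- if (along_rows) nrow(mat) else ncol(mat)
    for (o in -half:half) {
      w <- kern[o + half + 1L]
      src <- seq_len(n) + o
      keep <- src >= 1L & src <= n
      if (along_rows) {
        out[keep, ] <- out[keep, ] + w * mat[src[keep], ]
      } else {
        out[, keep] <- out[, keep] + w * mat[, src[keep]]
      }
    }
    out
  }
  blur_1d(blur_1d(m, k, TRUE), k, FALSE)
}

# --- beam model ------------------------------------------------------------

#' Toy transit beam model
#'
#' The aperture is an MLC bank pair plus rectangular jaws, rasterized onto
#' the simulation grid with sub-pixel edge weighting (so millimetre or
#' sub-millimetre leaf shifts change the fluence smoothly). Leaf-travel is
#' along x; leaf rows are bands along y.
#'
#' @param grid a [sim_grid()].
#' @param leaf_x1,leaf_x2 numeric vectors, one per leaf pair: bank A and
#'   bank B positions (mm, `leaf_x1 <= leaf_x2`; equal means closed).
#' @param leaf_edges numeric vector of length `nleaves + 1`: the y
#'   boundaries of the leaf rows, mm.
#' @param jaw `c(x1, x2, y1, y2)` jaw rectangle, mm.
#' @param mu monitor units (relative scalar, > 0).
#' @param output_per_mu open-air dose per MU (calibration constant k).
#' @param penumbra_sigma_mm Gaussian penumbra width, mm (default 3).
#' @param mu_atten_per_mm effective linear attenuation per mm
#'   water-equivalent (default 0.005, roughly a 6 MV beam).
#' @param collimator_angle_deg rotation of the whole aperture about the
#'   field (jaw) center.
#' @param segments optional list of MLC segments (each
#'   `list(leaf_x1, leaf_x2)`), modelling the control points of a
#'   modulated delivery; the fluence is the mean of the segment apertures.
#'   When `NULL` the beam has the single segment given by
#'   `leaf_x1`/`leaf_x2`.
#' @return object of class `beam_model`; field `aperture_mask` is the
#'   rasterized fractional opening in `[0, 1]` (segment-averaged).
#' @export
beam_model <- function(grid, leaf_x1, leaf_x2, leaf_edges, jaw,
                       mu = 100, output_per_mu = 1, penumbra_sigma_mm = 3,
                       mu_atten_per_mm = 0.005, collimator_angle_deg = 0,
                       segments = NULL) {
  stopifnot(length(leaf_x1) == length(leaf_x2),
            length(leaf_edges) == length(leaf_x1) + 1L,
            all(leaf_x1 <= leaf_x2 + 1e-9),
            jaw[1] < jaw[2], jaw[3] < jaw[4],
            mu > 0, output_per_mu > 0, penumbra_sigma_mm > 0,
            mu_atten_per_mm > 0, mu_atten_per_mm < 1)
  if (is.null(segments)) segments <- list(list(leaf_x1 = leaf_x1, leaf_x2 = leaf_x2))
  for (s in segments)
    stopifnot(length(s$leaf_x1) == length(leaf_x1),
              all(s$leaf_x1 <= s$leaf_x2 + 1e-9))
  beam <- structure(list(grid = grid, leaf_x1 = leaf_x1, leaf_x2 = leaf_x2,
                         leaf_edges = leaf_edges, jaw = jaw, mu = mu,
                         output_per_mu = output_per_mu,
                         penumbra_sigma_mm = penumbra_sigma_mm,
                         mu_atten_per_mm = mu_atten_per_mm,
                         collimator_angle_deg = collimator_angle_deg,
                         segments = segments),
                    class = "beam_model")
  beam$aperture_mask <- rasterize_aperture_spec(beam)
  beam
}

# segment-averaged fractional opening of the MLC-and-jaw aperture
rasterize_aperture_spec <- function(beam, supersample = 4L) {
  masks <- lapply(beam$segments, function(s)
    rasterize_leaves(beam$grid, beam$leaf_edges, s$leaf_x1, s$leaf_x2,
                     beam$jaw, beam$collimator_angle_deg, supersample))
  Reduce(`+`, masks) / length(masks)
}

# sub-pixel rasterization of one MLC-and-jaw opening, rotated by the
# collimator angle about the jaw center; returns fractional coverage
rasterize_leaves <- function(grid, leaf_edges, leaf_x1, leaf_x2, jaw,
                             angle_deg = 0, supersample = 4L) {
  cy <- mean(jaw[3:4]); cx <- mean(jaw[1:2])
  th <- angle_deg * pi / 180
  cth <- cos(th); sth <- sin(th)
  cov <- matrix(0, grid$n[1], grid$n[2])
  offs <- (seq_len(supersample) - 0.5) / supersample - 0.5
  co <- grid_coords(grid)
  for (oy in offs) {
    for (ox in offs) {
      y <- co$Y + oy * grid$spacing[1]
      x <- co$X + ox * grid$spacing[2]
      # inverse-rotate the sample point into the collimator frame
      yr <- cy + (-sth) * (x - cx) + cth * (y - cy)
      xr <- cx + cth * (x - cx) + sth * (y - cy)
      leaf <- findInterval(yr, leaf_edges)
      inside_band <- leaf >= 1L & leaf <= length(leaf_x1) &
        yr < leaf_edges[length(leaf_edges)]
      leaf[!inside_band] <- 1L # placeholder index, masked below
      open <- inside_band &
        xr >= leaf_x1[leaf] & xr <= leaf_x2[leaf] &
        xr >= jaw[1] & xr <= jaw[2] &
        yr >= jaw[3] & yr <= jaw[4]
      cov <- cov + open
    }
  }
  cov / supersample^2
}

open_fluence <- function(beam) {
  sig <- beam$penumbra_sigma_mm / beam$grid$spacing[1]
  beam$mu * beam$output_per_mu * gaussian_blur(beam$aperture_mask, sig)
}

# --- patient model ---------------------------------------------------------

#' Toy projected patient model
#'
#' The patient is represented by named thickness components (geometric
#' water path per tissue class, mm, on the detector-projected grid) and a
#' relative density per component; the effective water-equivalent
#' thickness is the density-weighted sum.
#'
#' @param grid a [sim_grid()].
#' @param components named list of non-negative thickness matrices, mm.
#' @param densities named numeric vector of relative attenuation
#'   multipliers, one per component.
#' @param ptv_mask logical matrix: the projected planning target volume.
#' @return object of class `patient_model` with derived fields
#'   `thickness_map` (total geometric thickness) and `region_masks`.
#' @export
patient_model <- function(grid, components, densities, ptv_mask) {
  stopifnot(length(components) >= 1,
            all(names(components) %in% names(densities)),
            is.logical(ptv_mask), any(ptv_mask))
  for (m in components) {
    stopifnot(all(dim(m) == grid$n), all(m >= 0), all(is.finite(m)))
  }
  stopifnot(all(dim(ptv_mask) == grid$n))
  structure(list(grid = grid, components = components,
                 densities = densities, ptv_mask = ptv_mask,
                 thickness_map = Reduce(`+`, components),
                 region_masks = lapply(components, function(m) m > 0)),
            class = "patient_model")
}

effective_thickness <- function(patient) {
  t_eff <- matrix(0, patient$grid$n[1], patient$grid$n[2])
  for (nm in names(patient$components))
    t_eff <- t_eff + patient$densities[[nm]] * patient$components[[nm]]
  t_eff
}

#' Predicted transit dose image
#'
#' Forward model: open-air fluence (MU x output x Gaussian-blurred
#' aperture) attenuated exponentially through the patient's effective
#' water-equivalent thickness.
#'
#' @param patient a [patient_model()].
#' @param beam a [beam_model()] on the same grid.
#' @return a [dose_image] on the simulation grid.
#' @export
transit_dose <- function(patient, beam) {
  stopifnot(inherits(patient, "patient_model"), inherits(beam, "beam_model"))
  if (!all(patient$grid$n == beam$grid$n))
    stop("patient and beam grids have inconsistent shapes")
  d <- open_fluence(beam) * exp(-beam$mu_atten_per_mm * effective_thickness(patient))
  dose_image(d, spacing = patient$grid$spacing, origin = patient$grid$origin,
             unit_label = "sim")
}

#' Surrogate PTV mean dose
#'
#' Scalar label standing in for the TPS-computed PTV mean dose of a plan:
#' the mean over the PTV mask of the open fluence attenuated to mid-depth,
#' `k * MU * fluence(x,y) * exp(-mu * t_eff(x,y) / 2)`. It is exactly
#' linear in MU and monotone in any attenuation change over the target,
#' which is all the downstream ROC labeling needs.
#'
#' @param patient a [patient_model()] (the delivered anatomy).
#' @param beam a [beam_model()] (the delivered beam).
#' @param ptv_mask mask over which to average; defaults to the patient's
#'   own PTV. Scenario labels use the planned PTV on the delivered anatomy.
#' @return positive scalar.
#' @export
surrogate_ptv_dmean <- function(patient, beam, ptv_mask = patient$ptv_mask) {
  stopifnot(all(dim(ptv_mask) == patient$grid$n))
  fl <- open_fluence(beam)
  if (max(fl[ptv_mask]) <= 1e-9 * max(fl))
    stop("degenerate scenario: beam aperture does not overlap the PTV")
  mean((fl * exp(-beam$mu_atten_per_mm * effective_thickness(patient) / 2))[ptv_mask])
}

# --- beam fitting and calibration ------------------------------------------

# Conformal MLC fit: per leaf band, open to the target extent plus margin.
# Closed bands get a zero gap at x = 0 (untouched by gap perturbations,
# which skip closed pairs).
fit_mlc_to_mask <- function(grid, target_mask, margin_mm = 7,
                            leaf_width_mm = 5, jaw_margin_mm = 10) {
  co <- grid_coords(grid)
  ys <- co$Y[target_mask]; xs <- co$X[target_mask]
  y_lo <- min(ys) - margin_mm; y_hi <- max(ys) + margin_mm
  nle <- ceiling((y_hi - y_lo) / leaf_width_mm)
  edges <- y_lo + (0:nle) * leaf_width_mm
  x1 <- numeric(nle); x2 <- numeric(nle)
  for (k in seq_len(nle)) {
    sel <- ys >= edges[k] - margin_mm & ys < edges[k + 1] + margin_mm
    if (any(sel)) {
      x1[k] <- min(xs[sel]) - margin_mm
      x2[k] <- max(xs[sel]) + margin_mm
    } # else closed at 0
  }
  jaw <- c(min(xs) - jaw_margin_mm, max(xs) + jaw_margin_mm,
           min(ys) - jaw_margin_mm, max(ys) + jaw_margin_mm)
  list(leaf_x1 = x1, leaf_x2 = x2, leaf_edges = edges, jaw = jaw)
}

# scale output_per_mu so the base transit image has maximum = 100
calibrate_beam <- function(beam, patient, target_max = 100) {
  peak <- max(transit_dose(patient, beam)$values)
  stopifnot(peak > 0)
  beam$output_per_mu <- beam$output_per_mu * target_max / peak
  beam
}

# --- error injection -------------------------------------------------------

# indices of the central band (middle third) of leaf pairs with an open gap
central_leaf_band <- function(beam, closed_gap_mm = 0.5) {
  open_idx <- which(beam$leaf_x2 - beam$leaf_x1 > closed_gap_mm)
  if (!length(open_idx)) return(integer(0))
  n <- length(open_idx)
  third <- max(1L, round(n / 3))
  start <- floor((n - third) / 2) + 1L
  open_idx[start:(start + third - 1L)]
}

#' Inject a linac hardware / output error into a beam
#'
#' Implements the study's first failure mode. `mlc_shift` moves each bank
#' of every open leaf pair outward (positive magnitude) or inward
#' (negative) by `magnitude / 2`, so the leaf-pair gap changes by
#' `magnitude` in total; `mlc_shift_central` restricts this to the middle
#' third of the open leaf pairs; `collimator` adds `magnitude` degrees to
#' the collimator angle; `mu_scale` scales MU by `(1 + magnitude / 100)`;
#' `mlc_retracted` pulls all leaves behind the jaws at unchanged MU (the
#' jaw rectangle becomes the aperture), reproducing the New York incident
#' geometry.
#'
#' @param beam a [beam_model()].
#' @param kind error type.
#' @param magnitude mm for MLC shifts, degrees for collimator, percent for
#'   `mu_scale`; ignored for `mlc_retracted`.
#' @param closed_gap_mm leaf pairs with a gap at or below this are treated
#'   as closed and never moved (default 0.5 mm).
#' @return the perturbed `beam_model` (aperture re-rasterized).
#' @export
apply_linac_error <- function(beam,
                              kind = c("mlc_shift", "mlc_shift_central",
                                       "collimator", "mu_scale", "mlc_retracted"),
                              magnitude = 0, closed_gap_mm = 0.5) {
  kind <- match.arg(kind)
  stopifnot(inherits(beam, "beam_model"), is.finite(magnitude))
  if (kind == "mu_scale") {
    beam$mu <- beam$mu * (1 + magnitude / 100)
    return(beam) # aperture unchanged
  }
  if (kind == "collimator") {
    beam$collimator_angle_deg <- beam$collimator_angle_deg + magnitude
  } else if (kind == "mlc_retracted") {
    beam$leaf_x1[] <- beam$jaw[1] - 5
    beam$leaf_x2[] <- beam$jaw[2] + 5
    beam$segments <- list(list(leaf_x1 = beam$leaf_x1, leaf_x2 = beam$leaf_x2))
  } else {
    # the central band is defined on the conformal (planned) gaps and the
    # shift is applied uniformly across all segments
    central <- central_leaf_band(beam, closed_gap_mm)
    shift_segment <- function(x1, x2) {
      idx <- if (kind == "mlc_shift_central") central
             else which(x2 - x1 > closed_gap_mm)
      a <- x1[idx] - magnitude / 2
      b <- x2[idx] + magnitude / 2
      closed <- a > b
      mid <- (a + b) / 2
      a[closed] <- mid[closed]; b[closed] <- mid[closed]
      x1[idx] <- a; x2[idx] <- b
      list(x1 = x1, x2 = x2)
    }
    beam$segments <- lapply(beam$segments, function(s) {
      sh <- shift_segment(s$leaf_x1, s$leaf_x2)
      list(leaf_x1 = sh$x1, leaf_x2 = sh$x2)
    })
    sh <- shift_segment(beam$leaf_x1, beam$leaf_x2)
    beam$leaf_x1 <- sh$x1; beam$leaf_x2 <- sh$x2
    if (all(vapply(beam$segments,
                   function(s) all(s$leaf_x2 - s$leaf_x1 <= 0), TRUE)))
      stop("degenerate scenario: MLC erosion closed the whole aperture")
  }
  beam$aperture_mask <- rasterize_aperture_spec(beam)
  beam
}

#' Inject an anatomy-related error into a patient model
#'
#' Implements failure modes II-V on the delivered anatomy. `breath_shift`
#' rebuilds a breathing thorax at a different phase displacement (or a
#' weighted phase average); `patient_swap` generates an independent patient
#' from a new seed; `fluid_change` toggles the fluid region between fluid
#' (density 1) and aerated-lung density; `bolus_removed` zeroes the bolus
#' thickness component (re-applying the stored bolus restores the original
#' map exactly).
#'
#' @param patient a [patient_model()]; for `breath_shift` it must have been
#'   built by [thorax_patient()], for `bolus_removed` it must carry a
#'   `bolus` component.
#' @param kind error type.
#' @param parameters named list, per kind: `breath_shift` takes
#'   `displacement_mm` (scalar, or vector with `weights` for an averaged
#'   CT); `fluid_change` takes `lung_density` (default 0.25);
#'   `patient_swap` takes the [breast_patient()] arguments to vary.
#' @param seed integer seed used by `patient_swap`.
#' @return the perturbed `patient_model`.
#' @export
apply_anatomy_error <- function(patient,
                                kind = c("breath_shift", "patient_swap",
                                         "fluid_change", "bolus_removed"),
                                parameters = list(), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(patient, "patient_model"))
  switch(kind,
    breath_shift = {
      pars <- attr(patient, "thorax_params")
      if (is.null(pars)) stop("breath_shift requires a thorax_patient()")
      d <- parameters$displacement_mm
      stopifnot(!is.null(d))
      w <- parameters$weights
      if (is.null(w)) w <- rep(1, length(d))
      thorax_patient_average(grid = patient$grid, displacements = d,
                             weights = w, params = pars,
                             planned_displacement = attr(patient, "planned_displacement"))
    },
    patient_swap = do.call(breast_patient,
                           c(list(grid = patient$grid, seed = seed), parameters)),
    fluid_change = {
      if (!"fluid" %in% names(patient$components))
        stop("fluid_change requires a patient with a fluid component")
      lung_density <- parameters$lung_density
      if (is.null(lung_density)) lung_density <- 0.25
      patient$densities[["fluid"]] <-
        if (patient$densities[["fluid"]] >= 0.99) lung_density else 1.0
      patient
    },
    bolus_removed = {
      if (!"bolus" %in% names(patient$components))
        stop("bolus_removed requires a patient with a bolus component")
      if (all(patient$components$bolus == 0)) {
        # toggling twice is an involution: re-add the stashed bolus
        stash <- attr(patient, "bolus_map")
        if (is.null(stash)) stop("no stashed bolus to restore")
        patient$components$bolus <- stash
      } else {
        attr(patient, "bolus_map") <- patient$components$bolus
        patient$components$bolus <- patient$components$bolus * 0
      }
      patient$thickness_map <- Reduce(`+`, patient$components)
      patient$region_masks <- lapply(patient$components, function(m) m > 0)
      patient
    })
}
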