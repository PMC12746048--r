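# Minimal treatment-plan model and DICOM RT Plan I/O for error injection.
#
# Leaf-position sign convention follows DICOM: bank A holds the smaller
# (more negative) coordinate along the leaf-travel (x) axis, bank B the
# larger; per pair bank_A <= bank_B, equal positions meaning a closed pair.

#' Minimal treatment-plan model
#'
#' @param beams list of beams; each beam is a list with `beam_number`,
#'   `collimator_angle_deg`, `mu` (beam meterset), `leaf_boundaries_mm`
#'   (length `n_pairs + 1`, y boundaries of the leaf pairs) and
#'   `control_points`: a list of control points, each with
#'   `bank_A_positions_mm`, `bank_B_positions_mm` (one per leaf pair),
#'   `jaw_x_mm = c(x1, x2)`, `jaw_y_mm = c(y1, y2)`.
#' @param dataset optional parsed DICOM dataset the model was read from;
#'   kept so that [write_rtplan()] copies all unmodelled attributes
#'   through unchanged.
#' @return object of class `plan_model`.
#' @export
plan_model <- function(beams, dataset = NULL) {
  stopifnot(length(beams) >= 1)
  for (b in beams) {
    stopifnot(b$mu > 0, length(b$control_points) >= 1)
    n_pairs <- length(b$control_points[[1]]$bank_A_positions_mm)
    stopifnot(length(b$leaf_boundaries_mm) == n_pairs + 1L)
    for (cp in b$control_points) {
      stopifnot(length(cp$bank_A_positions_mm) == n_pairs,
                length(cp$bank_B_positions_mm) == n_pairs,
                all(cp$bank_A_positions_mm <= cp$bank_B_positions_mm + 1e-9),
                cp$jaw_x_mm[1] < cp$jaw_x_mm[2],
                cp$jaw_y_mm[1] < cp$jaw_y_mm[2])
    }
  }
  structure(list(beams = beams, dataset = dataset), class = "plan_model")
}

#' @export
print.plan_model <- function(x, ...) {
  cat(sprintf("plan_model: %d beam(s)\n", length(x$beams)))
  for (b in x$beams)
    cat(sprintf("  beam %s: %.1f MU, collimator %g deg, %d control points, %d leaf pairs\n",
                b$beam_number, b$mu, b$collimator_angle_deg,
                length(b$control_points),
                length(b$control_points[[1]]$bank_A_positions_mm)))
  invisible(x)
}

#' Generate a small demonstration plan
#'
#' A one-beam plan with rectangular jaws and a roughly conformal MLC
#' opening, used as a fixture for round-trip and perturbation tests.
#'
#' @param n_pairs number of leaf pairs (default 10).
#' @param n_cp number of control points (default 2).
#' @param leaf_width_mm leaf width (default 5).
#' @param mu beam meterset (default 100).
#' @return a [plan_model()].
#' @export
demo_plan <- function(n_pairs = 10, n_cp = 2, leaf_width_mm = 5, mu = 100) {
  bounds <- (0:n_pairs - n_pairs / 2) * leaf_width_mm
  mid <- (bounds[-1] + bounds[-(n_pairs + 1)]) / 2
  half_width <- 25 * sqrt(pmax(0, 1 - (mid / (n_pairs * leaf_width_mm / 2))^2))
  cps <- lapply(seq_len(n_cp), function(k) {
    w <- half_width * (0.8 + 0.2 * k / n_cp)
    closed <- w < 1
    a <- -w; b <- w
    a[closed] <- 0; b[closed] <- 0
    list(bank_A_positions_mm = a, bank_B_positions_mm = b,
         jaw_x_mm = c(-30, 30), jaw_y_mm = c(bounds[1], bounds[n_pairs + 1]))
  })
  plan_model(list(list(beam_number = 1L, collimator_angle_deg = 0,
                       mu = mu, leaf_boundaries_mm = bounds,
                       control_points = cps)))
}

#' Perturb a treatment plan
#'
#' SEAFARER-style error injection. `mlc_gap_mm` changes every open leaf
#' pair's gap by the magnitude (each bank moves by half, symmetrically) at
#' every control point; `mlc_gap_central_mm` restricts the change to the
#' central band (middle third) of leaf pairs; `collimator_deg` adds to
#' each beam's collimator angle; `mu_pct` scales the beam meterset;
#' `retract_mlc` parks all leaves beyond the jaw aperture while jaws and
#' MU stay fixed.
#'
#' Pairs whose gap is at or below `closed_gap_mm` are treated as closed
#' and never moved. An erosion that would cross the banks clamps the pair
#' shut at its midpoint; if more than `max_clamped_frac` of the open
#' pairs clamp, a warning is raised, and emptying every pair is an error.
#'
#' @param plan a [plan_model()].
#' @param error one of `"mlc_gap_mm"`, `"mlc_gap_central_mm"`,
#'   `"collimator_deg"`, `"mu_pct"`, `"retract_mlc"`.
#' @param magnitude error magnitude (mm, degrees or percent; ignored for
#'   `retract_mlc`).
#' @param closed_gap_mm closed-pair threshold (default 0.5 mm).
#' @param max_clamped_frac warn when more than this fraction of open pairs
#'   clamp shut (default 0.5).
#' @return the perturbed `plan_model`.
#' @export
perturb_plan <- function(plan, error = c("mlc_gap_mm", "mlc_gap_central_mm",
                                         "collimator_deg", "mu_pct",
                                         "retract_mlc"),
                         magnitude = 0, closed_gap_mm = 0.5,
                         max_clamped_frac = 0.5) {
  error <- match.arg(error)
  stopifnot(inherits(plan, "plan_model"), is.finite(magnitude))
  plan$beams <- lapply(plan$beams, function(b) {
    if (error == "collimator_deg") {
      b$collimator_angle_deg <- b$collimator_angle_deg + magnitude
      return(b)
    }
    if (error == "mu_pct") {
      b$mu <- b$mu * (1 + magnitude / 100)
      return(b)
    }
    n_pairs <- length(b$control_points[[1]]$bank_A_positions_mm)
    central <- {
      third <- max(1L, round(n_pairs / 3))
      start <- floor((n_pairs - third) / 2) + 1L
      start:(start + third - 1L)
    }
    n_open <- 0L; n_clamped <- 0L
    b$control_points <- lapply(b$control_points, function(cp) {
      a <- cp$bank_A_positions_mm; bb <- cp$bank_B_positions_mm
      if (error == "retract_mlc") {
        a[] <- cp$jaw_x_mm[1] - 20
        bb[] <- cp$jaw_x_mm[2] + 20
      } else {
        idx <- which(bb - a > closed_gap_mm)
        if (error == "mlc_gap_central_mm") idx <- intersect(idx, central)
        n_open <<- n_open + length(idx)
        a2 <- a[idx] - magnitude / 2
        b2 <- bb[idx] + magnitude / 2
        crossed <- a2 > b2
        n_clamped <<- n_clamped + sum(crossed)
        mid <- (a2 + b2) / 2
        a2[crossed] <- mid[crossed]; b2[crossed] <- mid[crossed]
        a[idx] <- a2; bb[idx] <- b2
      }
      cp$bank_A_positions_mm <- a; cp$bank_B_positions_mm <- bb
      cp
    })
    if (error %in% c("mlc_gap_mm", "mlc_gap_central_mm")) {
      all_closed <- all(vapply(b$control_points, function(cp)
        all(cp$bank_B_positions_mm - cp$bank_A_positions_mm <= closed_gap_mm),
        TRUE))
      if (all_closed) stop("perturbation closed every leaf pair of beam ",
                           b$beam_number)
      if (n_open > 0L && n_clamped / n_open > max_clamped_frac)
        warning(sprintf("beam %s: %d of %d open pairs clamped shut",
                        b$beam_number, n_clamped, n_open))
    }
    b
  })
  plan
}

#' Rasterize the aperture of a plan control point
#'
#' Projects the composite MLC-and-jaw opening of one control point onto a
#' dose-image grid with sub-pixel edge weighting, rotated by the beam's
#' collimator angle about the jaw center.
#'
#' @param beam one element of `plan$beams`.
#' @param grid a [sim_grid()].
#' @param cp_index control point to project (default 1).
#' @param supersample sub-pixel sampling factor per axis (default 4).
#' @return numeric matrix of fractional coverage in `[0, 1]`.
#' @export
project_aperture <- function(beam, grid, cp_index = 1L, supersample = 4L) {
  cp <- beam$control_points[[cp_index]]
  rasterize_leaves(grid, beam$leaf_boundaries_mm,
                   cp$bank_A_positions_mm, cp$bank_B_positions_mm,
                   c(cp$jaw_x_mm, cp$jaw_y_mm),
                   beam$collimator_angle_deg, supersample)
}

# --- DICOM RT Plan ---------------------------------------------------------

#' Read a DICOM RT Plan into a plan model
#'
#' Parses the attributes the error-injection module needs (beam sequence,
#' control points, MLCX banks and jaws, collimator angle, beam meterset)
#' and keeps the full dataset so that [write_rtplan()] copies everything
#' else through unmodified.
#'
#' @param path DICOM RT Plan file.
#' @return a [plan_model()].
#' @export
read_rtplan <- function(path) {
  ds <- read_dicom_file(path)
  beam_items <- dcm_get(ds, "300A,00B0")
  if (is.null(beam_items)) stop("RT Plan: missing BeamSequence")
  metersets <- rtplan_metersets(ds)
  beams <- lapply(beam_items, function(bi) {
    bn <- as.integer(dcm_get(bi, "300A,00C0"))
    bld <- dcm_get(bi, "300A,00B6", required = FALSE)
    bounds <- NULL
    if (!is.null(bld)) {
      for (item in bld)
        if (identical(dcm_get(item, "300A,00B8"), "MLCX"))
          bounds <- dcm_get(item, "300A,00BE", required = FALSE)
    }
    cps <- dcm_get(bi, "300A,0111")
    angle <- 0
    control_points <- lapply(cps, function(ci) {
      pos <- dcm_get(ci, "300A,011A", required = FALSE)
      out <- list(jaw_x_mm = NULL, jaw_y_mm = NULL,
                  bank_A_positions_mm = NULL, bank_B_positions_mm = NULL)
      if (!is.null(pos)) {
        for (item in pos) {
          type <- dcm_get(item, "300A,00B8")
          vals <- dcm_get(item, "300A,011C")
          if (type %in% c("X", "ASYMX")) out$jaw_x_mm <- vals
          else if (type %in% c("Y", "ASYMY")) out$jaw_y_mm <- vals
          else if (type == "MLCX") {
            n <- length(vals) / 2
            out$bank_A_positions_mm <- vals[seq_len(n)]
            out$bank_B_positions_mm <- vals[n + seq_len(n)]
          }
        }
      }
      a <- dcm_get(ci, "300A,0120", required = FALSE)
      if (!is.null(a)) angle <<- a
      out
    })
    if (is.null(control_points[[1]]$bank_A_positions_mm))
      stop("RT Plan: beam ", bn, " has no MLCX device position sequence")
    if (is.null(bounds))
      stop("RT Plan: beam ", bn, " has no MLCX leaf position boundaries")
    # carry jaws forward through control points that omit them
    for (k in seq_along(control_points)) {
      if (is.null(control_points[[k]]$jaw_x_mm))
        control_points[[k]]$jaw_x_mm <- control_points[[1]]$jaw_x_mm
      if (is.null(control_points[[k]]$jaw_y_mm))
        control_points[[k]]$jaw_y_mm <- control_points[[1]]$jaw_y_mm
    }
    mu <- metersets[[as.character(bn)]]
    if (is.null(mu)) stop("RT Plan: beam ", bn, " has no referenced beam meterset")
    list(beam_number = bn, collimator_angle_deg = angle, mu = mu,
         leaf_boundaries_mm = bounds, control_points = control_points)
  })
  plan_model(beams, dataset = ds)
}

rtplan_metersets <- function(ds) {
  out <- list()
  fgs <- dcm_get(ds, "300A,0070", required = FALSE)
  if (!is.null(fgs)) {
    for (fg in fgs) {
      rbs <- dcm_get(fg, "300C,0004", required = FALSE)
      if (is.null(rbs)) next
      for (rb in rbs) {
        bn <- as.character(as.integer(dcm_get(rb, "300C,0006")))
        out[[bn]] <- as.numeric(dcm_get(rb, "300A,0086"))
      }
    }
  }
  out
}

#' Write a plan model as a DICOM RT Plan
#'
#' When the plan was read from a file, the modelled attributes are updated
#' inside the original dataset and every other attribute is written back
#' bit-for-bit; a plan built in memory is written as a fresh minimal RT
#' Plan.
#'
#' @param plan a [plan_model()].
#' @param path output file.
#' @export
write_rtplan <- function(plan, path) {
  stopifnot(inherits(plan, "plan_model"))
  ds <- if (is.null(plan$dataset)) rtplan_skeleton(plan) else plan$dataset
  ds <- rtplan_update(ds, plan)
  sop <- ds[["0008,0018"]]
  sop_instance <- if (is.null(sop)) content_uid(length(plan$beams)) else sop$value
  write_dicom_file(ds, path, UID_RTPLAN, sop_instance)
  invisible(path)
}

rtplan_skeleton <- function(plan) {
  sop_instance <- content_uid(length(plan$beams),
                              vapply(plan$beams, function(b) b$mu, 1))
  list(
    "0008,0016" = dcm_el("UI", UID_RTPLAN),
    "0008,0018" = dcm_el("UI", sop_instance),
    "0008,0060" = dcm_el("CS", "RTPLAN"),
    "300A,0002" = dcm_el("SH", "transitgamma"),
    "300A,0070" = dcm_el("SQ", list(list(
      "300A,0078" = dcm_el("IS", 1),
      "300C,0004" = dcm_el("SQ", lapply(plan$beams, function(b) list(
        "300A,0086" = dcm_el("DS", b$mu),
        "300C,0006" = dcm_el("IS", b$beam_number))))))),
    "300A,00B0" = dcm_el("SQ", lapply(plan$beams, rtplan_beam_item)))
}

rtplan_beam_item <- function(b) {
  n_pairs <- length(b$control_points[[1]]$bank_A_positions_mm)
  list(
    "300A,00C0" = dcm_el("IS", b$beam_number),
    "300A,00B6" = dcm_el("SQ", list(
      list("300A,00B8" = dcm_el("CS", "ASYMX"),
           "300A,00BC" = dcm_el("IS", 1)),
      list("300A,00B8" = dcm_el("CS", "ASYMY"),
           "300A,00BC" = dcm_el("IS", 1)),
      list("300A,00B8" = dcm_el("CS", "MLCX"),
           "300A,00BC" = dcm_el("IS", n_pairs),
           "300A,00BE" = dcm_el("DS", b$leaf_boundaries_mm)))),
    "300A,0111" = dcm_el("SQ", lapply(seq_along(b$control_points), function(k) {
      cp <- b$control_points[[k]]
      item <- list(
        "300A,0112" = dcm_el("IS", k - 1),
        "300A,011A" = dcm_el("SQ", list(
          list("300A,00B8" = dcm_el("CS", "ASYMX"),
               "300A,011C" = dcm_el("DS", cp$jaw_x_mm)),
          list("300A,00B8" = dcm_el("CS", "ASYMY"),
               "300A,011C" = dcm_el("DS", cp$jaw_y_mm)),
          list("300A,00B8" = dcm_el("CS", "MLCX"),
               "300A,011C" = dcm_el("DS", c(cp$bank_A_positions_mm,
                                            cp$bank_B_positions_mm))))))
      if (k == 1L)
        item[["300A,0120"]] <- dcm_el("DS", b$collimator_angle_deg)
      item
    })))
}

# push the model's values back into a parsed dataset tree
rtplan_update <- function(ds, plan) {
  by_number <- stats::setNames(plan$beams,
                               vapply(plan$beams, function(b)
                                 as.character(b$beam_number), ""))
  beam_items <- ds[["300A,00B0"]]$value
  for (i in seq_along(beam_items)) {
    bn <- as.character(as.integer(dcm_get(beam_items[[i]], "300A,00C0")))
    b <- by_number[[bn]]
    if (is.null(b)) next
    cps <- beam_items[[i]][["300A,0111"]]$value
    for (k in seq_along(cps)) {
      cp <- b$control_points[[k]]
      pos <- cps[[k]][["300A,011A"]]$value
      if (!is.null(pos)) {
        for (j in seq_along(pos)) {
          type <- dcm_get(pos[[j]], "300A,00B8")
          if (type %in% c("X", "ASYMX"))
            pos[[j]][["300A,011C"]] <- dcm_el("DS", cp$jaw_x_mm)
          else if (type %in% c("Y", "ASYMY"))
            pos[[j]][["300A,011C"]] <- dcm_el("DS", cp$jaw_y_mm)
          else if (type == "MLCX")
            pos[[j]][["300A,011C"]] <- dcm_el("DS", c(cp$bank_A_positions_mm,
                                                      cp$bank_B_positions_mm))
        }
        cps[[k]][["300A,011A"]]$value <- pos
      }
      if (!is.null(cps[[k]][["300A,0120"]]))
        cps[[k]][["300A,0120"]] <- dcm_el("DS", b$collimator_angle_deg)
    }
    beam_items[[i]][["300A,0111"]]$value <- cps
  }
  ds[["300A,00B0"]]$value <- beam_items
  fgs <- ds[["300A,0070"]]$value
  if (!is.null(fgs)) {
    for (f in seq_along(fgs)) {
      rbs <- fgs[[f]][["300C,0004"]]$value
      if (is.null(rbs)) next
      for (j in seq_along(rbs)) {
        bn <- as.character(as.integer(dcm_get(rbs[[j]], "300C,0006")))
        if (!is.null(by_number[[bn]]))
          rbs[[j]][["300A,0086"]] <- dcm_el("DS", by_number[[bn]]$mu)
      }
      fgs[[f]][["300C,0004"]]$value <- rbs
    }
    ds[["300A,0070"]]$value <- fgs
  }
  ds
}
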