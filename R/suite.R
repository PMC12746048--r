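# Assembly of the 22-scenario failure-mode suite.

#' Suite configuration
#'
#' Parameter grids for the five failure modes. The defaults reproduce the
#' study composition: 11 linac-error scenarios (MLC aperture +/- 1.0 and
#' +/- 1.5 mm, central leaves +2 and +5 mm, collimator +/- 1 degree,
#' MU +/- 2%, and the fully retracted MLC of the New York incident), 6
#' breathing-protocol scenarios (inspiration- and expiration-planned, each
#' delivered in the alternate phase, a 30-60% expiration-averaged CT and a
#' free-breathing average CT), 2 patient swaps, 2 wrong-CT scenarios and 1
#' missing bolus: 22 in total.
#'
#' @param grid a [sim_grid()]; default 256 x 256 at 1 mm.
#' @param mlc_shift_mm,mlc_central_mm,collimator_deg,mu_pct linac-error
#'   magnitude grids.
#' @param new_york include the retracted-MLC scenario.
#' @param breathing_amplitude_mm peak-to-peak diaphragm/tumor motion.
#' @param bolus_mm bolus thickness for failure mode V.
#' @return a config list for [generate_suite()].
#' @export
suite_config <- function(grid = sim_grid(),
                         mlc_shift_mm = c(1, -1, 1.5, -1.5),
                         mlc_central_mm = c(2, 5),
                         collimator_deg = c(1, -1),
                         mu_pct = c(2, -2),
                         new_york = TRUE,
                         breathing_amplitude_mm = 25,
                         bolus_mm = 10) {
  list(grid = grid, mlc_shift_mm = mlc_shift_mm,
       mlc_central_mm = mlc_central_mm, collimator_deg = collimator_deg,
       mu_pct = mu_pct, new_york = new_york,
       breathing_amplitude_mm = breathing_amplitude_mm, bolus_mm = bolus_mm)
}

new_scenario <- function(id, mode, parameters, reference, evaluated, delta) {
  stopifnot(all(dim(reference$values) == dim(evaluated$values)))
  structure(list(scenario_id = id, failure_mode = mode,
                 parameters = parameters, reference = reference,
                 evaluated = evaluated, delta_dmean_pct = delta),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario %s [%s]: surrogate PTV dDmean = %+.1f%%\n",
              x$scenario_id, x$failure_mode, x$delta_dmean_pct))
  invisible(x)
}

# percent change of the surrogate PTV mean dose, planned PTV mask held fixed
delta_dmean <- function(base_patient, base_beam, err_patient, err_beam) {
  base <- surrogate_ptv_dmean(base_patient, base_beam)
  err <- surrogate_ptv_dmean(err_patient, err_beam,
                             ptv_mask = base_patient$ptv_mask)
  100 * (err - base) / base
}

#' Generate the failure-mode scenario suite
#'
#' Builds every base plan, injects each configured error, computes the
#' base and erroneous transit dose images with [transit_dose()] and labels
#' each scenario with the surrogate PTV mean-dose change. Deterministic:
#' the same `(config, seed)` yields bitwise-identical images (per-scenario
#' randomness is sub-seeded by stable hashing of the scenario id).
#'
#' @param config a [suite_config()].
#' @param seed master integer seed.
#' @return list of `scenario` objects (22 under the default config).
#' @export
generate_suite <- function(config = suite_config(), seed = 1L) {
  grid <- config$grid
  scenarios <- list()
  add <- function(s) scenarios[[length(scenarios) + 1L]] <<- s

  ## I. linac hardware / output (head and neck)
  hn <- hn_patient(grid)
  hn_b <- hn_beam(hn, seed = seed)
  hn_ref <- transit_dose(hn, hn_b)
  linac <- function(id, kind, mag) {
    eb <- apply_linac_error(hn_b, kind, mag)
    new_scenario(id, "linac_hardware",
                 list(kind = kind, magnitude = mag),
                 hn_ref, transit_dose(hn, eb),
                 delta_dmean(hn, hn_b, hn, eb))
  }
  for (m in config$mlc_shift_mm)
    add(linac(sprintf("linac_mlc_%+g_mm", m), "mlc_shift", m))
  for (m in config$mlc_central_mm)
    add(linac(sprintf("linac_mlc_central_%+g_mm", m), "mlc_shift_central", m))
  for (m in config$collimator_deg)
    add(linac(sprintf("linac_collimator_%+g_deg", m), "collimator", m))
  for (m in config$mu_pct)
    add(linac(sprintf("linac_mu_%+g_pct", m), "mu_scale", m))
  if (isTRUE(config$new_york))
    add(linac("linac_new_york", "mlc_retracted", 0))

  ## II. breathing management (lung SBRT)
  A <- config$breathing_amplitude_mm
  tp <- thorax_params(); tp$amplitude_mm <- A
  phases_3060 <- c(0.3, 0.4, 0.5, 0.6)
  phases_all <- (0:9) / 10
  for (planned in c("insp", "exp")) {
    dp <- if (planned == "insp") 0 else A
    pat <- thorax_patient(grid, dp, params = tp)
    beam <- conformal_beam(pat)
    ref <- transit_dose(pat, beam)
    deliveries <- list(
      list(tag = if (planned == "insp") "exp" else "insp",
           d = A - dp, w = 1),
      list(tag = "avg3060", d = phase_displacement(phases_3060, A),
           w = rep(1, length(phases_3060))),
      list(tag = "avgall", d = phase_displacement(phases_all, A),
           w = rep(1, length(phases_all))))
    for (del in deliveries) {
      delivered <- apply_anatomy_error(pat, "breath_shift",
                                       list(displacement_mm = del$d,
                                            weights = del$w))
      add(new_scenario(sprintf("breath_%s_to_%s", planned, del$tag),
                       "breathing",
                       list(planned = planned, delivered = del$tag,
                            amplitude_mm = A),
                       ref, transit_dose(delivered, beam),
                       delta_dmean(pat, beam, delivered, beam)))
    }
  }

  ## III. patient identification (breast swap)
  pa <- breast_patient(grid, "A", seed = seed)
  pb <- breast_patient(grid, "B", seed = seed)
  ba <- conformal_beam(pa)
  bb <- conformal_beam(pb)
  add(new_scenario("swap_planA_on_B", "patient_id",
                   list(planned = "A", delivered = "B"),
                   transit_dose(pa, ba), transit_dose(pb, ba),
                   delta_dmean(pa, ba, pb, ba)))
  add(new_scenario("swap_planB_on_A", "patient_id",
                   list(planned = "B", delivered = "A"),
                   transit_dose(pb, bb), transit_dose(pa, bb),
                   delta_dmean(pb, bb, pa, bb)))

  ## IV. wrong CT / wrong adapted plan (lung fluid change)
  ct1 <- wrongct_patient(grid, fluid_present = TRUE)
  ct2 <- wrongct_patient(grid, fluid_present = FALSE)
  b1 <- conformal_beam(ct1)
  b2 <- conformal_beam(ct2)
  add(new_scenario("wrongct_plan1_on_ct2", "wrong_ct",
                   list(planned = "fluid", delivered = "no_fluid"),
                   transit_dose(ct1, b1), transit_dose(ct2, b1),
                   delta_dmean(ct1, b1, ct2, b1)))
  add(new_scenario("wrongct_plan2_on_ct1", "wrong_ct",
                   list(planned = "no_fluid", delivered = "fluid"),
                   transit_dose(ct2, b2), transit_dose(ct1, b2),
                   delta_dmean(ct2, b2, ct1, b2)))

  ## V. bolus placement (breast, bolus missing at delivery)
  pbol <- breast_patient(grid, "A", seed = derive_seed(seed, "bolus_patient"),
                         bolus_mm = config$bolus_mm)
  bbol <- conformal_beam(pbol)
  nobol <- apply_anatomy_error(pbol, "bolus_removed")
  add(new_scenario("bolus_missing", "bolus",
                   list(bolus_mm = config$bolus_mm),
                   transit_dose(pbol, bbol), transit_dose(nobol, bbol),
                   delta_dmean(pbol, bbol, nobol, bbol)))

  scenarios
}

#' Scenario manifest table
#'
#' @param scenarios list of scenarios from [generate_suite()].
#' @return data.frame: `scenario_id`, `failure_mode`, `parameters`
#'   (flattened `name=value` string), `delta_dmean_pct`.
#' @export
suite_manifest <- function(scenarios) {
  do.call(rbind, lapply(scenarios, function(s) {
    data.frame(scenario_id = s$scenario_id, failure_mode = s$failure_mode,
               parameters = paste(names(s$parameters),
                                  vapply(s$parameters, function(p)
                                    paste(format(p, digits = 6), collapse = "|"),
                                    ""),
                                  sep = "=", collapse = ";"),
               delta_dmean_pct = s$delta_dmean_pct,
               stringsAsFactors = FALSE)
  }))
}

#' Export a scenario suite to disk
#'
#' Writes one reference and one evaluated dose plane per scenario plus a
#' `manifest.csv`, so the analysis pipeline can be re-run from files.
#'
#' @param scenarios list of scenarios.
#' @param dir output directory (created if needed).
#' @param format dose-plane format, `"text-grid"` or `"dicom-rtdose"`.
#' @return the manifest data.frame, invisibly.
#' @export
export_suite <- function(scenarios, dir, format = c("text-grid", "dicom-rtdose")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "text-grid") "txt" else "dcm"
  man <- suite_manifest(scenarios)
  man$reference_file <- sprintf("%s_reference.%s", man$scenario_id, ext)
  man$evaluated_file <- sprintf("%s_evaluated.%s", man$scenario_id, ext)
  for (i in seq_along(scenarios)) {
    write_dose_plane(scenarios[[i]]$reference,
                     file.path(dir, man$reference_file[i]), format)
    write_dose_plane(scenarios[[i]]$evaluated,
                     file.path(dir, man$evaluated_file[i]), format)
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Load a scenario suite exported by [export_suite()]
#'
#' @param dir directory containing `manifest.csv` and the dose planes.
#' @return list of `scenario` objects (parameters as stored strings).
#' @export
load_suite <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    new_scenario(man$scenario_id[i], man$failure_mode[i],
                 list(stored = man$parameters[i]),
                 read_dose_plane(file.path(dir, man$reference_file[i])),
                 read_dose_plane(file.path(dir, man$evaluated_file[i])),
                 man$delta_dmean_pct[i])
  })
}
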