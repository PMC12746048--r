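#' Gamma comparison criterion
#'
#' Bundles the parameters of a 2D gamma-index comparison: the dose
#' difference tolerance (percent), the distance-to-agreement tolerance
#' (mm), the normalization mode, the low-dose threshold and the pass limit.
#'
#' With `normalization = "global"` the dose tolerance at every point is
#' `dose_diff_pct` percent of the normalization dose (the maximum of the
#' reference image); with `"local"` it is `dose_diff_pct` percent of the
#' reference dose at the point under evaluation. Reference points below
#' `threshold_pct` percent of the normalization dose are excluded from the
#' analysis. A point passes when its gamma value is less than or equal to
#' `pass_limit` (ties count as passes, the convention of common clinical
#' software; see [compute_gamma()]).
#'
#' @param dose_diff_pct dose-difference tolerance, percent (> 0).
#' @param dta_mm distance-to-agreement tolerance, mm (> 0).
#' @param normalization `"global"` or `"local"`.
#' @param threshold_pct low-dose threshold, percent of the normalization
#'   dose (default 20).
#' @param pass_limit gamma value defining a pass (default 1).
#' @return an object of class `gamma_criterion`.
#' @export
gamma_criterion <- function(dose_diff_pct, dta_mm,
                            normalization = c("global", "local"),
                            threshold_pct = 20, pass_limit = 1) {
  normalization <- match.arg(normalization)
  stopifnot(dose_diff_pct > 0, dta_mm > 0,
            threshold_pct >= 0, threshold_pct < 100, pass_limit > 0)
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 normalization = normalization,
                 threshold_pct = threshold_pct, pass_limit = pass_limit),
            class = "gamma_criterion")
}

#' @export
format.gamma_criterion <- function(x, ...) {
  sprintf("%g%%/%gmm (%s)", x$dose_diff_pct, x$dta_mm, x$normalization)
}

#' @export
print.gamma_criterion <- function(x, ...) {
  cat("gamma criterion:", format(x),
      sprintf("| threshold %g%%, pass limit %g\n", x$threshold_pct, x$pass_limit))
  invisible(x)
}

#' Default transit-dosimetry criteria set
#'
#' The seven dose-difference / DTA pairs evaluated throughout the study —
#' 3%/3mm, 5%/3mm, 5%/5mm, 7%/5mm, 10%/1mm, 10%/3mm, 10%/5mm — each with
#' both global and local normalization, giving 14 gamma metrics.
#'
#' @param normalizations which normalizations to include.
#' @param threshold_pct,pass_limit passed to [gamma_criterion()].
#' @return a list of [gamma_criterion] objects (14 by default).
#' @export
study_criteria <- function(normalizations = c("global", "local"),
                           threshold_pct = 20, pass_limit = 1) {
  pairs <- list(c(3, 3), c(5, 3), c(5, 5), c(7, 5), c(10, 1), c(10, 3), c(10, 5))
  out <- list()
  for (nm in normalizations)
    for (p in pairs)
      out[[length(out) + 1L]] <- gamma_criterion(p[1], p[2], nm,
                                                 threshold_pct, pass_limit)
  out
}

#' Compute the 2D gamma index between two dose images
#'
#' For every reference point above the low-dose threshold, the gamma value
#' is the minimum over candidate positions `r` in the evaluated
#' distribution of
#' `sqrt((|r - r_ref| / dta)^2 + ((D_eval(r) - D_ref(r_ref)) / tol)^2)`,
#' where `tol` is the absolute dose tolerance implied by the criterion
#' (global: percent of the reference maximum; local: percent of the
#' reference dose at the point). The evaluated image is interpolated
#' bilinearly and searched continuously with step
#' `min(pixel spacing, dta/10)` out to the radius where the distance term
#' alone reaches `gamma_cap`; gamma values above `gamma_cap` are reported
#' as `gamma_cap`.
#'
#' The two grids need not match: the search happens in physical
#' coordinates. Reference points whose search disc extends beyond the
#' evaluated extent are minimized over the available region; points with no
#' candidate position inside the evaluated extent at all are excluded (NA
#' in the map). The comparison is asymmetric — swapping the images changes
#' the result.
#'
#' @param reference the reference [dose_image] (defines the grid of the
#'   gamma map and the normalization dose).
#' @param evaluated the evaluated [dose_image].
#' @param criterion a [gamma_criterion].
#' @param gamma_cap ceiling above which gamma values are truncated
#'   (default 2).
#' @return an object of class `gamma_result`: `gamma_map` (matrix on the
#'   reference grid, NA at excluded points), `passing_rate_pct`,
#'   `n_included`, `n_pass`, `criterion`, `normalization_dose`.
#' @export
compute_gamma <- function(reference, evaluated, criterion, gamma_cap = 2) {
  validate_dose_image(reference); validate_dose_image(evaluated)
  stopifnot(inherits(criterion, "gamma_criterion"), gamma_cap > 0)
  d_norm <- max(reference$values)
  if (d_norm <= 0) stop("degenerate input: reference image has no dose")
  include <- reference$values >= criterion$threshold_pct / 100 * d_norm
  if (!any(include)) stop("no evaluable points: all reference points fall below the dose threshold")
  tol <- gamma_tolerance(reference, criterion, d_norm)
  step <- min(reference$spacing, evaluated$spacing, criterion$dta_mm / 10)
  gm <- gamma_search_cpp(reference$values,
                         reference$origin[1], reference$origin[2],
                         reference$spacing[1], reference$spacing[2],
                         evaluated$values,
                         evaluated$origin[1], evaluated$origin[2],
                         evaluated$spacing[1], evaluated$spacing[2],
                         include, tol, criterion$dta_mm, step, gamma_cap)
  gamma_result(gm, criterion, d_norm)
}

# absolute dose tolerance per reference point; local tolerance is only ever
# used at included points, which the threshold keeps strictly positive
gamma_tolerance <- function(reference, criterion, d_norm) {
  if (criterion$normalization == "global") {
    matrix(criterion$dose_diff_pct / 100 * d_norm,
           nrow(reference$values), ncol(reference$values))
  } else {
    stopifnot(criterion$threshold_pct > 0) # guarantees D_ref > 0 where used
    pmax(criterion$dose_diff_pct / 100 * reference$values, .Machine$double.xmin)
  }
}

gamma_result <- function(gamma_map, criterion, d_norm) {
  n_included <- sum(!is.na(gamma_map))
  if (n_included < 1L) stop("no evaluable points: evaluated image does not cover any included reference point")
  n_pass <- sum(gamma_map <= criterion$pass_limit, na.rm = TRUE)
  structure(list(gamma_map = gamma_map,
                 passing_rate_pct = 100 * n_pass / n_included,
                 n_included = n_included, n_pass = n_pass,
                 criterion = criterion, normalization_dose = d_norm),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma %s: passing rate %.1f%% (%d / %d points, D_norm = %g)\n",
              format(x$criterion), x$passing_rate_pct, x$n_pass,
              x$n_included, x$normalization_dose))
  invisible(x)
}

#' Exhaustive-search gamma oracle
#'
#' Same contract as [compute_gamma()], but the minimization is a plain-R
#' exhaustive scan over the evaluated image bilinearly upsampled by
#' `upsample_factor`, with no early termination. Intended as an independent
#' ground truth for small images (<= 64 x 64 recommended); it shares no
#' code path with the compiled search.
#'
#' @inheritParams compute_gamma
#' @param upsample_factor integer >= 1; the evaluated grid is refined to
#'   `spacing / upsample_factor` before the scan.
#' @return a `gamma_result`.
#' @export
brute_force_gamma <- function(reference, evaluated, criterion,
                              upsample_factor = 4, gamma_cap = 2) {
  validate_dose_image(reference); validate_dose_image(evaluated)
  stopifnot(inherits(criterion, "gamma_criterion"),
            upsample_factor >= 1, gamma_cap > 0)
  d_norm <- max(reference$values)
  if (d_norm <= 0) stop("degenerate input: reference image has no dose")
  include <- reference$values >= criterion$threshold_pct / 100 * d_norm
  if (!any(include)) stop("no evaluable points: all reference points fall below the dose threshold")
  tol <- gamma_tolerance(reference, criterion, d_norm)

  ey <- image_y(evaluated); ex <- image_x(evaluated)
  uy <- seq(ey[1], ey[length(ey)], by = evaluated$spacing[1] / upsample_factor)
  ux <- seq(ex[1], ex[length(ex)], by = evaluated$spacing[2] / upsample_factor)
  pts <- expand.grid(y = uy, x = ux, KEEP.OUT.ATTRS = FALSE)
  uv <- bilinear_sample(evaluated, pts$y, pts$x)$value

  uv <- matrix(uv, nrow = length(uy))

  ry <- image_y(reference); rx <- image_x(reference)
  dta2 <- criterion$dta_mm^2
  # positions farther than gamma_cap * dta contribute distance terms alone
  # >= gamma_cap, so restricting the exhaustive scan to that disc is
  # equivalent to scanning the whole image under the cap
  radius <- gamma_cap * criterion$dta_mm
  gm <- matrix(NA_real_, nrow(reference$values), ncol(reference$values))
  for (i in seq_along(ry)) {
    ii <- which(abs(uy - ry[i]) <= radius)
    if (!length(ii)) { next }
    dy2 <- (uy[ii] - ry[i])^2
    for (j in seq_along(rx)) {
      if (!include[i, j]) next
      jj <- which(abs(ux - rx[j]) <= radius)
      if (!length(jj)) next
      d2 <- outer(dy2, (ux[jj] - rx[j])^2, "+")
      g2 <- d2 / dta2 + ((uv[ii, jj, drop = FALSE] -
                          reference$values[i, j]) / tol[i, j])^2
      gm[i, j] <- min(sqrt(min(g2)), gamma_cap)
    }
  }
  gamma_result(gm, criterion, d_norm)
}

#' Evaluate a set of gamma criteria on one image pair
#'
#' Runs [compute_gamma()] once per criterion and tabulates the passing
#' rates. A criterion that errors is recorded as a failed row (NA passing
#' rate, message in `error`) rather than aborting the whole set.
#'
#' @inheritParams compute_gamma
#' @param criteria list of [gamma_criterion] objects; defaults to the 14
#'   study metrics of [study_criteria()].
#' @return a data.frame with one row per criterion: `dose_diff_pct`,
#'   `dta_mm`, `normalization`, `metric` (formatted label),
#'   `passing_rate_pct`, `n_included`, `n_pass`, `error`.
#' @export
evaluate_criteria_set <- function(reference, evaluated,
                                  criteria = study_criteria(),
                                  gamma_cap = 2) {
  stopifnot(length(criteria) >= 1)
  rows <- lapply(criteria, function(cr) {
    res <- tryCatch(compute_gamma(reference, evaluated, cr, gamma_cap),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(dose_diff_pct = cr$dose_diff_pct, dta_mm = cr$dta_mm,
                 normalization = cr$normalization, metric = format(cr),
                 passing_rate_pct = NA_real_, n_included = NA_integer_,
                 n_pass = NA_integer_, error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(dose_diff_pct = cr$dose_diff_pct, dta_mm = cr$dta_mm,
                 normalization = cr$normalization, metric = format(cr),
                 passing_rate_pct = res$passing_rate_pct,
                 n_included = res$n_included, n_pass = res$n_pass,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
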