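# Shared fixtures: smooth random dose fields and a lazily cached full study
# run (generated once, reused by the pipeline and acceptance tests).

smooth_field <- function(seed, n = 16, sigma = 7, base = 60, amp = 20) {
  set.seed(seed)
  pad <- 3 * sigma
  z <- matrix(stats::rnorm((n + 2 * pad)^2), n + 2 * pad)
  k <- stats::dnorm(-pad:pad, sd = sigma)
  k <- k / sum(k)
  z <- apply(z, 2, function(col) stats::convolve(col, k, type = "filter"))
  z <- t(apply(z, 1, function(row) stats::convolve(row, k, type = "filter")))
  z <- z[1:n, 1:n]
  base + amp * z / max(abs(z))
}

# a (reference, evaluated) pair: smooth field plus a smooth few-percent
# multiplicative perturbation on the same grid
smooth_pair <- function(seed, n = 16, perturb = 0.025) {
  ref <- dose_image(smooth_field(seed, n = n))
  mod <- smooth_field(seed + 5000, n = n, base = 0, amp = 1)
  list(reference = ref,
       evaluated = dose_image(pmax(ref$values * (1 + perturb * mod), 0)))
}

uniform_pair <- function(ref_dose, eval_dose, n = 5) {
  list(reference = dose_image(matrix(ref_dose, n, n)),
       evaluated = dose_image(matrix(eval_dose, n, n)))
}

# full default study under a fixed seed, computed on first use
.study_cache <- new.env(parent = emptyenv())
cached_study <- function() {
  if (is.null(.study_cache$study))
    .study_cache$study <- run_study(study_config(seed = 42L))
  .study_cache$study
}

# passing rates of the cached study in wide form (scenario x metric)
cached_rates_wide <- function() {
  r <- cached_study()$results
  stats::reshape(r[, c("scenario_id", "metric", "passing_rate_pct")],
                 idvar = "scenario_id", timevar = "metric",
                 direction = "wide")
}
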