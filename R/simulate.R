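#' Parameters of the synthetic anthocyanin-petal spectrum model
#'
#' The generator composes, on the measurement grid, a deterministic shape
#' `R(lambda) = scale * [base(lambda) - depth * G550(lambda) + uv bump]`
#' plus Gaussian measurement noise, clipped to (1e-6, 1]. `base` rises
#' sigmoidally from the visible baseline to the NIR plateau across the red
#' edge, `G550` is a Gaussian absorption trough centred on the anthocyanin
#' absorption band near 550 nm, and the UV bump adds the short-wavelength
#' reflectance component of the petals. The shape guarantees a reflectance
#' minimum near 550 nm and `R(800) > R(550)`, so ARI is positive.
#'
#' @param baseline Visible-range base reflectance (fraction).
#' @param antho_center_nm,antho_width_nm,antho_depth Centre (nm), Gaussian
#'   width (nm) and depth (fraction, < 1) of the anthocyanin trough.
#' @param uv_center_nm,uv_width_nm,uv_amp UV reflectance bump.
#' @param nir_plateau NIR plateau reflectance (fraction).
#' @param red_edge_nm,red_edge_width_nm Sigmoid midpoint and width of the
#'   red-edge rise.
#' @param noise_sd SD of additive measurement noise per wavelength.
#' @return List of class `spectrum_model_params`.
#' @export
spectrum_model_params <- function(baseline = 0.35,
                                  antho_center_nm = 550,
                                  antho_width_nm = 60,
                                  antho_depth = 0.22,
                                  uv_center_nm = 380,
                                  uv_width_nm = 30,
                                  uv_amp = 0.06,
                                  nir_plateau = 0.62,
                                  red_edge_nm = 640,
                                  red_edge_width_nm = 25,
                                  noise_sd = 0.01) {
  if (antho_depth < 0 || antho_depth >= 1) {
    stop("antho_depth must lie in [0, 1)", call. = FALSE)
  }
  structure(as.list(environment()), class = "spectrum_model_params")
}

#' Deterministic (noise-free) model reflectance
#'
#' The closed-form petal reflectance underlying the generator; useful for
#' computing exact expected values of downstream indices.
#'
#' @param lambda_nm Wavelengths (nm).
#' @param params A [spectrum_model_params()].
#' @param depth Anthocyanin trough depth (defaults to `params$antho_depth`).
#' @param scale Overall reflectance scaling.
#' @return Reflectance fractions (unclipped).
#' @export
model_reflectance <- function(lambda_nm, params, depth = params$antho_depth,
                              scale = 1) {
  base <- params$baseline + (params$nir_plateau - params$baseline) /
    (1 + exp(-(lambda_nm - params$red_edge_nm) / params$red_edge_width_nm))
  trough <- depth *
    exp(-((lambda_nm - params$antho_center_nm) / params$antho_width_nm)^2)
  uv <- params$uv_amp *
    exp(-((lambda_nm - params$uv_center_nm) / params$uv_width_nm)^2)
  scale * (base - trough + uv)
}

#' Treatment-effect configuration for the generator
#'
#' Encodes how the ozone treatments perturb the synthetic petals. Defaults
#' are calibrated to the study conditions the generator emulates: overall
#' reflectance increases from CFA through NFA to FU+; NFA petals get an
#' extra anthocyanin-trough depth (an ARI bump at ambient ozone); mean
#' petal area drops by 19.8% in NFA and 25% in FU+ relative to CFA, with
#' the chamber-less AMB plot behaving like NFA.
#'
#' @param reflectance_scale Named multipliers of overall reflectance per
#'   treatment.
#' @param ari_shift Extra trough depth added for NFA petals.
#' @param area_multiplier Named mean-area multipliers per treatment
#'   (relative to CFA = 1).
#' @param plant_sd SD of the per-plant intercept: multiplicative (log
#'   scale) on area, additive on the reflectance scale.
#' @param area_cv Coefficient of variation of the lognormal per-petal area
#'   noise.
#' @param base_area_cm2 Mean petal area of the control treatment, cm2.
#' @return List of class `treatment_effects`.
#' @export
treatment_effects <- function(
    reflectance_scale = c(AMB = 1.06, CFA = 1.00, NFA = 1.06, `FU+` = 1.12),
    ari_shift = 0.06,
    area_multiplier = c(AMB = 0.802, CFA = 1.000, NFA = 0.802,
                        `FU+` = 0.750),
    plant_sd = 0.08,
    area_cv = 0.25,
    base_area_cm2 = 0.8) {
  if (any(reflectance_scale <= 0) || any(area_multiplier <= 0)) {
    stop("scales and multipliers must be > 0", call. = FALSE)
  }
  structure(list(reflectance_scale = reflectance_scale,
                 ari_shift = ari_shift,
                 area_multiplier = area_multiplier,
                 plant_sd = plant_sd, area_cv = area_cv,
                 base_area_cm2 = base_area_cm2),
            class = "treatment_effects")
}

#' Simulation design configuration
#'
#' Defaults mirror a small open-top-chamber trial: three chambered ozone
#' treatments plus a chamber-less ambient plot, six plants per treatment,
#' three petals per plant, and the instrument's 325-1075 nm grid at 3-nm
#' resolution.
#'
#' @param treatments Treatment labels to simulate.
#' @param plants_per_treatment,petals_per_plant Design counts (>= 1).
#' @param grid_nm Measurement wavelength grid.
#' @param seed Integer master seed; every random draw derives from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(treatments = c("CFA", "NFA", "FU+", "AMB"),
                       plants_per_treatment = 6, petals_per_plant = 3,
                       grid_nm = seq(325, 1075, by = 3), seed = 1) {
  if (plants_per_treatment < 1 || petals_per_plant < 1) {
    stop("design counts must be >= 1", call. = FALSE)
  }
  stopifnot(all(treatments %in% treatment_levels()))
  structure(list(treatments = treatments,
                 plants_per_treatment = as.integer(plants_per_treatment),
                 petals_per_plant = as.integer(petals_per_plant),
                 grid_nm = grid_nm, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one petal spectrum
#'
#' @param params A [spectrum_model_params()].
#' @param effects A [treatment_effects()].
#' @param treatment Treatment label.
#' @param plant_scale_shift Additive per-plant shift of the reflectance
#'   scale (0 for the population-mean plant).
#' @param grid_nm Measurement grid.
#' @param petal_id,plant_id Metadata.
#' @return A [petal_spectrum()]. Uses the current RNG stream for noise.
#' @export
simulate_petal_spectrum <- function(params, effects, treatment,
                                    plant_scale_shift = 0,
                                    grid_nm = seq(325, 1075, by = 3),
                                    petal_id = NA_character_,
                                    plant_id = NA_character_) {
  scale <- effects$reflectance_scale[[treatment]] + plant_scale_shift
  depth <- params$antho_depth +
    if (treatment == "NFA") effects$ari_shift else 0
  r <- model_reflectance(grid_nm, params, depth = depth, scale = scale)
  if (mean(r <= 0) > 0.01) {
    stop("parameter combination drives reflectance <= 0 on > 1% of the grid",
         call. = FALSE)
  }
  r <- r + stats::rnorm(length(grid_nm), 0, params$noise_sd)
  r <- pmin(pmax(r, 1e-6), 1)
  petal_spectrum(grid_nm, r, petal_id = petal_id, plant_id = plant_id,
                 treatment = treatment)
}

#' Simulate a full petal dataset
#'
#' Generates, per plant, a random intercept (one standard-normal draw per
#' plant scaled by `plant_sd`: multiplicative on petal area after mean-one
#' lognormal correction, additive on the reflectance scale), then per
#' petal a spectrum and an area
#' `base_area * area_multiplier(treatment) * plant_effect * lognormal
#' noise` with mean-one lognormal noise of coefficient of variation
#' `area_cv`. Each plant consumes its own RNG sub-stream seeded from the
#' master seed, so adding plants or treatments does not perturb earlier
#' draws. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param params A [spectrum_model_params()].
#' @param effects A [treatment_effects()].
#' @return List: `set` (a [spectrum_set()]), `areas` (data.frame
#'   `petal_id`, `plant_id`, `treatment`, `area_cm2`), `config`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             params = spectrum_model_params(),
                             effects = treatment_effects()) {
  set.seed(config$seed)
  n_plants <- length(config$treatments) * config$plants_per_treatment
  plant_seeds <- sample.int(.Machine$integer.max - 1L, n_plants)
  sdlog <- sqrt(log(1 + effects$area_cv^2))
  spectra <- list()
  areas <- list()
  k <- 0L
  for (ti in seq_along(config$treatments)) {
    tr <- config$treatments[ti]
    for (pi in seq_len(config$plants_per_treatment)) {
      k <- k + 1L
      set.seed(plant_seeds[k])
      plant_id <- sprintf("%s_plant%02d", tr, pi)
      z <- stats::rnorm(1)
      # mean-one multiplicative plant effect on area; additive on scale
      area_mult <- exp(effects$plant_sd * z - effects$plant_sd^2 / 2)
      scale_shift <- effects$plant_sd * z
      for (qi in seq_len(config$petals_per_plant)) {
        petal_id <- sprintf("%s_petal%d", plant_id, qi)
        sp <- simulate_petal_spectrum(params, effects, tr,
                                      plant_scale_shift = scale_shift,
                                      grid_nm = config$grid_nm,
                                      petal_id = petal_id,
                                      plant_id = plant_id)
        noise <- exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
        area <- effects$base_area_cm2 * effects$area_multiplier[[tr]] *
          area_mult * noise
        spectra[[length(spectra) + 1L]] <- sp
        areas[[length(areas) + 1L]] <- data.frame(
          petal_id = petal_id, plant_id = plant_id, treatment = tr,
          area_cm2 = area, stringsAsFactors = FALSE)
      }
    }
  }
  list(set = spectrum_set(spectra), areas = do.call(rbind, areas),
       config = config)
}

#' Percent reduction in mean petal area vs a control treatment
#'
#' @param areas data.frame with `treatment` and `area_cm2` columns.
#' @param control Reference treatment label (default `"CFA"`).
#' @return data.frame `treatment`, `mean_area_cm2`, `percent_reduction`
#'   (100 (1 - mean/mean_control)); the control row has reduction 0.
#' @export
estimate_area_reductions <- function(areas, control = "CFA") {
  if (!control %in% areas$treatment) {
    stop(sprintf("control treatment '%s' absent", control), call. = FALSE)
  }
  means <- tapply(areas$area_cm2, areas$treatment, mean)
  ref <- means[[control]]
  data.frame(treatment = names(means),
             mean_area_cm2 = as.numeric(means),
             percent_reduction = 100 * (1 - as.numeric(means) / ref),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate an hourly ozone series
#'
#' A sinusoidal diurnal cycle peaking at 13:00, scaled in closed form so
#' that the 7-15 h window mean equals `window_mean_target` exactly (before
#' optional noise): `c(h) = target * p(h) / mean(p over window)` with
#' `p(h) = 1 + amplitude * cos(2 pi (h - 13) / 24)`.
#'
#' @param days Number of days (>= 1).
#' @param window_mean_target Target 7-15 h mean ozone, nL/L, >= 0.
#' @param shape `"diurnal"` or `"constant"`.
#' @param amplitude Relative amplitude of the diurnal cycle (0-1).
#' @param noise_sd SD of additive hourly noise (nL/L); draws use the
#'   current RNG stream and values are truncated at 0.
#' @param start Start timestamp (hour 00 of day 1), UTC.
#' @return An [hourly_series()] of `24 * days` hours.
#' @export
simulate_o3_series <- function(days, window_mean_target,
                               shape = c("diurnal", "constant"),
                               amplitude = 0.5, noise_sd = 0,
                               start = as.POSIXct("2019-04-01 00:00:00",
                                                  tz = "UTC")) {
  shape <- match.arg(shape)
  if (days < 1) stop("days must be >= 1", call. = FALSE)
  if (window_mean_target < 0) {
    stop("window_mean_target must be >= 0", call. = FALSE)
  }
  ts <- start + 3600 * (seq_len(24 * days) - 1)
  h <- as.integer(format(ts, "%H"))
  p <- if (shape == "constant") rep(1, length(h)) else
    1 + amplitude * cos(2 * pi * (h - 13) / 24)
  win <- h >= 7 & h < 15
  o3 <- window_mean_target * p / mean(p[win])
  if (noise_sd > 0) o3 <- pmax(o3 + stats::rnorm(length(o3), 0, noise_sd), 0)
  hourly_series(ts, o3)
}
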