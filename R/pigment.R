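#' Reflectance at a single wavelength
#'
#' Interpolated R(lambda), exact when the wavelength is on the grid.
#'
#' @param spectrum A [petal_spectrum()].
#' @param lambda_nm Wavelength in nm, within the measured range.
#' @return Reflectance fraction.
#' @export
reflectance_at <- function(spectrum, lambda_nm) {
  stopifnot(inherits(spectrum, "petal_spectrum"))
  rng <- range(spectrum$wavelengths_nm)
  if (lambda_nm < rng[1] || lambda_nm > rng[2]) {
    stop(sprintf("wavelength %g nm outside measured range %g-%g nm",
                 lambda_nm, rng[1], rng[2]), call. = FALSE)
  }
  stats::approx(spectrum$wavelengths_nm, spectrum$reflectance,
                xout = lambda_nm, method = "linear")$y
}

#' Anthocyanin reflectance index (ARI)
#'
#' ARI = (R800/R550) - (R800/R700), where R is relative reflectance at the
#' stated wavelength. Anthocyanins absorb near 550 nm, so a deeper
#' green-wavelength trough (smaller R550) raises ARI; the R700 term corrects
#' for the red-edge. ARI is invariant to a common rescaling of the spectrum.
#'
#' By default the three ordinates are point values on the 1-nm internal
#' grid; `band_nm` instead averages reflectance over +/- `band_nm` around
#' each wavelength.
#'
#' @param spectrum A [petal_spectrum()] covering at least 550-800 nm.
#' @param band_nm Optional half-width (nm) for band means; `NULL` (default)
#'   uses point wavelengths.
#' @return List with `petal_id`, `ari`, `r550`, `r700`, `r800`.
#' @export
#' @examples
#' sp <- petal_spectrum(c(500, 550, 700, 800, 900),
#'                      c(0.12, 0.10, 0.40, 0.50, 0.52))
#' ari(sp)$ari  # (0.5/0.1) - (0.5/0.4) = 3.75
ari <- function(spectrum, band_nm = NULL) {
  stopifnot(inherits(spectrum, "petal_spectrum"))
  rng <- range(spectrum$wavelengths_nm)
  if (rng[1] > 550 || rng[2] < 800) {
    stop("spectrum must cover 550-800 nm to compute ARI", call. = FALSE)
  }
  point <- function(lambda) {
    if (is.null(band_nm)) {
      reflectance_at(spectrum, lambda)
    } else {
      lo <- max(lambda - band_nm, rng[1])
      hi <- min(lambda + band_nm, rng[2])
      keep <- spectrum$wavelengths_nm >= lo & spectrum$wavelengths_nm <= hi
      mean(spectrum$reflectance[keep])
    }
  }
  r550 <- point(550)
  r700 <- point(700)
  r800 <- point(800)
  if (r800 > 0 && (r550 <= 0 || r700 <= 0)) {
    stop(sprintf(
      "petal '%s': ARI undefined (R550 = %g, R700 = %g; both must be > 0)",
      spectrum$meta$petal_id, r550, r700
    ), call. = FALSE)
  }
  a <- if (r800 == 0) 0 else (r800 / r550) - (r800 / r700)
  list(petal_id = spectrum$meta$petal_id, ari = a,
       r550 = r550, r700 = r700, r800 = r800)
}

#' Per-petal pigment and peak index table
#'
#' Applies [ari()] and [max_peak_height()] to every member of a spectrum
#' set, returning one row per petal. Petals with an undefined ARI are
#' reported in the `note` column, never silently dropped.
#'
#' @param set A [spectrum_set()] whose grid covers 550-800 nm.
#' @param peak_window Window (nm) for the peak-height metric.
#' @return data.frame with columns `petal_id`, `plant_id`, `treatment`,
#'   `ari`, `r550`, `r700`, `r800`, `peak_height`, `peak_wavelength_nm`,
#'   `note`.
#' @export
pigment_index_table <- function(set, peak_window = c(325, 600)) {
  stopifnot(inherits(set, "spectrum_set"))
  rows <- lapply(set$spectra, function(sp) {
    pk <- max_peak_height(sp, window = peak_window)
    res <- tryCatch(ari(sp), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(petal_id = sp$meta$petal_id, plant_id = sp$meta$plant_id,
                 treatment = sp$meta$treatment,
                 ari = NA_real_, r550 = NA_real_, r700 = NA_real_,
                 r800 = NA_real_, peak_height = pk$height,
                 peak_wavelength_nm = pk$wavelength_nm,
                 note = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(petal_id = sp$meta$petal_id, plant_id = sp$meta$plant_id,
                 treatment = sp$meta$treatment,
                 ari = res$ari, r550 = res$r550, r700 = res$r700,
                 r800 = res$r800, peak_height = pk$height,
                 peak_wavelength_nm = pk$wavelength_nm, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
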