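#' Construct a petal reflectance spectrum
#'
#' A `petal_spectrum` holds one petal's relative reflectance on a wavelength
#' grid, with the white reference scaled to 1. All downstream quantities
#' (ARI, peak height, quantum catches) are derived from this object.
#'
#' @param wavelengths_nm Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param reflectance Numeric vector of relative reflectance (fraction of the
#'   white reference; 1 = white), same length as `wavelengths_nm`, finite and
#'   non-negative.
#' @param petal_id,plant_id,treatment Optional metadata. `treatment` must be
#'   one of `"AMB"`, `"CFA"`, `"NFA"`, `"FU+"` when given.
#' @return An object of class `petal_spectrum`.
#' @export
#' @examples
#' sp <- petal_spectrum(c(400, 500, 600), c(0.1, 0.2, 0.3), petal_id = "p1")
#' sp
petal_spectrum <- function(wavelengths_nm, reflectance,
                           petal_id = NA_character_,
                           plant_id = NA_character_,
                           treatment = NA_character_) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths_nm) != length(reflectance)) {
    stop("wavelengths and reflectance must have equal length", call. = FALSE)
  }
  if (length(wavelengths_nm) == 0L) {
    stop("spectrum must contain at least one sample", call. = FALSE)
  }
  if (anyNA(wavelengths_nm) || any(!is.finite(wavelengths_nm))) {
    stop("wavelengths must be finite", call. = FALSE)
  }
  d <- diff(wavelengths_nm)
  if (length(d) && any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    stop(sprintf(
      "wavelengths must be strictly increasing: violation at sample %d (%g nm after %g nm)",
      bad, wavelengths_nm[bad], wavelengths_nm[bad - 1L]
    ), call. = FALSE)
  }
  if (anyNA(reflectance) || any(!is.finite(reflectance))) {
    stop("reflectance must be finite", call. = FALSE)
  }
  if (any(reflectance < 0)) {
    stop("reflectance must be non-negative", call. = FALSE)
  }
  if (!is.na(treatment) && !treatment %in% treatment_levels()) {
    stop(sprintf(
      "unknown treatment '%s' (expected one of %s)",
      treatment, paste(treatment_levels(), collapse = ", ")
    ), call. = FALSE)
  }
  structure(
    list(
      wavelengths_nm = wavelengths_nm,
      reflectance = reflectance,
      meta = list(petal_id = petal_id, plant_id = plant_id,
                  treatment = treatment)
    ),
    class = "petal_spectrum"
  )
}

#' Treatment labels used throughout the package
#'
#' `AMB` chamber-less ambient plot, `CFA` charcoal-filtered air, `NFA`
#' non-filtered (ambient) air, `FU+` non-filtered air supplemented with
#' 40 nL/L ozone.
#'
#' @return Character vector of the four labels.
#' @export
treatment_levels <- function() c("AMB", "CFA", "NFA", "FU+")

#' @export
print.petal_spectrum <- function(x, ...) {
  rng <- range(x$wavelengths_nm)
  cat(sprintf(
    "petal_spectrum '%s' (plant %s, treatment %s): %d samples, %g-%g nm, R in [%.4f, %.4f]\n",
    x$meta$petal_id, x$meta$plant_id, x$meta$treatment,
    length(x$wavelengths_nm), rng[1], rng[2],
    min(x$reflectance), max(x$reflectance)
  ))
  invisible(x)
}

#' Construct a set of spectra sharing one wavelength grid
#'
#' @param spectra List of [petal_spectrum()] objects, all on the identical
#'   wavelength grid and with unique petal ids.
#' @return An object of class `spectrum_set` with elements `spectra` and
#'   `grid_nm`.
#' @export
spectrum_set <- function(spectra) {
  if (!length(spectra)) stop("empty spectrum set", call. = FALSE)
  stopifnot(all(vapply(spectra, inherits, logical(1), "petal_spectrum")))
  grid <- spectra[[1L]]$wavelengths_nm
  same <- vapply(spectra, function(s) {
    length(s$wavelengths_nm) == length(grid) && all(s$wavelengths_nm == grid)
  }, logical(1))
  if (!all(same)) {
    stop("all spectra in a set must share one wavelength grid", call. = FALSE)
  }
  ids <- vapply(spectra, function(s) s$meta$petal_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicated petal ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(spectra = spectra, grid_nm = grid), class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d petals on a common %g-%g nm grid (%d samples)\n",
              length(x$spectra), min(x$grid_nm), max(x$grid_nm),
              length(x$grid_nm)))
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

#' Read petal spectra from CSV
#'
#' Accepts long format (columns `petal_id`, `wavelength_nm`, `reflectance`)
#' or wide format (a `wavelength_nm` column plus one reflectance column per
#' petal, header row = petal ids). Per-petal metadata (`plant_id`,
#' `treatment`, `area_cm2`) may be supplied in a sidecar CSV keyed by
#' `petal_id`.
#'
#' @param path Path to the spectra CSV.
#' @param metadata Optional path to a metadata CSV with columns `petal_id`,
#'   `plant_id`, `treatment` and optionally `area_cm2`.
#' @param percent If `TRUE`, reflectance in the file is on the 0-100 percent
#'   scale and is divided by 100 on read. Internally reflectance is always a
#'   fraction of the white reference.
#' @param format `"auto"` (default), `"long"` or `"wide"`.
#' @return A [spectrum_set()]. When `metadata` carries `area_cm2` the set
#'   gains an `areas` attribute: a data.frame `petal_id, area_cm2`.
#' @export
read_spectra_csv <- function(path, metadata = NULL, percent = FALSE,
                             format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("spectra file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "auto") {
    format <- if (all(c("petal_id", "wavelength_nm", "reflectance") %in%
                      names(raw))) "long" else "wide"
  }

  meta <- NULL
  if (!is.null(metadata)) {
    meta <- utils::read.csv(metadata, stringsAsFactors = FALSE)
    need <- c("petal_id", "plant_id", "treatment")
    if (!all(need %in% names(meta))) {
      stop("metadata CSV must contain columns petal_id, plant_id, treatment",
           call. = FALSE)
    }
  }

  scale <- if (isTRUE(percent)) 1 / 100 else 1

  if (format == "long") {
    need <- c("petal_id", "wavelength_nm", "reflectance")
    if (!all(need %in% names(raw))) {
      stop("long-format spectra CSV needs columns petal_id, wavelength_nm, reflectance",
           call. = FALSE)
    }
    pieces <- split(raw, raw$petal_id)
    spectra <- lapply(names(pieces), function(id) {
      p <- pieces[[id]]
      md <- lookup_meta(meta, id)
      petal_spectrum(p$wavelength_nm, p$reflectance * scale,
                     petal_id = id, plant_id = md$plant_id,
                     treatment = md$treatment)
    })
  } else {
    wl_col <- intersect(c("wavelength_nm", "wavelength"), names(raw))[1]
    if (is.na(wl_col)) {
      stop("wide-format spectra CSV needs a wavelength_nm column",
           call. = FALSE)
    }
    ids <- setdiff(names(raw), wl_col)
    if (!length(ids)) stop("no reflectance columns found", call. = FALSE)
    wl <- raw[[wl_col]]
    spectra <- lapply(ids, function(id) {
      md <- lookup_meta(meta, id)
      petal_spectrum(wl, raw[[id]] * scale,
                     petal_id = id, plant_id = md$plant_id,
                     treatment = md$treatment)
    })
  }

  if (!is.null(meta)) {
    missing_ids <- setdiff(vapply(spectra, function(s) s$meta$petal_id,
                                  character(1)), meta$petal_id)
    if (length(missing_ids)) {
      stop(sprintf("no metadata for petal(s): %s",
                   paste(missing_ids, collapse = ", ")), call. = FALSE)
    }
  }

  out <- spectrum_set(spectra)
  if (!is.null(meta) && "area_cm2" %in% names(meta)) {
    attr(out, "areas") <- meta[, c("petal_id", "area_cm2")]
  }
  out
}

lookup_meta <- function(meta, id) {
  if (is.null(meta)) {
    return(list(plant_id = NA_character_, treatment = NA_character_))
  }
  row <- meta[meta$petal_id == id, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop(sprintf("no metadata row for petal '%s'", id), call. = FALSE)
  }
  list(plant_id = as.character(row$plant_id[1]),
       treatment = as.character(row$treatment[1]))
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; no extrapolation. The standard internal grid is
#' 1 nm so that indices addressing exact wavelengths (550, 700, 800 nm) are
#' read off directly even though spectroradiometer output is coarser.
#'
#' @param spectrum A [petal_spectrum()].
#' @param grid Numeric vector of target wavelengths (nm), strictly
#'   increasing, within the measured range.
#' @return A [petal_spectrum()] on `grid`, metadata preserved.
#' @export
resample <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "petal_spectrum"))
  grid <- as.numeric(grid)
  rng <- range(spectrum$wavelengths_nm)
  if (min(grid) < rng[1] || max(grid) > rng[2]) {
    stop(sprintf(
      "requested grid %g-%g nm lies outside the measured range %g-%g nm (no extrapolation)",
      min(grid), max(grid), rng[1], rng[2]
    ), call. = FALSE)
  }
  r <- stats::approx(spectrum$wavelengths_nm, spectrum$reflectance,
                     xout = grid, method = "linear")$y
  petal_spectrum(grid, r,
                 petal_id = spectrum$meta$petal_id,
                 plant_id = spectrum$meta$plant_id,
                 treatment = spectrum$meta$treatment)
}

#' Trim a spectrum to a wavelength window
#'
#' Vision modelling uses spectra trimmed to 325-700 nm even though the
#' instrument records out to 1075 nm.
#'
#' @param spectrum A [petal_spectrum()].
#' @param lo_nm,hi_nm Window bounds in nm, `lo_nm < hi_nm`.
#' @return The sub-spectrum with `lo_nm <= lambda <= hi_nm`.
#' @export
trim <- function(spectrum, lo_nm, hi_nm) {
  stopifnot(inherits(spectrum, "petal_spectrum"))
  if (!(lo_nm < hi_nm)) stop("lo_nm must be < hi_nm", call. = FALSE)
  keep <- spectrum$wavelengths_nm >= lo_nm & spectrum$wavelengths_nm <= hi_nm
  if (!any(keep)) {
    stop(sprintf("trim window %g-%g nm contains no samples", lo_nm, hi_nm),
         call. = FALSE)
  }
  petal_spectrum(spectrum$wavelengths_nm[keep], spectrum$reflectance[keep],
                 petal_id = spectrum$meta$petal_id,
                 plant_id = spectrum$meta$plant_id,
                 treatment = spectrum$meta$treatment)
}

#' Average repeated scans of one petal
#'
#' Spectroradiometer protocols average many scans per petal (25 here);
#' this is the pointwise arithmetic mean.
#'
#' @param scans List of [petal_spectrum()] objects on a common grid.
#' @return A [petal_spectrum()]; metadata taken from the first scan.
#' @export
average_spectra <- function(scans) {
  if (!length(scans)) stop("need at least one scan", call. = FALSE)
  stopifnot(all(vapply(scans, inherits, logical(1), "petal_spectrum")))
  grid <- scans[[1L]]$wavelengths_nm
  ok <- vapply(scans, function(s) {
    length(s$wavelengths_nm) == length(grid) && all(s$wavelengths_nm == grid)
  }, logical(1))
  if (!all(ok)) stop("scans have mismatched wavelength grids", call. = FALSE)
  m <- rowMeans(vapply(scans, function(s) s$reflectance,
                       numeric(length(grid))))
  petal_spectrum(grid, m,
                 petal_id = scans[[1L]]$meta$petal_id,
                 plant_id = scans[[1L]]$meta$plant_id,
                 treatment = scans[[1L]]$meta$treatment)
}

#' Maximum peak height within a wavelength window
#'
#' Height of the tallest reflectance peak in the window, defined as the
#' maximum reflectance value there (with `above_min = TRUE`, the height
#' above the window's minimum instead). The default window, 325-600 nm,
#' brackets the short-wavelength reflectance peak of anthocyanin-rich
#' petals.
#'
#' @param spectrum A [petal_spectrum()].
#' @param window Length-2 numeric, window bounds in nm.
#' @param above_min Report height above the in-window minimum rather than
#'   the absolute maximum.
#' @return List with `height` (reflectance units) and `wavelength_nm` of the
#'   maximum.
#' @export
max_peak_height <- function(spectrum, window = c(325, 600),
                            above_min = FALSE) {
  stopifnot(inherits(spectrum, "petal_spectrum"), length(window) == 2L)
  rng <- range(spectrum$wavelengths_nm)
  if (window[1] < rng[1] || window[2] > rng[2]) {
    stop(sprintf("window %g-%g nm outside measured range %g-%g nm",
                 window[1], window[2], rng[1], rng[2]), call. = FALSE)
  }
  keep <- spectrum$wavelengths_nm >= window[1] &
    spectrum$wavelengths_nm <= window[2]
  r <- spectrum$reflectance[keep]
  wl <- spectrum$wavelengths_nm[keep]
  i <- which.max(r)
  height <- if (isTRUE(above_min)) r[i] - min(r) else r[i]
  list(height = height, wavelength_nm = wl[i])
}

#' Optional boxcar smoothing
#'
#' Off by default: spectra are analysed as measured. Provided for noisy
#' instruments; a centred moving average with edge truncation.
#'
#' @param spectrum A [petal_spectrum()].
#' @param width Odd integer window width in samples.
#' @return Smoothed [petal_spectrum()].
#' @export
smooth_boxcar <- function(spectrum, width = 5L) {
  stopifnot(inherits(spectrum, "petal_spectrum"))
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) {
    stop("width must be a positive odd integer", call. = FALSE)
  }
  n <- length(spectrum$reflectance)
  half <- width %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    j <- max(1L, i - half):min(n, i + half)
    mean(spectrum$reflectance[j])
  }, numeric(1))
  petal_spectrum(spectrum$wavelengths_nm, sm,
                 petal_id = spectrum$meta$petal_id,
                 plant_id = spectrum$meta$plant_id,
                 treatment = spectrum$meta$treatment)
}
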