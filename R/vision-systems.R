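#' A1 visual-pigment sensitivity template
#'
#' Generates a photoreceptor spectral sensitivity curve from its wavelength
#' of peak absorbance using the Govardovskii et al. (2000) A1 template:
#' an alpha band given by the standard three-exponential expression plus a
#' Gaussian beta band, summed and peak-normalized to 1. This makes the
#' package self-contained: any receptor is specified by its lambda-max
#' alone, and the lambda-max values for each pollinator guild live in the
#' configuration (see [visual_system()]), not in code.
#'
#' @param lambda_max_nm Peak wavelength of the alpha band, 300-700 nm.
#' @param grid Wavelength grid (nm) on which to evaluate the template.
#' @param name Receptor name carried in the result.
#' @return List of class `photoreceptor` with `name`, `lambda_max_nm`,
#'   `grid_nm` and `sensitivity` (max 1).
#' @export
#' @examples
#' r <- pigment_template(440, 325:700, name = "B")
#' max(r$sensitivity)  # 1
pigment_template <- function(lambda_max_nm, grid, name = "receptor") {
  if (lambda_max_nm < 300 || lambda_max_nm > 700) {
    stop("lambda_max_nm must lie in [300, 700]", call. = FALSE)
  }
  grid <- as.numeric(grid)
  x <- lambda_max_nm / grid
  # alpha band (Govardovskii A1 form)
  a <- 0.8795 + 0.0459 * exp(-(lambda_max_nm - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  # beta band
  lmb <- 189 + 0.315 * lambda_max_nm
  b <- -40.5 + 0.195 * lambda_max_nm
  beta <- 0.26 * exp(-((grid - lmb) / b)^2)
  s <- alpha + beta
  s <- pmax(s, 0)
  s <- s / max(s)
  structure(list(name = name, lambda_max_nm = lambda_max_nm,
                 grid_nm = grid, sensitivity = s),
            class = "photoreceptor")
}

# CIE standard illuminant D65, relative spectral power at 10-nm steps
# (normalized to 100 at 560 nm), 300-750 nm.
d65_table <- function() {
  data.frame(
    wl = seq(300, 750, by = 10),
    power = c(0.0341, 3.2945, 20.236, 37.0535, 39.9488, 44.9117, 46.6383,
              52.0891, 49.9755, 54.6482, 82.7549, 91.486, 93.4318, 86.6823,
              104.865, 117.008, 117.812, 114.861, 115.923, 108.811, 109.354,
              107.802, 104.79, 107.689, 104.405, 104.046, 100, 96.3342,
              95.788, 88.6856, 90.0062, 89.5991, 87.6987, 83.2886, 83.6992,
              80.0268, 80.2146, 82.2778, 78.2842, 69.7213, 71.6091, 74.349,
              61.604, 69.8856, 75.087, 63.5927)
  )
}

#' Standard daylight illuminant D65 in relative quanta
#'
#' CIE D65 relative spectral power interpolated to the working grid and
#' converted from energy to photon (quantal) units (power times wavelength),
#' then normalized to a maximum of 1. Vision models operate on photon
#' catches, hence the quantal convention.
#'
#' @param grid Wavelength grid in nm (within 300-750 nm).
#' @return Numeric vector of relative quanta on `grid`, strictly positive.
#' @export
d65_illuminant <- function(grid) {
  grid <- as.numeric(grid)
  tab <- d65_table()
  if (min(grid) < min(tab$wl) || max(grid) > max(tab$wl)) {
    stop("D65 table covers 300-750 nm only", call. = FALSE)
  }
  p <- stats::approx(tab$wl, tab$power, xout = grid)$y
  q <- p * grid
  q / max(q)
}

#' Synthetic green-foliage background reflectance
#'
#' A smooth idealized green-leaf reflectance: low in the UV/blue, a modest
#' green bump near 550 nm, a red trough from chlorophyll absorption, and a
#' sigmoidal red-edge rise to the NIR plateau. Used as the von Kries
#' adapting background, the role green foliage plays for flower-visiting
#' insects.
#'
#' @param grid Wavelength grid in nm.
#' @return Numeric vector of reflectance fractions, strictly positive.
#' @export
green_leaf_background <- function(grid) {
  grid <- as.numeric(grid)
  r <- 0.04 +
    0.08 * exp(-((grid - 550) / 45)^2) +
    0.46 / (1 + exp(-(grid - 712) / 14))
  pmax(r, 1e-6)
}

guild_lambda_max_defaults <- function() {
  list(
    bee = c(UV = 344, B = 436, G = 556),
    fly = c(R7p = 330, R7y = 350, R8p = 430, R8y = 530),
    butterfly = c(u = 360, s = 440, m = 530, l = 600)
  )
}

#' Assemble a pollinator visual system
#'
#' Builds the receptor set, illuminant and adapting background for one
#' pollinator guild on a common 1-nm working grid. Defaults: honeybee-like
#' trichromat (UV 344, B 436, G 556 nm); tetrachromat fly with paired
#' UV-sensitive R7 and longer-wavelength R8 photoreceptors (R7p 330, R7y
#' 350, R8p 430, R8y 530 nm); tetrachromat butterfly (u 360, s 440, m 530,
#' l 600 nm). Receptor curves come from [pigment_template()]; lambda-max
#' values are configuration, overridable per guild. Inputs to the vision
#' models are restricted to `trim_nm` (default 325-700 nm).
#'
#' @param guild `"bee"`, `"fly"` or `"butterfly"`.
#' @param lambda_max Optional named numeric vector overriding the default
#'   receptor peak wavelengths for this guild (names and count must match).
#' @param trim_nm Length-2 working wavelength range in nm.
#' @return Object of class `visual_system`: `guild`, `grid_nm`, `receptors`
#'   (list of `photoreceptor`), `illuminant`, `background`,
#'   `luminance_receptor` (name of the longest-wavelength receptor).
#' @export
visual_system <- function(guild = c("bee", "fly", "butterfly"),
                          lambda_max = NULL, trim_nm = c(325, 700)) {
  guild <- match.arg(guild)
  defaults <- guild_lambda_max_defaults()[[guild]]
  if (is.null(lambda_max)) lambda_max <- defaults
  if (length(lambda_max) != length(defaults) ||
      !setequal(names(lambda_max), names(defaults))) {
    stop(sprintf("%s system needs receptors named %s", guild,
                 paste(names(defaults), collapse = ", ")), call. = FALSE)
  }
  lambda_max <- lambda_max[names(defaults)]
  grid <- seq(trim_nm[1], trim_nm[2], by = 1)
  receptors <- lapply(names(lambda_max), function(nm) {
    pigment_template(lambda_max[[nm]], grid, name = nm)
  })
  names(receptors) <- names(lambda_max)
  structure(list(
    guild = guild,
    grid_nm = grid,
    receptors = receptors,
    illuminant = d65_illuminant(grid),
    background = green_leaf_background(grid),
    luminance_receptor = names(lambda_max)[which.max(lambda_max)]
  ), class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  lm <- vapply(x$receptors, function(r) r$lambda_max_nm, numeric(1))
  cat(sprintf(
    "visual_system '%s': receptors %s; grid %g-%g nm; luminance receptor '%s'\n",
    x$guild,
    paste(sprintf("%s(%g nm)", names(lm), lm), collapse = ", "),
    min(x$grid_nm), max(x$grid_nm), x$luminance_receptor
  ))
  invisible(x)
}
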