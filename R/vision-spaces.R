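#' Photoreceptor quantum catch
#'
#' Trapezoidal integral of stimulus reflectance x receptor sensitivity x
#' illuminant over the working grid: the photon catch of one receptor
#' viewing the stimulus under that light.
#'
#' @param reflectance Stimulus reflectance on `grid`.
#' @param sensitivity Receptor sensitivity on `grid`.
#' @param illuminant Illuminant relative quanta on `grid`.
#' @param grid Common wavelength grid (nm), strictly increasing.
#' @return Non-negative scalar Q.
#' @export
quantum_catch <- function(reflectance, sensitivity, illuminant, grid) {
  n <- length(grid)
  if (length(reflectance) != n || length(sensitivity) != n ||
      length(illuminant) != n) {
    stop("reflectance, sensitivity, illuminant and grid must share one length",
         call. = FALSE)
  }
  y <- reflectance * sensitivity * illuminant
  sum((y[-1] + y[-n]) / 2 * diff(grid))
}

#' von Kries chromatic adaptation
#'
#' Normalizes a receptor's stimulus catch by its catch for the adapting
#' background, so the background itself appears achromatic (q = 1 in every
#' receptor).
#'
#' @param q_stimulus Raw catch for the stimulus.
#' @param q_background Raw catch for the background, > 0.
#' @return Adapted catch q = q_stimulus / q_background.
#' @export
von_kries <- function(q_stimulus, q_background) {
  if (any(q_background <= 0)) {
    stop("background quantum catch must be > 0", call. = FALSE)
  }
  q_stimulus / q_background
}

#' Quantum catches of a petal in a pollinator visual system
#'
#' Resamples the petal spectrum onto the system's working grid (trimming to
#' its range), computes the raw catch Q per receptor, the von Kries adapted
#' catch q = Q / Q(background), and for trichromatic bees the receptor
#' excitation E = q / (q + 1).
#'
#' @param spectrum A [petal_spectrum()] covering the system's grid.
#' @param system A [visual_system()].
#' @return Object of class `quantum_catch_set`: `petal_id`, `guild`, `Q`,
#'   `q`, `E` (bee only, else `NULL`).
#' @export
petal_quantum_catches <- function(spectrum, system) {
  stopifnot(inherits(spectrum, "petal_spectrum"),
            inherits(system, "visual_system"))
  sp <- resample(spectrum, system$grid_nm)
  Q <- vapply(system$receptors, function(r) {
    quantum_catch(sp$reflectance, r$sensitivity, system$illuminant,
                  system$grid_nm)
  }, numeric(1))
  Qb <- vapply(system$receptors, function(r) {
    quantum_catch(system$background, r$sensitivity, system$illuminant,
                  system$grid_nm)
  }, numeric(1))
  if (any(Q <= 0)) {
    stop(sprintf("petal '%s': zero quantum catch in receptor(s) %s",
                 spectrum$meta$petal_id,
                 paste(names(Q)[Q <= 0], collapse = ", ")), call. = FALSE)
  }
  q <- von_kries(Q, Qb)
  structure(list(
    petal_id = spectrum$meta$petal_id,
    guild = system$guild,
    Q = Q, q = q,
    E = if (system$guild == "bee") q / (q + 1) else NULL
  ), class = "quantum_catch_set")
}

#' Bee colour-hexagon locus
#'
#' Receptor excitations E = q/(q+1) (hyperbolic transduction) are mapped to
#' the two hexagon coordinates: x = (sqrt(3)/2) (E_G - E_UV),
#' y = E_B - (E_UV + E_G)/2. The background maps to the centre (0,0); all
#' loci lie within unit distance of the centre. The hexagon is divided into
#' six 60-degree sectors centred on the three receptor directions and their
#' bisectors: Blue at 90 degrees, then Blue-Green, Green, UV-Green, UV,
#' UV-Blue going clockwise.
#'
#' @param q_uv,q_blue,q_green Adapted catches, all > 0.
#' @param petal_id Optional identifier carried through.
#' @return List of class `hexagon_locus`: `x`, `y`, `distance` from centre,
#'   `sector` (NA at the exact centre), `E` (named excitations).
#' @export
bee_hexagon <- function(q_uv, q_blue, q_green, petal_id = NA_character_) {
  if (any(c(q_uv, q_blue, q_green) <= 0)) {
    stop("adapted catches must be > 0", call. = FALSE)
  }
  E <- c(UV = q_uv, B = q_blue, G = q_green)
  E <- E / (E + 1)
  hexagon_locus_from_E(E, petal_id)
}

hexagon_locus_from_E <- function(E, petal_id = NA_character_) {
  x <- (sqrt(3) / 2) * (E[["G"]] - E[["UV"]])
  y <- E[["B"]] - (E[["UV"]] + E[["G"]]) / 2
  d <- sqrt(x^2 + y^2)
  sector <- if (d == 0) NA_character_ else hexagon_sector(atan2(y, x))
  structure(list(petal_id = petal_id, x = x, y = y, distance = d,
                 sector = sector, E = E),
            class = "hexagon_locus")
}

hexagon_sector <- function(theta) {
  deg <- (theta * 180 / pi) %% 360
  centers <- c("Blue" = 90, "Blue-Green" = 30, "Green" = 330,
               "UV-Green" = 270, "UV" = 210, "UV-Blue" = 150)
  diffs <- abs(((deg - centers + 180) %% 360) - 180)
  names(centers)[which.min(diffs)]
}

#' Default fly colour-category map
#'
#' Maps the sign pattern of the two opponent coordinates (sign of
#' q(R7p) - q(R8p), sign of q(R7y) - q(R8y)) to a named fly colour
#' category. UV-rich stimuli drive both short-wavelength R7 receptors above
#' their R8 partners (+,+); blue stimuli drive both R8 receptors harder
#' (-,-). The mapping is a configuration table, not hard-wired into the
#' classifier, because the sign convention differs between sources.
#'
#' @return Named character vector keyed by sign pattern `"++"`, `"+-"`,
#'   `"-+"`, `"--"`.
#' @export
fly_category_map <- function() {
  c("++" = "Fly UV", "+-" = "Fly Purple",
    "-+" = "Fly Yellow", "--" = "Fly Blue")
}

#' Fly categorical colour locus
#'
#' The fly colour space uses two opponent coordinates built from the paired
#' R7/R8 photoreceptors: cx = q(R7p) - q(R8p), cy = q(R7y) - q(R8y). Flies
#' are modelled as discriminating only between stimuli that fall in
#' different quadrants; loci with a coordinate exactly zero are labelled
#' `"boundary"`, never silently assigned.
#'
#' @param q_r7p,q_r7y,q_r8p,q_r8y Adapted catches, all > 0.
#' @param petal_id Optional identifier.
#' @param category_map Quadrant-to-name table, see [fly_category_map()].
#' @return List of class `fly_locus`: `cx`, `cy`, `category`, `boundary`
#'   flag.
#' @export
fly_categorical <- function(q_r7p, q_r7y, q_r8p, q_r8y,
                            petal_id = NA_character_,
                            category_map = fly_category_map()) {
  if (any(c(q_r7p, q_r7y, q_r8p, q_r8y) <= 0)) {
    stop("adapted catches must be > 0", call. = FALSE)
  }
  cx <- q_r7p - q_r8p
  cy <- q_r7y - q_r8y
  boundary <- (cx == 0 || cy == 0)
  category <- if (boundary) {
    "boundary"
  } else {
    key <- paste0(if (cx > 0) "+" else "-", if (cy > 0) "+" else "-")
    unname(category_map[[key]])
  }
  structure(list(petal_id = petal_id, cx = cx, cy = cy,
                 category = category, boundary = boundary),
            class = "fly_locus")
}

#' Reference tetrahedron vertices for tetrachromat colour space
#'
#' A regular tetrahedron with circumradius 1 and centroid at the origin;
#' the UV (u) vertex points along +z. Each receptor's "axis value" for a
#' locus is its projection onto the unit vector toward that receptor's
#' vertex.
#'
#' @return 4 x 3 numeric matrix, rows named u, s, m, l.
#' @export
tetrahedron_vertices <- function() {
  rbind(
    u = c(0, 0, 1),
    s = c(2 * sqrt(2) / 3, 0, -1 / 3),
    m = c(-sqrt(2) / 3, sqrt(6) / 3, -1 / 3),
    l = c(-sqrt(2) / 3, -sqrt(6) / 3, -1 / 3)
  )
}

#' Butterfly tetrahedral colour locus
#'
#' Adapted catches of the four receptors (u, s, m, l) are normalized to
#' relative catches summing to 1 and mapped into the reference tetrahedron
#' as their convex combination of the vertices. Equal catches (the adapted
#' background) map to the centroid (0,0,0); a pure single-receptor stimulus
#' maps to that receptor's vertex at unit distance.
#'
#' @param q_u,q_s,q_m,q_l Adapted catches, all > 0.
#' @param petal_id Optional identifier.
#' @return List of class `tetrahedron_locus`: `rel` (named relative catches
#'   summing to 1), `x`, `y`, `z`, `axis` (named projections onto the four
#'   vertex directions; the u axis value equals `z`).
#' @export
butterfly_tetrahedron <- function(q_u, q_s, q_m, q_l,
                                  petal_id = NA_character_) {
  q <- c(u = q_u, s = q_s, m = q_m, l = q_l)
  if (any(q <= 0)) stop("adapted catches must be > 0", call. = FALSE)
  rel <- q / sum(q)
  V <- tetrahedron_vertices()
  xyz <- as.numeric(rel %*% V)
  axis <- as.numeric(V %*% xyz)
  names(axis) <- rownames(V)
  structure(list(petal_id = petal_id, rel = rel,
                 x = xyz[1], y = xyz[2], z = xyz[3], axis = axis),
            class = "tetrahedron_locus")
}

#' Luminance (achromatic) signal
#'
#' The adapted catch of the guild's longest-wavelength photoreceptor, the
#' receptor conventionally driving achromatic vision in these insects.
#'
#' @param catches A `quantum_catch_set` from [petal_quantum_catches()].
#' @param system The matching [visual_system()].
#' @return Scalar adapted catch of the luminance receptor.
#' @export
luminance <- function(catches, system) {
  stopifnot(inherits(catches, "quantum_catch_set"),
            inherits(system, "visual_system"))
  nm <- system$luminance_receptor
  if (!nm %in% names(catches$q)) {
    stop(sprintf("luminance receptor '%s' missing from catches", nm),
         call. = FALSE)
  }
  unname(catches$q[[nm]])
}

#' Colour locus of one petal for a guild
#'
#' Runs the full chain spectrum -> quantum catches -> von Kries -> colour
#' space for one petal.
#'
#' @param spectrum A [petal_spectrum()].
#' @param system A [visual_system()].
#' @param ... Passed to the guild's locus function (e.g. `category_map`).
#' @return A `hexagon_locus`, `fly_locus` or `tetrahedron_locus`.
#' @export
petal_locus <- function(spectrum, system, ...) {
  qc <- petal_quantum_catches(spectrum, system)
  q <- qc$q
  id <- qc$petal_id
  switch(system$guild,
    bee = bee_hexagon(q[["UV"]], q[["B"]], q[["G"]], petal_id = id),
    fly = fly_categorical(q[["R7p"]], q[["R7y"]], q[["R8p"]], q[["R8y"]],
                          petal_id = id, ...),
    butterfly = butterfly_tetrahedron(q[["u"]], q[["s"]], q[["m"]], q[["l"]],
                                      petal_id = id)
  )
}

#' Colour loci of a spectrum set for one guild
#'
#' @param set A [spectrum_set()].
#' @param system A [visual_system()].
#' @param ... Passed to [petal_locus()].
#' @return List with `loci` (list of locus objects) and `table`, a
#'   data.frame with petal metadata, coordinates, sector/category and
#'   luminance.
#' @export
colour_loci <- function(set, system, ...) {
  stopifnot(inherits(set, "spectrum_set"))
  loci <- lapply(set$spectra, petal_locus, system = system, ...)
  lum <- vapply(set$spectra, function(sp) {
    luminance(petal_quantum_catches(sp, system), system)
  }, numeric(1))
  meta <- do.call(rbind, lapply(set$spectra, function(sp) {
    data.frame(petal_id = sp$meta$petal_id, plant_id = sp$meta$plant_id,
               treatment = sp$meta$treatment, stringsAsFactors = FALSE)
  }))
  tab <- switch(system$guild,
    bee = data.frame(meta,
      x = vapply(loci, `[[`, numeric(1), "x"),
      y = vapply(loci, `[[`, numeric(1), "y"),
      distance = vapply(loci, `[[`, numeric(1), "distance"),
      sector = vapply(loci, `[[`, character(1), "sector"),
      luminance = lum, stringsAsFactors = FALSE),
    fly = data.frame(meta,
      cx = vapply(loci, `[[`, numeric(1), "cx"),
      cy = vapply(loci, `[[`, numeric(1), "cy"),
      category = vapply(loci, `[[`, character(1), "category"),
      luminance = lum, stringsAsFactors = FALSE),
    butterfly = data.frame(meta,
      x = vapply(loci, `[[`, numeric(1), "x"),
      y = vapply(loci, `[[`, numeric(1), "y"),
      z = vapply(loci, `[[`, numeric(1), "z"),
      u = vapply(loci, function(l) l$rel[["u"]], numeric(1)),
      s = vapply(loci, function(l) l$rel[["s"]], numeric(1)),
      m = vapply(loci, function(l) l$rel[["m"]], numeric(1)),
      l = vapply(loci, function(l) l$rel[["l"]], numeric(1)),
      axis_u = vapply(loci, function(l) l$axis[["u"]], numeric(1)),
      luminance = lum, stringsAsFactors = FALSE)
  )
  list(loci = loci, table = tab)
}
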