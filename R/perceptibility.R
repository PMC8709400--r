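#' Perceptibility rule for a pollinator guild
#'
#' Encodes how two colour loci are judged "perceptibly different". The
#' defaults follow the discrimination criteria used for a 60%-correct
#' choice level: flies discriminate only across colour-space quadrants;
#' bees require a Euclidean hexagon distance of at least 0.09; butterflies
#' require at least 0.03 along one colour-space axis (default the UV
#' receptor axis u, where petal variation concentrates), with a
#' Euclidean-in-tetrahedron alternative available.
#'
#' @param guild `"bee"`, `"fly"` or `"butterfly"`.
#' @param rule `"quadrant_change"`, `"euclidean_threshold"` or
#'   `"axis_threshold"`; default depends on guild.
#' @param threshold Positive distance threshold (0.09 bee, 0.03 butterfly);
#'   ignored for `quadrant_change`.
#' @param axis Receptor axis name for `axis_threshold` (default `"u"`).
#' @return Object of class `perceptibility_rule`.
#' @export
perceptibility_rule <- function(guild = c("bee", "fly", "butterfly"),
                                rule = NULL, threshold = NULL, axis = "u") {
  guild <- match.arg(guild)
  if (is.null(rule)) {
    rule <- switch(guild, bee = "euclidean_threshold",
                   fly = "quadrant_change", butterfly = "axis_threshold")
  }
  rule <- match.arg(rule, c("quadrant_change", "euclidean_threshold",
                            "axis_threshold"))
  if (is.null(threshold)) {
    threshold <- switch(guild, bee = 0.09, butterfly = 0.03, fly = NA_real_)
  }
  if (rule != "quadrant_change" && (!is.finite(threshold) || threshold <= 0)) {
    stop("threshold must be > 0 for threshold rules", call. = FALSE)
  }
  structure(list(guild = guild, rule = rule, threshold = threshold,
                 axis = axis),
            class = "perceptibility_rule")
}

locus_guild <- function(locus) {
  if (inherits(locus, "hexagon_locus")) return("bee")
  if (inherits(locus, "fly_locus")) return("fly")
  if (inherits(locus, "tetrahedron_locus")) return("butterfly")
  stop("not a colour locus object", call. = FALSE)
}

locus_coords <- function(locus) {
  switch(locus_guild(locus),
         bee = c(locus$x, locus$y),
         fly = c(locus$cx, locus$cy),
         butterfly = c(locus$x, locus$y, locus$z))
}

#' Are two loci perceptibly different?
#'
#' Applies a [perceptibility_rule()] to two loci of the same guild. For
#' `quadrant_change`, loci labelled `"boundary"` are never scored
#' perceptible against anything (they belong to no quadrant).
#'
#' @param locus_a,locus_b Loci from the same guild's colour space.
#' @param rule A [perceptibility_rule()] matching the guild.
#' @return List: `perceptible` (logical), `distance` (Euclidean in the
#'   space, or |delta| on the rule's axis for `axis_threshold`).
#' @export
pair_perceptible <- function(locus_a, locus_b, rule) {
  stopifnot(inherits(rule, "perceptibility_rule"))
  ga <- locus_guild(locus_a)
  if (ga != locus_guild(locus_b)) {
    stop("loci come from different colour spaces", call. = FALSE)
  }
  if (ga != rule$guild) {
    stop(sprintf("rule is for guild '%s' but loci are '%s'",
                 rule$guild, ga), call. = FALSE)
  }
  d_euclid <- sqrt(sum((locus_coords(locus_a) - locus_coords(locus_b))^2))
  switch(rule$rule,
    quadrant_change = {
      boundary <- isTRUE(locus_a$boundary) || isTRUE(locus_b$boundary)
      list(perceptible = !boundary && locus_a$category != locus_b$category,
           distance = d_euclid)
    },
    euclidean_threshold = list(perceptible = d_euclid >= rule$threshold,
                               distance = d_euclid),
    axis_threshold = {
      da <- abs(locus_axis_value(locus_a, rule$axis) -
                  locus_axis_value(locus_b, rule$axis))
      list(perceptible = da >= rule$threshold, distance = da)
    }
  )
}

locus_axis_value <- function(locus, axis) {
  if (!inherits(locus, "tetrahedron_locus")) {
    stop("axis_threshold rules apply to tetrahedral loci", call. = FALSE)
  }
  if (!axis %in% names(locus$axis)) {
    stop(sprintf("unknown axis '%s'", axis), call. = FALSE)
  }
  locus$axis[[axis]]
}

#' Fly colour-category composition per treatment
#'
#' Counts and percentages of loci per colour category within each
#' treatment. Boundary loci (a coordinate exactly zero) are counted
#' separately and excluded from the percentages.
#'
#' @param loci List of `fly_locus` objects.
#' @param treatments Character vector of treatment labels, one per locus.
#' @return List of class `category_fractions`: `counts` (treatment x
#'   category table), `percent` (same shape, rows summing to 100 over
#'   non-boundary loci), `n_boundary` per treatment.
#' @export
category_fractions <- function(loci, treatments) {
  if (!length(loci)) stop("empty locus list", call. = FALSE)
  stopifnot(all(vapply(loci, inherits, logical(1), "fly_locus")),
            length(treatments) == length(loci))
  cats <- vapply(loci, `[[`, character(1), "category")
  treatments <- as.character(treatments)
  if (anyNA(treatments)) stop("treatment labels missing", call. = FALSE)
  boundary <- cats == "boundary"
  n_boundary <- tapply(boundary, treatments, sum)
  keep <- !boundary
  if (!any(keep)) stop("all loci are boundary loci", call. = FALSE)
  counts <- table(treatment = treatments[keep], category = cats[keep])
  percent <- 100 * prop.table(counts, margin = 1)
  structure(list(counts = counts, percent = percent,
                 n_boundary = n_boundary),
            class = "category_fractions")
}

#' Fraction of treated petals perceptibly different from a control group
#'
#' Scores each treated petal against a control reference and reports the
#' fraction perceptibly changed. Two reference constructions are offered:
#' `"centroid"` (default) compares each treated petal with the centroid of
#' the control loci, mirroring a single reference region for the control
#' group; `"strict"` requires the petal to be perceptible from every
#' individual control petal, which can only ever flag fewer petals.
#'
#' @param loci_control,loci_treated Non-empty lists of loci from one
#'   guild's colour space.
#' @param rule A [perceptibility_rule()].
#' @param mode `"centroid"` or `"strict"`.
#' @return List of class `perceptibility_summary`: `n_compared`,
#'   `n_perceptible`, `fraction`, `percent`, `mode`, per-petal logical
#'   `perceptible`.
#' @export
cross_treatment_perceptibility <- function(loci_control, loci_treated, rule,
                                           mode = c("centroid", "strict")) {
  mode <- match.arg(mode)
  if (!length(loci_control) || !length(loci_treated)) {
    stop("both groups must contain at least one locus", call. = FALSE)
  }
  flags <- if (mode == "centroid") {
    ref <- locus_centroid(loci_control)
    vapply(loci_treated, function(l) pair_perceptible(l, ref, rule)$perceptible,
           logical(1))
  } else {
    vapply(loci_treated, function(l) {
      all(vapply(loci_control,
                 function(c0) pair_perceptible(l, c0, rule)$perceptible,
                 logical(1)))
    }, logical(1))
  }
  n <- length(flags)
  k <- sum(flags)
  structure(list(n_compared = n, n_perceptible = k, fraction = k / n,
                 percent = 100 * k / n, mode = mode, perceptible = flags),
            class = "perceptibility_summary")
}

#' Centroid of a group of colour loci
#'
#' Coordinate-wise mean, returned as a locus of the same class so it can be
#' compared with individual loci. For fly loci the centroid's category is
#' the quadrant of the mean coordinates.
#'
#' @param loci Non-empty list of loci of one class.
#' @return A locus object of the group's class with `petal_id` "centroid".
#' @export
locus_centroid <- function(loci) {
  if (!length(loci)) stop("empty locus list", call. = FALSE)
  g <- locus_guild(loci[[1L]])
  stopifnot(all(vapply(loci, locus_guild, character(1)) == g))
  M <- do.call(rbind, lapply(loci, locus_coords))
  cm <- colMeans(M)
  switch(g,
    bee = {
      d <- sqrt(sum(cm^2))
      structure(list(petal_id = "centroid", x = cm[1], y = cm[2],
                     distance = d,
                     sector = if (d == 0) NA_character_
                              else hexagon_sector(atan2(cm[2], cm[1])),
                     E = NULL),
                class = "hexagon_locus")
    },
    fly = {
      boundary <- (cm[1] == 0 || cm[2] == 0)
      category <- if (boundary) "boundary" else {
        key <- paste0(if (cm[1] > 0) "+" else "-",
                      if (cm[2] > 0) "+" else "-")
        unname(fly_category_map()[[key]])
      }
      structure(list(petal_id = "centroid", cx = cm[1], cy = cm[2],
                     category = category, boundary = boundary),
                class = "fly_locus")
    },
    butterfly = {
      V <- tetrahedron_vertices()
      axis <- as.numeric(V %*% cm)
      names(axis) <- rownames(V)
      rel <- colMeans(do.call(rbind, lapply(loci, `[[`, "rel")))
      structure(list(petal_id = "centroid", rel = rel,
                     x = cm[1], y = cm[2], z = cm[3], axis = axis),
                class = "tetrahedron_locus")
    }
  )
}
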