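# Independent oracles and small fixture builders used across the suite.
# Each oracle is a separate, deliberately naive code path from the
# implementation it checks.

# flat spectrum at level r over a grid
flat_spectrum <- function(r = 0.4, grid = seq(325, 1075, by = 3),
                          id = "flat") {
  petal_spectrum(grid, rep(r, length(grid)), petal_id = id)
}

# spectrum passing exactly through given (wavelength, reflectance) knots,
# linearly interpolated onto a 1-nm grid
knot_spectrum <- function(wl, r, id = "knots") {
  grid <- seq(min(wl), max(wl), by = 1)
  petal_spectrum(grid, approx(wl, r, xout = grid)$y, petal_id = id)
}

# Gaussian bump over a baseline
bump_spectrum <- function(center = 450, amp = 0.25, base = 0.05,
                          width = 30, grid = seq(325, 1075, by = 1),
                          id = "bump") {
  petal_spectrum(grid, base + amp * exp(-((grid - center) / width)^2),
                 petal_id = id)
}

# naive trapezoidal catch: explicit loop, no vectorization
oracle_quantum_catch <- function(r, s, i, grid) {
  total <- 0
  for (k in seq_len(length(grid) - 1)) {
    y1 <- r[k] * s[k] * i[k]
    y2 <- r[k + 1] * s[k + 1] * i[k + 1]
    total <- total + (y1 + y2) / 2 * (grid[k + 1] - grid[k])
  }
  total
}

# naive hexagon pipeline: loops + scalar arithmetic only
oracle_hexagon_xy <- function(spectrum, system) {
  grid <- system$grid_nm
  sp <- resample(spectrum, grid)
  q <- numeric(3)
  names(q) <- c("UV", "B", "G")
  for (nm in names(q)) {
    s <- system$receptors[[nm]]$sensitivity
    qs <- oracle_quantum_catch(sp$reflectance, s, system$illuminant, grid)
    qb <- oracle_quantum_catch(system$background, s, system$illuminant, grid)
    q[nm] <- qs / qb
  }
  E <- q / (q + 1)
  c(x = sqrt(3) / 2 * (E[["G"]] - E[["UV"]]),
    y = E[["B"]] - (E[["UV"]] + E[["G"]]) / 2)
}

# closed-form single-df contrast F: (sum c_g ybar_g)^2 / (MSW sum c_g^2/n_g)
oracle_contrast_F <- function(y, groups, coeffs, levels) {
  groups <- factor(groups, levels = levels)
  ybar <- tapply(y, groups, mean)
  n_g <- tapply(y, groups, length)
  est <- sum(coeffs * ybar)
  ssw <- sum((y - ybar[groups])^2)
  msw <- ssw / (length(y) - length(levels))
  list(estimate = est, F = est^2 / (msw * sum(coeffs^2 / n_g)))
}

# naive exhaustive PERMANOVA: enumerate label placements with combn and
# compute pseudo-F from explicit double loops over the dissimilarity matrix
oracle_permanova_exhaustive <- function(D, groups) {
  n <- length(groups)
  f_of <- function(g) {
    sst <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) sst <- sst + D[i, j]^2
    sst <- sst / n
    ssw <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1) {
        for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx)) {
          ssw <- ssw + D[idx[a], idx[b]]^2
        }
      }
    }
    ssw <- ssw / (n / length(unique(g)))  # balanced designs only
    a <- length(unique(g))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  # balanced two-group enumeration
  labs <- sort(unique(groups))
  stopifnot(length(labs) == 2)
  k <- sum(groups == labs[1])
  f_obs <- f_of(groups)
  fs <- apply(utils::combn(n, k), 2, function(idx) {
    g <- rep(labs[2], n)
    g[idx] <- labs[1]
    f_of(g)
  })
  list(F = f_obs, p = mean(fs >= f_obs - 1e-12))
}

# balanced-design variance components by method of moments (ANOVA estimators)
oracle_variance_components <- function(y, plant) {
  plant <- factor(plant)
  m <- length(y) / nlevels(plant)
  ybar_p <- tapply(y, plant, mean)
  msw <- sum((y - ybar_p[plant])^2) / (length(y) - nlevels(plant))
  msb <- m * sum((ybar_p - mean(y))^2) / (nlevels(plant) - 1)
  c(sigma2_resid = msw, sigma2_plant = max((msb - msw) / m, 0))
}

# butterfly locus with a prescribed u-axis coordinate z; remaining catches
# split equally (u-axis value of the locus is (4 rel_u - 1) / 3)
tetra_locus_with_u <- function(z, id = "t") {
  rel_u <- (3 * z + 1) / 4
  rest <- (1 - rel_u) / 3
  butterfly_tetrahedron(rel_u, rest, rest, rest, petal_id = id)
}
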