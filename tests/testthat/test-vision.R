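test_that("pigment template peaks at lambda-max and is well-behaved", {
  grid <- 325:700
  for (lm in c(344, 436, 530, 600)) {
    tpl <- pigment_template(lm, grid)
    expect_equal(max(tpl$sensitivity), 1)
    expect_equal(grid[which.max(tpl$sensitivity)], lm, tolerance = 2)
    expect_true(all(tpl$sensitivity >= 0))
    # flanks at +/- 60 nm are strictly inside (0, 1)
    for (off in c(-60, 60)) {
      if (lm + off >= min(grid) && lm + off <= max(grid)) {
        v <- tpl$sensitivity[grid == lm + off]
        expect_gt(v, 0); expect_lt(v, 1)
      }
    }
  }
  # unimodal between beta and alpha peaks: no interior local minima deeper
  # than numerical tolerance for a mid-wavelength receptor
  tpl <- pigment_template(530, grid)
  s <- tpl$sensitivity
  beta_peak <- which.max(s[grid < 420])
  alpha_peak <- which.max(s)
  seg <- s[(beta_peak + 1):(alpha_peak - 1)]
  trough <- which.min(seg) + beta_peak
  expect_true(all(diff(s[trough:alpha_peak]) >= -1e-9))
  expect_error(pigment_template(250, grid), "300")
})

test_that("quantum catch matches brute-force trapezoidal summation", {
  grid <- 400:500
  ones <- rep(1, length(grid))
  expect_equal(quantum_catch(ones, ones, ones, grid), 100)
  expect_equal(quantum_catch(rep(0, 101), ones, ones, grid), 0)

  tri <- pmax(1 - abs(grid - 450) / 50, 0)
  tri2 <- pmax(1 - abs(grid - 430) / 40, 0)
  expect_equal(quantum_catch(tri, tri2, ones, grid),
               oracle_quantum_catch(tri, tri2, ones, grid),
               tolerance = 1e-12)
  expect_error(quantum_catch(ones, ones[-1], ones, grid), "length")
})

test_that("von Kries adaptation fixes the background at unity", {
  expect_equal(von_kries(3.2, 3.2), 1)
  expect_equal(von_kries(2 * 1.7, 1.7), 2)
  expect_error(von_kries(1, 0), "> 0")
})

test_that("background-equal petal sits at the neutral point of all spaces", {
  for (g in c("bee", "fly", "butterfly")) {
    sys <- visual_system(g)
    bg <- petal_spectrum(sys$grid_nm, green_leaf_background(sys$grid_nm),
                         petal_id = "bg")
    qc <- petal_quantum_catches(bg, sys)
    expect_equal(unname(qc$q), rep(1, length(qc$q)), tolerance = 1e-12)
    loc <- petal_locus(bg, sys)
    if (g == "bee") {
      expect_equal(loc$distance, 0, tolerance = 1e-10)
    } else if (g == "fly") {
      expect_equal(abs(loc$cx) + abs(loc$cy), 0, tolerance = 1e-10)
      expect_true(loc$boundary)
    } else {
      expect_equal(sqrt(loc$x^2 + loc$y^2 + loc$z^2), 0, tolerance = 1e-10)
    }
  }
})

test_that("hexagon coordinates follow the excitation geometry", {
  loc0 <- bee_hexagon(1, 1, 1)
  expect_equal(c(loc0$x, loc0$y), c(0, 0))
  expect_true(is.na(loc0$sector))

  # blue-only limit -> (0, 1); green-only limit -> (sqrt(3)/2, -1/2)
  eps <- 1e-9; big <- 1e9
  blue <- bee_hexagon(eps, big, eps)
  expect_equal(c(blue$x, blue$y), c(0, 1), tolerance = 1e-6)
  expect_equal(blue$sector, "Blue")
  green <- bee_hexagon(eps, eps, big)
  expect_equal(c(green$x, green$y), c(sqrt(3) / 2, -1 / 2),
               tolerance = 1e-6)
  expect_equal(green$distance, 1, tolerance = 1e-6)
  expect_equal(green$sector, "Green")

  # distance from centre bounded by 1 for any positive catches
  set.seed(8)
  for (i in 1:50) {
    q <- runif(3, 1e-4, 50)
    expect_lte(bee_hexagon(q[1], q[2], q[3])$distance, 1)
  }
  expect_error(bee_hexagon(0, 1, 1), "> 0")
})

test_that("hexagon pipeline agrees with an independent naive implementation", {
  sys <- visual_system("bee")
  set.seed(21)
  for (i in 1:10) {
    grid <- seq(325, 1075, by = 3)
    r <- pmin(pmax(0.05 + 0.5 * abs(sin(grid / runif(1, 30, 90))) +
                     rnorm(length(grid), 0, 0.01), 1e-4), 1)
    sp <- petal_spectrum(grid, r, petal_id = "rand")
    loc <- petal_locus(sp, sys)
    ora <- oracle_hexagon_xy(sp, sys)
    expect_equal(c(loc$x, loc$y), unname(ora), tolerance = 1e-10)
  }
})

test_that("fly categories come from quadrant signs with boundary handling", {
  expect_true(fly_categorical(1, 1, 1, 1)$boundary)
  expect_equal(fly_categorical(1, 1, 1, 1)$category, "boundary")

  mk <- function(cx, cy) fly_categorical(1 + pmax(cx, 0), 1 + pmax(cy, 0),
                                         1 - pmin(cx, 0), 1 - pmin(cy, 0))
  expect_equal(mk(0.2, -0.1)$category, mk(0.1, -0.3)$category)
  expect_false(mk(0.2, 0.1)$category == mk(0.2, -0.1)$category)

  # classification invariant to common positive scaling of the illuminant
  sys <- visual_system("fly")
  sys2 <- sys
  sys2$illuminant <- sys$illuminant * 7.3
  sim <- simulate_dataset(sim_config(treatments = "CFA",
                                     plants_per_treatment = 2,
                                     petals_per_plant = 2, seed = 9))
  for (sp in sim$set$spectra) {
    expect_equal(petal_locus(sp, sys)$category,
                 petal_locus(sp, sys2)$category)
  }
})

test_that("tetrahedral loci are normalized convex combinations of vertices", {
  cen <- butterfly_tetrahedron(1, 1, 1, 1)
  expect_equal(unname(cen$rel), rep(0.25, 4))
  expect_equal(c(cen$x, cen$y, cen$z), c(0, 0, 0), tolerance = 1e-12)

  u <- butterfly_tetrahedron(1, 1e-12, 1e-12, 1e-12)
  expect_equal(c(u$x, u$y, u$z), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(sqrt(u$x^2 + u$y^2 + u$z^2), 1, tolerance = 1e-9)

  set.seed(3)
  for (i in 1:20) {
    q <- runif(4, 0.01, 10)
    loc <- butterfly_tetrahedron(q[1], q[2], q[3], q[4])
    expect_equal(sum(loc$rel), 1)
    loc2 <- butterfly_tetrahedron(3 * q[1], 3 * q[2], 3 * q[3], 3 * q[4])
    expect_equal(loc$rel, loc2$rel)
  }
  expect_error(butterfly_tetrahedron(0, 1, 1, 1), "> 0")
})

test_that("luminance is the adapted catch of the longest-wavelength receptor", {
  sys <- visual_system("bee")
  expect_equal(sys$luminance_receptor, "G")
  sim <- simulate_dataset(sim_config(treatments = "CFA",
                                     plants_per_treatment = 1,
                                     petals_per_plant = 1, seed = 2))
  sp <- sim$set$spectra[[1]]
  qc <- petal_quantum_catches(sp, sys)
  expect_equal(luminance(qc, sys), unname(qc$q[["G"]]))

  bg <- petal_spectrum(sys$grid_nm, green_leaf_background(sys$grid_nm),
                       petal_id = "bg")
  expect_equal(luminance(petal_quantum_catches(bg, sys), sys), 1,
               tolerance = 1e-12)

  # doubling reflectance doubles the raw catch and (fixed background)
  # the luminance signal
  sp2 <- petal_spectrum(sp$wavelengths_nm, pmin(sp$reflectance * 2, 1e6),
                        petal_id = "x2")
  qc2 <- petal_quantum_catches(sp2, sys)
  expect_equal(unname(qc2$Q), unname(qc$Q) * 2, tolerance = 1e-9)
  expect_equal(luminance(qc2, sys), 2 * luminance(qc, sys),
               tolerance = 1e-9)
})

test_that("visual_system validates receptor overrides", {
  sys <- visual_system("bee", lambda_max = c(UV = 350, B = 440, G = 540))
  expect_equal(sys$receptors$B$lambda_max_nm, 440)
  expect_error(visual_system("bee", lambda_max = c(UV = 350)), "receptors")
})
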