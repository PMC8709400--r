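test_that("one-way ANOVA reproduces textbook sums of squares", {
  y <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("A", "B"), each = 3)
  tab <- oneway_anova(y, g)
  grp <- tab[tab$term == "group", ]
  expect_equal(grp$df, 1)
  expect_equal(grp$statistic, 13.5)
  expect_equal(tab$df[tab$term == "Residuals"], 4)

  # degenerate zero-variance case is reported as undefined, not Inf
  tab0 <- suppressWarnings(
    oneway_anova(c(1, 1, 2, 2), rep(c("A", "B"), each = 2)))
  expect_true(is.na(tab0$statistic[tab0$term == "group"]))

  # ANCOVA: a response that is exactly 2 x covariate leaves the group
  # factor nothing to explain
  set.seed(2)
  cov <- runif(30)
  g2 <- sample(rep(c("A", "B", "C"), each = 10))
  tab2 <- suppressWarnings(oneway_anova(2 * cov, g2, covariate = cov))
  expect_lt(tab2$sumsq[tab2$term == "group"] /
              tab2$sumsq[tab2$term == "covariate"], 1e-10)
  expect_equal(tab2$term[1], "covariate")  # covariate entered first
})

test_that("planned contrasts match the closed-form scores oracle", {
  lev <- c("CFA", "NFA", "FU+")
  set.seed(14)
  g <- rep(lev, each = 8)
  y <- rnorm(24, mean = rep(c(1, 2, 3), each = 8))

  spec_lin <- contrast_spec(lev, name = "linear_increase")
  res <- contrast_test(y, g, spec_lin)
  ora <- oracle_contrast_F(y, g, spec_lin$coefficients, lev)
  expect_gt(res$estimate, 0)
  expect_equal(res$F, ora$F, tolerance = 1e-9)
  expect_equal(res$estimate, ora$estimate, tolerance = 1e-9)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 21)

  # NFA-vs-rest coding on means (1, 4, 1): estimate 2*4 - 1 - 1 = 6
  y2 <- rep(c(1, 4, 1), each = 5)
  y2 <- y2 + rep(c(-0.1, 0, 0.1), 5)  # within-group spread, balanced
  spec_nfa <- contrast_spec(lev, name = "nfa_vs_rest")
  expect_equal(spec_nfa$coefficients, c(-1, 2, -1))
  res2 <- contrast_test(y2, rep(lev, each = 5), spec_nfa)
  ora2 <- oracle_contrast_F(y2, rep(lev, each = 5), c(-1, 2, -1), lev)
  expect_equal(res2$estimate, 6, tolerance = 1e-9)
  expect_equal(res2$F, ora2$F, tolerance = 1e-9)

  # equal group means: estimate and F are zero
  y3 <- rep(c(0.3, 0.7), times = 3)
  res3 <- contrast_test(y3, rep(lev, each = 2), spec_lin)
  expect_equal(res3$estimate, 0, tolerance = 1e-12)
  expect_equal(res3$F, 0, tolerance = 1e-12)

  expect_error(contrast_test(y, g, contrast_spec(c("A", "B", "C"),
                                                 c(-1, 0, 1))),
               "do not match")
  expect_error(contrast_spec(lev, c(1, 1, 1)), "sum to zero")
})

test_that("orthogonal single-df contrasts decompose the between-group SS", {
  lev <- c("CFA", "NFA", "FU+")
  set.seed(33)
  g <- rep(lev, each = 7)
  y <- rnorm(21, rep(c(0, 1, 3), each = 7))
  pol <- stats::contr.poly(3)
  ss_between <- oneway_anova(y, g)
  msw <- ss_between$meansq[ss_between$term == "Residuals"]
  ssb <- ss_between$sumsq[ss_between$term == "group"]
  ss_contrast <- vapply(1:2, function(k) {
    res <- contrast_test(y, g, contrast_spec(lev, pol[, k]))
    res$F * msw  # single-df SS = F * MSW
  }, numeric(1))
  expect_equal(sum(ss_contrast), ssb, tolerance = 1e-9)
})

test_that("contrast works with a covariate (adjusted means)", {
  lev <- c("CFA", "NFA", "FU+")
  set.seed(51)
  g <- rep(lev, each = 10)
  cov <- runif(30)
  y <- 2 * cov + rnorm(30, 0, 0.1)  # no true group effect
  res <- contrast_test(y, g, contrast_spec(lev, name = "linear_increase"),
                       covariate = cov)
  expect_equal(res$df2, 26)  # 30 - 3 groups - 1 covariate
  expect_gt(res$p, 0.01)
})

test_that("random-intercept ML fit agrees with lme4 and moment estimators", {
  skip_if_not_installed("lme4")
  set.seed(61)
  n_plants <- 12; m <- 6
  plant <- rep(paste0("pl", 1:n_plants), each = m)
  g <- rep(rep(c("CFA", "NFA", "FU+"), each = m * 2), length.out = n_plants * m)
  plant_eff <- rep(rnorm(n_plants, 0, 0.5), each = m)
  y <- rep(c(1, 2, 3), each = m * 4)[seq_along(plant)] + plant_eff +
    rnorm(n_plants * m, 0, 0.3)
  fit <- fit_random_intercept(y, g, plant)

  lfit <- lme4::lmer(y ~ 0 + g + (1 | plant), REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(fit$logLik_mixed, as.numeric(stats::logLik(lfit)),
               tolerance = 1e-6)
  expect_equal(fit$sigma2_plant, vc$vcov[vc$grp == "plant"],
               tolerance = 1e-4)
  expect_equal(fit$sigma2_resid, vc$vcov[vc$grp == "Residual"],
               tolerance = 1e-4)
  expect_equal(unname(sort(fit$fixed_effects)),
               unname(sort(lme4::fixef(lfit))), tolerance = 1e-5)

  # balanced single-group design: ML close to method-of-moments at large n
  set.seed(62)
  n_p2 <- 40; m2 <- 20
  plant2 <- rep(paste0("q", 1:n_p2), each = m2)
  y2 <- rep(rnorm(n_p2, 0, 0.7), each = m2) + rnorm(n_p2 * m2, 0, 0.4)
  fit2 <- fit_random_intercept(y2, rep("CFA", length(y2)), plant2)
  mom <- oracle_variance_components(y2, plant2)
  expect_equal(fit2$sigma2_resid, unname(mom["sigma2_resid"]),
               tolerance = 0.02)
  expect_equal(fit2$sigma2_plant, unname(mom["sigma2_plant"]),
               tolerance = 0.06)
})

test_that("random-intercept fit is location-invariant and validates design", {
  set.seed(71)
  plant <- rep(paste0("pl", 1:6), each = 4)
  g <- rep(c("CFA", "NFA", "FU+"), each = 8)
  y <- rnorm(24)
  f1 <- fit_random_intercept(y, g, plant)
  f2 <- fit_random_intercept(y + 100, g, plant)
  expect_equal(f1$sigma2_plant, f2$sigma2_plant, tolerance = 1e-6)
  expect_equal(f1$sigma2_resid, f2$sigma2_resid, tolerance = 1e-6)
  expect_equal(f1$treatment_chisq, f2$treatment_chisq, tolerance = 1e-5)

  expect_error(fit_random_intercept(y, g, rep(c("a", "b"), 12)),
               "fewer plants")
  # a plant spanning two treatments violates nesting
  bad_plant <- plant; bad_plant[9] <- "pl1"
  expect_error(fit_random_intercept(y, g, bad_plant), "nested")
})
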