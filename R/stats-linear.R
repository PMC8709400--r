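#' One-way ANOVA / ANCOVA
#'
#' Least-squares one-way analysis of variance, optionally with a covariate
#' (ANCOVA) entered before the group factor, as when petal area is used to
#' adjust reflectance-derived responses. Sums of squares are sequential, so
#' the group test is conditional on the covariate.
#'
#' @param y Numeric response.
#' @param groups Group labels (2+ groups).
#' @param covariate Optional numeric covariate.
#' @return data.frame with columns `term`, `df`, `sumsq`, `meansq`,
#'   `statistic` (F), `p`; residual row included. F is `NA` when the
#'   residual mean square is zero (degenerate 0/0 case).
#' @export
oneway_anova <- function(y, groups, covariate = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  dat <- data.frame(y = y, g = groups)
  if (is.null(covariate)) {
    fit <- stats::lm(y ~ g, data = dat)
  } else {
    dat$cov <- covariate
    fit <- stats::lm(y ~ cov + g, data = dat)
  }
  if (stats::df.residual(fit) <= 0L) {
    stop("zero residual degrees of freedom", call. = FALSE)
  }
  a <- stats::anova(fit)
  ms_resid <- a["Residuals", "Mean Sq"]
  out <- data.frame(
    term = rownames(a),
    df = a$Df,
    sumsq = a$`Sum Sq`,
    meansq = a$`Mean Sq`,
    statistic = a$`F value`,
    p = a$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  out$term[out$term == "g"] <- "group"
  out$term[out$term == "cov"] <- "covariate"
  # degenerate 0/0: an exact fit leaves no residual variation to test against
  if (!is.finite(ms_resid) || ms_resid <= 1e-12 * stats::var(y)) {
    out$statistic[out$term != "Residuals"] <- NA_real_
    out$p[out$term != "Residuals"] <- NA_real_
  }
  attr(out, "fit") <- fit
  out
}

contrast_presets <- function(levels) {
  k <- length(levels)
  poly1 <- stats::contr.poly(k)[, 1]
  presets <- list(linear_increase = poly1,
                  linear_decrease = -poly1)
  if (identical(sort(levels), sort(c("CFA", "NFA", "FU+")))) {
    nfa <- ifelse(levels == "NFA", 2, -1)
    ctl <- ifelse(levels == "CFA", 2, -1)
    presets$nfa_vs_rest <- nfa
    presets$control_vs_rest <- ctl
  }
  presets
}

#' A-priori contrast specification
#'
#' Either a named preset or explicit coefficients over the ordered
#' treatment levels. Presets: `linear_increase` / `linear_decrease`
#' (orthogonal polynomial linear scores over equally spaced levels, the
#' coding behind a "linear trend with ozone dose" hypothesis);
#' `nfa_vs_rest` (CFA = -1, NFA = 2, FU+ = -1, the treatment-means coding
#' for a hump at ambient ozone); `control_vs_rest` (CFA = 2, NFA = -1,
#' FU+ = -1, control different from both ozone treatments).
#'
#' @param levels Ordered character vector of treatment levels.
#' @param coefficients Numeric contrast coefficients summing to zero, one
#'   per level; omit when `name` is a preset.
#' @param name Preset name or a free-text label for explicit coefficients.
#' @return Object of class `contrast_spec`.
#' @export
contrast_spec <- function(levels, coefficients = NULL, name = "custom") {
  levels <- as.character(levels)
  if (is.null(coefficients)) {
    presets <- contrast_presets(levels)
    if (!name %in% names(presets)) {
      stop(sprintf("unknown preset '%s' for levels (%s); available: %s",
                   name, paste(levels, collapse = ", "),
                   paste(names(presets), collapse = ", ")), call. = FALSE)
    }
    coefficients <- presets[[name]]
  }
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != length(levels)) {
    stop("one coefficient per level required", call. = FALSE)
  }
  if (abs(sum(coefficients)) > 1e-10 || all(coefficients == 0)) {
    stop("contrast coefficients must sum to zero and not all be zero",
         call. = FALSE)
  }
  structure(list(levels = levels, coefficients = coefficients, name = name),
            class = "contrast_spec")
}

#' Single-degree-of-freedom planned contrast test
#'
#' Tests H0: sum_g c_g mu_g = 0 within the one-way (or covariate-adjusted)
#' linear model, returning the contrast estimate and its F statistic on
#' (1, df_residual) degrees of freedom.
#'
#' @param y Numeric response.
#' @param groups Group labels; must match `spec$levels` exactly as a set.
#' @param spec A [contrast_spec()].
#' @param covariate Optional numeric covariate (entered with the groups in
#'   the model; the contrast applies to adjusted group means).
#' @return Object of class `contrast_result`: `name`, `estimate`, `F`,
#'   `df1` (= 1), `df2`, `p`.
#' @export
contrast_test <- function(y, groups, spec, covariate = NULL) {
  stopifnot(inherits(spec, "contrast_spec"))
  groups <- as.character(groups)
  if (!setequal(unique(groups), spec$levels)) {
    stop(sprintf("group labels (%s) do not match contrast levels (%s)",
                 paste(sort(unique(groups)), collapse = ", "),
                 paste(sort(spec$levels), collapse = ", ")), call. = FALSE)
  }
  g <- factor(groups, levels = spec$levels)
  dat <- data.frame(y = y, g = g)
  if (is.null(covariate)) {
    fit <- stats::lm(y ~ 0 + g, data = dat)
    L <- matrix(spec$coefficients, nrow = 1)
  } else {
    dat$cov <- covariate
    fit <- stats::lm(y ~ 0 + g + cov, data = dat)
    L <- matrix(c(spec$coefficients, 0), nrow = 1)
  }
  est <- as.numeric(L %*% stats::coef(fit))
  lh <- car::linearHypothesis(fit, L, rhs = 0)
  Fv <- lh$F[2]
  df2 <- lh$Res.Df[2]
  structure(list(name = spec$name, estimate = est, F = Fv, df1 = 1,
                 df2 = df2, p = lh$`Pr(>F)`[2],
                 coefficients = stats::setNames(spec$coefficients,
                                                spec$levels)),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast '%s': estimate = %.4g, F(%d, %d) = %.4g, p = %.4g\n",
              x$name, x$estimate, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

# profile log-likelihood machinery for the one-random-intercept model:
# y = X beta + b[plant] + e,  b ~ N(0, lambda sigma2),  e ~ N(0, sigma2).
# For fixed lambda the covariance is sigma2 (I + lambda Z Z'), block
# diagonal by plant, so solves and determinants are closed-form per block.
ri_profile <- function(lambda, y, X, plant) {
  n <- length(y)
  idx <- split(seq_len(n), plant)
  # whiten y and X blockwise: V0^{-1} = I - (lambda/(1+m lambda)) J per block
  apply_vinv <- function(M) {
    M <- as.matrix(M)
    out <- M
    for (ii in idx) {
      m <- length(ii)
      w <- lambda / (1 + m * lambda)
      block <- M[ii, , drop = FALSE]
      out[ii, ] <- block - w * matrix(colSums(block), nrow = m,
                                      ncol = ncol(M), byrow = TRUE)
    }
    out
  }
  Vy <- apply_vinv(y)
  VX <- apply_vinv(X)
  XtVX <- crossprod(X, VX)
  beta <- solve(XtVX, crossprod(X, Vy))
  r <- y - X %*% beta
  rss <- sum(r * apply_vinv(r))
  sigma2 <- rss / n
  logdet <- sum(vapply(idx, function(ii) log1p(length(ii) * lambda),
                       numeric(1)))
  ll <- -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2
  list(logLik = ll, beta = beta, sigma2 = sigma2, lambda = lambda)
}

ri_ml_fit <- function(y, X, plant, tol = 1e-8) {
  obj <- function(loglam) -ri_profile(exp(loglam), y, X, plant)$logLik
  opt <- stats::optimize(obj, interval = c(log(1e-10), log(1e6)), tol = tol)
  best <- ri_profile(exp(opt$minimum), y, X, plant)
  at_zero <- ri_profile(0, y, X, plant)
  if (at_zero$logLik >= best$logLik) best <- at_zero
  best
}

#' Random-intercept model fit and AIC model choice
#'
#' Fits the mixed model `y = treatment effects + plant intercept + noise`
#' by maximum likelihood, profiling the likelihood over the variance ratio
#' `sigma2_plant / sigma2_resid` with a one-dimensional search (tolerance
#' 1e-8 on the log-ratio scale), and compares it by AIC with the fixed-only
#' least-squares model. ML rather than REML is used throughout so the AICs
#' of models with different fixed effects are comparable. A likelihood-ratio
#' chi-square for the treatment effect (mixed model with vs without the
#' treatment term) is reported alongside.
#'
#' @param y Numeric response.
#' @param groups_fixed Treatment labels (the fixed effect).
#' @param plant_ids Plant identifiers; each plant must belong to exactly one
#'   treatment, and there must be at least as many plants as treatments.
#' @return Object of class `random_intercept_fit`: `fixed_effects` (named
#'   treatment means from the mixed fit), `sigma2_plant`, `sigma2_resid`,
#'   `logLik_mixed`, `logLik_fixed`, `aic_mixed`, `aic_fixed`,
#'   `chosen` (`"mixed"` or `"fixed"`), `treatment_chisq`, `treatment_df`,
#'   `treatment_p`.
#' @export
fit_random_intercept <- function(y, groups_fixed, plant_ids) {
  g <- factor(groups_fixed)
  plant <- factor(plant_ids)
  if (nlevels(plant) < nlevels(g)) {
    stop("fewer plants than treatments", call. = FALSE)
  }
  cross <- table(plant, g)
  if (any(rowSums(cross > 0) > 1L)) {
    stop("each plant must belong to exactly one treatment (nested design)",
         call. = FALSE)
  }
  n <- length(y)
  X <- if (nlevels(g) == 1L) matrix(1, n, 1,
                                    dimnames = list(NULL, levels(g)))
       else stats::model.matrix(~ 0 + g)
  X0 <- matrix(1, n, 1)

  mixed <- ri_ml_fit(y, X, plant)
  mixed_null <- ri_ml_fit(y, X0, plant)

  # fixed-only ML fit (ordinary least squares)
  fit_lm <- stats::lm.fit(X, y)
  rss <- sum(fit_lm$residuals^2)
  ll_fixed <- -n / 2 * (log(2 * pi * rss / n) + 1)

  p <- ncol(X)
  aic_mixed <- 2 * (p + 2) - 2 * mixed$logLik    # + sigma2_plant, sigma2_resid
  aic_fixed <- 2 * (p + 1) - 2 * ll_fixed        # + sigma2_resid

  chisq <- 2 * (mixed$logLik - mixed_null$logLik)
  df_t <- p - 1
  structure(list(
    fixed_effects = stats::setNames(as.numeric(mixed$beta), levels(g)),
    sigma2_plant = mixed$lambda * mixed$sigma2,
    sigma2_resid = mixed$sigma2,
    logLik_mixed = mixed$logLik,
    logLik_fixed = ll_fixed,
    aic_mixed = aic_mixed,
    aic_fixed = aic_fixed,
    chosen = if (aic_mixed < aic_fixed) "mixed" else "fixed",
    treatment_chisq = max(chisq, 0),
    treatment_df = df_t,
    treatment_p = stats::pchisq(max(chisq, 0), df_t, lower.tail = FALSE)
  ), class = "random_intercept_fit")
}

#' @export
print.random_intercept_fit <- function(x, ...) {
  cat(sprintf(
    "random-intercept fit (ML): sigma2_plant = %.4g, sigma2_resid = %.4g\n",
    x$sigma2_plant, x$sigma2_resid))
  cat(sprintf("AIC mixed = %.3f, AIC fixed-only = %.3f -> chosen: %s\n",
              x$aic_mixed, x$aic_fixed, x$chosen))
  cat(sprintf("treatment LRT: chisq(%d) = %.4g, p = %.4g\n",
              x$treatment_df, x$treatment_chisq, x$treatment_p))
  invisible(x)
}
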