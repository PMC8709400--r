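#' Bray-Curtis dissimilarity of spectra
#'
#' Builds a petals x petals Bray-Curtis dissimilarity matrix from a petals
#' x wavelengths reflectance matrix. A square-root transform is applied
#' elementwise first (the default) to keep high-reflectance wavelengths
#' from dominating the dissimilarities; `transform = "none"` uses the raw
#' values.
#'
#' @param x Non-negative numeric matrix, rows = petals (rownames used as
#'   labels), columns = wavelengths.
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return Object of class `dissimilarity_matrix`: `labels` and `D`, a
#'   symmetric matrix with zero diagonal and entries in [0, 1].
#' @export
bray_curtis <- function(x, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  x <- as.matrix(x)
  if (any(x < 0)) stop("reflectance matrix must be non-negative", call. = FALSE)
  zero <- rowSums(x) == 0
  if (any(zero)) {
    lab <- rownames(x)[zero]
    if (is.null(lab)) lab <- which(zero)
    stop(sprintf("all-zero spectrum for petal(s): %s",
                 paste(lab, collapse = ", ")), call. = FALSE)
  }
  if (transform == "sqrt") x <- sqrt(x)
  D <- as.matrix(vegan::vegdist(x, method = "bray"))
  labels <- rownames(x)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(x)))
  dimnames(D) <- list(labels, labels)
  structure(list(labels = labels, D = D), class = "dissimilarity_matrix")
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  a <- length(unique(groups))
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  df1 <- a - 1
  df2 <- n - a
  list(F = (ss_between / df1) / (ss_within / df2),
       df_between = df1, df_within = df2,
       ss_between = ss_between, ss_within = ss_within,
       ss_total = ss_total)
}

enumerate_group_assignments <- function(groups) {
  # all distinct arrangements of the multiset of labels
  rec <- function(labels, positions) {
    if (length(unique(labels)) == 1L) {
      return(list(rep(labels[1L], length(labels))))
    }
    lab1 <- sort(unique(labels))[1L]
    k <- sum(labels == lab1)
    rest_labels <- labels[labels != lab1]
    idx_sets <- utils::combn(length(labels), k, simplify = FALSE)
    out <- list()
    for (idx in idx_sets) {
      sub <- rec(rest_labels, seq_len(length(labels) - k))
      for (s in sub) {
        v <- character(length(labels))
        v[idx] <- lab1
        v[-idx] <- s
        out[[length(out) + 1L]] <- v
      }
    }
    out
  }
  rec(as.character(groups), seq_along(groups))
}

#' Permutational multivariate ANOVA (one factor)
#'
#' Partitions the sum of squared dissimilarities into between- and
#' within-group components and forms the pseudo-F statistic
#' `(SS_B / (a-1)) / (SS_W / (n-a))`. Significance comes from permuting
#' group labels: `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`. With
#' `exhaustive = TRUE` every distinct label arrangement is evaluated
#' instead and `p = #{F >= F_obs} / N` over all `N` arrangements (the
#' observed arrangement counting itself).
#'
#' @param D A [bray_curtis()] result or any `dissimilarity_matrix`.
#' @param groups Group labels, one per row of `D`, at least two groups.
#' @param n_perm Number of random permutations (default 9999).
#' @param seed Integer seed for the permutation stream (required for the
#'   random path so results are reproducible).
#' @param exhaustive Enumerate all distinct arrangements instead of
#'   sampling (feasible for small designs only).
#' @return Object of class `permanova_result`: `pseudo_F`, `df_between`,
#'   `df_within`, `ss_between`, `ss_within`, `ss_total`, `p_perm`,
#'   `n_permutations`, `seed`, `exhaustive`.
#' @export
permanova <- function(D, groups, n_perm = 9999, seed = NULL,
                      exhaustive = FALSE) {
  stopifnot(inherits(D, "dissimilarity_matrix"))
  groups <- as.character(groups)
  n <- length(groups)
  if (n != nrow(D$D)) stop("groups length must match D", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least two groups", call. = FALSE)
  if (n - length(sizes) <= 0L) {
    stop("no within-group degrees of freedom (all groups are singletons)",
         call. = FALSE)
  }
  d2 <- D$D^2
  obs <- permanova_f(d2, groups)
  eps <- 1e-12 * max(1, abs(obs$F))
  if (exhaustive) {
    arrangements <- enumerate_group_assignments(groups)
    fs <- vapply(arrangements, function(g) permanova_f(d2, g)$F, numeric(1))
    p <- sum(fs >= obs$F - eps) / length(fs)
    n_perm_used <- length(fs)
  } else {
    if (is.null(seed)) stop("seed is required for random permutations",
                            call. = FALSE)
    set.seed(as.integer(seed))
    count <- 0L
    for (i in seq_len(n_perm)) {
      fp <- permanova_f(d2, groups[sample.int(n)])$F
      if (fp >= obs$F - eps) count <- count + 1L
    }
    p <- (1 + count) / (1 + n_perm)
    n_perm_used <- n_perm
  }
  structure(list(pseudo_F = obs$F, df_between = obs$df_between,
                 df_within = obs$df_within, ss_between = obs$ss_between,
                 ss_within = obs$ss_within, ss_total = obs$ss_total,
                 p_perm = p, n_permutations = n_perm_used,
                 seed = if (exhaustive) NA_integer_ else as.integer(seed),
                 exhaustive = exhaustive),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F(%d, %d) = %.4g, p = %.4g (%s, %d permutations)\n",
    x$df_between, x$df_within, x$pseudo_F, x$p_perm,
    if (x$exhaustive) "exhaustive" else "sampled", x$n_permutations
  ))
  invisible(x)
}
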