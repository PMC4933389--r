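# Permutational inference linking biological predictors to genetic
# response variables across species. With as few observations as species
# (here seven), classical F-table p-values are fragile; the whole-model
# pseudo-F is therefore referenced against unrestricted permutations of
# the raw response values. Model choice across predictor subsets uses
# AIC = n*ln(RSS/n) + 2K with K counting all fitted parameters including
# the intercept; the subset search is exhaustive (exact and reproducible
# for the small predictor registries this is meant for).

#' Pairwise collinearity screen for a predictor matrix
#'
#' Pearson correlations between all predictor pairs, with a warning for
#' any pair above the threshold (the draftsman-plot check done by eye in
#' field practice, made explicit).
#'
#' @param predictors numeric matrix or data.frame with named columns.
#' @param threshold absolute correlation above which a pair is flagged.
#' @return list with `correlations` (matrix) and `flagged` (data.frame of
#'   offending pairs, possibly empty).
#' @export
check_collinearity <- function(predictors, threshold = 0.95) {
  X <- as.matrix(predictors)
  if (ncol(X) < 2) stop("need at least two predictors")
  const <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(const))
    warning("degenerate predictor(s) with zero variance: ",
            paste(colnames(X)[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(X))
  up <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = colnames(X)[up[, 1]],
                        var2 = colnames(X)[up[, 2]],
                        r = r[up])
  if (nrow(flagged))
    warning("collinear predictor pair(s) above |r| = ", threshold, ": ",
            paste(flagged$var1, flagged$var2, sep = "~", collapse = ", "))
  list(correlations = r, flagged = flagged)
}

#' @keywords internal
.ols <- function(y, X) {
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xi, y)
  if (fit$rank < ncol(Xi)) stop("rank error: singular design matrix")
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  list(coef = fit$coefficients, rss = rss, tss = tss,
       r2 = if (tss > 0) 1 - rss / tss else NA_real_)
}

#' Permutational multiple regression
#'
#' Least-squares fit of a numeric response on a predictor matrix, with the
#' whole-model pseudo-F tested by unrestricted permutation of the response
#' values. The permutation machinery affects only the p-value: R2, RSS and
#' the coefficients are the closed-form OLS quantities.
#'
#' @param response numeric vector (one value per species/observation).
#' @param predictors numeric matrix or data.frame with named columns.
#' @param n_perm number of response permutations.
#' @param seed optional RNG seed.
#' @param log10_response apply log10 to the response before fitting
#'   (the convention for haplotype-diversity responses).
#' @return object of class `perm_regression`: `coefficients`, `r2`, `rss`,
#'   `aic`, `pseudo_f`, `p_perm`, `n_perm`, `selected` (predictor names),
#'   `transform_log`.
#' @export
permutational_regression <- function(response, predictors, n_perm = 9999,
                                     seed = NULL, log10_response = FALSE) {
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- if (log10_response) log10(response) else response
  n <- length(y)
  k <- ncol(X)
  if (n < k + 2)
    stop("insufficient sample: need n >= number of predictors + 2")
  fit <- .ols(y, X)
  df2 <- n - k - 1
  f_of <- function(rss, tss) ((tss - rss) / k) / (rss / df2)
  f_obs <- if (fit$rss == 0) Inf else f_of(fit$rss, fit$tss)
  .set_seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pf <- .ols(sample(y), X)
    f_b <- if (pf$rss == 0) Inf else f_of(pf$rss, pf$tss)
    if (f_b >= f_obs - 1e-12) hits <- hits + 1L
  }
  K <- k + 1
  aic <- n * log(max(fit$rss, fit$tss * 1e-12, .Machine$double.xmin) / n) +
    2 * K
  structure(list(coefficients = fit$coef, r2 = fit$r2, rss = fit$rss,
                 aic = aic, pseudo_f = f_obs, p_perm = .perm_p(hits, n_perm),
                 n_perm = n_perm, selected = colnames(X),
                 transform_log = log10_response, n = n),
            class = "perm_regression")
}

#' @export
print.perm_regression <- function(x, ...) {
  cat(sprintf("Permutational regression (%s): R2 = %.4f, F = %.3f, P = %.4g (%d perms)\n",
              paste(x$selected, collapse = " + "), x$r2, x$pseudo_f,
              x$p_perm, x$n_perm))
  invisible(x)
}

#' Exhaustive AIC subset selection with a permutation test of the winner
#'
#' Evaluates every non-empty predictor subset by
#' AIC = n*ln(RSS/n) + 2K (K = predictors + intercept), then runs
#' [permutational_regression()] on the minimizing subset. Ties go to the
#' smaller subset. Setting `penalty = 0` reduces the criterion to max-R2
#' selection, which is used as an internal consistency check.
#'
#' @inheritParams permutational_regression
#' @param penalty the per-parameter penalty (2 for AIC).
#' @return list with `best` (a `perm_regression`), `table` (data.frame of
#'   all subsets with K, RSS, R2, AIC, sorted by AIC).
#' @export
aic_subset_search <- function(response, predictors, n_perm = 999,
                              seed = NULL, log10_response = FALSE,
                              penalty = 2) {
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) > 15) stop("exhaustive search limited to <= 15 predictors")
  y <- if (log10_response) log10(response) else response
  n <- length(y)
  vars <- colnames(X)
  rows <- list()
  for (k in seq_along(vars)) {
    if (n < k + 2) next  # unfittable subset size
    for (sub in utils::combn(vars, k, simplify = FALSE)) {
      fit <- try(.ols(y, X[, sub, drop = FALSE]), silent = TRUE)
      if (inherits(fit, "try-error")) next
      K <- k + 1
      # exact fits are floored at a common tiny RSS so ties resolve to the
      # smaller subset instead of machine-epsilon residual noise
      aic <- n * log(max(fit$rss, fit$tss * 1e-12,
                         .Machine$double.xmin) / n) + penalty * K
      rows[[length(rows) + 1L]] <-
        data.frame(subset = paste(sub, collapse = "+"), K = K,
                   rss = fit$rss, r2 = fit$r2, aic = aic)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aic, tab$K), ]
  rownames(tab) <- NULL
  best_sub <- strsplit(tab$subset[1], "+", fixed = TRUE)[[1]]
  best <- permutational_regression(response, X[, best_sub, drop = FALSE],
                                   n_perm = n_perm, seed = seed,
                                   log10_response = log10_response)
  list(best = best, table = tab)
}

#' Levene-type heteroscedasticity screen
#'
#' Classical grouped-replicate variance checks (Cochran's C) need several
#' observations per cell, which a species-level table does not have; this
#' screen instead runs the Levene construction — a one-way permutational
#' ANOVA on absolute deviations from group medians — across the levels of
#' a categorical split, flagging responses whose spread differs by group.
#'
#' @param response numeric vector.
#' @param group categorical vector of the same length.
#' @param n_perm label permutations.
#' @param seed optional RNG seed.
#' @return list with `statistic` (the pseudo-F on absolute deviations),
#'   `p_perm`, and `heteroscedastic` (TRUE when p_perm < alpha).
#' @param alpha flag level for the `heteroscedastic` field.
#' @export
check_heteroscedasticity <- function(response, group, n_perm = 999,
                                     seed = NULL, alpha = 0.05) {
  f <- droplevels(as.factor(group))
  if (nlevels(f) < 2) stop("factor error: need at least two levels")
  med <- tapply(response, f, stats::median)
  z <- abs(response - med[f])
  a <- permutational_anova(z, f, n_perm = n_perm, seed = seed)
  list(statistic = a$pseudo_f, p_perm = a$p_perm,
       heteroscedastic = a$p_perm < alpha)
}

#' Permutational one-way ANOVA
#'
#' One-way pseudo-F on Euclidean (squared-difference) partitioning of a
#' numeric response across the levels of a categorical trait, with the
#' p-value from permutation of the group labels.
#'
#' @param response numeric vector.
#' @param factor categorical vector (coerced to factor) of the same length.
#' @param n_perm label permutations.
#' @param seed optional RNG seed.
#' @return list of class `perm_anova`: `pseudo_f`, `p_perm`, `df`.
#' @export
permutational_anova <- function(response, factor, n_perm = 9999,
                                seed = NULL) {
  f <- droplevels(as.factor(factor))
  g <- nlevels(f)
  if (g < 2) stop("factor error: need at least two levels")
  n <- length(response)
  f_of <- function(y, f) {
    gm <- tapply(y, f, mean)
    ng <- tabulate(f)
    ssb <- sum(ng * (gm - mean(y))^2)
    ssw <- sum((y - gm[f])^2)
    if (ssw == 0) return(Inf)
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  f_obs <- f_of(response, f)
  .set_seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm))
    if (f_of(response, sample(f)) >= f_obs - 1e-12) hits <- hits + 1L
  list(pseudo_f = f_obs, p_perm = .perm_p(hits, n_perm),
       df = c(g - 1, n - g))
}
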