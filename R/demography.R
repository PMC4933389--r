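# Demographic-history inference from a single population sample: mismatch
# distributions, sudden-expansion model fits (demographic and spatial) with
# parametric-bootstrap confidence intervals, the raggedness index, and the
# Tajima's D / Fu's Fs / R2 neutrality tests with coalescent nulls.
#
# Both expected mismatch curves are exact closed forms. The coalescence
# time T of a sequence pair (in pair-mutational units, so differences are
# Poisson(T)) has a piecewise-exponential density; mixing Poisson classes
# over it gives incomplete-gamma expressions evaluated with pgamma:
#   int_0^tau e^{-a s} s^j / j! ds = a^{-(j+1)} P(j+1, a*tau)
# which keeps every term finite on the log scale even for tiny theta0.

#' Mismatch distribution of pairwise differences
#'
#' Histogram over all C(n,2) sequence pairs of raw nucleotide differences,
#' normalized to relative frequencies over classes 0..d.
#'
#' @param spec a `hap_spectrum`.
#' @param population population label or `"TOT"` (default) for the pooled
#'   sample, which is how whole-species demographic history is assessed.
#' @return object of class `mismatch_dist`: list with `x` (relative
#'   frequencies over classes `0:d`), `d`, `n_pairs` and `n`.
#' @export
mismatch <- function(spec, population = "TOT") {
  cnt <- .pop_counts(spec, population)
  n <- sum(cnt)
  if (n < 2) stop("insufficient sample: need n >= 2 sequences")
  keep <- cnt > 0
  cnt <- cnt[keep]
  D <- spec$diffs[keep, keep, drop = FALSE]
  dmax <- if (length(cnt) > 1L) max(D) else 0L
  counts <- numeric(dmax + 1L)
  counts[1L] <- sum(choose(cnt, 2))            # identical-haplotype pairs
  if (length(cnt) > 1L)
    for (i in 1:(length(cnt) - 1)) for (j in (i + 1):length(cnt))
      counts[D[i, j] + 1L] <- counts[D[i, j] + 1L] + cnt[i] * cnt[j]
  n_pairs <- choose(n, 2)
  structure(list(x = counts / n_pairs, d = dmax, n_pairs = n_pairs, n = n),
            class = "mismatch_dist")
}

#' Build a mismatch distribution from raw pair counts
#'
#' Constructor for workflows that already hold a pairwise-difference
#' histogram (e.g. straight from [simulate_coalescent_stats()]).
#'
#' @param counts numeric vector of pair counts over difference classes
#'   `0, 1, ..., d`.
#' @param n the sample size the pairs came from.
#' @return a `mismatch_dist`.
#' @export
mismatch_from_counts <- function(counts, n) {
  structure(list(x = counts / sum(counts), d = length(counts) - 1L,
                 n_pairs = choose(n, 2), n = n),
            class = "mismatch_dist")
}

#' @keywords internal
.mismatch_from_counts <- mismatch_from_counts

#' Expected mismatch distribution under sudden demographic expansion
#'
#' Two-epoch model (Rogers & Harpending 1992): a population at mutation
#' parameter `theta1` today changed instantaneously from `theta0` at
#' pair-mutational time `tau` in the past. At `tau = 0` the curve reduces
#' to the stationary geometric-like form
#' \eqn{\hat F_j(\theta) = \theta^j/(1+\theta)^{j+1}}.
#'
#' @param j vector of difference classes (integers >= 0).
#' @param tau expansion age in pair-mutational units.
#' @param theta0,theta1 pre- and post-expansion mutation parameters.
#' @return expected relative frequencies for the classes in `j`.
#' @export
expected_mismatch_demographic <- function(j, tau, theta0, theta1) {
  a <- 1 + 1 / theta1
  b <- 1 + 1 / theta0
  piece1 <- if (tau > 0)
    exp(-(j + 1) * log(a) + stats::pgamma(a * tau, j + 1, log.p = TRUE)) / theta1
  else 0
  piece2 <- exp(-tau / theta1 + tau / theta0 - (j + 1) * log(b) +
                stats::pgamma(b * tau, j + 1, lower.tail = FALSE,
                              log.p = TRUE)) / theta0
  piece1 + piece2
}

#' Expected mismatch distribution under spatial (range) expansion
#'
#' Infinite-island colonization model (Excoffier 2004): the sampled deme
#' has mutation parameter `theta` and exchanges migrants at scaled rate `M`;
#' at pair-mutational time `tau` in the past all lineages trace back to one
#' ancestral deme of the same size. As `M` grows the curve converges to the
#' demographic model with an effectively infinite post-expansion size.
#'
#' @param j vector of difference classes.
#' @param tau expansion age in pair-mutational units.
#' @param theta deme mutation parameter.
#' @param M scaled migration rate (2Nm).
#' @return expected relative frequencies for the classes in `j`.
#' @export
expected_mismatch_spatial <- function(j, tau, theta, M) {
  a <- 1 + (1 + M) / theta
  b <- 1 + 1 / theta
  piece1 <- if (tau > 0)
    exp(-(j + 1) * log(a) + stats::pgamma(a * tau, j + 1, log.p = TRUE)) / theta
  else 0
  # probability the pair has not coalesced by tau: either separated into
  # distinct demes (never to re-meet before tau) or still together unevented
  e <- exp(-(1 + M) * tau / theta)
  A <- M / (1 + M) * (1 - e) + e
  piece2 <- A * exp(tau / theta - (j + 1) * log(b) +
                    stats::pgamma(b * tau, j + 1, lower.tail = FALSE,
                                  log.p = TRUE)) / theta
  piece1 + piece2
}

#' @keywords internal
.fit_mismatch <- function(x, model, starts, lower, upper,
                          weighted = FALSE, n_pairs = NULL) {
  j <- seq_along(x) - 1
  fj <- if (model == "demographic")
    function(p) expected_mismatch_demographic(j, p[1], p[2], p[3])
  else
    function(p) expected_mismatch_spatial(j, p[1], p[2], p[3])
  obj <- function(p) {
    e <- fj(p)
    if (any(!is.finite(e))) return(1e10)
    if (weighted) {
      # binomial-style variance weights on the class frequencies
      w <- 1 / pmax(e * (1 - e) / n_pairs, 1e-8)
      sum(w * (x - e)^2)
    } else {
      sum((x - e)^2)
    }
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    ft <- try(stats::nlminb(starts[s, ], obj, lower = lower, upper = upper),
              silent = TRUE)
    if (inherits(ft, "try-error")) next
    if (is.null(best) || ft$objective < best$objective) best <- ft
  }
  if (is.null(best))
    stop("optimizer error: mismatch fit failed from all starting points")
  best
}

#' Fit the sudden demographic-expansion model to a mismatch distribution
#'
#' Least-squares fit of the two-epoch expected curve
#' ([expected_mismatch_demographic()]) over the observed difference
#' classes, with an optional parametric bootstrap for the tau confidence
#' interval: coalescent samples of the same size are simulated under the
#' fitted model, refitted, and the empirical percentiles taken.
#'
#' @param md a `mismatch_dist`.
#' @param n_boot parametric-bootstrap replicates for the tau CI (0 skips).
#' @param seed optional RNG seed.
#' @param ci_level confidence level for the percentile interval.
#' @param theta1_max upper bound for the post-expansion parameter
#'   (effectively infinite size; stabilizes the optimizer).
#' @param weighted use binomial-style variance weights on the class
#'   frequencies instead of the plain (default) sum of squared deviations.
#' @return object of class `expansion_fit`: `model`, `tau`, `theta0`,
#'   `theta1`, `ssd`, `tau_ci`, `boot_tau`, `converged`.
#' @export
fit_demographic_expansion <- function(md, n_boot = 1000, seed = NULL,
                                      ci_level = 0.95, theta1_max = 99999,
                                      weighted = FALSE) {
  stopifnot(inherits(md, "mismatch_dist"))
  if (md$d < 1) warning("boundary fit: flat mismatch distribution (d < 1)")
  x <- md$x
  m1 <- sum((seq_along(x) - 1) * x)
  starts <- rbind(c(max(m1, 0.5), 0.1, 1000),
                  c(max(m1, 0.5), 1.0, 100),
                  c(max(m1 / 2, 0.25), 0.5, theta1_max / 10),
                  c(1, 0.01, 1000))
  lower <- c(0, 1e-6, 1e-6)
  upper <- c(20 * (md$d + 1), 100, theta1_max)
  ft <- .fit_mismatch(x, "demographic", starts, lower, upper,
                      weighted = weighted, n_pairs = md$n_pairs)
  par <- ft$par
  .set_seed(seed)
  boot_tau <- numeric(0)
  if (n_boot > 0) {
    boot_tau <- vapply(seq_len(n_boot), function(b) {
      sim <- .simulate_under_fit("demographic", par, md$n)
      bx <- .mismatch_from_counts(sim, md$n)$x
      bstart <- rbind(par, starts[1, ])
      bf <- try(.fit_mismatch(bx, "demographic", bstart, lower, upper,
                              weighted = weighted, n_pairs = md$n_pairs),
                silent = TRUE)
      if (inherits(bf, "try-error")) NA_real_ else bf$par[1]
    }, numeric(1))
    boot_tau <- boot_tau[!is.na(boot_tau)]
  }
  al <- (1 - ci_level) / 2
  ci <- if (length(boot_tau))
    stats::quantile(boot_tau, c(al, 1 - al), names = FALSE)
  else c(NA_real_, NA_real_)
  structure(list(model = "demographic", tau = par[1], theta0 = par[2],
                 theta1 = par[3], ssd = ft$objective,
                 tau_ci = ci, boot_tau = boot_tau,
                 converged = ft$convergence == 0, n = md$n),
            class = "expansion_fit")
}

#' Fit the spatial (range) expansion model to a mismatch distribution
#'
#' Same least-squares machinery as [fit_demographic_expansion()] but with
#' the infinite-island expected curve ([expected_mismatch_spatial()]) and
#' parameters tau, theta, M.
#'
#' @inheritParams fit_demographic_expansion
#' @return an `expansion_fit` with `model = "spatial"` and fields `tau`,
#'   `theta`, `M`.
#' @export
fit_spatial_expansion <- function(md, n_boot = 1000, seed = NULL,
                                  ci_level = 0.95, weighted = FALSE) {
  stopifnot(inherits(md, "mismatch_dist"))
  if (md$d < 1) warning("boundary fit: flat mismatch distribution (d < 1)")
  x <- md$x
  m1 <- sum((seq_along(x) - 1) * x)
  starts <- rbind(c(max(m1, 0.5), 1, 1),
                  c(max(m1, 0.5), 0.5, 50),
                  c(max(m1 / 2, 0.25), 2, 10),
                  c(1, 0.1, 1))
  lower <- c(0, 1e-4, 1e-4)
  upper <- c(20 * (md$d + 1), 100, 1e5)
  ft <- .fit_mismatch(x, "spatial", starts, lower, upper,
                      weighted = weighted, n_pairs = md$n_pairs)
  par <- ft$par
  .set_seed(seed)
  boot_tau <- numeric(0)
  if (n_boot > 0) {
    boot_tau <- vapply(seq_len(n_boot), function(b) {
      sim <- .simulate_under_fit("spatial", par, md$n)
      bx <- .mismatch_from_counts(sim, md$n)$x
      bstart <- rbind(par, starts[1, ])
      bf <- try(.fit_mismatch(bx, "spatial", bstart, lower, upper,
                              weighted = weighted, n_pairs = md$n_pairs),
                silent = TRUE)
      if (inherits(bf, "try-error")) NA_real_ else bf$par[1]
    }, numeric(1))
    boot_tau <- boot_tau[!is.na(boot_tau)]
  }
  al <- (1 - ci_level) / 2
  ci <- if (length(boot_tau))
    stats::quantile(boot_tau, c(al, 1 - al), names = FALSE)
  else c(NA_real_, NA_real_)
  structure(list(model = "spatial", tau = par[1], theta = par[2], M = par[3],
                 ssd = ft$objective, tau_ci = ci, boot_tau = boot_tau,
                 converged = ft$convergence == 0, n = md$n),
            class = "expansion_fit")
}

#' @export
print.expansion_fit <- function(x, ...) {
  if (x$model == "demographic")
    cat(sprintf("Sudden demographic expansion: tau = %.3f (theta0 = %.3g, theta1 = %.3g)",
                x$tau, x$theta0, x$theta1))
  else
    cat(sprintf("Spatial expansion: tau = %.3f (theta = %.3g, M = %.3g)",
                x$tau, x$theta, x$M))
  if (!anyNA(x$tau_ci))
    cat(sprintf(", tau CI [%.3f, %.3f]", x$tau_ci[1], x$tau_ci[2]))
  cat(sprintf("; SSD = %.3g\n", x$ssd))
  invisible(x)
}

# simulate one coalescent sample under a fitted expansion model and return
# its pairwise-difference histogram counts (classes 0, 1, ...)
#' @keywords internal
.simulate_under_fit <- function(model, par, n) {
  if (model == "demographic") {
    tau <- par[1]; theta0 <- par[2]; theta1 <- par[3]
    g <- .sim_genealogy(n, growth_factor = theta1 / theta0,
                        growth_time = tau / theta1)
    X <- .drop_mutations(g, theta = theta1)
  } else {
    tau <- par[1]; theta <- par[2]; M <- par[3]
    g <- .sim_genealogy_structured(n_per_deme = n, migration = M,
                                   islands = Inf,
                                   collapse_time = tau / theta)
    X <- .drop_mutations(g, theta = theta)
  }
  dac <- colSums(X)
  poly <- dac > 0L & dac < nrow(X)
  Dm <- .pairdiff_matrix(X[, poly, drop = FALSE])
  dd <- Dm[upper.tri(Dm)]
  tabulate(dd + 1L, nbins = max(dd) + 1L)
}

#' Raggedness index of a mismatch distribution
#'
#' \eqn{rg = \sum_{j=1}^{d+1} (x_j - x_{j-1})^2} with the closing term
#' \eqn{x_{d+1} = 0} (Harpending 1994 convention). Smooth, expansion-like
#' distributions have small rg; any spike strictly increases it.
#'
#' @param md a `mismatch_dist`, or a numeric vector of relative frequencies
#'   over classes 0..d.
#' @return the raggedness index.
#' @export
raggedness <- function(md) {
  x <- if (inherits(md, "mismatch_dist")) md$x else md
  sum(diff(c(x, 0))^2)
}

#' Parametric-bootstrap test of the raggedness index
#'
#' Simulates coalescent samples under the fitted expansion model (the null
#' hypothesis of population expansion) and reports the fraction with
#' raggedness at least as large as observed.
#'
#' @param md the observed `mismatch_dist`.
#' @param fit an `expansion_fit` for `md`.
#' @param n_boot bootstrap replicates.
#' @param seed optional RNG seed.
#' @return the bootstrap p-value.
#' @export
raggedness_test <- function(md, fit, n_boot = 10000, seed = NULL) {
  stopifnot(inherits(fit, "expansion_fit"))
  if (!isTRUE(fit$converged)) stop("optimizer error: fit did not converge")
  rg_obs <- raggedness(md)
  par <- if (fit$model == "demographic") c(fit$tau, fit$theta0, fit$theta1)
         else c(fit$tau, fit$theta, fit$M)
  .set_seed(seed)
  hits <- 0L
  for (b in seq_len(n_boot)) {
    cnt <- .simulate_under_fit(fit$model, par, md$n)
    if (raggedness(cnt / sum(cnt)) >= rg_obs - 1e-12) hits <- hits + 1L
  }
  .perm_p(hits, n_boot)
}

#' Tajima's D statistic
#'
#' \eqn{D = (\hat k - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}} with the constants
#' of Tajima (1989). Negative values indicate an excess of low-frequency
#' variants, the signature of population expansion (or selection).
#'
#' @param S segregating sites (>= 1).
#' @param n sample size (>= 4).
#' @param k_hat mean pairwise differences per sequence pair.
#' @return the D statistic.
#' @export
tajima_d <- function(S, n, k_hat) {
  if (S < 1) stop("undefined statistic: Tajima's D needs S >= 1")
  if (n < 4) stop("insufficient sample: Tajima's D needs n >= 4")
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# log unsigned Stirling numbers of the first kind, row n: log|s(n, k)|,
# k = 1..n, by the recurrence |s(n+1,k)| = n|s(n,k)| + |s(n,k-1)| on the
# log scale (stable for the sample sizes used here, n in the hundreds)
#' @keywords internal
.log_stirling1 <- function(n) {
  l <- 0  # row 1: |s(1,1)| = 1
  if (n == 1L) return(l)
  for (m in 1:(n - 1)) {
    lshift <- c(-Inf, l)
    lkeep <- c(l, -Inf) + log(m)
    mx <- pmax(lshift, lkeep)
    l <- mx + log(exp(lshift - mx) + exp(lkeep - mx))
    l[!is.finite(mx)] <- -Inf
  }
  l
}

#' Fu's Fs statistic
#'
#' \eqn{F_s = \ln(S'/(1-S'))} where \eqn{S' = \Pr(K \ge k_{obs})} under the
#' Ewens sampling formula at \eqn{\theta} estimated by the mean pairwise
#' differences. Probabilities use unsigned Stirling numbers of the first
#' kind on the log scale, so large samples do not overflow. A strongly
#' negative Fs (an excess of haplotypes for the observed diversity) is the
#' expansion signature.
#'
#' @param k_obs observed number of distinct haplotypes.
#' @param n sample size.
#' @param theta mutation parameter estimate (usually `k_hat`); must be > 0.
#' @return the Fs statistic.
#' @export
fu_fs <- function(k_obs, n, theta) {
  if (theta <= 0) stop("undefined statistic: Fu's Fs needs theta > 0")
  if (n < 2) stop("insufficient sample: need n >= 2")
  if (k_obs < 1 || k_obs > n) stop("k_obs must be in 1..n")
  if (k_obs == 1)  # S' = P(K >= 1) = 1 identically
    stop("overflow: S' = 1 gives an infinite Fs (k_obs = 1)")
  ls <- .log_stirling1(n)
  k <- seq_len(n)
  logp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1)))
  sp <- exp(.logsumexp(logp[k >= k_obs]))
  sp <- min(max(sp, 0), 1)
  if (sp >= 1 - 1e-14 || sp <= 0)
    stop("overflow: S' = ", sp, " gives an infinite Fs (k_obs = ", k_obs, ")")
  log(sp / (1 - sp))
}

#' Ramos-Onsins and Rozas' R2 statistic
#'
#' \eqn{R_2 = \sqrt{\frac{1}{n}\sum_i (U_i - \hat k/2)^2} / S} where
#' \eqn{U_i} counts the singleton sites (minor-allele frequency 1) at which
#' sequence i carries the minor allele. Small R2 means singletons are
#' spread evenly at the level expected after an expansion.
#'
#' @param seqs character matrix of aligned sequences (rows = individuals)
#'   restricted to usable sites, or a 0/1 matrix of derived states.
#' @return the R2 statistic.
#' @export
r2_stat <- function(seqs) {
  X <- as.matrix(seqs)
  n <- nrow(X)
  if (n < 3) stop("insufficient sample: R2 needs n >= 3")
  U <- integer(n)
  S <- 0L
  npair_diffs <- 0
  for (col in seq_len(ncol(X))) {
    v <- X[, col]
    tab <- table(v)
    if (length(tab) < 2L) next
    S <- S + 1L
    cnts <- as.integer(tab)
    npair_diffs <- npair_diffs + (choose(n, 2) - sum(choose(cnts, 2)))
    mx <- max(cnts)
    for (s in which(cnts == 1L))
      if (1L < mx) U[v == names(tab)[s]] <- U[v == names(tab)[s]] + 1L
  }
  if (S == 0L) stop("undefined statistic: R2 needs S >= 1")
  k_hat <- npair_diffs / choose(n, 2)
  sqrt(mean((U - k_hat / 2)^2)) / S
}

#' Coalescent-simulation p-values for the neutrality tests
#'
#' Simulates neutral constant-size coalescent samples conditioned on the
#' observed number of segregating sites (fixed-S mode: exactly S mutations
#' placed uniformly on the genealogy) and reports, for each supplied
#' statistic, the fraction of simulated values at least as extreme. The
#' default tail is lower (the expansion direction) for all three
#' statistics; `tail = "two_sided"` doubles the smaller tail.
#'
#' @param S observed segregating sites (>= 1).
#' @param n sample size.
#' @param d_obs,fs_obs,r2_obs observed statistics (NULL skips one).
#' @param n_sim simulated samples.
#' @param seed optional RNG seed.
#' @param tail `"lower"` (default) or `"two_sided"`.
#' @return list with the requested elements `p_d`, `p_fs`, `p_r2`.
#' @export
neutrality_pvalues <- function(S, n, d_obs = NULL, fs_obs = NULL,
                               r2_obs = NULL, n_sim = 1000, seed = NULL,
                               tail = c("lower", "two_sided")) {
  tail <- match.arg(tail)
  if (S < 1) stop("undefined statistic: need S >= 1")
  .set_seed(seed)
  ls <- if (!is.null(fs_obs)) .log_stirling1(n) else NULL
  hits_d <- hits_fs <- hits_r2 <- 0L
  nd <- nfs <- nr2 <- 0L
  for (b in seq_len(n_sim)) {
    st <- simulate_coalescent_stats(n, S = S, mode = "fixed_S")
    if (!is.null(d_obs) && st$S >= 1) {
      nd <- nd + 1L
      if (tajima_d(st$S, n, st$k_hat) <= d_obs + 1e-12) hits_d <- hits_d + 1L
    }
    if (!is.null(fs_obs) && st$k_hat > 0) {
      k <- seq_len(n)
      logp <- ls + k * log(st$k_hat) - sum(log(st$k_hat + 0:(n - 1)))
      sp <- exp(.logsumexp(logp[k >= st$K]))
      sp <- min(max(sp, .Machine$double.xmin), 1 - 1e-15)
      fs <- log(sp / (1 - sp))
      nfs <- nfs + 1L
      if (fs <= fs_obs + 1e-12) hits_fs <- hits_fs + 1L
    }
    if (!is.null(r2_obs) && st$S >= 1) {
      r2 <- sqrt(mean((st$U - st$k_hat / 2)^2)) / st$S
      nr2 <- nr2 + 1L
      if (r2 <= r2_obs + 1e-12) hits_r2 <- hits_r2 + 1L
    }
  }
  two <- function(p) min(1, 2 * min(p, 1 - p + 1 / (n_sim + 1)))
  out <- list()
  if (!is.null(d_obs)) {
    out$p_d <- .perm_p(hits_d, nd)
    if (tail == "two_sided") out$p_d <- two(out$p_d)
  }
  if (!is.null(fs_obs)) {
    out$p_fs <- .perm_p(hits_fs, nfs)
    if (tail == "two_sided") out$p_fs <- two(out$p_fs)
  }
  if (!is.null(r2_obs)) {
    out$p_r2 <- .perm_p(hits_r2, nr2)
    if (tail == "two_sided") out$p_r2 <- two(out$p_r2)
  }
  out
}

#' Neutrality-test summary for one population
#'
#' Computes S, k_hat, the haplotype count, Tajima's D, Fu's Fs and R2 for a
#' population (or the pooled sample) of a spectrum, with coalescent
#' p-values at the conventional simulation counts (10,000 for D and Fs,
#' 1,000 for R2).
#'
#' @param spec a `hap_spectrum`.
#' @param population population label or `"TOT"`.
#' @param n_sim_dfs simulations for D and Fs.
#' @param n_sim_r2 simulations for R2.
#' @param seed optional RNG seed.
#' @return one-row data.frame with statistics and p-values.
#' @export
neutrality_tests <- function(spec, population = "TOT",
                             n_sim_dfs = 10000, n_sim_r2 = 1000,
                             seed = NULL) {
  cnt <- .pop_counts(spec, population)
  n <- sum(cnt)
  S <- segregating_sites(spec, population)
  k_hat <- nucleotide_diversity(spec, population)$k_hat
  K <- sum(cnt > 0)
  d <- tajima_d(S, n, k_hat)
  fs <- fu_fs(K, n, k_hat)
  X <- spec$haplotypes[.expand_individuals(spec, population), , drop = FALSE]
  r2 <- r2_stat(X)
  .set_seed(seed)
  p1 <- neutrality_pvalues(S, n, d_obs = d, fs_obs = fs, n_sim = n_sim_dfs)
  p2 <- neutrality_pvalues(S, n, r2_obs = r2, n_sim = n_sim_r2)
  data.frame(population = population, n = n, S = S, k_hat = k_hat,
             n_hap = K, tajima_d = d, p_d = p1$p_d,
             fu_fs = fs, p_fs = p1$p_fs, r2 = r2, p_r2 = p2$p_r2)
}

#' Convert an expansion age tau into years
#'
#' Li's relation t = tau / (2u) with u the mutation rate per *sequence* per
#' year: with a per-site rate of `mu_percent_per_myr` percent per million
#' years over `L` sites, \eqn{t = \tau / (2 \mu_{site} L)} years. Under the
#' `per_site` convention tau is first divided by L and then by twice the
#' per-site rate, which yields the same number; the convention used is
#' recorded in the output for audit.
#'
#' @param tau expansion age in pair-mutational units (>= 0).
#' @param mu_percent_per_myr per-site mutation rate, percent per million
#'   years (e.g. 1.66).
#' @param L sequence length in sites.
#' @param convention `"per_sequence"` or `"per_site"`.
#' @return list with `t_years`, `mu_site` (per site per year), `L`,
#'   `convention`.
#' @export
expansion_time <- function(tau, mu_percent_per_myr, L,
                           convention = c("per_sequence", "per_site")) {
  convention <- match.arg(convention)
  if (tau < 0) stop("parameter error: tau must be >= 0")
  if (mu_percent_per_myr <= 0 || L <= 0)
    stop("parameter error: mutation rate and L must be positive")
  mu_site <- mu_percent_per_myr / 100 / 1e6
  t_years <- if (convention == "per_sequence")
    tau / (2 * mu_site * L)
  else
    (tau / L) / (2 * mu_site)
  list(t_years = t_years, mu_site = mu_site, L = L, convention = convention)
}
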