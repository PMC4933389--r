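# Among-population differentiation: one-level AMOVA with permutation nulls,
# pairwise fixation indexes, Nei's gamma-st, Hudson's Snn, the exact test of
# haplotype differentiation (Markov chain over fixed-margin tables) and a
# Monte-Carlo contingency chi-squared.
#
# Permutation p-values everywhere use (count + 1)/(B + 1): the observed
# arrangement is counted in numerator and denominator, so no p is zero.
# Negative variance components are reported as computed, never clamped.

# core one-level variance decomposition from haplotype counts and a matrix
# of squared inter-haplotype distances (Excoffier, Smouse & Quattro 1992)
#' @keywords internal
.amova_core <- function(counts, d2) {
  np <- rowSums(counts)
  N <- sum(np)
  P <- nrow(counts)
  ctot <- colSums(counts)
  ssd_tot <- 0.5 * drop(ctot %*% d2 %*% ctot) / N
  ssd_w <- sum(vapply(seq_len(P), function(p) {
    cp <- counts[p, ]
    0.5 * drop(cp %*% d2 %*% cp) / np[p]
  }, numeric(1)))
  ssd_a <- ssd_tot - ssd_w
  df_a <- P - 1
  df_w <- N - P
  sigma_w <- ssd_w / df_w
  n_c <- (N - sum(np^2) / N) / (P - 1)
  sigma_a <- (ssd_a / df_a - sigma_w) / n_c
  tot <- sigma_a + sigma_w
  phi <- if (tot == 0) 0 else sigma_a / tot
  list(ssd_among = ssd_a, ssd_within = ssd_w,
       sigma_among = sigma_a, sigma_within = sigma_w, phi = phi)
}

#' One-level analysis of molecular variance (AMOVA)
#'
#' Partitions molecular variance among and within populations from squared
#' inter-individual distances and tests the fixation index Phi-st by
#' permuting individuals among populations (sample sizes kept fixed). With
#' `dist = NULL` every pair of distinct haplotypes is at squared distance 1,
#' which is the haplotype-frequency-only mode (a conventional Fst); passing
#' a [tajima_nei_matrix()] result gives the genetic-distance mode, whose
#' matrix entries are treated as squared distances.
#'
#' @param spec a `hap_spectrum` with at least two populations.
#' @param dist `NULL`, a `hap_dist`, or a symmetric numeric matrix of squared
#'   inter-haplotype distances.
#' @param n_perm number of permutations for the p-value.
#' @param seed optional RNG seed.
#' @return list of class `amova`: sums of squares, variance components
#'   (possibly negative), percentages of total variation, `phi_st`, the
#'   permutation `p`, and `mode`.
#' @export
amova <- function(spec, dist = NULL, n_perm = 10000, seed = NULL) {
  counts <- spec$counts
  if (nrow(counts) < 2)
    stop("structure error: AMOVA needs at least two populations")
  if (inherits(dist, "hap_dist")) {
    d2 <- dist$d
    mode <- "genetic_distance"
  } else if (is.matrix(dist)) {
    d2 <- dist
    mode <- "genetic_distance"
  } else {
    H <- ncol(counts)
    d2 <- 1 - diag(H)
    mode <- "haplotype_frequencies"
  }
  obs <- .amova_core(counts, d2)
  if (obs$sigma_among + obs$sigma_within == 0)
    warning("all sequences identical: Phi-st defined as 0")

  .set_seed(seed)
  np <- rowSums(counts)
  ind <- rep.int(seq_len(ncol(counts)), colSums(counts))
  grp <- rep.int(seq_along(np), np)
  H <- ncol(counts)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(ind)
    cnt <- matrix(0, nrow(counts), H)
    for (p in seq_along(np))
      cnt[p, ] <- tabulate(perm[grp == p], nbins = H)
    if (.amova_core(cnt, d2)$phi >= obs$phi - 1e-12) hits <- hits + 1L
  }
  tot <- obs$sigma_among + obs$sigma_within
  structure(list(ss_among = obs$ssd_among, ss_within = obs$ssd_within,
                 var_among = obs$sigma_among, var_within = obs$sigma_within,
                 pct_among = if (tot == 0) 0 else 100 * obs$sigma_among / tot,
                 pct_within = if (tot == 0) 100 else 100 * obs$sigma_within / tot,
                 phi_st = obs$phi, p = .perm_p(hits, n_perm),
                 mode = mode, n_perm = n_perm),
            class = "amova")
}

#' @export
print.amova <- function(x, ...) {
  cat(sprintf("AMOVA (%s): Phi_st = %.4f, P = %.4g (%d permutations)\n",
              x$mode, x$phi_st, x$p, x$n_perm))
  cat(sprintf("  among:  SS = %.3f, var = %.4f (%.2f%%)\n",
              x$ss_among, x$var_among, x$pct_among))
  cat(sprintf("  within: SS = %.3f, var = %.4f (%.2f%%)\n",
              x$ss_within, x$var_within, x$pct_within))
  invisible(x)
}

#' Pairwise fixation indexes with permutation p-values
#'
#' [amova()] applied to every pair of populations. No multiple-testing
#' correction is applied by default (raw pairwise significance); set
#' `p_adjust` to a [stats::p.adjust()] method to correct.
#'
#' @inheritParams amova
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return list with symmetric matrices `index` and `p`.
#' @export
pairwise_fixation <- function(spec, dist = NULL, n_perm = 1000, seed = NULL,
                              p_adjust = "none") {
  pops <- rownames(spec$counts)
  P <- length(pops)
  if (P < 2) stop("structure error: need at least two populations")
  idx <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  pv <- idx
  .set_seed(seed)
  for (i in 1:(P - 1)) for (j in (i + 1):P) {
    sub <- spec
    sub$counts <- spec$counts[c(i, j), , drop = FALSE]
    a <- amova(sub, dist = dist, n_perm = n_perm, seed = NULL)
    idx[i, j] <- idx[j, i] <- a$phi_st
    pv[i, j] <- pv[j, i] <- a$p
  }
  if (p_adjust != "none") {
    up <- upper.tri(pv)
    pv[up] <- stats::p.adjust(pv[up], method = p_adjust)
    pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
  }
  list(index = idx, p = pv)
}

#' Nei's gamma-st coefficient of haplotype subdivision
#'
#' \eqn{\gamma_{st} = (h_T - h_S)/h_T}, with \eqn{h_S} the unbiased
#' within-population haplotype diversity averaged (unweighted) over
#' populations and \eqn{h_T} the total diversity computed from the
#' unweighted mean haplotype frequencies, with the \eqn{N/(N-1)} small-
#' sample correction. The primary reported statistic is the average of
#' gamma-st over all population pairs; the global value and the pairwise
#' matrix are returned alongside. `unbiased = FALSE` drops both small-sample
#' corrections for comparison.
#'
#' @param spec a `hap_spectrum` with >= 2 populations of n >= 2 each.
#' @param unbiased apply small-sample corrections (default TRUE).
#' @return list with `average_pairwise` (the headline statistic),
#'   `overall`, `pairwise` matrix, `h_s`, `h_t`.
#' @export
gamma_st <- function(spec, unbiased = TRUE) {
  counts <- spec$counts
  if (nrow(counts) < 2) stop("structure error: need at least two populations")
  if (any(rowSums(counts) < 2))
    stop("insufficient sample: every population needs n >= 2")
  gst_of <- function(cnt) {
    p <- cnt / rowSums(cnt)
    if (unbiased) {
      n <- rowSums(cnt)
      hs <- mean(n / (n - 1) * (1 - rowSums(p^2)))
      xbar <- colMeans(p)
      N <- sum(cnt)
      ht <- N / (N - 1) * (1 - sum(xbar^2))
    } else {
      hs <- mean(1 - rowSums(p^2))
      xbar <- colMeans(p)
      ht <- 1 - sum(xbar^2)
    }
    if (ht <= 0)
      stop("undefined statistic: total haplotype diversity is zero (monomorphic)")
    (ht - hs) / ht
  }
  pops <- rownames(counts)
  P <- length(pops)
  pw <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  for (i in 1:(P - 1)) for (j in (i + 1):P)
    pw[i, j] <- pw[j, i] <- gst_of(counts[c(i, j), , drop = FALSE])
  hs_ht <- local({
    p <- counts / rowSums(counts)
    n <- rowSums(counts)
    list(hs = mean(n / (n - 1) * (1 - rowSums(p^2))),
         ht = sum(counts) / (sum(counts) - 1) * (1 - sum(colMeans(p)^2)))
  })
  list(average_pairwise = mean(pw[upper.tri(pw)]),
       overall = gst_of(counts),
       pairwise = pw, h_s = hs_ht$hs, h_t = hs_ht$ht)
}

#' Hudson's Snn nearest-neighbour test of population differentiation
#'
#' For each sequence, the fraction of its nearest neighbours (minimum raw
#' difference, self excluded, ties shared equally) that belong to its own
#' population; Snn is the mean of these fractions and its significance is
#' assessed by permuting population labels. Sequences equidistant from
#' everything simply contribute their tie-shared fraction.
#'
#' @param spec a `hap_spectrum` with at least two populations.
#' @param n_perm label permutations.
#' @param seed optional RNG seed.
#' @return list with `snn` and permutation `p`.
#' @export
snn_test <- function(spec, n_perm = 10000, seed = NULL) {
  counts <- spec$counts
  if (nrow(counts) < 2) stop("structure error: need at least two populations")
  hap <- unlist(lapply(seq_len(nrow(counts)), function(p)
    rep.int(seq_len(ncol(counts)), counts[p, ])))
  lab <- rep.int(seq_len(nrow(counts)), rowSums(counts))
  n <- length(hap)
  D <- spec$diffs[hap, hap, drop = FALSE]
  diag(D) <- Inf
  nn <- lapply(seq_len(n), function(i) which(D[i, ] == min(D[i, ])))
  snn_of <- function(lab) mean(vapply(seq_len(n), function(i)
    mean(lab[nn[[i]]] == lab[i]), numeric(1)))
  obs <- snn_of(lab)
  .set_seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm))
    if (snn_of(sample(lab)) >= obs - 1e-12) hits <- hits + 1L
  list(snn = obs, p = .perm_p(hits, n_perm))
}

#' Exact test of haplotype differentiation
#'
#' Markov-chain estimate (Raymond & Rousset 1995) of the probability, under
#' the multivariate hypergeometric distribution of population x haplotype
#' tables with fixed margins, of tables no more probable than the observed
#' one. The chain proposes unit "diamond" swaps between two rows and two
#' columns and accepts with the Metropolis ratio of table probabilities.
#'
#' @param counts population x haplotype contingency table.
#' @param steps Markov chain steps retained after burn-in.
#' @param burn_in initial steps discarded.
#' @param seed optional RNG seed.
#' @return the estimated exact p-value.
#' @export
exact_test <- function(counts, steps = 10000, burn_in = 1000, seed = NULL) {
  counts <- as.matrix(counts)
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (ncol(counts) < 2 || nrow(counts) < 2) return(1)  # degenerate table
  .set_seed(seed)
  logp <- function(x) -sum(lgamma(x + 1))  # variable part of table log-prob
  x <- counts
  lp <- logp(x)
  lp_obs <- lp
  R <- nrow(x); C <- ncol(x)
  hits <- 0L; kept <- 0L
  for (s in seq_len(burn_in + steps)) {
    i <- sample.int(R, 2L); j <- sample.int(C, 2L)
    # move one individual: x[i1,j1]--, x[i2,j2]--, x[i1,j2]++, x[i2,j1]++
    if (x[i[1], j[1]] > 0 && x[i[2], j[2]] > 0) {
      new11 <- x[i[1], j[1]] - 1L; new22 <- x[i[2], j[2]] - 1L
      new12 <- x[i[1], j[2]] + 1L; new21 <- x[i[2], j[1]] + 1L
      # delta of log-probability, i.e. of -sum(lgamma(x + 1))
      dlp <- (lgamma(x[i[1], j[1]] + 1) - lgamma(new11 + 1)) +
             (lgamma(x[i[2], j[2]] + 1) - lgamma(new22 + 1)) +
             (lgamma(x[i[1], j[2]] + 1) - lgamma(new12 + 1)) +
             (lgamma(x[i[2], j[1]] + 1) - lgamma(new21 + 1))
      if (dlp >= 0 || log(stats::runif(1)) < dlp) {
        x[i[1], j[1]] <- new11; x[i[2], j[2]] <- new22
        x[i[1], j[2]] <- new12; x[i[2], j[1]] <- new21
        lp <- lp + dlp
      }
    }
    if (s > burn_in) {
      kept <- kept + 1L
      if (lp <= lp_obs + 1e-9) hits <- hits + 1L
    }
  }
  .perm_p(hits, kept)
}

#' Monte-Carlo contingency chi-squared test of haplotype heterogeneity
#'
#' Pearson chi-squared on the population x haplotype table without pooling
#' rare haplotypes; the p-value is the fraction of randomized tables
#' (individuals permuted holding both margins, via Patefield's algorithm)
#' with a statistic at least as large as observed.
#'
#' @param counts population x haplotype contingency table.
#' @param n_rand number of randomized tables.
#' @param seed optional RNG seed.
#' @return list with `chi2`, `df` and Monte-Carlo `p`.
#' @export
chi2_monte_carlo <- function(counts, n_rand = 20000, seed = NULL) {
  counts <- as.matrix(counts)
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c))
    warning("zero-margin rows/columns dropped")
  counts <- counts[keep_r, keep_c, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("structure error: need >= 2 populations and >= 2 haplotypes")
  r <- rowSums(counts); cc <- colSums(counts); N <- sum(counts)
  E <- outer(r, cc) / N
  chi2_of <- function(x) sum((x - E)^2 / E)
  obs <- chi2_of(counts)
  .set_seed(seed)
  sims <- stats::r2dtable(n_rand, r, cc)
  hits <- sum(vapply(sims, chi2_of, numeric(1)) >= obs - 1e-12)
  list(chi2 = obs, df = (nrow(counts) - 1) * (ncol(counts) - 1),
       p = .perm_p(hits, n_rand))
}
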