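# Within-population diversity indexes and model-corrected distances.
#
# theta_pi and theta_w are reported as percent per site (the convention of
# the comparative tables this package reproduces); the per-sequence
# quantities k_hat (mean pairwise differences) and S are kept uncorrected
# because Tajima's D and Fu's Fs consume them on that scale. theta_pi uses
# raw difference counts, never model-corrected distances: it is defined as
# the mean number of differences between sequence pairs. Model-corrected
# (Tajima-Nei) distances are used only for AMOVA/Phi-st.

#' Haplotype diversity (gene diversity) with standard error
#'
#' The unbiased probability that two sequences drawn without replacement
#' from the population carry different haplotypes:
#' \eqn{h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}.
#' The standard error follows Nei (1987, eq. 8.12).
#'
#' @param counts non-negative integer vector of per-haplotype counts for one
#'   population.
#' @return list with elements `h` and `se`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("insufficient sample: need n >= 2 sequences")
  p <- counts / n
  s2 <- sum(p^2)
  h <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  list(h = h, se = sqrt(max(v, 0)))
}

#' Nucleotide diversity (percent per site)
#'
#' Mean number of raw nucleotide differences between all sequence pairs of a
#' population (`k_hat`), scaled to percent per usable site.
#'
#' @inheritParams segregating_sites
#' @return list with `k_hat` (mean pairwise differences per sequence pair)
#'   and `theta_pi` (percent per site).
#' @export
nucleotide_diversity <- function(spec, population = "TOT") {
  cnt <- .pop_counts(spec, population)
  n <- sum(cnt)
  if (n < 2) stop("insufficient sample: need n >= 2 sequences")
  if (spec$usable_sites <= 0) stop("no usable sites")
  # sum over unordered sequence pairs of pairwise differences:
  # cross-haplotype pairs contribute c_i * c_j * d_ij; within-haplotype 0
  tot <- 0.5 * drop(cnt %*% spec$diffs %*% cnt)
  k_hat <- tot / choose(n, 2)
  list(k_hat = k_hat, theta_pi = 100 * k_hat / spec$usable_sites)
}

#' Watterson's diversity estimator (percent per site)
#'
#' \eqn{\theta_w = S / a_n} per sequence, with \eqn{a_n = \sum_{i=1}^{n-1} 1/i},
#' reported as percent per usable site. This is the "historical" diversity
#' counterpart to the current diversity [nucleotide_diversity()].
#'
#' @param S number of segregating sites.
#' @param n sample size (sequences).
#' @param usable_sites sites retained after missing-data masking.
#' @return theta_w in percent per site.
#' @export
watterson_theta <- function(S, n, usable_sites) {
  if (n < 2) stop("insufficient sample: need n >= 2 sequences")
  if (usable_sites <= 0) stop("no usable sites")
  100 * S / (.harmonic(n - 1) * usable_sites)
}

#' Classify recent demographic history from the two diversity estimators
#'
#' Current diversity exceeding historical diversity (theta_pi > theta_w)
#' signals recent population growth; the reverse signals a bottleneck;
#' equality within `eps` is reported as equilibrium.
#'
#' @param theta_pi current nucleotide diversity (percent per site).
#' @param theta_w historical (Watterson) diversity (percent per site).
#' @param eps equality tolerance on the percent scale.
#' @return one of `"growth"`, `"bottleneck"`, `"equilibrium"`.
#' @export
classify_history <- function(theta_pi, theta_w, eps = 1e-9) {
  if (abs(theta_pi - theta_w) <= eps) return("equilibrium")
  if (theta_pi > theta_w) "growth" else "bottleneck"
}

#' Tajima-Nei corrected distances between haplotypes
#'
#' Equal-input model distance for unequal base frequencies,
#' \eqn{d = -b \log(1 - p/b)} with \eqn{b = 1 - \sum_i g_i^2}, where the
#' base frequencies g are pooled over all sequences (weighted by haplotype
#' counts) at usable sites. With equal frequencies (b = 3/4) this reduces to
#' the Jukes-Cantor correction. A plain p-distance is available as fallback.
#'
#' @param spec a `hap_spectrum`.
#' @param model `"tajima_nei"` (default) or `"p_distance"`.
#' @return list of class `hap_dist` with `labels`, `d` (symmetric matrix of
#'   substitutions per site) and `model`.
#' @export
tajima_nei_matrix <- function(spec, model = c("tajima_nei", "p_distance")) {
  model <- match.arg(model)
  if (spec$usable_sites <= 0) stop("no usable sites")
  hm <- spec$haplotypes
  H <- nrow(hm)
  p <- spec$diffs / spec$usable_sites
  if (model == "p_distance") {
    d <- p
  } else {
    cnt <- colSums(spec$counts)
    tab <- numeric(4); names(tab) <- .valid_bases
    for (i in seq_len(H)) {
      b <- hm[i, ][hm[i, ] %in% .valid_bases]
      t_i <- table(factor(b, levels = .valid_bases))
      tab <- tab + cnt[i] * as.numeric(t_i)
    }
    g <- tab / sum(tab)
    b <- 1 - sum(g^2)
    if (any(p >= b)) {
      bad <- which(p >= b & upper.tri(p), arr.ind = TRUE)[1, ]
      stop("saturation error: Tajima-Nei distance undefined for pair ",
           rownames(hm)[bad[1]], "-", rownames(hm)[bad[2]])
    }
    d <- -b * log(1 - p / b)
  }
  dimnames(d) <- dimnames(spec$diffs)
  structure(list(labels = rownames(hm), d = d, model = model),
            class = "hap_dist")
}

#' Per-population diversity summary table
#'
#' One row per population plus a pooled `TOT` row: sample size, number of
#' haplotypes, segregating sites, haplotype diversity with its standard
#' error, current (theta_pi) and historical (theta_w) diversity in percent
#' per site, and the growth/bottleneck classification.
#'
#' @param spec a `hap_spectrum`.
#' @param eps equality tolerance passed to [classify_history()].
#' @return data.frame, one row per population and one `TOT` row.
#' @export
diversity_table <- function(spec, eps = 1e-9) {
  pops <- c(rownames(spec$counts), "TOT")
  rows <- lapply(pops, function(pp) {
    cnt <- .pop_counts(spec, pp)
    n <- sum(cnt)
    if (n < 2) {
      return(data.frame(population = pp, n = n, n_hap = sum(cnt > 0),
                        S = NA_integer_, h = NA_real_, h_se = NA_real_,
                        k_hat = NA_real_, theta_pi = NA_real_,
                        theta_w = NA_real_, history = NA_character_))
    }
    hd <- haplotype_diversity(cnt)
    nd <- nucleotide_diversity(spec, pp)
    S <- segregating_sites(spec, pp)
    tw <- watterson_theta(S, n, spec$usable_sites)
    data.frame(population = pp, n = n, n_hap = sum(cnt > 0), S = S,
               h = hd$h, h_se = hd$se, k_hat = nd$k_hat,
               theta_pi = nd$theta_pi, theta_w = tw,
               history = classify_history(nd$theta_pi, tw, eps))
  })
  do.call(rbind, rows)
}
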