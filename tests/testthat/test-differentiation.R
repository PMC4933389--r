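test_that("AMOVA handles the fully sorted and panmictic extremes", {
  # two populations fixed for different haplotypes: all variation among
  spec <- toy_spectrum(c("AAAA", "AAAA", "TTTT", "TTTT"),
                       c("P1", "P1", "P2", "P2"))
  a <- amova(spec, n_perm = 99, seed = 1)
  expect_equal(a$phi_st, 1)
  expect_equal(a$pct_among, 100)
  expect_equal(a$mode, "haplotype_frequencies")

  # identical compositions: no among-population variance
  spec2 <- toy_spectrum(c("AAAA", "AAAA", "TTTT", "AAAA", "AAAA", "TTTT"),
                        c("P1", "P1", "P1", "P2", "P2", "P2"))
  a2 <- amova(spec2, n_perm = 99, seed = 1)
  expect_lte(a2$var_among, 1e-12)
  expect_lte(a2$phi_st, 1e-12)

  one <- toy_spectrum(c("AAAA", "TTTT"), c("P1", "P1"))
  expect_error(amova(one), "structure error")

  mono <- toy_spectrum(rep("AAAA", 4), c("P1", "P1", "P2", "P2"))
  expect_warning(a3 <- amova(mono, n_perm = 19), "identical")
  expect_equal(a3$phi_st, 0)
})

test_that("AMOVA variance components equal the naive double-loop oracle", {
  set.seed(10)
  for (rep in 1:6) {
    n_pops <- sample(2:3, 1)
    spec <- random_spectrum(sample(8:14, 1), n_pops = n_pops)
    if (ncol(spec$counts) < 2) next
    for (use_dist in c(FALSE, TRUE)) {
      d2 <- if (use_dist) {
        m <- spec$diffs / spec$usable_sites
        m
      } else 1 - diag(ncol(spec$counts))
      a <- amova(spec, dist = if (use_dist) d2 else NULL, n_perm = 0)
      o <- naive_amova(spec$counts, d2)
      expect_equal(a$ss_among, o$ssd_among, tolerance = 1e-10)
      expect_equal(a$ss_within, o$ssd_within, tolerance = 1e-10)
      expect_equal(a$var_among, o$sigma_among, tolerance = 1e-10)
      expect_equal(a$var_within, o$sigma_within, tolerance = 1e-10)
    }
  }
})

test_that("Phi-st is invariant to uniform rescaling of the distances", {
  set.seed(11)
  spec <- random_spectrum(10, n_pops = 2)
  d2 <- spec$diffs
  a1 <- amova(spec, dist = d2, n_perm = 0)
  a2 <- amova(spec, dist = d2 * 7.3, n_perm = 0)
  expect_equal(a1$phi_st, a2$phi_st, tolerance = 1e-12)
})

test_that("pairwise fixation returns all pairs with sensible extremes", {
  spec <- toy_spectrum(
    c("AAAA", "AAAA", "TTTT", "TTTT", "AAAA", "TTTT"),
    c("P1", "P1", "P2", "P2", "P3", "P3"))
  pw <- pairwise_fixation(spec, n_perm = 99, seed = 2)
  expect_equal(dim(pw$index), c(3, 3))
  expect_equal(pw$index, t(pw$index))
  expect_equal(sum(!is.na(pw$index[upper.tri(pw$index)])), 3)
  expect_equal(pw$index["P1", "P2"], 1)  # fully sorted pair
})

test_that("gamma-st behaves at the panmictic and fixed-difference extremes", {
  # two populations fixed for different haplotypes: gamma-st = 1 (h_S = 0)
  spec <- toy_spectrum(c(rep("AAAA", 10), rep("TTTT", 10)),
                       c(rep("P1", 10), rep("P2", 10)))
  g <- gamma_st(spec)
  expect_equal(g$average_pairwise, 1)
  expect_equal(g$h_s, 0)

  # identical distributions: near zero (small-sample corrections leave
  # an O(1/n) residual)
  spec2 <- toy_spectrum(c(rep(c("AAAA", "TTTT"), 5), rep(c("AAAA", "TTTT"), 5)),
                        c(rep("P1", 10), rep("P2", 10)))
  expect_lt(abs(gamma_st(spec2)$average_pairwise), 0.1)

  mono <- toy_spectrum(rep("AAAA", 8), c(rep("P1", 4), rep("P2", 4)))
  expect_error(gamma_st(mono), "undefined")
})

test_that("Snn matches hand enumeration and detects full sorting", {
  # hand case: haps A=AA (P1), B=AT (one in each pop), C=TT (P2)
  spec <- toy_spectrum(c("AA", "AT", "AT", "TT"),
                       c("P1", "P1", "P2", "P2"))
  s <- snn_test(spec, n_perm = 99, seed = 1)
  expect_equal(s$snn, 0.25)

  sorted <- toy_spectrum(c("AAAA", "AAAT", "TTTT", "TTTA"),
                         c("P1", "P1", "P2", "P2"))
  expect_equal(snn_test(sorted, n_perm = 99, seed = 1)$snn, 1)
})

test_that("random labels on a panmictic sample give Snn near one half", {
  set.seed(12)
  vals <- replicate(60, {
    sim <- simulate_alignment(20, theta = 4, L = 200)
    pm <- sim$popmap
    pm$group <- sample(rep(c("A", "B"), 10))
    snn_test(collapse_haplotypes(sim$alignment, pm), n_perm = 0)$snn
  })
  expect_equal(mean(vals), 0.5, tolerance = 0.05)
})

test_that("the exact test agrees with exhaustive enumeration", {
  # 2x2 diagonal table: Fisher two-sided probability 2/252
  tab <- rbind(c(5, 0), c(0, 5))
  p_true <- enumerate_exact_p(tab)
  expect_equal(p_true, 2 / choose(10, 5), tolerance = 1e-12)
  p_chain <- exact_test(tab, steps = 20000, seed = 3)
  se <- sqrt(p_true * (1 - p_true) / 20000)
  expect_lt(abs(p_chain - p_true), 3 * se + 2 / 20000)

  # identical rows are the modal table: p = 1
  expect_gt(exact_test(rbind(c(3, 3), c(3, 3)), steps = 5000, seed = 4), 0.95)

  # 2x3 toy against enumeration (hand value 0.6)
  tab23 <- rbind(c(2, 1, 0), c(0, 1, 2))
  p23 <- enumerate_exact_p(tab23)
  expect_equal(p23, 0.6, tolerance = 1e-12)
  p_chain23 <- exact_test(tab23, steps = 20000, seed = 5)
  se23 <- sqrt(p23 * (1 - p23) / 20000)
  expect_lt(abs(p_chain23 - p23), 3 * se23)

  # degenerate: a single haplotype
  expect_equal(exact_test(rbind(5, 5)), 1)
})

test_that("Monte-Carlo chi-squared reproduces the Pearson statistic", {
  r <- chi2_monte_carlo(rbind(c(5, 0), c(0, 5)), n_rand = 2000, seed = 6)
  expect_equal(r$chi2, 10)
  expect_equal(r$df, 1)
  expect_lt(r$p, 0.05)

  r2 <- chi2_monte_carlo(rbind(c(3, 3), c(3, 3)), n_rand = 500, seed = 7)
  expect_equal(r2$chi2, 0)
  expect_gt(r2$p, 0.95)

  expect_warning(chi2_monte_carlo(rbind(c(2, 0, 2), c(2, 0, 2)),
                                  n_rand = 100, seed = 8), "dropped")
})
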