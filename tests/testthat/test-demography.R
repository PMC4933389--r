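test_that("mismatch histograms enumerate all sequence pairs", {
  spec <- toy_spectrum(c("ACGT", "ACGT"), c("P", "P"))
  md <- mismatch(spec)
  expect_equal(md$x, 1.0)
  expect_equal(md$d, 0L)

  # counts (2,2) with 3 differences: 2 pairs at 0, 4 pairs at 3
  s1 <- strrep("A", 10)
  s2 <- paste0("TTT", strrep("A", 7))
  spec2 <- toy_spectrum(c(s1, s1, s2, s2), rep("P", 4))
  md2 <- mismatch(spec2)
  expect_equal(md2$x, c(1 / 3, 0, 0, 2 / 3))
  expect_equal(md2$n_pairs, 6)

  expect_error(mismatch(toy_spectrum("ACGT", "P")), "insufficient")
})

test_that("expected mismatch curves hit their closed-form limits", {
  th <- 1.3
  j <- 0:12
  stat <- th^j / (1 + th)^(j + 1)
  expect_equal(expected_mismatch_demographic(j, 0, th, th), stat,
               tolerance = 1e-12)
  expect_equal(expected_mismatch_spatial(j, 0, th, 2), stat,
               tolerance = 1e-12)
  # large-M spatial converges to the infinite-theta1 demographic curve
  expect_equal(expected_mismatch_spatial(0:15, 2, 1, 1e7),
               expected_mismatch_demographic(0:15, 2, 1, 1e7),
               tolerance = 1e-6)
  # every curve is a (sub-normalized) probability vector
  expect_true(all(expected_mismatch_demographic(0:60, 3, 0.5, 50) >= 0))
  expect_lte(sum(expected_mismatch_demographic(0:200, 3, 0.5, 50)), 1 + 1e-8)
})

test_that("expansion fits are self-consistent at the optimum", {
  # demographic: exact expected curve tau = 3, theta0 = 0.5, theta1 = 50
  x <- expected_mismatch_demographic(0:30, 3, 0.5, 50)
  md <- structure(list(x = x / sum(x), d = 30L, n_pairs = choose(50, 2),
                       n = 50), class = "mismatch_dist")
  f <- fit_demographic_expansion(md, n_boot = 0)
  expect_equal(f$tau, 3, tolerance = 0.1)

  # spatial: tau = 2, theta = 1, M = 5
  xs <- expected_mismatch_spatial(0:30, 2, 1, 5)
  mds <- structure(list(x = xs / sum(xs), d = 30L, n_pairs = choose(50, 2),
                        n = 50), class = "mismatch_dist")
  fs <- fit_spatial_expansion(mds, n_boot = 0)
  expect_equal(fs$tau, 2, tolerance = 0.15)

  # the variance-weighted objective finds the same optimum on exact data
  fw <- fit_demographic_expansion(md, n_boot = 0, weighted = TRUE)
  expect_equal(fw$tau, 3, tolerance = 0.1)
})

test_that("raggedness follows the closing-term convention and penalizes spikes", {
  expect_equal(raggedness(c(1.0)), 1.0)
  expect_equal(raggedness(c(0.5, 0.5)), 0.25)
  md <- mismatch(toy_spectrum(c("ACGT", "ACGT"), c("P", "P")))
  expect_equal(raggedness(md), 1.0)

  smooth <- expected_mismatch_demographic(0:10, 0, 1, 1)
  spiked <- smooth
  spiked[5] <- spiked[5] + 0.1
  spiked[6] <- spiked[6] - 0.1
  expect_gt(raggedness(spiked), raggedness(smooth))
})

test_that("the raggedness bootstrap flags distributions no expansion explains", {
  set.seed(20)
  st <- simulate_coalescent_stats(30, theta = 20, growth_factor = 100,
                                  growth_time = 3 / 20)
  md <- comppop:::.mismatch_from_counts(st$mismatch_counts, 30)
  f <- fit_demographic_expansion(md, n_boot = 0)
  p_null <- raggedness_test(md, f, n_boot = 200, seed = 21)
  expect_gte(p_null, 1 / 201)
  expect_lte(p_null, 1)

  # strongly bimodal artificial distribution: small p against the same fit
  bimodal <- c(0.45, 0, 0, 0, 0.1, 0, 0, 0, 0.45)
  md_b <- structure(list(x = bimodal, d = 8L, n_pairs = choose(30, 2),
                         n = 30), class = "mismatch_dist")
  f_b <- fit_demographic_expansion(md_b, n_boot = 0)
  expect_lt(raggedness_test(md_b, f_b, n_boot = 200, seed = 22), 0.05)
})

test_that("Tajima's D evaluates the 1989 constants", {
  # numerator zero when k equals S/a1
  a1 <- sum(1 / 1:9)
  expect_equal(tajima_d(5, 10, 5 / a1), 0)
  # frozen from an independent re-derivation of the constants
  expect_equal(tajima_d(5, 10, 1.0), -1.7410958652, tolerance = 1e-9)
  expect_error(tajima_d(0, 10, 1), "S >= 1")
  expect_error(tajima_d(3, 3, 1), "n >= 4")
})

test_that("Fu's Fs follows the Ewens sampling formula", {
  # n = 3, theta = 1: |s(3,k)| = (2, 3, 1), S' = P(K >= 2) = 2/3
  expect_equal(fu_fs(2, 3, 1), log(2), tolerance = 1e-12)
  # k_obs = 1 means S' = 1: guarded overflow
  expect_error(fu_fs(1, 3, 1), "overflow")
  # excess of haplotypes at tiny theta: strongly negative
  expect_equal(fu_fs(10, 10, 0.2), -27.82458, tolerance = 1e-4)
  expect_error(fu_fs(2, 3, 0), "theta > 0")
})

test_that("R2 matches the full hand computation", {
  # n = 3, one singleton: U = (0,1,0), k = 2/3, R2 = sqrt(2/9)
  seqs <- rbind(strsplit("AAAA", "")[[1]],
                strsplit("ATAA", "")[[1]],
                strsplit("AAAA", "")[[1]])
  expect_equal(r2_stat(seqs), sqrt(2 / 9), tolerance = 1e-12)

  # no singletons: all U_i = 0, R2 = (k/2)/S
  seqs2 <- rbind(strsplit("AAT", "")[[1]], strsplit("AAT", "")[[1]],
                 strsplit("AAA", "")[[1]], strsplit("AAA", "")[[1]])
  k <- (4 * 1) / choose(4, 2)
  expect_equal(r2_stat(seqs2), (k / 2) / 1, tolerance = 1e-12)

  expect_error(r2_stat(rbind(rep("A", 4), rep("A", 4), rep("A", 4))),
               "S >= 1")
})

test_that("coalescent p-values centre on one half at the simulated median", {
  set.seed(30)
  null_d <- replicate(400, {
    st <- simulate_coalescent_stats(10, S = 5, mode = "fixed_S")
    tajima_d(5, 10, st$k_hat)
  })
  d_med <- stats::median(null_d)
  p <- neutrality_pvalues(5, 10, d_obs = d_med, n_sim = 400, seed = 31)$p_d
  expect_lt(abs(p - 0.5), 0.15)
})

test_that("the neutrality summary runs end to end on simulated data", {
  sim <- simulate_alignment(12, theta = 4, L = 300, seed = 32)
  spec <- collapse_haplotypes(sim$alignment, sim$popmap)
  nt <- neutrality_tests(spec, n_sim_dfs = 200, n_sim_r2 = 200, seed = 33)
  expect_true(all(c("tajima_d", "fu_fs", "r2") %in% names(nt)))
  expect_true(all(nt[, c("p_d", "p_fs", "p_r2")] >= 0 &
                  nt[, c("p_d", "p_fs", "p_r2")] <= 1))
})

test_that("expansion-age conversion follows t = tau / (2 u L)", {
  expect_equal(expansion_time(0, 1.66, 656)$t_years, 0)
  t1 <- expansion_time(2.31, 1.66, 656)
  expect_equal(t1$t_years, 2.31 / (2 * 1.66e-8 * 656), tolerance = 1e-12)
  # doubling the rate halves the time
  t2 <- expansion_time(2.31, 3.32, 656)
  expect_equal(t2$t_years, t1$t_years / 2)
  # both conventions agree numerically
  expect_equal(expansion_time(2.31, 1.66, 656, "per_site")$t_years,
               t1$t_years)
  expect_error(expansion_time(-1, 1.66, 656), "tau")
  expect_error(expansion_time(1, 0, 656), "positive")
})
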