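# Reproductive-output derivation from field traits: per-female fecundity,
# spawning frequency, adult density and the vegetation-coverage correction
# combine into per-area egg production. The three products share the same
# factors, so the two factorizations eggs_m2_yr = eggs_m2 * spawnings_yr =
# density * eggs_f_yr * coverage agree exactly, and every derived metric is
# homogeneous of degree 1 in density.

#' @keywords internal
.check_nonneg <- function(...) {
  vals <- list(...)
  for (nm in names(vals))
    if (any(vals[[nm]] < 0, na.rm = TRUE))
      stop("parameter error: ", nm, " must be non-negative")
}

#' Eggs produced per female per year
#'
#' @param eggs_per_spawning mean eggs per female per spawning event.
#' @param spawnings_yr spawning events per year.
#' @return eggs female^-1 year^-1 (vectorized).
#' @export
eggs_per_female_year <- function(eggs_per_spawning, spawnings_yr) {
  .check_nonneg(eggs_per_spawning = eggs_per_spawning,
                spawnings_yr = spawnings_yr)
  eggs_per_spawning * spawnings_yr
}

#' Eggs produced per square metre per spawning event, coverage-corrected
#'
#' Adult density times per-female fecundity, corrected by the fraction of
#' the forest actually covered by the vegetation belt the species occupies.
#'
#' @param density adult density, individuals m^-2.
#' @param eggs_per_spawning mean eggs per female per spawning event.
#' @param coverage vegetation-coverage correction, a fraction in [0, 1].
#' @return eggs m^-2 (vectorized).
#' @export
eggs_per_m2 <- function(density, eggs_per_spawning, coverage) {
  .check_nonneg(density = density, eggs_per_spawning = eggs_per_spawning,
                coverage = coverage)
  if (any(coverage > 1, na.rm = TRUE))
    stop("parameter error: coverage must be a fraction in [0, 1]")
  density * eggs_per_spawning * coverage
}

#' Eggs produced per square metre per year, coverage-corrected
#'
#' @inheritParams eggs_per_m2
#' @param spawnings_yr spawning events per year.
#' @return eggs m^-2 year^-1 (vectorized).
#' @export
eggs_per_m2_year <- function(density, eggs_per_spawning, spawnings_yr,
                             coverage) {
  eggs_per_m2(density, eggs_per_spawning, coverage) * spawnings_yr
}

#' Read a species trait table
#'
#' @param path TSV with one row per species; required columns
#'   `species`, `spawnings_yr`, `density_m2`, `eggs_per_spawning`,
#'   `coverage`; further trait columns are carried through.
#' @return data.frame of traits.
#' @export
read_trait_table <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "spawnings_yr", "density_m2", "eggs_per_spawning",
            "coverage")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trait table lacks column(s): ", paste(miss, collapse = ", "))
  tr
}

#' Add derived reproductive-output columns to a trait table
#'
#' Computes `eggs_f_yr`, `eggs_m2` and `eggs_m2_yr` from the primary trait
#' columns.
#'
#' @param traits a trait table as returned by [read_trait_table()].
#' @return the table with the three derived columns appended.
#' @export
derive_reproductive_output <- function(traits) {
  traits$eggs_f_yr <- eggs_per_female_year(traits$eggs_per_spawning,
                                           traits$spawnings_yr)
  traits$eggs_m2 <- eggs_per_m2(traits$density_m2, traits$eggs_per_spawning,
                                traits$coverage)
  traits$eggs_m2_yr <- eggs_per_m2_year(traits$density_m2,
                                        traits$eggs_per_spawning,
                                        traits$spawnings_yr, traits$coverage)
  traits
}

#' Bundled trait table for the seven mangrove crab species
#'
#' Life-history and ecological traits (family, distribution range, habitat,
#' spawning events per year, spawning zone, pelagic larval duration, adult
#' density, per-spawning fecundity) for the seven co-occurring Western
#' Indian Ocean mangrove crabs, compiled from published field surveys. The
#' vegetation-coverage correction is 0.225 for every species, the single
#' value consistent with the published corrected egg outputs; maximum
#' carapace width is shipped as missing (the printed source value is an
#' evident typesetting fault).
#'
#' @return data.frame, one row per species.
#' @export
crab_traits <- function() {
  read_trait_table(system.file("extdata", "mangrove_crab_traits.tsv",
                               package = "comppop", mustWork = TRUE))
}

#' Bundled genetic summary table for the seven mangrove crab species
#'
#' Published per-species genetic summaries (sample size, haplotype count,
#' segregating sites, haplotype diversity with SE, current and historical
#' nucleotide diversity, average pairwise gamma-st, Tajima's D, Fu's Fs,
#' R2, raggedness, and expansion ages tau under the demographic and spatial
#' models with 95% CIs), used as inputs to the trait-genetics regressions.
#'
#' @return data.frame, one row per species.
#' @export
crab_genetics <- function() {
  utils::read.delim(system.file("extdata", "mangrove_crab_genetics.tsv",
                                package = "comppop", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Fecundity-body size regression
#'
#' Ordinary least squares of per-spawning fecundity (optionally log10) on
#' carapace width, with a permutation p-value for the slope.
#'
#' @param eggs_per_spawning numeric vector of fecundities.
#' @param cw numeric vector of carapace widths (same length).
#' @param n_perm permutations for the p-value.
#' @param seed optional RNG seed.
#' @param log10_eggs regress log10(fecundity) instead of fecundity.
#' @return list with `slope`, `r2`, `p`.
#' @export
fecundity_size_regression <- function(eggs_per_spawning, cw, n_perm = 999,
                                      seed = NULL, log10_eggs = FALSE) {
  if (length(eggs_per_spawning) != length(cw))
    stop("vectors must have equal length")
  if (length(cw) < 3) stop("insufficient sample: need n >= 3")
  if (stats::var(cw) == 0)
    stop("degenerate regression: predictor has zero variance")
  y <- if (log10_eggs) log10(eggs_per_spawning) else eggs_per_spawning
  fit <- permutational_regression(y, cbind(cw = cw), n_perm = n_perm,
                                  seed = seed)
  list(slope = unname(fit$coefficients["cw"]), r2 = fit$r2, p = fit$p_perm)
}
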