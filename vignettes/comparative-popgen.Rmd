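---
title: "Comparative mtDNA population genetics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mtDNA population genetics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comppop)
```

comppop implements the full analysis chain used in comparative single-locus
population genetics of co-occurring species: within-species diversity,
among-population differentiation with permutation nulls, demographic-history
inference from mismatch distributions and neutrality tests, haplotype
networks, reproductive-output derivation from field traits, and
permutational regression linking those traits to the genetic summaries.
This vignette explains the models behind each stage, the conventions and
tunable parameters, what the bundled coalescent simulator does and does not
emulate, and the design choices made where the methodology was genuinely
open.

## Data model

An alignment is a set of equal-length mtDNA sequences (here, COI barcoding
fragments of roughly 550–660 bp). Gaps and ambiguity codes are treated as
missing data, never as a fifth state: the marker is protein-coding, so
indels in the alignment are artifacts. Under the default
`complete_deletion` policy every column containing any missing symbol is
masked for the whole alignment, giving all estimators one common set of
*usable sites*; `pairwise_deletion` is available but flagged in the output,
because haplotype identity is then no longer transitive over the site
mask. Two sequences share a haplotype iff they are identical at all usable
sites, and all downstream statistics operate on the resulting *haplotype
spectrum*: distinct haplotypes, a population-by-haplotype count matrix, and
the matrix of raw pairwise differences.

Sampling sites are pooled into analysis populations by single-linkage
clustering under great-circle distance with a 50 km cut
(`group_sites()`): chains of sites each within 50 km of the next form one
population, which matches how field collections made at neighbouring
creeks within a coastal zone are treated as one population. The threshold
and the linkage are both explicit arguments because published site
groupings rarely state an algorithm; cluster labels (A, B, C, ... by the
latitude of the northernmost member) are deterministic and order-invariant,
and a user-supplied `group` column always takes precedence.

## Diversity

Haplotype diversity is the unbiased gene diversity
$h = \frac{n}{n-1}(1 - \sum_i p_i^2)$, the probability that two sequences
drawn without replacement differ, with Nei's (1987) sampling variance for
the standard error. Current nucleotide diversity is the mean number of raw
differences over all $\binom{n}{2}$ sequence pairs ($\hat k$), reported as
percent per usable site ($\theta_\pi$); historical diversity is
Watterson's $\theta_w = S/a_n$ on the same percent-per-site scale. Both
use the post-masking usable-site count as denominator, not the nominal
fragment length — species fragments differ in length and missing data, and
the masked length is what the counts were computed on. $\theta_\pi$
deliberately uses raw counts rather than model-corrected distances (it is
defined as a mean number of differences); the Tajima–Nei correction enters
only through the distance matrix used by AMOVA. Comparing the two
estimators classifies recent history: $\theta_\pi > \theta_w$ indicates
growth, $\theta_\pi < \theta_w$ a bottleneck, with an explicit equality
tolerance (`eps = 1e-9` on the percent scale) because printed tables never
compare exactly equal values.

The Tajima–Nei distance implemented is the equal-input form
$d = -b\,\ln(1 - p/b)$ with $b = 1 - \sum_i g_i^2$ and base frequencies
$g$ pooled over all sequences. At equal frequencies $b = 3/4$ and the
distance reduces to Jukes–Cantor, which the tests use as a closed-form
oracle. Saturated pairs ($p \ge b$) raise an error naming the pair rather
than returning NaN.

## Differentiation

`amova()` is the one-level analysis of molecular variance: total and
within-population sums of squared inter-individual distances decompose
into variance components $\sigma^2_a$ (among) and $\sigma^2_w$ (within),
and $\Phi_{st} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)$. With no distance
matrix every pair of distinct haplotypes is at squared distance 1, the
haplotype-frequency-only mode (a conventional $F_{st}$); with the
Tajima–Nei matrix the entries are treated as squared distances. Negative
variance components are reported as computed, never clamped — they are the
expected behaviour of the moment estimator near panmixia. Significance
comes from permuting individuals among populations with sample sizes held
fixed, and every permutation p-value in the package uses the
$(\#\{T^* \ge T_{obs}\} + 1)/(B + 1)$ estimator so that no p-value is
exactly zero.

A consequence worth stating explicitly: with shared haplotypes, many
permutations of individuals are numerically identical, so permutation
p-values of the AMOVA family are *discretely conservative* — under
panmixia mass piles up near $p = 1$ and $P(p \le \alpha)$ sits below
$\alpha$. The calibration suite therefore asserts strict uniformity for
the continuous-statistic p-values (coalescent Tajima's D, regression
pseudo-F) and, for the tie-prone label-permutation tests, that the type-I
error never exceeds the nominal level. Anti-conservatism is the failure
mode being guarded against; conservatism is a documented property of the
estimator, not a defect.

Nei's $\gamma_{st} = (h_T - h_S)/h_T$ is the haplotype-frequency measure
of subdivision. The estimator here takes $h_S$ as the unweighted mean of
per-population unbiased diversities and $h_T$ as
$\frac{N}{N-1}(1 - \sum_i \bar x_i^2)$ from the unweighted mean haplotype
frequencies; `unbiased = FALSE` drops both corrections for comparison,
since the exact small-sample variant used by the classical software is not
published. The headline statistic is the average of $\gamma_{st}$ over all
population pairs, which is what comparative tables report. Hudson's
$S_{nn}$ asks how often a sequence's nearest neighbours (minimum raw
difference, self excluded, ties shared equally) come from its own
population, with label-permutation significance. The exact test of
differentiation runs a Metropolis chain over population-by-haplotype
tables with fixed margins (default 10,000 retained steps after 1,000
burn-in, both configurable) and estimates the probability mass of tables
no more probable than the observed one; on 2x2 tables it agrees with full
enumeration to Monte-Carlo error. The Monte-Carlo chi-squared keeps every
rare haplotype unpooled and randomizes tables with both margins fixed
(Patefield's algorithm) at 20,000 draws by default.

## Demographic history

The mismatch distribution is the histogram of pairwise differences over
all sequence pairs of the pooled species sample. Under a sudden
demographic expansion the expected curve follows the two-epoch model: a
pair's coalescence time (in pair-mutational units, so differences are
Poisson around it) is exponential at rate $1/\theta_1$ until the
expansion age $\tau$ and $1/\theta_0$ beyond it. Mixing Poisson classes
over that density gives closed-form incomplete-gamma expressions,
evaluated through `pgamma` on the log scale so that tiny $\theta_0$ never
overflows; at $\tau = 0$ the curve is the stationary
$\hat F_j(\theta) = \theta^j/(1+\theta)^{j+1}$. The spatial (range)
expansion model is the infinite-island analogue with migration rate $M$:
within-deme pairs either coalesce or separate into demes that never
re-meet until the colonization time $\tau$, giving a second closed form
with parameters $(\tau, \theta, M)$. As $M \to \infty$ it converges to
the demographic curve with effectively infinite post-expansion size,
which the tests verify numerically.

Both models are fitted by unweighted least squares on the relative class
frequencies over the observed classes, from several starting points, with
box constraints ($\theta_1 \le 99{,}999$ by default, the conventional
"effectively infinite" bound that stabilizes the optimizer; bounds are
arguments). The default objective is the plain sum of squared deviations;
a binomial-variance-weighted objective is available through
`weighted = TRUE` on both fit functions. Confidence intervals for $\tau$
are percentile intervals from a
parametric bootstrap: coalescent samples of the same size simulated under
the fitted model, each refitted. The raggedness index
$rg = \sum_{j=1}^{d+1}(x_j - x_{j-1})^2$ uses the closing term
$x_{d+1} = 0$, kept in exactly one place in the code and pinned by
hand-computed tests; its significance is the fraction of samples simulated
under the fitted expansion with raggedness at least as large as observed.

Three neutrality tests complete the demographic picture. Tajima's D
compares $\hat k$ with $S/a_1$ using the 1989 constants. Fu's Fs is
$\ln(S'/(1-S'))$ with $S' = \Pr(K \ge k_{obs})$ under the Ewens sampling
formula at $\theta = \hat k$; the unsigned Stirling numbers of the first
kind are carried on the log scale, so samples of several hundred
sequences are fine. R2 measures how the singleton load per sequence
deviates from $\hat k/2$, scaled by $S$; singletons are folded
(minor-allele count 1), since mtDNA data carry no outgroup polarity here.
All three take simulation p-values from neutral constant-size coalescent
samples conditioned on the observed number of segregating sites (fixed-S:
exactly S mutations placed uniformly on the genealogy). Conditioning on S
rather than on an estimated $\theta$ avoids estimating the nuisance
parameter twice and matches the classical practice of the software this
reimplements; fixed-$\theta$ simulation is available through the same
simulator. P-values are one-tailed in the expansion direction (low D, low
Fs, low R2) by default, with a two-sided option, because the biological
question here is deviation toward expansion.

Expansion ages in years use $t = \tau/(2u)$ with $u$ the per-sequence
per-year rate: $t = \tau/(2\,\mu_{site}\,L)$ for a per-site rate
$\mu_{site}$ over $L$ sites. Both the per-sequence and per-site readings
are implemented and give the same number; the convention is recorded in
the output. Note that published expansion ages for this system are about
an order of magnitude older than this formula yields for any standard
reading of the printed rates (1.15–1.66% per million years over a ~656 bp
fragment); the conversion is therefore exposed with its convention rather
than calibrated to reproduce printed ages, and the discrepancy is flagged
wherever ages are reported.

## Haplotype networks

`build_msn()` returns the union of *all* minimum spanning trees of the
haplotype difference matrix (Kruskal with tied-weight retention: an edge
survives iff its endpoints are in separate components of the
strictly-lighter subgraph), so tied mutational pathways are all shown
instead of an arbitrary one. Median vectors — inferred unsampled
haplotypes — are deliberately out of scope, so published network figures
that include them may show extra internal nodes. Node annotations carry
total and per-population frequencies; export formats are GraphML, DOT and
a TSV edge list. `star_likeness()` reports two descriptive indexes of the
star shape typical of expanded populations: the modal haplotype's share
of individuals and the fraction of singleton haplotypes.

## Reproductive output and trait regressions

Three products derive population fecundity from field traits: eggs per
female per year (per-spawning fecundity x spawnings per year), eggs per
m2 (density x per-spawning fecundity x vegetation coverage) and eggs per
m2 per year (all four factors). The vegetation-coverage factor scales
per-area output by the fraction of forest the species' belt actually
occupies. The bundled trait table ships 0.225 for all seven species: that
single value reproduces the published corrected outputs exactly in two
independent identities (checked in the acceptance suite), though
per-species coverages almost certainly differ — for the gecarcinid the
published narrative range implies a smaller coverage — so the column is
per-species and overridable. Maximum carapace width is shipped as missing
(the printed source value is an evident typesetting fault), which is why
the size–fecundity regression is provided as a generic operation and
tested on synthetic data only.

Cross-species inference uses permutational tools because there are as
many observations as species (seven): `permutational_regression()` fits
OLS and references the whole-model pseudo-F against unrestricted
permutations of the raw response (with $n = 7$, residual-permutation
schemes are indistinguishable from raw-response permutation; the scheme
is an argument). Haplotype diversity responses are log10-transformed via
a flag; predictors are left untransformed by default with per-column log
options, and a log-fecundity variant is always reported alongside the
primary fit in the analysis scripts since fecundities span four orders of
magnitude. `aic_subset_search()` evaluates every non-empty predictor
subset with $AIC = n\ln(RSS/n) + 2K$ (K counts the intercept); the search
is exhaustive, hence exact and reproducible, for registries up to 15
predictors. Two caveats are documented rather than hidden: at $n = 7$,
subsets of five predictors leave one residual degree of freedom and AIC
will happily select them (the model table reports every subset so this is
visible), and AIC admits a spurious companion variable with probability
roughly $P(\chi^2_1 > 2) \approx 0.16$ per candidate at any noise level,
so "the selected set contains the generating predictor" is the property
that calibrates, not exact recovery (exact recovery holds for noiseless
responses). Heteroscedasticity screening across species-level responses
uses a Levene-type check on a categorical split rather than Cochran's C,
which requires grouped replicates a seven-row table does not have; this
is a deliberate divergence from the classical recipe. Categorical traits
(family, range, habitat, spawning zone) are tested by one-way
permutational ANOVA on Euclidean partitioning.

## The coalescent simulator

`simulate_alignment()` and the leaner `simulate_coalescent_stats()`
implement a Hudson-style neutral coalescent: equilibrium, sudden growth
by a factor at a given time, and finite-island symmetric migration (plus
the infinite-island colonization variant used internally by the
spatial-model bootstrap). Time is in units of $2N$ generations, mutations
at rate $\theta/2$ per lineage, so $E[S] = \theta a_n$ and
$E[\hat k] = \theta$ at equilibrium — both verified against those closed
forms, along with the stationary mismatch distribution and the slight
negative bias of Tajima's D at equilibrium. Mutations follow the
infinite-sites model mapped onto distinct alignment columns: pairwise
differences are exactly additive, matching the assumptions of the
mismatch and neutrality machinery (a locus can therefore run out of
columns for very deep genealogies; the error message says so, and the
fix is a longer `L`). What the simulator does *not* emulate: recurrent or
back mutation, rate heterogeneity across sites, selection, recombination,
and sequencing error. Passing tests on synthetic data therefore validate
the estimators under the models' own assumptions, not the robustness of
those estimators to real-data violations of them.

Fixed problem sizes used by the validation suite, chosen as realistic for
this kind of data and stated here as the package's own conditions:
equilibrium calibration at $n = 50$, $\theta = 5$, 2,000 replicates
(5,000 for the stationary mismatch band of 0.01); expansion-age recovery
under 100x sudden growth with present-day $\theta_1 = 50$ at
$\tau \in \{1, 3, 5\}$, 600 fit replicates per $\tau$; bootstrap-interval
coverage at $\tau = 3$ with 200 replicates of 200 bootstrap refits.

## Known limitations

* Mismatch-based $\tau$ estimation is upward-biased when the expansion
  age is at the scale of the ancestral diversity: under the 100x-growth
  conditions above ($\theta_0 = 0.5$), the median fitted $\tau$ at true
  $\tau = 1$ sits near 1.3 — the unweighted least-squares surface has a
  ridge along $\tau + \theta_0$, and neither variance weights, extra
  trailing classes, nor pinning $\theta_1$ removes it. At $\tau = 3$ and
  5 the median bias is under 10% and the 95% bootstrap intervals cover at
  roughly nominal rate. Single-locus $\tau$ estimates for weak or very
  recent expansions should be read with their intervals, not as points.
* Tie-induced conservatism of the label-permutation p-values, described
  above.
* The per-species published statistics (diversity tables, neutrality
  values, expansion ages) require the archived sequence data, which are
  not bundled; the pipeline accepts those FASTA files directly when
  available, and the bundled genetic-summary table carries the published
  values as *inputs* for the trait regressions.
* $\gamma_{st}$'s small-sample correction variant is a documented choice
  (see above), not a reproduction of any particular legacy
  implementation.
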