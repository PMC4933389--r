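# Neutral coalescent simulator: equilibrium, sudden growth, finite-island
# migration, and the infinite-island colonization model used by the
# spatial-expansion bootstrap. Infinite-sites mutations are mapped onto
# distinct alignment columns, so pairwise differences are additive and
# match the assumptions of the mismatch/neutrality machinery.
#
# Time is measured in coalescent units (2N generations of the present-day
# deme): a pair of lineages in one deme coalesces at rate 1, a lineage
# carries mutations at rate theta/2, so E[pairwise differences] = theta at
# equilibrium and E[S] = theta * a_n. A sudden growth by `growth_factor` at
# time `growth_time` multiplies coalescence rates by that factor further
# back in time (the ancestral population is smaller). `growth_time` is in
# coalescent units; the pair-mutational expansion age is tau = theta *
# growth_time, which is how fitted tau values map onto the simulator.

# genealogy of n lineages under piecewise-constant size; returns, for each
# non-root node, its branch length and the set of descendant tips
#' @keywords internal
.sim_genealogy <- function(n, growth_factor = 1, growth_time = Inf) {
  n_nodes <- 2L * n - 1L
  time <- numeric(n_nodes)
  desc <- vector("list", n_nodes)
  for (i in seq_len(n)) desc[[i]] <- i
  active <- seq_len(n)
  parent <- integer(n_nodes)
  t_now <- 0
  nxt <- n
  while (length(active) > 1L) {
    k <- length(active)
    rate <- choose(k, 2)
    dt <- stats::rexp(1, rate * if (t_now >= growth_time) growth_factor else 1)
    if (t_now < growth_time && t_now + dt > growth_time) {
      # crossed the size change: restart the memoryless wait at the new rate
      t_now <- growth_time
      dt <- stats::rexp(1, rate * growth_factor)
    }
    t_now <- t_now + dt
    pick <- sample.int(k, 2L)
    nxt <- nxt + 1L
    ch <- active[pick]
    parent[ch] <- nxt
    time[nxt] <- t_now
    desc[[nxt]] <- c(desc[[ch[1]]], desc[[ch[2]]])
    active <- c(active[-pick], nxt)
  }
  len <- time[parent[-n_nodes]] - time[-n_nodes]
  list(n = n, branch_len = len, desc = desc[-n_nodes],
       total_len = sum(len), tmrca = t_now)
}

# structured genealogy: finite symmetric island model (n_pops demes,
# per-lineage migration rate M/2) or, with islands = Inf, the infinite-
# island colonization model where all demes collapse into one ancestral
# deme at `collapse_time` (used by the spatial-expansion bootstrap)
#' @keywords internal
.sim_genealogy_structured <- function(n_per_deme, migration,
                                      growth_factor = 1, growth_time = Inf,
                                      islands = length(n_per_deme),
                                      collapse_time = Inf) {
  n <- sum(n_per_deme)
  n_nodes <- 2L * n - 1L
  time <- numeric(n_nodes)
  desc <- vector("list", n_nodes)
  for (i in seq_len(n)) desc[[i]] <- i
  parent <- integer(n_nodes)
  deme <- rep.int(seq_along(n_per_deme), n_per_deme)
  active <- seq_len(n)
  adem <- deme
  t_now <- 0
  nxt <- n
  next_deme <- length(n_per_deme)
  repeat {
    k <- length(active)
    if (k == 1L) break
    counts <- table(adem)
    mult <- if (t_now >= growth_time) growth_factor else 1
    coal_rate <- sum(choose(counts, 2)) * mult
    # with infinitely many islands a lineage alone in its deme can never be
    # joined, so only migrations out of shared demes are observable events
    movable <- if (is.infinite(islands))
      which(adem %in% as.integer(names(counts))[counts >= 2L])
    else seq_len(k)
    mig_rate <- if (t_now >= collapse_time) 0
                else length(movable) * migration / 2
    rate <- coal_rate + mig_rate
    if (rate == 0) {
      if (is.finite(collapse_time) && t_now < collapse_time) {
        t_now <- collapse_time
        adem[] <- 0L  # single ancestral deme
        next
      }
      stop("structure error: lineages cannot coalesce (migration rate 0 ",
           "with lineages in separate demes)")
    }
    dt <- stats::rexp(1, rate)
    crossed_g <- t_now < growth_time && t_now + dt > growth_time
    crossed_c <- is.finite(collapse_time) && t_now < collapse_time &&
                 t_now + dt > collapse_time
    if (crossed_g || crossed_c) {
      t_next <- min(growth_time[crossed_g], collapse_time[crossed_c])
      t_now <- t_next
      if (crossed_c && t_next == collapse_time) adem[] <- 0L
      next  # redraw under the new rates (memoryless)
    }
    t_now <- t_now + dt
    if (stats::runif(1) < coal_rate / rate) {
      # coalescence within a deme chosen proportionally to C(k_d, 2)
      w <- choose(counts, 2)
      d_pick <- as.integer(names(counts))[sample.int(length(w), 1L, prob = w)]
      in_d <- which(adem == d_pick)
      pick <- in_d[sample.int(length(in_d), 2L)]
      nxt <- nxt + 1L
      ch <- active[pick]
      parent[ch] <- nxt
      time[nxt] <- t_now
      desc[[nxt]] <- c(desc[[ch[1]]], desc[[ch[2]]])
      active <- c(active[-pick], nxt)
      adem <- c(adem[-pick], d_pick)
    } else {
      i <- movable[sample.int(length(movable), 1L)]
      if (is.infinite(islands)) {
        next_deme <- next_deme + 1L  # fresh, never-visited deme
        adem[i] <- next_deme
      } else {
        adem[i] <- sample(setdiff(seq_len(islands), adem[i]), 1L)
      }
    }
  }
  len <- time[parent[-n_nodes]] - time[-n_nodes]
  list(n = n, branch_len = len, desc = desc[-n_nodes],
       total_len = sum(len), tmrca = t_now)
}

# place mutations on a genealogy: Poisson(theta/2 * L_total) or exactly S,
# branches chosen proportionally to length; returns n x S 0/1 matrix of
# derived states (infinite sites: one column per mutation)
#' @keywords internal
.drop_mutations <- function(g, theta = NULL, S = NULL) {
  n_mut <- if (!is.null(S)) as.integer(S)
           else stats::rpois(1, theta / 2 * g$total_len)
  X <- matrix(0L, g$n, n_mut)
  if (n_mut > 0L) {
    br <- sample.int(length(g$branch_len), n_mut, replace = TRUE,
                     prob = g$branch_len)
    for (m in seq_len(n_mut)) X[g$desc[[br[m]]], m] <- 1L
  }
  X
}

# summary statistics from a 0/1 derived-state matrix
#' @keywords internal
.stats_from_matrix <- function(X) {
  n <- nrow(X)
  dac <- colSums(X)                      # derived allele counts
  poly <- dac > 0L & dac < n
  S <- sum(poly)
  npair <- choose(n, 2)
  k_hat <- if (S) sum(dac[poly] * (n - dac[poly])) / npair else 0
  K <- length(unique(apply(X[, poly, drop = FALSE], 1L, paste0, collapse = "")))
  # folded singletons: columns whose minor allele has count 1
  minor1 <- poly & pmin(dac, n - dac) == 1L
  U <- integer(n)
  for (m in which(minor1)) {
    carrier <- if (dac[m] == 1L) which(X[, m] == 1L) else which(X[, m] == 0L)
    U[carrier] <- U[carrier] + 1L
  }
  # pairwise-difference histogram over classes 0..max
  Dm <- .pairdiff_matrix(X[, poly, drop = FALSE])
  dd <- Dm[upper.tri(Dm)]
  mm <- tabulate(dd + 1L, nbins = max(dd) + 1L)
  list(S = S, k_hat = k_hat, K = K, U = U, n = n,
       mismatch_counts = mm)
}

#' @keywords internal
.pairdiff_matrix <- function(X) {
  if (ncol(X) == 0L) return(matrix(0L, nrow(X), nrow(X)))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  D <- X %*% t(1 - X)
  D + t(D)
}

#' Simulate neutral coalescent summary statistics
#'
#' Fast path used by the null distributions of the neutrality tests, the
#' calibration checks and the parametric bootstraps: simulates one sample
#' and returns its summary statistics without materialising an alignment.
#'
#' @param n sample size (single population).
#' @param theta per-sequence scaled mutation rate (ignored in `fixed_S`
#'   mode).
#' @param S with `mode = "fixed_S"`, place exactly `S` mutations uniformly
#'   on the genealogy.
#' @param growth_factor,growth_time sudden growth by `growth_factor` at
#'   `growth_time` coalescent units in the past (1 and `Inf` = equilibrium).
#' @param mode `"fixed_theta"` (Poisson mutations) or `"fixed_S"`.
#' @return list with `S`, `k_hat` (mean pairwise differences), `K`
#'   (distinct haplotypes), `U` (per-sequence folded singleton counts),
#'   `n`, and `mismatch_counts` (pair counts per difference class 0, 1, ...).
#' @export
simulate_coalescent_stats <- function(n, theta = NULL, S = NULL,
                                      growth_factor = 1, growth_time = Inf,
                                      mode = c("fixed_theta", "fixed_S")) {
  mode <- match.arg(mode)
  if (mode == "fixed_S") {
    if (is.null(S) || S < 1) stop("fixed_S mode needs S >= 1")
    theta <- NULL
  } else {
    if (is.null(theta) || theta < 0) stop("fixed_theta mode needs theta >= 0")
    S <- NULL
  }
  g <- .sim_genealogy(n, growth_factor, growth_time)
  .stats_from_matrix(.drop_mutations(g, theta = theta, S = S))
}

#' Simulate an aligned haplotype sample under the neutral coalescent
#'
#' Generates a Hudson-style genealogy (optionally with sudden growth and/or
#' symmetric island migration between populations), places infinite-sites
#' mutations on distinct alignment columns, and returns a standard
#' alignment plus population map so synthetic data flow through the
#' identical public pipeline as real data.
#'
#' @param n_samples integer vector: sample size per population (length 1 for
#'   a panmictic sample).
#' @param theta per-sequence scaled mutation rate.
#' @param L alignment length in sites (mutation columns are drawn without
#'   replacement from these).
#' @param growth_factor,growth_time sudden growth specification (see
#'   [simulate_coalescent_stats()]).
#' @param migration scaled symmetric island migration rate M (required when
#'   more than one population; per-lineage rate M/2).
#' @param mode,S `"fixed_theta"` or `"fixed_S"` with exactly `S` mutations.
#' @param seed optional RNG seed.
#' @return list with `alignment` (a `dna_alignment`) and `popmap`.
#' @export
simulate_alignment <- function(n_samples, theta, L = 600,
                               growth_factor = 1, growth_time = Inf,
                               migration = NULL,
                               mode = c("fixed_theta", "fixed_S"), S = NULL,
                               seed = NULL) {
  mode <- match.arg(mode)
  .set_seed(seed)
  n <- sum(n_samples)
  if (length(n_samples) == 1L) {
    g <- .sim_genealogy(n, growth_factor, growth_time)
  } else {
    if (is.null(migration) || migration <= 0)
      stop("island model with >1 population needs migration > 0")
    g <- .sim_genealogy_structured(n_samples, migration,
                                   growth_factor, growth_time)
  }
  X <- .drop_mutations(g, theta = if (mode == "fixed_theta") theta else NULL,
                       S = if (mode == "fixed_S") S else NULL)
  n_mut <- ncol(X)
  if (n_mut > L)
    stop("capacity error: ", n_mut, " mutations exceed L = ", L, " sites")
  ref <- sample(.valid_bases, L, replace = TRUE)
  seqm <- matrix(rep(ref, each = n), nrow = n)
  if (n_mut > 0L) {
    cols <- sample.int(L, n_mut)
    for (m in seq_len(n_mut)) {
      derived <- sample(setdiff(.valid_bases, ref[cols[m]]), 1L)
      seqm[X[, m] == 1L, cols[m]] <- derived
    }
  }
  ids <- sprintf("S%03d", seq_len(n))
  pops <- paste0("Pop", seq_along(n_samples))
  pm <- popmap(data.frame(
    sample_id = ids,
    site = rep.int(pops, n_samples),
    latitude = rep.int(seq_along(n_samples), n_samples),
    longitude = 0,
    group = rep.int(pops, n_samples)))
  list(alignment = alignment(ids, seqm), popmap = pm)
}

#' Simulate a trait table with a known linear link to genetic summaries
#'
#' Builds a response `X beta + N(0, noise_sd)` over a predictor matrix
#' (supplied genetic summaries, or standard-normal predictors), returning
#' the true coefficients so regression and model-selection machinery can be
#' tested for parameter recovery.
#'
#' @param n_species number of rows (species).
#' @param beta numeric coefficient vector (its length sets the number of
#'   predictors when `predictors` is NULL).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param predictors optional matrix of genetic summaries to use as X.
#' @param seed optional RNG seed.
#' @return list with `predictors`, `response` and `beta`.
#' @export
simulate_trait_table <- function(n_species, beta, noise_sd = 0,
                                 predictors = NULL, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  .set_seed(seed)
  if (is.null(predictors)) {
    predictors <- matrix(stats::rnorm(n_species * length(beta)),
                         nrow = n_species,
                         dimnames = list(NULL, paste0("x", seq_along(beta))))
  }
  stopifnot(ncol(predictors) == length(beta), nrow(predictors) == n_species)
  response <- drop(predictors %*% beta) + stats::rnorm(n_species, 0, noise_sd)
  list(predictors = predictors, response = response, beta = beta)
}
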