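# fixture builders shared across test files; everything is generated in
# code so the suite carries no binary data

write_fasta <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

toy_popmap <- function(ids, sites, lat = NULL, lon = NULL) {
  usite <- unique(sites)
  if (is.null(lat)) lat <- seq_along(usite)
  if (is.null(lon)) lon <- rep(0, length(usite))
  popmap(data.frame(sample_id = ids, site = sites,
                    latitude = lat[match(sites, usite)],
                    longitude = lon[match(sites, usite)]))
}

# spectrum straight from sequence strings and population labels
toy_spectrum <- function(seqs, pops, ids = sprintf("s%02d", seq_along(seqs))) {
  aln <- alignment(ids, seqs)
  pm <- popmap(data.frame(sample_id = ids, site = pops,
                          latitude = 0, longitude = 0, group = pops))
  collapse_haplotypes(aln, pm)
}

# random small spectrum for property tests
random_spectrum <- function(n, L = 12, n_pops = 1, alphabet = c("A", "T")) {
  seqs <- replicate(n, paste0(sample(alphabet, L, replace = TRUE),
                              collapse = ""))
  pops <- paste0("P", sort(rep_len(seq_len(n_pops), n)))
  toy_spectrum(seqs, pops)
}

# naive one-level AMOVA from expanded individuals (independent oracle:
# explicit double loops over individual pairs)
naive_amova <- function(counts, d2) {
  hap <- unlist(lapply(seq_len(nrow(counts)), function(p)
    rep.int(seq_len(ncol(counts)), counts[p, ])))
  pop <- rep.int(seq_len(nrow(counts)), rowSums(counts))
  N <- length(hap)
  ssd_tot <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    ssd_tot <- ssd_tot + d2[hap[i], hap[j]]
  ssd_tot <- ssd_tot / N
  ssd_w <- 0
  for (p in unique(pop)) {
    ii <- which(pop == p)
    s <- 0
    for (a in seq_along(ii)) for (b in seq_along(ii))
      if (a < b) s <- s + d2[hap[ii[a]], hap[ii[b]]]
    ssd_w <- ssd_w + s / length(ii)
  }
  P <- nrow(counts)
  np <- rowSums(counts)
  sigma_w <- ssd_w / (N - P)
  n_c <- (N - sum(np^2) / N) / (P - 1)
  sigma_a <- ((ssd_tot - ssd_w) / (P - 1) - sigma_w) / n_c
  list(ssd_among = ssd_tot - ssd_w, ssd_within = ssd_w,
       sigma_among = sigma_a, sigma_within = sigma_w,
       phi = sigma_a / (sigma_a + sigma_w))
}

# exhaustive exact-test p over all 2-row tables with fixed margins
enumerate_exact_p <- function(obs) {
  r <- rowSums(obs); cc <- colSums(obs)
  stopifnot(nrow(obs) == 2)
  lp_obs <- -sum(lgamma(obs + 1))
  grid <- lapply(cc, function(m) 0:m)
  combos <- expand.grid(grid)
  tot <- 0; hit <- 0
  for (k in seq_len(nrow(combos))) {
    top <- as.numeric(combos[k, ])
    if (sum(top) != r[1]) next
    x <- rbind(top, cc - top)
    w <- exp(-sum(lgamma(x + 1)))
    tot <- tot + w
    if (-sum(lgamma(x + 1)) <= lp_obs + 1e-9) hit <- hit + w
  }
  hit / tot
}

# all minimum spanning trees by exhaustive enumeration of spanning edge
# subsets; returns the union of their edge sets as an indicator matrix
msn_bruteforce <- function(D) {
  H <- nrow(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  ne <- nrow(pairs)
  connected <- function(sel) {
    comp <- seq_len(H)
    for (e in sel) {
      ci <- comp[pairs[e, 1]]; cj <- comp[pairs[e, 2]]
      if (ci != cj) comp[comp == cj] <- ci
    }
    length(unique(comp)) == 1L
  }
  best_w <- Inf
  union_mat <- matrix(FALSE, H, H)
  for (sel in utils::combn(ne, H - 1, simplify = FALSE)) {
    if (!connected(sel)) next
    w <- sum(D[pairs[sel, , drop = FALSE]])
    if (w < best_w - 1e-9) {
      best_w <- w
      union_mat[] <- FALSE
    }
    if (abs(w - best_w) <= 1e-9)
      for (e in sel)
        union_mat[pairs[e, 1], pairs[e, 2]] <- TRUE
  }
  union_mat
}
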