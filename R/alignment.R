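# Alignment input, population metadata, haplotype collapsing and site grouping.
#
# Sequences are stored as a character matrix (one row per sample, one column
# per alignment site, upper-case IUPAC symbols). Gaps ('-') and ambiguity
# codes are treated as missing data, never as a fifth character state: the
# marker is a protein-coding mtDNA fragment, so indels in the alignment are
# artifacts. Internally columns are addressed 0-based half-open nowhere;
# plain 1-based R indexing is used throughout and reported as such.

#' Construct an aligned sequence set
#'
#' @param ids character vector of unique sample identifiers.
#' @param seqs character vector of equal-length sequence strings, or a
#'   character matrix with one row per sample and one column per site.
#' @param missing_policy how missing data (gaps, N, ambiguity codes) are
#'   masked downstream: `"complete_deletion"` (default) drops every column
#'   with any missing symbol for the whole alignment; `"pairwise_deletion"`
#'   drops sites per sequence pair and is flagged in downstream output.
#'
#' @return An object of class `dna_alignment`: a list with elements `ids`,
#'   `seq` (character matrix), `L` (alignment length) and `missing_policy`.
#' @export
alignment <- function(ids, seqs,
                      missing_policy = c("complete_deletion", "pairwise_deletion")) {
  missing_policy <- match.arg(missing_policy)
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    if (length(seqs) == 0L) stop("empty input: alignment has no sequences")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("alignment length error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("empty input: alignment has no sequences or zero length")
  ids <- as.character(ids)
  if (length(ids) != nrow(m)) stop("ids and sequences differ in number")
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  bad <- setdiff(unique(as.vector(m)), .iupac)
  if (length(bad))
    stop("format error: non-IUPAC symbol(s) in alignment: ",
         paste(bad, collapse = " "))
  rownames(m) <- ids
  structure(list(ids = ids, seq = m, L = ncol(m),
                 missing_policy = missing_policy),
            class = "dna_alignment")
}

#' Read an aligned FASTA file
#'
#' Thin wrapper around [ape::read.FASTA()] that enforces equal sequence
#' lengths and records the missing-data policy used by downstream site
#' masking.
#'
#' @param path path to a FASTA file of pre-aligned sequences.
#' @inheritParams alignment
#' @return A `dna_alignment` object.
#' @export
read_alignment <- function(path,
                           missing_policy = c("complete_deletion", "pairwise_deletion")) {
  missing_policy <- match.arg(missing_policy)
  dna <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(dna) || length(dna) == 0L)
    stop("empty input: no sequences in ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("alignment length error: ragged FASTA (lengths ",
         paste(sort(unique(lens)), collapse = ", "), ") in ", path)
  m <- toupper(as.character(as.matrix(dna)))
  alignment(names(dna), m, missing_policy = missing_policy)
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("Alignment:", length(x$ids), "sequences x", x$L, "sites;",
      "missing-data policy:", x$missing_policy, "\n")
  invisible(x)
}

#' Read a population map
#'
#' The population map links each sample to a sampling site and each site to
#' geographic coordinates; an optional `group` column assigns sites to
#' analysis populations (otherwise see [group_sites()]).
#'
#' @param path TSV file with columns `sample_id`, `site`, `latitude`,
#'   `longitude` and optionally `group`.
#' @return A data.frame of class `popmap`.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  popmap(pm)
}

#' @rdname read_popmap
#' @param x data.frame with the columns described above.
#' @export
popmap <- function(x) {
  need <- c("sample_id", "site", "latitude", "longitude")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("metadata error: population map lacks column(s): ",
         paste(miss, collapse = ", "))
  if (any(!is.na(x$latitude) & abs(x$latitude) > 90))
    stop("metadata error: latitude outside [-90, 90]")
  if (any(!is.na(x$longitude) & abs(x$longitude) > 180))
    stop("metadata error: longitude outside [-180, 180]")
  class(x) <- c("popmap", "data.frame")
  x
}

#' Group nearby sampling sites into analysis populations
#'
#' Sites are clustered by single-linkage agglomeration under great-circle
#' (haversine) distance and the tree is cut at `threshold_km`, so chains of
#' sites each within the threshold of the next end up in one population.
#' Clusters are labelled deterministically A, B, C, ... ordered by the
#' latitude of their northernmost member (ties broken alphabetically by
#' site name), which makes the labelling invariant to input order.
#'
#' @param pm a `popmap` (every site must have coordinates).
#' @param threshold_km linkage distance cut, in kilometres (default 50, the
#'   scale at which neighbouring mangrove sites are pooled).
#' @return The popmap with its `group` column filled.
#' @export
group_sites <- function(pm, threshold_km = 50) {
  stopifnot(inherits(pm, "popmap"))
  sites <- unique(pm[, c("site", "latitude", "longitude")])
  sites <- sites[!duplicated(sites$site), ]
  if (any(is.na(sites$latitude) | is.na(sites$longitude)))
    stop("metadata error: missing coordinates for site(s): ",
         paste(sites$site[is.na(sites$latitude) | is.na(sites$longitude)],
               collapse = ", "))
  sites <- sites[order(sites$site), ]
  if (nrow(sites) == 1L) {
    cl <- 1L
  } else {
    d_km <- geosphere::distm(cbind(sites$longitude, sites$latitude),
                             fun = geosphere::distHaversine) / 1000
    hc <- stats::hclust(stats::as.dist(d_km), method = "single")
    cl <- stats::cutree(hc, h = threshold_km)
  }
  north <- tapply(sites$latitude, cl, max)
  first_site <- tapply(sites$site, cl, function(s) min(s))
  ord <- order(-north, first_site)
  lab <- .alpha_labels(length(ord))
  relabel <- stats::setNames(lab, names(north)[ord])
  sites$group <- unname(relabel[as.character(cl)])
  pm$group <- sites$group[match(pm$site, sites$site)]
  pm
}

#' Collapse aligned sequences into a haplotype spectrum
#'
#' Two sequences share a haplotype iff they are identical at all usable
#' sites. Under `complete_deletion` (the default policy stored in the
#' alignment) usable sites are the columns where every sequence carries an
#' unambiguous base; all estimators downstream then share one site mask.
#' Under `pairwise_deletion` haplotype identity uses the full sequence
#' string and pairwise differences ignore sites missing in either member of
#' the pair; the policy is carried in the result so reports can flag it.
#'
#' @param aln a `dna_alignment`.
#' @param pm a `popmap` covering every sample in `aln`; samples are assigned
#'   to `group` if present, otherwise to `site`.
#' @return An object of class `hap_spectrum`: list with `haplotypes`
#'   (character matrix, one row per distinct haplotype over usable sites),
#'   `counts` (population x haplotype matrix), `diffs` (symmetric matrix of
#'   raw nucleotide differences), `usable_sites`, `n` and `missing_policy`.
#' @export
collapse_haplotypes <- function(aln, pm) {
  stopifnot(inherits(aln, "dna_alignment"))
  idx <- match(aln$ids, pm$sample_id)
  if (anyNA(idx))
    stop("metadata error: unmapped sample(s): ",
         paste(aln$ids[is.na(idx)], collapse = ", "))
  pop <- if (!is.null(pm$group) && !anyNA(pm$group[idx]))
    as.character(pm$group[idx]) else as.character(pm$site[idx])

  m <- aln$seq
  valid <- matrix(m %in% .valid_bases, nrow = nrow(m))
  if (aln$missing_policy == "complete_deletion") {
    usable <- which(colSums(valid) == nrow(m))
    sub <- m[, usable, drop = FALSE]
    key <- apply(sub, 1L, paste0, collapse = "")
    usable_sites <- length(usable)
  } else {
    sub <- m
    key <- apply(m, 1L, paste0, collapse = "")
    usable_sites <- NA_integer_  # set below from pairwise-valid site counts
  }

  hap_key <- unique(key)                       # ordered by first occurrence
  hap_id <- paste0("H", seq_along(hap_key))
  hap_of <- match(key, hap_key)
  H <- length(hap_key)

  pops <- unique(pop)
  counts <- matrix(0L, nrow = length(pops), ncol = H,
                   dimnames = list(pops, hap_id))
  for (i in seq_along(pop)) counts[pop[i], hap_of[i]] <- counts[pop[i], hap_of[i]] + 1L

  first <- match(hap_key, key)
  hm <- sub[first, , drop = FALSE]
  rownames(hm) <- hap_id

  diffs <- matrix(0L, H, H, dimnames = list(hap_id, hap_id))
  if (H > 1L) {
    hv <- matrix(hm %in% .valid_bases, nrow = H)
    npairs_valid <- numeric(0)
    for (i in 1:(H - 1)) for (j in (i + 1):H) {
      ok <- hv[i, ] & hv[j, ]
      diffs[i, j] <- diffs[j, i] <- sum(hm[i, ok] != hm[j, ok])
      npairs_valid <- c(npairs_valid, sum(ok))
    }
    if (is.na(usable_sites)) usable_sites <- as.integer(round(mean(npairs_valid)))
  } else if (is.na(usable_sites)) {
    usable_sites <- sum(hm[1, ] %in% .valid_bases)
  }

  structure(list(haplotypes = hm, counts = counts, diffs = diffs,
                 usable_sites = as.integer(usable_sites),
                 n = sum(counts), missing_policy = aln$missing_policy),
            class = "hap_spectrum")
}

#' @export
print.hap_spectrum <- function(x, ...) {
  cat("Haplotype spectrum:", ncol(x$counts), "haplotypes,",
      nrow(x$counts), "population(s),", x$n, "sequences;",
      x$usable_sites, "usable sites (", x$missing_policy, ")\n")
  invisible(x)
}

# counts vector for one population label or the pooled sample ("TOT")
#' @keywords internal
.pop_counts <- function(spec, population = "TOT") {
  if (identical(population, "TOT") || is.null(population))
    return(colSums(spec$counts))
  if (!population %in% rownames(spec$counts))
    stop("unknown population: ", population)
  spec$counts[population, ]
}

# expand a spectrum back to one haplotype index per individual
#' @keywords internal
.expand_individuals <- function(spec, population = "TOT") {
  cnt <- .pop_counts(spec, population)
  rep(seq_along(cnt), cnt)
}

#' Segregating sites in a population
#'
#' Number of usable alignment columns with more than one base state among
#' the sequences of `population` (or of the pooled sample).
#'
#' @param spec a `hap_spectrum`.
#' @param population population label, or `"TOT"` for the pooled sample.
#' @return integer count of segregating sites.
#' @export
segregating_sites <- function(spec, population = "TOT") {
  cnt <- .pop_counts(spec, population)
  hm <- spec$haplotypes[cnt > 0, , drop = FALSE]
  if (nrow(hm) <= 1L) return(0L)
  sum(apply(hm, 2L, function(col) {
    b <- col[col %in% .valid_bases]
    length(unique(b)) > 1L
  }))
}
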