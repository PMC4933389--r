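# internal helpers shared across modules

#' @keywords internal
.set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# permutation/Monte-Carlo p-value with the (count + 1)/(B + 1) bias correction,
# so no estimated p can be exactly zero
#' @keywords internal
.perm_p <- function(count_extreme, n_perm) {
  (count_extreme + 1) / (n_perm + 1)
}

#' @keywords internal
.valid_bases <- c("A", "C", "G", "T")

# IUPAC nucleotide symbols accepted on input; everything outside ACGT is
# treated as missing downstream
#' @keywords internal
.iupac <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N", "-", "?", ".")

#' @keywords internal
.harmonic <- function(m) if (m < 1) 0 else sum(1 / seq_len(m))

# deterministic cluster labels: A, B, ..., Z, AA, AB, ...
#' @keywords internal
.alpha_labels <- function(k) {
  if (k <= 26L) return(LETTERS[seq_len(k)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(k)]
}

#' @keywords internal
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
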