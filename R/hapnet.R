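# Minimum spanning haplotype networks: the union of all minimum spanning
# trees of the inter-haplotype difference matrix (so ties are retained,
# unlike a single arbitrary MST), with node annotations carrying total and
# per-population frequencies. Median vectors (inferred unsampled
# haplotypes) are deliberately not reconstructed.

#' Build a minimum spanning haplotype network
#'
#' Kruskal's algorithm with tied-weight edge retention: processing edge
#' weights in increasing order, an edge is kept iff its endpoints are in
#' different components at the start of its weight class. The retained
#' edge set is exactly the union of all minimum spanning trees of the
#' difference matrix.
#'
#' @param spec a `hap_spectrum`.
#' @return object of class `hap_network`: list with `graph` (an
#'   [igraph::graph] whose vertices carry `freq_total` and one
#'   `freq_<population>` attribute per population, edges carry `weight`),
#'   `edges` (data.frame), `nodes` (data.frame) and `is_spanning = TRUE`.
#' @export
build_msn <- function(spec) {
  H <- ncol(spec$counts)
  hap_id <- colnames(spec$counts)
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0))
  if (H > 1L) {
    D <- spec$diffs
    comp <- seq_len(H)                    # union-find by relabelling
    find <- function(i) comp[i]
    pairs <- which(upper.tri(D), arr.ind = TRUE)
    w <- D[upper.tri(D)]
    keep_i <- integer(0); keep_j <- integer(0); keep_w <- numeric(0)
    for (wc in sort(unique(w))) {
      in_class <- which(w == wc)
      cand <- in_class[comp[pairs[in_class, 1]] != comp[pairs[in_class, 2]]]
      keep_i <- c(keep_i, pairs[cand, 1])
      keep_j <- c(keep_j, pairs[cand, 2])
      keep_w <- c(keep_w, w[cand])
      for (e in cand) {                   # merge after the whole class
        ci <- comp[pairs[e, 1]]; cj <- comp[pairs[e, 2]]
        if (ci != cj) comp[comp == cj] <- ci
      }
    }
    edges <- data.frame(from = hap_id[keep_i], to = hap_id[keep_j],
                        weight = keep_w)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = hap_id))
  igraph::V(g)$freq_total <- as.integer(colSums(spec$counts))
  for (p in rownames(spec$counts))
    g <- igraph::set_vertex_attr(g, paste0("freq_", p),
                                 value = as.integer(spec$counts[p, ]))
  nodes <- data.frame(haplotype = hap_id,
                      freq_total = as.integer(colSums(spec$counts)))
  structure(list(graph = g, edges = edges, nodes = nodes,
                 counts = spec$counts, is_spanning = TRUE),
            class = "hap_network")
}

#' @export
print.hap_network <- function(x, ...) {
  cat("Minimum spanning haplotype network:", nrow(x$nodes), "haplotypes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Star-likeness descriptors of a haplotype network
#'
#' Two descriptive indexes of the star-like shape typical of recently
#' expanded populations: the fraction of individuals carried by the modal
#' haplotype, and the fraction of haplotypes observed exactly once
#' (singletons).
#'
#' @param x a `hap_network` or a `hap_spectrum`.
#' @return list with `max_freq_fraction` and `singleton_fraction`.
#' @export
star_likeness <- function(x) {
  counts <- if (inherits(x, "hap_network")) x$counts else x$counts
  tot <- colSums(counts)
  list(max_freq_fraction = max(tot) / sum(tot),
       singleton_fraction = mean(tot == 1))
}

#' Export a haplotype network
#'
#' @param net a `hap_network`.
#' @param path output file path.
#' @param format `"graphml"`, `"dot"` or `"edgelist"` (TSV edge list with
#'   weights).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "dot", "edgelist")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(net$graph, path, format = format)
  }
  invisible(path)
}
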