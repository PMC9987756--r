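#' Seeded two-level co-occurrence network
#'
#' Extracts the first and second compositional network around a seed
#' taxon.  Level 1 contains every partner `g` with `|R(seed, g)| >
#' r_cutoff` and `p < p_cutoff`, sorted by descending R; level 2 contains,
#' for each level-1 partner, its own significant partners excluding only
#' the seed (other level-1 members may re-appear), again sorted by
#' descending R within each parent.  Both cutoffs are strict.
#'
#' @param est a `correlation_estimate` with p-values (see
#'   [permutation_pvalues]).
#' @param seed_taxon taxon to seed the network from.
#' @param r_cutoff strict `|R|` threshold (default 0.3).
#' @param p_cutoff strict p threshold (default 0.05).
#' @return A `seed_network`: list with `seed_taxon`, `level1_edges`
#'   (partner, R, sign, p) and `level2_edges` (parent, partner, R, sign,
#'   p), plus the cutoffs used.
#' @export
seeded_two_level_network <- function(est, seed_taxon, r_cutoff = 0.3,
                                     p_cutoff = 0.05) {
  stopifnot(inherits(est, "correlation_estimate"))
  if (is.null(est$p)) stop_ko("estimate carries no p-values; run permutation_pvalues()")
  taxa <- est$taxon_labels
  if (!seed_taxon %in% taxa) stop_ko("unknown seed taxon '", seed_taxon, "'")
  sig_partners <- function(g, exclude) {
    ok <- abs(est$R[g, ]) > r_cutoff & est$p[g, ] < p_cutoff &
      !is.na(est$p[g, ]) & !(taxa %in% c(g, exclude))
    partners <- taxa[ok]
    r <- est$R[g, partners]
    ord <- order(-r, partners)
    data.frame(partner = partners[ord], R = unname(r[ord]),
               sign = ifelse(r[ord] > 0, "Positive", "Negative"),
               p = unname(est$p[g, partners[ord]]),
               stringsAsFactors = FALSE)
  }
  lvl1 <- sig_partners(seed_taxon, exclude = character(0))
  lvl2 <- do.call(rbind, c(list(
    data.frame(parent = character(0), partner = character(0), R = numeric(0),
               sign = character(0), p = numeric(0), stringsAsFactors = FALSE)),
    lapply(lvl1$partner, function(g1) {
      e <- sig_partners(g1, exclude = seed_taxon)
      if (nrow(e)) cbind(parent = g1, e, stringsAsFactors = FALSE) else NULL
    })))
  structure(list(seed_taxon = seed_taxon, level1_edges = lvl1,
                 level2_edges = lvl2, r_cutoff = r_cutoff,
                 p_cutoff = p_cutoff),
            class = "seed_network")
}

#' @export
print.seed_network <- function(x, ...) {
  ct <- count_network_edges(x)
  cat(sprintf("seed_network around %s: level1 %d+/%d-, level2 %d+/%d-\n",
              x$seed_taxon, ct["level1_positive"], ct["level1_negative"],
              ct["level2_positive"], ct["level2_negative"]))
  invisible(x)
}

#' Tally network edges by level and sign
#'
#' Level-2 edges are counted with multiplicity per parent branch, matching
#' how published two-level networks report their totals.
#'
#' @param net a `seed_network`.
#' @return Named integer vector: `level1_positive`, `level1_negative`,
#'   `level2_positive`, `level2_negative`.
#' @export
count_network_edges <- function(net) {
  stopifnot(inherits(net, "seed_network"))
  c(level1_positive = sum(net$level1_edges$sign == "Positive"),
    level1_negative = sum(net$level1_edges$sign == "Negative"),
    level2_positive = sum(net$level2_edges$sign == "Positive"),
    level2_negative = sum(net$level2_edges$sign == "Negative"))
}

network_edge_frame <- function(net) {
  l1 <- net$level1_edges
  l2 <- net$level2_edges
  rbind(
    data.frame(source = rep(net$seed_taxon, nrow(l1)), target = l1$partner,
               level = rep(1L, nrow(l1)), R = l1$R, sign = l1$sign, p = l1$p,
               stringsAsFactors = FALSE),
    data.frame(source = l2$parent, target = l2$partner,
               level = rep(2L, nrow(l2)), R = l2$R, sign = l2$sign, p = l2$p,
               stringsAsFactors = FALSE))
}

#' Export a seeded network
#'
#' Writes the edge list as TSV (`source`, `target`, `level`, `R`, `sign`,
#' `p`) or as GraphML with the same edge attributes, loadable by standard
#' graph tooling (igraph, Cytoscape, networkx).
#'
#' @param net a `seed_network`.
#' @param path output file path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_edges <- function(net, path, format = c("edge_tsv", "graphml")) {
  stopifnot(inherits(net, "seed_network"))
  format <- match.arg(format)
  edges <- network_edge_frame(net)
  if (format == "edge_tsv") {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    edges$p[is.na(edges$p)] <- -1              # GraphML has no NA
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
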