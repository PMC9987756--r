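# Shared fixtures and small oracles used across the suite.

# tiny relative table with named dims
rel_table <- function(values, samples = NULL, taxa = NULL, site = "unspecified") {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(values)))
  if (is.null(taxa)) taxa <- paste0("t", seq_len(ncol(values)))
  dimnames(values) <- list(samples, taxa)
  abundance_table(values, "relative", site)
}

count_table <- function(values, samples = NULL, taxa = NULL, site = "unspecified") {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(values)))
  if (is.null(taxa)) taxa <- paste0("t", seq_len(ncol(values)))
  dimnames(values) <- list(samples, taxa)
  abundance_table(values, "counts", site)
}

dmat <- function(m) {
  dimnames(m) <- list(paste0("s", seq_len(nrow(m))), paste0("s", seq_len(nrow(m))))
  dist_matrix(m)
}

euclid_dmat <- function(x) dmat(as.matrix(dist(x)))

# adjusted Rand index between two labelings (permutation-invariant)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# exhaustive k-medoids oracle: optimal objective over all medoid sets
brute_force_pam_objective <- function(D, k) {
  best <- Inf
  for (med in utils::combn(nrow(D), k, simplify = FALSE)) {
    o <- sum(apply(D[med, , drop = FALSE], 2L, min))
    if (o < best) best <- o
  }
  best
}

# direct term-by-term JSD oracle (natural log, sqrt metric)
jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
  sqrt(0.5 * kl(p, m) + 0.5 * kl(q, m))
}

# minimal cluster_solution wrapper for metric functions
solution_from_labels <- function(d, labels) {
  k <- max(labels)
  med <- vapply(seq_len(k), function(c) which(labels == c)[1L], integer(1))
  structure(list(k = k, labels = as.integer(labels), sample_ids = rownames(d),
                 medoid_ids = rownames(d)[med], medoid_index = med,
                 objective = NA_real_, dominant_taxon = NULL),
            class = "cluster_solution")
}

# small three-cluster Dirichlet-multinomial table for k-selection tests
three_cluster_table <- function(n = 60, n_taxa = 12, boost = 50, depth = 5000,
                                seed = 1) {
  set.seed(seed)
  cl <- sample(rep(1:3, length.out = n))
  counts <- matrix(0L, n, n_taxa,
                   dimnames = list(sprintf("s%02d", 1:n),
                                   sprintf("g%02d", 1:n_taxa)))
  for (i in seq_len(n)) {
    a <- rep(1, n_taxa); a[cl[i]] <- boost
    g <- rgamma(n_taxa, a)
    counts[i, ] <- as.integer(rmultinom(1, depth, g / sum(g)))
  }
  list(table = abundance_table(counts, "counts"), labels = cl)
}
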