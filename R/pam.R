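#' Partitioning around medoids on a distance matrix
#'
#' Deterministic k-medoids: greedy BUILD initialisation (each new medoid
#' is the point that most reduces the total distance from every point to
#' its nearest medoid) followed by steepest-descent SWAP (the single
#' best-improving medoid/non-medoid exchange is applied until no exchange
#' improves the objective \eqn{\sum_x d(x, \mathrm{medoid}(x))}).  All
#' ties break towards the lowest sample index, so the result is a pure
#' function of the distance matrix.
#'
#' Small instances (at most `exact_threshold` candidate medoid sets) are
#' instead solved by exact enumeration of all medoid sets, with ties
#' broken towards the lexicographically smallest set; the heuristic and
#' the exact path optimise the same objective, so the switch only ever
#' improves the solution.
#'
#' @param d a [dist_matrix].
#' @param k number of clusters, `2 <= k < n` (`k = 1` is permitted and
#'   returns the 1-medoid minimiser).
#' @param exact_threshold enumerate all medoid sets exactly when
#'   `choose(n, k)` does not exceed this (default 1000).
#' @return A `cluster_solution`: list with `k`, `labels` (integer 1..k per
#'   sample, named), `medoid_ids`, `objective`, and `dominant_taxon`
#'   (unset until [dominant_taxon_labels]).
#' @export
pam_cluster <- function(d, k, exact_threshold = 1000) {
  stopifnot(inherits(d, "dist_matrix"))
  n <- nrow(d)
  if (k < 1L || k >= n)
    stop_ko(sprintf("k must satisfy 1 <= k < n (k=%d, n=%d)", k, n))
  D <- unclass(d)
  objective_of <- function(med) sum(apply(D[med, , drop = FALSE], 2L, min))

  if (choose(n, k) <= exact_threshold) {
    # exact: enumerate medoid sets in lexicographic order, keep first optimum
    sets <- utils::combn(n, k, simplify = FALSE)
    objs <- vapply(sets, objective_of, numeric(1))
    medoids <- sets[[which.min(objs)]]
  } else {
    medoids <- pam_build_swap(D, k, objective_of)
  }

  medoids <- sort(medoids)
  labels <- apply(D[medoids, , drop = FALSE], 2L, which.min)  # lowest index ties
  labels[medoids] <- seq_along(medoids)      # a medoid carries its own label
  names(labels) <- rownames(D)
  structure(list(k = as.integer(k), labels = as.integer(labels),
                 sample_ids = rownames(D),
                 medoid_ids = rownames(D)[medoids],
                 medoid_index = medoids,
                 objective = objective_of(medoids),
                 dominant_taxon = NULL),
            class = "cluster_solution")
}

# Greedy BUILD then steepest-descent SWAP; deterministic (lowest-index ties).
pam_build_swap <- function(D, k, objective_of) {
  n <- nrow(D)
  medoids <- which.min(rowSums(D))          # lowest index on ties (which.min)
  nearest <- D[medoids, ]
  while (length(medoids) < k) {
    gain <- vapply(seq_len(n), function(h) {
      if (h %in% medoids) return(-Inf)
      sum(pmax(nearest - D[h, ], 0))
    }, numeric(1))
    medoids <- c(medoids, which.max(gain))
    nearest <- pmin(nearest, D[medoids[length(medoids)], ])
  }
  obj <- objective_of(medoids)
  repeat {
    best_delta <- 0; best_swap <- NULL
    non_med <- setdiff(seq_len(n), medoids)
    for (ii in seq_along(medoids)) {
      others <- medoids[-ii]
      base <- if (length(others))
        apply(D[others, , drop = FALSE], 2L, min) else rep(Inf, n)
      for (h in non_med) {
        cand <- sum(pmin(base, D[h, ]))
        delta <- cand - obj
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_swap <- c(ii, h)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1L]] <- best_swap[2L]
    obj <- obj + best_delta
  }
  medoids
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: k=%d, sizes %s\n", x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  if (!is.null(x$dominant_taxon))
    cat("dominant taxa:", paste(x$dominant_taxon, collapse = ", "), "\n")
  invisible(x)
}

check_solution <- function(d, s) {
  stopifnot(inherits(d, "dist_matrix"), inherits(s, "cluster_solution"))
  if (length(s$labels) != nrow(d) || !identical(s$sample_ids, rownames(d)))
    stop_ko("cluster solution is not defined on this distance matrix")
  sizes <- tabulate(s$labels, s$k)
  if (any(sizes == 0L)) stop_ko("empty cluster in solution")
  invisible(sizes)
}

#' Calinski-Harabasz index for a medoid clustering
#'
#' Medoid-based CH generalised to an arbitrary distance matrix:
#' within-dispersion \eqn{W = \sum_x d(x, \mathrm{medoid}(x))^2};
#' between-dispersion \eqn{B = \sum_c n_c\, d(\mathrm{medoid}_c, g)^2}
#' where \eqn{g} is the global medoid minimising \eqn{\sum_x d(x,\cdot)^2};
#' \eqn{CH = (B/(k-1)) / (W/(n-k))}.  Degenerate \eqn{W = 0} returns
#' `Inf`.
#'
#' @param d a [dist_matrix].
#' @param s a `cluster_solution` on `d` with `k >= 2`.
#' @return The CH value (higher = better-separated clustering).
#' @export
ch_index <- function(d, s) {
  check_solution(d, s)
  if (s$k < 2L) stop_ko("ch_index requires k >= 2")
  D <- unclass(d)
  n <- nrow(D)
  W <- sum(D[cbind(s$medoid_index[s$labels], seq_len(n))]^2)
  g <- which.min(colSums(D^2))
  sizes <- tabulate(s$labels, s$k)
  B <- sum(sizes * D[s$medoid_index, g]^2)
  if (W == 0) return(Inf)
  (B / (s$k - 1)) / (W / (n - s$k))
}

#' Mean silhouette width
#'
#' Standard silhouette computed from the distance matrix: for each sample,
#' `a` = mean distance to its own cluster's other members, `b` = smallest
#' mean distance to another cluster, silhouette `(b-a)/max(a,b)`.
#' Members of singleton clusters contribute 0 by convention.
#'
#' @param d a [dist_matrix].
#' @param s a `cluster_solution` on `d` with `k >= 2`.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_mean <- function(d, s) {
  sizes <- check_solution(d, s)
  if (s$k < 2L) stop_ko("silhouette requires k >= 2")
  D <- unclass(d)
  n <- nrow(D)
  # mean distance from each sample to each cluster
  member <- outer(s$labels, seq_len(s$k), "==") + 0
  tot <- D %*% member                          # n x k sums
  sil <- numeric(n)
  for (i in seq_len(n)) {
    ci <- s$labels[i]
    if (sizes[ci] == 1L) { sil[i] <- 0; next }
    a <- tot[i, ci] / (sizes[ci] - 1L)
    b <- min((tot[i, -ci] / sizes[-ci]))
    sil[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(sil)
}

#' Choose the number of clusters
#'
#' Runs [pam_cluster] for each `k` in `2..k_max`, records the CH index and
#' mean silhouette width, and selects the `k` maximising CH (ties broken
#' towards the smallest `k`).
#'
#' @param d a [dist_matrix].
#' @param k_max largest candidate `k` (default 10; must be `< n`).
#' @return A `k_selection` list: `candidate_ks`, `ch_values`,
#'   `silhouette_values`, `chosen_k`, and `solutions` (the fitted
#'   `cluster_solution` per candidate).
#' @export
select_k <- function(d, k_max = 10L) {
  stopifnot(inherits(d, "dist_matrix"))
  n <- nrow(d)
  if (k_max >= n) stop_ko("k_max must be smaller than the number of samples")
  if (k_max < 2L) stop_ko("k_max must be at least 2")
  ks <- 2L:as.integer(k_max)
  sols <- lapply(ks, function(k) pam_cluster(d, k))
  ch <- vapply(sols, function(s) ch_index(d, s), numeric(1))
  sil <- vapply(sols, function(s) silhouette_mean(d, s), numeric(1))
  chosen <- ks[which.max(ch)]                  # which.max: smallest k on ties
  structure(list(candidate_ks = ks, ch_values = ch, silhouette_values = sil,
                 chosen_k = chosen, solutions = sols),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("k  CH        silhouette\n")
  for (i in seq_along(x$candidate_ks))
    cat(sprintf("%-2d %-9.4g %.4f%s\n", x$candidate_ks[i], x$ch_values[i],
                x$silhouette_values[i],
                if (x$candidate_ks[i] == x$chosen_k) "  <- chosen" else ""))
  invisible(x)
}
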