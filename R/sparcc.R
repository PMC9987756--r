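#' SparCC compositional correlations
#'
#' Estimates basis (absolute-abundance) correlations from compositional
#' count data under the sparsity assumption.  Each inner iteration draws
#' per-sample fractions from Dirichlet(counts + 1), forms the log-ratio
#' variance matrix \eqn{T_{ij} = \mathrm{Var}\,\log(f_i/f_j)} (n-1
#' denominator), solves the sparsity linear system for the basis
#' variances \eqn{\omega} (coefficient matrix with \eqn{D-1} on the
#' diagonal and 1 off it, right-hand side the row sums of \eqn{T}),
#' and sets \eqn{\rho_{ij} = (\omega_i + \omega_j - T_{ij}) /
#' (2\sqrt{\omega_i \omega_j})} clipped to \eqn{[-1, 1]}.  The strongest
#' pair with \eqn{|\rho|} above `exclusion_threshold` is then iteratively
#' removed from the system and the system re-solved, up to
#' `max_exclusions` rounds.  The reported matrix is the element-wise
#' median over the inner iterations; deterministic given `seed`.
#'
#' @param t a counts [abundance_table] with at least 4 taxa and no
#'   all-zero taxon.
#' @param n_inner Dirichlet resampling iterations (default 20).
#' @param exclusion_threshold `|rho|` above which the strongest pair is
#'   removed from the basis-variance system (default 0.1).
#' @param max_exclusions maximum exclusion rounds per iteration (default 10).
#' @param seed RNG seed.
#' @return A `correlation_estimate`: list with `taxon_labels`, `R`
#'   (symmetric, unit diagonal), `p` (`NULL` until
#'   [permutation_pvalues]), and provenance fields `n_inner`, `seed`.
#' @export
sparcc <- function(t, n_inner = 20L, exclusion_threshold = 0.1,
                   max_exclusions = 10L, seed = 1L) {
  stopifnot(is_abundance_table(t))
  if (t$mode != "counts") stop_ko("sparcc expects raw counts, not relative abundances")
  counts <- t$values
  D <- ncol(counts)
  if (D < 4L) stop_ko("sparcc needs at least 4 taxa (basis system is degenerate below)")
  zero <- colSums(counts) == 0
  if (any(zero))
    stop_ko("taxon with zero total count: ",
            paste(taxon_labels(t)[zero], collapse = ", "))
  iters <- with_seed(seed, {
    lapply(seq_len(n_inner), function(i) {
      g <- matrix(rgamma(length(counts), shape = counts + 1, rate = 1),
                  nrow = nrow(counts))
      f <- g / rowSums(g)
      sparcc_one(log(f), exclusion_threshold, max_exclusions)
    })
  })
  R <- apply(simplify2array(iters), c(1L, 2L), median)
  diag(R) <- 1
  dimnames(R) <- list(taxon_labels(t), taxon_labels(t))
  structure(list(taxon_labels = taxon_labels(t), R = R, p = NULL,
                 n_inner = as.integer(n_inner), n_perm = NULL,
                 seed = as.integer(seed)),
            class = "correlation_estimate")
}

# One SparCC estimate from a matrix of per-sample log fractions.
sparcc_one <- function(logf, exclusion_threshold, max_exclusions) {
  D <- ncol(logf)
  V <- var(logf)                               # n-1 denominator
  Tm <- outer(diag(V), diag(V), "+") - 2 * V   # T_ij = Var(log fi - log fj)
  M <- matrix(1, D, D); diag(M) <- D - 1
  tvec <- rowSums(Tm)
  solve_rho <- function(M, tvec) {
    omega <- tryCatch(solve(M, tvec), error = function(e) NULL)
    if (is.null(omega)) return(NULL)           # exclusions made system singular
    omega <- pmax(omega, 1e-12)                # clamp: negative basis variance
    rho <- (outer(omega, omega, "+") - Tm) / (2 * sqrt(outer(omega, omega)))
    pmin(pmax(rho, -1), 1)
  }
  rho <- solve_rho(M, tvec)
  if (is.null(rho)) stop_ko("basis-variance system is singular; need more taxa")
  excluded <- matrix(FALSE, D, D)
  for (round in seq_len(max_exclusions)) {
    cand <- abs(rho)
    cand[excluded | row(cand) >= col(cand)] <- -Inf
    ij <- arrayInd(which.max(cand), dim(cand))
    if (cand[ij] <= exclusion_threshold) break
    i <- ij[1L]; j <- ij[2L]
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    tvec[i] <- tvec[i] - Tm[i, j]
    tvec[j] <- tvec[j] - Tm[i, j]
    if (any(diag(M) < 1)) break                # component fully excluded; stop
    new_rho <- solve_rho(M, tvec)
    if (is.null(new_rho)) break                # keep last solvable estimate
    rho <- new_rho
  }
  rho
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat(sprintf("correlation_estimate: %d taxa, n_inner=%d%s\n",
              length(x$taxon_labels), x$n_inner,
              if (is.null(x$p)) "" else sprintf(", n_perm=%d", x$n_perm)))
  invisible(x)
}

#' Permutation p-values for SparCC correlations
#'
#' Null distribution by independently shuffling each taxon's counts across
#' samples (breaking all between-taxon association while preserving
#' marginals) and re-estimating SparCC; two-sided
#' \eqn{p_{ij} = (\#\{|R_{perm}| \ge |R_{obs}|\} + 1)/(n_{perm} + 1)}.
#' Permutation re-estimates use a reduced number of inner iterations
#' (`n_inner_perm`, default 5) for tractability.
#'
#' @param t the counts [abundance_table] used for `est`.
#' @param est a `correlation_estimate` from [sparcc].
#' @param n_perm number of permutations (default 100; below 19 a warning
#'   is issued since p < 0.05 is then unattainable).
#' @param n_inner_perm inner iterations per permutation (default 5).
#' @param seed RNG seed.
#' @return `est` with the `p` matrix and `n_perm` filled in.
#' @export
permutation_pvalues <- function(t, est, n_perm = 100L, n_inner_perm = 5L,
                                seed = 1L) {
  stopifnot(is_abundance_table(t), inherits(est, "correlation_estimate"))
  if (!identical(taxon_labels(t), est$taxon_labels))
    stop_ko("table and correlation estimate cover different taxa")
  if (n_perm < 19L)
    warning("n_perm < 19 cannot resolve p < 0.05")
  obs <- abs(est$R)
  n <- nrow(t$values)
  exceed <- matrix(0L, ncol(t$values), ncol(t$values))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- apply(t$values, 2L, function(col) col[sample.int(n)])
      rownames(perm) <- sample_ids(t)
      pr <- sparcc(abundance_table(perm, "counts"), n_inner = n_inner_perm,
                   seed = sample.int(.Machine$integer.max, 1L))
      exceed <- exceed + (abs(pr$R) >= obs)
    }
  })
  p <- (exceed + 1) / (n_perm + 1)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(est$R)
  est$p <- p
  est$n_perm <- as.integer(n_perm)
  est
}
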