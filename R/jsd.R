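#' Jensen-Shannon divergence distance matrix
#'
#' Computes the root-JSD metric between every pair of sample composition
#' vectors: zeros are replaced by an additive pseudocount and each profile
#' renormalised, then
#' \eqn{JSD(p,q) = \frac{1}{2} KL(p\,\|\,m) + \frac{1}{2} KL(q\,\|\,m)}
#' with \eqn{m = (p+q)/2} and natural logarithms, and the distance is
#' \eqn{\sqrt{JSD}}.  Root-JSD is a metric bounded by \eqn{\sqrt{\ln 2}}
#' (attained by disjoint supports).
#'
#' @param t a relative [abundance_table].
#' @param pseudocount additive zero-replacement (default `1e-9`).
#' @return A `dist_matrix`: square symmetric matrix with zero diagonal and
#'   sample ids as dimnames.
#' @export
jsd_distance_matrix <- function(t, pseudocount = 1e-9) {
  stopifnot(is_abundance_table(t))
  if (t$mode != "relative") stop_ko("jsd_distance_matrix expects a relative table")
  v <- t$values
  if (nrow(v) == 0L || ncol(v) == 0L) stop_ko("empty abundance table")
  v[v == 0] <- pseudocount
  v <- v / rowSums(v)
  # entropy identity: JSD(p,q) = H(m) - (H(p)+H(q))/2, H in nats
  H <- -rowSums(v * log(v))
  n <- nrow(v)
  d2 <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1L)) {
    m <- (v[rep(i, n - i), , drop = FALSE] + v[(i + 1L):n, , drop = FALSE]) / 2
    Hm <- -rowSums(m * log(m))
    jsd <- Hm - (H[i] + H[(i + 1L):n]) / 2
    d2[i, (i + 1L):n] <- d2[(i + 1L):n, i] <- pmax(jsd, 0)
  }
  dist_matrix(sqrt(d2))
}

#' Distance matrix container
#'
#' Validates a square symmetric non-negative matrix with zero diagonal and
#' sample ids as dimnames; the container all clustering operations consume.
#'
#' @param values square numeric matrix.
#' @return A `dist_matrix` object (the validated matrix).
#' @export
dist_matrix <- function(values) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop_ko("distance matrix must be square")
  if (is.null(rownames(values)))
    dimnames(values) <- list(paste0("s", seq_len(nrow(values))),
                             paste0("s", seq_len(nrow(values))))
  if (max(abs(values - t(values))) > 1e-12)
    stop_ko("distance matrix must be symmetric within 1e-12")
  values <- (values + t(values)) / 2
  if (any(diag(values) != 0)) stop_ko("distance matrix diagonal must be zero")
  if (any(values < 0)) stop_ko("distances must be non-negative")
  class(values) <- c("dist_matrix", "matrix", "array")
  values
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d samples, range [0, %.4g]\n", nrow(x), max(x)))
  invisible(x)
}
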