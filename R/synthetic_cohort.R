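#' Cohort simulation specification
#'
#' Defines a paired oral/gut cohort with two dominant-genus clusters per
#' body site.  Defaults reproduce the study conditions the pipeline is
#' validated against: 112 subjects, oral clusters led by *Streptococcus*
#' and *Haemophilus* with mixture weights (0.554, 0.446), gut clusters led
#' by *Bacteroides* and *Prevotella* with oral-conditional coupling rows
#' (0.694, 0.306) and (0.720, 0.280), Dirichlet concentration 1 per genus
#' with the cluster's dominant genus boosted 50-fold, and multinomial
#' depth 20000.
#'
#' @param n_subjects number of subjects (one oral + one gut sample each).
#' @param oral_taxa,gut_taxa genus labels per site; must contain the
#'   corresponding dominant taxa.
#' @param oral_dominant,gut_dominant the two cluster-defining genera per
#'   site, in cluster order.
#' @param base_concentration either a single number recycled per taxon or
#'   a list with per-site vectors (`oral`, `gut`).
#' @param dominance_boost multiplier (>= 1) applied to the dominant
#'   genus's Dirichlet concentration within its own cluster.
#' @param mixture_weights length-2 oral cluster probabilities, summing to 1.
#' @param coupling 2x2 matrix; row i = gut-cluster probabilities given
#'   oral cluster i; rows sum to 1.
#' @param depth multinomial sequencing depth per sample.
#' @param seed RNG seed recorded in the spec and used by the simulator.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 112L,
                        oral_taxa = default_oral_taxa(),
                        gut_taxa = default_gut_taxa(),
                        oral_dominant = c("Streptococcus", "Haemophilus"),
                        gut_dominant = c("Bacteroides", "Prevotella"),
                        base_concentration = 1,
                        dominance_boost = 50,
                        mixture_weights = c(0.554, 0.446),
                        coupling = matrix(c(0.694, 0.306, 0.720, 0.280),
                                          nrow = 2, byrow = TRUE),
                        depth = 20000L,
                        seed = 1L) {
  check_scalar_number(n_subjects, "n_subjects", min = 1)
  check_scalar_number(dominance_boost, "dominance_boost", min = 1)
  check_scalar_number(depth, "depth", min = 1)
  if (length(mixture_weights) != 2L || abs(sum(mixture_weights) - 1) > 1e-8 ||
      any(mixture_weights < 0))
    stop_ko("mixture_weights must be two non-negative probabilities summing to 1")
  if (!is.matrix(coupling) || any(dim(coupling) != c(2L, 2L)) ||
      any(coupling < 0) || any(abs(rowSums(coupling) - 1) > 1e-8))
    stop_ko("coupling must be a 2x2 row-stochastic matrix")
  if (!all(oral_dominant %in% oral_taxa))
    stop_ko("oral_dominant taxa must appear in oral_taxa")
  if (!all(gut_dominant %in% gut_taxa))
    stop_ko("gut_dominant taxa must appear in gut_taxa")
  if (anyDuplicated(oral_taxa) || anyDuplicated(gut_taxa))
    stop_ko("taxon label lists must be duplicate-free")
  conc <- if (is.list(base_concentration)) base_concentration else
    list(oral = rep(base_concentration, length(oral_taxa)),
         gut = rep(base_concentration, length(gut_taxa)))
  if (length(conc$oral) != length(oral_taxa) || length(conc$gut) != length(gut_taxa))
    stop_ko("base_concentration length must match the taxa lists")
  if (any(unlist(conc) <= 0)) stop_ko("base_concentration entries must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 oral_taxa = oral_taxa, gut_taxa = gut_taxa,
                 oral_dominant = oral_dominant, gut_dominant = gut_dominant,
                 base_concentration = conc,
                 dominance_boost = dominance_boost,
                 mixture_weights = mixture_weights,
                 coupling = coupling,
                 depth = as.integer(depth),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

default_oral_taxa <- function() c(
  "Streptococcus", "Haemophilus", "Neisseria", "Prevotella", "Veillonella",
  "Rothia", "Granulicatella", "Gemella", "Actinomyces", "Fusobacterium",
  "Porphyromonas", "Leptotrichia", "Megasphaera", "Selenomonas",
  "Corynebacterium", "Lautropia", "Alloprevotella", "Atopobium",
  "Capnocytophaga", "Treponema")

default_gut_taxa <- function() c(
  "Bacteroides", "Prevotella", "Faecalibacterium", "Blautia", "Roseburia",
  "Bifidobacterium", "Ruminococcus", "Akkermansia", "Alistipes", "Dialister",
  "Phascolarctobacterium", "Parabacteroides", "Lachnospira", "Megamonas",
  "Sutterella", "Coprococcus", "Dorea", "Collinsella", "Oscillospira",
  "Escherichia-Shigella")

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a paired oral/gut cohort
#'
#' For each subject: draw the oral cluster from `mixture_weights`, the gut
#' cluster from the oral cluster's `coupling` row, a composition from a
#' Dirichlet whose dominant-genus concentration is boosted, and counts
#' from a multinomial at the given depth.  Deterministic given
#' `spec$seed`.
#'
#' @param spec a [cohort_spec].
#' @return A list with `oral` and `gut` count [abundance_table]s, `meta`
#'   ([sample_metadata]) and `truth` (a data.frame with per-subject planted
#'   `ko_label`, `gut_label`, `koga_label`).
#' @export
simulate_paired_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    subj <- sprintf("subj%03d", seq_len(n))
    oral_cl <- 1L + (runif(n) > spec$mixture_weights[1L])
    gut_cl <- vapply(oral_cl, function(c1)
      1L + (runif(1) > spec$coupling[c1, 1L]), integer(1))
    draw_site <- function(taxa, conc, dominant, cl) {
      counts <- matrix(0L, n, length(taxa), dimnames = list(NULL, taxa))
      for (i in seq_len(n)) {
        a <- conc
        j <- match(dominant[cl[i]], taxa)
        a[j] <- a[j] * spec$dominance_boost
        counts[i, ] <- as.integer(rmultinom(1, spec$depth, rdirichlet1(a)))
      }
      counts
    }
    oral_counts <- draw_site(spec$oral_taxa, spec$base_concentration$oral,
                             spec$oral_dominant, oral_cl)
    gut_counts <- draw_site(spec$gut_taxa, spec$base_concentration$gut,
                            spec$gut_dominant, gut_cl)
    rownames(oral_counts) <- paste0(subj, "_o")
    rownames(gut_counts) <- paste0(subj, "_g")
    ko <- substr(spec$oral_dominant, 1L, 1L)[oral_cl]
    gl <- substr(spec$gut_dominant, 1L, 1L)[gut_cl]
    list(oral = abundance_table(oral_counts, "counts", "oral"),
         gut = abundance_table(gut_counts, "counts", "gut"),
         meta = sample_metadata(c(rownames(oral_counts), rownames(gut_counts)),
                                c(subj, subj),
                                rep(c("oral", "gut"), each = n)),
         truth = data.frame(subject_id = subj, ko_label = ko, gut_label = gl,
                            koga_label = paste0(ko, gl),
                            stringsAsFactors = FALSE),
         seed = spec$seed)
  })
}

#' Specification for correlated compositional counts
#'
#' Generative model under which SparCC is consistent: per-sample basis
#' abundances are lognormal with the given log-scale mean and covariance,
#' normalised to fractions, then sampled as multinomial counts.
#'
#' @param n_samples,n_taxa dimensions (`n_taxa >= 3`).
#' @param basis_log_mean length-`n_taxa` vector (default 0).
#' @param basis_log_covariance symmetric positive-semidefinite matrix
#'   (default identity).
#' @param depth multinomial depth per sample.
#' @param seed RNG seed.
#' @return A `correlated_count_spec` object.
#' @export
correlated_count_spec <- function(n_samples, n_taxa,
                                  basis_log_mean = rep(0, n_taxa),
                                  basis_log_covariance = diag(n_taxa),
                                  depth = 10000L, seed = 1L) {
  check_scalar_number(n_samples, "n_samples", min = 2)
  check_scalar_number(n_taxa, "n_taxa", min = 3)
  check_scalar_number(depth, "depth", min = 1)
  if (length(basis_log_mean) != n_taxa)
    stop_ko("basis_log_mean must have length n_taxa")
  S <- basis_log_covariance
  if (!is.matrix(S) || any(dim(S) != n_taxa) || max(abs(S - t(S))) > 1e-8)
    stop_ko("basis_log_covariance must be a symmetric n_taxa x n_taxa matrix")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop_ko("basis_log_covariance is not positive semidefinite")
  structure(list(n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
                 basis_log_mean = basis_log_mean, basis_log_covariance = S,
                 depth = as.integer(depth), seed = as.integer(seed)),
            class = "correlated_count_spec")
}

#' Simulate correlated compositional counts
#'
#' @param spec a [correlated_count_spec].
#' @return A counts [abundance_table] (taxa `taxon01`, ...), with the true
#'   basis log-abundance matrix in attribute `"basis_log"` for use as an
#'   oracle in tests.
#' @export
simulate_correlated_counts <- function(spec) {
  stopifnot(inherits(spec, "correlated_count_spec"))
  with_seed(spec$seed, {
    logs <- MASS::mvrnorm(spec$n_samples, mu = spec$basis_log_mean,
                          Sigma = spec$basis_log_covariance)
    logs <- matrix(logs, nrow = spec$n_samples)
    basis <- exp(logs)
    frac <- basis / rowSums(basis)
    counts <- t(vapply(seq_len(spec$n_samples),
                       function(i) as.integer(rmultinom(1, spec$depth, frac[i, ])),
                       integer(spec$n_taxa)))
    dimnames(counts) <- list(sprintf("samp%03d", seq_len(spec$n_samples)),
                             sprintf("taxon%02d", seq_len(spec$n_taxa)))
    out <- abundance_table(counts, "counts")
    attr(out, "basis_log") <- logs
    out
  })
}

#' Deterministic prevalence-filter fixture table
#'
#' Builds a relative table whose per-taxon mean abundances are exact by
#' construction: `n_passing` taxa sit strictly above the cutoff and the
#' rest strictly below, so exactly `n_passing` survive
#' [prevalence_filter].  Mirrors a genus table where 75 of 215 genera
#' exceed the 0.01% mean-abundance cutoff.
#'
#' @param n_samples,n_taxa,n_passing table shape and intended pass count.
#' @param min_mean_frac the cutoff the table is built around.
#' @return A relative [abundance_table].
#' @export
prevalence_fixture_table <- function(n_samples = 112L, n_taxa = 215L,
                                     n_passing = 75L, min_mean_frac = 1e-4) {
  if (n_passing < 1L || n_passing >= n_taxa)
    stop_ko("need 1 <= n_passing < n_taxa")
  n_fail <- n_taxa - n_passing
  low <- min_mean_frac / 2                      # strictly below cutoff
  mass_low <- low * n_fail
  hi <- (1 - mass_low) / n_passing              # strictly above for sane shapes
  if (hi <= min_mean_frac)
    stop_ko("shape leaves no room above the cutoff; reduce n_taxa or cutoff")
  p <- c(rep(hi, n_passing), rep(low, n_fail))
  v <- matrix(rep(p, each = n_samples), nrow = n_samples,
              dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                              sprintf("taxon%03d", seq_len(n_taxa))))
  abundance_table(v, "relative")
}
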