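#' Label clusters by their dominant taxon
#'
#' For every cluster, the labelling score of a taxon is its mean relative
#' abundance inside the cluster minus its mean outside; the cluster is
#' named after the taxon maximising this contrast (ties resolved
#' alphabetically).  The inside-outside contrast separates, e.g., a
#' *Haemophilus* cluster even when *Streptococcus* is globally the most
#' abundant genus.  With `k = 1` the contrast reduces to the inside mean.
#'
#' @param t a relative [abundance_table] on the clustered samples.
#' @param s a `cluster_solution` from [pam_cluster].
#' @param rule `"contrast"` (inside - outside mean, default) or
#'   `"inside_mean"`.
#' @return `s` with `dominant_taxon` filled (one label per cluster).
#' @export
dominant_taxon_labels <- function(t, s, rule = c("contrast", "inside_mean")) {
  rule <- match.arg(rule)
  stopifnot(is_abundance_table(t), inherits(s, "cluster_solution"))
  if (!identical(sample_ids(t), s$sample_ids))
    stop_ko("table and cluster solution cover different samples")
  if (t$mode != "relative") stop_ko("dominant_taxon_labels expects a relative table")
  v <- t$values
  lab <- character(s$k)
  for (c in seq_len(s$k)) {
    inside <- s$labels == c
    mu_in <- colMeans(v[inside, , drop = FALSE])
    score <- if (rule == "contrast" && any(!inside))
      mu_in - colMeans(v[!inside, , drop = FALSE]) else mu_in
    ord <- order(-score, colnames(v))           # ties -> alphabetical
    lab[c] <- colnames(v)[ord[1L]]
  }
  s$dominant_taxon <- lab
  s
}

typing_letter <- function(taxon) toupper(substr(taxon, 1L, 1L))

#' Assign oral community types
#'
#' The oral half of the typing pipeline: JSD distances on the filtered
#' relative genus table, CH-driven choice of the cluster number,
#' deterministic PAM at that `k`, and dominant-genus labelling.  Each
#' subject's oral type label is the first letter of its cluster's dominant
#' genus (S for a *Streptococcus*-dominant cluster, H for *Haemophilus*).
#'
#' @param oral a relative oral [abundance_table], already prevalence
#'   filtered (see [prevalence_filter]).
#' @param meta a [sample_metadata] covering the oral samples.
#' @param k_max passed to [select_k].
#' @param pseudocount passed to [jsd_distance_matrix].
#' @param force_k optional integer overriding the CH choice.
#' @return A list: `assignments` (data.frame subject_id, ko_label),
#'   `solution` (labelled `cluster_solution`), `k_report` (`k_selection`),
#'   `distance` (the JSD [dist_matrix]).
#' @export
assign_ko_types <- function(oral, meta, k_max = 10L, pseudocount = 1e-9,
                            force_k = NULL) {
  stopifnot(is_abundance_table(oral), inherits(meta, "sample_metadata"))
  d <- jsd_distance_matrix(oral, pseudocount)
  rep <- select_k(d, k_max = min(k_max, nrow(d) - 1L))
  k <- if (is.null(force_k)) rep$chosen_k else as.integer(force_k)
  sol <- rep$solutions[[match(k, rep$candidate_ks)]]
  if (is.null(sol) || is.na(match(k, rep$candidate_ks))) sol <- pam_cluster(d, k)
  sol <- dominant_taxon_labels(oral, sol)
  idx <- match(sample_ids(oral), meta$sample_id)
  if (anyNA(idx)) stop_ko("oral sample(s) missing from metadata")
  assignments <- data.frame(
    subject_id = meta$subject_id[idx],
    ko_label = typing_letter(sol$dominant_taxon[sol$labels]),
    stringsAsFactors = FALSE)
  list(assignments = assignments, solution = sol, k_report = rep, distance = d)
}

#' Assign composite oral-gut types
#'
#' The nested half of the pipeline: the gut table is split by each
#' subject's oral type and the same clustering pipeline (optional
#' prevalence filter, JSD, CH-selected PAM, dominant-genus labels) is run
#' *within each oral-type subgroup*.  The composite label concatenates the
#' oral letter with the gut cluster's dominant-genus letter (SB, SP, HB,
#' HP for Streptococcus/Haemophilus crossed with Bacteroides/Prevotella).
#'
#' @param gut a gut [abundance_table] (counts or relative; counts are
#'   normalised internally).
#' @param meta a [sample_metadata] covering the gut samples.
#' @param ko the result of [assign_ko_types] (or its `assignments` frame).
#' @param min_mean_frac prevalence cutoff re-applied per subgroup, or
#'   `NULL` if the table is already filtered (default `NULL`: global
#'   filtering is the caller's responsibility).
#' @param k_max,pseudocount,force_k as in [assign_ko_types].
#' @return A list: `assignments` (subject_id, ko_label, gut_label,
#'   koga_label), `subgroup_solutions`, `subgroup_k_reports`.
#' @export
assign_koga_types <- function(gut, meta, ko, min_mean_frac = NULL,
                              k_max = 10L, pseudocount = 1e-9, force_k = NULL) {
  stopifnot(is_abundance_table(gut), inherits(meta, "sample_metadata"))
  assignments <- if (is.data.frame(ko)) ko else ko$assignments
  if (!all(c("subject_id", "ko_label") %in% names(assignments)))
    stop_ko("'ko' must carry subject_id and ko_label")
  gut_rel <- if (gut$mode == "counts") to_relative(gut) else gut
  idx <- match(sample_ids(gut_rel), meta$sample_id)
  if (anyNA(idx)) stop_ko("gut sample(s) missing from metadata")
  subj_of_sample <- meta$subject_id[idx]
  ko_of_sample <- assignments$ko_label[match(subj_of_sample, assignments$subject_id)]
  if (anyNA(ko_of_sample))
    stop_ko("gut sample(s) belong to subjects with no oral type")
  out <- data.frame(subject_id = subj_of_sample, ko_label = ko_of_sample,
                    gut_label = NA_character_, stringsAsFactors = FALSE)
  sols <- list(); reps <- list()
  for (lv in sort(unique(ko_of_sample))) {
    in_grp <- ko_of_sample == lv
    if (sum(in_grp) < 4L)
      stop_ko(sprintf("oral-type subgroup '%s' has %d gut samples; need >= 4 to cluster",
                      lv, sum(in_grp)))
    sub <- subset_table(gut_rel, samples = which(in_grp))
    if (!is.null(min_mean_frac)) sub <- prevalence_filter(sub, min_mean_frac)
    d <- jsd_distance_matrix(sub, pseudocount)
    rep <- select_k(d, k_max = min(k_max, nrow(d) - 1L))
    k <- if (is.null(force_k)) rep$chosen_k else as.integer(force_k)
    sol <- rep$solutions[[match(k, rep$candidate_ks)]]
    sol <- dominant_taxon_labels(sub, sol)
    out$gut_label[in_grp] <- typing_letter(sol$dominant_taxon[sol$labels])
    sols[[lv]] <- sol; reps[[lv]] <- rep
  }
  out$koga_label <- paste0(out$ko_label, out$gut_label)
  list(assignments = out, subgroup_solutions = sols, subgroup_k_reports = reps)
}

#' Type frequency table
#'
#' Counts and percentages (half-up, one decimal) per type label, e.g.
#' counts 43/19/36/14 of 112 give 38.4/17.0/32.1/12.5%.
#'
#' @param labels character vector of type labels (one per subject).
#' @return A data.frame with `label`, `count`, `percent`.
#' @export
type_frequencies <- function(labels) {
  if (length(labels) == 0L) stop_ko("no labels supplied")
  tab <- table(labels)
  data.frame(label = names(tab), count = as.integer(tab),
             percent = round_half_up(100 * as.integer(tab) / length(labels), 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Principal coordinates analysis
#'
#' Classical (Gower) scaling of a distance matrix via [stats::cmdscale],
#' returning the leading axes with positive eigenvalues.  Each axis's sign
#' is fixed so that its largest-magnitude coordinate is positive, making
#' the embedding reproducible.
#'
#' @param d a [dist_matrix].
#' @param n_axes number of axes requested (default 2); truncated with a
#'   warning if fewer positive eigenvalues exist.
#' @return A list: `coordinates` (samples x axes), `eigenvalues`,
#'   `variance_share` (eigenvalue / sum of positive eigenvalues).
#' @export
pcoa <- function(d, n_axes = 2L) {
  stopifnot(inherits(d, "dist_matrix"))
  n <- nrow(d)
  if (n < 2L) stop_ko("pcoa needs at least two samples")
  fit <- cmdscale(unclass(d), k = n - 1L, eig = TRUE)
  pos <- sum(fit$eig > 1e-10)
  if (n_axes > pos) {
    warning(sprintf("only %d positive eigenvalues; returning %d axes", pos, pos))
    n_axes <- pos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = fit$eig[seq_len(n_axes)],
       variance_share = fit$eig[seq_len(n_axes)] / sum(fit$eig[fit$eig > 0]))
}

#' Distance-based PERMANOVA
#'
#' One-way permutational multivariate ANOVA on a distance matrix.  With
#' \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / n} and \eqn{SS_{within}} the
#' analogous per-group sums, the pseudo-F is
#' \eqn{((SS_t - SS_w)/(a-1)) / (SS_w/(n-a))} for \eqn{a} groups; the
#' p-value is `(#\{F_perm >= F_obs\} + 1) / (n_perm + 1)` over seeded
#' label permutations.
#'
#' @param d a [dist_matrix].
#' @param groups group label per sample (>= 2 distinct values).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return A list: `pseudo_F`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(d, "dist_matrix"))
  n <- nrow(d)
  groups <- as.factor(groups)
  if (length(groups) != n) stop_ko("one group label per sample required")
  a <- nlevels(groups)
  if (a < 2L) stop_ko("permanova needs at least two groups")
  D2 <- unclass(d)^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  f_stat <- function(g) {
    ss_w <- 0
    for (lv in levels(g)) {
      idx <- which(g == lv)
      if (length(idx) > 1L)
        ss_w <- ss_w + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }
    ((ss_total - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_stat(groups)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(i) f_stat(groups[sample.int(n)]) >= f_obs,
               logical(1)))
  })
  list(pseudo_F = f_obs, p_value = (exceed + 1) / (n_perm + 1),
       n_perm = as.integer(n_perm))
}

#' Per-taxon two-group rank-sum screen
#'
#' Two-sided Mann-Whitney U per taxon with the normal approximation and
#' tie correction, no continuity correction and no multiplicity
#' adjustment; significance is flagged with the conventional star levels.
#' A taxon constant across both groups has zero tie-corrected variance
#' and is reported as `U = nm/2`, `p = 1`.
#'
#' @param t an [abundance_table].
#' @param groups two-level label per sample.
#' @return A data.frame with `taxon`, `U`, `p`, `stars` (`""`, `"*"`,
#'   `"**"`, `"***"` for p < 0.05 / 0.01 / 0.001).
#' @export
rank_sum_differential <- function(t, groups) {
  stopifnot(is_abundance_table(t))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop_ko("exactly two groups required")
  if (length(groups) != nrow(t$values)) stop_ko("one group label per sample required")
  n1 <- sum(groups == levels(groups)[1L])
  n2 <- sum(groups == levels(groups)[2L])
  if (n1 == 0L || n2 == 0L) stop_ko("both groups must be non-empty")
  res <- t(apply(t$values, 2L, function(x) {
    r <- rank(x)
    U <- sum(r[groups == levels(groups)[1L]]) - n1 * (n1 + 1) / 2
    n <- n1 + n2
    ties <- table(x)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(c(U = n1 * n2 / 2, p = 1))
    z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    c(U = U, p = min(1, 2 * pnorm(-abs(z))))
  }))
  stars <- cut(res[, "p"], c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  data.frame(taxon = taxon_labels(t), U = res[, "U"], p = res[, "p"],
             stars = as.character(stars), stringsAsFactors = FALSE,
             row.names = NULL)
}
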