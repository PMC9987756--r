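#' Species panel
#'
#' A validated table of scored species with their role (`beneficial` or
#' `harmful`) and body site (`oral` or `gut`).  Harmful species enter the
#' score with a reversed z-score so that *lower* abundance contributes a
#' *higher* score.
#'
#' @param species character vector of species labels.
#' @param role `"beneficial"` or `"harmful"` per species.
#' @param body_site `"oral"` or `"gut"` per species.
#' @return A data.frame of class `species_panel`.
#' @export
species_panel <- function(species, role, body_site) {
  if (length(species) != length(role) || length(species) != length(body_site))
    stop_ko("species, role and body_site must have equal length")
  if (!all(role %in% c("beneficial", "harmful")))
    stop_ko("role must be 'beneficial' or 'harmful'")
  if (!all(body_site %in% c("oral", "gut")))
    stop_ko("body_site must be 'oral' or 'gut'")
  key <- paste(species, body_site)
  if (anyDuplicated(key)) stop_ko("duplicate (species, body_site) pairs in panel")
  structure(data.frame(species = as.character(species), role = as.character(role),
                       body_site = as.character(body_site),
                       stringsAsFactors = FALSE),
            class = c("species_panel", "data.frame"))
}

#' Per-type mean abundances of panel species
#'
#' Arithmetic mean relative abundance of each panel species over the
#' samples assigned to each community type.  A panel species absent from
#' the table is recorded as an all-zero row with a warning.
#'
#' @param t a relative species-level [abundance_table].
#' @param assign data.frame mapping `sample_id` to `type` (one row per
#'   sample of `t`).
#' @param panel a [species_panel].
#' @return A species x type matrix of mean abundances.
#' @export
type_means <- function(t, assign, panel) {
  stopifnot(is_abundance_table(t), inherits(panel, "species_panel"))
  if (!all(c("sample_id", "type") %in% names(assign)))
    stop_ko("'assign' must have columns sample_id and type")
  idx <- match(sample_ids(t), assign$sample_id)
  if (anyNA(idx)) stop_ko("sample(s) missing from the assignment table")
  type <- assign$type[idx]
  types <- sort(unique(assign$type))
  missing_types <- setdiff(types, type)
  if (length(missing_types))
    stop_ko("type(s) with zero samples: ", paste(missing_types, collapse = ", "))
  absent <- setdiff(panel$species, taxon_labels(t))
  if (length(absent))
    warning("panel species absent from the table, filled with zeros: ",
            paste(absent, collapse = ", "))
  out <- matrix(0, nrow(panel), length(types),
                dimnames = list(panel$species, types))
  present <- intersect(panel$species, taxon_labels(t))
  for (ty in types) {
    rows <- type == ty
    out[present, ty] <- colMeans(t$values[rows, present, drop = FALSE])
  }
  out
}

#' Standardise type means per species
#'
#' Converts each species row of a species x type mean-abundance matrix to
#' z-scores with the sample (n-1) standard deviation across types.  A row
#' with identical means in every type is degenerate and maps to all-zero
#' z-scores (with a warning), which later scores 3 in every type.
#'
#' @param means species x type matrix with at least two type columns.
#' @return The z-score matrix of the same shape.
#' @export
z_across_types <- function(means) {
  if (!is.matrix(means) || ncol(means) < 2L)
    stop_ko("need a species x type matrix with >= 2 types")
  z <- t(apply(means, 1L, function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  if (any(apply(means, 1L, sd) == 0))
    warning("species with identical means across all types score z = 0 everywhere: ",
            paste(rownames(means)[apply(means, 1L, sd) == 0], collapse = ", "))
  dimnames(z) <- dimnames(means)
  z
}

#' Reverse harmful species' z-scores
#'
#' Negates the z rows of harmful panel species so that scarcity of a
#' harmful species raises the health score; beneficial rows are untouched.
#' Applying it twice is the identity.
#'
#' @param z species x type z matrix, rows aligned with `panel`.
#' @param panel a [species_panel].
#' @return The adjusted z matrix.
#' @export
reverse_harmful <- function(z, panel) {
  stopifnot(inherits(panel, "species_panel"))
  if (nrow(z) != nrow(panel)) stop_ko("z rows must align with the panel")
  harmful <- panel$role == "harmful"
  z[harmful, ] <- -z[harmful, , drop = FALSE]
  z
}

#' Normal-CDF percentile of a z-score
#'
#' \eqn{\Phi(z) \cdot 100} rounded half-away-from-zero to the nearest
#' integer (e.g. \eqn{\Phi(-0.6902) = 0.24506 \to 25}).  Rounding before
#' binning is part of the statistic's definition: it decides boundary
#' species and hence the type totals.
#'
#' @param z finite numeric (vectorised).
#' @return Integer percentile(s) in 0..100.
#' @export
percentile_from_z <- function(z) {
  if (any(!is.finite(z))) stop_ko("z must be finite")
  as.integer(round_half_up(100 * pnorm(z)))
}

#' Quartile score of a percentile
#'
#' Bins `[0,25) -> 1`, `[25,50) -> 2`, `[50,75) -> 3`, `[75,100] -> 4`;
#' the endpoints 0 and 100 clamp into the outer bins.
#'
#' @param percentile integer(s) in 0..100.
#' @return Integer score(s) in 1..4.
#' @export
quartile_score <- function(percentile) {
  if (any(percentile < 0 | percentile > 100)) stop_ko("percentile out of [0, 100]")
  ifelse(percentile < 25, 1L,
         ifelse(percentile < 50, 2L, ifelse(percentile < 75, 3L, 4L)))
}

#' Score a species panel
#'
#' Applies [percentile_from_z] and [quartile_score] elementwise to a
#' role-adjusted z matrix (harmful rows already reversed) and totals the
#' quartile scores per body site and type.
#'
#' @param z species x type z matrix with roles applied, rows aligned with
#'   `panel`; columns are the type labels.
#' @param panel a [species_panel] (one row per z row).
#' @return A `score_card`: list with `type_labels`, `table` (long
#'   data.frame: species, body_site, role, type, z, percentile, quartile)
#'   and `site_totals` (site x type matrix of summed quartile scores).
#' @export
score_panel <- function(z, panel) {
  stopifnot(inherits(panel, "species_panel"))
  if (nrow(z) != nrow(panel)) stop_ko("z rows must align with the panel")
  if (is.null(colnames(z))) stop_ko("z needs type labels as colnames")
  types <- colnames(z)
  pct <- matrix(percentile_from_z(z), nrow(z), dimnames = dimnames(z))
  qs <- matrix(quartile_score(pct), nrow(z), dimnames = dimnames(z))
  long <- data.frame(
    species = rep(panel$species, times = ncol(z)),
    body_site = rep(panel$body_site, times = ncol(z)),
    role = rep(panel$role, times = ncol(z)),
    type = rep(types, each = nrow(z)),
    z = as.vector(z), percentile = as.vector(pct), quartile = as.vector(qs),
    stringsAsFactors = FALSE)
  sites <- sort(unique(panel$body_site))
  site_totals <- t(vapply(sites, function(s)
    colSums(qs[panel$body_site == s, , drop = FALSE]), numeric(ncol(z))))
  rownames(site_totals) <- sites
  structure(list(type_labels = types, table = long,
                 site_totals = site_totals),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat("score_card totals (quartile-score sums):\n")
  print(x$site_totals)
  invisible(x)
}

#' Grand totals across body sites
#'
#' Elementwise sum of the per-type site totals of an oral and a gut score
#' card (labels must match).
#'
#' @param oral,gut `score_card`s with matching `type_labels`, each scoring
#'   a single body site.
#' @return Named numeric vector of per-type grand totals.
#' @export
grand_totals <- function(oral, gut) {
  stopifnot(inherits(oral, "score_card"), inherits(gut, "score_card"))
  if (!identical(oral$type_labels, gut$type_labels))
    stop_ko("type labels differ between the two score cards")
  colSums(oral$site_totals) + colSums(gut$site_totals)
}

#' End-to-end panel scoring from a cohort
#'
#' Composes [type_means], [z_across_types], [reverse_harmful] and
#' [score_panel] on a relative species-level table: the full scoring
#' statistic from per-sample abundances and type assignments.
#'
#' @param t a relative species-level [abundance_table].
#' @param assign data.frame with `sample_id` and `type`.
#' @param panel a [species_panel].
#' @return A `score_card`.
#' @export
score_cohort <- function(t, assign, panel) {
  mu <- type_means(t, assign, panel)
  z <- reverse_harmful(z_across_types(mu), panel)
  score_panel(z, panel)
}
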