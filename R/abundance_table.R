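#' Abundance tables
#'
#' An `abundance_table` is the canonical container used throughout the
#' package: a numeric matrix with samples as rows and taxa as columns,
#' carrying a `mode` flag (`"counts"` or `"relative"`) and a `body_site`
#' tag (`"oral"`, `"gut"` or `"unspecified"`).  Relative tables must have
#' rows summing to one.
#'
#' @param values numeric matrix, rows = samples, columns = taxa, with
#'   unique non-empty dimnames.
#' @param mode `"counts"` or `"relative"`.
#' @param body_site `"oral"`, `"gut"` or `"unspecified"`.
#' @return An `abundance_table` object.
#' @export
abundance_table <- function(values, mode = c("counts", "relative"),
                            body_site = c("unspecified", "oral", "gut")) {
  mode <- match.arg(mode)
  body_site <- match.arg(body_site)
  if (!is.matrix(values) || !is.numeric(values))
    stop_ko("'values' must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_ko("'values' must carry sample ids (rownames) and taxon labels (colnames)")
  if (anyDuplicated(rownames(values)))
    stop_ko("duplicate sample ids: ",
            paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_ko("duplicate taxon labels: ",
            paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop_ko("abundance values must be finite and non-missing")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop_ko(sprintf("negative abundance at sample '%s', taxon '%s'",
                    rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (mode == "relative") {
    rs <- rowSums(values)
    if (any(rs == 0))
      stop_ko("relative table has all-zero row(s): ",
              paste(rownames(values)[rs == 0], collapse = ", "))
    if (any(abs(rs - 1) > 1e-9))
      stop_ko("relative table rows must sum to 1 (worst deviation ",
              format(max(abs(rs - 1))), ")")
  }
  structure(list(values = values, mode = mode, body_site = body_site),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$mode, x$body_site))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' @rdname abundance_table
#' @param x object to test / subset.
#' @export
is_abundance_table <- function(x) inherits(x, "abundance_table")

sample_ids <- function(t) rownames(t$values)
taxon_labels <- function(t) colnames(t$values)

# Subset an abundance table by sample ids and/or taxon labels (keeps mode;
# no renormalisation -- callers decide).
subset_table <- function(t, samples = NULL, taxa = NULL, revalidate = TRUE) {
  v <- t$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(taxa)) v <- v[, taxa, drop = FALSE]
  out <- t
  out$values <- v
  if (revalidate && t$mode == "relative") out$mode <- "relative"
  out
}

#' Read an abundance table from TSV
#'
#' Expects a UTF-8 tab-delimited file with one header row and one label
#' column.  The canonical orientation is samples as rows; files written
#' taxa-as-rows are transposed on read.
#'
#' @param path path to a TSV file.
#' @param mode `"counts"` or `"relative"`.
#' @param orientation `"samples_as_rows"` (default) or `"taxa_as_rows"`.
#' @param body_site body-site tag attached to the table.
#' @return An [abundance_table].
#' @export
read_abundance <- function(path, mode = c("counts", "relative"),
                           orientation = c("samples_as_rows", "taxa_as_rows"),
                           body_site = c("unspecified", "oral", "gut")) {
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  body_site <- match.arg(body_site)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = NA)
  if (ncol(df) < 2L) stop_ko("TSV must have a label column plus at least one data column")
  labels <- as.character(df[[1L]])
  num <- df[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    col <- num[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(conv <- as.numeric(col))
      if (anyNA(conv)) {
        i <- which(is.na(conv))[1L]
        stop_ko(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                        labels[i], names(num)[j], col[i]))
      }
      num[[j]] <- conv
    }
    if (anyNA(num[[j]]))
      stop_ko(sprintf("missing value at row '%s', column '%s'",
                      labels[which(is.na(num[[j]]))[1L]], names(num)[j]))
  }
  m <- as.matrix(num)
  rownames(m) <- labels
  if (orientation == "taxa_as_rows") m <- t(m)
  abundance_table(m, mode = mode, body_site = body_site)
}

#' Write an abundance table to TSV
#'
#' Inverse of [read_abundance] in the canonical samples-as-rows layout;
#' `read_abundance(write_abundance(t))` reproduces `t` exactly on labels
#' and to full printed precision on values.
#'
#' @param t an [abundance_table].
#' @param path output path.
#' @param label_header header for the sample-id column.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(t, path, label_header = "sample_id") {
  stopifnot(is_abundance_table(t))
  df <- data.frame(check.names = FALSE, row.names = NULL,
                   stats::setNames(list(sample_ids(t)), label_header))
  vals <- as.data.frame(t$values, check.names = FALSE)
  df <- cbind(df, vals)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample's counts by its total.  Refuses already-relative
#' input (double normalisation) and all-zero samples.
#'
#' @param t an [abundance_table] with `mode = "counts"`.
#' @return A relative [abundance_table].
#' @export
to_relative <- function(t) {
  stopifnot(is_abundance_table(t))
  if (t$mode != "counts")
    stop_ko("table is already relative; refusing double normalisation")
  rs <- rowSums(t$values)
  if (any(rs == 0))
    stop_ko("sample(s) with zero total count: ",
            paste(sample_ids(t)[rs == 0], collapse = ", "))
  abundance_table(t$values / rs, mode = "relative", body_site = t$body_site)
}

#' Drop unnamed taxa
#'
#' Removes taxa whose lineage label carries the empty-rank marker `";__"`
#' as a suffix (or is just `"__"`), i.e. reads classified only to a higher
#' rank.  Relative tables are renormalised afterwards.
#'
#' @param t an [abundance_table].
#' @return The reduced [abundance_table].
#' @export
drop_unnamed_taxa <- function(t) {
  stopifnot(is_abundance_table(t))
  lab <- taxon_labels(t)
  unnamed <- endsWith(lab, ";__") | lab == "__"
  if (all(unnamed)) stop_ko("all taxa are unnamed; nothing left to analyse")
  if (!any(unnamed)) return(t)
  v <- t$values[, !unnamed, drop = FALSE]
  if (t$mode == "relative") {
    rs <- rowSums(v)
    if (any(rs == 0))
      stop_ko("sample(s) left with zero abundance after dropping unnamed taxa: ",
              paste(rownames(v)[rs == 0], collapse = ", "))
    v <- v / rs
  }
  abundance_table(v, mode = t$mode, body_site = t$body_site)
}

#' Mean-abundance prevalence filter
#'
#' Keeps exactly the taxa whose mean relative abundance across the samples
#' of the table is strictly greater than `min_mean_frac` (default 1e-4,
#' i.e. 0.01%).  The reduced table is *not* renormalised: downstream
#' clustering consumes it as-is.
#'
#' @param t a relative [abundance_table].
#' @param min_mean_frac strict lower cutoff on the per-taxon mean relative
#'   abundance (fraction, default `1e-4`).
#' @return The reduced [abundance_table], with the removed taxa recorded in
#'   attribute `"removed_taxa"`.
#' @export
prevalence_filter <- function(t, min_mean_frac = 1e-4) {
  stopifnot(is_abundance_table(t))
  if (t$mode != "relative")
    stop_ko("prevalence_filter expects a relative table; call to_relative() first")
  check_scalar_number(min_mean_frac, "min_mean_frac", min = 0)
  mu <- colMeans(t$values)
  keep <- mu > min_mean_frac
  if (!any(keep))
    stop_ko("no taxon exceeds mean relative abundance ", format(min_mean_frac))
  out <- t
  out$values <- t$values[, keep, drop = FALSE]
  attr(out, "removed_taxa") <- taxon_labels(t)[!keep]
  out
}

#' Sample metadata
#'
#' Validated table pairing sample ids with subject ids and body sites.
#' Each subject may contribute at most one oral and one gut sample.
#'
#' @param sample_id,subject_id character vectors of equal length.
#' @param body_site character vector in `{"oral","gut"}`.
#' @return A `data.frame` of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, subject_id, body_site) {
  if (length(sample_id) != length(subject_id) ||
      length(sample_id) != length(body_site))
    stop_ko("sample_id, subject_id and body_site must have equal length")
  if (!all(body_site %in% c("oral", "gut")))
    stop_ko("body_site must be 'oral' or 'gut'")
  if (anyDuplicated(sample_id)) stop_ko("duplicate sample ids in metadata")
  key <- paste(subject_id, body_site)
  if (anyDuplicated(key))
    stop_ko("subject(s) with more than one sample per body site: ",
            paste(unique(key[duplicated(key)]), collapse = ", "))
  structure(data.frame(sample_id = as.character(sample_id),
                       subject_id = as.character(subject_id),
                       body_site = as.character(body_site),
                       stringsAsFactors = FALSE),
            class = c("sample_metadata", "data.frame"))
}
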