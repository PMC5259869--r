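#' Expression matrix container
#'
#' A light container for a features-by-samples expression matrix with unique
#' feature and sample identifiers. Missing entries are represented as `NA`
#' and can be removed with [impute_missing()].
#'
#' @param values numeric matrix (features in rows, samples in columns).
#' @param feature_ids,sample_ids character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @return An object of class `expr_mat`: a list with element `values`, a
#'   numeric matrix carrying the identifiers as dimnames.
#' @examples
#' m <- expr_mat(matrix(1:6, 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))))
#' feature_ids(m)
#' @export
expr_mat <- function(values, feature_ids = rownames(values),
                     sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids))
    stopf("expression matrix needs feature and sample identifiers")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stopf("%d feature ids for %d rows", length(feature_ids), nrow(values))
  if (length(sample_ids) != ncol(values))
    stopf("%d sample ids for %d columns", length(sample_ids), ncol(values))
  if (anyDuplicated(feature_ids))
    stopf("duplicate feature id(s): %s",
          paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stopf("duplicate sample id(s): %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(values = values), class = "expr_mat")
}

#' @rdname expr_mat
#' @param x an `expr_mat`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname expr_mat
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
as.matrix.expr_mat <- function(x, ...) x$values

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d features x %d samples (%d missing values)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Average probe-level rows mapping to the same feature
#'
#' Probe rows are collapsed to one row per feature by the per-sample
#' arithmetic mean over non-missing probe values (so one missing probe does
#' not lose the other probes' signal for that sample). A sample missing in
#' all probes of a feature stays missing.
#'
#' @param expr an [expr_mat] whose rows are probes.
#' @param id_of mapping from probe id to feature id: either a named character
#'   vector (names = probes) or a two-column data frame (probe, feature).
#' @return An [expr_mat] with one row per distinct feature, in first-probe
#'   appearance order.
#' @export
collapse_duplicates <- function(expr, id_of) {
  if (is.data.frame(id_of)) {
    map <- as.character(id_of[[2L]])
    names(map) <- as.character(id_of[[1L]])
  } else {
    map <- as.character(id_of)
    names(map) <- names(id_of)
  }
  probes <- feature_ids(expr)
  missing_probe <- setdiff(probes, names(map))
  if (length(missing_probe))
    stopf("probe(s) missing from the id mapping: %s",
          paste(utils::head(missing_probe, 5L), collapse = ", "))
  grp <- factor(map[probes], levels = unique(map[probes]))
  v <- expr$values
  sums <- rowsum(ifelse(is.na(v), 0, v), grp)
  cnts <- rowsum((!is.na(v)) * 1, grp)
  out <- sums / cnts          # 0/0 -> NaN where every probe was missing
  out[cnts == 0] <- NA_real_
  expr_mat(out, feature_ids = levels(grp), sample_ids = sample_ids(expr))
}

#' Impute missing entries by the feature's mean across samples
#'
#' Each `NA` entry is replaced by the mean of the feature's non-missing
#' values; a fully missing feature row is an error.
#'
#' @param expr an [expr_mat].
#' @return An [expr_mat] without missing entries.
#' @export
impute_missing <- function(expr) {
  v <- expr$values
  nas <- is.na(v)
  if (!any(nas)) return(expr)
  n_ok <- rowSums(!nas)
  if (any(n_ok == 0L))
    stopf("feature(s) with no observed values: %s",
          paste(utils::head(feature_ids(expr)[n_ok == 0L], 5L), collapse = ", "))
  mu <- rowSums(v, na.rm = TRUE) / n_ok
  idx <- which(nas, arr.ind = TRUE)
  v[idx] <- mu[idx[, 1L]]
  expr_mat(v, feature_ids(expr), sample_ids(expr))
}

#' Keep the most variable features
#'
#' Rows are ranked by unbiased sample variance (denominator n-1) across
#' samples; either the `top_n` most variable rows or all rows with variance
#' strictly above `min_var` are kept, exactly one of the two criteria being
#' given. Ties at the `top_n` boundary are broken by input order. The output
#' is ordered by decreasing variance; the attribute `"original_index"`
#' records where each kept row sat in the input.
#'
#' @param expr an [expr_mat] (no missing values).
#' @param top_n number of rows to keep.
#' @param min_var variance cutoff (strict).
#' @return A filtered [expr_mat] with attributes `"variances"` and
#'   `"original_index"`.
#' @export
filter_by_variance <- function(expr, top_n = NULL, min_var = NULL) {
  if (is.null(top_n) == is.null(min_var))
    stopf("give exactly one of `top_n` or `min_var`")
  v <- expr$values
  vars <- apply(v, 1L, stats::var)
  ord <- order(-vars)                     # stable: input order breaks ties
  if (!is.null(top_n)) {
    top_n <- as.integer(top_n)
    if (top_n < 1L || top_n > nrow(v))
      stopf("`top_n` = %d outside 1..%d features", top_n, nrow(v))
    keep <- ord[seq_len(top_n)]
  } else {
    keep <- ord[vars[ord] > min_var]
  }
  out <- expr_mat(v[keep, , drop = FALSE], feature_ids(expr)[keep],
                  sample_ids(expr))
  attr(out, "variances") <- vars[keep]
  attr(out, "original_index") <- keep
  out
}

#' Restrict two expression matrices to their common samples
#'
#' Both matrices are restricted to the intersection of their sample ids, in
#' the order the shared samples appear in `expr_a`. At least three shared
#' samples are required (Pearson correlation is degenerate below that).
#'
#' @param expr_a,expr_b [expr_mat] objects.
#' @return A list with elements `a` and `b`, sample-aligned.
#' @export
align_samples <- function(expr_a, expr_b) {
  common <- intersect(sample_ids(expr_a), sample_ids(expr_b))
  if (length(common) < 3L)
    stopf("only %d shared sample(s); need at least 3", length(common))
  sub <- function(e) expr_mat(e$values[, common, drop = FALSE],
                              feature_ids(e), common)
  list(a = sub(expr_a), b = sub(expr_b))
}
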