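#' Read an expression matrix from TSV
#'
#' Dialect: tab-separated with a header row of sample ids; first column
#' holds the feature ids. Missing values may be written as `NA` or an empty
#' field. Ragged rows and duplicate ids are errors naming the offending
#' line / id.
#'
#' @param path file path.
#' @return An [expr_mat].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1L)
    stopf("ragged TSV %s: line(s) %s have a different field count",
          path, paste(utils::head(which(nf != nf[1L]), 5L), collapse = ", "))
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          comment.char = "", na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("expression TSV needs an id column plus samples")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stopf("duplicate feature id(s) in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  expr_mat(m, feature_ids = ids, sample_ids = colnames(df)[-1L])
}

#' Write an expression matrix to TSV
#'
#' Values are serialized with 17 significant digits so a write/read
#' round-trip reproduces them exactly; missing entries are written as `NA`.
#'
#' @param expr an [expr_mat].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  v <- expr$values
  ch <- matrix(formatC(v, digits = 17, format = "g"), nrow(v), ncol(v))
  ch[is.na(v)] <- "NA"
  df <- data.frame(feature_id = feature_ids(expr), ch,
                   stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("feature_id", sample_ids(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read known gene-miRNA interaction pairs
#'
#' Two-column TSV (gene id, miRNA id), miRTarBase style; extra columns are
#' ignored. Duplicated pairs are dropped with a logged count. When
#' `header = "auto"`, the first row is treated as a header only if `ids`
#' are supplied and neither of its first two fields occurs among them.
#'
#' @param path file path.
#' @param header `TRUE`, `FALSE`, or `"auto"`.
#' @param ids optional character vector of node ids used by the auto rule.
#' @return Data frame with columns `gene`, `mirna`, de-duplicated.
#' @export
read_interaction_pairs <- function(path, header = "auto", ids = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty interaction file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stopf("interaction file %s needs >= 2 columns on every line", path)
  if (identical(header, "auto")) {
    header <- if (is.null(ids)) FALSE
              else !any(fields[[1L]][1:2] %in% ids)
  }
  if (isTRUE(header)) fields <- fields[-1L]
  if (!length(fields)) stopf("interaction file %s holds only a header", path)
  df <- data.frame(gene = vapply(fields, `[`, character(1), 1L),
                   mirna = vapply(fields, `[`, character(1), 2L),
                   stringsAsFactors = FALSE)
  ndup <- sum(duplicated(df))
  if (ndup) co_log("dropped %d duplicated interaction pair(s)", ndup)
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' Write interaction pairs to TSV
#'
#' @param pairs data frame with gene and miRNA columns.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_interaction_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a miRNA genomic-cluster table
#'
#' TSV with columns cluster_id and mirna_id (further columns such as
#' chromosome/start/end are kept but unused).
#'
#' @param path file path.
#' @return Named list: cluster id -> character vector of miRNA ids.
#' @export
read_mirna_clusters <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) stopf("cluster TSV needs cluster_id and mirna_id columns")
  split(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, fields tab-separated: name, description,
#' then members.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stopf("GMT lines need name, description and >= 1 member")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  sets
}

modules_to_list <- function(modules) {
  lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    list(id = sprintf("M%03d", i),
         genes = as.list(m$genes),
         mirnas = as.list(m$mirnas),
         n_genes = length(m$genes),
         n_mirnas = length(m$mirnas),
         source_runs = m$source_runs,
         edge_counts = if (is.null(m$edge_counts)) NULL
                       else as.list(m$edge_counts),
         valid = isTRUE(m$valid))
  })
}

#' Write modules to JSON
#'
#' Deterministic serialization (stable ordering and formatting), so two
#' runs with the same configuration and seed produce byte-identical files.
#'
#' @param modules list of `gm_module` objects.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_modules_json <- function(modules, path) {
  json <- jsonlite::toJSON(modules_to_list(modules), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read modules back from JSON
#'
#' @param path file written by [write_modules_json()].
#' @return List of `gm_module` objects.
#' @export
read_modules_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    structure(list(genes = as.character(unlist(r$genes)),
                   mirnas = as.character(unlist(r$mirnas)),
                   source_runs = r$source_runs,
                   edge_counts = if (is.null(r$edge_counts)) NULL
                                 else unlist(r$edge_counts),
                   valid = isTRUE(r$valid)),
              class = "gm_module")
  })
}

#' Long-format module membership table
#'
#' @param modules list of `gm_module` objects.
#' @return Data frame (module_id, node_id, node_type).
#' @export
modules_to_table <- function(modules) {
  do.call(rbind, lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    data.frame(module_id = sprintf("M%03d", i),
               node_id = c(m$genes, m$mirnas),
               node_type = c(rep("gene", length(m$genes)),
                             rep("mirna", length(m$mirnas))),
               stringsAsFactors = FALSE)
  }))
}

#' Export a network as an edge list or GraphML
#'
#' @param x an [adjacency] or [cross_adjacency].
#' @param path output file path.
#' @param format `"edgelist"` (TSV: from, to) or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(x, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (inherits(x, "adjacency")) {
    g <- igraph::graph_from_adjacency_matrix(x$A, mode = "undirected")
  } else if (inherits(x, "cross_adjacency")) {
    B <- rbind(cbind(matrix(0, nrow(x$C), nrow(x$C)), x$C),
               cbind(t(x$C), matrix(0, ncol(x$C), ncol(x$C))))
    dimnames(B) <- list(c(x$gene_ids, x$mirna_ids),
                        c(x$gene_ids, x$mirna_ids))
    g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  } else stopf("cannot export object of class %s", class(x)[1L])
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    utils::write.table(data.frame(from = el[, 1L], to = el[, 2L]),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a planted dataset to a directory
#'
#' Emits the expression TSVs, the known-pair TSV, a cluster TSV (each
#' planted module's miRNAs as one cluster) and a ground-truth label TSV,
#' all re-readable by the package's own readers.
#'
#' @param ds a `planted_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_planted_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(ds$expr_g, file.path(dir, "gene_expression.tsv"))
  write_expression(ds$expr_m, file.path(dir, "mirna_expression.tsv"))
  write_interaction_pairs(ds$known_pairs, file.path(dir, "known_pairs.tsv"))
  cl <- do.call(rbind, lapply(names(ds$clusters), function(cn)
    data.frame(cluster_id = cn, mirna_id = ds$clusters[[cn]],
               stringsAsFactors = FALSE)))
  utils::write.table(cl, file.path(dir, "mirna_clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  labels <- data.frame(
    node_id = c(names(ds$true_gene_labels), names(ds$true_mirna_labels)),
    node_type = c(rep("gene", length(ds$true_gene_labels)),
                  rep("mirna", length(ds$true_mirna_labels))),
    module = c(ds$true_gene_labels, ds$true_mirna_labels))
  utils::write.table(labels, file.path(dir, "true_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
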