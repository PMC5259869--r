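#' Pipeline configuration
#'
#' All tunables of the end-to-end pipeline with their defaults. Unknown
#' fields are rejected; every field is validated.
#'
#' Defaults follow the method's reference analysis: 3200 most-variable
#' genes, within-type threshold 0.6, gene-miRNA threshold grid 0.1..0.9 by
#' 0.1, module numbers 100..200 by 10, lambda 1, merge overlap 0.9,
#' enrichment minimum overlap 3 and alpha 0.05, scale-free acceptance
#' R-squared 0.8. For small (e.g. simulated) data pass smaller `K_grid`
#' and `gene_variance_top_n`.
#'
#' @param gene_variance_top_n how many most-variable genes to keep
#'   (`NULL` = keep all; capped at the number of genes with a log line).
#' @param coexpr_tau within-type correlation threshold, or `"auto"` to
#'   pick per network by scale-free fit over `within_tau_grid`.
#' @param within_tau_grid grid for `coexpr_tau = "auto"`.
#' @param min_r2 scale-free acceptance R-squared for `"auto"`.
#' @param gm_tau gene-miRNA threshold, or `"auto"` to select by rank-AUC
#'   over `gm_tau_grid`.
#' @param gm_tau_grid candidate gene-miRNA thresholds.
#' @param K_grid module numbers to run.
#' @param lambda coupling weight.
#' @param merge_overlap overlap fraction above which modules merge.
#' @param overlap_method `"min"` or `"jaccard"`.
#' @param min_overlap minimum overlap for an enrichment test.
#' @param alpha enrichment significance level (adjusted p).
#' @param seed top-level seed; stage seeds are derived from it
#'   deterministically (the k-means run at module number K uses
#'   `seed + K`).
#' @param kmeans_nstart k-means++ restarts.
#' @param kmeans_normalize_rows cluster row-normalized embeddings.
#' @param impute_before_collapse impute missing values before probe
#'   collapsing instead of after.
#' @param ... unknown fields - always an error.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(gene_variance_top_n = 3200L,
                            coexpr_tau = 0.6,
                            within_tau_grid = seq(0.1, 0.9, by = 0.1),
                            min_r2 = 0.8,
                            gm_tau = "auto",
                            gm_tau_grid = seq(0.1, 0.9, by = 0.1),
                            K_grid = seq(100L, 200L, by = 10L),
                            lambda = 1,
                            merge_overlap = 0.9,
                            overlap_method = "min",
                            min_overlap = 3L,
                            alpha = 0.05,
                            seed = 1L,
                            kmeans_nstart = 50L,
                            kmeans_normalize_rows = TRUE,
                            impute_before_collapse = FALSE,
                            ...) {
  extra <- list(...)
  if (length(extra))
    stopf("unknown configuration field(s): %s",
          paste(names(extra), collapse = ", "))
  chk_num <- function(x, nm, lo, hi) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
      stopf("`%s` must be a single number in [%g, %g]", nm, lo, hi)
  }
  if (!is.null(gene_variance_top_n))
    chk_num(gene_variance_top_n, "gene_variance_top_n", 1, Inf)
  if (!identical(coexpr_tau, "auto")) chk_num(coexpr_tau, "coexpr_tau", 0, 1 - 1e-12)
  if (!identical(gm_tau, "auto")) chk_num(gm_tau, "gm_tau", 0, 1 - 1e-12)
  if (any(within_tau_grid < 0 | within_tau_grid >= 1) ||
      any(gm_tau_grid < 0 | gm_tau_grid >= 1))
    stopf("threshold grids must lie in [0, 1)")
  chk_num(min_r2, "min_r2", 0, 1)
  if (!length(K_grid) || any(K_grid < 1)) stopf("`K_grid` must be positive")
  chk_num(lambda, "lambda", 0, Inf)
  chk_num(merge_overlap, "merge_overlap", 1e-12, 1)
  if (!overlap_method %in% c("min", "jaccard"))
    stopf("`overlap_method` must be 'min' or 'jaccard'")
  chk_num(min_overlap, "min_overlap", 0, Inf)
  chk_num(alpha, "alpha", 0, 1)
  chk_num(seed, "seed", -2^31, 2^31)
  chk_num(kmeans_nstart, "kmeans_nstart", 1, Inf)
  structure(list(gene_variance_top_n = if (is.null(gene_variance_top_n)) NULL
                                       else as.integer(gene_variance_top_n),
                 coexpr_tau = coexpr_tau,
                 within_tau_grid = as.numeric(within_tau_grid),
                 min_r2 = min_r2,
                 gm_tau = gm_tau,
                 gm_tau_grid = as.numeric(gm_tau_grid),
                 K_grid = as.integer(sort(unique(K_grid))),
                 lambda = lambda,
                 merge_overlap = merge_overlap,
                 overlap_method = overlap_method,
                 min_overlap = as.integer(min_overlap),
                 alpha = alpha,
                 seed = as.integer(seed),
                 kmeans_nstart = as.integer(kmeans_nstart),
                 kmeans_normalize_rows = isTRUE(kmeans_normalize_rows),
                 impute_before_collapse = isTRUE(impute_before_collapse)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm,
                paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

#' Run the full co-module detection pipeline
#'
#' Orchestrates preprocess -> network construction -> threshold tuning ->
#' per-K detection -> filtering -> merging -> enrichment, writing every
#' intermediate artifact plus a machine-readable manifest into `out_dir`.
#' All input paths are checked before any computation; any stage error
#' halts the run with the stage name, leaving earlier artifacts in place.
#' Reruns with the same configuration and inputs are byte-identical in
#' their module output.
#'
#' @param config a [pipeline_config].
#' @param gene_expr,mirna_expr paths to expression TSVs
#'   (see [read_expression()]).
#' @param known_pairs path to the known-interaction TSV.
#' @param probe_map optional path to a probe-to-gene two-column TSV; when
#'   given, gene probes are collapsed first.
#' @param mirna_clusters optional path to a miRNA cluster TSV; when given,
#'   cluster/module enrichment is run in both directions.
#' @param out_dir output directory (created).
#' @return Invisibly, a list with the networks, tuning table, merged
#'   modules, enrichment tables and the manifest.
#' @export
run_pipeline <- function(config, gene_expr, mirna_expr, known_pairs,
                         probe_map = NULL, mirna_clusters = NULL, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- c(gene_expr = gene_expr, mirna_expr = mirna_expr,
             known_pairs = known_pairs, probe_map = probe_map,
             mirna_clusters = mirna_clusters)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stopf("missing input file(s): %s", paste(missing, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    co_log("[%s] ...", name)
    tryCatch(code, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  prep <- stage("preprocess", {
    eg <- read_expression(gene_expr)
    em <- read_expression(mirna_expr)
    if (!is.null(probe_map)) {
      pm <- utils::read.delim(probe_map, stringsAsFactors = FALSE, quote = "")
      if (config$impute_before_collapse) eg <- impute_missing(eg)
      eg <- collapse_duplicates(eg, pm)
    }
    eg <- impute_missing(eg)
    em <- impute_missing(em)
    if (!is.null(config$gene_variance_top_n)) {
      top_n <- min(config$gene_variance_top_n, nrow(eg$values))
      if (top_n < config$gene_variance_top_n)
        co_log("only %d genes available; variance filter capped", top_n)
      eg <- filter_by_variance(eg, top_n = top_n)
    }
    al <- align_samples(eg, em)
    write_expression(al$a, file.path(out_dir, "gene_expression_clean.tsv"))
    write_expression(al$b, file.path(out_dir, "mirna_expression_clean.tsv"))
    al
  })
  known <- stage("read-known-pairs", {
    read_interaction_pairs(known_pairs,
                           ids = c(feature_ids(prep$a), feature_ids(prep$b)))
  })

  nets <- stage("netbuild", {
    corr_g <- correlation_matrix(prep$a)
    corr_m <- correlation_matrix(prep$b)
    pick <- function(corr, label) {
      if (identical(config$coexpr_tau, "auto")) {
        fit <- select_scale_free_threshold(corr, config$within_tau_grid,
                                           config$min_r2)
        co_log("%s threshold %.2f by scale-free fit (R2 = %.3f)",
               label, fit$threshold, fit$r_squared)
        list(adj = threshold_adjacency(corr, fit$threshold), fit = fit)
      } else {
        list(adj = threshold_adjacency(corr, config$coexpr_tau), fit = NULL)
      }
    }
    g <- pick(corr_g, "gene"); m <- pick(corr_m, "miRNA")
    export_network(g$adj, file.path(out_dir, "gene_network_edges.tsv"))
    export_network(m$adj, file.path(out_dir, "mirna_network_edges.tsv"))
    list(adj_g = g$adj, adj_m = m$adj, fit_g = g$fit, fit_m = m$fit)
  })

  tune <- stage("tune-gm-threshold", {
    if (identical(config$gm_tau, "auto")) {
      K_grid <- config$K_grid[config$K_grid <=
                                nrow(nets$adj_g$A) + nrow(nets$adj_m$A)]
      if (!length(K_grid)) stopf("every K in the grid exceeds the node count")
      sel <- select_gm_threshold(prep$a, prep$b, known,
                                 tau_grid = config$gm_tau_grid,
                                 K_grid = K_grid, lambda = config$lambda,
                                 adj_g = nets$adj_g, adj_m = nets$adj_m)
      utils::write.table(sel$table, file.path(out_dir, "auc_grid.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      co_log("gene-miRNA threshold %.2f (mean AUC %.3f)", sel$tau, sel$auc$auc)
      sel
    } else {
      list(tau = config$gm_tau, auc = NULL, table = NULL)
    }
  })

  net <- stage("integrate", {
    corr_gm <- correlation_matrix(prep$a, prep$b)
    C <- combine_cross_network(threshold_adjacency(corr_gm, tune$tau), known)
    export_network(C, file.path(out_dir, "cross_network_edges.tsv"))
    integrated_network(nets$adj_g, nets$adj_m, C, config$lambda)
  })

  runs <- stage("detect", {
    n <- n_nodes(net)
    out <- list()
    for (K in config$K_grid) {
      if (K >= n) { co_log("skipping K = %d (>= %d nodes)", K, n); next }
      det <- detect_comodules(net, K = K, seed = config$seed + K,
                              normalize_rows = config$kmeans_normalize_rows,
                              nstart = config$kmeans_nstart)
      out[[as.character(K)]] <- det
    }
    if (!length(out)) stopf("no usable K in the grid")
    out
  })

  modules <- stage("merge", {
    all_valid <- lapply(runs, function(r) valid_modules(r$modules))
    merged <- merge_module_runs(all_valid, overlap_frac = config$merge_overlap,
                                method = config$overlap_method)
    merged <- lapply(merged, count_module_edges, net = net)
    write_modules_json(merged, file.path(out_dir, "modules.json"))
    tab <- modules_to_table(merged)
    if (!is.null(tab))
      utils::write.table(tab, file.path(out_dir, "modules.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    merged
  })
  co_log("identified %d merged co-modules", length(modules))

  enrich <- NULL
  if (!is.null(mirna_clusters)) {
    enrich <- stage("enrich", {
      clusters <- read_mirna_clusters(mirna_clusters)
      mod_sets <- lapply(modules, `[[`, "mirnas")
      names(mod_sets) <- sprintf("M%03d", seq_along(mod_sets))
      bg <- net$adj_m$node_ids
      by_cluster <- set_enrichment(mod_sets, clusters, bg,
                                   config$min_overlap, config$alpha)
      by_module <- set_enrichment(clusters, mod_sets, bg,
                                  config$min_overlap, config$alpha)
      utils::write.table(by_cluster,
                         file.path(out_dir, "module_cluster_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(by_module,
                         file.path(out_dir, "cluster_module_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(modules_by_clusters = by_cluster, clusters_by_modules = by_module)
    })
  }

  manifest <- list(
    package = "comodule",
    version = as.character(utils::packageVersion("comodule")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    inputs = as.list(paths),
    chosen_gm_tau = tune$tau,
    n_genes = length(net$adj_g$node_ids),
    n_mirnas = length(net$adj_m$node_ids),
    n_known_pairs = nrow(known),
    K_run = as.integer(names(runs)),
    n_modules = length(modules))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"),
             file.path(out_dir, "manifest.json"))

  invisible(list(preprocessed = prep, networks = nets, tuning = tune,
                 net = net, runs = runs, modules = modules,
                 enrichment = enrich, manifest = manifest))
}

#' Replay a pipeline run from its manifest
#'
#' Re-executes [run_pipeline()] using only the configuration and input
#' paths recorded in a manifest, demonstrating that the manifest suffices
#' to reproduce a run.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir output directory for the replay.
#' @return Invisibly, the [run_pipeline()] result.
#' @export
replay_run <- function(manifest_path, out_dir) {
  man <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, man$config)
  inp <- man$inputs
  run_pipeline(cfg, gene_expr = inp$gene_expr, mirna_expr = inp$mirna_expr,
               known_pairs = inp$known_pairs,
               probe_map = inp$probe_map %||% NULL,
               mirna_clusters = inp$mirna_clusters %||% NULL,
               out_dir = out_dir)
}
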