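#' Simulate a planted gene-miRNA co-module dataset
#'
#' Generates paired expression matrices with block-correlation structure:
#' each planted module k has one latent factor per sample, and every member
#' gene and miRNA is `loading * factor + Normal(0, noise_sd)` noise around
#' it, so within-module features (of either type) share expected absolute
#' correlation `loading^2 / (loading^2 + noise_sd^2)` while between-module
#' and background correlations are centred at zero. Background features are
#' pure standard-normal noise. Known interactions are sampled Bernoulli:
#' rate `known_within_rate` for same-module gene-miRNA pairs and
#' `known_background_rate` for all other pairs. Everything is reproducible
#' from `seed`.
#'
#' The defaults (6 modules of 30 genes + 5 miRNAs, 50 background genes, 20
#' background miRNAs, 200 samples, loading 0.85, noise 0.5, within rate
#' 0.3, background rate 0.005, seed 11) give within-module correlations
#' around 0.74 - comfortably separated from background at 200 samples, the
#' regime the detection method assumes.
#'
#' @param n_modules,genes_per_module,mirnas_per_module planted structure.
#' @param n_background_genes,n_background_mirnas unstructured features.
#' @param n_samples number of samples.
#' @param loading latent factor loading in `(0, 1]`.
#' @param noise_sd feature noise standard deviation.
#' @param known_within_rate,known_background_rate Bernoulli rates for the
#'   known-interaction list.
#' @param seed RNG seed.
#' @return An object of class `planted_dataset`: list with `expr_g`,
#'   `expr_m` ([expr_mat]), `known_pairs` (data frame gene/mirna),
#'   `true_gene_labels`, `true_mirna_labels` (named integers, 0 =
#'   background), `clusters` (each planted module's miRNAs, as a genomic
#'   cluster stand-in), and `params`.
#' @export
generate_planted_dataset <- function(n_modules = 6L,
                                     genes_per_module = 30L,
                                     mirnas_per_module = 5L,
                                     n_background_genes = 50L,
                                     n_background_mirnas = 20L,
                                     n_samples = 200L,
                                     loading = 0.85,
                                     noise_sd = 0.5,
                                     known_within_rate = 0.3,
                                     known_background_rate = 0.005,
                                     seed = 11L) {
  counts <- c(n_modules, genes_per_module, mirnas_per_module, n_samples)
  if (any(counts < 1L)) stopf("module/sample counts must be >= 1")
  if (n_background_genes < 0L || n_background_mirnas < 0L)
    stopf("background counts must be >= 0")
  if (loading <= 0 || loading > 1) stopf("`loading` must lie in (0, 1]")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (any(c(known_within_rate, known_background_rate) < 0 |
          c(known_within_rate, known_background_rate) > 1))
    stopf("known-pair rates must lie in [0, 1]")
  ng <- n_modules * genes_per_module + n_background_genes
  nm <- n_modules * mirnas_per_module + n_background_mirnas
  gene_ids <- sprintf("gene_%03d", seq_len(ng))
  mirna_ids <- sprintf("mir_%03d", seq_len(nm))
  glab <- c(rep(seq_len(n_modules), each = genes_per_module),
            rep(0L, n_background_genes))
  mlab <- c(rep(seq_len(n_modules), each = mirnas_per_module),
            rep(0L, n_background_mirnas))
  names(glab) <- gene_ids; names(mlab) <- mirna_ids
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
    draw <- function(lab) {
      v <- matrix(stats::rnorm(length(lab) * n_samples, sd = 1),
                  length(lab), n_samples)
      member <- lab > 0L
      if (any(member))
        v[member, ] <- loading * Z[lab[member], , drop = FALSE] +
          matrix(stats::rnorm(sum(member) * n_samples, sd = noise_sd),
                 sum(member), n_samples)
      v
    }
    vg <- draw(glab)
    vm <- draw(mlab)
    prob <- outer(glab, mlab, function(a, b)
      ifelse(a > 0L & a == b, known_within_rate, known_background_rate))
    hit <- which(matrix(stats::runif(ng * nm), ng, nm) < prob, arr.ind = TRUE)
  })
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  known <- data.frame(gene = gene_ids[hit[, 1L]], mirna = mirna_ids[hit[, 2L]],
                      stringsAsFactors = FALSE)
  known <- known[order(known$gene, known$mirna), , drop = FALSE]
  rownames(known) <- NULL
  clusters <- split(mirna_ids[mlab > 0L], mlab[mlab > 0L])
  names(clusters) <- sprintf("cluster_%02d", as.integer(names(clusters)))
  structure(list(
    expr_g = expr_mat(vg, gene_ids, sample_ids),
    expr_m = expr_mat(vm, mirna_ids, sample_ids),
    known_pairs = known,
    true_gene_labels = glab,
    true_mirna_labels = mlab,
    clusters = clusters,
    params = list(n_modules = n_modules, genes_per_module = genes_per_module,
                  mirnas_per_module = mirnas_per_module,
                  n_background_genes = n_background_genes,
                  n_background_mirnas = n_background_mirnas,
                  n_samples = n_samples, loading = loading,
                  noise_sd = noise_sd,
                  known_within_rate = known_within_rate,
                  known_background_rate = known_background_rate,
                  seed = seed)),
    class = "planted_dataset")
}

#' @export
print.planted_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<planted_dataset> %d modules (%dg + %dm each), ",
                     "%d+%d background, %d samples, %d known pairs (seed %d)\n"),
              p$n_modules, p$genes_per_module, p$mirnas_per_module,
              p$n_background_genes, p$n_background_mirnas, p$n_samples,
              nrow(x$known_pairs), p$seed))
  invisible(x)
}

#' Simulate graphs with known degree behaviour
#'
#' Reproducible test graphs for the scale-free fit: a preferential
#' attachment graph (heavy-tailed degrees, good power-law fit) or a uniform
#' random graph (Poisson-like degrees, poor power-law fit).
#'
#' @param kind `"preferential_attachment"` or `"uniform_random"`.
#' @param n number of nodes (>= 10).
#' @param param edges added per step (preferential attachment, default 2)
#'   or mean degree (uniform random, default 10).
#' @param seed RNG seed.
#' @return An [adjacency].
#' @export
generate_degree_test_graphs <- function(kind = c("preferential_attachment",
                                                 "uniform_random"),
                                        n, param = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (n < 10L) stopf("`n` must be >= 10")
  g <- with_seed(seed, {
    if (kind == "preferential_attachment")
      igraph::sample_pa(n, m = param %||% 2L, directed = FALSE)
    else
      igraph::sample_gnp(n, p = (param %||% 10) / (n - 1))
  })
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  A <- pmin(A, 1); diag(A) <- 0
  adjacency(A, sprintf("n%04d", seq_len(n)))
}

#' Planted-module recovery metrics
#'
#' `recovery_ari()` scores a clustering against the planted labels with the
#' Adjusted Rand Index, restricted by default to planted module members
#' (true label > 0): background features are not part of the planted
#' partition - the co-module validity filter, not k-means, is what rejects
#' them. `planted_modules_recovered()` counts how many planted modules are
#' matched by a valid detected module under bidirectional majority overlap.
#'
#' @param labels named integer clustering labels (e.g. from
#'   [detect_comodules()]'s assignment).
#' @param truth named integer planted labels (0 = background).
#' @param include_background score background nodes too (default FALSE).
#' @return `recovery_ari()`: the ARI over the scored nodes.
#' @export
recovery_ari <- function(labels, truth, include_background = FALSE) {
  if (!requireNamespace("mclust", quietly = TRUE))
    stopf("recovery_ari() needs the 'mclust' package")
  common <- intersect(names(labels), names(truth))
  if (!length(common)) stopf("no shared node ids between labels and truth")
  t0 <- truth[common]
  if (!include_background) common <- common[t0 > 0L]
  if (length(common) < 2L) stopf("fewer than 2 nodes to score")
  mclust::adjustedRandIndex(labels[common], truth[common])
}

#' @rdname recovery_ari
#' @param modules list of `gm_module` objects (only valid ones count).
#' @param ds a `planted_dataset`.
#' @param min_frac majority fraction for a match (default 0.5, strict).
#' @return `planted_modules_recovered()`: integer count of planted modules
#'   matched.
#' @export
planted_modules_recovered <- function(modules, ds, min_frac = 0.5) {
  modules <- valid_modules(modules)
  truth <- c(ds$true_gene_labels, ds$true_mirna_labels)
  recovered <- 0L
  for (k in seq_len(ds$params$n_modules)) {
    planted <- names(truth)[truth == k]
    hit <- any(vapply(modules, function(m) {
      nodes <- c(m$genes, m$mirnas)
      inter <- length(intersect(nodes, planted))
      inter > min_frac * length(planted) && inter > min_frac * length(nodes)
    }, logical(1)))
    if (hit) recovered <- recovered + 1L
  }
  recovered
}
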