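#' Integrated gene-miRNA network
#'
#' Bundles the gene coexpression network, the miRNA coexpression network,
#' the gene-miRNA cross network and the coupling weight lambda. The global
#' node ordering is genes first (in `adj_g` order) then miRNAs; every
#' stacked matrix in the package follows it.
#'
#' @param adj_g,adj_m [adjacency] objects for genes and miRNAs.
#' @param cross a [cross_adjacency]; its id lists must match the two
#'   adjacencies.
#' @param lambda coupling weight (>= 0) balancing within-network modularity
#'   against cross-network connectivity; the method's default is 1.
#' @return An object of class `integrated_network`.
#' @export
integrated_network <- function(adj_g, adj_m, cross, lambda = 1) {
  stopifnot(inherits(adj_g, "adjacency"), inherits(adj_m, "adjacency"),
            inherits(cross, "cross_adjacency"))
  if (!identical(adj_g$node_ids, cross$gene_ids))
    stopf("gene ids of the cross network do not match the gene adjacency")
  if (!identical(adj_m$node_ids, cross$mirna_ids))
    stopf("miRNA ids of the cross network do not match the miRNA adjacency")
  if (length(intersect(adj_g$node_ids, adj_m$node_ids)))
    stopf("gene and miRNA identifiers overlap")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stopf("`lambda` must be a single value >= 0")
  structure(list(adj_g = adj_g, adj_m = adj_m, cross = cross,
                 lambda = lambda),
            class = "integrated_network")
}

#' @export
print.integrated_network <- function(x, ...) {
  cat(sprintf(
    "<integrated_network> %d genes (%d edges), %d miRNAs (%d edges), %d cross edges, lambda=%g\n",
    length(x$adj_g$node_ids), sum(x$adj_g$A) / 2,
    length(x$adj_m$node_ids), sum(x$adj_m$A) / 2,
    sum(x$cross$C), x$lambda))
  invisible(x)
}

n_nodes <- function(net) length(net$adj_g$node_ids) + length(net$adj_m$node_ids)

node_ids <- function(net) c(net$adj_g$node_ids, net$adj_m$node_ids)

# union graph over both node types (within edges plus cross edges)
union_graph <- function(net) {
  ng <- length(net$adj_g$node_ids); nm <- length(net$adj_m$node_ids)
  U <- matrix(0, ng + nm, ng + nm)
  U[seq_len(ng), seq_len(ng)] <- net$adj_g$A
  U[ng + seq_len(nm), ng + seq_len(nm)] <- net$adj_m$A
  U[seq_len(ng), ng + seq_len(nm)] <- net$cross$C
  U[ng + seq_len(nm), seq_len(ng)] <- t(net$cross$C)
  dimnames(U) <- list(node_ids(net), node_ids(net))
  U
}

#' Assemble the integrated modularity matrix L
#'
#' Builds `L_g = 2*A_g - D_g`, `L_m = 2*A_m - D_m`, the block diagonal
#' `L_w = diag(L_g, L_m)`, the off-diagonal coupling
#' `L_b = rbind(cbind(0, C), cbind(t(C), 0))` and returns
#' `L = L_w + lambda * L_b`. Maximizing `Tr(S~' L S~)` over orthonormal
#' relaxed indicators is the spectral surrogate of the combined modularity
#' objective (see [discrete_objective()]).
#'
#' @param net an [integrated_network].
#' @param check_connected refuse a disconnected union graph (default TRUE).
#'   Spectral embedding of a disconnected graph is well defined, but module
#'   labels across components are arbitrary; run components separately (or
#'   see [detect_comodules()], which takes the largest component).
#' @return Symmetric numeric matrix with node ids as dimnames.
#' @export
build_integrated_matrix <- function(net, check_connected = TRUE) {
  ng <- length(net$adj_g$node_ids); nm <- length(net$adj_m$node_ids)
  if (check_connected) {
    g <- igraph::graph_from_adjacency_matrix(union_graph(net), mode = "undirected")
    if (!igraph::is_connected(g))
      stopf(paste0("the integrated network is disconnected (%d components); ",
                   "divide it into connected parts and run each separately"),
            igraph::count_components(g))
  }
  Lg <- 2 * net$adj_g$A - diag(rowSums(net$adj_g$A), ng)
  Lm <- 2 * net$adj_m$A - diag(rowSums(net$adj_m$A), nm)
  L <- matrix(0, ng + nm, ng + nm)
  L[seq_len(ng), seq_len(ng)] <- Lg
  L[ng + seq_len(nm), ng + seq_len(nm)] <- Lm
  L[seq_len(ng), ng + seq_len(nm)] <- net$lambda * net$cross$C
  L[ng + seq_len(nm), seq_len(ng)] <- net$lambda * t(net$cross$C)
  dimnames(L) <- list(node_ids(net), node_ids(net))
  L
}

#' Top-K spectral embedding of the integrated matrix
#'
#' Columns of the returned matrix `T` are orthonormal eigenvectors of the K
#' largest (algebraic) eigenvalues of `L`; over all orthonormal K-frames
#' this maximizes `Tr(T' L T)` (Ky Fan). Eigenvector signs are canonicalized
#' so the largest-magnitude entry of each column is positive.
#'
#' @param L symmetric matrix from [build_integrated_matrix()].
#' @param K number of modules (1..nrow(L)).
#' @return An object of class `spectral_embedding`: list with `T` (nodes x
#'   K, node ids as rownames) and `eigenvalues` (non-increasing).
#' @export
spectral_embedding <- function(L, K) {
  n <- nrow(L)
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K > n)
    stopf("`K` must lie in 1..%d", n)
  K <- as.integer(K)
  eig <- eigen(L, symmetric = TRUE)
  V <- eig$vectors[, seq_len(K), drop = FALSE]
  V <- canonicalize_signs(V)
  rownames(V) <- rownames(L)
  structure(list(T = V, eigenvalues = eig$values[seq_len(K)]),
            class = "spectral_embedding")
}

canonicalize_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# k-means++ style seeding: first center uniform, then points sampled with
# probability proportional to squared distance from the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, x[idx[1L], ], "-")^2)
    for (j in 2:k) {
      if (sum(d2) <= 0)
        stopf("fewer than %d distinct embedding rows; cannot seed k-means", k)
      idx[j] <- sample.int(n, 1L, prob = d2)
      d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[j], ], "-")^2))
    }
  }
  x[idx, , drop = FALSE]
}

#' Cluster the spectral embedding with restarted k-means
#'
#' Nodes are clustered by k-means on the rows of the embedding (by default
#' row-normalized to unit length, so clustering acts on embedding
#' directions). Seeding is k-means++ style with `nstart` independent
#' restarts; the restart with the lowest within-cluster sum of squares
#' wins. Fully deterministic given `seed`.
#'
#' @param emb a [spectral_embedding].
#' @param K number of clusters; defaults to the embedding width.
#' @param seed integer seed driving all restarts.
#' @param normalize_rows cluster unit-normalized rows (default TRUE);
#'   all-zero rows are left at zero and end up in a common cluster.
#' @param nstart number of k-means++ restarts (default 50).
#' @param iter_max Lloyd iteration cap per restart (default 100).
#' @return An object of class `module_assignment`: list with `labels`
#'   (named integer vector, values 1..K), `K`, `seed`, and `tot_withinss`.
#' @export
cluster_embedding <- function(emb, K = ncol(emb$T), seed = 1L,
                              normalize_rows = TRUE, nstart = 50L,
                              iter_max = 100L) {
  x <- emb$T
  if (nrow(x) < K)
    stopf("embedding has %d rows but K = %d", nrow(x), K)
  if (normalize_rows) x <- row_unit_normalize(x)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(nstart)) {
      centers <- kmeanspp_centers(x, K)
      fit <- suppressWarnings(
        stats::kmeans(x, centers = centers, iter.max = iter_max,
                      algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  labels <- as.integer(best$cluster)
  names(labels) <- rownames(emb$T)
  structure(list(labels = labels, K = as.integer(K), seed = as.integer(seed),
                 tot_withinss = best$tot.withinss),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment> %d nodes in %d clusters (seed %d)\n",
              length(x$labels), x$K, x$seed))
  invisible(x)
}

#' Binary indicator matrix of an assignment
#'
#' @param labels integer cluster labels (1..K).
#' @param K number of clusters.
#' @return Binary matrix (length(labels) x K), each row summing to one.
#' @export
assignment_matrix <- function(labels, K) {
  S <- matrix(0, length(labels), K)
  S[cbind(seq_along(labels), labels)] <- 1
  rownames(S) <- names(labels)
  S
}

#' Combined modularity objective of a discrete assignment
#'
#' Evaluates
#' `Psi = Psi_g + Psi_m + lambda * sum_k s_g(.,k)' C s_m(.,k) / (||s_g(.,k)|| ||s_m(.,k)||)`,
#' where the per-type terms are Rayleigh quotients of `2A - D` over the
#' module indicator columns. A module empty on either side contributes 0 to
#' the cross term (the limit of the normalized term); a fully empty module
#' contributes 0 throughout.
#'
#' @param assign a module assignment from [cluster_embedding()] over the network's nodes (genes
#'   first, then miRNAs).
#' @param net an [integrated_network].
#' @return The scalar objective value.
#' @export
discrete_objective <- function(assign, net) {
  ng <- length(net$adj_g$node_ids); nm <- length(net$adj_m$node_ids)
  if (length(assign$labels) != ng + nm)
    stopf("assignment covers %d nodes but the network has %d",
          length(assign$labels), ng + nm)
  lg <- assign$labels[seq_len(ng)]
  lm <- assign$labels[ng + seq_len(nm)]
  Mg <- 2 * net$adj_g$A - diag(rowSums(net$adj_g$A), ng)
  Mm <- 2 * net$adj_m$A - diag(rowSums(net$adj_m$A), nm)
  total <- 0
  for (k in seq_len(assign$K)) {
    ig <- which(lg == k); im <- which(lm == k)
    if (length(ig))
      total <- total + sum(Mg[ig, ig]) / length(ig)
    if (length(im))
      total <- total + sum(Mm[im, im]) / length(im)
    if (length(ig) && length(im))
      total <- total + net$lambda * sum(net$cross$C[ig, im, drop = FALSE]) /
        (sqrt(length(ig)) * sqrt(length(im)))
  }
  total
}

#' Co-module scores from a spectral embedding
#'
#' Rows of the embedding are scaled to unit norm (`T~`) and the score matrix
#' `S = T~ T~'` returned; entry (i, j) measures how likely nodes i and j are
#' to fall in the same module (1 = identical embedding directions,
#' 0 = orthogonal). All-zero rows yield zero score rows and are logged.
#'
#' @param emb a [spectral_embedding].
#' @return Symmetric score matrix with unit diagonal (zero for zero rows),
#'   entries in `[-1, 1]`.
#' @export
comodule_scores <- function(emb) {
  Tn <- row_unit_normalize(emb$T)
  zero <- rowSums(abs(Tn)) == 0
  if (any(zero))
    co_log("%d node(s) with all-zero embedding rows; their scores are 0",
           sum(zero))
  S <- Tn %*% t(Tn)
  dimnames(S) <- list(rownames(emb$T), rownames(emb$T))
  S
}

# gene x miRNA block of the co-module score matrix, without forming the full S
cross_comodule_scores <- function(emb, n_genes) {
  Tn <- row_unit_normalize(emb$T)
  G <- Tn[seq_len(n_genes), , drop = FALSE]
  M <- Tn[n_genes + seq_len(nrow(Tn) - n_genes), , drop = FALSE]
  S <- G %*% t(M)
  dimnames(S) <- list(rownames(emb$T)[seq_len(n_genes)],
                      rownames(emb$T)[-seq_len(n_genes)])
  S
}

#' Filter clusters down to valid gene-miRNA co-modules
#'
#' A cluster is a valid co-module when it contains at least one gene and one
#' miRNA and all three connection types appear among its members: a
#' gene-gene edge, a miRNA-miRNA edge, and a gene-miRNA edge, each induced
#' within the cluster. Every cluster is returned as a module; failing ones
#' carry `valid = FALSE` (see [valid_modules()]).
#'
#' @param assign a module assignment from [cluster_embedding()].
#' @param net the [integrated_network] it was computed on.
#' @param source_K the module-number run this assignment came from (for
#'   provenance; defaults to `assign$K`).
#' @return A list of `gm_module` objects (genes, mirnas, source_runs,
#'   edge_counts, valid).
#' @export
filter_candidate_modules <- function(assign, net, source_K = assign$K) {
  ng <- length(net$adj_g$node_ids)
  lg <- assign$labels[seq_len(ng)]
  lm <- assign$labels[-seq_len(ng)]
  out <- vector("list", assign$K)
  for (k in seq_len(assign$K)) {
    genes <- net$adj_g$node_ids[lg == k]
    mirnas <- net$adj_m$node_ids[lm == k]
    ig <- which(lg == k); im <- which(lm == k)
    e_gg <- sum(net$adj_g$A[ig, ig]) / 2
    e_mm <- sum(net$adj_m$A[im, im]) / 2
    e_gm <- sum(net$cross$C[ig, im, drop = FALSE])
    valid <- length(genes) >= 1L && length(mirnas) >= 1L &&
      e_gg >= 1 && e_mm >= 1 && e_gm >= 1
    out[[k]] <- structure(
      list(genes = genes, mirnas = mirnas,
           source_runs = list(list(K = source_K, cluster = k)),
           edge_counts = c(gene_gene = e_gg, mirna_mirna = e_mm,
                           gene_mirna = e_gm),
           valid = valid),
      class = "gm_module")
  }
  out
}

#' @export
print.gm_module <- function(x, ...) {
  cat(sprintf("<gm_module> %d genes + %d miRNAs (%s)\n",
              length(x$genes), length(x$mirnas),
              if (isTRUE(x$valid)) "valid" else "invalid"))
  invisible(x)
}

#' Keep only valid co-modules
#'
#' @param modules list of `gm_module` objects.
#' @return The sub-list with `valid = TRUE`.
#' @export
valid_modules <- function(modules) {
  Filter(function(m) isTRUE(m$valid), modules)
}

module_nodes <- function(m) c(m$genes, m$mirnas)

module_overlap <- function(a, b, method = "min") {
  na <- module_nodes(a); nb <- module_nodes(b)
  inter <- length(intersect(na, nb))
  if (inter == 0L) return(0)
  switch(method,
         min = inter / min(length(na), length(nb)),
         jaccard = inter / length(union(na, nb)),
         stopf("unknown overlap method '%s'", method))
}

#' Merge near-duplicate modules across module-number runs
#'
#' Modules produced at different K often re-find the same subnetwork. Any
#' two modules whose overlap percentage is strictly greater than
#' `overlap_frac` are replaced by their union (gene sets and miRNA sets
#' merged separately, provenance concatenated), iterating to a fixed point.
#' The overlap percentage is the intersection size over the smaller module
#' (`method = "min"`, the default, which also de-duplicates nested
#' modules); `method = "jaccard"` divides by the union instead. Output is
#' ordered by each module's smallest node id; merged modules have their
#' edge counts dropped (recompute with [count_module_edges()]).
#'
#' @param runs a list of module lists (one per K run), or a flat list of
#'   modules.
#' @param overlap_frac merge threshold in `(0, 1]`; the method's default is
#'   0.9 ("larger than 90 percent" overlap merges).
#' @param method overlap denominator, `"min"` or `"jaccard"`.
#' @return A flat list of merged `gm_module` objects.
#' @export
merge_module_runs <- function(runs, overlap_frac = 0.9, method = "min") {
  if (!is.numeric(overlap_frac) || overlap_frac <= 0 || overlap_frac > 1)
    stopf("`overlap_frac` must lie in (0, 1]")
  mods <- if (length(runs) && inherits(runs[[1L]], "gm_module")) runs
          else do.call(c, runs)
  mods <- Filter(function(m) length(m$genes) + length(m$mirnas) > 0L, mods)
  repeat {
    n <- length(mods)
    if (n < 2L) break
    merged <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (module_overlap(mods[[i]], mods[[j]], method) > overlap_frac) {
          u <- structure(
            list(genes = sort(union(mods[[i]]$genes, mods[[j]]$genes)),
                 mirnas = sort(union(mods[[i]]$mirnas, mods[[j]]$mirnas)),
                 source_runs = c(mods[[i]]$source_runs, mods[[j]]$source_runs),
                 edge_counts = NULL,
                 valid = isTRUE(mods[[i]]$valid) && isTRUE(mods[[j]]$valid)),
            class = "gm_module")
          mods[[i]] <- u
          mods[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  first_id <- vapply(mods, function(m) min(module_nodes(m)), character(1))
  mods[order(first_id)]
}

#' Recount a module's internal edges
#'
#' @param module a `gm_module`.
#' @param net an [integrated_network] containing its nodes.
#' @return The module with `edge_counts` filled in.
#' @export
count_module_edges <- function(module, net) {
  ig <- match(module$genes, net$adj_g$node_ids)
  im <- match(module$mirnas, net$adj_m$node_ids)
  if (anyNA(ig) || anyNA(im))
    stopf("module contains nodes absent from the network")
  module$edge_counts <- c(
    gene_gene = sum(net$adj_g$A[ig, ig]) / 2,
    mirna_mirna = sum(net$adj_m$A[im, im]) / 2,
    gene_mirna = sum(net$cross$C[ig, im, drop = FALSE]))
  module
}

# subset helpers used when working on one connected component
subset_adjacency <- function(adj, ids) {
  idx <- match(ids, adj$node_ids)
  adjacency(adj$A[idx, idx, drop = FALSE], ids)
}

subset_cross <- function(cross, gene_ids, mirna_ids) {
  gi <- match(gene_ids, cross$gene_ids)
  mi <- match(mirna_ids, cross$mirna_ids)
  cross_adjacency(cross$C[gi, mi, drop = FALSE], gene_ids, mirna_ids,
                  cross$provenance[gi, mi, drop = FALSE])
}

#' Detect gene-miRNA co-modules at a given module number
#'
#' Runs the full detection step on an integrated network: restricts to the
#' largest connected component (or errors, per `on_disconnected`), builds
#' the integrated matrix, embeds with the top-K eigenvectors, clusters with
#' restarted k-means, and filters clusters to valid co-modules.
#'
#' @param net an [integrated_network].
#' @param K number of modules to ask for.
#' @param seed k-means seed.
#' @param on_disconnected `"largest"` (default) analyses the largest
#'   connected component; `"error"` refuses disconnected input.
#' @param normalize_rows,nstart passed to [cluster_embedding()].
#' @return List with `assignment` (a [cluster_embedding()] result over the
#'   analysed nodes), `modules` (all clusters, validity-flagged),
#'   `embedding`, `nodes` (list of gene/miRNA ids analysed), and
#'   `component_sizes`.
#' @export
detect_comodules <- function(net, K, seed = 1L,
                             on_disconnected = c("largest", "error"),
                             normalize_rows = TRUE, nstart = 50L) {
  on_disconnected <- match.arg(on_disconnected)
  g <- igraph::graph_from_adjacency_matrix(union_graph(net), mode = "undirected")
  comp <- igraph::components(g)
  sizes <- sort(comp$csize, decreasing = TRUE)
  sub <- net
  if (comp$no > 1L) {
    if (on_disconnected == "error")
      stopf(paste0("the integrated network is disconnected (%d components); ",
                   "divide it into connected parts and run each separately"),
            comp$no)
    keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
    co_log("disconnected network: analysing the largest component (%d of %d nodes)",
           max(comp$csize), n_nodes(net))
    gk <- intersect(net$adj_g$node_ids, keep)
    mk <- intersect(net$adj_m$node_ids, keep)
    if (!length(gk) || !length(mk))
      stopf("the largest component contains only one node type")
    sub <- integrated_network(subset_adjacency(net$adj_g, gk),
                              subset_adjacency(net$adj_m, mk),
                              subset_cross(net$cross, gk, mk), net$lambda)
  }
  L <- build_integrated_matrix(sub, check_connected = FALSE)
  emb <- spectral_embedding(L, K)
  assign <- cluster_embedding(emb, K = K, seed = seed,
                              normalize_rows = normalize_rows, nstart = nstart)
  modules <- filter_candidate_modules(assign, sub, source_K = K)
  list(assignment = assign, modules = modules, embedding = emb,
       nodes = list(genes = sub$adj_g$node_ids, mirnas = sub$adj_m$node_ids),
       component_sizes = sizes)
}
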