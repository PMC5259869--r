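# Shared fixtures and independent oracles. Every oracle here is computed by a
# route disjoint from the implementation it checks (normal equations instead
# of lm-based fits, pair counting instead of rank algebra, enumeration instead
# of distribution functions).

options(comodule.verbose = FALSE)

# --- tiny deterministic builders -------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_expr <- function(values, features = NULL, samples = NULL) {
  if (is.null(dim(values))) {
    nr <- if (!is.null(features)) length(features) else 1L
    values <- matrix(as.numeric(values), nrow = nr)
  }
  features <- features %||% sprintf("f%d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(values)))
  comodule::expr_mat(values, features, samples)
}

rand_sym_binary <- function(n, p = 0.5) {
  A <- matrix(stats::rbinom(n * n, 1, p), n, n)
  A <- ((A + t(A)) > 0) * 1
  diag(A) <- 0
  A
}

# random integrated network on small node counts
rand_integrated_net <- function(ng, nm, lambda, p = 0.5) {
  gid <- paste0("g", seq_len(ng)); mid <- paste0("m", seq_len(nm))
  integrated_network(
    adjacency(rand_sym_binary(ng, p), gid),
    adjacency(rand_sym_binary(nm, p), mid),
    cross_adjacency(matrix(stats::rbinom(ng * nm, 1, p), ng, nm,
                           dimnames = list(gid, mid))),
    lambda)
}

# 2 genes with one edge + 1 isolated miRNA, C = (1,1)', the worked example
# whose integrated matrix is known in closed form
toy_triplet_net <- function(lambda = 1) {
  integrated_network(
    adjacency(matrix(c(0, 1, 1, 0), 2, 2,
                     dimnames = list(c("g1", "g2"), c("g1", "g2")))),
    adjacency(matrix(0, 1, 1, dimnames = list("m1", "m1"))),
    cross_adjacency(matrix(1, 2, 1, dimnames = list(c("g1", "g2"), "m1"))),
    lambda)
}

manual_assignment <- function(labels, K) {
  structure(list(labels = labels, K = as.integer(K), seed = NA_integer_),
            class = "module_assignment")
}

# small planted preset: cheap enough for unit tests, still well separated
small_planted <- function(seed = 7) {
  generate_planted_dataset(n_modules = 3L, genes_per_module = 10L,
                           mirnas_per_module = 3L, n_background_genes = 8L,
                           n_background_mirnas = 4L, n_samples = 80L,
                           loading = 0.9, noise_sd = 0.3,
                           known_within_rate = 0.3,
                           known_background_rate = 0.005, seed = seed)
}

planted_network <- function(ds, tau = 0.6, lambda = 1, with_known = TRUE) {
  adj_g <- threshold_adjacency(correlation_matrix(ds$expr_g), tau)
  adj_m <- threshold_adjacency(correlation_matrix(ds$expr_m), tau)
  C <- threshold_adjacency(correlation_matrix(ds$expr_g, ds$expr_m), tau)
  if (with_known) C <- combine_cross_network(C, ds$known_pairs)
  integrated_network(adj_g, adj_m, C, lambda)
}

# --- independent oracles ----------------------------------------------------

# OLS through the closed-form normal equations (no lm)
ols_oracle <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  yhat <- yb + slope * (x - xb)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - yb)^2)
  list(slope = slope, r_squared = r2)
}

# Mann-Whitney by explicit pair counting, ties counting one half
concordant_auc_oracle <- function(scores, is_known) {
  pos <- scores[as.logical(is_known)]
  neg <- scores[!as.logical(is_known)]
  tot <- 0
  for (s in pos) tot <- tot + sum(s > neg) + 0.5 * sum(s == neg)
  tot / (length(pos) * length(neg))
}

# hypergeometric upper tail by exact enumeration over the counting formula
hyper_tail_oracle <- function(background, successes, draws, observed) {
  ks <- observed:min(successes, draws)
  sum(choose(successes, ks) * choose(background - successes, draws - ks)) /
    choose(background, draws)
}

# random orthonormal K-frame via QR
rand_orthonormal <- function(n, k) {
  qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
}

# Maximum of the discrete combined-modularity objective over every
# assignment in which each of the K modules holds at least one gene and one
# miRNA (exactly the assignments whose normalized indicators lie in the
# relaxed feasible set). Vectorized over labelings.
max_discrete_objective <- function(net, K) {
  ng <- length(net$adj_g$node_ids); nm <- length(net$adj_m$node_ids)
  Mg <- 2 * net$adj_g$A - diag(rowSums(net$adj_g$A), ng)
  Mm <- 2 * net$adj_m$A - diag(rowSums(net$adj_m$A), nm)
  surjective <- function(n) {
    lab <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
    lab[apply(lab, 1L, function(r) length(unique(r)) == K), , drop = FALSE]
  }
  gl <- surjective(ng); ml <- surjective(nm)
  if (!nrow(gl) || !nrow(ml)) return(-Inf)
  psi_g <- matrix(0, nrow(gl), K)
  P <- lapply(seq_len(K), function(k) matrix(0, nrow(gl), nm))
  for (i in seq_len(nrow(gl))) for (k in seq_len(K)) {
    idx <- which(gl[i, ] == k)
    psi_g[i, k] <- sum(Mg[idx, idx]) / length(idx)
    P[[k]][i, ] <- colSums(net$cross$C[idx, , drop = FALSE]) / sqrt(length(idx))
  }
  psi_m <- matrix(0, nrow(ml), K)
  Q <- lapply(seq_len(K), function(k) matrix(0, nrow(ml), nm))
  for (j in seq_len(nrow(ml))) for (k in seq_len(K)) {
    idx <- which(ml[j, ] == k)
    psi_m[j, k] <- sum(Mm[idx, idx]) / length(idx)
    Q[[k]][j, idx] <- 1 / sqrt(length(idx))
  }
  cross <- Reduce(`+`, lapply(seq_len(K), function(k) P[[k]] %*% t(Q[[k]])))
  total <- outer(rowSums(psi_g), rowSums(psi_m), `+`) + net$lambda * cross
  max(total)
}

make_module <- function(genes, mirnas = character(), valid = TRUE) {
  structure(list(genes = genes, mirnas = mirnas,
                 source_runs = list(list(K = NA, cluster = NA)),
                 edge_counts = NULL, valid = valid),
            class = "gm_module")
}
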