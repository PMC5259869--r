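#' Rank-based AUC of known interactions
#'
#' Given a score for every candidate gene-miRNA pair and a flag marking the
#' known interacting pairs, computes
#' `AUC = (sum_i R_i - q(q+1)/2) / (p*q)`, where `R_i` is the rank of the
#' i-th known pair (rank 1 = smallest score, ties receiving average ranks),
#' `q` the number of known pairs and `p` the number of non-known pairs.
#' With average ranks this is exactly the Mann-Whitney statistic: the
#' fraction of (known, non-known) pairs in which the known pair scores
#' higher, ties counting one half.
#'
#' @param scores numeric vector of pair scores.
#' @param is_known logical (or 0/1) vector of the same length.
#' @return An object of class `auc_result`: list with `auc`, `q`, `p`.
#' @export
auc_rank <- function(scores, is_known) {
  if (length(scores) != length(is_known))
    stopf("`scores` and `is_known` lengths differ")
  is_known <- as.logical(is_known)
  if (anyNA(scores) || anyNA(is_known)) stopf("missing scores or labels")
  q <- sum(is_known); p <- sum(!is_known)
  if (q == 0L || p == 0L)
    stopf("AUC undefined: need at least one known and one non-known pair")
  r <- rank(scores)                       # average ranks for ties
  auc <- (sum(r[is_known]) - q * (q + 1) / 2) / (p * q)
  structure(list(auc = auc, q = q, p = p), class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> AUC = %.4f (q = %d known, p = %d non-known)\n",
              x$auc, x$q, x$p))
  if (!is.null(x$K_values))
    cat(sprintf("  mean over K in {%s}; per-K AUC: %s\n",
                paste(x$K_values, collapse = ", "),
                paste(sprintf("%.3f", x$per_K_auc), collapse = ", ")))
  invisible(x)
}

# logical gene x miRNA matrix marking the known pairs resolvable in the network
known_pair_matrix <- function(gene_ids, mirna_ids, known_pairs) {
  M <- matrix(FALSE, length(gene_ids), length(mirna_ids),
              dimnames = list(gene_ids, mirna_ids))
  if (is.null(known_pairs) || nrow(known_pairs) == 0L) return(M)
  gi <- match(as.character(known_pairs[[1L]]), gene_ids)
  mi <- match(as.character(known_pairs[[2L]]), mirna_ids)
  ok <- !is.na(gi) & !is.na(mi)
  if (any(!ok))
    co_log("%d known pair(s) not resolvable against the network ids", sum(!ok))
  M[cbind(gi[ok], mi[ok])] <- TRUE
  M
}

#' Mean rank-AUC over a grid of module numbers
#'
#' For each K the integrated matrix is embedded with the top-K
#' eigenvectors, rows are unit-normalized, the gene-miRNA block of the
#' co-module score matrix is extracted, and [auc_rank()] is computed over
#' all gene-miRNA pairs against the known interactions. Connectivity is not
#' enforced here: the score of two nodes in different components is simply
#' zero. The computation is deterministic (no clustering step is involved).
#'
#' @param net an [integrated_network].
#' @param known_pairs data frame of known (gene, miRNA) pairs.
#' @param K_grid module numbers to average over.
#' @return An `auc_result` whose `auc` is the mean over the grid, with
#'   `K_values` and `per_K_auc` filled in.
#' @export
mean_auc_over_K <- function(net, known_pairs, K_grid) {
  if (!length(K_grid)) stopf("empty K grid")
  K_grid <- as.integer(K_grid)
  if (any(K_grid < 1L | K_grid > n_nodes(net)))
    stopf("K grid must lie in 1..%d", n_nodes(net))
  ng <- length(net$adj_g$node_ids)
  known <- known_pair_matrix(net$adj_g$node_ids, net$adj_m$node_ids, known_pairs)
  L <- build_integrated_matrix(net, check_connected = FALSE)
  eig <- eigen(L, symmetric = TRUE)
  per_K <- vapply(K_grid, function(K) {
    V <- canonicalize_signs(eig$vectors[, seq_len(K), drop = FALSE])
    rownames(V) <- rownames(L)
    emb <- structure(list(T = V, eigenvalues = eig$values[seq_len(K)]),
                     class = "spectral_embedding")
    S <- cross_comodule_scores(emb, ng)
    auc_rank(as.vector(S), as.vector(known))$auc
  }, numeric(1))
  structure(list(auc = mean(per_K), q = sum(known),
                 p = length(known) - sum(known),
                 K_values = K_grid, per_K_auc = per_K),
            class = "auc_result")
}

#' Select the gene-miRNA coexpression threshold by rank-AUC
#'
#' For each candidate threshold the gene-miRNA coexpression network is
#' built by hard thresholding (the known interactions being ranked are NOT
#' added to C at this stage), the mean AUC over the K grid computed, and
#' the threshold with the highest mean AUC returned (ties broken toward the
#' smaller threshold).
#'
#' @param expr_g,expr_m sample-aligned [expr_mat] objects (genes, miRNAs).
#' @param known_pairs data frame of known (gene, miRNA) pairs.
#' @param tau_grid candidate thresholds; the method's default grid is 0.1
#'   to 0.9 in steps of 0.1.
#' @param K_grid module numbers to average over; the method's default at
#'   full scale is 100 to 200 in steps of 10.
#' @param lambda coupling weight (default 1).
#' @param adj_g,adj_m within-type networks; built at `tau_within` from the
#'   expression matrices when omitted.
#' @param tau_within threshold for the within-type networks when they are
#'   not supplied (default 0.6).
#' @return List with `tau` (chosen threshold), `auc` (its `auc_result`),
#'   and `table`: long data frame of (tau, K, auc) plus the per-tau mean.
#' @export
select_gm_threshold <- function(expr_g, expr_m, known_pairs,
                                tau_grid = seq(0.1, 0.9, by = 0.1),
                                K_grid = seq(100, 200, by = 10),
                                lambda = 1,
                                adj_g = NULL, adj_m = NULL,
                                tau_within = 0.6) {
  if (!length(tau_grid) || !length(K_grid)) stopf("empty grid")
  if (any(tau_grid < 0 | tau_grid >= 1)) stopf("thresholds must lie in [0, 1)")
  if (is.null(adj_g)) adj_g <- threshold_adjacency(correlation_matrix(expr_g), tau_within)
  if (is.null(adj_m)) adj_m <- threshold_adjacency(correlation_matrix(expr_m), tau_within)
  corr_gm <- correlation_matrix(expr_g, expr_m)
  tau_grid <- sort(tau_grid)
  results <- lapply(tau_grid, function(tau) {
    C <- threshold_adjacency(corr_gm, tau)
    net <- integrated_network(adj_g, adj_m, C, lambda)
    mean_auc_over_K(net, known_pairs, K_grid)
  })
  means <- vapply(results, function(r) r$auc, numeric(1))
  pick <- which.max(means)                 # which.max takes the first tie
  tab <- do.call(rbind, lapply(seq_along(tau_grid), function(i)
    data.frame(tau = tau_grid[i], K = results[[i]]$K_values,
               auc = results[[i]]$per_K_auc, mean_auc = means[i])))
  list(tau = tau_grid[pick], auc = results[[pick]], table = tab)
}

#' Alternate optimization of lambda and the gene-miRNA threshold
#'
#' Coordinate ascent over the two finite grids: holding lambda fixed, pick
#' the threshold with the highest mean AUC; holding that threshold fixed,
#' pick the best lambda; repeat until neither changes or `max_rounds` is
#' reached. Ties always break toward the smaller grid value, and the mean
#' AUC of accepted steps is non-decreasing.
#'
#' @inheritParams select_gm_threshold
#' @param lambda_grid candidate coupling weights.
#' @param max_rounds cap on alternation rounds (default 5).
#' @return List with `tau`, `lambda`, `auc` (final `auc_result`), and
#'   `trace`: data frame of the accepted (round, tau, lambda, mean_auc)
#'   steps.
#' @export
alternate_lambda_threshold <- function(expr_g, expr_m, known_pairs,
                                       tau_grid, lambda_grid,
                                       K_grid, max_rounds = 5L,
                                       adj_g = NULL, adj_m = NULL,
                                       tau_within = 0.6) {
  if (!length(tau_grid) || !length(lambda_grid) || !length(K_grid))
    stopf("empty grid")
  if (max_rounds < 1L) stopf("`max_rounds` must be >= 1")
  if (is.null(adj_g)) adj_g <- threshold_adjacency(correlation_matrix(expr_g), tau_within)
  if (is.null(adj_m)) adj_m <- threshold_adjacency(correlation_matrix(expr_m), tau_within)
  corr_gm <- correlation_matrix(expr_g, expr_m)
  tau_grid <- sort(tau_grid); lambda_grid <- sort(lambda_grid)
  eval_at <- function(tau, lambda) {
    C <- threshold_adjacency(corr_gm, tau)
    mean_auc_over_K(integrated_network(adj_g, adj_m, C, lambda),
                    known_pairs, K_grid)
  }
  lambda <- lambda_grid[1L]
  tau <- tau_grid[1L]
  best <- NULL
  trace <- NULL
  for (round in seq_len(max_rounds)) {
    res_tau <- lapply(tau_grid, eval_at, lambda = lambda)
    m <- vapply(res_tau, `[[`, numeric(1), "auc")
    new_tau <- tau_grid[which.max(m)]
    res_lam <- lapply(lambda_grid, function(l) eval_at(new_tau, l))
    m2 <- vapply(res_lam, `[[`, numeric(1), "auc")
    new_lambda <- lambda_grid[which.max(m2)]
    best <- res_lam[[which.max(m2)]]
    trace <- rbind(trace, data.frame(round = round, tau = new_tau,
                                     lambda = new_lambda, mean_auc = best$auc))
    if (round > 1L && new_tau == tau && new_lambda == lambda) break
    changed <- new_tau != tau || new_lambda != lambda
    tau <- new_tau; lambda <- new_lambda
    if (!changed) break
  }
  list(tau = tau, lambda = lambda, auc = best, trace = trace)
}

#' Plot mean AUC against the candidate threshold
#'
#' Base-graphics line plot of the per-threshold mean AUC table produced by
#' [select_gm_threshold()].
#'
#' @param table the `table` element of a [select_gm_threshold()] result.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the (tau, mean_auc) data frame plotted.
#' @export
plot_auc_grid <- function(table, ...) {
  agg <- unique(table[, c("tau", "mean_auc")])
  graphics::plot(agg$tau, agg$mean_auc, type = "b", pch = 16,
                 xlab = "gene-miRNA coexpression threshold",
                 ylab = "mean AUC over K grid", ...)
  invisible(agg)
}
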