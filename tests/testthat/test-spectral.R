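test_that("integrated matrix assembles L_w + lambda L_b with the known toy form", {
  net <- toy_triplet_net(lambda = 1)
  L <- build_integrated_matrix(net)
  expect_equal(unname(L),
               matrix(c(-1, 2, 1, 2, -1, 1, 1, 1, 0), 3, 3), tolerance = 1e-12)
  expect_identical(rownames(L), c("g1", "g2", "m1"))
  expect_identical(L, t(L))

  # lambda = 0: block diagonal, spectrum = union of the block spectra
  set.seed(4)
  net0 <- rand_integrated_net(5, 4, lambda = 0)
  L0 <- build_integrated_matrix(net0, check_connected = FALSE)
  ev <- eigen(L0, symmetric = TRUE, only.values = TRUE)$values
  evg <- eigen(2 * net0$adj_g$A - diag(rowSums(net0$adj_g$A), 5),
               symmetric = TRUE, only.values = TRUE)$values
  evm <- eigen(2 * net0$adj_m$A - diag(rowSums(net0$adj_m$A), 4),
               symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), sort(c(evg, evm)), tolerance = 1e-10)
})

test_that("disconnected integrated networks are refused with advice", {
  net <- integrated_network(
    adjacency(matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))),
    adjacency(matrix(0, 1, 1, dimnames = list("m1", "m1"))),
    cross_adjacency(matrix(c(1, 0), 2, 1,
                           dimnames = list(c("g1", "g2"), "m1"))),
    1)
  expect_error(build_integrated_matrix(net), "disconnected")
  expect_error(detect_comodules(net, K = 2, on_disconnected = "error"),
               "disconnected")
})

test_that("spectral embedding solves the trace maximization", {
  # complete graph on 3 genes: 2A - D has spectrum {2, -4, -4},
  # top eigenvector (1,1,1)/sqrt(3)
  A <- matrix(1, 3, 3) - diag(3)
  dimnames(A) <- list(paste0("g", 1:3), paste0("g", 1:3))
  L <- 2 * A - diag(rowSums(A))
  emb <- spectral_embedding(L, 1)
  expect_equal(emb$eigenvalues, 2, tolerance = 1e-12)
  expect_equal(unname(emb$T[, 1]), rep(1 / sqrt(3), 3), tolerance = 1e-12)
  expect_equal(sort(eigen(L, symmetric = TRUE)$values), c(-4, -4, 2),
               tolerance = 1e-12)

  set.seed(9)
  net <- rand_integrated_net(6, 4, lambda = 1)
  L <- build_integrated_matrix(net, check_connected = FALSE)
  # full basis: trace identity
  full <- spectral_embedding(L, 10)
  expect_equal(sum(diag(t(full$T) %*% L %*% full$T)), sum(diag(L)),
               tolerance = 1e-10)
  # columns orthonormal, eigenvalues non-increasing
  for (K in c(2, 4)) {
    emb <- spectral_embedding(L, K)
    expect_equal(crossprod(emb$T), diag(K), tolerance = 1e-10)
    expect_true(all(diff(emb$eigenvalues) <= 1e-12))
    # beats 100 random orthonormal frames
    val <- sum(diag(t(emb$T) %*% L %*% emb$T))
    rand_vals <- replicate(100, {
      Q <- rand_orthonormal(10, K)
      sum(diag(t(Q) %*% L %*% Q))
    })
    expect_true(all(val >= rand_vals - 1e-10))
  }
  expect_error(spectral_embedding(L, 11), "K")
  expect_error(spectral_embedding(L, 0), "K")
})

test_that("discrete objective reproduces hand-computed values", {
  net <- toy_triplet_net(lambda = 1)
  all_one <- manual_assignment(setNames(c(1L, 1L, 1L), c("g1", "g2", "m1")), 1)
  expect_equal(discrete_objective(all_one, net), 1 + sqrt(2), tolerance = 1e-12)

  # lambda 0, singleton modules, no edges: objective 0
  net0 <- integrated_network(
    adjacency(matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))),
    adjacency(matrix(0, 1, 1, dimnames = list("m1", "m1"))),
    cross_adjacency(matrix(0, 2, 1, dimnames = list(c("g1", "g2"), "m1"))),
    0)
  singles <- manual_assignment(setNames(c(1L, 2L, 3L), c("g1", "g2", "m1")), 3)
  expect_equal(discrete_objective(singles, net0), 0)

  # complete gene triangle as one module: Psi_g = (2*6 - 6)/3 = 2
  A <- matrix(1, 3, 3) - diag(3)
  dimnames(A) <- list(paste0("g", 1:3), paste0("g", 1:3))
  net3 <- integrated_network(
    adjacency(A),
    adjacency(matrix(0, 1, 1, dimnames = list("m1", "m1"))),
    cross_adjacency(matrix(0, 3, 1, dimnames = list(paste0("g", 1:3), "m1"))),
    1)
  tri <- manual_assignment(setNames(c(1L, 1L, 1L, 2L),
                                    c(paste0("g", 1:3), "m1")), 2)
  expect_equal(discrete_objective(tri, net3), 2)
})

test_that("co-module scores equal their direct formula and are rotation-invariant", {
  set.seed(21)
  V <- matrix(rnorm(30), 10, 3)
  rownames(V) <- paste0("n", 1:10)
  emb <- structure(list(T = V, eigenvalues = c(3, 2, 1)),
                   class = "spectral_embedding")
  S <- comodule_scores(emb)
  # brute-force recomputation row by row
  Vn <- V / sqrt(rowSums(V^2))
  expect_equal(S, Vn %*% t(Vn), ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 10), tolerance = 1e-12)
  expect_true(all(S >= -1 - 1e-12 & S <= 1 + 1e-12))

  # invariant under orthogonal rotation of the columns
  Q <- rand_orthonormal(3, 3)
  embQ <- structure(list(T = V %*% Q, eigenvalues = c(3, 2, 1)),
                    class = "spectral_embedding")
  expect_equal(comodule_scores(embQ), S, tolerance = 1e-10)

  # identical rows score 1, orthogonal rows score 0, zero rows give 0
  W <- rbind(c(1, 0), c(2, 0), c(0, 3), c(0, 0))
  rownames(W) <- paste0("w", 1:4)
  embW <- structure(list(T = W, eigenvalues = c(1, 1)),
                    class = "spectral_embedding")
  SW <- comodule_scores(embW)
  expect_equal(SW["w1", "w2"], 1)
  expect_equal(SW["w1", "w3"], 0)
  expect_equal(unname(SW["w4", ]), rep(0, 4))
})

test_that("k-means on the embedding recovers planted structure deterministically", {
  # two groups of identical embedding rows: exact recovery
  V <- rbind(matrix(rep(c(1, 0), each = 4), 4, 2),
             matrix(rep(c(0, 1), each = 4), 4, 2))
  rownames(V) <- paste0("n", 1:8)
  emb <- structure(list(T = V, eigenvalues = c(2, 1)),
                   class = "spectral_embedding")
  asg <- cluster_embedding(emb, K = 2, seed = 1)
  expect_equal(length(unique(asg$labels[1:4])), 1L)
  expect_equal(length(unique(asg$labels[5:8])), 1L)
  expect_false(asg$labels[1] == asg$labels[5])
  expect_identical(cluster_embedding(emb, K = 1, seed = 1)$labels,
                   setNames(rep(1L, 8), rownames(V)))

  # planted 3-module network: perfect recovery against planted labels
  skip_if_not_installed("mclust")
  ds <- small_planted(seed = 7)
  det <- detect_comodules(planted_network(ds), K = 3, seed = 7)
  expect_equal(recovery_ari(det$assignment$labels, ds$true_gene_labels), 1)
  expect_equal(recovery_ari(det$assignment$labels, ds$true_mirna_labels), 1)

  # determinism given the seed
  det2 <- detect_comodules(planted_network(ds), K = 3, seed = 7)
  expect_identical(det$assignment$labels, det2$assignment$labels)
})

test_that("candidate filter demands both types and all three edge kinds", {
  # g1-g2 edge, m1-m2 edge, g1-m1 cross edge; g3/m3 isolated-ish extras
  gid <- paste0("g", 1:3); mid <- paste0("m", 1:3)
  Ag <- matrix(0, 3, 3, dimnames = list(gid, gid)); Ag["g1", "g2"] <- Ag["g2", "g1"] <- 1
  Am <- matrix(0, 3, 3, dimnames = list(mid, mid)); Am["m1", "m2"] <- Am["m2", "m1"] <- 1
  C <- matrix(0, 3, 3, dimnames = list(gid, mid)); C["g1", "m1"] <- 1; C["g3", "m3"] <- 1
  net <- integrated_network(adjacency(Ag), adjacency(Am), cross_adjacency(C), 1)

  # cluster 1 = {g1,g2,m1,m2}: valid; cluster 2 = {g3,m3}: no within edges
  asg <- manual_assignment(setNames(c(1L, 1L, 2L, 1L, 1L, 2L), c(gid, mid)), 2)
  mods <- filter_candidate_modules(asg, net)
  expect_true(mods[[1]]$valid)
  expect_equal(unname(mods[[1]]$edge_counts), c(1, 1, 1))
  expect_false(mods[[2]]$valid)
  expect_length(valid_modules(mods), 1)

  # gene-only cluster rejected
  asg2 <- manual_assignment(setNames(c(1L, 1L, 1L, 2L, 2L, 2L), c(gid, mid)), 2)
  mods2 <- filter_candidate_modules(asg2, net)
  expect_false(any(vapply(mods2, `[[`, logical(1), "valid")))

  # both types present but no cross edge: rejected
  C0 <- matrix(0, 3, 3, dimnames = list(gid, mid)); C0["g3", "m3"] <- 1
  net0 <- integrated_network(adjacency(Ag), adjacency(Am),
                             cross_adjacency(C0), 1)
  mods3 <- filter_candidate_modules(asg, net0)
  expect_false(mods3[[1]]$valid)
})

test_that("module merging is strict at the boundary, transitive, idempotent", {
  ten <- sprintf("x%02d", 1:10)
  m1 <- make_module(genes = ten)
  m2 <- make_module(genes = c(ten[1:9], "x11"))      # overlap 9/10 = 90%
  kept <- merge_module_runs(list(m1, m2), overlap_frac = 0.9)
  expect_length(kept, 2)                              # not > 90%: kept apart

  m3 <- make_module(genes = ten)                      # identical to m1
  expect_length(merge_module_runs(list(m1, m3), 0.9), 1)

  # chain merging: A~B and B~C above threshold, A~C not
  a <- make_module(genes = sprintf("a%02d", 1:20))
  b <- make_module(genes = c(sprintf("a%02d", 1:19), "b01"))
  c_ <- make_module(genes = c(sprintf("a%02d", 2:20), "c01", "b01"))
  merged <- merge_module_runs(list(a, b, c_), overlap_frac = 0.9)
  expect_length(merged, 1)
  expect_setequal(merged[[1]]$genes,
                  unique(c(a$genes, b$genes, c_$genes)))

  # second pass changes nothing
  again <- merge_module_runs(merged, overlap_frac = 0.9)
  expect_equal(lapply(again, `[`, c("genes", "mirnas")),
               lapply(merged, `[`, c("genes", "mirnas")))

  # nested modules merge under the min denominator
  small <- make_module(genes = ten[1:5])
  expect_length(merge_module_runs(list(m1, small), 0.9, method = "min"), 1)
  expect_length(merge_module_runs(list(m1, small), 0.9, method = "jaccard"), 2)

  expect_error(merge_module_runs(list(m1), overlap_frac = 0), "\\(0, 1\\]")
})

test_that("embeddings, scores and modules are permutation-equivariant", {
  ds <- small_planted(seed = 13)
  net <- planted_network(ds)
  det <- detect_comodules(net, K = 3, seed = 5)

  # permute genes and miRNAs and rebuild
  set.seed(99)
  pg <- sample(net$adj_g$node_ids)
  pm <- sample(net$adj_m$node_ids)
  gi <- match(pg, net$adj_g$node_ids); mi <- match(pm, net$adj_m$node_ids)
  netp <- integrated_network(
    adjacency(net$adj_g$A[gi, gi], pg),
    adjacency(net$adj_m$A[mi, mi], pm),
    cross_adjacency(net$cross$C[gi, mi], pg, pm,
                    net$cross$provenance[gi, mi]),
    net$lambda)
  detp <- detect_comodules(netp, K = 3, seed = 5)

  # same partition of the same nodes (cluster ids may be renamed)
  common <- intersect(names(det$assignment$labels), names(detp$assignment$labels))
  expect_setequal(names(det$assignment$labels), names(detp$assignment$labels))
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(det$assignment$labels[common],
                                         detp$assignment$labels[common]), 1)

  # valid module node sets identical as sets
  sets <- function(d) sort(vapply(valid_modules(d$modules), function(m)
    paste(sort(c(m$genes, m$mirnas)), collapse = ","), character(1)))
  expect_identical(sets(det), sets(detp))
})
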