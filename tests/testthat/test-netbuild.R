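test_that("Pearson correlations match hand calculations and flag constants", {
  x <- toy_expr(c(1, 2, 3), features = "x")
  y <- toy_expr(c(1, 2, 4), features = "y")
  r <- correlation_matrix(x, y)
  expect_equal(r["x", "y"], 9 / sqrt(84), tolerance = 1e-12)

  self <- correlation_matrix(toy_expr(rbind(c(1, 2, 3), c(3, 2, 1)),
                                      features = c("u", "v")))
  expect_equal(self["u", "v"], -1)
  expect_equal(diag(self), c(u = 1, v = 1))

  cst <- expr_mat(rbind(c(1, 1, 1), c(1, 2, 3)),
                  c("flat", "ok"), paste0("s", 1:3))
  expect_message(
    withr::with_options(list(comodule.verbose = TRUE),
                        r2 <- correlation_matrix(cst)),
    "constant")
  expect_equal(unname(r2["flat", ]), c(0, 0))

  expect_error(correlation_matrix(toy_expr(c(1, 2), features = "x")),
               "3 samples")
  a <- toy_expr(1:6, features = c("a", "b"), samples = c("s1", "s2", "s3"))
  b <- toy_expr(1:6, features = c("c", "d"), samples = c("t1", "t2", "t3"))
  expect_error(correlation_matrix(a, b), "orderings differ")
})

test_that("hard thresholding uses strict |r| > tau and zero diagonal", {
  corr <- matrix(c(1, .7, -.65, .7, 1, .2, -.65, .2, 1), 3, 3,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  adj <- threshold_adjacency(corr, 0.6)
  expect_s3_class(adj, "adjacency")
  expect_equal(sum(adj$A) / 2, 2)                   # edges a-b and a-c only
  expect_equal(adj$A["a", "b"], 1)
  expect_equal(adj$A["a", "c"], 1)
  expect_equal(adj$A["b", "c"], 0)
  expect_equal(diag(adj$A), c(a = 0, b = 0, c = 0))

  expect_equal(sum(threshold_adjacency(corr, 0.99)$A), 0)

  # boundary is strict: |r| equal to tau gives no edge
  expect_equal(threshold_adjacency(corr, 0.7)$A["a", "b"], 0)

  # rectangular input becomes a cross network
  cr <- threshold_adjacency(matrix(c(.9, .1), 1, 2,
                                   dimnames = list("g1", c("m1", "m2"))), 0.5)
  expect_s3_class(cr, "cross_adjacency")
  expect_equal(unname(cr$C[1, ]), c(1, 0))
  expect_identical(unname(cr$provenance[1, ]), c("coexpression", "none"))

  expect_error(threshold_adjacency(corr, 1), "\\[0, 1\\)")
})

test_that("thresholding is antitone in tau and always yields valid adjacency", {
  set.seed(11)
  for (rep in 1:5) {
    e <- expr_mat(matrix(rnorm(15 * 20), 15, 20),
                  sprintf("f%d", 1:15), sprintf("s%d", 1:20))
    corr <- correlation_matrix(e)
    taus <- sort(runif(4, 0, 0.9))
    adjs <- lapply(taus, threshold_adjacency, corr = corr)
    for (i in seq_along(adjs)) {
      A <- adjs[[i]]$A
      expect_identical(A, t(A))
      expect_true(all(diag(A) == 0))
      expect_true(all(A %in% c(0, 1)))
      if (i > 1) expect_true(all(A <= adjs[[i - 1]]$A))  # nested edge sets
    }
  }
})

test_that("scale-free fit matches the normal-equations oracle", {
  # exact power law f(d) = 16 d^-2
  fit <- scale_free_fit(setNames(c(16, 4, 1), c(1, 2, 4)))
  expect_equal(fit$slope, -2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # flat frequencies: slope 0
  flat <- scale_free_fit(setNames(c(5, 5, 5), c(1, 2, 3)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  # random graphs: agree with an independent closed-form OLS to 1e-10
  for (seed in c(5, 17)) {
    g <- generate_degree_test_graphs("preferential_attachment", 300,
                                     seed = seed)
    fit <- scale_free_fit(g)
    tab <- table(degrees(g)[degrees(g) >= 1])
    orc <- ols_oracle(log10(as.numeric(names(tab))), log10(as.numeric(tab)))
    expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
    expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-10)
  }

  expect_error(scale_free_fit(setNames(c(4, 2), c(1, 2))), "3 distinct")
})

test_that("scale-free threshold selection picks the smallest adequate tau", {
  ds <- small_planted()
  corr <- correlation_matrix(ds$expr_g)
  sel <- select_scale_free_threshold(corr, c(0.3, 0.5, 0.7), min_r2 = 0)
  # min_r2 = 0 is reached everywhere defined: smallest tau wins
  expect_equal(sel$threshold, min(sel$grid$tau[!is.na(sel$grid$r_squared)]))
  expect_named(sel$grid, c("tau", "slope", "r_squared", "mean_degree"))
  expect_true(all(diff(sel$grid$mean_degree) <= 0))   # sparser as tau grows

  # unreachable min_r2 falls back to argmax with a flag
  sel2 <- select_scale_free_threshold(corr, c(0.3, 0.5, 0.7), min_r2 = 1)
  expect_identical(sel2$flag, "no_tau_reached_min_r2")
  expect_equal(sel2$r_squared, max(sel2$grid$r_squared, na.rm = TRUE))

  expect_error(select_scale_free_threshold(corr, c(0.5, 1.2)), "\\[0, 1\\)")
  expect_error(select_scale_free_threshold(corr, numeric()), "empty")
})

test_that("cross network union keeps provenance and drops unknown ids", {
  co <- cross_adjacency(matrix(c(1, 0, 0, 0), 2, 2,
                               dimnames = list(c("g1", "g2"), c("m1", "m2"))))
  # empty known set: identity
  expect_identical(combine_cross_network(co, NULL)$C, co$C)

  known <- data.frame(gene = c("g1", "g2", "gX"),
                      mirna = c("m1", "m2", "m1"))
  out <- combine_cross_network(co, known)
  expect_equal(out$C["g1", "m1"], 1)
  expect_equal(out$C["g2", "m2"], 1)
  expect_identical(out$provenance["g1", "m1"], "both")
  expect_identical(out$provenance["g2", "m2"], "known")
  expect_identical(out$provenance["g2", "m1"], "none")
  expect_equal(sum(out$C), 2)
})

test_that("adjacency constructor enforces its invariants", {
  expect_error(adjacency(matrix(c(0, 1, 0, 0), 2, 2,
                                dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
  expect_error(adjacency(matrix(c(1, 0, 0, 0), 2, 2,
                                dimnames = list(c("a", "b"), c("a", "b")))),
               "diagonal")
  expect_error(adjacency(matrix(c(0, 2, 2, 0), 2, 2,
                                dimnames = list(c("a", "b"), c("a", "b")))),
               "0/1")
  A <- rand_sym_binary(6)
  dimnames(A) <- list(paste0("n", 1:6), paste0("n", 1:6))
  adj <- adjacency(A)
  expect_equal(sum(degrees(adj)), 2 * (sum(A) / 2))  # handshake lemma
})
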