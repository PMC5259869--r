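#' Binary within-type network
#'
#' A symmetric binary adjacency matrix with zero diagonal over one node type
#' (genes or miRNAs).
#'
#' @param A binary symmetric matrix with zero diagonal.
#' @param node_ids unique node identifiers; default rownames of `A`.
#' @return An object of class `adjacency`.
#' @export
adjacency <- function(A, node_ids = rownames(A)) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (is.null(node_ids)) stopf("adjacency needs node identifiers")
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stopf("duplicate node ids in adjacency")
  if (nrow(A) != ncol(A) || nrow(A) != length(node_ids))
    stopf("adjacency dimensions do not match node ids")
  if (!is_binary01(A)) stopf("adjacency entries must be 0/1")
  if (!isTRUE(all.equal(A, t(A)))) stopf("adjacency must be symmetric")
  if (any(diag(A) != 0)) stopf("adjacency diagonal must be zero")
  dimnames(A) <- list(node_ids, node_ids)
  structure(list(A = A, node_ids = node_ids), class = "adjacency")
}

#' @rdname adjacency
#' @param adj an `adjacency`.
#' @return `degrees()`: named integer vector of node degrees.
#' @export
degrees <- function(adj) {
  d <- rowSums(adj$A)
  names(d) <- adj$node_ids
  d
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("<adjacency> %d nodes, %d edges (mean degree %.2f)\n",
              length(x$node_ids), sum(x$A) / 2, mean(rowSums(x$A))))
  invisible(x)
}

#' Binary gene-by-miRNA cross network
#'
#' The cross matrix C joining the two node types; each edge carries a
#' provenance: from coexpression, from the known-interaction list, or both.
#'
#' @param C binary gene x miRNA matrix.
#' @param gene_ids,mirna_ids identifiers; default dimnames of `C`.
#' @param provenance character matrix (same shape) in
#'   `c("none","coexpression","known","both")`; defaults to "coexpression"
#'   wherever `C` is 1.
#' @return An object of class `cross_adjacency`.
#' @export
cross_adjacency <- function(C, gene_ids = rownames(C), mirna_ids = colnames(C),
                            provenance = NULL) {
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  if (is.null(gene_ids) || is.null(mirna_ids))
    stopf("cross network needs gene and miRNA identifiers")
  gene_ids <- as.character(gene_ids); mirna_ids <- as.character(mirna_ids)
  if (nrow(C) != length(gene_ids) || ncol(C) != length(mirna_ids))
    stopf("cross network dimensions do not match id lists")
  if (!is_binary01(C)) stopf("cross network entries must be 0/1")
  if (is.null(provenance)) {
    provenance <- matrix("none", nrow(C), ncol(C))
    provenance[C == 1] <- "coexpression"
  }
  if (!all(provenance %in% c("none", "coexpression", "known", "both")))
    stopf("invalid provenance label")
  dimnames(C) <- list(gene_ids, mirna_ids)
  dimnames(provenance) <- dimnames(C)
  structure(list(C = C, gene_ids = gene_ids, mirna_ids = mirna_ids,
                 provenance = provenance),
            class = "cross_adjacency")
}

#' @export
print.cross_adjacency <- function(x, ...) {
  cat(sprintf("<cross_adjacency> %d genes x %d miRNAs, %d edges (%d known)\n",
              length(x$gene_ids), length(x$mirna_ids), sum(x$C),
              sum(x$provenance %in% c("known", "both"))))
  invisible(x)
}

#' Pearson correlations between feature rows
#'
#' Computes the Pearson correlation between every row of `x` and every row
#' of `y` (or of `x` with itself when `y` is absent). Constant rows have an
#' undefined correlation; their entries are set to 0 and the features are
#' reported in a message.
#'
#' @param x an [expr_mat] (no missing values).
#' @param y optional second [expr_mat] with the identical sample ordering.
#' @return A correlation matrix with feature ids as dimnames.
#' @export
correlation_matrix <- function(x, y = NULL) {
  if (ncol(x$values) < 3L) stopf("need at least 3 samples for correlations")
  if (anyNA(x$values) || (!is.null(y) && anyNA(y$values)))
    stopf("missing values present; run impute_missing() first")
  if (!is.null(y) && !identical(sample_ids(x), sample_ids(y)))
    stopf("sample orderings differ; run align_samples() first")
  flag_constant <- function(e, label) {
    cst <- apply(e$values, 1L, function(r) max(r) == min(r))
    if (any(cst))
      co_log("correlation undefined for %d constant %s feature(s) (%s); set to 0",
             sum(cst), label,
             paste(utils::head(feature_ids(e)[cst], 5L), collapse = ", "))
    cst
  }
  cx <- flag_constant(x, "x")
  r <- suppressWarnings(
    if (is.null(y)) stats::cor(t(x$values))
    else stats::cor(t(x$values), t(y$values))
  )
  if (is.null(y)) {
    r[cx, ] <- 0; r[, cx] <- 0; diag(r)[cx] <- 0
  } else {
    cy <- flag_constant(y, "y")
    r[cx, ] <- 0; r[, cy] <- 0
  }
  r[is.na(r)] <- 0
  r
}

#' Hard-threshold a correlation matrix into a binary network
#'
#' An edge is assigned wherever the absolute correlation is strictly greater
#' than `tau`. A square matrix with identical row and column names is
#' treated as a within-type network (symmetric [adjacency], diagonal forced
#' to zero); anything else becomes a [cross_adjacency].
#'
#' @param corr correlation matrix with dimnames.
#' @param tau threshold in `[0, 1)`.
#' @return An [adjacency] or [cross_adjacency].
#' @export
threshold_adjacency <- function(corr, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau >= 1)
    stopf("`tau` must be a single value in [0, 1)")
  E <- (abs(corr) > tau) * 1
  self <- nrow(corr) == ncol(corr) && !is.null(rownames(corr)) &&
    identical(rownames(corr), colnames(corr))
  if (self) {
    diag(E) <- 0
    E <- pmax(E, t(E))            # guard against asymmetric float input
    adjacency(E, rownames(corr))
  } else {
    cross_adjacency(E, rownames(corr), colnames(corr))
  }
}

#' Scale-free topology fit of a degree distribution
#'
#' Ordinary least squares of `log10 f(d)` on `log10 d`, where `f(d)` is the
#' number of nodes with degree exactly `d`; zero-degree nodes are excluded
#' (their log-degree is undefined). A network whose degree distribution
#' follows a power law gives a straight line with negative slope and
#' R-squared near 1.
#'
#' @param adj an [adjacency], or a named numeric vector of degree
#'   frequencies (names = degrees) for direct use.
#' @return An object of class `scale_free_fit`: list with `slope`,
#'   `r_squared`, `n_points` (distinct degrees used), `threshold` (filled by
#'   [select_scale_free_threshold()]), and the `(d, f)` table.
#' @export
scale_free_fit <- function(adj) {
  if (inherits(adj, "adjacency")) {
    d <- degrees(adj)
    d <- d[d >= 1]
    tab <- table(d)
    dd <- as.numeric(names(tab))
    ff <- as.numeric(tab)
  } else {
    dd <- as.numeric(names(adj))
    ff <- as.numeric(adj)
    keep <- dd >= 1 & ff > 0
    dd <- dd[keep]; ff <- ff[keep]
  }
  if (length(dd) < 3L)
    stopf("scale-free fit needs >= 3 distinct positive degrees (got %d)",
          length(dd))
  lx <- log10(dd); ly <- log10(ff)
  fit <- stats::lm(ly ~ lx)
  # suppressWarnings: summary.lm warns on exact power-law input (perfect fit)
  r2 <- if (stats::var(ly) == 0) 0 else suppressWarnings(summary(fit)$r.squared)
  structure(list(threshold = NA_real_,
                 slope = unname(stats::coef(fit)[2L]),
                 r_squared = r2,
                 n_points = length(dd),
                 freq = data.frame(degree = dd, count = ff)),
            class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("<scale_free_fit> tau=%s slope=%.3f R2=%.3f over %d degrees\n",
              ifelse(is.na(x$threshold), "?", format(x$threshold)),
              x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Choose a within-type threshold by scale-free topology
#'
#' For each candidate threshold the correlation matrix is hard-thresholded
#' and the scale-free fit computed; the smallest threshold whose R-squared
#' reaches `min_r2` is returned (sparser networks discard more of the
#' correlation signal, so the smallest adequate threshold keeps the most).
#' If no threshold qualifies, the one with maximal R-squared is returned
#' with `flag = "no_tau_reached_min_r2"`.
#'
#' @param corr square correlation matrix (self-correlations).
#' @param tau_grid candidate thresholds in `[0, 1)`.
#' @param min_r2 required scale-free R-squared (default 0.8).
#' @return A `scale_free_fit` for the chosen threshold, with an element
#'   `grid`: data frame of (tau, slope, r_squared, mean_degree) over the
#'   whole grid, and `flag` (NA or the fallback marker).
#' @export
select_scale_free_threshold <- function(corr, tau_grid, min_r2 = 0.8) {
  if (!length(tau_grid)) stopf("empty threshold grid")
  if (any(tau_grid < 0 | tau_grid >= 1)) stopf("thresholds must lie in [0, 1)")
  tau_grid <- sort(tau_grid)
  rows <- lapply(tau_grid, function(tau) {
    adj <- threshold_adjacency(corr, tau)
    fit <- tryCatch(scale_free_fit(adj), error = function(e) NULL)
    data.frame(tau = tau,
               slope = if (is.null(fit)) NA_real_ else fit$slope,
               r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
               mean_degree = mean(rowSums(adj$A)))
  })
  grid <- do.call(rbind, rows)
  ok <- which(!is.na(grid$r_squared) & grid$r_squared >= min_r2)
  flag <- NA_character_
  if (length(ok)) {
    pick <- ok[1L]
  } else {
    if (all(is.na(grid$r_squared)))
      stopf("scale-free fit undefined at every threshold in the grid")
    pick <- which.max(grid$r_squared)
    flag <- "no_tau_reached_min_r2"
    co_log("no threshold reached R2 >= %.2f; falling back to tau = %.2f (R2 = %.3f)",
           min_r2, grid$tau[pick], grid$r_squared[pick])
  }
  out <- scale_free_fit(threshold_adjacency(corr, grid$tau[pick]))
  out$threshold <- grid$tau[pick]
  out$grid <- grid
  out$flag <- flag
  out
}

#' Union of coexpression and known gene-miRNA interactions
#'
#' The integrated cross matrix C has an edge wherever the coexpression
#' network has one or the pair appears in the known-interaction list; edge
#' provenance records which. Known pairs whose identifiers are not in the
#' network are dropped with a logged count.
#'
#' @param coexpr a [cross_adjacency] from thresholded gene-miRNA
#'   correlations.
#' @param known_pairs data frame (or 2-column matrix) of known (gene, miRNA)
#'   interactions.
#' @return A [cross_adjacency] with provenance.
#' @export
combine_cross_network <- function(coexpr, known_pairs) {
  C <- coexpr$C
  prov <- coexpr$provenance
  if (is.null(known_pairs) || nrow(known_pairs) == 0L)
    return(coexpr)
  g <- as.character(known_pairs[[1L]])
  m <- as.character(known_pairs[[2L]])
  gi <- match(g, coexpr$gene_ids)
  mi <- match(m, coexpr$mirna_ids)
  ok <- !is.na(gi) & !is.na(mi)
  if (any(!ok))
    co_log("dropped %d known pair(s) with ids absent from the network", sum(!ok))
  idx <- unique(cbind(gi[ok], mi[ok]))
  if (nrow(idx)) {
    prov[idx] <- ifelse(C[idx] == 1, "both", "known")
    C[idx] <- 1
  }
  cross_adjacency(C, coexpr$gene_ids, coexpr$mirna_ids, prov)
}
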