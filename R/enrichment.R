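#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= observed)` for X hypergeometric: `draws` balls drawn without
#' replacement from an urn of `background` balls of which `successes` are
#' white. Computed through [stats::phyper()] (log-space-stable).
#'
#' @param background urn size (the background universe).
#' @param successes number of background elements in the reference set.
#' @param draws number of background elements in the query set.
#' @param observed overlap whose tail probability is wanted.
#' @return The tail probability in `[0, 1]`; `observed = 0` gives 1.
#' @export
hypergeom_tail <- function(background, successes, draws, observed) {
  args <- c(background = background, successes = successes,
            draws = draws, observed = observed)
  if (any(args < 0) || any(args != round(args)))
    stopf("all counts must be non-negative integers")
  if (successes > background || draws > background)
    stopf("successes/draws cannot exceed the background size")
  if (observed > min(successes, draws))
    stopf("observed overlap %d exceeds min(successes = %d, draws = %d)",
          observed, successes, draws)
  stats::phyper(observed - 1, successes, background - successes, draws,
                lower.tail = FALSE)
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests, capping at 1.
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
bonferroni_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "bonferroni")
}

#' Pairwise hypergeometric set enrichment
#'
#' Tests every pair of one set from `collections_a` (the "query" side,
#' e.g. detected module miRNA sets) against one from `collections_b` (the
#' reference side, e.g. genomic miRNA clusters). Sets are restricted to the
#' background universe first; pairs with overlap below `min_overlap` are
#' not tested. The Bonferroni multiplier is the number of tests actually
#' performed. Swapping the two collections exchanges the hypergeometric
#' roles (draws vs successes), which leaves each pair's raw p-value
#' unchanged; the enrichment "direction" differs only in which side is
#' reported as the query.
#'
#' @param collections_a,collections_b named lists of character vectors.
#' @param background character vector: the universe the sets live in.
#' @param min_overlap minimum overlap to test (the method's default is 3).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return Data frame with columns module_id, set_id, overlap, module_size,
#'   set_size, background_size, p_raw, p_adj, significant; one row per
#'   tested pair.
#' @export
set_enrichment <- function(collections_a, collections_b, background,
                           min_overlap = 3L, alpha = 0.05) {
  background <- unique(as.character(background))
  if (!length(background)) stopf("empty background universe")
  if (is.null(names(collections_a)))
    names(collections_a) <- paste0("A", seq_along(collections_a))
  if (is.null(names(collections_b)))
    names(collections_b) <- paste0("B", seq_along(collections_b))
  ca <- lapply(collections_a, function(s) intersect(unique(s), background))
  cb <- lapply(collections_b, function(s) intersect(unique(s), background))
  rows <- list()
  for (i in names(ca)) for (j in names(cb)) {
    ov <- length(intersect(ca[[i]], cb[[j]]))
    if (ov < min_overlap) next
    rows[[length(rows) + 1L]] <- data.frame(
      module_id = i, set_id = j, overlap = ov,
      module_size = length(ca[[i]]), set_size = length(cb[[j]]),
      background_size = length(background),
      p_raw = hypergeom_tail(length(background), length(cb[[j]]),
                             length(ca[[i]]), ov),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    co_log("no set pair reached the minimum overlap of %d", min_overlap)
    return(data.frame(module_id = character(), set_id = character(),
                      overlap = integer(), module_size = integer(),
                      set_size = integer(), background_size = integer(),
                      p_raw = numeric(), p_adj = numeric(),
                      significant = logical()))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha
  out
}

#' Normalize miRNA identifiers for matching
#'
#' Lower-cases and strips a leading "hsa-" prefix. When `match_against` is
#' given, identifiers that still fail to match also have a trailing
#' -5p/-3p arm suffix stripped as a fallback (logged).
#'
#' @param ids character vector of miRNA identifiers.
#' @param match_against optional normalized universe to resolve against.
#' @return Normalized identifiers.
#' @export
normalize_mirna_ids <- function(ids, match_against = NULL) {
  norm <- sub("^hsa-", "", tolower(as.character(ids)))
  if (!is.null(match_against)) {
    miss <- !(norm %in% match_against)
    if (any(miss)) {
      fallback <- sub("-[35]p$", "", norm[miss])
      hit <- fallback %in% match_against
      if (any(hit))
        co_log("%d miRNA id(s) matched only after dropping the arm suffix",
               sum(hit))
      norm[miss][hit] <- fallback[hit]
    }
  }
  norm
}

#' Cancer-miRNA annotation of detected modules
#'
#' One global over-representation test (are the miRNAs captured by the
#' modules enriched for the cancer list, over the background universe?)
#' plus a per-module count table with per-module hypergeometric tests,
#' Bonferroni-corrected across modules.
#'
#' @param modules list of `gm_module` objects (only valid ones are used).
#' @param cancer_list character vector of cancer-associated miRNA ids.
#' @param background character vector: the miRNA universe.
#' @return List with `global` (data frame: one row with the global test)
#'   and `per_module` (data frame: module, n_mirnas, n_cancer, p_raw,
#'   p_adj).
#' @export
annotate_cancer_mirnas <- function(modules, cancer_list, background) {
  background <- unique(normalize_mirna_ids(background))
  if (!length(background)) stopf("empty miRNA background")
  cancer <- intersect(unique(normalize_mirna_ids(cancer_list, background)),
                      background)
  modules <- valid_modules(modules)
  mod_mirnas <- lapply(modules, function(m)
    intersect(unique(normalize_mirna_ids(m$mirnas, background)), background))
  all_mod <- unique(unlist(mod_mirnas))
  overlap <- length(intersect(all_mod, cancer))
  global <- data.frame(
    background_size = length(background),
    cancer_size = length(cancer),
    module_mirnas = length(all_mod),
    overlap = overlap,
    p = if (length(all_mod) == 0L || length(cancer) == 0L) 1
        else hypergeom_tail(length(background), length(cancer),
                            length(all_mod), overlap))
  per <- do.call(rbind, lapply(seq_along(modules), function(i) {
    nm <- length(mod_mirnas[[i]])
    nc <- length(intersect(mod_mirnas[[i]], cancer))
    data.frame(module = i, n_mirnas = nm, n_cancer = nc,
               p_raw = if (nm == 0L || length(cancer) == 0L) 1
                       else hypergeom_tail(length(background), length(cancer),
                                           nm, nc))
  }))
  if (!is.null(per)) per$p_adj <- bonferroni_adjust(per$p_raw)
  list(global = global, per_module = per)
}
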