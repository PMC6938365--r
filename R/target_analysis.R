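## Leading-edge target calling and co-targeting structure. A factor's
## targets are the query genes whose ChIP signal exceeds the argument of
## the CDF-gap supremum (the KS argument) -- the gene-set analogue of a
## GSEA leading edge. Factors are then grouped by Fisher-exact overlap of
## their target lists.

#' Leading-edge target genes of a factor
#'
#' The query genes driving the CDF gap: all query genes with ChIP signal
#' strictly greater than `c_star`, the argument of `d_sup`.
#'
#' @param curves `enrichment_curves` for the factor (must be right-shifted,
#'   i.e. pass [triage()]).
#' @param query_signals Named numeric vector: query gene -> ChIP signal for
#'   this factor.
#' @return Character vector of target gene symbols (possibly empty).
#' @export
leading_edge_targets <- function(curves, query_signals) {
  if (!triage(curves)) {
    stop("factor did not pass triage; leading-edge targets are undefined")
  }
  if (is.null(names(query_signals))) {
    stop("query_signals must be named by gene symbol")
  }
  names(query_signals)[query_signals > curves$c_star]
}

#' Target sets for every non-triaged factor
#'
#' Convenience wrapper: runs (or reuses) the factor screen and extracts the
#' leading-edge target set of every factor that passed triage.
#'
#' @param mat Normalized gene x factor matrix.
#' @param query,background Gene lists as in [run_factor_analysis()].
#' @param scores Optional FactorScore table with attached curves
#'   (`keep_curves = TRUE`); recomputed when omitted.
#' @param ... Passed to [run_factor_analysis()].
#' @return Named list, factor -> character vector of target genes.
#' @export
factor_targets <- function(mat, query, background, scores = NULL, ...) {
  if (is.null(scores) || is.null(attr(scores, "curves"))) {
    scores <- run_factor_analysis(mat, query, background,
                                  keep_curves = TRUE, ...)
  }
  curves <- attr(scores, "curves")
  kept <- scores$factor[!scores$triaged]
  out <- lapply(kept, function(f) {
    leading_edge_targets(curves[[f]], setNames(mat[query, f], query))
  })
  names(out) <- kept
  out
}

#' Pairwise Fisher-overlap map of factor target sets
#'
#' For every pair of target sets, a Fisher's exact test of overlap within
#' the query-list universe. Cells with a significant positive association
#' (odds ratio > 1 and p < 0.05) carry `-log10(p)`; all other cells are
#' masked to 0 (displayed white on heatmaps).
#'
#' @param target_sets Named list of target gene vectors (>= 2), all subsets
#'   of `universe`.
#' @param universe Character vector, the query gene list.
#' @return A list of class `factor_group_map`: `scores` (masked
#'   `-log10(p)`, symmetric), `p` (raw two-sided p), `odds_ratio`
#'   (conditional MLE).
#' @export
pairwise_overlap_map <- function(target_sets, universe) {
  if (length(target_sets) < 2L) stop("need >= 2 target sets")
  if (is.null(names(target_sets))) stop("target_sets must be named")
  for (nm in names(target_sets)) {
    extra <- setdiff(target_sets[[nm]], universe)
    if (length(extra)) {
      stop("target set '", nm, "' not contained in the universe: ",
           paste(head(extra, 5), collapse = ", "))
    }
  }
  k <- length(target_sets)
  nms <- names(target_sets)
  pmat <- matrix(1, k, k, dimnames = list(nms, nms))
  ormat <- matrix(0, k, k, dimnames = list(nms, nms))
  smat <- matrix(0, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ov <- overlap_test(target_sets[[i]], target_sets[[j]], universe)
      pmat[i, j] <- pmat[j, i] <- ov$p
      ormat[i, j] <- ormat[j, i] <- ov$odds_ratio
      val <- if (ov$odds_ratio > 1 && ov$p < 0.05) -log10(ov$p) else 0
      smat[i, j] <- smat[j, i] <- val
    }
  }
  structure(list(scores = smat, p = pmat, odds_ratio = ormat),
            class = "factor_group_map")
}

#' Group factors by Pearson distance over their overlap profiles
#'
#' Rows of the overlap-score matrix are clustered hierarchically
#' (complete linkage, distance = 1 - Pearson correlation); factors sharing
#' a subtree entirely below `cut` are grouped. Constant rows (zero
#' variance, correlation undefined) are given zero correlation with every
#' other row, which places them above any practical cut as singletons.
#'
#' @param map A `factor_group_map` (or a plain numeric matrix of overlap
#'   scores with factor row names).
#' @param cut Pearson-distance threshold; factors merge only strictly below
#'   it (default 0.7, i.e. correlation > 0.3). `cut = 0` yields singletons.
#' @return A list with `groups` (named list of factor-name vectors),
#'   `membership` (named integer vector) and `hclust`.
#' @export
group_factors <- function(map, cut = 0.7) {
  m <- if (inherits(map, "factor_group_map")) map$scores else map
  if (nrow(m) < 2L) {
    return(list(groups = list(rownames(m)),
                membership = setNames(1L, rownames(m)), hclust = NULL))
  }
  cc <- suppressWarnings(cor(t(m)))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  d <- 1 - cc
  hc <- hclust(as.dist(d), method = "complete")
  membership <- if (cut <= 0) {
    setNames(seq_len(nrow(m)), rownames(m))
  } else {
    cutree(hc, h = cut - 1e-8)
  }
  groups <- split(names(membership), membership)
  names(groups) <- NULL
  list(groups = groups, membership = membership, hclust = hc)
}

#' Write per-factor target lists as text blocks
#'
#' One block per factor: a `>FACTOR` header line followed by one gene per
#' line, blocks separated by blank lines.
#'
#' @param target_sets Named list of target gene vectors.
#' @param path Output file.
#' @export
write_target_sets <- function(target_sets, path) {
  blocks <- vapply(names(target_sets), function(f) {
    paste(c(paste0(">", f), target_sets[[f]]), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}
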