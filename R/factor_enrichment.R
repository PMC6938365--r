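## The core screen. For one factor, the ChIP signals of a query gene list
## are compared with those of a background list via paired empirical CDFs:
## the factor is triaged when the query CDF is left-shifted, otherwise a
## one-tailed Mann-Whitney-Wilcoxon test (query drawn within the background,
## Q subset of B) yields a p-value that is BH-corrected across surviving
## factors and combined with a top-tail signal ratio into a Score.

#' Paired empirical CDFs of background and query ChIP signals
#'
#' Builds the step CDFs B(c) (background, N genes) and Q(c) (query, X genes,
#' a subset of the background) over the sorted union of observed signal
#' values, and locates the extremes of their difference:
#' `d_sup = sup_c(B(c) - Q(c))` and `d_inf = inf_c(B(c) - Q(c))`. Both CDFs
#' are 0 below the smallest observed value, so `d_inf <= 0 <= d_sup`.
#' `c_star` is the smallest c attaining `d_sup` (the Kolmogorov-Smirnov
#' argument for a right-shifted query); it is `NA` when the difference never
#' rises above zero.
#'
#' @param background_values Numeric vector of background ChIP signals.
#' @param query_values Numeric vector of query ChIP signals; every value
#'   must occur in the background (the query genes are background genes).
#' @return An object of class `enrichment_curves`: list with `grid`, `B`,
#'   `Q`, `d_sup`, `d_inf`, `c_star`, `n_background`, `n_query`, and the
#'   input value vectors.
#' @export
empirical_cdfs <- function(background_values, query_values) {
  if (length(background_values) == 0L || length(query_values) == 0L) {
    stop("background and query values must be non-empty")
  }
  if (!all(query_values %in% background_values)) {
    stop("query signals must be a subset of the background signals (Q in B)")
  }
  grid <- sort(unique(c(background_values, query_values)))
  # counts of values <= each grid point via a sorted-vector rank lookup
  B <- findInterval(grid, sort(background_values)) / length(background_values)
  Q <- findInterval(grid, sort(query_values)) / length(query_values)
  diff <- B - Q
  d_sup <- max(0, max(diff))
  d_inf <- min(0, min(diff))
  c_star <- if (max(diff) > 0) grid[which.max(diff)] else NA_real_
  structure(list(grid = grid, B = B, Q = Q,
                 d_sup = d_sup, d_inf = d_inf, c_star = c_star,
                 n_background = length(background_values),
                 n_query = length(query_values),
                 background_values = background_values,
                 query_values = query_values),
            class = "enrichment_curves")
}

#' Triage factors whose query CDF is not right-shifted
#'
#' A factor is kept for testing only when the query distribution is
#' right-shifted relative to the background, i.e. `|d_sup| > |d_inf|`.
#' Ties (including the flat case `d_sup = d_inf = 0`) are triaged.
#'
#' @param curves An `enrichment_curves` object.
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
triage <- function(curves) {
  abs(curves$d_sup) > abs(curves$d_inf)
}

#' One-tailed Mann-Whitney-Wilcoxon probability of a right-shifted query
#'
#' Tests whether the query ranks high within the background it is drawn
#' from. The statistic is the query's midrank sum inside the background;
#' the null holds every same-size subset of the background equally likely.
#' Small problems (subset count within `exact_limit`) are solved by exact
#' enumeration; larger ones use the normal approximation with tie
#' correction and continuity correction. A fully tied background gives
#' p = 0.5 (a note is emitted via `message()`).
#'
#' @param background_values Numeric vector (N signals).
#' @param query_values Numeric vector (X signals, values a subset of the
#'   background's).
#' @param exact_limit Maximum number of subsets for exact enumeration
#'   (default 2e5).
#' @return One-tailed p-value, P(rank sum >= observed).
#' @export
mww_one_tailed <- function(background_values, query_values,
                           exact_limit = 2e5) {
  if (!all(query_values %in% background_values)) {
    stop("query signals must be a subset of the background signals")
  }
  N <- length(background_values)
  X <- length(query_values)
  r_bg <- rank(background_values)
  t_obs <- sum(r_bg[match(query_values, background_values)])
  if (X == N) return(0.5)
  n_subsets <- choose(N, X)
  if (is.finite(n_subsets) && n_subsets <= exact_limit) {
    sums <- combn(N, X, function(i) sum(r_bg[i]))
    return(mean(sums >= t_obs - 1e-9))
  }
  mu <- X * (N + 1) / 2
  tie_tab <- table(background_values)
  tie_term <- sum(tie_tab^3 - tie_tab)
  v <- X * (N - X) / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) {
    message("all background values tied; MWW p set to 0.5")
    return(0.5)
  }
  pnorm((t_obs - 0.5 - mu) / sqrt(v), lower.tail = FALSE)
}

#' Top-tail signal ratio between query and background
#'
#' Compares the mean of the top `n` ChIP signals in the query list (length
#' X, `n = max(1, round(frac * X))`) with the mean of the top `n` signals in
#' the background. Because the query is part of the background, the ratio
#' lies in `[0, 1]` and measures how much of the compendium's extreme tail
#' the query captures.
#'
#' @param background_values,query_values Numeric signal vectors.
#' @param frac Tail fraction of the query length (default 0.05).
#' @return List with `n`, `u_q` (query tail mean), `u_b` (background tail
#'   mean) and `r = u_q / u_b`.
#' @export
tail_ratio <- function(background_values, query_values, frac = 0.05) {
  X <- length(query_values)
  if (X < 1L) stop("query must be non-empty")
  n <- max(1L, round(frac * X))
  u_q <- mean(sort(query_values, decreasing = TRUE)[seq_len(n)])
  u_b <- mean(sort(background_values, decreasing = TRUE)[seq_len(n)])
  if (u_b == 0) stop("background top-tail mean is zero (degenerate compendium)")
  list(n = n, u_q = u_q, u_b = u_b, r = u_q / u_b)
}

#' Rank factors by enrichment of a query gene list
#'
#' Runs the full per-factor screen over a normalized ChIP matrix: empirical
#' CDFs, triage of left-shifted factors, one-tailed Mann-Whitney-Wilcoxon
#' test for the survivors, Benjamini-Hochberg correction across the
#' surviving factors only, and the Score
#' `S = -log(p_corr, log_base) * r` where `r` is the top-tail signal ratio.
#' Factors are sorted by Score, descending; triaged factors are listed after
#' the scored ones with `NA` statistics.
#'
#' @param mat Normalized gene x factor matrix ([normalize_matrix()]).
#' @param query Character vector of query gene symbols; must be a subset of
#'   `background`.
#' @param background Character vector of background gene symbols; must be a
#'   subset of the matrix's genes.
#' @param tail_frac Tail fraction for [tail_ratio()] (default 0.05).
#' @param log_base Base of the logarithm in the Score (default 10).
#' @param keep_curves If `TRUE`, attach the per-factor `enrichment_curves`
#'   as attribute `"curves"` (named list) for downstream target calling.
#' @return A `FactorScore` data.frame with columns `factor`, `d_sup`,
#'   `d_inf`, `c_star`, `n`, `u_q`, `u_b`, `r`, `p_raw`, `p_corr`, `score`,
#'   `triaged`.
#' @export
run_factor_analysis <- function(mat, query, background,
                                tail_frac = 0.05, log_base = 10,
                                keep_curves = FALSE) {
  missing_bg <- setdiff(background, rownames(mat))
  if (length(missing_bg)) {
    stop("background genes absent from the matrix: ",
         paste(head(missing_bg, 10), collapse = ", "))
  }
  bad <- setdiff(query, background)
  if (length(bad)) {
    stop("query genes not in the background: ",
         paste(head(bad, 10), collapse = ", "))
  }
  factors <- colnames(mat)
  res <- data.frame(factor = factors,
                    d_sup = NA_real_, d_inf = NA_real_, c_star = NA_real_,
                    n = NA_integer_, u_q = NA_real_, u_b = NA_real_,
                    r = NA_real_, p_raw = NA_real_, p_corr = NA_real_,
                    score = NA_real_, triaged = FALSE,
                    stringsAsFactors = FALSE)
  curves_list <- vector("list", length(factors))
  names(curves_list) <- factors
  for (i in seq_along(factors)) {
    bg_vals <- mat[background, factors[i]]
    q_vals <- mat[query, factors[i]]
    cv <- empirical_cdfs(bg_vals, q_vals)
    curves_list[[i]] <- cv
    res$d_sup[i] <- cv$d_sup
    res$d_inf[i] <- cv$d_inf
    res$c_star[i] <- cv$c_star
    if (!triage(cv)) {
      res$triaged[i] <- TRUE
      next
    }
    tr <- tail_ratio(bg_vals, q_vals, frac = tail_frac)
    res$n[i] <- tr$n; res$u_q[i] <- tr$u_q; res$u_b[i] <- tr$u_b
    res$r[i] <- tr$r
    res$p_raw[i] <- mww_one_tailed(bg_vals, q_vals)
  }
  kept <- !res$triaged
  res$p_corr[kept] <- p.adjust(res$p_raw[kept], method = "BH")
  res$score[kept] <- -log(res$p_corr[kept], base = log_base) * res$r[kept]
  ord <- order(res$triaged, -ifelse(is.na(res$score), -Inf, res$score),
               res$factor)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  if (keep_curves) attr(res, "curves") <- curves_list
  res
}

#' Write a FactorScore table as TSV
#'
#' @param scores FactorScore data.frame from [run_factor_analysis()].
#' @param path Output file.
#' @export
write_factor_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
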