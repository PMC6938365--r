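## Human-cohort workflow: detection-based probe filtering, k-medians
## co-expression modules, per-module factor screening, binarized factor
## concordance across gene lists, and module expression comparison between
## cohorts.

#' Filter and normalize a probe-level cohort matrix
#'
#' Keeps probes detected (detection p < `detect_cut`) in at least `frac` of
#' samples, collapses probes to gene symbols by the per-sample median probe
#' value, divides each sample by its median expression (equal column
#' weighting), and retains the variable genes: those whose coefficient of
#' variation across samples exceeds the cohort's median coefficient of
#' variation (`variance_filter = "cv"`, the default) or, alternatively,
#' whose variance exceeds the median variance
#' (`variance_filter = "variance"`).
#'
#' @param expr Probe x sample numeric matrix (probe ids as row names).
#' @param detection_p Probe x sample matrix of detection p-values, aligned
#'   with `expr`.
#' @param probe_symbols Named character vector: probe id -> gene symbol.
#' @param detect_cut Detection p-value threshold (default 0.05).
#' @param frac Minimum fraction of samples in which a probe must be
#'   detected (default 0.2).
#' @param variance_filter Variability criterion, `"cv"` or `"variance"`.
#' @return Gene x sample numeric matrix of normalized, variable genes.
#' @export
preprocess_cohort <- function(expr, detection_p, probe_symbols,
                              detect_cut = 0.05, frac = 0.2,
                              variance_filter = c("cv", "variance")) {
  variance_filter <- match.arg(variance_filter)
  if (!identical(dim(expr), dim(detection_p))) {
    stop("expr and detection_p must be aligned matrices")
  }
  keep <- rowMeans(detection_p < detect_cut) >= frac
  expr <- expr[keep, , drop = FALSE]
  if (nrow(expr) == 0L) stop("no probe passes the detection filter")
  syms <- probe_symbols[rownames(expr)]
  if (anyNA(syms)) {
    stop("probes without a symbol mapping: ",
         paste(head(rownames(expr)[is.na(syms)], 5), collapse = ", "))
  }
  idx <- split(seq_len(nrow(expr)), syms)
  genes <- vapply(idx, function(i) {
    apply(expr[i, , drop = FALSE], 2L, median)
  }, numeric(ncol(expr)))
  genes <- t(genes)
  colnames(genes) <- colnames(expr)
  med <- apply(genes, 2L, median)
  if (any(med == 0)) {
    stop("sample(s) with zero median expression: ",
         paste(colnames(genes)[med == 0], collapse = ", "))
  }
  genes <- sweep(genes, 2L, med, "/")
  mu <- rowMeans(genes)
  v <- apply(genes, 1L, stats::var)
  crit <- switch(variance_filter,
                 cv = sqrt(v) / mu,
                 variance = v)
  genes[crit > median(crit), , drop = FALSE]
}

## L1 distance from every row of x to one center (vector)
.l1_to_center <- function(x, center) {
  rowSums(abs(sweep(x, 2L, center)))
}

## single k-medians run from given initial centers; returns assignment,
## centers, cost and per-iteration cost trace
.kmedians_once <- function(x, centers, max_iter) {
  k <- nrow(centers)
  n <- nrow(x)
  assign_old <- rep(0L, n)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d <- vapply(seq_len(k), function(j) .l1_to_center(x, centers[j, ]),
                numeric(n))
    assignment <- max.col(-d, ties.method = "first")
    nearest <- d[cbind(seq_len(n), assignment)]
    for (j in which(tabulate(assignment, k) == 0L)) {
      worst <- which.max(nearest)
      assignment[worst] <- j
      nearest[worst] <- 0
    }
    centers <- t(vapply(seq_len(k), function(j) {
      apply(x[assignment == j, , drop = FALSE], 2L, median)
    }, numeric(ncol(x))))
    d <- vapply(seq_len(k), function(j) .l1_to_center(x, centers[j, ]),
                numeric(n))
    trace <- c(trace, sum(d[cbind(seq_len(n), assignment)]))
    if (identical(assignment, assign_old)) break
    assign_old <- assignment
  }
  cost <- sum(d[cbind(seq_len(n), assignment)])
  list(assignment = assignment, centers = centers, cost = cost,
       trace = trace)
}

#' k-medians clustering of genes into co-expression modules
#'
#' Partitions genes (rows) into `k` modules by L1 (Manhattan) distance:
#' genes are assigned to the nearest center and centers are updated to the
#' per-sample median of their members, iterating to convergence. Centers
#' are initialized k-means++-style (first center uniform, subsequent ones
#' with probability proportional to the L1 distance to the nearest chosen
#' center); the best of `restarts` seeded runs by total L1 cost is
#' returned. Emptied clusters are re-seeded from the worst-fit gene.
#'
#' @param expr Gene x sample numeric matrix.
#' @param k Number of modules (default 10).
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param restarts Number of random restarts (default 20).
#' @param max_iter Iteration cap per run (default 100).
#' @return A `module_assignment` list: `k`, `assignment` (named integer
#'   vector, gene -> module 1..k), `centers` (k x sample matrix), `cost`
#'   (total L1), `cost_trace` (per-iteration cost of the winning run).
#' @export
kmedians <- function(expr, k = 10, seed = 1, restarts = 20, max_iter = 100) {
  if (k <= 0 || k > nrow(expr)) {
    stop("k must be between 1 and the gene count (", nrow(expr), ")")
  }
  set.seed(seed)
  best <- NULL
  for (rs in seq_len(restarts)) {
    centers_idx <- sample.int(nrow(expr), 1L)
    while (length(centers_idx) < k) {
      d <- do.call(pmin, lapply(centers_idx, function(i) {
        .l1_to_center(expr, expr[i, ])
      }))
      d <- as.numeric(d)
      if (sum(d) == 0) {
        cand <- setdiff(seq_len(nrow(expr)), centers_idx)
        centers_idx <- c(centers_idx, cand[seq_len(k - length(centers_idx))])
        break
      }
      centers_idx <- c(centers_idx, sample.int(nrow(expr), 1L, prob = d))
    }
    run <- .kmedians_once(expr, expr[centers_idx, , drop = FALSE], max_iter)
    if (is.null(best) || run$cost < best$cost) best <- run
  }
  structure(list(k = k,
                 assignment = setNames(best$assignment, rownames(expr)),
                 centers = best$centers,
                 cost = best$cost,
                 cost_trace = best$trace),
            class = "module_assignment")
}

#' Screen every co-expression module for enriched factors
#'
#' Runs [run_factor_analysis()] with each module's gene list as the query
#' against a common background. Modules smaller than `min_size` genes are
#' skipped with a warning.
#'
#' @param mat Normalized gene x factor matrix.
#' @param assignment `module_assignment` from [kmedians()].
#' @param background Character vector of background genes (the retained
#'   cohort genes); must be present in `mat`.
#' @param min_size Minimum module size to screen (default 5).
#' @param ... Passed to [run_factor_analysis()].
#' @return Named list of FactorScore tables, one per screened module
#'   (`"M-1"`, `"M-2"`, ...).
#' @export
module_factor_screen <- function(mat, assignment, background,
                                 min_size = 5, ...) {
  out <- list()
  for (m in seq_len(assignment$k)) {
    genes <- names(assignment$assignment)[assignment$assignment == m]
    genes <- intersect(genes, background)
    label <- paste0("M-", m)
    if (length(genes) < min_size) {
      warning("module ", label, " has fewer than ", min_size,
              " genes; skipped")
      next
    }
    out[[label]] <- run_factor_analysis(mat, genes, background, ...)
  }
  out
}

#' Binarized factor-presence matrix across gene lists, with column clustering
#'
#' Combines the factor FDRs of several screens (modules, DEG lists) into a
#' factor x gene-list matrix, digitizes it (1 if FDR < `fdr_cut`, else 0 --
#' triaged factors count as absent), and clusters the gene-list columns by
#' 1 - Pearson correlation with complete linkage. Constant columns get zero
#' correlation with the rest.
#'
#' @param fdr_tables Named list of FactorScore tables (one per gene list),
#'   as produced by [run_factor_analysis()] / [module_factor_screen()].
#' @param fdr_cut Presence threshold (default 0.05).
#' @return A list with `presence` (binary factor x list matrix) and
#'   `hclust` (the column dendrogram).
#' @export
factor_presence_clustering <- function(fdr_tables, fdr_cut = 0.05) {
  if (length(fdr_tables) < 2L) stop("need >= 2 gene lists")
  if (is.null(names(fdr_tables))) stop("fdr_tables must be named")
  factors <- sort(unique(unlist(lapply(fdr_tables, `[[`, "factor"))))
  V <- sapply(fdr_tables, function(tab) {
    fdr <- setNames(tab$p_corr, tab$factor)[factors]
    as.integer(!is.na(fdr) & fdr < fdr_cut)
  })
  rownames(V) <- factors
  cc <- suppressWarnings(cor(V))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  hc <- hclust(as.dist(1 - cc), method = "complete")
  list(presence = V, hclust = hc)
}

#' Compare a module's expression level between two cohorts
#'
#' For each module gene present in both cohorts, computes its mean
#' expression across samples within each cohort, then compares the two
#' per-gene mean vectors with a two-sample Mann-Whitney test. The direction
#' is the sign of the median per-gene difference (cohort b minus cohort a).
#'
#' @param module Character vector of module gene symbols.
#' @param cohort_a,cohort_b Gene x sample matrices (e.g. normalized control
#'   and disease cohorts). Only symbols shared by both and by the module
#'   are used (a note reports how many).
#' @return List with `p` (two-sided MWW), `direction`
#'   (`"higher_in_b"` / `"lower_in_b"` / `"none"`), `median_diff`,
#'   `n_genes`.
#' @export
module_expression_test <- function(module, cohort_a, cohort_b) {
  shared <- intersect(intersect(module, rownames(cohort_a)),
                      rownames(cohort_b))
  if (length(shared) == 0L) stop("no module gene present in both cohorts")
  if (length(shared) < length(module)) {
    message(length(module) - length(shared),
            " module gene(s) missing from a cohort; using ",
            length(shared), " shared genes")
  }
  mean_a <- rowMeans(cohort_a[shared, , drop = FALSE])
  mean_b <- rowMeans(cohort_b[shared, , drop = FALSE])
  p <- suppressWarnings(
    stats::wilcox.test(mean_a, mean_b, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)$p.value
  )
  if (is.nan(p)) p <- 1
  md <- median(mean_b - mean_a)
  direction <- if (md < 0) "lower_in_b" else if (md > 0) "higher_in_b" else "none"
  list(p = p, direction = direction, median_diff = md,
       n_genes = length(shared))
}

#' Write a module assignment as TSV (gene, module)
#'
#' @param assignment `module_assignment` from [kmedians()].
#' @param path Output file.
#' @export
write_module_assignment <- function(assignment, path) {
  df <- data.frame(gene = names(assignment$assignment),
                   module = paste0("M-", assignment$assignment),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
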