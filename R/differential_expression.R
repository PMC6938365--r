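## Consortium-style DEG calling: per-model median collapse, Student t-tests
## across model medians, BH FDR plus a +/- 2 SD fold-change envelope,
## persistence overlaps by Fisher's exact test, and sample clustering with
## uncentered Pearson distance.

#' Read an expression matrix TSV (first column gene, one column per sample)
#'
#' @param path TSV with header; first column holds gene symbols.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  storage.mode(mat) <- "double"
  mat
}

#' Read a sample-metadata table
#'
#' @param path TSV with header columns `sample_id`, `model`, `condition`
#'   (`control` or `case`) and `timepoint`.
#' @return data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "model", "condition", "timepoint")
  if (!all(need %in% names(m))) {
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  }
  m
}

#' Collapse replicate samples to per-model medians
#'
#' Animal-to-animal variability within a laboratory/model is removed by
#' replacing each (model, condition, timepoint) group of samples with the
#' per-gene median of the group. Downstream contrasts then compare models,
#' not animals.
#'
#' @param expr Numeric matrix, genes x samples; column names are sample ids.
#' @param meta data.frame with `sample_id`, `model`, `condition`,
#'   `timepoint`; one row per column of `expr`.
#' @return A list with `values` (genes x groups matrix) and `meta`
#'   (data.frame with one row per group: `model`, `condition`, `timepoint`).
#' @export
collapse_to_model_medians <- function(expr, meta) {
  if (!all(colnames(expr) %in% meta$sample_id)) {
    stop("every expression column needs a metadata row")
  }
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  tp_key <- ifelse(is.na(meta$timepoint), "", as.character(meta$timepoint))
  key <- interaction(meta$model, meta$condition, tp_key,
                     drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(ncol(expr)), key)
  if (any(lengths(groups) == 0L)) stop("group with zero samples")
  vals <- vapply(groups, function(idx) {
    apply(expr[, idx, drop = FALSE], 1L, median)
  }, numeric(nrow(expr)))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(expr))
  rownames(vals) <- rownames(expr)
  first <- vapply(groups, `[`, integer(1), 1L)
  gmeta <- data.frame(model = meta$model[first],
                      condition = meta$condition[first],
                      timepoint = meta$timepoint[first],
                      stringsAsFactors = FALSE)
  colnames(vals) <- paste(gmeta$model, gmeta$condition, gmeta$timepoint,
                          sep = ".")
  list(values = vals, meta = gmeta)
}

#' Call differentially expressed genes for one timepoint
#'
#' For the chosen `day`, compares case model-median columns against control
#' model-median columns with an unpaired equal-variance (Student) two-sided
#' t-test per gene, corrects p-values with Benjamini-Hochberg over all
#' genes, and labels a direction only for genes that both clear the FDR cut
#' and whose log2 fold change lies more than `sd_mult` standard deviations
#' from the day's mean fold change, in the matching tail.
#'
#' Controls without a matching timepoint annotation (or annotated `NA`) are
#' shared across days. Genes with zero variance in both groups get p = 1
#' (a count is reported via `message()`).
#'
#' @param collapsed Result of [collapse_to_model_medians()].
#' @param day Timepoint to contrast.
#' @param sd_mult Width of the fold-change envelope in SD units (default 2).
#' @param fdr_cut FDR threshold (default 0.05).
#' @return A `DegTable` data.frame: `gene`, `log2_fold_change`, `p`, `fdr`,
#'   `direction` (`up` / `down` / `none`).
#' @export
call_degs <- function(collapsed, day, sd_mult = 2, fdr_cut = 0.05) {
  vals <- collapsed$values
  meta <- collapsed$meta
  case_idx <- which(meta$condition == "case" & meta$timepoint == day)
  ctrl_idx <- which(meta$condition == "control" & meta$timepoint == day)
  if (length(ctrl_idx) == 0L) {
    ctrl_idx <- which(meta$condition == "control")
  }
  if (length(case_idx) < 2L || length(ctrl_idx) < 2L) {
    stop("need >= 2 case and >= 2 control model columns for day ", day)
  }
  x <- vals[, ctrl_idx, drop = FALSE]
  y <- vals[, case_idx, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  degenerate <- v1 == 0 & v2 == 0
  if (any(degenerate)) {
    message(sum(degenerate), " gene(s) with zero variance in both groups; p set to 1")
    p[degenerate] <- 1
  }
  lfc <- m2 - m1
  fdr <- p.adjust(p, method = "BH")
  mu <- mean(lfc); s <- sd(lfc)
  direction <- rep("none", length(lfc))
  direction[fdr < fdr_cut & lfc > mu + sd_mult * s] <- "up"
  direction[fdr < fdr_cut & lfc < mu - sd_mult * s] <- "down"
  data.frame(gene = rownames(vals), log2_fold_change = lfc, p = p,
             fdr = fdr, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fisher's exact test for the overlap of two gene lists
#'
#' Builds the 2x2 table of a universe partitioned by membership in lists A
#' and B and tests association with a two-sided Fisher's exact test. The
#' headline `odds_ratio` is the conditional maximum-likelihood estimate
#' (what [stats::fisher.test()] returns); the crude sample odds ratio
#' `ad/bc` is reported alongside.
#'
#' @param list_a,list_b Character vectors of gene symbols; both must be
#'   subsets of `background`.
#' @param background Character vector, the gene universe.
#' @return A list of class `overlap_result`: counts `a` (in both), `b` (A
#'   only), `c` (B only), `d` (neither), `odds_ratio` (conditional MLE),
#'   `odds_ratio_sample`, and two-sided `p`.
#' @export
overlap_test <- function(list_a, list_b, background) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  background <- unique(background)
  extra <- setdiff(c(list_a, list_b), background)
  if (length(extra)) {
    stop("gene list members missing from background: ",
         paste(head(extra, 10), collapse = ", "))
  }
  a <- length(intersect(list_a, list_b))
  b <- length(list_a) - a
  c_ <- length(list_b) - a
  d <- length(background) - a - b - c_
  ft <- fisher.test(matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE))
  or_sample <- if (b == 0L || c_ == 0L) {
    if (a == 0L || d == 0L) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }
  if (a == 0L) or_sample <- 0
  structure(list(a = a, b = b, c = c_, d = d,
                 odds_ratio = unname(ft$estimate),
                 odds_ratio_sample = or_sample,
                 p = ft$p.value),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Gene-list overlap (Fisher's exact test)\n")
  cat(sprintf("  2x2 table: a=%d b=%d c=%d d=%d (universe %d)\n",
              x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d))
  cat(sprintf("  odds ratio (conditional MLE) = %.4g, sample = %.4g\n",
              x$odds_ratio, x$odds_ratio_sample))
  cat(sprintf("  two-sided p = %.4g\n", x$p))
  invisible(x)
}

#' Uncentered Pearson correlation between columns
#'
#' @param mat Numeric matrix; correlation is computed between columns
#'   without centering: `sum(x*y) / sqrt(sum(x^2) * sum(y^2))`.
#' @return Symmetric correlation matrix.
#' @export
uncentered_cor <- function(mat) {
  norms <- sqrt(colSums(mat^2))
  if (any(norms == 0)) {
    stop("all-zero column(s): uncentered correlation undefined for ",
         paste(colnames(mat)[norms == 0], collapse = ", "))
  }
  crossprod(mat) / outer(norms, norms)
}

#' Hierarchically cluster samples on a gene set
#'
#' Distance between samples is 1 minus the uncentered Pearson correlation
#' of their expression over `genes`; merging uses complete linkage.
#'
#' @param expr Genes x samples matrix.
#' @param genes Gene subset to cluster on (default: all rows).
#' @return An `hclust` object over samples.
#' @export
cluster_samples <- function(expr, genes = rownames(expr)) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop("genes absent from the matrix: ", paste(head(missing, 10), collapse = ", "))
  }
  if (ncol(expr) < 2L) stop("need >= 2 samples to cluster")
  sub <- expr[genes, , drop = FALSE]
  d <- 1 - uncentered_cor(sub)
  hclust(as.dist(d), method = "complete")
}

#' Write an hclust dendrogram as Newick
#'
#' @param hc An `hclust` object.
#' @param path Output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write a DegTable as TSV
#'
#' @param deg DegTable from [call_degs()].
#' @param path Output file.
#' @export
write_deg_table <- function(deg, path) {
  write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
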