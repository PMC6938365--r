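## Fully in-silico fixtures with planted ground truth: a narrowPeak
## compendium in which one factor's signals are elevated over a chosen
## target-gene set, and expression matrices in which the same targets are
## shifted in case samples. Every stage of the screen is testable against
## the plant without external downloads.

#' Construct the ground truth of a synthetic experiment
#'
#' @param planted_factor Name of the factor whose ChIP signal is elevated
#'   at the target genes.
#' @param target_genes Character vector of planted target gene symbols.
#' @param signal_scale Multiplier applied to the planted factor's signals
#'   at target genes (1 = null, no elevation).
#' @param expression_effect log2 down-shift applied to target genes in case
#'   samples.
#' @param seed Integer seed driving all randomness.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(planted_factor = "TF01",
                            target_genes = sprintf("G%04d", 1:50),
                            signal_scale = 10,
                            expression_effect = 2,
                            seed = 1) {
  stopifnot(signal_scale >= 1, expression_effect >= 0)
  structure(list(planted_factor = planted_factor,
                 target_genes = target_genes,
                 signal_scale = signal_scale,
                 expression_effect = expression_effect,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Generate a synthetic ChIP-seq peak compendium
#'
#' Lays `n_genes` genes on four chromosomes with enough spacing that
#' flanked domains never overlap, then emits peaks for `n_factors` factors
#' over 1-3 "cell types" each. Per cell type, each gene carries a peak with
#' probability `bind_prob`; signal values are log-normal (heavy right
#' tail, `meanlog = 1`, `sdlog = 0.75`, echoing the skew of real ChIP
#' signalValues while keeping a 10x planted driver separable from the
#' background tail). The planted factor's peak signals at target genes are
#' multiplied by `truth$signal_scale`; its binding probability is the same
#' as every other factor's, so at `signal_scale = 1` the plant is
#' statistically indistinguishable.
#'
#' @param n_genes Number of genes (>= 50; default 2000).
#' @param n_factors Number of factors (>= 2; default 20).
#' @param truth A `synthetic_truth`; its seed drives all randomness.
#' @param bind_prob Per-cell-type probability that a gene carries a peak
#'   (default 0.85).
#' @param out_dir Optional directory; when given, narrowPeak files, the
#'   annotation BED, a peak manifest TSV and a truth JSON are written there.
#' @return A list with `annotation` (gene table), `peaks_by_source`
#'   (factor -> list of peak data.frames), `genes`, `truth`, and -- when
#'   `out_dir` is given -- `manifest_path`, `annotation_path`,
#'   `truth_path`.
#' @export
generate_compendium <- function(n_genes = 2000, n_factors = 20,
                                truth = synthetic_truth(),
                                bind_prob = 0.85, out_dir = NULL) {
  if (n_genes < 50L) stop("n_genes must be >= 50")
  if (n_factors < 2L) stop("n_factors must be >= 2")
  genes <- sprintf("G%04d", seq_len(n_genes))
  extra <- setdiff(truth$target_genes, genes)
  if (length(extra)) {
    stop("truth target genes outside the generated gene set: ",
         paste(head(extra, 5), collapse = ", "))
  }
  set.seed(truth$seed)
  chrom <- paste0("chr", rep_len(1:4, n_genes))
  len <- sample(2000:20000, n_genes, replace = TRUE)
  start <- integer(n_genes)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    # 12 kb gaps keep 5 kb-flanked domains disjoint
    start[idx] <- cumsum(c(10000, head(len[idx], -1) + 12000))
  }
  annotation <- data.frame(chrom = chrom, start = start,
                           end = start + len, symbol = genes,
                           stringsAsFactors = FALSE)
  factors <- sprintf("TF%02d", seq_len(n_factors))
  if (!truth$planted_factor %in% factors) {
    factors[1L] <- truth$planted_factor
  }
  is_target <- genes %in% truth$target_genes
  peaks_by_source <- list()
  for (fac in factors) {
    n_cells <- sample.int(3L, 1L)
    cells <- lapply(seq_len(n_cells), function(ct) {
      bound <- runif(n_genes) < bind_prob
      sig <- rlnorm(n_genes, meanlog = 1, sdlog = 0.75)
      if (fac == truth$planted_factor) {
        sig[is_target] <- sig[is_target] * truth$signal_scale
      }
      width <- sample(200:500, n_genes, replace = TRUE)
      offset <- floor(runif(n_genes) * pmax(1, len - width))
      pk <- data.frame(chrom = chrom,
                       start = start + offset,
                       end = start + offset + width,
                       signal_value = round(sig, 4),
                       stringsAsFactors = FALSE)
      pk[bound, , drop = FALSE]
    })
    names(cells) <- paste0("cell", seq_len(n_cells))
    peaks_by_source[[fac]] <- cells
  }
  out <- list(annotation = annotation, peaks_by_source = peaks_by_source,
              genes = genes, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rows <- list()
    for (fac in names(peaks_by_source)) {
      for (ct in names(peaks_by_source[[fac]])) {
        pk <- peaks_by_source[[fac]][[ct]]
        fn <- paste0(fac, "_", ct, ".narrowPeak")
        lines <- sprintf("%s\t%d\t%d\t%s_%s_pk%d\t0\t.\t%s\t-1\t-1\t-1",
                         pk$chrom, pk$start, pk$end, fac, ct,
                         seq_len(nrow(pk)),
                         format(pk$signal_value, trim = TRUE,
                                scientific = FALSE))
        writeLines(lines, file.path(out_dir, fn))
        rows[[length(rows) + 1L]] <- data.frame(
          file_path = fn, factor = fac, cell_type = ct,
          stringsAsFactors = FALSE)
      }
    }
    manifest <- do.call(rbind, rows)
    manifest_path <- file.path(out_dir, "peaks_manifest.tsv")
    write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    annotation_path <- file.path(out_dir, "genes.bed")
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t+", annotation$chrom,
                       annotation$start, annotation$end, annotation$symbol),
               annotation_path)
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(unclass(truth), truth_path, auto_unbox = TRUE,
                         pretty = TRUE)
    out$manifest_path <- manifest_path
    out$annotation_path <- annotation_path
    out$truth_path <- truth_path
    out$dir <- out_dir
  }
  out
}

#' Default rodent-style and cohort-style expression designs
#'
#' `rodent_design()` mirrors a multi-model consortium: `n_models`
#' laboratories/models, each contributing `n_per_group` control animals and
#' `n_per_group` case animals per timepoint. `cohort_design()` mirrors a
#' human disease cohort plus an independent control cohort, with
#' probe-level output and detection p-values.
#'
#' @param n_genes Number of genes.
#' @param n_models Number of models/laboratories (rodent).
#' @param n_per_group Animals per (model, condition, timepoint) group.
#' @param timepoints Case timepoints (days).
#' @param n_case,n_control Cohort sample counts.
#' @param n_modules Number of planted co-expression archetypes (cohort).
#' @return A design list consumed by [generate_expression()].
#' @export
rodent_design <- function(n_genes = 2000, n_models = 5, n_per_group = 6,
                          timepoints = c(1, 3, 10)) {
  list(type = "rodent", n_genes = n_genes, n_models = n_models,
       n_per_group = n_per_group, timepoints = timepoints)
}

#' @rdname rodent_design
#' @export
cohort_design <- function(n_genes = 2000, n_case = 129, n_control = 55,
                          n_modules = 5) {
  list(type = "cohort", n_genes = n_genes, n_case = n_case,
       n_control = n_control, n_modules = n_modules)
}

#' Generate synthetic expression data with planted differential targets
#'
#' Baseline log2 expression per gene is N(8, 1); within-group noise is
#' N(0, 0.25). In case samples, the truth's target genes are shifted by
#' `-expression_effect` log2 units (planted repression). Cohort-style
#' output adds planted module structure (genes load on one of `n_modules`
#' sample archetypes; the targets form their own archetype) and a
#' probe-level matrix with detection p-values, two probes per gene for a
#' random 10% of genes.
#'
#' @param design From [rodent_design()] or [cohort_design()].
#' @param truth A `synthetic_truth`; seeds the generator (offset so that
#'   expression draws are independent of the compendium's).
#' @return Rodent: list with `values` (gene x sample), `meta` (sample
#'   metadata), `genes`, `truth`. Cohort: additionally `control_values`,
#'   `probe_values`, `detection_p`, `probe_symbols`.
#' @export
generate_expression <- function(design, truth = synthetic_truth()) {
  n_genes <- design$n_genes
  genes <- sprintf("G%04d", seq_len(n_genes))
  extra <- setdiff(truth$target_genes, genes)
  if (length(extra)) {
    stop("truth target genes outside the generated gene set: ",
         paste(head(extra, 5), collapse = ", "))
  }
  set.seed(truth$seed + 10000L)
  baseline <- rnorm(n_genes, mean = 8, sd = 1)
  is_target <- genes %in% truth$target_genes
  noise_sd <- 0.25
  if (identical(design$type, "rodent")) {
    if (design$n_per_group < 2L) stop("need >= 2 samples per group")
    meta <- list(); cols <- list()
    sample_no <- 0L
    for (m in seq_len(design$n_models)) {
      model <- paste0("model", m)
      for (cond in c("control", "case")) {
        tps <- if (cond == "control") NA else design$timepoints
        for (tp in tps) {
          for (i in seq_len(design$n_per_group)) {
            sample_no <- sample_no + 1L
            sid <- sprintf("S%03d", sample_no)
            mu <- baseline
            if (cond == "case") {
              mu <- mu - truth$expression_effect * is_target
            }
            cols[[sid]] <- mu + rnorm(n_genes, sd = noise_sd)
            meta[[sid]] <- data.frame(sample_id = sid, model = model,
                                      condition = cond, timepoint = tp,
                                      stringsAsFactors = FALSE)
          }
        }
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    return(list(values = values, meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
                genes = genes, truth = truth))
  }
  if (!identical(design$type, "cohort")) {
    stop("unknown design type: ", design$type)
  }
  if (design$n_case < 2L || design$n_control < 2L) {
    stop("need >= 2 samples per cohort")
  }
  # module structure: each gene loads on one sample archetype; planted
  # targets share their own archetype so they co-express
  k <- design$n_modules
  module_of <- sample.int(k, n_genes, replace = TRUE)
  module_of[is_target] <- k + 1L
  arch_case <- matrix(rnorm((k + 1L) * design$n_case, sd = 1),
                      nrow = k + 1L)
  loading <- runif(n_genes, 0.5, 1.5)
  case <- baseline - truth$expression_effect * is_target +
    loading * arch_case[module_of, , drop = FALSE] +
    matrix(rnorm(n_genes * design$n_case, sd = noise_sd), n_genes)
  rownames(case) <- genes
  colnames(case) <- sprintf("TLE%03d", seq_len(design$n_case))
  arch_ctrl <- matrix(rnorm((k + 1L) * design$n_control, sd = 1),
                      nrow = k + 1L)
  ctrl <- baseline +
    loading * arch_ctrl[module_of, , drop = FALSE] +
    matrix(rnorm(n_genes * design$n_control, sd = noise_sd), n_genes)
  rownames(ctrl) <- genes
  colnames(ctrl) <- sprintf("CTL%03d", seq_len(design$n_control))
  # probe level: 10% of genes measured by two probes; small fraction of
  # probes undetected across most samples
  dup <- sample(genes, max(1L, round(0.1 * n_genes)))
  probe_symbols <- c(setNames(genes, paste0(genes, "_p1")),
                     setNames(dup, paste0(dup, "_p2")))
  probe_values <- rbind(case,
                        case[dup, , drop = FALSE] +
                          matrix(rnorm(length(dup) * ncol(case), sd = 0.1),
                                 length(dup)))
  rownames(probe_values) <- names(probe_symbols)
  n_probes <- nrow(probe_values)
  detection_p <- matrix(runif(n_probes * ncol(case), 0, 0.04),
                        n_probes, ncol(case),
                        dimnames = dimnames(probe_values))
  undetected <- sample.int(n_probes, max(1L, round(0.05 * n_probes)))
  detection_p[undetected, ] <- runif(length(undetected) * ncol(case),
                                     0.1, 1)
  list(values = case, control_values = ctrl, probe_values = probe_values,
       detection_p = detection_p, probe_symbols = probe_symbols,
       meta = data.frame(sample_id = colnames(case), model = "cohort",
                         condition = "case", timepoint = NA,
                         stringsAsFactors = FALSE),
       genes = genes, truth = truth)
}

#' Write a synthetic expression set as TSV files
#'
#' @param sim Result of [generate_expression()].
#' @param out_dir Output directory; `expression.tsv` and `samples.tsv` are
#'   written (plus `control_expression.tsv`, `probes.tsv`,
#'   `detection_p.tsv`, `probe_symbols.tsv` for cohort-style output).
#' @return The directory, invisibly.
#' @export
write_expression_set <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv <- function(mat, path, id = "gene") {
    df <- data.frame(mat[, 0], check.names = FALSE)
    df[[id]] <- rownames(mat)
    df <- cbind(df, as.data.frame(mat, check.names = FALSE))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .write_tsv(sim$values, file.path(out_dir, "expression.tsv"))
  write.table(sim$meta, file.path(out_dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(sim$control_values)) {
    .write_tsv(sim$control_values,
               file.path(out_dir, "control_expression.tsv"))
    .write_tsv(sim$probe_values, file.path(out_dir, "probes.tsv"),
               id = "probe")
    .write_tsv(sim$detection_p, file.path(out_dir, "detection_p.tsv"),
               id = "probe")
    write.table(data.frame(probe = names(sim$probe_symbols),
                           symbol = sim$probe_symbols,
                           stringsAsFactors = FALSE),
                file.path(out_dir, "probe_symbols.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
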