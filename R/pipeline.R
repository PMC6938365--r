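## One-shot orchestration: matrix building, per-day DEG calling,
## persistence overlaps, factor enrichment, target calling and grouping,
## with a JSON run manifest recording seeds and output checksums.

#' Build, read and write a run configuration
#'
#' A `RunConfig` is a plain named list holding the input paths and the
#' thresholds of a full run; it round-trips losslessly through JSON.
#'
#' @param peaks_manifest,annotation,expr,meta,background Input paths
#'   (background optional: a gene-list file; defaults to all matrix genes).
#' @param matrix_path Optional pre-built ChIP matrix TSV (skips the
#'   build-matrix stage).
#' @param out_dir Output directory.
#' @param days Timepoints to contrast.
#' @param fdr_cut,sd_mult,flank,tail_frac,distance_cut,k,log_base
#'   Thresholds (defaults 0.05, 2, 5000, 0.05, 0.7, 10, 10).
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(peaks_manifest = NULL, annotation = NULL,
                       expr = NULL, meta = NULL, background = NULL,
                       matrix_path = NULL, out_dir = "factorscan_out",
                       days = c(1, 3, 10), fdr_cut = 0.05, sd_mult = 2,
                       flank = 5000, tail_frac = 0.05, distance_cut = 0.7,
                       k = 10, log_base = 10, seed = 1) {
  cfg <- list(peaks_manifest = peaks_manifest, annotation = annotation,
              expr = expr, meta = meta, background = background,
              matrix_path = matrix_path, out_dir = out_dir, days = days,
              fdr_cut = fdr_cut, sd_mult = sd_mult, flank = flank,
              tail_frac = tail_frac, distance_cut = distance_cut, k = k,
              log_base = log_base, seed = as.integer(seed))
  thresholds <- c("fdr_cut", "sd_mult", "flank", "tail_frac",
                  "distance_cut", "k", "log_base")
  if (any(unlist(cfg[thresholds]) <= 0)) {
    stop("all thresholds must be positive")
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg[!vapply(cfg, is.null, logical(1))])
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full screen end-to-end
#'
#' Stages: build (or load) the ChIP matrix; call DEGs per day; test
#' persistence overlaps (first vs last day, per direction); run factor
#' enrichment on the persistent up- and down-regulated sets; call
#' leading-edge targets and group co-targeting factors for each query. All
#' outputs are plain TSV/JSON under `config$out_dir`, listed with md5
#' checksums in `manifest.json`. Any stage failure aborts with the stage
#' name.
#'
#' @param config A `run_config`.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  mat <- if (!is.null(config$matrix_path)) {
    .stage("load-matrix", {
      if (!file.exists(config$matrix_path)) {
        stop("matrix file not found: ", config$matrix_path)
      }
      read_chip_matrix(config$matrix_path)
    })
  } else {
    .stage("build-matrix", {
      m <- build_chip_matrix(config$peaks_manifest, config$annotation,
                             flank = config$flank)
      write_chip_matrix(m, file.path(out, "matrix.tsv"))
      m
    })
  }
  background <- if (!is.null(config$background)) {
    .stage("background", intersect(read_gene_list(config$background),
                                   rownames(mat)))
  } else {
    rownames(mat)
  }
  expr <- .stage("read-expression", read_expression_matrix(config$expr))
  meta <- .stage("read-metadata", read_sample_metadata(config$meta))
  collapsed <- .stage("collapse", collapse_to_model_medians(expr, meta))
  degs <- list()
  for (day in config$days) {
    degs[[as.character(day)]] <- .stage(paste0("call-degs-day", day), {
      d <- call_degs(collapsed, day, sd_mult = config$sd_mult,
                     fdr_cut = config$fdr_cut)
      write_deg_table(d, file.path(out, paste0("degs_day", day, ".tsv")))
      d
    })
  }
  deg_genes <- function(day, dir) {
    d <- degs[[as.character(day)]]
    intersect(d$gene[d$direction == dir], background)
  }
  first <- config$days[1L]
  last <- config$days[length(config$days)]
  queries <- list()
  for (dir in c("up", "down")) {
    if (length(config$days) >= 2L) {
      ov <- .stage(paste0("overlap-", dir), {
        o <- overlap_test(deg_genes(first, dir), deg_genes(last, dir),
                          background)
        jsonlite::write_json(unclass(o),
                             file.path(out, paste0("overlap_", dir, ".json")),
                             auto_unbox = TRUE, digits = NA)
        o
      })
      persistent <- intersect(deg_genes(first, dir), deg_genes(last, dir))
    } else {
      persistent <- deg_genes(first, dir)
    }
    queries[[paste0("persistent_", dir)]] <- persistent
  }
  for (qname in names(queries)) {
    q <- queries[[qname]]
    if (length(q) < 2L) {
      message("query '", qname, "' has fewer than 2 genes; skipped")
      next
    }
    scores <- .stage(paste0("enrich-", qname), {
      s <- run_factor_analysis(mat, q, background,
                               tail_frac = config$tail_frac,
                               log_base = config$log_base,
                               keep_curves = TRUE)
      write_factor_scores(s, file.path(out, paste0("factors_", qname, ".tsv")))
      s
    })
    .stage(paste0("targets-", qname), {
      tsets <- factor_targets(mat, q, background, scores = scores)
      write_target_sets(tsets, file.path(out, paste0("targets_", qname, ".txt")))
      if (length(tsets) >= 2L) {
        map <- pairwise_overlap_map(tsets, q)
        write.table(data.frame(factor = rownames(map$scores), map$scores,
                               check.names = FALSE),
                    file.path(out, paste0("overlap_map_", qname, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        grp <- group_factors(map, cut = config$distance_cut)
        jsonlite::write_json(grp$groups,
                             file.path(out, paste0("groups_", qname, ".json")))
      }
    })
  }
  files <- setdiff(list.files(out), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("factorscan")),
    seed = config$seed,
    config = unclass(config),
    checksums = as.list(tools::md5sum(file.path(out, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(out)
}
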