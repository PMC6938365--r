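## Building the gene x factor ChIP signal matrix from narrowPeak files.
## Coordinates are BED-style 0-based half-open throughout; they are converted
## to 1-based closed IRanges only at the overlap step.

#' Read a narrowPeak (BED6+4) file
#'
#' Parses a tab-delimited ENCODE-style narrowPeak file and returns one row
#' per peak with the coordinates and the peak enrichment magnitude
#' (`signalValue`, column 7). Columns beyond the seventh are ignored.
#'
#' @param path Path to a narrowPeak file.
#' @return A data.frame with columns `chrom` (character), `start` (0-based
#'   inclusive), `end` (0-based exclusive) and `signal_value` (non-negative
#'   numeric). Zero rows for an empty file.
#' @examples
#' tf <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t200\tpk\t0\t.\t7.5\t-1\t-1\t50", tf)
#' read_narrowpeak(tf)
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("narrowPeak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), signal_value = numeric(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7L)) {
    stop("narrowPeak parse error in ", path, ": line ",
         which(nf < 7L)[1L], " has ", nf[which(nf < 7L)[1L]],
         " columns (>= 7 required)")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  signal <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 7L)))
  bad <- which(is.na(start) | is.na(end) | is.na(signal))
  if (length(bad)) {
    stop("narrowPeak parse error in ", path, ": line ", bad[1L],
         " has non-numeric coordinates or signalValue")
  }
  if (any(start >= end)) {
    stop("narrowPeak parse error in ", path, ": line ",
         which(start >= end)[1L], " has start >= end")
  }
  if (any(signal < 0)) {
    stop("narrowPeak parse error in ", path, ": line ",
         which(signal < 0)[1L], " has negative signalValue")
  }
  data.frame(chrom = chrom, start = start, end = end,
             signal_value = signal, stringsAsFactors = FALSE)
}

#' Build flanked gene domains from a gene annotation
#'
#' Each gene body is extended by `flank` bp on both sides to form the window
#' used for peak-to-gene assignment. Records sharing a symbol are merged to
#' the union span before flanking; the start is clamped at 0.
#'
#' @param annotation A data.frame with columns `chrom`, `start` (0-based
#'   inclusive), `end` (0-based exclusive) and `symbol`. Extra columns
#'   (score, strand) are ignored.
#' @param flank Flank size in bp added to each side of the gene body
#'   (default 5000).
#' @return A data.frame with one row per unique symbol and columns `symbol`,
#'   `chrom`, `start`, `end` (0-based half-open).
#' @export
build_gene_domains <- function(annotation, flank = 5000) {
  need <- c("chrom", "start", "end", "symbol")
  if (!all(need %in% names(annotation))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(annotation) == 0L) stop("annotation is empty")
  if (any(annotation$start >= annotation$end)) {
    stop("annotation has records with start >= end: ",
         paste(annotation$symbol[annotation$start >= annotation$end],
               collapse = ", "))
  }
  chrom_by_sym <- tapply(annotation$chrom, annotation$symbol,
                         function(ch) unique(ch), simplify = FALSE)
  multi <- names(chrom_by_sym)[lengths(chrom_by_sym) > 1L]
  if (length(multi)) {
    stop("symbol(s) annotated on multiple chromosomes: ",
         paste(multi, collapse = ", "))
  }
  sym <- unique(annotation$symbol)
  idx <- split(seq_len(nrow(annotation)), annotation$symbol)[sym]
  start <- vapply(idx, function(i) min(annotation$start[i]), numeric(1))
  end <- vapply(idx, function(i) max(annotation$end[i]), numeric(1))
  chrom <- vapply(idx, function(i) annotation$chrom[i[1L]], character(1))
  data.frame(symbol = sym, chrom = chrom,
             start = pmax(0, start - flank), end = end + flank,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign each factor its maximal ChIP signal per gene domain
#'
#' For every (gene, factor) pair, takes the maximum `signalValue` over all
#' peaks of that factor -- from any cell type -- overlapping the gene domain
#' by at least 1 bp; 0 where no peak overlaps. Peaks on chromosomes absent
#' from the annotation are ignored (a count is reported via `message()`).
#'
#' @param peaks_by_source A named list: factor name -> list of peak
#'   data.frames (one per cell type, as returned by [read_narrowpeak()]).
#' @param domains Gene domains from [build_gene_domains()].
#' @return An unnormalized numeric matrix, genes (rows, named by symbol) x
#'   factors (columns).
#' @export
assign_chip_values <- function(peaks_by_source, domains) {
  if (length(peaks_by_source) == 0L) stop("no peak sources supplied")
  if (is.null(names(peaks_by_source)) || any(!nzchar(names(peaks_by_source)))) {
    stop("peaks_by_source must be a named list (factor names)")
  }
  if (nrow(domains) == 0L) stop("domains are empty")
  dom_gr <- GenomicRanges::GRanges(
    seqnames = domains$chrom,
    ranges = IRanges::IRanges(start = domains$start + 1L, end = domains$end)
  )
  mat <- matrix(0, nrow = nrow(domains), ncol = length(peaks_by_source),
                dimnames = list(domains$symbol, names(peaks_by_source)))
  n_skipped <- 0L
  for (fac in names(peaks_by_source)) {
    sources <- peaks_by_source[[fac]]
    if (is.data.frame(sources)) sources <- list(sources)
    peaks <- do.call(rbind, sources)
    if (is.null(peaks) || nrow(peaks) == 0L) next
    known <- peaks$chrom %in% domains$chrom
    n_skipped <- n_skipped + sum(!known)
    peaks <- peaks[known, , drop = FALSE]
    if (nrow(peaks) == 0L) next
    pk_gr <- GenomicRanges::GRanges(
      seqnames = peaks$chrom,
      ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
    )
    hits <- GenomicRanges::findOverlaps(dom_gr, pk_gr, minoverlap = 1L)
    if (length(hits) == 0L) next
    best <- tapply(peaks$signal_value[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), max)
    mat[as.integer(names(best)), fac] <- as.numeric(best)
  }
  if (n_skipped > 0L) {
    message(n_skipped,
            " peak(s) on chromosomes absent from the annotation were ignored")
  }
  mat
}

#' Normalize a ChIP matrix so every factor column sums to 100,000
#'
#' The per-factor sum of signal values is arbitrary (it depends on how many
#' cell types were profiled); rescaling each column to a fixed total of
#' 100,000 makes signals comparable across factors. Factor columns that are
#' all zero carry no information and are dropped with a warning.
#'
#' @param mat Gene x factor matrix from [assign_chip_values()].
#' @param total Column total after rescaling (default 1e5).
#' @return The rescaled matrix.
#' @export
normalize_matrix <- function(mat, total = 1e5) {
  if (!is.matrix(mat) || nrow(mat) < 1L || ncol(mat) < 1L) {
    stop("matrix must have at least one gene and one factor")
  }
  if (any(mat < 0)) stop("ChIP matrix must be non-negative")
  sums <- colSums(mat)
  zero <- sums == 0
  if (any(zero)) {
    warning("dropping all-zero factor column(s): ",
            paste(colnames(mat)[zero], collapse = ", "))
    mat <- mat[, !zero, drop = FALSE]
    sums <- sums[!zero]
    if (ncol(mat) == 0L) stop("all factor columns were zero")
  }
  sweep(mat, 2L, sums / total, "/")
}

#' Export the most highly ChIPed genes of a factor as a GMT record
#'
#' Selects the `top_n` genes with the highest signal in `factor`'s column
#' (descending signal, ties broken by lexicographic symbol order) and
#' formats them as a single GMT line.
#'
#' @param mat Normalized ChIP matrix.
#' @param factor Factor (column) name.
#' @param top_n Number of genes to export (default 500).
#' @param set_name Name of the gene set; defaults to `<factor>_top<top_n>`.
#' @param description Free-text description field of the GMT record.
#' @param path Optional file to append the GMT line to.
#' @return Invisibly, the GMT line (tab-separated character scalar).
#' @export
export_top_gene_set <- function(mat, factor, top_n = 500,
                                set_name = NULL, description = "",
                                path = NULL) {
  if (!factor %in% colnames(mat)) {
    stop("unknown factor '", factor, "'; available: ",
         paste(colnames(mat), collapse = ", "))
  }
  if (top_n < 1L || top_n > nrow(mat)) {
    stop("top_n must be between 1 and the gene count (", nrow(mat), ")")
  }
  sig <- mat[, factor]
  ord <- order(-sig, rownames(mat))
  genes <- rownames(mat)[ord][seq_len(top_n)]
  if (is.null(set_name)) set_name <- paste0(factor, "_top", top_n)
  line <- paste(c(set_name, description, genes), collapse = "\t")
  if (!is.null(path)) cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(line)
}

#' Read a peak manifest (file_path, factor, cell_type)
#'
#' @param path Tab-separated manifest with header columns `file_path`,
#'   `factor`, `cell_type`. Relative `file_path`s are resolved against the
#'   manifest's directory.
#' @return A data.frame with absolute file paths.
#' @export
read_peak_manifest <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("file_path", "factor", "cell_type")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$file_path)
  m$file_path[rel] <- file.path(dirname(path), m$file_path[rel])
  m
}

#' Build a normalized ChIP matrix from a manifest and annotation
#'
#' Convenience wrapper chaining [read_peak_manifest()], [read_narrowpeak()],
#' [build_gene_domains()], [assign_chip_values()] and [normalize_matrix()].
#'
#' @param manifest Path to a peak manifest, or a data.frame already in
#'   manifest layout.
#' @param annotation Gene annotation data.frame or path to a BED-like file
#'   (chrom, start, end, symbol, optionally score and strand; no header).
#' @param flank Domain flank in bp (default 5000).
#' @return Normalized gene x factor matrix.
#' @export
build_chip_matrix <- function(manifest, annotation, flank = 5000) {
  if (is.character(manifest)) manifest <- read_peak_manifest(manifest)
  if (is.character(annotation)) annotation <- read_gene_annotation(annotation)
  peaks_by_source <- lapply(split(manifest$file_path, manifest$factor),
                            function(paths) lapply(paths, read_narrowpeak))
  domains <- build_gene_domains(annotation, flank = flank)
  normalize_matrix(assign_chip_values(peaks_by_source, domains))
}

#' Read a BED-like gene annotation (chrom, start, end, symbol)
#'
#' @param path Tab-separated file without header; columns 1-4 are chrom,
#'   start, end, symbol. Further columns are ignored.
#' @return A data.frame with columns `chrom`, `start`, `end`, `symbol`.
#' @export
read_gene_annotation <- function(path) {
  a <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(a) < 4L) stop("annotation BED needs >= 4 columns")
  data.frame(chrom = a[[1L]], start = a[[2L]], end = a[[3L]],
             symbol = a[[4L]], stringsAsFactors = FALSE)
}

#' Write / read a ChIP matrix as TSV (genes as rows, factors as columns)
#'
#' @param mat Gene x factor matrix.
#' @param path Output TSV path.
#' @export
write_chip_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chip_matrix
#' @export
read_chip_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Plain-text file, one gene symbol per line; blank lines and
#'   lines starting with `#` are skipped.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
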