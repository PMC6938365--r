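# Small in-code fixtures shared across test files.

# Write narrowPeak lines to a temp file and return the path.
write_narrowpeak_lines <- function(lines) {
  path <- tempfile(fileext = ".narrowPeak")
  writeLines(lines, path)
  path
}

# A tiny normalized matrix with a factor ("HOT") elevated on `hot_genes`.
toy_chip_matrix <- function(n_genes = 40, hot_genes = sprintf("g%02d", 1:8),
                            seed = 7) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  mat <- cbind(
    HOT = rlnorm(n_genes, 1, 1),
    COLD = rlnorm(n_genes, 1, 1),
    FLAT = rlnorm(n_genes, 1, 1)
  )
  rownames(mat) <- genes
  mat[genes %in% hot_genes, "HOT"] <- mat[genes %in% hot_genes, "HOT"] * 20
  normalize_matrix(mat)
}

# Signals arranged so a chosen query holds exact values; genes named g1..gN.
signals_with_names <- function(values) {
  setNames(values, paste0("g", seq_along(values)))
}
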