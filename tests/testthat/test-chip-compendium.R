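test_that("read_narrowpeak maps fields, handles empty files, rejects bad lines", {
  p <- write_narrowpeak_lines("chr1\t100\t200\tpk\t0\t.\t7.5\t-1\t-1\t50")
  pk <- read_narrowpeak(p)
  expect_equal(pk, data.frame(chrom = "chr1", start = 100, end = 200,
                              signal_value = 7.5, stringsAsFactors = FALSE))

  empty <- write_narrowpeak_lines(character(0))
  expect_equal(nrow(read_narrowpeak(empty)), 0L)

  short <- write_narrowpeak_lines(c("chr1\t1\t2\tpk\t0\t.\t1\t-1\t-1\t-1",
                                    "chr1\t5\t9\tx\t0"))
  expect_error(read_narrowpeak(short), "line 2")

  bad <- write_narrowpeak_lines("chr1\tabc\t200\tpk\t0\t.\t7.5")
  expect_error(read_narrowpeak(bad), "non-numeric")
})

test_that("gene domains flank by 5 kb, clamp at 0, and merge duplicate symbols", {
  ann <- data.frame(chrom = "chr1", start = 10000, end = 20000,
                    symbol = "A", stringsAsFactors = FALSE)
  d <- build_gene_domains(ann)
  expect_equal(d$start, 5000)
  expect_equal(d$end, 25000)

  near0 <- data.frame(chrom = "chr1", start = 2000, end = 3000,
                      symbol = "B", stringsAsFactors = FALSE)
  d0 <- build_gene_domains(near0)
  expect_equal(d0$start, 0)
  expect_equal(d0$end, 8000)

  dup <- data.frame(chrom = "chr2", start = c(100, 150), end = c(200, 400),
                    symbol = "G", stringsAsFactors = FALSE)
  dd <- build_gene_domains(dup)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$start, 0)   # max(0, 100 - 5000)
  expect_equal(dd$end, 5400)  # 400 + 5000

  bad <- data.frame(chrom = "chr1", start = 10, end = 10, symbol = "X")
  expect_error(build_gene_domains(bad), "start >= end")
})

test_that("assignment takes the per-domain maximum over all cell types", {
  domains <- data.frame(symbol = c("A", "B"), chrom = "chr1",
                        start = c(0, 10000), end = c(1000, 11000),
                        stringsAsFactors = FALSE)
  peaks <- list(F1 = list(
    data.frame(chrom = "chr1", start = 100, end = 200, signal_value = 5.0),
    data.frame(chrom = "chr1", start = 300, end = 400, signal_value = 8.0)
  ))
  m <- assign_chip_values(peaks, domains)
  expect_equal(m["A", "F1"], 8.0)
  expect_equal(m["B", "F1"], 0)
})

test_that("a 1-bp boundary overlap counts; off-annotation chromosomes are ignored", {
  domains <- data.frame(symbol = "A", chrom = "chr1",
                        start = 1000, end = 2000, stringsAsFactors = FALSE)
  # peak [990, 1001) overlaps [1000, 2000) by exactly 1 bp
  graze <- list(F1 = data.frame(chrom = "chr1", start = 990, end = 1001,
                                signal_value = 3.2))
  expect_equal(assign_chip_values(graze, domains)["A", "F1"], 3.2)
  # [980, 1000) touches but does not overlap under half-open coordinates
  miss <- list(F1 = data.frame(chrom = "chr1", start = 980, end = 1000,
                               signal_value = 3.2))
  expect_equal(assign_chip_values(miss, domains)["A", "F1"], 0)

  stray <- list(F1 = data.frame(chrom = c("chr1", "chrUn"),
                                start = c(1500, 10), end = c(1600, 20),
                                signal_value = c(1, 9)))
  expect_message(m <- assign_chip_values(stray, domains), "1 peak")
  expect_equal(m["A", "F1"], 1)
})

test_that("assignment equals an exhaustive peak-by-domain scan on random toys", {
  for (seed in 1:3) {
    set.seed(seed)
    domains <- data.frame(symbol = paste0("g", 1:10),
                          chrom = sample(c("chr1", "chr2"), 10, TRUE),
                          start = sample(0:5000, 10),
                          stringsAsFactors = FALSE)
    domains$end <- domains$start + sample(200:2000, 10)
    peaks <- lapply(setNames(nm = c("F1", "F2", "F3")), function(f) {
      lapply(1:2, function(ct) {
        n <- sample(5:30, 1)
        st <- sample(0:6000, n)
        data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                   start = st, end = st + sample(50:500, n, TRUE),
                   signal_value = round(rlnorm(n), 3))
      })
    })
    expect_equal(assign_chip_values(peaks, domains),
                 oracle_assign_chip(peaks, domains))
  }
})

test_that("matrix cells are invariant to peak-file read order", {
  domains <- data.frame(symbol = paste0("g", 1:5), chrom = "chr1",
                        start = (0:4) * 10000, stringsAsFactors = FALSE)
  domains$end <- domains$start + 3000
  set.seed(11)
  cells <- lapply(1:3, function(ct) {
    st <- sample(0:45000, 20)
    data.frame(chrom = "chr1", start = st, end = st + 300,
               signal_value = round(rlnorm(20), 3))
  })
  m1 <- assign_chip_values(list(F1 = cells), domains)
  m2 <- assign_chip_values(list(F1 = rev(cells)), domains)
  expect_equal(m1, m2)
})

test_that("normalization fixes every column sum at 100,000 and drops zero columns", {
  m <- cbind(A = c(2, 3, 5), B = c(1, 1, 2))
  rownames(m) <- c("g1", "g2", "g3")
  nm <- normalize_matrix(m)
  expect_equal(nm[, "A"], c(g1 = 20000, g2 = 30000, g3 = 50000))
  for (seed in 1:5) {
    set.seed(seed)
    r <- matrix(rlnorm(60), 20, 3, dimnames = list(paste0("g", 1:20), LETTERS[1:3]))
    expect_true(all(abs(colSums(normalize_matrix(r)) - 1e5) / 1e5 < 1e-9))
  }
  z <- cbind(A = c(1, 2), Z = c(0, 0))
  rownames(z) <- c("g1", "g2")
  expect_warning(nz <- normalize_matrix(z), "all-zero")
  expect_equal(colnames(nz), "A")
})

test_that("top-gene-set export orders by signal with lexicographic tie-break", {
  m <- cbind(F = c(9, 7, 7, 1))
  rownames(m) <- c("d", "c", "b", "a")
  line <- export_top_gene_set(m, "F", top_n = 2, set_name = "S", description = "x")
  expect_equal(strsplit(line, "\t")[[1]], c("S", "x", "d", "b"))
  all4 <- export_top_gene_set(m, "F", top_n = 4)
  expect_equal(strsplit(all4, "\t")[[1]][-(1:2)], c("d", "b", "c", "a"))
  expect_error(export_top_gene_set(m, "F", top_n = 0), "between 1")
  expect_error(export_top_gene_set(m, "NOPE", top_n = 1), "available")
})

test_that("manifest-driven build matches the in-memory path", {
  truth <- synthetic_truth(target_genes = sprintf("G%04d", 1:5), seed = 3)
  dir <- tempfile()
  comp <- generate_compendium(n_genes = 60, n_factors = 3, truth = truth,
                              out_dir = dir)
  m_files <- build_chip_matrix(comp$manifest_path, comp$annotation_path)
  m_mem <- normalize_matrix(assign_chip_values(
    comp$peaks_by_source, build_gene_domains(comp$annotation)))
  expect_equal(m_files, m_mem, tolerance = 1e-8)
})
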