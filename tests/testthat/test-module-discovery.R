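test_that("probe filtering, median collapse and normalization follow the recipe", {
  # 10 samples: probe p2 detected in only 1 (10% < 20%) -> dropped
  expr <- rbind(p1 = rep(4, 10), p2 = rep(9, 10), p3 = rep(6, 10),
                p4 = 1:10)
  det <- rbind(p1 = rep(0.01, 10), p2 = c(0.01, rep(0.5, 9)),
               p3 = rep(0.01, 10), p4 = rep(0.01, 10))
  colnames(expr) <- colnames(det) <- paste0("s", 1:10)
  syms <- c(p1 = "A", p2 = "B", p3 = "A", p4 = "C")
  out <- preprocess_cohort(expr, det, syms)
  expect_false("B" %in% rownames(out))
  # probes 4 and 6 for symbol A collapse to 5, then each sample is divided
  # by its median; the flat gene A drops out of the variable-gene filter
  # while the sloped gene C stays
  expect_equal(rownames(out), "C")

  set.seed(41)
  n_probes <- 1000; n_samples <- 20
  probes <- matrix(rlnorm(n_probes * n_samples, 2, 0.5), n_probes,
                   dimnames = list(sprintf("p%04d", 1:n_probes),
                                   paste0("s", 1:n_samples)))
  det <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
                dimnames = dimnames(probes))
  syms <- setNames(sprintf("G%03d", sample(500, n_probes, TRUE)),
                   rownames(probes))
  got <- preprocess_cohort(probes, det, syms)
  # independent step-by-step oracle
  keep <- rowSums(det < 0.05) / n_samples >= 0.2
  kp <- probes[keep, ]
  ks <- syms[rownames(kp)]
  coll <- t(sapply(split(seq_len(nrow(kp)), ks), function(i) {
    apply(kp[i, , drop = FALSE], 2, median)
  }))
  norm <- sweep(coll, 2, apply(coll, 2, median), "/")
  cv <- apply(norm, 1, sd) / rowMeans(norm)
  expect_equal(nrow(got), sum(cv > median(cv)))
  expect_setequal(rownames(got), rownames(norm)[cv > median(cv)])
})

test_that("k-medians with k = 1 returns the per-sample median as center", {
  set.seed(42)
  x <- matrix(rnorm(50), 10, 5, dimnames = list(paste0("g", 1:10), NULL))
  km <- kmedians(x, k = 1, seed = 1, restarts = 2)
  expect_true(all(km$assignment == 1L))
  expect_equal(as.numeric(km$centers), apply(x, 2, median))
})

test_that("well-separated planted blobs are exactly recovered at k = 2", {
  set.seed(43)
  a <- matrix(rnorm(200, mean = 0, sd = 0.3), 20, 10)
  b <- matrix(rnorm(150, mean = 5, sd = 0.3), 15, 10)
  x <- rbind(a, b)
  rownames(x) <- paste0("g", 1:35)
  km <- kmedians(x, k = 2, seed = 9, restarts = 5)
  expect_equal(length(unique(km$assignment[1:20])), 1L)
  expect_equal(length(unique(km$assignment[21:35])), 1L)
  expect_false(km$assignment[1] == km$assignment[21])
  # duplicate rows land in the same module
  expect_equal(unname(km$assignment[1]),
               unname(kmedians(rbind(x, x[1, , drop = FALSE]),
                               k = 2, seed = 9,
                               restarts = 5)$assignment[36]))
})

test_that("k-medians cost is monotone non-increasing and restarts never hurt", {
  set.seed(44)
  x <- matrix(rnorm(600), 60, 10, dimnames = list(paste0("g", 1:60), NULL))
  km <- kmedians(x, k = 4, seed = 2, restarts = 10)
  expect_true(all(diff(km$cost_trace) <= 1e-9))
  single <- kmedians(x, k = 4, seed = 2, restarts = 1)
  expect_lte(km$cost, single$cost + 1e-9)
  expect_error(kmedians(x, k = 0), "between")
  expect_error(kmedians(x, k = 61), "between")
  # determinism
  expect_equal(kmedians(x, k = 4, seed = 2, restarts = 3)$assignment,
               kmedians(x, k = 4, seed = 2, restarts = 3)$assignment)
})

test_that("module screening finds the planted factor and skips tiny modules", {
  truth <- synthetic_truth(target_genes = sprintf("G%04d", 1:25),
                           signal_scale = 10, seed = 45)
  comp <- generate_compendium(n_genes = 300, n_factors = 6, truth = truth)
  mat <- normalize_matrix(assign_chip_values(
    comp$peaks_by_source, build_gene_domains(comp$annotation)))
  assignment <- structure(list(
    k = 3,
    assignment = setNames(c(rep(1L, 25), rep(2L, 272), rep(3L, 3)),
                          rownames(mat)),
    centers = NULL, cost = NA, cost_trace = numeric(0)
  ), class = "module_assignment")
  expect_warning(screens <- module_factor_screen(mat, assignment,
                                                 rownames(mat)),
                 "M-3")
  expect_named(screens, c("M-1", "M-2"))
  expect_equal(screens[["M-1"]]$factor[1], truth$planted_factor)
  expect_lt(screens[["M-1"]]$p_corr[1], 0.05)
})

test_that("random modules rarely produce significant factors", {
  truth <- synthetic_truth(target_genes = sprintf("G%04d", 1:10),
                           signal_scale = 1, seed = 46)
  comp <- generate_compendium(n_genes = 300, n_factors = 5, truth = truth)
  mat <- normalize_matrix(assign_chip_values(
    comp$peaks_by_source, build_gene_domains(comp$annotation)))
  any_hit <- vapply(1:50, function(seed) {
    set.seed(seed)
    q <- sample(rownames(mat), 30)
    res <- run_factor_analysis(mat, q, rownames(mat))
    any(res$p_corr < 0.05, na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(!any_hit), 0.9)
})

test_that("factor presence is binarized at FDR 0.05 and clustered by column", {
  tab <- function(factors, fdrs) {
    data.frame(factor = factors, p_corr = fdrs, triaged = is.na(fdrs),
               stringsAsFactors = FALSE)
  }
  lists <- list(
    L1 = tab(c("EZH2", "SUZ12", "CTCF"), c(1e-10, 0.01, 0.5)),
    L2 = tab(c("EZH2", "SUZ12", "CTCF"), c(1e-8, 0.04, 0.9)),
    L3 = tab(c("EZH2", "SUZ12", "CTCF"), c(0.9, NA, 0.01))
  )
  fp <- factor_presence_clustering(lists)
  expect_setequal(as.vector(fp$presence), c(0L, 1L))
  expect_equal(fp$presence["EZH2", ], c(L1 = 1L, L2 = 1L, L3 = 0L))
  expect_equal(fp$presence["SUZ12", "L3"], 0L)  # triaged counts as absent
  # identical calls cluster at distance 0
  m <- fp$hclust$merge
  first <- which(fp$hclust$height == 0)
  expect_length(first, 1L)
  pair <- colnames(fp$presence)[-m[first, ]]
  expect_setequal(pair, c("L1", "L2"))
  # row order of the tables does not matter
  shuffled <- lapply(lists, function(t) t[c(3, 1, 2), ])
  expect_equal(factor_presence_clustering(shuffled)$presence, fp$presence)
})

test_that("module expression differences between cohorts are detected with direction", {
  set.seed(47)
  genes <- paste0("g", 1:100)
  a <- matrix(rnorm(100 * 30, 8, 0.5), 100, dimnames = list(genes, NULL))
  ident <- module_expression_test(genes, a, a)
  expect_gt(ident$p, 0.9)
  expect_equal(ident$direction, "none")

  b <- a - 1 + matrix(rnorm(100 * 30, 0, 0.1), 100)
  shifted <- module_expression_test(genes, a, b)
  expect_equal(shifted$direction, "lower_in_b")
  expect_lt(shifted$p, 1e-10)

  flipped <- module_expression_test(genes, b, a)
  expect_equal(flipped$direction, "higher_in_b")
  expect_equal(flipped$p, shifted$p)

  # gene order is irrelevant
  perm <- module_expression_test(sample(genes), a, b)
  expect_equal(perm$p, shifted$p)

  expect_error(module_expression_test("zz", a, b), "no module gene")
})
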