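# deconvolution: constrained least squares + tertile stratification

make_sig_fixture <- function(seed = 1) make_signature_matrix(6, 4, seed = seed)

test_that("pure and degenerate samples are recovered exactly", {
  sig <- make_sig_fixture()
  # bulk equal to column j of S (linear scale) -> fraction 1 for type j
  j <- 2
  bulk <- expression_matrix(matrix(log2(sig$profiles[, j] + 1),
                                   dimnames = list(sig$marker_gene_ids, "A"))[, 1, drop = FALSE])
  fr <- nnls_fractions(bulk, sig)
  expect_equal(as.numeric(fr[1, sig$cell_type_names[j]]), 1, tolerance = 1e-8)
  expect_equal(sum(as.numeric(fr[1, setdiff(names(fr), c("sample_id", sig$cell_type_names[j]))])),
               0, tolerance = 1e-8)

  # all-zero bulk -> everything in "other"
  zero <- expression_matrix(matrix(0, nrow = length(sig$marker_gene_ids), ncol = 1,
                                   dimnames = list(sig$marker_gene_ids, "Z")))
  fz <- nnls_fractions(zero, sig)
  expect_equal(as.numeric(fz[1, "other"]), 1)
})

test_that("noise-free mixtures are recovered within solver tolerance", {
  sig <- make_sig_fixture(3)
  set.seed(7)
  for (i in 1:10) {
    f <- rgamma(4, 2); f <- f / sum(f)
    b <- drop(sig$profiles %*% f)
    bulk <- expression_matrix(matrix(log2(b + 1), dimnames = list(sig$marker_gene_ids, "X"))[, 1, drop = FALSE])
    fr <- nnls_fractions(bulk, sig)
    expect_equal(as.numeric(fr[1, sig$cell_type_names]), f, tolerance = 1e-6)
  }
})

test_that("output rows always lie on the simplex", {
  sig <- make_sig_fixture(5)
  set.seed(8)
  vals <- matrix(runif(length(sig$marker_gene_ids) * 20, 0, 12),
                 nrow = length(sig$marker_gene_ids),
                 dimnames = list(sig$marker_gene_ids, sprintf("S%02d", 1:20)))
  fr <- nnls_fractions(expression_matrix(vals), sig)
  m <- as.matrix(fr[, -1])
  expect_true(all(m >= 0))
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
})

test_that("coverage and rank errors are informative", {
  sig <- make_sig_fixture()
  keep <- sig$marker_gene_ids[1:12]  # drops all markers of types 3 and 4
  bulk <- expression_matrix(matrix(rnorm(24, 6), nrow = 12, ncol = 2,
                                   dimnames = list(keep, c("A", "B"))))
  expect_error(nnls_fractions(bulk, sig), "no shared marker genes for cell type")

  # duplicated signature column is rank-deficient at construction
  prof <- sig$profiles
  prof[, 2] <- prof[, 1]
  expect_error(signature_matrix(prof), "rank-deficient")
})

test_that("tertile labelling: even split, ties, degenerate input", {
  sc <- setNames(as.numeric(1:9), paste0("s", 1:9))
  g <- score_tertiles(sc)
  expect_equal(sum(g == "high"), 3)
  expect_equal(sum(g == "low"), 3)
  expect_equal(sum(g == "mid"), 3)
  expect_setequal(names(g)[g == "low"], paste0("s", 1:3))

  same <- setNames(rep(1, 6), paste0("s", 1:6))
  g2 <- score_tertiles(same)
  expect_true(all(g2 == "mid"))

  expect_error(score_tertiles(setNames(1:2, c("a", "b"))), ">= 3 samples")

  # 459 distinct values: |high| and |low| fixed by the nearest-rank rule
  big <- setNames(sample(seq_len(459)), sprintf("t%03d", 1:459))
  g3 <- score_tertiles(big)
  expect_equal(sum(g3 == "low"), 152)
  expect_equal(sum(g3 == "high"), 152)
})

test_that("fraction_tertiles validates the cell type", {
  sig <- make_sig_fixture()
  set.seed(2)
  vals <- matrix(runif(length(sig$marker_gene_ids) * 9, 0, 10),
                 nrow = length(sig$marker_gene_ids),
                 dimnames = list(sig$marker_gene_ids, sprintf("S%d", 1:9)))
  fr <- nnls_fractions(expression_matrix(vals), sig)
  expect_error(fraction_tertiles(fr, "NOT_A_TYPE"), "unknown cell type")
  g <- fraction_tertiles(fr, sig$cell_type_names[1])
  expect_s3_class(g, "stratified_groups")
})
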