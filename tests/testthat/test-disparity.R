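# proteomic_disparity: paired dominance counts and the candidate filter

make_ppt <- function(normal, tumor, genes = NULL, pairs = NULL) {
  genes <- genes %||% sprintf("G%02d", seq_len(nrow(normal)))
  pairs <- pairs %||% sprintf("P%02d", seq_len(ncol(normal)))
  dimnames(normal) <- dimnames(tumor) <- list(genes, pairs)
  paired_protein_table(normal, tumor)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("count arithmetic matches the printed two-decimal convention", {
  expect_equal(disparity_from_counts("DDX60", 73, 24)$frac_normal, 75.26)
  expect_equal(disparity_from_counts("DDX60", 73, 24)$frac_cancer, 24.74)
  expect_equal(disparity_from_counts("GZMA", 77, 20)$frac_normal, 79.38)
  all_norm <- disparity_from_counts("X", 4, 0)
  expect_equal(all_norm$frac_normal, 100)
  expect_equal(all_norm$frac_cancer, 0)
})

test_that("tie policies change the denominator as documented", {
  # 10 pairs: 5 normal-dominant, 3 tumor-dominant, 2 exact ties
  normal <- matrix(c(2, 2, 2, 2, 2, 1, 1, 1, 5, 5), nrow = 1)
  tumor <- matrix(c(1, 1, 1, 1, 1, 2, 2, 2, 5, 5), nrow = 1)
  ppt <- make_ppt(normal, tumor, genes = "G1")

  d <- disparity(ppt, "G1")  # default exclude
  expect_equal(d$n_pairs_used, 8L)
  expect_equal(d$n_high_normal, 5L)
  expect_equal(d$frac_normal, round(100 * 5 / 8, 2))

  expect_equal(disparity(ppt, "G1", tie_policy = "cancer")$n_high_cancer, 5L)
  expect_equal(disparity(ppt, "G1", tie_policy = "normal")$n_high_normal, 7L)

  all_tied <- make_ppt(matrix(1, 1, 4), matrix(1, 1, 4), genes = "G1")
  expect_error(disparity(all_tied, "G1"), "no informative pairs")
  expect_error(disparity(ppt, "MISSING"), "absent")
})

test_that("antisymmetry: swapping normal and tumor swaps the counts", {
  set.seed(3)
  nm <- matrix(rnorm(60, 10), 5, 12)
  tm <- matrix(rnorm(60, 10), 5, 12)
  a <- disparity_table(make_ppt(nm, tm))
  b <- disparity_table(make_ppt(tm, nm))
  expect_equal(a$n_high_normal, b$n_high_cancer)
  expect_equal(a$frac_normal, b$frac_cancer)
})

test_that("fractions are invariant to strictly monotone transforms", {
  set.seed(4)
  nm <- matrix(rnorm(40, 5, 2), 4, 10)
  tm <- matrix(rnorm(40, 5, 2), 4, 10)
  f <- function(x) exp(x / 3) + x  # strictly increasing
  a <- disparity_table(make_ppt(nm, tm))
  b <- disparity_table(make_ppt(f(nm), f(tm)))
  expect_equal(a$frac_normal, b$frac_normal)
  expect_equal(a$n_pairs_used, b$n_pairs_used)
})

test_that("candidate filter keeps screen/DE members above the cut, ranked", {
  disp <- rbind(
    disparity_from_counts("AAA", 80, 17),   # 82.47, in screen+DE
    disparity_from_counts("BBB", 70, 27),   # 72.16, in screen only
    disparity_from_counts("CCC", 75, 22),   # 77.32, in screen+DE
    disparity_from_counts("DDD", 40, 57),   # below cut
    disparity_from_counts("EEE", 90, 7))    # not in screen
  screen_genes <- c("AAA", "BBB", "CCC", "DDD")
  de <- c("AAA", "CCC", "DDD", "EEE")
  out <- filter_candidates(screen_genes, disp, de, min_frac_normal = 70)
  expect_identical(out$gene_id, c("AAA", "CCC"))

  # min_frac_normal = 0 keeps every intersected gene, ranked by fraction
  out0 <- filter_candidates(screen_genes, disp, de, min_frac_normal = 0)
  expect_identical(out0$gene_id, c("AAA", "CCC", "DDD"))
  expect_true(!is.unsorted(rev(out0$frac_normal)))
})

test_that("planted high-disparity genes occupy the top ranks", {
  tr <- synthetic_truth(n_samples = 30, planted_regulators = sprintf("R%02d", 1:5),
                        disparity_prob = 0.75, seed = 5)
  b <- make_bulk_dataset(tr, n_noise_genes = 60, n_pairs = 97)
  d <- disparity_table(b$protein)
  d <- d[order(-d$frac_normal, d$gene_id), ]
  top10 <- d$gene_id[1:10]
  expect_gte(sum(tr$planted_regulators %in% top10), 4)
})

test_that("shipped printed counts are self-consistent (HLA-DMB excepted)", {
  tab <- crc_disparity_counts()
  expect_equal(nrow(tab), 32)
  ok <- tab$gene_id != "HLA-DMB"
  recomputed <- do.call(rbind, Map(disparity_from_counts,
                                   tab$gene_id[ok], tab$n_high_normal[ok],
                                   tab$n_high_cancer[ok]))
  expect_equal(recomputed$frac_normal, tab$frac_normal[ok])
  expect_equal(recomputed$frac_cancer, tab$frac_cancer[ok])
  expect_true(all(recomputed$n_pairs_used == 97))
})
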