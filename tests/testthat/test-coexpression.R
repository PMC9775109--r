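# coexpression_screen: Pearson with p, per-anchor screen, intersections

test_that("pearson_with_p matches the closed form and the t reference", {
  expect_equal(pearson_with_p(c(1, 2, 3), c(2, 4, 6)), list(r = 1, p = 0, n = 3))
  expect_equal(pearson_with_p(1:4, 4:1)$r, -1)

  x <- c(1, 2, 3, 4, 5); y <- c(1, 3, 2, 5, 4)
  got <- pearson_with_p(x, y)
  expect_equal(got$r, 0.8)
  # frozen from t = r*sqrt((n-2)/(1-r^2)) = 2.309401 on 3 df
  expect_equal(got$p, 0.1040880, tolerance = 1e-6)
  # dual route: agree with stats::cor.test
  ref <- cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  expect_error(pearson_with_p(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_with_p(1:2, 1:2), ">= 3")
})

test_that("screen_anchor honors thresholds, excludes the anchor, skips constants", {
  ex <- tiny_expr(10, 25, seed = 3)
  hits <- screen_anchor(ex, "G01", r_min = 0, p_max = 1)
  expect_setequal(hits, setdiff(ex$gene_ids, "G01"))
  expect_error(screen_anchor(ex, "NOPE"), "absent")

  vals <- ex$values
  vals["G05", ] <- 4  # constant gene
  ex2 <- expression_matrix(vals)
  expect_warning(hits2 <- screen_anchor(ex2, "G01", r_min = 0, p_max = 1),
                 "zero-variance")
  expect_false("G05" %in% hits2)
})

test_that("intersect_many equals a brute-force membership scan", {
  expect_identical(intersect_many(list(c("A", "B", "C"), c("B", "C", "D"))), c("B", "C"))
  expect_identical(intersect_many(list(c("C", "A"))), c("A", "C"))

  set.seed(10)
  universe <- sprintf("g%03d", 1:500)
  sets <- lapply(1:6, function(i) sample(universe, 100))
  expect_identical(intersect_many(sets), intersect_oracle(sets, universe))
})

test_that("run_screen: nested chain, signature no-op, monotonicity, permutation", {
  tr <- synthetic_truth(n_samples = 120, coupling = 0.85, seed = 6)
  b <- make_bulk_dataset(tr, n_noise_genes = 80)
  res <- run_screen(b$expression, anchor_panel(), b$signature_set)

  expect_true(all(res$signature_overlap %in% res$mhc_tap_common))
  expect_true(all(res$mhc_tap_common %in% res$mhc_common))
  expect_true(all(res$mhc_tap_common %in% res$tap_common))
  anchors <- c(res$panel$mhc_anchors, res$panel$tap_anchors)
  expect_false(any(anchors %in% unlist(res$per_anchor_hits)))

  # signature covering the whole universe is a no-op on the overlap
  uni <- gene_set("UNIVERSE", b$expression$gene_ids)
  res_u <- run_screen(b$expression, anchor_panel(), uni)
  expect_identical(res_u$signature_overlap, res_u$mhc_tap_common)

  # raising r_min / lowering p_max never adds genes
  strict <- run_screen(b$expression, anchor_panel(), b$signature_set,
                       r_min = 0.5, p_max = 0.01)
  for (a in names(strict$per_anchor_hits))
    expect_true(all(strict$per_anchor_hits[[a]] %in% res$per_anchor_hits[[a]]))
  expect_true(all(strict$signature_overlap %in% res$signature_overlap))

  # over-strict threshold empties downstream sets
  empty <- run_screen(b$expression, anchor_panel(), b$signature_set, r_min = 0.999)
  expect_length(empty$signature_overlap, 0)

  # consistent sample permutation leaves every hit set unchanged
  perm <- sample(b$expression$sample_ids)
  resp <- run_screen(expression_matrix(b$expression$values[, perm]),
                     anchor_panel(), b$signature_set)
  expect_identical(resp$per_anchor_hits, res$per_anchor_hits)
})

test_that("noise genes at n = 459 essentially never pass the r > 0.3 screen", {
  tr <- synthetic_truth(n_samples = 459, planted_regulators = "REG01", seed = 8)
  b <- make_bulk_dataset(tr, n_noise_genes = 400)
  res <- run_screen(b$expression, anchor_panel(), b$signature_set)
  noise_hits <- grep("^NOISE", unlist(res$per_anchor_hits), value = TRUE)
  # analytic null tail at |r| > 0.3, n = 459 is ~1e-11 per gene/anchor
  expect_length(noise_hits, 0)
})
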