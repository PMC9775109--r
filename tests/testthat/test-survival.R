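# survival_prognosis: KM, log-rank, stratification, horizon ROC

test_that("KM closed forms: no events, all events", {
  all_cens <- clinical_table(paste0("s", 1:5), time = c(3, 8, 1, 9, 2), event = rep(0, 5))
  km <- km_estimate(all_cens)
  expect_length(km$event_times, 0)

  all_ev <- clinical_table(paste0("s", 1:3), time = c(1, 2, 3), event = c(1, 1, 1))
  km2 <- km_estimate(all_ev)
  expect_equal(km2$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km2$at_risk, c(3L, 2L, 1L))
  expect_error(km_estimate(all_ev[0, ]), "empty")
})

test_that("KM equals brute-force risk-set recomputation and survfit", {
  cl <- tiny_clinical(20, seed = 7)
  km <- km_estimate(cl)
  orc <- km_oracle(cl$time, cl$event)
  expect_equal(km$event_times, orc$event_times)
  expect_equal(km$survival, orc$survival)
  # step values are non-increasing, within [0, 1]
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))

  sf <- survival::survfit(survival::Surv(cl$time, cl$event) ~ 1)
  expect_equal(km$survival, summary(sf, times = km$event_times)$surv, tolerance = 1e-12)

  # with no censoring, KM at the last event time = empirical fraction
  nc <- clinical_table(paste0("x", 1:15), time = sort(runif(15, 1, 50)), event = rep(1, 15))
  kmn <- km_estimate(nc)
  expect_equal(kmn$survival[length(kmn$survival)], 0)
  mid <- kmn$event_times[7]
  expect_equal(kmn$survival[7], mean(nc$time > mid))
})

test_that("log-rank: degenerate identity, symmetry, oracle, survdiff", {
  cl <- tiny_clinical(20, seed = 3)
  same <- logrank(cl, cl)
  expect_equal(same$chi_square, 0)
  expect_equal(same$p, 1)

  a <- tiny_clinical(14, seed = 4); b <- tiny_clinical(17, seed = 5)
  ab <- logrank(a, b); ba <- logrank(b, a)
  expect_equal(ab$chi_square, ba$chi_square)
  expect_equal(ab$p, ba$p)
  expect_equal(sum(ab$observed), sum(ab$expected), tolerance = 1e-9)

  orc <- logrank_oracle(a$time, a$event, b$time, b$event)
  expect_equal(ab$chi_square, orc$chi_square)
  expect_equal(ab$p, orc$p)

  sd <- survival::survdiff(survival::Surv(c(a$time, b$time), c(a$event, b$event)) ~
                             rep(1:2, c(nrow(a), nrow(b))))
  expect_equal(ab$chi_square, sd$chisq, tolerance = 1e-9)

  expect_error(logrank(a[0, ], b), "non-empty")
  expect_error(logrank(clinical_table("s1", 5, 0), clinical_table("s2", 6, 0)),
               "at least one event")
})

test_that("log-rank is invariant under common monotone time transforms", {
  a <- tiny_clinical(15, seed = 9); b <- tiny_clinical(15, seed = 10)
  ref <- logrank(a, b)
  tf <- function(cl) clinical_table(cl$sample_id, sqrt(cl$time) + log1p(cl$time), cl$event)
  tr <- logrank(tf(a), tf(b))
  expect_equal(tr$chi_square, ref$chi_square)
})

test_that("combined stratification: identity, disjoint error, expected size", {
  set.seed(12)
  n <- 900
  s1 <- setNames(rnorm(n), sprintf("s%03d", 1:n))
  s2 <- setNames(rnorm(n), sprintf("s%03d", 1:n))
  g1 <- score_tertiles(s1); g2 <- score_tertiles(s2)
  comb <- combined_stratify(g1, g2)
  # independent tertiles: |high| ~ n/9 = 100; allow 4 binomial sd
  expect_lt(abs(sum(comb == "high") - n / 9), 4 * sqrt(n * (1 / 9) * (8 / 9)))

  expect_identical(as.character(combined_stratify(g1, g1)), as.character(g1))

  # disjoint highs -> stratum empty error
  inv <- setNames(-s1, names(s1))
  ginv <- score_tertiles(inv)
  expect_error(combined_stratify(g1, ginv), "stratum empty")
})

test_that("ROC: perfect, constant, pair-counting oracle, monotone invariance", {
  cl <- clinical_table(sprintf("p%02d", 1:20),
                       time = c(seq(5, 50, length.out = 10), seq(70, 120, length.out = 10)),
                       event = rep(c(1, 0), each = 10))
  # higher score protective: give controls the high scores
  perfect <- setNames(c(seq_len(10), 100 + seq_len(10)), cl$sample_id)
  expect_equal(prognostic_roc(perfect, cl, horizon = 60)$auc, 1)

  constant <- setNames(rep(1, 20), cl$sample_id)
  expect_equal(prognostic_roc(constant, cl, horizon = 60)$auc, 0.5)

  set.seed(21)
  cl2 <- tiny_clinical(50, seed = 21)
  score <- setNames(rnorm(50) + 0.02 * cl2$time, cl2$sample_id)
  roc <- prognostic_roc(score, cl2, horizon = 40)
  case <- cl2$event == 1 & cl2$time <= 40
  ctrl <- cl2$time > 40
  keep <- case | ctrl
  expect_equal(roc$auc, auc_oracle(-score[keep], case[keep]))
  # curve anchored at (0,0) and (1,1), both coordinates non-decreasing
  expect_equal(unlist(roc$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc$points[nrow(roc$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$points$fpr) >= 0) && all(diff(roc$points$tpr) >= 0))

  mono <- setNames(exp(score / 2), names(score))
  expect_equal(prognostic_roc(mono, cl2, horizon = 40)$auc, roc$auc)

  expect_error(prognostic_roc(score, cl2, horizon = 1e6), "no controls")
})

test_that("tertile log-rank has power when the planted hazard effect is large", {
  rej <- vapply(1:5, function(seed) {
    tr <- synthetic_truth(n_samples = 459, hazard_beta = 1, seed = seed)
    b <- make_bulk_dataset(tr, n_noise_genes = 5)
    g <- score_tertiles(b$anchor_score)
    compare_strata(b$clinical, g)$p < 0.05
  }, logical(1))
  expect_true(all(rej))
})
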