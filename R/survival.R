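# Kaplan-Meier estimation, Mantel-Cox log-rank testing, tertile and
# combined two-marker stratification, and fixed-horizon prognostic
# ROC/AUC. Implemented from the standard formulas:
#
#   S(t) = prod_{t_i <= t} (1 - d_i / n_i)
#
# over distinct event times t_i with d_i events among n_i at risk; subjects
# censored at time c leave the risk set after c (events at a tied time are
# processed before censorings, the standard convention). The two-group
# log-rank statistic uses the hypergeometric moments at each event time:
#   e_Aj = n_Aj d_j / n_j,
#   v_j  = d_j (n_j - d_j) n_Aj n_Bj / (n_j^2 (n_j - 1)),
#   chi^2 = (sum o_Aj - sum e_Aj)^2 / sum v_j,  1 df.

#' Kaplan-Meier survival curve
#'
#' @param clinical a [clinical_table] (or subset of one).
#' @return a `km_curve`: list with `event_times` (distinct, increasing),
#'   `survival` (non-increasing step values), `at_risk`, `n_events`, and
#'   `n` (subjects).
#' @export
km_estimate <- function(clinical) {
  if (nrow(clinical) < 1L) stop_("empty clinical subset")
  tm <- clinical$time; ev <- clinical$event
  tt <- sort(unique(tm[ev == 1]))
  n <- length(tm)
  s <- 1
  surv <- at_risk <- d <- numeric(length(tt))
  for (i in seq_along(tt)) {
    # events at a tied time precede censorings: at risk = time >= t
    at_risk[i] <- sum(tm >= tt[i])
    d[i] <- sum(tm == tt[i] & ev == 1)
    s <- s * (1 - d[i] / at_risk[i])
    surv[i] <- s
  }
  structure(list(event_times = tt, survival = surv,
                 at_risk = as.integer(at_risk), n_events = as.integer(d),
                 n = n),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d subjects, %d distinct event times\n",
              x$n, length(x$event_times)))
  invisible(x)
}

#' Mantel-Cox log-rank test for two groups
#'
#' @param groupA,groupB [clinical_table] subsets (non-empty, >= 1 event
#'   overall).
#' @return a `logrank_result`: `chi_square`, `df` (1), `p`, and per-group
#'   `observed` / `expected` event counts.
#' @export
logrank <- function(groupA, groupB) {
  if (nrow(groupA) < 1L || nrow(groupB) < 1L) stop_("both groups must be non-empty")
  tm <- c(groupA$time, groupB$time)
  ev <- c(groupA$event, groupB$event)
  grp <- rep(c("A", "B"), c(nrow(groupA), nrow(groupB)))
  if (sum(ev) < 1L) stop_("log-rank needs at least one event")
  tt <- sort(unique(tm[ev == 1]))
  oA <- eA <- v <- numeric(length(tt))
  for (i in seq_along(tt)) {
    at <- tm >= tt[i]
    nj <- sum(at)
    nA <- sum(at & grp == "A")
    dj <- sum(tm == tt[i] & ev == 1)
    dA <- sum(tm == tt[i] & ev == 1 & grp == "A")
    oA[i] <- dA
    eA[i] <- nA * dj / nj
    v[i] <- if (nj > 1) dj * (nj - dj) * nA * (nj - nA) / (nj^2 * (nj - 1)) else 0
  }
  V <- sum(v)
  if (V <= 0) stop_("log-rank variance is zero (degenerate risk sets)")
  chi <- (sum(oA) - sum(eA))^2 / V
  obs <- c(A = sum(oA), B = sum(ev) - sum(oA))
  expd <- c(A = sum(eA), B = sum(ev) - sum(eA))
  structure(list(chi_square = chi, df = 1L,
                 p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 observed = obs, expected = expd),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi^2 = %.4f (df = %d), p = %.4g\n",
              x$chi_square, x$df, x$p))
  invisible(x)
}

#' Tertile groups on an expression-derived per-sample score
#'
#' The score is either a single gene's log2 expression or the unweighted
#' mean log2 expression of a gene set (used for the HLA-A/B/C composite).
#'
#' @param expr an [expression_matrix].
#' @param genes one gene id or several (averaged).
#' @inheritParams score_tertiles
#' @return a `stratified_groups` labelling (see [score_tertiles()]).
#' @export
expression_tertiles <- function(expr, genes, lower = 33, upper = 67) {
  stopifnot(inherits(expr, "expression_matrix"))
  missing <- setdiff(genes, expr$gene_ids)
  if (length(missing)) stop_("gene(s) absent: %s", paste(missing, collapse = ", "))
  sc <- if (length(genes) == 1L) expr$values[genes, ]
        else colMeans(expr$values[genes, , drop = FALSE])
  score_tertiles(sc, lower = lower, upper = upper)
}

#' Combine two stratifications (both-high vs both-low)
#'
#' `high` = high on both scores; `low` = low on both; every other sample is
#' excluded (`mid`). Used for the "MHC-I high AND T-cell infiltration
#' high" comparison.
#'
#' @param groups1,groups2 `stratified_groups` over the same sample universe.
#' @return a `stratified_groups` labelling.
#' @export
combined_stratify <- function(groups1, groups2) {
  if (!setequal(names(groups1), names(groups2)))
    stop_("stratifications cover different sample universes")
  g2 <- groups2[names(groups1)]
  lab <- rep("mid", length(groups1))
  names(lab) <- names(groups1)
  lab[groups1 == "high" & g2 == "high"] <- "high"
  lab[groups1 == "low" & g2 == "low"] <- "low"
  if (!any(lab == "high")) stop_("stratum empty: no sample is high on both scores")
  if (!any(lab == "low")) stop_("stratum empty: no sample is low on both scores")
  structure(lab, class = "stratified_groups")
}

#' Log-rank comparison of the high vs low strata of a labelling
#'
#' @param clinical a [clinical_table] covering the labelled samples.
#' @param groups a `stratified_groups` labelling.
#' @return a `logrank_result` comparing high vs low (mid excluded).
#' @export
compare_strata <- function(clinical, groups) {
  idx <- match(names(groups), clinical$sample_id)
  if (anyNA(idx)) stop_("labelled sample(s) missing from clinical table")
  hi <- clinical[idx[groups == "high"], , drop = FALSE]
  lo <- clinical[idx[groups == "low"], , drop = FALSE]
  if (nrow(hi) == 0L || nrow(lo) == 0L)
    stop_("high/low strata must both be non-empty (all-mid stratification?)")
  logrank(hi, lo)
}

#' Fixed-horizon prognostic ROC and AUC
#'
#' Cases are subjects with an observed event within the horizon; controls
#' are subjects followed beyond the horizon without an event by then.
#' Subjects censored before the horizon are excluded (no inverse-
#' probability weighting). The score is assumed PROTECTIVE (higher score,
#' better survival) and is negated before the threshold sweep, so AUC > 0.5
#' means the score separates cases from controls in the protective
#' direction. AUC is the trapezoid area, identical to the normalized
#' Mann-Whitney statistic.
#'
#' @param score named numeric vector of per-sample scores.
#' @param clinical a [clinical_table] covering the scored samples.
#' @param horizon_months classification horizon (default 60 = 5-year
#'   survival).
#' @param higher_protective set `FALSE` if a higher score predicts death.
#' @return a `roc_result`: data frame of `(fpr, tpr)` points from (0,0) to
#'   (1,1), plus `auc`, `horizon_months`, `n_cases`, `n_controls`.
#' @export
prognostic_roc <- function(score, clinical, horizon_months = 60,
                           higher_protective = TRUE) {
  idx <- match(names(score), clinical$sample_id)
  if (anyNA(idx)) stop_("scored sample(s) missing from clinical table")
  tm <- clinical$time[idx]; ev <- clinical$event[idx]
  case <- ev == 1 & tm <= horizon_months
  control <- tm > horizon_months
  keep <- case | control
  if (!any(case)) stop_("no cases (events within the horizon)")
  if (!any(control)) stop_("no controls (followed beyond the horizon)")
  y <- case[keep]
  s <- if (higher_protective) -score[keep] else score[keep]
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  n_case <- sum(y); n_ctrl <- sum(!y)
  # sweep thresholds at distinct score values (ties move together)
  brk <- c(which(diff(s) != 0), length(s))
  tpr <- c(0, cumsum(y)[brk] / n_case)
  fpr <- c(0, cumsum(!y)[brk] / n_ctrl)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc, horizon_months = horizon_months,
                 n_cases = as.integer(n_case), n_controls = as.integer(n_ctrl)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d cases, %d controls, %g-month horizon)\n",
              x$auc, x$n_cases, x$n_controls, x$horizon_months))
  invisible(x)
}

#' Write a KM curve as a step table
#' @param x a `km_curve`.
#' @param path output path.
#' @export
write_km <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", provenance_comment()), con)
  writeLines("time\tsurvival\tat_risk\tn_events", con)
  writeLines(sprintf("%s\t%s\t%d\t%d", num_chr(x$event_times),
                     num_chr(x$survival), x$at_risk, x$n_events), con)
  invisible(path)
}

#' Write an ROC point table with its AUC
#' @param x a `roc_result`.
#' @param path output path.
#' @export
write_roc <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", provenance_comment()), con)
  writeLines(sprintf("# auc=%s horizon_months=%s n_cases=%d n_controls=%d",
                     num_chr(x$auc), num_chr(x$horizon_months),
                     x$n_cases, x$n_controls), con)
  writeLines("fpr\ttpr", con)
  writeLines(sprintf("%s\t%s", num_chr(x$points$fpr), num_chr(x$points$tpr)), con)
  invisible(path)
}
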