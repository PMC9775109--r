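# The candidate-discovery core: correlate every gene against the MHC-I/TAP
# anchor panel (HLA-A, HLA-B, HLA-C, B2M; TAP1, TAP2), keep genes passing
# |r| > r_min and p < p_max (strict inequalities, matching the published
# thresholds r > 0.3 or < -0.3 and p < 0.05), intersect the per-anchor hit
# sets, and overlap the result with an interferon-gamma signature.
#
# Anchors are excluded from every hit set: a candidate regulator is by
# definition not a member of the panel, and self-correlation r = 1 is
# uninformative. No multiple-testing correction is applied by default,
# mirroring the raw p < 0.05 rule; Benjamini-Hochberg is available as an
# option.

#' Define the anchor panel for the co-expression screen
#'
#' @param mhc_anchors MHC-I component genes (heavy chains + B2M light chain).
#' @param tap_anchors peptide-transport genes.
#' @return an `anchor_panel` object.
#' @export
anchor_panel <- function(mhc_anchors = c("HLA-A", "HLA-B", "HLA-C", "B2M"),
                         tap_anchors = c("TAP1", "TAP2")) {
  mhc_anchors <- as.character(mhc_anchors)
  tap_anchors <- as.character(tap_anchors)
  if (!length(mhc_anchors) || !length(tap_anchors))
    stop_("both anchor groups must be non-empty")
  if (length(intersect(mhc_anchors, tap_anchors)))
    stop_("MHC and TAP anchor groups must be disjoint")
  if (anyDuplicated(c(mhc_anchors, tap_anchors)))
    stop_("duplicate anchor id")
  structure(list(mhc_anchors = mhc_anchors, tap_anchors = tap_anchors),
            class = "anchor_panel")
}

all_anchors <- function(panel) c(panel$mhc_anchors, panel$tap_anchors)

#' Pearson correlation with a two-sided p-value
#'
#' r is the product-moment coefficient; the p-value comes from the t
#' statistic `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. `|r| = 1` returns `p = 0`.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with elements `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_("x and y must have equal length")
  if (n < 3L) stop_("correlation needs >= 3 observations")
  if (anyNA(x) || anyNA(y)) stop_("missing values in correlation input")
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sum(xc^2); sy <- sum(yc^2)
  if (sx == 0 || sy == 0) stop_("zero variance in correlation input")
  r <- sum(xc * yc) / sqrt(sx * sy)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

# Correlation of every gene row against one anchor row, vectorized.
# Returns a data.frame of correlation records; zero-variance genes are
# dropped with a single warning.
anchor_correlations <- function(expr, anchor) {
  if (!anchor %in% expr$gene_ids) stop_("anchor '%s' absent from expression matrix", anchor)
  X <- expr$values
  n <- ncol(X)
  if (n < 3L) stop_("correlation needs >= 3 samples")
  a <- X[anchor, ]
  if (stats::var(a) == 0) stop_("anchor '%s' has zero variance", anchor)
  keep <- rownames(X) != anchor
  G <- X[keep, , drop = FALSE]
  gvar <- rowSums((G - rowMeans(G))^2)
  if (any(gvar == 0)) {
    warn_("skipping %d zero-variance gene(s) for anchor %s", sum(gvar == 0), anchor)
    G <- G[gvar > 0, , drop = FALSE]
    gvar <- gvar[gvar > 0]
  }
  ac <- a - mean(a)
  r <- drop((G - rowMeans(G)) %*% ac) / sqrt(gvar * sum(ac^2))
  r <- pmax(-1, pmin(1, r))
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps)),
                            df = n - 2))
  data.frame(gene_id = rownames(G), anchor_id = anchor, r = r, p = p, n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen one anchor: genes passing the correlation thresholds
#'
#' @param expr an [expression_matrix].
#' @param anchor anchor gene id (must be present in `expr`).
#' @param r_min absolute-correlation threshold; strict (`|r| > r_min`).
#' @param p_max p-value threshold; strict (`p < p_max`).
#' @param adjust `"none"` (default, raw p-values) or `"BH"`
#'   (Benjamini-Hochberg across the genes tested for this anchor).
#' @return character vector of passing gene ids (anchor excluded).
#' @export
screen_anchor <- function(expr, anchor, r_min = 0.3, p_max = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  rec <- anchor_correlations(expr, anchor)
  p <- if (adjust == "BH") stats::p.adjust(rec$p, method = "BH") else rec$p
  rec$gene_id[abs(rec$r) > r_min & p < p_max]
}

#' Intersect several gene sets
#'
#' @param sets list of character vectors (or [gene_set] objects).
#' @return character vector: the exact intersection, order-independent
#'   (returned sorted).
#' @export
intersect_many <- function(sets) {
  if (!length(sets)) stop_("need at least one set")
  sets <- lapply(sets, function(s) if (inherits(s, "gene_set")) s$members else as.character(s))
  out <- sets[[1L]]
  for (s in sets[-1L]) out <- intersect(out, s)
  sort(unique(out))
}

#' Run the full anchor-panel co-expression screen
#'
#' Per-anchor hit sets are intersected within the MHC-I group and within
#' the TAP group; their intersection is then overlapped with the supplied
#' signature. The nested-subset chain
#' `signature_overlap <= mhc_tap_common <= mhc_common  (and tap_common)`
#' holds by construction and is asserted.
#'
#' @param expr an [expression_matrix] containing all anchors.
#' @param panel an [anchor_panel].
#' @param signature a [gene_set] (e.g. an interferon-gamma response
#'   signature) used as the pathway filter.
#' @inheritParams screen_anchor
#' @return a `screen_result` with per-anchor hits, the intersection sets,
#'   and the full correlation-record table.
#' @export
run_screen <- function(expr, panel = anchor_panel(), signature,
                       r_min = 0.3, p_max = 0.05, adjust = c("none", "BH")) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(panel, "anchor_panel"),
            inherits(signature, "gene_set"))
  adjust <- match.arg(adjust)
  anchors <- all_anchors(panel)
  missing <- setdiff(anchors, expr$gene_ids)
  if (length(missing))
    stop_("anchor(s) absent from expression matrix: %s", paste(missing, collapse = ", "))
  records <- do.call(rbind, lapply(anchors, function(a) anchor_correlations(expr, a)))
  hits <- lapply(anchors, function(a) {
    rec <- records[records$anchor_id == a, ]
    p <- if (adjust == "BH") stats::p.adjust(rec$p, method = "BH") else rec$p
    setdiff(rec$gene_id[abs(rec$r) > r_min & p < p_max], anchors)
  })
  names(hits) <- anchors
  mhc_common <- intersect_many(hits[panel$mhc_anchors])
  tap_common <- intersect_many(hits[panel$tap_anchors])
  mhc_tap_common <- sort(intersect(mhc_common, tap_common))
  signature_overlap <- sort(intersect(mhc_tap_common, signature$members))
  stopifnot(all(signature_overlap %in% mhc_tap_common),
            all(mhc_tap_common %in% mhc_common),
            all(mhc_tap_common %in% tap_common),
            !any(anchors %in% unlist(hits)))
  structure(list(per_anchor_hits = hits,
                 mhc_common = mhc_common,
                 tap_common = tap_common,
                 mhc_tap_common = mhc_tap_common,
                 signature_overlap = signature_overlap,
                 records = records,
                 panel = panel,
                 r_min = r_min, p_max = p_max, adjust = adjust),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  for (a in names(x$per_anchor_hits))
    cat(sprintf("  %-8s %5d hits\n", a, length(x$per_anchor_hits[[a]])))
  cat(sprintf("  MHC-I common: %d | TAP common: %d | both: %d | in signature: %d\n",
              length(x$mhc_common), length(x$tap_common),
              length(x$mhc_tap_common), length(x$signature_overlap)))
  invisible(x)
}

#' Write screen outputs (hit lists, intersections, correlation table)
#'
#' @param x a `screen_result`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_screen <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (a in names(x$per_anchor_hits))
    writeLines(x$per_anchor_hits[[a]], file.path(dir, paste0("hits_", gsub("[^A-Za-z0-9]", "_", a), ".txt")))
  writeLines(x$mhc_common, file.path(dir, "mhc_common.txt"))
  writeLines(x$tap_common, file.path(dir, "tap_common.txt"))
  writeLines(x$mhc_tap_common, file.path(dir, "mhc_tap_common.txt"))
  writeLines(x$signature_overlap, file.path(dir, "signature_overlap.txt"))
  rec <- x$records
  con <- file(file.path(dir, "correlations.tsv"), "w")
  writeLines(paste0("# ", provenance_comment(),
                    sprintf(" | r_min=%g p_max=%g adjust=%s", x$r_min, x$p_max, x$adjust)), con)
  writeLines("gene_id\tanchor_id\tr\tp\tn", con)
  writeLines(sprintf("%s\t%s\t%s\t%s\t%d", rec$gene_id, rec$anchor_id,
                     num_chr(rec$r), num_chr(rec$p), rec$n), con)
  close(con)
  invisible(dir)
}
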