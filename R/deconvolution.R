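# Constrained least-squares immune-cell deconvolution.
#
# The mixing model is linear in cell abundance: the bulk profile of a
# sample over marker genes is modeled as S f, where S is a non-negative
# signature matrix (marker genes x cell types) and f >= 0 are the cell-type
# fractions. Because expression matrices in this package are log2-scale,
# bulk values are un-logged (2^x - 1) before solving. Per sample we solve
#   min || S f - b ||^2   subject to f >= 0
# by the Lawson-Hanson active-set algorithm, then close the composition
# with an "other" (uncharacterized cells) component: other = 1 - sum(f)
# clipped at 0; if sum(f) > 1 the fractions are rescaled to sum to 1.

#' Construct a validated cell-type signature matrix
#'
#' @param profiles non-negative numeric matrix, marker genes x cell types,
#'   linear-scale expression; rownames = marker gene ids, colnames = cell
#'   type names. Must have full column rank and no all-zero column.
#' @return a `signature_matrix` object.
#' @export
signature_matrix <- function(profiles) {
  if (!is.matrix(profiles) || !is.numeric(profiles))
    stop_("signature profiles must be a numeric matrix")
  if (is.null(rownames(profiles)) || is.null(colnames(profiles)))
    stop_("signature matrix needs marker rownames and cell-type colnames")
  if (anyDuplicated(rownames(profiles))) stop_("duplicate marker gene id")
  if (anyDuplicated(colnames(profiles))) stop_("duplicate cell type name")
  if (any(profiles < 0)) stop_("signature profiles must be non-negative")
  zero <- colSums(profiles) == 0
  if (any(zero))
    stop_("all-zero signature column(s): %s",
          paste(colnames(profiles)[zero], collapse = ", "))
  if (qr(profiles)$rank < ncol(profiles))
    stop_("signature matrix is rank-deficient (%d types, rank %d)",
          ncol(profiles), qr(profiles)$rank)
  structure(list(marker_gene_ids = rownames(profiles),
                 cell_type_names = colnames(profiles),
                 profiles = profiles),
            class = "signature_matrix")
}

#' Read a signature matrix (markers x cell types, tab-separated)
#' @param path file path; first column marker gene id, header = cell types.
#' @return a [signature_matrix].
#' @export
read_signature <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  signature_matrix(m)
}

#' Write a signature matrix
#' @param x a [signature_matrix].
#' @param path output path.
#' @export
write_signature <- function(x, path) {
  write_tsv_matrix(x$profiles, path, id_col = "marker_gene_id")
}

# Lawson-Hanson non-negative least squares: min ||A x - b||^2, x >= 0.
nnls_solve <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  passive <- logical(n)
  x <- numeric(n)
  w <- drop(crossprod(A, b - A %*% x))
  it <- 0L; maxit <- 50L * n
  while (any(!passive) && any(w[!passive] > tol) && it < maxit) {
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      it <- it + 1L
      s <- numeric(n)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) { x <- s; break }
      viol <- passive & (s <= tol)
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * (s - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
      if (it >= maxit) break
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

#' Estimate immune-cell fractions by non-negative least squares
#'
#' For each sample, the bulk profile restricted to the signature's marker
#' genes (un-logged to the linear scale) is decomposed against the
#' signature matrix under a non-negativity constraint, and the residual
#' mass is assigned to an `"other"` (uncharacterized cells) column so each
#' row lies on the simplex.
#'
#' @param bulk an [expression_matrix] (log2 scale).
#' @param sig a [signature_matrix] (linear scale).
#' @return a `fraction_table`: data frame with `sample_id`, one column per
#'   cell type, and `other`; rows are non-negative and sum to 1.
#' @export
nnls_fractions <- function(bulk, sig) {
  stopifnot(inherits(bulk, "expression_matrix"), inherits(sig, "signature_matrix"))
  shared <- intersect(sig$marker_gene_ids, bulk$gene_ids)
  S <- sig$profiles[shared, , drop = FALSE]
  # a cell type is covered only if at least one of the genes where it is
  # the DOMINANT type (row maximum) is shared with the bulk matrix
  dominant <- max.col(sig$profiles, ties.method = "first")
  covered <- vapply(seq_len(ncol(sig$profiles)), function(j) {
    mk <- sig$marker_gene_ids[dominant == j]
    any(mk %in% shared)
  }, logical(1))
  if (!all(covered))
    stop_("no shared marker genes for cell type(s): %s",
          paste(sig$cell_type_names[!covered], collapse = ", "))
  if (length(shared) < ncol(S) || qr(S)$rank < ncol(S))
    stop_("shared-marker signature submatrix is rank-deficient")
  B <- 2^bulk$values[shared, , drop = FALSE] - 1
  B[B < 0] <- 0
  n_types <- ncol(S)
  frac <- matrix(0, nrow = length(bulk$sample_ids), ncol = n_types + 1L,
                 dimnames = list(NULL, c(sig$cell_type_names, "other")))
  for (i in seq_along(bulk$sample_ids)) {
    b <- B[, i]
    f <- if (all(b == 0)) numeric(n_types) else nnls_solve(S, b)
    tot <- sum(f)
    if (tot > 1) {
      f <- f / tot
      oth <- 0
    } else {
      oth <- 1 - tot
    }
    frac[i, ] <- c(f, oth)
  }
  out <- data.frame(sample_id = bulk$sample_ids, frac,
                    check.names = FALSE, stringsAsFactors = FALSE)
  structure(out, class = c("fraction_table", "data.frame"))
}

#' Write / read a fraction table
#' @param x a `fraction_table`.
#' @param path file path.
#' @export
write_fractions <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", provenance_comment()), con)
  writeLines(paste(names(x), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(x$sample_id[i], num_chr(as.numeric(x[i, -1L]))), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_fractions
#' @export
read_fractions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  structure(df, class = c("fraction_table", "data.frame"))
}

#' Tertile stratification of samples by a numeric score
#'
#' Samples at or above the 67th nearest-rank percentile are labelled
#' `"high"`, at or below the 33rd percentile `"low"`, all others `"mid"`
#' (excluded by downstream survival comparisons). When the two cutpoints
#' coincide (massive ties), affected samples fall to `"mid"`: ties are
#' resolved conservatively, away from the extreme groups.
#'
#' @param score named numeric vector (names = sample ids).
#' @param lower,upper percentile cutpoints (defaults 33 and 67).
#' @return a `stratified_groups` object: named character vector of labels
#'   in `{"high","low","mid"}`.
#' @export
score_tertiles <- function(score, lower = 33, upper = 67) {
  if (is.null(names(score))) stop_("score must be named by sample id")
  if (length(score) < 3L) stop_("tertile stratification needs >= 3 samples")
  if (anyNA(score)) stop_("score contains missing values")
  srt <- sort(score)
  n <- length(srt)
  cut_low <- srt[max(1L, ceiling(n * lower / 100))]
  cut_high <- srt[max(1L, ceiling(n * upper / 100))]
  lab <- rep("mid", n)
  names(lab) <- names(score)
  lab[score <= cut_low] <- "low"
  lab[score >= cut_high] <- "high"
  # overlap (cut_low == cut_high, or tied values spanning both cuts) -> mid
  if (cut_high <= cut_low) {
    lab[score >= cut_high & score <= cut_low] <- "mid"
  }
  structure(lab, class = "stratified_groups")
}

#' Tertile groups on a deconvolved cell-type fraction
#'
#' @param fractions a `fraction_table` from [nnls_fractions()].
#' @param cell_type name of the cell-type column to stratify on.
#' @inheritParams score_tertiles
#' @return a `stratified_groups` labelling (see [score_tertiles()]).
#' @export
fraction_tertiles <- function(fractions, cell_type, lower = 33, upper = 67) {
  stopifnot(inherits(fractions, "fraction_table"))
  if (!cell_type %in% names(fractions))
    stop_("unknown cell type '%s'; available: %s", cell_type,
          paste(setdiff(names(fractions), "sample_id"), collapse = ", "))
  sc <- fractions[[cell_type]]
  names(sc) <- fractions$sample_id
  score_tertiles(sc, lower = lower, upper = upper)
}
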