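# Readers/writers and validated containers for the tabular formats the
# pipeline touches: log2 expression matrices, clinical tables, paired
# tumor/normal protein tables, and GMT gene-set files (GSEA dialect).
#
# All on-disk tables are tab-separated text. Writers prepend '#'-prefixed
# header comment lines recording the tool version and parameters; readers
# skip them. Gene identifiers are matched case-sensitively and no alias
# resolution is attempted.

#' Construct a validated expression matrix
#'
#' @param values numeric matrix (genes x samples) of log2-scale expression,
#'   with unique rownames (gene ids) and colnames (sample ids).
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_("expression values must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop_("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(gid))
    stop_("duplicate gene id: %s", gid[duplicated(gid)][1])
  if (anyDuplicated(sid))
    stop_("duplicate sample id: %s", sid[duplicated(sid)][1])
  if (anyNA(values)) stop_("expression matrix contains missing values")
  structure(list(gene_ids = gid, sample_ids = sid, values = values),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (log2 scale)\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Read a log2 expression matrix from tab-separated text
#'
#' First column holds gene ids, the header row holds sample ids. Lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @param missing_policy what to do with genes carrying missing values:
#'   `"drop_gene"` (default; removes the gene and reports the count) or
#'   `"error"`.
#' @param log2_transform if `TRUE`, apply `log2(x + 1)` on load (for inputs
#'   still on the linear scale). Default `FALSE`: values are assumed to be
#'   log2 already.
#' @return an [expression_matrix].
#' @export
read_expression <- function(path, missing_policy = c("drop_gene", "error"),
                            log2_transform = FALSE) {
  missing_policy <- match.arg(missing_policy)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop_("expression file needs a gene column plus >=1 sample: %s", path)
  gid <- df[[1L]]
  if (anyDuplicated(gid))
    stop_("duplicate gene id in %s: %s", path, gid[duplicated(gid)][1])
  raw <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(vals <- array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) & !is.na(raw) & !(raw %in% c("NA", "NaN", "")),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop_("non-numeric value '%s' at row %d (gene %s), column %d in %s",
          raw[bad[1, 1], bad[1, 2]], bad[1, 1], gid[bad[1, 1]], bad[1, 2], path)
  }
  dimnames(vals) <- list(gid, colnames(raw))
  if (anyNA(vals)) {
    drop <- unique(which(is.na(vals), arr.ind = TRUE)[, 1L])
    if (missing_policy == "error")
      stop_("missing values in %d gene(s), first: %s", length(drop), gid[drop[1]])
    message(sprintf("read_expression: dropped %d gene(s) with missing values", length(drop)))
    vals <- vals[-drop, , drop = FALSE]
  }
  if (log2_transform) vals <- log2(vals + 1)
  expression_matrix(vals)
}

#' Write an expression matrix to tab-separated text
#'
#' @param x an [expression_matrix].
#' @param path output path.
#' @param comment optional extra header comment lines (without the `#`).
#' @export
write_expression <- function(x, path, comment = character()) {
  stopifnot(inherits(x, "expression_matrix"))
  write_tsv_matrix(x$values, path, id_col = "gene_id", comment = comment)
}

write_tsv_matrix <- function(m, path, id_col, comment = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in c(provenance_comment(), comment))
    writeLines(paste0("# ", cm), con)
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], num_chr(m[i, ])), collapse = "\t"), character(1))
  writeLines(body, con)
  invisible(path)
}

provenance_comment <- function() {
  sprintf("mhcscreen %s", as.character(utils::packageVersion("mhcscreen")))
}

#' Construct a gene set
#'
#' @param name set name.
#' @param members character vector of gene ids; duplicates are removed with
#'   a warning.
#' @param description free-text description.
#' @return a `gene_set` object.
#' @export
gene_set <- function(name, members, description = "") {
  members <- as.character(members)
  if (!length(members)) stop_("gene set '%s' has no members", name)
  if (anyDuplicated(members)) {
    warn_("gene set '%s': %d duplicate member(s) removed", name,
          sum(duplicated(members)))
    members <- unique(members)
  }
  structure(list(name = as.character(name),
                 description = as.character(description),
                 members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' GSEA dialect: one set per line -- name, description, then one or more
#' members, tab-separated.
#'
#' @param path file path.
#' @return a named list of [gene_set] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop_("GMT line %d has %d field(s); need name, description, >=1 member",
            i, length(f))
    sets[[i]] <- gene_set(f[1], f[-(1:2)], description = f[2])
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_set] or list of them.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a clinical table
#'
#' @param sample_ids unique sample identifiers.
#' @param time non-negative follow-up time in months.
#' @param event event indicator: 1 = death observed, 0 = censored.
#' @return a `clinical_table` data frame.
#' @export
clinical_table <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop_("duplicate sample id: %s", sample_ids[duplicated(sample_ids)][1])
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) != length(sample_ids) || length(event) != length(sample_ids))
    stop_("sample_ids, time and event must have equal length")
  if (anyNA(time) || any(time < 0)) stop_("survival time must be >= 0 and non-missing")
  if (!all(event %in% c(0, 1))) stop_("event must be 0 (censored) or 1 (death)")
  structure(data.frame(sample_id = sample_ids, time = time, event = as.integer(event),
                       stringsAsFactors = FALSE),
            class = c("clinical_table", "data.frame"))
}

#' Read a clinical table (sample, time in months, event flag)
#'
#' @param path tab-separated file with columns `sample_id`, `time`, `event`.
#' @return a [clinical_table].
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop_("clinical file %s must have columns: %s", path, paste(need, collapse = ", "))
  clinical_table(df$sample_id, df$time, df$event)
}

#' Write a clinical table
#' @param x a [clinical_table].
#' @param path output path.
#' @export
write_clinical <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", provenance_comment()), con)
  writeLines("sample_id\ttime\tevent", con)
  writeLines(sprintf("%s\t%s\t%d", x$sample_id, num_chr(x$time), x$event), con)
  invisible(path)
}

#' Construct a paired tumor/normal protein abundance table
#'
#' @param normal_values numeric matrix (genes x pairs) of normal-tissue
#'   abundance; rownames = gene ids, colnames = pair ids.
#' @param tumor_values matching matrix of tumor abundance.
#' @return a `paired_protein_table` object.
#' @export
paired_protein_table <- function(normal_values, tumor_values) {
  for (m in list(normal_values, tumor_values))
    if (!is.matrix(m) || !is.numeric(m)) stop_("protein values must be numeric matrices")
  if (!identical(dim(normal_values), dim(tumor_values)))
    stop_("normal and tumor matrices differ in shape")
  if (!identical(rownames(normal_values), rownames(tumor_values)))
    stop_("normal and tumor gene ids disagree")
  if (!identical(colnames(normal_values), colnames(tumor_values)))
    stop_("normal and tumor pair ids disagree")
  if (is.null(rownames(normal_values)) || is.null(colnames(normal_values)))
    stop_("protein matrices need gene rownames and pair colnames")
  if (anyDuplicated(rownames(normal_values)))
    stop_("duplicate gene id in protein table")
  if (anyDuplicated(colnames(normal_values)))
    stop_("duplicate pair id in protein table")
  structure(list(gene_ids = rownames(normal_values),
                 pair_ids = colnames(normal_values),
                 normal_values = normal_values,
                 tumor_values = tumor_values),
            class = "paired_protein_table")
}

#' @export
print.paired_protein_table <- function(x, ...) {
  cat(sprintf("<paired_protein_table> %d genes x %d tumor/normal pairs\n",
              length(x$gene_ids), length(x$pair_ids)))
  invisible(x)
}

#' Read a paired tumor/normal protein table from two matched files
#'
#' Both files are gene-by-pair tab-separated matrices (first column gene id,
#' header = pair ids) and must agree on gene and pair indexing.
#'
#' @param path_normal path to the normal-tissue abundance matrix.
#' @param path_tumor path to the tumor abundance matrix.
#' @return a [paired_protein_table].
#' @export
read_paired_protein <- function(path_normal, path_tumor) {
  rd <- function(p) {
    df <- utils::read.delim(p, sep = "\t", comment.char = "#",
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop_("non-numeric protein values in %s", p)
    rownames(m) <- df[[1L]]
    m
  }
  nm <- rd(path_normal); tm <- rd(path_tumor)
  if (!identical(rownames(nm), rownames(tm)))
    stop_("gene ids disagree between %s and %s", path_normal, path_tumor)
  if (!identical(colnames(nm), colnames(tm)))
    stop_("pair ids disagree between %s and %s", path_normal, path_tumor)
  paired_protein_table(nm, tm)
}

#' Write a paired protein table to two matched files
#' @param x a [paired_protein_table].
#' @param path_normal,path_tumor output paths.
#' @export
write_paired_protein <- function(x, path_normal, path_tumor) {
  write_tsv_matrix(x$normal_values, path_normal, id_col = "gene_id")
  write_tsv_matrix(x$tumor_values, path_tumor, id_col = "gene_id")
  invisible(c(path_normal, path_tumor))
}
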