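# Synthetic-data generator: every pipeline input with known planted
# structure, so each stage has a ground-truth recovery test without any
# external download.
#
# The stated world:
#   * bulk expression on marker genes = signature %*% t(fractions) with
#     Dirichlet cell-type fractions, log2-transformed, plus gaussian noise;
#   * the six anchor genes (HLA-A/B/C, B2M, TAP1, TAP2) share a latent
#     per-sample factor L ~ N(0,1);
#   * planted regulator genes are coupled to L with a chosen population
#     correlation: g = coupling * L + sqrt(1 - coupling^2) * z;
#   * noise genes are independent gaussians;
#   * survival times are exponential with rate lambda0 * exp(-beta * score)
#     where score is the standardized mean anchor expression, with
#     independent uniform censoring tuned for ~30% censoring at beta = 0;
#   * in the paired protein table each pair is normal-dominant with a
#     per-gene probability (the planted disparity probability), the
#     dominant side sitting one abundance unit above the other.
#
# One user seed fans out to fixed per-component substreams
# (substream_seed), so enlarging one component never perturbs another.

#' Planted ground truth for a synthetic dataset
#'
#' @param n_samples number of tumor samples (>= 20 for survival realism).
#' @param cell_types names of the admixed cell types (>= 2).
#' @param planted_regulators ids of the planted regulator genes.
#' @param coupling population correlation (in (0,1)) between each planted
#'   gene and the anchors' latent factor; recycled per gene.
#' @param hazard_beta log-hazard decrease per unit of the standardized
#'   prognostic score (positive = protective anchors).
#' @param disparity_prob probability that a tumor/normal protein pair is
#'   normal-dominant for a planted gene (background genes sit at 0.5).
#' @param dirichlet_alpha symmetric Dirichlet concentration for the
#'   cell-type fractions.
#' @param seed integer seed; all randomness fans out from it.
#' @return a `synthetic_truth` object (fractions rows on the simplex).
#' @export
synthetic_truth <- function(n_samples = 459,
                            cell_types = c("B", "CD4T", "CD8T", "DC", "M1",
                                           "Mono", "Neutro", "NK", "Treg"),
                            planted_regulators = c("REG01", "REG02", "REG03"),
                            coupling = 0.8,
                            hazard_beta = 0.5,
                            disparity_prob = 0.75,
                            dirichlet_alpha = 2,
                            seed = 1L) {
  if (n_samples < 20L) stop_("n_samples must be >= 20 for survival realism")
  if (length(cell_types) < 2L) stop_("need >= 2 cell types")
  if (any(coupling <= 0 | coupling >= 1)) stop_("coupling must lie in (0,1)")
  if (any(disparity_prob < 0 | disparity_prob > 1)) stop_("disparity_prob must lie in [0,1]")
  coupling <- rep_len(coupling, length(planted_regulators))
  names(coupling) <- planted_regulators
  set.seed(substream_seed(seed, 1L))
  g <- matrix(stats::rgamma(n_samples * length(cell_types), shape = dirichlet_alpha),
              nrow = n_samples)
  fr <- g / rowSums(g)
  colnames(fr) <- cell_types
  rownames(fr) <- sprintf("S%04d", seq_len(n_samples))
  stopifnot(all(abs(rowSums(fr) - 1) < 1e-9), all(fr >= 0))
  structure(list(planted_regulators = planted_regulators,
                 coupling_strength = coupling,
                 true_fractions = fr,
                 hazard_beta = hazard_beta,
                 disparity_prob = disparity_prob,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Synthetic cell-type signature matrix
#'
#' Each cell type receives `n_markers_per_type` dedicated markers drawn
#' lognormal with the location shifted `fold`-fold above the off-target
#' level, giving a well-conditioned full-column-rank matrix.
#'
#' @param n_markers_per_type markers per cell type.
#' @param n_types number of cell types (>= 2).
#' @param seed integer seed.
#' @param type_names optional cell-type names (defaults `CT1..CTk`).
#' @param fold on-target over off-target abundance fold (default 32).
#' @param base_mean off-target linear abundance location (default 2).
#' @param sdlog lognormal spread (default 0.3).
#' @return a [signature_matrix].
#' @export
make_signature_matrix <- function(n_markers_per_type, n_types, seed = 1L,
                                  type_names = NULL, fold = 32,
                                  base_mean = 2, sdlog = 0.3) {
  if (n_types < 2L) stop_("n_types must be >= 2")
  type_names <- type_names %||% sprintf("CT%d", seq_len(n_types))
  stopifnot(length(type_names) == n_types)
  set.seed(substream_seed(seed, 0L))
  m <- n_markers_per_type * n_types
  prof <- matrix(stats::rlnorm(m * n_types, meanlog = log(base_mean), sdlog = sdlog),
                 nrow = m, ncol = n_types)
  rn <- character(m)
  for (j in seq_len(n_types)) {
    rows <- (j - 1L) * n_markers_per_type + seq_len(n_markers_per_type)
    prof[rows, j] <- stats::rlnorm(n_markers_per_type,
                                   meanlog = log(base_mean * fold), sdlog = sdlog)
    rn[rows] <- sprintf("%s_M%02d", type_names[j], seq_len(n_markers_per_type))
  }
  dimnames(prof) <- list(rn, type_names)
  signature_matrix(prof)
}

#' Generate the full synthetic input bundle
#'
#' Produces the bulk log2 expression matrix (markers + anchors + planted
#' regulators + noise genes), the clinical table, the paired protein
#' table, plus a synthetic interferon-gamma-style signature gene set and a
#' differentially-expressed-protein gene set that both contain the planted
#' regulators.
#'
#' @param truth a [synthetic_truth].
#' @param anchors an [anchor_panel]; anchor ids must not collide with
#'   planted regulator ids.
#' @param sig optional [signature_matrix]; generated when `NULL`.
#' @param n_markers_per_type markers per type when generating `sig`.
#' @param n_noise_genes independent background genes.
#' @param noise_sd gaussian noise sd (log2 scale) on marker mixtures.
#' @param anchor_loading latent-factor loading of each anchor.
#' @param anchor_noise_sd anchor-specific noise sd.
#' @param n_pairs tumor/normal protein pairs (default 97).
#' @param lambda0 baseline hazard (default `log(2)/60`: 60-month median).
#' @param censor_max upper bound of the uniform censoring window; default
#'   `3.2 / lambda0`, giving ~30% censoring under the null.
#' @param signature_size member count of the synthetic pathway signature.
#' @param seed defaults to the truth's seed.
#' @return list with `expression`, `clinical`, `protein`, `signature`
#'   (the deconvolution signature matrix), `signature_set`, `de_set`,
#'   `latent`, `anchor_score`, `truth`.
#' @export
make_bulk_dataset <- function(truth, anchors = anchor_panel(), sig = NULL,
                              n_markers_per_type = 10, n_noise_genes = 500,
                              noise_sd = 0.5, anchor_loading = 1,
                              anchor_noise_sd = 0.5, n_pairs = 97,
                              lambda0 = log(2) / 60, censor_max = NULL,
                              signature_size = 250, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(anchors, "anchor_panel"))
  fr <- truth$true_fractions
  n <- nrow(fr)
  types <- colnames(fr)
  anc <- all_anchors(anchors)
  planted <- truth$planted_regulators
  noise_ids <- sprintf("NOISE%04d", seq_len(n_noise_genes))
  if (length(intersect(anc, c(planted, noise_ids))))
    stop_("anchor ids overlap planted/noise gene ids")
  if (length(intersect(planted, noise_ids)))
    stop_("planted regulator ids overlap noise gene ids")
  if (is.null(sig))
    sig <- make_signature_matrix(n_markers_per_type, length(types),
                                 seed = seed, type_names = types)
  if (length(intersect(sig$marker_gene_ids, c(anc, planted, noise_ids))))
    stop_("marker gene ids overlap anchor/planted/noise ids")
  samples <- rownames(fr)

  # marker genes: linear mixture, log2, gaussian noise
  set.seed(substream_seed(seed, 2L))
  mix <- sig$profiles %*% t(fr)                     # markers x samples, linear
  marker_expr <- log2(mix + 1) +
    matrix(stats::rnorm(length(mix), 0, noise_sd), nrow = nrow(mix))

  # anchors: shared latent factor
  set.seed(substream_seed(seed, 3L))
  L <- stats::rnorm(n)
  anchor_mu <- stats::runif(length(anc), 7, 10)
  anchor_expr <- matrix(0, nrow = length(anc), ncol = n,
                        dimnames = list(anc, samples))
  for (i in seq_along(anc))
    anchor_expr[i, ] <- anchor_mu[i] + anchor_loading * L +
      stats::rnorm(n, 0, anchor_noise_sd)

  # planted regulators: coupled to L with the stated population correlation
  set.seed(substream_seed(seed, 4L))
  planted_expr <- matrix(0, nrow = length(planted), ncol = n,
                         dimnames = list(planted, samples))
  planted_mu <- stats::runif(length(planted), 5, 8)
  for (i in seq_along(planted)) {
    rho <- truth$coupling_strength[i]
    planted_expr[i, ] <- planted_mu[i] +
      rho * L + sqrt(1 - rho^2) * stats::rnorm(n)
  }

  # background noise genes
  set.seed(substream_seed(seed, 5L))
  noise_mu <- stats::runif(n_noise_genes, 2, 10)
  noise_expr <- matrix(stats::rnorm(n_noise_genes * n), nrow = n_noise_genes) + noise_mu
  dimnames(noise_expr) <- list(noise_ids, samples)

  vals <- rbind(marker_expr, anchor_expr, planted_expr, noise_expr)
  colnames(vals) <- samples
  expr <- expression_matrix(vals)

  # survival: exponential hazard tied to the standardized mean anchor score
  set.seed(substream_seed(seed, 6L))
  score <- colMeans(anchor_expr)
  score <- (score - mean(score)) / stats::sd(score)
  rate <- lambda0 * exp(-truth$hazard_beta * score)
  t_true <- stats::rexp(n, rate = rate)
  censor_max <- censor_max %||% (3.2 / lambda0)
  cens <- stats::runif(n, 0, censor_max)
  clinical <- clinical_table(samples,
                             time = pmax(pmin(t_true, cens), .Machine$double.eps),
                             event = as.integer(t_true <= cens))

  # paired protein table over all non-marker genes
  set.seed(substream_seed(seed, 7L))
  prot_genes <- c(anc, planted, noise_ids)
  pprob <- stats::setNames(rep(0.5, length(prot_genes)), prot_genes)
  pprob[planted] <- rep_len(truth$disparity_prob, length(planted))
  pair_ids <- sprintf("P%03d", seq_len(n_pairs))
  tumor <- matrix(stats::rnorm(length(prot_genes) * n_pairs, 10, 1),
                  nrow = length(prot_genes),
                  dimnames = list(prot_genes, pair_ids))
  normal_dom <- matrix(stats::runif(length(prot_genes) * n_pairs),
                       nrow = length(prot_genes)) < pprob
  shift <- 1  # only the sign pattern matters to the disparity statistic
  normal <- tumor + ifelse(normal_dom, shift, -shift)
  protein <- paired_protein_table(normal, tumor)

  # synthetic pathway signature + DE-protein set, both containing planted
  set.seed(substream_seed(seed, 8L))
  extra <- sample(noise_ids, min(signature_size - length(planted), n_noise_genes))
  signature_set <- gene_set("IFNG_RESPONSE_SYNTHETIC", c(planted, extra),
                            description = "synthetic interferon-gamma-style signature")
  de_extra <- sample(noise_ids, min(200L, n_noise_genes))
  de_set <- gene_set("DE_PROTEINS_SYNTHETIC", unique(c(planted, de_extra)),
                     description = "synthetic differentially expressed proteins")

  list(expression = expr, clinical = clinical, protein = protein,
       signature = sig, signature_set = signature_set, de_set = de_set,
       latent = stats::setNames(L, samples),
       anchor_score = stats::setNames(score, samples),
       truth = truth)
}

#' Write a synthetic input bundle to a directory
#'
#' Emits `expression.tsv`, `clinical.tsv`, `protein_normal.tsv`,
#' `protein_tumor.tsv`, `signature_matrix.tsv`, `signature.gmt`,
#' `de_genes.txt`, and a `truth.json` sidecar recording the planted truth.
#'
#' @param bundle output of [make_bulk_dataset()].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(bundle$expression, file.path(dir, "expression.tsv"))
  write_clinical(bundle$clinical, file.path(dir, "clinical.tsv"))
  write_paired_protein(bundle$protein, file.path(dir, "protein_normal.tsv"),
                       file.path(dir, "protein_tumor.tsv"))
  write_signature(bundle$signature, file.path(dir, "signature_matrix.tsv"))
  write_gmt(list(bundle$signature_set, bundle$de_set), file.path(dir, "signature.gmt"))
  writeLines(bundle$de_set$members, file.path(dir, "de_genes.txt"))
  tr <- bundle$truth
  jsonlite::write_json(
    list(planted_regulators = tr$planted_regulators,
         coupling_strength = as.list(tr$coupling_strength),
         hazard_beta = tr$hazard_beta,
         disparity_prob = tr$disparity_prob,
         seed = tr$seed,
         n_samples = nrow(tr$true_fractions),
         cell_types = colnames(tr$true_fractions)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
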