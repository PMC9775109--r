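# End-to-end orchestration: simulate (or load) -> deconvolve -> screen ->
# disparity -> survival -> ROC, writing every intermediate artifact plus a
# manifest under one run directory. Outputs carry no timestamps, so an
# identical config and seed reproduces a byte-identical run directory.

#' Build a run configuration
#'
#' Flat list of every knob the pipeline uses. When `simulate = TRUE` the
#' inputs are generated by [make_bulk_dataset()]; otherwise the `*_path`
#' entries must point at existing files.
#'
#' @param seed integer seed governing all randomness.
#' @param simulate generate synthetic inputs (default) or read from paths.
#' @param n_samples,n_noise_genes,coupling,hazard_beta,disparity_prob,noise_sd,n_pairs
#'   synthetic-world parameters (see [synthetic_truth()] /
#'   [make_bulk_dataset()]).
#' @param planted_regulators planted regulator ids for simulation.
#' @param r_min,p_max screen thresholds (strict; defaults 0.3 and 0.05).
#' @param min_frac_normal disparity filter threshold in percent (default 70).
#' @param tertile_lower,tertile_upper tertile percentile cutpoints.
#' @param roc_horizon ROC horizon in months (default 60).
#' @param tie_policy proteomic tie policy (default `"exclude"`).
#' @param mhc_anchors,tap_anchors anchor panel.
#' @param mhc_score_genes genes averaged into the MHC-I composite score.
#' @param tcell_types deconvolved fractions summed into the T-cell score.
#' @param expression_path,clinical_path,protein_normal_path,protein_tumor_path,signature_matrix_path,signature_gmt_path,signature_name,de_genes_path
#'   input locations when `simulate = FALSE`.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       simulate = TRUE,
                       n_samples = 459L,
                       n_noise_genes = 500L,
                       planted_regulators = c("REG01", "REG02", "REG03"),
                       coupling = 0.8,
                       hazard_beta = 0.5,
                       disparity_prob = 0.75,
                       noise_sd = 0.5,
                       n_pairs = 97L,
                       r_min = 0.3, p_max = 0.05,
                       min_frac_normal = 70,
                       tertile_lower = 33, tertile_upper = 67,
                       roc_horizon = 60,
                       tie_policy = "exclude",
                       mhc_anchors = c("HLA-A", "HLA-B", "HLA-C", "B2M"),
                       tap_anchors = c("TAP1", "TAP2"),
                       mhc_score_genes = c("HLA-A", "HLA-B", "HLA-C"),
                       tcell_types = c("CD4T", "CD8T"),
                       expression_path = NULL, clinical_path = NULL,
                       protein_normal_path = NULL, protein_tumor_path = NULL,
                       signature_matrix_path = NULL, signature_gmt_path = NULL,
                       signature_name = NULL, de_genes_path = NULL) {
  stopifnot(r_min >= 0, r_min <= 1, p_max > 0, p_max <= 1,
            min_frac_normal >= 0, min_frac_normal <= 100,
            tertile_lower > 0, tertile_upper < 100, tertile_lower < tertile_upper,
            roc_horizon > 0, tie_policy %in% c("exclude", "cancer", "normal"))
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration (lossless JSON round-trip)
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

load_inputs <- function(config) {
  if (isTRUE(config$simulate)) {
    truth <- synthetic_truth(n_samples = config$n_samples,
                             planted_regulators = config$planted_regulators,
                             coupling = config$coupling,
                             hazard_beta = config$hazard_beta,
                             disparity_prob = config$disparity_prob,
                             seed = config$seed)
    make_bulk_dataset(truth,
                      anchors = anchor_panel(config$mhc_anchors, config$tap_anchors),
                      n_noise_genes = config$n_noise_genes,
                      noise_sd = config$noise_sd,
                      n_pairs = config$n_pairs,
                      seed = config$seed)
  } else {
    need <- c("expression_path", "clinical_path", "protein_normal_path",
              "protein_tumor_path", "signature_matrix_path",
              "signature_gmt_path", "de_genes_path")
    miss <- need[vapply(config[need], is.null, logical(1))]
    if (length(miss))
      stop_("simulate = FALSE but input path(s) missing: %s", paste(miss, collapse = ", "))
    sets <- read_gmt(config$signature_gmt_path)
    sig_set <- if (is.null(config$signature_name)) sets[[1L]]
               else sets[[config$signature_name]] %||%
                    stop_("signature '%s' not in %s", config$signature_name,
                          config$signature_gmt_path)
    list(expression = read_expression(config$expression_path),
         clinical = read_clinical(config$clinical_path),
         protein = read_paired_protein(config$protein_normal_path,
                                       config$protein_tumor_path),
         signature = read_signature(config$signature_matrix_path),
         signature_set = sig_set,
         de_set = gene_set("DE_PROTEINS", readLines(config$de_genes_path)),
         truth = NULL)
  }
}

#' Run the full pipeline into a directory
#'
#' Executes simulate/load, deconvolution, the co-expression screen, the
#' proteomic disparity filter, survival stratification (MHC-I composite,
#' T-cell fractions, and their combination) and fixed-horizon ROC, writing
#' every artifact plus `manifest.json` (package version, parameters, stage
#' list, file checksums). Identical config and seed give a byte-identical
#' run directory.
#'
#' @param config a [run_config()].
#' @param dir output directory (created; must not be an existing non-empty
#'   run unless `overwrite = TRUE`).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, a list with the in-memory stage results
#'   (`bundle`, `fractions`, `screen`, `candidates`, `survival`, `roc`).
#' @export
run_all <- function(config = run_config(), dir, overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(dir) && length(dir(dir)) && !overwrite)
    stop_("run directory %s exists and is non-empty", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  step <- function(name) {
    message(sprintf("[mhcscreen] stage: %s", name))
    stages <<- c(stages, name)
  }

  step("simulate")
  bundle <- load_inputs(config)
  if (isTRUE(config$simulate)) write_synthetic_inputs(bundle, file.path(dir, "inputs"))
  expr <- bundle$expression

  step("deconvolve")
  fractions <- nnls_fractions(expr, bundle$signature)
  write_fractions(fractions, file.path(dir, "fractions.tsv"))

  step("screen")
  panel <- anchor_panel(config$mhc_anchors, config$tap_anchors)
  screen <- run_screen(expr, panel, bundle$signature_set,
                       r_min = config$r_min, p_max = config$p_max)
  write_screen(screen, file.path(dir, "screen"))

  step("disparity")
  genes_in_protein <- intersect(screen$signature_overlap, bundle$protein$gene_ids)
  disp <- if (length(genes_in_protein))
    disparity_table(bundle$protein, genes_in_protein, tie_policy = config$tie_policy)
  else
    disparity_from_counts("NONE", 1L, 0L)[0, ]
  candidates <- filter_candidates(screen, disp, bundle$de_set,
                                  min_frac_normal = config$min_frac_normal)
  write_candidates(disp, file.path(dir, "disparity.tsv"))
  write_candidates(candidates, file.path(dir, "candidates.tsv"))

  step("survival")
  surv_dir <- file.path(dir, "survival")
  dir.create(surv_dir, showWarnings = FALSE)
  mhc_groups <- expression_tertiles(expr, config$mhc_score_genes,
                                    lower = config$tertile_lower,
                                    upper = config$tertile_upper)
  tc <- rowSums(as.matrix(fractions[, config$tcell_types, drop = FALSE]))
  names(tc) <- fractions$sample_id
  tcell_groups <- score_tertiles(tc, lower = config$tertile_lower,
                                 upper = config$tertile_upper)
  combined <- combined_stratify(mhc_groups, tcell_groups)
  surv <- list(
    mhc = compare_strata(bundle$clinical, mhc_groups),
    tcell = compare_strata(bundle$clinical, tcell_groups),
    combined = compare_strata(bundle$clinical, combined)
  )
  for (lab in c("high", "low")) {
    sub <- bundle$clinical[combined[bundle$clinical$sample_id] == lab, , drop = FALSE]
    write_km(km_estimate(sub), file.path(surv_dir, sprintf("km_combined_%s.tsv", lab)))
  }
  lr <- data.frame(stratification = names(surv),
                   chi_square = vapply(surv, `[[`, numeric(1), "chi_square"),
                   p = vapply(surv, `[[`, numeric(1), "p"))
  con <- file(file.path(surv_dir, "logrank.tsv"), "w")
  writeLines(paste0("# ", provenance_comment()), con)
  writeLines("stratification\tchi_square\tp", con)
  writeLines(sprintf("%s\t%s\t%s", lr$stratification,
                     num_chr(lr$chi_square), num_chr(lr$p)), con)
  close(con)

  step("roc")
  roc_dir <- file.path(dir, "roc")
  dir.create(roc_dir, showWarnings = FALSE)
  mhc_score <- colMeans(expr$values[config$mhc_score_genes, , drop = FALSE])
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  comb_score <- zs(mhc_score) + zs(tc[names(mhc_score)])
  rocs <- list(
    mhc = prognostic_roc(mhc_score, bundle$clinical, config$roc_horizon),
    tcell = prognostic_roc(tc, bundle$clinical, config$roc_horizon),
    combined = prognostic_roc(comb_score, bundle$clinical, config$roc_horizon)
  )
  for (nm in names(rocs)) write_roc(rocs[[nm]], file.path(roc_dir, sprintf("roc_%s.tsv", nm)))

  write_run_config(config, file.path(dir, "config.json"))
  files <- sort(setdiff(list.files(dir, recursive = TRUE), "manifest.json"))
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- list(
    tool = "mhcscreen",
    version = as.character(utils::packageVersion("mhcscreen")),
    stages = stages,
    parameters = unclass(config),
    checksums = stats::setNames(as.list(unname(sums)), files)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)

  invisible(list(bundle = bundle, fractions = fractions, screen = screen,
                 disparity = disp, candidates = candidates,
                 groups = list(mhc = mhc_groups, tcell = tcell_groups,
                               combined = combined),
                 survival = surv, roc = rocs))
}
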