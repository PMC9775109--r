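# mhcscreen

Tumors that downregulate MHC class I antigen presentation escape CD8+
T-cell surveillance and resist checkpoint-blockade immunotherapy.
`mhcscreen` is an R package for the in-silico arm of finding candidate
*regulators* of the MHC-I machinery from bulk tumor data. It is aimed at
computational biologists who have a bulk log2 expression matrix, clinical
follow-up, and paired tumor/normal proteomics, and want a reproducible,
tested version of the standard discovery chain:

1. **Anchor-panel co-expression screen** — correlate every gene with
   HLA-A, HLA-B, HLA-C, B2M (MHC-I components) and TAP1/TAP2 (peptide
   transport): a hit requires `|r| > 0.3` and `p < 0.05` (Pearson,
   two-sided t on n−2 df; strict inequalities). Hits are intersected
   across anchors and overlapped with an IFN-γ response signature.
2. **Paired proteomic disparity filter** — per gene, the percent of
   tumor/normal pairs where normal tissue has the higher protein level;
   candidates must be normal-dominant in ≥ 70% of pairs.
3. **Immune deconvolution** — per-sample cell-type fractions by
   non-negative least squares `min ‖S f − b‖², f ≥ 0` against a signature
   matrix, closed to the simplex with an "other cells" component.
4. **Prognosis** — Kaplan–Meier `S(t) = Π(1 − dᵢ/nᵢ)`, Mantel–Cox
   log-rank `χ² = (Σ(o−e))²/Σv` on top/bottom-tertile strata, and
   5-year-horizon ROC/AUC for MHC-I, T-cell, and combined scores.

A synthetic-data generator plants known structure (a latent co-expression
factor behind the anchors, coupled regulator genes, Dirichlet cell
fractions, exponential survival tied to a prognostic score, per-gene
normal-dominance probabilities) so every stage has a ground-truth
recovery test with no external download.

## Worked example

```r
library(mhcscreen)

truth  <- synthetic_truth(n_samples = 200, coupling = 0.8,
                          hazard_beta = 0.5, disparity_prob = 0.8, seed = 7)
bundle <- make_bulk_dataset(truth, n_noise_genes = 300)

screen <- run_screen(bundle$expression, anchor_panel(), bundle$signature_set)
screen
#> <screen_result>
#>   HLA-A        3 hits
#>   HLA-B        3 hits
#>   HLA-C        3 hits
#>   B2M          3 hits
#>   TAP1         3 hits
#>   TAP2         3 hits
#>   MHC-I common: 3 | TAP common: 3 | both: 3 | in signature: 3

disp <- disparity_table(bundle$protein,
                        intersect(screen$signature_overlap, bundle$protein$gene_ids))
filter_candidates(screen, disp, bundle$de_set, min_frac_normal = 70)[, 1:5]
#>   gene_id n_high_normal frac_normal n_high_cancer frac_cancer
#> 1   REG02            78       80.41            19       19.59
#> 2   REG01            76       78.35            21       21.65
#> 3   REG03            69       71.13            28       28.87

groups <- expression_tertiles(bundle$expression, c("HLA-A", "HLA-B", "HLA-C"))
compare_strata(bundle$clinical, groups)
#> <logrank_result> chi^2 = 17.6180 (df = 1), p = 2.7e-05

mhc_score <- colMeans(bundle$expression$values[c("HLA-A", "HLA-B", "HLA-C"), ])
prognostic_roc(mhc_score, bundle$clinical, horizon_months = 60)
#> <roc_result> AUC = 0.6579 (98 cases, 69 controls, 60-month horizon)
```

Reading: the three planted regulators (coupling 0.8 to the anchors'
latent factor) are the only genes passing all six anchors, all fall
inside the synthetic IFN-γ signature, and all clear the 70%
normal-dominance cut (planted probability 0.8 over 97 pairs). High
MHC-I-composite tumors survive significantly longer than low ones
(planted log-hazard 0.5 per score unit), and the MHC-I score alone
predicts 5-year death with AUC 0.66.

`run_all(run_config(seed = 1), "run1")` executes the whole chain into a
run directory (inputs, fractions, screen lists, candidate table, KM /
log-rank / ROC tables, checksummed `manifest.json`); the same config and
seed reproduce it byte-for-byte. A CLI shim is installed as
`exec/mhcscreen` with subcommands
`simulate | deconvolve | screen | disparity | survival | roc | run-all`.

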