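---
title: "Discovering candidate MHC-I regulators from bulk tumor data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering candidate MHC-I regulators from bulk tumor data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcscreen)
```

## The problem

MHC class I molecules (heavy chains HLA-A/B/C plus the B2M light chain,
loaded via the TAP1/TAP2 peptide transporters) present intracellular
peptides to CD8+ T cells. Tumors that downregulate MHC-I escape T-cell
surveillance and respond poorly to checkpoint blockade, so genes whose
expression tracks the MHC-I machinery are candidate regulators worth
wet-lab follow-up. `mhcscreen` implements the in-silico arm of such a
discovery program as one reproducible pipeline:

1. **Anchor-panel co-expression screen.** Every gene in a bulk log2
   expression matrix is Pearson-correlated with each member of the anchor
   panel (HLA-A, HLA-B, HLA-C, B2M; TAP1, TAP2). A gene is a hit for an
   anchor when `|r| > r_min` and `p < p_max` (strict inequalities;
   defaults 0.3 and 0.05, the conventional screen thresholds). Hits are
   intersected across the four MHC-I anchors, across the two TAP anchors,
   then across both groups, and finally overlapped with an
   interferon-gamma response signature — IFN-gamma signaling being the
   canonical inducer of MHC-I.
2. **Proteomic disparity filter.** For each surviving gene, paired
   tumor/normal protein measurements are reduced to the fraction of pairs
   in which the *normal* tissue has the higher abundance. A regulator that
   tumors silence should be normal-dominant in most pairs; the default cut
   keeps genes with `frac_normal >= 70%`.
3. **Deconvolution and prognosis.** Immune-cell fractions are estimated by
   constrained least squares against a signature matrix; samples are
   stratified into top/bottom tertiles of an MHC-I composite score and of
   T-cell infiltration; Kaplan–Meier curves, Mantel–Cox log-rank tests,
   and a fixed-horizon ROC quantify the prognostic value of each score and
   of their combination.

## Models and formulas

**Pearson screen.** `r = Σ(x−x̄)(y−ȳ)/√(Σ(x−x̄)²Σ(y−ȳ)²)` with the
two-sided p-value from `t = r√((n−2)/(1−r²))` on `n−2` df. No
multiple-testing correction is applied by default, mirroring the
raw-p idiom of this kind of screen; Benjamini–Hochberg is available via
`adjust = "BH"`. Both correlation signs pass the threshold, as the rule
is printed with `|r|`, even though the interesting candidates are
positively correlated. Constant (zero-variance) genes are skipped with a
warning rather than an error: they are common in filtered matrices.
Anchors are excluded from all hit sets — a candidate regulator is by
definition not the panel itself.

**Deconvolution.** Bulk mixing is linear in abundance, so log2 inputs are
un-logged (`2^x − 1`) before solving `min ‖S f − b‖²` s.t. `f ≥ 0`
(Lawson–Hanson active set). The composition is closed with an `other`
(uncharacterized cells) component: `other = max(0, 1 − Σf)`, with
rescaling when `Σf > 1`, so every output row lies on the simplex. The
mRNA-content corrections and marker filtering of published deconvolution
tools are intentionally out of scope; this package implements the plain
least-squares core. (The study this design follows describes the
least-squares/quanTIseq route in its methods while once crediting "TIMER
methods" in its results; the two are never reconciled there, and only the
least-squares method is implemented here.)

**Tertiles.** Nearest-rank percentiles: `high` = score at or above the
67th percentile value, `low` = at or below the 33rd. When massive ties
make the two cutpoints coincide, affected samples fall to `mid` — ties
resolve conservatively, away from the extreme groups, so a degenerate
constant score yields all-`mid` and an informative downstream error.

**Survival.** Kaplan–Meier `S(t) = Π(1 − d_i/n_i)`; events at a tied time
precede censorings. Two-group log-rank with hypergeometric moments
`e_Aj = n_Aj d_j/n_j`, `v_j = d_j(n_j−d_j)n_Aj n_Bj/(n_j²(n_j−1))`,
`χ² = (Σ(o−e))²/Σv` on 1 df. p-values are reported uncorrected.

**Prognostic ROC.** At horizon `h` (default 60 months — the 5-year
framing standard in colorectal cancer), cases are events by `h`, controls
are subjects followed beyond `h`; subjects censored before `h` are
excluded rather than IPCW-weighted (the simplest defensible estimator;
time-dependent ROC is a non-goal). Scores are treated as protective and
negated before the sweep; AUC is the trapezoid area, equal to the
normalized Mann–Whitney pair count. The MHC-I composite score is the
unweighted mean of HLA-A/B/C log2 values and the T-cell score is the sum
of the CD4+ and CD8+ fractions — the minimal combination rules given that
only the constituents, not the weights, are specified by the underlying
design; both are overridable.

## The synthetic stated world

Real inputs at the scale this procedure was designed for (hundreds of
TCGA tumors, a 97-pair proteome) are not downloadable at test time, so
`synthetic_truth()` + `make_bulk_dataset()` generate all inputs with
planted structure:

* **Cell fractions** are symmetric Dirichlet(2) rows on the simplex —
  concentration 2 gives every sample a non-trivial share of each of the
  nine immune types without the near-vertex sparsity of α < 1, a
  reasonable stand-in for bulk-tumor immune admixture.
* **Markers**: bulk = `S·fᵀ` on the linear scale, log2-transformed, plus
  gaussian noise (default sd 0.5 log2 units; recovery tests use 0.05 as
  the "low noise" regime). The signature matrix places each type's
  markers 32-fold above the off-target level (lognormal, sdlog 0.3).
* **Anchors** share a latent factor `L ~ N(0,1)` with loading 1 and
  anchor noise sd 0.5; a **planted regulator** with coupling ρ is
  `ρL + √(1−ρ²)ε`, so its population correlation with the latent factor
  is exactly ρ (≈ 0.72 with each anchor at the default noise).
* **Survival**: exponential times with rate `λ₀·exp(−β·score)`,
  `λ₀ = log(2)/60` (60-month baseline median, typical of an unselected
  CRC cohort) and `score` the standardized mean anchor expression;
  independent uniform censoring on `[0, 3.2/λ₀]` gives ≈30% censoring
  under the null, typical of TCGA CRC follow-up.
* **Paired proteins**: each tumor/normal pair is normal-dominant with the
  gene's planted probability (default 0.75 for planted regulators — the
  regime of the strongest printed candidates — and 0.5 for background),
  the dominant side sitting one abundance unit higher. Only the sign
  pattern matters to the disparity statistic; continuous noise makes
  exact ties probability-zero events, isolating tie handling to the
  consumer's documented policy (`exclude` by default, shrinking the
  denominator).

One user seed fans out to fixed per-component substreams, so enlarging
one component (e.g. adding noise genes) never perturbs another (e.g. the
survival draws) — this keeps regression tests stable.

What the generator does **not** emulate: real gene–gene correlation
structure, batch effects, tumor purity, read-count noise. A green
recovery test therefore establishes that the *procedure* recovers planted
signal at realistic n and effect sizes — not that any particular gene
list from real data is correct.

## Worked run

```{r, eval = FALSE}
truth <- synthetic_truth(n_samples = 200, coupling = 0.8,
                         hazard_beta = 0.5, disparity_prob = 0.8, seed = 7)
bundle <- make_bulk_dataset(truth, n_noise_genes = 300)
screen <- run_screen(bundle$expression, anchor_panel(), bundle$signature_set)
disp <- disparity_table(bundle$protein,
                        intersect(screen$signature_overlap, bundle$protein$gene_ids))
filter_candidates(screen, disp, bundle$de_set, min_frac_normal = 70)
```

At these settings the three planted regulators pass all six anchors and
the 70% disparity cut (REG02 80.41%, REG01 78.35%, REG03 71.13% of 97
pairs normal-dominant with planted probability 0.8). `run_all()` executes
the same chain from a `run_config()` into a run directory with a
checksummed manifest; identical config and seed reproduce the directory
byte-for-byte (no timestamps are written into artifacts).

## Numerical and policy choices

* Disparity fractions are rounded **half-up** to 2 decimals, matching the
  printed precision of published candidate tables (base R's `round()`
  rounds half-to-even).
* The `min_frac_normal = 70` default is a *reconstruction*: it is the
  smallest round value that retains the published five-gene shortlist
  region (ISG15 at 70.10%) while excluding the next gene down (65.98%).
  It is exposed as a parameter and should not be read as a published
  constant.
* Screen thresholds are strict inequalities, as conventionally printed
  (`r > 0.3`, `p < 0.05`).
* The differential-protein-expression membership consumed by
  `filter_candidates()` is an input gene set, not recomputed: the
  underlying differential test belongs to the upstream proteogenomics
  resource.
* NNLS tolerance 1e-10; noise-free mixtures are recovered to 1e-8.
  Deconvolution fractions are scale-equivariant before the simplex
  closure, so cross-sample rank comparisons assume comparably normalized
  input (TPM-like).
* The shipped `crc_mhci_disparity_counts.tsv` reference table contains
  one row (HLA-DMB) whose printed counts and percentages disagree; it is
  retained for completeness but excluded from consistency checks.

## Known limitations

No gene-ID alias resolution; no Cox regression, IPCW, or KM confidence
bands; no multiple-testing correction by default; no attempt to reproduce
external deconvolution tools' bias corrections; the literature-driven
triage that narrows a statistical shortlist to wet-lab candidates is
human judgment and out of scope.
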