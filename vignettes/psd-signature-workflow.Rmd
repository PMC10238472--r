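---
title: "Quantifying PSD proteome signatures and scoring drug-induced reversal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PSD proteome signatures and scoring drug-induced reversal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdsig)
```

## The problem

Psychosis occurs in roughly half of people with Alzheimer disease (AD+P) and
marks a more aggressive clinical course. The postsynaptic density (PSD) — the
protein scaffold beneath excitatory synapses — is a plausible substrate:
synapse loss tracks cognitive decline, and an exaggerated loss of specific
postsynaptic signaling machinery could distinguish AD+P from AD without
psychosis (AD-P). `psdsig` implements an end-to-end quantitative workflow for
this question on multiplexed (TMT) peptide-level proteomics of biochemically
enriched PSD fractions, and carries the resulting disease signature forward
into a computational drug-repurposing chain. Because the real cohort data are
not bundled, every pipeline input can be generated synthetically with known
ground truth, which is what the test suite and the acceptance script exercise.

## The measurement model

Subjects are processed in plexes of 10–11, balanced for diagnosis and sex,
with two pooled-control channels per plex made from a common reference
sample. On the log2 scale a peptide's reported abundance is modeled by the
synthetic generator as

    log2 y[p, s] = b[prot(p)] + o[p] + d[p] * 1(s in AD+P)
                   + covariate terms + batch[p, plex(s)] + e[p, s]

with protein baseline `b`, peptide ionization offset `o`, disease effect
`d[p] = -log2(1.17)` for the altered fraction `pi` of proteins, a per-plex
per-peptide batch effect (SD `batch_sd`), and residual noise with SD
`log2_sd = 1.0`. The defaults — 59 AD+P, 47 AD-P, 19 cognitively normal
subjects, ratio 1.17, `pi = 0.15`, SD 1.0 — are the cohort sizes and the
power-analysis assumptions of the study design this package operationalizes.
Unquantified peptides are recorded as zero, and zero is always interpreted
as missing, never as a true zero.

## Quality control and normalization

`normalize_psd()` runs, in order:

1. **Zeros to missing.** Exact zeros become `NA`; positive values are
   untouched.
2. **Sample loading normalization.** Each channel is scaled so channel
   totals (over present values) equal the grand mean of totals. The target
   is a design choice — any common constant works — and the grand mean
   preserves the overall scale.
3. **Pooled-control filter.** A peptide missing in *both* pooled channels in
   at least half of the plexes (`>= n_plexes / 2`, real-valued comparison)
   cannot be bridged across plexes and is removed.
4. **Multi-mapped removal.** Peptides mapping to more than one protein or
   gene are removed; the surviving map is one-to-one.
5. **Outlier samples.** Subject channels whose log2 total deviates from the
   median by more than `k = 3` scaled MADs are flagged and removed. The rule
   is an automated, reproducible analogue of visual total-abundance
   inspection. Outlier status is judged on the *raw* totals: loading
   normalization equalizes totals by construction, so running the rule
   afterwards could never flag anything.
6. **Internal reference scaling (IRS).** Per peptide and plex, all channels
   are multiplied by (overall pooled mean) / (within-plex pooled mean).
   Afterwards each peptide's pooled means agree across plexes wherever
   defined (the suite asserts agreement to 1e-9 relative). A peptide that
   survived the pooled filter but has no pooled observation in some plex has
   no valid factor there; its values in that plex are set missing rather
   than guessed.
7. **Median normalization.** Channel medians are equalized at the overall
   median of present values computed before scaling.
8. **Present-call filter.** Retains peptides present in at least a given
   fraction of *subject* channels; pooled channels are excluded from the
   denominator because present-call thresholds are statements about
   subjects. `1.0` is the conservative "quantified in everyone" analysis,
   `0.5` the liberal one.

All steps are positive per-channel (or per-channel-per-peptide, for IRS)
rescalings, so within-channel peptide ratios are invariant under the loading
and median steps. Loading normalization is computed over all channels,
pooled included; computing it over subject channels only would change the
factors negligibly and the choice is recorded here as the package's
convention.

## Yield adjustment and protein roll-up

PSD yield (µg PSD protein per µg gray matter) is itself biology — a proxy
for synapse loss — and group differences in yield are deliberately
reintroduced: each subject's normalized linear-scale abundances are
multiplied by that subject's yield (`yield_adjust()`). Multiplication is on
the linear scale because that is the scale of the normalized abundances at
this stage.

Before roll-up, `pecora_flag()` screens for peptides whose condition effect
disagrees with their protein-mates (a peptide-correlation screen in the
PeCorA style): for each peptide of a multi-peptide protein, all of the
protein's observations (peptide-centered, log2) are fit as
`value ~ group * is_target`, and the interaction F-test p-values are BH
adjusted across all tested peptides. The flagging threshold (adjusted
p < 0.01) is a configuration default, not a literature constant; it is
exposed as `alpha`.

`rollup_protein()` then z-scores each peptide's log2 values across subject
channels and averages the z-scores of a protein's peptides. Flagged
peptides are split out as independent entries named `"<protein>|<peptide>"`
so a deviant peptide (for example, one inside a proteolytic fragment) can
carry its own signal. Z-scores are computed over subject channels only;
pooled channels serve normalization, not inference. Zero-variance peptides
have no defined z-score and are excluded with a warning. An explicit-loop
oracle in the test suite reproduces the roll-up to 1e-12 on random
fixtures.

## Differential abundance

`fit_contrast()` fits, per protein entry, an ordinary least squares model
of the rolled-up value on a group indicator plus covariates (complete-case
per protein). The primary contrast adjusts for age, PMI, sex, APOE*ε4,
Lewy-body positivity and log2 phospho-tau area; contrasts against the
cognitively normal group adjust for age, PMI and sex only, since the AD
pathology covariates are confounded with that comparison. Binary covariates
are 0/1 indicators; phospho-tau enters as log2 of the area fraction.

Residual variances are moderated by empirical Bayes: the prior degrees of
freedom and prior variance are estimated from the spread of log residual
variances by moment matching (digamma/trigamma inversion), and each
protein's posterior variance is the df-weighted blend of its observed and
the prior variance. This is implemented natively in the package so that the
repository is self-contained; the implementation is checked in the test
suite against `limma::squeezeVar` as an independent oracle. When the
variances show no excess spread the prior df is infinite and every
moderated t equals its unmoderated value. Unmoderated OLS is available via
`moderate = FALSE`; the global-shift distribution is computable from either.

`global_shift_test()` is the one-sample two-sided t-test of the log2
fold-change vector against zero (df = number of proteins − 1), quantifying
the coordinated proteome-wide shift; `de_set()` thresholds raw or
BH-adjusted p-values. In simulation at the study conditions the model
recovers the injected `-log2(1.17) ≈ -0.2265` mean effect and holds the
nominal 5% false-positive rate; both checks are in the acceptance suite.
The recovery simulations feed the generator's output to the roll-up and
model directly, without the loading/median steps: equalizing totals removes
part of a one-sided global shift by construction (in the full pipeline the
yield multiplication restores it), and the recovery check is about the
estimator, not about that mean-preservation.

## Interaction-network enrichment

`interaction_enrichment()` asks whether differentially expressed proteins
are over-represented among the interaction partners of a seed set (e.g. a
kinase module) given an exported edge list. A protein "interacts" when it
has at least one edge to a seed member; seed members are excluded from both
the DE set and the background. The 2×2 table is tested with Pearson's
chi-square *without* continuity correction: on the published counts (76/217
versus 348/1373) this reproduces χ² = 8.97, df = 1, p = 0.0027, whereas the
Yates-corrected statistic (≈ 8.6) would not. An edge-score threshold is
exposed but defaults to accepting every edge in the file.

## The drug-repurposing chain

The currency of the chain is the `SignedSignature`: entities with a
direction (±1) and optional magnitude. The disease signature takes the sign
of each protein's model-based log2 fold change (`mode = "full"`), or only
the nominally significant subset (`mode = "top"`, raw p < 0.05 — the
"240-of-1613"-style subset).

1. **Knockdown screen** (`correlate_knockdown()`): Spearman correlation
   between each atlas gene's knockdown signature and the disease signature
   over shared entities. Spearman is the default because the upstream
   correlation engine's metric is unpublished and rank correlation is
   robust to magnitude scaling; Pearson is available. Genes with fewer than
   10 shared entities are skipped — rank correlations below that are too
   unstable to sign reliably.
2. **Action alignment** (`nominate_drugs()`): a negatively correlated gene
   (knockdown opposes disease) is paired with inhibitors, antagonists and
   negative modulators; a positively correlated gene with agonists,
   potentiators and positive modulators. Only genes whose correlation
   passes a significance screen (p < 0.01) enter nomination — the screen
   mirrors consuming only the genes reported *as correlated* by the atlas,
   and it is what keeps chance correlations of null genes from nominating
   decoy drugs. Free-text action strings are normalized onto a closed
   vocabulary via an editable map (e.g. "blocker" → antagonist).
3. **Subset consistency** (`subset_consistency_filter()`): candidates whose
   correlation against the top-DE subset flips sign relative to the full
   signature are dropped (the behavior that excludes an MTOR-like target
   and its potentiator); candidates untestable on the subset are kept but
   flagged.
4. **LINCS-style validation** (`lincs_signature()`): profiles are kept only
   from CNS-derived cell lines at doses ≥ 1 µM, repeated tests of a gene
   are averaged, and genes with |mean Z| > 1 form the drug signature.
   Missing-drug and non-CNS-only cases return empty signatures with
   explicit statuses ("not found", "not tested in CNS cells").
5. **Signed Jaccard Index** (`signed_jaccard()`):
   `J = (|A+∩B+| + |A-∩B-| - |A+∩B-| - |A-∩B+|) / |supp(A) ∪ supp(B)|`,
   in [−1, +1], where the support is the signed entity set; zero-signed
   entities are excluded and an empty union scores 0. The index equals
   plain Jaccard when all shared signs agree. The published description
   fixes only the range semantics; this formula is the package's fixed
   definition of it.

One documented tension: the narrative worked example in the source
literature ("a negatively correlated gene's knockout *recapitulates* the
alterations") reads opposite to its own results table, where negative
correlation plus antagonist is the nominated reversing pattern. The
implementation follows the table and the subset-exclusion logic, which are
internally consistent; the discrepancy is documented rather than resolved.

## Treatment-experiment evaluation

`treatment_log2fc()` computes per-protein treated-minus-vehicle means on
rolled-up values; `reversal_test()` runs one-sample two-sided t-tests of
those fold changes over (a) all proteins shared with the full disease
signature and (b) the top-subset overlap, and scores reversal with the same
`signed_jaccard()` used by the screening chain (single implementation). The
drug-effect signature uses all overlapping proteins with nonzero fold
change — no significance filter — mirroring the use of every quantified
overlap protein in the motivating experiment. The mouse-style arm of the
pipeline reuses the same QC and roll-up with species-agnostic identifiers;
yield adjustment defaults to the same treatment as the human arm and can be
bypassed by simply not calling `yield_adjust()`.

## What the synthetic data do and do not emulate

The generator reproduces the *structure* the pipeline must survive:
plexes with pooled-control channels, zero-as-missing missingness (missing
completely at random), per-plex multiplicative batch effects, a one-sided
disease shift in a fraction of proteins, covariate structure, group-specific
PSD yields, discordant peptides, knockdown signatures correlated with the
disease signature, action-annotated drug tables, replicate Z profiles across
cell lines and doses, and a partially reversing two-arm treatment
experiment with an optional low-yield outlier animal.

It does not simulate spectra or peptide-spectrum matches, intensity-dependent
missingness, correlated peptide noise within a protein, isotopic-impurity
channel crosstalk, or heterogeneous per-protein effect sizes (the disease
effect is a uniform shift by default, matching the "average ratio"
formulation; per-protein jitter can be layered on via
`covariate_effect_sizes`-style extensions). Passing tests therefore
demonstrate correctness of the computations and calibration under this
generative model, not robustness to every pathology of real LC-MS/MS data.

## Numerical choices and problem sizes

- Tolerances: IRS/median postconditions asserted to 1e-9 relative; roll-up
  and BH against brute-force oracles to 1e-12; normal-equations comparisons
  to 1e-10.
- Degenerate inputs: all-missing channels error by name; zero-MAD outlier
  detection flags nothing with a warning; constant knockdown vectors and
  sub-overlap genes are skipped with reasons; empty LINCS results carry
  statuses instead of NAs.
- Trigamma inversion for the moderation prior uses Newton iteration to
  ~1e-10 relative, with closed-form limits at the extremes.
- The test and acceptance suites run the Monte-Carlo checks at deliberately
  compact sizes chosen to make the checks sharp but cheap: 200 simulated
  cohorts of 47/59 subjects × 150 proteins for parameter recovery and
  type-I calibration, 100 seeds for the pharmacology chain, 200 seeds for
  treatment reversal, with Monte-Carlo acceptance bands fixed at the 99%
  confidence level before the suites were run.
- The spec-level command-line interface is fulfilled by the exported
  functions plus `run_pipeline()`, which validates stage dependencies,
  writes every artifact as headered TSV (missing = empty field) or JSON,
  and records an md5 manifest so a rerun with the same seed is verifiably
  identical. An `Rscript` wrapper would add nothing for an audience that
  drives analyses from R.

## Known limitations

- The empirical-Bayes prior assumes roughly exchangeable residual
  variances; strongly heteroskedastic protein families would call for
  covariate-dependent priors.
- The PeCorA-style screen fits one model per peptide and is quadratic in
  peptides-per-protein; for very deep proteomes a grouped formulation
  would be preferable.
- Signed Jaccard ignores magnitudes; two drugs with identical sign patterns
  but very different effect sizes score identically.
- The power-analysis figure of the original study design (0.75–0.84 for
  90–120 subjects) is not reproduced: the underlying test and group split
  are under-specified, so the package only exposes the stated assumptions
  (`pi`, ratio 1.17, SD 1.0) as generator parameters.
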