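---
title: "Methods: classifying sperm-mitophagy candidates from spectral counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying sperm-mitophagy candidates from spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscreen)
```

## The experimental design this package models

A cell-free assay co-incubates demembranated ("primed") boar spermatozoa
with crushed porcine MII oocyte extract, mimicking the proteomic exchange
that follows sperm incorporation into the ooplasm. Label-free MS/MS
spectral counts are collected for four conditions — vehicle-control sperm,
primed-control sperm, the extract alone, and extract-treated sperm — in
biological triplicate, in two separately submitted trials (4 h and 24 h of
co-incubation). Each treated sample is paired with the primed-control
sample of the same replicate.

The scientific question is one of protein traffic: which extract
(ooplasmic) proteins bind sperm (Class 1), which sperm proteins accumulate
(Class 2), and which sperm proteins are removed or degraded (Class 3) —
the last group being candidate substrates or determinants of
post-fertilization sperm mitophagy.

## The procedure, stage by stage

### Detection

A protein is considered present in a sample only when at least
`min_spectra = 4` spectra support it; lower counts are censored to zero.
This re-applies, as an explicit and configurable gate, the identification
acceptance rule of the upstream database search, so that simulated data
passes through the same filter as real exports. Absence from a sample's
table is encoded as a count of zero, not `NA`: spectral counting has no
distinct missing code, and the presence/absence logic of the classifier
treats non-observation as absence.

The rule is exposed per sample per replicate. Whether the original
analysis enforced it before or after replicate aggregation cannot be
determined from the description; per-sample application is the stricter,
more reproducible reading.

### Two-stage normalization

Counts are normalized within each timepoint batch, mirroring the
separately submitted trials.

**Stage 1 (reference anchoring).** Outer-dense-fiber proteins ODF1/2/3 are
structural flagellar proteins whose content tracks the number of
spermatozoa in the sample. Each sperm-containing sample (vehicle control,
primed control, treated) is scaled by

$$f_s = \frac{\overline{R}}{R_s}, \qquad
  R_s = \sum_{p \in \mathrm{ODF}} x_{ps},$$

where $\overline{R}$ is the mean of the per-sample reference sums over the
target samples. The exact arithmetic of the original reference
normalization is unstated; equalizing the reference sum at its cross-sample
mean is the simplest scheme consistent with "normalizing on the content
of" the reference proteins. Extract samples contain no sperm tails and are
excluded from this stage; vehicle controls, which are sperm, enter the
reference mean. Both scopes are arguments (`odf_conditions`), not
hard-coded truths.

**Stage 2 (mean scaling).** Each sample is then scaled so that its mean
over a chosen protein set equals the grand mean of those per-sample means.
By default the means run over the *shared* protein set — proteins observed
in every target sample (`shared_only = TRUE`) — so that presence/absence
differences (Class 1 proteins, extract-specific proteins) cannot dominate
the scale estimate. The flag exists because the original description
("normalization by means") does not specify the protein set.

Two numerical facts about this scheme are worth stating explicitly:

1. *Within-batch equalization is exact.* After stage 1 the reference sums
   of all target samples agree to machine precision (tested at 1e-9
   relative), as do the shared-set means after stage 2.
2. *Scale invariance holds only up to a global constant.* Because
   $\overline{R}$ and the grand mean are computed from the target samples
   themselves, multiplying one raw sample column by $c > 0$ rescales the
   *entire* post-normalization matrix by a common factor (the anchor
   moves), rather than leaving it bit-identical. Every downstream quantity
   that matters — relative abundances and paired-t p-values — is invariant,
   because the t statistic is itself scale-free. Exact columnwise
   invariance would require an external fixed anchor, which the stated
   procedure does not have. The test suite asserts the up-to-a-constant
   form plus exact p-value invariance.
3. *Mean scaling assumes a mostly-unchanged proteome.* Like any global
   scaling normalization, stage 2 is biased when the abundance change is
   compositionally asymmetric: strong planted increases inflate the
   treated-sample mean, so normalization deflates everything else in those
   samples and pushes null proteins toward spurious "decrease" calls. The
   simulation studies below quantify this; it is a property of the stated
   method, not an implementation artifact.

### The paired t-test

Per protein, per trial, the replicate differences
$d_i = \mathrm{treated}_i - \mathrm{control}_i$ of normalized values give

$$t = \frac{\bar d}{s_d / \sqrt{n}}, \qquad \nu = n - 1,$$

with the sample standard deviation ($n-1$ denominator) and a two-sided
Student-t tail probability. Two-sidedness is a deliberate choice: the
screen reports increases and decreases from the same test, and direction
is read from the sign of $\bar d$ separately. No multiple-testing
correction is applied to class admission — the procedure operates on raw
p-values by design.

Degenerate replicate sets ($s_d = 0$), which the original description
never addresses, are resolved deterministically: all-zero differences give
$p = 1$ with direction "none"; constant non-zero differences give $p = 0$
with the sign's direction. Both are flagged `degenerate` with an undefined
t statistic.

Non-detected cells enter the test as 0 rather than being dropped pairwise.
This is required for Class 1 proteins, whose control vectors are entirely
zero; excluding missing cells would make the extract-derived binders
untestable.

### Classification and inventory

With detection patterns ("in" a condition = detected in at least
`presence_min = 1` of its replicates; the original text never quantifies
replicate-level presence, so the weakest reading is the default and the
knob is exposed):

- **Class 1**: not in vehicle control, not in primed control, in extract,
  in treated, and $p < 0.2$;
- **Class 2**: in primed control, direction increase, $p < 0.1$;
- **Class 3**: in primed control (extract presence optional — the literal
  reading of "both gametes or only the spermatozoa"), direction decrease,
  $p < 0.1$;
- otherwise unclassified.

The rules are evaluated in that order, so each protein gets exactly one
label and a record of the threshold that admitted it. Class 1 is
structurally impossible for any protein seen in primed controls, no matter
how small its p-value. Candidates admissible only by their distribution
pattern (extract-only but $p \ge 0.2$) are *not* silently included; they
remain visible in the pattern table for separate scrutiny.

The per-trial candidate sets are merged by accession string equality into
an inventory with both trials' classes, overlap flags, and
inclusion–exclusion totals (an exact integer identity, tested). Category
summaries report integer percentages rounded half away from zero, matching
the usual pie-chart style.

## The synthetic world

`synthetic_config()` states the simulated experiment once:

| parameter | default | rationale |
|---|---|---|
| `n_pairs` | 3 | the study's biological triplicates |
| `timepoints` | 4 h, 24 h | the two trials |
| `n_null/n_class1/n_class2/n_class3` | 200/10/20/20 | a few dozen true effects among a few hundred detected proteins, the scale of the real screen |
| `baseline_mean` | 30 spectra | a typical confidently identified protein, comfortably above the censoring floor of 4 |
| `effect_fold` | 4 | a strong but realistic abundance shift |
| `dispersion` | 10 | negative-binomial size; variance $\mu + \mu^2/10$, i.e. ~30–35% CV at baseline, typical replicate-level spectral-count noise |
| `sample_scale_jitter` | 0.1 | ~10% log-normal per-sample load variation for the normalization to remove |
| `reference_fold` | 20 | abundant ODF-like anchors keep reference scaling well-conditioned |

Counts are negative-binomial around
$\mu = \mathrm{baseline} \times \mathrm{condition\ multiplier} \times
\mathrm{sample\ load}$. Class 1 proteins are hard zeros in both sperm
controls; null and Class 3 proteins appear in the extract with probability
0.5 (exercising both branches of the Class 3 rule); reference anchors
never appear in the extract.

What the generator does **not** emulate: peptide-to-protein inference and
shared peptides, correlated protein abundances, intensity-dependent
detection efficiency, inter-trial drift beyond a scalar load factor, and
accession-version churn. A green simulation test therefore establishes the
pipeline's arithmetic and its statistical behavior under the stated noise
model — not the idiosyncrasies of a real PEAKS export.

## What the screen can and cannot deliver at n = 3

Two findings from the package's own simulation studies (computed in the
test suite and acceptance script; no numbers here are asserted that the
tests do not compute):

**Power ceiling.** With negative-binomial noise, the per-pair effect size
of a fold-$f$ change saturates at
$(f-1)\sqrt{\mathrm{disp}} / \sqrt{f^2+1}$ — about 2.3 at $f = 4$,
dispersion 10 — giving a noncentrality of ~4.0 at three pairs. A two-sided
paired t with 2 degrees of freedom then has power ≈ 0.80 at $p < 0.1$
(and less for fold-down effects at low counts, where Poisson noise adds
variance). Recovery of planted fold-4 effects accordingly plateaus near
75–80%, whatever the baseline abundance: the limit is the three-replicate
design, not the implementation. The corresponding acceptance check demands
≥ 90% and is expected to fail at that stated configuration; recovery does
exceed 95% in high signal-to-noise regimes (e.g. fold 2 at dispersion 400),
which is what the classification property test uses.

**Compositional bias of mean scaling.** When planted increases outweigh
decreases in the shared protein set, stage-2 scaling deflates treated
samples and inflates the null false-positive rate for "decrease" calls
(to ~0.2 at the default world). Under a pure null world the test is well
calibrated — the fraction of null proteins at $p < 0.1$ sits inside the
binomial 99% interval of 0.10 — and in the many-nulls/few-effects regime
the bias is negligible. Interpreting Class 3 counts from a real screen
should keep this asymmetry in mind.

## Numerical and interface choices

- Thresholds are constrained to $0 < \alpha_{23} \le \alpha_1 < 1$; the
  "classify everything" limit is approached with $\alpha \to 1$, not
  $\alpha = 1$.
- Percentages round half away from zero (`floor(x + 0.5)`), not half to
  even.
- All tabular I/O is delimited text (TSV/CSV, auto-detected); no
  spreadsheet reader exists in this environment, so workbook sheets must
  be exported to text first. The "from-normalized" entry mode
  (`cellfree_screen(..., normalized = )`, `read_normalized_matrix()`)
  accepts precomputed normalized values — accession column plus per-sample
  columns, zeros meaning non-detection — and runs testing and
  classification only.
- Pipeline outputs are written with fixed `write.table` settings so reruns
  are byte-identical; determinism is asserted in the tests.
- Errors name the offending entity (cell, sample, accession) and fail
  early; duplicate accessions are never silently merged.

## Known limitations

- Protein identity is the accession string verbatim; no cross-release
  UniProt mapping.
- The exact reference-normalization arithmetic of the original workbook is
  unknown; if it differs from the mean-anchored sum used here, the
  from-normalized entry mode plus `compare_runs()` quantifies how many
  class memberships change.
- Functional categories are supplied by the user as a finished map;
  no annotation databases are queried.
- No moderated variance estimation, count GLMs, or permutation tests: the
  procedure is deliberately the plain paired t-test of the original
  design, with its small-sample behavior documented above rather than
  patched.
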