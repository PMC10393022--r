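# mitoscreen

Label-free spectral-count screening for candidate determinants of
post-fertilization sperm mitophagy.

## The problem

After fertilization, the sperm-borne mitochondria (and their mtDNA) are
degraded in the zygote, enforcing maternal mitochondrial inheritance. A
cell-free assay recapitulates the relevant early-fertilization proteomics:
demembranated ("primed") boar spermatozoa are co-incubated with porcine
MII oocyte extract, and mass-spectrometry spectral counts are collected for
four conditions — vehicle-control sperm, primed-control sperm, the oocyte
extract itself, and extract-treated sperm — in biological triplicate at two
co-incubation timepoints (4 h and 24 h). `mitoscreen` turns those
per-replicate protein count tables into a classified candidate inventory:

- **Class 1** — absent from both sperm controls, present in the extract and
  on treated sperm: an ooplasmic factor that binds sperm.
- **Class 2** — present in primed-control sperm, increased after treatment.
- **Class 3** — present in sperm (with or without the extract), decreased
  after treatment: a candidate degradation substrate or determinant.

## The procedure

For each timepoint batch, with spectral counts $x_{ps}$ for protein $p$ in
sample $s$:

1. **Detection filter.** $p$ is detected in $s$ iff $x_{ps} \ge 4$ spectra;
   sub-threshold counts are censored to 0.
2. **Two-stage normalization.** Sperm samples are scaled so the summed
   counts of the outer-dense-fiber reference proteins (ODF1/2/3) equal
   their cross-sample mean (sperm-load anchoring); then all samples are
   scaled so per-sample means over the shared protein set equal the grand
   mean (batch-variance reduction).
3. **Paired t-test.** Per protein, replicate differences
   $d_i = \mathrm{treated}_i - \mathrm{control}_i$ give
   $t = \bar d / (s_d/\sqrt n)$ with $n-1$ degrees of freedom, two-sided;
   direction is the sign of $\bar d$. Non-detected cells enter as 0, so
   extract-only proteins are still testable.
4. **Classification.** Class 2/3 require $p < 0.1$; Class 1 is admitted at
   the loosened $p < 0.2$ because its all-zero control pattern is itself
   informative.
5. **Inventory.** Both timepoints' class assignments are merged with
   overlap accounting and functional-category frequency summaries.

A negative-binomial generator (`simulate_experiment()`) reproduces this
design with planted Class 1/2/3 truth, ODF-like anchors, per-sample load
jitter and a detection-censoring floor, so the whole pipeline is testable
without any external data.

## Worked example

```r
library(mitoscreen)
sim <- simulate_experiment(synthetic_config(), seed = 42)
sc4 <- cellfree_screen(sim$counts, sim$sheet, "4h")
print(sc4)
#> Cell-free screen, 4h trial
#>   proteins tested: 253
#>   class1 (extract-derived binders): 10
#>   class2 (increased on sperm):      15
#>   class3 (degraded from sperm):     67
#>   unclassified:                     161

inv <- build_inventory(sc4, cellfree_screen(sim$counts, sim$sheet, "24h"))
print(inv)
#> Candidate inventory: 136 proteins (4 h: 92, 24 h: 86, overlap: 42)
#>   4 h  by class:  class1=10  class2=15  class3=67
#>   24 h by class:  class1=10  class2=12  class3=64

round(attr(truth_confusion(sc4, sim$truth), "recovery"), 2)
#> class1 class2 class3
#>   1.00   0.75   0.90
```

All 10 planted extract-derived proteins are recovered; the planted
fold-4 increases/decreases are recovered at the rate a two-sided paired t
with two degrees of freedom allows (see the methods vignette for the power
analysis). The 67 Class 3 calls at 4 h include false positives from the
compositional bias of mean scaling under asymmetric planted effects —
also discussed in the vignette.

`run_pipeline(counts, sheet, out_dir = "...")` writes every intermediate
table (normalized matrices, scale factors, test results, assignments,
per-timepoint inventories, category frequencies) as TSV and returns a
per-stage report. A thin command-line wrapper with `simulate` and `run`
subcommands is at `inst/scripts/mitoscreen.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Simulates the default synthetic world at the given seed, runs the full
pipeline at both timepoints (writing all tables), prints the run report and
the planted-vs-assigned confusion matrix, and writes the result file.
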