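# gatefinder

Discovery and calibration of surface-marker gating panels that purify rare
colony-forming progenitors — megakaryocyte progenitors (MKPs) being the
motivating case — from index-sort flow cytometry data, together with
reference-based cell-type projection for single-cell RNA-seq with a
calibrated rejection threshold, and the associated single-cell QC and
marker-selection rules.

## Who this is for

Labs running index sorts with a functional readout per well (e.g. a
colony-forming-unit assay: each sorted single cell either grows a colony
or does not) who want to turn those plates into a sorter-ready gating
strategy; and anyone projecting in-vitro differentiation time courses onto
an annotated in-vivo reference while refusing to label cells the reference
does not contain.

## The methods in brief

**Panel discovery.** Wells are scored positive when their colony exceeds
three cells. After replicate- and outlier-exclusion, marker intensities
are rank-normalized within plates. Because positives are ~1% of wells,
each replicate is balanced by SMOTE (synthetic positives interpolated
between a positive and one of its *k* = 5 nearest positive neighbours, no
downsampling of negatives), and a bagged ensemble of 1000 CART trees is
fitted per replicate. Traversing each tree depth first, the i-th distinct
marker encountered gets *first-occurrence rank* i; the per-replicate rank
profiles, together with combined-data Wilcoxon rank-sum p-values, rank the
candidate markers. Cutoffs are then discovered sequentially: wells
surviving the previous gates are split into 60 equal-frequency expression
bins for each remaining marker and the cumulative curve

&nbsp;&nbsp;&nbsp;&nbsp;x = cumulative fraction of wells (from the
extreme-expression end), y = 1 − cumulative colony fraction

has its inflection located as a two-segment binomial change point (one
colony rate inside the candidate gate, one outside, profile likelihood
maximized over bin boundaries). At each stage the remaining marker with
the largest likelihood gain is gated — positive-selection gates before
depletion gates — retaining the top (or, for negative markers, bottom) x
fraction; the data are subset and discovery repeats until no marker
remains informative or too few wells survive.

**Reference projection.** Marker genes are the union over reference types
of *positive markers* (one-vs-rest rank AUC > 0.5 and fold change ≥ 2 on
log-normalized expression); a 100-tree random forest over those genes
yields per-cell class probabilities as tree-vote fractions. The
assignment threshold is calibrated on a negative-control population known
to be absent from the reference: the smallest grid value (step 0.01)
assigning fewer than 1% of control cells. Query cells below the threshold
are returned `UNASSIGNED`.

**QC filters.** Four literal rule sets: time-course droplets (keep ≥1000
genes, ≤60,000 UMIs, ≤10% mitochondrial), in-vivo reference (keep >1000
features, <10% MT, >20% ribosomal-protein), sorted-MKP droplets (no UMI
cap), and Smart-Seq (≥200,000 reads); genes detected in fewer than 3
cells are dropped.

## Worked example

Simulate 20 index-sort plates of 384 wells whose ground truth is the
published MKP panel — top 20% PVR, top 50% MICB, top 85% CD51, top 62%
CD168, bottom 25% VEGFR1, nested in that order — with 2% colony-outcome
label noise and plate batch effects, then run the full discovery pipeline:

```r
library(gatefinder)

cfg <- sim_config(n_plates = 20, wells_per_plate = 384,
                  truth_panel = mkp_reference_panel(),
                  label_flip_rate = 0.02, batch_shift_sd = 0.3, seed = 1)
plates <- simulate_index_sort(cfg)
res <- rank_and_build(plates, n_trees = 1000, seed = 1)

res$rank_summary
#>   marker n_median_rank1 mean_median_rank mean_usage  p_value
#> 1    PVR              6             3.23      0.975 2.14e-15
#> 2   MICB              3             4.15      0.956 1.38e-12
#> 3  CD168              1             4.30      0.970 1.86e-12
#> 4   CD41              2             4.10      0.957 1.20e-05
#> 5 VEGFR1              3             3.65      0.975 1.76e-05
#> ...

res$panel
#> Gating panel (5 sequential gates)
#>   1. PVR^hi: top 20%
#>   2. MICB^hi: top 50%
#>   3. CD168^hi: top 60%
#>   4. CD51^hi: top 88%
#>   5. VEGFR1^lo: bottom 25%

res$evaluation
#>     gate enrichment sensitivity specificity selected_fraction
#> 1  panel      30.68       0.412       1.000            0.0134
#> 2    PVR       2.48       0.498       0.809            0.2005
#> 3   MICB       1.39       0.695       0.506            0.5000
#> ...
```

The PVR analog wins median rank 1 in the most replicates and anchors the
panel; the recovered retained fractions (20/50/60/88/25) sit within a few
percentage points of the generating truth (20/50/62/85/25 — note CD168
and CD51 swap discovery order, which nested percentiles tolerate). The
evaluation table says the full panel selects 1.3% of wells, captures 41%
of all colonies there (sensitivity is bounded by the ~60% of observed
colonies that are pure label noise at this flip rate), and enriches
colony formation 30-fold over the bulk rate; each single gate alone
enriches only 1–2.5-fold.

Applying a panel to new wells and projecting cells onto a reference:

```r
mask <- predict(res$panel, new_plates)        # logical well selection

sim <- simulate_reference_query(ref_query_config(seed = 1))
genes <- select_discriminative_genes(sim$reference$counts, sim$reference$labels)
model <- train_celltype_model(sim$reference$counts, sim$reference$labels,
                              genes, n_trees = 100, seed = 2)
model$threshold <- calibrate_threshold(model, control_counts)  # <1% rule
predict_types(model, sim$query$counts)        # label / UNASSIGNED per cell
```

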