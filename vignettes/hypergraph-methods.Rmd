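---
title: "Hypergraph analysis of dynamic functional connectivity: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypergraph analysis of dynamic functional connectivity: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperdfc)
```

## The method

Dynamic functional connectivity (DFC) asks how the correlation structure of
regional brain signals evolves over the course of a scan. `hyperdfc`
implements a hypergraph formulation of that question:

1. **Band-pass filtering.** Each regional BOLD signal is restricted to
   0.06–0.125 Hz, the band carrying task-related fluctuations, with a
   zero-phase 4th-order Butterworth filter run forward and backward
   (`bandpass_filter()`). Zero-phase filtering avoids shifting signal
   features across window boundaries. Runs acquired at different TRs are
   filtered per run because one digital filter cannot span two sampling
   rates.
2. **Windowed node–node graphs.** The filtered series is cut into
   consecutive non-overlapping windows aligned to run starts (60 s by
   default), and a full Pearson correlation matrix over the `N` regions is
   computed per window (`segment_windows()`, `windowed_connectivity()`).
   Edges are never thresholded at this stage: weak and strong correlations
   are equally part of the dynamics.
3. **Edge weight time series.** The `E = N(N-1)/2` per-window edge weights
   are rearranged into an `E × W` matrix (`build_edge_timeseries()`), one
   row per edge in canonical upper-triangle order.
4. **Edge–edge graph and hyperedges.** Every pair of edge time series is
   correlated; two-sided p-values from the t transform (df `W − 2`) are
   thresholded by a false discovery rate correction over all `E(E−1)/2`
   pairs of one subject, and surviving pairs of either sign become *links*
   (`edge_edge_correlation()`, `fdr_binarize()`). The connected components
   of the link graph are the *hyperedges*: sets of edges whose weights rise
   and fall together (`extract_hypergraph()`). Edges with no links are
   singletons and are excluded from all metrics.
5. **Metrics.** Hyperedge *size* is its member-edge count; *hypergraph
   cardinality* is the number of non-singleton hyperedges; *hyperedge node
   degree* counts, per region, the hyperedges containing at least one edge
   incident to it. Pooled cumulative size distributions and their log–log
   line fits summarise a cohort (`size_distribution()`, `powerlaw_fit()`).
6. **Task-specific hyperedges.** A hyperedge is specific to a task when its
   coherence (mean absolute pairwise correlation of member-edge weights)
   on that task's windows exceeds a permutation null built from equally
   sized window sets drawn from all tasks, after Bonferroni correction
   across hyperedges × tasks; hyperedges surviving for more than one task
   are left unclassified (`classify_task_specific()`).
7. **Individual differences.** Behavioural measures grouped into five
   categories are reduced per category by SVD, keeping the smallest factor
   count that retains ≥ 75% of the category variance (`choose_factors()`).
   Hypergraph cardinality is regressed on all factors plus always-retained
   covariates (head motion); each category's contribution is the drop in
   R² when its factors are held out, i.e. a hierarchical regression with
   that category entered last (`r2_change_regression()`). Coefficient
   t-tests are Bonferroni-corrected over the whole session's tests
   (`bonferroni_flags()`); the age–cardinality association is additionally
   summarised by a Spearman rank correlation (`spearman_age()`) and an
   age-group comparison of node-degree maps
   (`age_group_degree_comparison()`).

## Interpretation choices the method required

**Hyperedge size.** The size of a hyperedge is defined here as the number of
member edges (the vertex count of the component). A literal sum over the
binarized edge–edge matrix within the component would count links instead;
the two only agree on trees. The member count is the reading consistent with
singletons having size 1 and with the maximum possible size being the system
size `E`; the link count remains available as
`hyperedge_link_count()` for diagnostics.

**FDR variant.** The correction is Benjamini–Hochberg by default, with
Benjamini–Yekutieli as an option; the FDR family is the `E(E−1)/2`
upper-triangle tests of one subject. Links arise from significant
correlations of either sign; self-correlations are never links.

**p-values for edge–edge correlations.** The analytic t transform is used;
tests verify it against a permutation oracle. For the short, band-limited
windows used here the edge weights are bounded, platykurtic quantities, so
the analytic tail is conservative at the extreme quantiles the FDR stage
probes under the global null — the temporal-shuffle null model therefore
yields clean all-singleton hypergraphs.

**Task-specificity test.** The coherence statistic, resampling scheme and
permutation count are not fully determined by the method's description; the
package uses the mean absolute pairwise correlation (matching the
absolute-valued link definition; a signed variant is available), draws
window subsets without replacement from the pooled windows preserving the
task's window count, uses a one-sided add-one permutation p-value, and
corrects over hyperedges × tasks within a subject.

**Degenerate inputs.** Regions constant within a window get zero
correlations with a warning rather than an error, so one flat region cannot
abort a cohort run; constant edge rows get `r = 0, p = 1` and can only be
singletons; a constant dependent variable skips the regression stage.

**Indices.** All in-memory and exported ids are 1-based. Edges are ranked in
row-major upper-triangle order: (1,2), (1,3), …, (1,N), (2,3), …

## The synthetic cohort model

No raw data accompanies the method, so validation rests on a generator whose
recovery properties are known by construction.

Each planted *module* is a set of ≥ 3 regions sharing a band-limited common
component. The component is present in a sparse subset of analysis windows —
a fixed fraction `active_fraction` (default 0.10) assigned by seeded
permutation, with log-normal amplitude jitter (`modulation_strength`, sdlog,
default 0.5) inside active windows — and absent elsewhere. Members receive
the component plus independent white noise (`noise_sd`, default 0.25);
background regions are pure noise. Within-module node pairs are therefore
strongly correlated exactly in the active windows, so all module edges'
weights co-fluctuate and the analysis should recover one hyperedge per
module: hypergraph cardinality equals the planted module count `K`.

Cohorts (`cohort_spec()`, `generate_cohort()`) draw ages uniformly over
18–75 years and plant `K(age) = base_modules + round(slope × (age − 18))`
modules (defaults: base 2, slope 1/15 per year), mirroring the reported
age-linked fragmentation of connectivity dynamics. The accompanying
42-measure table has five categories (6 performance, 4 demographics, 10
state-of-mind, 10 cognitive, 12 personality; the demographics category
covers age, education, sex and handedness, the four measures named in the
field's common batteries). Every category has a two-factor low-rank
structure with residual noise of sd 0.3 — small enough that the 75% rule
reliably selects about two factors; the first demographics factor is
standardized age itself. A head-motion proxy mildly correlated with age
(slope 0.3 on the z-scale) is included, since motion is a known confound of
FC–age associations.

### Why sparse activity, and why a fixed active-window count

Two statistical facts shaped the generator, and both are worth recording
because they constrain *any* generator for this analysis:

*The halo effect.* If two module members are strongly correlated in a
window, then their edges to any third region carry nearly identical weights
in that window. Across windows, the correlation between the weight series
of edges (i, j) and (i′, j) — members i, i′, any third region j — equals
the *average* shared-signal fraction of the member pair. A generator whose
members are strongly coupled most of the time therefore links every member
pair to every third region, producing hundreds of spurious two- and
three-edge "halo" hyperedges. Keeping the active fraction near 0.1 pushes
the halo correlation to ≈ 0.1, far below the significance threshold, while
the within-module edge–edge correlation (≈ 0.65 at the defaults) remains
detectable. Because window correlations are scale-free, the *noise
amplitude* is not the lever — the *activity duty cycle* is.

*Active-count variance.* With independently drawn per-window gains, the
number of active windows a module realizes is binomial; modules at the low
tail lose their links and are not recovered. Drawing exactly
`round(active_fraction × W)` active windows by permutation removes that
failure mode while keeping placement random.

### The validation regime

`well_separated_spec()` and `recovery_config()` bundle the reference
recovery experiment: 50 regions, 100 windows of 120 s (TR 2 s, three
concatenated runs), generator defaults, and analysis with 120 s windows and
the Benjamini–Yekutieli correction.

Two of these choices deserve their rationale:

* **120 s windows.** In the 0.06–0.125 Hz band a 60 s window contains only
  ≈ 8 effective degrees of freedom, so single-window edge weights carry
  sampling noise of sd ≈ 0.35. The corridor between detectable
  within-module correlations and undetectable halo correlations closes at
  that noise level; 120 s windows (≈ 16 d.o.f.) reopen it, and window
  lengths of 40–120 s are within the range over which hyperedge
  distributions are reported to be robust. The 60 s default is unchanged
  for data analysis.
* **Benjamini–Yekutieli for exact recovery.** BH at level α controls the
  expected *proportion* of false links, so a subject with R true links is
  expected to carry ≈ αR false ones — each typically a spurious two-edge
  hyperedge. With α = 0.05 and R = 3K this puts a ceiling of about
  e^(−0.15K) on the probability that recovered cardinality *exactly*
  equals K, regardless of generator settings. Exact-equality validation is
  therefore run under BY, whose expected false-link count (≈ 0.004R) is
  negligible. This is a property of FDR control, not of the
  implementation; data analysis keeps BH, where a handful of small spurious
  components is the accepted price of its power.

At these settings the measured per-subject exact-recovery rate is ≈ 1.00
(K = 1), ≈ 0.95 (K = 3) and ≈ 0.93 (K = 5) over 60-seed experiments, and
30-subject cohorts recover the planted age effect (demographics as the top
normalized R² change, Bonferroni-significant, Spearman ρ ≈ 0.95) in 10 of
10 seeded cohorts.

### What the generator does and does not emulate

It reproduces the statistical skeleton the analysis assumes: band-limited
signals, window-locked co-fluctuation of planted edge groups, an age-linked
module count, a categorized measure table with low-rank structure, and a
motion proxy. It does **not** emulate hemodynamic response shapes, spatial
(voxel) autocorrelation, realistic fMRI noise spectra (1/f, physiological
cycles), scanner drift, or motion artefacts beyond the scalar proxy. Passing
recovery tests therefore demonstrates that the pipeline's inference chain is
sound under its own assumptions — not that those assumptions hold in any
particular empirical data set. Real cohorts also exhibit near-system-size
hyperedges and power-law size distributions spanning orders of magnitude,
which the minimal three-region modules deliberately do not generate.

## Problem sizes and numerical notes

The edge–edge stage is quadratic in `E`: a 50-region subject has
`E = 1225` edges and ≈ 750k link tests; the full 194-region parcellation has
`E = 18721` and ≈ 1.75 × 10⁸ tests, whose dense correlation matrix
(≈ 2.8 GB) should be processed blockwise — the package stores thresholded
matrices sparsely (`Matrix`), and validation experiments use 50-region
cohorts, 100–150 windows and 10–30 subjects so that every experiment runs in
minutes on one core. Zero-phase filtering leaves short transients at run
boundaries; `drop_boundary_windows` (and `per_run_filter`) expose the
published variants for suppressing them. Ties in the "largest hyperedge"
removal of `size_distribution()` are broken by the lowest member edge id;
ages are rounded to whole years; all randomness in `run_pipeline()` descends
from the single config seed.

## Known limitations

* Exact-cardinality recovery is validated for minimal (3-region) modules;
  overlapping functional communities, nested modules or between-module
  coupling are outside the generator's vocabulary.
* The permutation task-specificity test is quadratic in hyperedge size;
  for near-system-size hyperedges a member-pair subsample would be needed.
* The analytic edge–edge p-values lean on approximate normality of window
  correlations; at very short windows they are conservative rather than
  exact (the permutation oracle in the test suite quantifies this).
* `powerlaw_fit()` is a least-squares line on the log–log cumulative
  counts — the field's reporting convention — not a maximum-likelihood
  power-law estimator.
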