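---
title: "Methods: quantitative chromatin comparison with spike-in calibration"
author: "chromaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative chromatin comparison with spike-in calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaquant)
```

# The problem

Two cell states can differ not only in *where* a histone modification sits
but in *how much* of it each cell carries genome-wide. Standard
sequencing-depth ("library size") normalization destroys exactly that
signal: if condition A has twice the H3K27me3 of condition B everywhere,
equalizing read totals reports no difference at all. chromaquant implements
a calibrated comparison pipeline in which an exogenous spike-in genome,
added at a constant amount per cell, anchors every sample to a common
per-cell scale. Around that core it provides the downstream analyses such a
comparison needs — peak calling and three-way differential region
classification, histone-PTM relative-abundance quantification from mass
spectrometry peptidoform tables, differential screening of the
chromatin-bound proteome, and a writer/eraser network integration of the
two — together with a synthetic-data generator that plants known truth so
every stage is testable by parameter recovery.

# Spike-in calibration

## Model

Each sequenced sample mixes fragments from the target genome and from a
spike-in genome. The biological premise is that spike-in material is added
in fixed proportion to cell number, so the expected spike-in count for
sample $s$ is

$$ E[S_s] = d_s \cdot n_{\mathrm{cells}} \cdot r $$

with $d_s$ the sample's sequencing-depth scale and $r$ a condition-invariant
rate, while target counts are $E[T_s] = d_s \cdot n_{\mathrm{cells}} \cdot
g_{c(s)} \cdot (1 + m_{c(s)})$, where $g_c$ is the condition's genome-wide
coating level and $m_c$ the extra mass contributed by enriched domains.
Because $d_s$ enters both, the ratio $T_s / S_s$ estimates per-cell target
signal up to a shared constant — that is the whole trick.

## Procedure

1. **Quality filtering** (`filter_quality`): fragments with mapping quality
   strictly greater than 20 are retained (a record at exactly 20 is
   dropped), then deduplicated to one record per exact coordinate triple
   per genome — the "unique tags" used for counting. Records with unknown
   MAPQ pass, so simulated data need not model an aligner.
2. **Factors** (`compute_calibration_factors`): sample $s$ receives
   $f_s = \min_t S_t / S_s \in (0, 1]$. The sample with the fewest spike-in
   fragments anchors the experiment at $f = 1$ and everything else is
   scaled *down* to it, never up.
3. **Downsampling** (`downsample_fragments`): exactly
   $\mathrm{round}(f_s \cdot N_s)$ target fragments are kept, sampled
   uniformly without replacement under a caller-supplied seed. Exact
   sampling (rather than Bernoulli thinning) makes the output cardinality
   assertable; rounding is round-half-to-even for cross-platform
   determinism. Spike-in records are dropped from the output — after the
   factor is computed their job is done.

`calibrate_experiment` composes the three steps and optionally computes
factors within batches (e.g. the specific-antibody samples and the IgG
controls each anchored separately, since a shared anchor across antibodies
is not meaningful). The default is a single batch; the choice is exposed
because experiments differ in whether control libraries should share the
anchor.

## Error sources, quantified

Calibration is exact only in expectation. Its residual scale error between
two samples is the counting noise of the spike-in totals,
$\sqrt{1/S_1 + 1/S_2}$ — about 1–2% at $10^4$ spike-in fragments — plus,
when deduplication is on and the genome is small relative to the library,
a saturation bias (deeper libraries lose proportionally more coincidental
coordinate duplicates). On real genomes at typical depths saturation is
negligible; on compact simulated genomes it is not, which is why the test
suite checks the depth-invariance property with dedup off and abundant
spike-in, and checks the tolerance-based ratio recovery (within 10% of a
true 2× ratio at ~$3\times10^5$ fragments) under the realistic defaults.

# Binned quantification and tracks

`bin_counts` tiles the genome into 1-kb bins (the final partial bin of a
contig is kept so counts are conserved exactly) and assigns each fragment
to the bin containing its integer midpoint. Midpoint assignment is used
everywhere an interval membership is needed — bins, FRiP, repeat classes,
region counts — because it is unambiguous and never double-counts;
any-overlap assignment is the main alternative and would change totals. The
global-level display is a Gaussian kernel density estimate of log2 bin
counts (`log_density`), with Silverman bandwidth and a 512-point grid over
the data range ± 3 bandwidths. Zero bins have no log2 value; by default
they are excluded, and a pseudocount policy is available instead. The
choice is recorded in the returned object.

Replicate reproducibility (`bin_correlation`) is Pearson correlation of
log(1 + count) over identical bin frames. On sparse synthetic backgrounds
most bins are small-count Poisson noise, so this statistic is dominated by
the planted structure; values well below 1 are expected and the workflow
prints them without embellishment.

`coverage_track` piles fragments into maximal constant-value bedGraph runs;
$\sum \mathrm{value} \times \mathrm{width}$ equals the summed fragment
lengths times the scale factor exactly, an identity the tests assert.
`frip` is the percentage of fragment midpoints inside a merged peak set.

# Peak calling and differential regions

## Sparse-enrichment caller

`call_peaks_sparse` forms candidate blocks from a coverage track and
retains those whose area under the curve (block score) reaches the
$1 - \texttt{retain\_fraction}$ quantile of block scores; ties at the
threshold are all kept, so the retained count equals the quantile-oracle
count deterministically. The conventional retention is the top 1%.

Block formation has one numerical choice that matters. Strictly, blocks are
maximal runs of positive coverage (`max_gap = 0`). That definition is the
right one when background is truly sparse — scattered fragments leave
near-empty gaps between enriched blocks. At appreciable background density
it degenerates: run lengths inside an enriched domain are roughly
exponential with mean $(\mathrm{e}^{\lambda L} - 1)/\lambda$ (start rate
$\lambda$, fragment length $L$), so a broad domain shatters into many short
runs, and *no* retention fraction can reconstruct it afterwards — retaining
few runs leaves islands separated by more than any merge distance, and
retaining many floods the output with background. Passing the pipeline's
merge distance as `max_gap` (here 300 bp) fuses blocks across
sub-threshold gaps *before* scoring, which reconstructs broad domains and,
on sparse data, coincides with calling strictly and merging afterwards. The
package therefore defaults to the strict definition and lets pipelines over
denser tracks opt in; a subsequent `merge_peaks` pass is then idempotent.

## Peak-set algebra

`merge_peaks` merges peaks strictly *closer than* `max_gap` (a gap of
exactly 300 bp does not merge), transitively, summing member scores.
`intersect_replicates` keeps first-replicate peaks overlapping the second
by at least 1 bp — the reproducibility filter that builds each condition's
final set. `combine_peak_lists` concatenates per-condition sets and
coalesces overlapping intervals into their union: "de-duplication" is
interpreted as coalescing because the differential step needs disjoint
regions to count into; removing only exact duplicates would leave partial
overlaps that double-count fragments. `filter_exclusion` removes any
region touching an exclusion-list interval (coverage-artifact windows).
All four are tested against brute-force oracles (base-painting and
pairwise-overlap implementations that share no code with the package).

## Differential classification

`differential_regions` tests each combined region for a condition effect on
calibrated midpoint counts. Counts enter post-calibration, so size factors
are fixed at 1 — re-normalizing by library size here would undo the
calibration. The model is negative binomial with a single common
dispersion estimated by method of moments pooled over all regions and
conditions,

$$ \hat\alpha = \frac{\sum (s^2 - \bar x)}{\sum \bar x^2}, $$

floored at $10^{-8}$. With two replicates per condition — the design's
replication level — per-region dispersion is simply not estimable, and
pooling is what makes a test possible at all; the cost is that regions with
atypical variability are tested at the shared dispersion. The test is a
Wald test on the log2 fold change of condition means (pseudocount 1), with
delta-method standard error and Benjamini–Hochberg correction across
regions. Regions with $q < 0.05$ are classified toward the condition with
the larger mean; everything else is `common` — enriched in neither, the
three-way partition used throughout.

One behaviour is worth stating because it is the method's point: when one
condition genuinely carries a higher global coating, a calibrated test
correctly classifies domains of *equal relative* enrichment toward that
condition — absolute abundance, not within-library proportion, is what is
compared. The workflow's third step demonstrates this on planted truth.

`annotate_regions` flags regions overlapping a ±3-kb promoter window
around any TSS and reports the nearest gene by TSS distance, calling it a
*marked gene* only within 10 kb.

# Histone PTM quantification

Peptidoform tables carry one row per peptide-with-modifications, annotated
with `histone:residue:state` triplets and one intensity column per sample.
`normalize_total` rescales each sample so its total over all histone
peptides matches the grand mean — the loading correction; relative
abundances are invariant to it, so its placement relative to any upstream
normalization is immaterial to the ratios (and is therefore not
configurable). `rollup_relative_abundance` computes, per residue and state,

$$ \mathrm{RA} = 100 \times
   \frac{\sum \mathrm{intensity\ of\ peptidoforms\ in\ that\ state}}
        {\sum \mathrm{intensity\ of\ all\ peptidoforms\ at\ the\ residue}} $$

so the states of one residue always sum to 100%. A co-modified peptidoform
(say K27me3–K36me2) contributes its full intensity to both residues'
tallies: the quantity is the per-residue marginal, not a joint
distribution, so no intensity splitting is performed. Residues with zero
total intensity in a sample yield missing abundances with a warning.
Missed-cleavage peptides that cover a residue twice are outside the
synthetic model and would need a policy on real data.

`hptm_differential` takes log2 fold changes of condition-mean abundances
with a pseudocount of 0.01 percentage points and applies a two-sided
equal-variance Student t-test per mark (Welch available by argument; the
equal-variance form is the package's default deliberately), BH-corrected
across all marks in the comparison. Two groups with zero variance and
equal means give $p = 1$ by convention rather than an error.
`cross_dataset_compare` intersects two named fold-change panels (at least
three shared marks), fits OLS, and returns the pointwise 95% confidence
band of the mean response.

# Chromatin proteome screening

The LFQ matrix of chromatin-bound proteins passes three stages.
`filter_proteins` removes database-artifact rows (reverse hits, potential
contaminants, only-identified-by-site) and then applies the valid-values
rule: at least 3 non-missing values in at least one group. `impute_missing`
performs detection-limit imputation: per sample (column-wise), missing
values are drawn from $\mathcal{N}(\mu_s - 1.8\,\sigma_s,
(0.3\,\sigma_s)^2)$, where $\mu_s, \sigma_s$ are the sample's observed
mean and SD — the conventional width-0.3 / downshift-1.8 defaults, pinned
numerically here for reproducibility. Observed values are never altered,
draws are seeded, and matrix-wide (as opposed to column-wise) imputation
is deliberately not offered: missingness in these data is a per-run
detection property. `differential_proteins` runs an equal-variance Student
t-test per protein and gates significance jointly on $p < 0.05$ **and**
linear fold change > 2 ($|\mathrm{log2fc}| > 1$). No multiple-testing
correction applies by default — the fold-change gate plays that role in
this screening design — but a BH-gated mode exists by argument.

# Writer/eraser integration

`build_network` joins per-protein and per-mark log2 fold changes over a
curated write/erase edge table (a starter table ships in `extdata`;
replace it freely). Edges missing either measurement keep status
`missing` — the grey nodes of a network figure. `score_concordance` is a
sign rule with a neutrality band: an edge is `neutral` if either fold
change is smaller than 0.5 log2 units in magnitude, otherwise `concordant`
when the mark moves the way the modifier change predicts (same direction
for a writer, opposite for an eraser) and `discordant` otherwise. A sign
rule, not a correlation, because each node contributes exactly one fold
change; the 0.5 threshold is the conventional high-change cutoff. The
discordant case is the interesting one: a mark rising while its erasers
also rise on chromatin is the signature of activity decoupled from
abundance. The rule, including its formalization as a threshold-plus-sign
test, is this package's own; a network figure drawn by eye has no numeric
rule to inherit.

# The synthetic-data generator

`simulate_cutrun` draws per-sample target totals from
$\mathrm{Poisson}(d_s\, n_{\mathrm{cells}}\, g_{c}\, (1 + m_c))$ and places
fragment starts uniformly with density multiplied by `fold` inside domains
active for the sample's condition (`common` domains active in both;
`igg = TRUE` ignores all planting). Fragments have a single fixed length,
truncated at contig ends — adequate for count-level statistics, which is
all the pipeline consumes. Spike-in totals are
$\mathrm{Poisson}(d_s\, n_{\mathrm{cells}}\, r)$ with one $r$ for all
samples: the calibration premise is baked into the generator, so tests of
calibration are tests of the analysis, not of a helpful simulator.
Defaults mirror a two-condition, two-replicate design at 50,000 target
cells with spike-in material at 0.4 per-cell rate (the 20,000-per-50,000
proportion of the motivating design) and a 2× coating difference.

`simulate_peptidoforms` draws intensities lognormally around
$\mathrm{total} \times \mathrm{proportion}$, parameterised so the mean is
exact and the CV is as requested; `cv = 0` reproduces truth exactly, which
anchors the rollup's correctness test. `simulate_proteome` draws per-protein
baselines, shifts a planted fraction by the true log2 fold change in one
group, censors values below a global intensity quantile (missingness
concentrated at the detection limit, matching the imputation model), and
appends flagged decoy rows. All generators are byte-identical under a
fixed seed.

What the generators do **not** emulate: fragment-length mixtures, PCR
duplicates, GC/mappability bias, chromatin contamination of the spike-in,
peptide misidentification, or correlated protein abundances. Passing tests
therefore show that the analyses recover what their models assume from
data satisfying those assumptions — they do not show robustness to the
real-data artifacts listed, which is the usual gap between simulation and
bench.

# Problem sizes and tolerances

The test suite and the acceptance script run simulations sized for
desk-scale reproduction: ~$2$–$3\times10^5$ fragments on 4–10-Mb genomes,
60–200 regions, 1,000 proteins, 12–15 marks. These sizes were chosen so
every tolerance has comfortable statistical margin (e.g. the 2× ratio
recovery to within 10% sits ~5 counting SDs from failure) while the whole
suite completes in minutes. Key numeric conventions collected in one
place: MAPQ strictly > 20; merge strictly < 300 bp; retention quantile
ties kept; round-half-to-even downsampling; dispersion floor $10^{-8}$;
log2fc pseudocounts 1 (region counts) and 0.01 (abundance percentages);
neutrality band 0.5 log2 units; Perseus-convention imputation 1.8/0.3.

# Known limitations

- With 2 replicates per condition the NB test leans entirely on pooled
  dispersion; heterogeneous-variability regions are mis-calibrated.
- The Wald test is asymptotic; at region counts below a few tens its
  type-I control degrades (the suite tests at ≥ 50 expected counts).
- Strict-run peak calling is inappropriate at dense background;
  gap-tolerant block formation is provided but the density regime is the
  user's to judge.
- Spike-in calibration inherits the spike-in's constancy assumption; if
  spike-in recovery varies across samples, the error propagates linearly
  and invisibly.
- Coordinate deduplication conflates PCR duplicates with coincidental
  overlaps as saturation rises; both dedup modes are exposed.
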