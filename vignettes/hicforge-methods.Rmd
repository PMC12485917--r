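---
title: "Models and methods behind hicforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hicforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hicforge does two things that are designed to meet in the middle: it
estimates the large-scale organization statistics that binned Hi-C contact
maps support (compartments, territoriality, distance decay, insulation,
telomere/centromere clustering, mitochondrial background), and it simulates
contact maps with exactly the structures those estimators look for. Every
estimator can therefore be validated by parameter recovery — simulate with a
known truth, estimate, compare — without downloading any sequencing data.
This vignette explains the models, the defaults, and the design decisions
that were genuinely open.

## The generative model

A simulated map is a multinomial sample over unordered bin pairs from an
expected probability matrix built per pair:

* **Distance decay (cis).** A broken power law in midpoint separation `s`:
  `s^-alpha1` up to the crossover `s0` (default 2 Mb), continuing smoothly as
  `s^-alpha2` beyond it. Neuronal maturation presets use `alpha2 > alpha1`,
  which depletes contacts beyond a few megabases — the regime where contacts
  between compartment domains dominate. Self-pairs use `s = bin_size`.
* **Compartment affinity.** Each bin carries a label A, B or ambiguous. Cis
  pairs are multiplied by `c_AA`, `c_BB` or `c_AB`; trans pairs by `t_*`.
  Ambiguous bins are neutral (multiplier 1). Presets derive the heterotypic
  term as `c_AB = 1/sqrt(c_AA * c_BB)`: affinity is log-bilinear in a
  per-bin compartment score, so heterotypic contacts are *depleted* (the
  below-1 corners real saddle plots show) and compartment-free bins sit
  exactly at the neutral level. The alternative `c_AB = 1` (supported via
  `sim_params()`) makes the A and B blocks two independent one-sided
  enrichments whose eigenvectors are near-degenerate and smear onto neutral
  bins; it is kept for closed-form tests but not used in presets.
* **Insulating boundaries.** Each planted boundary attenuates pairs that
  straddle it by `(1 - beta)`, only below 3 Mb separation — TADs are a
  sub-megabase phenomenon and compartment-scale structure should not feel
  them.
* **End-region clustering.** Pairs in which both bins lie in a terminal
  `end_size` region (telomere ends) or within `end_size` of the centromere
  midpoint are multiplied by `w_tel` / `w_cen`, cis and trans — a Rabl-like
  configuration knob.
* **Mitochondrial leak.** Pairs involving the mitochondrial contig get
  `lambda_mito` times the mean trans pair probability; this emulates the
  background mito-nuclear ligation signal, elevated when mitochondrial
  integrity is lost.
* **Mass bookkeeping.** Cis and trans blocks are rescaled so the cis share
  is exactly `f_cis`, with the mitochondrial mass carved out of the trans
  share; the matrix then sums to 1 over unordered pairs.

Switch-track sampling draws a three-letter category (state of a bin in
fibroblasts, iPSCs, motor neurons) independently per bin, then rearranges
each chromosome's drawn categories into contiguous runs with geometric
lengths of mean 1 Mb: maps get domain-scale block structure while the
planted category masses keep per-bin multinomial precision (about half a
percentage point on a 7,500-bin genome), which is what makes round-trip
recovery of the category shares a sharp test. Per-bin planted eigenvector
magnitudes are `|Normal(1, 0.2)|` with the category sign, near zero
(`Normal(0, 0.02)`) for ambiguous bins. Default category masses: always-A
0.165, always-B 0.199, 0.07 for each of the six mixed orders, the remaining
0.216 ambiguous.

### Presets

The six presets encode the maturation arc as parameters: cis share 0.70,
0.70, 0.72, 0.78, 0.85 across PF, iPSC, MN-W0, MN-W3, MN-W6; homotypic
affinity dipping at iPSC and peaking at PF and MN-W6 (B-B slightly below
A-A at W6); `alpha2` rising so long-range cis contacts fall with maturation;
telomere/centromere clustering absent in PF/iPSC and rising monotonically
from W0 to W6. The ALS preset models reduced maturation: every parameter
sits between MN-W3 and MN-W6 (closer to W3), except the mitochondrial leak,
which is elevated fourfold.

## Estimators

**Balancing.** Iterative correction (symmetric Sinkhorn), diagonal included,
tolerance 1e-5 on the relative marginal spread, at most 200 iterations.
Non-convergence is a warning plus a status field, never silent: matrices
with structurally zero entries on the diagonal can approach balance only
algebraically. Before balancing, bins whose log marginal falls more than
`mad_k = 5` raw median-absolute-deviations below the median (or whose
marginal is zero) are masked; masking never mutates stored counts.

**P(s).** Mean balanced contact per log-spaced distance bin (8 per decade),
distances between bin midpoints, pooled across chromosomes. Curves are
normalized to unit area in log space, making cross-sample comparisons
shape-only — the published curves are relative, so only shape is
comparable. The derivative of `log10 P` vs `log10 s` is a centered finite
difference after 5-point moving-average smoothing.

**Compartment eigenvector.** Per chromosome, the balanced cis matrix is
distance-normalized (each diagonal divided by its mean), clipped at the
99.9th percentile (a single stray count at a sparsely covered distance can
otherwise dominate the spectrum), centered, and eigendecomposed. This is
principal component analysis of the interaction matrix itself. We
deliberately do not interpose a row-correlation matrix: Pearson correlation
renormalizes every row to unit scale, which amplifies the rows of
compartment-free bins — pure noise — up to a depth-independent floor of
order `1/sqrt(n_bins)`; with the centered observed/expected matrix, their
eigenvector entries shrink with sequencing depth instead. Among the top
three eigenvectors, the one best correlated with a per-bin reference track
(GC-like proxy on real data, the planted track in simulations) is selected —
the largest eigenvector does not always carry the compartment signal — and
sign-oriented so the correlation is positive. The vector is scaled
unit-norm times `sqrt(eigenvalue)`, putting per-bin values on the
observed/expected amplitude scale on which the conventional A/B call
thresholds of +/-0.05 are meaningful. Pairs in which both bins are
telomeric (or both centromeric) are zeroed before the decomposition by
default: Rabl-like clustering is a real but non-compartmental structure
that otherwise contaminates the leading eigenvectors of strongly clustered
maps. Chromosomes with fewer than 20 usable bins yield an undefined track
and a warning.

**Saddle strength.** Bins sorted by EV1 into 50 quantile groups (ambiguous
bins excluded), observed/expected enrichment (cis: distance-normalized;
trans: chromosome-pair block mean) averaged per quantile cell, cells with
fewer than 10 pairs dropped. Strength is the mean of the homotypic corner
over the heterotypic corner for the extreme 20% of quantiles — on expected
maps with affinities `(c_hom, c_het)` this recovers `c_hom / c_het` up to
binning error, which is how the estimator is tested.

**Switch taxonomy.** Per-bin three-letter category from three call tracks;
any ambiguous state makes the bin ambiguous. Shares are reported both as
genome fractions (all bins with defined calls — the scale on which the
always-A and always-B shares are quoted) and as fractions of classified
bins. The cross-replicate intersection fraction counts bins identically
categorized in every replicate, over bins non-ambiguous everywhere.

**Insulation and boundaries.** The insulation score of bin `i` is the mean
balanced contact in the `w x w` diamond just off the diagonal (rows
`i-w..i-1`, columns `i+1..i+w`), log2-normalized by the chromosome mean
diamond value; undefined within `w` bins of chromosome ends. The canonical
high-resolution setting is 25 kb bins with a 250 kb window — a 10-bin
diamond; desk-scale tests keep that window/bin ratio (250 kb bins, 2.5 Mb
window), since a narrower diamond averages too few pairs for stable
prominence at moderate depth. Boundaries are strict local
minima (plateaus take the leftmost bin); strength is the *prominence* — the
difference to the lower of the two flanking maxima — rather than the raw
insulation value, which is robust to chromosome-wide offsets; the
strong-boundary threshold is strength > 0.1 (strict). Boundary sets are
compared by greedy nearest matching within +/-1 bin by default (the
matching tolerance is a parameter, since published union/intersection
counts do not state one). Aggregate profiles stack insulation at
boundaries +/-200 kb by default, with 100 kb available via the `flank`
argument (both flank sizes appear in published figure variants).

**Territory statistics.** Scaled trans maps average length-rescaled
(p -> q oriented, coverage-weighted) observed/expected trans blocks over
ordered chromosome pairs; telomere peaks appear at the scaled corners and
centromere peaks at length-proportional positions. Telomere/centromere
aggregate enrichments divide mean observed/expected over both-flagged trans
pairs by the mean over all trans pairs. The telomere pair matrix reports
every unordered pair of terminal 1 Mb arm ends, normalized by the
genome-wide mean trans contact (cis p-q entries share that trans scale and
are therefore large; they are flagged `cis`); arms shorter than `end_size`
yield explicitly undefined entries, never silent zeros. Virtual 4C profiles
are anchor-row means normalized to sum 1 over the anchor chromosome. The
mitochondrial score is the mito-nuclear count share divided by the
mito-nuclear share of bin pairs, so 1 means "proportional background".

**Group comparison.** Statistic-wise exact label-permutation tests on the
difference of group means (enumerated when feasible, so the smallest
attainable p at 2 vs 2 is 1/6), with Welch t-tests as a secondary output
for comparability with common small-sample practice, and per-group
standard deviations to surface clone-level variability.

## Problem sizes and study conditions

Two simulation genomes ship with the package, chosen so the full test
battery runs on a laptop: a small 8-chromosome genome (30-60 Mb plus a
16.6 kb mitochondrial contig, ~1,400 bins at 250 kb) for everything driven
by per-map statistics, and a 22-chromosome genome with human length
proportions scaled by 0.65 (~1.9 Gb, ~7,500 bins at 250 kb) where per-bin
classification needs many bins. Cis-percentage round trips use 5e6
contacts. The switch-taxonomy round trip uses 1e8 contacts per state: this
matches the per-cis-pair coverage (roughly 45-50 expected contacts per
250 kb pair) of a ~1.5 billion-contact human library analyzed at 100 kb —
the data regime in which per-bin A/B calling with a +/-0.05 band is
actually practiced. Boundary-recovery experiments use 2e6 contacts with the
10-bin diamond.

## What the generator does and does not emulate

It emulates power-law decay with a crossover, block-structured two-state
compartments with homotypic preference and heterotypic depletion, planted
insulating boundaries, a tunable cis share, end-region clustering, and a
mitochondrial background — the structures the estimators quantify. It does
not emulate loop extrusion (no corner dots or stripes), replication timing
or lamina association, copy-number or translocation artifacts, GC- or
mappability-driven coverage bias (balancing is therefore nearly a no-op on
simulated maps and is validated separately on biased toy matrices), read
pairs at sub-bin resolution, or inter-individual variation beyond what the
seeds provide. Passing parameter-recovery tests consequently demonstrates
estimator correctness on maps satisfying the model's assumptions, not
robustness to every artifact of real libraries.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open, bp everywhere; distances are between bin
midpoints. Bins spanning the centromere take their arm from the bin
midpoint. The mitochondrial contig is exempt from the minimum-length check
and carries no arm or end flags; it is excluded from cis statistics by
definition of territoriality. Single-chromosome genomes are supported as
degenerate inputs: the generator then has no trans mass, and the telomere
pair matrix falls back to the overall mean contact as its normalizer.
Eigenvector sign at exactly zero reference correlation stays as returned
by the decomposition, with a warning that no compartment structure was
found. Ties in insulation minima resolve to the leftmost bin; boundary
matching sorts candidate pairs by distance and then position so the
partition is symmetric under swapping the inputs. All thresholds
(call band, strong-boundary strength, quantile count, corner fraction,
masking `mad_k`, balancing tolerance) are function arguments surfaced in
the pipeline configuration; none is hard-coded downstream.

## Known limitations

The eigenvector reference track is required (there is no GC composition in
a synthetic genome); on real data a GC or gene-density proxy plays that
role, and a poor proxy can flip or mis-select eigenvectors on individual
chromosomes — the per-chromosome selection table is attached to every
track for auditing. Compartment amplitude and saddle strength are related
but not identical quantities; saddle strengths on shallow maps are biased
by noisy extreme quantiles even with the minimum-pair filter. The
insulation prominence definition differs from implementations that
threshold the insulation value itself; the strong-boundary count is
therefore comparable only within this package. The 2x2 zero-diagonal
balancing example in the test suite documents that some matrices admit no
exact balanced fixed point; convergence reporting exists precisely for
such cases. Two further subtleties the test suite makes explicit: with
domain-structured labels, short-range pairs are enriched for homotypic
contacts, so the distance-normalized expected absorbs part of the
compartment signal and saddle strength sits slightly below the planted
affinity ratio (the closed-form identity is tested with
distance-independent per-bin labels); and telomere/centromere enrichments
on compartment-labelled maps fold in the compartment identity of the end
regions, which cancels in the cross-state comparisons they are meant for
because the label tracks are shared.
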