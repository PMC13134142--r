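---
title: "Models and methods behind hicdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hicdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicdyn)
```

# Scope

`hicdyn` analyses binned Hi-C contact matrices across an ordered series of
cellular stages — the setting of terminal erythroid differentiation, where
chromatin condenses progressively from BFU-E to orthochromatic
erythroblasts — together with the 3D bead-model ensembles that such studies
derive from Hi-C. The package covers: matrix balancing, distance-decay and
observed/expected (O/E) transforms, A/B compartment calling and switching,
saddle plots and compartment strength, long-range contact fractions, per-bin
distal-to-local ratios (DLR) and interchromosomal contact frequencies (ICF),
insulation-score TAD boundary detection with pileups and strength dynamics,
interval fold-enrichment, and a radial-positioning classifier for simulated
nuclei. Because the primary human datasets of such studies are
access-controlled, a first-class synthetic-data generator with planted
ground truth substitutes for real input in every test.

# The synthetic contact model

Expected cis contact between bins $i$ and $j$ on one chromosome is
multiplicative:

$$E_{ij} \propto |i-j|^{-\alpha}\,(1 + s\,p_i p_j)\; b^{\mathbf 1[\text{same TAD}]}\;
\lambda^{\mathbf 1[d_{ij} > d_0]},$$

with $p_i \in \{+1,-1\}$ the planted compartment profile, $s \in [0,1)$ the
compartment strength, $b \ge 1$ an intra-TAD boost, and $\lambda \ge 1$ a
boost for pairs separated by more than a cutoff $d_0$ (50 Mb by default, the
threshold at which late-stage erythroblasts gain contacts). Trans pairs get
$E_{ij} \propto \tau (1 + s\,p_i p_j)$. Expectations are scaled to a total
sequencing depth and counts drawn Poisson, the standard noise model for
Hi-C counts. The multiplicative form is chosen for closed-form testability:
every downstream statistic has an analytic target (O/E of same-label pairs
$\to 1+s$, domain strength $\to \log_2 b$, and so on).

Two properties of this model matter when reading the tests:

* **Profile autocorrelation.** The distance expectation at separation $d$
  averages $1 + s\,p_i p_{i+d}$ over the chromosome. A strictly periodic
  profile makes every separation single-class, so the expectation absorbs
  the compartment signal and O/E class contrasts vanish. Contracts about
  O/E class means therefore use seeded random profiles (zero positional
  autocorrelation); block profiles are used where only label recovery
  matters.
* **Balancing vs planted boosts.** Equal-marginal balancing deliberately
  removes per-bin coverage differences — including the real extra coverage
  that a planted intra-TAD boost gives TAD bins. On a noise-free $b = 2$
  fixture the intra/flank log-ratio is 0.92 on raw counts but 0.62 after
  balancing. TAD strength and pileup recovery are therefore measured on raw
  synthetic counts, which are the faithful realization of the planted
  model; the operations accept either matrix and record which was used.

Defaults are calibration choices, not literature values (real decay
exponents and compartment strengths are unknown for the restricted data):
$\alpha = 1$, $s = 0.4$, depth $2\times10^6$ counts per ~350-bin genome,
$\tau = 0.01$, toy genomes of 2–3 chromosomes of 100–250 bins at 1 Mb so
that 50 Mb and 80 Mb cutoffs are exercisable at desk scale, and 50-kb bins
for TAD fixtures (sizes 150–500 kb, $b = 2$).

# Balancing and O/E

`balance_matrix()` implements iterative proportional correction to the
equal-marginal contract: weights $w$ such that $w_i w_j c_{ij}$ has
marginal coefficient of variation below `tolerance` (default $10^{-9}$) on
unmasked bins, scaled so the mean marginal is 1. The classical KR algorithm
satisfies the same contract; the testable property (equal marginals) is
what downstream statistics rely on. Non-convergence raises an error rather
than returning partial output. Bins with marginal below 10% of the median
(a repo default; the underlying studies do not state their filter) are
masked first and excluded from every statistic.

`expected_by_distance()` averages balanced values per separation within
each chromosome; `observed_over_expected()` divides by it (trans entries by
the genome-wide trans mean). By construction each cis diagonal of the O/E
matrix averages to exactly 1, which the suite asserts to $10^{-12}$,
together with the exact reconstruction identity O/E × expectation =
balanced value.

The self-diagonal is excluded from every statistic. The container does not
force it to zero, because sum-pooling to a coarser grid must conserve the
total count exactly and the pooled diagonal absorbs near-diagonal pairs;
simulated matrices nevertheless emit zero diagonals.

# Compartments

PC1 is computed per chromosome as the leading eigenvector of the Pearson
correlation matrix of cis O/E rows (correlation, not covariance, so
amplitude differences between bins do not dominate). The only NAs inside
the unmasked submatrix sit on the self-diagonal; they are imputed with
column means so the fast complete-observation correlation path applies —
pairwise-complete correlation is cubic in bin count and prohibitive at
2,000 bins. The eigenvector sign is arbitrary, so `orient_pc1()` flips it
when its correlation with a reference track (gene density, GC, or planted
truth) is negative — an automated stand-in for the manual curation used in
practice, required for unattended testing.

Switching between consecutive stages is tabulated per bin into
A→A/A→B/B→A/B→B; the switching fraction is (A→B + B→A) over classified
bins. Whether "2% of the genome" counts bins or bp is ambiguous in the
field; on the uniform bin grids used here the two conventions coincide,
and the table reports counts so either can be derived.

Saddle plots rank bins by PC1 into equal-occupancy quantiles (default 50,
reduced to the classified-bin count on toy data) and average cis O/E per
quantile pair. Strength is (AA-corner mean + BB-corner mean) / (2 ×
AB-corner mean) with corners the extreme 20% of quantiles — a repo
definition, since the upstream `compartment_strength` utility is not
specified formula-wise in the literature it comes from. Rank-based
construction makes the statistic invariant to any monotone rescaling of
PC1.

# Distance-stratified metrics

Separation is always the distance between bin starts, so it is a multiple
of the resolution. DLR follows the published definition: per bin, log2 of
cis contacts beyond 3 Mb over cis contacts within 3 Mb, with pairs at
exactly 3 Mb counted local ("within"). ICF is the trans share of a bin's
total contacts — the proportion form is the default because the source
figure plots a bounded score; a log2 variant is available. The two tracks
satisfy an exact conservation identity (local + distal + trans = bin
marginal) that the suite checks, and both equal brute-force
pair-enumeration oracles to $10^{-9}$ on matrices of up to 300 bins.
Group contrasts (whole genome / compartment A / compartment B) use
two-sided Wilcoxon rank-sum tests; the source figures print p-values
without naming a test, and the rank-based choice avoids normality
assumptions on log-ratio tracks.

# TADs

The insulation score averages contacts between the $w$-bin blocks upstream
and downstream of each bin, z-scores per chromosome and window, and
averages across windows (defaults 150/250/500 kb at 50-kb bins — the
published pipeline says only "a sliding window of variable size").
Boundaries are local minima whose depth below the nearer flanking maxima
is at least `delta` (0.01, the published parameter), leftmost bin on
plateaus; domains between consecutive boundaries are kept within the
published 150–500 kb bounds, with all candidates retained separately.
Z-scoring makes the track invariant to global rescaling, and boundary
calls are invariant to adding a constant.

Pileups rescale each domain ± 0.5 Mb window to a 90 × 90 pixel grid by
NA-aware bilinear interpolation and average; domains touching a chromosome
edge are skipped and logged. Domain strength is log2(mean intra-domain
O/E / mean domain-to-flank O/E) with equal-length flanks — a repo formula
for a phrase the literature uses without one. Stage dynamics summarize each
domain by relative variance (variance/mean of per-stage strengths); the
selection of "stable" domains is left to the user via the ranked table,
since no threshold is published.

# Radial classifier

Per model: center = centroid of valid beads, distance = Euclidean norm
after centering, nuclear radius = mean of the farthest 5% of distances
(ceiling rule, stable tie order). QC excludes models with fewer than 20
valid beads, then models whose radius deviates more than 3 SD from the
survivor mean (the multiplier is configurable; the source states only
"standard deviation-based filtering", and we filter per-model radii rather
than per-bead distances — an interpretation the exclusion log makes
auditable). Note a structural property of SD rules: a single outlier among
$n$ values cannot exceed $(n-1)/\sqrt n$ standard deviations, so lone
extreme models are only detectable for $n \gtrsim 10$; tests exercise the
rule at 40 models.

Classes use the published strict cuts — center $r < 0.2$, peripheral
$r > 0.8$, boundaries intermediate, $r > 1$ allowed and peripheral.
Relative distance is computed against each model's own radius (an
ensemble-mean-radius mode is available behind a flag). For a uniform ball
the top-5% radius is $0.9914R$ in closed form, giving peripheral and
center fractions of $1 - (0.8 \cdot 0.9914)^3 \approx 0.50$ and
$(0.2 \cdot 0.9914)^3 \approx 0.008$, which both the Monte-Carlo oracle and
the generator reproduce within 1%. Ensemble profiles average diploid
duplicate beads within each model before averaging across models; LAD
flags require ≥ 50% bin overlap.

The bead generator places non-LAD beads uniformly in a ball and LAD beads
with radial density $\propto r^{2+\beta}$, whose mean relative radius is
$(3+\beta)/(4+\beta)$ — $\beta = 0$ recovers the uniform 3/4, making the
bias testable in closed form.

# Enrichment

Fold enrichment of a state against a feature is
(overlap bp / state bp) / (feature bp / genome bp), computed on per-label
merged intervals via `GenomicRanges`. Overlap is measured in base pairs
(not interval counts) for scale invariance. Track aggregation over
intervals weights bin values by overlap bp.

# What passing tests do and do not show

The generator emulates power-law decay, checkerboard compartments, planted
TADs and switches, long-range/trans boosts, Poisson noise, and peripherally
biased LAD beads. It does not emulate restriction-fragment structure,
mappability or GC bias, copy-number variation, centromeres/telomeres, or
inter-cell heterogeneity beyond Poisson noise. Recovery rates measured here
(e.g. ≥ 95% compartment label agreement at $s = 0.4$, ≥ 90% boundary
recovery at $b = 2$) therefore characterize the algorithms under the
planted model, not expected performance on real libraries. Problem sizes
are deliberately desk-scale: 100–2,000 bins per matrix, $10^5$ beads per
ball fixture, 10 seeds per stochastic contract — the package's own choice
of study conditions, stated here so results are interpretable.

# Numerical choices

* Balancing tolerance $10^{-9}$ marginal CV, cap 5,000 iterations, loud
  failure.
* O/E undefined (NA) where a separation has no unmasked pair; NAs
  propagate, never silently zeroed.
* DLR undefined where either sum is zero; ICF undefined for zero-marginal
  bins.
* Boundary tie-break: leftmost bin of a flat minimum.
* Pileup interpolation: bilinear with missing-neighbor weight
  renormalization.
* All generators take explicit seeds and restore the caller's RNG state;
  identical seeds give bit-identical output, which the pipeline turns into
  byte-identical TSVs.
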