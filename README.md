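# hicdyn

Chromatin-architecture dynamics from multi-stage Hi-C. `hicdyn` is for
computational biologists studying how genome folding reorganizes across an
ordered series of cell states — the motivating setting is terminal
erythroid differentiation (BFU-E → CFU-E → ProE → basophilic →
polychromatic → orthochromatic erythroblasts), where heterochromatin
condenses, B–B compartment contacts strengthen, and chromatin shifts toward
the nuclear periphery. The package turns binned contact matrices and 3D
bead-model ensembles into the standard quantitative read-outs of that
process, and ships a synthetic-data generator with planted ground truth so
every statistic is testable without access-controlled data.

## What it computes

* **Matrix layer** — sparse bin-pair / dense text I/O (0-based half-open
  coordinates), coverage masking, iterative-proportional balancing to the
  equal-marginal contract, distance-expected profiles, observed/expected
  (O/E) transforms, sum-pool coarsening, replicate Pearson correlation.
* **Compartments** — per-chromosome PC1 from the correlation of cis O/E
  rows (labels: A where PC1 > 0), automatic sign orientation against a
  reference track, stage-to-stage switch tables
  (A→A/A→B/B→A/B→B), saddle plots by PC1 quantile, compartment strength
  (AA+BB over 2·AB corner means), and log2 A–A/B–B/A–B contact ratios.
* **Distance metrics** — P(s)-style decay curves in logarithmic bins,
  long-range contact fraction (> 50 Mb by default), per-bin
  **DLR** = log2(cis contacts > 3 Mb / cis contacts ≤ 3 Mb), per-bin
  **ICF** = trans share of a bin's contacts, with compartment-stratified
  Wilcoxon contrasts.
* **TADs** — multi-window insulation score (mean z-scored block contact),
  boundary calling by prominent local minima (delta 0.01, domains
  150–500 kb), boundary-anchored profiles, rescaled O/E pileups, domain
  strength log2(intra/flank) and its across-stage relative variance,
  inter-TAD contact proportions per distance window (incl. > 80 Mb).
* **Radial 3D** — bead-model ensembles (TSV or cmm-like XML): centroid
  distances, nuclear radius (mean of farthest 5% of beads), QC (≥ 20 valid
  beads, 3-SD radius filter, logged exclusions), center / intermediate /
  peripheral classes at 20% / 80% of the radius, ensemble-averaged per-bin
  radial profiles with LAD overlay.
* **Annotation** — BED interval sets, per-label merging, coverage fold
  enrichment of states against features relative to the genome, track
  aggregation over intervals, log10 interval-size distributions.
* **Pipeline** — `run_pipeline()` drives all of the above per stage and
  across stages from one config (list or YAML) and writes a TSV bundle
  plus a manifest with a config fingerprint; fixed config + seed gives
  byte-identical output.

## Worked example

```r
library(hicdyn)

# two chromosomes at 1 Mb, planted checkerboard compartments (s = 0.4)
genome <- genome_spec(c(chr1 = 200e6, chr2 = 150e6), 1e6)
prof   <- rep(rep(c(1, -1), each = 5), length.out = n_bins(genome))
stage  <- stage_spec("ProE", alpha = 1, profile = prof, s = 0.4,
                     trans_level = 0.01, depth = 2e6, seed = 3)

cm <- simulate_contact_matrix(genome, stage)
cm <- balance_matrix(mask_low_coverage(cm))

ct <- compartment_track(cm, reference = prof)
mean(ct$label == ifelse(prof > 0, "A", "B"), na.rm = TRUE)
#> [1] 1

saddle(cm, ct, n_quantiles = 20)$strength
#> [1] 1.787854

compartment_contact_ratio(cm, ct)
#>         AA         BB         AB
#>  0.2894049  0.2881837 -0.5718917

long_range_fraction(cm, 50e6)
#> [1] 0.1101904
```

All 350 planted labels are recovered; compartment strength 1.79 means the
AA/BB saddle corners are ~1.8× the AB corners; positive AA/BB and negative
AB log2 ratios show same-compartment enrichment; 11% of cis contacts span
more than 50 Mb under the α = 1 decay.

For a full run, `run_pipeline(list(stages = c("early", "late")))` writes
per-stage compartment/DLR/ICF/insulation tracks, boundary calls, switch
tables, strength dynamics and a manifest under `hicdyn_out/`.

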