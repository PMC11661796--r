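---
title: "Methods: sort-seq analysis of promoter emergence in motif-dense sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sort-seq analysis of promoter emergence in motif-dense sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandscan)
```

# The problem

Bacterial genomes contain "promoter islands": AT-rich, often horizontally
transferred regions densely packed with predicted sigma70 −10 (consensus
`TATAAT`) and −35 (consensus `TTGACA`) boxes that nonetheless rarely drive
transcription. Sort-seq mutagenesis probes how promoters emerge from such
sequences: a 150 bp template ("parent") is mutagenized by error-prone PCR
into a library of point-mutant "daughters", the library is cloned between
divergent GFP/RFP reporters, cells are FACS-sorted into four fluorescence
bins per channel, and each bin is deep-sequenced. Each genetic strand is
analyzed as an independent parent (GFP reports the top strand, RFP the
bottom).

`islandscan` implements the complete downstream analysis of such an
experiment, plus a ground-truth simulator so that every stage can be
validated end to end without access to the original sequencing data.

# Fluorescence scoring and filtering

A daughter observed `R_f` times in bin `f` (1 = none, 2 = low,
3 = moderate, 4 = high) gets the read-weighted mean bin index

$$F = \frac{\sum_{f=1}^{4} f\,R_f}{\sum_{f=1}^{4} R_f} \in [1, 4]
\;\text{a.u.},$$

computed independently per channel (`fluorescence_score`). A sequence is
called a promoter at `F >= 1.5` a.u. The boundary convention is
configurable (`classify_promoter(strict = )`): we default to `>=` because a
parent scoring 1.49 a.u. must be called a non-promoter.

Quality filters (`filter_daughters`) retain daughters that (i) match the
150 bp template length, (ii) occur at least once in the unsorted library,
(iii) accumulate at least 30 reads in the entire dataset, and (iv) map to
their closest parent (minimal Hamming distance, ties broken by input order
and flagged) at distance at most 10; parents with fewer than 2000 surviving
unique daughters are then dropped entirely. "Entire dataset" is read as the
sum of all nine counts (both channels' bins plus the unsorted library);
this is configurable (`count_unsorted`) because the wording admits either
reading.

# PWM scanning

`build_pwm` converts aligned instances into a log2-odds matrix against a
uniform background,
$\mathrm{LO}_{i,b} = \log_2\!\big(\tfrac{c_{i,b} + a}{n + 4a} / 0.25\big)$
with pseudocount $a$ (default 0: an unobserved base scores $-\infty$, which
can never clear a finite threshold). The default hit threshold is the total
information content
$\mathrm{IC} = \sum_i \big(2 + \sum_b p_{i,b}\log_2 p_{i,b}\big)$, the only
reading compatible with hexamer thresholds of 3.98 bits (−10) and 3.39 bits
(−35) from RegulonDB-derived instance sets; "low-affinity" scans halve
these thresholds. Motifs published only as an IUPAC consensus (the UP
element, `NNAAAWWTWTTTTNNWAAASYM`, threshold 19.2 bits, relaxed 4.8 bits)
expand degenerate letters to equal frequencies (`pwm_from_consensus`).

Coordinates are 0-based, half-open, on the analyzed strand; bottom-strand
(RFP) scans run on the reverse complement. Overlap between intervals means
non-empty intersection of half-open intervals throughout. `pair_boxes`
pairs −35/−10 hits at spacers of 15–20 bp
(spacer = start10 − (start35 + 6)); `annotate_tgn` flags extended −10 boxes
(`TG` + one spacer base immediately upstream). Every above-threshold start
position counts as a hit; overlapping same-class hits at adjacent offsets
are counted separately.

# Mutual-information footprints and hotspots

For each parent's daughter set, records are split into three equal-sized
pseudo-replicates (`split_pseudoreplicates`) to expose sampling noise. Per
replicate and position $i$, the corrected mutual information between base
identity $b$ and the fluorescence score rounded half-up to
$f \in \{1,2,3,4\}$ is

$$I_i(b,f) = \sum_b \sum_f p_i(b,f)\,
\log_2\frac{p_i(b,f)}{p_i(b)\,p(f)}
\;-\; \frac{(n_b-1)(n_f-1)\log_2 e}{2N},$$

with $n_b = n_f = 4$ and $N$ the replicate size; $0\log 0$ terms contribute
0 and the $O(N^{-2})$ remainder of the bias expansion is unspecified in the
source method and dropped. Each replicate profile is smoothed with a
Gaussian kernel ($\sigma = 1$ position, radius $4\sigma$, reflect
boundary — the common image-filter default); the mean and (population)
standard deviation are then taken across replicates. Whether smoothing
precedes or follows the mean/std is not fully pinned by the method's
description; both orders are implemented (`mi_profile(smooth_first = )`),
defaulting to smoothing each replicate first, which matches figure legends
describing the shaded band as the replicate standard deviation of the
plotted (smoothed) curves.

The *adjusted* MI is mean − std with values below 0.0005 bits truncated to
0. Hotspots are interior positions at or above the 90th percentile of the
whole adjusted profile (zeros included; linear interpolation between order
statistics, the numpy/R type-7 default) that strictly exceed both
neighbours. The rounding of `F` to bins is half-up (1.5 → 2); boundary
positions cannot be hotspots. Downstream proximity tests use peak ± 3 bp.

# Motif gain/loss association

For each parent, channel and PWM, a width-wide window slides one position
at a time (`scan_associations`). Daughters are partitioned by their own
window score into Motif(+) and Motif(−) lists; when both lists exceed 10
values, a two-sided Mann-Whitney U test compares them (exact for tie-free
groups below 9 per side, otherwise the normal approximation with tie and
continuity correction, matching the scipy default the original analysis
used). Tests with p < 0.05 lying within ±3 bp of a hotspot peak are
recorded; Benjamini-Hochberg q-values are computed over the recorded set
(poolable across parents per motif class and channel via `pool_bh`;
channels are kept separate by default). A significant effect additionally
requires |ΔF| > 0.5 a.u., where ΔF = median(F+) − median(F−). Direction is
"loss" where the parent itself carries an above-threshold motif in the
window, "gain" otherwise.

`new_box_census` lists positions where daughters gain boxes absent from
the parent; `classify_gain` labels gains overlapping a preexisting box of
the same class as homo-gains and of the other class as hetero-gains (homo
takes precedence when both overlap, and all overlapped hits are reported);
`census_spacing_and_tgn` counts new boxes with a cognate box at legal
spacing and new −10 boxes with the TG extension.

# Emergence statistics

`compute_pnew` is the fraction of daughters at or above the promoter
threshold. The emergence probability versus parent fluorescence is fitted
with the increasing logistic

$$P_{new} = \frac{L}{1 + e^{-k (x - x_0)}}$$

by Levenberg-Marquardt least squares (`fit_sigmoid`; start values
L = max(y), x0 = 1.5 a.u., k = 10; L bounded in (0, 1]). Note some
write-ups print the exponent as $-k(x_0 - x)$, which is decreasing for
k > 0; we implement the canonical increasing form (matching a rising
emergence probability), so a fit quoted in the decreasing parameterization
carries k of the opposite sign. Flat responses are flagged degenerate
rather than fitted. Per-parameter Wald p-values come from the nls summary.

`feature_regression` is ordinary least squares with a Wald test on the
slope and squared Pearson correlation. `kmer_analysis` enumerates all
$\sum_{k=1}^{6} 4^k = 5460$ k-mers, counts overlapping occurrences on each
parent's analyzed strand only (GFP: top, RFP: reverse complement — P_new is
channel-specific), keeps k-mers occurring at least 3 times in at least one
parent, regresses P_new on the counts, applies BH at FDR 0.05, and refits
leaving each parent out — operationalizing the observation that a single
extreme parent can carry all k-mer significance. Whether occurrence
counting should allow overlaps is not specified; overlapping counting was
chosen and fixed.

Scrambling nulls: `scramble_whole_parent` permutes a parent uniformly
(composition conserved); `overlap_null_counts` re-classifies every
hotspot's −10/−35 overlap on scrambled parents with hotspot coordinates
held fixed; `chisq_goodness_of_fit` compares the two 4-category count
vectors with $\chi^2 = \sum (O-E)^2/E$ on 3 degrees of freedom, using the
comparison group's counts as expected values — the only formulation that
reproduces all three published statistics (46.1, 21.4, 2.51) from the
published count vectors; a 2×4 contingency test would not. One scrambled
replicate per parent is the default (`n_reps` configurable; the original
count is not stated). `scramble_motif_region` permutes only a motif's span,
preserving regional GC content and flanking spacing, and retries (up to
1000 times) until no new above-threshold hit of any avoided PWM overlaps
the region. `hns_candidate_outliers` applies the two-sided Tukey fence
(1.5 × IQR, type-7 quartiles) to per-parent knockout-vs-wild-type
fluorescence changes.

# The simulator

`simulate_sortseq` generates data the pipeline can be held against:

* **Parents**: random background at 40% GC (promoter islands are AT-rich)
  with one planted consensus −35/−10 pair per template (default spacer
  17 bp, top strand), plus 4 decoy consensus boxes placed uniformly at
  random subject to non-overlap and to not forming a legally spaced pair —
  keeping the ground-truth activity attributable to the planted promoter.
* **Daughters**: substitution counts follow a zero-truncated Poisson
  calibrated so the truncated mean equals 2.5, capped at 10 (only the mean
  and range of the error-prone PCR are documented; the cap redistributes
  negligible mass). Positions are uniform without replacement,
  substitutions uniform over the three alternatives (the polymerase's
  transition bias is not documented; a weight matrix would be a
  straightforward extension). Daughters are deduplicated to the requested
  count, so Hamming distance to the parent equals the drawn count.
* **Latent activity**: per strand, boxes are windows scoring at or above
  an activity PWM's information-content threshold (single-consensus
  matrices with pseudocount 0.01); the activity is the best legal-spacing
  pair score sum, 0 if none, minus a repression term while a planted H-NS
  site is intact; fluorescence is
  $F = 1 + 3/(1 + e^{-(a - a_0)/s})$ with $a_0 = 20$, $s = 0.6$, chosen so
  an intact consensus pair saturates (F > 3.99), a single box-destroying
  substitution collapses to the floor, and a pairless sequence sits at
  F ≈ 1. This logistic-of-scores model is the simplest one consistent with
  the pairing requirement and graded fluorescence; it is a stand-in, not a
  claim about sigma70 biophysics.
* **Reads**: the true bin is F rounded half-up; `depth` reads (default 50
  per channel) are multinomial with probability 1 − 2ε on the true bin and
  ε on each existing adjacent bin (edges renormalized), ε = 0.05 by
  default; unsorted-library counts are Poisson with mean 5. Sequencing
  errors, PCR duplicates and FACS mis-sorts beyond nearest-neighbour
  spillover are deliberately not modelled — so passing recovery tests
  demonstrates correctness of the analysis under idealized noise, not
  robustness to every artefact of real libraries.

All generators are bit-reproducible under a fixed seed.

# Validation and problem sizes

The test suite checks each operation against independent oracles
(brute-force MI double sums, exact Mann-Whitney enumeration, a hand-written
BH step-up, type-7 percentile arithmetic) and the published closed-form
values. `recovery_benchmark` runs the full pipeline on 20 seeded replicates
of 10 parents × 2000 daughters at depth 50 and ε = 0.05 — sizes chosen to
mirror one parent's worth of real data while keeping a complete run in the
low minutes on a single core — and measures that at least 90% of planted
promoters yield a hotspot within 3 bp of a planted box and at least 95% of
planted −10 positions recover the loss-effect sign:

```{r, eval = FALSE}
bench <- recovery_benchmark(n_replicates = 20, n_templates = 10, seed = 1)
bench$hotspot_recovery   # 1.000 on the default seeds
bench$sign_recovery      # 0.995
```

# Known limitations

* Published analyses derived their box PWMs from 145 RegulonDB-curated
  instances; those instance files are external inputs. The packaged
  instance sets (`synthetic_minus10_instances` etc.) are synthetic
  stand-ins for examples and simulation, so information contents computed
  from them do not reproduce the published 3.98/3.39 bit values — supply
  the real instance files to `build_pwm` for that.
* Binary thresholds everywhere (motif presence, promoter call, hotspot
  call) inherit the method's own bluntness: near-threshold effects are
  invisible by construction.
* The MI correction drops the unspecified $O(N^{-2})$ term; profiles from
  very small replicates (< ~50 records) can go noticeably negative before
  adjustment.
* Fluorescence conflates transcription and translation; nothing here
  separates them.
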