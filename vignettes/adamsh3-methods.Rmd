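---
title: "Methods: SH3 interaction profiling of ADAM tails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SH3 interaction profiling of ADAM tails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
underlying experimental design leaves them open.

## Motif grammar and scanning

SH3 domains recognize proline-rich peptides; the canonical consensus motifs
are class I `+ΦPxxP` and class II `PxΦPx+` (`+` = K or R, `Φ` hydrophobic,
`x` any residue), with an atypical `PxxDY` motif recognized by Eps8-family
SH3 domains, and family-specific high-affinity motifs `RxAPxxP` (SNX9),
`RxLPxxP` (nephrocystin) and `RxIPxxP` (its ADAM19-style relative).
`compile_pattern()` turns such a specification into an ordered list of
allowed-residue sets; `scan_motifs()` tests every window of a tail against
every pattern and reports **all** matches, overlapping ones included,
because overlapping motifs within one proline cluster are the biological
norm. Deduplication happens only on identical (start, pattern) pairs.

Choices that the motif literature does not fix:

* **Hydrophobic set `Φ`** — no single definition is universal; the default
  `{A, V, L, I, M, F, W, Y, P}` is a superset of common definitions, erring
  toward sensitivity (a candidate site wrongly flagged costs one extra
  array peptide; one missed costs an interaction). It is configurable and
  echoed in every report header.
* **Coordinates** — 1-based with inclusive ends, relative to the tail's
  first residue, not to the full-length protein; stated in output headers.
* **Cluster merging** — hits whose spans lie within `gap_merge = 8`
  residues of one another merge into one proline cluster; 8 residues makes
  the multi-motif blocks on the densest tails coalesce into single clusters
  while keeping clearly separate sites apart. Clusters are numbered with
  Roman numerals from the membrane-proximal end, the field's convention.
* **Peptide tiling** — array peptides are 14–17-mers. A cluster is given a
  flank of 4 residues each side (clipped at the termini); if the flanked
  region fits one window a single centered peptide is emitted, otherwise
  17-mer tiles advance left-to-right with at least 7 residues of overlap,
  so any motif up to 7 long appears whole in some tile. Multiple tiles get
  suffix letters (`A12-IIIb` style). Tails shorter than 14 residues yield a
  single full-tail peptide flagged `short`.

The exact residue spans of the published cluster circles and the exact 36
array peptides are not printed anywhere; the tiler approximates them and
the package does not claim to reproduce that panel identically. Under the
strict consensus grammar the ADAM10 and ADAM17 tails contain no hit —
consistent with those two baits showing no SH3 selectivity in panning —
although both tails do contain less canonical proline-rich stretches.

## Phage-screen statistics and tier classification

A screen is a clone-count vector over SH3 identities plus a reported
enrichment factor (parsed as a flagged lower bound when written `">10,000"`,
never silently truncated). `dominance_fraction()` is the share of sequenced
clones taken by the top-*k* domains, the statistic used to describe strong
screens (94% top-2 in the strongest ones) and to decide when a reduction
library is warranted.

The published tier labels are qualitative. The package operationalizes them
with configurable thresholds, echoed in all reports:

* **dominant** — clone fraction ≥ 0.40 in at least one *complete-library*
  screen (a binder can dominate a reduction screen merely because stronger
  competitors were removed, so reduction screens cannot confer this tier);
* **strongly selected** — fraction ≥ 0.10 in ≥ 2 independent screens (any
  library);
* **significantly enriched** — ≥ 2 clones in each of ≥ 2 independent
  screens;
* highest satisfied tier wins.

"Independent screens" means distinct screen ids; the experimental
requirement that libraries be independently prepared is carried as a
`library_id` attribute but not enforced. Because the per-SH3 clone counts
behind the published tier table were never released, these thresholds
cannot be replayed against real counts; they are instead validated by
parameter recovery on the synthetic generator (below), and the packaged
tier table is checked against the independently published selected-domain
totals (8, 7, 0, 8, 14, 0, 14), which it reproduces exactly.

Reduction libraries (`design_reduction_library()`) exclude the
dominant-tier (optionally also strongly-selected) domains and renormalize;
excluding everything is an error. All libraries in this design additionally
lack the Crk(II) and CrkL(II) SH3 phages, which are prone to
affinity-independent selection. A clone of an excluded SH3 in loaded data
is treated as a contamination signal and raises an error rather than a
warning.

## Biopanning simulator

Capture is modelled as single-hit binding proportional to
abundance × affinity with a nonspecific floor: per round,
`f_i ∝ a_i·max(w_i, floor)`, and the next round starts from those
frequencies; sequencing draws a multinomial sample from the final
frequencies. Affinity weights are relative, with 1.0 defined as
background-level; the floor (default 0.01) reproduces the observed
phenomenon that negative-control panning retains a small, unbiased set of
phages. The simulated enrichment factor is `Σ a_i w_i / Σ a_i·floor`. There
is no amplification-bias term: no amplification data exists to calibrate
one, so enrichment calibration against the measured 5–>10,000 range is
qualitative only.

Defaults are the study's conditions: sequencing depth 150 clones per screen
(mid-range of the 47–384 observed), two screens per library stage (every
bait was screened at least twice per library), and **two capture rounds**
per screen. The round count is the one genuinely open parameter: standard
biopanning uses more than one round, and with two rounds two planted strong
binders (w = 50 in a 40-domain uniform library) sit at an expected
frequency of `50²/Σ ≈ 0.48` each — the regime matching the observed 72–94%
top-2 dominance — whereas a single round would place them at ≈ 0.36,
below any sensible dominance threshold. The sequential-screening simulator
alternates panning and reduction design until no domain is newly excludable
under the chosen policy, which terminates within the library size.

Recovery behaviour under these defaults, verified in the test suite over
200 seeded runs: planted w = 50 binders are classified dominant in ≥ 95% of
runs, and planted w = 10 binders — invisible above the strong threshold
while the dominant pair monopolizes the clones — reach strongly-selected
after one reduction stage in ≥ 90% of runs.

## Array quantification chain

Each slide is one SH3 probing: every peptide spotted in triplicate plus 33
empty spots. The chain follows the experimental processing order exactly:

1. **Background** = mean(empties) + 2 × SD(empties). The *sample* (n − 1)
   SD is used — the experimental description says only "standard
   deviations" — and the multiplier is configurable. Fewer than two empties
   is an error (SD undefined).
2. **Averaging then subtraction** — triplicates are averaged first, then
   the slide background subtracted (the stated processing order; whether
   clipping preceded averaging is unstated). Negative results are clipped
   to 0 explicitly, with the clip count logged: 0 is defined as
   background-level binding ("white" in the heat-map convention).
3. **Per-probe normalization** — each probe column is scaled so its
   strongest peptide sits at exactly 2; all-zero columns stay zero and are
   flagged `all-background` rather than divided by zero. The operation is
   idempotent and invariant to rescaling a slide's raw signals, so probe
   concentration (2–20 µg/ml, chosen empirically per probe to balance
   signal) is carried as metadata only and never corrected for.
4. **Clustering** — agglomerative, distance 1 − centered Pearson
   correlation, average linkage: the common configuration of the Cluster 3
   tool. Zero-variance rows/columns have no defined correlation; they are
   assigned the maximum distance 2.0 to every other leaf and flagged. The
   agglomeration itself is delegated to `stats::hclust` and cross-checked
   in the tests against an independently written naive O(n³) agglomerator;
   ties are resolved deterministically by input order. GST-only control
   probings are ordinary columns that can be excluded from clustering.
5. **Export** — TSV (full precision, bit-exact round trip) and
   CDT/GTR/ATR in Java TreeView's line-positional format, rows and columns
   in dendrogram leaf order, node similarity written as 1 − merge height.
   Grayscale convention: 0 → white (background), 2 → black (strongest
   binding per probe).

The array simulator draws spot signal as
`truncated-Normal background + truth × lognormal noise` with unit-mean
noise of configurable CV (default 0.2); lognormal multiplicative noise was
chosen over additive Gaussian because fluorescence signals are non-negative
and span the wide per-probe concentration regime. With zero noise the chain
recovers scaled truth exactly; at CV 0.2 the normalized output correlates
with scaled truth above 0.9 in ≥ 95% of seeded runs.

## Orchestration and provenance

`run_full_pipeline()` chains scan → tile → simulated sequential screening
(affinities derived from the packaged tier table: dominant 50, strongly
selected 10, significantly enriched 3, background 1) → classification →
array simulation and quantification → clustered heat-map export. Every
TSV/FASTA/JSON output embeds the configuration hash (computed over the
scientific configuration, not the output location) and seed, so two runs
with equal hashes are byte-identical; the TreeView files are the one
exception, because that parser tolerates no comment lines — their
provenance lives in the run's JSON summary. ADAM19, whose tail sequence
was never printed, is excluded from all sequence-level analyses and
reported as `"sequence unavailable"`; its screen-level fixtures (tier
assignments, totals) are first-class.

## Problem sizes and what the tests do (and do not) show

The test suite exercises: scanner–oracle equivalence on 1,000 random
sequences (lengths 20–200) for all shipped patterns; the normalization
contract, idempotence and scale equivariance on 1,000 random matrices;
multinomial sampling error bounds over 500 seeded draws at n = 10,000;
planted-binder recovery over 200 seeded screening series; and clustering
against the naive reference on 10×8 matrices. These sizes make the full
suite run in a few minutes on one CPU while keeping Monte-Carlo bounds
meaningful.

The generators emulate the *statistical* structure the analysis assumes —
multinomial capture, lognormal spot noise, triplicate layout — not phage
growth kinetics, display biology, sequencing errors, spatial slide
artifacts, or peptide synthesis failures. Passing recovery tests therefore
demonstrates that the analysis chain is correct and well-calibrated under
its own model, not that the model captures every feature of real panning
or array data. Known limitations: tier thresholds are a numeric
operationalization of qualitative published labels; the peptide panel is
approximated by the tiler; and enrichment factors are carried as reported
inputs, not re-derived from titers, which were never published.
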