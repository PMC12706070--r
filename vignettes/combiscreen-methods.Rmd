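---
title: "Models and methods behind combiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind combiscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combiscreen)
```

# Setting

Combinatorial activator screens fuse ordered tuples of activation
domains (ADs) and inert protein folders (PFs) onto a recruitable
scaffold, tag each part with a fixed 8-nt barcode and each transduction
event with a 6-nt UMI, and read out two phenotypes by sequencing:
**activation**, from the distribution of each construct's reads across
four extreme FACS bins of target expression, and **toxicity**, from
each construct's depletion in transduced cells relative to the plasmid
pool. A 25-part library expands to 25 single, 625 bipartite and 15,625
tripartite ordered fusions; order matters, so `A-B` and `B-A` are
distinct constructs, with position 1 defined as the part closest to the
scaffold.

This vignette documents the generative model of the simulator, the
scoring procedures, the numerical choices, and the design decisions
that were genuinely open — the things a maintainer would want written
down.

# The synthetic screen generator

`simulateScreen()` is first-class, tested code, not a fixture: it
produces complete screens with known per-part ground truth so that
every downstream stage can be validated end to end.

**Transduction.** Integrations per cell are Poisson with mean `moi`
(default 0.1, the low-MOI regime real screens target so that most
infected cells carry a single provirus). Cells with at least one
integration keep one construct drawn proportional to plasmid abundance;
a cell with several integrations keeps a uniform choice among them.
Each transduction event receives a fresh random UMI, mirroring how UMI
diversity in the plasmid pool individualizes infection events.

**Growth.** A construct with per-passage fitness cost *c* (log2 units)
depletes deterministically as 2^(−*c* × passages); the default is 4
passages, matching the 2–4 selection passages of a typical screen.
Deterministic expected-count depletion (rather than per-passage
multinomial resampling) keeps the model minimal; sampling noise is
reintroduced at the sequencing step.

**Latent parameters.** AD strengths are log-normal (median 20
fluorescence units, log-SD 0.9), giving the order-of-magnitude spread
between weak and potent domains that single-domain screens show;
folders contribute zero activation. Every part carries a
gamma-distributed fitness cost (shape 1.5, mean 0.25 per passage), so
construct toxicity — defined as the **sum** of part costs, the additive
behavior reported for multi-part constructs — varies continuously
across the library and rank-recovery statistics are well defined. The
pairwise interaction matrix defaults to zero (bipartite activation is
approximately additive); an `order_sensitivity` flag switches to
position-ordered, asymmetric interaction terms to emulate
order-dependent behavior of triple fusions.

**Sorting.** Per-cell fluorescence is
`exp(log(baseline + summed strength) + N(0, noise_sd))` with
`noise_sd = 0.5` on the log scale — enough biological/staining spread
that every construct population straddles several gates (without it,
mid-strength constructs would vanish entirely into the discarded middle
50% and coverage would be unrealistically sparse). Cells are ranked and
gated at population quantiles into four bins of 12.5% each covering
only the extremes (two low, two high); ties are broken by construct id
then UMI, a stable rule that makes sorting deterministic even in the
degenerate zero-noise, equal-strength case. The per-bin mean
fluorescence intensities are returned alongside the bin memberships —
they are the external MFI input the scoring stage needs, not constants.

**Sequencing.** Per condition (four bins, unsorted cells, plasmid),
reads are multinomial over (construct, UMI) cell counts at
`read_depth` per condition. With probability `jackpot_prob` a
(construct, UMI) unit's count is multiplied by `jackpot_factor`,
exercising the outlier-UMI filter. The plasmid pool is log-normally
jittered around equal representation (log-SD 0.3, a typical pooled
cloning skew) and splits each construct's mass over a few cloning UMIs.

**Controls.** Three barcoded control types are spiked into the plasmid
pool (default 1.5% each, the bi/tripartite spike level; 3.6% matches
the single-domain screens): a *supernatant* control that cannot be
packaged and reaches cells only as a strongly attenuated plasmid
carryover trace; a *multi-copy* control that lacks selection resistance
and therefore survives only in cells carrying a second, resistant
integration; and a *mutant-scaffold* control that behaves as a
zero-strength construct. Control reads carry their own barcodes,
disjoint from part barcodes, and are dropped before scoring.

**What the generator does not emulate.** No base-call error model
(malformed reads are injected explicitly in tests instead), no
PCR chimera or lentiviral recombination between barcodes, no
cell-cycle or batch effects, and the fluorescence-vs-potency link is an
assumed additive-lognormal stand-in — the screens themselves do not
constrain its functional form. Passing recovery tests therefore shows
the pipeline is self-consistent under a plausible generative model, not
that real data obey that model.

# Read layout and extraction

Reads are anchored on an upstream anchor followed by scar-delimited
14-nt blocks (8-nt barcode + 6-nt UMI) and terminal context. Because
each cloning round inserts the new domain between the previous ORF and
its barcode, barcodes accumulate **innermost-last**: the block of
position 1 is read last. The layout is configurable
(`block_order = "innermost_first"`) since amplicon designs vary.

Each block carries a UMI, but a clone is identified by a single UMI;
the package places the clone UMI in the position-1 block and fills the
other blocks with deterministic nucleotide rotations of it, making
encode→decode lossless — a modeling convenience, documented here
because real libraries carry independent per-round UMIs whose
combination identifies the clone.

Anchor and scar matching is exact, case-insensitive and forward-strand
only (amplicon sequencing with fixed primers); all offsets are 0-based
half-open internally. Rejections are data, not errors: every read is
classified as accepted, control, or rejected with a typed reason
(`missing_anchor`, `truncated_block`, `invalid_barcode`, `invalid_umi`,
`missing_scar`, `too_many_blocks`, `unknown_barcode`, `ambiguous`), and
`accepted + control + rejected = total` always. An `N` in a barcode
rejects the read; an `N` in a UMI is kept as a distinct symbol. Barcode
matching is exact by default — whether the original pipelines tolerated
mismatches is unknowable from the outside — with an optional
unambiguous Hamming-1 mode; equidistant matches reject as `ambiguous`.

# Scoring

**Outlier UMIs.** Within each (construct, condition, replicate,
target), a UMI whose count strictly exceeds `umi_outlier_fraction`
(default 0.5) of the construct's condition total is discarded,
protecting against PCR jackpots and amplicon contamination. The default
scope removes the UMI only from the offending condition;
`outlier_scope = "global"` removes it from every condition of that
population, the stricter reading of "an outlier in any condition". One
consequence worth knowing: a construct observed through a *single* UMI
loses all its reads at the 0.5 default — by design, since a lone
dominant clone is indistinguishable from a jackpot.

**Grouping and normalization.** UMIs are pooled by their first *k*
nucleotides: *k* = 3 gives 64 groups, *k* = 2 gives 16, and *k* = 0
aggregates everything into one group per construct (the right choice
when coverage is low, e.g. a 15,625-member tripartite screen). Within
each condition, one scalar rescales all group counts so their mean is
`normalization_target` (default 100) — "average of 100 reads" is
interpreted as the mean over scored units within the condition, since
it is the grouped counts being normalized. Normalization is idempotent
and makes all downstream scores invariant to per-condition sequencing
depth. A condition with zero total reads cannot be normalized and is
dropped with a warning.

**Coverage threshold.** Groups whose summed normalized reads across the
four bins fall below `min_bin_sum` are not scored. The exact thresholds
used in the original screens are not recoverable from the main text, so
they are explicit configuration with defaults of 10 for prefix-grouped
and 40 for aggregated UMIs — stricter when all UMIs form one group,
consistent with thresholds being set higher for aggregated analyses.
Every threshold applied is echoed in `scoreMetadata()` and in the
pipeline manifest; there are no silent defaults.

**Activation.** A scored group's activation score is
`sum(normalized_reads_bin * MFI_bin)` over the four bins; bin MFIs are
per-sort inputs, kept per replicate (whether the original analysis
pooled MFIs across replicates is unstated; per-replicate is the more
conservative choice and is what the simulator provides). Construct
scores are the mean over groups within replicate, then over replicates.
The score strictly increases when read mass moves to a brighter bin.

**Toxicity.** All UMIs are pooled, cells and plasmid conditions are
normalized to the same mean, and
`toxicity = -log2((cells + 1)/(plasmid + 1))`. The source material
prints the ratio without the minus sign in one place but describes the
score as a *negative* log2 ratio wherever values are interpreted
(higher = more toxic, depleted constructs positive); only that sign
convention is self-consistent, so it is the default, with
`negate_toxicity = FALSE` available to flip it. The outlier-UMI filter
is applied to cell counts but **not** plasmid counts (plasmid pools
contain no clonal outliers). Population scores are averaged over the
endogenous-target populations × replicates; reporter populations
derive from the same transductions and are excluded to avoid double
counting. The pseudoread (default 1) bounds the score: a construct
absent from cells scores `log2(101) ≈ 6.66` at the defaults rather
than infinity.

# Combinatorial analyses

Order effects correlate score vectors of order-reversed pairs, one
point per unordered pair. Palindromic constructs (`A-A`, `A-B-A`) are
their own reversal; including them would contribute exact-equality
points and inflate the correlation, so they are excluded. For
tripartite data the analysis can be restricted to constructs with
exactly two ADs and one PF.

Position and copy-number effects take medians over the constructs
carrying a given AD at a given position, or at a given copy number with
inert folders filling the remaining positions. Part classification is
an input annotation: of the three folders in a 25-part library only two
are treated as inert fillers (the third is excluded from filler sets by
default), and folders are rejected as the *focal* part of positional
analyses. Additivity predicts each multi-part score as the sum of its
parts' single-domain scores and reports the Pearson correlation;
residuals flag non-additive (interacting) combinations.

Correlation conventions follow the field's rule: Pearson for
score-vs-score comparisons (replicates, order pairs, additivity),
Spearman for comparisons across measurement modalities (screen score vs
ground-truth strength, screen vs flow validation).

# Sequence features

Net charge per residue counts K/R positive and D/E negative over the
sequence length; histidine is neutral at physiological pH. Hydropathy
is the mean Kyte–Doolittle value rescaled linearly from [−4.5, 4.5] to
[0, 9], the convention of the standard disorder-analysis tooling. The
disorder-promoting set is `{T,A,G,R,D,H,Q,K,S,E,P}`; both sets are
configurable. All features are case-insensitive, and unknown residue
letters are an error rather than silently skipped.

**Kappa and omega** share one blob-patterning engine: residues are
ternary-mapped to group A, group B or neutral; for blob sizes 5 and 6
the local asymmetry `sigma = (fA − fB)² / (fA + fB)` (0 when neither
group is present) is computed over all sliding windows, `delta(g)` is
the mean squared deviation of window sigma from whole-sequence sigma,
and the score is the mean over blob sizes of `delta/delta_max`. Kappa
uses A = {K,R}, B = {D,E}; omega uses A = {W,F,Y,L}, B = {D,E},
implementing its verbal definition (hydrophobe/acidic mixing; lower =
better mixed) rather than any other published variant. Kappa shows no
hit/miss difference in this setting but is implemented for
completeness. The score is undefined (`NA`) when either group is
absent, and such values propagate as missing rather than zero.

**The normalizer.** `delta_max` must be the largest delta attainable at
the sequence's composition. With no neutral residues that is the
classic all-A-then-all-B arrangement. With neutrals present it is not:
a window covers an interior residue *g* times but a terminal residue
once, so when groups are dilute the delta-maximizing arrangement places
the segregated blocks in the interior, not at the ends — naively
normalizing by the A-neutrals-B arrangement can push scores above 1.
The package therefore computes `delta_max` exactly over all
arrangements in which each group forms one contiguous block and the
neutrals split into up to three runs around them (O(n²) arrangements,
deterministic; block arrangements dominate scattered ones because
clustering maximizes the spread of window sigma). A Monte-Carlo
shuffle-max normalizer is available for cross-checking and agrees to
within sampling error in tests. Exhaustive enumeration over all 252
arrangements of a 5+5 two-group sequence confirms the segregated
arrangement is the unique maximum at exactly 1.

**Native position.** A domain of length `Ld` starting at residue `N` of
an `Lp`-residue protein has relative coordinates `start = (N−1)/Lp`,
`end = (N−1+Ld)/Lp`. The protein is divided into 20 sections and every
section the domain's half-open interval genuinely overlaps (boundary
touches do not count) is flagged; hit/miss section frequencies are
relative to group size, with multi-section domains counted in each
section they span.

**Hits and statistics.** A hit is two-fold-or-greater activation
(boundary inclusive) on at least one target; both thresholds are
arguments. Hit/miss feature comparisons use the unpaired two-sided
t-test with pooled variance by default (the variance treatment in the
original analyses is unstated; `welch = TRUE` is available), excluding
missing feature values. Predictor evaluation reports sensitivity
`TP/(TP+FN)` and precision `TP/(TP+FP)` against the hit calls, with
zero-denominator metrics flagged as undefined. The deep-learning AD
predictor itself is out of scope; its predictions are an optional input
vector.

# Determinism and problem sizes

One global seed fully determines every simulator output: per-stage
seeds are derived with a fixed multiplicative hash (kept below 2³¹),
so identical configurations are bit-identical and the pipeline
manifest — which records the effective configuration, seed, package
version and every threshold — is a sufficient reproduction recipe.

The test suite exercises unit behavior on hand-built tables and small
screens (8–10 parts, 2×10⁴–2×10⁵ cells), and validates ground-truth
recovery on the full default bipartite setting: 625 constructs, 10⁶
cells and 10⁶ reads per condition, two targets × two replicates. At
those sizes, recovery of latent strength and fitness cost by Spearman
correlation exceeds 0.8 with comfortable margin (typically ≈0.88 and
≈0.997); the toxicity recovery is tighter because dropout depends on
depth alone while activation is additionally filtered through gated
sorting.

# Known limitations

- The fluorescence model is a stand-in; activation scores are validated
  for rank recovery, not absolute calibration.
- The clone-UMI-plus-rotations read encoding is simpler than real
  multi-round UMI accumulation; parsers for real data should treat
  filler-block UMIs as independent features.
- Multi-copy cells are reduced to a single kept construct by default;
  the multi-copy control estimates, but the scorer does not correct
  for, double-infection artifacts.
- No variance or confidence estimation beyond replicate means is
  provided, matching the mean-and-correlation reporting the analyses
  are built around.
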