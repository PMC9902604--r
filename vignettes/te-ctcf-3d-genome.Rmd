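---
title: "Methods: transposable-element origins of CTCF loop anchors and TAD boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transposable-element origins of CTCF loop anchors and TAD boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloop)
```

# The question and the model

Transposable elements (TEs) carry transcription-factor binding motifs, and
repeated TE insertion has seeded a substantial share of the CTCF binding
sites in mammalian genomes. Where such a site lands near a chromatin loop
anchor or a TAD border, the TE has effectively rewired 3D genome folding.
`teloop` turns that observation into a measurable pipeline with four
quantities at its core:

* the fraction of loop-anchor and TAD-boundary CTCF sites that are
  **repeat-derived**,
* the fraction of loops/boundaries that are **conserved** across a species
  pair versus lineage-specific,
* the fraction of loops with an attributable **regulatory function**
  (enhancer–promoter or polycomb-repressive), and
* the **contact-map consequences** of deleting one TE-derived anchor.

## CTCF site assignment

Loop anchors (as called, typically 5–10 kb pixels) and TAD borders
standardized to ±5 kb windows are scanned with a position weight matrix on
both strands. The log-odds score of a window $w$ is

$$S(w) = \sum_i \log_2 \frac{p_i(w_i) + c\,b(w_i)}{(1+c)\,b(w_i)}$$

with position probabilities $p_i$, background $b$ and pseudocount $c$
(default 0.01); `N` bases contribute 0 and the minus strand scores the
reverse complement. A hit becomes the anchor's CTCF site only when it
overlaps a CTCF ChIP peak by at least 1 bp — the ChIP gate, not the scan
threshold, carries the specificity, so the default scan threshold is a
permissive fraction of the maximum attainable score (0.6 for general
scanning; the pipeline default is 0.8 because the synthetic motifs are
exact consensus). Per anchor, the highest-scoring peak-supported hit is
kept; ties go to the smaller start so reruns are identical. A bundled
synthetic consensus-style 19-column CTCF matrix makes the pipeline
runnable offline; it should be replaced by a database-derived matrix for
real analyses (`default_ctcf_pwm()` documents this).

## Repeat attribution: the 10 bp rule

A CTCF site is *RE-derived* when its motif overlaps a single RepeatMasker
element by **at least 10 bp** (inclusive). When several repeats qualify,
the largest overlap wins and equal overlaps go to the repeat with the
smaller start — a deterministic maximal-evidence rule. Loops with at least
one RE-derived anchor CTCF are RE-derived loops; loops whose two anchors
both carry CTCF sites, none repeat-derived, are non-RE-derived; loops with
a CTCF-less anchor and no RE evidence are *excluded* and never enter
denominators. The same dichotomy applies to TADs through their two border
windows.

Summaries count **unique motif coordinates**, not structures, because
anchors are shared between loops; percentages are reported against two
denominators — all RE-derived sites, and the TE-only subset (classes SINE,
LINE, LTR, DNA, RC, Retroposon, with `?`-suffixed variants normalized) —
since repeats also include simple/low-complexity sequence. Pooling across
samples sums numerators and denominators rather than averaging percents.

The *random expectation* null re-places each motif uniformly on its own
chromosome (length- and chromosome-preserving) and re-applies the 10 bp
rule; this keeps chromosome-scale repeat density intact while destroying
the anchor–repeat association. The empirical two-sided p uses the
add-one estimator.

## Orthology: chain lifting and conservation

Interval lifting is implemented directly on UCSC chain files: the
best-scoring chain overlapping the interval is block-walked; the lifted
interval is the span of the mapped base images; and the interval maps when
the **fraction of its bases inside aligned blocks is ≥ 0.1** (inclusive),
the minMatch semantics of command-line liftOver. Intervals with mapped
bases on more than one chain are reported `split` and treated as unmapped,
matching liftOver's default refusal to choose.

A lifted loop is **conserved** when some target loop has both anchors
within $t = \min(\text{loop span}/2,\ 50\,\text{kb})$, anchor distances
measured between anchor midpoints (anchors are pixels, so midpoints are
resolution-robust) after genome-ordering both anchor pairs. The 50 kb cap
absorbs residual liftOver error; it applies per anchor — both anchors must
qualify — which is the stricter of the two possible readings. The nearest
qualifying target (by the larger of the two anchor distances) is recorded
so assignment is unique. TAD-boundary conservation lifts the boundary CTCF
motifs (ChIP-supported motifs within the 40 kb boundary region) and asks
for a target boundary motif within 50 kb.

Conservation is reflexive under identity chains and the conserved set is
monotone non-decreasing in the threshold; both are asserted in the tests.

## Loop function and candidate selection

A loop is **enhancer–promoter** when a promoter state (TssA, TssAFlnk)
lies within 10 kb of one anchor and an enhancer state (Enh, EnhG, plus
EnhA1/EnhA2 where the segmentation provides them) within 10 kb of the
opposite anchor; a promoter opposite polycomb repression (ReprPC,
ReprPCWk) gives a **repressive** loop. Distances are measured from anchor
interval edges (overlap = 0) and are inclusive at 10 kb. Both
orientations are tested, so labels are symmetric under anchor swap. When
an enhancer and a repressor both flank the opposite anchor the call is
enhancer–promoter with an explicit conflict flag — the two outcomes are
reported as disjoint, so precedence must be stated rather than silent.
E–P loops subclassify by the strongest qualifying state per side
(EnhA1/EnhA2 strong, Enh/EnhG weak; TssA active, TssAFlnk weak; the map is
configurable).

Deletion candidates are filtered in a fixed order, each loop recording the
first filter that rejected it so the audit telescopes
(input = passed + Σ rejected-per-filter):

1. ≥ 1 RE-derived anchor CTCF **and** lineage-specific;
2. attributed function (E–P or repressive);
3. ≤ 1 active CTCF ChIP peak within 15 kb of the candidate anchor
   (the anchor's own peak counts, so a second peak rejects);
4. the candidate motif must not overlap a p300 peak (to avoid deleting an
   enhancer along with the anchor).

When both anchors are RE-derived the higher-scoring motif is audited as
the candidate anchor. Survivors rank GeneHancer-supported first, then by
motif score; absent GeneHancer evidence never excludes.

## Contact statistics

Matrices are binned, symmetric, region-scoped objects (text COO or dense
input; 5 kb default bins). Balancing solves $B = DAD$ with equal unmasked
row sums via the symmetric fixed-point iteration
$x \leftarrow \sqrt{x / (Ax)}$ — the diagonal-scaling problem the
Knight–Ruiz algorithm accelerates — with all-zero rows masked, a row-sum
CV tolerance of $10^{-6}$ and a hard iteration cap whose breach is an
error carrying the residual, never a silent partial result. The balanced
matrix is rescaled to the mean raw row sum so totals stay interpretable.

Observed/expected divides each entry by the mean count at its bin
distance (0/0 → 0; the transform is idempotent). Long-range interaction
fractions consider upper-triangle bin pairs with genomic distance
**strictly greater than 30 kb** and both bin midpoints inside the region
of interest: the intra fraction is the contact mass with both bins in the
upstream partition, the inter fraction the mass bridging the two
partitions, both as percents of that denominator — hence invariant to
global rescaling, so raw counts are the default input (normalization is
available but changes nothing structurally). An empty denominator is
flagged, not silently zero. Virtual 4C averages the anchor bins' rows,
optionally smoothed by a centered moving average that leaves edge bins
unsmoothed. Focal enrichment is the mean O/E in the 3×3 peak square over
the mean in the surrounding 11×11 donut (peak excluded) — a validation
score for known pixels, deliberately not a loop caller.

# The synthetic study system

The generator builds two "species": A has 2 chromosomes × 2 Mb; B is A
with one 20 kb deletion and one 30 kb insertion per chromosome, described
exactly by emitted chain files in both directions. Per chromosome, 30
anchor slots in a conserved zone and 30 in each species-specific zone are
paired into 15 loops of 62–197 kb span; conserved loops occupy identical
coordinates in both species, species-specific loops sit in aligned
sequence (so they lift cleanly but find no partner ≥ 50 kb around),
and TEs inside the deletion/insertion blocks exercise the unliftable
path. TAD borders sit at slot midpoints; on chromosome 1 of species A one
border coincides with the candidate anchor motif, mirroring an element
that anchors both a loop and a domain boundary.

Planted conditions (the defaults of `sim_config()`): **30%** of anchor
CTCF sites are embedded in a TE with full-motif overlap (the two
simple-repeat sites among them keep the RE/TE distinction honest), **50%**
of loops and TAD boundaries are conserved, **40%** of loops carry
enhancer–promoter chromatin and **10%** polycomb repression, and exactly
one lineage-specific TE-derived E–P loop is engineered to survive all four
candidate filters (every other would-be candidate carries a planted p300
peak on its motif). Background sequence is i.i.d. uniform and motifs are
planted as exact consensus of a sharp PWM (one mismatch costs ~10 bits),
so scan recall is exactly 1 at the 80% threshold and downstream logic is
tested in isolation from scanner sensitivity. Contact maps follow

$$\mu_{ij} = A\,(1 + d_{ij}/d_0)^{-\alpha}\; \tau_{ij}\; \lambda_{ij},
\qquad \text{counts} \sim \text{Poisson}(\mu)$$

with $A = 50$, $d_0 = 20$ kb, $\alpha = 1$, a within-TAD factor
$\tau = 3$ and a 3×3 loop-pixel factor $\lambda = 4$ — decay and contrast
in the range of shallow mammalian Hi-C at 5 kb bins. The knockout map
resets the candidate pixel's loop factor and removes its TAD boundary,
with independent Poisson noise (a separate library, as in a real
experiment).

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: TE sequence decay and subfamily phylogeny
(real motif matches are degenerate, so scanner sensitivity matters),
repeat-dense backgrounds (here decoy TEs are kept ≥ 500 bp from motifs, so
the shuffle null sits near 2% and the planted 30% is far *above* random
expectation, whereas genome-wide repeat densities of ~50% put the real
null far higher), polymer-physics contact features (stripes, compartments,
distance-dependent noise), and calling uncertainty in the input loop/TAD
lists, which enter this pipeline as ground truth.

# Numerical choices and degenerate inputs

* All "within X kb" rules are interval-edge distances, inclusive at X;
  the overlap rule is inclusive at 10 bp; minMatch is inclusive at 0.1.
  Every threshold is exercised at value and value ± 1 in the tests.
* Ties break toward smaller genomic start everywhere (scan hits, repeat
  attribution, candidate anchors), making every output order-stable.
* Loops arriving with anchors in reverse genome order are swapped;
  inter-chromosomal rows are skipped with one warning; exact duplicate
  anchor pairs are dropped and near-duplicates within one resolution unit
  are flagged but kept, since the de-duplication rule for merged published
  lists is a judgment call that should stay visible.
* Empty denominators (no CTCF sites, no long-range mass, no RE-derived
  sites) warn and return NA/empty rather than fabricating zeros.
* TAD borders are taken as the unique interval edges of the TAD call set;
  borders closer than 5 kb to a chromosome end get clipped windows.
* The region of interest and partitions for interaction fractions are
  explicit configuration, echoed into the report, because published
  region definitions are occasionally internally inconsistent and the
  reader should see exactly which coordinates produced the numbers.

# Problem sizes

The default study conditions are deliberately desk-scale: 2 × 2 Mb
chromosomes per species, 120 anchor sites and 16 boundary sites per
species, 120-bin contact matrices, 200-shuffle nulls and 100 simulated
WT/KO map pairs. The full test suite and the acceptance script each run
in about a minute on one core.

# Known limitations

Chain inversion is implemented for `+`/`+` chains (all the generator
emits); minus-strand target chains are handled in lifting but not
inversion. The focal-enrichment score uses a single donut geometry and is
not multiple-kernel loop calling. Function attribution considers state
presence, not state coverage fractions, within the 10 kb window. The
shuffle null preserves per-chromosome placement but not local GC or
repeat clustering.
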