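# teloop

Quantifying how transposable elements (TEs) supply the CTCF binding sites
that anchor chromatin loops and TAD boundaries — and what happens to the 3D
genome when such a TE-derived anchor is deleted.

A large fraction of mammalian CTCF binding sites were deposited by TE
expansions, and some of those sites now anchor chromatin loops and insulate
topologically associating domains (TADs). `teloop` implements the full
computational chain needed to study this phenomenon from standard file
formats, for genomicists working with Hi-C loop/TAD calls, ChIP-seq peaks,
RepeatMasker annotations and ChromHMM segmentations:

1. **CTCF site assignment** — PWM log-odds scanning of loop anchors and
   TAD boundary windows on both strands, keeping at most one
   ChIP-peak-supported motif per anchor.
2. **Repeat attribution** — an anchor CTCF site is *RE-derived* when its
   motif overlaps a repetitive element by ≥ 10 bp; loops with ≥ 1
   RE-derived anchor are RE-derived, loops whose two CTCF anchors are all
   non-repeat are non-RE-derived, and the remainder are excluded from
   denominators. Class/family/subfamily summaries count unique sites, with
   a chromosome- and length-preserving shuffle null for random expectation.
3. **Orthology** — from-scratch UCSC-chain lifting (minMatch = 0.1). A
   lifted loop is *conserved* when a target loop has both anchor midpoints
   within t = min(half loop span, 50 kb); a lifted TAD boundary CTCF motif
   is conserved within 50 kb of a target boundary motif. Everything else
   liftable is *lineage-specific*.
4. **Function** — a loop is *enhancer–promoter* when a ChromHMM promoter
   state (TssA/TssAFlnk) lies within 10 kb of one anchor and an enhancer
   state (Enh/EnhG/EnhA1/EnhA2) within 10 kb of the other; polycomb states
   (ReprPC/ReprPCWk) give *repressive* loops. E–P loops subclassify by
   strong/weak enhancer × active/weak promoter.
5. **Candidate selection** — deletion candidates are lineage-specific
   TE-derived functional loops whose candidate anchor has ≤ 1 active CTCF
   peak within 15 kb and whose motif does not touch a p300 peak;
   GeneHancer-supported pairs rank first.
6. **Contact statistics** — Knight–Ruiz balancing, observed/expected
   transforms, > 30 kb intra/inter-domain interaction fractions, virtual
   4C profiles and a focal-enrichment score for loop pixels.
7. **Synthetic data** — a deterministic two-species generator (genomes,
   chains, TEs, motifs, loops, TADs, ChromHMM tracks, peaks and Poisson
   contact maps with planted ground truth) so that every stage is testable
   offline.

All coordinates are 0-based half-open; 1-based formats (RepeatMasker
`.out`) are converted at the parser boundary.

## Worked example

The numbered scripts under `analysis/` run the whole study on the synthetic
system (2 species × 2 chromosomes × 2 Mb; 60 loops, 12 TADs and ~200 TEs
per species):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_attribution.R
Rscript analysis/03_orthology.R
Rscript analysis/04_function_candidates.R
Rscript analysis/05_contacts.R
```

which prints, among other things:

```
species A: 30.0% of loop anchor CTCF sites RE-derived (36/120)
shuffle null (200 shuffles): mean 2.02%, observed 30.0%, p = 0.010
A_vs_B: 30/60 loops conserved (50%), 0 unliftable
TAD boundary CTCF motifs: 8/16 conserved (50%)
candidate filter audit over 60 loops:
   1    2    3    4 <NA>
  43    7    2    7    1
1 loop(s) pass all filters: chr1:1030000-1035000_1163000-1168000
long-range (>30 kb) interactions, upstream domain: WT 33.9% -> KO 21.4%
cross-boundary interactions:                       WT 31.3% -> KO 58.0%
focal enrichment at the candidate loop pixel: WT 3.98, KO 0.99
```

Read: the pipeline recovers the generator's planted 30% RE-derived anchor
fraction and 50% conserved fraction exactly; exactly one engineered loop
survives the four candidate filters; and deleting its TE-derived anchor in
the simulated contact maps collapses the loop's focal enrichment (3.98 →
0.99) while long-range contacts leak across the lost TAD boundary (intra
33.9% → 21.4%, inter 31.3% → 58.0%).

The same machinery runs on real data by pointing a config at your own
BEDPE/BED/narrowPeak/RepeatMasker/chain/ChromHMM/contact-matrix files; see
`?run_pipeline` and the methods vignette
(`vignettes/te-ctcf-3d-genome.Rmd`).

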