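---
title: "Exon-level orthology assignment: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-level orthology assignment: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoexon)
```

## The problem

Gene-level orthology between two species (say, human and mouse) is well
catalogued, but genes are mosaics: individual exons are gained, lost,
duplicated, fused and split during evolution, and alternative splicing
annotates overlapping exon variants within one gene. `orthoexon` starts
from a list of *gene* ortholog pairs and assigns orthology at the *exon*
level, the resolution needed for studying intron gain/loss, exonization
and reading-frame conservation.

The unit of assignment is the **united exon**: all exon variants of a
gene that overlap by at least one base are merged transitively into one
interval (minimum start to maximum end of the overlap component). This
collapses alternative acceptor/donor variants — which would otherwise
force spurious one-to-many relationships — into a single unit. Exons
that merely abut are *not* merged: zero shared bases is no overlap, and
keeping them separate is what makes fused/split detection meaningful.
United exons are ranked 5' to 3' along the gene and classified into six
gene-region categories from the union CDS span over the gene's coding
isoforms: `UTR5`, `UTR5_CDS`, `CDS`, `CDS_UTR3`, `UTR3`, and `SLR` (a
single long region running from the 5' UTR through the CDS into the 3'
UTR). Genes with no coding transcript receive a `no_CDS` sentinel and
participate in orthology but are excluded from region statistics.

## The two-step homology search

Within each gene pair, every exon of one gene is searched against every
exon of the other, in both directions. Step 1 is a nucleotide local
alignment, kept when the e-value is at or below **1e-5**. Exons with no
step-1 hit are re-searched in step 2 with a translated aligner (all 3x3
forward frame pairs under BLOSUM62, stop codons retained as the
low-scoring `*` symbol), kept at or below **1e-3**. A query exon
therefore never carries both nucleotide and translated hits. The
rationale for the fallback is synonymous-site saturation: an exon whose
third codon positions have diverged past nucleotide detectability can
still align perfectly at the peptide level.

Only forward frames are searched. Exon sequences are extracted in
transcript orientation (minus-strand exons are reverse-complemented on
read), so within an annotated gene pair the orthologous signal is always
co-oriented; reverse frames could only contribute chance hits.

### The aligner and its statistics

The built-in backend is an affine-gap (Gotoh) Smith–Waterman over
integer-coded sequences with an explicit determinism contract: the
alignment endpoint is the first maximal cell in row-major order, and
ties while filling prefer diagonal, then gap-in-subject, then
gap-in-query, with gap states preferring opening over extension. This
makes results byte-reproducible across platforms and lets the test suite
compare score *and* span against an independently written full-matrix
oracle. Hits can also be injected from an external BLAST+ run through
the tabular (outfmt 6) import, and exported in the same layout.

E-values use the Karlin–Altschul form `E = K * m * n * exp(-lambda * S)`
with the search space `m * n` taken per comparison (query length times
subject length; peptide lengths for the translated pass). Defaults are a
+1/−2 nucleotide scheme with `lambda = 1.28`, `K = 0.46`, gap open/extend
2/2, and BLOSUM62 with gap 11/1, `lambda = 0.267`, `K = 0.041`. The
thresholds are the method's; the statistical constants are standard
published values for these scoring schemes and are configurable in
`search_config()` — the method depends on the thresholds, not on the
precise constants, because planted-ortholog scores sit many orders of
magnitude below the cutoffs while chance scores sit above.

## From hits to assignments

Assignment proceeds in stages, each consuming what the previous stage
left unresolved:

1. **Best-reciprocal hits.** Exons with exactly one hit each, pointing
   at each other, become one-to-one pairs, lifted to their united exons.
2. **Multi-hit collapse.** An exon hitting several exons that are all
   members of *one* united exon of the partner gene is assigned to that
   united exon, provided at least one of those exons links back to it in
   the reverse search. The backward criterion is stated ambiguously in
   the field (all members vs at least one); we require at least one,
   since member variants are fragments of the same region and a missing
   backward hit for a short variant is an alignment-sensitivity artifact,
   not evidence against orthology.
3. **Fused/split events.** A united exon hit by two or more distinct
   united exons of the partner gene is screened as an intron gain/loss
   (or retrocopy) candidate: the summed split lengths must be within
   **5%** of the fused length, the split exons must be adjacent
   (consecutive ranks — no other exon inserted), and the summed aligned
   fraction of the splits on the fused exon must lie in **0.75–1.1**.
   The aligned fraction sums raw split-side aligned lengths without
   merging overlaps; that is the only reading under which the 1.1 upper
   bound is reachable. Candidates are verified by rejoining the split
   sequences in rank order and locally aligning the concatenation to the
   fused exon: the single best alignment must cross the first and last
   joint point and cover at least **70%** of the fused exon. Verified
   fused exons report as one-to-many with their splits as partners; each
   split reports one-to-one; provenance `fused_split` keeps them
   distinguishable in every output.
4. **Anchor mapping.** Everything confirmed so far becomes an *anchor*,
   ordered by rank on both sides (a fused exon anchors against the rank
   span of its splits). For each remaining united exon with hits, the
   nearest flanking anchors by rank are located (one-sided at gene
   ends); a hit is in-order iff its partner's rank falls strictly
   between the flanking anchors' partner ranks. All in-order hits are
   accepted — one partner gives `one_to_one`, several `one_to_multi`
   (this is what keeps tandem exon duplications). An out-of-order hit is
   accepted only under the exception rule — length difference at most
   **6 bp** and e-value below **1e-10** — and is then tagged
   `out_of_order`, preserving duplicated/repetitive exon cases while
   controlling false positives. Genes with fewer than **2** anchors
   abandon their unresolved exons (reported as lack of anchors).
5. **Finalization.** Every exon and united exon receives exactly one
   status: `one_to_one`, `one_to_multi`, `no_hit` (no hit in either
   search step) or `ignored` (had hits, none accepted). The four counts
   partition the total at both levels, and summary percentages are
   recomputed from counts to two decimals.

## Downstream analyses

`region_distribution()` tabulates, per gene-region category, the
fraction of united exons with and without an orthologous partner.
`length_conservation()` restricts to one-to-one pairs and splits them
into equal and unequal united-exon lengths per region.
`mod3_distribution()` takes the unequal pairs and reports the remainder
of the absolute length difference modulo 3 — remainder zero means the
downstream reading frame is preserved, the expected signature of
selection in coding exons. `small_diff_histogram()` counts unequal pairs
with differences up to 30 bp. A pair's region follows the species-A
united exon (a pair must be plotted under one category; both sides are
carried and a mismatch flag is set when the two species classify
differently).

## The synthetic-data generator

`generate_dataset()` builds species-A genes from uniform random
sequence — a configurable number of exon regions (default 4–9 per gene,
60–300 bp each, introns 80–400 bp), one pure-UTR exon at each end, a CDS
of whole codons anchored well inside its boundary exons, and 1–3
isoforms whose extra transcripts may shift an internal exon's 5'
boundary (creating overlapping variants that must merge) or skip an
exon. Species B is derived by per-region substitutions (default 5%,
roughly the neutral human–mouse scale) and indels, plus planted
structural events: exon fission into k adjacent pieces (total sequence
conserved, so the 5% criterion holds by construction), fission *decoys*
whose later pieces are replaced by random sequence (no event may be
detected for them), tandem exon duplications, species-specific exon gain
and loss (UTR-biased placement, reflecting where new exons tend to
arise), and optional whole-gene duplication producing one-to-multi gene
pairs. Species-B coordinates are re-laid-out on fresh chromosomes with
resampled introns and random strands, so only sequence and exon order —
never genomic coordinates — carry information into the pipeline, as in
real data.

Fission and decoy events are planted by exact dataset-wide counts
(`n_fission`, `n_decoy`) rather than per-exon probabilities: detection
studies need a known number of events, and a binomial draw would make
"all 30 planted events recovered" an ill-defined claim. The remaining
event classes keep per-gene/per-region probabilities. CDS indels are
restricted to multiples of three by default (`cds_indel_mod3`),
emulating frame preservation; indel events are spaced so deletions never
overlap, which keeps the planted net length change exact. A single
integer seed fully determines the output; generation uses only R's
integer RNG stream, and two runs with one seed are byte-identical.

What the generator does *not* emulate: base composition and repeat
structure of real genomes (no Alu-like elements, no low-complexity
tracts), splice-site motifs, exon rearrangements that change order, and
realistic divergence heterogeneity along a gene. Passing the planted
recovery tests therefore demonstrates the pipeline's logic — search,
reciprocity, order constraints, event criteria — not calibrated
performance on real human/mouse annotation.

## Numerical and degenerate-input choices

Internal coordinates are 0-based half-open everywhere; GTF is converted
on read and write. Exon identity is the pair (gene, interval), so
isoforms sharing an exon reference one record and counting is
unambiguous. Empty genes produce empty united-exon sets, not errors;
all-`N` input to the translated aligner is an error (nothing can be
translated); score-0 alignments return empty spans rather than
degenerate ones. The sequence-identity of an alignment is matches over
aligned columns, gaps included. United exons are built once per gene and
reused across the several pairs of a duplicated gene.

Problem sizes in the shipped tests were chosen to exercise every code
path at desk scale: 500 random aligner-oracle pairs at up to 50 bp, 200
random reciprocity graphs, 100 random multi-isoform genes, 200-gene
recovery and mod-3 studies, a 120-gene fused/split study with 30 events
and 30 decoys. The acceptance script's mixed study uses 150 genes with
every event class enabled.

## Known limitations

* Anchor mapping is the stated greedy rule; no global (dynamic
  programming) assignment over exon chains is attempted, so a locally
  consistent but globally suboptimal anchor can propagate.
* Fused/split events are reported without mechanism: intron gain, intron
  loss and retrocopy insertion all emit the same event shape.
* The translated fallback admits occasional chance hits at 1e-3 on
  species-specific exons; these are rejected downstream (status
  `ignored`, zero partners) but inflate the ignored count slightly.
* Candidate split sets must be exactly the linked united exons; a fused
  exon with an additional spurious link to a non-adjacent exon fails the
  adjacency screen rather than being trimmed.
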