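---
title: "Methods: characterizing S-RNase allele families from C2-C5 amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing S-RNase allele families from C2-C5 amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnase)
```

## The problem

Gametophytic self-incompatibility (GSI) in *Prunus* is controlled by the
S-locus: the pistil-expressed determinant is a ribonuclease (S-RNase)
whose allelic identity decides which pollen is rejected. S-genotyping
surveys amplify part of the *S-RNase* gene between the second (C2) and
fifth (C5) conserved regions. That amplicon contains the full second
intron, whose length is wildly polymorphic (tens of bp to more than a
kilobase), so allele calls are traditionally read off gel band sizes.
In polyploids this breaks down: many alleles per genotype, co-migrating
fragments, and preferential amplification all conspire to undercount
alleles, and sequencing the cloned amplicons becomes the ground truth.

`srnase` implements the downstream analysis of such a survey as a
reusable, tested pipeline: exon/intron annotation of each cloned
amplicon, deduced-protein translation and conserved-region mapping,
loss-of-function calling, three-level identity matrices, trans-specific
allele classification, a region-resolved replacement profile, and a
distance-based phylogeny. A synthetic allele-family generator with a
complete truth table makes every stage testable without any external
data.

## Gene annotation

Amplicons are assumed to start inside C2 (the forward consensus primer
is anchored there), so the reading frame is fixed by requiring the
translation to open with the C2 consensus. Candidate introns are
`GT..NG` intervals; for each candidate the spliced translation is scored
as the sum of the best ordered, ungapped placements of the C2, C3, RC4
and C5 consensus motifs (PAM250 similarity, presence threshold 0.6 of a
motif's self-score), minus a spacing penalty of 0.75 score points per
residue of deviation from the reference inter-motif spacings, plus a
small splice-signal term (donor consensus `GTAAGT`, polypyrimidine tract,
canonical `AG` acceptor bonus). The motif score dominates; the spacing
and splice-signal terms only separate candidates whose translations are
equally good, such as equal-length decoy intervals falling inside the
unconstrained segment between C2 and C3. Acceptors are deliberately not
restricted to `AG`, because a defective acceptor (the `AG -> GG` class)
must still be annotatable; the defect is then reported by the splice
assessment rather than hidden by the search.

The hypervariable region RHV carries no consensus by definition, so it
is assigned positionally: a fixed offset and width after the end of C2,
clipped at C3. All coordinates are 0-based and half-open internally;
reports are 1-based.

Two situations are not decidable from a single sequence. First, a
frameshifted pseudogene truncated shortly after C2 gives every candidate
intron the same (C2-only) score; the search reports the tie as an
ambiguity rather than guessing. Second, the search can be actively
misled: a decoy interval that splices the lesion itself out of the
reading frame can restore a high-scoring -- sometimes even fully clean
looking -- ORF. Both are resolved the way such alleles are annotated in
practice, by comparison with close relatives: alleles at or above 97 %
amplicon identity are clustered (near-identical sequences must share a
gene structure), each cluster is anchored on its best-supported member
(a clean gene model -- canonical splice sites, stop-free full-length
translation, all regions present -- with the strongest splice-signal
context as tie-break, since genuine sites carry consensus context and
decoys rarely do), and any member whose own detection is unclean or
disagrees with the anchor by more than 6 bp at the intron boundaries
receives the anchor's structure mapped through a global alignment.
Concordant detections keep their own structure, which is what preserves
a defective `GG` acceptor instead of papering over it. The cluster
anchor also serves as the paired wild type for frameshift calling.

Functional status follows a fixed precedence: splice defect
(non-canonical donor/acceptor) over premature stop (an in-frame stop
with C5 undetectable) over frameshift truncation (an exonic indel of
length not divisible by 3 relative to the paired wild type) over
putative functional. A full-length, stop-free protein whose *internal*
motif (say RC4) scores below the presence threshold while later regions
are present is treated as diverged, not missing -- highly divergent
alleles are expected to erode motif scores -- and stays
putative-functional with a note; only a missing *suffix* of regions is
evidence of a truncated product. For non-canonical acceptors the unspliced mRNA is
translated through the retained intron and the number of novel residues
before the first stop is reported; candidate cryptic `AG` acceptors
within 50 bp are listed without choosing among them, since their use
cannot be established without cDNA.

Synonymous/nonsynonymous counts between near-identical allele pairs are
codon-by-codon in the shared frame; codons hit at several positions are
counted by enumerating all substitution orderings and averaging
(pathway counting), which leaves the common single-hit case untouched.

## Identities and trans-specificity

Identity is computed at three levels per allele pair -- concatenated
exon nucleotides, deduced amino acids, and second-intron nucleotides --
from global pairwise alignments (protein: PAM250, gap open 10 / extend
0.5; DNA: match +2 / mismatch -1, gap open 10 / extend 0.2, the
ClustalW-family defaults). The default identity denominator counts every
column bearing at least one residue, so gaps count as mismatches; the
convention is recorded in the output and two alternatives (gapless
columns, shorter-sequence length) are selectable. Pairwise rather than
multiple alignment is used; for divergent pairs a multiple-alignment
convention could shift values by about a point, which is why summary
comparisons carry a tolerance of that order.

Trans-specific candidates are cross-species pairs classified by a
multi-evidence rule: *supported* requires deduced-protein identity at or
above 96 % and, when a tree is available, mutual nearest-neighborhood in
it; identity in the 92-96 % band, or high protein identity with intron
identity below 90 %, yields *ambiguous*; everything else is
*unsupported*. RHV replacements are attached as a caution flag because
they argue for changed allele specificity. The thresholds mirror the
tiers used in the S-RNase literature and are all configurable.

## Region-resolved replacement profile

For a roster of closely related pairs (default: all pairs at or above
80 % protein identity plus every wild-type/mutant pair; an explicit
roster overrides), each differing alignment column becomes an event.
Maximal gap runs collapse to one indel event. Substitutions are
classified conservative/non-conservative by the sign of their PAM250
score and labelled with the structural region of the reference sequence
(the lexicographically first of the pair -- a deterministic convention).
Indels are tallied separately and excluded from the percentage base:
"replacement" means an amino acid exchanged for another, and gaps have
no PAM score. Raw fractions are kept; rounding happens only in reports.

## Phylogeny

The tree stage follows standard distance-based practice: alignment
columns below 95 % site coverage are masked; pairwise distances use
p-distance, a gamma-corrected Poisson transform
(d = a[(1-p)^(-1/a) - 1], shape 0.8 by default), or maximum-likelihood
JTT distances with 4 gamma rate categories; neighbor joining builds the
tree; bootstrap support is the percentage of column-resampled replicate
trees containing each original bipartition. Negative NJ branch estimates
are clamped to zero with the deficit moved to an adjacent branch.
A minimum-evolution search with close-neighbor-interchange would differ
from plain NJ mainly in branch lengths, not in the topology that feeds
the trans-specificity calls, so NJ (the ME search's own starting tree)
is used directly. The pipeline builds its tree over putative-functional
alleles, whose deduced proteins align without gaps in the synthetic
setting; unequal-length inputs are aligned with MAFFT when available, or
an externally aligned FASTA can be supplied.

## The synthetic family generator

The generator emulates the salient features of a polyploid cherry-laurel
S-RNase survey, and its defaults are the study conditions used by the
test suite:

* 20 base alleles plus 3 mutant derivatives (the 23-allele fixture);
* second-intron lengths uniform on 81-1116 bp, so amplicons span roughly
  0.5-1.55 kb with intron length dominating the variation;
* deduced proteins of 144 residues (the midpoint of the 134-155 band;
  exonic indels are deliberately absent so proteins stay alignable and
  the intron remains the sole driver of length polymorphism);
* per-allele protein divergence from the common ancestor uniform on
  5-30 % of mutable residues, which reproduces intra-family identity
  ranges of roughly 53-93 % at the protein level and a higher exon than
  intron identity, as observed in real families;
* replacement placement by per-segment weights 8 : 16 : 8 : 3 : 17 : 5 : 43
  (C2-RHV, RHV, RHV-C3, C3, C3-RC4, RC4, RC4-C5), concentrating
  replacements between RC4 and C5; C2 and C5 themselves are never
  mutated, since terminal regions are only partially covered by the
  amplicon;
* three planted loss-of-function classes: a 1-nt deletion just upstream
  of C5 (frameshift that reads through to the amplicon end), a 1-nt
  deletion after C2 (premature stop, typically under 40 residues), and
  an A-to-G at the intron's penultimate base (`AG -> GG` acceptor);
* trans-specific duplicates: 60 % of base alleles are copied into a
  second species label with 0.5-3.5 % further protein divergence and
  near-identical introns, mirroring the fraction of alleles with
  high-identity cross-species partners in real data;
* samples drawing 22 allele copies with replacement (docosaploid dosage,
  multiple genomic copies of an allele), banded on a 60-bp-resolution
  gel model with single-linkage co-migration.

Two details of the ancestor are engineered rather than random, so the
planted mutation classes behave deterministically in every descendant:
the C5 codon block reads through without stops in both shifted frames
(making the upstream-of-C5 frameshift a read-through truncation rather
than a premature stop), and the segment after C2 carries an early
shifted-frame stop (making the after-C2 frameshift truncate early).
Both blocks are outside the mutable segments, or the property is only
probabilistic, in which case the planting routine scans deletion
positions and falls back to the earliest achievable stop upstream of C5.

What the generator does **not** emulate: coalescent genealogies under
balancing selection, recombination, codon-usage bias, sequencing or
cloning error, preferential amplification beyond a simple dropout
probability, and microsatellite noise in capillary sizing. Passing the
synthetic acceptance suite therefore demonstrates correctness of the
pipeline's logic under known truth, not robustness to every artifact of
real data.

## Numerical choices and degenerate inputs

* Band grouping is single-linkage with strict `gap < resolution`
  chaining (adjacent smears merge on a gel); resolution 0 degenerates to
  distinct sizes. Capillary size categories are exact integers, keeping
  1-bp neighbors distinct.
* Identity of a zero-length alignment, an empty FASTA, an all-masked
  alignment, fewer than 3 taxa for NJ, and an empty event list are all
  errors, not silent defaults.
* Codons containing `N` translate to `X`; `X` scores 0 in motif
  placement and makes replacement conservativeness undefined (`NA` with
  a warning) rather than guessed.
* Saturated distances (p >= 1) are set to a configurable ceiling with a
  warning.
* Ties: equal-scoring intron candidates raise an error listing them;
  NJ tie-breaking follows the deterministic agglomeration order of the
  underlying implementation; report rows are sorted by their first
  column so all outputs are byte-stable under a fixed seed.

## Problem sizes used by the tests and the acceptance script

The checked-in suites run the 23-allele fixture once and cache it;
region-rate recovery uses 40 base alleles (about 870 planted
replacements, comfortably above the 500 the binomial check needs); NJ
consistency uses 100 random additive matrices on 4-6 taxa; the
alignment oracle uses 200 random pairs of length 2-8 (the exhaustive
enumeration is exponential, so short sequences are the honest regime);
end-to-end determinism uses a 6-allele family with 25 bootstrap
replicates, run twice. The pipeline default of 1000 bootstrap
replicates matches standard practice for publication trees; the smaller
replicate counts in the tests only exercise reproducibility, not
support accuracy.

## Known limitations

* The acceptance checks against the published cherry-laurel statistics
  need the deposited GenBank records on disk (see the README); they are
  not bundled.
* Motif consensus patterns ship as editable configuration; for real
  data they should be refined from a curated reference alignment of the
  target clade.
* The RHV is positional, so its boundaries inherit any error in the C2
  placement.
* Pathway-averaged substitution counts treat paths through stop codons
  as nonsynonymous steps rather than excluding them; for the
  single-hit codons that dominate near-identical pairs this is
  irrelevant.
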