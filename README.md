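# srnase

Characterization and molecular-evolution analysis of S-RNase allele
families from partial amplicon sequences.

## What this is for

In *Prunus* and other Rosaceae, gametophytic self-incompatibility is
controlled by the S-locus: the pistil rejects pollen whose S-haplotype
matches its own, and the pistil determinant is a polymorphic
ribonuclease, the S-RNase. Allele surveys amplify the gene between its
second (C2) and fifth (C5) conserved regions; that fragment contains the
second intron, whose extreme length polymorphism (roughly 0.08-1.1 kb)
drives gel-based genotyping, and the coding sequence for the
hypervariable region (RHV) and the conserved regions C3, RC4 and C5.

`srnase` is aimed at researchers running such surveys — especially in
polyploids, where co-migrating fragments undercount alleles and cloned
amplicons must be analysed by sequence. It turns a FASTA of cloned
C2–C5 amplicons into:

* exon2/intron2/exon3 annotation per amplicon (motif-anchored reading
  frame, GT..NG intron search scored by conserved-motif recovery), with
  GFF3 output;
* deduced proteins, conserved-region maps, and loss-of-function calls
  with the precedence *splice-defect* > *premature-stop* >
  *frameshift-truncated* > *putative-functional*, including
  retained-intron translation for defective acceptors and
  pathway-averaged synonymous/nonsynonymous counts for near-identical
  pairs;
* gel-band grouping at limited resolution (single-linkage, default
  60 bp) and capillary size-category binning;
* pairwise identity matrices at three levels — exon nucleotide, deduced
  amino acid, second intron — and a multi-evidence trans-specificity
  classifier (supported when amino-acid identity >= 96 % and the pair is
  mutually nearest in the tree; intron identity and RHV replacements as
  auxiliary evidence);
* a region-resolved replacement profile: each amino-acid difference is
  assigned to C2, C2–RHV, RHV, RHV–C3, C3, C3–RC4, RC4, RC4–C5 or C5
  and classified conservative/non-conservative by the sign of its
  PAM250 score;
* a neighbor-joining tree on gamma-corrected distances
  (d = a[(1−p)^(−1/a) − 1], default shape a = 0.8, or ML JTT distances)
  after masking columns below 95 % site coverage, with seeded bootstrap
  supports written to Newick.

A seeded synthetic allele-family generator (`simulate_family()`) with a
complete truth table — planted gene structures, mutation classes,
trans-specific pairs and per-sample allele multisets — makes the entire
pipeline testable offline. See `vignettes/srnase-methods.Rmd` for the
underlying models and every numerical choice.

## Worked example

```r
library(srnase)

fam <- simulate_family(family_config(seed = 7, n_base_alleles = 6,
                                     n_mutant_derivatives = 3,
                                     trans_specific_fraction = 0.5,
                                     n_samples = 4))
ann <- annotate_alleles(fam$records)
as.data.frame(ann)[, c("allele_id", "intron2_bp", "protein_aa",
                       "status", "missing_regions")]
```

```
 allele_id intron2_bp protein_aa               status missing_regions
        S1        883        144  putative-functional
        S2        976        144  putative-functional
        ...
       S3m        854        143 frameshift-truncated              C5
       S5m        299         15       premature-stop   RHV,C3,RC4,C5
       S2m        976        144        splice-defect
```

Each row is one cloned amplicon: its second-intron length (the quantity
a gel assay sizes), the deduced-protein length, and the functional
verdict. Here the three planted mutants are recovered: a frameshift
just upstream of C5 (protein reads through but C5 is lost), a
frameshift after C2 (premature stop after 15 residues), and an AG→GG
acceptor defect (full-length protein, but the intron cannot be spliced
canonically).

```r
mats <- build_identity_matrices(fam$records, ann)
summarize_identity(mats)
```

```
      level mean   min min_pair   max max_pair n_pairs
1   exon_nt 85.6 78.01   S4-S5h 100.0   S2-S2m      66
2        aa 68.6  7.64   S1-S5m 100.0   S2-S2m      66
3 intron_nt 48.1 22.76  S5m-S2m  99.8   S3-S3h      66
```

Introns diverge much faster than exons — the pattern that makes intron
identity useful corroborating evidence for trans-specificity.

```r
calls <- classify_trans_specific(mats, fam$records)
calls[calls$verdict == "supported",
      c("allele_a", "allele_b", "aa_identity", "intron_identity")]
```

```
 allele_a allele_b aa_identity intron_identity   verdict
       S3      S3h        97.9            99.8 supported
       S5      S5h        99.3            99.7 supported
       S6      S6h        97.9            99.2 supported
```

Exactly the three planted cross-species pairs are called supported:
amino-acid identity above the 96 % threshold with near-identical
introns, while every other cross-species pair stays below the band.

`run_pipeline(pipeline_config(...))` chains all stages (annotation,
identities, tree with bootstrap, trans-specificity, region profile,
band report) and writes a deterministic report bundle plus a JSON
manifest; `load_config()` reads the same settings from YAML.

## Analysing the published cherry-laurel alleles

The deposited GenBank records of the *P. laurocerasus* survey
(MG593769–MG593775, MG595258–MG595259, MG601104–MG601115,
MG922592–MG922593) are not bundled. To analyse them, fetch the
nucleotide FASTA, name each record by its allele label (`>S1
accession=MG593769 species=Plau` ...), save it as
`inst/extdata/deposited/plau_srnase.fasta`, and reinstall; the
acceptance tests against the published statistics then run against it.

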