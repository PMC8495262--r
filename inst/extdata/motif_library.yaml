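# Conserved-region motif library used by the annotation stage.
# Edit the consensus patterns (and spacings) to match a curated reference
# alignment of your target clade, then load with load_motif_library().
motifs:
  C2: FTVHGLWPSN
  C3: FWEHEWNKHGTC
  RC4: IWSKQWEPQL
  C5: CFDSTIQNCH
threshold: 0.6        # motif presence: fraction of the motif self-score
rhv_offset: 12        # residues between the end of C2 and the RHV start
rhv_length: 12        # RHV width (residues)
expected_gaps:        # reference inter-motif spacings (residues)
  C2.C3: 34
  C3.RC4: 14
  RC4.C5: 54
width_penalty: 0.75   # score deducted per residue of spacing deviation
matrix_name: PAM250
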