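# Example locus configuration for equid MHC class II exon 2 analysis.
#
# exon2_length is the amplicon length in bp: DQB amplicons cover the full
# 269-bp exon; DRB amplicons are 260 bp because the nested reverse primer
# sits on the exon-intron boundary and the nine 3'-terminal exon
# nucleotides are missing.
#
# abs_codons is an EXAMPLE antigen-binding-site list derived from the
# classical human class II beta1-domain peptide-contact residues; supply
# your own list for publication-grade annotation.
#
# Primers are the horse locus-specific exon-2 primer pairs (nested second
# round for DRB; degenerate positions resolved to a single base so the
# identity-based read sorting is exact). Intervals are 0-based half-open
# on a synthetic reference ("demo_ref"), for use with the simulators.
DRB1:
  exon2_length: 260
  frame_offset: 2
  abs_codons: [9, 11, 13, 26, 28, 30, 32, 37, 38, 47, 56, 60, 61, 65, 68, 70, 71, 74, 78, 81, 82, 85]
  primer_fwd: TGACCGGATCCTTCCTGTAC
  primer_rev: GCGCTCACCTCGCCGAC
  reference: demo_ref
  start: 1000
  end: 1600
DRB2:
  exon2_length: 260
  frame_offset: 2
  abs_codons: [9, 11, 13, 26, 28, 30, 32, 37, 38, 47, 56, 60, 61, 65, 68, 70, 71, 74, 78, 81, 82, 85]
  primer_fwd: TGACCCGATCCTTCCTGTAT
  primer_rev: GCGCTCACCTCGCCGAG
  reference: demo_ref
  start: 3000
  end: 3600
DRB3:
  exon2_length: 260
  frame_offset: 2
  abs_codons: [9, 11, 13, 26, 28, 30, 32, 37, 38, 47, 56, 60, 61, 65, 68, 70, 71, 74, 78, 81, 82, 85]
  primer_fwd: TGACCGGATCCTTCCTGTAA
  primer_rev: GCGCTCACCTCGCCGAT
  reference: demo_ref
  start: 5000
  end: 5600
DQB1:
  exon2_length: 269
  frame_offset: 2
  abs_codons: [9, 11, 13, 26, 28, 30, 32, 37, 38, 47, 56, 57, 60, 61, 65, 67, 68, 70, 71, 74, 78, 81, 85, 86, 89]
  primer_fwd: CCTCTGGGGTAACGTTCCAG
  primer_rev: CGGCCTTGCTTTAGGTTTATC
  reference: demo_ref
  start: 7000
  end: 7600
DQB2:
  exon2_length: 269
  frame_offset: 2
  abs_codons: [9, 11, 13, 26, 28, 30, 32, 37, 38, 47, 56, 57, 60, 61, 65, 67, 68, 70, 71, 74, 78, 81, 85, 86, 89]
  primer_fwd: AGGTTTCTCCCACTCAACTGC
  primer_rev: CTGAGGACGCGCCCACC
  reference: demo_ref
  start: 9000
  end: 9600
DQB3:
  exon2_length: 269
  frame_offset: 2
  abs_codons: [9, 11, 13, 26, 28, 30, 32, 37, 38, 47, 56, 57, 60, 61, 65, 67, 68, 70, 71, 74, 78, 81, 85, 86, 89]
  primer_fwd: AGGTTTATCCGATCCAACCG
  primer_rev: GCTGCGCCCTCCCAGCT
  reference: demo_ref
  start: 11000
  end: 11600
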