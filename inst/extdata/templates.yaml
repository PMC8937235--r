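# Template fixtures for the one-pot (A-D) and branched (sc8211 I/II)
# experiments.  Positions are 1-based triplet positions after the P9_1 primer.
#
# Position-3 barcodes (ATA/AAA/TTA/ATC for A-D) are the published
# classification barcodes.  The barcode identities at positions 6 and 9 are
# SYNTHETIC placeholders (the published ones live in a supplementary table not
# bundled here): they are drawn from the 14-triplet substrate alphabet,
# distinct per template at each slot, with mixed GC at position 6 and high GC
# at position 9.  Swap in the real triplets via this file if you have them.
#
# The branched product barcode is taken as CGC (the Methods triplet alphabet
# spelling); the figure prose also names GCG - flagged discrepancy, CGC used.
#
# Linear templates carry the expected continuation through position 18 for
# fidelity scoring; instruction_len marks where template instruction actually
# ends (synthesis beyond it is non-templated).
alphabet: [CTG, ATA, CCA, CCC, AAA, CAC, GGG, TTA, TCC, GGC, ATC, GAT, CGC, GAA]
primer: GAAGAACTG
adapter: GTCGAATAT
templates:
  - name: A_circ
    template: A
    topology: circular
    circle_len_nt: 36
    expected: [GAA, GAA, ATA, GAA, GAA, CAC, GAA, GAA, GGG, GAA, GAA, CTG]
    barcodes: {3: ATA, 6: CAC, 9: GGG}
  - name: B_circ
    template: B
    topology: circular
    circle_len_nt: 36
    expected: [GAA, GAA, AAA, GAA, GAA, TCC, GAA, GAA, CCC, GAA, GAA, CTG]
    barcodes: {3: AAA, 6: TCC, 9: CCC}
  - name: C_circ
    template: C
    topology: circular
    circle_len_nt: 36
    expected: [GAA, GAA, TTA, GAA, GAA, GAT, GAA, GAA, CGC, GAA, GAA, CTG]
    barcodes: {3: TTA, 6: GAT, 9: CGC}
  - name: D_circ
    template: D
    topology: circular
    circle_len_nt: 36
    expected: [GAA, GAA, ATC, GAA, GAA, CCA, GAA, GAA, GGC, GAA, GAA, CTG]
    barcodes: {3: ATC, 6: CCA, 9: GGC}
  - name: A_lin
    template: A
    topology: linear
    instruction_len: 9
    expected: [GAA, GAA, ATA, GAA, GAA, CAC, GAA, GAA, GGG,
               GAA, GAA, CTG, GAA, GAA, ATA, GAA, GAA, CAC]
    barcodes: {3: ATA, 6: CAC, 9: GGG}
  - name: B_lin
    template: B
    topology: linear
    instruction_len: 9
    expected: [GAA, GAA, AAA, GAA, GAA, TCC, GAA, GAA, CCC,
               GAA, GAA, CTG, GAA, GAA, AAA, GAA, GAA, TCC]
    barcodes: {3: AAA, 6: TCC, 9: CCC}
  - name: C_lin
    template: C
    topology: linear
    instruction_len: 9
    expected: [GAA, GAA, TTA, GAA, GAA, GAT, GAA, GAA, CGC,
               GAA, GAA, CTG, GAA, GAA, TTA, GAA, GAA, GAT]
    barcodes: {3: TTA, 6: GAT, 9: CGC}
  - name: D_lin
    template: D
    topology: linear
    instruction_len: 9
    expected: [GAA, GAA, ATC, GAA, GAA, CCA, GAA, GAA, GGC,
               GAA, GAA, CTG, GAA, GAA, ATC, GAA, GAA, CCA]
    barcodes: {3: ATC, 6: CCA, 9: GGC}
  - name: sc8211_I
    template: I
    topology: circular
    circle_len_nt: 36
    expected: [GAA, GAA, ATA, GAA, GAA, CTG, GAA, GAA, CGC, GAA, GAA, CTG]
    barcodes: {3: ATA}
  - name: sc8211_II
    template: II
    topology: circular
    circle_len_nt: 36
    expected: [GAA, GAA, CGC, GAA, GAA, CTG, GAA, GAA, ATA, GAA, GAA, CTG]
    barcodes: {3: CGC}
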