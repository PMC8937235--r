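---
title: "Quantifying RNA-catalyzed rolling circle synthesis from reads and gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNA-catalyzed rolling circle synthesis from reads and gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripletRCS)
```

## The system and the questions

A triplet polymerase ribozyme (TPR) extends an RNA primer on a small circular
RNA (scRNA) template using trinucleotide triphosphates (triplets) as
substrates. On a circular template, synthesis can continue past one full turn
of the circle: each new triplet pairing at the 3'-end is compensated by
displacement of three base pairs at the nascent strand's 5'-end, so rolling
circle synthesis (RCS) yields concatemeric products. Two data types quantify
this process:

* **Deep-sequenced extension products.** Reads have the structure
  `[sample barcode] + primer (GAAGAACTG) + triplets + 3' adapter
  (GTCGAATAT...)`. Barcode triplets placed at positions 3, 6 and 9 of the
  extension identify which of four mixed templates (A-D) a product came from.
  The questions are: with what per-position fidelity is each triplet
  incorporated, how far does fully templated synthesis reach, and how much
  more likely is a circular template than a linear one to support correct
  synthesis beyond full length (where the linear template has run out of
  instruction and only non-templated terminal-transferase (TT) appending
  remains)?
* **Gel densitometry of extension ladders.** Each band b of a lane is a
  product extended by b triplets. Band intensities give per-junction
  extension efficiencies, their oscillation reflects the helical geometry of
  the template circle, and time courses give band-formation velocities.

The package implements both quantifications plus a seeded generator of
synthetic reads and lanes with ground truth, so that every statistic can be
validated by parameter recovery and by brute-force counting oracles.

## Positions, geometry, and the triplet alphabet

Triplet positions are **1-based from the first extension triplet after the
primer**; the primer occupies the preceding slots. On a 36 nt circle primed
with the 9 nt primer P9_1 the expected triplets repeat with period 12, the
last three period slots being the primer's own triplets — so position 12
carries the primer's final CTG and position 15 repeats position 3. Full
length is `full_circle_triplets(36, 9) = 9` incorporations;
`product_length_nt(9, k)` and `circle_coverage()` convert between
incorporations, nucleotides, and turns of the circle. Circles whose length is
not a multiple of 3 (the experimental 34-58 nt series) carry an explicit
`full_circle_override` rather than any silent rounding; they take part in gel
arithmetic only.

All sequence handling is in DNA representation (reads are sequenced cDNA);
`rna_to_dna()` maps U to T one-way at ingest. The substrate alphabet is the
14 triplets CTG, ATA, CCA, CCC, AAA, CAC, GGG, TTA, TCC, GGC, ATC, GAT, CGC,
GAA; fidelity denominators sum over exactly this set.

The bundled `templates.yaml` fixture defines templates A-D (circular and
linear) and the two branched-synthesis products I/II. The position-3
barcodes (ATA, AAA, TTA, ATC) are the published classification barcodes; the
position-6 and position-9 barcode identities are **synthetic placeholders**
chosen from the alphabet with the documented GC-content pattern, and are
meant to be replaced in the fixture if the real identities are available.
For the branched product barcode the fixture uses CGC, the spelling
consistent with the substrate alphabet (the same triplet is sometimes
written as its rotation GCG). Linear one-pot
templates carry expected triplets through position 18 — the continuation a
circular repeat would instruct — because fidelity beyond the template's end
is scored against that continuation, while `instruction_len = 9` tells the
simulator where instruction truly stops.

## Decoding reads

`decode_reads()` mirrors exact-substring processing: optional demultiplexing
by exact barcode prefix, anchoring at the **first** exact occurrence of the
primer (reads without it are discarded and counted), then non-overlapping
triplet segmentation up to the first adapter occurrence. Matching is exact by
default (a Hamming tolerance exists for demultiplexing but defaults to 0)
because the fidelity statistics are defined over exact matches. Reads whose
adapter does not start on a triplet boundary are decoded but flagged
(`frame_ok = FALSE`) and excluded from fidelity counting: they cannot be
assigned triplet positions. Reads are processed in the deposited orientation;
no reverse-complement search is attempted.

## Fidelity (prefix-conditioned counting)

Classification uses the triplet at position 3: `classify_template()` maps it
through the position-3 barcode table, which forces the position-3 fidelity of
classified reads to exactly 100%.

`count_conditional()` implements the counting scheme behind the fidelity
statistic. For position a on template Y it counts the observed triplet of
every read whose positions 1..a-1 all match Y's expected triplets — the
generalization of querying `primer + expected(1..a-1) + xxx` for each
alphabet triplet xxx. The fidelity is then

$$F(a, xxx, Y) = 100 \cdot \frac{n(xxx, a, Y)}{\sum_{XXX} n(XXX, a, Y)},$$

with the sum over the 14-triplet alphabet. Observed triplets outside the
alphabet are tallied as "other" and excluded from the denominator (the
statistic sums over the substrate alphabet only), but never silently dropped.
Cells with denominator n at or below 5 are masked as low-n (threshold
configurable). An `unconditional` counting mode (ignore upstream errors) is
available for sensitivity analysis, since with real data one cannot always
know how far upstream conditioning extended; prefix conditioning is the
default because it makes the cumulative product exact (next section).

`cumulative_correct()` multiplies the correct-triplet fidelities from
position 3 through X, giving the probability that a classified product is
fully templated through X; `fold_difference()` is the circular/linear ratio
of these probabilities, with a zero linear probability reported as an `Inf`
sentinel rather than an error.

**Telescoping identity.** With prefix conditioning, the denominator at
position a+1 is exactly the count of reads correct at position a, so the
cumulative product collapses to (reads fully correct through X) / (reads
counted at position 3). This identity is exact **when every counted read
spans the full position range**, which matches how the data are produced
(products are gel-excised above full length and sequenced through the 3'
adapter). Reads terminating inside the range break the telescoping
denominators; the tests therefore use termination distributions with support
at or beyond the top analysis position, and the identity is asserted in
integer count arithmetic. What passing these tests shows is that the counting
machinery is self-consistent — not that real reads satisfy the spanning
assumption; with partially spanning reads the cumulative product estimates a
chain of conditional extension fidelities instead.

## Concatemer spectrum

For branched RCS (two primer sites on one circle, products I and II),
`count_correct_products()` counts reads that are **exactly** k correct
triplets ending in the adapter in frame — full-length exact match, not
prefix match, because a product "of a specific length ending in the 3'
adapter" is the unit of counting. Counts are reported for both products
against every read; a read can match several products only where their
expected sequences coincide (shared prefixes at small k), and such reads are
counted for each and flagged. Disabling the adapter requirement can only
grow counts (asserted as a property). `spectrum_summary()` reports the
longest observed product and its circle coverage.

## Gel densitometry

From band intensities $I_0..I_n$, the efficiency of junction b is

$$E_b = \frac{\sum_{i=b}^{n} I_i}{\sum_{i=b-1}^{n} I_i},$$

the fraction of molecules that reached band b-1 and were extended through
junction b. A zero denominator yields a missing value, never 0 or 1:
absence of signal is not evidence of inefficiency. The survival fraction to
band k telescopes to $\prod_{b\le k} E_b$ (asserted exactly on integer
lanes), and every statistic is invariant to rescaling the lane (loading
differences cancel).

`mean_efficiency()` is the arithmetic mean of $E_1..E_k$ — the conventional
reading of "mean junction efficiency" — with a geometric option since the
product of efficiencies has the survival interpretation. The default
averaging window is the full ladder.

`periodicity()` quantifies the helical modulation: junction b sits
`3 * b` bp from the primer junction (one triplet = 3 bp of new duplex), the
series is fit jointly with an intercept, a linear trend, and a sinusoid at
each scanned period (default 2-20 bp in 0.05 bp steps), and the period
maximizing variance explained beyond the trend is returned with its R².
Joint fitting (rather than detrending first) keeps the peak unbiased at the
modest series lengths gels provide. Two numerical safeguards matter: series
with no variance beyond the trend return "no significant period" (R²
threshold 0.2), and periods at or below twice the junction spacing are
scanned but never selected while longer candidates exist, because 3-bp
sampling cannot distinguish a sub-Nyquist period from its alias (the two fit
identically); exact ties resolve toward the longer period. The default
reference pitch constant is 11.3 bp/turn (A-form dsRNA).

`band_velocity()` is the least-squares slope of a band's intensity fraction
(fractions, to cancel lane loading) against time — applied to the full-length
band and the first beyond-full-length band it gives the extension and
strand-invasion velocities. `parity_size()` fits mean efficiency against
circle size and solves for the size at which the fitted line reaches a linear
template's mean efficiency, flagging extrapolation beyond the observed sizes.

## The synthetic-data generator

`simulate_dataset()` inverts the decoding pipeline: reads are
`[barcode] + primer + triplets + [adapter]`, the triplet at templated
position a is the expected one with probability `p_correct[a]`, otherwise
drawn from an error distribution over the alphabet **excluding the expected
triplet** (so `p_correct` is exactly the correct-incorporation probability —
required for binomial parameter-recovery checks). Beyond a linear template's
instruction, triplets come from the TT distribution; termination is an
explicit distribution over the number of incorporations (it absorbs any
per-step stopping probability); the adapter is present with probability
`p_adapter`, followed by a fixed documented filler. Quality strings are a
constant "I" — the analysis is sequence-only. One seed drives a single
pseudo-random stream consumed in a fixed order, so identical configs give
byte-identical FASTQ.

The default fidelity profile (`default_fidelity_profile()`) mimics the
qualitative structure the one-pot experiments display: a plateau up to full
length (0.90 circular / 0.79 linear), a sharp dip at the strand-invasion
position (0.109), and partial recovery beyond (0.5). These are generator
conditions, not estimates: the real system's values are data. In the
analysis scripts the TT distribution down-weights GAA (weight 0.09 against 1
for the other 13 triplets, giving it a ~0.7% draw probability) because
non-templated appending rarely provides the very triplet the repeat expects
next — this is what makes the linear templates' beyond-full-length fidelity
collapse while circular templates stay templated. The branched-synthesis
emulation uses a sustained templated plateau (0.95 throughout, no invasion
dip, double priming maintains invasion) and a geometric length spectrum over
k = 9..29.

`simulate_lane()` generates gel lanes with junction efficiencies
`e_b = e0 * (1 - A * (1 + cos(2*pi*(3b + phase)/pitch))/2)` and band
intensities that conserve the number of loaded molecules (asserted exactly);
optional multiplicative log-normal noise models densitometry error. The
efficiency series computed from a noiseless simulated lane equals the
injected series exactly, which is what makes lane round-trips sharp tests.

What the generator does **not** emulate: instrument substitution/indel
errors, RT-PCR chimeras, and the blunt-end ligation artifacts occasionally
seen on linear templates. Passing the recovery tests therefore validates the
statistics under the biochemical error structure, not robustness to
sequencing artifacts.

## Problem sizes and reproducibility

The bundled analyses run on synthetic datasets of 10,000 reads per
experiment (2,500 per template for the one-pot mixtures, 5,000 per branched
product) and 9-12-junction lanes — sizes at which binomial standard errors
on fidelities are well below a percentage point at the plateau while every
script completes in seconds. `scripts/acceptance.R` recomputes the headline
quantities from scratch under a caller-supplied seed. The full-scale
deposited datasets are not bundled; `analysis/06_deposited_data.R` runs the
identical pipeline on them when the files are supplied locally.

## Known limitations

* File readers load whole files (desk-scale inputs), not streams.
* Reads with a second internal primer occurrence are anchored at the first
  (logged, not resolved).
* Fidelity differences between templates are reported, not tested
  statistically.
* The position-6/9 barcode placeholders mean template-level fidelity
  *between* the fixture's templates is only as realistic as those choices;
  all position-level statistics are unaffected.
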