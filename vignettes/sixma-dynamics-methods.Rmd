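---
title: "Methods: duplex-aware 6mA dynamics between growth conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplex-aware 6mA dynamics between growth conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sixmaDyn)
```

## The problem

In ciliates such as *Tetrahymena thermophila*, N6-methyladenine (6mA) sits
almost exclusively in 5'-ApT-3' dinucleotides of the polyploid somatic
macronucleus (MAC, ~45 genome copies), concentrated in the linker DNA
between phased nucleosomes downstream of transcription start sites. Because
an ApT presents an adenine on both strands, each duplex can be **symmetric**
(both adenines methylated), **asymmetric / hemimethylated** (one adenine),
or unmethylated; methylated adenines outside ApT context are **non-ApT**
sites. Comparing two growth conditions (vegetative growth vs starvation)
asks how individual sites move between these states, how the methylation
*level* distribution shifts, and whether gene-level 6mA changes track
expression changes and nucleosome positioning.

`sixmaDyn` implements that analysis as a reusable pipeline over
single-molecule (SMRT-style) base-modification calls, plus a synthetic-data
generator that emulates every input so the whole pipeline is testable
without external data.

## Site model and classification

A **call** is a strand-resolved adenine with coverage, a modification
quality value (Qv) and a methylated fraction `frac` in [0, 1] — the
estimated proportion of MAC copies methylated at that position. Fractions
are stored in [0, 1] throughout; percent scales appear only in printed
summaries, which avoids double-scaling bugs.

Coordinates are 0-based half-open everywhere inside the package; 1-based
conventions exist only at file boundaries (GFF3, qPCR site names). A
"Crick-strand adenine at coordinate p" means the Watson base at p is T, so
calls on both strands share genomic coordinates.

Processing order is:

1. **Normalise coverage** to a common target (default 100x) by one global
   scalar, target / mean raw coverage over calls. The mean is taken over
   calls because only calls carry coverage in the input. Normalisation
   precedes filtering — the package assumes the stated order "normalised
   coverage > 25x", and this is the one place where that assumption
   matters.
2. **Filter** with strict inequalities: `qv > 30` and `coverage > 25`
   (defaults; both configurable).
3. **Classify** each surviving adenine: non-ApT if its strand-local 3'
   neighbour is not T; otherwise symmetric when the duplex partner adenine
   is also in the filtered set, else asymmetric. Symmetry is therefore
   evaluated *after* filtering: a partner removed by the confidence filter
   leaves the survivor asymmetric. This is an interpretation — observed
   hemimethylation is indistinguishable from sub-threshold methylation of
   the partner — and it is stated as such wherever it matters.
4. **Bin levels**: L1 [0, 0.2), L2 [0.2, 0.4), L3 [0.4, 0.6),
   L4 [0.6, 0.8), L5 [0.8, 1]; bins are left-closed with L5 closed at 1.

Composition tables count symmetric sites as individual adenines (a fully
methylated duplex contributes 2), and percentages are rounded to one
decimal with half-away-from-zero, matching printed-table style. Density
denominators (6mA/A) count strand-resolved adenines — Watson A plus Watson
T, N excluded — because the calls are strand-resolved; a Watson-A-only
switch is provided. Bins with no adenine at all report `NA`, never 0.

## Cross-condition dynamics

`match_conditions()` joins two classified sets on strand-resolved adenine
keys; an adenine absent from one condition's filtered set is
"unmethylated" there (same caveat as above — this is "not confidently
called", a documented limitation). Accounting is adenine-level because the
composition tables count adenines; the duplex-level view is derived from
it. Published transition percentages mix denominator conventions, so
`transition_fraction(count, denominator)` requires the denominator
explicitly rather than guessing.

Conversion/retain GATC sites for restriction-qPCR validation are duplexes
symmetric in condition A and, respectively, fully unmethylated or still
symmetric in condition B, whose A/T occupies positions 2-3 of a Watson
GATC tetramer (the DpnI/DpnII recognition site).

## Gene-level statistics

The **6mA amount** of a region is the sum of `frac` over its methylated
adenines — site count weighted by level. Gene windows are strand-aware
relative to the TSS; the default analysis window is the first kilobase
downstream, `[TSS, TSS + 1000)`, oriented along the gene (one open choice
here: windows could pool both strands symmetrically around the TSS; the
package uses the strand-oriented window). Windows running off a chromosome
end are truncated, and the gene is retained.

Composite profiles are densities (they sum to 1 over their axis):

* **metagene**: genes longer than 1 kb scaled to unit length, extended one
  unit each side, bin width 0.05 scaled units;
* **TSS**: per-base from 1 kb upstream to 2 kb downstream.

Expression input is consumed, not fitted: the table carries raw counts per
condition, log2 fold change and an adjusted p value from an upstream
differential-expression tool. Gene classes use strict gates: DEGs at
`padj < 0.05` and `|log2fc| > 2`; starvation-induced means counts
A < 300 and B > 1500 (repressed is the reverse); "highly regulated" is the
top decile of `|log2fc|`, ranked among effectively-expressed genes when an
FPKM flag column is present. The decile definition is ambiguous in the
source material; ranking by |log2fc| among expressed genes is this
package's documented choice, and both the fraction and the pool are
configurable. The amount-change/expression-change association is a plain
two-sided Pearson test on raw values (`amount_B − amount_A` vs log2fc),
refusing n < 3 or zero variance.

## Nucleosome phasing

Dyads are midpoints of mononucleosome-sized fragments (120-180 bp gate,
configurable), the standard MNase convention. The composite dyad profile
accumulates dyads per base in a strand-oriented `[-500, 1500)` window
around TSSs, applies a centred moving average (width 31 bp; a plain moving
average was chosen over a Gaussian kernel for transparency — the window
parameters matter far more than the kernel shape), and normalises to unit
area.

**Positioning degree** is this package's explicit, testable statistic —
the upstream literature defers the exact formula to prior work, so the
definition here is a declared substitute and absolute published degree
values are not reproduction targets. For nucleosome +k (spacing s = 200 bp
default): the peak is the profile maximum in
`[s(k-1), s(k-1) + s + 50)`; flanking troughs are minima between adjacent
peaks (between the TSS and the +1 peak on the left end, and between the
last peak and the window end on the right); peak and trough heights are
mean densities within ±20 bp of the located extremum, and

degree = (peak − trough) / (peak + trough),

with the trough height averaged over the two flanks. Numerical details
that turned out to matter: trough searches stay one averaging half-width
away from flanking peaks, so a sharp peak cannot leak into its own
trough's averaging window, and tied extrema resolve to the middle of the
tied run so a flat trough is probed at its centre. A flat profile scores
exactly 0, an ideal profile with empty linkers scores 1, and the statistic
is invariant under positive rescaling. On a cosine profile of amplitude
`a` over mean `m` the degree is `a·c/m` with `c` the discrete ±20 bp
averaging attenuation — a closed form the tests check against.

**Periodicity** is the lag of the first local maximum of the profile
autocorrelation beyond 50 bp, after undoing the triangular taper of the
n-denominator autocorrelation estimate and refining the peak by parabolic
interpolation. A bare "first local maximum" rule fires on white noise
almost surely, so the maximum must also exceed a floor (0.1 by default)
for the profile to count as periodic; otherwise the function raises an
"aperiodic" error.

6mA-to-dyad phasing reports, for each methylated adenine between two
consecutive dyads, its relative position `(pos − d_i)/(d_{i+1} − d_i)`
with its level bin; inter-dyad gaps over 400 bp are excluded as not
representing neighbouring nucleosomes.

## qPCR arithmetic

DpnI cuts methylated GATC, DpnII cuts unmethylated GATC. With
`dCt = Ct_digested − Ct_undigested` per digest,
`ddCt = dCt_DpnI − dCt_DpnII` (the undigested Ct cancels algebraically —
asserted explicitly in the tests) and
`dddCt = ddCt_A − ddCt_B` across conditions. Conversion sites give
dddCt > 0; retain sites give dddCt near 0. "Near" is |dddCt| < 1 cycle by
default — the source material gives no threshold, so 1 cycle is this
package's configurable choice. No PCR-efficiency correction is applied
(none is used upstream).

## The synthetic-data generator

`sim_config()` fixes every distributional choice once; a single seed
determines all outputs through per-generator substreams, so stages can be
rerun in any order and reruns are byte-identical.

What it emulates, and the defaults (chosen from the study conditions or,
where unstated, at values a practitioner would call realistic — and not
revisited):

* AT-rich genome: i.i.d. bases at 75% A+T; genes > 1 kb tiled on
  alternating strands.
* Duplex 6mA: condition-A duplex states from a
  symmetric/asymmetric/unmethylated mixture (0.55 / 0.40 / 0.05), plus
  non-ApT adenine units (90% methylated in condition A); condition-B
  states through a 4x4 transition kernel shaped like the
  vegetative-to-starved flux (much symmetric methylation becomes
  hemimethylated or lost; non-ApT methylation largely disappears).
  Structurally impossible targets — a duplex becoming non-ApT or vice
  versa — are renormalised away per unit kind.
* Levels: class-conditional beta mixtures (symmetric concentrated high,
  asymmetric bimodal, non-ApT broad), continuous by default for speed; a
  copy-number mode draws binomial(45)/45 to mirror the ~45-copy MAC.
* Coverage: negative binomial, mean 103 (the study's average depth),
  dispersion 10, so the confidence filter has realistic bite. Qv: offset
  gamma with ~18% below the cutoff.
* Nucleosomes: true dyads at TSS + 100 + 200k, Gaussian positional jitter
  (sd 10 bp), fragment lengths ~N(147, 12) — giving ~50 bp linkers at
  200 bp spacing.
* Expression: `log2fc = beta * standardised(amount change) + N(0, sd)`;
  `beta_for_rho()` inverts the implied correlation. p values come from a
  permutation-style null (zero-coupling fold changes), BH-adjusted.
* Ct quadruplets: a 5-cycle digest shift on the sensitive enzyme,
  measurement noise sd 0.3.

What it does **not** emulate: sequence composition beyond i.i.d. bases
(no isochores, no codon structure), kinetic signal and its error modes
(calls are drawn, not modelled from IPDs), mappability and coverage
autocorrelation along the genome, MNase sequence bias, and biological
replicate structure in expression. Passing tests on synthetic data
therefore demonstrate the *arithmetic and inference* of the pipeline —
classification, matching, profile and degree computation, correlation
recovery — not robustness to the error structure of real sequencing data.

## Problem sizes used in the test suite

Synthetic checks run at sizes where the tested statistics are
well-resolved: 1e5 duplexes (on a 2 Mb two-chromosome genome) for exact
class-label recovery and 3-sigma kernel recovery; 2,000 genes for the
correlation point estimate and 100 replicates of 500 genes for sign
recovery; ~20-gene composites with ~3,300 dyads for phasing statistics.
These are the package's chosen desk-scale study conditions; all thresholds
in the tests (3-sigma binomial bounds, ±10 bp periodicity, strict
zero-noise qPCR identities) were fixed before the corresponding data were
drawn.

## Known limitations

* "Unmethylated" after filtering conflates absence with sub-threshold
  methylation; transition counts involving that state inherit the
  ambiguity.
* The positioning degree is a substitute definition; compare trends, not
  absolute values, against other work.
* Genome-scale absolute counts and densities require the full reference
  genome and raw kinetics data; the package reproduces the published
  *arithmetic* on printed counts but does not claim the genome-wide
  numbers from synthetic data.
* The rDNA (or any other) chromosome is excluded by an explicit name
  list in the pipeline configuration; no automatic identification is
  attempted.
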