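---
title: "Models and methods behind icemob"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind icemob}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icemob)
```

icemob analyses the life cycle of integrative and conjugative elements
(ICEs): excision from the chromosome by recombination between flanking
direct repeats, quantification of the excised fraction by qPCR,
identification of the regulatory sites of the LysR-family transfer
activator, dissection of the origin of transfer (*oriT*), and paired-read
expression analysis of the regulatory cascade.  This vignette explains the
models, their assumptions, the tunable parameters, and the design choices
made where the problem was genuinely open.

## The excision model

An integrated element is represented as
`host_left – R – payload – R – host_right`, where `R` is the boundary
direct repeat (default `GATTTTAAG`, 9 bp, the repeat flanking the element
this package models).  `excise()` implements site-specific recombination
between the two identical copies as pure string/interval arithmetic:

* the crossover is placed at the repeat's **left edge**, so the circle
  keeps the attL copy and the chromosome keeps the attR copy.  Because the
  two copies are identical, any consistent crossover convention produces
  identical molecules; the convention only fixes which *coordinates* are
  reported.  This is tested by the byte-identity of
  `integrateICE(excise(x))` round trips.
* circular molecules are stored linearly with the junction repeat at
  position 1 plus a `circular` flag.  Operations that must see the
  junction (fragment simulation, primer search) scan the doubled sequence
  `seq + seq[1..max_product]`; truth intervals on circles are stored
  modulo the circle length.
* features wholly inside the excised interval are remapped to the circle,
  wholly outside to the shortened chromosome; a feature straddling a
  junction has no well-defined image and is dropped with a warning.

`detectBoundaryRepeat()` recovers `R` as the longest *maximal* direct
repeat pair — identical same-strand substrings that cannot be extended by
one base on either side.  The minimum considered length defaults to 6 bp:
below that, chance pairs dominate even in short contexts.  Two search
modes exist because chance repeats are a fact of genome-scale sequence:
a genome-wide seed-and-extend scan, and a hinted mode that searches only
windows (default ±60 bp) around a supplied element boundary.  On a random
multi-kilobase host, chance maximal repeats of 9+ bp are *expected*
(roughly `L²/4^9` seed pairs), so the genome-wide mode reports whatever
is genuinely longest, while the hinted mode answers the targeted question
"what repeat flanks *this* element".  The synthetic generator regenerates
its random host until the planted repeat occurs exactly twice, is
non-extendable, and is the unique longest pair within those hint windows,
which makes hinted detection on generated fixtures exact by construction.

### qPCR quantification

The excision assay uses three primer sets: one spanning the attP junction
(amplifies only the circle), one spanning the attB junction (amplifies
only the post-excision chromosome; on the integrated form its product
would span the whole element and is suppressed by the product-size cap),
and one internal to the element (amplifies integrated and circular forms
alike — the internal standard for total element copies).
`designDiagnosticPrimers()` derives such a set from any annotated
integrated genome; the real assay's primer sequences are not printed in
the main text of the study this models, so the packaged primers are
synthetic and reproduce the placement logic, not the oligos.

`quantifyExcision()` works at the relative-copy level:
`normalized(t, target) = raw(t, target) / raw(t, internal standard)`
cancels DNA input differences, and
`fold(t, target) = normalized(t) / normalized(t0)` sets the first
timepoint to 1.  The panel is scale-invariant per timepoint by
construction.  Cq values can be converted with `cqToCopies()`, which
assumes amplification efficiency 2 (no efficiency calibration is
modelled).  Simulated panels (`simulateQpcrPanel()`) use multiplicative
log-normal noise with CV 0.2 — typical qPCR technical variability — and
the tests require a programmed 100-fold excision increase (fraction
1e-5 → 1e-3) to be recovered within 2-fold.

## The paired-read mapper

The mapper reimplements a deliberately minimal published algorithm, so its
simplicity is a feature, not a shortcut:

* **seeds**: the first `k = 21` bases of each mate, matched at 100 %
  identity on either strand via an exact hash index.  Seeds containing N
  are unmappable; reads shorter than 21 nt are rejected at the door.
* **placements**: the two seeds must land on opposite strands facing
  inward (forward mate's 5' end at or left of the reverse mate's 5' end).
  The published description does not state an orientation constraint;
  requiring a proper pair matches paired-end chemistry and prevents
  nonsense spans, and is flagged here as an interpretation.
* **distance rule**: end-to-end distance = rightmost covered base −
  leftmost covered base + 1, bounds 20 and 2000 bp **inclusive**; among
  in-range placements the shortest wins.  Ties at the minimum are
  reported `ambiguous` and excluded from counting (conservative; the
  source algorithm only says the shortest is selected).  Orientation-valid
  placements that all fall out of range are `distance_violation`; a seed
  with no hit, or hits that admit no inward-facing opposite-strand
  pairing, is `unmapped`.
* **counting**: each mapped span increments every gene feature it
  overlaps by ≥ 1 bp (feature attribution is not defined by the source;
  multi-overlap counting is symmetric and testable).  Expression is
  normalized to a reference gene (`rrn` by design) and compared across
  conditions as a ratio of normalized counts; genes absent from the
  baseline are reported as flagged infinities rather than numbers.

The mapper is verified against a brute-force oracle (exhaustive seed
placement via an independent string-matching route, same distance rule) on
hundreds of random genomes including engineered duplications that force
multi-hit seeds and exact distance ties.

## Regulatory-site scanning

LysR-family binding sites follow the `T–N11–A` consensus embedded in an
interrupted inverted repeat.  `findTN11A()` defines the arms to *include*
the conserved T and A as their innermost bases — consistent with the
printed site `CGTTTT…AAAACG`, where the boxed T/A sit inside the repeat —
with `armLen` defaulting to 5 and a mismatch budget defaulting to 1
("interrupted" is never quantified by the source; the budget is a
parameter, and the bundled sites document working presets: the
xis-upstream site is perfect at 6-bp arms, the second full site needs 3
mismatches).  Because the arms are an inverted repeat, the reverse
complement of a TN11A site is again a TN11A site; both-strand scans
therefore report mirror duplicates and default to forward-only.
Minus-strand hits give `t_pos`/`a_pos` as forward coordinates of the
bases read as T/A on that strand, so `|a_pos − t_pos| = 12` always.

Similarity and half-site searches are Hamming-only (substitutions, no
indels), matching how the source compares sites ("3 mismatches across 14
nucleotides").  All scanners are cross-checked against naive sliding-window
oracles.

### Promoter boxes

`predictPromoters()` scores every −35/−10 hexamer pair with spacer 15–21 bp
using a positional base-frequency table with consensus `TTGACA`/`TATAAT`.
The exact weight matrix of the promoter-prediction method the source cites
is not printed there; the packaged table is assembled from the classic
E. coli sigma-70 promoter compilations and is exposed via
`sigma70WeightTable()`.  The score is `Σ ln(f/25)` over the 12 hexamer
positions minus 0.35 per bp of spacer deviation from 17, rescaled so the
consensus arrangement scores 100 and the worst possible 0.  Because exact
matrix values are not authoritative, all promoter tests are
property-based — consensus maximality (every single substitution scores
strictly lower) and spacer bounds — never matrix-value assertions.
`sitePromoterArchitecture()` pairs each site with the nearest downstream
−35 box and flags gaps ≤ 5 bp as "immediately upstream" (the printed site
diagrams show sites abutting the −35 box; the threshold is configurable).

## oriT dissection

`findInvertedRepeats()` anchors on every innermost base pair with loop
≤ `maxLoop`, extends arms greedily within the mismatch budget, trims
terminal mismatches so arms end in complementary pairs, and suppresses
hits contained in longer hits with no more mismatches.  It is
strand-symmetric and equal to an exhaustive oracle on small inputs.

`findConservedWindow()` scores each reference window by its best Hamming
identity over all offsets of each homolog (both strands) and returns the
window maximizing the mean — leftmost on ties.  A full multiple alignment
would be the classical route; best-offset identity needs no aligner, is
oracle-checkable, and answers the same question for a fixed window length
(default 20 bp, the size of the conserved core in the modelled *oriT*).
Homologs shorter than the window are an error rather than a partial
overlap, to keep identities comparable.

`classifyConstructs()` encodes the functional rule distilled from the
published deletion series: transfer requires retaining the conserved
20-bp core **and** the innermost inverted repeat REPT1; retaining both
but losing REPT2 attenuates transfer (about two orders of magnitude,
still detectable); anything else is nonfunctional.  Quantitative
frequency prediction is out of scope — the classes are qualitative.
`essentialRegion()` intersects the retained intervals of the
transfer-competent constructs (order-invariant; empty or non-contiguous
intersections are errors) and warns if a nonfunctional construct contains
the result, which would contradict the rule.

The bundled fixture (`oritDeletionFixture()`) encodes the *printed*
construct endpoints (261, 298, 318, 393, and the full 463-bp region) with
the published transfer phenotypes.  The feature coordinates
(conserved core, REPT1/2/3, the two dispensable LysR motifs) are
**synthetic stand-ins**: the true intra-region coordinates are only
available in figure images, so the fixture places them consistently with
every printed phenotype, and the file is named accordingly
(`orit_features_synthetic.tsv`).  Likewise `makeOriTRegion()` builds a
463-bp stand-in sequence carrying palindromes and the conserved core at
those coordinates; it is a labelled synthetic object, not the real region.

## The synthetic-data generator

The generator exists so that every analysis stage has realistic,
truth-annotated input offline.  Its defaults are the study conditions:

| parameter | default | rationale |
|---|---|---|
| `attRepeat` | `GATTTTAAG` (9 bp) | the modelled element's boundary repeat |
| `excisionFraction` | 1e-5 | baseline excised fraction (one excised copy per 1e5 chromosomes) |
| `readLength` | 75 nt | typical short-read paired-end length; must be ≥ 21 for the seed mapper |
| `insertMean`, `insertSd` | 300 ± 50 bp | the real library's insert distribution is unstated; these are conventional paired-end values, exposed in the config |
| `errorRate` | 0 | the mapper demands perfect seeds; errors exist only to probe mapper loss |
| FASTQ quality | constant `I` (Q40) | qualities are unused downstream |

Fragments are drawn from templates with probability proportional to
`template weight × expression weight` of the anchor feature, lengths are
truncated-normal by rejection (rejections are counted), mate 1 is the
forward strand of the fragment start and mate 2 the reverse complement of
its end.  One root seed, with child streams derived per operation in a
fixed order (0 genome assembly, 1 read simulation, 2 qPCR noise,
3 homolog generation), makes identical configs byte-identical.

What the generator does **not** emulate: empirical error and quality
profiles, adapters, GC or coverage bias, transcript-boundary effects
(fragments are anchored on features but not confined to them), or real
regulatory sequence context.  Passing tests therefore demonstrate the
correctness of the algorithms under the stated model — exact repeats,
uniform random background, error-free reads — not performance on real
libraries, where seed errors and low-complexity sequence would reduce
mapping rates.

## Numerical and testing choices

* Coordinates are 1-based inclusive everywhere, matching the archival
  format the field annotates against; "positions 261 and 318 (58 bp)"
  confirms both ends inclusive (318 − 261 + 1 = 58).
* Tie-breaks are deterministic and documented: leftmost conserved window,
  smallest start for equal-length repeat pairs, `ambiguous` status for
  distance ties.
* Problem sizes in the test suite are chosen to finish in about two
  minutes while keeping statistical checks well-powered: mapper/oracle
  equivalence runs 100 random genomes of 1–10 kb with 40 pairs each
  (half containing engineered duplications); expression-ratio recovery
  uses 2 × 10,000 pairs, which puts the programmed 10-fold ratio within
  ±3 binomial standard deviations of the [8, 12] acceptance band; the
  binomial weight check uses 10,000 fragments.
* The real host-genome accession (and the element's true 61.8-kb span and
  463-bp *traF–traI* intergenic region) is a network download; the
  package ships only the measurement operations (`elementSpan()`,
  `intergenicLength()`, `loadAnnotatedGenome()`), exercised on annotated
  synthetic records.

## Known limitations

* The mapper models exact seeds only — no mismatch rescue, no gapped
  alignment, no SAM/BAM output.  This mirrors the source tool.
* Promoter scoring is a homology score, not a thermodynamic or learned
  model, and its absolute values depend on the packaged frequency table;
  only ordering properties should be relied on.
* The excision model treats recombination as exact and instantaneous;
  integrase/excisionase kinetics, multimer intermediates, and tandem
  integrations are out of scope.
* The deletion-series classifier predicts qualitative classes; it does
  not predict transfer frequencies.
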