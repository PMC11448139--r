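# icemob

Sequence analysis of **integrative and conjugative elements (ICEs)** — mobile
elements that excise from the host chromosome by site-specific recombination
between flanking `attL`/`attR` direct repeats, circularize, transfer by
conjugation from an origin of transfer (*oriT*), and reintegrate.  The package
is aimed at microbial geneticists dissecting the regulation of ICE transfer:
it models the excision reaction itself, the qPCR assay that quantifies it, the
regulatory sites of the LysR-family activator that drives it, the *oriT*
architecture that licenses it, and the paired-read expression analysis used to
read the regulatory cascade out of RNA-seq data.  A synthetic-data generator
reproduces the structure of all of these inputs, so every stage runs and is
tested fully offline.

## What it computes

**att-site recombination.**  An integrated element is
`host_left – R – payload – R – host_right`, with `R` a short direct repeat
(9 bp in the modelled element, `GATTTTAAG`).  Excision returns a circle
carrying one repeat copy (*attP*) and a chromosome carrying the other
(*attB*), with `len(circle) + len(chromosome) = len(integrated)`;
integration is its exact inverse.  `detectBoundaryRepeat()` recovers `R` as
the longest maximal direct-repeat pair; `predictAmplicons()` and
`quantifyExcision()` model the three-primer-set qPCR assay
(a → circle, b → attB chromosome, c → both forms as internal standard), with
fold changes relative to the first timepoint.

**Exact-seed paired-read mapping.**  The mapper takes the first 21-mer of
each mate, requires 100 % identity on either strand, keeps placements with
the two seeds on opposite strands facing inward and an end-to-end distance
*d* = rightmost − leftmost + 1 within **[20, 2000] bp**, and selects the
minimum-*d* placement (ties → `ambiguous`).  The spanned range is counted as
one transcript fragment for every gene it overlaps; expression is normalized
to a reference gene (`rrn`) and compared across conditions as

```
fold(g) = (count_B(g) / count_B(rrn)) / (count_A(g) / count_A(rrn))
```

**Regulatory-site scanning.**  LysR-family sites follow the `T–N11–A`
consensus: a conserved T and a conserved A separated by an 11-nt spacer, as
the innermost bases of an interrupted inverted repeat.  `findTN11A()` reports every such pair whose
`armLen`-long arms are reverse complements within a mismatch budget;
`findHalfSites()` finds single arms (`CAAAACG` and variants) bound by one
monomer of the dimer; `predictPromoters()` scores −35/−10 hexamer pairs
(consensus `TTGACA`/`TATAAT`, spacer 15–21 bp) with a positional-frequency
homology score, and `sitePromoterArchitecture()` flags sites sitting
immediately upstream of a −35 box.

**oriT dissection.**  `findInvertedRepeats()` enumerates mismatch-tolerant
inverted repeats; `findConservedWindow()` locates the best-conserved fixed
window across homologous regions (best-offset Hamming identity, both
strands); `classifyConstructs()` predicts deletion-construct phenotypes from
the features they retain (transfer requires the conserved 20-bp core and the
innermost repeat REPT1; losing REPT2 attenuates); `essentialRegion()`
intersects the transfer-competent constructs down to the minimal essential
interval.

## Worked example

```r
library(icemob)

## 1. the published xis-upstream binding site is a textbook TN11A motif
findTN11A(traRBindingSites()[["BSxis"]], armLen = 6)
#>   seq_id t_pos a_pos spacer_len arm_len arm_mismatches strand  site_seq
#> 1    seq     6    18         11       6              0      +  CGTTTTGATGGAGACGCAAAACG
```

The conserved T (position 6) and A (position 18) are separated by an 11-nt
spacer, and the 6-bp arms `CGTTTT`/`AAAACG` are a perfect inverted repeat.

```r
## 2. build a toy integrated genome and excise it
g <- makeIntegratedGenome(SimConfig(hostLength = 300, iceLength = 1000, seed = 1))
excise(g)
#> ExcisionProducts: boundary repeat GATTTTAAG ( 9 bp )
#>   attP circle    : 1009 bp
#>   attB chromosome: 309 bp
```

300 bp host + 1000 bp element + 2 × 9 bp repeats = 1318 bp; the products
(1009 + 309) conserve that length, each keeping one repeat copy.
`integrateICE()` on the two products reconstitutes the input byte for byte.

```r
## 3. deletion-series classification and the essential oriT interval
fx <- oritDeletionFixture()
cls <- classifyConstructs(fx$constructs, fx$features)
cls[, c("name", "retains_conserved20", "retains_REPT1", "predicted_class")]
#>       name retains_conserved20 retains_REPT1 predicted_class
#> 1 pICEoriT                TRUE          TRUE      functional
#> 2     del4                TRUE          TRUE      functional
#> 3     del8               FALSE          TRUE   nonfunctional
#> 4     del6                TRUE          TRUE      functional
#> 5     del7                TRUE          TRUE      attenuated
#> 6     del9                TRUE          TRUE      attenuated
#> 7    del17                TRUE         FALSE   nonfunctional
#> 8    del25                TRUE          TRUE      attenuated

essentialRegion(lapply(which(cls$transfers),
                       function(i) fx$constructs[i, c("start", "end")]))
#> $start
#> [1] 261
#> $end
#> [1] 318
#> $length
#> [1] 58
```

The transfer-competent constructs intersect to positions 261–318: a 58-bp
essential region containing exactly the conserved 20-bp core and REPT1.

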