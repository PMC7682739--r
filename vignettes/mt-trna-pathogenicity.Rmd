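---
title: "Interpreting mitochondrial tRNA variants: structure, conservation and the pathogenicity rubric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting mitochondrial tRNA variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mttrnascore)
```

## The problem

The 22 tRNA genes of the human mitochondrial genome are disproportionately
represented among pathogenic mtDNA mutations, yet most substitutions found
in patient screens are benign population variants. Deciding which reported
mt-tRNA substitutions deserve a pathogenic label is therefore a recurring
desk-analysis task: it combines three independent lines of argument, each
of which this package implements as a tested module.

1. **Structure.** Where does the substitution sit on the tRNA cloverleaf
   (acceptor stem, D-arm, anticodon arm, variable region, T-arm), and does
   it disrupt — or newly create — a classic Watson–Crick (WC) base pair in
   a stem?
2. **Conservation.** Is the affected position conserved across species?
   The conservation index (CI) of a position is the percentage of
   non-human species in a multi-species alignment carrying the human
   reference base; CI > 75 % is taken as evidence of functional potential.
3. **Evidence scoring.** A point-based rubric over published evidence
   (independent reports, conservation, heteroplasmy, segregation,
   histochemistry, biochemistry, single-fiber studies, steady-state /
   trans-mitochondrial cybrid studies) yields a total and one of four
   classes: *neutral polymorphism*, *possibly*, *probably* or *definitely
   pathogenic*.

The packaged fixture (`ndm_fixture()`) carries the nine mt-tRNA
substitutions reported in a screening cohort of non-dystrophic myotonia
patients, together with their published structural characterization and
scoring columns; the `analysis/` scripts replay the full reanalysis on it.

## The gene catalogue as curated data

Canonical (Sprinzl-style) tRNA numbering is not derivable from a gene span
by arithmetic: mitochondrial tRNAs are truncated relative to the canonical
73-position cloverleaf, so a nucleotide's 5′ offset and its canonical label
diverge (rCRS position 4454 is the 53rd nucleotide of tRNA-Met yet carries
canonical number 58). Because the source analysis supplies position labels
rather than a numbering algorithm, the catalogue is a curated data table
(`inst/extdata/trna_*.tsv`), validated at load time:

* rCRS (NC_012920) spans and strands for all 22 genes;
* full coordinate → (canonical position, element) maps for the six genes
  the fixture exercises, anchored so each of the nine published
  (coordinate, canonical position, element) calls is exact;
* the remaining 16 genes carry plain 5′-offset numbering with a generic
  element template, flagged `numbering = "offset"` — adequate for gene
  lookup, not for canonical-position claims;
* reference bases (tRNA orientation) only where the published analysis
  constrains them — the nine variant sites and the cited pair partners —
  and `"N"` elsewhere; the strict reference check skips `N` sites rather
  than invent bases;
* a base-pair inventory restricted to the pairs the published structural
  calls name: 7A–66T in tRNA-Arg, 31T–39A and 27C–43G in tRNA-Thr. Pair
  rows must satisfy their declared class (WC or G–T wobble) or loading
  aborts.

Two deliberate oddities follow the published table rather than textbook
cloverleaf geometry, and are encoded as-is: positions 33 (tRNA-Cys) and 37
(tRNA-Arg) are labelled *anticodon stem* although canonical numbering puts
them in or at the loop; and the stem positions 62 (tRNA-Trp) and 22
(tRNA-Thr) carry no pair in the inventory because the published analysis
reports no pairing effect for substitutions there. Junction positions 8–9
are binned with the D-loop and 26 with the anticodon stem, since the
element vocabulary is closed.

For light-strand genes (e.g. tRNA-Cys) variants are supplied in rCRS
heavy-strand notation, as the literature writes them, and complemented
internally; all catalogue bases are stored in tRNA orientation.

## Pair-effect calls

A substitution at a stem position *disrupts* a pair when the reference
pair is classic WC and the alternate base no longer complements the
partner; turning a WC pair into a G–T wobble counts as disrupted, and
mutating a wobble pair never does (the rubric's footnote restricts to
classic WC pairs). A *created* call is only ever emitted at positions
carrying an explicit potential-partner entry in the catalogue: the entry
records the completing base a mutant must WC-pair with, plus a verbatim
display label. This is data, not folding — the package performs no
secondary-structure prediction.

One fixture entry needs a remark. The published analysis states that
A12308G, at canonical position 44 in the variable region of
tRNA-Leu(CUN), "created a new base-pairing (25 A-37T)". That label cannot
be reconciled with the bases involved (the reference A would already pair
T, the mutant G would not), and position 44 is not position 25 or 37. The
catalogue therefore declares a potential partner at position 44 whose
completing base is C — making the created call fire exactly for A→G — and
reports the label `25A-37T` verbatim. The inconsistency is in the source;
we chose to reproduce its call and its label rather than silently correct
either.

## Conservation index

`compute_ci()` locates the alignment column of a 1-based ungapped
reference position by walking the reference row's gaps, then tallies
non-reference species matching the reference base. The denominator is, by
default, the species with a non-gap base in the column (`"nongap"`); the
fixed-panel denominator (`"all"`) is available by flag. The choice matters
only in gapped columns: with `"nongap"` an all-gap comparison column is an
undefined-CI error rather than a silent 0. The functional-potential flag
is strict — CI must exceed the threshold (default 75), so CI = 75.0 does
not qualify.

The published CI percentages for the nine fixture variants (59.6, 82.6,
75.0, 100, 21.1, 100, 65.4, 100, 100) are carried as *supplied* metadata
and surfaced as such in the report (`ci_source = "supplied"`): the
15-species alignment behind them is not publicly deposited, several of the
printed values are not multiples of 1/14, and we do not claim to recompute
them. What the package *can* assert is the estimator itself, which is what
the tests do (see below).

## The scoring rubric

Point weights, read directly off the published scoring table:

| criterion | points |
|---|---|
| more than one independent report | 2 |
| evolutionary conservation of the base pair | 0–2 |
| variant heteroplasmy | 2 |
| segregation of the mutation with disease | 2 |
| histochemical evidence of mitochondrial disease | 2 |
| biochemical defect in complex I, III or IV | 2 |
| single-fiber segregation with the biochemical defect | 5 |
| steady-state level / cybrid evidence | weak 2, strong 5 |

Classes: total ≤ 6 neutral polymorphism; 7–10 possibly pathogenic; ≥ 11
definitely pathogenic with functional evidence (single-fiber, steady-state
or cybrid), otherwise probably pathogenic (feasible only at 11–12, since
the six non-functional criteria cap at 12; a total ≥ 14 without
functional evidence raises an infeasibility error that matters only for
custom rubrics). The classification boundary at 6 follows the tabulated
"≤ 6" rather than the narrative "< 6", which would leave 6 unclassified.

A scale note: the rubric is conventionally printed as a score "/20", and
`default_rubric()$nominal_scale` records that label, but the criterion
maxima above sum to 22 — the published worked columns force single-fiber
= 5 *and* strong functional = 5 (totals 15, 13 and 10 are reproducible
with no other weights). The package reports plain sums and treats "/20"
as the nominal printed scale; `rubric_maximum()` returns the arithmetic
maximum (22, or 12 without functional evidence). The corresponding
acceptance check in the test suite documents this discrepancy by failing
against the printed 20.

The conservation criterion's 0/1/2 gradation is not defined in the
source, which prints only "No changes → 2". `conservation_points` is
therefore a direct input of the evidence record; when the pipeline runs
with `auto_conservation`, points are derived from the computed CI as 2 at
CI = 100, 1 above the threshold, 0 otherwise — a package choice, exposed
as a switch, not a claim about the source.

Of the nine fixture variants only three have published per-criterion
columns; for the other six only totals (4, 4, 2, 4, 4, 2) are printed.
The fixture ships one consistent synthetic decomposition per variant
(flagged `provenance = "synthetic"`) so the pipeline can run end to end;
tests assert the totals and classes, never the decomposition.

## Synthetic data and what the tests show

`generate_alignment()` implements the simplest generative model under
which the CI estimand equals a named parameter: a uniform random
reference row, non-reference bases equal to the reference with a
per-column conservation probability *p* (otherwise uniform over the three
other bases), and i.i.d. gaps in non-reference rows. The default panel is
15 species — the conventional size for this analysis, one human reference
against 14 others. Everything is reproducible from a single integer seed
scoped to the call (`withr::with_seed`); the global RNG stream is left
untouched.

Property tests check the estimator against a hand-written brute-force
column tally on 200 random small alignments, and parameter recovery at
*p* = 0.8 with 200 comparison species and 500 columns, where the mean CI
must land within three analytic binomial standard errors
(100·√(p(1−p)/200/500) ≈ 0.13 points) of 80. `generate_evidence()` draws
evidence records by rejection against the classifier until a requested
class mix is met exactly, with a bounded attempt budget so unreachable
requests fail rather than loop.

What the generator does *not* emulate: phylogenetic correlation between
species (rows are i.i.d. given the reference), realistic gap structure
(indels are not contiguous), base composition bias, and any relationship
between structural elements and conservation. Passing tests therefore
validate the estimator's arithmetic and the pipeline's plumbing, not the
biological calibration of the 75 % threshold on real alignments.

## Problem sizes and determinism

The suite runs in well under a minute: the evidence-space enumerations
are exhaustive but tiny (96–576 records), the oracle-equivalence loops
use alignments of at most 10 × 25, and the one larger simulation is the
201 × 500 recovery check. The pipeline is deterministic end to end:
rerunning on unchanged inputs reproduces the output TSVs byte for byte
(asserted in the tests), which is why the fixture CI values are data
rather than recomputed quantities.

## Known limitations

* Canonical numbering and elements are authoritative only for the six
  curated genes; offset-numbered genes answer "which gene" but not
  "which canonical position".
* The pair inventory is deliberately sparse (only source-anchored pairs),
  so pair-effect calls outside the curated sites return `"none"` by
  construction rather than by structural argument.
* Supplied CI values are reported, not verified; computing CI requires
  the user to provide per-gene alignments.
* The rubric automates the published arithmetic and thresholds; it does
  not weigh evidence quality, and `generate_evidence()` samples fields
  independently, which real evidence records are not.
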