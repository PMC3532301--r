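---
title: "Reaction difference fingerprints and nearest-neighbour EC assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction difference fingerprints and nearest-neighbour EC assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

An enzymatic reaction is characterised by the bonds it makes and breaks.
`rdfec` captures that pattern without any atom mapping: each molecule is
reduced to the counts of its *linear fragments* — simple paths of 0 to
`max_len` bonds in the hydrogen-suppressed molecular graph — and a
reaction's descriptor is the stoichiometry-weighted difference

$$\mathrm{RFP} \;=\; \sum_{i \in \text{reactants}} c_i\,\mathrm{MFP}_i
\;-\; \sum_{j \in \text{products}} c_j\,\mathrm{MFP}_j,$$

a sparse signed-integer vector.  Fragments untouched by the transformation
occur equally on both sides and cancel; what remains is a local signature
of the chemical change.  Reactions are compared by the Euclidean distance
between their difference fingerprints, and a query reaction inherits the
three-level EC number (sub-subclass) of its nearest labelled neighbour.

The assumptions are explicit and worth keeping in mind:

* **Whole equations, no cofactor stripping.**  Every compound in the
  equation participates, so a methylation using one methyl donor is at a
  non-zero distance from the same methylation using another donor.  This
  avoids any manual reactant-pair curation, at the price of donor/acceptor
  context entering the descriptor.
* **Stereochemistry is invisible.**  Fragments carry no stereo labels, so
  racemisations and epimerisations have identically zero difference
  fingerprints.  Such reactions are unclassifiable by this descriptor; the
  dataset filter removes them (category 6) and `assign_ec()` refuses
  zero-fingerprint queries rather than returning an arbitrary neighbour.
* **Elemental balance.**  For a heavy-atom-balanced equation all length-0
  (single-atom) entries cancel, so distances between balanced reactions are
  carried entirely by bonded fragments.

## The fragment dialect

Published descriptions of path-based reaction fingerprints delegate
fragment generation to external toolkits and rarely pin down the atom
typing, so the package fixes one dialect and records it in every report
header (`dialect=element+aromaticity linear fragments v1`):

* **Atom symbols** are element symbols, lower-cased for atoms in aromatic
  rings (`c`, `n`).  Formal charges are appended (`N+1`) only when
  `use_charge = TRUE` (default off); attached-hydrogen counts are never
  part of the type — the reference examples shipped with the package (a
  racemisation with an exactly zero fingerprint, and a pair of
  N-methylations differing in a single fragment) are only consistent with
  H-free heavy-atom typing.
* **Bond symbols** are `-`, `=`, `#`, `:`.  Aromaticity is perceived by
  Open Babel during input normalisation, so Kekulized and aromatic
  spellings of the same ring yield identical fragments.  Open Babel's MOL2
  output writes carboxylate groups with the same `ar` bond code as true
  aromatic rings; the parser accepts the aromatic flag only for bonds that
  lie in a ring, which separates the two cases.
* **Fragments are simple paths** (no repeated atom).  Ring-closure and
  branched fragments are not emitted.  Each fragment string is
  canonicalised as the lexicographic minimum of its forward and reversed
  spelling.

### Counting convention

Path enumerators differ in whether an undirected path is counted once or
once per traversal direction, and the two conventions give proportional
but not identical fingerprints.  `count_mode = "path"` (the default)
counts every undirected path once, which is what a hand enumeration
naturally produces: ethanol at `max_len = 2` is
`{C:2, O:1, C-C:1, C-O:1, C-C-O:1}`.  `count_mode = "traversal"` counts
each path of length ≥ 1 once per direction, i.e. doubles every bonded
entry.  The traversal convention is the one under which the package's
reference N-methylation example reproduces its published minimum distance
of 2: the tryptophan and serotonin methylations differ in exactly one net
`C-C-N-C` fragment (the methylated nitrogen sits next to a branched
α-carbon in one case and an unbranched methylene in the other), of weight
1 under path counting and 2 under traversal counting.

On strictly balanced reactions the choice scales all distances by exactly
2 (length-0 entries vanish), so nearest neighbours, votes and
cross-validation results are identical under either mode.  Fingerprints
computed under different modes (or different `max_len`, or charge typing)
are deliberately incomparable and raise an error.

## Dataset curation

`filter_dataset()` applies six exclusion cases in a fixed order, reporting
each reaction once under the first case that matches:

1. **Elementally unbalanced equations.**  The check compares
   coefficient-weighted heavy-atom element counts of the two sides.  This
   is a proxy for "molecules missing from the equation": hydrogen and
   charge bookkeeping are invisible in H-suppressed structures, so an
   alcohol/aldehyde pair differing only in H counts as balanced.  The check
   is skipped (never fired) when a missing structure, wildcard atom or
   symbolic coefficient makes element counts undefined.
2. **Glycan participants**, detected by the `G` identifier prefix (an
   id-namespace property of glycan databases), with an override list for
   false positives.
3. **Missing or shallow EC labels.**  Since the classifier predicts
   three-level labels, labels with fewer than `require_ec_level = 3`
   defined components are unusable for training and are reported here.
4. **Compounds declared without structure records** (empty or `-` entries
   in the compound table).  A compound id that is missing from the table
   altogether is a data-integrity *error*, not a category: silently
   treating a typo as "no structure" would corrupt corpus statistics.
5. **Wildcard/R-group atoms and polymer notation** (symbolic coefficients
   such as `n` or `(n+1)`).
6. **Zero difference fingerprints** at the configured `max_len`.

The order is declared in the report header; categories overlap and a
different order would shift counts between categories (not membership of
the kept set).  Re-running the filter on its own kept set excludes nothing
new, except category 6 at a smaller `max_len`.

Training EC labels deeper than three components are truncated on ingest
(with a message); labels are never padded.

## The classifier and its numerical choices

* Distances are compared on **exact integer squared values**; only
  reported distances take a square root.  There is therefore no
  floating-point ambiguity about which training reactions attain the
  minimum, and assignment is invariant under training-set permutation.
* Among minimum-distance training reactions the most frequent three-level
  EC wins; *reactions* are counted, not distinct labels.  Residual
  frequency ties break to the smallest EC in component-wise numeric order
  (`2.1.9` before `2.1.10` — string order would invert these).  The
  `tie_broken` flag records when this last resort decided.
* `loocv()` scores each reaction against all others and reports accuracy
  at main-class, subclass and sub-subclass level, plus a per-main-class
  breakdown.
* `length_sweep()` re-applies the filter per length (category 6 depends on
  it) and reports both the kept-set accuracies and `acc_overall`, the
  sub-subclass accuracy over *all* input reactions with unassignable ones
  counted as failures.  The kept-set accuracy can rise as reactions drop
  out; `acc_overall` is the honest monotone quantity.
* `distance_binned_accuracy()` uses half-open bins with the last bin
  closed at +Inf.  The default edges `c(0, 10, 20, 50)` emphasise the
  regions below 20 and below 50 where nearest-neighbour assignments are
  most reliable; they are configurable because sensible edges depend on
  the corpus.

The default `max_len = 3` follows the length-selection result for this
class of descriptor: discrimination improves steeply up to three bonds and
then degrades slowly as fragments become too specific, and all shipped
reference distances are computed at length 3.  The full supported range is
0–6 bonds (7 atoms).

## What the synthetic generator emulates — and what it does not

`generate_reaction_set()` builds labelled corpora from transformation
templates: a structural edit (suffix rewriting on a scaffold SMILES) plus
an optional cosubstrate/coproduct pair keeping the equation heavy-atom
balanced by construction.  The six built-in templates span five EC main
classes with *staggered discriminating lengths*:

| template            | EC     | discriminates from length |
|---------------------|--------|---------------------------|
| amine methylation   | 2.1.1  | 1                         |
| decarboxylation     | 4.1.1  | 1                         |
| alcohol oxidation   | 1.1.1  | 2                         |
| ester hydrolysis    | 3.1.1  | 3 (collides with ether at 2) |
| ether hydrolysis    | 3.3.1  | 3 (collides with ester at 2) |
| racemisation        | 5.1.1  | never (zero fingerprint; emitted only on request) |

The default scaffolds are linear alkyl chains of 3–7 carbons: their local
neighbourhood at the attachment point is identical, so within-template
difference fingerprints coincide exactly and the inter/intra distance gap
is maximal.  This is deliberate — the generator produces *clean* class
structure so that classifier properties (perfect recovery, monotone
degradation below the discriminating length, filter behaviour) are exactly
assertable at small problem sizes (tests use 4–5 templates × 2–5
reactions, ≤ 60 compounds; the brute-force fragment oracle runs on 200
random graphs of ≤ 10 heavy atoms).

What passing these tests does **not** show: real reaction corpora have
heterogeneous molecule sizes, overlapping edit signatures across EC
classes, proton/water bookkeeping errors, multiple labels per reaction and
heavily skewed class frequencies.  Accuracies close to 1 on the synthetic
sets say the machinery is correct, not that real-corpus accuracy will be
comparable; corpus-scale accuracy depends on corpus curation and is out of
the package's test surface.

## Degenerate inputs and edge behaviour

* Single-heavy-atom molecules (water, ammonia, methane) fingerprint to one
  length-0 fragment; the empty molecule gives an empty fingerprint.
* Identity reactions, and any atom-balanced aromaticity-preserving
  rearrangement invisible at the configured length, give empty difference
  fingerprints and are filtered rather than classified.
* Queries citing compounds absent from the compound table are errors
  naming the compound; records that fail structure conversion are errors
  naming the record.
* `length_sweep()` rows whose kept set shrinks below two reactions report
  `NA` accuracies and `acc_overall = 0` rather than failing.

## Known limitations

* Predictions stop at the sub-subclass; serial numbers (fourth EC
  component) require substrate-identity reasoning beyond a bond-change
  descriptor.
* The descriptor cannot separate transformations whose bond-change
  patterns coincide within `max_len` bonds — e.g. transfer versus
  hydrolysis of the same group when the local context is identical, or
  inter- versus intra-molecular variants of the same transfer.  These are
  intrinsic confusion modes of difference fingerprints, visible in the
  ester/ether collision of the synthetic templates.
* Whole-equation fingerprints make the method sensitive to cofactor
  choice: the same chemistry with a different donor sits at a non-zero
  distance.
* No confidence calibration is attempted; the minimum distance is reported
  and distance-binned accuracy gives an empirical reliability curve, but
  no probability.
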