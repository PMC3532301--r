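# rdfec — EC number assignment with reaction difference fingerprints

Many enzymatic reactions found in metabolic pathways have no official
Enzyme Commission (EC) number, because formal assignment requires published
enzyme characterisation.  `rdfec` assigns a provisional three-level EC
number (main class, subclass, sub-subclass — e.g. `2.1.1`, a
methyltransferase) to a reaction using nothing but the chemical structures
of its substrates and products.  It is aimed at people curating reaction
databases or reconstructing metabolic networks who need a reproducible,
fully automatic first-pass classification.

## The method

Every molecule is fingerprinted by counting its **linear fragments**: simple
paths of 0–6 bonds in the hydrogen-suppressed molecular graph, spelled as
alternating atom and bond symbols (`C-C=O`, `c:c:c`) and canonicalised as
the lexicographic minimum of the two reading directions.  The molecular
fingerprint MFP is the sparse count vector over these fragments.

A reaction with stoichiometric coefficients *c* has the **reaction
difference fingerprint**

    RFP  =  Σ_reactants c_i · MFP_i  −  Σ_products c_j · MFP_j ,

a sparse signed-integer vector that encodes the bond-change pattern of the
transformation and cancels everything the reaction leaves untouched.  Two
reactions are compared by the **Euclidean distance** between their
difference fingerprints; a query inherits the three-level EC number of its
nearest labelled training reaction, with a majority vote among training
reactions tied at the minimum distance (residual ties break to the
numerically smallest EC, so results never depend on input order).

Around this core the package provides

* the six-case dataset exclusion filter used to curate training corpora
  (unbalanced equations, glycans, missing EC labels, missing structures,
  R-group/polymer records, zero difference fingerprints),
* leave-one-out cross-validation with per-level and per-main-class
  accuracies, a fingerprint-length sweep, and distance-binned accuracy
  reports,
* a seeded synthetic reaction-set generator built from transformation
  templates (methylation, ester/ether hydrolysis, oxidation,
  decarboxylation, racemisation), so the whole pipeline is testable
  without any database download,
* a command-line interface (`exec/rdfec`) over TSV compound/reaction
  tables.

Structure input (SMILES or MDL mol/SDF) is normalised through Open Babel
via ChemmineOB: hydrogens suppressed, aromaticity perceived, stereo
discarded — a racemisation therefore has a zero difference fingerprint, and
is rightly unclassifiable by this descriptor.

## Worked example

A difference fingerprint by hand: urea-1-carboxylate hydrolysis
(`C01010 + C00001 <=> 2 C00011 + 2 C00014`, i.e. urea-1-carboxylate + water
→ 2 CO₂ + 2 NH₃) at fragment length 1:

```r
library(rdfec)
cmp <- read_compound_table(system.file("extdata", "worked_compounds.tsv", package = "rdfec"))
reaction_difference_fingerprint("C01010 + C00001 <=> 2 C00011 + 2 C00014", cmp, max_len = 1)
#> <reaction difference fingerprint> max_len=1 count_mode=path
#> C-N C-O C=O
#>   3   1  -2
```

Three C–N bonds and one C–O single bond are consumed, two C=O double bonds
are formed (beyond the two already present); the length-0 (single-atom)
entries cancel exactly because the equation is elementally balanced.

Classification on a synthetic benchmark:

```r
set <- generate_reaction_set(n_per_template = 4, seed = 42)
fit <- rdf_knn(set$reactions, set$compounds, max_len = 3)
fit
#> Nearest-neighbour EC assignment model (reaction difference fingerprints)
#>   training reactions: 20  max_len: 3  count_mode: path
#>   main classes:  EC1:4  EC2:4  EC3:8  EC4:4
loocv(fit)
#> Leave-one-out cross-validation (20 reactions, max_len=3)
#>   accuracy: main 1.000  subclass 1.000  sub-subclass 1.000
```

With well-separated transformation templates every reaction's nearest
neighbour shares its template, so all levels reach accuracy 1.  Shortening
the fingerprint below the templates' discriminating path length degrades
the sweep monotonically (`acc_overall` counts reactions rendered invisible
at a given length as failures):

```r
length_sweep(set$reactions, set$compounds, 1:3)
#>   max_len n_input n_kept acc_main acc_subclass acc_subsubclass acc_overall
#> 1       1      20      8        1          1.0             1.0         0.4
#> 2       2      20     20        1          0.6             0.6         0.6
#> 3       3      20     20        1          1.0             1.0         1.0
```

At length 2 the ester- and ether-hydrolysis templates have identical
difference fingerprints (`{C-O-C: +1}`) and misclassify each other; at
length 1 they (and the oxidations) are invisible entirely.

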