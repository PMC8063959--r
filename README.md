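# glycoscan

Detection, classification and removal of sugar moieties in molecular
collections, with dataset-level glycosylation statistics.

Natural products are frequently glycosides: an aglycone core decorated with
circular (furanose/pyranose/heptose ring) or linear (open-chain, 4–7
carbon) sugar units, usually attached through O-glycosidic bonds. For
scaffold-centric analyses these repetitive decorations obscure the core
chemistry, so one wants to find them, characterise them and strip the
terminal ones. glycoscan implements this for SMILES/SDF collections, for
anyone profiling glycosylation in natural-product or screening libraries.

At its centre is the exocyclic oxygen ratio of a candidate sugar ring,

    r_exo = n_exo / n_inc

the number of oxygen atoms bonded directly to ring atoms divided by the
ring heavy-atom count. Rings of size 5–7 with one ring oxygen, no
ring-internal unsaturation and `r_exo >= 0.5` (default) are accepted as
circular sugars, subject to switchable spiro/keto/isolated-cycle/glycosidic
filters. Linear sugars are oxygenated acyclic carbon chains of 4–7 carbons
(non-acidic, outside rings by default). A moiety is *terminal* if removing
it does not split the remainder into two or more surviving fragments
(preservation threshold 5 heavy atoms); terminal moieties are removed
iteratively to yield the aglycone. Per-molecule profiles aggregate into the
full statistics taxonomy (moiety counts, ring classes, terminal/non-terminal
splits, ratio histograms).

Also included: stereoisomer grouping on stereo-erased canonical SMILES,
substructure-frequency analysis of curated moiety libraries, MaxMin
diversity picking and cross-set exclusion for collection curation, and a
synthetic glycoside generator with ground truth used throughout the tests.
Molecular I/O runs on OpenBabel (ChemmineOB/ChemmineR); graph algorithms on
igraph.

## Worked example

```r
library(glycoscan)

mols <- read_collection(system.file("extdata", "example_collection.smi",
                                    package = "glycoscan"), "smiles")
res <- glyco_analysis(mols)
summary(res)
#> 10 molecules, 6 (60.00%) with sugar moieties
#>   circular: 5 molecules, linear: 1, both: 0
#>   consists only of sugars: 3
#>   total moieties: 8
```

Six of the ten demo molecules carry sugars; maltose, fructose and the
open-chain deoxyhexose decompose entirely into sugar units ("consists only
of sugars"). Deglycosylation exposes aglycones and exports the removed
moieties:

```r
r <- remove_sugars(mols[[1]])            # phenyl glucoside
as_smiles(r$aglycone)
#> [1] "c1ccccc1"
as_smiles(extract_moieties(r)[[1]])      # the pyranose ring + its 4 oxygens
#> [1] "OC1COC(C(C1O)O)O"

p <- profile_molecule(mols[[10]])        # a doubly bridged diglycoside
p$has_only_nonterminal_circular; p$n_circular
#> [1] TRUE
#> [1] 2
```

The benzene aglycone is what remains after the glucose ring leaves with its
exocyclic oxygens (including the glycosidic bridge oxygen); the bridged
diglycoside keeps both sugars because removing either would cut the
molecule in two.

A thin command-line front end over the same functions lives at
`inst/cli/glycoscan.R` (`profile`, `synth`, `curate` subcommands).

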