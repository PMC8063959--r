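---
title: "Sugar-moiety perception and removal: methods and design notes"
author: "glycoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sugar-moiety perception and removal: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoscan)
```

## The problem

Many natural products are glycosides: a non-sugar core (the aglycone)
decorated with one or more sugar units, usually attached through an
O-glycosidic bond. For structure-centric analyses — scaffold statistics,
dereplication, comparing natural-product collections with synthetic
catalogues — these repetitive sugar decorations are noise, and one wants to
(1) detect them reliably, (2) classify them (circular vs. open-chain,
terminal vs. non-terminal, ring size), and (3) remove the terminal ones to
expose the aglycone. glycoscan implements this pipeline for collections
supplied as SMILES or SDF files, together with the dataset-level statistics
taxonomy, a curated-library substructure analysis, collection-curation
utilities, and a synthetic-glycoside generator that provides ground truth
for validation.

All molecular I/O and canonicalization is delegated to OpenBabel (via
ChemmineOB/ChemmineR); the detection, classification and removal logic
operates on a heavy-atom graph (element symbols, bond orders) and uses
igraph for connectivity, ring perception, and subgraph matching.

## Circular sugar detection

A circular sugar candidate is a ring of 5, 6 or 7 heavy atoms (furanose,
pyranose, heptose class respectively) with exactly one ring oxygen, all
other ring atoms carbon, and no ring-internal bond of order greater than
one. The last condition is what excludes ascorbic acid's unsaturated
lactone ring from candidacy.

Candidates are filtered on the *exocyclic oxygen ratio*

$$ r_{exo} = \frac{n_{exo}}{n_{inc}}, $$

where \(n_{exo}\) counts oxygen atoms bonded directly to ring atoms (the
ring oxygen never counts; each oxygen atom counts once even when multiply
bonded) and \(n_{inc}\) is the ring heavy-atom count. A candidate is
accepted when \(r_{exo} \ge t\); the default threshold \(t = 0.5\) means a
pyranose or furanose needs at least three attached oxygens. The comparison
is deliberately inclusive: 2,6-dideoxy pyranoses — the digitoxose-type
sugars of cardiac glycosides — carry exactly three oxygens
(\(r_{exo} = 0.5\)) and must be detected.

The ratio is a rational number bounded below 2 (each ring carbon can bear
at most two oxygens), and its value pins the ring class in several
intervals: no furanose can fall in \([0.5, 0.6)\) (3/5 = 0.6 already),
\([0.3, 0.4)\) contains only pyranoses (2/6), and \([0.7, 0.8)\) only
heptoses (5/7). The test suite verifies these statements by exhaustively
enumerating all decorated rings of sizes 5–7 with 0–2 hydroxyls per carbon
(1053 structures).

Further default filters, each separately switchable:

| filter | default | option |
|---|---|---|
| ratio threshold \(t\) | 0.5 | `ratio_threshold` |
| isolated cycle (no shared ring bond) | required | `require_isolated_cycle` |
| spiro rings (one shared atom) | rejected | `allow_spiro` |
| ring keto group (exocyclic C=O on a ring carbon) | rejected | `allow_keto` |
| O-glycosidic bond (ring-C–O–X bridge) | not required | `require_glycosidic_bond` |

A keto oxygen still counts toward \(n_{exo}\) when the keto filter is
disabled. Accepted rings are made mutually atom-disjoint; on overlap the
candidate with the higher ratio wins, ties broken by lowest atom index, so
results are order-independent.

Ring perception uses relevant smallest rings: for every bond on a cycle,
the smallest cycle through that bond (breadth-first search with the bond
removed), deduplicated. Sugar rings are chordless, so this recovers them
exactly; a brute-force enumeration of all simple cycles serves as an
independent oracle in the tests.

## Linear sugar detection

This toolkit follows a structural-pattern definition of an open-chain
sugar: a simple path of *eligible* carbons — no triple bonds, no
carbon–carbon double bonds, outside rings unless `allow_in_rings` — of 4 to
7 carbons (tetrose/pentose/hexose/heptose) in which at least
\(\mathrm{length} - 2\) carbons bear an oxygen substituent (hydroxyl,
carbonyl, ester or glycosidic oxygen all count). The two-position deoxy
tolerance is pinned by open-chain 2-deoxy sugars and by phosphorylated,
thio-substituted ketose derivatives, both of which must be detected as one
moiety. Since no published pattern list defines the exact tolerance bounds,
this choice is a documented design decision of the package rather than a
reproduction of a reference pattern set.

Acidity: a candidate containing a carboxyl carbon (a carbon with a
double-bonded oxygen plus a terminal single-bonded oxygen — connectivity
only, so the deprotonated form is covered too) marks the entire contiguous
eligible-carbon stretch as acidic, and the stretch is skipped unless
`allow_acidic`. Rejecting the whole stretch, not just paths through the
carboxyl carbon, is required for open-chain sugar acids to yield zero
moieties: otherwise a shorter window of the same chain would sneak through.
Phosphate and sulfate esters do not disqualify a chain.

Chains never overlap an accepted circular sugar (ring atoms plus its
exocyclic oxygens), maximal chains absorb contained ones, and overlapping
chains resolve to the longest (ties: lowest atom index), making the
accepted set disjoint and deterministic. With `allow_in_rings` the
path may run inside rings, which is how pseudosugars (carbocyclic polyols
such as inositol) and polyol stretches of macrolides become detectable.

## Terminality and removal

A moiety is *terminal* when excising its atoms does not split the remaining
structure into two or more fragments that each reach the preservation
threshold (5 heavy atoms by default); smaller fragments — a stranded
CH2OH, a short side chain — are discarded and tallied rather than counted
as aglycone parts.

Removal iterates: detect all moieties once on the intact molecule, then
repeatedly remove every currently-terminal moiety and re-evaluate
terminality of the remainder until nothing terminal is left. Detection is
deliberately *not* re-run between rounds: peeling a sugar chain takes the
bridging oxygen with the outer sugar, which lowers the inner ring's
\(n_{exo}\); re-detection would then strand chains of ratio-marginal
sugars (the digitoxose trisaccharide of cardiac glycosides would stop
peeling after one unit). Detect-once semantics makes such chains fully
removable, which is the behaviour the worked examples require.

Two further conventions:

* The glycosidic bridge oxygen leaves with the sugar (it is one of the
  ring's exocyclic oxygens); the aglycone's attachment atom is
  hydrogen-saturated implicitly. Where two sugars share a bridge oxygen the
  first moiety in deterministic order claims it, so atom conservation
  (input = aglycone + removed + discarded, checked on every run) holds
  exactly.
* A removal that would split off only sub-threshold fragments still counts
  as terminal; this is what makes a sugar carrying a small side chain
  removable.

Non-terminal moieties are classified by a second pass: after the
terminal-only fixpoint, a remove-all pass on the aglycone excises and
labels everything that remains detectable. The per-molecule profile
(`has_only_terminal_circular`, `has_nonterminal_linear`, counts, the
sugar-only/monomer/polymer flags, …) is assembled from both passes, and all
partition identities of the statistics taxonomy hold exactly by
construction — the aggregator re-asserts them on every call.

One caveat inherited from the statistics taxonomy itself: published
molecule-level tables of this kind contain an internal inconsistency in one
non-terminal count; the profiler always trusts the partition identity
(only-terminal + only-non-terminal + both = has-moiety-type).

## Histograms

The moiety-count histogram bins molecules by their total number of detected
moieties (with circular-only and linear-only companions). The ratio
histogram enumerates candidates with the threshold lowered to 0, bins
\(r_{exo}\) into half-open intervals \([x, x + 0.1)\) for \(x = 0, \dots,
1.9\), and splits each bin at the configured threshold; the passing counts
sum to the accepted circular-moiety count. Because \(r_{exo}\) is rational,
exact tenths (3/6, 2/5…) sit on bin edges; the binning adds a nudge of
1e-9 before flooring so such values land in the interval they open.

## Library analysis and substructure matching

A curated moiety library is grouped by stereoisomers using stereo-erased
canonical SMILES (stereo descriptors are stripped textually and the result
re-canonicalized with OpenBabel), concatenating member identifiers.
Detectability of each representative is decided by running detection on the
standalone structure under a named settings configuration — lowering the
ratio threshold can only grow the detectable set, a monotonicity the tests
assert.

Substructure frequencies are presence-per-molecule counts (a molecule with
three embeddings counts once) under monomorphism matching on the heavy-atom
graph: pattern atoms map to distinct target atoms of the same element,
pattern bonds to target bonds of the same order, attachment positions
unconstrained, stereochemistry ignored. Matching is done with igraph's VF2;
an independent backtracking matcher in the test suite checks agreement.
Because both sides are kekulized by the same toolkit, aromatic bond-order
assignment is consistent between pattern and target.

## Curation utilities

MaxMin diversity picking starts from a seeded random molecule and greedily
adds the molecule whose minimum distance to the selected set is maximal.
The distance backend is 1 minus the atom-pair Tanimoto similarity
(ChemmineR); since only the algorithm, not the fingerprint, is canonical,
the backend is injectable (`dist_fun`) and the default is fixed for
reproducibility. Ties break on the lexicographically smallest stereo-erased
canonical SMILES, so a seed fully determines the pick. Cross-set exclusion
removes every molecule whose stereo-erased key occurs in any reference set,
so unannotated stereoisomers of reference structures are caught. The
stereoisomer-grouping statistics report records-per-group averages
separately for sugar-containing and sugar-free representatives.

## The synthetic generator

`generate_glycosides()` emulates the glycosylation structure of
natural-product collections with known ground truth: sugar-free scaffold
cores (aromatic, aliphatic, fused-ring and steroid-like templates, each
validated sugar-free by the test suite and decorated with random alkyl caps
for diversity) carry O-linked sugar units as terminal chains (outermost
unit removable first), as bridges between two scaffolds (non-terminal by
construction), or both. Defaults follow the reported shape of large NP
collections: 12% of molecules glycosylated, a halving moiety-count
distribution (half of the glycosides carry one sugar, the vast majority
five or fewer), a 96:4 circular:linear mix, about 20% of glycosides
bridging, and ring classes dominated by pyranoses. Decoy classes
(pseudosugar, keto ring, spiro ring, acidic chain, low-oxygen ring) are
constructed so that default settings reject them and exactly one
non-default option makes each detectable — the option-specificity the
tests assert. Stereo duplication emits anomer pairs for grouping tests.

Ground truth records planted counts, classes and terminality labels plus
the expected profile booleans per molecule (atom-level sets are not
recorded: atom numbering after parsing is toolkit-dependent, whereas the
counts and labels are invariant). What the generator does *not* emulate:
realistic aglycone chemotypes, C- and N-glycosides, sugar rings with
heteroatom substitution of the ring oxygen, tautomerism, or counterion
records — so passing recovery tests demonstrate correctness of the
perception/removal logic on well-formed O-glycosides, not robustness to
every structure a real database contains.

## Numerical and determinism choices

* All randomness (generator, MaxMin start) runs under explicit seeds and
  restores the caller's RNG state.
* Candidate and moiety sets are sorted deterministically (ratio, then
  lowest atom index), so output is invariant under input atom permutation —
  a property the tests check with random permutations.
* Stereo descriptors survive parsing and canonical keys, but molecules
  derived by graph editing (aglycones, extracted moieties) are emitted
  without stereo: removal does not attempt to preserve or remap
  stereocentres whose substituents changed.
* Multi-fragment inputs are processed as-is; nothing selects the largest
  component silently.

## Validation problem sizes

The test suite exercises: the 1053-structure exhaustive ring enumeration;
synthetic batches of 30–120 molecules for partition identities and
properties; a 500-molecule decoy-free batch for exact ground-truth
recovery; 5 x 6–8 molecule decoy batches for option specificity; and
brute-force oracles on all fixtures up to ~30 heavy atoms.
`scripts/acceptance.R` re-runs the same computations from scratch at the
same sizes and writes the resulting numbers as JSON.

## Known limitations

* Sugar rings with nitrogen or sulfur replacing the ring oxygen are out of
  scope, as are anomeric configuration assignment and monosaccharide
  naming.
* The linear-sugar pattern is a documented approximation (deoxy tolerance
  of two, component-level acidity rejection); reference implementations
  with an explicit pattern list may classify borderline chains differently.
* Extracted moieties comprise the ring/chain plus directly attached
  oxygens; small carbon side chains (e.g. the exocyclic CH2OH of a
  hexopyranose) are tallied as discarded fragments rather than kept with
  the exported sugar.
* Stereochemistry is not tracked through graph editing (see above).
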