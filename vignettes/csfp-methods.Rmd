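---
title: "The core-substituent fingerprint: design, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The core-substituent fingerprint: design, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The idea

Most 2D fingerprints in use today — MACCS structural keys, ECFP-style
circular environments — encode far more structural features per molecule than
a medicinal chemist would name when describing it. The core-substituent
fingerprint (CSFP) implemented by `csfpr` takes the opposite, structurally
minimalist position: a compound is represented only by the ring fragments of
its core and by its substituents (R-groups). The result is a keyed 1000-bit
fingerprint — every bit position corresponds 1:1 to one recorded fragment,
with no hashing and no bit collisions — whose typical feature count per
molecule is an order of magnitude below MACCS or ECFP4, yet which supports
competitive similarity searching and machine learning.

The 1000 positions are balanced by construction: 250 single rings, 250 fused
ring systems, 500 substituents, each category frequency-ranked over a
compound collection. Three stages produce the fragment catalogs.

**Analogue series and cores.** Compounds are fragmented systematically at
all combinations of 1–5 exocyclic bonds (acyclic single bonds between heavy
atoms; bonds to hydrogen are never cut), subject to a 2:1 core-to-substituent
heavy-atom ratio — the compound–core relationship (CCR) scheme. Because each
cuttable bond is a bridge, cutting k bonds always yields k+1 components; a
combination is admitted when one ring-containing component (the core) touches
every cut and each other component touches exactly one. Cores are generalized
by hydrogen-capping the substitution sites, and compounds sharing a
generalized core form an analogue series. Only series cores (shared by at
least two compounds) feed the ring catalogs, which keeps the recorded rings
generalizable rather than idiosyncratic.

**Ring fragments.** Deleting all acyclic bonds and atoms of a core leaves
its ring systems: components with two or more smallest rings are fused
systems (rings sharing a bond; rings sharing only an atom — spiro — are
treated as fused by default, controllable via `merge_spiro`), everything else
is a single ring. Fused systems are additionally decomposed into their
smallest rings (SSSR, computed as a Horton-style minimum cycle basis).
Critically, a ring cut out of a fused system *keeps the aromaticity and
hybridization states its atoms had in the fused context*. Half of
naphthalene is not cyclohexadiene: it is an aromatic six-ring "model
fragment" that cannot exist as an isolated molecule but re-matches inside any
larger aromatic system. `csfpr` represents every fragment as a constraint
graph (element, aromaticity, hybridization per atom; bond orders and
aromatic bonds), which is exactly what makes model fragments expressible. A
decomposition ring is flagged `is_model` when any fusion atom is aromatic or
sp2 — the operational rule for "the ring's electronic state depends on
its fused environment"; decalin's rings, with sp3 fusion atoms, are ordinary
cyclohexanes and are not flagged.

**Substituents.** The substituent-side products of the systematic cuts are
collected with one attachment point each, represented by a wildcard atom.
Frequencies are counted per occurrence; a pluggable retrosynthetic cutter
(`retro_cuts()`, a deliberately small RECAP/BRICS-flavored rule set) can
contribute a second source, merged by canonical pattern with frequencies
summed. Two exclusions apply: hydrogen is never a substituent (only
heavy-atom bonds are cut), and the unsubstituted benzene ring is excluded so
that benzene is recorded only as a ring fragment.

**Assembly and substructure closure.** The top 250/250/500 fragments per
category (ties broken lexicographically by canonical pattern, for
determinism) are assigned bit positions in category order. At assembly time
the library's substructure-closure map is computed by pairwise matching:
each fused ring records which library single rings it contains, and each
substituent records which library substituents it contains. When a fragment
matches a molecule, its closure bits are set too — a substituent containing
two recorded substituents sets three bits. Closure is a property of the
recorded library, computed once, not per molecule.

## Matching semantics

Fragments are matched as non-induced subgraph monomorphisms (igraph's LAD
solver on a bipartite atom/bond-node encoding, with per-node compatibility
domains). Ring-fragment atoms constrain element, aromaticity and
hybridization; substituent atoms constrain element, aromaticity and *exact
heavy-atom degree* (counting the attachment), so a methyl pattern matches
terminal methyls and not ring CH2 carbons. The attachment wildcard maps to
any heavy atom — including ring atoms, which maximizes recall of
R-group-like features — through a single non-aromatic bond.

Two consequences of these semantics are worth stating. First, closure is
compositional: if fragment Q is recorded as contained in fragment F, any
embedding of F into a molecule yields an embedding of Q, so closure bits are
a subset of what direct matching would find anyway; the closure map still
matters as an explicit, auditable record (and provenance distinguishes
`direct` from `closure` bits). Second, the degree constraints mean a
substituent matches exactly as an R-group, which is the chemically intended
reading.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_cuts` | 5 | maximum simultaneous bond cuts (CCR) |
| `ratio` | 2.0 | minimum core : substituent heavy-atom ratio |
| `n_single`, `n_fused`, `n_subs` | 250/250/500 | library quotas (1000 bits) |
| `merge_spiro` | TRUE | treat spiro unions as fused systems |
| `fused_to_fused` | FALSE | also close fused rings over contained fused rings |
| `k` | 1/5/10 | nearest neighbors in similarity search |
| `n_trials` | 20 | independent benchmark trials |
| `potency_cutoff_nM` | 10000 | activity-curation potency cutoff (10 µM) |
| `mw_cutoff_Da` | 1000 | activity-curation weight cutoff |

The quotas, cut limits, ratio, potency and weight cutoffs, trial counts and
grids are the published protocol's constants. Catalogs smaller than a quota
shrink the library with a warning rather than failing; the realized sizes
are recorded in the library metadata.

## Benchmark protocol

Similarity search follows the k-NN scheme: per trial, 100 actives are
sampled, 10 become references and 90 hits are spiked into a background
database; every database compound is scored by its maximum (k = 1) or mean
top-k Tanimoto similarity to the references, and the trial is scored as the
AUC ROC (Mann–Whitney formulation, ties credited 1/2) of hits versus
background. The protocol-scale background is 100,000 compounds; the packaged
fixtures use 1,000.

Classification uses random forest and a Tanimoto-kernel SVM with balanced
class weights. Per trial, half the actives train and half validate;
negatives are sampled at 3x the positives, separately for training and
validation; hyperparameters come from stratified 10-fold internal
cross-validation maximizing mean balanced accuracy over the published grids
(RF: trees in 25/50/100/200/400 and minimum node size 2/3/5/10 — the node
size is the R analog of scikit-learn's minimum-samples-to-split — giving 20
candidates; SVM: C in 0.1/1/10/50/100/200/1000, 7 candidates). Metrics are
BA, MCC, F1, precision and recall from the confusion counts, with MCC
defined as 0 when a denominator factor vanishes. Paired per-class
comparisons use the two-sided Wilcoxon signed-rank test.

Per-trial seeds are derived from the master seed by trial index and recorded
in the outputs, so every run is reproducible bit for bit.

## The synthetic fixture collection

The package ships no third-party data; everything is generated. The fixture
generator emulates the structure that matters to this method: analogue
series sharing a ring-containing core (a fused ring system linked to a
single ring) and varying R-groups at one or two substitution sites. Ring
skeletons (3- to 8-membered saturated rings, aromatic five- and six-rings,
ten fused skeleton families) are enumerated with systematic heteroatom
placements and deduplicated at the fragment-pattern level, giving pools of
roughly 260 single-ring and 430 fused-ring patterns; R-groups are ~630
element-word chains with halogen caps and common functional groups. R-group
draws respect the 2:1 ratio budget of their core so that every designed
series core is recoverable by the fragmentation stage. Default study sizes:
300 series of 3 compounds for library construction; a 100-member series as
the benchmark activity class; 1,000 singleton decoys (excluding the class's
ring patterns, mirroring protocols that exclude the activity class from the
background) as background; RF/SVM benchmark checks run 3–10 trials, the
search benchmark the full 20.

What the fixtures do *not* emulate: real medicinal-chemistry property
distributions (logP, molecular weight spectra), stereochemistry, charged
species beyond simple neutralization, tautomerism, and the scale of ChEMBL
(hundreds of thousands of compounds, 100k-compound backgrounds). Passing
tests therefore demonstrate correctness of the algorithms and the qualitative
behavior of the fingerprint (low feature counts, effective analogue
retrieval), not performance numbers transferable to real screening decks.

## Numerical and design choices

- **Canonicalization** is delegated to Open Babel (via ChemmineOB):
  canonical SMILES, largest-fragment salt stripping, +1/-1 charge
  neutralization. Aromaticity comes from Open Babel's MOL2 typing; kekulé
  orders and formal charges from its SDF output.
- **Fragment identity** is a canonical serialization of the constraint
  graph (BLISS canonical labeling with attribute-derived vertex colors), so
  identical chemistry always maps to the same bit regardless of input atom
  order. Tie-breaks in every ranking are lexicographic on this pattern.
- **SSSR** uses per-edge shortest cycles accepted greedily under GF(2)
  independence; candidate order is (length, canonical bond set), making the
  basis deterministic.
- **Exocyclic double bonds** (e.g. a ring carbonyl oxygen) are not part of
  ring fragments: ring systems are defined by deleting acyclic bonds, and
  the C=O bond is acyclic. The oxygen travels with the substituent side.
- **"Unique cores"** can be counted per analogue series or per
  compound-core pair; `build_analogue_series()` records all cores per
  compound by default (`per_compound = "all"`), with `"largest"` as the
  alternative.
- **Curation direction**: the potency filter keeps interactions at or below
  10 µM and discards weaker ones — the conventional reading for assembling
  active compound sets — and is configurable (`potency_direction`).
  Duplicates per (compound, target) collapse to the median potency.
- **Degenerate inputs**: molecules matching no fragment give the all-zero
  vector, and the Tanimoto coefficient of two zero vectors is defined as 0;
  both situations are permitted rather than errors because a keyed library
  cannot cover all chemistry.
- **Closure scope**: fused→single and substituent→substituent, matching the
  published design; fused→fused closure exists behind a flag
  (`fused_to_fused`) and is off by default.
- **Comparators**: MACCS (keys 1–166) and ECFP4 (4096 bits folded by OR to
  1024) are produced by Open Babel through ChemmineR — the cheminformatics
  toolkit of this package's ecosystem — with the same molecule
  standardization as CSFP.

## Problem sizes used in validation

The shipped validation suites run at desk scale, chosen to exercise every
code path on a single CPU: the library-constants check builds the default
1000-bit library from the 900-compound fixture collection; the brute-force
oracle comparison covers 200 molecules against a 30-fragment toy library;
the feature-count comparison covers 1,000 molecules; the benchmark sanity
check runs 20 search trials against 1,000 decoys and 3–10 classification
trials. The acceptance script (`scripts/acceptance.R`) recomputes all of
these from scratch under a caller-supplied seed.

## Known limitations

- Formal-charge and isotope constraints are not part of fragment patterns;
  after neutralization this rarely matters, but zwitterions recorded in
  rings will match their neutral-pattern analogs.
- Stereochemistry is ignored throughout (2D fingerprint by design).
- Bridged polycycles are handled by the SSSR basis; envelope macrocycle
  rings are not emitted as separate fragments.
- Intermediate pairwise-fused subsystems of ≥3-ring systems are not
  recorded separately: a fused system contributes itself plus its single
  rings. This follows the published decomposition figures; recording
  intermediates would be a catalog-side extension.
- Open Babel's canonical SMILES is the identity for cores; a different
  toolkit's canonicalization would re-derive the same series but with
  different string keys.
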