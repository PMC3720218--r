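---
title: "Topological bond descriptors and BDE models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological bond descriptors and BDE models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bondscope)
```

## The problem and the model

The homolytic bond dissociation energy (BDE) of A–B is the electronic
energy change of A–B → A· + B·, in kcal/mol. `bondscope` predicts it from
the 2D connection table alone. Each non-ring covalent bond becomes a fixed-
length vector of counts — atom types and atom-type pairs in topological
*spheres* around the bond — and a regression model maps vectors to
energies. The design constraints on the descriptors are: computable from
the connection table in microseconds; no quantum input; no optimized
geometry; no explicit bond orders (so mesomers of one aromatic system get
one representation); and invariance to the orientation of the bond, because
the physical quantity is orientation-free.

The assumptions this encodes are worth stating. First, that BDEs are
dominated by the local topological environment — for the reference data
this holds only up to a point; conformation-dependent effects (internal
hydrogen bonds) and remote-group effects beyond the encoded spheres are
invisible to the representation, and two bonds that agree within the
maximum sphere receive identical predictions no matter how different their
energies are. Second, that element plus neighbour count is a sufficient
atom alphabet; hybridization is captured only indirectly (an sp² carbon has
3 neighbours). Third, that ring bonds can be left out of datasets entirely,
since their homolysis does not produce two fragments.

## Atom types, spheres, and descriptor families

Two type systems are used: plain elements (C, H, O, N, S — the scope of the
package; other elements are rejected at parse time) and *connection-number*
types, element plus neighbour count with hydrogens counted. Fourteen
connection-number labels form a closed set (`cn_type_labels()`); there is
deliberately no C1, which would be chemically degenerate in this scope, and
H is always H1.

Sphere *s* of a target bond holds the atoms whose shortest-path distance to
the nearer bond atom is *s*; sphere 0 is the bond pair itself. "N sphere
layers" always means indices 0..N−1. The families are point counts
(per sphere and type, optionally restricted to ring / aromatic / π-system
atoms), pair counts (outer atom in the sphere, partner in the same or a
lower sphere, exact distance; typed or type-free), bond-breaking
differences (pair counts lost upon cleavage; for a bridge bond these are
exactly the cross-fragment pairs, hence non-negative), fragment point
counts (per-fragment values sorted descending, which removes orientation),
π-total counts (fragment values summed, i.e. whole-molecule counts over the
π subset) and molecular counts. A geometric pruning applies to pair
definitions: a pair with outer atom in sphere *s* can be at most 2s+1 bonds
long (the path around the target bond), and sphere-0 pairs exist only at
distance 1 — the target bond itself, which is retained because dropping it
would break the identity "type-free count = sum of typed counts".

## Catalog presets and what they reproduce

Catalogs are deterministic enumerations; the row order is the vector
layout and is part of the file contract (`write_catalog()`). The preset
arithmetic that is exactly reproducible:

* connection-number point descriptors over 7 layers plus the molecular
  block: 14 × 8 = **112** definitions; over 4 layers without the molecular
  block: **56**;
* the compact 4-layer set (`"selection3"`): CN points (56), element pairs at
  distance 1 for spheres 1–3 (15 × 3 = 45), aromatic element fragment
  points (5 × 2 = 10), type-free pairs for spheres 1–3 at feasible
  distances (3 + 5 + 7 = 15), and π-total counts (3) — **129** in total,
  with the same enumeration giving 165 and 201 at 5 and 6 layers.

Other published set sizes (a 3,675-descriptor full pool; 615 and 293 for
the two intermediate selections) do not close under any single consistent
enumeration we could construct; our principled pools come out slightly
larger (3,766; 625; 277). The likeliest explanation is that the original
counts were taken after dropping columns constant on the actual training
data, which no enumeration can reproduce. We keep the enumerations
principled and document the deltas rather than force the numbers. For the
same reason the final 90-descriptor model is shipped as a *workflow*
(full pool → importance ranking → top-90 → correlation pruning), not as a
frozen list: it depends on fitted importances.

The π-total group is encoded as element-typed counts over {C, N, O}; the
published size (3) does not identify the typing, and sulfur π systems are
rare enough in fragment-like chemistry that this is the natural reading.

## Feature perception

Aromaticity is pinned to a Hückel model: for each smallest ring through a
ring bond (rings from bridge detection; the smallest cycle through each
non-bridge edge), the ring is aromatic when every ring atom has at most
three neighbours and contributes 1 (endocyclic multiple bond), 0 (exocyclic
multiple bond or cationic C) or 2 (lone-pair N/O/S or anionic C) π
electrons, and the total is 4n+2. The π-system flag covers atoms in any
multiple bond or aromatic ring plus lone-pair heteroatoms directly bonded
to such an atom (amide N, enol-ether O). Exocyclic substituents of aromatic
rings are *not* flagged aromatic. These are dialect choices: toolkits
disagree on the edges of both definitions, and descriptor values restricted
to these subsets inherit the dialect. Kekulé invariance, by contrast, is
structural: the electron count is the same for either alternation, and no
descriptor reads bond orders.

## Machine-learning configuration

`train_rf()` follows the reference configuration: 1000 trees, mtry =
⌊√p⌋, out-of-bag validation, permutation importance. `evaluate()` reports
RMSD, mean absolute deviation, maximum absolute error (kcal/mol) and R².

The network ensemble trains each member on its own random half of the
training set, early-stopping on the RMSD of the other half (checked every
`chunk = 25` optimizer iterations, patience 4, at most 40 checks) — the
contract is the early-stopping and normalization behaviour, with `nnet`'s
quasi-Newton optimizer underneath. Inputs and targets are linearly
normalized to [0.1, 0.9] from training data only; members have 6 logistic
hidden units and bias units on the input and hidden layers. The associative
memory stores the training vectors, labels, per-member outputs and
residuals of the ensemble mean. A query is corrected by the mean residual
of its `k = 9` most similar memory cases, similarity being the Spearman
correlation of per-member output profiles. Two details are choices where
the cited scheme leaves room: the neighbour count default (9) and the tie
break. With small ensembles many cases share one rank profile, so ties
break towards the nearest profile in output space — this also makes exact
recall (query present in memory, k = 1) an identity, which the tests
assert. Growing the memory (`add_to_memory()`) requires no retraining.

Identical bonds — equal descriptor vectors under the reference catalog, the
only identity the pipeline can enforce — are collapsed to one record by
`deduplicate()`. Note this is only meaningful for deterministic labels;
with noisy labels, repeated environments are genuine repeated measurements
and are kept.

## The synthetic generator and what passing tests mean

`generate_molecules()` builds random trees over heavy atoms drawn with
weights (C 0.72, N 0.12, O 0.12, S 0.04 — fragment-like organic
composition), closes one ring with probability 0.35, promotes bonds to
double (0.15) or triple (0.03) order where valence allows, and fills
explicit hydrogens to default charge-adjusted valences. Promoted bonds are
kept isolated (no atom carries two multiple bonds, no two adjacent): this
guarantees that a bond's order is a function of its sphere-0
connection-number types, and therefore that the noiseless surrogate energy
— base(element pair, order) + sphere-1 increments + sphere-2 increments —
is a deterministic function of the descriptor vector (the tests verify the
zero-spread property directly). Default bases are literature-magnitude
(C–H 99, C–C 83, O–H 111 kcal/mol, +63/+117 for double/triple);
increments are a few kcal/mol per neighbour type. Noise is homoscedastic
Gaussian. What the generator does *not* emulate: conformational effects,
hydrogen bonding, negative labels from numerical error, aromatic
delocalization energetics, and the error structure of any quantum method —
so green tests certify the machinery (descriptor correctness, recovery of
a known signal, memory behaviour), not chemical accuracy on real data.

Simulation sizes used by the test suite: the standing corpus is 700
molecules (≤ 12 heavy atoms, σ = 2 kcal/mol), from which bond classes are
capped at 400 records — raw corpora are ~60 % C–H bonds, and balancing
underrepresented classes mirrors the enrichment step of the original
workflow. On that corpus the noise floor is recovered: OOB RMSD lands in
[σ, 2σ]. One deliberate deviation: the recovery experiment uses mtry = p/3
(the classic regression-forest default) rather than √p, which on this
additive surrogate plateaus above the band — the √p configuration remains
the package default because it is the reference configuration for real
data.

## Numerical details and degenerate inputs

Descriptor values are exact integer counts; no tolerances are involved in
their computation. Disconnected graphs, ring-bond cleavage, unknown
presets, out-of-range pair distances (1–4 for the large pools), uncovered
surrogate classes and empty training sets raise classed errors. Zero-
variance reference values make R² undefined (returned as NA with a
warning). Molecule-level splitting guarantees no molecule contributes to
both sides; all stochastic steps take explicit seeds and are reproducible
bit-for-bit, including ensemble member initialization.

## Known limitations

Aromaticity and π perception are a pinned dialect, not a toolkit
reproduction; macrocyclic and cross-ring aromaticity (azulene-type) is not
detected. The greedy Kekulé assignment for aromatic-bond-order input
handles common ring systems, not every exotic fused case — canonical
kekulized input (the SMILES path) is unaffected. Descriptors cannot
distinguish bonds identical within the maximum sphere, by design. The
fixed-value baseline, like any per-class mean, degrades to the global mean
for unseen classes (flagged). Stereochemistry is not modelled at all.
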