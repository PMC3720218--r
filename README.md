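# bondscope

Ultra-fast estimation of homolytic bond dissociation energies (BDEs) from
molecular topology alone.

Quantum-chemistry pipelines can label tens of thousands of covalent bonds
with accurate BDEs, but are far too slow for data-mining applications (mass
spectrum interpretation, metabolic soft-spot screening, reactivity triage)
that need on-the-fly energies for millions of bonds. `bondscope` is for
cheminformaticians who want to learn those labels once and then predict in
microseconds: it encodes each bond as a vector of cheap, orientation-free
topological counts and trains standard machine-learning models on
BDE-annotated structure files.

## The descriptors

For a target bond A–B in a molecule with explicit hydrogens, every atom is
assigned to a **sphere**: sphere 0 is the bond itself, sphere *s* holds the
atoms *s* bonds from the nearer bond atom along the shortest path. Two atom
typing systems are used — plain elements (C, H, O, N, S) and
**connection-number types** (element + neighbour count: methane's carbon is
C4, an acetylenic carbon is C2; 14 labels form a closed set). On top of
these, the descriptor families are:

* **point** — count of atoms of a type in a sphere, optionally restricted to
  ring / aromatic / π-system atoms;
* **pair** — count of unordered atom pairs with the outer atom in sphere
  *s*, the partner in the same or a lower sphere, at an exact shortest-path
  distance *d* (typed, or type-free for low dimensionality);
* **bond-breaking difference** — pair counts before cleavage minus
  same-fragment pair counts after (equivalently: cross-fragment pairs);
* **fragment point** — per-fragment counts after homolytic cleavage, the
  two values sorted so the vector never depends on bond orientation;
* **molecular** — whole-molecule counts, identical for every bond.

All counts come from the connection table only: no 3D geometry, no quantum
calculations, and no explicit bond orders, so different Kekulé resolutions
of an aromatic system produce identical vectors.

## Models

* `train_rf()` — a 1000-tree random forest (out-of-bag validation,
  permutation importances) with `select_descriptors()` for importance-based
  selection plus correlation pruning;
* `train_ensemble()` / `asnn_predict()` — an ensemble of single-hidden-layer
  feed-forward networks (6 logistic hidden units, inputs and targets
  normalized to [0.1, 0.9], each member early-stopped on its own held-out
  half) with an associative memory: the ensemble mean is corrected by the
  mean residual of the *k* training cases whose per-member output profiles
  are most rank-correlated with the query's;
* `baseline_fixed_values()` — the per-(element pair, bond order) mean used
  as a fixed-value reference.

A synthetic module (`generate_molecules()`, `surrogate_bde()`,
`make_dataset()`) produces valence-legal CHONS molecules and additive
per-bond surrogate energies with Gaussian noise, so the whole pipeline is
testable without quantum chemistry.

## Worked example

```r
library(bondscope)

g <- example_molecule()            # 14 heavy atoms, target bond 8-9
env <- assign_spheres(g, c(8, 9))
which(env$sphere == 1)
#> [1]  5 10
which(env$sphere == 2)
#> [1]  4  6 11 14
pair_descriptors(env, "element", sphere = 2, distance = 2)[["C.C"]]
#> [1] 4
```

The four counted pairs are 4–6, 4–8, 6–8 and 9–11: the outer atom of a pair
sits in sphere 2, the partner in the same or a lower sphere, two bonds
apart.

A miniature end-to-end run on synthetic data:

```r
ds   <- make_dataset(250, surrogate_params(sigma = 2), seed = 42)
cat3 <- build_catalog("selection3")          # 129 descriptors, 4 sphere layers
recs <- build_records(list(molecules = ds$molecules, labels = ds$bonds), cat3)
bal  <- stratified_sample(recs, per_class = 300, seed = 7)  # balance classes
x    <- bal[descriptor_columns(bal)]
rf   <- train_rf(x, bal$bde, trees = 1000, mtry = floor(ncol(x) / 3), seed = 1)
glance(rf)
#> # A tibble: 1 x 5
#>    rmsd   mad max_error    r2     n
#>   <dbl> <dbl>     <dbl> <dbl> <int>
#> 1  4.21  2.37      46.5 0.958  1601
```

`rmsd`/`mad`/`max_error` are in kcal/mol against the surrogate labels
(generated with 2 kcal/mol Gaussian noise); out-of-bag validation means
each bond is predicted only by trees whose bootstrap never saw it, so the
forest sits about a factor two above the noise floor on 1,601 bonds.

## Command line

A thin wrapper over the same functions lives in `inst/cli/bondscope.R`:

```sh
Rscript inst/cli/bondscope.R simulate --n 100 --sigma 2 --seed 7 --out synth.sdf
Rscript inst/cli/bondscope.R compute --in synth.sdf --preset selection3 --out desc.tsv
Rscript inst/cli/bondscope.R build-dataset --sdf synth.sdf --bde-tag BDE --out ds.tsv
```
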