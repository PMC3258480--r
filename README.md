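# catkit

Enzymes perform their chemistry with a small toolkit: the 20 amino acids
(of which ten — Arg, Asp, Cys, Glu, His, Lys, Ser, Thr, Trp, Tyr — do almost
all of the catalytic work), a handful of metal ions, and small organic
cofactors. `catkit` analyses mechanism-level enzyme corpora — records that
pair chain sequences with curated catalytic/binding residue annotations,
CATH domain assignments, cofactors and EC numbers — and asks three
questions:

1. **Which residues are catalytic, and what do they do?** The *catalytic
   propensity* of residue type *r* in EC class *C* is

   ```
   P(r, C) = [ n_cat(r, C) / n_cat(C) ] / [ n(r, C) / n(C) ]
   ```

   the share of the catalytic toolkit that is type *r*, over the background
   share of *r* in the class's sequences. P = 1 means no enrichment; His
   and Cys are classic high-propensity types. Each annotation also carries
   one or more of seven mechanistic role categories (activation, steric,
   stabilization, proton shuttling, hydrogen-radical shuttling, electron
   shuttling, covalent catalysis), plus hydride shuttling for organic
   cofactors only, giving role profiles per catalytic entity kind.

2. **How many times has each reaction evolved?** For every EC node (a
   fully defined four-level EC number), records are clustered into
   evolutionary families two ways. *Sequence* route (upper bound): exact
   global alignment, an identity/coverage threshold graph, single-linkage
   clustering (connected components — the blastclust criterion), then
   singleton clusters are absorbed into multi-member clusters by
   position-frequency-profile scoring. *Structure* route (lower bound):
   records grouped by their canonical CATH H-level domain-combination
   multiset, refined by a sequence-identity floor so analogous same-fold
   pairs stay apart.

3. **How are enzymes built from domains?** A domain is *catalytic* if it
   furnishes at least one catalytic residue, *binding* if it furnishes
   none but at least three binding residues. The catalytic unit (the
   smallest assembly containing the active site) gets a canonical
   signature (`A*`, `A*B`, `A*A*`, ... — letters are domain identities,
   `*` marks catalytic), the corpus gets a configuration census, and each
   CATH code gets a promiscuity count (distinct EC nodes and classes it
   serves).

Because curated corpora of this kind cannot be redistributed, the package
includes a synthetic generator (`generate_dataset`) that plants known
family structure (controlled within/between-family percent identity),
propensity multipliers, role assignments and domain architectures, so
every estimator can be validated against ground truth.

## Worked example

```r
library(catkit)

# a two-record corpus shipped with the package
toy <- read_dataset(system.file("extdata", "toy", package = "catkit"))
summary(toy)
#> Enzyme dataset summary
#>   records:              2
#>   chains:               3
#>   catalytic residues:   3
#>   ...

# synthetic corpus: 12 EC nodes, His boosted 4x
cfg <- generator_config(n_ec_nodes = 12,
                        propensity_multipliers = c(H = 4), rng_seed = 7)
corpus <- generate_dataset(cfg)
corpus$dataset
#> <enzyme_dataset> 105 records, 105 chains, 333 residue annotations, 141 domains

fc <- families_per_node(corpus$dataset)
summary(fc)
#> EC nodes:            12
#> raw clusters:        35 (mean/node 2.92, singleton nodes 0%)
#> merged clusters:     35 (mean/node 2.92, singleton nodes 0%)
```

The mean/node value is the headline statistic: on this corpus the same
overall chemistry is performed by about three distinct evolutionary
families per EC node. The planted truth is recovered exactly:

```r
est <- setNames(fc$per_node$merged, fc$per_node$node)
recovery_report(est, corpus$truth)
#> Recovery vs planted truth: exact-match rate 1, mean count bias 0 over 12 node(s)

pt <- catalytic_propensity(corpus$dataset)
round(pt$values["H", ], 2)
#>    1    2    3    4    5    6  all
#> 2.26 4.42 3.10 3.59 4.55 3.10 3.54
```

The all-classes His propensity (3.54) sits close to its closed form
`20 * 4 / (19 + 4) = 3.48` — boosting one of 20 uniform types by 4x yields
a propensity below 4 because the boost also inflates the background. The
structural (lower-bound) counts and the architecture census come from:

```r
structural_families_per_node(corpus$dataset)
#> Structural families per EC node (12 nodes)
#>   clusters: 32 (mean 2.67, singleton nodes 17%)

head(configuration_census(corpus$dataset)$census)
#>   pattern n_bio_domains count
#> 1      A*             1    75
#> 2     A*B             2    27
#> 3   A*BCD             4     3
```

`run_pipeline()` chains all stages (optionally writing TSV tables and
`report.json`), and `plot(pt)` draws the propensity balloon chart (blue
circles: propensity >= 1; red: < 1).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates a synthetic corpus under the given seed, runs the complete
pipeline (propensity table, sequence and structural families per node,
census), prints the summary report and the recovery check against the
planted truth, and writes the acceptance JSON to `--out`.
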