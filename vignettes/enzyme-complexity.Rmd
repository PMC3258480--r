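---
title: "Methods: propensities, families per EC node, and domain architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propensities, families per EC node, and domain architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catkit)
```

This vignette is the package's own account of its methods: the statistics
it computes, the conventions and tunable parameters behind them, what the
synthetic generator does and does not emulate, and the decisions taken
where the design was genuinely open.

## The data model

A record is one mechanism-level enzyme entry: chain sequences (20-letter
alphabet plus `X`; selenocysteine and pyrrolysine are rejected at parse
time because mechanism-level catalytic annotation does not cover them),
CATH H-level domain assignments as 1-based inclusive segment ranges,
catalytic and binding residue annotations, cofactors (metal ions or
organic molecules), EC numbers, and the chain composition of the
biological and catalytic units. Catalytic annotations carry an involvement
flag (*reactant* residues change chemically during the reaction,
*spectator* residues assist without changing), one or more of seven role
categories, and the acting chemical part — the side chain for the polar
types, a main-chain NH or CO group for the nonpolar types, which rarely
act through their side chains. Exactly one catalytic unit is stored per
record; corpora that annotate several active sites must pick one, which
mirrors how mechanism databases are curated.

## Catalytic propensity

For residue type $r$ and EC class $C$:

$$P(r,C) = \frac{n_{\mathrm{cat}}(r,C)\,/\,n_{\mathrm{cat}}(C)}
                {n_{\mathrm{bg}}(r,C)\,/\,n_{\mathrm{bg}}(C)}$$

The verbal definition ("the percentage of that residue type that is
catalytic over the total percentage of that residue") is ambiguous between
two readings: numerator = share of the catalytic toolkit that is type $r$
(the convention of the active-site literature this statistic comes from),
or numerator = fraction of type-$r$ residues that are catalytic. The two
ratios are algebraically identical once each is normalized by its own
denominator, and `catalytic_propensity(convention =)` exposes both; the
default is the toolkit-share reading because it makes the key invariant
transparent: the composition-weighted mean of every class column is
exactly 1,

$$\sum_r f_{\mathrm{bg}}(r,C)\, P(r,C) \;=\;
  \sum_r \frac{n_{\mathrm{cat}}(r,C)}{n_{\mathrm{cat}}(C)} \;=\; 1,$$

which the test suite asserts to $10^{-9}$. Cells with zero background
count are *undefined* and flagged, never reported as 0; a class with
sequences but no catalytic annotations yields a flagged column rather
than fabricated values. Class membership uses the first digit of each
complete EC node; records with several nodes count in each class, and
each annotation counts once per record (mechanism-level corpora are
non-redundant by construction, so no family-size down-weighting is
applied).

Role profiles tally (entity kind × role × class) incidences, an
annotation with $k$ roles contributing $k$. Hydride shuttling is a
cofactor-only role: the generator's default rule forces its weight to
zero for residues and metal ions, mirroring the empirical observation
that only organic cofactors perform it.

## Families per EC node — sequences (upper bound)

Per EC node, all-vs-all exact Needleman–Wunsch global alignment
(BLOSUM62, gap open 10, extend 0.5 — `alignment_params()`), percent
identity = identical pairs / alignment columns, coverage = mutually
aligned span / shorter length. An edge joins two records when identity
≥ 30% and coverage ≥ 0.8; families are the connected components
(single linkage — the blastclust criterion). The original analysis used
blastclust with unreported parameters; 30%/0.8 are conventional
family-level settings and both are exposed. Exact alignment replaces
BLAST heuristics deliberately: at corpus scale it is affordable,
deterministic, and lets a brute-force transitive-closure oracle verify
the partition exactly.

Single-linkage produces many singleton clusters. The follow-up step that
placed singletons with established clusters via hidden Markov models is
realized here as a documented profile merge, since no HMM software,
parameters or acceptance rule were recorded: each multi-member cluster
gets a center-star position-frequency profile (center = longest member,
ties to the smallest id; +0.1 pseudocount per residue type, columns
renormalized, so a column seen in both of two members scores
$(2+0.1)/(2+2)=0.525$), and each singleton is scored against each
profile as the mean log column frequency of its residues along a global
alignment to the profile consensus. The singleton joins the best-scoring
cluster if the score reaches $\tau = -1.0$ (natural log per aligned
column), ties breaking toward the lexicographically smallest cluster
label. Under these defaults a singleton ~90% identical to a 3-member
cluster scores about $-0.8$ and merges, while an unrelated sequence
scores about $-3.7$ and is refused. The merge never splits a block, so
the merged count is bounded by the raw count — the analogue of the
published 9312 ≤ 13 150. Singletons merge only into multi-member
clusters, not with each other: whether the original procedure also
merged singleton pairs is unrecorded, and the conservative choice keeps
the raw partition the sole source of multi-member structure.

Cluster labels are assigned by each block's smallest member id, which
makes partitions invariant under input order (asserted by
permutation-property tests, along with monotonicity of the cluster count
in the identity threshold).

## Families per EC node — structures (lower bound)

Structural similarity outlives sequence similarity, so grouping records
by their CATH domain combinations bounds the family count from below.
The combination key is the sorted multiset of H-level codes over the
catalytic-unit chains (numeric field-by-field sort, `+`-joined,
multiplicity kept: two chains carrying the same domain give
`code+code`). The published procedure also "incorporated sequence
information" through an appendix that is not available; here that step is
a declared stand-in: each combination group is split by single-linkage at
identity ≥ 20% (no coverage requirement), so same-fold analogues remain
distinct families. The floor is exposed, and `seq_refine = FALSE`
recovers pure combination counting. Combinations are computed over the
catalytic unit rather than the whole biological unit because family
counting concerns the catalytic machinery; `whole_unit = TRUE` is
available. Records are flagged `has_structure` in `units.tsv` (the
solved-structure criterion); the matched-subset comparison — sequence
families restricted to structure-bearing records versus structural
families — is what makes the upper/lower-bound framing meaningful, and
the tests assert structural ≤ raw sequence counts per node on that
subset.

## Domain architecture

A domain is *catalytic* iff it furnishes ≥ 1 catalytic residue and
*binding* iff it furnishes none but ≥ 3 binding residues; anything else
is *other*. Catalytic residues falling outside every segment (linkers)
never invent a pseudo-domain — they are counted and surfaced as a QC
message, because silently attaching them to the nearest domain would
distort the census. The catalytic unit is the annotated chain set when
present, otherwise the chains carrying at least one catalytic or binding
domain (always a subset of the biological unit). The architecture
signature orders the catalytic-unit domains catalytic-first then by CATH
code, assigns letters in first-occurrence order (identical codes share a
letter) and stars the catalytic ones: `A*`, `A*B`, `A*A*`. The census
tallies (signature, biological-unit domain count) pairs and always sums
to the corpus size; the census emits whatever signatures the corpus
contains rather than a fixed row set. Promiscuity counts, per CATH code
that is catalytic in at least one record (`all_domains = TRUE` widens
this), the distinct complete EC nodes and classes the code serves.

## The synthetic world

The generator's defaults are one fixed stated world, not tuning knobs:

| parameter | default | why |
|---|---|---|
| families per node | sampled 1–4 | half of EC nodes hold one family, a tail holds many |
| members per family | 3 | small curated corpora have few sequences per family |
| chain length | 150 aa | a typical single-domain enzyme chain |
| within-family identity | 90% | comfortably above any family threshold |
| between-family cap | 15% | random-sequence background, below threshold |
| background frequencies | uniform 1/20 | makes planted propensities exactly interpretable |
| catalytic sites/record | 3 | typical active-site size |
| cofactor probability | 0.3 | minority of records cofactor-dependent |
| structure probability | 0.5 | a structure-bearing subset large enough to compare |
| architecture weights | 86:24:5:2:10:10 over `A*`,`A*B`,`A*BC`,`A*BCD`,`A*A*`,`A*B+` | census-shaped: single-domain dominates |

Separability requires within-family identity > clustering threshold >
between-family cap (90 > 30 > 15); the config validator rejects anything
else. Family founders are i.i.d. uniform sequences, re-drawn (≤ 100
retries) until all founder pairs sit under the cap. Members are mutated
from the founder at *half* the target divergence: substitution-only star
topology, so two members diverged 5% each from the founder sit at ≈ 90%
pairwise identity. Mutating each member by the full 10% would put
pairwise identity near $0.9^2 \approx 81\%$ and violate the generator's
contract. Substitution-only is the default because it keeps identity
targeting exact and alignments trivial to reason about; an indel mode
(`indel_rate`) exists but is off. Catalytic residue types are drawn with
probability ∝ background × class multiplier and the sequence letter is
overwritten at the planted position, so annotations always resolve. With
one type boosted $m$-fold over a uniform background the implied
propensity is $20m/(19+m)$, the closed form the recovery tests check
(±15% at 500 records).

What the generator does **not** emulate: real amino-acid composition,
real CATH code frequencies, multi-chain biological units (the analysis
supports them and hand-built fixtures test them, but generated records
are single-chain), indel divergence by default, and annotation noise. A
green recovery test therefore establishes correctness of the estimators
under a separable, noise-free world — it does not certify performance on
borderline real corpora, where family identity can straddle the
threshold.

## Numerical conventions and degenerate inputs

* Residue indexing is 1-based with inclusive segment ranges, stated in
  every file header; all five on-disk tables are plain TSV/FASTA and
  writes are canonically sorted, hence byte-stable.
* Display rounding of per-node means is half-away-from-zero at 2
  decimals (3.504 → 3.50, 1.876 → 1.88); raw values are always carried
  alongside. `percentage()` *truncates* at the requested decimal place by
  default (63.75% of drug targets reads "63%"), with `method = "round"`
  available.
* All randomness flows through one config seed; identical config + seed
  gives byte-identical corpora and reports.
* Empty or degenerate selections fail loudly (empty class selections,
  empty per-node count vectors, singleton profile requests), skipped
  nodes are logged, and undefined propensity cells are flagged rather
  than zeroed.

## Limitations

The family counts inherit every caveat of threshold clustering: they are
bounds, not measurements, and shift with the identity threshold (the
sensitivity is exposed, not hidden). The profile merge is a transparent
stand-in for a published-but-unspecified HMM step; it preserves the
step's observable contract (singletons absorbed, counts shrink) but not
its exact membership decisions. The structural refinement rule replaces
an unavailable appendix procedure and is labelled as such. No statistical
significance is attached to propensity differences between classes.
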