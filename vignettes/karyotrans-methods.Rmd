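---
title: "Models and methods behind karyotrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind karyotrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyotrans)
```

# The system

The spiny frog *Quasipaa boulengeri* segregates a reciprocal translocation
between chromosome 1 and chromosome 6. Exchanging (almost all of) the short
arm of chromosome 1 with chromosome 6 material produces two derived
chromosome forms: a telocentric chromosome 1 (`T`, long arm only) and a
sub-telocentric chromosome 6 (`St`, chromosome 6 plus the chromosome 1
short arm). Together with the normal forms (`M`, metacentric chromosome 1;
`m`, chromosome 6), the diploid combinations define five named karyomorphs:

| karyomorph | chromosome 1 pair | chromosome 6 pair |
|---|---|---|
| I   | M/M | m/m  |
| II  | M/M | m/St |
| III | M/T | m/m  |
| IV  | M/T | m/St |
| V   | M/T | St/St |

Type IV is the translocation heterozygote. The species has an XX/XY sex
system whose sex-determining region, and a sex-linked microsatellite locus,
sit on the chromosome 1 long arm (`S1q`) — the segment that both `M` and
`T` carry. Because karyomorphs II--V occur in both sexes, the central
question is *which* chromosome the translocation arose on. The package
makes the competing hypotheses executable:

* `HX` — the translocation hit an X chromosome, so `T` carries an X allele
  (the "rearranged X", Xr) and the population holds three haplotype
  lineages at the sex-linked locus: Y, normal X (Xn) and Xr.
* `HY` — the translocation hit the Y, so `T` carries the Y allele and
  females can never inherit it.

# Meiosis, crosses and reachability

A type IV heterozygote forms a translocation quadrivalent; the package's
default segregation model pairs each chromosome-1-centromere chromosome
with each chromosome-6-centromere chromosome (alternate plus adjacent-1
segregation with independent assortment), which yields exactly four gamete
types. Adjacent-2 products (both chromosome 1 centromeres, or both
chromosome 6 centromeres, in one gamete) are excluded by construction —
the model's gamete always has one centromere of each — and an
`alternate_only` model restricted to the balanced `(M,m)`/`(T,St)` gametes
is available for sensitivity analyses. All gamete types transmit with
equal probability by default; a per-gamete weight vector can encode
meiotic drive or fertility differences.

Zygote viability defaults to *nullisomy lethality*: a genotype is
inviable iff some segment (`S1q`, `S1p`, `S6`) is entirely absent. The
observed karyomorphs I--V all pass; products such as `T/T;m/m` (no short
arm anywhere) do not. Combinations like `M/M;St/St` are viable but fall
outside the five named types; they are retained in enumerations and
reported as `OTHER`, while reachability results are intersected with
I--V.

`reachable_karyomorphs()` closes the founder set `{wild-type female,
wild-type male, one type IV carrier}` under random mating (every female
pool genotype crossed with every male pool genotype, frequencies ignored)
until the genotype pool stops growing. Under `HX` the closure reaches all
five karyomorphs in both sexes in three rounds; under `HY` females are
confined to types I and II — the discriminating prediction, since all
five karyomorphs are observed in wild females. The closure is exact
enumeration over a genotype space of a few dozen states, so these results
are combinatorial facts, not simulations.

# Marker dosage and haplotype-count predictions

If the sex-linked marker sat on the short arm (`S1p`), its copy number
would track the translocation: 2, 3, 1, 2, 3 across karyomorphs I--V. On
the long arm it is always 2. Observed individuals of rearranged
karyotypes consistently show two haplotypes, which only the long-arm
placement explains. `marker_copy_number()`, `haplotype_profile()` and
`expected_distinct_haplotypes()` expose these predictions per genotype
and per (sex, karyomorph) cell; one prediction worth noting is that
type II females carry `M(X)/M(X)` and hence a *single* haplotype class —
the only rearranged cell with one haplotype. The default cohort
generator therefore places rearranged females on the T-carrying types
III/IV/V (see below); type II females can be requested explicitly.

# The synthetic cohort generator

The generator is a stand-in for the study's deposited sequences: it
emulates a ~400 bp microsatellite-containing fragment of the sex-linked
locus in three reference classes (Y, Xn, Xr) and samples diploid cohorts
that mirror the study design (74 frogs: 12 + 12 normal-karyotype females
and males, 33 + 17 rearranged females and males over 13 population
labels). Defaults, all configurable through `locus_config()`:

* `Xn` is the base haplotype: 170 bp flanks around a 30-unit `CA` repeat
  (400 bp total).
* `Xr` differs by three fewer repeat units (6 bp shorter) plus 5 private
  flanking substitutions.
* `Y` differs by a 25 bp flanking deletion plus three fewer repeat units
  (31 bp shorter — the midpoint of the observed 27--35 bp range, realized
  as one contiguous indel since the data do not localize it) plus 37
  flanking and 5 repeat-tract private substitutions.

This puts 47 variable columns in the three-sequence alignment, split 5 in
the repeat tract and 42 in the flanks (within the observed 4--6 / 41--43
ranges), and makes the Y lineage the diverged one, with the Xn--Xr
contrast much shallower — the topology the real tree shows. The
construction is *constructive*: lengths and site counts follow from the
configuration exactly for every seed, which is what makes them usable as
acceptance checks. The true multiple alignment is known by construction
and carried along; user-supplied sequences must arrive pre-aligned, since
the package deliberately does not re-implement progressive multiple
alignment.

Each simulated individual draws a genotype consistent with its category
(normal = type I; rearranged = karyomorph from the configured weights,
genotype uniform among reachable genotypes of that sex and karyomorph)
and copies its two allele sequences from the class references, so every
cohort is exactly consistent with the marker model. What the generator
does *not* emulate: within-class polymorphism is off by default (real
flanking sequences vary within lineages; `within_class_substitutions`
adds private variants), there is no population structure behind the
population labels, no microsatellite mutation during transmission, and no
PCR/cloning artifacts. Passing the recovery tests therefore shows the
inference chain is sound on clean class-structured data, not that it is
robust to every complication of the real amplicons.

# Haplogroup inference

`infer_haplogroups()` runs the distance pipeline: p-distance matrix with
pairwise gap deletion (`ape::dist.dna`; Jukes--Cantor optional), a
neighbour-joining tree, optional column-resampling bootstrap, extraction
of `k = 3` clades, and composition-based labelling (the all-male group is
Y; among the rest, the rearranged-only group is Xr; the remainder Xn).
`k` is a parameter defaulted to the three-lineage result, not
auto-selected.

Numerical choices that matter:

* **NJ tie-breaking and identical sequences.** The default cohort
  contains only three distinct haplotypes among 148 sequences. Plain
  Saitou--Nei agglomeration does not keep identical sequences together:
  once clusters begin to collapse, the Q-criterion favours cross-cluster
  joins over the remaining zero-distance joins (for cluster sizes
  $n_A \ge 2$, $Q_{BC} = -n_A a - 2c$ undercuts $Q_{AA} = -2a - 2c$),
  which strands members of the largest class on near-zero-length chain
  edges and destroys its bipartition. `nj_tree()` therefore collapses
  indistinguishable leaves (zero distance, identical distance rows)
  before agglomeration and re-attaches them afterwards as zero-length
  fans on their representative's branch. Their internal arrangement
  carries no information, and the fan keeps every identical-sequence set
  monophyletic. Remaining Q-ties break deterministically by label order,
  so trees are reproducible. If a bootstrap replicate erases all
  differences between two classes, singletons are split off the largest
  group so agglomeration still has three lineages; such replicates then
  (correctly) fail to support the erased bipartition.
* **Gap handling.** Pairwise gap deletion compares each pair over its own
  column set; this makes distances slightly non-additive across triples
  (the 25 bp Y deletion changes denominators), which is why the package's
  tests check the triangle inequality only up to a small slack.
* **Negative branch lengths** are clamped to zero; **bootstrap support**
  for a labelled clade is the fraction of replicate trees containing that
  exact leaf-set bipartition.
* **Degenerate inputs**: trees with no internal edge set yielding `k`
  non-empty, single-edge-separable groups raise a partition failure (a
  star tree, for instance); labelling failures report the group
  compositions instead of guessing.

# Hypothesis scoring

`consistency_score()` is a deterministic consistency fraction, not a
likelihood — the argument it formalizes is qualitative compatibility, and
per-individual consistency counting is its most direct executable form. An
individual is consistent iff its karyomorph is realizable for its sex
under the hypothesis and its observed haplotypes fit the marker
placement. For the long arm, the observed clade-label multiset must be
among the predicted multisets of its (sex, karyomorph) cell. For the
short arm, the predicted number of distinguishable alleles is the segment
copy number; an individual matches iff its observed distinct count equals
that copy number, with a single observed haplotype also accepted below it
(complete homozygosity). This reproduces the dosage argument exactly:
individuals of types II, III and V with two observed haplotypes are
inconsistent with a short-arm marker (3, 1, 3 expected), types I and IV
are not, and one-haplotype normal females are unremarkable. Clade labels
(not raw sequences) form the interface between inference and evaluation,
so tree quality and hypothesis logic stay decoupled. Individuals with
missing fields are excluded from the denominator and reported rather than
silently dropped. `discriminate()` ranks candidates by score, breaking
ties by fewer unrealizable-karyomorph (hard) violations.

# Drift

`wright_fisher()` formalizes the claim that the polymorphism can persist
in small populations by drift alone: discrete generations, enforced 1:1
sex ratio, random mating, each offspring drawn from the exact cross
distribution of a freshly sampled parental pair. The tracked quantity is
the frequency of `T` among all chromosome-1 chromosomes; zero is
absorbing. Two modelling points:

* Under `HX`, `T` is X-linked: it can never displace the Y-bearing `M`,
  so it cannot fix in the whole chromosome 1 pool and effectively
  segregates in the X pool of size $3N/2$. With an equal sex ratio the
  expected `T` count is conserved generation to generation (each female
  X copy and each male X copy has reproductive value $2/(3N)$), so a
  single neutral copy is lost with probability $1 - 2/(3N)$ — the value
  the tests check by simulation.
* Exact neutrality requires `viability_rule = "all_viable"`: under
  nullisomy lethality the renormalization after discarding unbalanced
  zygotes is itself weak selection against `T` (it only bites in
  carrier x carrier matings, so the effect is second order at low
  frequency). The package default for crosses stays `nullisomy_lethal`;
  the drift tests that assert martingale behaviour switch viability off
  and say so.

Fertility penalties are implemented as per-karyomorph offspring
rejection with parent redraw, the simplest mechanism consistent with
"rearrangements may reduce fertility"; a penalty of 1 on all T-carrying
karyomorphs removes `T` in a single generation.

# Problem sizes and reproducibility

Everything is seeded: cohorts, bootstraps and drift replicates reproduce
byte-identically from a seed, and `run_pipeline()` writes the resolved
configuration (plus its hash, stamped into artifacts) into every output
directory so a run can be replayed from its own files. The test suite
exercises the combinatorial layer exhaustively (it is desk-scale: a few
dozen genotypes) and uses deliberately moderate stochastic sizes — the
full 74-individual cohort with 100 bootstrap replicates at one seed,
label recovery across 20 seeds, drift with a few hundred replicates at
$N \le 72$ — chosen so that Monte-Carlo error bars (3 SE) are far smaller
than the effects being asserted.

# Known limitations

* No recombination between the sex-determining region and the marker
  (the locus is modelled inside the non-recombining region), hence no
  multi-locus genetics.
* No physical breakpoint or heterochromatin model; segments are atomic.
* The consistency score has no statistical test attached; it ranks
  qualitative compatibility and is not a posterior.
* Multiple sequence alignment is not estimated; analyses rely on the
  constructively known alignment or pre-aligned input.
* Wright--Fisher here has no overlapping generations, population
  structure, or mutation; it quantifies drift of an existing
  polymorphism only.
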