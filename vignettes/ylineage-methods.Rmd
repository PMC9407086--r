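---
title: "Models and methods behind ylineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ylineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ylineage)
```

ylineage analyses the non-recombining portion of the Y chromosome with
two complementary marker classes. Y-STRs mutate fast (published
father–son rates span roughly 4×10⁻⁴ to 7×10⁻² per generation per
locus), so multi-locus STR haplotypes resolve individual paternal
lineages at forensic depth. Y-SNPs mutate about seven orders of
magnitude more slowly, so their derived states define a stable rooted
clade hierarchy — haplogroups — that records deep paternal ancestry.
Everything in the package is organised around that contrast: STR
haplotypes for within-population diversity and between-population
differentiation, SNP haplogroups for lineage classification, and their
joint use for haplotype networks within a clade.

This vignette documents the models, the estimators, the defaults, and
the numerical choices, in that order; it ends with what the simulator
does and does not emulate, and the package's known limitations.

## Data model

An STR profile stores, per locus, a *sorted list* of decimal repeat
values. The list form accommodates the three departure types the
screening stage reports:

* **microvariants** — alleles with a fractional repeat part
  (e.g. 17.2), constrained to steps .1/.2/.3;
* **copy-number variants (CNVs)** — more alleles than the locus's
  expected copy number (the built-in panels expect two copies only at
  DYS385a/b, DYF387S1a/b and DYS527a/b);
* **nulls** — an empty list, i.e. no amplification.

Sorting makes genotype identity order-free: `"13-17"` and `"17-13"` at
DYS385a/b are the same genotype. Locus names are normalised through an
alias table (`DYS389-2` → `DYS389II`, `YGATA-H4` → `YGATAH4`,
`DYS387S1a/b` → `DYF387S1a/b`, …) because published tables vary in
spelling.

The four built-in panels mirror the common commercial kits at 17, 23,
27 and 38 loci (multi-copy loci counted twice). The 38-locus panel is
defined as a superset of the other three: a sample typed once on the
large panel can then be evaluated under any of the four, which is how a
single genotyping run yields four panel-specific parameter columns.
Beyond the union of the three smaller kits and the loci the screening
literature names (DYS444, DYS645, DYS527a/b), the remaining slots of
the 38-locus definition follow the kit's published content; custom
panels can be supplied as TSV (`locus, copies`).

## Forensic parameters

All four summary statistics are functions of the haplotype frequency
spectrum alone — `s[k]` distinct haplotypes seen exactly `k` times, `n`
samples, `H` distinct haplotypes:

$$MP = \sum_k s_k \left(\frac{k}{n}\right)^2, \quad
  HD = \frac{n}{n-1}(1 - MP), \quad
  DC = \frac{H}{n}, \quad
  FUH = \frac{s_1}{n}.$$

Per-locus gene diversity uses the same unbiased form,
$GD = \frac{n}{n-1}(1-\sum_i p_i^2)$, with multi-copy allele lists
counted as single units. Internally everything is kept at full double
precision; printing rounds *half away from zero* to 5 decimals (4 for
GD), the convention of forensic parameter tables — base R's
round-half-even would differ on boundary values.

Samples with a null call at any panel locus are excluded from that
panel's spectrum only, so each kit's `n` can differ on incomplete data;
on complete data all panels see the full sample. Microvariant- and
CNV-bearing samples stay in the spectrum — their haplotypes are simply
distinct — which is the behaviour that reproduces published parameter
tables computed on full sample sizes.

## Rst by AMOVA on repeat scores

Differentiation between populations uses the microsatellite-specific
Rst: a two-level analysis of molecular variance on per-sample vectors
of repeat counts over single-copy loci, with squared-difference
distances $d(i,j)=\sum_l (a_{il}-a_{jl})^2$. With $K$ groups and $N$
samples,

$$SS_{total} = \frac{1}{N}\sum_{i<j} d(i,j), \qquad
  SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d(i,j),$$

$MS_{among} = (SS_{total}-SS_{within})/(K-1)$,
$MS_{within} = SS_{within}/(N-K)$,
$n_c = (N-\sum_g n_g^2/N)/(K-1)$,
$\sigma^2_{among} = (MS_{among}-MS_{within})/n_c$, and

$$R_{st} = \frac{\sigma^2_{among}}{\sigma^2_{among} + MS_{within}}.$$

Three policy choices matter:

* **Loci.** Only single-copy loci enter; repeat-score arithmetic is
  ill-defined on unordered multi-copy allele pairs. Samples with a null
  or duplicated call at a chosen locus are dropped pairwise;
  microvariant alleles enter with their decimal value (a 38.2 is 0.2
  repeats away from 38). DYS389II can be used raw (default) or with
  DYS389I subtracted (`dys389ii = "minus_389I"`); reference practice is
  not standardised, so both are exposed.
* **Negative estimates.** For identical or near-identical populations
  the unbiased estimator is slightly *negative* — with duplicated
  polymorphic multisets, $SS_{among}=0$ forces
  $\sigma^2_{among}=-MS_{within}/n_c < 0$. These values are reported
  raw with a `"negative"` attribute rather than truncated, so the
  estimator's sampling behaviour stays testable; truncation is left to
  the caller. Exact zero occurs only in the fully monomorphic case.
* **Determinism.** `rst_matrix()` is a deterministic function of its
  inputs; permuting population order permutes labels identically.

## Ordination and trees

Classical (Torgerson) scaling double-centres $-\tfrac12 D^2$ and takes
the top-two eigenvectors scaled by the square roots of their
eigenvalues; when all off-diagonal dissimilarities are positive, a
Kruskal non-metric refinement (`MASS::isoMDS`, up to 200 iterations,
convergence at stress improvement < 1e-6 — MASS's own criterion) starts
from that configuration. Reported stress is Kruskal's stress-1 as a
fraction; the package also exposes `stress1()` (metric form) so the
classical start and any configuration can be compared on the same
scale. Negative dissimilarities — possible under the raw Rst estimator
— are clamped to zero with a message before embedding; ties at zero
(duplicated populations) keep the classical solution, which places
duplicates at coincident coordinates.

Neighbor-joining is implemented directly (rather than through an
existing tree package) because deterministic tie-breaking is part of
the contract: ties in the Q-criterion
$Q_{ij}=(r-2)d_{ij}-R_i-R_j$ resolve towards the lexicographically
first label pair, so repeated runs and label permutations give
reproducible topologies. Branch lengths use the standard Saitou–Nei
formulas with the three-point closed form at the final join; on
additive matrices the tree reproduces the input distances exactly
(verified to 1e-10 in the tests, with `ape::nj` as an independent
cross-check). Negative branch lengths are legal NJ output and are
written to Newick as-is, with a message.

## Haplogroup calling

The built-in tree holds the 24 pedigree-tagging markers, from the
primary haplogroups (E-M96, D-JST021355, C-M130, G-M201, IJK-M522 with
IJ-M429/I-M170 and K-M9, under which N-M231, O-P186 and QR-M45) down
through the O subclades to O2a2b1a1-M117. The caller assigns the
deepest clade whose defining marker is derived and whose *typed*
ancestors are all derived, with two deliberate softenings:

* a **no-call at an intermediate marker does not block** deeper
  assignment — a derived descendant state implies the ancestor, which
  is recorded in the call as imputed;
* samples derived only at an **internal marker** (e.g. K-M9 with the
  N/O/QR markers ancestral) keep the internal label — "K", "IJ", "QR"
  are legitimate terminal labels at this marker resolution.

Derived markers off the chosen root-to-label path are biologically
impossible under a strict tree; they are reported as conflicts and
clear `path_consistent` instead of silently winning or losing. Samples
with no supporting derived marker are `"unresolved"` and are excluded
from frequency denominators (logged), since published frequency lists
sum to ~100% over resolved labels.

Clade aggregation (`clade_frequency()`) operates on the tree structure,
not on observed labels: "O2" sums O2 itself plus every descendant
present in the vector, so aggregates exist even for internal clades
that never occur as calls. PCA of population × clade frequency matrices
defaults to correlation mode (columns standardised — the common
default of desktop statistics packages; covariance mode by flag, since
source analyses rarely state the setting), drops constant columns with
a message, orders components by eigenvalue and fixes signs so each
component's largest-magnitude loading is positive.

## Median-joining networks

Within a haplogroup, 15-locus haplotype vectors (DYS19, DYS389I,
DYS389b, DYS390, DYS391, DYS392, DYS393, DYS437, DYS438, DYS439,
DYS448, DYS456, DYS458, DYS635, YGATAH4) are compared under a weighted
Manhattan metric $d_w(x,y)=\sum_l w_l |x_l - y_l|$. DYS389b is the
derived distal stretch DYS389II − DYS389I; including DYS389I alongside
it means the pair jointly encodes DYS389II without double-counting the
shared segment. (Published locus lists for this analysis name 14 loci
while stating 15; including DYS389I is this package's resolution of
that ambiguity.)

Locus weights follow the conventional 1–5 scale, lower mutation rate →
higher weight, constructed as quintile bins of log₁₀(rate): the
lowest-rate quintile gets 5, the highest 1, equal rates always get
equal weights, and all-equal rates fall in the middle bin (3). The
binning is this package's construction; only the interval and the
direction are conventional. The packaged rate table is assembled from
published father–son magnitudes and is fully overridable.

Network construction iterates: evaluate the component-wise median
vectors of node triples as candidate Steiner points, add the candidate
that most reduces the total spanning cost (deterministic tie-break by
vector order), repeat until no candidate helps, prune median vectors
whose removal leaves the spanning cost unchanged, then connect the
final node set by the ε-relaxed minimum spanning network (an edge
survives if its length is within ε of the level at which its endpoints'
clusters merge; ε = 0, the default, gives the strict MSN, whose edge
set contains a minimum spanning tree). Candidates are generated from
*all* node triples rather than only network-adjacent ones: the
adjacency restriction of the classical formulation can miss
cost-reducing medians even on five-haplotype instances, whereas the
all-triples greedy provably matches an exhaustive Steiner-point search
over median candidates on every small instance in the test suite.
Fractional (microvariant) alleles at network loci exclude the sample
from this stage with a log entry — a step metric across a 0.2 offset
has no parsimony interpretation.

The ancestral haplotype is the count-weighted medoid: the observed
vector minimising $\sum_j c_j\, d_w(h, h_j)$, ties broken by larger own
count, then lexicographic vector order. Per-population mean distance to
that node summarises who sits "downstream" of whom — a daughter
population founded from a source lineage and then drifted shows the
larger mean.

## The simulator

`simulate_population()` is a forward-time Wright–Fisher model of male
lineages: constant population size, each son drawing a father
uniformly at random, no recombination (the NRY is effectively
non-recombining), no female demography. Per generation and per allele
copy:

* **stepwise mutation** with the locus's rate, ±1 repeat with equal
  probability (single-step SMM; multi-step mutation is a config
  extension point), reflecting at one repeat so alleles stay physical;
* **microvariant events** (default 1e-4) give an integer allele a
  heritable ".2" offset (+0.2 or −0.8 with equal probability — a
  partial-repeat insertion or deletion); the offset is inherited and
  subsequent ±1 steps preserve it, mimicking lineage-stable
  microvariants that track a clade;
* **duplication events** (default 5e-5) convert a call into a
  two-allele list that is thereafter inherited and mutates per copy;
* the **haplogroup is inherited unchanged** — at ~1e-9 per generation,
  Y-SNP mutation is invisible on these time scales, so SNP states are
  generated exactly from the founder clade's root path.

Founders start at modal repeat values with clades drawn from
configurable weights; one global RNG stream seeded explicitly makes
every output byte-reproducible. `simulate_divergent_pair()` evolves one
ancestral deme, copies it at the split, and evolves the copies
independently — the knob for Rst parameter-recovery experiments.

What the simulator *does* emulate: singleton-dominated haplotype
spectra, divergence-time-monotone Rst, founder-effect elevation of a
clade in a drifted isolate, clade-linked microvariants, and
spectrum/frequency bookkeeping with known truth. What it does *not*:
real mutation-rate heterogeneity beyond the packaged table, multi-step
mutations, population growth or migration, marker no-call noise
(no-calls must be injected by the caller), or sex-biased demography.
Passing tests on simulated data therefore validate the estimators'
arithmetic and their qualitative response to drift — not the demographic
realism of any particular population.

Test and validation problem sizes are deliberately modest: demes of
60–150 males for drift experiments (with 20 seeds × four divergence
times for the Rst monotonicity grid) and a single larger run (N = 2000,
300 generations, 100 sampled) for the singleton-dominance regime —
chosen from coalescent arithmetic: the probability two sampled lineages
carry identical haplotypes is ≈ 1/(1 + 2Nμ_total), so sampling a small
fraction of a large deme is what makes FUH > 0.8 attainable, while
sampling most of a small deme never is, whatever the rates.

## Numerical conventions

* Display rounding is half-away-from-zero (`round_half_up()`), 5
  decimals for parameters, 4 for GD, 2 for percent frequencies.
* Allele tokens accept at most one fractional digit, fractional part
  ∈ {.1, .2, .3}; cells accept `-`, `,` or `/` as intra-cell
  delimiters on read and write `-`.
* Spanning costs and medoid scores compare with absolute tolerance
  1e-9 (all quantities are small-integer combinations).
* NJ Q-ties and medoid ties break lexicographically; median-candidate
  ties break by vector key — every algorithm is deterministic.
* Degenerate inputs fail loudly: all-zero distance matrices, empty
  frequency tables, n < 2, unknown clades, duplicate observed network
  vectors.

## Limitations

* The haplogroup tree is marker-complete for the 24-marker system but
  intentionally shallow elsewhere; clades never observed under this
  system (e.g. deeper E/G/I structure) exist only as attachment points.
* Rst uses repeat scores; it does not implement haplotype-wise
  (infinite-allele) AMOVA distances.
* The median-joining implementation targets the small, within-clade
  networks this analysis needs (tens of haplotypes); its all-triples
  candidate generation is cubic per round and not meant for
  thousand-node networks.
* MDS exposes no per-iteration stress trace (the refinement is
  delegated to `MASS::isoMDS`); convergence behaviour is asserted by
  comparing stress at different iteration caps.
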