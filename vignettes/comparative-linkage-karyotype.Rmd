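---
title: "Sex-specific linkage maps and comparative karyotype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific linkage maps and comparative karyotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyomapr)
```

# The problem

Atlantic salmon (*Salmo salar*) on the two sides of the Atlantic carry
visibly different karyotypes: European populations typically show 29
chromosome pairs with a fundamental number (NF, the diploid chromosome-arm
count) of 74 — 8 metacentric pairs plus 21 acrocentric — while the standard
North American karyotype has 27 pairs, NF 72 and 9 metacentric pairs.
Dense SNP linkage maps built in pedigreed families make it possible to
identify the rearrangements behind such differences without a genome
assembly: two maps are aligned on the markers they share, and linkage
groups that split or join between the maps reveal fissions, fusions and
translocations.  Three events reconcile the two salmon karyotypes:

1. a whole-arm translocation of the ssa01 p arm onto the acrocentric
   ssa23 (a centromere-to-centromere join), leaving the ssa01 q arm behind
   as a new acrocentric — pairs and NF unchanged;
2. a Robertsonian (centromere-to-centromere) fusion of the acrocentrics
   ssa26 and ssa28 into a new metacentric — one pair fewer, NF unchanged;
3. a tandem fusion attaching the acrocentric ssa29 end-to-end to the q arm
   of the metacentric ssa08, which keeps the ssa08 centromere — one pair
   fewer and NF reduced by two.

`karyomapr` implements the full inference chain as testable components: a
karyotype model with rearrangement operators and 2n/NF accounting, a
synthetic-data generator (truth maps, rearranged genomes, pedigrees,
meioses), a two-point linkage mapper, and the comparative layer that
classifies events and predicts the derived karyotype.

```{r arithmetic}
eu <- build_european_reference()
karyotype_summary(eu)
na <- apply_event_set(eu, na_standard_events())
karyotype_summary(na)
```

# The statistical model

## Two-point recombination fractions

For each meiosis of a genotyped parent we deduce, marker by marker, which
allele the parent transmitted.  With unphased SNP genotypes this is
possible when the parent is heterozygous and either the offspring is
homozygous or the other parent is homozygous; transmissions that remain
ambiguous (heterozygous offspring of two heterozygous parents, or of a
half-sib family's untyped parent) are treated as uninformative.  A marker
pair then yields, per parent, `n` informative meioses of which `r` are
recombinant *under an arbitrary phase labelling*.  Parental linkage phase
is unknown, so each parent contributes the symmetric mixture likelihood

$$L_p(\theta) = \tfrac12\,\theta^{r_p}(1-\theta)^{n_p-r_p}
             + \tfrac12\,\theta^{n_p-r_p}(1-\theta)^{r_p},
\qquad 0 \le \theta \le \tfrac12,$$

and the recombination fraction is maximized by EM: the E-step computes
each parent's phase posterior from its own offspring, the M-step sets
$\theta$ to the expected recombinant fraction.  The observed-data
log-likelihood is non-decreasing across iterations (a property the test
suite asserts), convergence is declared at $|\Delta\theta| < 10^{-6}$
(initial value 0.25, at most 200 iterations), and the LOD score is the
base-10 log-likelihood ratio against $\theta = 0.5$.  Sex-specific
estimates use only the meioses of parents of that sex; the pooled
("combined") estimate uses all of them.  A pair with no informative
meiosis reports $\theta = 0.5$ with LOD 0.

Two consequences of the mixture shape matter in practice and drive
several design choices below:

* a parent with very few informative meioses contributes almost pure
  noise, because its phase cannot be established (with $n_p = 2, r_p = 1$
  the likelihood is $\propto \theta(1-\theta)$, maximized at 0.5).
  Parents with fewer than 5 informative meioses for a pair are therefore
  excluded from the *sex-specific* estimates, which typically rest on a
  handful of doubly heterozygous parents;
* LOD scores of unlinked pairs are heavy-tailed: across the roughly
  30,000 unlinked pairs of a desk-scale panel we measured about one
  spurious pair with LOD between 5 and 6 per data set.  Single-linkage
  grouping joins chromosomes through any single such edge, so the default
  grouping threshold is LOD 10; genuinely adjacent markers at desk scale
  carry LODs of 30-70, so the margin is wide on both sides.

## Grouping, ordering and map distances

Markers are partitioned into linkage groups by single-linkage transitive
closure over pairs with LOD at or above the threshold.  Within a group,
markers with no observed recombination collapse into co-segregating bins —
but only when the zero estimate is backed by at least 20 informative
meioses of which at least 10 are female: male meioses cannot separate
*interior* markers at any distance (male crossovers are telomeric), so a
handful of non-recombinant male meioses must not merge markers that may
lie tens of cM apart.  Bins are seriated to minimize the sum of adjacent
recombination fractions.  Because two-point estimates are only reliable
at short range (distant pairs saturate towards 0.5 and their
phase-mixture estimates are biased), the global layout is obtained by
embedding *shortest-path* distances — Haldane-transformed thetas summed
along the graph of short links with at least 40 supporting meioses — on
the first principal coordinate; a greedy nearest-neighbour chain from the
most distal pair, and (when a reference map is supplied) the reference
order itself, serve as alternative starts.  All starts are polished by
2-opt segment reversals plus or-opt segment relocations (lengths 1-4,
either orientation) until the objective stops improving, and the best
polished order wins — so a published reference can rescue a folded
embedding but never overrides what the data prefer.  Bin members, which
the data cannot order, are ordered by the reference map when one is
supplied (exactly as maps for a new population are ordered against a
published one), else by input order; with a reference the whole group is
also flipped, if needed, so shared-marker positions correlate positively
with it.

Adjacent recombination fractions are converted to centimorgans with
Haldane's function $d = -50\ln(1-2\theta)$ — exact for the simulator's
interference-free crossover process — or Kosambi's
$d = 25\ln\!\frac{1+2\theta}{1-2\theta}$ (the package default, matching
common practice for real data).  Positions are not accumulated from
adjacent pairs alone: each sex's positions are fitted by inverse-variance
weighted least squares over *all* adequately supported pairs in the
group, with non-negative inter-marker gaps.  With only adjacent estimates
this reduces exactly to the cumulative sum; with the full set it stops
the map-length inflation (up to two-fold in our measurements) that
adjacent-only accumulation suffers when an occasional interval estimate
is weak.  An interval with no usable information of either sex
contributes zero length; an adjacent pair whose pooled estimate is 0.5
despite at least 20 informative meioses raises an ordering/grouping
inconsistency error.

## Comparing two maps

Shared markers define a bipartite correspondence graph between the
linkage groups of the two maps; edges require at least `min_shared = 3`
markers and carry the Spearman rank correlation of the shared positions
(its sign is the relative orientation).  Events are classified per
connected component, relative to the reference map: one-to-one components
are conserved; two reference groups meeting in one query group are a
fusion; one reference group spread over several query groups is a
fission; a split reference group whose fragment joins a second, intact
reference group is a translocation-plus-fission with the pure fragment as
the fission residue.  Anything else is "complex" — a fallback label,
never an error.  Shared markers are ranked by query position with ties
(bin members, whose internal order is meaningless) broken by reference
group, so bins straddling a junction do not count as misplaced.
Junction geometry follows from the orientation
convention that position 0 of an acrocentric group is its centromeric
(proximal) end: a block whose proximal end meets the junction contributes
a "head", its distal end a "tail".

Fusion architecture is read off the male recombination profile.  Male
crossovers cluster at the telomeres, so a true centromere — including a
fusion junction that now acts as one — is male-recombination-cold.  A
fusion-like event is called centromere-to-centromere when the junction
window (±10% of the group's female span) carries less than 15% of the
group's male map length while both distal ends recombine in males, the
geometry is head-to-head, and both participants were acrocentric; it is
called tandem when the tail-side participant is the single metacentric in
a tail-to-head join under the same cold-junction condition; otherwise it
stays undetermined.  The 15% threshold separates the three regimes we
measured: about 2.5% of male length falls in the window for a true
centromeric junction, about 20% would under a uniform male map, and 45%
or more when a junction coincides with a telomeric hotspot.

Interpretable events are mapped back onto karyotype operators
(`events_to_karyotype()`): centromere-to-centromere fusions become
Robertsonian fusions, tandem fusions keep the metacentric participant as
centromere donor, translocation-plus-fission becomes a whole-arm
translocation whose residue is the renamed leftover arm.  Complex events,
and fusions whose architecture stayed undetermined, are refused with an
error: their NF effect is not deterministic.

# The synthetic world

The generator states a world with the structure the analysis assumes and
nothing more:

* **Chromosomes and maps.** Linkage groups default to 80 cM (female) and
  36 cM (male) — the per-chromosome scale implied by genome totals of
  roughly 2,150 and 970 cM over 27 groups.  Female crossovers are uniform
  along the chromosome; male crossover positions follow a
  piecewise-uniform density that puts `telomere_mass = 0.9` of the
  probability into two terminal windows of width `telomere_window = 0.1`.
  Published salmonid maps report the telomeric concentration only
  qualitatively; these two values are calibration choices stated once.  Crossover counts are
  Poisson with mean equal to the sex-specific map length in Morgans — no
  interference, so Haldane's function is exact for simulated data.
* **Markers.** `markers_per_chromosome = 24` by default (desk scale,
  far below the thousands of a real array), placed at the centres of
  equal intervals.  Evenly spaced panels emulate the intent of array
  design and keep adjacent intervals resolvable at desk-scale meiosis
  counts; uniform-random placement (`marker_spacing = "random"`) is
  available but produces arbitrarily tight pairs whose true order no
  pedigree of this size can recover.  Minor allele frequencies are drawn
  from Uniform(0.1, 0.5); founder haplotypes are in linkage equilibrium.
* **Pedigrees.** Families of one sire and one dam with
  `offspring_per_family = 20` offspring; `half_sib_fraction = 0.15` of
  families have one parent withheld from the genotype matrix (the
  offspring are still true mosaics of both parents); genotypes are
  unphased 0/1/2 with `missing_rate = 0.02` masking.
* **Rearranged genomes.** A planted event list transforms the query
  genome: fused groups concatenate their marker coordinates (reversing a
  participant for head-to-head joins), translocations split a metacentric
  at its centromere (`arm_split = 0.45` of its female length), and male
  positions are regenerated from the *new* group's telomere profile — the
  recombination machinery sees the rearranged chromosome, which is
  exactly the signal the architecture test reads.  The query karyotype is
  produced by the same `apply_event_set()` used for analysis, so
  simulator truth and predicted karyotypes are comparable object by
  object.
* **FISH abstraction.** Polymorphic fusions are population annotations;
  an individual is homozygous fused, heterozygous, or homozygous unfused,
  and `simulate_fish_counts()` reports how many chromosomes carry both
  probes together versus separately (a heterozygote shows the joined
  signal on one chromosome and single signals on the two unfused
  homologs).  Meiosis in fusion heterozygotes is not modelled.

What a green end-to-end test establishes, therefore, is that the
inference chain recovers planted events of the three kinds from
pedigree genotypes with the stated information content — not that it
would resolve every event on real array data, which has error modes
(genotyping error, segregation distortion, residual tetrasomy) this
world does not contain.

Before ordering and position fitting, each group's estimates pass a
profile-consistency check: a near-zero estimate (θ ≤ 0.1) between two
markers is discarded when their recombination fractions to third markers
disagree by more than 0.12 on average.  Truly co-located markers must
have matching profiles; with a few dozen informative meioses the
probability of observing zero recombinants is appreciable even for
markers ~20 cM apart, and every such artefact would otherwise create a
false co-segregation bin or a "free" adjacency that folds or compresses
the group.

# Numerical and design choices

* **Two-point only.** Multipoint phase reconstruction is deliberately out
  of scope; ordering quality comes from the seriation contract.  The
  information ceiling of two-point SNP data is low: at desk scale an
  adjacent interval's pooled estimate has a standard error near 0.01
  against true adjacent fractions near 0.016, so occasional local order
  errors (adjacent swaps, short displaced runs) are expected and the
  comparison layer tolerates up to 5 misplaced shared markers per block
  boundary before declaring an event complex.
* **Ties.** Greedy chaining and bin naming break ties by lexicographic
  marker id; group labels are assigned by decreasing size then first
  marker id.  Everything is deterministic given the seed.
* **Degenerate inputs.** Monomorphic markers become singletons (no
  informative meioses); a group of one marker maps at 0 cM; an empty map
  summarizes to zeros; complex events are refused only at the
  karyotype-mapping step, with an explanation.
* **File formats.** The map table is the 8-column supplementary layout
  (marker id, group, 1-based order, female cM, male cM, meioses count,
  accession, population-specific flag written as a literal `x`), TSV,
  UTF-8, positions to 3 decimals.  Readers auto-detect a header and
  validate monotonicity, order permutations and the 0 cM origin per
  group, naming the offending group or line.

# Known limitations

The hardest limitation is quantitative.  Exact marker-order recovery from
two-point estimates alone is bounded by the panel's informative-meiosis
yield: with 1,200 offspring, biallelic markers and unknown phase, roughly
10% of meioses are informative per pair, the adjacent-pair estimates have
standard errors comparable to half the adjacent recombination fractions,
and each adjacent order decision carries a few percent error.  Recovering
every adjacency of every chromosome in a 250-marker genome is therefore a
low-probability event per data set, however good the seriation — the test
suite's parameter-recovery check reports this honestly rather than hiding
it.  Resolving it requires multipoint phase reconstruction, which is
deliberately outside this package's scope.  Event-level inference is far
more forgiving: fusion/fission/translocation classification, junction
geometry and architecture survive local order noise, which is why the
end-to-end recovery of planted events succeeds at the same scale.


* Sex-specific map lengths for weakly informative intervals borrow the
  pooled estimate, slightly smoothing female/male contrast there.
* The architecture call needs a male map; a query population mapped only
  through dams would leave every fusion undetermined.
* Whether the ssa01p/23 product keeps the ssa23 or the ssa01 centromere
  cannot be decided from linkage data; the karyotype model keeps exactly
  one centromere for the product and does not name its donor.
* The acrocentric "short versus long" distinction is not computed — no
  size criterion is available to the model — so summaries report total
  acrocentric counts only.
* Fusions segregating in a population are annotations; maps are treated
  as homozygous for the derived state.
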