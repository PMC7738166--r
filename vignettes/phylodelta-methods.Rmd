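---
title: "Concordance factors and the Delta test: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concordance factors and the Delta test: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodelta)
```

## The problem

When hundreds to thousands of gene trees are estimated across a genome, many
disagree with the species tree. Two biological processes dominate that
discordance: incomplete lineage sorting (ILS), in which ancestral
polymorphism persists across short internodes, and introgression, in which
lineages exchange genes after divergence. `phylodelta` quantifies per-branch
discordance (gene and site concordance factors), tests whether the
discordance is *asymmetric* in the way introgression — but not ILS —
produces (the Δ statistic with a gene-tree bootstrap), and ships simulators
(multispecies coalescent with introgression pulses; forward Wright–Fisher
with purifying selection) that generate data with known truth for
validating every step.

## Branch contexts

Every internal branch of a rooted binary species tree partitions the taxa
into four groups: the two child clades below the branch (A and B), the
sister clade (C) and everything else (D). A gene tree is **decisive** for
the branch if it carries at least one member of each group; a decisive tree
is **concordant** if one of its splits places all its members of A∪B against
all of C∪D, and otherwise realises one of the two nearest-neighbour
alternatives — ALT1 = AC|BD, ALT2 = AD|BC — or none of the three
(**paraphyletic**). ALT1/ALT2 identity is fixed by the group labels, never
by observed frequency, so classification is deterministic and
order-independent; frequency ranking happens only inside the Δ test.

The two branches incident to the root induce the same unrooted split and
yield a single context; a rooted binary tree on *n* taxa therefore has
*n* − 3 contexts. Supplying `ingroup =` to `branch_contexts()` keeps only
contexts whose distal clade is a proper subset of the ingroup, the usual
convention when outgroups are present (29 taxa with a 26-taxon ingroup give
26 contexts, 24 of them inside the ingroup). Taxon names are matched by
**exact string equality** throughout — no trimming, case folding or
underscore/space conversion.

## Concordance factors

For each branch, gCF is the percentage of decisive gene trees that are
concordant; gDF1, gDF2 and gDFP are the percentages of the two alternatives
and of paraphyletic trees. The four percentages sum to 100 by construction;
branches with no decisive tree are reported with `NA` rather than a
division by zero. Paraphyletic trees are kept in the decisive denominator
(the standard definition).

The site concordance factor samples `n_quartets` (default 300) quartets per
branch, one taxon uniformly from each group (with replacement across
quartets, which also covers small groups). For a quartet, a site is
decisive when all four states are unambiguous A/C/G/T and the column
pattern matches exactly one pairing (xxyy, xyxy or xyyx); gaps and
ambiguity codes disqualify the site. sCF is the unweighted mean, over
quartets with at least one decisive site, of the fraction of decisive sites
supporting the concordant pairing.

`polytomy_chi2()` is a two-degree-of-freedom goodness-of-fit test of the
three resolution counts around a branch against equal thirds. It operates
on whole-tree topology counts; quartet-based polytomy tests (as in
ASTRAL) use different inputs and need not give the same p-value, which is
why no attempt is made to reproduce published quartet-based values.

## The Δ statistic and its bootstrap null

Under ILS alone the two discordant classes are exchangeable, so their
counts differ only by sampling noise. Writing DF1 for the more frequent and
DF2 for the less frequent discordant class,

$$\Delta = \frac{n_{DF1} - n_{DF2}}{n_{DF1} + n_{DF2}} \in [0, 1],$$

with Δ = 0 expected under pure ILS and Δ > 0 under introgression between
non-sister lineages. Branches are screened before testing: only those where
the discordant fraction of decisive trees exceeds
`min_discordant_fraction` (default 0.05) are tested — with almost no
discordance there is nothing for Δ to measure. Decisive trees are used as
the screening denominator because non-decisive trees carry no information
about the branch.

Significance comes from a gene-tree bootstrap (default 2,000
pseudo-replicates): the full gene-tree list is resampled with replacement,
and Δ is recomputed per replicate **with the DF1/DF2 identities frozen**
from the observed data. Re-ranking within each replicate would fold the
null distribution at zero and bias the bootstrap spread upward. The
resampling unit is the whole gene tree: in `delta_test()` the same
resampled datasets are used for every branch, so branch statistics co-vary
across replicates as they should.

Three numerical choices deserve explanation:

* **Z-score**: Z = Δ_obs / sd(Δ_boot), centred at 0 (the null value of Δ),
  not at the bootstrap mean. Centring at the bootstrap mean would test
  Δ = Δ_obs against itself and have essentially no power.
* **p-value**: Δ_obs is non-negative *by ranking*, so under the null it is
  the absolute value of an approximately centred normal deviate; the upper
  tail of its null distribution is the folded-normal tail
  p = 2(1 − Φ(Z)). Using the plain one-sided normal tail 1 − Φ(Z) would
  double the nominal type-I rate (a test at α = 0.05 would reject ~10% of
  null datasets). The package's construction is calibrated: on simulated
  pure-ILS datasets the rejection rate at α = 0.05 sits inside the exact
  binomial interval around 5% (the acceptance suite verifies this).
* **Degenerate cases**: no discordant trees at all gives an undefined Δ
  (`NA`, flagged); a zero bootstrap SD with Δ_obs = 0 gives p = 1, and
  with Δ_obs > 0 is flagged `degenerate` rather than silently assigned.

Family-wise error over the m tested branches is controlled with the
Dunn–Šidák cutoff 1 − (1 − α)^(1/m) (α = 0.05, m = 17 gives 0.00301); m
defaults to the number of branches actually tested and is exposed as a
configuration knob for follow-up designs that inherit the screening m.

The four-taxon follow-up (`quartet_followup()`) restricts the gene-tree set
to one taxon per group — so the tested branch is internal in every
restricted tree — drops trees missing any chosen taxon, and reruns the
bootstrap, reporting the number of usable loci. Genome-scale studies
often re-extract orthologs for the chosen quartet to enlarge this set;
this package instead restricts the supplied trees, and accepts a larger
quartet-specific tree set whenever the user has one.

Like all topology-asymmetry tests, Δ cannot see gene flow between sister
lineages (it shifts no class frequencies), cannot orient the direction of
exchange, and can be mimicked by sharply structured ancestral populations
or asymmetric reconstruction bias.

## The coalescent simulator

`simulate_gene_trees()` implements the multispecies coalescent backward in
time. Branch lengths are in coalescent units (1 unit = 2N generations,
diploid convention; `units = "generations"` with `N` and `ploidy` converts).
Within a population holding k lineages, coalescences occur at rate
k(k−1)/2 per unit; survivors pass to parent populations at speciation
nodes, and the ancestral population above the root absorbs everything. An
introgression pulse (donor, recipient, time, γ) is instantaneous: each
lineage in the recipient at that time reroutes to the donor independently
with probability γ. Pulses are instantaneous rather than continuous
migration so that per-locus truth attribution ("did this pulse reroute a
lineage here?") is unambiguous; the truth log records, per locus, the gene
tree, the per-pulse reroute flag and the topology class at every species
branch.

Missing data are emulated by dropping each taxon independently per locus
with probability `missing_prob` (at least two taxa are always retained),
matching the "single-copy in at least 27 of 29 taxa" structure of real
ortholog sets. Per-locus random substreams are derived from the master
seed, so locus i's genealogy does not depend on how many loci are simulated
or in which order — runs are reproducible and prefix-stable.

`simulate_alignment()` evolves JC69 sequences along a gene tree (through
`phangorn::simSeq`), with `scale` converting coalescent-unit branch lengths
to substitutions per site. What the generator does **not** emulate: rate
variation across sites and loci, selection on sequences, alignment error,
gene-tree estimation error. Passing tests on these simulations therefore
validates the counting, testing and calibration machinery — not robustness
to reconstruction artefacts in real data.

## The Wright–Fisher selection check

A persistent worry is that purifying selection might distort gene-tree
topology frequencies and masquerade as asymmetry. `simulate_wf_genealogies()`
replays the standard check on the species tree ((p2,p3),p1): haploid
Wright–Fisher populations with multiplicative fitness (1+s)^k over k
deleterious mutations at a non-recombining locus, irreversible
deleterious-only mutation at rate U per offspring per locus, and defaults
mirroring the strong-selection condition: Ns = −7.5, U = 3 × 10⁻⁷ (high
condition 3 × 10⁻⁵), internal branch 0.01 N generations, tip branches 8 N
generations, p3 at 0.04 N. The simulation is haploid because the claim
under test concerns genealogical distributions, not diploid dosage; the
`ploidy` flag only changes the coalescent-unit conversion. The default
N = 500 keeps the forward simulation desk-scale while preserving the
population-scaled parameters Ns and (per-locus) U as given.

One chromosome per population is sampled per locus and its pedigree traced
backward; the first pair to coalesce determines the rooted triplet
topology. The pedigree is stored only where coalescence is possible (the
internal branch and the ancestral population); through the tip branches,
where each population carries a single sampled lineage, founder indices
are propagated forward instead — an exact reformulation that bounds memory
by N × (ancestral + internal) generations. The ancestral population runs
for 2 N generations before the first split; the chance that the sampled
triplet has not found its first coalescence within that span is ≈ e⁻⁶, and
such loci are reported as `unresolved` rather than forced into a class.

`topology_bias_test()` compares pooled topology counts between two
conditions (3 × 2 chi-square, exact-test fallback for small expected
cells). The replication target is a *negative* result — no significant
shift under selection — together with agreement of the neutral run with
the closed-form concordance probability.

## Closed-form oracles and test design

For an internal branch of length T coalescent units the probability that a
gene tree is concordant is 1 − (2/3)e^(−T) (`expected_concordance()`); at
T = 0 every resolution is equally likely and at large T ILS vanishes. The
test-suite problem sizes were chosen so that every stochastic check has
narrow Monte-Carlo error while staying desk-scale: 10,000 loci per branch
length for the coalescent oracle (binomial SE ≤ 0.005); 100 datasets of 500
gene trees with 500 bootstrap replicates for type-I calibration (the
bootstrap count is scaled down from the 2,000 default, which only affects
the Monte-Carlo error of the SD estimate); 20 replicates of 2,000 loci for
power and attribution at γ = 0.3; 100 replicates of 50 loci per condition
for the selection check; 20 replicates per setting for sCF monotonicity.
JC69 divergence is checked against the closed form
p = (3/4)(1 − e^(−4t/3)).

## Known limitations

* Gene trees are taken as observed; uncertainty in their estimation is not
  propagated (no support-based weighting or collapsing).
* The Δ test localises introgression to a branch but not to a direction,
  and overlapping events can mask one another.
* The bitmask split engine is exact but assumes the taxon set fits the
  packed representation (31 taxa per machine word; larger sets fall back to
  multi-word masks transparently).
* `polytomy_chi2()` is the whole-tree-count approximation of quartet-based
  polytomy tests, as discussed above.
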