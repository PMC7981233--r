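---
title: "Methods: spatial distribution, kinship and parentage in a fenced park population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial distribution, kinship and parentage in a fenced park population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and design choices behind
`anolespat`. The package analyses a closed, fenced lizard population sampled
as seasonal mark–recapture snapshots: every captured animal is sexed,
measured (snout–vent length, SVL, mm), assigned to a numbered perimeter bush,
and genotyped at codominant microsatellite loci. Four questions structure the
pipeline: (1) do home-range sizes differ between the sexes, (2) does range
size scale with body size, (3) is male–male spacing driven by body size or by
relatedness, and (4) is dispersal sex-biased, i.e. do offspring inherit or
leave their parents' ranges?

## Spatial model

**Bush coarsening.** GPS capture fixes carry metre-scale error, so every
capture is coarsened to the geographic centre of the bush of capture. All
distances and ranges are built from bush polygons in a local planar frame
(metres, origin at the southwest fence corner). Two individuals in the same
bush are at distance zero — a floor effect we accept and document rather than
mask.

**Distance metrics.** `bush_distance_matrix()` offers straight-line
centroid distances and a perimeter metric: centroids are projected
perpendicularly onto the fence polyline and the shorter along-fence arc is
taken. The perimeter metric is the default because the open park centre is
not lizard habitat and not a movement corridor; the source observations do
not record which convention the original distance matrix used, so both are
provided and the choice is a flag. Perimeter distances are never smaller
than straight-line ones, a tested invariant.

**Home ranges.** With few recaptures per animal, kernel estimators are not
an option. A home range is the region spanning an individual's farthest
capture points and all area in between: we realise it as the convex hull of
the union of its capture-bush polygons, which is the minimal deterministic
region with that property and accommodates female ranges that cut across the
park interior. A single-bush individual receives that bush polygon as its
range, flagged `single_bush` so analyses can exclude such animals. Areas are
exact (shoelace formula) and log-transformed before modelling, since raw
areas are strongly right-skewed.

**Average distance.** For a focal male in a cohort with $n$ males,
$d' = (d_1 + \dots + d_{n-1})/(n-1)$, the mean distance to every other male.
The mean of all males' $d'$ equals the mean off-diagonal of the male–male
distance matrix; this algebraic identity is tested. $d'$ is computed within
size-class pairs (lightweight–lightweight, heavyweight–heavyweight,
lightweight–heavyweight, the morph cut at SVL ≥ 64 mm) and modelled on class
and cohort; a male-density covariate enters only if a partial-F test at
α = 0.05 improves the model. Because an individual grows, its morph is
evaluated per cohort from that cohort's SVL; one animal can be a lightweight
in spring and a heavyweight a year later.

## Population genetics

**Summaries.** Allele frequencies are gene counts over non-missing calls.
Observed heterozygosity is the fraction of heterozygous individuals; expected
heterozygosity uses Nei's small-sample correction
$(2n/(2n-1))(1-\sum_a p_a^2)$.

**Hardy–Weinberg.** The exact test conditions on allele counts: alleles are
pooled and randomly re-paired, and the p-value is the proportion of pairings
whose conditional probability is no larger than the observed configuration's
(Monte-Carlo, default 999 pairings, +1 correction). Ties count towards the
p-value, which makes the test conservative on very discrete configurations;
the test battery is corrected with the Holm–Bonferroni sequential rule, whose
starting threshold for the eight-locus battery is 0.0065 (i.e. roughly
α/m).

**Linkage disequilibrium.** A genotypic test: the G statistic of the
two-locus genotype contingency table, with a null built by permuting one
locus's genotypes across individuals (default 999 permutations). Pairs
sharing fewer than 10 genotyped individuals are skipped and flagged.

**Kinship.** Pairwise kinship uses the Loiselle et al. (1995) estimator:
with $p_{i,la}$ individual $i$'s dosage/2 of allele $a$ at locus $l$ and
$\bar p_{la}$ the reference frequency,
$$k_{ij} = \frac{\sum_l \sum_a (p_{i,la}-\bar p_{la})(p_{j,la}-\bar p_{la}) + \bar p_{la}(1-\bar p_{la})/(n_l-1)}{\sum_l \sum_a \bar p_{la}(1-\bar p_{la})},$$
where $n_l$ is the number of gene copies sampled at locus $l$ in the
reference. The additive term is the small-sample bias correction; with it,
the estimator centres near zero over unrelated dyads and recovers ≈ 0.25
for parent–offspring and full-sib dyads and ≈ 0.125 for half sibs, which the
test suite checks against simulated pedigrees. Loci missing in either dyad
member drop out of both numerator and denominator for that dyad. The default
allele-frequency baseline is the whole genotyped dataset — with under a
thousand individuals the gain in frequency precision outweighs cohort
specificity — but any reference set (e.g. a single cohort) can be passed via
`reference_ids`.

**Spatial structure.** Autocorrelograms bin dyads into five equal-frequency
(quantile) distance classes — robust to the clumped perimeter geometry,
and the convention of the standard spatial-genetics software when no class
bounds are supplied — and compare each class mean kinship against a
permutation envelope (default 999 shuffles of individuals over the occupied
positions, 2.5/97.5 % quantiles). Class means weighted by pair counts
reproduce the overall mean kinship exactly, another tested identity. Overall
isolation by distance uses a Mantel test: Pearson correlation of
off-diagonals, one-tailed permutation p with a +1 correction. The
heavyweight neighbour contrast (is a territorial male less related to the
males inside his range than to the rest of the cohort?) reports both the
conventional t-test on per-focal differences — kept for comparability even
though dyadic kinship values are not independent — and a neighbour-label
permutation test, which is the inference we recommend.

## Parentage

**Likelihood.** For offspring observed alleles $(u, v)$ at a locus with $K$
alleles, each observed allele is independently mistyped with probability
$\varepsilon$ (default 0.01): $e(a \mid b) = 1-\varepsilon$ if $a=b$, else
$\varepsilon/(K-1)$. Writing $a_P(u)$ for the mean of $e(u \mid \cdot)$ over
a parent's two alleles, the trio likelihood at one locus is
$a_S(u)a_D(v) + a_S(v)a_D(u)$ for heterozygous observations and
$a_S(u)a_D(u)$ for homozygous ones — the exact sum over transmitted alleles
and error events, which factorises by parent and makes candidate evaluation
fast. An unsampled parent contributes $a_{pop}(u) = \sum_b p_b\, e(u \mid b)$.
Mistyping is modelled on the offspring side only; a single-allele mismatch
therefore degrades, but never zeroes, a candidate's likelihood. Candidate
genotypes missing a locus fall back to population terms at that locus, and
offspring missing more than half their loci are skipped with a logged reason.

**Assignment.** For each offspring, every configuration — sire and dam pair,
single sire, single dam, no sampled parent — is weighted by its likelihood
times a prior built from the probability that a true parent is among the
candidates (default 0.5). To keep the evaluation linear in candidates, trios
are evaluated over the top-20 single-parent shortlists per role; the
shortlist size is configurable and in synthetic runs the true parent
essentially never falls outside it. A parent link is assigned from the
best-supported configuration and retained only if the posterior probability
that *no sampled parent of that role exists* falls below 0.05 — our
operationalisation of the "retain links with p < 0.05" rule, since the
reference software's internal p-value is not documented. Candidates with
exactly tied support refuse assignment: conservative and deterministic.

**Sequential stacking and consensus.** Cohorts are processed
chronologically; at step $k$ the offspring are the individuals first seen in
cohort $k$ and the candidates are everyone seen in cohorts $1..k$ (males as
sires, females as dams). Accepted links become fixed "known parentage"
priors and are never revisited. The whole procedure runs in triplicate with
distinct seeds; each replicate re-masks a random 1 % of genotype calls
(matching the assumed genotyping-error rate) before running, so a link that
hinges on one or two possibly erroneous calls will not survive all three
runs. The consensus pedigree keeps links recovered in every replicate; it is
by construction a subset of each replicate, and in simulation its precision
exceeds each single run's. Setting the perturbation to zero makes the
engine fully deterministic, in which case the three replicates and the
consensus coincide — useful for debugging and tested as such. Because the
re-masking is a small random perturbation, the consensus-vs-replicate
precision ordering is a statistical, not a logical, guarantee; across
simulated parks it holds in the clear majority of runs, with occasional
one-link ties.

**Inbreeding.** $F$ of an individual is the kinship of its two parents over
the known pedigree, computed by the recursive tabular method with unknown
parents treated as unrelated founders; a path-counting oracle validates the
recursion on random four-generation pedigrees. The cohort trajectory reports
the mean and sd of $F$ over all individuals with two assigned parents after
each sequential step. Note this is a *pedigree-depth-limited* quantity: with
founders assumed unrelated it starts near zero and grows only as deep
pedigrees accumulate, so it measures how inbreeding signal builds with
sampling, not the absolute inbreeding of the real population.

## Home-range inheritance

An offspring is "inside" a parent's range if any bush in which the offspring
was ever captured intersects the parent's all-cohort home-range polygon
(touching counts). The parent's range is its all-cohort hull by default — the
natural reading when breeding cohorts are unknown — with a per-cohort
variant available. Counts are tabulated per parent-role × offspring-sex, as
raw offspring counts and additionally averaged per parent (both are
reported because either reading of "percentage of its offspring" is
defensible); each role's inside/outside × offspring-sex 2×2 table gets a
Yates-corrected chi-square, $\sum (|O-E|-0.5)^2/E$ in its classical
(unclamped) form, with Fisher's exact test added as a robustness check
whenever an expected cell is below 5.

## The synthetic park

`simulate_population()` provides ground truth for every stage. It emulates:

* a 100 × 100 m fenced park with 38 rectangular bushes, 2 m deep, random
  lengths 5–9 m, placed with ≥ 0.5 m gaps along the four walls;
* 8 loci with 13–33 founder alleles, frequencies drawn from a symmetric
  Dirichlet(1) — high polymorphism without extra parameters;
* ten seasonal cohorts (spring/fall over five years), ~150 founders and
  on the order of 800 unique individuals;
* polygynous mating: a female's offspring is sired by her bush's resident
  heavyweight with probability 0.8, otherwise by a random lightweight
  "sneaker";
* growth as a truncated-normal seasonal SVL increment (males mean 8 mm, sd
  2, asymptote 72 mm; females 6/2/60), so the lightweight-to-heavyweight
  transition and with it territory acquisition *emerge* from growth;
* territories: exactly one bush per heavyweight, claimed at the morph
  transition (largest SVL first, ties by earlier id; spacing preference for
  the free bush farthest from existing territories) and held for life;
* dispersal: daughters settle in the natal bush with probability 0.8, sons
  with probability 0 by default; dispersing sons additionally avoid, for
  life, any bush inside their father's home range, and a claiming male will
  not take a bush that would pull a dispersed son's bush inside his own
  range. This structural sire–son exclusion is the generator's form of
  "male offspring are forced out of the father's territory"; switching
  `sire_range_avoidance` off (together with equal stay probabilities and no
  female ranging) yields the sex-symmetric null used to check that the
  inheritance chi-square stays calibrated;
* observation: per-season capture probability 0.85, per-allele mistyping
  1 %, 2 % missing calls.

Demographic rates (survival 0.6 per season, Poisson fecundity 2.3 recruits
per adult female per season, maturity at 45 mm) are modelling assumptions
chosen to hold the population near stationarity at the study's scale; they
are not estimates of any real population. What the simulator does *not*
emulate: within-season movement, density-dependent vital rates, null alleles
or allele homoplasy, immigration through the fence, or observation
heterogeneity among bushes. Passing the recovery tests therefore shows the
estimators are correct under the stated model, not that real data meet that
model.

## Numerical and testing choices

* Probabilities in the parentage engine are accumulated in log space; the
  no-parent configuration anchors the posterior normalisation.
* Ties: equal-SVL territory contests break by earlier individual id;
  equal-support parent candidates refuse assignment; permutation p-values
  use the +1 finite-sample correction and count ties conservatively.
* Degenerate inputs are flagged rather than silently dropped: constant
  matrices in Mantel tests, single-male cohorts in $d'$, one-sex range sets,
  monomorphic loci.
* Geometry is validated against independent oracles (fan-triangulation
  areas, dense 1 mm fence sampling for perimeter distances, loop-mean $d'$).
* Test problem sizes are chosen for tight feedback: calibration checks use
  1,000 null replicates at 199 permutations each; estimator-recovery checks
  use 200-individual references and 300 dyads per relationship class; the
  end-to-end parentage check runs the full default park once and the
  dispersal checks run twenty reduced-observation replicates. The
  dispersal contrast in the acceptance checks is evaluated on the
  simulator's true pedigree so that it isolates the spatial inference from
  parentage-assignment error.

## Known limitations

* The parentage engine is a pairwise/trio categorical-allocation likelihood;
  it does not reconstruct sibships jointly, so half-sib families with no
  sampled parent contribute nothing, and a sampled close relative of an
  unsampled true parent is the dominant error mode (typically ~3–4 % of
  consensus links in simulation).
* Hand-drawn range polygons of the original field workflow are not exactly
  reproducible; the convex-hull definition is deterministic but can only
  approximate them, and for perimeter-hugging capture sets it covers
  interior area no lizard uses.
* The GPS error statement in the source data ("0.08 % ≈ ±1.30 m") has no
  stated reference length; the package records raw coordinates but bases no
  analysis on them.
* Reported F-trajectories depend on pedigree depth and sampling; comparing
  absolute values across studies with different candidate coverage is not
  meaningful.
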