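---
title: "Methods: scanning a strain phylogeny for co-diversification versus geography"
author: "codivscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning a strain phylogeny for co-diversification versus geography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the statistic

Host-associated bacterial strains whose phylogeny mirrors the host
phylogeny may have co-diversified with their hosts through partner
fidelity, or may simply reflect isolation by distance: host populations
that are phylogenetically close are often geographically close, and
bacterial gene flow may be limited by distance rather than by host
identity. Because host phylogeny and host geography are correlated
predictors, each bacterial clade must be tested against both.

`codivscan` operationalises this as a per-node Mantel scan. Let $D$ be the
patristic distance matrix among a clade's strains. For the same strains we
build two reference matrices: $H_{ij}$, the patristic distance between the
*host taxa* of strains $i$ and $j$ on the host tree (0 for conspecific
hosts — hosts, not individuals, are the phylogenetic unit), and $G_{ij}$,
the great-circle distance between their sampling *sites* (0 for
same-site strains — sites are the unit of geography). The test statistics
are the Mantel correlations

$$ r_\text{phylo} = \mathrm{cor}\big(\mathrm{ut}(D), \mathrm{ut}(H)\big),
\qquad
r_\text{geo} = \mathrm{cor}\big(\mathrm{ut}(D), \mathrm{ut}(G)\big), $$

Pearson correlations over strictly-upper-triangle entries, and their
difference $\Delta = r_\text{phylo} - r_\text{geo}$: positive when a
clade's diversification tracks the host tree more than the map, negative
in the opposite case.

## Which clades are tested

Only clades in the *distal tenth* of the strain phylogeny are tested:
internal nodes whose maximum within-clade tip-to-tip distance is at most
10 % (inclusive) of the tree-wide maximum tip-to-tip distance. This
windows the test onto recent diversification at the timescale of host
speciation; the fraction is the `max_diameter_fraction` control. All
qualifying nodes are tested, including nested ones — overlap is handled
only when branch-length fractions are computed, where the *union* of edges
is taken so nothing is double-counted. By convention a clade's branch
length includes the edge subtending its root (that edge carries history
unique to the clade); `include_stem = FALSE` switches this off, and both
the per-clade weights and the fraction computation honour the switch.

Two further testability floors are applied (the clade-size and
degeneracy conventions are not dictated by the statistic itself, so we
state ours): a node needs at least `min_tips = 6` tips, which guarantees
$6! = 720$ distinct permutations so a 1000-draw permutation null is not
degenerate, and at least 2 distinct host taxa (respectively sites) for the
corresponding test; below that, or when a reference triangle is constant,
the node is flagged *untestable* for that side. Untestable results are
excluded from the multiple-testing family rather than being assigned
$p = 1$ — they carry no evidence either way.

## The permutation test and multiple testing

Significance is assessed by jointly permuting the rows and columns of the
reference matrix (equivalently, relabeling which strain carries which
host/site), recomputing $r$, and counting permutations at least as extreme
as the observed value:

$$ p = \frac{1 + \#\{r_\pi \ge r_\text{obs}\}}{1 + N}, \qquad N = 1000 . $$

The test is one-tailed (greater) because co-diversification and
isolation-by-distance both predict *positive* association; the $+1$
correction keeps $p > 0$; ties count toward the numerator (conservative).
Ties are detected with a $10^{-9}$ tolerance so that floating-point jitter
in permuted correlations of discrete-valued references does not silently
drop exact ties.

P-values are Benjamini–Hochberg corrected across all tested nodes,
*separately* for the host-phylogeny family and the geography family. The
families could instead be pooled; separate correction matches reporting
significance calls per reference and is the package's convention.

Classification uses $r > 0.7$ with BH $q < 0.05$ for each side;
`phylo_independent_of_geo` additionally requires $\Delta > 0.5$ and a
non-significant geography test ($q_\text{geo} > \alpha$), mirrored for
`geo_independent_of_phylo`; both-significant clades with $|\Delta|$ at or
below threshold are `both`. All thresholds are `scan_control()` parameters.

### Reproducibility of the permutation streams

One master seed is supplied; each node's permutation stream is seeded by a
stable 31-fold hash of (master seed, node identifier, reference tag),
where the node identifier is itself a hash of the *sorted* tip-label set.
Results are therefore byte-identical across runs and invariant to the
order in which nodes are visited, to tip ordering inside the Newick file,
and to row order of the metadata table.

## Sympatry fidelity test

Clades containing strains from both host genera at a shared site allow a
sharp test: under partner fidelity a strain should remain closer to
strains from congeneric hosts at *other* sites (allopatric) than to
strains from the heterogeneric host it shares a site with. For each strain
whose site hosts both genera we compare minimum patristic distances to the
two comparator sets; minimum (nearest neighbour) rather than mean distance
is the distance-matrix analogue of asking who a strain's closest relative
is, and a mean-based variant is available (`use_mean = TRUE`). Strains
with an empty comparator set are not evaluated; a clade with no evaluable
strain is `not_applicable`. The clade verdict is unanimous by default
(`host_faithful` only when *every* evaluated strain is faithful), matching
the all-or-nothing character of the question; a majority rule is available
behind a flag. Ties ($A = B$) count as not faithful and are flagged.

## Taxon-level summaries

Clades are assigned to a bacterial phylum or genus only when all their
tips agree at that rank. Per-taxon centroids are branch-length-weighted
means of $(r_\text{geo}, r_\text{phylo})$, each tested node weighted by
its clade branch length; nested nodes overlap in these weights — no
de-overlap rule is imposed — and a union-weight alternative can be
obtained by computing weights via `significant_branch_fraction()` on each
taxon's nodes. An excess of taxa with $r_\text{phylo} > r_\text{geo}$ is
tested with an exact sign test, one-sided (greater) by default since
partner fidelity predicts the excess direction; the two-sided exact test
is available via `alternative = "two.sided"` (for 99 successes out of 156
the two-sided value is the one that prints as 0.001 at 3 decimal places;
the one-sided tail is 0.0005).

Between-phylum comparisons of per-genus mean $\Delta$ use a weighted
Welch t-test with reliability weights: weighted means and variances,
effective sample sizes $n_\mathrm{eff} = (\sum w)^2 / \sum w^2$ and
Satterthwaite degrees of freedom, so equal weights recover the ordinary
Welch test exactly and rescaling all weights changes nothing. Each genus
is weighted by its *unique branch length* — the total branch length of the
minimal subtree spanning the genus's tips, edges counted once. All phylum
pairs with at least 5 genera are compared and Holm-corrected.

Lifestyle-trait effects (oxygen class, spore formation) on a genus's
maximum $\Delta$ are tested with a simulation-based phylogenetic ANOVA:
the observed one-way $F$ is compared to $F$ values from Brownian-motion
simulations of the trait on the genus-level tree, with the BM rate
estimated from the data by maximum likelihood
($\hat\sigma^2 = (x-\hat\mu)^\top C^{-1} (x-\hat\mu)/n$ with the GLS mean
$\hat\mu$ and phylogenetic covariance $C$), and
$p = (1 + \#\{F_\text{sim} \ge F_\text{obs}\})/(1 + N)$. On a star tree
the simulations are i.i.d. normal draws and the p-value converges to the
ordinary ANOVA p, which the test suite checks.

## The synthetic generator: what it emulates and what it does not

The generator produces complete datasets with ground-truth regime labels,
default 20 clades per regime:

* **codiv** — the clade topology *is* the host tree rescaled to the target
  clade diameter, each host taxon contributing `strains_per_host_taxon`
  (default 3) tips attached with $|\mathcal N(0, \sigma)|$ branch lengths;
  sites are drawn uniformly from the taxon's range. Zero noise and one
  strain per taxon give $r_\text{phylo} = 1$ exactly.
* **geo** — a site tree built by average-linkage clustering of the
  haversine site matrix perturbed by symmetric normal noise (default
  50 km); strains attach at their site's tip and take a host taxon
  uniformly from the site's occupants, so host identity is decoupled from
  the tree and sympatric heterogeneric strains are nearest neighbours — a
  true negative control for partner fidelity.
* **random** — a random bifurcating topology with exponential branch
  lengths; host and site assignments uniform (site within the host's
  range). Scan p-values on these clades are approximately uniform.

The default host tree is a fixed six-taxon, two-genus clade (three
chimpanzee-like subspecies plus a bonobo-like sister under one genus; two
gorilla-like species under the other) with the genera at patristic
distance 4.0 versus 0.3–1.2 within genera; the 17 default sites span
equatorial-African-like coordinates, with three western sites and one
eastern site hosting taxa of both genera (sympatry). These are documented
constants of the generator, not measured values. The default tip noise is
$\sigma = 0.05$ clade diameters — small relative to the shallowest host
split so that regime recovery is expected, but non-zero so the scan is not
tested only at a degenerate optimum.

Clades are grafted onto a *star* backbone with stem length
`backbone_scale = 12` clade diameters. Since the only internal node
touching backbone edges is then the root, whose diameter is the whole
tree's, exactly the simulated clades (roots and their internal nodes) can
qualify for the distal-tenth window; assembly verifies the 10 % separation
and raises a configuration error naming any violating clade.

What the generator does **not** emulate: sequence-level evolution and tree
estimation error; topological discordance within clades (noise enters as
branch-length perturbation, chosen for reproducibility); uneven sampling
effort across hosts and sites; incomplete strain recovery; and
recombination or host switching within a regime. Passing the recovery
tests therefore demonstrates that the scan's statistics behave correctly
under the generative assumptions, not that real MAG datasets are free of
these complications.

## Numerical choices and problem sizes

* Earth radius fixed at 6371.0 km (mean radius; configurable). The radius
  rescales all geographic distances jointly and cannot change any Mantel
  correlation.
* Missing branch lengths in Newick input are an error by default
  (`assume_zero_lengths = TRUE` maps them to 0); silent zeros would
  corrupt the distal-tenth criterion.
* Exhaustive-enumeration cross-checks of the permutation p use all $n!$
  joint relabelings for clades of up to 7 tips; the sampled estimator is
  required to agree within 2 Monte-Carlo standard errors at 10,000 draws.
* Calibration checks use 500 null clades at 999 permutations (raw-p
  rejection within 3 binomial SE of 5 %), regime-recovery checks the
  default 60-clade dataset at 1000 permutations, and the star-tree ANOVA
  reduction uses 40 tips and 10,000 simulations; the full suite runs in a
  couple of minutes on one core.
* Weighted-variance denominators use $n_\mathrm{eff}/(n_\mathrm{eff}-1)$
  so the equal-weight case is exactly unbiased.

## Known limitations

* The Mantel scan tests association, not directionality or event history;
  no cophylogenetic reconciliation (duplication–loss–switch) is attempted.
* Geographic distance is straight great-circle; habitat or least-cost
  paths are out of scope.
* Host distances are taken between host taxa, not individuals; any
  within-taxon host structure is invisible to the test.
* With heavily nested significant clades, centroid weights deliberately
  overlap; interpretations that require disjoint weights should use the
  union-based branch fractions instead.
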