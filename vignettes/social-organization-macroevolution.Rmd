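---
title: "Modeling transitions among primate social organization states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling transitions among primate social organization states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primsoc)
```

## The scientific problem

Primate species organize themselves in strikingly different ways: roughly a
third of species are solitary, about a fifth live in male--female pairs, and
the rest form unimale or multimale groups. How lineages moved among these
states -- in particular whether pair living arose from solitary or from
group-living ancestors -- is a long-standing controversy, because the two
routes implicate different selective forces (female spacing versus pair
bonds dissolving out of groups). `primsoc` implements the comparative
machinery needed to address the question on a dated phylogeny: constrained
Markov models of discrete trait evolution, Bayesian and information-theoretic
model comparison, reversible-jump search over model structures, ancestral
state reconstruction with stochastic character mapping, phylogenetic signal
statistics, and a taxon-subsampling robustness experiment. A synthetic-data
module generates trees and trait histories with known ground truth so that
every stage of the pipeline is testable without any external data.

## The Mk model and the candidate transition structures

A K-state social-organization character evolves along the tree as a
continuous-time Markov chain with instantaneous rate matrix $Q$, whose
off-diagonal entries $q_{ij} \ge 0$ are transition rates in events per
million years and whose rows sum to zero. The likelihood of the tip data is
computed by Felsenstein's pruning algorithm with per-node rescaling;
transition kernels $P(t) = e^{Qt}$ are computed by eigendecomposition when
$Q$ is diagonalizable to working precision and by scaling-and-squaring Padé
approximation otherwise (some non-reversible structures in the catalog can
be defective). Polymorphic species enter either as admissible-state sets
(indicator tip partials, the default for likelihood and Bayesian fits) or as
probability weights (two recorded states mean $P_1 = P_2 = 0.5$, the
convention for stochastic mapping).

A *model specification* assigns each ordered off-diagonal cell of $Q$ to a
rate class or to a structural-zero class. The catalog contains the six
candidate structures compared in the literature on primate social
organization, with their free-parameter counts on the four-state
(S, P, UM, MM) scheme:

```{r catalog}
s4 <- state_space("four")
for (nm in c("ER", "SYM", "ARD", "IC", "SHULTZ", "RJ_DERIVED")) {
  cat(sprintf("%-11s %2d free rates\n", nm,
              n_free_rates(model_catalog(nm, s4))))
}
print(model_catalog("RJ_DERIVED", s4))
```

`IC` ("increasing complexity") permits only the ladder S--P--UM--MM. The
`RJ_DERIVED` structure differs by routing pair living directly to multimale
groups (S--P, P--MM, MM--UM, all reversible): pair living is a stepping stone
between solitary living and group living. `SHULTZ` encodes the competing
hypothesis of group-first evolution (S to MM, MM to P and UM), with the
constraint that solitary living is never regained. The published text for
that model names arrows whose count is ambiguous against its printed
four-parameter size; the catalog fixes the four-arrow reading consistent
with the parameter count and exposes `SHULTZ_5` (adding P to MM) for
sensitivity checks. On the three-state scheme the RJ-derived structure
coincides with IC, and the "modified" Shultz structure is S to G, G to P.

## Fitting, model comparison, and priors

`fit_ml()` maximizes the pruning likelihood over non-negative rates in log
space (L-BFGS-B) after a coarse shared-rate scan that places the starting
scale near the optimum; one-parameter models are additionally profiled with
a golden-section search. The scan matters: on saturation plateaus
(`rate` $\to \infty$) the boxed optimizer can otherwise accept a single
step to the bound. `fit_models()` warm-starts SYM from ER and ARD from SYM,
which guarantees the nested likelihood ordering
$\log L_{ARD} \ge \log L_{SYM} \ge \log L_{ER}$. Akaike weights follow
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$.

Bayesian fits use Metropolis--Hastings on log rates with an exponential
prior whose mean is either fixed or hierarchical: mean $m \sim U(0, 10)$,
rates $\sim \mathrm{Exp}(1/m)$, with $m$ resampled by MH (the "exp (0 10)"
convention of multistate Bayesian software). Marginal likelihoods come from
stepping-stone sampling: stones at quantiles of a Beta(0.3, 1) distribution
between prior ($\beta = 0$) and posterior ($\beta = 1$), each power
posterior sampled by a chain warm-started from its cooler neighbor, and the
marginal likelihood assembled from the standard stepping-stone identity. A
model with no free rates needs no integration and returns its likelihood
exactly. Log Bayes factors are $2(\log ML_1 - \log ML_2)$, interpreted on
the conventional scale (below 2 weak, 2--5 positive, 5--10 strong, above 10
very strong).

## Reversible-jump search over structures

`rj_mcmc()` samples jointly over (partition of the rate cells into classes
plus a structural-zero bin, class rates). Moves reassign one cell to the
zero bin, an existing class, or a fresh class whose rate is drawn from the
rate prior -- with prior-draw births the rate-prior densities cancel in the
acceptance ratio, leaving the likelihood ratio and a menu-size Hastings
correction. Two design choices deserve comment:

* **Structure prior.** A prior uniform over raw configurations is dominated
  by the Bell-number growth of many-class partitions: the prior probability
  that any given cell is structurally zero is only about 0.14 for twelve
  cells, and sparse structures can never become modal. The package instead
  uses a prior uniform over strata defined by (number of zero cells, number
  of classes) and uniform within each stratum (stratum sizes
  $\binom{n}{z} S_2(n-z, k)$), which weights model dimensions evenly --
  the behavior that lets reversible-jump searches concentrate on sparse
  structures.
* **Rate scale.** The U(0, 10) hyperprior on the exponential mean is not
  scale-free: it is calibrated for rates of order 0.1--10 per unit branch
  length. Trees dated in millions of years put primate social-organization
  rates near 0.02/My, where the adapted hyperprior mean nearly removes the
  Occam penalty that distinguishes a structural zero from a merely small
  rate. Analyses that feed dated trees to `rj_mcmc()` should rescale them
  to unit root depth first (the recovery experiments below do exactly
  that); likelihood-based stages are invariant to this except for the
  units of the reported rates.

Structures are reported as canonical model strings (`"A Z Z A ..."`,
row-major cell order, classes lettered by first appearance, so relabeling
classes never changes the string), ranked by posterior frequency; the
zero-pattern table aggregates over class partitions.

## Ancestral states and stochastic mapping

`marginal_asr()` computes marginal posterior state probabilities at every
internal node by the standard two-pass (rootward/tipward) algorithm,
equivalent to re-rooting at each node for reversible models; reporting
nodes are addressed as MRCAs of named tips since node numbers are
tree-dependent. `stochastic_map()` draws complete character histories:
node states by backward pruning and forward sampling, tip states from their
probability weights, and branch paths conditional on endpoints by
uniformization (dominating rate $\Lambda = \max_i |q_{ii}|$, bridge-sampled
jump chain, uniform order-statistic jump times). Uniformization was chosen
over naive forward simulation with rejection, which stalls on long branches
with constrained endpoints; the rejection sampler survives in the test
suite as a cross-check. Realized transition counts and dwell times
summarize over maps, and histories serialize to SIMMAP-annotated Newick
(segments tipward-first, the phytools dialect). Supplying a posterior tree
sample distributes maps evenly across trees.

## Phylogenetic signal

Three statistics cover the conventions in this literature. Blomberg's K
(through \pkg{picante}'s implementation, with tip-shuffle randomization of
the contrast variance; negative z means signal) requires a numeric coding
of the categorical trait, which the literature leaves unstated; the default
is the ordinal complexity rank S=1, P=2, UM=3, MM=4 (three-state S=1, P=2,
G=3), configurable and recorded in every result -- published K values for
this trait therefore are not exact reproduction targets. Pagel's lambda for
the discrete character jointly maximizes over $\lambda \in [0,1]$ (internal
branches scaled, terminal branches extended to preserve root-to-tip depths)
and the base model's rates, with a 1-df likelihood-ratio test against
$\lambda = 0$ and AICc using $k$ = free rates + 1 and $n$ = tips (each tip
is the sampling unit). The Fritz--Purvis D statistic for binary traits
scales the observed sum of sister-clade differences in nodal values
(unweighted daughter means) between a threshold-Brownian expectation (D = 0)
and a tip-shuffle expectation (D = 1); the Brownian null thresholds
simulated Brownian values at the observed prevalence, and both nulls use
the same nodal estimator as the observed statistic, which is what makes the
statistic self-calibrating. Reported p values are lower-tail rank
probabilities with add-one smoothing.

## The synthetic-data generator

`simulate_tree()` draws constant-rate birth--death trees conditioned on the
number of extant tips and rescales them to root depth 70 (a primate-like
crown age in My). `simulate_trait()` evolves the character by exact
Gillespie simulation down every branch, recording the full realized history
-- the ground truth against which mapping and counting are tested -- and
`inject_uncertainty()` makes a chosen fraction of taxa polymorphic by
adding a state adjacent under the generating model, emulating intraspecific
variability. What the generator does *not* emulate: correlation between
diversification and the trait (state-independent birth--death), fossil or
non-ultrametric sampling, and classification error beyond the polymorphism
mechanism -- so passing tests demonstrate correctness of the inference
machinery, not robustness to those real-data complications.

The validation battery fixes these study conditions (chosen once, stated
here as the package's own design):

* **Likelihood oracle:** 200 random fixtures of at most 6 tips across the
  whole catalog, compared with brute-force enumeration over internal-node
  assignments to $10^{-10}$.
* **Stepping-stone oracle:** one- and two-parameter toys on a 4-tip tree
  with a fixed-mean exponential prior, compared with numeric quadrature
  (tolerances 0.1 and 0.15 log units; repeated-run SD under 0.15).
* **Mapping consistency:** on a 5-tip fixture, mean mapped transition
  counts over 10,000 maps against analytic expected counts obtained by
  enumeration plus Simpson quadrature, within 3 Monte Carlo standard
  errors.
* **Recovery:** ten replicates of 362-tip, depth-70 birth--death datasets
  (birth 1, death 0.5/My) generated under the four-state RJ-derived
  structure with rates 0.024--0.03/My chosen to give a near-balanced
  stationary distribution (0.27/0.22/0.25/0.26) -- balanced occupancy keeps
  all twelve rate cells informed, which is what makes exact structure
  recovery a fair ask at this scale -- root states drawn from that
  stationary distribution. ML/AICw must rank the generating structure or
  its SYM superset first in at least 7/10; the reversible jump (30,000
  iterations, 8,000 burn-in, thin 10, on unit-depth-rescaled trees) must
  make the generating zero pattern modal in at least 6/10.
* **Signal calibration:** D near 0 (mean within 0.15 over 20 replicates)
  on threshold-Brownian traits and near 1 (within 0.2) on shuffled traits,
  on 200-tip trees; lambda at least 0.9 (median over 10 replicates) with
  significant LRTs on conserved simulated traits. After shuffling, the
  lambda profile is nearly flat and the point estimate is weakly
  identified -- a known property of discrete-trait lambda under no signal
  -- so the calibrated check is LRT non-significance in most replicates,
  with the median estimate merely bounded away from the strong-signal
  regime.

Desk-scale MCMC defaults (500k iterations, 100k burn-in, thin 100; the
tests use smaller explicit settings listed above) replace the much longer
production runs used historically for this problem; the posterior for at
most 12 rates on a few hundred tips mixes in a small fraction of that.

## Numerical choices and degenerate inputs

Rates are optimized in log space with a floor of $10^{-9}$; structurally
impossible data return $-\infty$ with a warning rather than an error;
near-zero node marginals are renormalized with a warning. Root priors:
uniform (default), stationary, FitzJohn (data-derived weights), or a fixed
vector. Trees without branch lengths get unit lengths with a warning.
Subsample sizes use round-half-up, fixed by the published scheme sizes
(75% of 362 is 272). The subsampling RNG is partitioned per scheme, so
adding a scheme never changes earlier draws under the same seed; replicates
whose subsample lacks trait variation are redrawn and logged. Effective
sample sizes below 200 and MH acceptance rates outside (0.05, 0.95) produce
warnings.

## Known limitations

The package fits state-independent models only (no trait-dependent
diversification, hidden-rate, or correlated-character models); the
reversible-jump results inherit the usual prior sensitivity of Bayesian
structure selection (mitigated, not removed, by the stratified structure
prior); K for a categorical trait depends on an arbitrary numeric coding;
and the taxon-name join between tree and table is exact (whitespace
normalized to underscores) by design, to keep merges auditable.

## A minimal worked run

```{r worked, eval = FALSE}
states <- state_space("four")
spec <- model_catalog("RJ_DERIVED", states)
q <- build_q(spec, c(0.024, 0.03, 0.03, 0.025, 0.025, 0.024))
tree <- simulate_tree(100, seed = 1)
d <- simulate_trait(tree, q, root_state = "stationary", seed = 2)

fits <- fit_models(tree, d$tip_states,
                   c("ER", "SYM", "ARD", "IC", "SHULTZ", "RJ_DERIVED"),
                   states, seed = 3)
aic_table(fits)

maps <- stochastic_map(tree, d$tip_states,
                       build_q(spec, fits$RJ_DERIVED$rates),
                       n_maps = 1000, seed = 4)
summarize_transitions(maps)$mean_counts
```
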