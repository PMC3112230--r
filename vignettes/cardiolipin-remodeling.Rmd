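---
title: "Inferring cardiolipin remodeling mechanisms from steady-state lipidomic profiles"
author: "clremodel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cardiolipin remodeling mechanisms from steady-state lipidomic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clremodel)
```

## The scientific problem

Cardiolipin (CL) is the signature phospholipid of the inner mitochondrial
membrane. Unlike ordinary diacyl phospholipids it carries four acyl
chains, at positions conventionally labeled sn-1, sn-1′, sn-2 and sn-2′.
After de novo synthesis CL is extensively remodeled through the Lands
cycle: chains are removed by phospholipases and replaced by chains taken
from acyl donors — the sn-2 position of phosphatidylcholine (PC) and
phosphatidylethanolamine (PE), phosphatidylglycerol (PG), and the acyl
CoA pool. Which chains end up in CL, and with what frequencies, shapes
mitochondrial bioenergetics and is perturbed in Barth syndrome, heart
failure and tumors.

Shotgun lipidomics quantifies CL as *mass peaks*: species distinguished
only by the total number of acyl carbons and total double bonds over the
four chains (a peak like 72:8 pools every isomer whose chains sum to 72
carbons and 8 double bonds). The inference problem this package solves
is: given a sample's CL peak profile and the chain compositions of its
acyl donor classes, what remodeling mechanism is consistent with the
data?

The analysis is a two-step interrogation of steady-state profiles:

1. **Positional question.** Are the four chain positions independently
   and identically remodeled? Under the IID model a CL isomer carrying
   chains $\alpha_i,\alpha_j,\alpha_k,\alpha_h$ has probability
   $P(\alpha_i)P(\alpha_j)P(\alpha_k)P(\alpha_h)$ for a single
   per-position chain distribution $P$, and a mass peak $(c,d)$ collects
   every ordered 4-tuple with total carbons $c$ and total double bonds
   $d$ — i.e. the peak distribution is the 4-fold convolution of $P$
   over the $(c,d)$ lattice. The IDD variant allows one distribution for
   the sn-1/sn-1′ pair and another for sn-2/sn-2′.
2. **Donor question.** Is the inferred CL chain composition explained by
   head-group-proportional donation,
   $P_{CL}(\alpha) = \sum_c W_c f_c(\alpha)$, where $f_c$ is donor class
   $c$'s chain composition and the weights $W_c \ge 0$, $\sum_c W_c = 1$
   measure each class's contribution? If so, remodeling enzymes select
   donors by head group, not by chain length or saturation.

## Fitting the positional models

`fitIID()` minimizes the squared error between the model peak
distribution and the observed peak values over the observed peak set.
Assuming independent Gaussian measurement errors with a common variance
across peaks — reasonable when one platform quantifies all CL species —
this least-squares estimate is the maximum-likelihood estimate.

Numerical choices that matter:

* **Simplex constraints.** The chain probabilities are optimized under
  $p_i \ge 0$, $\sum_i p_i = 1$ through the smooth reparameterisation
  $p_i = x_i^2 / \sum_j x_j^2$ with analytic gradients, solved by
  L-BFGS-B. The objective convergence factor is `factr = 10` (about
  2e-15 relative tolerance) with at most 2000 iterations; a stalled line
  search at that precision is accepted as convergence. Final iterates
  are renormalized exactly onto the simplex.
* **Initialization.** The uniform distribution, deterministically. An
  optional seeded multi-start (`restarts > 0`, Dirichlet(1) draws)
  probes local minima but is off by default so that repeated runs are
  bit-identical.
* **Objective domain.** The model is compared with the data only on the
  observed peak set; model mass falling on unmeasured peaks is reported
  as `unassignedMass` but never renormalized away, and never penalized.
  Peaks recorded at zero concentration participate like any other peak,
  while observed peaks unreachable from the candidate chain support
  raise a warning and contribute their squared observed value to the
  error.
* **IDD starts.** Because IID is the equal-pair special case of IDD, the
  IDD optimum can never be genuinely worse. Gradient descent alone does
  not guarantee this — the uniform start is a symmetric stationary point
  — so `fitIDD()` polishes from three deterministic starts: uniform, an
  antisymmetric tilt (to break the sn-1/sn-2 exchange symmetry), and the
  IID solution duplicated at both pairs. The best optimum is kept, which
  enforces the nesting property by construction.
* **Fit quality.** Each fit reports the squared error and the Pearson
  correlation between predicted and observed peak values; a sample
  counts as *explained* when $r > 0.7$. The correlation of identical
  vectors is defined as 1 (covers the perfect single-peak fit); any
  other zero-variance comparison is reported as undefined (`NA`).

The candidate chain types are those observed with positive probability
in any donor pool of the sample (`chainSupport()`), since donated chains
must come from somewhere.

## Fitting the proportional-incorporation model

`fitProportional()` regresses the IID-fitted CL chain composition on the
donor compositions under the simplex constraints — a convex quadratic
program in at most 4 weights. It is solved *exactly* by active-set
enumeration: for each nonempty subset of donor classes allowed nonzero
weight, the equality-constrained least-squares KKT system is solved and
the best feasible candidate kept. The CL composition used is the IID fit
rather than a direct measurement, because per-position CL chain
compositions are not measured by the peak-level platform. Chains are
aligned on the union support with zeros imputed, every chain weighted
equally. The sum-to-one constraint is imposed so that weights read as
fractions of donated chains.

Per-chain residuals (CL minus fitted mixture) sum to zero by
construction; a positive residual flags a chain in excess in CL over
proportional donation, i.e. a candidate substrate of a chain-selective
enzyme. When donor compositions are affinely dependent the weights are
not unique; the fit carries a `nonUnique` flag instead of pretending
otherwise.

## Validation machinery

* **Cross-validation** (`crossValidateCL()`): peaks are randomly split
  into 4 folds of near-equal size; each fold is predicted from a model
  fit to the others; held-out predictions are merged and correlated with
  the observed values, giving one $r$ per run, with 3 independently
  randomized runs by default. Held-out predictions are compared
  unnormalized — Pearson correlation is location/scale invariant, so no
  renormalization of partial fits is needed.
* **Label permutation** (`labelPermutationTest()`): the null datasets
  shuffle concentration values across peak keys, severing the link
  between a peak's identity and its value. Three permuted datasets are
  cross-validated (3 runs each) and compared with the real data's CV
  correlations by a one-tailed Welch t-test (real greater). The number
  of permuted datasets is configurable; 3 datasets with 3 runs each is
  the default protocol. A comparison in which both groups are constant
  (e.g. all-equal concentrations, where permutation is a no-op) raises
  a classed degenerate-case error rather than fabricating a p-value.
* **Donor permutation** (`donorPermutationTest()`): each donor pool's
  probabilities are independently shuffled across chain labels, the
  weights refit, and the fit correlation recorded; 10000 permutations by
  default. The empirical p-value uses the add-one correction
  $p = (1 + \#\{r_{null} \ge r_{obs}\})/(n+1)$, so it is bounded away
  from zero; the raw exceedance count is reported alongside.
* **IDD vs IID** (`compareIDDvsIID()`): both models are cross-validated
  and the per-run correlations compared with a two-sided Welch t-test
  (the direction of a genuine difference is not assumed); identical
  score sets give $p = 1$.

All randomized procedures require an explicit seed and derive
independent sub-streams from it, so a pipeline run is reproducible
bit-for-bit.

## Residual analysis across samples

`residualMatrix()` stacks per-sample proportional residuals on the union
chain set (chains absent from a sample's support are missing, not zero).
`chainResidualCorrelation()` computes pairwise squared Pearson
correlations ($R^2$) over shared samples — chains whose residuals co-vary
across samples plausibly respond to the same selective enzyme — and
`clusterChains()` clusters chains agglomeratively on the distance
$d = 1 - R^2$. The linkage is a genuine design choice: nothing in the
underlying theory dictates one, and average linkage is the conventional
default for similarity-derived distances, with complete and single
linkage available. Trees serialize to Newick (`writeChainTree()`), with
`:` in chain labels rewritten to `_` because the colon is reserved in
that format. Box statistics (`residualBoxStats()`) use the inclusive
quartile convention (R type 7).

## The dynamic model behind the steady state

The steady-state models correspond to a linear kinetic system: chains of
type $\alpha$ enter CL from donor class $c$ at rate
$k_c f_c(\alpha)$ and leave by first-order degradation at rate $\gamma$.
`simulateDynamics()` integrates this system (deSolve, `lsoda`,
tolerances 1e-10) and `steadyStateWeights()` gives the closed-form fixed
point: the normalized steady-state composition is
$\sum_c W_c f_c$ with $W_c = k_c / \sum_{c'} k_{c'}$ — exactly the
proportional-incorporation model, with $\gamma$ canceling. The package
treats this correspondence as a property check (the integrated fixed
point must match the closed form to 1e-8); inferring rate constants from
timecourse data is out of scope. The donation term is generalized to
every donor class present (PG and acyl CoA included), consistent with
the steady-state model it must reduce to.

## What the synthetic generator emulates — and what it does not

`sampleDonorPools()` and `generateDataset()` produce tables with the
structure the models assume: a chain catalog of even-carbon chains
(14–24 carbons, 0–6 double bonds) centered on the species dominating
mitochondrial profiles; donor pools drawn from a symmetric Dirichlet law
(concentration 1 by default — uniform over the simplex, giving realistic
spiky pools); CL peak profiles generated forward through the IID/IDD
convolution or the proportional mixture; and per-replicate additive
Gaussian noise on peak probabilities, truncated at zero and renormalized,
with equal variance across peaks — matching the Gaussian error model
under which the least-squares fit is maximum likelihood. Default study
conditions are 3 replicates and noise standard deviations in the
0.002–0.005 range, comparable to replicate scatter in shotgun lipidomics
probability profiles.

The generator deliberately does not emulate mass-spectrometric reality:
no isotope envelopes, peak-shape or m/z error, no within-peak isomer
structure, no abundance-dependent measurement variance, and no
correlated (compositional) noise. Passing recovery tests on these data
therefore demonstrates the correctness and conditioning of the inference
itself, not robustness to instrument systematics.

Benchmark sizes used throughout the tests and the acceptance script are
small by design — supports of 2–8 chains, tens of peaks, 10–100
replicate trials, 50 calibration repeats — chosen so the full recovery
and calibration studies re-run in minutes while each still estimates its
quantity stably.

## Degenerate inputs and edge conventions

* Zero-probability chains are retained in distributions (for reporting)
  but dropped from enumeration and support construction.
* A replicate whose class total is zero is an error, as is a duplicated
  species within a replicate; species missing from some replicates are
  below-detection zeros, not structurally missing.
* Normalization happens per replicate *before* averaging; the two orders
  differ whenever replicate totals differ, and per-replicate
  normalization is what makes replicates exchangeable.
* Empty sample selections produce an empty report; a sample failing
  anywhere is logged and skipped without aborting the cohort run.

## Known limitations

* Fits operate on peak-level (total carbon/double-bond) data; isomeric
  structure within a peak is invisible to the likelihood.
* The positional least-squares problem is non-convex; the deterministic
  start protocol plus optional multi-start has recovered every synthetic
  truth we generate, but there is no global-optimality certificate.
* The proportional model has no per-chain selectivity parameters — by
  design, since departures from it are exactly what the residual
  analysis is meant to expose.
* Input is plain delimited text (tidy or wide); spreadsheet formats
  should be exported to CSV/TSV first.

## A worked example

```{r example}
pools <- sampleDonorPools(6, nClasses = 3, seed = 8)
truth <- syntheticTruth(pools,
                        weights = c(PG = 0.2, PC_sn2 = 0.5, PE_sn2 = 0.3),
                        sigma = 0.002, seed = 8)
ds <- generateDataset(truth, mode = "proportional")
report <- runPipeline(ds$table, nPermDonor = 999, seed = 3)
report$positional
report$donor
```

The positional table shows the IID fit reproducing the generated profile
(error near zero, $r$ near 1, cross-validation stable, label-permutation
p-value small), and the donor table recovers the generating weights
(0.2, 0.5, 0.3) to within the injected noise.
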