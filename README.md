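# clremodel

Inference of steady-state cardiolipin (CL) remodeling mechanisms from
class-resolved shotgun-lipidomics tables.

CL, the signature phospholipid of the inner mitochondrial membrane,
carries four acyl chains (sn-1, sn-1′, sn-2, sn-2′) that are extensively
remodeled after synthesis: chains are swapped in from acyl donors — the
sn-2 chains of PC and PE, PG, and the acyl CoA pool. Mass spectrometry
quantifies CL only as mass peaks keyed by *total* carbons : *total*
double bonds (e.g. `72:8`), pooling all isomers. This package is for
lipidomics and mitochondrial-biology researchers who want to turn such
peak tables into mechanistic statements about remodeling.

## The models

**Positional (IID/IDD).** If the four positions are independently and
identically remodeled, each draws a chain from one distribution
*P* over chain types α (labels like `18:1` = 18 carbons, 1 double bond),
and the probability of mass peak (c, d) is

    P(c, d) = Σ P(α_i) P(α_j) P(α_k) P(α_h)   over ordered 4-tuples with
                                              Σ carbons = c, Σ double bonds = d

— the 4-fold convolution of *P* on the (carbons, double-bonds) lattice.
`fitIID()` inverts this: it finds the simplex-constrained *P* minimizing
the squared error against the observed profile (the maximum-likelihood
estimate under homoscedastic Gaussian peak noise). The IDD variant
(`fitIDD()`) gives the sn-1/sn-1′ and sn-2/sn-2′ pairs separate
distributions. Fits are judged by squared error, Pearson *r* (explained
when r > 0.7), 4-fold cross-validation over peaks, and a
label-permutation null.

**Proportional incorporation.** If donation is head-group-determined and
chain-blind, the CL chain composition is a mixture of donor compositions

    P_CL(α) = W_PG f_PG(α) + W_PC f_PC(α) + W_PE f_PE(α) [+ W_AC f_AC(α)],
    W ≥ 0, Σ W = 1.

`fitProportional()` solves this constrained regression exactly; the
weights say what fraction of CL's chains each donor class contributes,
and per-chain residuals expose chains enriched or depleted beyond
proportional donation (candidate targets of selective enzymes).
`donorPermutationTest()` supplies an empirical p-value (10000
permutations), and `residualMatrix()` / `clusterChains()` find chains
whose residuals co-vary across samples. `simulateDynamics()` verifies
that the proportional model is the steady state of the underlying
donation/degradation kinetics, with `W_c = k_c / Σ k`.

## Worked example

Generate a benchmark cohort with known ground truth and run the full
two-step pipeline:

```r
library(clremodel)
pools <- sampleDonorPools(6, nClasses = 3, seed = 8)
truth <- syntheticTruth(pools,
                        weights = c(PG = 0.2, PC_sn2 = 0.5, PE_sn2 = 0.3),
                        sigma = 0.002, seed = 8)
ds <- generateDataset(truth, mode = "proportional")
report <- runPipeline(ds$table, nPermDonor = 999, seed = 3)

report$positional
#>      sample    error pearson_r cv_r_mean   cv_r_sd p_label_perm explained
#> 1 synthetic 8.89e-05    0.9947    0.9939 0.0004226    3.465e-11      TRUE

report$donor
#>      sample   W_PG   W_PC   W_PE W_AC pearson_r p_donor_perm     error explained
#> 1 synthetic 0.2079 0.4877 0.3045   NA    0.9998        0.001 5.771e-06      TRUE
```

Reading the output: the IID model reproduces the observed peak profile
(squared error 8.9e-05, r = 0.995 > 0.7, so the sample is *explained*;
cross-validation r = 0.994 ± 0.0004 with a label-permutation p of
3e-11, so the fit is not an artifact of flexibility), and the donor
regression recovers the generating weights (0.2, 0.5, 0.3) as
(0.208, 0.488, 0.305) with an empirical p of 0.001 — exactly the
two-step conclusion the pipeline is designed to reach. With real tables
(`readConcentrationTable()`, tidy or wide delimited text) the same
report ranks donor contributions per sample and flags samples whose CL
profile is *not* explained by position-independent, head-group-blind
remodeling.

A thin command-line front end is included at
`inst/scripts/clremodel-cli.R` (`run`, `synth`, `simulate` subcommands).

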