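# eatr

Time-dependent rate estimation and reaction-coordinate (RC) quality scoring
for biased molecular simulations.

## The problem

Enhanced-sampling methods such as metadynamics accelerate rare transitions
(ligand unbinding, conformational changes) by depositing a history-dependent
bias V(s, t) along a collective variable (CV) s. Infrequent metadynamics
(iMetaD) recovers unbiased kinetics from such runs through the acceleration
factor

    alpha(t) = < exp(beta V(s, t)) >_M ,    tau_accel = alpha(t) * t ,

but this only works when the biased CV is a good approximation of the true
RC. The **EATR** (exponential-average time-dependent rate) and **KTR**
(Kramers time-dependent rate) methods generalize iMetaD by modelling the
biased hazard as

    k(t) = k0 * f(t),   f(t) = exp(beta * gamma * V(t))        (EATR)
                        f(t) = exp(beta * gamma * Vmax(t))     (KTR)

and fitting the survival function S(t) = exp(-k0 ∫ f dt') to the observed
(possibly right-censored) transition times. The dimensionless parameter
**gamma ∈ [0, 1]** measures the fraction of the applied bias that actually
accelerates the transition: gamma = 1 means the bias acts along the true
transition path (a perfect RC), gamma = 0 means it acts orthogonally (a
useless RC). gamma is therefore a practical, quantitative score of RC
quality — for instance for deciding whether successive machine-learned RC
iterations are improving — and correlates inversely with the mean
accelerated time across RC iterations. Closed-form predictors

    gamma ≈ 1 - log(k0 * (tauBar - cov(t, alpha))) / log(alphaBar)   (pred. 1)
    gamma ≈ 1 - log(k0 * tauBar) / log(alphaBar)                     (pred. 2)

give a fast diagnostic when a full survival fit is impractical.

The package implements the whole pipeline: PLUMED-dialect COLVAR/HILLS I/O,
acceleration profiles, the three hazard models with per-trajectory or
ensemble-mean averaging, censoring-aware maximum-likelihood fitting with
bootstrap uncertainties, the Poisson-CDF fit with its Kolmogorov–Smirnov
diagnostic, iteration reports, and two synthetic generators with known
ground truth (an inhomogeneous-Poisson time-rescaling sampler, and a 2D
Langevin double well biased along a rotatable CV).

## Worked example

Generate a biased ensemble whose transition times follow the hazard
k0 exp(beta * gamma * V(t)) with gamma_true = 0.8 (an imperfect RC: only
80 % of the recorded ramp bias accelerates the escape), then fit gamma with
k0 held fixed:

```r
library(eatr)
sched <- linearRamp(0.015)                       # beta*V reaches 15 at t = 1000
ens <- sampleTransitionTimes(sched, gammaTrue = 0.8, k0 = 1e-4,
                             n = 100, tMax = 1000, seed = 3)
fit <- fitEATR(ens, k0 = 1e-4, nBoot = 200, seed = 1)
fit
#> RateFit [eatr, per_trajectory]
#>   gamma = 0.8004
#>   gamma 95% CI = [0.7763, 0.8370] (bootstrap, n = 200)
#>   k0 = 0.0001 (fixed)
#>   loglik = -584.0148 on 100 transitions, 0 censored

ensembleSummary(ens)
#> EnsembleAccelSummary: 100 transitioned / 0 censored
#>   mean tau_accel = 31135.3, mean alpha = 71.8969, cov(t, alpha) = 4682.86 (population)
#>   tau_MFPT = 31135.3

predictGamma(ens, k0 = 1e-4)
#> GammaPrediction: pred1 = 0.7725, pred2 = 0.7343
```

The fit recovers gamma = 0.80 with a tight interval; the moment-based
predictors land nearby without any fitting (prediction 1, which keeps the
covariance term, is the closer of the two). The mean accelerated time
(3.1e4) overestimates the true timescale 1/k0 = 1e4 because the RC is
imperfect — exactly the situation gamma diagnoses.

The 2D Langevin engine provides an end-to-end testbed where RC quality is
dialled by the angle theta between the biased CV and the true coordinate:

```r
cfg <- toySystemConfig(theta = 30, seed = 42)    # 8 kBT barrier, 16 runs
res <- langevinMetad(cfg)
fitEATR(res$ensemble, k0 = res$k0Ref, averaging = "ensemble_mean")
```

A shell entry point wrapping the same functions ships as
`inst/scripts/eatr` (subcommands `simulate`, `accel`, `fit`,
`predict-gamma`, `pace-scan`, `report`).

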