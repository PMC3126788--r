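# fretBayes

Bayesian inference of the in vivo dissociation constant and intrinsic
FRET efficiency of a protein–protein interaction from three-cube FRET
intensity data.

## The problem

Förster resonance energy transfer (FRET) between a donor-tagged and an
acceptor-tagged protein lets fluorescence microscopy watch an
interaction inside living cells. Turning the three intensity channels of
a standard three-cube acquisition (donor, acceptor, FRET) into a binding
constant is confounded twice over: spectral cross-talk and bleed-through
mix every species into every channel, and the FRET efficiency
*E*<sub>fr</sub> and dissociation constant *K*<sub>d</sub> scale the
signal jointly, so a single sample cannot separate them. fretBayes is
for experimentalists and modellers who have (or plan) three-cube
measurements across samples with varying fluorophore concentrations and
want a posterior distribution — not a point estimate — for
*K*<sub>d</sub> and *E*<sub>fr</sub>.

## The model

Observed intensities are linear in the species concentrations,

    I = M ([D], [A], [DA])'

with the 3×3 mixing matrix *M* built from nine photophysical constants
κ<sub>i</sub><sup>(S)</sup> (channel i; species contribution S ∈ {D, A,
F}); the complex column is κ<sup>(D)</sup>(1−E<sub>fr</sub>) +
κ<sup>(A)</sup> + κ<sup>(F)</sup>E<sub>fr</sub>. Concentrations follow
the 1:1 equilibrium [D][A]/[DA] = K<sub>d</sub>. Replicate measurements
are Gaussian around the predictions; the unknown per-sample totals
([D<sub>0</sub>], [A<sub>0</sub>]) are profiled by Nelder–Mead and
integrated out with a Laplace approximation at every proposal; a
Metropolis–Hastings random walk (step sizes auto-tuned to a 40–60%
acceptance rate, three chains, burn-in detection, Gelman–Rubin check)
samples (log₁₀K<sub>d</sub>, E<sub>fr</sub>). Calibration of the κ
constants from donor-only, acceptor-only and tandem-construct samples —
absolute, or relative to κ₁<sup>(D)</sup> ≡ 1 — and inference of the
apparent efficiency E<sub>d</sub> and ratio r<sub>da</sub> are included.
The methods vignette (`vignettes/fretBayes-methods.Rmd`) derives all of
this and records the numerical choices.

## Worked example

Simulate the reference study — three cells with equal donor and acceptor
totals of 0.2, 1 and 5 µM, truth K<sub>d</sub> = 1 µM and
E<sub>fr</sub> = 0.4, ten measurements per cell per channel, 5% noise —
and fit it:

```r
library(fretBayes)

fs <- simulateFretData(Kd = 1e-6, efr = 0.4,
                       D0 = c(0.2, 1, 5) * 1e-6, A0 = c(0.2, 1, 5) * 1e-6,
                       n = 10, r = 0.05, seed = 7)
fit <- fitKd(fs, defaultKappa(), nSteps = 20000, seed = 7,
             truth = list(Kd = 1e-6, efr = 0.4))
fit
#> FretFit
#> ProposalSpec: step SD log10(Kd) = 0.08754, E_fr = 0.008754
#>   PSRF: log10_kd = 1.036, efr = 1.017 (pass = TRUE)
#>              mean           sd        cv          q05          q50          q95
#> Kd   9.031503e-07 2.613124e-07 0.2893343 5.574652e-07 8.987606e-07 1.314852e-06
#> E_fr 3.744838e-01 4.002667e-02 0.1068849 3.279931e-01 3.768229e-01 4.266348e-01
#>            error n_draws
#> Kd   -0.04423997   60000
#> E_fr -0.02551620   60000
```

Reading the table: the pooled posterior mean of K<sub>d</sub> is
0.90 µM with a 29% coefficient of variation (the relative-uncertainty
measure), the 5–95% interval 0.56–1.31 µM covers the generating 1 µM,
and the efficiency posterior centres at 0.374 against a truth of 0.4.
`error` is log₁₀(mean/truth) for K<sub>d</sub> (0 means perfect) and
the plain difference of means for E<sub>fr</sub>. The PSRF line shows
the three independent chains agreed.

Real measurements enter the same way through a CSV
(`readFretData()`; header `sample_id, replicate, I_D, I_A, I_F`),
with κ from `calibrateAbsolute()` / `calibrateRelative()` or a YAML
table (`readKappa()`). A thin command-line wrapper with
`simulate | fit | grid | calibrate | apparent | experiment` subcommands
is installed at `system.file("scripts", "fret_cli.R", package =
"fretBayes")`, and `runExperiment()` reruns the simulation studies
(noise, replication, concentration design, ratio, prior benefit) at
configurable scale.

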