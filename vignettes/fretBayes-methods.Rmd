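---
title: "Inferring binding strength from three-cube FRET: model and methods"
author: "fretBayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring binding strength from three-cube FRET: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretBayes)
```

## The problem

Förster resonance energy transfer (FRET) between a donor-tagged and an
acceptor-tagged protein reports on their physical interaction in living
cells. Quantifying that interaction — as an in vivo dissociation constant
$K_d$ — from fluorescence intensities is hard for two reasons. First,
the donor and acceptor spectra overlap, so every spectral channel mixes
direct emission, cross-talk (the "wrong" fluorophore being excited) and
bleed-through (a fluorophore emitting into the other channel's filter).
Second, the intrinsic FRET efficiency $E_{fr}$ and $K_d$ both scale the
FRET signal, so neither is identifiable from a single sample: a weak
efficiency with tight binding mimics a strong efficiency with loose
binding. fretBayes resolves both issues with an explicit forward model
and Bayesian inference over data from samples with varying fluorophore
concentrations.

## Forward model

**Binding equilibrium.** Donors and acceptors form 1:1 complexes,
$D + A \rightleftharpoons DA$, with $K_d = [D][A]/[DA]$. Given totals
$[D_0] = [D] + [DA]$ and $[A_0] = [A] + [DA]$, the complex concentration
is the smaller root of

$$[DA]^2 - ([D_0] + [A_0] + K_d)\,[DA] + [D_0][A_0] = 0 .$$

`solveEquilibrium()` evaluates it as
$2[D_0][A_0] / (b + \sqrt{b^2 - 4[D_0][A_0]})$ with
$b = [D_0]+[A_0]+K_d$. The textbook "smaller root" expression subtracts
two nearly equal numbers when $K_d \gg [D_0]+[A_0]$ — exactly the
weak-binding regime the concentration-plateau analyses probe — while the
rationalized form keeps full relative precision there.

**Spectral mixing.** Observed intensities in the donor, acceptor and
FRET channels are linear in the species concentrations,
$\mathbf{I} = M \,([D], [A], [DA])^T$. The matrix $M$ is built from nine
constants $\kappa_i^{(S)}$ (`KappaTable`), one per channel $i$ and
species contribution $S \in \{D, A, F\}$, each folding together
illumination intensity, molar extinction, quantum yield and detection
sensitivity. Those four factors are never needed individually; only in
the calibration shortcut for the FRET-sensitized constants does their
factorization surface (see below). The complex column of $M$ is

$$\kappa^{(D)}(1 - E_{fr}) + \kappa^{(A)} + \kappa^{(F)} E_{fr},$$

i.e. donor emission attenuated by transfer, unchanged acceptor emission,
and sensitized emission in proportion to $E_{fr}$. All cross-talk and
bleed-through terms are carried in the $\kappa$ values, so any
measurable contamination is representable. The model is restricted to
three channels (the ubiquitous three-cube acquisition) and to 1:1
complexes; collisional FRET between unbound fluorophores is neglected.

**Units.** All concentrations are molar internally. Readers and the
simulator accept micromolar through an explicit `units` flag and convert
immediately; nothing downstream ever sees mixed units.

## Likelihood and marginalization of the totals

Replicate measurements are modelled as Gaussian around the predicted
intensities with per-sample, per-channel scales $\sigma$
(`estimateNoise()` uses the replicate standard deviation, floored at
$10^{-12}(|\bar I| + 1)$; noise is estimated per sample because its
magnitude tracks the local signal, and samples can differ 25-fold in
concentration). The negative log likelihood ("energy") of a sample
depends on its replicates only through their count, mean and variance,
which is what the compiled evaluation uses.

The totals $[D_0], [A_0]$ of every sample are nuisance parameters. For
each proposal $(K_d, E_{fr})$ they are profiled by Nelder–Mead simplex
minimization of the energy — multi-started from a moment-based guess
(donor-channel mean over $\kappa_1^{(D)}$, acceptor-channel mean over
$\kappa_2^{(A)}$), from the optimum of the previously accepted proposal,
and from ten times the moment guess — and then integrated out with a
Laplace approximation:

$$\log P(\text{sample} \mid K_d, E_{fr})
  \approx -E_{\min} + \log 2\pi - \tfrac12 \log \det H,$$

where $H$ is the $2\times2$ Hessian of the energy at the optimum, taken
by central finite differences with step $\max(10^{-5} x^\*, 10^{-12}\,
\text{M})$ per coordinate. The step is a compromise measured against a
quadrature oracle: much smaller steps lose the Hessian in roundoff on
the energy (the energy changes by only $\sim H h^2$), much larger ones
bias the curvature of non-quadratic energies; at $10^{-5}x^\*$ the step
is still three orders of magnitude below the posterior width of the
totals. The integral runs over the whole plane rather than the positive
quadrant — accurate whenever the optimum sits several posterior SDs away
from zero, which holds for any sample with detectable signal. When
$E_{fr} = 0$ the predictions are linear in the totals, the energy is
exactly quadratic, and the approximation is exact; the test suite pins
this case against brute-force 2-D quadrature at $10^{-6}$ log units and
randomized curved cases at $0.05$. A non-positive-definite Hessian marks
the proposal invalid ($-\infty$ log posterior) rather than being
regularized, so a pathological fit can never masquerade as evidence.

## Priors

* $K_d$: uniform in $\log_{10} K_d$ on a bounded support, default
  $[-12, -2]$ ($\log_{10}$ molar). Bounded because data taken far from
  the binding transition only bound $K_d$ from one side; with an
  unbounded flat prior in log space the posterior would be improper.
  The bounds are user-configurable and reported with results.
* $E_{fr}$: uniform on $[0, 1]$, or a Gaussian truncated to $[0, 1]$
  when an independent measurement (e.g. from lifetime imaging) exists.
  The conventional example used throughout is mean $0.45$ with spread
  $0.15$; the spread is interpreted as a standard deviation — reading
  $0.15$ as a variance would imply an SD of $0.39$, wider than the
  uniform prior's own SD, which cannot represent "limited information".

## Posterior sampling

`fitKd()` samples $(\log_{10} K_d, E_{fr})$ with Metropolis–Hastings:
independent Gaussian increments per coordinate, acceptance
$\min(1, P_j/P_{j-1})$ evaluated in log space, proposals outside the
support rejected through the prior's $-\infty$ (with a symmetric
proposal this preserves detailed balance). The log scale for $K_d$
matters: posteriors routinely span several decades, and a natural-scale
walk cannot traverse a plateau that is flat in $\log K_d$.

**Step-size tuning.** Pilot blocks of 100 steps multiply both step SDs
by $\mathrm{clip}(a/0.5, 1/3, 3)$, where $a$ is the block acceptance
rate, until a block lands in the 40–60% band; a 300-step confirmation
stretch without adaptation must then also land in band before the
proposal is frozen. Freezing before recording keeps the recorded chain a
genuine Markov chain. If 50 blocks never settle (a flat target accepts
everything at any step size), the best proposal found is returned with a
warning.

**Burn-in.** The recorded energy trace is scanned with a 100-state
window; burn-in ends at the first window whose mean energy lies within
two window-SDs of the final-quarter mean, capped at half the chain
(with a warning when the cap binds).

**Convergence.** Three chains start from overdispersed draws from the
prior. The potential scale reduction factor is computed per parameter on
the post-burn-in draws and floored at 1 (the floor makes "identical
chains" read exactly 1 instead of $\sqrt{(n-1)/n}$); convergence
requires PSRF $< 1.1$ for both parameters plus pairwise overlap of the
chains' interquartile ranges.

**Summaries.** Pooled post-burn-in draws give the posterior mean, SD,
coefficient of variation and 5/50/95 percentiles, with $K_d$ reported on
the natural molar scale. SDs use the population ($1/N$) normalization:
the draws are treated as the distribution being described, and on real
chain lengths the difference from $1/(N-1)$ is negligible. When the
truth is known (simulations), the $K_d$ error is
$\log_{10}(\langle K_d\rangle / K_d^{\text{true}})$ — zero for a perfect
estimate and symmetric on the scale the recovery studies plot.

## Calibration of the kappa constants

With known fluorophore concentrations, donor-only and acceptor-only
samples give the six donor/acceptor constants by division
(`calibrateAbsolute()`), enabling absolute $K_d$ estimates. Otherwise
`calibrateRelative()` works in a fixed gauge: rescaling all $\kappa$ by
$c$ and all concentrations by $1/c$ leaves every prediction unchanged,
so only ratios are identifiable and $\kappa_1^{(D)}$ is pinned to 1.
Downstream $K_d$ estimates are then scaled by that reference constant,
and the result object says so.

Each calibration block (donor-only, acceptor-only, tandem
donor–acceptor construct) has one unknown concentration; the construct's
predictions use the complex column above with its own efficiency
$E'_{fr}$. The block likelihood is marginalized analytically over a
shared noise scale under a Jeffreys prior, yielding a Student-type
$S(c)^{-3n/2}$ in the residual sum of squares, and then over the
concentration by a one-dimensional Laplace approximation at the
least-squares optimum (validated against quadrature at the 1% level in
the tests). A per-channel-$\sigma$ variant plugs the replicate SDs in
directly. The FRET-sensitized constants are tied to the acceptor
constants by the per-channel extinction-coefficient ratio,
$\kappa_i^{(F)} = \kappa_i^{(A)} \,\varepsilon_i^{(D)}/
\varepsilon_i^{(A)}$ — sensitized emission is acceptor emission driven
by donor absorption — with the ratios supplied by the user from spectra.

The five free ratios (log scale) and $E'_{fr}$ are sampled jointly. The
acceptor scale and $E'_{fr}$ are pinned only jointly by the construct
block and are therefore strongly correlated; the sampler learns the
posterior covariance in a pilot phase and records with
covariance-shaped proposals (scaled $2.4/\sqrt{d}$, the usual
random-walk rule), starting the two recorded chains several covariance
lengths apart. A PSRF above 1.2 on any coordinate raises an error
rather than returning unconverged estimates.

## Apparent quantities

When only relative calibration exists and concentrations are unknown,
the instrument-independent observables are the apparent donor efficiency
$E_d$ ($E_{fr}$ times the fraction of donors in complex) and the ratio
$r_{da} = [D_0]/[A_0]$, with $E_a = E_d\, r_{da}$. Writing
$[D_0] = r_{da}[A_0]$ and $E_{fr}[DA] = E_d\, r_{da} [A_0]$ makes the
predictions linear in $[A_0]$, so the per-sample total is profiled in
closed form by weighted least squares (`optimalA0()`) instead of simplex
search. `inferApparent()` then samples $(E_d, \log_{10} r_{da})$ with
the same shaped-proposal pipeline; $r_{da}$ moves on the log scale
because ratios span decades and donor- and acceptor-excess regimes
should be treated symmetrically. The prior on $\log_{10} r_{da}$ is
uniform on $[-3, 3]$ by default — no principled reference exists, so the
support simply covers every ratio a FRET experiment could plausibly
produce, and it is user-configurable.

## The simulator and what passing tests mean

`simulateFretData()` generates the study conditions used across the
recovery experiments: noiseless intensities from the forward model, plus
independent Gaussian noise per replicate with SD equal to $r$ times that
sample's noiseless channel mean. The reference configuration is three
cells at $[D_0]=[A_0]$ of 0.2, 1 and 5 µM, truth $K_d = 1\ \mu$M and
$E_{fr} = 0.4$, ten measurements per cell per channel, $r = 5\%$.
Negative intensities occasionally produced at large $r$ are kept — the
Gaussian likelihood is defined on all reals and clamping would bias
inference.

The shipped default `KappaTable` represents a donor–acceptor pair with
considerable spectral overlap: own-channel constants largest, donor
brighter than acceptor, FRET-channel bleed-through and cross-talk near
20% of the respective own-channel constants, and small but nonzero
acceptor contributions in the donor channel
($\kappa_D = (1, 0.05, 0.2)$, $\kappa_A = (0.01, 0.75, 0.15)$,
$\kappa_F = (0.01, 0.05, 0.75)$ per molar, channels ordered donor,
acceptor, FRET). Parameter-recovery results are not sensitive to the
exact table: the inference is tested as a round trip against whatever
table generated the data.

The simulator emulates background-corrected, replicate intensity
measurements with signal-proportional Gaussian noise. It does not
emulate photobleaching, dark states, incomplete labelling, shot-noise
(Poisson) statistics, log-normal noise, or spatial structure in images —
so green tests demonstrate correctness of the inference given the
model's assumptions, not robustness to those effects in real data.
Calibration error is likewise not propagated into the main fit: the
$\kappa$ table is treated as known once calibrated.

## Problem sizes and defaults

Default inference runs 3 chains of 20,000 recorded steps after a tuning
phase — posterior summaries then rest on roughly 55–60k pooled draws.
The replicate studies in `runExperiment()` default to 10 datasets per
condition analyzed with a single tuned walk each; the original studies
used 50 datasets and walks of 10,000–36,000 steps, and both knobs are
arguments. The test suite runs the reference configuration at full
scale and the sweeps at the 10-dataset default.

## Known limitations

* The Laplace integral over the totals extends over the whole plane; for
  samples whose signal is comparable to the noise floor (totals within a
  few posterior SDs of zero) it overestimates the marginal likelihood.
* $\sigma$ is plugged in from replicate SDs, not given a prior; with
  very few replicates (n = 3) the noise estimate itself is noisy, which
  widens but does not bias the posterior in the recovery studies.
* Acceptance-rate tuning adapts a single scale factor for the main
  2-parameter fit; heavily correlated ridges (single-sample data) mix
  slowly, which is visible as elongated high-probability regions rather
  than resolved by reparameterization.
* The relative calibration ties $\kappa^{(F)}$ to $\kappa^{(A)}$ through
  user-supplied extinction ratios; errors in those ratios propagate
  directly into $E'_{fr}$ and downstream efficiencies.
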