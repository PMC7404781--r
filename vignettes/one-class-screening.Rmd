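---
title: "Non-targeted adulteration screening with one-class class models"
author: "OneClassSpectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-targeted adulteration screening with one-class class models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OneClassSpectra)
```

## The problem

Targeted authentication methods can only detect adulterants that were part
of the calibration design; an unknown diluent evades them entirely.
Non-targeted screening inverts the question: model only the *authentic*
class — here, pure almond powder measured by FT-IR or FT-NIR reflectance —
and flag any sample that deviates from it, whatever the cause.  This
package implements the two one-class class models used for that task,
data-driven SIMCA (DD-SIMCA) and one-class partial least squares (OCPLS),
together with the spectral pretreatments, study metrics, and a synthetic
data generator for a two-variety almond / apricot / peanut
adulteration design, so that the whole workflow is testable end to end
without measured spectra.

## DD-SIMCA

A PCA model with $k$ components is fitted to the column-centered pure
calibration matrix.  Each sample then has two distances:

* the **score distance** $h_i = \sum_{a \le k} t_{ia}^2 / \lambda_a$, a
  Mahalanobis-type leverage within the model subspace, and
* the **orthogonal distance** $v_i$, the squared residual norm outside it.

Both are treated as scaled chi-square variables with data-estimated
degrees of freedom.  The classical method of moments gives
$N = 2\,\bar{x}^2/\mathrm{var}(x)$ (a robust quantile-matching variant is
available for contaminated training sets).  The total distance

$$c_i \;=\; N_h \frac{h_i}{h_0} + N_v \frac{v_i}{v_0}
  \;\sim\; \chi^2(N_h + N_v)$$

yields the acceptance boundary $c_{crit} = \chi^2_{1-\alpha}(N_h+N_v)$ and
an outlier boundary at significance $\gamma$, adjusted for multiplicity
over the training set as $\gamma_{adj} = 1-(1-\gamma)^{1/n}$ so that
$\gamma$ is a per-dataset error.  Training samples between the two
boundaries are *extreme*, beyond the outer one *outliers*; test samples
are judged by acceptance ($c \le c_{crit}$) alone, with ties counting as
accepted (a closed acceptance region).  The `extremePlotData()` table
compares the observed number of extremes with its expectation $n\alpha$
across a grid of significance levels, with a 95% binomial envelope.

Two identities pin the implementation down and are asserted in the tests:
the training score distances satisfy $\overline{h} = k(n-1)/n$ exactly,
and when the data lie exactly in a $k$-dimensional subspace all $v_i = 0$
— the fit then reports the degeneracy and judges samples by $h$ alone,
rejecting anything measurably outside the subspace.

The number of components is chosen by target-class sensitivity: the
cross-validated acceptance rate is computed per candidate $k$ and the
smallest $k$ within one binomial standard error of the maximum is taken.
On well-calibrated data this curve is nearly flat in $k$ (each candidate
model adapts its thresholds to its own residuals), so the rule
deliberately prefers parsimony; candidates above the numerical rank
collapse onto the rank, making the curve constant there.

## OCPLS

OCPLS regresses the constant unit response $y \equiv 1$ on the
*uncentered* training spectra by NIPALS PLS1.  Centering the columns
would annihilate the method — the first weight vector is
$w \propto X_c^\top \mathbf{1} = 0$ on column-centered data — so the raw
spectra enter the regression and the response is never centered (a
constant response cannot be).  Membership of a new sample is judged by
two statistics:

* **Hotelling's $T^2$** of its $A$ latent-variable scores, centered and
  standardized by the training score moments, against the F-bound
  $\frac{A(n^2-1)}{n(n-A)} F_{1-\alpha}(A, n-A)$, and
* the **absolute centered residual** $\mathrm{ACR}_i = |r_i - \bar{r}|$ of
  its predicted response, $r_i = \hat{y}_i - 1$, against the Gaussian
  two-sided bound $z_{1-\alpha/2}\,\mathrm{sd}(r)$.

A sample is accepted only when both statistics are inside their limits;
the four quadrants (regular / good leverage / response outlier / bad
leverage) say which statistic was violated.  The number of latent
variables is selected by Monte-Carlo cross-validation: repeated random
splits, unit-response prediction of the held-out part, and the standard
deviation of the pooled residuals per candidate count; the chosen $A$ is
the smallest whose residual sd is within 5% of the minimum.  The MCCV
defaults (100 splits, 20% holdout, 5% tolerance) are exposed in the
configuration.

A useful exact property: with $A = $ the data rank, the unit-response PLS
fit reproduces the no-intercept least-squares fit, so on noiseless
rank-$r$ mixtures whose mass fractions obey closure (fractions sum to 1)
the MCCV residual curve drops to numerical zero exactly at $r$ — the
construction used by the latent-variable recovery tests.  Without
closure, $\mathbf{1}$ is generally not in the column space of the data
and the curve has no elbow, which is why the recovery fixture is built
from closed mixtures.

## Preprocessing

Five pretreatments are provided as pure matrix transforms: max/area
normalization, SNV (row-wise centering and scaling, $n-1$ denominator),
MSC (per-spectrum OLS regression onto a reference, then inversion of the
fitted slope and offset; the reference defaults to the calibration mean),
and Savitzky–Golay smoothing/derivatives.  "Smoothing" is Savitzky–Golay
with derivative order 0.  The local polynomial is fitted in physical axis
units, so first-derivative output is per cm$^{-1}$ and grid-independent;
edges are handled by a full-width one-sided window evaluated at the edge
point, which keeps the axis length constant and is always solvable for
any legal window/order combination.  SNV and MSC are exactly invariant to
per-spectrum affine (offset + positive scale) distortions, which is why
SNV is the default pipeline pretreatment: it cancels the multiplicative
scatter and offset artifacts the generator (and a powder measurement)
produces.

## The synthetic study generator

The generator produces the reference study design the package is built
around:
100 pure calibration samples from two almond varieties (50 each);
validation set 1 on variety 1 with 10 pure samples plus 5–50% adulterant
in 5% steps, 10 replicates each (110 samples); validation set 2 on
variety 2 with 10 pure plus 7, 15, 22, 30% (50 samples); apricot and
peanut as adulterants, giving four validation sets that share one
calibration model.  Grids are 650–4000 cm$^{-1}$ in 4 cm$^{-1}$ steps
(838 points, MIR) and 4000–10000 cm$^{-1}$ in 8 cm$^{-1}$ steps (751
points, NIR).

Endmembers are sums of Gaussian bands.  All three materials share one
band table — the same functional groups occur in all three powders — and
differ in amplitudes: apricot carries coherent macronutrient contrasts
versus almond (more carbohydrate, less lipid and protein) plus small
fingerprint band shifts, and peanut is a seed-deterministic jittered copy
of apricot.  Rendered spectra therefore satisfy the qualitative structure
the analysis assumes: the two adulterants are far more similar to each
other than either is to almond (asserted by cosine similarity in the
tests).  Samples are exact mass-fraction mixtures,
$(1-c)\,\mathrm{almond} + c\,\mathrm{adulterant}$, so with artifacts
disabled a render at concentration $c$ equals the convex combination of
the renders at 0 and 100 — exactly.

Within-class variability and measurement artifacts are layered on top:

* four bounded **composition factors** (lipid, protein, carbohydrate,
  moisture) that perturb band groups coherently;
* a fixed per-variety amplitude signature (variety 2 = variety 1 bands
  $\times (1 \pm 4\%)$), small enough that a pooled two-variety
  calibration remains one class;
* multiplicative scatter ($1 \pm 5\%$), additive offset, and a linear
  baseline tilt — the distortions SNV removes;
* a **smooth correlated-noise component** confined to a fixed basis of 12
  Gaussian-smoothed random functions (correlation length about 30 grid
  points), plus a token white-noise floor.

Three of these choices are deliberate and matter for the statistics
rather than the looks of the spectra.  First, the structural factors
clearly dominate the per-dimension residual variance, so a 4–6 component
PCA captures structure and not noise.  Second, the residual noise lives
in a *fixed* low-dimensional basis drawn once per study: if instead every
sample drew fresh random directions in an 800-point space, a PCA fitted
on 100 samples would absorb training-set-specific noise directions and
the training orthogonal distances would underestimate the test ones by
10–40%, wrecking the nominal error rate of any one-class model — an
instrument's correlated noise is also, physically, a property of the
instrument rather than of the sample.  Third, factor and artifact
coefficients are drawn from bounded uniform distributions (matched mean
and variance): natural composition varies within bounded ranges, and the
slightly light tails leave headroom for the finite-sample noise of the
estimated chi-square thresholds.  Even so, the realized type-I error of a
DD-SIMCA model fitted on 100 samples fluctuates between about 1% and 5%
at nominal $\alpha = 1\%$ — a property of the classical moment-estimated
thresholds, not of this implementation — which is why calibration
properties are asserted at the study's own pure-subset sizes or averaged
over seeds rather than demanded of a single fitted model.

Two presets are shipped and fixed once: **separable** (composition sd
0.03, smooth-noise sd 0.0025) on which both classifiers reject every
sample at or above 15% adulteration while keeping pure-sample acceptance
at its nominal level, and **hard** (composition sd 0.045, smooth-noise sd
0.004) on which the 5% and 7% levels are only partially detected
(roughly 20–40%) while 15% and above remain essentially fully detected —
mirroring the observation that screening failures concentrate in the
lowest-concentration sets.  What passing tests on these data do *not*
show: real powder spectra have Lorentzian/Voigt band shapes, nonlinear
particle-size effects, water-vapor interference and instrument drift,
none of which the generator attempts; it reproduces the statistical
structure the classifiers rely on, not the physics.

## Numerical choices and edge cases

* PCA components with eigenvalues below $10^{-12}$ of the leading one are
  dropped; requesting more components than the numerical rank silently
  caps at the rank (recorded in the model).
* An exactly rank-deficient training set (all $v_i = 0$) triggers a
  degenerate-residual mode: acceptance by score distance alone, with any
  sample whose residual exceeds a scaled tolerance declared an outlier.
* Ties at any boundary count as accepted (closed acceptance regions).
* Degrees of freedom are kept as positive reals by default; an optional
  integer-rounding mode (clipped to [1, 250]) exists for parity with
  toolbox conventions.
* The CSV interchange format prints 17 significant digits, so
  write-then-read is value-exact and byte-stable.
* Percentages in reports are truncated (not rounded) at two decimals;
  the truncation convention screening reports commonly use
  (e.g. 50/55 prints as 90.90).
* The pipeline's optional outlier-removal refit (on by default) drops
  training samples beyond the outlier boundary (DD-SIMCA) or outside the
  acceptance limits (OCPLS) and refits once.

## A worked run

```{r run, eval = FALSE}
cfg <- runConfig("ddsimca", preset = "separable", ncomp = 4, seed = 1,
                 outputDir = "run1")
report <- runStudy(cfg)
report$metrics$val1_apricot
report$per_level$val1_apricot
exportPlotData("run1")
```

On the separable preset at seed 1 this prints accuracies of 97.27% and
100% for the variety-1 and variety-2 apricot sets (the only misses being
part of the 5% replicates and one pure sample), detection rates of 1.0 at
every level from 10% upward, and writes the model JSON, per-set
classification CSVs, metrics and plot tables into `run1/`.

## Problem sizes used in the test suite

The automated tests run the full study (100 + 110 + 50 samples, 838-point
MIR grid) for both classifiers and both presets, a 20-seed type-I
calibration simulation (train 200, 100 variables, rank 5, 500 test
samples per seed), 100,000-draw degrees-of-freedom recovery, a 100-signal
Savitzky–Golay oracle comparison, and 20-seed MCCV rank recovery at
n = 60.  These sizes keep the suite under a minute while leaving every
statistical assertion with comfortable power.

## Limitations

DD-SIMCA's chi-square acceptance is approximate at small training sizes;
its realized type-I error exceeds the nominal $\alpha$ by a factor of
roughly two at $n = 100$.  OCPLS has no X-residual statistic, so an
adulterant whose spectral shift is orthogonal to both the latent-variable
space and the regression vector is invisible to it at low concentration —
the reason its low-concentration detection trails DD-SIMCA on the same
data.  The PC-selection rule by target-class sensitivity cannot recover a
"true" rank on well-calibrated data (the acceptance curve is flat in
$k$); it is a parsimony device, and the extreme plot is the intended
diagnostic for over- or under-fitting.  Quantitative concentration
prediction is out of scope: the package classifies, it does not
calibrate.
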