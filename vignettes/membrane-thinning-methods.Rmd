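---
title: "Measuring local membrane thinning: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring local membrane thinning: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memthin)
```

`memthin` quantifies how much a lipid bilayer thins in the immediate
neighbourhood of a membrane protein — the "TM window" of a signal peptidase
complex being the motivating case — from multi-frame coordinate ensembles.
This vignette is the package's own account of the underlying models, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely open.

## The thickness model

Phosphate headgroups (Martini `PO4` beads, or `P` atoms in atomistic
systems) trace the two leaflet surfaces. Their number density along the
membrane normal — fixed to the z-axis, as membrane systems are conventionally
oriented — is a two-peaked curve, and we model it as a sum of Gaussians

$$\rho(z) \;=\; \sum_{k=1}^{K} A_k \exp\!\left(-\frac{(z-\mu_k)^2}{2\sigma_k^2}\right),
\qquad K \in \{2, 3\}.$$

* **K = 2** for a protein-free bulk membrane: one component per leaflet.
* **K = 3** for the TM window: polar residues lining the window can
  coordinate phosphates *deep inside* the membrane, producing a small
  mid-plane population that would otherwise bias a two-component fit. The
  third component absorbs it.

**Thickness is the separation of the two outermost component means**,
$\max_k \mu_k - \min_k \mu_k$. This reading is invariant to amplitude
scaling and to rigid shifts along z, and it reduces exactly to the K = 2
definition when the mid component vanishes — which is why we prefer it over
any amplitude-weighted alternative. The identity is exercised in the test
suite on constructed mixtures where a two-component fit is measurably biased
inward and the three-component fit is not.

### Window selection is dynamic

The TM window is defined as the phosphates within a cutoff (default
**6 Å**) of *any* protein bead, re-evaluated **independently in every
frame**: lipids exchange between the window and the bulk on the timescale of
the ensembles, so a static selection taken from one frame would mix
populations. The implementation uses a vectorized squared-distance
expansion; the test suite pins it, frame by frame, to a brute-force
all-pairs double loop.

### Replicate aggregation

Thickness is estimated once per replicate ensemble and aggregated as mean ±
SEM (standard deviation across replicates over $\sqrt{n}$). We never compute
a per-frame SEM: frames within one trajectory are autocorrelated, and the
replicate is the natural independent unit. A replicate whose fit does not
converge is excluded with a warning and the replicate count decremented — it
is never silently imputed. A single surviving replicate reports SEM 0, again
with a warning.

Derived comparisons are percent thinning, $(T_\text{bulk} -
T_\text{window})/T_\text{bulk} \times 100$, and thickness differences with
SEMs propagated in quadrature, $\sqrt{s_a^2 + s_b^2}$ — the standard
first-order propagation for independent estimates; the package reports
quadrature only and does not attempt to model correlations between systems.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| window cutoff | 6 | Å | first-shell protein–phosphate contact distance in coarse-grained systems |
| profile bin width | 1 | Å | resolves leaflet peaks (σ ≈ 1–2 Å) without starving bins of counts |
| components K | 2 bulk / 3 window | — | see above |
| fit weighting | unweighted | — | bins have similar counting error near the peaks that determine the means; density weighting available via `weighted = TRUE` |
| angle folding | off | — | crossing angles are reported in [0°, 180°]; `fold_to_90 = TRUE` folds antiparallel onto parallel where topology makes the sign meaningless |
| RMSF superposition | on | — | removes rigid-body drift before measuring fluctuations; off mode exists for the analytic isotropic-jitter check |

## The synthetic generator

`generate_bilayer()` plants ground truth so every downstream stage can be
validated by parameter recovery. It emulates:

* two phosphate monolayers on jittered square lattices (default 64 Å² per
  lipid) at $z = \pm T(\rho)/2$, with per-frame Gaussian vertical noise
  (default σ = 1 Å) and lateral jitter;
* a radial thinning funnel
  $T(\rho) = T_w + (T_b - T_w)\bigl(1 - e^{-\max(0,\rho - r_p)^2 / 2w^2}\bigr)$
  interpolating smoothly from the window value at the protein surface to the
  bulk value far away. The decay length defaults to **25 Å**, a realistic
  membrane-deformation decay that keeps the lipids inside the 6 Å annulus
  representative of the window value. The funnel is the *minimal* smooth
  monotone deformation supporting recovery tests — no claim is made that real
  deformations are Gaussian in shape;
* a transmembrane protein as a rigid cylinder of backbone beads whose half
  height defaults to $T_w/2 + 5$ Å so it always spans the local membrane;
* a small fraction (default 5%) of window lipids whose phosphate dwells near
  the mid-plane, emulating deeply coordinated headgroups and giving the
  K = 3 fit a genuine third population;
* the ten-species ER model composition
  (DYPC:YOPC:POPI:PYPI:DYPE:YOPE:ERGO:YOPA:YOPS:POPS at
  42:28:21:14:10:10:7:6:6:6), apportioned by largest remainder; a
  single-species POPC mode mirrors control membranes;
* optionally, a uniform water phase outside the membrane slab (the core
  stays dry — there is no pore model);
* replicate band-intensity tables with multiplicative lognormal noise of
  chosen coefficient of variation, for the cleavage statistics.

It does **not** emulate lipid tails, curvature, leaflet asymmetry,
flip-flop, correlated lateral dynamics (an optional AR(1) mode adds temporal
z-correlation only), or protein flexibility. Passing recovery tests on this
generator therefore demonstrates that the *measurement pipeline* is unbiased
and correctly seeded — not that any particular force field or real membrane
behaves this way.

All randomness derives from a single integer seed (per-replicate seeds are
deterministic functions of it), and the generator restores the global RNG
state, so results are bitwise reproducible.

## Numerical choices in the Gaussian fit

Fitting uses bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with the
**analytic Jacobian** of the mixture. We deliberately avoid the
formula-interface wrapper: it finalizes fits through a numeric-derivative
step whose relative step size degenerates when a parameter converges to
zero — and the mid component's mean is ~0 by construction.

* **Initialization.** The two outermost interior local maxima above 20% of
  the profile maximum seed the leaflet means (the threshold rejects
  single-bin counting noise in the tails); their heights seed the
  amplitudes; σ starts at twice the bin width. For K = 3 the mid component
  starts at the inter-peak midpoint with at least 5% of the peak amplitude.
  Fewer than two detectable peaks, or fewer than $2K+1$ nonzero bins, is an
  initialization error naming the profile — never a silent fit.
* **Bounds.** Amplitudes ≥ 0; σ at least a quarter bin width; the mid
  component is confined to the central half of the inter-peak region with
  σ between one bin width and half the peak separation. Without this the
  unidentifiable third component chases individual noisy bins.
* **Profiles are fitted on a unit-peak scale** (amplitudes rescaled
  afterwards) for conditioning; the thickness depends only on the means.
* **Convergence.** The optimizer's own convergence report is accepted; when
  it instead exhausts iterations, up to two warm restarts are tried and the
  fit is accepted if the residual sum of squares has become stationary
  (relative change ≤ 10⁻⁶). If the mid component's amplitude has collapsed
  to zero — the maximum-likelihood answer when the core is empty — the two
  leaflet components are refit alone and the mid component is reported
  explicitly with amplitude 0, flagged in the fit message. A genuinely
  unconverged fit carries `converged = FALSE` and cannot be read for a
  thickness.
* **Uncertainties** are Gauss–Newton standard errors,
  $\sigma^2 (J^\top J)^{-1}$ at the solution.

## Geometry conventions

Helix axes are the vector between the centroids of the first three and last
three residues of a user-supplied residue range (file numbering; ranges are
inclusive, and reversing the range flips the axis). Endpoint centroids of
three residues largely cancel the helical phase offset; the test suite shows
a single-residue endpoint is measurably worse on noisy helices. Crossing
angles are $\arccos$ of the unit-vector dot product in [0°, 180°].
Superposition is Kabsch (SVD with determinant correction, proper rotations
only, collinear selections rejected), cross-checked against a quaternion
oracle. `helix_span()` uses the canonical 1.5 Å per residue rise of an ideal
α-helix; real helices with non-canonical geometry will deviate from it.

## Cleavage statistics

Cleavage efficiency is `cleaved × 100 / (cleaved + full_length)` — scale
invariant, as densitometry units are arbitrary. Profiles report the mean and
*sample* standard deviation (n − 1) across replicates per construct length.
Point-by-point comparisons use two-sided two-sample t tests — Welch by
default, pooled-variance Student optionally — annotated with the
conventional star ladder (`*` ≤ 0.05 … `****` ≤ 0.0001, inclusive
thresholds). Raw p-values are the primary output, matching the
multiple-individual-tests convention of gel quantification; a Holm-adjusted
column is reported alongside for transparency and never replaces them.

One calibration subtlety the test suite documents: with only three
replicates per group — the typical gel experiment — a *correctly implemented*
Welch test is measurably conservative (empirical type-I rate ≈ 0.035–0.04
at α = 0.05), a known property of the Satterthwaite degrees-of-freedom
approximation compounded by the mild skew of the intensity ratio. The
calibration test therefore asserts the nominal 0.05 ± 0.01 rate at ten
replicates per group, and separately asserts that the three-replicate test
errs on the conservative side, never the anti-conservative one.

## Validation study and problem sizes

`run_validation()` is the end-to-end study: a protein-free bulk reference
and two TM-window systems planted at 38.1 / 20.1 / 23.1 Å, five replicates
of 100 frames with 200 lipids per leaflet and σ = 1 Å vertical noise,
analyzed blind and compared against the planted values with a |bias| ≤
0.5 Å pass criterion per system. These sizes give each window profile a few
thousand phosphate observations — enough that fit noise is a few hundredths
of an angstrom — while the whole study runs in seconds on a single core.
The same configuration, at exactly these sizes, is what
`scripts/acceptance.R` re-runs.

## Known limitations

* The membrane normal is assumed to be z; no normal estimation or curvature
  correction is performed, and only orthorhombic boxes are supported.
* The window annulus samples the thinning funnel over its full 6 Å depth,
  so recovered window thickness carries a small positive bias (a few tenths
  of an angstrom at the default decay length) relative to the value planted
  exactly at the protein surface. This is a property of the measurement
  definition, not a fitting error, and the validation tolerance accounts
  for it.
* Residue renumbering conventions differ between modelling pipelines;
  selections and helix ranges are always interpreted against the numbering
  in the source file, and users must translate published residue ranges
  accordingly.
* No binary trajectory formats (XTC/TRR/DCD) — analyses consume GRO/PDB
  frames or in-memory ensembles.
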