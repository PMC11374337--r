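---
title: "Mapping binding interfaces from HSQC titrations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping binding interfaces from HSQC titrations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspfit)
```

## The problem

When an unlabelled ligand is titrated into a ^15^N-labelled protein and
the pair exchanges quickly on the chemical-shift timescale, every amide
crosspeak in the ^1^H-^15^N HSQC moves continuously from its free
position toward its bound position. The observed shift at each titration
point is the population-weighted average of the two states, so the
displacement of a residue's peak is directly proportional to the bound
fraction of the protein, and the *pattern* of displacements across the
sequence localises the binding interface. `cspfit` implements the full
chain from assigned peak lists to a fitted dissociation constant and a
classified interface, with a synthetic-data generator that makes every
stage testable against known ground truth.

This workflow was built around titrations of integrin β cytoplasmic
tails against the tandem LIM2/3 domains of paxillin (and the reverse
experiment), but nothing in it is specific to that system.

## Combined amide CSP

For residue $r$ at titration point $i$, with shift differences relative
to the free reference $\Delta\delta_H$ and $\Delta\delta_N$ (ppm), the
combined CSP is

$$\Delta\delta = s\sqrt{\Delta\delta_H^2 + w\,\Delta\delta_N^2},
\qquad w = 0.14,\; s = 0.5 .$$

The nitrogen weight compensates for the larger ^15^N shift dispersion
(the widely used Williamson-style convention); the overall scale of 0.5
is cosmetic but kept for comparability with published bar plots. Both
are arguments of `combine_csp()`, so alternative conventions
($w = 0.2$, $s = 1$, ...) are one flag away. The quantity is in ppm,
non-negative, invariant to the signs of its inputs, and monotone in
each of $|\Delta\delta_H|$ and $|\Delta\delta_N|$ — properties the test
suite checks directly.

Peaks are tracked by assignment identity (residue + atom across
tables). Trajectory-based tracking of unassigned spectra is out of
scope: the inputs are assigned peak lists. A residue missing either
amide resonance at a point (proline, overlap, exchange broadening) is
flagged missing at that point and simply dropped from downstream sums —
absence is data, never an error.

## The ligand-depletion binding model

At the concentrations NMR needs (hundreds of μM of labelled protein),
the ligand is consumed by binding and the hyperbolic
excess-ligand isotherm is biased. The exact single-site solution is
quadratic in the complex concentration; in terms of the bound fraction
$f_B$ of the labelled protein $P$ at total ligand $L$:

$$f_B(P, L, K_D) =
\frac{(P + L + K_D) - \sqrt{(P + L + K_D)^2 - 4PL}}{2P}.$$

`fraction_bound()` evaluates the algebraically equivalent form
$2L/\bigl(b + \sqrt{b^2 - 4PL}\bigr)$, $b = P+L+K_D$, which is immune
to the catastrophic cancellation the textbook form suffers when
$4PL \ll b^2$. Tests verify it against an independent equilibrium
root-finder, the $K_D \to 0$ and $K_D \to \infty$ limits, monotonicity
in $L$ and $K_D$, and the symmetry of the complex concentration under
$P \leftrightarrow L$ exchange. Near the stoichiometric point $L = P$
the $K_D \to 0$ limit converges only like $\sqrt{K_D}$; the limit tests
account for that.

Under fast exchange the predicted CSP of residue $r$ is
$\Delta\delta_{r}(L) = \Delta\delta_{max,r}\, f_B(P, L, K_D)$: one
saturation amplitude per residue, one $K_D$ for the site.

## Global fitting

`fit_global_kd()` minimises

$$\sum_r \sum_i \left(\Delta\delta_{obs,r,i} -
\Delta\delta_{max,r}\, f_B(P_i, L_i, K_D)\right)^2$$

with $K_D$ shared across residues and $\Delta\delta_{max,r}$ free per
residue, using Levenberg–Marquardt least squares (`minpack.lm`).
Numerical choices, each of which mattered in practice:

* **$K_D$ on a log scale**, bounded to $[10^{-3}, 10^{6}]$ μM. The
  parameter is positive, spans orders of magnitude, and its residual
  surface is far better conditioned in $\log K_D$.
* **Initialisation**: $K_D$ starts at the ligand concentration where
  the strongest responder crosses half its endpoint CSP (linear
  interpolation); each $\Delta\delta_{max,r}$ starts at the residue's
  endpoint CSP. These are within a factor of a few of the optimum for
  any monotone data set, and the fit is insensitive to them.
* **Unweighted residuals** by default — titration peak lists carry no
  per-point uncertainties. A `sigma` column is honoured when present.
* **Missing points are dropped per residue**, never imputed.
* Each fitted residue must contribute **at least 3 valid points**: its
  trajectory informs two quantities (its amplitude and its share of the
  shared $K_D$), and fewer points leave no residual information.

Residue selection for the fit (`select_fit_residues()`) defaults to
endpoint CSP above the mean + 1 s.d. of all endpoint CSPs with ≥ 3
valid points; an explicit residue list overrides the rule.

Two uncertainty measures are reported and labelled distinctly: the
covariance-based standard error of the converged fit (delta-method
transformed back from the log scale) and a case-resampling bootstrap
percentile interval (`bootstrap_kd()`, resampling residues by default,
observations optionally). They answer different questions — the
covariance error assumes the model and i.i.d. residuals; the residue
bootstrap is dominated by between-residue heterogeneity. With the
handful of residues a typical interface provides, the residue-level
percentile interval undercovers its nominal level (few resampling
units); the observation-resampling variant is the calibrated one, and
it is the one whose coverage the test suite checks against its nominal
95% level over seeded replicates.

Because the model is linear in each $\Delta\delta_{max,r}$ at fixed
$K_D$, the per-residue amplitudes profile out in closed form
($\hat{\Delta\delta}_{max,r} = \sum_i f_i y_i / \sum_i f_i^2$), leaving
a one-dimensional profiled RSS in $K_D$. `profile_kd_grid()` exploits
this as an independent route to the same optimum; the suite requires
the two routes to agree to better than 0.5% in $K_D$ on randomised
instances. Non-convergence and a $K_D$ pinned at a bound are flagged
explicitly, never silently returned as a best effort.

The fit also reports the **endpoint bound fraction**
$f_B(P_{end}, L_{end}, \hat K_D)$ as a saturation diagnostic: weak
interactions rarely reach saturation at feasible titrant
concentrations, and an endpoint fraction well below 1 warns that
$\Delta\delta_{max}$ and $K_D$ are partially degenerate and the $K_D$
accuracy is concentration-limited.

## Interface classification

`classify_by_sd()` implements the standard mean + n·s.d. tier rule:
mean and *sample* (n−1) standard deviation are computed once over all
residues with a defined endpoint CSP — responders and non-responders
alike, with no iterative outlier trimming — and a residue joins the
highest tier whose threshold its CSP *strictly* exceeds (> 1, > 2,
> 3 s.d.). Ties fall to the lower tier. With all-equal inputs the
s.d. is zero and every tier is empty, which the degenerate-case test
pins down. Tiers are nested by construction and invariant to residue
order and to positive rescaling of the data (thresholds scale with the
data).

Endpoint CSPs use the highest-titrant point at which each residue is
valid. The fitted $\Delta\delta_{max}$ is an alternative endpoint
definition; it is available from the fit, but the classification
deliberately uses the observed endpoint so that classification never
depends on fit convergence.

`map_classification_to_structure()` writes tier codes (0–3) into the
B-factor column of a PDB model for surface colouring. Shift-table and
model numbering rarely agree (construct-local vs. full-length), so the
mapping takes an explicit `offset` and first cross-checks amino-acid
types at shared positions — an off-by-one offset almost always breaks
type agreement and is rejected loudly.

## Dynamics and histidine classifiers

Two small rule classifiers round out the interpretation toolkit:

* **hetNOE rigidity** (`classify_rigidity()`): the steady-state
  ^15^N{^1^H} NOE intensity ratio reports ps–ns backbone motion.
  Ratios ≥ 0.8 are labelled rigid, smaller values flexible. The
  inclusive boundary follows the usual reading that 0.8 itself
  indicates rigidity; both the boundary value and, implicitly, its
  inclusiveness are configurable. Ratios outside [−1.5, 1.2] warn —
  they usually indicate an intensity-extraction problem upstream.
* **Histidine zinc coordination**
  (`classify_histidine_coordination()`): in zinc fingers the
  difference δ(C^ε1^) − δ(C^δ2^) discriminates the coordinating
  nitrogen; a difference strictly greater than 17 ppm indicates
  coordination via N^δ1^. Because only that side of the rule is firmly
  established, the other label is the deliberately non-committal
  `Nepsilon2_or_ambiguous`, and the numeric difference is always
  reported alongside.

Both are pure, monotone step functions of their statistic, which the
suite checks property-style.

## The synthetic titration generator

`simulate_titration()` forward-simulates exactly the model the fit
inverts: per point, per residue,

$$\delta_{obs} = \delta_{free} + f_B(P, L, K_D^{true})\,
\Delta\delta_{max} + \varepsilon,$$

independently for ^1^H and ^15^N, with Gaussian $\varepsilon$ applied
to the *shifts* at every point including the free reference — so
reference noise propagates into CSPs exactly as in real data.
Non-binders have zero shift difference plus noise. Whole crosspeaks
(H and N together) vanish independently with `peak_loss_prob`,
emulating exchange broadening as binary peak loss. Defaults: noise
s.d. 0.002 ppm (^1^H) and 0.01 ppm (^15^N), typical peak-position
reproducibility in a well-resolved HSQC; peak loss 2%.

Three presets encode the concentration schedules of the titrations the
package was validated against: `beta3` (P = 300 μM, L up to 900 μM,
true $K_D$ 528 μM, eight C-terminal binders), `beta1` (P = 300 μM, L
up to 650 μM, $K_D$ 52 μM) and `reverse` (P = 250 μM, L up to
2420 μM, $K_D$ 532 μM). Where only endpoint concentrations are
published, intermediate points are interpolated. True per-residue
saturation amplitudes are not published anywhere, so the presets use
an order-of-magnitude ladder (amide ^1^H 0.02–0.15 ppm, ^15^N
fourfold larger); they are recorded in the emitted ground truth and
are simulation inputs, never asserted as literature values.

What the generator does *not* emulate — and therefore what passing
recovery tests do not demonstrate about real data: lineshape and
linewidth effects, intermediate-exchange peak trajectories, correlated
(temperature/referencing) shift drifts, peak overlap, and assignment
errors. The generator validates the *estimator*, not the spectroscopy.

### Validation protocol

The acceptance suite simulates ≥ 100 seeded replicates per design,
runs the full pipeline (profiles → selection → global fit) on each,
and requires the median recovered $K_D$ to fall within the replicate
interquartile range of the generating value; noiseless data must be
recovered to 10^−6^ relative. At these problem sizes (41–120 residues,
4–7 points, 100 replicates) each design takes a few seconds on one
core. One published quantity is *not* reproduced by the pipeline: with
P = 300 μM, L = 900 μM and $K_D$ = 528 μM the endpoint bound fraction
is ≈ 0.58, not the ~70% quoted alongside those numbers; the pipeline
reports its own computed value.

The ungapped LIM2/LIM3 segment-identity check (`segment_identity()`,
39% for P381–D436 vs. P440–E495 of human paxillin isoform a) needs the
reference protein sequence (accession NM_002859.4), which is not
redistributed with the package; supply it as
`inst/extdata/paxillin_isoform_a.fasta` to activate that check. The
identity utility itself is ungapped by design — the compared segments
are equal-length (56 residues) — and general alignment is explicitly
out of scope.

## Known limitations

* One-site, two-state, fast-exchange only. No multi-site or
  cooperative models, no slow/intermediate exchange, no lineshape
  analysis.
* Concentrations are taken per point from the manifest; dilution
  corrections belong upstream.
* The covariance standard error understates uncertainty when residuals
  are structured; prefer the bootstrap interval when the two disagree.
* The NMR-STAR reader covers the assigned-chemical-shift loop of BMRB
  v3 files, not the full STAR grammar.
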