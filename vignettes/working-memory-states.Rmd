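---
title: "Simulating and decoding working-memory states in visual cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding working-memory states in visual cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`wmiem` models a delayed-discrimination working-memory experiment in which
two oriented gratings are briefly shown left and right of fixation and a
retro-cue marks one of them as the item to be tested first. On
remember-both (RB) trials the un-cued item stays relevant for a later
test; on remember-single (RS) trials it can be dropped. Items therefore
pass through distinct functional states during the retention intervals:
*cued* (attended now), *future-relevant* (needed later), and
*future-irrelevant* (discardable). The package provides a generative model
of multivoxel responses in early visual cortex under these states, the
inverted-encoding-model (IEM) and decoding analyses that read the states
out, permutation-based group inference, and a fitting layer that asks
*which* tuning-curve modulation (gain, width, or preferred-orientation
shift) best explains a given reconstruction.

## Trial design

Each run holds 24 trials: the full factorial of condition (RB/RS), cued
side (left/right), and ordered base-orientation pair, where the three base
orientations are 15°, 75° and 135° and the two sides never share a base.
Every orientation is jittered by an integer uniformly drawn from −10..+10
degrees, which yields exactly 63 distinct orientations (3 bases × 21
jitters, non-overlapping because the bases are 60° apart). Jitter
sampling is uniform and independent per side; the design constraint fixes
only counterbalancing of the factorial cells, which
`generate_trial_table()` enforces exactly, not approximately. Inter-trial
intervals are stored as metadata and play no role in analysis.

State labels are a total function of (condition, epoch, side):

| condition | epoch  | cued side | other side |
|-----------|--------|-----------|------------|
| RB        | delay1 | cued      | fut_rel    |
| RB        | delay2 | fut_irr   | cued       |
| RS        | delay1 | cued      | fut_irr    |

with the stimulus epoch labeling both items `stim`.

## The forward model

Voxel responses are generated as `B = W C + ε_BOLD`, with `W` a voxels ×
channels weight matrix drawn uniformly on (0, 1) and row-normalized to
sum to 1 (the distribution's bounds are a modeling choice; only the
relative weight pattern matters after z-scoring). Channel responses are

```
C = M (φ · S + ε_neural),   then floored at 0
```

where `M` tabulates k = 9 idealized tuning channels over the 180°
orientation circle — each channel responds with `cos(π d / 180)^8` at
circular distance `d` from its center — and `S` is the stimulus drive: a
delta at the presented orientation convolved with a circular Gaussian of
amplitude 1 and sd 18°, admitting sensory uncertainty. `φ` scales the
drive (1 during stimulus presentation; smaller values model weakened
memory traces). The neural noise is Gaussian with mean 0.2 and sd 0.05,
read as a positive baseline consistent with the firing-rate floor, and is
added to the 180-point drive before the channel projection (the
parenthesization of the generative equation). The rectification floor is
applied after the projection.

BOLD noise is calibrated so that sd(noiseless signal entries) / sd(noise)
equals 0.7 over all trials and voxels. The SNR definition is not uniquely
determined by that ratio's name; this one is simple, global, and the
simulations are only quantitatively (not qualitatively) sensitive to it.

### State-dependent modulation

During memory, the test-phase channel matrix is a biased version of the
training one. For a channel at circular distance θ from the remembered
orientation:

* **gain** — the channel is scaled by `α = 1 − γ(1 + cos 2θ)`. Positive γ
  suppresses channels near the remembered orientation down to `1 − 2γ`;
  for γ > 0.5 the gain inverts.
* **width** — the tuning exponent becomes `β = 8 e^{−μ(1 − 2 cos 2θ)}`.
  At μ = 0 this is exactly the training exponent, and for μ > 0 channels
  far from the remembered orientation widen. A second convention that
  multiplies an extra factor `e` into the exponent is selectable as
  `width_variant = "printed"`; it is not the default because it fails the
  basic consistency requirement that (γ, μ, ω) = (0, 0, 0) reproduce the
  training channels.
* **shift** — the preferred orientation moves toward the remembered one
  along the shorter arc by `δ = ω d / (1 + e^{−a(d−b)})`, a sigmoid in
  the distance d with fixed slope a = −0.1 and midpoint b = 20°.

Per-state defaults follow the retained/suppressed pattern: `stim`
φ = 0.98; `cued` φ = 0.61; `fut_rel` φ = 0.03; `fut_irr` φ = 0.49 with
γ = 0.95. The last combination inverts the channel gains near the
remembered orientation and produces the negative (inverted)
reconstructions characteristic of discarded items.

A consequence of the firing-rate floor worth knowing: in *noiseless*
simulations, once γ exceeds 0.5 the inverted channel responses are
clipped at zero, so fidelity stops falling and saturates near a small
negative value (with ~10⁻³ non-monotone ripple). With noise present, the
positive neural baseline keeps distant channels active and the inversion
is expressed as a clear relative dip. Parameter-recovery experiments are
therefore run in the γ ≤ 0.5 regime, where the noiseless mapping from
parameters to curves is well conditioned.

## The inverted encoding model

Training data are z-scored per voxel across trials, separately within the
training and test sets of each leave-one-run-out fold, removing
non-orientation-selective baseline differences between epochs. Weights
solve the least-squares problem `B₁ ≈ C₁ Wᵀ` where `C₁` evaluates a
9-channel basis raised to the 9th power at each trial's *exact* jittered
orientation (the IEM is continuous; base bins are used only by the
decoder). Inversion estimates test-trial channel responses
`C₂ = (WᵀW)⁻¹WᵀB₂`, and the reconstruction is the channel-weighted sum of
basis curves, circularly re-centered so 0° is the trial's remembered
orientation. Representational fidelity is the cosine-weighted mean
`RF = mean(r(θ) cos 2θ)` over θ = −90..89°: 0.5 for a pure cosine, 0 for
a flat curve, −0.5 for an inverted cosine — exactly, on the integer grid.

Two numerical points deserve emphasis:

* **Truncated inversion.** Nine `|cos|⁹` channels tile orientation space
  almost perfectly: their sum is constant to ~4·10⁻⁶. After per-voxel
  mean-centering, that constant channel combination is unconstrained by
  the data, and the textbook inverse would amplify it by ~10⁶, burying
  curves (and even fidelity) under noise. `invert_channels()` therefore
  solves through the SVD of `W` and projects out directions whose
  singular value falls below 10⁻⁸ of the largest. On well-conditioned
  weights the result equals the printed formula to machine precision
  (asserted in tests at 10⁻¹⁰).
* **Noiseless degeneracy.** The exponent-8 training channels tile
  *exactly* (their harmonics all alias to the constant under 9-fold
  sampling), so noiseless z-scored training data are exactly rank 8.
  Noiseless round-trip checks and noiseless model fits therefore run
  without z-scoring — there are no baseline shifts to remove in that
  regime — and `fit_config()` ties the z-scoring default to the noise
  flag.

The simulation analysis exponents follow the two printed conventions:
analysis basis 9th power, simulated tuning 8th power, both configurable.

## Decoding

The decoder is a three-class, one-vs-rest logistic regression on base
bins with an L2 penalty of 10, defined as the coefficient of
`‖β‖²/2` added to the summed negative log-likelihood (intercepts
unpenalized); dividing by the training-set size converts it to
per-observation parameterizations such as glmnet's λ. "Evidence" for a
bin is the fitted one-vs-rest probability, normalized across the three
bins (the normalized reading of an evidence score that the original
toolbox leaves undefined; raw probabilities are also returned). The
decoding statistic is the evidence for the tested (contralateral) item's
bin minus the evidence for the bin absent on that trial, which cancels
the large baseline shifts between epochs with and without stimuli on
screen. Permutation refits use a fixed-Hessian (majorized) Newton solver
that factors `XᵀX/4 + penalty` once per fold and is verified against the
exact solver.

## Permutation inference

Null distributions shuffle *training* labels only, within runs, moving
whole trials so left/right orientation pairings stay intact; per-run
label counts are preserved exactly. Each of the 1,000 default
permutations retrains the model (weights or classifier) and re-scores the
unchanged test data. At the second level, per-participant means are
summarized by a signed-rank statistic against zero — the signed sum of
ranks; any strictly monotone variant gives identical p-values, since only
the statistic's rank among its permutation distribution matters.
One-tailed p-values are exceedance fractions with ties counted as
exceeding (conservative); the two-tailed p doubles the smaller one-tailed
p, capped at 1. A fraction of 0 is reported as "< 1/n_perm" while the raw
value is kept in machine-readable output. State differences use the same
machinery on difference scores, and the omnibus comparison across the
three delay states is a permutation repeated-measures ANOVA (observed F
against the permuted F distribution).

With six participants the signed-rank statistic saturates whenever all
six means share a sign, so the attainable two-tailed p is bounded below
by twice the fraction of null iterations that are unanimous in sign —
about 2/64 under a symmetric null. This is a property of the design size,
not of the implementation, and it is why group p-values here should not
be read below ~0.03.

## Model fitting

Fitting asks which modulation parameters (φ, γ, μ, ω) make simulated
reconstructions match target curves. To limit over-fitting, the state
curve (re-centered on the remembered orientation) and the companion curve
for the held-out orientation are fit *simultaneously*; the cost is the
summed squared error over both. Each cost evaluation simulates fresh
datasets (averaged over `n_rep` replicates, default 5) with seeds derived
deterministically from the fit seed, so the objective is reproducible and
refinement cannot chase noise. Initialization is a full-factorial grid of
11 steps per free parameter (the one-at-a-time reading of "independently
varying each parameter" cannot seed a joint optimum and is provided only
as an option); refinement is Nelder-Mead on a sinusoidal
reparameterization that enforces the bounds (−1 ≤ γ, μ ≤ 1; 0 ≤ ω, φ ≤
1), returning the best candidate ever evaluated so the refined error
never exceeds the grid error. On noiseless targets generated at a grid
vertex the fit returns that vertex exactly.

Model comparison uses nested F-tests with the data's effective degrees of
freedom taken as 24 (8 tuning curves × center/height/width — kept as
printed even though the analysis basis has 9 channels, a tension the
source leaves unresolved) and a parameter count of 6 fixed generative
parameters plus the free ones. That is the only counting that yields the
reference df of (1, 16) when testing memory-strength-only against memory
strength + gain, and it is asserted in tests. Assessment quantities (R²,
adjusted R², the fraction of curve points within one between-subject
standard error of the target) are computed on the state-of-interest
curve; fitting targets are grand means across participants.

A note on the memory-strength-only fit to gain-suppressed targets: its
optimum lies at the boundary φ = 0, whose simulated curve is signal-free
noise — the sign of its correlation with the target is a coin flip across
seeds. The deterministic content of the claim "memory strength alone
cannot mimic suppression" is that *every* nonzero-φ reconstruction (a
positive peak) anticorrelates with an inverted target, and that is what
the test suite asserts, together with the low φ-only R² and the nested-F
rejection.

## What the generator does and does not emulate

The pseudo-experiment stands in for unavailable fMRI data: two
hemisphere-equivalent pools of 200 voxels, each representing only the
contralateral item (no reliable ipsilateral representations being
modeled), 18 runs of 24 trials, six participants. It emulates the
design's counterbalancing, the state-dependent representation strengths,
an SNR of 0.7, and run-matched train/test structure. It does **not**
emulate hemodynamic convolution or temporal autocorrelation, spatial
noise correlations between voxels, voxel selection from a localizer,
attention or arousal drifts, or trial-to-trial variability in the
modulation parameters themselves. Passing tests therefore demonstrate
that the analysis machinery is correct and that the modulation account is
internally consistent and recoverable — not that real cortex implements
these modulations.

## Problem sizes used by the test suite

Unit tests run at reduced sizes (2–4 runs, 16–60 voxels) chosen so the
full suite completes in minutes while every check retains its power: the
type-I calibration uses 200 null replicates of a 6-participant,
2-run, 16-voxel design at 200 permutations; parameter recovery uses
noiseless 2-run, 40-voxel simulations over 20 planted (φ, γ) pairs;
mechanism dissociation uses noisy 4-run, 60-voxel simulations with
2-replicate cost averaging; and the end-to-end state-pattern check runs
the full 18-run, 200-voxel, 6-participant design with 600 fidelity
permutations and 60 decoder permutations. The pipeline default remains
1,000 permutations.

## A short session

```{r example}
library(wmiem)

# design and data for one simulated participant
tab <- generate_trial_table(n_runs = 18, seed = 1)
part <- simulate_pseudo_experiment(tab, seed = 2)

# IEM + decoder, with permutation nulls
res <- analyze_participant(part, n_perm = 200, seed = 3)
res$rf   # per-state mean representational fidelity
res$ev   # per-state mean evidence difference

# the full group, with inference
group <- run_group_analysis(n_participants = 6, seed = 1, n_perm = 1000)
summary(group)

# which mechanism explains the discarded state?
targets <- group_fit_targets(group, "fut_irr")
cmp <- compare_mechanisms(targets, fit_config(n_runs = 6, n_rep = 2),
  seed = 4
)
cmp$table
cmp$comparisons[["phi_vs_phi+gamma"]]
```
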