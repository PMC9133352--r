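---
title: "Hemodynamic cloud features for aneurysm rupture-status classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemodynamic cloud features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Scalar descriptors of an intracranial aneurysm — its morphology (height,
neck width, aspect and size ratio, area, volume) and cycle-averaged
hemodynamics (wall shear stress, oscillatory shear index, low-shear area,
energy loss) — are the workhorses of rupture-risk modelling. They discard,
however, the *spatial arrangement* of the flow: where the inflow jet
strikes the dome, whether the impingement is a single focused patch or a
set of scattered foci, how wide the high-velocity footprint is. This
package implements an integrated pipeline that quantifies exactly that
residual information: it feeds the point cloud of the impingement zone and
inflow jet through a permutation-invariant point-set network, max-pools a
1,024-dimensional "hemodynamic cloud feature", and measures — under
repeated stratified cross-validation — how much five standard classifiers
gain when that feature block is added to the 28 scalar descriptors.

Because patient-specific CFD datasets of this kind are not publicly
deposited, the package ships a fully synthetic cohort generator whose
class signal can be placed *only* in the spatial pattern, *only* in the
scalar descriptor means, in both, or nowhere. The pipeline's claims are
therefore tested as properties: spatially-coded cohorts must be invisible
to the scalar descriptors but visible to the cloud feature, and
signal-free cohorts must yield chance performance.

## Synthetic sacs and fields

### Geometry

A sac is a point-sampled spherical cap: a sphere of radius $r$ cut by the
neck plane implied by the neck (ostium) width $w$, giving dome height
$h = r + \sqrt{r^2 - (w/2)^2}$. Points are drawn area-uniformly (uniform
height, uniform azimuth — Archimedes' hat-box), an explicit ring of points
marks the neck curve, and the apex is included exactly. Per-point area
weights split the analytic zone area $2\pi r h$ evenly; "irregular" sacs
superimpose 2–3 smooth radial lobes (daughter-sac-like bumps) on the dome
with the weights rescaled by the squared radial stretch. Cohort parameter
ranges — radius 1.8–4.2 mm, neck 1.0–1.9 × radius (capped at the equator),
parent vessel 2.8–4.6 mm, 35% irregular, 45% bifurcation — are typical of
clinical series of internal-carotid aneurysms; both flags and all geometry
parameters are drawn independently of class so that geometry never carries
label information.

### Pulsatile fields

The inlet waveform is a two-harmonic positive pulse (cycle 0.8 s sampled
at 0.01 s, i.e. 80 frames; systolic peak at 0.12 s; mean speed 0.35 m/s).
The WSS vector at surface point $p$ and time $t$ is

$$\tau(p,t) = B(p)\, m(t)\,\bigl[\cos(\theta(p)s(t))\,e_1(p) +
\sin(\theta(p)s(t))\,e_2(p)\bigr] + \varepsilon,$$

where $B$ is the spatial magnitude profile (Pa), $m(t)$ the waveform shape
normalized to mean 1, $s(t)=m(t)-1$ its zero-mean fluctuation, $e_1,e_2$
an orthonormal tangent frame, $\theta$ a smooth "oscillation" field, and
$\varepsilon$ i.i.d. Gaussian component noise (default sd 0.08 Pa).
Rotating the direction rather than adding a transverse component is a
deliberate choice: it decouples the OSI structure from every
magnitude-based descriptor exactly, and it makes OSI vanish identically
for a flat waveform ($s \equiv 0$), which pins down the degenerate-case
contract.

The magnitude profile $B$ is a baseline (1.2 Pa) plus a jet-impingement
patch (Gaussian lobes, amplitude 3 Pa) minus a low-shear "shadow" dip in
the lower dome; the near-wall velocity channel shares the patch footprint.
Pressure is a smooth head plus a small patch elevation. Inlet/outlet
energy states are drawn dissipative so the energy loss is positive.

### Where the class signal lives

* **summary** mode: ruptured sacs get 15% higher WSS magnitudes, 12%
  higher velocities and 30% stronger oscillation, with identical spatial
  texture generation. Scalar descriptors separate the classes.
* **spatial** mode: ruptured sacs concentrate the whole patch load in a
  single lobe ($\sigma = 1$ mm); unruptured sacs fragment the same load
  into three smaller foci ($\sigma = 1/\sqrt3$ mm, equal peak amplitude)
  scattered over the dome. To keep the scalar descriptors blind to this,
  the area-weighted mean, the peak and the trough of the per-subject
  profile are pinned by a two-sided affine rescale with an exact mean
  restore, and the pinning targets themselves carry class-independent
  between-subject jitter (±8–12%), the way real sacs differ in baseline
  and peak shear. Without the pinning, lobe-count extreme-value effects
  (the maximum of several noisy sites grows with the number of sites)
  leak into `wss_max`-type descriptors; with it, the residual
  standardized class gaps of all 18 descriptors sit at the weak-signal
  floor (|d| ≲ 0.25 on 300-subject runs), while the paired class means of
  `wss_avg` and `osi_avg` agree to well within half the noise sd.
* **both** applies both mechanisms; **none** makes classes exchangeable.

What the generator does *not* emulate: vortex structures and secondary
flows, wall thickness/compliance, spatially correlated measurement noise,
inter-subject waveform variability, and any realistic covariance between
morphology and hemodynamics. Passing tests on these cohorts therefore
demonstrates that the *pipeline* extracts spatial-pattern information
when it is present and fabricates none when it is absent — not that the
synthetic fields are hemodynamically realistic in detail.

## Descriptors

**Morphology (10):** neck width (largest distance across the neck ring),
height (distance from the least-squares neck plane to the dome; a
max-distance-from-centroid variant is exposed as an option), parent-vessel
diameter, size ratio SR = height/vessel diameter, aspect ratio AR =
height/neck width (the dominant literature definitions — the quantities
are conventionally named but not uniquely defined), surface area (sum of
the area weights), volume, S/V, shape and location flags. Volume uses the
divergence theorem $V = \tfrac13\oint (x-c)\cdot n\,dA$ about the
neck-ring centroid $c$, with the neck opening closed by a flat disk; the
centroid origin makes the discrete estimate exactly translation-invariant
even though the sampled flux is only approximately closed.

**Hemodynamics (18):** max/area-weighted-mean/min of systolic WSS
magnitude, TAWSS, OSI, pressure and velocity, plus the high-OSI area
fraction (OSI > 0.2), the low-shear area fraction (TAWSS < 10% of the
parent-artery reference) and the energy loss
$\sum_{in}(P+\tfrac{\rho u^2}{2})Q - \sum_{out}(P+\tfrac{\rho u^2}{2})Q$
with blood density 1,060 kg/m³. The OSI uses the standard definition
$\tfrac12(1 - \lVert\int\tau\,dt\rVert / \int\lVert\tau\rVert\,dt)$, set
to 0 where WSS vanishes all cycle. Cycle integrals use the periodic
trapezoidal rule on the uniform frame grid (equivalently the frame mean),
which is exact for frame-wise constant series and spectrally accurate for
smooth ones; tests pin it against `integrate()` at `1e-3` relative. The
LSA (10%) and HOA (0.2) thresholds are common literature conventions and
both are configurable, as no single standard exists. Statistics are
area-weighted, not count-weighted, because the clouds are surface samples
of unequal density. The systolic frame is the argmax of the inlet
waveform.

## Regions and the point-set network

The impingement zone is the set of points with systolic WSS above 80% of
the sac maximum (strict `>`, with a `>=`-at-max fallback so uniform
fields keep their argmax), unioned with the jet's surface footprint (points
within 10% of sac height of the maximum-velocity point — the footprint
radius is a geometric operationalization of a concept usually shown only
pictorially). The inflow jet is the analogous 80% rule on the velocity
channel. From the union, N points (default 5,000; desk-scale runs use
128–512) are sampled uniformly — without replacement when the region is
large enough, with replacement otherwise so N stays fixed — and assembled
into an N×8 matrix with the fixed column order
`(x, y, z, wss_sys, osi, pressure, velocity, tawss)`.

The extractor is a compact point-set network: an input T-net (a small
shared-MLP/max-pool network predicting an 8×8 affine applied to each
channel vector), a shared MLP lifting 8→64→64, a feature T-net (64×64), a
second shared MLP lifting 64→128→1024, and a channel-wise max over points.
Max-pooling over the point dimension is what buys exact permutation and
duplication invariance, which the tests assert to 1e-6 over 100 random
permutations; both T-nets are zero-initialized onto the identity. Training
attaches a 512–256–2 softmax head on rupture labels (cross-entropy, Adam,
mini-batches of subjects) with an orthogonality penalty
$\lVert I - TT^\top\rVert_F^2$ (weight 1e-3) on the feature transform.
Input channels are z-standardized with training-subject statistics stored
in the checkpoint. All layers and the full backward pass are implemented
as dense matrix algebra; gradients are verified against central finite
differences to ~1e-8 relative in the tests.

Two choices here were genuinely open. First, the supervision signal: a
rupture-label head is the standard usage of this architecture family and
is what we adopt; the 1,024-vector is read off *before* the head. Second,
evaluation hygiene: cloud features for cross-validation are produced by an
extractor retrained on the training folds of every split (`extractor =
"fold"`), so a test subject's feature never saw its label. A single-fit
mode (`extractor = "single"`) is kept for comparison; it is optimistically
biased and not used in any reported number.

## Feature groups and preprocessing

Group A is the 28 base descriptors, z-normalized. Group B appends the
cloud-feature block processed as normalize → RFE → kernel PCA: the 1,024
columns are screened to 64 by recursive feature elimination (linear-kernel
SVM weights as importance; the wide block uses fractional elimination,
halving per iteration, while the exported `rfe_select()` defaults to
classic one-at-a-time) and reduced to 16 RBF-KPCA components with the
median-heuristic bandwidth. All counts and the kernel are configurable.
Applying the reduction pipeline only to the cloud block — leaving the 28
interpretable descriptors untouched — is this package's resolution of an
ambiguity in how such pipelines are usually described; it keeps group A
nested in group B so the comparison isolates the cloud features'
contribution. Every fitted transform (scaler, RFE subset, KPCA map, and
the extractor itself) is fold-contained: fitted on training rows, applied
to held-out rows.

## Evaluation design

Stratified k-fold (default k = 10) is reshuffled per repetition with
derived seeds; stratification matters because a ~26% minority class makes
unstratified 10-folds occasionally single-class. Per repetition, fold test
scores are pooled and summarized once into accuracy, AUC (rank statistic
with midrank ties), sensitivity and specificity, with ruptured as the
positive class and a 0.5 probability threshold. The per-model
hyperparameters are fixed defaults (RF 300 trees; KNN k = 5; XGB 60
rounds, depth 3, η = 0.1, single-thread; SVM RBF, C = 10, γ = 1/p on
pre-normalized features — at C = 1 an RBF-SVM on a ~26%-minority cohort
collapses to base-rate voting and its accuracy saturates at the majority
fraction, while C = 10 commits to decisions (optional inverse-frequency
class weights are exposed but off by default, as they overshoot the
operating point toward sensitivity) — scores via the logistic of the
decision value; ridge logistic λ = 0.05) and stay constant across
repetitions. The
repetition-level AUC interval is the normal approximation
$\bar x \pm 1.96\,s/\sqrt{n}$. Feature groups are compared by a two-sided
Wilcoxon signed-rank test on per-repetition metric differences — exact
null for n ≤ 25 without zeros/ties, normal approximation with continuity
correction otherwise, p = 1 flagged degenerate when all differences
vanish; the exact branch is pinned against full $2^n$ enumeration in the
tests.

One subtlety of null calibration deserves a note: repeating CV on a
*fixed* small cohort with one fixed label shuffle does not drive the AUC
to 0.5, because every repetition re-measures the same spurious
separability of that single pseudo-labelling — at 60 subjects the
dataset-level spread of that quantity is roughly ±0.15. The calibration
check therefore re-permutes the labels independently for every
repetition, i.e. it samples the permutation null, whose mean over 10
repetitions sits tightly at chance.

The headline experiment runs the five-classifier comparison on a
60-subject spatial-mode cohort with 6 repetitions of stratified 10-fold
CV. Six repetitions rather than five is a deliberate design point: the
smallest attainable two-sided exact signed-rank p with n pairs is
$2/2^n$, so n = 5 cannot reach 0.05 even when group B wins every
repetition, while n = 6 can (p = 0.03125).

## Numerical and scale choices

* Desk-scale problem sizes: 60 subjects at 500 surface points, region
  sample N = 128, 10 epochs, batch 18, learning rate 2e-3. The full-size
  settings (5,000-point regions, deeper schedules) are plain config
  changes. With per-fold extractor retraining the headline experiment is
  ~10 minutes on one CPU; the demonstration preset (24 subjects, N = 64,
  2 repetitions) runs in about a minute.
* Every generator, sampler and trainer is a pure function of its seed;
  sub-seeds are derived arithmetically and kept within 32-bit range, and
  generators restore the caller's RNG state.
* Degenerate inputs have documented conventions: OSI of an all-zero
  series is 0; uniform fields fall back to `>=`-at-max region masks;
  constant feature columns normalize to zero with a warning; all-zero
  paired differences give p = 1.
* Report files are written with fixed 10-digit formatting so identical
  configurations are byte-identical.

## Known limitations

The synthetic cohort is a property-testing instrument, not a hemodynamic
simulator: absolute metric values on it do not transfer to patient data,
and no claim about clinical performance follows from these experiments.
The jet/impingement proxy uses near-wall velocity rather than true
streamline integration (the generator provides no volumetric field). KNN
probabilities are vote fractions of k = 5 neighbours, so its AUC is
coarse at small n. Training the extractor inside every fold is honest but
expensive; at 100 repetitions × 10 folds it is the dominant cost, which
is why the shipped experiment uses 6 repetitions at desk scale.
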