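---
title: "Prospective E-field-informed TMS motor mapping with farthest point sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prospective E-field-informed TMS motor mapping with farthest point sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpsmap)
```

## The mapping problem

TMS motor mapping asks which cortical compartments drive a peripheral
muscle. The statistical approach regresses motor evoked potential (MEP)
amplitudes onto the induced electric-field magnitude |E| at each
compartment of a region of interest (ROI): for every compartment a sigmoid
input-output curve is fitted across stimulations, and the per-compartment
coefficients of determination form an R² map whose peak is read as the
muscle representation. Because a session affords only a few hundred pulses,
the *choice* of coil configurations matters: randomly placed coils produce
many redundant |E| patterns, wasting trials.

`fpsmap` implements the prospective alternative: given a pre-computed
candidate set of |E| maps (one per coil position × orientation), *farthest
point sampling* (FPS) greedily selects, at each step, the candidate whose
minimum Euclidean distance to the already-selected maps is maximal,

$$ s_n = \arg\max_{E_c \in C \setminus S} \; \min_{E_j \in S}
   \lVert E_c - E_j \rVert . $$

The first sample is drawn uniformly at random; ties in the argmax resolve
to the smallest candidate index so runs are reproducible across platforms.
The selection order is invariant to a global positive rescaling of the
maps, so it does not matter whether candidates are stored at the reference
or at the mapping intensity.

The package bundles everything needed to run the benchmark end-to-end with
no external data: synthetic folded-cortex geometry, a parametric |E| model
standing in for FEM simulation, a generative MEP model, the R²-map
estimator, overlap scoring, EMG preprocessing rules, and the experiment
drivers. Externally computed candidate matrices (e.g. from an FEM
pipeline) can replace the parametric model through
`load_candidates()` without any other change.

## The generative MEP model

Excitability of compartment $k$ for a muscle representation centred at
$k_{\max}$ is a geodesic Gaussian (the *MEP generation map*, MGM):

$$ m_k = \frac{1}{\sigma\sqrt{2\pi}}
   \exp\!\left(-\tfrac{1}{2}\frac{d(k, k_{\max})^2}{\sigma^2}\right), $$

with $d$ the geodesic distance along the cortical patch and $\sigma$ the
spatial extent. The formula is applied literally per compartment, with no
renormalization after discretization; note that because the 1-D Gaussian
prefactor meets a 2-D surface, the discrete mass
$\sum_k m_k\,a_k$ approximates $\sigma\sqrt{2\pi}$ (not 1) on a fine flat
patch — the tests assert exactly that, and any scale effect is absorbed by
the turning-point calibration below.

Stimulation strength is the inner product $x = \langle M, E\rangle$; the
clean response is the sigmoid
$y = y_{\max} / (1 + e^{-k(x - x_0)})$; noise is zero-mean Gaussian with a
sigmoid-modulated standard deviation
$P / (1 + e^{-k(x - x_0)})$, so it saturates at $P$ for strong stimulation
and vanishes for weak stimulation; finally $\tilde y = \max(0, y +
\varepsilon)$, since peak-to-peak amplitudes are non-negative. Clamping
happens only after noise addition — the clean response is already
positive. MEP waveform morphology and latencies are not modelled.

### Parameter defaults and why

Numerical values for $\sigma$, $\psi = \{x_0, y_{\max}, k\}$ and $P$ are
deliberate package choices, set once to values a motor-mapping
practitioner would call plausible:

* `sigma = 5` mm — a focal hand-muscle representation a few compartments
  wide; smaller values make every mapping harder (tested behaviour, not a
  tuned constant).
* `ymax = 1` mV — a typical FDI saturation amplitude.
* `noise_p = 0.2 * ymax` — trial-to-trial MEP variability of tens of
  percent near saturation, at the conservative end of what EMG shows.
* $x_0$ — the median of the noise-free strength sweep over the candidate
  set, and the slope $k = 8/(q_{90} - q_{10})$ of that sweep, so the
  central 80 % of candidate stimulations spans the active range of the
  sigmoid. Crucially, this calibration is done **once per fixture**,
  anchored at the crown-centre placement (`fixture_mep_params()`): the
  analog of fixing the stimulator output relative to the resting motor
  threshold at the motor hotspot. Representations in attenuated-field
  regions are then genuinely harder to map, as in a fixed-intensity
  experiment; recalibrating per placement would erase that physics.

## Synthetic geometry and the parametric field

The ROI is a jittered triangulated disc with a sinusoidal fold,
$z = A\sin(2\pi y/\lambda)$; sulcal depth is the vertical drop from the
crown envelope, shifted to a zero minimum. Defaults ($A = 7$ mm,
$\lambda = 24$ mm, patch radius 25 mm, ~1560 triangles, analysis cylinder
20 mm → ~1000 compartments) give gyral-crown, sulcal-wall and fundus bands
at scales resembling the precentral gyrus. Compartments are the surface
triangles; their centroids carry all distances.

Geodesics are shortest paths on the compartment adjacency graph with
centroid-Euclidean edge weights. One-ring (vertex-sharing) adjacency is
augmented with chords to all two-ring neighbours, which widens the
available move directions enough to keep the worst-case metric stretch on
a flat patch under 5 % — sufficient for every metric derived from the
distances (MGM shape, peak distances, MDS flattening). The backend is
pluggable (`ring`, `adjacency` arguments) and the exact-geodesic
alternative was judged unnecessary at this accuracy. Two-ring chords can
slightly undercut a strongly folded surface; at the default fold scale the
effect is below the jitter-induced irregularity. The 2-D views come from
classical multidimensional scaling of the geodesic matrix
(`flatten_mds()`), used for reporting only — the eigendecomposition is
deterministic, which is why the function takes no seed.

The parametric |E| model for a coil at tangent offset $(x, y)$ with
orientation $\alpha$ is

$$ E_k = A_0 \, e^{-\rho_k^2 / 2\lambda_k^2} \,
   e^{-(\text{depth}_k + \text{standoff})/\delta}
   \left(1 + \beta\cos 2(\alpha - \phi_k)\right), $$

clipped at zero, 180°-periodic in $\alpha$ (which is why orientations at
and beyond 180° are excluded from grids). $\phi_k$ is the local fold
direction from the triangle's height gradient. The lateral spread grows
with depth, $\lambda_k = \lambda + c\,(\text{depth}_k + \text{standoff})$
with $c = 0.5$: induced fields lose focality with coil-to-cortex
distance, so deep compartments see smoother, mutually correlated maps.
This term is what makes representations inside the fold genuinely harder
to localize — with a depth-independent spread, the multiplicative noise
model scales signal and noise identically in the sigmoid's lower tail and
the fold penalty disappears, contrary to what field-based mapping shows.
A consequence is that depth-monotonicity of the field holds near the coil
axis but not arbitrarily far off-axis; the tests check the property in
the regime where it is physically expected. Defaults: peak 1.5 V/m at the
1 %-MSO reference (linearly scaled to the mapping intensity, default 60 %
MSO), $\lambda = 10$ mm, $\delta = 12$ mm, $\beta = 0.2$.

## Mapping, scoring and the benchmark

Per-compartment sigmoid fits use an own Levenberg–Marquardt optimizer
with analytic Jacobian (C++), initialized at
$y_{\max,0} = \max y$, $x_{0,0}$ = the $y$-weighted median of the
predictor, slope $4 y_{\max,0}/\text{range}(x)$, and bounded by
$y_{\max} \in (0, 2\max y]$, slope $> 0$. The goodness of fit is
$R^2 = 1 - SS_{res}/SS_{tot}$ floored at 0 to preserve the $[0,1]$ map
contract; constant responses, constant predictors and non-convergent fits
are flagged failed with $R^2 = 0$. A stalled damping parameter (no
possible improvement) counts as convergence — it is a local minimum;
only iteration exhaustion is failure. The compiled fitter exists because
the benchmark refits on the order of $10^6$ curves; `minpack.lm::nlsLM`
serves as an independent cross-check in the test suite.

Two maps are compared by the normalized inner product (cosine overlap)
$\mathrm{score}_f = \langle R^2_{ref}, \hat R^2\rangle /
(\lVert R^2_{ref}\rVert\,\lVert \hat R^2\rVert) \in [0, 1]$,
and by the geodesic distance between their peaks. The
samples-to-criterion count $n_{95}$ is the smallest evaluated sample
count whose score strictly exceeds 0.95 against the reference; curves are
evaluated every other sample (stride 2) and runs that never cross within
the budget of 150 are censored at 150 and included at that value in all
summaries (linear-interpolation percentiles, `stats::quantile` type 7).
All-zero subset maps score 0 by convention (no recovered structure).
Because curves need not be monotone, $n_{95}$ is found by a linear scan
with early stopping, never bisection.

Three reference-map modes mirror the three analyses: the generating MGM
(placement sweep), a high-resolution map fitted from a dense 2 mm / 10°
grid (12,762 configurations; sample-efficiency benchmark), and the
all-samples map (for subset-versus-target analyses of experimental
blocks).

`run_subsampling_experiment()` crosses 10 sampling seeds with 5 noise
seeds (50 paired runs) for each of three placements (crown-centre,
wall-centre, crown-edge) and both methods. The noise stream is indexed by
candidate, so paired methods see identical noise for identical
configurations — a variance-reduction contract the tests assert. FPS
selections depend only on the maps and the sampling seed and are computed
once and shared. Problem sizes (~1000 compartments, 2034 candidates, 50
pairs) are the package's default study conditions; they complete in
minutes on one CPU while leaving the orderings of interest clearly
resolved.

## EMG preprocessing

Trial-level rules mirror a standard recording chain at 5 kHz: the MEP
peak-to-peak amplitude is the max-minus-min over the inclusive 18–35 ms
post-stimulus window (timestamps round to the nearest sample), and a
trial is rejected when pre-stimulus activity in the 100 ms before the
pulse strictly exceeds 50 µV peak-to-peak — "exceeding" reads as strict,
so exactly 50 µV keeps the trial; window bounds are inclusive since the
convention is unstated in the protocols this follows. Extraction is DC-
offset invariant and rejection is monotone in the threshold.

## What the synthetic fixture does and does not show

The generator emulates the features that drive sampler behaviour:
crown/wall/fundus depth structure, distance- and depth-attenuated,
orientation-sensitive candidate maps with realistic mutual correlations,
sigmoidal input-output with heteroscedastic noise, and censored
samples-to-criterion outcomes. It does not emulate subject anatomy, FEM
field detail, coil-cortex distance variability, physiological drift or
multi-muscle representations — so passing benchmarks here demonstrate the
*relative* sample-efficiency ordering of FPS versus random sampling under
controlled conditions, not absolute trial counts for any human
experiment. Known limitations carried over from the method itself: FPS is
biased toward high-|E| (crown) regions; R² maps assume a single
compartment drives the response and can be spatially inconclusive for
multimodal representations.

## Numerical and degenerate-input conventions

* Distances: plain Euclidean over length-K map vectors, no normalization;
  FPS ties (duplicate maps) resolve to the smallest index, and a
  duplicate of a selected map is never chosen while any candidate has
  positive distance.
* Cylinder membership is closed (boundary compartments included); the
  coil lattice is axis-aligned and origin-anchored.
* Disconnected meshes are rejected naming the isolated compartments; the
  patch generator keeps the largest connected component of the jittered
  triangulation.
* CSV persistence writes doubles with 17 significant digits, so
  candidate-set and mesh round trips are exact.
* Random draws always flow through one explicit integer seed per call;
  the caller's RNG state is saved and restored.
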