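---
title: "beatflow: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{beatflow: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatflow)
```

# The problem

Cultured cardiomyocyte monolayers beat spontaneously. Label-free time-lapse
microscopy (brightfield or phase contrast, typically 10 frames/s) records
the resulting tissue motion, but raw motion is an ambiguous readout: a high
cell density culture is a mechanical continuum, so passive tissue far from
an actively contracting cell group can move as much as the contracting cells
themselves. `beatflow` implements a pipeline that

1. estimates dense displacement fields between frames by block-matching
   particle image velocimetry (PIV),
2. condenses them into beat patterns and beat frequencies, and
3. converts them into *convergence* maps — the negative divergence
   $C = -\nabla\cdot u$ — which, under an elastic-sheet model of the
   monolayer, is the quantity proportional to local active contractility
   rather than to passive motion.

The package also contains the forward elastic model itself (closed-form and
numerical solutions) and a synthetic movie generator driven by that model,
so every stage of the pipeline can be validated against exact ground truth
without any external data.

# Optical flow by two-pass block matching

Each frame pair is analyzed with overlapping square tiles. For a tile of
brightness $h_1(x)$ in the first image, every integer shift within the
search range in the second image is scored by the cross-correlation
$\sum_x h_1(x) h_2(x)$, and the best-scoring shift is taken as the tile's
displacement. A first pass uses 64-px tiles and a ±32 px search; the sparse
result is smoothed by a thin-plate spline and used to predict, at each node
of a finer 32-px-tile lattice, where a ±4 px second-pass search should be
centered. Displacements are therefore integers, bounded by
`coarse_search + fine_search`.

Design points worth knowing:

* **Score variants.** The raw product score degenerates under uneven
  illumination, so by default tiles are mean-subtracted first
  (`score = "zero_mean"`); the raw score remains available. Neither variant
  is normalized by tile variance, and this has a real consequence: the
  score is biased toward high-variance windows, so on very smooth textures
  (Gaussian correlation length ≳ 1.5 px) a neighboring window can outscore
  the exact match by a pixel even for a rigid shift. On fine-grained
  speckle — which is what cell-culture images at this magnification look
  like, and what the synthetic generator produces by default (correlation
  length 1.2 px) — recovery of integer rigid shifts is exact at every
  interior node. `score = "ncc"` (true normalized cross-correlation) is
  provided for material where the bias matters.
* **Integer displacements, no sub-pixel peak fit.** This keeps the matcher
  exactly equivalent to its brute-force oracle, at the cost of ±0.5 px
  quantization; mean traces inherit a ripple on the order of 0.1 px, which
  matters when choosing extrema thresholds (below).
* **Ties** between equal scores go to the smallest shift magnitude, then
  row-major scan order, making results fully deterministic.
* **Masking, not clamping.** Nodes whose tile or full search window leaves
  the frame, and zero-contrast (flat) tiles, are masked; downstream
  statistics use valid nodes only.
* **Thin-plate spline.** The classic $r^2\log r$ radial-basis interpolant
  with an affine part, ridge-regularized on unit-normalized coordinates.
  Smoothing 0 interpolates exactly; affine fields are reproduced for any
  smoothing. The default weight (1) was calibrated once so that a single
  8 px outlier among an 8×8 uniform field is attenuated below 2 px — the
  spline only needs to be good enough to center a ±4 px second-pass search.
* **Coordinates.** Matrices are indexed (row = y, col = x); node pixel
  coordinates are 1-based, x rightward, y downward. A displacement
  (ux, uy) means the tile content moved by that many pixels from the first
  to the second frame.

# Beat patterns

The mean motility trace is $V(t) = \langle |v(t,x)|\rangle_x$ over
consecutive-pair flows (mean of magnitudes, not magnitude of the mean).
Velocity traces show doublet peaks — fast contraction, slower relaxation —
so displacement relative to a relaxed reference frame gives a cleaner beat
pattern. The bootstrap is fixed and documented: the global minimum of
$V(t)$ provides a working reference $t^*$; flows of every frame against
$t^*$ give $U_{t^*}(t)$; the prominent minima of that trace become the
reference set $t_k^{\min}$; and the reported beat pattern is the pointwise
minimum $U(t) = \min_k U_{t_k^{\min}}(t)$, whose inter-beat baseline is ≈ 0
by construction. When $V$- and $U$-minima disagree, the $U$-minima win.

One subtlety: during rest, sub-pixel motion quantizes to exactly zero, so
the motility minimum is a *plateau* of tied frames rather than a point.
Relaxation is exponential, so the deepest rest state is the **last** frame
of that plateau — and that is the frame used as a reference. (Extrema
*reporting* still uses the earliest plateau frame.) Choosing the plateau
start instead leaves ~30% residual activation in the reference; rest-phase
frames then register as expansions and their positive convergence halo
leaks into $s^*$ over passively dragged tissue.

**Extrema detection.** Minima and maxima must alternate, each maximum must
be the absolute maximum between its flanking minima (and vice versa), and
consecutive extrema must differ by at least a threshold $\Delta$. The
implementation is a single forward scan with running extrema; equal-valued
plateaus report their earliest frame. Endpoints get asymmetric treatment: a
maximum still rising at the end of the recording never dropped by $\Delta$
and is therefore unconfirmed and unreported, while a trailing minimum is
kept when it satisfies the drop condition; a lone minimum with no maxima at
all collapses to an empty result (a monotone ramp has no beats). The
default $\Delta$ is 20% of the signal's interdecile range; it is the
method's main free parameter and should be chosen above the integer
quantization ripple of the traces (~0.1 px for typical fields of view) and
below the genuine beat amplitude. For the full-scale synthetic benchmark we
state $\Delta = 0.2$ px explicitly for this reason.

**Re-referencing shortcut.** Computing $U_T(t)$ for every reference $T$ by
fresh PIV costs (references × frames) passes. The difference approximation
$u_T(t,x) \approx u_{t^*}(t,x) - u_{t^*}(T,x)$ is exact for rigid motion
and accurate while displacements stay within the fine search range; it
engages automatically when the exact cost would exceed a configurable
budget (default `Inf`, i.e. always exact — long recordings should pass a
finite budget). One behavioral difference is worth noting: fresh PIV
quantizes sub-threshold motion to zero, while the difference of two integer
fields preserves ±1 px noise at scattered nodes, so approximate traces show
the quantization ripple more clearly.

**Beat frequency** is 60 divided by the mean period (in seconds) between
consecutive retained maxima. At 10 frames/s a 120 bpm rhythm leaves only 5
frames per beat; estimates at or above that rate are flagged unreliable
(the equivalent frames-per-beat limit is applied at other frame rates).

# Convergence and contractility maps

On the flow lattice with spacing $d$, convergence is estimated by central
differences,
$C \approx [u_x(x-d,y)-u_x(x+d,y)]/2d + [u_y(x,y-d)-u_y(x,y+d)]/2d$,
with one-sided differences at borders (flagged so downstream statistics can
exclude them). Three noise filters are applied, in a fixed order chosen so
that impulsive PIV outliers are removed before they can enter the temporal
recursion:

1. **Spatial median** over adjacent grid points (3×3 by default):
   idempotent on piecewise-constant maps, preserves step edges exactly.
2. **Temporal high-pass** per node:
   $C'(t) = q\,[C'(t-1) + C(t) - C(t-1)] + (1-q)M$, with $M$ the node's
   temporal mean. Initialization is $C'(0) = M$ and $C(0) := M$, which
   makes any constant series a fixed point from the first step. The DC gain
   from $C$ is zero and the output DC is exactly $M$: the filter removes
   slow reference-drift (a linear ramp of slope $\beta$ converges to
   $M + \beta q/(1-q)$, slope removed) while maintaining the average of a
   stationary sequence to machine precision. Default $q = 0.9$ at 10 fps
   puts the cut-off near 0.17 Hz, well below beat frequencies ≥ 0.5 Hz.
3. **Contrast weighting**: $C'(r,t) = C(r,t)\,w(r,t)$, where $w$ is the
   standard deviation of image brightness in a 16×16 px window around each
   node. Windowed SD is unbounded, so $w$ is normalized to [0, 1] by the
   stack-wide maximum windowed SD (a fixed saturation constant can be
   supplied instead). Cell-free areas — the dominant noise source, where
   low contrast lets the matcher track debris or nothing — get weights
   near 0.

Relative contractility is then the thresholded convergence
$s^*(r) = \max(C(r), 0)$: nonnegative, idempotent, with missing nodes
mapped to 0. Per-focus beat patterns (used for multi-center phase analysis)
are taken as the sum of $s^*$ over a disk or connected component around
each focus — the integration region is a user choice, as no unique
definition exists.

Tile-based covariance (`tile_aggregate`) splits a map and a same-field
image into non-overlapping tiles (remainder dropped) and returns paired
totals, the quantitation used to correlate convergence-derived
contractility with immunofluorescence intensity.

# The contractile elastic sheet model

The monolayer is an isotropic linear elastic plate with Hooke's law
$\sigma = c_1\varepsilon + c_2 I\,\mathrm{Tr}\,\varepsilon$ and an active
isotropic stress $\sigma^* I$ inside a disk of radius $r_0$; mechanical
equilibrium is $\nabla\cdot(\sigma + \sigma^*) - k u = 0$ with an optional
elastic substrate drag $k$. For radially symmetric fields
($\varepsilon_{rr} = u'$, $\varepsilon_{\phi\phi} = u/r$, shear exactly 0)
the equilibrium reduces to the equidimensional equation for $k = 0$ —
solutions $u = br$ (regular) and $u = a/r$ (decaying, divergence-free) —
and to the modified Bessel equation of order 1 for $k > 0$, with
$u = A I_1(r/\lambda)$ inside and $u = B K_1(r/\lambda)$ outside, where
$\lambda = \sqrt{(c_1+c_2)/k}$. Convergence follows as
$C_{in} = -A I_0(r/\lambda)/\lambda$ and
$C_{out} = B K_0(r/\lambda)/\lambda$: a positive core surrounded by a
negative "divergent halo" that deepens with $k$, decaying asymptotically as
$\sqrt{\pi/2\rho}\,e^{-\rho}$.

Two modelling subtleties deserve an explicit account, because the package
exposes both resolutions:

* **Matching at $r_0$ for $k = 0$.** The classical presentation fixes the
  inner coefficient by requiring the total stress to vanish inside the
  core, $b = -\sigma^*/(c_1+2c_2)$, and then matches displacement at $r_0$
  (giving $a = b r_0^2$ and the inner convergence plateau
  $2\sigma^*/(c_1+2c_2)$). That solution leaves a jump in the total radial
  traction at $r_0$. Imposing continuity of both displacement *and* total
  traction instead yields $b = -\sigma^*/(2(c_1+c_2))$. The two cannot hold
  simultaneously. `solve_uniform_core` defaults to the first convention
  (`matching = "stress-free-core"`, the classical plateau value) and offers
  `matching = "traction"`, which is the self-consistent variant — and the
  one the $k > 0$ branch (which needs both conditions for uniqueness)
  converges to as $k \to 0$.
* **The point response kernel.** For general contractility distributions
  the displacement is a superposition of point responses
  $u \propto -K_1(|r-r'|/\lambda)\,\hat{s}$. Taking the negative divergence
  of that kernel gives, for $s > 0$, $+K_0(s/\lambda)/\lambda$ *plus a
  local delta contribution* at the source — not the
  $\tfrac{1}{2\lambda}(K_1 - K_2)$ form sometimes quoted, which is negative
  everywhere and cannot produce a positive convergence core at all. The
  derivation is elementary: a point isotropic stress source is curl-free,
  so $u = \nabla\phi$ with $(c_1+c_2)\Delta\phi - k\phi = -s\,\delta^2$,
  hence $\phi \propto K_0(r/\lambda)$ and
  $C = \sigma^*(r)/(c_1+c_2) - \frac{1}{2\pi\lambda^2 (c_1+c_2)}
  \int \sigma^*(r') K_0(|r-r'|/\lambda)\,dr'$.
  `response_kernel` exposes both the `"printed"` form (for reference) and
  the `"consistent"` smooth tail; `convergence_from_contractility` uses the
  consistent kernel with the analytic local term, which is why it agrees
  with `solve_uniform_core` to quadrature accuracy (≤ 0.5% in the shipped
  tests) and with the finite-difference divergence of
  `displacement_from_contractility` at second order in lattice spacing.

**Convolution numerics.** Direct quadrature on the source lattice, chunked
to bound memory. The $K_1$ kernel's singular cell is dropped (its angular
integral cancels by symmetry); the $K_0$ kernel's singular cell is
integrated analytically over an equal-area disk using
$\int_0^X x K_0(x)\,dx = 1 - X K_1(X)$. Sharp-edged disk sources are
antialiased by subsampling boundary cells' coverage. Evaluation points
within half a lattice spacing of the discontinuity at $r_0$ are the only
place where the discretized and analytic solutions disagree noticeably; a
source lattice of $r_0/100$ keeps the overall profile error well below 1%.

# The synthetic beating-monolayer generator

A movie is: a seeded band-limited random texture (white noise smoothed to a
1.2 px correlation length, rescaled into an 8-bit-like range), warped per
frame by the superposition of each contractile center's model displacement
field scaled by its activation waveform, plus Gaussian read noise, plus —
optionally — flat "cell-free" rectangles containing drifting bright blobs
that emulate debris carried by medium convection. Warping is inverse
(pull-back) with bilinear interpolation: forward splatting would leave
holes. All randomness flows through explicit seeds; movies are
byte-identical across runs.

The activation waveform rises linearly to 1 over `contraction_rise`
(default 0.1 s — contraction is swift) and relaxes exponentially with
`relaxation_tau` (default 0.25 s), repeating with the beat period. These
defaults emulate the asymmetric contraction/relaxation cycles seen in
cultured cardiomyocytes at ~60 bpm.

Superposition of centers is only valid in the linear regime, so the
generator enforces peak displacements ≤ 8 px (default 6 px, representative
of what 5–10× magnification recordings show). Ground truth — per-center
unit fields, per-frame activations, convergence maps, beat times — is
returned alongside the movie, exactly consistent with the mechanics module
by construction.

What the generator deliberately does **not** emulate: photobleaching and
illumination drift, cell rearrangement between beats (the slow reference
decorrelation that the temporal high-pass exists for is only present via
debris/noise), out-of-plane motion, nonlinear tissue rheology, and
amplitude variability between beats. A green end-to-end test therefore
establishes that the pipeline recovers what the linear model world
contains — frequencies, focus positions, passive-vs-active distinction —
not that it is robust to every artifact of real recordings.

**Full-scale benchmark choices** (256×256 px, 300 frames, 10 fps, one
60 bpm center): core radius $r_0 = 24$ px against a 16 px analysis-grid
spacing, so the flat convergence plateau of a uniform core spans ≤ 2 grid
nodes and "argmax within 2 nodes of the true center" is geometrically
meaningful; $\lambda = 40$ px so that a substantial passively-dragged
annulus (≳ 2 grid spacings beyond the core, where the finite-difference
stencil cannot reach core convergence) still moves at ≥ 30% of the peak
displacement; PIV search reduced to ±12 px coarse (displacements are ≤ 6 px
by construction), keeping the run inside its time budget on one CPU.

# Known limitations

* Displacements are integer pixels; quantities derived from them inherit
  ±0.5 px quantization. Sub-pixel refinement is explicitly out of scope.
* The unnormalized correlation scores can mis-match on very smooth or
  periodic textures (use `"ncc"` there).
* The convergence-to-contractility correspondence rests on an isotropic,
  linear, homogeneous sheet; anisotropic or viscoelastic rheology and the
  inverse deconvolution of contractility from observed convergence are not
  implemented.
* Beat-frequency estimation requires at least two confirmed maxima and
  degrades above ~120 bpm at 10 fps.
* The minimal TIFF codec reads/writes uncompressed single-channel baseline
  files only; PNG is not supported (overlays are written as PPM).
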