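# beatflow

Non-invasive quantification of cardiomyocyte contractility from label-free
time-lapse microscopy.

Beating cardiomyocyte cultures are routinely recorded by brightfield or
phase-contrast videomicroscopy (~10 frames/s). `beatflow` turns such
recordings into quantitative readouts without dyes or reporters:

* **Optical flow / PIV** — dense integer-pixel displacement fields between
  frames by two-pass block-matching cross-correlation (64 px tiles / ±32 px
  search, then 32 px tiles / ±4 px around a thin-plate-spline-smoothed
  coarse prediction).
* **Beat patterns** — the motility trace $V(t)=\langle|v(t,x)|\rangle_x$,
  displacement patterns $U(t)$ relative to automatically chosen relaxed
  reference frames, prominence-filtered alternating extrema, and beat
  frequency in bpm (flagged unreliable above the ~120 bpm resolution limit
  of 10 fps recordings).
* **Contractility maps** — the convergence $C = -\nabla\cdot u$ of the
  displacement field, cleaned by a spatial median filter, a temporal
  high-pass recursion $C'(t)=q[C'(t-1)+C(t)-C(t-1)]+(1-q)M$, and local
  image-contrast weighting, then thresholded to the nonnegative
  contractility estimate $s^*(r)=\max(C(r),0)$. Under an elastic-sheet
  model of the monolayer, $s^*$ localizes actively contracting cell groups
  and stays at background on tissue that merely moves passively.
* **The forward model** — an isotropic linear elastic sheet
  ($\sigma = c_1\varepsilon + c_2 I\,\mathrm{Tr}\,\varepsilon$) with active
  stress $\sigma^* I$ in a core of radius $r_0$ and substrate drag $k$:
  closed forms $u=br$, $u=a/r$ for the free sheet and
  $A\,I_1(r/\lambda)$ / $B\,K_1(r/\lambda)$ with
  $\lambda=\sqrt{(c_1+c_2)/k}$ for the tethered sheet, plus convolution
  solutions for arbitrary contractility distributions.
* **A synthetic generator** — ground-truth-annotated beating-monolayer
  movies made by warping seeded textures with the model's fields under a
  swift-contraction / exponential-relaxation waveform, including cell-free
  regions with drifting debris.

See the methods vignette (`vignettes/beatflow-methods.Rmd`) for the models,
parameter choices and their rationale.

## Worked example

```r
library(beatflow)

# a synthetic culture: one contractile focus at (64, 64), 60 bpm, 10 fps
spec <- scene_spec(
  size = 128,
  centers = list(list(
    position = c(64, 64),
    params = sheet_params(c1 = 1, c2 = 1, k = 0.01, sigma_star = 1, r0 = 12),
    waveform = beat_waveform(period = 1, contraction_rise = 0.1,
                             relaxation_tau = 0.25),
    phase = 0, peak_displacement = 5)),
  texture_seed = 7, noise_sd = 2, fps = 10)
movie <- generate_movie(spec, n_frames = 50, seed = 21)

cfg <- piv_config(coarse_tile = 32, coarse_search = 8,
                  fine_tile = 16, fine_search = 3)
res <- contractility_pipeline(movie$stack, cfg, budget = 500)

beat_frequency(res$beats$U)$bpm
#> [1] 60
stot <- Reduce(`+`, lapply(res$s, `[[`, "values"))
am <- which(stot == max(stot), arr.ind = TRUE)[1, ]
c(x = res$s[[1]]$x[am[2]], y = res$s[[1]]$y[am[1]])
#>  x  y
#> 73 65
```

The recovered beat frequency matches the generator (60 bpm), and the node
with the largest time-summed contractility sits at pixel (73, 65) — just
over one 8-px grid node from the true center at (64, 64), inside the flat
convergence plateau of the 12-px core where any plateau node can win the
argmax. The surrounding tissue
ring moves strongly (it is dragged by the core) yet carries near-zero
$s^*$: convergence analysis separates active contraction from passive
motion, which displacement maps alone cannot.

The analytic model is available directly:

```r
sol <- solve_uniform_core(sheet_params(c1 = 1, c2 = 1, k = 0,
                                       sigma_star = 1, r0 = 1))
sol$C(0.5)   # inner convergence plateau: 2*sigma*/(c1+2c2)
#> [1] 0.6666667
sol$C(2)     # the free sheet is divergence-free outside the core
#> [1] 0
```

## Command line

```sh
Rscript inst/cli/beatflow.R simulate-movie --size 256 --frames 100 --bpm 60 --out movie.tif
Rscript inst/cli/beatflow.R beats --input movie.tif --out beats.csv
Rscript inst/cli/beatflow.R converge --input movie.tif --q 0.9 --out sstar/
Rscript inst/cli/beatflow.R flow --input movie.tif --pair 1 5 --out flow.csv
```

Readers accept multi-page uncompressed grayscale TIFF (8/16-bit) or
directories of TIFF/PGM frames; numeric outputs are plain CSV, overlays PPM.

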