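---
title: "Methods: tissue-attenuation contrast and type-II fuzzy sharpening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-attenuation contrast and type-II fuzzy sharpening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radenhance)
```

## The model

Radiographs of musculoskeletal anatomy image the line integral of tissue
attenuation. Soft tissue and fat contribute a smooth, high-attenuation
component that compresses the intensity range available to bone detail; the
result is a flat, low-contrast image in which the structures of diagnostic
interest occupy a narrow band. `radenhance` treats enhancement as two
separable problems — recovering contrast and recovering sharpness — and
solves them in sequence.

### Stage 1: tissue-attenuation contrast enhancement

The input is normalized by its own observed maximum, `I_nor = I / I_max`, so
the method is invariant to global exposure scaling (a `norm_by_depth` option
divides by the bit-depth maximum instead, for workflows that need absolute
intensities). The normalized image is decomposed implicitly into a detail
component and a *removable* component. Per-pixel local extrema over a
`window × window` neighborhood (grayscale dilation and erosion with a square
structuring element, replicate padding at borders) give the local maximum
`G` and the local minimum `T`; `T` is the proxy for the highest-attenuation
tissue content at that location.

How much of `T` is safe to subtract is decided by the data, not a tuning
knob: the removable factor is `beta = exp(-G * var(T) / T)`, with `var(T)`
the scalar sample variance (n−1 denominator) of the whole local-minimum map.
Images whose attenuation floor is flat (`var(T)` small) keep more of it
removable (`beta` near 1); strongly structured floors are subtracted
cautiously. The removable component is `R = beta * T`, and the stretch

```
E = (I_nor − R) / (G^psi − R),  psi = log(1 − R (1/G − 1)) / log(G)
```

expands what remains. The exponent `psi` is the brightness-consistency term:
it equals 0 when `R = 0` (so the stage degrades gracefully to the identity)
and is constructed so that `G^psi = 1 − R (1/G − 1)`, which makes every local
maximum a fixed point of the stretch (`E = G` where `I_nor = G`) and pins the
zero point at `I_nor = R`. Between those anchors the map is strictly
increasing, so ordering of intensities is preserved within each neighborhood.

The flattened typography of the published formulas admits more than one
reading; the parses above are the ones under which the stage has these
boundary properties (identity at `R = 0`, fixed points at local maxima), and
each is isolated behind a single function (`brightness_exponent()`,
`apply_contrast_enhancement()`) so an alternate parse can be swapped without
touching the rest of the pipeline.

### Stage 2: interval type-II fuzzy sharpening

The contrast-enhanced image is fuzzified by a min-max stretch `f` onto
`[0, 1]` membership grades. A type-I membership function would commit to one
grade per pixel; a type-II set instead carries an interval of plausible
grades, modelling uncertainty about the right membership function for this
image. The interval is parameterised by the global statistics of `f` (mean
`mu`, sample standard deviation `sigma`, both over all pixels):

- upper bound `u = f^alpha + (1 − f^alpha) * sigma^(2*alpha)` — a
  gamma-style brightening floored at `sigma^(2*alpha)`, reaching 1 at
  `f = 1` and monotone in `f`;
- lower bound `w = (alpha*mu / (sigma + alpha)) * (f − alpha*mu)` — a linear
  stretch around the anchor `alpha*mu`, clamped to `[0, u]` (negative raw
  values mean "no support", and interval semantics require `w ≤ u`; the
  clamp bounds are a design choice, since the source formula states none).

The two bounds are fused by the Hamacher t-conorm with parameter
`lambda = sigma^2`:

```
S(u, w) = (u + w + (sigma^2 − 2) u w) / (1 − (1 − sigma^2) u w)
```

This is the parametric Hamacher sum; reading the flattened numerator any
other way breaks the boundary law `S(a, 0) = a`, which is how the parse was
confirmed. The fusion acts as a fuzzy OR: pixels supported by either bound
are brightened, with the image's own variance steering how disjunctive the
fusion is. A final max-preserving gamma correction
`L = max(t) * (t / max(t))^gamma` shapes the tone curve without moving the
maximum, and the quantizer maps `[0,1]` to `[0,255]` with no re-stretching,
so max-preservation survives into the saved file.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `window` | 15 | px | local-extrema neighborhood; unspecified by the source method, chosen to span soft-tissue structure at typical radiograph resolutions while staying local; CLI-configurable |
| `alpha` | 0.7 | — | sharpening strength, open interval (0,1); above ≈0.6 sharpening is pronounced, so the default sits just inside that regime |
| `gamma` | 1.2 | — | final tone exponent; 1 = identity; the experimental value used for the published tables is unreported, 1.2 is a mild conventional choice |
| `eps` | 1e-6 | — | guard for quotients/logs; clamps are applied after, never before, the governing formula |
| `degenerate_policy` | pass_through | — | constant neighborhoods have no contrast to enhance; passing through is the conservative default (a `zero` policy exists) |

Because `alpha`, `gamma`, and `window` for the published experiments are not
reported, exact reproduction of the published score tables is not an
acceptance requirement; the tests assert the method's structural properties
and directions of effect instead. All run parameters are embedded in the CSV
report and in a JSON sidecar per output image.

## The phantom generator

`generate_phantom()` emulates the degradations the pipeline targets: bright
elongated "bone" ridges (anti-aliased thick segments, intensity 0.65–0.9)
over a smooth background of broad Gaussian "soft-tissue" blobs (amplitude
≤ 0.5, rescaled so the brightest blob hits the upper bound), then a global
range compression `a + b·x` (offset 0.15, factor 0.55 — chosen so
`a + b ≤ 1` and nothing clips), Gaussian blur (σ = 1 px), and additive
Gaussian noise (σ = 0.02, about five 8-bit gray levels, a realistic detector
noise floor). Sampling is driven by R's Mersenne-Twister generator with
inversion normals, seeded per phantom and restored on exit, so phantoms are
bit-exact across platforms.

What the phantom does *not* emulate: anatomy, beam hardening, scatter,
Poisson statistics of photon counting (additive Gaussian noise is used
because the method is noise-model-agnostic and the tests need controlled
degradation). A green phantom test therefore establishes that the
implementation has the stated mathematical behavior on radiograph-*like*
statistics, not that it improves clinical images; the latter claim rests on
the published evaluation and can be re-run by supplying the corresponding
images to the one intentionally red acceptance test.

One direction-of-effect subtlety: with the default noise level, the
*degraded* phantom has a higher average gradient than its clean counterpart,
because AG is noise-sensitive and the clean phantom is mostly smooth. The
degradation-reduces-AG property is therefore asserted with the noise term
switched off, where blur and range compression provably lower AG.

## Numerical choices

- All quotient and log guards use `eps = 1e-6`; guarded quantities are
  clamped after the formula is applied, so the guard never distorts
  non-degenerate pixels.
- `psi` is set to 1 by convention where `G ≥ 1 − eps` (the limit of the
  formula as `G → 1` depends on `R`; the convention keeps the fixed point
  `E = G = 1` exact).
- Quantization rounds half away from zero, stated so tests can be bit-exact.
- `t`-conorm denominators below `eps` (only possible as `u w → 1` with
  `sigma → 0`) yield 1, the absorbing element.
- The sample (n−1) variance/s.d. is used everywhere a variance appears, for
  both `var(T)` and `sigma`.
- `var(T)` is the scalar variance of the whole local-minimum map; a
  per-pixel local variance was rejected because it would need a second
  window definition the method never gives.

## Known limitations

- AG and IE are the only built-in metrics; learned no-reference metrics
  (BIQME, FADE, MA) need externally trained models and are supported only
  through the metric registry.
- The raster layer reads PNG/JPEG/PGM and writes PNG (8-bit) and PGM
  (8/16-bit); no TIFF or DICOM codec is available in the dependency set, so
  16-bit intermediates dump as plain-text PGM.
- The method assumes a single-channel radiograph; color inputs are averaged
  to luminance rather than rejected, since grayscale is sometimes stored as
  3 channels.
- Very noisy inputs are sharpened noise and all: the pipeline contains no
  denoiser, by design.
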