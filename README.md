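# radenhance

Two-stage contrast and sharpness enhancement for grayscale radiographs.

Shoulder (and other musculoskeletal) X-rays are often flat and mildly blurred:
subtle grayscale differences between bone, soft tissue, and background are
compressed into a narrow intensity band, and methods that only stretch
contrast tend to leave the image unsharp or amplify noise. `radenhance`
implements a two-stage pipeline for radiologists' image-preparation workflows
and for researchers benchmarking enhancement methods:

1. **Tissue-attenuation contrast stage.** The input is normalized by its own
   maximum, I_nor = I / I_max. Per-pixel local extrema over a square window
   give the local maximum G(y) and local minimum T(y) (the highest-attenuation
   tissue content). A data-driven removable factor

       β(y) = exp(−G(y) · var(T) / T(y)),

   with var(T) the scalar sample variance of the local-minimum map, scales
   the removable component R(y) = β(y)·T(y). A brightness-consistency
   exponent ψ(y) = log(1 − R(1/G − 1)) / log(G) then shapes the stretch

       E(y) = (I_nor − R) / (G^ψ − R),

   which subtracts the removable tissue and expands the remaining dynamic
   range while leaving local maxima fixed (E = G there) and keeping overall
   brightness consistent.

2. **Type-II fuzzy sharpening stage.** E is fuzzified by a min-max stretch f;
   global mean μ and sample s.d. σ parameterise an interval type-II
   membership: upper bound u = f^α + (1 − f^α)·σ^{2α} and lower bound
   w = (αμ/(σ+α))·(f − αμ) clamped to [0, u]. The bounds are fused by the
   Hamacher t-conorm with parameter σ²,

       S(u, w) = (u + w + (σ² − 2)uw) / (1 − (1 − σ²)uw),

   and a max-preserving gamma correction L = max(t)·(t/max(t))^γ produces the
   output. α ∈ (0,1) (default 0.7) sets sharpening strength; γ > 0 (default
   1.2) the final tone curve.

The package also provides formula-based no-reference quality metrics —
average gradient (AG, mean local gradient magnitude on the 0–255 scale) and
information entropy (IE, Shannon entropy of the 256-bin histogram in bits) —
plus a registry for plugging in external learned metrics; a seeded synthetic
radiograph **phantom** generator (bright bone-like ridges over smooth
soft-tissue blobs, degraded by range compression, blur, and noise) so the
whole pipeline is testable without clinical data; and a CLI with batch and
ablation runners.

## Worked example

```r
library(radenhance)

# four seeded phantoms, enhanced under all three ablation modes
batch <- make_fixture_batch(4, base_seed = 1)
dir.create("demo/in", recursive = TRUE)
for (i in seq_along(batch))
  write_image(batch[[i]]$image, sprintf("demo/in/ph%02d.png", i))
res <- run_ablation(list.files("demo/in", full.names = TRUE),
                    enhancement_config(), "demo/out")
print(res$table, row.names = FALSE)
#>       model       ag       ie
#>    -w/o REM 28.29532 7.011399
#>    -w/o CEM 11.70247 6.222723
#>  Full Model 29.36671 7.071947
```

The mode rows mirror the standard ablation layout: `-w/o REM` is the contrast
stage alone, `-w/o CEM` the sharpening stage alone, `Full Model` both. On
these phantoms the full pipeline has the highest mean AG (29.37) and IE
(7.07): both stages contribute, and the contrast stage dominates the AG gain
— the same ordering the method reports on clinical images. Per image:

```r
score_image(read_image("demo/in/ph01.png"))    # AG  6.6736, IE 6.0650
score_image(read_image("demo/out/ph01_full.png")) # AG 31.0349, IE 7.1387
```

i.e. the degraded phantom's detail contrast roughly quintuples and its
histogram spreads by about a bit of entropy.

The same run from the shell:

```sh
exec/radenhance phantom --seed 1 -o demo/in
exec/radenhance ablate demo/in -o demo/out
exec/radenhance enhance demo/in/phantom_seed1.png -o out.png \
    --alpha 0.7 --gamma 1.2 --window 15
exec/radenhance metrics demo/in/phantom_seed1.png out.png
```

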