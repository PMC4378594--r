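# odseg — optic disc segmentation by a texture-driven balloon snake

`odseg` segments the optic nerve head in color fundus photographs, the
measurement that underpins cup-to-disc–ratio glaucoma screening. The two
classical failure modes — fuzzy disc boundaries and peripapillary atrophy
(PPA), the bright crescent next to the disc that gradient-based contours
mistake for disc tissue — are addressed by one design: a **balloon snake**
(a closed contour inflated by an isotropic pressure force) whose image force
comes from a **rotation-invariant texture response** instead of the
intensity gradient, evolved from a small circle *inside* the disc after the
texture noise that is not disc rim (cup boundary, residual vessel edges)
has been clustered away and inpainted.

The contour `u(s)` descends the energy

    E = alpha/2 ∮ |u_s|^2 ds  +  beta/2 ∮ |u_ss|^2 ds
        - rho/2 ∮ (u_s × u) ds  +  xi ∮ P(u) ds

with `P = -(normalized MR8 edge response)` of the red channel, i.e. per
iteration

    u_t = alpha u_ss - beta u_ssss - rho (u_s)^⊥ - xi ∂P/∂u ,

solved semi-implicitly for the internal terms and explicitly for pressure
and image force. Around this core the package implements the full method:

* **Localization** — Pearson template matching (401×401 bright-core
  template) on the HSI intensity channel, then Canny + circle Hough
  (radii 140–230, step 15) inside a 900×900 ROI;
* **Vessel removal** — harmonic (Laplace) diffusion inpainting over a
  vessel mask, with grayscale closing and neighborhood-mean replacement as
  alternatives;
* **Texture** — the 12-kernel isotropic Schmid bank and the 38-kernel
  RFS / 8-response MR8 maximum-response bank, plus CLAHE enhancement;
* **Noise suppression** — 3-feature fuzzy c-means in a disc-centred
  analysis region (estimated radius + 50 px), morphological cleanup,
  harmonic inpainting of the background texture;
* **Evaluation** — dice coefficient, two baselines (gradient-force snake,
  FCM texture clustering + direct least-squares ellipse fit), batch
  scoring, and a seeded synthetic fundus generator with exact ground-truth
  disc/cup/vessel/PPA masks.

## Worked example

```r
library(odseg)

# a synthetic fundus image with PPA and known ground truth
sample <- generate_fundus(random_fundus_spec(seed = 3, ppa_enabled = TRUE))
result <- segment_image(sample$rgb, sample$vessel_mask)
print(result)
#> <odseg_result> disc at (724.0, 728.0), radius 155 px
#>   mask area: 65546 px; snake iterations: 1146 (converged)
#>   vessel removal: inpaint; noise suppression: fcm

dice(sample$disc_mask, result$disc_mask)
#> <segmentation_score> dice 0.9934 (|A| = 64794, |B| = 65546, |A&B| = 64740)
```

`result` retains every stage artifact (devesseled ROI, raw/enhanced/cleaned
texture, edge-region mask, contour, iteration trace), so each step can be
inspected. The printed numbers mean: the disc was localized at (724, 728)
with Hough radius 155 px (truth: centre (724, 712), mean semi-axis
144 px — within one radius step), the balloon converged in 1146
iterations, and the predicted mask overlaps the ground-truth disc with
dice 0.993.

The three-method benchmark on 20 seeded PPA fixtures:

```r
bench <- run_benchmark(seeds = 1:20)
colMeans(bench[, c("dice_proposed", "dice_snake", "dice_cluster")])
#> dice_proposed    dice_snake  dice_cluster
#>     0.9838452     0.9579205     0.9932165
```

The texture balloon snake stays on the disc rim while the gradient snake
is dragged down by the seeds where PPA or a fuzzy rim captures it. The
ellipse-fit baseline scores highest *on this synthetic phantom only*: the
generator's discs are exact ellipses, so a conic fit to a correct texture
ring is a near-oracle here — see the methods vignette for why that
comparison inverts on real, irregular discs.

A command-line interface wrapping these functions ships at
`inst/cli/odseg.R` (`synth`, `locate`, `devessel`, `textures`, `segment`,
`eval`, `bench`).

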