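# transillum3d

Reconstructing deblurred 3D absorber structure in a turbid medium from a
single blurred 2D near-infrared transillumination (NIR-TI) image.

When near-infrared light is shone through body tissue, internal absorbers —
blood vessels, lesions — cast shadows on the exit surface. Scattering blurs
those shadows, and the blur grows with the absorber's depth in a way that is
described in closed form by the depth-dependent point spread function (PSF)
of the diffusion approximation:

    PSF(rho; d) ∝ [ (µs' + µa) + (κd + 1/r) · d/r ] · exp(−κd·r) / r,
    r = sqrt(rho² + d²),   κd = sqrt(3·µa·(µs' + µa))

with reduced scattering coefficient `µs'` and absorption coefficient `µa`
(mm⁻¹, tissue-like values 1.0 and 0.01). Because blur encodes depth, a
single 2D image carries recoverable 3D information. This package implements
two recovery techniques plus the forward simulator that makes them testable
end to end without laboratory data:

1. **Lookup-table inversion of 1D profiles** — for curvilinear absorbers
   (vessel-like). The Michelson contrast `CM = (Imax − Imin)/(Imax + Imin)`
   and the FWHM of the intensity dip across the absorber are precomputed on
   a (depth × diameter) grid and inverted at query time by 4-node
   interpolation, yielding depth *and* diameter per slice, hence a 3D
   cylinder reconstruction.
2. **Focus stacking over a depth-swept deconvolution** — for volumetric
   absorbers. The image is Wiener-deconvolved with the PSF at 31 hypothesis
   depths; per-pixel windowed gray-level variance over the stack forms a
   focus curve whose Gaussian-fitted peak is the best-focus depth, and a
   selectivity-gated weighting fuses the stack into a noise-robust
   all-in-focus image plus depth map.

## Worked example

```r
library(transillum3d)

opt <- optical_properties(1.0, 0.01)   # tissue-like turbid medium
opt
#> Turbid medium: mu_s' = 1 /mm, mu_a = 0.01 /mm (kappa_d = 0.174069 /mm)

# simulate the shadow of a 3 mm bar, 30 mm long, tilted 5 degrees in depth
# (ends at 2.2 and 5.0 mm), on a 36 x 56 mm grid at 0.1 mm/px
g   <- image_grid(360, 560, 0.1)
ph  <- make_cylinder_phantom(3.0, 30, 5, 2.2, 5.0, g)
img <- add_noise(blur_image(ph, opt), snr_db = 21, seed = 42)
img
#> Transillumination image (synthetic): 360 x 560 px at 0.1 mm/px, range [0.7207, 1.024]

# build the feature lookup table and reconstruct the bar slice by slice
lut <- build_lookup_table(depth_range = c(1, 10), diameter_range = c(1, 10),
                          step = 0.1, optical = opt)
lut
#> Lookup table: 91 depths [1, 10] x 91 diameters [1, 10] mm
rec <- reconstruct_cylinder_3d(img, lut)
head(subset(rec, !inestimable)[, c("y_mm", "depth", "diameter")])

# single profile query: an absorber at 4.25 mm depth, 3 mm diameter
ft <- profile_features(cylinder_profile(4.25, 3.0, opt))
ft
#> Profile features: CM = 0.12775, FWHM = 12.251 mm (gauss)
estimate_depth_1d(ft, lut)
#> Depth estimate: depth 4.25 mm, diameter 3 mm (cell)
```

The depth estimate lands within a micrometer-scale error of the true
4.25 mm although that depth lies between table nodes — the table's feature
map is smooth enough that 4-node interpolation is nearly exact.

For a volumetric absorber, the focus-stacking route:

```r
dm <- estimate_depth_map(img, opt, depths = c(0.1, 1:30))  # 31-layer sweep
dm$fused      # all-in-focus image
dm$depth      # per-pixel best-focus depth (mm); calibrate with
cal <- calibrate_depths(given = ph$true_depth[ph$occupancy],
                        estimated = dm$depth[ph$occupancy])
rec3 <- reconstruct_3d(dm, threshold = 0.9)
write_points_3d(rec3$points, "bar.ply", mask = rec3$mask)
```

Raw best-focus depths rise monotonically with true depth but with a
compressed slope; `calibrate_depths()` applies the first-order linear
calibration that is part of the procedure.

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/transillum3d.R simulate --phantom cylinder --diameter 3 \
    --tilt 5 --depth-top 2.2 --depth-bottom 5 --snr-db 21 --out bar.tif
Rscript inst/cli/transillum3d.R lut-build --step 0.1 --out lut.csv
Rscript inst/cli/transillum3d.R depth-1d --image bar.tif --lut lut.csv
Rscript inst/cli/transillum3d.R stack --image bar.tif --depths 0.1,1:30:1
```

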