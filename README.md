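# holoproj

Comparative holographic projection of brain MR follow-up exams, as a
reproducible R package.

Following a glioblastoma patient means comparing two MR exams — after
chemo-radiation and at progression — and judging how the lesion changed.
`holoproj` implements an optical-display route to that comparison end to
end: it segments brain tissue and tumor from axial T1-weighted
post-contrast slices, encodes the segmented structures as phase-only
computer-generated holograms, and simulates their reconstruction through
a Fourier lens, either as a layered 3D tumor map or as the two exams side
by side with the tumor highlighted. Everything runs on synthetic phantoms
with ground truth, so the whole chain is testable on any machine.

## The methods at its core

**Segmentation.** Per slice, seed points inside the brain tissue are
found automatically by running the Canny detector twice (relative high
thresholds 0.1 and 0.2, low threshold 0) and subtracting the edge maps:
high-contrast skull/tumor contours cancel, faint tissue contours remain.
A pixel weight matrix

    W(x, y) = 1 / (1 + (|I(x, y) − μ|/κ)²),   κ = 0.1

(μ = mean seed intensity) feeds the fast marching method as the speed
F in the Eikonal equation |∇T| = 1/F. Thresholding the normalized
arrival-time map at 0.009 and keeping the seeded component (holes
filled) yields the brain mask; the tumor is segmented the same way,
seeded at the brightest skull-stripped pixel and restricted to the brain
support.

**Holography.** A Gerchberg–Saxton-type iterative Fourier transform
algorithm alternates amplitude constraints between object plane (√I) and
SLM plane (unit amplitude) until the hologram phase changes by less than
ε = 0.05 rad RMS (max 200 iterations). Holograms are modulated by
quadratic chirps χ_z = exp(i k λ² z |v|²/2) for axial layer placement and
by exact DFT-bin phase ramps for lateral separation, then superposed by
complex addition. A factor-4 zero-padded frame (4320 × 7680 for the
1080 × 1920 SLM) is cut into 16 SLM-sized tiles whose reconstructed
intensities add incoherently — temporal multiplexing that suppresses
speckle (contrast C = σ/μ drops roughly by half).

**Metrics.** Dice, boundary-F1, RMSE, scaled SNR (scale factor
β = ‖I‖/‖I_d‖), speckle contrast, and tumor area/solidity/volume
(Σ area × 6.5 mm slice separation).

## Worked example

```r
library(holoproj)

phantom <- phantom_config(seed = 42)          # 320 x 260 px, 0.6875 mm/px
truth   <- make_brain_slice(phantom)
series  <- normalize_series(as_mr_series(truth))
seg     <- segment_brain_and_tumor(series)
sl      <- seg$slices[[1]]

dice(sl$brain$mask, truth$brain_mask)         # 0.999
dice(sl$tumor$mask, truth$tumor_mask)         # 0.987
region_properties(sl$tumor$mask, phantom$pixel_spacing)
#> area 4.92 cm^2, solidity 0.92

optics <- optics_config(slm_shape = c(96, 128))   # scaled-down SLM
fit    <- ifta(zero_pad_center(sl$tumor$gray_mask, optics = optics),
               optics = optics)
fit$trace$iterations                          # 4 (phase change < 0.05 rad)

tiles <- tile_hologram(fit$hologram)          # 16 sub-holograms
supp  <- NULL  # object support; see vignette
speckle_contrast(fourier_reconstruct(tiles[[1]])$intensity)   # single tile
multiplexed_reconstruct(tiles)                # mean of 16 intensities
```

On this phantom the printed numbers mean: the automated segmentation
overlaps the ground truth almost perfectly (Dice 0.999 brain / 0.987
tumor); the 4.9 cm² lesion has solidity 0.92 (fairly compact); the
phase-retrieval loop converged after 4 iterations; and averaging the 16
tile reconstructions drops the object-support speckle contrast from
about 1.22 to 0.49 — the speckle-suppression effect the tiled display
exists for.

The end-to-end schemes are one call each (or one CLI call via
`inst/cli/holoproj`):

```r
run_pipeline("compare", "out/", optics = optics)   # side-by-side + highlighting
run_pipeline("stack", "out2/", optics = optics)    # layered 3D tumor map
```

Both write masks, holograms, reconstructions, a metrics report and a
checksummed manifest; reruns with the same seed are bit-identical.

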