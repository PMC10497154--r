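# actnet

Automated extraction and quantification of cytoskeletal filament networks
(actin in the first place) from single-channel fluorescence micrographs and
z-stacks.

Plant cells organise filamentous actin into cables and fine networks whose
architecture changes with genotype, tissue and drug treatment. Comparing
those architectures needs an automatic route from a raw micrograph to
numbers. `actnet` provides that route:

1. **Extraction** — top-hat background subtraction (ball structuring
   element), multi-scale Hessian (Frangi) tubular enhancement, in-ROI
   percentile thresholding (default: 90th percentile, strictly greater),
   small-object removal (< 20 px), and topology-preserving thinning to a
   single-pixel backbone. The frame is rotated so the cell's major axis is
   horizontal; rotation is applied both before and after skeletonisation
   along two parallel paths whose results are OR-combined and re-thinned,
   so neither binary fragmentation nor edge blurring is paid in full.
2. **Labelling** — branch-point pixels (≥ 3 neighbours, 8-connectivity)
   are removed, fragments are flood-filled, and at every junction the pair
   of fragment ends closest to a straight continuation is re-joined, so a
   filament keeps one label across its branches; unpaired ends are the
   branches.
3. **Measures** — seventeen per-cell and per-filament quantities: ROI size,
   cell orientation, skeleton density, structure sizes, branch ratio,
   branch-point density, filament widths, 2-D/3-D lengths
   (diagonal steps weighted √2) and angles, average length, signed and
   unsigned Menger curvature over a fixed physical window (λ = 475 nm),
   deviation from straight, and 2-D/3-D branch angles.
4. **Synthetic benchmark** — a generator that draws random spline
   filaments at 19× supersampling (5 nm effective pixels), blurs with the
   lens PSF, block-averages down to 200×200 px at 95 nm/px and adds
   PSF-blurred impulse noise of calibrated amplitude — with the exact
   centreline ground truth retained — plus a harness scoring sensitivity
   (TPR) and precision (PPV) at 1-px tolerance across sweeps of SNR,
   network density, threshold and numerical aperture.

## Worked example

```r
library(actnet)

params <- scene_params(n_filaments = 10, noise_max = 0.14)
scene  <- simulate_scene(params, seed = 1)
scene
#> synthetic scene: 200 x 200 px, 10 filaments, SNR 4.14 (seed 1)

skel <- extract_skeleton(scene$image, params = extraction_params(rotate = FALSE))
match_skeletons(skel, scene$truth)
#> match: TP 952 FP 53 FN 40 | TPR 0.960 PPV 0.947 (tol 1 px)

net <- label_filaments(skel)
net
#> labelled network: 30 filaments, 33 branch points on 200 x 200

measures <- compute_measures(net)
measures
#> measure set: 30 filaments, 3 structures, 27 branch angles
#>   cellSize 40000 px, skelDensity 0.0251, branchRatio 1.100, avgLen 3812 nm
```

At a realised SNR of 4.1, 96% of the true centreline pixels are recovered
within one pixel and 95% of the reported skeleton lies within one pixel of
the truth. The ten generated filaments appear as 30 labels because blurred
crossings break and re-join imperfectly at this noise level; the labelled
network's 33 junctions and the per-filament lengths, angles and curvatures
feed the measure table (`as_measure_list(measures)` returns exactly the
seventeen named entries; `write_measures()` exports CSV/JSON).

Real images enter the same way:

```r
img <- read_image("cell.tif", pixel_size_nm = 95, z_spacing_nm = 550)
roi <- read_roi("cell_roi.png", dim = dim(img$data)[2:3])
skel <- extract_skeleton(img, roi)
measures <- compute_measures(label_filaments(skel), stack = img)
```

A thin command-line front end wraps the same functions
(`inst/cli/actnet.R`; subcommands `extract`, `measure`, `simulate`,
`validate`, `batch`).

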