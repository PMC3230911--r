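# canaliq

Automated quantification of membrane protein translocation in two-channel
confocal images of bile canaliculi.

## The problem

Hepatocytes secrete bile through transport proteins (Bsep, Mrp2) in their
canalicular membrane. Cholestasis retrieves these transporters from the
membrane into intracellular vesicles. In confocal sections stained for a
structural marker (Zo-1, tight junctions) and a functional marker (the
transporter), a canaliculus lying in the image plane shows two roughly
parallel bright Zo-1 lines; the transporter's membrane-vs-cytoplasm
distribution along the axis perpendicular to them is the quantity of
interest. Manual densitometry of such images is slow, subjective and
limited to a handful of profiles per image; canaliq automates the whole
measurement chain for anyone comparing transporter distributions between
biological conditions.

## What it computes

For each image the package

1. detects canalicular membrane foreground by supervised texture
   classification (15-px window features, ridge-regularised logistic
   regression) and cleans the mask morphologically (3 × 3 opening,
   125-px area filter, closing, 250-px area filter; thresholds scale with
   `(300 nm / pixel size)²`);
2. thins the mask to one-pixel centerlines by deleting border pixels whose
   removal preserves the Euler characteristic `E = e − k + f` of their
   3 × 3 neighbourhood, prunes branch points and fragments < 7 px;
3. extracts 81-px intensity profile pairs orthogonal to the centerline
   (0.3 µm averaged width, bilinear interpolation), and accepts a profile
   with principal peaks `maxValue1 ≥ maxValue2`, inter-peak minimum
   `minValue` and remaining local maxima percentile `P60` iff

   `(maxValue1 − maxValue2)/maxValue2 < 0.15`,
   `7 < |positionMax1 − positionMax2| < 26`,
   `minValue/maxValue2 < 0.2`,
   `P60/maxValue2 < 0.4`;
4. ranks accepted profiles by the unweighted combination of the peak
   difference (`r1`) and valley ratio (`r2`) criteria, centers them
   against the average ("model") profile by dot-product search over
   ±10 px, cuts them to 61 px;
5. places fixed-length zones around the peaks (membrane zones 2a/2b,
   peri-membrane 3a/3b, deep cytoplasm 4a/4b, canalicular interior 1 and
   5, outside 6a/6b) and computes the descriptors
   `X = sum1/sum2`, …, `D = sum2/sum4`, `E = sum2/(sum3+sum4)`,
   `F = sum5/(sum5+sum6)` (internalization degree) plus the legacy
   positional variance of the profile;
6. compares two conditions per descriptor with the unpaired Wilcoxon
   rank-sum test under a 100-vs-100 subsampling protocol (100
   repetitions, median p), and evaluates a density-crossing threshold
   classifier by precision/recall/F-score.

A synthetic image generator (`generate_image()` / `generate_dataset()`)
produces two-channel canaliculus images with ground truth and a
controllable membrane fraction, so the whole chain is testable without
microscopy data.

## Worked example

```r
library(canaliq)

template <- canaliculus_spec(path = rbind(c(0, 0), c(1, 1)),
                             membrane_fraction = 0.9)      # control
control <- generate_dataset(template, n_images = 4, seed = 11)
template$membrane_fraction <- 0.5                          # internalized
cholestatic <- generate_dataset(template, n_images = 4, seed = 21)

res_k <- run_extraction(control)
res_t <- run_extraction(cholestatic)
res_k
#> <dataset_result> 4 image(s); profiles extracted 670, accepted 670
#> median descriptors:
#>        X        Y        Z        A        B        C        D        E
#>   0.1080   0.4840   0.4610   0.0879   0.2320   4.5400   4.4800   2.2400
#>        F variance
#>   0.4440   0.0361

cmp <- run_comparison(res_k, res_t, seed = 1)
cmp$comparison
#> <comparison_result> 80 x 80 subsampling, 100 repetitions
#>        X        Y        Z        A        B        C        D        E
#> 5.67e-19 1.41e-01 4.69e-14 7.50e-06 5.48e-11 3.35e-21 1.59e-22 2.66e-24
#>        F variance
#> 3.80e-22 1.13e-19
cmp$classifier
#> <classifier_eval> precision 82.42%, recall 93.75%, F 87.72% (threshold 3.426, positive 'B' below)
```

The membrane-concentration descriptors C, D and E separate the two
conditions most sharply (median p ≈ 1e-21…1e-24): internalization moves
functional signal from the membrane zones (2a/2b) into the cytoplasmic
zones (3, 4), lowering those ratios. Descriptor `F` is the fraction of
functional signal inside the canaliculus — directly interpretable as an
internalization degree. The classifier line reports how well a single
threshold on descriptor D distinguishes the conditions.

A thin command-line front end wrapping these functions is installed at
`system.file("cli/canaliq.R", package = "canaliq")` with `simulate`,
`extract`, `compare` and `classify` subcommands (TIFF images in, CSV
tables and JSON/YAML manifests out).

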