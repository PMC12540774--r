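# coacervate

Quantitative analysis of complex coacervates formed by short arginine
peptides (R<sub>N</sub>) with single-stranded DNA and RNA oligonucleotides —
minimal, prebiotically plausible models of membraneless compartments. The
package is aimed at experimentalists and simulators characterising such
systems: it turns plate-reader titrations, atomistic and coarse-grained
simulation frames, FRAP traces, fluorescence micrographs and gel lane
profiles into the standard condensate observables.

## What it computes

* **Critical salt concentration (CSC)** from turbidity titrations.
  Turbidity = 100 (1 − 10^(Abs_blank − Abs)); the dilution-corrected
  turbidity-vs-NaCl curve is fitted with a line *y = ax + b* over every
  three consecutive points, the steepest window is the tangent at the
  inflection, and CSC = −b/a. Also: coacervation onset (first concentration
  with turbidity > 20%) and the minimal complex concentration (x-intercept
  of the steepest rising tangent of a dilution series).
* **Minimal peptide length** N<sub>min</sub> from the linear relation
  CSC = m/N + c, as the zero crossing N<sub>min</sub> = −m/c.
* **Contact classification** of arginine–nucleotide interactions in
  atomistic frames: hydrogen bonds (Wernet–Nilsson cone,
  r < 0.33 − 0.000044 θ² nm), ionic contacts (CZ–OP1/OP2 < 0.6 nm without a
  hydrogen bond between the residues), and guanidinium–nucleobase stacking
  (CZ within 0.45 nm of the ring centroid, inter-plane angle < 30°), with
  per-frame per-nucleotide rates, replicate means ± SD, generic 0.45 nm
  molecule contacts and excess-peptide counts.
* **Coarse-grained contacts** (distance < 0.5(σᵢ + σⱼ) + 0.1 nm, minimum
  image) and slab-coexistence density profiles.
* **FRAP recovery times** τ from pre-bleach-normalised traces via the
  exponential I(t) = P − (P − B) e^(−t/τ), with mobile fraction
  (P − B)/(1 − B) and multi-droplet averaging.
* **Partition coefficients**
  K_p = (I_droplet − I_dark)/(I_dilute − I_dark) from segmented
  micrographs.
* **Primer-extension yields** from background-subtracted gel lanes
  (asymmetric-least-squares baseline, explicit band windows, yields over a
  reaction time course).
* **Seeded synthetic generators** for all six input kinds with planted
  ground truth, so every stage is testable by parameter recovery.

## A worked example

```r
library(coacervate)

# a synthetic NaCl titration (planted tangent-intercept CSC: 220 mM)
sim <- gen_titration(seed = 1, label = "R4/RNA8 4:1")
extract_csc(sim$record)
#> Critical salt concentration [R4/RNA8 4:1]
#>   CSC = 221.0 mM NaCl
#>   tangent: slope -2.16 %/mM over 3 points from index 25

# minimal peptide length from a CSC vs 1/N series (planted N_min: 3.5)
series <- gen_length_series(seed = 1)
fit_nmin(series$peptide_lengths, series$csc_values)
#> Minimal peptide length fit: CSC = m/N + c
#>   m = -2845 mM*N, c = 807 mM, R2 = 0.998
#>   N_min = 3.53 residues

# classify contacts in a frame with 3 planted hydrogen bonds, 2 ionic
# contacts, 1 stacking contact and 5 decoys
g <- gen_frame(seed = 1)
table(classify_contacts(g$frame)$mode)
#>    hbond    ionic stacking
#>        3        2        1

# FRAP recovery (planted tau: 10 s, mobile fraction 0.75)
fit_recovery(gen_frap(seed = 1)$trace)
#> FRAP exponential recovery fit
#>   tau = 10.2 s, plateau = 0.801, bleach depth = 0.208 (freeB)
#>   mobile fraction = 0.749, R2 = 0.9781

# partition coefficient from a micrograph (planted K_p: 8)
img <- gen_droplet_image(seed = 1, kp = 8)
kp_from_images(img$image, img$dark)
#> Partition coefficient Kp = 8.014
#>   I_droplet = 89.97, I_dilute = 19.99, I_dark = 10.01
#>   5 droplets, 7.9% of FOV
```

The CSC is read off where the steepest three-point tangent of the turbidity
decay crosses zero — here 221 mM against a planted 220 mM (the 1% noise and
finite sampling account for the difference). The N<sub>min</sub> fit says a
peptide of at least ~3.5 arginines is needed to coacervate with the planted
oligonucleotide series, and the FRAP fit reports an incomplete recovery
(plateau 0.80) with a mobile fraction of 0.75.

See `vignettes/methods.Rmd` for the models, parameter choices and
limitations, and `?extract_csc`, `?classify_contacts`, `?fit_recovery`,
`?kp_from_images`, `?quantify_bands` for the individual interfaces.

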