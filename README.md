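# beadpull

Quantitative image analysis for bead-based fluorescent pull-down assays.

## The problem

In an imaging bead pull-down assay, a GST-tagged bait protein is immobilized
on glutathione agarose beads, the beads are incubated with cell lysate
containing a GFP-fused prey, and — instead of eluting and blotting — the
washed beads are simply photographed under an epifluorescence microscope.
The fluorescence retained on each bead is a direct, linear readout of how
much prey the bait captured. What makes the method quantitative is the image
analysis: beads must be found and segmented reliably (including touching
beads and low signal-to-noise fields), their mean intensities measured above
a fair background estimate, and the numbers normalized so that assays taken
at different exposure times, prey concentrations and bait loadings are
comparable.

`beadpull` implements that detection stage end to end, for assay developers
and bench scientists who want a scriptable, auditable replacement for
interactive ImageJ sessions.

## The statistic

For bead *i* in a condition with exposure time *t* (ms), prey input *P*
(mock-corrected mean lysate fluorescence per ms) and bait input *B*
(protein per bead volume, µg/µl or µM):

```
a_i = (I_i / t) / (P · B)
```

where `I_i` is the bead's mean fluorescence after rolling-ball background
subtraction, residual-background correction and blank-bead autofluorescence
subtraction. A condition is summarized by the mean, SD (n−1) and n of its
per-bead affinities; within a comparison set, affinities are reported
relative to the largest, scaled so the maximum is 100. When every condition
shares the same bait (or prey), that input is set to 1. Conditions are
compared with fold changes and two-tailed Welch t-tests.

The default segmentation recipe is the assay's standard one: Gaussian
filter (radius 1 px), rolling-ball background subtraction (radius 400 px),
Otsu threshold, watershed separation of touching beads, then particle
filtering by size (≥ 200 px²), circularity (0.60–1.00) and edge contact.

## Worked example

```r
library(beadpull)

# a synthetic field: 120 beads of ~30 um at 0.5 um/px, SNR 4, exact truth
sc  <- render_scene(scene_spec(n_beads = 120, seed = 7))
res <- quantify_image(sc$image)

res$stage_counts
#>               masked        size_filtered circularity_filtered
#>                  120                  120                  120
#>        edge_filtered
#>                  120


nrow(res$measurements)          # beads measured
#> [1] 120
round(mean(res$measurements$mean_intensity_corrected), 1)
#> [1] 194.4                     # true rendered bead signal: 200
round(snr(res$corrected, res$labels), 1)
#> [1] 17.2                      # after 1-px Gaussian denoising
```

All 120 beads survive every filter; the measured mean is within 3% of the
rendered truth (boundary pixels dilute disk means slightly), and smoothing
lifts the raw SNR of 4 to ~17 on the corrected image.

To turn measurements from several conditions into affinities:

```r
aff <- run_affinity("out/all_beads.csv",
                    meta = data.frame(condition = c("wt", "mut"),
                                      bait_input = c(16, 16),
                                      prey_input_per_ms = c(5.1, 5.1)))
aff$affinities    # mean, SD, n, relative (max = 100) per condition
aff$comparisons   # fold change, Welch t, df, p per pair
```

A thin command-line wrapper (`inst/cli/beadpull.R`) exposes `simulate`,
`quantify` and `affinity`/`compare` subcommands over the same functions.

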