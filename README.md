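# mitogranule

Quantification of mitochondrial RNA **inhibition granules** from
fluorescence images, and of mitochondrial transcript **decay kinetics** from
NanoStrings-style count time courses.

When mitochondrial transcription is arrested (EtBr, the POLRMT inhibitor
IMT1B), mitochondrial mRNAs redistribute from a diffuse state along the
mitochondrial network into discrete RNA clusters. This package implements
the two analysis arms used to characterise that phenotype, for cell
biologists working with RNA-FISH images and nCounter-style count data:

**Imaging arm** — flat-field correction
(`out = (sample − dark) / (flat − dark)`, then sum z-projection), RNA-object
segmentation (Kirsch 8-direction compass edge enhancement → minimum
cross-entropy (Li) global threshold, smoothing scale 1.3488 → intensity-guided
declumping with watershed-style dividing lines → hole filling), assignment
of objects to hand-drawn or ground-truth cell masks, and three per-cell
granularity statistics:

- *fraction of cellular area occupied* `= Σ RNA object area / cell area`
  (decreases when signal clusters),
- *skewness* `g1 = m3 / m2^(3/2)` of the per-cell pixel intensities
  (increases with a bright right tail),
- *area-normalized integrated intensity*.

Conditions are compared with one-sided two-sample t-tests
(area: "less", skewness: "greater", no multiple-testing adjustment).

**Counts arm** — reference normalization (GAPDH, c-MYC or spike-ins),
two-window log-linear half-life estimation
(`t1/2 = (log10 0.5 − log10 1) / slope`, early window {0, 2, 5} h anchored
at 0 h, late window {5, 8, 24} h anchored at 5 h), two-state decay
classification (`t_late / t_early ≥ 4` ⇒ biphasic: a fast-decaying and a
stabilized RNA population), log2 fold changes, Pearson r², plus the 4sU
labeling analyses: transient-transcription metagene with t-distribution
confidence ribbon, and spike-in-normalized decay of the unlabeled RNA pool.

A first-class **synthetic-data module** generates multi-channel fluorescence
fields (cells, branched mitochondrial network, diffuse or clustered puncta,
PSF/illumination/camera noise) and count tables (two-population exponential
decay, lognormal replicate noise) with exported ground truth, so every stage
of both arms is testable without downloads.

## Worked example

Half-life estimation on simulated counts with known kinetics:

```r
library(mitogranule)
p <- count_sim_params(c("MT-ND5", "MT-CO1"),
                      h_fast = c(1, 2.4), h_slow = c(20, 5),
                      f = c(0.85, 0.9), lognormal_noise_sd = 0.05, seed = 7)
sim  <- simulate_decay_counts(p)
fits <- two_phase_halflives(normalize_to_reference(sim$counts, "GAPDH"))
fits[, c("transcript", "t_early_half", "t_late_half", "classification")]
```

```
 transcript t_early_half t_late_half classification
     MT-ND5         1.90       17.00      two-state
     MT-CO1         2.64        3.29      one-state
```

MT-ND5 (85% of molecules with a 1-h half-life, the rest at 20 h) shows the
biphasic signature — fast early loss, strong late stabilization — while
MT-CO1's two similar rates collapse to one state. The simulator's analytic
truth for the same windows is 1.88 h / 16.51 h, so the noisy estimates are
within a few percent.

The imaging arm runs the same way from a simulated field:

```r
p   <- image_sim_params(granular = TRUE, seed = 1)
out <- quantify_field(p)         # correct -> segment -> assign -> metrics
head(out$metrics)
```

## Analysis workflow

The `analysis/` scripts are thin numbered drivers over the package and
write their tables and figures under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_images.R` | generate paired diffuse/granular fields + flat-fields + ground truth (TIFF/CSV) |
| `02_granule_quantification.R` | imaging arm end-to-end; per-cell metrics and one-sided condition tests |
| `03_decay_kinetics.R` | half-life recovery on simulated counts; published-table round trip; two-state classification |
| `04_labeling_kinetics.R` | 4sU metagene during recovery; unlabeled-pool decay |

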