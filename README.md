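# speckletools

Quantitative pipelines for studies of stress-regulated, IRES-dependent
translation and its link to nuclear paraspeckles. During stress such as
hypoxia, cap-dependent translation initiation shuts down while internal
ribosome entry sites (IRESs) keep specific mRNAs — notably those of
(lymph)angiogenic and cardioprotective factors — translated, under the
control of IRES trans-acting factors (ITAFs) and, per recent work, of the
paraspeckle (a nuclear body scaffolded by the lncRNA *Neat1* with DBHS
proteins such as p54^nrb^/NONO). Investigating that link takes four very
different quantitative readouts, all implemented here for analysts who
receive the raw tables and images:

1. **Spot imaging** — detection of nuclear RNA foci in FISH/smiFISH
   images by Laplacian-of-Gaussian (LoG) local maxima, DAPI-based nucleus
   segmentation (Otsu + watershed declumping), per-cell focus counts, and
   distance-based two-channel colocalization
   (`segment_nuclei()`, `detect_spots()`, `count_foci()`, `colocalize()`).
2. **AP-MS differential interactome** — label-free quantification with
   the fixed order *sum unique peptides → median normalization →
   5%-quantile imputation of missing values → log2 → technical-replicate
   averaging → pooled-variance Student t-test*; enrichment calls at
   |log2FC| > 1 and p < 0.05, confidence filters on PSM counts (> 4) and
   pre-imputation replication (≥ 2 biological replicates in a group),
   volcano summaries, and overlap with a packaged 40-component
   paraspeckle annotation (`run_enrichment()`, `annotate_paraspeckle()`).
3. **Polysome PCR array** — 2^-ΔΔCt relative quantification
   (RQ = 2^−(ΔCt_treatment − ΔCt_calibrator), ΔCt = Ct_gene − Ct_reference),
   polysomal/total recruitment ratios, the signed fold-change convention
   (RQ < 1 → −1/RQ), and per-gene-class repression/induction summaries
   (`delta_delta_ct()`, `recruitment()`, `summarize_classes()`).
4. **Dual-luciferase reporter** — background subtraction, the LucF/LucR
   ratio of a bicistronic reporter (LucF is IRES-driven, LucR
   cap-driven), replicate aggregation, reference normalization, and exact
   Mann–Whitney group comparisons (`ires_activity()`, `mann_whitney()`).

Seeded simulators (`simulate_images()`, `simulate_lfq()`,
`simulate_ct()`, `simulate_plate()`) emulate each input with known ground
truth, so every stage is testable without external data. The methods
vignette (`vignettes/methods.Rmd`) documents the models, defaults, and
known limitations (e.g. the fold-change bias that quantile imputation
introduces under left-censored missingness).

## Worked example

Simulate one smiFISH field (8 nuclei, 2 expected foci per cell, spot
amplitude 5x the noise), segment, detect, and count:

```r
library(speckletools)
sim  <- simulate_images(sim_image_config(seed = 42, n_fields = 1,
                                         n_nuclei_per_field = 8,
                                         spots_per_cell_rate = c(Cy3 = 2),
                                         spot_amplitude = 100, noise_sd = 20))
mask <- segment_nuclei(sim$fields[[1]])
#> <nucleus_mask> 128 x 128 px, 8 nuclei
spots <- detect_spots(sim$fields[[1]], "Cy3", sigma = 1.5,
                      threshold = 50, mask = mask)
count_foci(spots, mask)
#> <foci_summary> 8 cells, 2 foci/cell, 87.5% cells with >= 1 focus
```

The detector recovered exactly the simulated Poisson truth: 2 foci per
cell on average, with 7 of 8 cells harbouring at least one focus.

Compare IRES activities between conditions (9 biological replicates per
group, as in a typical reporter design):

```r
mann_whitney(c(0.21, 0.24, 0.20, 0.23, 0.26, 0.22, 0.25, 0.27, 0.19),
             c(0.41, 0.38, 0.45, 0.40, 0.37, 0.44, 0.39, 0.42, 0.36))
#>     n_a   n_b     U   p_value method mean_a mean_b   sd_a   sd_b
#> 1     9     9     0 0.0000411 exact    0.23  0.402 0.0274 0.0307
```

U = 0 means complete separation of the two groups; the p-value 4.1e-5 is
exact (full enumeration of rank assignments, n1 + n2 ≤ 20 without ties).

`run_demo(outdir, seed)` chains all four arms on simulated inputs and
writes every result as CSV plus a provenance record.

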