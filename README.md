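# dida — Digital Image Disintegration Analysis

`dida` turns a video of a fast-disintegrating tablet (FDT) in a small, dark
disintegration vessel into a quantitative **disintegration profile**:
% tablet remaining versus time. FDTs must break apart in the mouth within
seconds, in far less liquid than compendial disintegration baths use; an
image-based assay resolves their behaviour in 0.05–0.7 mL of medium by
exploiting the contrast between the white formulation and a matte black
vessel, filmed from above at 10 frames/s.

The core quantity is the **mean grey value (MGV)** over a fixed region of
interest covering the formulation. With the background (medium-only)
recording anchoring 0% and the background-corrected intact-tablet recording
anchoring 100%,

```
R(t) = 100 · (G(t) − Ḡ_bg) / (Ḡ_tab − Ḡ_bg)
```

R(t) is not clipped: sustained values above 100% are read as **swelling**
(gel-forming excipients such as hypromellose take up water and grow instead
of disintegrating), and slightly negative values measure the noise floor.
Profiles are summarized at the pharmacopoeial timepoints (10 s, 30 s,
3 min), classified into *instant / fast / prolonged / partial / swelling*
(fast ≤ 30 s is the FDA limit, prolonged ≤ 3 min the Ph. Eur. limit), and
conditions are compared with Welch t-tests computed from summary statistics.
A built-in simulator renders synthetic assay recordings with closed-form
kinetics, so every stage is validated against analytic ground truth.

The package is aimed at formulation scientists and QC labs running
small-volume image-based disintegration assays, and at anyone needing a
tested reference implementation of the MGV normalization and classification
logic.

## Worked example

Simulate a 250 s assay (10 Hz, sensor noise sd 2 grey levels, three
replicates) of a tablet decaying to an 8% residue with rate k = 0.1 /s,
then analyze it exactly as a real recording would be:

```r
library(dida)

cfg <- simulation_config(
  kinetics   = kinetics_model("decay_to_plateau", rate_k_per_s = 0.1,
                              plateau_pct = 8),
  noise_sd   = 2, duration_s = 250, seed = 1, n_replicates = 3)
bundle   <- generate_assay(cfg)
refs     <- measure_references(bundle$background, bundle$tablet_only, bundle$roi)
profiles <- lapply(seq_along(bundle$replicates), function(i)
  build_profile(mgv_series(bundle$replicates[[i]], bundle$roi), refs,
                replicate_id = paste0("replicate_", i)))

summarize_timepoints(profiles, c(10, 30, 180))
#>   timepoint_s mean_percent sd_percent n
#> 1          10    41.818401 0.04316114 3
#> 2          30    12.573064 0.05154773 3
#> 3         180     8.041779 0.03445197 3

classify_profile(profiles[[1]])
#> <dida_classification> prolonged (endpoint 38.2 s, max 63.8%, final 8.0%)
```

The 10 s mean (41.8%) sits on the analytic curve 8 + 92·e^(−1) ≈ 41.84, and
the tiny replicate sds (~0.04 points) reflect the averaging of 9216 ROI
pixels. The classifier reports *prolonged* with an endpoint of 38.2 s: the
profile first stays at or below the 10% completion threshold from 38.2 s on
— just past the 30 s "fast" bound, matching the kinetics, which cross 10% at
ln(46)/0.1 ≈ 38.3 s.

Comparing two published conditions from their summary statistics
(% remaining at 3 min, 21 ± 3 vs 8 ± 1, n = 3 each):

```r
welch_t_from_summary(21, 3, 3, 8, 1, 3)
#> <dida_comparison> t = 7.1204, df = 2.439, p = 0.01093 *
```

## Command line

A thin CLI wraps the same functions (`inst/cli/dida.R`):

```sh
Rscript inst/cli/dida.R simulate -c sim.yaml  -o bundle/
Rscript inst/cli/dida.R analyze  -c run.yaml  -o out/
Rscript inst/cli/dida.R compare  -a out_a/timepoint_summary.csv \
                                 -b out_b/timepoint_summary.csv -t 180
```

`analyze` writes one profile CSV per replicate (`time_s, mgv,
percent_remaining, flags`), a timepoint-summary CSV, a classification JSON
and a run log carrying the package version and a config hash; reruns on the
same inputs are byte-identical. Exit codes: 0 ok, 1 input error, 2 internal
error.

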