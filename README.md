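# omapr — cardiac optical mapping analysis in R

Optical mapping records the electrical activity of intact cardiac
preparations (Langendorff-perfused whole hearts, superfused atria)
through voltage-sensitive fluorescent dyes, producing movies in which
every pixel is an optical action potential.  `omapr` turns such movies
into the quantities electrophysiologists report:

* **APD maps** — action potential duration at a repolarisation level
  (APD80: time from maximum upstroke velocity, max dV/dt, to the 80%
  repolarisation crossing),
* **activation maps** — per-pixel depolarisation midpoint (50% upstroke
  crossing, sub-sample interpolated) or max-dV/dt time,
* **conduction velocity** — the multi-vector method: a local polynomial
  surface `T(x, y)` is fitted to activation times in each 5×5 window and
  `v = ∇T / |∇T|²`, in cm/s,
* **heterogeneity** — `(P95 − P5) / P50` of any map,
* **alternans (ΔAPD80)** — mean absolute APD difference between
  consecutive single beats,
* **optical wave similarity (OWS)** — weighted mean pairwise cosine
  similarity of amplitude-normalised single-beat waveforms, in [0, 1],
* **dominant frequency (DF)** — peak of the Hann-windowed, zero-padded
  power spectrum in 0.5–50 Hz at 0.05 Hz resolution.

Upstream of these sit the standard preprocessing steps (per-pixel
polarity inversion for voltage dyes, 3×3 Gaussian spatial filter with
masked renormalisation, top-hat morphological baseline correction,
amplitude-based tissue masking), automated beat and pacing-cycle-length
(PCL) detection, and ensemble averaging of the last 10 beats per PCL.
Movies are read from MAT containers (v6/v7 natively, v7.3 via the
`h5py` bridge); all maps export as CSV + PNG.

Because the deposited experimental recordings are multi-gigabyte
downloads, the package ships a first-class synthetic generator
(`simulate_paced_movie()`, `simulate_irregular_movie()`) producing
movies with *exact* ground truth — programmed conduction speed, APD,
alternans, pacing schedule, noise, drift, dye polarity, and a
transmural-breakthrough artefact term — against which the entire
pipeline is validated.

## Worked example

Simulate a mouse-whole-heart-like recording (51×51 px, 156 µm/px,
1 kHz, planar wave at 50 cm/s, APD80 45 ms, paced at 110 ms, SNR 20)
and analyse it:

```r
library(omapr)

spec <- sim_spec(grid = c(51, 51), pixel_size = 156, frame_rate = 1000,
                 geometry = "planar", speed = 50,
                 pcl_schedule = cbind(pcl_ms = 110, n_beats = 12),
                 apd80 = 45, noise_sd = 0.05, seed = 7)
sim   <- simulate_paced_movie(spec)

movie <- apply_polarity(sim$movie)          # upstroke-positive
mask  <- segment_tissue(movie)
movie <- gaussian_spatial_filter(movie, mask = mask)
movie <- tophat_baseline(movie, kernel_ms = 100)

sig   <- global_signal(movie, mask)
beats <- identify_pcls(detect_beats(sig, 1000, refine_midpoint = TRUE),
                       1000)
beats
#> <beat_table> 12 beats in 1 PCL group(s)
#>  pcl_group nominal_pcl beat_count
#>          1         110         12

ens     <- ensemble_average(movie, beats, group = 1)
apd_map <- map_beat(ens, mask, "apd")
act_map <- map_beat(ens, mask, "activation")
cvm     <- cv_map(act_map, pixel_size = 156)
roi <- matrix(FALSE, 51, 51); roi[4:48, 4:48] <- TRUE

sprintf("mean APD80 %.1f ms | heterogeneity %.3f | CV %.1f cm/s | DF %.2f Hz",
        mean(map_values(apd_map)), heterogeneity(apd_map),
        roi_mean_cv(cvm, tissue_mask(roi)),
        dominant_frequency(sig, 1000)$df)
#> "mean APD80 45.6 ms | heterogeneity 0.029 | CV 50.0 cm/s | DF 9.10 Hz"
```

The recovered numbers sit on the programmed truth: APD80 45 ms (the
+0.6 ms is noise-floor), CV 50 cm/s, and DF 9.10 Hz is the pacing
fundamental 1000/110 = 9.09 Hz on the 0.05 Hz grid.  The low APD
heterogeneity reflects the homogeneous simulated tissue.

`run_pipeline()` wraps the whole chain (including alternans, OWS and DF
maps, summary CSV and a config-echo log) over a movie, folder or
`fluor_movie` object; `inst/cli/omapr.R` is a thin Rscript front end
(`analyze`/`simulate` subcommands) over the same functions.

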