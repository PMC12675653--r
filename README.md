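# psaqc

Quantification of the **pupil-size artifact (PSA)** in video-based eye
tracking. When the pupil dilates or constricts, the pupil center migrates
and pupil-based gaze estimation reports an apparent gaze displacement even
though the eye never rotated. `psaqc` implements a complete, tested
analysis pipeline for measuring this artifact with a bright/dark fixation
paradigm, for vision scientists and eye-tracking methodologists who want
to benchmark devices or validate analysis code without access to raw
recordings.

The package covers five stages:

1. **Synthetic sessions** (`generate_session()`, `generate_pupil_trace()`,
   `render_scene_frame()`): ground-truth-known bright/dark fixation
   sessions — 3 trials of a 10-s bright then 10-s dark period, each split
   into a 5-s adaptation and a 5-s measurement phase, with a central
   fixation target, AR(1) gaze noise, Poisson blinks and an injected PSA
   shift — plus rendered scene-camera frames (white/black screen, gray
   bullseye target, four green corner markers) at a 930-mm viewing
   distance.
2. **Scene-camera mapping** (`detect_markers()`, `undistort_points()`,
   `compute_scaling_factor()`, `estimate_viewing_distance()`,
   `map_gaze_to_degrees()`, `eyelink_pixels_to_degrees()`): head-mounted
   trackers report gaze in scene-camera pixels; the pipeline detects the
   five screen elements (thresholding, connected components, k-means),
   undistorts, converts pixels to millimeters via the known marker
   spacing,

       scaling factor = physical distance (mm) / apparent distance (px)
       gaze_mm  = (gaze_px - screen_center_px) * scaling factor
       gaze_deg = arctan(gaze_mm / distance_mm)

   and estimates the viewing distance from the pinhole relation
   `distance = f_px * marker_mm / marker_px`. Desktop trackers that report
   their own pixels-per-degree resolution use the linear conversion
   `gaze_deg = (gaze_px - center_px) / resolution`.
3. **Preprocessing** (`trim_trial()`, `distance_filter()`,
   `sd_outlier_filter()`, `clean_pipeline()`, `pupil_area_to_mm()`):
   keep the middle 75% of each trial, remove points more than 10° from
   the target (blink artifacts), then remove points beyond 3 SD from the
   mean in either dimension; convert device pupil area to mm via an
   artificial-pupil calibration, `D_mm = D_art * sqrt(area / area_art)`.
4. **Quality metrics** (`accuracy()`, `apparent_gaze_shift()`,
   `std_precision()`, `rms_s2s()`, `data_loss()`): with valid samples
   `(x_i, y_i)`, target `T` and centroid `(mu_x, mu_y)`,

       accuracy = mean_i || (x_i, y_i) - T ||
       apparent gaze shift = mean over sequential trial pairs of
                             || bright centroid - dark centroid ||
       STD      = sqrt( mean_i [ (x_i - mu_x)^2 + (y_i - mu_y)^2 ] )
       RMS-S2S  = sqrt( mean over consecutive valid pairs of
                        || sample_{i+1} - sample_i ||^2 )
       data loss = 100 * N_invalid / N_total   (before cleaning)

5. **Statistics** (`paired_t()`, `one_sample_t_vs_zero()`, `bonferroni()`,
   `cohens_d_paired()`, `summarize_comparisons()`,
   `shift_vs_zero_table()`): per-device bright-vs-dark paired t tests,
   Bonferroni adjustment, paired Cohen's d (`d = mean(diff)/sd(diff) =
   t/sqrt(n)`) with the conventional bins (negligible < 0.2 <= small
   < 0.5 <= medium < 0.8 <= large), and shift-greater-than-zero tests.

## Worked example

```r
library(psaqc)

device      <- device_profile(sampling_rate = 100, noise_std = 0.3,
                              blink_rate = 0.2)
participant <- participant_profile(psa_shift = c(2, 0))  # 2 deg artifact
session     <- generate_session(device, participant, trial_schedule(),
                                seed = 42)

res <- analyze_session(session$recordings)
res$metrics
#>   trial condition  accuracy       std   rms_s2s data_loss n_valid
#> 1     1    bright 0.2629606 0.2954882 0.4175711       3.0     360
#> 2     1      dark 2.0110135 0.3089914 0.4432626       0.0     376
#> 3     2    bright 0.2668809 0.2981263 0.4220117       0.0     376
#> 4     2      dark 2.0000154 0.2930918 0.4168477       3.0     361
#> 5     3    bright 0.2726534 0.3057008 0.4344788       0.8     374
#> 6     3      dark 2.0073787 0.2958949 0.4201172      12.0     343
res$shift$mean_shift
#> [1] 1.997569
```

Bright-condition accuracy sits near the 0.3° noise floor; in the dark
condition the injected 2° artifact dominates accuracy, while precision
(STD, RMS-S2S) is unchanged — exactly the dissociation the paradigm is
designed to expose. The apparent gaze shift recovers the injected
magnitude to within sampling noise, and `data_loss` reports the blink
percentage of each raw trial.

For the scene-camera route:

```r
cam <- camera_model(distortion = c(-0.1, 0, 0, 0, 0))
scr <- screen_geometry()                 # 476 x 268 mm screen, 930 mm
frame <- render_scene_frame(cam, scr, "bright", gaze_angle = c(3, -2))
det   <- undistort_detection(detect_markers(frame$image), cam)
scale <- compute_scaling_factor(det, scr)             # mm per pixel
dist  <- estimate_viewing_distance(det, scr, cam)     # ~930 mm
map_gaze_to_degrees(undistort_points(frame$truth$gaze_px, cam),
                    det, scale, dist)
#>         deg_x     deg_y
#> [1,] 2.999028 -1.999352
```

## Command line

A dispatcher script is installed at
`system.file("cli", "psaqc", package = "psaqc")`:

```sh
psaqc simulate  --config config.yaml --seed 1 --out session/
psaqc preprocess --in trial.csv --target-x 0 --target-y 0 --radius 10 \
                 --sd-k 3 --trim 0.125 --out clean.csv --report report.json
psaqc metrics   --in clean.csv --raw trial.csv --out metrics.json
psaqc map       --gaze gaze_px.csv --markers markers.csv \
                --camera camera.yaml --screen screen.yaml --out gaze_deg.csv
psaqc stats     --metrics tidy.csv --family per-metric --out report.csv
```

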