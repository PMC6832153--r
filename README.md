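# mipipe

Two-class motor-imagery (MI) EEG classification in R: blind source
separation with spectral-template sorting, Morse-wavelet scalogram images,
and a small convolutional network, plus a fully synthetic EEG generator so
the whole pipeline is testable and reproducible without any external data.

## The method

EEG channels record an instantaneous linear mixture `x(t) = A s(t)` of
cortical sources and artifacts. Imagined movement modulates the mu
(8–13 Hz) and beta (14–26 Hz) rhythms over the sensorimotor cortex, but a
blind source separation of each trial returns its estimated sources
`s'(t) = B x(t)` in an arbitrary order — fatal for a downstream classifier
that expects stable input rows. The pipeline:

1. selects two 9-channel sensorimotor clusters (FC5…CP1 / FC2…CP6) and
   band-pass filters them (Butterworth, 0.5–90 Hz by default);
2. estimates sources per trial and per cluster with fastICA (fixed-point
   negentropy maximization) or SOBI (joint diagonalization of lagged
   covariances);
3. **sorts** the estimated sources by the Pearson correlation between
   their Welch power spectrum and a movement-related independent component
   (MRIC) template — two Gaussian bumps at 10.5 Hz and 20 Hz on a
   0.5–45 Hz grid — so mu/beta-rich sources occupy stable top rows and
   artifacts sink;
4. computes generalized Morse wavelet scalograms (γ = 3, β = 20) over
   1.0-s windows stepped by 0.25 s, stacks them per window (left cluster
   above right), and resizes each stack to a 128×256 image in [0, 1];
5. trains a compact CNN — conv 250 (3,1)/(2,1) + pool (4,4), conv 150
   (1,2) + pool (3,3), dense 2048, dropout 0.4, softmax — and reports
   k-fold accuracy tables (a reduced 8/8/32 variant ships for desk-scale
   experiments).

A synthetic generator produces datasets with known sources, known mixing
matrices, lateralized class-dependent mu/beta gains (event-related
desynchronization), and full ground truth, which is what the test suite
exercises end to end. See the methods vignette
(`vignettes/motor-imagery-pipeline.Rmd`) for the model details and design
decisions.

## A worked example

```r
library(mipipe)

cfg <- pipeline_config(
  synthetic  = synthetic_config(n_trials_per_class = 10, seed = 501),
  filter_band = c(0.5, 45),             # below the 50 Hz Nyquist at fs = 100
  bss = "fastica", sorting = "mric",
  architecture = reduced_architecture_spec(),
  training = train_config(epochs = 16, batch_size = 16, learning_rate = 2e-3),
  k = 10, seed = 201)

run <- run_pipeline(cfg, "runs/sorted")
print(run)
#> <pipeline_run> fastica/mric: k-fold mean 87.27% (std 14.97), mean val acc 0.576

run$report
#> <eval_report> synthetic: 10 folds, mean 87.27%, std 14.97
```

The k-fold numbers use the max-over-epochs protocol (best stored epoch per
fold); `evaluate_kfold(..., mode = "plain")` scores the final parameters
only. Rerunning an identical config reproduces `report.csv` byte for byte.

The scientific point of the sort shows up in the ablation: with sorting
disabled (`sorting = "shuffled"`), the same network memorizes the training
windows but fails to generalize (train accuracy ≈ 0.95, validation ≈ 0.47
here), while the sorted arm's validation accuracy climbs well above
chance. `compare_arms()` tabulates such runs side by side:

```r
runs <- list(run, run_pipeline(modifyList(cfg, list(sorting = "shuffled")),
                               "runs/shuffled"))
compare_arms(runs)
```

A thin CLI with the same verbs (`generate`, `run`, `compare`,
`export-images`) is installed at `system.file("cli", "mipipe",
package = "mipipe")`.

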