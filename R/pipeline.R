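# End-to-end orchestration: data -> preprocess -> source separation ->
# MRIC sort -> scalogram images -> CNN -> k-fold report, with on-disk run
# directories and ablation comparison.

#' Pipeline configuration
#'
#' Bundles every stage's parameters. Data comes either from a
#' [synthetic_config()] (the dataset seed lives there, so different
#' ablation arms can share one dataset) or from a recording on disk.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading a
#'   recording.
#' @param recording Path to an EDF file or a delimited matrix (with JSON
#'   sidecar) holding a continuous recording with markers.
#' @param montage A [cluster_montage()].
#' @param filter_band Band-pass cut-offs in Hz (`high` must stay below the
#'   Nyquist frequency of the data actually used).
#' @param filter_order Butterworth design order.
#' @param epoch_window MI segment `c(start, end)` in seconds after trial
#'   onset (recording input only).
#' @param bss `"fastica"`, `"sobi"`, or `"none"` (channels pass through).
#' @param sorting `"mric"`, `"none"` (keep the arbitrary separation
#'   order), or `"shuffled"` (explicitly permute sources per trial, the
#'   no-sort ablation).
#' @param template An MRIC template; defaults to [default_template()].
#' @param cwt List of Morse CWT parameters: `gamma`, `beta`,
#'   `voices_per_octave`, `window` (s), `step` (s).
#' @param architecture An [architecture_spec()]. The full-size reference
#'   architecture is the default; [reduced_architecture_spec()] is the
#'   desk-scale choice for synthetic experiments.
#' @param training A [train_config()].
#' @param k Number of evaluation folds.
#' @param sobi_max_lag Largest covariance lag (samples) used when
#'   `bss = "sobi"`; 30 samples spans 0.3 s at 100 Hz, enough for mu/beta
#'   autocorrelation.
#' @param seed Global seed for separation, training and shuffling (the
#'   dataset seed is `synthetic$seed`).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), recording = NULL,
                            montage = cluster_montage(), filter_band = c(0.5, 90),
                            filter_order = 2, epoch_window = c(4.5, 8.0),
                            bss = c("fastica", "sobi", "none"),
                            sorting = c("mric", "none", "shuffled"),
                            template = NULL,
                            cwt = list(gamma = 3, beta = 20, voices_per_octave = 12,
                                       window = 1.0, step = 0.25),
                            architecture = architecture_spec(),
                            training = train_config(), k = 10, sobi_max_lag = 30,
                            seed = 1) {
  bss <- match.arg(bss)
  sorting <- match.arg(sorting)
  mp_assert(xor(is.null(synthetic), is.null(recording)),
            "provide exactly one of synthetic or recording", "parameter")
  if (!is.null(synthetic)) {
    mp_assert(inherits(synthetic, "synthetic_config"),
              "synthetic must be a synthetic_config", "parameter")
  }
  mp_assert(length(filter_band) == 2 && filter_band[1] < filter_band[2],
            "filter_band must be c(low, high)", "parameter")
  defaults <- list(gamma = 3, beta = 20, voices_per_octave = 12, window = 1.0, step = 0.25)
  cwt <- utils::modifyList(defaults, cwt)
  structure(list(synthetic = synthetic, recording = recording, montage = montage,
                 filter_band = filter_band, filter_order = filter_order,
                 epoch_window = epoch_window, bss = bss, sorting = sorting,
                 template = template, cwt = cwt, architecture = architecture,
                 training = training, k = as.integer(k),
                 sobi_max_lag = as.integer(sobi_max_lag), seed = as.integer(seed)),
            class = "pipeline_config")
}

# Apply separation + ordering to one cluster of one trial.
process_cluster <- function(xc, cfg, template, trial_seed) {
  src <- switch(cfg$bss,
                none = xc,
                fastica = fastica(xc, contrast_spec(seed = trial_seed))$sources,
                sobi = sobi(xc, lags = seq_len(min(cfg$sobi_max_lag,
                                                   floor(ncol(xc) / 3))))$sources)
  switch(cfg$sorting,
         mric = sort_sources(src, attr(xc, "fs"), template)$sources,
         none = src,
         shuffled = src[with_seed(trial_seed + 1L, sample.int(nrow(src))), , drop = FALSE])
}

#' Run the full pipeline
#'
#' Generates or loads the data, band-pass filters each trial, separates
#' and orders sources per hemisphere cluster, converts every sliding
#' window to a stacked 128x256 scalogram image, trains the CNN on a
#' stratified trial-level split (windows inherit their trial's split and
#' label), and evaluates with [evaluate_kfold()]. All stage outputs land
#' in `out_dir`; rerunning an identical config reproduces identical
#' reports byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created; contents overwritten).
#' @param verbose Print per-stage progress.
#' @return A `pipeline_run`: config, manifest, training history, the
#'   [eval_report()], and `dir`.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  mp_assert(inherits(config, "pipeline_config"), "config must be a pipeline_config",
            "parameter")
  mp_assert(config$training$epochs >= 1, "run_pipeline needs at least one training epoch",
            "parameter")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    if (verbose) message(msg)
  }
  stage <- function(name, code, trial = NA) {
    tryCatch(code, error = function(e) {
      line <- sprintf("FAILED at stage '%s'%s: %s", name,
                      if (is.na(trial)) "" else sprintf(" (trial %s)", trial),
                      conditionMessage(e))
      writeLines(c(log_lines, line), log_path)
      mp_abort(line, "stage")
    })
  }

  say("stage data")
  ts <- stage("data", {
    if (!is.null(config$synthetic)) generate_dataset(config$synthetic)
    else {
      rec <- if (grepl("\\.edf$", config$recording, ignore.case = TRUE)) {
        read_edf(config$recording)
      } else {
        read_eeg_delim(config$recording)
      }
      epoch_trials(rec, config$epoch_window[1], config$epoch_window[2])
    }
  })
  dataset_hash <- rlang::hash(list(ts$trials, ts$labels, ts$fs))
  montage <- config$montage
  template <- config$template %||% default_template()
  n_trials <- length(ts$trials)
  mp_assert(n_trials >= 4, "need at least 4 trials", "parameter")

  say("stage preprocess+bss+sort+cwt (%d trials)", n_trials)
  images <- list()
  for (i in seq_len(n_trials)) {
    stage("trial", trial = i, {
      rec <- eeg_recording(ts$trials[[i]], ts$channel_names, ts$fs)
      clusters <- select_clusters(rec, montage)
      trial_seed <- derive_seed(config$seed, paste0("trial", i))
      ordered <- lapply(clusters, function(xc) {
        xc <- bandpass(xc, ts$fs, config$filter_band[1], config$filter_band[2],
                       config$filter_order)
        attr(xc, "fs") <- ts$fs
        process_cluster(xc, config, template, trial_seed)
      })
      stacked <- rbind(ordered$left, ordered$right)
      maps <- window_maps(stacked, ts$fs, config$cwt$window, config$cwt$step,
                          config$cwt$gamma, config$cwt$beta, config$cwt$voices_per_octave)
      for (w in seq_along(maps)) {
        images[[length(images) + 1L]] <- rescale_image(maps[[w]], trial_id = i,
                                                       window_index = w,
                                                       label = ts$labels[i])
      }
    })
  }

  say("stage split+train")
  run <- stage("train", {
    frac <- config$training$train_fraction
    train_trials <- unlist(lapply(split(seq_len(n_trials), ts$labels), function(idx) {
      idx[seq_len(floor(length(idx) * frac))]
    }))
    img_trial <- vapply(images, function(im) im$trial_id, numeric(1))
    train_imgs <- images[img_trial %in% train_trials]
    test_imgs <- images[!(img_trial %in% train_trials)]
    train_is <- image_set(train_imgs)
    test_is <- image_set(test_imgs)
    model <- build_model(config$architecture, seed = derive_seed(config$seed, "init"))
    tc <- config$training
    tc$seed <- derive_seed(config$seed, "train")
    model <- train(model, train_is, tc, validation_set = test_is)
    list(model = model, test_is = test_is,
         n_train = length(train_imgs), n_test = length(test_imgs))
  })

  say("stage evaluate (k = %d)", config$k)
  report <- stage("evaluate", {
    evaluate_kfold(run$model, run$test_is, k = config$k, subject_id = "synthetic")
  })

  h <- run$model$history
  manifest <- list(package = "mipipe",
                   version = as.character(utils::packageVersion("mipipe")),
                   bss = config$bss, sorting = config$sorting,
                   seed = config$seed, dataset_hash = dataset_hash,
                   config_hash = rlang::hash(config),
                   n_trials = n_trials, n_train_images = run$n_train,
                   n_test_images = run$n_test, k = config$k,
                   epochs = config$training$epochs,
                   train_accuracy_final = h$accuracy[nrow(h)],
                   val_accuracy_mean = mean(h$val_accuracy),
                   # burn-in discarded: mean over the second half of training
                   val_accuracy_late = mean(h$val_accuracy[(nrow(h) %/% 2 + 1):nrow(h)]),
                   val_accuracy_max = max(h$val_accuracy),
                   kfold_mean = report$mean, kfold_std = report$std,
                   stages = c("data", "preprocess", "bss", "mric_sort", "cwt", "cnn",
                              "evaluate"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(h, file.path(out_dir, "history.csv"), row.names = FALSE)
  write_eval_reports(list(report), file.path(out_dir, "report.csv"))
  writeLines(log_lines, log_path)
  structure(list(dir = out_dir, config = config, manifest = manifest,
                 history = h, report = report, model = run$model),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %s/%s: k-fold mean %.2f%% (std %.2f), mean val acc %.3f\n",
              x$manifest$bss, x$manifest$sorting, x$manifest$kfold_mean,
              x$manifest$kfold_std, x$manifest$val_accuracy_mean))
  invisible(x)
}

#' Compare ablation arms
#'
#' Reads the manifests of two or more completed runs (which must share a
#' dataset) and tabulates their accuracies, best arm first.
#'
#' @param runs List of `pipeline_run` objects or run directory paths.
#' @return A tibble with one row per arm: `arm` (`<bss>/<sorting>`), mean
#'   and max per-epoch validation accuracy, final train accuracy, and the
#'   k-fold mean/std.
#' @export
compare_arms <- function(runs) {
  mp_assert(length(runs) >= 2, "need at least two completed runs", "parameter")
  manifests <- lapply(runs, function(r) {
    if (inherits(r, "pipeline_run")) return(r$manifest)
    path <- file.path(r, "manifest.json")
    mp_assert(file.exists(path), paste0("no manifest in ", r), "parameter")
    jsonlite::read_json(path, simplifyVector = TRUE)
  })
  hashes <- vapply(manifests, `[[`, character(1), "dataset_hash")
  if (length(unique(hashes)) != 1) {
    mp_abort("runs were made on different datasets (dataset_hash mismatch)", "comparison")
  }
  out <- tibble::tibble(
    arm = vapply(manifests, function(m) paste(m$bss, m$sorting, sep = "/"), character(1)),
    val_accuracy_mean = vapply(manifests, `[[`, numeric(1), "val_accuracy_mean"),
    val_accuracy_late = vapply(manifests, `[[`, numeric(1), "val_accuracy_late"),
    val_accuracy_max = vapply(manifests, `[[`, numeric(1), "val_accuracy_max"),
    train_accuracy_final = vapply(manifests, `[[`, numeric(1), "train_accuracy_final"),
    kfold_mean = vapply(manifests, `[[`, numeric(1), "kfold_mean"),
    kfold_std = vapply(manifests, `[[`, numeric(1), "kfold_std"))
  out[order(-out$val_accuracy_mean), ]
}

#' Export trial images as PNG files
#'
#' @param x A `pipeline_run` (re-deriving images is not attempted; pass
#'   images) or a list of `trial_image` objects.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
export_images <- function(x, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    mp_abort("the 'png' package is required for PNG export", "parameter")
  }
  imgs <- if (inherits(x, "trial_image")) list(x) else x
  mp_assert(is.list(imgs) && all(vapply(imgs, inherits, logical(1), "trial_image")),
            "x must be trial_image objects", "parameter")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(imgs), function(i) {
    im <- imgs[[i]]
    p <- file.path(dir, sprintf("trial%s_win%02d_class%s.png", im$trial_id,
                                im$window_index, im$label))
    png::writePNG(im$pixels, p)
    p
  }, character(1))
  invisible(paths)
}
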