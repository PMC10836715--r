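# End-to-end orchestration: synthetic (or loaded) recording -> staging ->
# irreversibility -> network-state dynamics -> latent-space analysis, with
# per-stage outputs, a reproducibility manifest and a summary table.

#' Pipeline run configuration
#'
#' Collects every tunable of the full analysis in one validated list.
#' All defaults match the package-wide defaults of the individual modules;
#' any field can be overridden. The configuration round-trips losslessly
#' through JSON serialization.
#'
#' @param input `"synth"` (generate with [gen_stage_recording()]) or a
#'   file path prefix for [load_recording()].
#' @param seed master integer seed; every stochastic step derives its own
#'   stream from it.
#' @param out_dir output directory (created if missing).
#' @param synth list of overrides for [gen_stage_recording()]
#'   (`duration_s`, `fs`, ...).
#' @param staging list: `win_s`, `step_s`, `n_freqs`, `n_pcs`, `k`,
#'   `z_thresh`, `pad_s`.
#' @param irrev list: `fs` (analysis rate), `window_s`, `shift_frames`,
#'   `run_bands`, `band_lo`, `band_hi`.
#' @param statedyn list: `K`, `n_restarts`, `embed_lags`.
#' @param latent list: `run` (enable/disable), `d`, `window_s`,
#'   `n_undersample`, `n_splits`, `num_trees`, `max_epochs`, `patience`,
#'   `min_per_class` (smallest per-stage window count accepted by the
#'   classifier), `max_train_frames` (autoencoder training-frame budget;
#'   encoding always uses the full recording).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = "synth", seed = 1, out_dir = tempfile("narun"),
                       synth = list(), staging = list(), irrev = list(),
                       statedyn = list(), latent = list()) {
  cfg <- list(
    input = input, seed = as.integer(seed), out_dir = out_dir,
    synth = modifyList(list(duration_s = 600, fs = 256), synth),
    staging = modifyList(list(win_s = 60, step_s = 5, n_freqs = 14,
                              n_pcs = 8, k = 3, z_thresh = 10, pad_s = 10),
                         staging),
    irrev = modifyList(list(fs = 100, window_s = 1, shift_frames = 1,
                            run_bands = TRUE, band_lo = 0, band_hi = 50),
                       irrev),
    statedyn = modifyList(list(K = 5, n_restarts = 5, embed_lags = 0),
                          statedyn),
    latent = modifyList(list(run = TRUE, d = 7, window_s = 5,
                             n_undersample = 10, n_splits = 10,
                             num_trees = 300, max_epochs = 150,
                             patience = 30, min_per_class = 5,
                             max_train_frames = 30000), latent)
  )
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  req <- c("input", "seed", "out_dir", "synth", "staging", "irrev",
           "statedyn", "latent")
  missing <- setdiff(req, names(cfg))
  if (length(missing)) {
    stop("run_config is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  if (!is.na(cfg$seed) && !is.integer(cfg$seed)) stop("'seed' must be integer")
  if (!is.character(cfg$input)) stop("'input' must be 'synth' or a path")
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> input:", x$input, " seed:", x$seed, "\n")
  cat("  out_dir:", x$out_dir, "\n")
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (synthetic generation or file
#' load), spectral staging, resampling + windowed irreversibility with
#' system decomposition (and optionally the 1-Hz band sweep), region PCA +
#' leakage correction + hidden-Markov network states with per-stage
#' dynamics metrics, and the autoencoder latent-space classification.
#' Every stage writes its table under `out_dir`; a JSON manifest records
#' seeds, parameters and completion state. A failed stage keeps all
#' earlier outputs and is recorded in the manifest.
#'
#' @param config a [run_config].
#' @return list with the per-stage results (`recording`, `stages`,
#'   `irrev`, `bands`, `statedyn`, `latent`), the `summary` data.frame and
#'   the `manifest`.
#' @export
run_full <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("neuroarrow")),
                   r_version = R.version.string,
                   seed = config$seed,
                   config = unclass(config),
                   completed = character(0), failed = NULL)
  res <- list()
  record <- function(stage) {
    manifest$completed <<- c(manifest$completed, stage)
    write_manifest(manifest, config$out_dir)
  }
  run_stage <- function(stage, expr) {
    out <- try(expr, silent = TRUE)
    if (inherits(out, "try-error")) {
      manifest$failed <<- list(stage = stage,
                               error = attr(out, "condition")$message %||%
                                 as.character(out))
      write_manifest(manifest, config$out_dir)
      stop("pipeline stage '", stage, "' failed: ",
           manifest$failed$error, call. = FALSE)
    }
    record(stage)
    out
  }

  # -- input ---------------------------------------------------------------
  res$input <- run_stage("input", {
    if (config$input == "synth") {
      do.call(gen_stage_recording,
              c(list(seed = child_seed(config$seed, 1L)), config$synth))
    } else {
      list(recording = load_recording(config$input), stages = NULL,
           network_states = NULL)
    }
  })
  rec <- res$input$recording

  # -- staging -------------------------------------------------------------
  res$staging <- run_stage("staging", {
    sg <- config$staging
    feat <- compute_stage_features(rec, win_s = sg$win_s, step_s = sg$step_s,
                                   n_freqs = sg$n_freqs)
    feat <- reject_artifacts(feat, z_thresh = sg$z_thresh, pad_s = sg$pad_s)
    seq <- cluster_stages(feat, n_pcs = sg$n_pcs, k = sg$k,
                          seed = child_seed(config$seed, 2L))
    if (sg$k == 3) seq <- assign_stage_names(seq, feat)
    tab <- stage_table(seq, feat)
    write.csv(tab, file.path(config$out_dir, "stages.csv"),
              row.names = FALSE)
    list(features = feat, sequence = seq, table = tab)
  })
  stage_seq <- res$input$stages %||% res$staging$sequence

  # -- irreversibility -----------------------------------------------------
  res$irrev <- run_stage("irreversibility", {
    iv <- config$irrev
    rec_i <- resample_recording(rec, iv$fs)
    ser <- irreversibility_windows(rec_i, window_s = iv$window_s,
                                   shift_frames = iv$shift_frames)
    grp <- group_by_system(ser, stages = stage_seq)
    write.csv(as.data.frame(ser),
              file.path(config$out_dir, "irreversibility_windows.csv"),
              row.names = FALSE)
    write.csv(grp$per_window,
              file.path(config$out_dir, "irreversibility_systems.csv"),
              row.names = FALSE)
    if (!is.null(grp$per_stage)) {
      write.csv(grp$per_stage,
                file.path(config$out_dir, "irreversibility_per_stage.csv"),
                row.names = FALSE)
    }
    list(recording = rec_i, series = ser, systems = grp)
  })

  res$bands <- if (isTRUE(config$irrev$run_bands)) {
    run_stage("band_sweep", {
      bp <- band_sweep(res$irrev$recording, lo = config$irrev$band_lo,
                       hi = min(config$irrev$band_hi,
                                res$irrev$recording$fs / 2),
                       window_s = config$irrev$window_s,
                       shift_frames = config$irrev$shift_frames)
      write.csv(as.data.frame(bp),
                file.path(config$out_dir, "band_profile.csv"),
                row.names = FALSE)
      bp
    })
  } else NULL

  # -- network-state dynamics ---------------------------------------------
  res$statedyn <- run_stage("statedyn", {
    sdn <- config$statedyn
    rec3 <- region_pca_signals(res$irrev$recording)
    rec3 <- leakage_correct(rec3)
    fit <- fit_network_states(rec3, K = sdn$K,
                              seed = child_seed(config$seed, 3L),
                              n_restarts = sdn$n_restarts,
                              embed_lags = sdn$embed_lags)
    metrics <- per_stage_metrics(fit$states, stage_seq)
    write.csv(metrics, file.path(config$out_dir, "state_metrics.csv"),
              row.names = FALSE)
    list(regions = rec3, fit = fit, metrics = metrics)
  })

  # -- latent space --------------------------------------------------------
  res$latent <- if (isTRUE(config$latent$run)) {
    run_stage("latent", {
      lt <- config$latent
      spec <- autoencoder_spec(lt$d, n_channels = n_channels(rec),
                               max_epochs = lt$max_epochs,
                               patience = lt$patience)
      ae <- train_autoencoder(decimate_for_training(rec,
                                                    lt$max_train_frames),
                              spec = spec,
                              seed = child_seed(config$seed, 4L))
      trace <- encode_recording(rec, ae)
      fw <- entropy_feature_windows(trace, window_s = lt$window_s)
      labels <- window_labels(stage_seq, fw$window_start_s, fw$window_s)
      cls <- balanced_stage_classification(
        fw$features, labels, seed = child_seed(config$seed, 5L),
        n_undersample = lt$n_undersample, n_splits = lt$n_splits,
        num_trees = lt$num_trees, min_per_class = lt$min_per_class)
      feat_df <- data.frame(window_start_s = fw$window_start_s,
                            stage = labels, fw$features,
                            check.names = FALSE)
      write.csv(feat_df, file.path(config$out_dir, "latent_features.csv"),
                row.names = FALSE)
      list(autoencoder = ae, trace = trace, features = fw,
           classification = cls)
    })
  } else NULL

  # -- summary -------------------------------------------------------------
  summary_df <- res$irrev$systems$per_stage %||%
    data.frame(stage = "all",
               within = res$irrev$systems$summary$within,
               between = res$irrev$systems$summary$between)
  summary_df <- merge(summary_df, res$statedyn$metrics, by = "stage",
                      all = TRUE)
  if (!is.null(res$latent)) {
    attr(summary_df, "latent_accuracy") <-
      res$latent$classification$mean_accuracy
  }
  write.csv(summary_df, file.path(config$out_dir, "summary.csv"),
            row.names = FALSE)
  manifest$summary_written <- TRUE
  write_manifest(manifest, config$out_dir)

  c(res, list(summary = summary_df, manifest = manifest))
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}
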