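# Validated run configuration and the end-to-end pipeline driver.

config_defaults <- function() {
  list(
    dataset = list(K = 4L, n_channels = 22L, fs = 250, duration_s = 4.5,
                   n_trials_per_class = 72L),
    simulate = list(subjects = list()),
    preprocess = list(low_hz = 0.5, high_hz = 40, order = 6L,
                      decay = 1e-3, eps = 1e-4),
    cwt = list(fmin = 4, fmax = 40, n_freqs = 64L, pool = 5L,
               beta_adm = 1),
    model = list(conv_channels = c(32L, 64L), kernel = 5L, pool = 2L,
                 dropout = 0.25, se_reduction = 8L, leaky_slope = 0.2,
                 enc_channels = c(32L, 64L, 128L), gen_kernel = 4L),
    train = list(lr_pretrain = 2e-4, epochs_pretrain = 3000L,
                 lr_gen = 3e-3, epochs_gen = 600L, batch_size = 32L,
                 alpha = 0.1, beta_w = 1, gamma = 1, holdout = 0.25,
                 seed = 1L, threshold_pct = 70, variant = "full"),
    eval = list(out_dir = "")
  )
}

merge_validate <- function(user, defaults, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    abort_arg(sprintf("config block `%s` must be a mapping.",
                      paste(path, collapse = "$")))
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort_arg(sprintf("unknown config key%s: %s",
                      if (length(unknown) > 1L) "s" else "",
                      paste(paste(c(path, unknown[1L]), collapse = "$"),
                            collapse = ", ")))
  }
  out <- defaults
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && nm != "subjects" &&
        !is.null(names(defaults[[nm]]))) {
      out[[nm]] <- merge_validate(user[[nm]], defaults[[nm]], c(path, nm))
    } else {
      out[[nm]] <- user[[nm]]
    }
  }
  out
}

#' Load (or build) a validated run configuration
#'
#' Defaults reproduce the published operating point: pretraining learning
#' rate 2e-4 for 3000 epochs, generator learning rate 0.003 for 600
#' epochs, and loss weights alpha = 0.1, beta_w = 1, gamma = 1. Unknown
#' keys are rejected; invariant violations (e.g. a negative loss weight)
#' raise a validation error naming the key.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Optional named list merged over the file contents.
#' @return A `run_config` object (a named list of blocks) with
#'   `config_hash` attribute.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort_arg(sprintf("config file `%s` not found.", path))
    user <- yaml::read_yaml(path) %||% list()
  }
  cfg <- merge_validate(user, config_defaults())
  if (!is.null(overrides)) cfg <- merge_validate(overrides, cfg)
  cfg <- canonicalize_config(cfg)
  check_number(cfg$train$alpha, "train$alpha", lower = 0)
  check_number(cfg$train$beta_w, "train$beta_w", lower = 0)
  check_number(cfg$train$gamma, "train$gamma", lower = 0)
  check_number(cfg$train$holdout, "train$holdout", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(cfg$preprocess$decay, "preprocess$decay", lower = 0,
               upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  if (!cfg$train$variant %in% c("full", "no_content", "no_style",
                                "no_semantic")) {
    abort_arg("train$variant must be full/no_content/no_style/no_semantic.")
  }
  structure(cfg, class = "run_config",
            config_hash = object_checksum(cfg))
}

# Normalize YAML-read scalars/sequences to the reference types so that a
# save -> load round trip is the identity (and hashes agree).
canonicalize_config <- function(cfg) {
  int_fields <- list(
    dataset = c("K", "n_channels", "n_trials_per_class"),
    preprocess = "order",
    cwt = c("n_freqs", "pool"),
    model = c("conv_channels", "kernel", "pool", "se_reduction",
              "enc_channels", "gen_kernel"),
    train = c("epochs_pretrain", "epochs_gen", "batch_size", "seed"))
  num_fields <- list(
    dataset = c("fs", "duration_s"),
    preprocess = c("low_hz", "high_hz", "decay", "eps"),
    cwt = c("fmin", "fmax", "beta_adm"),
    model = c("dropout", "leaky_slope"),
    train = c("lr_pretrain", "lr_gen", "alpha", "beta_w", "gamma",
              "holdout", "threshold_pct"))
  for (blk in names(int_fields)) {
    for (f in int_fields[[blk]]) {
      cfg[[blk]][[f]] <- as.integer(unlist(cfg[[blk]][[f]]))
    }
  }
  for (blk in names(num_fields)) {
    for (f in num_fields[[blk]]) {
      cfg[[blk]][[f]] <- as.numeric(unlist(cfg[[blk]][[f]]))
    }
  }
  cfg$train$variant <- as.character(cfg$train$variant)
  cfg$eval <- list(out_dir = as.character(cfg$eval$out_dir %||% ""))
  cfg
}

#' Save a configuration back to YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

subject_profiles_from_config <- function(cfg) {
  subs <- cfg$simulate$subjects
  if (!length(subs)) abort_arg("config$simulate$subjects is empty.")
  lapply(subs, function(s) {
    subject_profile(subject_id = s$subject_id,
                    erd_depth = s$erd_depth %||% 0.6,
                    snr = s$snr %||% 2,
                    mu_center_hz = s$mu_center_hz %||% 10,
                    beta_center_hz = s$beta_center_hz %||% 22,
                    seed = s$seed %||% derive_seed(cfg$train$seed,
                                                   s$subject_id))
  })
}

#' Run the full pipeline end to end on a simulated population
#'
#' Simulate -> preprocess -> scalograms -> pretrain every subject ->
#' select the source and flag illiterates -> train a generator per
#' illiterate target -> evaluate with the soft-voting ensemble. Two
#' independent sessions are simulated per subject: a training session
#' (pretraining, generator training) and a test session (evaluation only).
#'
#' @param config A `run_config` whose `simulate$subjects` block lists the
#'   subject profiles.
#' @param out_dir Optional directory for artifacts (datasets, checkpoints,
#'   loss tables, manifest JSON).
#' @return The run manifest (a list), invisibly written to
#'   `out_dir/manifest.json` when `out_dir` is given.
#' @export
run_end_to_end <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  profiles <- subject_profiles_from_config(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("stage `%s` failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
  }
  ds <- cfg$dataset
  sessions <- stage("simulate", {
    lapply(c(train = "train", test = "test"), function(sess) {
      sets <- lapply(profiles, function(p) {
        p2 <- p
        p2$seed <- derive_seed(p$seed, sess)
        simulate_subject(p2, ds$n_trials_per_class, ds$n_channels,
                         ds$duration_s, ds$fs, ds$K)
      })
      names(sets) <- vapply(profiles, `[[`, "", "subject_id")
      sets
    })
  })
  pp <- cfg$preprocess
  sessions <- stage("preprocess", {
    lapply(sessions, function(sets) {
      lapply(sets, preprocess_epochs, low_hz = pp$low_hz,
             high_hz = pp$high_hz, order = pp$order, decay = pp$decay,
             eps = pp$eps)
    })
  })
  cw <- cfg$cwt
  freqs <- default_freqs(cw$fmin, cw$fmax, cw$n_freqs)
  mp <- morlet_params(cw$beta_adm)
  scalos <- stage("cwt", {
    lapply(sessions, function(sets) {
      lapply(sets, cwt_transform, freqs_hz = freqs, params = mp,
             time_downsample = cw$pool)
    })
  })
  d <- dim(scalos$train[[1L]]$images)
  md <- cfg$model
  cspec <- classifier_spec(d[2L], d[3L], d[4L], K = ds$K,
                           conv_channels = md$conv_channels,
                           kernel = md$kernel, pool = md$pool,
                           dropout = md$dropout,
                           se_reduction = md$se_reduction,
                           leaky_slope = md$leaky_slope)
  tr <- cfg$train
  pretrains <- stage("pretrain", {
    lapply(names(scalos$train), function(id) {
      pretrain_classifier(scalos$train[[id]], spec = cspec,
                          lr = tr$lr_pretrain, n_epochs = tr$epochs_pretrain,
                          batch_size = tr$batch_size, holdout = tr$holdout,
                          seed = derive_seed(tr$seed, "pretrain", id))
    })
  })
  names(pretrains) <- names(scalos$train)
  source_id <- select_source(pretrains)
  illiterates <- flag_illiterates(pretrains, tr$threshold_pct)
  illiterates <- setdiff(illiterates, source_id)
  weights <- loss_weights(tr$alpha, tr$beta_w, tr$gamma)
  gspec <- generator_spec(d[2L], d[3L], d[4L],
                          enc_channels = md$enc_channels,
                          kernel = md$gen_kernel, dropout = md$dropout,
                          leaky_slope = md$leaky_slope)
  transfers <- list()
  evals <- list()
  for (id in illiterates) {
    bundle <- transfer_bundle(pretrains[[source_id]], pretrains[[id]],
                              weights,
                              seed = derive_seed(tr$seed, "transfer", id))
    tfr <- stage("transfer", run_ablation(
      tr$variant, bundle, scalos$train[[id]], scalos$train[[source_id]],
      lr = tr$lr_gen, n_epochs = tr$epochs_gen,
      batch_size = tr$batch_size, gen_spec = gspec))
    ev <- stage("evaluate", evaluate_subject(
      tfr, pretrains[[source_id]], pretrains[[id]], scalos$test[[id]]))
    transfers[[id]] <- tfr
    evals[[id]] <- ev
  }
  manifest <- list(
    config_hash = attr(cfg, "config_hash"),
    seed = tr$seed,
    variant = tr$variant,
    source_subject = source_id,
    illiterate_subjects = illiterates,
    pretrain_accuracy = lapply(pretrains, function(p)
      list(train = p$train_accuracy, test = p$test_accuracy)),
    transfer = lapply(evals, function(e) list(
      ensemble_accuracy = e$accuracy,
      source_path_accuracy = e$source_path_accuracy,
      target_path_accuracy = e$target_path_accuracy,
      pre_transfer_accuracy = e$pre_transfer_accuracy)),
    artifacts = character()
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c()
    for (id in names(pretrains)) {
      p <- file.path(out_dir, sprintf("classifier_%s.ckpt", id))
      save_checkpoint(pretrains[[id]]$model, p)
      paths <- c(paths, p)
    }
    for (id in names(transfers)) {
      p <- file.path(out_dir, sprintf("generator_%s.ckpt", id))
      save_checkpoint(transfers[[id]]$generator, p)
      lt <- file.path(out_dir, sprintf("loss_%s.csv", id))
      utils::write.csv(transfers[[id]]$loss_table, lt, row.names = FALSE)
      paths <- c(paths, p, lt)
    }
    manifest$artifacts <- paths
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(manifest = manifest, pretrains = pretrains,
                 transfers = transfers, evals = evals),
            class = "ssstn_run")
}
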