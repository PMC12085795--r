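# Config-driven pipeline: simulate -> select-rois -> featurize -> train
# -> evaluate, restartable at any stage from the previous stage's on-disk
# artifacts. One global seed drives every stage through fixed small
# offsets; a config hash is recorded with each run for provenance.

#' Default pipeline configuration
#'
#' Five blocks mirroring the pipeline stages plus a global `seed` and
#' `out_dir`. The `data` defaults are the emulated study profile
#' (220 + 335 subjects, 512 x 512 px); tests and examples override them
#' with smaller sizes.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "skelage_run",
    data = list(n_male = 220L, n_female = 335L, age_sampler = "table",
                image_height = 512L, image_width = 512L,
                sex_lag = 1.25, noise_level = 0.2, format = "png"),
    roi = list(patch_size = 40L, k = 13L, min_separation = 20,
               base = 2, method = "ga",
               population_size = 60L, generations = 80L,
               crossover_rate = 0.8, mutation_rate = 0.1,
               mutation_step = 10L, elitism = 2L),
    features = list(bank = "default"),
    model = list(hidden_units = 32L, activation = "tanh",
                 max_epochs = 1000L, learning_rate = 5e-3,
                 batch_size = 32L, early_stop_patience = 60L,
                 aggregator = "mean",
                 fractions = c(0.70, 0.15, 0.15)),
    eval = list(icc_form = "icc2_1", loa_multiplier = 1.96,
                partition = "validation")
  )
}

# recursively check cfg against defaults; unknown keys are rejected by name
.check_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    skel_stop(sprintf("unknown config key%s: %s",
                      if (length(extra) > 1) "s" else "",
                      paste0(path, extra, collapse = ", ")),
              "skelage_config_error")
  for (nm in names(cfg))
    if (is.list(ref[[nm]]) && nm != "fractions")
      .check_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
}

#' Read and validate a pipeline config
#'
#' YAML file with (any subset of) the blocks of [default_config()];
#' missing keys take their defaults, unknown keys raise an error naming
#' the offending key.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list merged on top (CLI flags).
#' @return Validated full config list.
#' @export
read_config <- function(path = NULL, overrides = NULL) {
  ref <- default_config()
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  .check_keys(cfg, ref)
  merged <- utils::modifyList(ref, cfg)
  if (!is.null(overrides)) {
    .check_keys(overrides, ref)
    merged <- utils::modifyList(merged, overrides)
  }
  merged$seed <- as.integer(merged$seed)
  merged
}

#' Hash of a config (provenance)
#'
#' MD5 of the canonical JSON serialization.
#'
#' @param cfg Config list.
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(tmp))
}

.log_stage <- function(stage, t0, quiet) {
  if (!quiet)
    message(sprintf("[skelage] %-12s done in %.1f s", stage,
                    as.numeric(Sys.time()) - t0))
}

.cohort_spec_of <- function(cfg) {
  d <- cfg$data
  cohort_spec(n_male = d$n_male, n_female = d$n_female,
              age_sampler = d$age_sampler,
              image_height = d$image_height, image_width = d$image_width,
              sex_lag = d$sex_lag, noise_level = d$noise_level,
              seed = cfg$seed)
}

#' Pipeline stages
#'
#' Each stage reads the previous stage's artifacts from `cfg$out_dir` and
#' writes its own, so the pipeline is restartable at any stage:
#' `stage_simulate` writes `manifest.csv` + `images/`; `stage_select_rois`
#' writes `rois.csv`; `stage_featurize` writes `features.csv`;
#' `stage_train` writes `model_M.json` / `model_F.json` +
#' `split.csv`; `stage_evaluate` writes `report/`. Per-stage seeds are
#' derived from the global seed by fixed small offsets.
#'
#' @param cfg Config list from [read_config()].
#' @param quiet Suppress per-stage log messages?
#' @return Each stage returns its main artifact, invisibly.
#' @export
stage_simulate <- function(cfg, quiet = FALSE) {
  t0 <- as.numeric(Sys.time())
  manifest <- generate_cohort(.cohort_spec_of(cfg), cfg$out_dir,
                              format = cfg$data$format)
  meta <- list(tool = "skelage", version = as.character(utils::packageVersion("skelage")),
               seed = cfg$seed, config_hash = config_hash(cfg))
  jsonlite::write_json(meta, file.path(cfg$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .log_stage("simulate", t0, quiet)
  invisible(manifest)
}

#' @rdname stage_simulate
#' @export
stage_select_rois <- function(cfg, quiet = FALSE) {
  t0 <- as.numeric(Sys.time())
  manifest <- read_manifest(file.path(cfg$out_dir, "manifest.csv"))
  r <- cfg$roi
  roisets <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_radiograph(file.path(cfg$out_dir, manifest$image_path[i]))
    if (r$method == "ga") {
      params <- ga_params(r$population_size, r$generations,
                          r$crossover_rate, r$mutation_rate,
                          r$mutation_step, r$elitism,
                          seed = cfg$seed + 1000L + i)
      ga_select_rois(img, r$patch_size, r$k, r$min_separation, params,
                     base = r$base)
    } else {
      brute_force_rois(img, r$patch_size, r$k, r$min_separation,
                       base = r$base)
    }
  })
  names(roisets) <- manifest$subject_id
  write_roisets(roisets, file.path(cfg$out_dir, "rois.csv"))
  .log_stage("select-rois", t0, quiet)
  invisible(roisets)
}

#' @rdname stage_simulate
#' @export
stage_featurize <- function(cfg, quiet = FALSE) {
  t0 <- as.numeric(Sys.time())
  manifest <- read_manifest(file.path(cfg$out_dir, "manifest.csv"))
  roisets <- read_roisets(file.path(cfg$out_dir, "rois.csv"))
  features <- featurize_cohort(manifest, roisets, default_filter_bank())
  write_features(features, file.path(cfg$out_dir, "features.csv"))
  .log_stage("featurize", t0, quiet)
  invisible(features)
}

#' @rdname stage_simulate
#' @export
stage_train <- function(cfg, quiet = FALSE) {
  t0 <- as.numeric(Sys.time())
  manifest <- read_manifest(file.path(cfg$out_dir, "manifest.csv"))
  features <- read_features(file.path(cfg$out_dir, "features.csv"))
  m <- cfg$model
  split <- split_cohort(manifest, m$fractions, seed = cfg$seed + 2000L)
  write.csv(as.data.frame(split), file.path(cfg$out_dir, "split.csv"),
            row.names = FALSE, quote = FALSE)
  models <- list()
  for (sx in c("M", "F")) {
    spec <- mlp_spec(m$hidden_units, m$activation, m$max_epochs,
                     m$learning_rate, m$batch_size, m$early_stop_patience,
                     seed = cfg$seed + 3000L + (sx == "F"))
    models[[sx]] <- train_sex_model(features, split, sx, spec,
                                    aggregator = m$aggregator)
    save_model(models[[sx]], file.path(cfg$out_dir,
                                       sprintf("model_%s.json", sx)))
  }
  .log_stage("train", t0, quiet)
  invisible(models)
}

#' @rdname stage_simulate
#' @export
stage_evaluate <- function(cfg, quiet = FALSE) {
  t0 <- as.numeric(Sys.time())
  manifest <- read_manifest(file.path(cfg$out_dir, "manifest.csv"))
  features <- read_features(file.path(cfg$out_dir, "features.csv"))
  split_df <- read.csv(file.path(cfg$out_dir, "split.csv"),
                       stringsAsFactors = FALSE)
  split_df$partition <- factor(split_df$partition,
                               levels = c("train", "test", "validation"))
  models <- list(M = load_model(file.path(cfg$out_dir, "model_M.json")),
                 F = load_model(file.path(cfg$out_dir, "model_F.json")))
  report <- evaluate_model(models, features, split_df,
                           partition = cfg$eval$partition,
                           icc_form = cfg$eval$icc_form,
                           loa_multiplier = cfg$eval$loa_multiplier)
  write_eval_report(report, file.path(cfg$out_dir, "report"))
  .log_stage("evaluate", t0, quiet)
  invisible(report)
}

#' Run the full pipeline
#'
#' Chains simulate, select-rois, featurize, train, evaluate under one
#' global seed. Deterministic: two runs with the same config and seed
#' produce byte-identical manifests, models and reports.
#'
#' @param cfg Config list from [read_config()] / [default_config()].
#' @param quiet Suppress per-stage log messages?
#' @return The final `eval_report`, invisibly.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stage_simulate(cfg, quiet)
  stage_select_rois(cfg, quiet)
  stage_featurize(cfg, quiet)
  stage_train(cfg, quiet)
  stage_evaluate(cfg, quiet)
}

#' @rdname run_pipeline
#' @param config Path to a YAML config file, or `NULL` for defaults.
#' @param out_dir Output directory overriding the config's.
#' @export
cli_simulate <- function(config = NULL, out_dir = NULL) {
  cfg <- read_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  stage_simulate(cfg)
}

#' @rdname run_pipeline
#' @export
cli_run_all <- function(config = NULL, out_dir = NULL) {
  cfg <- read_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  run_pipeline(cfg)
}

#' Predict bone age for a single image
#'
#' Selects ROIs on the image (same method and geometry as the pipeline
#' config), extracts features, and runs the matching sex model.
#'
#' @param image_path PNG/TIFF image file.
#' @param sex `"M"` or `"F"`.
#' @param model A `sex_model` or path to a saved model file.
#' @param cfg Config list (ROI block is used).
#' @return Estimated bone age in years.
#' @export
predict_image <- function(image_path, sex, model, cfg = default_config()) {
  if (is.character(model)) model <- load_model(model)
  img <- read_radiograph(image_path)
  r <- cfg$roi
  rs <- if (identical(r$method, "brute_force"))
    brute_force_rois(img, r$patch_size, r$k, r$min_separation, base = r$base)
  else
    ga_select_rois(img, r$patch_size, r$k, r$min_separation,
                   ga_params(r$population_size, r$generations,
                             r$crossover_rate, r$mutation_rate,
                             r$mutation_step, r$elitism, seed = cfg$seed),
                   base = r$base)
  bank <- default_filter_bank()
  X <- t(vapply(seq_len(nrow(rs$rois)), function(j)
    extract_features(img, rs$rois[j, ], rs$patch_size, bank),
    numeric(feature_length(bank))))
  predict_bone_age(model, X, sex = sex)
}
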