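#' Pipeline configuration
#'
#' One configuration object drives the whole pipeline: capture input (a
#' directory of TIFF+JSON captures, or the synthetic generator), optics,
#' segmentation, the anomaly-detection filter, classifier training and
#' output paths. Defaults define the desk-scale synthetic study:
#' 8 captures per condition of 30 cells each in a 384x384 field, induced
#' captures containing 75% induced-class and 25% alive cells (the label
#' impurity the filter removes), Gaussian phase noise of 0.05 rad, and a
#' small CNN trained for 15 epochs at learning rate 1e-3.
#'
#' @param seed Global integer seed; every random sub-step derives its
#'   stream from it.
#' @param captures_dir Directory of capture TIFFs (with sidecars) to use
#'   instead of synthetic generation; `NULL` enables the generator.
#' @param out_dir Output directory for artifacts (`NULL` = keep results in
#'   memory only).
#' @param optics [optical_params()].
#' @param segmentation [segmentation_params()].
#' @param sad List: `enabled`, `threshold`, `extractor`, `score_kind`,
#'   `cost`, `n_ref` (named reference-crop counts; the reference protocol
#'   is 200 alive / 100 apoptotic / 100 necroptotic).
#' @param classifier List: `backbone` and `train` (a [train_config()]).
#' @param synthetic List of generator settings (see Details above).
#' @param morphology [morphology_params()].
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(
    seed = 1L,
    captures_dir = NULL,
    out_dir = NULL,
    optics = optical_params(),
    segmentation = segmentation_params(),
    sad = list(enabled = TRUE, threshold = 0.01, extractor = "classical",
               score_kind = "probability", cost = 1,
               n_ref = c(alive = 200L, apoptosis = 100L, necroptosis = 100L)),
    classifier = list(
      backbone = "small_cnn",
      train = train_config(epochs = 15L, learning_rate = 1e-3)
    ),
    synthetic = list(
      n_captures_per_condition = 8L, n_cells_per_capture = 30L,
      induced_fraction = 0.75, image_shape = c(384L, 384L),
      noise_sd_rad = 0.05, min_separation_px = 40
    ),
    morphology = morphology_params()) {
  check_that(is_count(seed), "`seed` must be a whole number.")
  check_that(inherits(optics, "optical_params"),
             "`optics` must be an `optical_params`.")
  check_that(inherits(segmentation, "segmentation_params"),
             "`segmentation` must be a `segmentation_params`.")
  check_that(inherits(classifier$train, "train_config"),
             "`classifier$train` must be a `train_config`.")
  check_that(sad$threshold >= 0, "`sad$threshold` must be non-negative.")
  structure(
    list(seed = as.integer(seed), captures_dir = captures_dir,
         out_dir = out_dir, optics = optics, segmentation = segmentation,
         sad = sad, classifier = classifier, synthetic = synthetic,
         morphology = morphology),
    class = "pipeline_config"
  )
}

# Generate (or read) the captures for one pipeline run. `stream_offset`
# separates training captures from holdout captures in seed space.
pipeline_captures <- function(config, stream_offset = 0L) {
  if (!is.null(config$captures_dir)) {
    paths <- list.files(config$captures_dir, pattern = "\\.tiff?$",
                        full.names = TRUE, ignore.case = TRUE)
    check_that(length(paths) > 0L,
               sprintf("No capture TIFFs found in '%s'.",
                       config$captures_dir))
    return(lapply(sort(paths), read_capture))
  }
  syn <- config$synthetic
  f <- syn$induced_fraction
  mixes <- list(
    alive = c(alive = 1, apoptosis = 0, necroptosis = 0),
    apoptosis = c(alive = 1 - f, apoptosis = f, necroptosis = 0),
    necroptosis = c(alive = 1 - f, apoptosis = 0, necroptosis = f)
  )
  captures <- list()
  stream <- stream_offset
  for (cond in CONDITIONS) {
    for (i in seq_len(syn$n_captures_per_condition)) {
      stream <- stream + 1L
      spec <- scene_spec(
        image_shape = syn$image_shape,
        n_cells = syn$n_cells_per_capture,
        class_mix = mixes[[cond]],
        noise_sd_rad = syn$noise_sd_rad,
        min_separation_px = syn$min_separation_px,
        seed = derive_seed(config$seed, stream),
        condition = cond,
        time_post_induction_min = if (cond == "alive") NULL else 60 * i
      )
      captures <- c(captures, list(generate_capture(
        spec, config$morphology, config$optics
      )$capture))
    }
  }
  captures
}

# Segment every capture and bind the kept crops; returns crops + counts.
pipeline_crop_stage <- function(captures, params) {
  pieces <- lapply(captures, function(cap) {
    det <- detect_cells(cap, params)
    crops <- crop_cells(cap, det, params)
    list(crops = crops, n_detections = nrow(det))
  })
  crops <- dplyr::bind_rows(lapply(pieces, `[[`, "crops"))
  list(crops = crops,
       n_detections = sum(vapply(pieces, `[[`, numeric(1), "n_detections")))
}

#' Run the full training pipeline
#'
#' Executes the stages in order — capture acquisition (synthetic or from
#' disk), segmentation and cropping, anomaly-detection label purification,
#' class balancing, stratified train/validation split, classifier
#' training — and evaluates the trained model on the validation split.
#' Every stage's input/kept/discarded counts are logged; kept + discarded
#' equals input at each stage. Fully deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#'
#' @return An object of class `pipeline_result`: list with `sad` (the
#'   fitted filter or `NULL` when disabled), `classifier`, `report`
#'   (validation [build_report()]), `verdicts`, `dataset` (the balanced,
#'   split crop tibble), `log` (stage-count tibble) and `config`. When
#'   `config$out_dir` is set, artifacts (manifest, verdicts, history,
#'   report, config echo) are serialized there too.
#' @export
run_training_pipeline <- function(config = pipeline_config()) {
  check_that(inherits(config, "pipeline_config"),
             "`config` must be a `pipeline_config`.")
  log <- list()
  note <- function(stage, n_in, n_kept) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      stage = stage, n_in = as.integer(n_in), n_kept = as.integer(n_kept),
      n_discarded = as.integer(n_in - n_kept)
    )
  }

  captures <- pipeline_captures(config, stream_offset = 0L)
  check_that(
    all(CONDITIONS %in% vapply(captures, `[[`, character(1), "condition")),
    "Need at least one capture per condition."
  )

  seg <- pipeline_crop_stage(captures, config$segmentation)
  crops <- seg$crops
  note("segmentation", seg$n_detections, nrow(crops))
  check_that(nrow(crops) > 0L, "Segmentation produced no crops.")

  sad_model <- NULL
  verdicts <- NULL
  if (isTRUE(config$sad$enabled)) {
    ref <- sad_reference_crops(config)
    sad_model <- train_sad(
      ref,
      extractor = feature_extractor(config$sad$extractor,
                                    seed = derive_seed(config$seed, 401L)),
      threshold = config$sad$threshold,
      score_kind = config$sad$score_kind %||% "probability",
      cost = config$sad$cost %||% 1,
      seed = derive_seed(config$seed, 402L)
    )
    verdicts <- apply_sad(sad_model, crops)
    kept <- crops[verdicts$kept, , drop = FALSE]
    note("sad_filter", nrow(crops), nrow(kept))
    crops <- kept
  }
  check_that(
    all(CONDITIONS %in% crops$condition),
    "A class is empty after filtering; cannot build a balanced dataset."
  )

  balanced <- balance_classes(crops, seed = derive_seed(config$seed, 403L))
  note("balance", nrow(crops), nrow(balanced))

  dataset <- split_train_val(
    balanced,
    val_fraction = config$classifier$train$val_fraction,
    seed = derive_seed(config$seed, 404L)
  )
  train_set <- dataset[dataset$split == "train", , drop = FALSE]
  val_set <- dataset[dataset$split == "val", , drop = FALSE]
  note("split_train", nrow(dataset), nrow(train_set))

  model <- build_model(config$classifier$backbone,
                       seed = derive_seed(config$seed, 405L))
  model <- train_classifier(model, train_set, val_set,
                            config = config$classifier$train)
  report <- build_report(predict(model, val_set), val_set$condition)

  result <- structure(
    list(sad = sad_model, classifier = model, report = report,
         verdicts = verdicts, dataset = dataset,
         log = dplyr::bind_rows(log), config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result)
  result
}

# Reference crops emulating the hand-picked supervised set: n_ref["alive"]
# alive plus n_ref["apoptosis"]/n_ref["necroptosis"] dead morphologies.
sad_reference_crops <- function(config) {
  n_ref <- config$sad$n_ref
  n_max <- max(n_ref)
  pool <- generate_labeled_dataset(
    n_max, morph = config$morphology, optics = config$optics,
    seed = derive_seed(config$seed, 400L),
    noise_sd_rad = config$synthetic$noise_sd_rad %||% 0.05,
    id_prefix = "sadref"
  )
  dplyr::bind_rows(lapply(CONDITIONS, function(cls) {
    rows <- pool[pool$condition == cls, , drop = FALSE]
    rows[seq_len(n_ref[[cls]]), , drop = FALSE]
  }))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$log)
  print(x$report)
  invisible(x)
}

#' Evaluate the trained model on held-out captures
#'
#' Holdout captures come from experiments never seen in training; this is
#' enforced by capture-id disjointness and errors on any overlap. The
#' stages mirror deployment: segment and crop, purify with the
#' anomaly-detection filter (when supplied), predict, and compare the
#' predictions with the capture conditions — which are never visible to
#' the prediction path.
#'
#' @param x A `pipeline_result`, or a trained [build_model()] classifier
#'   (then pass `sad` explicitly if filtering is wanted).
#' @param config A [pipeline_config()]; defaults to the result's config.
#' @param holdout Optional list of [phase_capture()]s. By default,
#'   synthetic holdout captures are generated from a seed stream disjoint
#'   from the training captures'.
#' @param sad Optional [train_sad()] filter.
#'
#' @return List with `report` (an [build_report()] `eval_report`),
#'   `verdicts` and `log`.
#' @export
run_holdout_evaluation <- function(x, config = NULL, holdout = NULL,
                                   sad = NULL) {
  if (inherits(x, "pipeline_result")) {
    classifier <- x$classifier
    sad <- sad %||% x$sad
    config <- config %||% x$config
  } else {
    classifier <- x
    check_that(!is.null(config), "Provide `config` when passing a bare classifier.")
  }
  check_that(inherits(classifier, "cell_classifier") && classifier$trained,
             "`x` must contain a trained classifier.")
  if (is.null(holdout)) {
    holdout <- pipeline_captures(config, stream_offset = 500L)
  }
  check_that(length(holdout) > 0L, "Empty holdout capture set.")
  holdout_ids <- vapply(holdout, `[[`, character(1), "capture_id")
  overlap <- intersect(holdout_ids, classifier$train_capture_ids)
  check_that(
    length(overlap) == 0L,
    paste0("Holdout captures overlap training captures: ",
           paste(head(overlap, 3), collapse = ", "),
           ". Holdout must consist of unseen experiments."),
    class = "phasedeath_holdout_overlap"
  )

  log <- list()
  seg <- pipeline_crop_stage(holdout, config$segmentation)
  crops <- seg$crops
  log[[1]] <- tibble::tibble(
    stage = "segmentation", n_in = seg$n_detections, n_kept = nrow(crops),
    n_discarded = seg$n_detections - nrow(crops)
  )
  check_that(nrow(crops) > 0L, "Holdout segmentation produced no crops.")
  verdicts <- NULL
  if (!is.null(sad)) {
    verdicts <- apply_sad(sad, crops)
    kept <- crops[verdicts$kept, , drop = FALSE]
    log[[2]] <- tibble::tibble(
      stage = "sad_filter", n_in = nrow(crops), n_kept = nrow(kept),
      n_discarded = nrow(crops) - nrow(kept)
    )
    crops <- kept
  }
  check_that(nrow(crops) > 0L, "No holdout crops survived filtering.")
  predictions <- predict(classifier, crops)
  report <- build_report(predictions, crops$condition)
  list(report = report, verdicts = verdicts,
       log = dplyr::bind_rows(log), predictions = predictions,
       crops = crops)
}

write_pipeline_artifacts <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$log, file.path(dir, "stage_log.csv"),
                   row.names = FALSE)
  if (!is.null(result$verdicts)) {
    utils::write.csv(result$verdicts, file.path(dir, "sad_verdicts.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(
    result$dataset[, setdiff(names(result$dataset), "pixels")],
    file.path(dir, "dataset_manifest.csv"), row.names = FALSE
  )
  utils::write.csv(result$classifier$history,
                   file.path(dir, "training_history.csv"),
                   row.names = FALSE)
  write_eval_report(result$report, dir)
  if (!is.null(result$sad)) save_sad(result$sad, file.path(dir, "sad"))
  save_classifier(result$classifier, file.path(dir, "classifier"))
  cfg <- result$config
  yaml::write_yaml(
    list(
      seed = cfg$seed,
      optics = unclass(cfg$optics),
      segmentation = unclass(cfg$segmentation),
      sad = cfg$sad[setdiff(names(cfg$sad), "n_ref")],
      sad_n_ref = as.list(cfg$sad$n_ref),
      classifier = list(backbone = cfg$classifier$backbone,
                        train = unclass(cfg$classifier$train)),
      synthetic = cfg$synthetic
    ),
    file.path(dir, "config_echo.yaml")
  )
  invisible(dir)
}
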