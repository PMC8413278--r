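#' Feature extractor for the anomaly-detection filter
#'
#' The alive-vs-dead filter separates crops in an embedding space; the
#' embedding itself is a pluggable contract (any deterministic crop-to-
#' vector map works — a pretrained CNN feature map can be slotted in when
#' weights are available). Two built-in extractors:
#'
#' * `"classical"` (default): 20 deterministic intensity/shape descriptors
#'   of the phase patch — moments of the value distribution, footprint
#'   area and radius of gyration of the above-threshold mask, compactness,
#'   peak statistics, local-maximum (bleb) count and gradient energy.
#'   Captures exactly the morphology axes that distinguish alive from
#'   dying cells (size, height, boundary texture).
#' * `"cnn_random"`: the flattened conv-stack activations of a seeded,
#'   randomly initialised desk-scale CNN (random-projection features).
#'
#' Both are bit-stable for a fixed extractor instance.
#'
#' @param name `"classical"` or `"cnn_random"`.
#' @param seed Seed fixing the `"cnn_random"` weights (ignored by
#'   `"classical"`).
#'
#' @return An object of class `feature_extractor` with fields `name`,
#'   `embed_dim`, `deterministic` and the embedding function.
#' @export
feature_extractor <- function(name = c("classical", "cnn_random"),
                              seed = 1L) {
  name <- match.arg(name)
  if (name == "classical") {
    structure(
      list(name = name, embed_dim = 20L, deterministic = TRUE,
           fn = classical_features, seed = NULL),
      class = "feature_extractor"
    )
  } else {
    model <- build_model("small_cnn", seed = seed)
    flatten_at <- which(vapply(model$net$layers,
                               function(l) l$type == "flatten",
                               logical(1)))
    fn <- function(px) {
      x <- preprocess_batch(list(px), model$input_shape)
      as.numeric(nn_forward(model$net, x, upto = flatten_at))
    }
    structure(
      list(name = name, embed_dim = model$net$layers[[flatten_at]]$out_shape,
           deterministic = TRUE, fn = fn, seed = as.integer(seed)),
      class = "feature_extractor"
    )
  }
}

# 20 deterministic intensity + shape descriptors of a phase patch.
classical_features <- function(px) {
  v <- as.numeric(px)
  lo <- min(v); hi <- max(v); rng <- hi - lo
  qs <- stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  thr <- lo + 0.25 * rng
  mask <- px > thr
  area <- sum(mask)
  if (area > 0) {
    idx <- which(mask, arr.ind = TRUE)
    cen <- colMeans(idx)
    rg <- sqrt(mean((idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2))
    mean_in <- mean(px[mask])
    compact <- area / (pi * max(rg, 0.5)^2)
  } else {
    rg <- 0; mean_in <- 0; compact <- 0
  }
  # local maxima above half range: bleb/peak count
  n <- nrow(px); m <- ncol(px)
  core <- px[2:(n - 1), 2:(m - 1)]
  is_max <- core > px[1:(n - 2), 2:(m - 1)] &
    core > px[3:n, 2:(m - 1)] &
    core > px[2:(n - 1), 1:(m - 2)] &
    core > px[2:(n - 1), 3:m] &
    core > px[1:(n - 2), 1:(m - 2)] &
    core > px[1:(n - 2), 3:m] &
    core > px[3:n, 1:(m - 2)] &
    core > px[3:n, 3:m] &
    core > lo + 0.5 * rng
  grad <- mean(abs(diff(px))) + mean(abs(t(diff(t(px)))))
  c(mean(v), stats::sd(v), lo, hi, rng, qs,
    area, rg, compact, mean_in,
    if (rng > 0) (hi - mean(v)) / rng else 0,
    sum(is_max), grad,
    sum(v > lo + 0.5 * rng), sum(v > lo + 0.75 * rng),
    mean(v > thr))
}

#' Embed crops into feature space
#'
#' @param extractor A [feature_extractor()].
#' @param crops Crop tibble with a `pixels` list-column.
#' @return Numeric matrix, one row per crop (rownames = crop ids).
#' @export
embed_crops <- function(extractor, crops) {
  check_that(inherits(extractor, "feature_extractor"),
             "`extractor` must be a `feature_extractor`.")
  check_that(is.data.frame(crops) && "pixels" %in% names(crops) &&
               nrow(crops) > 0L,
             "`crops` must be a non-empty tibble with a `pixels` column.")
  emb <- t(vapply(crops$pixels, extractor$fn,
                  numeric(extractor$embed_dim)))
  rownames(emb) <- crops$crop_id
  emb
}

#' Train the supervised anomaly-detection filter
#'
#' Cell-death induction is asynchronous: an induced culture still contains
#' morphologically alive cells, so labeling every crop from an induced
#' capture as dead would poison the training set. The filter is a linear
#' SVM over crop embeddings trained on reference crops of known
#' morphology — alive crops versus pooled apoptotic + necroptotic crops
#' ("Death") — and later discards crops whose predicted state contradicts
#' their capture's condition.
#'
#' @param crops Reference crop tibble; `label_col` must hold the three
#'   condition values (apoptosis and necroptosis are pooled into Death).
#'   The reference protocol uses 200 alive + 100 apoptotic + 100
#'   necroptotic hand-picked crops.
#' @param extractor A [feature_extractor()].
#' @param threshold Score cutoff `T`; crops whose score does not exceed it
#'   are discarded even when the predicted class agrees with the
#'   experiment. Default 0.01.
#' @param score_kind `"probability"` (default): score is the probability
#'   gap `p(predicted) - p(other)`, clipped at zero — a small nonnegative
#'   quantity commensurate with the default threshold. `"margin"`: the
#'   absolute SVM decision value.
#' @param cost SVM cost parameter `C`.
#' @param seed Seed for the (Platt-scaled) probability fit.
#' @param label_col Label column name.
#'
#' @return An object of class `sad_model`. A warning is raised when the
#'   two classes are not separable in embedding space (training accuracy
#'   below 0.9).
#' @export
train_sad <- function(crops, extractor = feature_extractor("classical"),
                      threshold = 0.01,
                      score_kind = c("probability", "margin"),
                      cost = 1, seed = 1L, label_col = "condition") {
  score_kind <- match.arg(score_kind)
  check_that(threshold >= 0, "`threshold` must be non-negative.")
  check_that(is.data.frame(crops) && label_col %in% names(crops),
             sprintf("`crops` must contain a '%s' column.", label_col))
  labels <- crops[[label_col]]
  check_condition(labels)
  y <- factor(ifelse(labels == "alive", "Alive", "Death"),
              levels = c("Alive", "Death"))
  check_that(all(table(y) > 0L),
             "Both the Alive and the Death class need at least one crop.")
  emb <- embed_crops(extractor, crops)
  # constant embedding dimensions (e.g. dead rectifier units) cannot be
  # standardised; leave them unscaled
  scale_cols <- apply(emb, 2L, stats::sd) > 0
  fit <- with_seed(seed, e1071::svm(
    x = emb, y = y, kernel = "linear", cost = cost,
    probability = TRUE, scale = scale_cols
  ))
  train_pred <- predict(fit, emb)
  train_acc <- mean(train_pred == y)
  if (train_acc < 0.9) {
    rlang::warn(sprintf(
      "Alive and Death reference crops are poorly separable in embedding space (training accuracy %.2f); the filter may be unreliable.",
      train_acc
    ))
  }
  structure(
    list(extractor = extractor, svm = fit, threshold = threshold,
         score_kind = score_kind, cost = cost, seed = as.integer(seed),
         classes = c("Alive", "Death"),
         n_train = as.integer(table(y)), train_accuracy = train_acc),
    class = "sad_model"
  )
}

#' @export
print.sad_model <- function(x, ...) {
  cat(sprintf(
    "<sad_model> %s embedding (%d-d), linear SVM (C = %g), T = %g (%s score); trained on %d Alive / %d Death, training accuracy %.3f\n",
    x$extractor$name, x$extractor$embed_dim, x$cost, x$threshold,
    x$score_kind, x$n_train[1], x$n_train[2], x$train_accuracy
  ))
  invisible(x)
}

# Predicted class + score for a crop embedding matrix.
sad_score <- function(model, emb) {
  pred <- predict(model$svm, emb, probability = TRUE,
                  decision.values = TRUE)
  predicted <- as.character(pred)
  if (model$score_kind == "probability") {
    pr <- attr(pred, "probabilities")[, model$classes, drop = FALSE]
    score <- pmax(pr[cbind(seq_len(nrow(pr)),
                           match(predicted, model$classes))] -
                    pr[cbind(seq_len(nrow(pr)),
                             3L - match(predicted, model$classes))],
                  0)
  } else {
    score <- abs(as.numeric(attr(pred, "decision.values")))
  }
  list(predicted = predicted, score = unname(score))
}

#' Apply the anomaly-detection filter to crops
#'
#' A crop is kept iff its predicted state coordinates with the capture's
#' experimental condition (Alive with alive experiments; Death with
#' apoptosis or necroptosis experiments) *and* its score strictly exceeds
#' the model threshold. Mismatching crops get reason `"class_mismatch"`
#' (checked first), low-score ones `"below_threshold"`; the three verdict
#' groups partition the input.
#'
#' @param model A [train_sad()] model.
#' @param crops Crop tibble.
#' @param condition Experiment condition; defaults to the crops'
#'   `condition` column (may vary per row).
#'
#' @return Verdict tibble: `crop_id`, `condition`, `predicted`, `score`,
#'   `kept`, `reason`, plus `time_post_induction_min` when present in
#'   `crops`.
#' @export
apply_sad <- function(model, crops, condition = NULL) {
  check_that(inherits(model, "sad_model"), "`model` must be a `sad_model`.")
  if (is.null(condition)) {
    check_that("condition" %in% names(crops),
               "Provide `condition` or a `condition` column in `crops`.")
    condition <- crops$condition
  }
  if (length(condition) == 1L) condition <- rep(condition, nrow(crops))
  check_condition(condition)
  emb <- embed_crops(model$extractor, crops)
  sc <- sad_score(model, emb)
  coordinates <- ifelse(condition == "alive",
                        sc$predicted == "Alive",
                        sc$predicted == "Death")
  reason <- dplyr::case_when(
    !coordinates ~ "class_mismatch",
    sc$score <= model$threshold ~ "below_threshold",
    TRUE ~ "kept"
  )
  out <- tibble::tibble(
    crop_id = crops$crop_id,
    condition = condition,
    predicted = sc$predicted,
    score = sc$score,
    kept = reason == "kept",
    reason = reason
  )
  if ("time_post_induction_min" %in% names(crops)) {
    out$time_post_induction_min <- crops$time_post_induction_min
  }
  out
}

#' Fraction of crops classed as dead over time
#'
#' Groups verdicts by time post induction and reports the fraction the
#' filter predicts as Death per time bin — the label-free analogue of a
#' dye-uptake death curve. Monotone increase is a property of the data,
#' not enforced.
#'
#' @param verdicts Verdict tibble from [apply_sad()] carrying
#'   `time_post_induction_min`.
#'
#' @return Tibble `time_post_induction_min`, `dead_fraction`, `n`, ordered
#'   by time.
#' @export
kept_fraction_over_time <- function(verdicts) {
  check_that(
    is.data.frame(verdicts) &&
      "time_post_induction_min" %in% names(verdicts) &&
      !all(is.na(verdicts$time_post_induction_min)),
    "`verdicts` must carry non-missing `time_post_induction_min` metadata."
  )
  verdicts %>%
    dplyr::filter(!is.na(.data$time_post_induction_min)) %>%
    dplyr::group_by(time_post_induction_min = .data$time_post_induction_min) %>%
    dplyr::summarise(
      dead_fraction = mean(.data$predicted == "Death"),
      n = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$time_post_induction_min)
}

#' @rdname train_sad
#' @param x A `sad_model`.
#' @exportS3Method generics::glance
glance.sad_model <- function(x, ...) {
  tibble::tibble(
    extractor = x$extractor$name,
    embed_dim = x$extractor$embed_dim,
    threshold = x$threshold,
    score_kind = x$score_kind,
    cost = x$cost,
    n_alive = x$n_train[1],
    n_death = x$n_train[2],
    train_accuracy = x$train_accuracy
  )
}

#' Save / load the anomaly-detection filter
#'
#' RDS blob plus JSON descriptor (extractor name, embedding dimension,
#' threshold, score kind).
#'
#' @param model A `sad_model`.
#' @param dir Output directory.
#' @return `dir` (save) / the restored model (load).
#' @export
save_sad <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "sad_model.rds"))
  jsonlite::write_json(
    list(format_version = 1L, extractor = model$extractor$name,
         embed_dim = model$extractor$embed_dim,
         threshold = model$threshold, score_kind = model$score_kind),
    file.path(dir, "sad_model.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname save_sad
#' @export
load_sad <- function(dir) readRDS(file.path(dir, "sad_model.rds"))
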