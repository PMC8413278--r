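#' Balance class counts by random subsampling
#'
#' Subsamples every class without replacement down to the smallest class
#' count, e.g. post-filter counts of 8475 / 19,339 / 10,728 become 8475 in
#' all three groups. Selection is seeded and invariant to input row order
#' (rows are ordered by id before sampling); classes already at the
#' minimum are passed through untouched, which makes the operation
#' idempotent.
#'
#' @param data Tibble with one row per crop and a class label column.
#' @param seed Integer seed for the subsampling.
#' @param label_col Name of the label column (default `"condition"`).
#'
#' @return Tibble with equal class counts, ordered by label then id.
#' @export
balance_classes <- function(data, seed = 1L, label_col = "condition") {
  check_that(is.data.frame(data) && label_col %in% names(data),
             sprintf("`data` must contain a '%s' column.", label_col))
  labels <- data[[label_col]]
  present <- unique(labels)
  counts <- table(labels)
  check_that(nrow(data) > 0L && all(counts > 0L),
             "Every class must have at least one row.")
  m <- min(counts)
  id_col <- if ("crop_id" %in% names(data)) data$crop_id
            else as.character(seq_len(nrow(data)))
  with_seed(seed, {
    kept <- unlist(lapply(sort(present), function(cls) {
      idx <- which(labels == cls)
      idx <- idx[order(id_col[idx])]
      if (length(idx) > m) idx <- idx[sample.int(length(idx), m)]
      sort(idx)
    }))
    data[kept, , drop = FALSE]
  })
}

#' Stratified train/validation split
#'
#' Splits each class independently: `floor(n * val_fraction)` rows per
#' class go to validation, the rest to training — e.g. 8475 per class at
#' 0.20 gives 1695 validation and 6780 training rows per class. The split
#' is seeded and invariant to input row order.
#'
#' @param data Tibble of labeled rows (typically [balance_classes()]
#'   output).
#' @param val_fraction Fraction per class assigned to validation, in
#'   (0, 1).
#' @param seed Integer seed.
#' @param label_col Name of the label column.
#'
#' @return `data` with an added `split` column (`"train"` / `"val"`);
#'   the two subsets are disjoint and exhaustive.
#' @export
split_train_val <- function(data, val_fraction = 0.2, seed = 1L,
                            label_col = "condition") {
  check_that(is.numeric(val_fraction) && length(val_fraction) == 1L &&
               val_fraction > 0 && val_fraction < 1,
             "`val_fraction` must lie strictly between 0 and 1.")
  check_that(is.data.frame(data) && label_col %in% names(data),
             sprintf("`data` must contain a '%s' column.", label_col))
  labels <- data[[label_col]]
  id_col <- if ("crop_id" %in% names(data)) data$crop_id
            else as.character(seq_len(nrow(data)))
  split <- rep(NA_character_, nrow(data))
  with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      idx <- idx[order(id_col[idx])]
      n_val <- floor(length(idx) * val_fraction)
      check_that(
        n_val >= 1L && n_val < length(idx),
        sprintf(
          "Class '%s' (n = %d) is too small for a non-empty split at val_fraction = %g.",
          cls, length(idx), val_fraction
        )
      )
      shuffled <- idx[sample.int(length(idx))]
      split[shuffled[seq_len(n_val)]] <- "val"
      split[shuffled[-seq_len(n_val)]] <- "train"
    }
  })
  data$split <- split
  data
}

#' Preprocess one crop into a network input tensor
#'
#' Min-max normalises the phase patch to \[0, 1\] (a constant patch maps to
#' all zeros), bilinearly resizes to the target spatial size when it
#' differs, and replicates the single channel three times — phase images
#' are monochrome, but the VGG-19 input contract is three-channel.
#'
#' @param pixels Numeric matrix (one crop's phase patch).
#' @param target_shape Integer vector `(rows, cols, 3)`.
#'
#' @return Numeric array of dimension `target_shape`; all three channels
#'   identical.
#' @export
preprocess_crop <- function(pixels, target_shape = c(66L, 66L, 3L)) {
  check_that(is.matrix(pixels) && is.numeric(pixels),
             "`pixels` must be a numeric matrix.")
  lo <- min(pixels); rng <- max(pixels) - lo
  norm <- if (rng > 0) (pixels - lo) / rng else matrix(0, nrow(pixels), ncol(pixels))
  if (!identical(dim(norm), as.integer(target_shape[1:2]))) {
    norm <- EBImage::imageData(EBImage::resize(
      EBImage::Image(norm), w = target_shape[1], h = target_shape[2]
    ))
  }
  array(norm, c(target_shape[1], target_shape[2], 3L))
}

# Stack a list of crop patches into the engine's (H, W, N, C) layout.
preprocess_batch <- function(pixel_list, input_shape) {
  n <- length(pixel_list)
  x <- array(0, c(input_shape[1], input_shape[2], n, 3L))
  for (i in seq_len(n)) {
    norm <- preprocess_crop(pixel_list[[i]], input_shape)[, , 1L]
    x[, , i, 1L] <- norm
    x[, , i, 2L] <- norm
    x[, , i, 3L] <- norm
  }
  x
}

# Layer definitions per backbone. The head — fully connected width 64,
# ReLU, fully connected width 3 (then softmax at prediction) — is the
# transfer-learning surgery and is shared by both backbones; in the VGG-19
# arrangement it replaces the original final classification stack, so it
# attaches after the second 4096-wide fully connected layer.
classifier_defs <- function(backbone) {
  head <- list(
    list(type = "dense", units = 64L, role = "head"),
    list(type = "relu", role = "head"),
    list(type = "dense", units = 3L, role = "head")
  )
  bb <- function(l) c(l, list(role = "backbone"))
  if (backbone == "small_cnn") {
    defs <- list(
      bb(list(type = "conv", filters = 8L)), bb(list(type = "relu")),
      bb(list(type = "pool")),
      bb(list(type = "conv", filters = 16L)), bb(list(type = "relu")),
      bb(list(type = "pool")),
      bb(list(type = "conv", filters = 32L)), bb(list(type = "relu")),
      bb(list(type = "pool")),
      bb(list(type = "flatten"))
    )
  } else if (backbone == "vgg19_full") {
    block <- function(filters, n_conv) {
      out <- list()
      for (i in seq_len(n_conv)) {
        out <- c(out, list(bb(list(type = "conv", filters = filters)),
                           bb(list(type = "relu"))))
      }
      c(out, list(bb(list(type = "pool"))))
    }
    defs <- c(
      block(64L, 2L), block(128L, 2L), block(256L, 4L),
      block(512L, 4L), block(512L, 4L),
      list(
        bb(list(type = "flatten")),
        bb(list(type = "dense", units = 4096L)), bb(list(type = "relu")),
        bb(list(type = "dense", units = 4096L)), bb(list(type = "relu"))
      )
    )
  } else {
    rlang::abort(sprintf("Unknown backbone '%s'.", backbone))
  }
  c(defs, head)
}

#' Build the three-class cell-death classifier
#'
#' Constructs the convolutional classifier with the transfer-learning head
#' (fully connected width 64, ReLU, fully connected width 3, softmax).
#' `"vgg19_full"` reproduces the VGG-19 arrangement — 3x3 same-padded
#' convolution + ReLU blocks of depth 64/128/256/512/512 with 2x2 max
#' pooling halving the spatial size after each block, ending at a 7x7x512
#' feature map for 224x224x3 input, flattened (25,088 values) into two
#' 4096-wide fully connected layers — with the head replacing the original
#' classification stack. Weights are randomly initialised (seeded He
#' normal); no pretrained weights are shipped. `"small_cnn"` is the
#' desk-scale default: three conv(8/16/32)+ReLU+pool blocks on 66x66x3
#' input feeding the same head.
#'
#' @param backbone `"small_cnn"` or `"vgg19_full"`.
#' @param seed Integer seed for weight initialisation.
#' @param input_shape Spatial input shape; defaults to `(66, 66, 3)` for
#'   `small_cnn` and `(224, 224, 3)` for `vgg19_full`.
#'
#' @return An object of class `cell_classifier`.
#' @export
build_model <- function(backbone = c("small_cnn", "vgg19_full"),
                        seed = 1L, input_shape = NULL) {
  backbone <- match.arg(backbone)
  if (is.null(input_shape)) {
    input_shape <- if (backbone == "vgg19_full") c(224L, 224L, 3L)
                   else c(66L, 66L, 3L)
  }
  check_that(length(input_shape) == 3L && input_shape[3] == 3L,
             "`input_shape` must be (rows, cols, 3).")
  net <- with_seed(seed,
                   nn_build(classifier_defs(backbone), as.integer(input_shape)))
  structure(
    list(
      backbone = backbone,
      input_shape = as.integer(input_shape),
      net = net,
      class_order = CONDITIONS,
      trained = FALSE,
      seed = as.integer(seed),
      history = NULL,
      train_capture_ids = character()
    ),
    class = "cell_classifier"
  )
}

#' @export
print.cell_classifier <- function(x, ...) {
  cat(sprintf(
    "<cell_classifier> backbone = %s, input %s, classes (%s), %strained\n",
    x$backbone, paste(x$input_shape, collapse = "x"),
    paste(x$class_order, collapse = ", "),
    if (x$trained) "" else "un"
  ))
  invisible(x)
}

#' Final convolutional feature map of the backbone
#'
#' Runs the convolutional stack (everything before flattening) on one
#' preprocessed input and returns the resulting feature map — for the
#' VGG-19 arrangement on 224x224x3 input this is 7x7x512, flattening to
#' the 25,088-long vector that feeds the fully connected stage.
#'
#' @param model A [build_model()] object.
#' @param input Array `(rows, cols, 3)`, e.g. from [preprocess_crop()].
#'
#' @return Numeric array `(rows, cols, depth)` of conv-stack activations.
#' @export
backbone_feature_map <- function(model, input) {
  check_that(inherits(model, "cell_classifier"),
             "`model` must be a `cell_classifier`.")
  check_that(identical(as.integer(dim(input)), model$input_shape),
             "`input` shape must match the model input shape.")
  flatten_at <- which(vapply(model$net$layers,
                             function(l) l$type == "flatten", logical(1)))
  x <- aperm(array(input, c(dim(input)[1:2], 3L, 1L)), c(1, 2, 4, 3))
  fm <- nn_forward(model$net, x, upto = flatten_at - 1L)
  array(fm, dim(fm)[c(1, 2, 4)])
}

#' Training configuration
#'
#' Hyperparameters of the fine-tuning run. None of these is dictated by
#' the method itself; defaults are conventional for small transfer-learning
#' heads (adaptive-moment optimiser, learning rate 1e-4, 10 epochs, batch
#' 32, no augmentation, 20% validation).
#'
#' @param seed Integer seed covering shuffling and initial state.
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param optimizer_name Only `"adam"` is implemented.
#' @param freeze_backbone If `TRUE`, only head layers are updated.
#' @param val_fraction Validation fraction used when the caller asks this
#'   config to drive [split_train_val()].
#'
#' @return An object of class `train_config`.
#' @export
train_config <- function(seed = 1L, epochs = 10L, batch_size = 32L,
                         learning_rate = 1e-4, optimizer_name = "adam",
                         freeze_backbone = FALSE, val_fraction = 0.2) {
  check_that(val_fraction > 0 && val_fraction < 1,
             "`val_fraction` must lie strictly between 0 and 1.")
  check_that(identical(optimizer_name, "adam"),
             "Only the 'adam' optimizer is implemented.")
  check_that(is_count(epochs) && epochs >= 1, "`epochs` must be >= 1.")
  check_that(is_count(batch_size) && batch_size >= 1,
             "`batch_size` must be >= 1.")
  structure(
    list(seed = as.integer(seed), epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, optimizer_name = optimizer_name,
         freeze_backbone = isTRUE(freeze_backbone),
         val_fraction = val_fraction),
    class = "train_config"
  )
}

#' Train the classifier
#'
#' Minibatch cross-entropy training with Adam. Fully deterministic given
#' the config seed; the returned model carries the weights of the epoch
#' with the best validation accuracy (earliest epoch on ties) and a
#' per-epoch history of train/validation loss and accuracy.
#'
#' @param model An untrained or trained [build_model()] object.
#' @param train_data Crop tibble with label column and `pixels`.
#' @param val_data Crop tibble used for validation-while-training; must be
#'   disjoint from `train_data`.
#' @param config A [train_config()].
#' @param label_col Label column name (values in [class_order()]).
#'
#' @return The trained `cell_classifier`, with `$history` (tibble of
#'   `epoch`, `train_loss`, `train_accuracy`, `val_loss`, `val_accuracy`)
#'   and `$train_capture_ids` recording capture provenance for holdout
#'   isolation.
#' @export
train_classifier <- function(model, train_data, val_data,
                             config = train_config(),
                             label_col = "condition") {
  check_that(inherits(model, "cell_classifier"),
             "`model` must be a `cell_classifier`.")
  check_that(is.data.frame(train_data) && nrow(train_data) > 0L,
             "`train_data` must be a non-empty crop tibble.")
  check_that(is.data.frame(val_data) && nrow(val_data) > 0L,
             "`val_data` must be a non-empty crop tibble.")
  check_that(length(intersect(train_data$crop_id, val_data$crop_id)) == 0L,
             "`train_data` and `val_data` must be disjoint.")
  y_train_lab <- train_data[[label_col]]
  check_condition(y_train_lab)
  check_that(length(unique(y_train_lab)) >= 2L,
             "Training labels are degenerate: at least two classes required.")
  y_train <- match(y_train_lab, model$class_order)
  y_val <- match(val_data[[label_col]], model$class_order)

  x_train <- preprocess_batch(train_data$pixels, model$input_shape)
  x_val <- preprocess_batch(val_data$pixels, model$input_shape)
  n <- length(y_train)

  with_seed(config$seed, {
    net <- model$net
    opt <- adam_init(net)
    best <- list(acc = -Inf, net = net, epoch = 0L)
    history <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, n)]
        xb <- x_train[, , idx, , drop = FALSE]
        fw <- nn_forward(net, xb, train = TRUE)
        lg <- nn_loss_grad(fw$out, y_train[idx])
        ep_loss <- ep_loss + lg$loss * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(lg$probs, ties.method = "first") == y_train[idx])
        grads <- nn_backward(net, fw$caches, lg$dlogits)
        upd <- adam_step(net, grads, opt, config$learning_rate,
                         freeze_backbone = config$freeze_backbone)
        net <- upd$net; opt <- upd$opt
      }
      val_eval <- evaluate_on(net, x_val, y_val)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_loss = ep_loss / n,
        train_accuracy = ep_correct / n,
        val_loss = val_eval$loss,
        val_accuracy = val_eval$accuracy
      )
      if (val_eval$accuracy > best$acc) {
        best <- list(acc = val_eval$accuracy, net = net, epoch = epoch)
      }
    }
    model$net <- best$net
    model$trained <- TRUE
    model$best_epoch <- best$epoch
    model$history <- dplyr::bind_rows(history)
    model$train_capture_ids <-
      unique(c(train_data$capture_id, val_data$capture_id))
    model
  })
}

evaluate_on <- function(net, x, y_idx, chunk = 256L) {
  n <- length(y_idx)
  loss <- 0; correct <- 0L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    logits <- nn_forward(net, x[, , idx, , drop = FALSE])
    lg <- nn_loss_grad(logits, y_idx[idx])
    loss <- loss + lg$loss * length(idx)
    correct <- correct +
      sum(max.col(lg$probs, ties.method = "first") == y_idx[idx])
  }
  list(loss = loss / n, accuracy = correct / n)
}

#' Predict class probabilities for crops
#'
#' Applies the softmax head to each crop and returns the three class
#' probabilities plus the argmax class (ties broken towards the earlier
#' entry of [class_order()]). Prediction never reads label columns.
#'
#' @param object A trained (or freshly built) `cell_classifier`.
#' @param new_data Crop tibble with a `pixels` list-column, or a bare list
#'   of pixel matrices.
#' @param ... Unused.
#'
#' @return Tibble with `crop_id`, `p_alive`, `p_apoptosis`,
#'   `p_necroptosis` (rows sum to 1) and `.pred_class`.
#' @export
predict.cell_classifier <- function(object, new_data, ...) {
  if (is.data.frame(new_data)) {
    check_that("pixels" %in% names(new_data),
               "`new_data` must have a `pixels` list-column.")
    pixel_list <- new_data$pixels
    ids <- new_data$crop_id %||% as.character(seq_along(pixel_list))
  } else {
    pixel_list <- new_data
    ids <- as.character(seq_along(pixel_list))
  }
  check_that(length(pixel_list) > 0L, "No crops to predict on.")
  n <- length(pixel_list)
  probs <- matrix(NA_real_, n, 3L)
  for (start in seq(1L, n, by = 256L)) {
    idx <- start:min(start + 255L, n)
    x <- preprocess_batch(pixel_list[idx], object$input_shape)
    probs[idx, ] <- nn_softmax(nn_forward(object$net, x))
  }
  pred <- object$class_order[max.col(probs, ties.method = "first")]
  tibble::tibble(
    crop_id = ids,
    p_alive = probs[, 1], p_apoptosis = probs[, 2],
    p_necroptosis = probs[, 3],
    .pred_class = factor(pred, levels = object$class_order)
  )
}

#' @rdname train_classifier
#' @param x A `cell_classifier`.
#' @exportS3Method generics::tidy
tidy.cell_classifier <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), train_loss = numeric(),
                          train_accuracy = numeric(), val_loss = numeric(),
                          val_accuracy = numeric()))
  }
  x$history
}

#' @rdname train_classifier
#' @exportS3Method generics::glance
glance.cell_classifier <- function(x, ...) {
  tibble::tibble(
    backbone = x$backbone,
    trained = x$trained,
    n_parameters = sum(vapply(
      x$net$layers,
      function(l) if (is.null(l$w)) 0 else length(l$w) + length(l$b),
      numeric(1)
    )),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_accuracy = if (is.null(x$history)) NA_real_
                        else max(x$history$val_accuracy)
  )
}

#' @rdname train_classifier
#' @param object A trained `cell_classifier` with history.
#' @exportS3Method ggplot2::autoplot
autoplot.cell_classifier <- function(object, ...) {
  h <- tidy(object)
  check_that(nrow(h) > 0L, "Model has no training history to plot.")
  long <- tidyr::pivot_longer(
    h, -"epoch", names_to = c("set", "metric"), names_sep = "_"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$epoch, y = .data$value, colour = .data$set
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training history")
}

#' Save / load a classifier checkpoint
#'
#' Writes the weights as an RDS blob plus a JSON descriptor (backbone,
#' input shape, class order, seed, best epoch) for provenance.
#'
#' @param model A `cell_classifier`.
#' @param dir Checkpoint directory (created if missing).
#' @return `dir` (save) or the restored model (load), invisibly/visibly.
#' @export
save_classifier <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "classifier.rds"))
  jsonlite::write_json(
    list(format_version = 1L, backbone = model$backbone,
         input_shape = model$input_shape, class_order = model$class_order,
         seed = model$seed, trained = model$trained,
         best_epoch = model$best_epoch %||% NA),
    file.path(dir, "classifier.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  readRDS(file.path(dir, "classifier.rds"))
}
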