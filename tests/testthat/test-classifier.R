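fake_crops <- function(counts) {
  dplyr::bind_rows(lapply(names(counts), function(cls) {
    tibble::tibble(
      crop_id = sprintf("%s_%05d", cls, seq_len(counts[[cls]])),
      condition = cls
    )
  }))
}

test_that("balancing trims every class to the smallest and is idempotent", {
  d <- fake_crops(c(alive = 3L, apoptosis = 7L, necroptosis = 5L))
  b <- balance_classes(d, seed = 2)
  expect_equal(unname(table(b$condition)), rep(3L, 3),
               ignore_attr = TRUE)
  expect_true(all(b$crop_id %in% d$crop_id))
  # idempotent: balancing a balanced set is the identity
  expect_identical(balance_classes(b, seed = 9), b)
  # invariant to input row order
  shuffled <- d[withr::with_seed(1, sample(nrow(d))), ]
  expect_identical(
    dplyr::arrange(balance_classes(shuffled, seed = 2), crop_id),
    dplyr::arrange(b, crop_id)
  )
  expect_error(balance_classes(d[0, ], seed = 1), "class|row")
})

test_that("stratified split matches the floor arithmetic and is reproducible", {
  d <- fake_crops(c(alive = 8475L, apoptosis = 8475L, necroptosis = 8475L))
  s <- split_train_val(d, val_fraction = 0.20, seed = 3)
  tab <- table(s$condition, s$split)
  expect_true(all(tab[, "val"] == 1695L))
  expect_true(all(tab[, "train"] == 6780L))
  # disjoint and exhaustive
  expect_identical(sum(tab), nrow(d))
  # same seed twice gives the identical assignment
  expect_identical(split_train_val(d, 0.20, seed = 3)$split, s$split)
  # and the split is invariant to input row order
  shuffled <- d[withr::with_seed(4, sample(nrow(d))), ]
  s2 <- split_train_val(shuffled, 0.20, seed = 3)
  expect_identical(s2$split[order(shuffled$crop_id)],
                   s$split[order(d$crop_id)])
  # a class too small for a non-empty validation set errors
  expect_error(
    split_train_val(fake_crops(c(alive = 3L, apoptosis = 3L,
                                 necroptosis = 3L)),
                    val_fraction = 0.05, seed = 1),
    "too small"
  )
})

test_that("preprocessing normalises, resizes and replicates channels", {
  withr::with_seed(10, {
    px <- matrix(rnorm(66 * 66), 66, 66)
    t1 <- preprocess_crop(px, c(224L, 224L, 3L))
    expect_identical(dim(t1), c(224L, 224L, 3L))
    expect_gte(min(t1), 0); expect_lte(max(t1), 1)
    expect_identical(t1[, , 1], t1[, , 2])
    expect_identical(t1[, , 1], t1[, , 3])
    # native size: normalisation only
    t2 <- preprocess_crop(px, c(66L, 66L, 3L))
    expect_equal(t2[, , 1], (px - min(px)) / diff(range(px)))
    # constant crop maps to all zeros
    expect_identical(preprocess_crop(matrix(5, 66, 66), c(66L, 66L, 3L)),
                     array(0, c(66, 66, 3)))
  })
})

test_that("small_cnn architecture halves spatial size per pool and ends in 3-way softmax", {
  m <- build_model("small_cnn", seed = 1)
  shapes <- lapply(m$net$layers, `[[`, "out_shape")
  pools <- which(vapply(m$net$layers, function(l) l$type == "pool",
                        logical(1)))
  expect_equal(shapes[[pools[1]]][1:2], c(33, 33))
  expect_equal(shapes[[pools[2]]][1:2], c(16, 16))
  expect_equal(shapes[[pools[3]]][1:2], c(8, 8))
  flatten <- which(vapply(m$net$layers, function(l) l$type == "flatten",
                          logical(1)))
  expect_equal(shapes[[flatten]], 8 * 8 * 32)
  # head: FC-64 -> ReLU -> FC-3
  tail_types <- vapply(m$net$layers[(length(m$net$layers) - 2):
                                      length(m$net$layers)],
                       `[[`, character(1), "type")
  expect_identical(tail_types, c("dense", "relu", "dense"))
  expect_equal(m$net$layers[[length(m$net$layers) - 2]]$out_shape, 64)
  expect_equal(m$net$out_dim, 3)

  # softmax output is a probability triplet for any input
  probs <- predict(m, tiny_dataset(n = 5, seed = 3)[1:6, ])
  p <- as.matrix(probs[, c("p_alive", "p_apoptosis", "p_necroptosis")])
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("training is deterministic, rejects degenerate labels, and learns", {
  ds <- split_train_val(tiny_dataset(n = 36, seed = 71), 0.2, seed = 5)
  tr <- ds[ds$split == "train", ]
  va <- ds[ds$split == "val", ]
  cfg <- train_config(seed = 9, epochs = 3, learning_rate = 1e-3)

  m1 <- train_classifier(build_model("small_cnn", seed = 2), tr, va, cfg)
  m2 <- train_classifier(build_model("small_cnn", seed = 2), tr, va, cfg)
  expect_identical(tidy(m1), tidy(m2))
  expect_identical(predict(m1, va), predict(m2, va))

  # learning happened: loss decreased from the first epoch to the last
  h <- tidy(m1)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])

  # degenerate label sets and overlapping splits are rejected
  single <- tr[tr$condition == "alive", ]
  expect_error(train_classifier(build_model("small_cnn"), single, va,
                                cfg),
               "degenerate|two classes")
  expect_error(train_classifier(build_model("small_cnn"), tr, tr, cfg),
               "disjoint")
})

test_that("prediction is order-independent and never reads labels", {
  ds <- split_train_val(tiny_dataset(n = 36, seed = 71), 0.2, seed = 5)
  m <- train_classifier(build_model("small_cnn", seed = 2),
                        ds[ds$split == "train", ], ds[ds$split == "val", ],
                        train_config(seed = 9, epochs = 2,
                                     learning_rate = 1e-3))
  probe <- tiny_dataset(n = 10, seed = 73)
  p_all <- predict(m, probe)
  perm <- withr::with_seed(3, sample(nrow(probe)))
  p_perm <- predict(m, probe[perm, ])
  expect_equal(p_perm, p_all[perm, ], ignore_attr = TRUE)
  # dropping the label column changes nothing
  unlabeled <- probe[, setdiff(names(probe), c("condition", "true_class"))]
  expect_identical(predict(m, unlabeled), p_all)
})
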