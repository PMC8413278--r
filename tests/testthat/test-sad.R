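test_that("reference crops with distinct morphologies train a separating filter", {
  ref <- dplyr::bind_rows(
    tiny_dataset(n = 100, seed = 11) %>% dplyr::filter(condition == "alive"),
    tiny_dataset(n = 100, seed = 11) %>%
      dplyr::filter(condition != "alive") %>% dplyr::slice(1:100)
  )
  # 100 alive + 100 pooled death, planted well-separated
  sad <- train_sad(ref, seed = 3)
  expect_s3_class(sad, "sad_model")
  expect_gte(glance(sad)$train_accuracy, 0.95)

  # determinism: same seed gives identical verdicts on a probe set
  probe <- tiny_dataset(n = 20, seed = 55)
  sad2 <- train_sad(ref, seed = 3)
  expect_equal(apply_sad(sad, probe), apply_sad(sad2, probe))
})

test_that("indistinguishable reference classes are flagged as non-separable", {
  alive <- tiny_dataset(n = 20, seed = 9) %>%
    dplyr::filter(condition == "alive")
  fake_death <- alive %>%
    dplyr::mutate(condition = "apoptosis",
                  crop_id = paste0(crop_id, "_dup"))
  expect_warning(train_sad(dplyr::bind_rows(alive, fake_death), seed = 1),
                 "separable")
  # an empty class is a hard error
  expect_error(train_sad(alive, seed = 1), "class")
})

test_that("verdicts implement the coordinate-and-threshold keep rule", {
  ref <- tiny_dataset(n = 80, seed = 21)
  sad <- train_sad(ref, seed = 4)
  probe <- tiny_dataset(n = 25, seed = 77)
  alive_probe <- probe %>% dplyr::filter(condition == "alive")
  dead_probe <- probe %>% dplyr::filter(condition != "alive")

  # alive-looking crops in a death experiment: discarded as mismatches
  v_mm <- apply_sad(sad, alive_probe, condition = "apoptosis")
  expect_true(all(v_mm$reason[v_mm$predicted == "Alive"] ==
                    "class_mismatch"))
  expect_false(any(v_mm$kept[v_mm$predicted == "Alive"]))
  # symmetric rule: death-looking crops discarded from alive experiments
  v_sym <- apply_sad(sad, dead_probe, condition = "alive")
  expect_true(all(v_sym$reason[v_sym$predicted == "Death"] ==
                    "class_mismatch"))

  # a coordinating prediction whose score does not exceed T is discarded
  sad_high <- sad
  sad_high$threshold <- 0.999999
  v_thr <- apply_sad(sad_high, dead_probe, condition = "necroptosis")
  coord <- v_thr$predicted == "Death"
  expect_true(all(v_thr$reason[coord & v_thr$score <= sad_high$threshold] ==
                    "below_threshold"))

  # threshold 0 with all-coordinating predictions keeps everything
  sad_zero <- sad
  sad_zero$threshold <- 0
  v0 <- apply_sad(sad_zero, alive_probe, condition = "alive")
  expect_true(all(v0$kept[v0$predicted == "Alive"]))
})

test_that("filter is threshold-monotone and partitions its input", {
  ref <- tiny_dataset(n = 80, seed = 21)
  sad <- train_sad(ref, seed = 4)
  probe <- tiny_dataset(n = 40, seed = 88)
  kept_counts <- vapply(c(0, 0.01, 0.1, 0.5, 0.9, 1), function(thr) {
    s <- sad; s$threshold <- thr
    v <- apply_sad(s, probe)
    # the three verdict groups always partition the input
    expect_identical(
      sum(v$reason == "kept") + sum(v$reason == "class_mismatch") +
        sum(v$reason == "below_threshold"),
      nrow(probe)
    )
    expect_identical(v$kept, v$reason == "kept")
    sum(v$kept)
  }, integer(1))
  expect_true(all(diff(kept_counts) <= 0))
})

test_that("false-keep rate of alive crops in death experiments stays below 5%", {
  ref <- tiny_dataset(n = 100, seed = 31)
  sad <- train_sad(ref, seed = 6)
  alive_crops <- tiny_dataset(n = 100, seed = 99) %>%
    dplyr::filter(condition == "alive")
  v_apo <- apply_sad(sad, alive_crops, condition = "apoptosis")
  v_nec <- apply_sad(sad, alive_crops, condition = "necroptosis")
  expect_lte(mean(v_apo$kept), 0.05)
  expect_lte(mean(v_nec$kept), 0.05)
})

test_that("dead fraction over time recovers planted death fractions", {
  ref <- tiny_dataset(n = 80, seed = 41)
  sad <- train_sad(ref, seed = 2)
  planted <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  times <- c(30, 60, 120, 240, 480)
  pool <- tiny_dataset(n = 120, seed = 43)
  crops <- dplyr::bind_rows(lapply(seq_along(planted), function(i) {
    n_dead <- round(40 * planted[i])
    mix <- dplyr::bind_rows(
      pool %>% dplyr::filter(condition == "apoptosis") %>%
        dplyr::slice((i - 1) * 24 + seq_len(n_dead)),
      pool %>% dplyr::filter(condition == "alive") %>%
        dplyr::slice((i - 1) * 24 + seq_len(40 - n_dead))
    )
    dplyr::mutate(mix, time_post_induction_min = times[i],
                  crop_id = paste0(crop_id, "_t", i))
  }))
  v <- apply_sad(sad, crops, condition = "apoptosis")
  tab <- kept_fraction_over_time(v)
  expect_identical(tab$time_post_induction_min, times)
  expect_identical(sum(tab$n), nrow(crops))
  expect_true(all(abs(tab$dead_fraction - planted) <= 0.1))

  # all-alive time course: dead fraction near zero in every bin
  alive_tc <- pool %>% dplyr::filter(condition == "alive") %>%
    dplyr::mutate(time_post_induction_min = rep(times, length.out = 120))
  tab0 <- kept_fraction_over_time(apply_sad(sad, alive_tc,
                                            condition = "alive"))
  expect_true(all(tab0$dead_fraction <= 0.05))

  # single time bin gives a single row; missing time errors
  one <- dplyr::mutate(pool[1:10, ], time_post_induction_min = 60)
  expect_identical(
    nrow(kept_fraction_over_time(apply_sad(sad, one, "alive"))), 1L
  )
  no_time <- dplyr::mutate(pool[1:5, ],
                           time_post_induction_min = NA_real_)
  expect_error(
    kept_fraction_over_time(apply_sad(sad, no_time, "alive")),
    "time"
  )
})

test_that("embeddings are bit-stable and extractors are pluggable", {
  crops <- tiny_dataset(n = 10, seed = 61)[1:6, ]
  fx <- feature_extractor("classical")
  expect_identical(embed_crops(fx, crops), embed_crops(fx, crops))
  fx_cnn <- feature_extractor("cnn_random", seed = 8)
  e1 <- embed_crops(fx_cnn, crops)
  expect_identical(e1, embed_crops(fx_cnn, crops))
  expect_identical(ncol(e1), as.integer(fx_cnn$embed_dim))
  # a filter trained on CNN features also separates the planted classes
  sad_cnn <- train_sad(tiny_dataset(n = 40, seed = 62),
                       extractor = feature_extractor("cnn_random", seed = 8),
                       seed = 9)
  expect_gte(glance(sad_cnn)$train_accuracy, 0.9)
})
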