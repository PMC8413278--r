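# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Connected-component labelling by explicit flood fill.
oracle_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  next_lab <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    next_lab <- next_lab + 1L
    queue <- start
    lab[start] <- next_lab
    while (length(queue) > 0L) {
      p <- queue[1]; queue <- queue[-1]
      pr <- ((p - 1L) %% nr) + 1L
      pc <- ((p - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(nb))) {
        r <- pr + nb[k, 1]; c <- pc + nb[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc) {
          q <- (c - 1L) * nr + r
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- next_lab
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Re-measure a thresholded capture from scratch and count the crops the
# area/border filters should keep.
oracle_crop_count <- function(phase, threshold, crop_size = 66L,
                              area_min = 80, area_max = 600,
                              connectivity = 8L) {
  mask <- phase > threshold
  lab <- oracle_label(mask, connectivity)
  if (max(lab) == 0L) return(0L)
  half_lo <- crop_size %/% 2L
  half_hi <- crop_size - half_lo - 1L
  kept <- 0L
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)
    area <- nrow(idx)
    r <- round(mean(idx[, 1])); c <- round(mean(idx[, 2]))
    if (area > area_min && area < area_max &&
        r - half_lo >= 1 && c - half_lo >= 1 &&
        r + half_hi <= nrow(phase) && c + half_hi <= ncol(phase)) {
      kept <- kept + 1L
    }
  }
  kept
}

# AUC by exhaustive positive/negative pair comparison, ties worth 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Small labeled crop sets shared across tests (seeded, cached per session).
tiny_dataset <- local({
  cache <- new.env()
  function(n = 30L, seed = 101L) {
    key <- paste0("d", n, "_", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_labeled_dataset(n, seed = seed)
    }
    cache[[key]]
  }
})

# A fast pipeline configuration for orchestration tests.
tiny_pipeline_config <- function(seed = 5L, ...) {
  pipeline_config(
    seed = seed,
    sad = list(enabled = TRUE, threshold = 0.01, extractor = "classical",
               score_kind = "probability", cost = 1,
               n_ref = c(alive = 60L, apoptosis = 30L, necroptosis = 30L)),
    classifier = list(backbone = "small_cnn",
                      train = train_config(epochs = 2L,
                                           learning_rate = 1e-3)),
    synthetic = list(n_captures_per_condition = 2L,
                     n_cells_per_capture = 12L,
                     induced_fraction = 0.75,
                     image_shape = c(256L, 256L),
                     noise_sd_rad = 0.05, min_separation_px = 40),
    ...
  )
}
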