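# Minimal CNN engine used by the classifier and the CNN feature extractor.
#
# Activations are 4-D arrays in (height, width, batch, channel) layout,
# which lets same-padded 3x3 convolution reduce to one BLAS matrix product
# per layer via im2col with no permutation on the output. All randomness
# (weight init, batch shuffling) flows through the caller's seeded RNG.

# --- im2col / col2im ------------------------------------------------------

# x: (H, W, N, C) -> matrix (k*k*C) x (H*W*N), stride 1, zero padding `pad`.
# Row order (i fastest, then j, then c) matches the column-major reshape of
# a (k, k, C, F) weight array into (k*k*C, F).
nn_im2col <- function(x, k, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  xp <- array(0, c(H + 2L * pad, W + 2L * pad, N, C))
  xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  cols <- matrix(0, k * k * C, H * W * N)
  idx <- 0L
  for (c in seq_len(C)) {
    for (j in seq_len(k)) {
      for (i in seq_len(k)) {
        idx <- idx + 1L
        cols[idx, ] <- xp[i:(i + H - 1L), j:(j + W - 1L), , c]
      }
    }
  }
  cols
}

nn_col2im <- function(dcols, in_dim, k, pad) {
  H <- in_dim[1]; W <- in_dim[2]; N <- in_dim[3]; C <- in_dim[4]
  dxp <- array(0, c(H + 2L * pad, W + 2L * pad, N, C))
  idx <- 0L
  for (c in seq_len(C)) {
    for (j in seq_len(k)) {
      for (i in seq_len(k)) {
        idx <- idx + 1L
        slice <- dxp[i:(i + H - 1L), j:(j + W - 1L), , c, drop = FALSE]
        dxp[i:(i + H - 1L), j:(j + W - 1L), , c] <-
          slice + array(dcols[idx, ], dim(slice))
      }
    }
  }
  dxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
}

# --- network construction -------------------------------------------------

# defs: list of layer definitions, each a list with $type in
# conv/relu/pool/flatten/dense and, where relevant, $filters or $units,
# plus $role ("backbone" or "head") controlling freeze_backbone.
nn_build <- function(defs, input_shape) {
  shape <- input_shape # c(H, W, C) until flatten, then scalar D
  layers <- vector("list", length(defs))
  for (li in seq_along(defs)) {
    def <- defs[[li]]
    layer <- def
    if (def$type == "conv") {
      k <- def$k %||% 3L
      fan_in <- k * k * shape[3]
      layer$k <- k
      layer$pad <- (k - 1L) %/% 2L
      layer$w <- array(stats::rnorm(fan_in * def$filters, 0,
                                    sqrt(2 / fan_in)),
                       c(k, k, shape[3], def$filters))
      layer$b <- numeric(def$filters)
      shape[3] <- def$filters
    } else if (def$type == "pool") {
      shape[1] <- shape[1] %/% 2L
      shape[2] <- shape[2] %/% 2L
    } else if (def$type == "flatten") {
      shape <- prod(shape)
    } else if (def$type == "dense") {
      fan_in <- shape[1]
      layer$w <- matrix(stats::rnorm(fan_in * def$units, 0,
                                     sqrt(2 / fan_in)),
                        fan_in, def$units)
      layer$b <- numeric(def$units)
      shape <- def$units
    } else if (def$type != "relu") {
      rlang::abort(sprintf("Unknown layer type '%s'.", def$type))
    }
    layer$out_shape <- shape
    layers[[li]] <- layer
  }
  list(layers = layers, input_shape = input_shape, out_dim = shape)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- forward / backward ---------------------------------------------------

# x: (H, W, N, C). Returns logits (N x classes); with train = TRUE also the
# caches needed for the backward pass. `upto` stops after that many layers
# (used to read intermediate feature maps).
nn_forward <- function(net, x, train = FALSE, upto = NULL) {
  n_layers <- if (is.null(upto)) length(net$layers) else upto
  caches <- if (train) vector("list", n_layers) else NULL
  for (li in seq_len(n_layers)) {
    layer <- net$layers[[li]]
    if (layer$type == "conv") {
      d <- dim(x)
      cols <- nn_im2col(x, layer$k, layer$pad)
      wmat <- layer$w; dim(wmat) <- c(layer$k^2 * d[4], dim(layer$w)[4])
      out <- crossprod(wmat, cols) + layer$b
      x_new <- array(t(out), c(d[1], d[2], d[3], dim(layer$w)[4]))
      if (train) caches[[li]] <- list(cols = cols, in_dim = d)
      x <- x_new
    } else if (layer$type == "relu") {
      if (train) caches[[li]] <- list(mask = x > 0)
      x <- x * (x > 0)
    } else if (layer$type == "pool") {
      d <- dim(x)
      H2 <- 2L * (d[1] %/% 2L); W2 <- 2L * (d[2] %/% 2L)
      ro <- seq(1L, H2, 2L); re <- seq(2L, H2, 2L)
      co <- seq(1L, W2, 2L); ce <- seq(2L, W2, 2L)
      a <- x[ro, co, , , drop = FALSE]; b <- x[re, co, , , drop = FALSE]
      cc <- x[ro, ce, , , drop = FALSE]; dd <- x[re, ce, , , drop = FALSE]
      m <- pmax(a, b, cc, dd)
      if (train) {
        m1 <- a == m; m2 <- (b == m) & !m1
        m3 <- (cc == m) & !(m1 | m2); m4 <- (dd == m) & !(m1 | m2 | m3)
        caches[[li]] <- list(in_dim = d, masks = list(m1, m2, m3, m4))
      }
      x <- m
    } else if (layer$type == "flatten") {
      d <- dim(x)
      if (train) caches[[li]] <- list(in_dim = d)
      x <- aperm(x, c(1L, 2L, 4L, 3L))
      dim(x) <- c(d[1] * d[2] * d[4], d[3])
      x <- t(x)
    } else if (layer$type == "dense") {
      if (train) caches[[li]] <- list(x = x)
      x <- sweep(x %*% layer$w, 2L, layer$b, "+")
    }
  }
  if (train) list(out = x, caches = caches) else x
}

nn_softmax <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

# Cross-entropy loss and gradient wrt logits; y_idx is 1-based class index.
nn_loss_grad <- function(logits, y_idx) {
  n <- nrow(logits)
  probs <- nn_softmax(logits)
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), y_idx)], 1e-12)))
  dlogits <- probs
  dlogits[cbind(seq_len(n), y_idx)] <-
    dlogits[cbind(seq_len(n), y_idx)] - 1
  list(loss = loss, dlogits = dlogits / n, probs = probs)
}

# Backward pass; returns per-layer gradients (NULL for parameter-free
# layers).
nn_backward <- function(net, caches, dout) {
  n_layers <- length(net$layers)
  grads <- vector("list", n_layers)
  for (li in rev(seq_len(n_layers))) {
    layer <- net$layers[[li]]
    cache <- caches[[li]]
    if (layer$type == "dense") {
      grads[[li]] <- list(dw = crossprod(cache$x, dout),
                          db = colSums(dout))
      dout <- tcrossprod(dout, layer$w)
    } else if (layer$type == "flatten") {
      d <- cache$in_dim
      dout <- t(dout)
      dim(dout) <- c(d[1], d[2], d[4], d[3])
      dout <- aperm(dout, c(1L, 2L, 4L, 3L))
    } else if (layer$type == "pool") {
      d <- cache$in_dim
      H2 <- 2L * (d[1] %/% 2L); W2 <- 2L * (d[2] %/% 2L)
      ro <- seq(1L, H2, 2L); re <- seq(2L, H2, 2L)
      co <- seq(1L, W2, 2L); ce <- seq(2L, W2, 2L)
      dx <- array(0, d)
      ms <- cache$masks
      dx[ro, co, , ] <- dout * ms[[1]]
      dx[re, co, , ] <- dout * ms[[2]]
      dx[ro, ce, , ] <- dout * ms[[3]]
      dx[re, ce, , ] <- dout * ms[[4]]
      dout <- dx
    } else if (layer$type == "relu") {
      dout <- dout * cache$mask
    } else if (layer$type == "conv") {
      d <- cache$in_dim
      f <- dim(layer$w)[4]
      dout_mat <- matrix(dout, d[1] * d[2] * d[3], f)
      dw <- cache$cols %*% dout_mat
      dim(dw) <- dim(layer$w)
      db <- colSums(dout_mat)
      grads[[li]] <- list(dw = dw, db = db)
      wmat <- layer$w; dim(wmat) <- c(layer$k^2 * d[4], f)
      dout <- nn_col2im(wmat %*% t(dout_mat), d, layer$k, layer$pad)
    }
  }
  grads
}

# --- Adam optimiser -------------------------------------------------------

adam_init <- function(net) {
  list(t = 0L, m = purrr::map(net$layers, function(l) {
    if (!is.null(l$w)) list(mw = l$w * 0, vw = l$w * 0,
                            mb = l$b * 0, vb = l$b * 0)
  }))
}

adam_step <- function(net, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      freeze_backbone = FALSE) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    if (freeze_backbone &&
        identical(net$layers[[li]]$role %||% "backbone", "backbone")) next
    s <- opt$m[[li]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$dw
    s$vw <- beta2 * s$vw + (1 - beta2) * g$dw^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    net$layers[[li]]$w <- net$layers[[li]]$w -
      lr * (s$mw / bc1) / (sqrt(s$vw / bc2) + eps)
    net$layers[[li]]$b <- net$layers[[li]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    opt$m[[li]] <- s
  }
  list(net = net, opt = opt)
}
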