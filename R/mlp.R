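# Compact feed-forward binary classifier: fully connected ReLU layers with a
# logistic output, trained by minibatch Adam with early stopping on a held-out
# validation slice of the training data. Plain matrix arithmetic throughout.

mlp_init <- function(p, hidden) {
  sizes <- c(p, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(
      W = matrix(rnorm(sizes[i] * sizes[i + 1], sd = sqrt(2 / sizes[i])),
                 sizes[i], sizes[i + 1]),
      b = rep(0, sizes[i + 1])
    )
  })
}

mlp_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1]] <- x
  for (i in seq_along(layers)) {
    z <- sweep(acts[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    acts[[i + 1]] <- if (i < length(layers)) pmax(z, 0) else z
  }
  acts
}

mlp_logits <- function(layers, x) drop(mlp_forward(layers, x)[[length(layers) + 1L]])

mlp_fit <- function(x, y, hidden = c(1024, 512, 256), epochs = 30L,
                    batch_size = 256L, lr = 1e-3, l2 = 1e-4,
                    val_frac = 0.1, patience = 5L, seed = 1L) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  withr::with_seed(seed, {
    n <- nrow(x)
    n_val <- max(1L, floor(val_frac * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    xt <- x[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
    xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx]

    layers <- mlp_init(ncol(x), hidden)
    m <- v <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
    best <- list(loss = Inf, layers = layers, stale = 0L)

    logloss <- function(lg, yy) {
      p <- clamp(plogis(lg), 1e-12, 1 - 1e-12)
      -mean(yy * log(p) + (1 - yy) * log(1 - p))
    }

    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(tr_idx))
      for (start in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, length(ord))]
        acts <- mlp_forward(layers, xt[idx, , drop = FALSE])
        nl <- length(layers)
        delta <- (plogis(acts[[nl + 1L]]) - yt[idx]) / length(idx)
        step <- step + 1L
        for (i in rev(seq_len(nl))) {
          gW <- crossprod(acts[[i]], delta) + l2 * layers[[i]]$W
          gb <- colSums(delta)
          if (i > 1L) {
            delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
          }
          m[[i]]$W <- b1 * m[[i]]$W + (1 - b1) * gW
          m[[i]]$b <- b1 * m[[i]]$b + (1 - b1) * gb
          v[[i]]$W <- b2 * v[[i]]$W + (1 - b2) * gW^2
          v[[i]]$b <- b2 * v[[i]]$b + (1 - b2) * gb^2
          corr <- lr * sqrt(1 - b2^step) / (1 - b1^step)
          layers[[i]]$W <- layers[[i]]$W - corr * m[[i]]$W / (sqrt(v[[i]]$W) + eps)
          layers[[i]]$b <- layers[[i]]$b - corr * m[[i]]$b / (sqrt(v[[i]]$b) + eps)
        }
      }
      vl <- logloss(mlp_logits(layers, xv), yv)
      if (vl < best$loss - 1e-5) {
        best <- list(loss = vl, layers = layers, stale = 0L)
      } else {
        best$stale <- best$stale + 1L
        if (best$stale >= patience) break
      }
    }
    structure(list(layers = best$layers, hidden = hidden,
                   val_loss = best$loss), class = "riskpipe_mlp")
  })
}
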