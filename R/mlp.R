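# Minimal feed-forward network for propensity scoring: ReLU hidden layers,
# sigmoid output, minibatch Adam on binary cross-entropy with decoupled L2
# weight decay. Written in plain matrix algebra; the grids used here (one or
# two small hidden layers, 15 epochs, batch 128) keep it fast at cohort scale.

mlp_init <- function(n_in, hidden, seed) {
  set.seed(substream_seed(seed, "mlp_init"))
  dims <- c(n_in, hidden, 1L)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    layers[[l]] <- list(
      w = matrix(rnorm(fan_in * dims[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, dims[l + 1]),
      b = rep(0, dims[l + 1])
    )
  }
  layers
}

mlp_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1]] <- x
  for (l in seq_along(layers)) {
    a <- sweep(acts[[l]] %*% layers[[l]]$w, 2, layers[[l]]$b, "+")
    if (l < length(layers)) a <- pmax(a, 0)
    acts[[l + 1]] <- a
  }
  acts
}

fit_ps_mlp <- function(x, z, setting, seed) {
  n <- nrow(x)
  layers <- mlp_init(ncol(x), setting$hidden, seed)
  adam <- lapply(layers, function(lay) {
    list(mw = lay$w * 0, vw = lay$w * 0, mb = lay$b * 0, vb = lay$b * 0)
  })
  lr <- setting$lr
  decay <- setting$decay
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  set.seed(substream_seed(seed, "mlp_batches"))
  for (epoch in seq_len(setting$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = setting$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + setting$batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      zb <- z[idx]
      acts <- mlp_forward(layers, xb)
      p <- plogis(acts[[length(acts)]][, 1])
      # gradient of mean BCE wrt the output pre-activation
      delta <- matrix((p - zb) / length(idx), ncol = 1)
      step <- step + 1L
      for (l in rev(seq_along(layers))) {
        gw <- crossprod(acts[[l]], delta) + decay * layers[[l]]$w
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(layers[[l]]$w)) * (acts[[l]] > 0)
        }
        st <- adam[[l]]
        st$mw <- b1 * st$mw + (1 - b1) * gw
        st$vw <- b2 * st$vw + (1 - b2) * gw^2
        st$mb <- b1 * st$mb + (1 - b1) * gb
        st$vb <- b2 * st$vb + (1 - b2) * gb^2
        corr1 <- 1 - b1^step
        corr2 <- 1 - b2^step
        layers[[l]]$w <- layers[[l]]$w -
          lr * (st$mw / corr1) / (sqrt(st$vw / corr2) + eps)
        layers[[l]]$b <- layers[[l]]$b -
          lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
        adam[[l]] <- st
      }
    }
  }
  list(kind = "mlp", model = layers)
}

mlp_predict <- function(layers, x) {
  acts <- mlp_forward(layers, as.matrix(x))
  plogis(acts[[length(acts)]][, 1])
}
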