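# Minimal neural-network layer framework.
#
# Batches are 4-D arrays (height, width, channels, n) for convolutional
# stages and (features, n) matrices after global average pooling. Convolution
# is im2col + BLAS matrix product; all layers implement forward and backward
# passes so the whole classifier trains by stochastic gradient descent (Adam).
# Layers are plain lists tagged by `type`; a `residual` layer composes a main
# path and a shortcut path with a rectifier after the add.

layer_conv <- function(in_channels, out_channels, kernel = 3, stride = 1,
                       pad = 1, init = c("he", "zero")) {
  init <- match.arg(init)
  K <- kernel * kernel * in_channels
  W <- if (init == "he") {
    matrix(stats::rnorm(K * out_channels, sd = sqrt(2 / K)), K, out_channels)
  } else matrix(0, K, out_channels)
  list(type = "conv", W = W, b = numeric(out_channels),
       kernel = kernel, stride = stride, pad = pad,
       in_channels = in_channels, out_channels = out_channels)
}

layer_bn <- function(n_features) {
  list(type = "bn", gamma = rep(1, n_features), beta = numeric(n_features),
       running_mean = numeric(n_features), running_var = rep(1, n_features),
       momentum = 0.1, eps = 1e-5, n_features = n_features)
}

layer_relu <- function() list(type = "relu")

layer_maxpool <- function(size = 3, stride = 2, pad = 1) {
  list(type = "maxpool", size = size, stride = stride, pad = pad)
}

layer_gap <- function() list(type = "gap")

layer_dropout <- function(rate = 0.5) list(type = "dropout", rate = rate)

layer_dense <- function(in_features, out_features, init = c("he", "zero")) {
  init <- match.arg(init)
  W <- if (init == "he") {
    matrix(stats::rnorm(in_features * out_features, sd = sqrt(2 / in_features)),
           in_features, out_features)
  } else matrix(0, in_features, out_features)
  list(type = "dense", W = W, b = numeric(out_features),
       in_features = in_features, out_features = out_features)
}

layer_residual <- function(main, shortcut = NULL) {
  list(type = "residual", main = main, shortcut = shortcut)
}

# --- im2col indexing ------------------------------------------------------

# 1-based linear indices into a padded (hp, wp, c) volume: one row per output
# position (row-major within-column first), one column per (ki, kj, ci).
im2col_index <- function(hp, wp, channels, kernel, stride, oh, ow) {
  hp <- as.integer(hp); wp <- as.integer(wp); stride <- as.integer(stride)
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  posoff <- (oi - 1L) * stride + ((oj - 1L) * stride) * hp       # 0-based
  k <- seq_len(kernel * kernel * channels) - 1L
  ki <- k %% kernel + 1L
  kj <- (k %/% kernel) %% kernel + 1L
  ci <- k %/% (kernel * kernel)
  keloff <- ki + (kj - 1L) * hp + ci * hp * wp                   # 1-based
  outer(posoff, keloff, "+")
}

pad_batch <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

conv_out_size <- function(n, kernel, stride, pad) {
  (n + 2 * pad - kernel) %/% stride + 1L
}

# --- forward passes -------------------------------------------------------

forward_conv <- function(layer, x) {
  d <- dim(x); h <- d[1]; w <- d[2]; ch <- d[3]; n <- d[4]
  k <- layer$kernel; s <- layer$stride; p <- layer$pad
  oh <- conv_out_size(h, k, s, p); ow <- conv_out_size(w, k, s, p)
  xp <- pad_batch(x, p)
  hp <- h + 2 * p; wp <- w + 2 * p
  idx <- im2col_index(hp, wp, ch, k, s, oh, ow)
  L <- hp * wp * ch
  IDX <- idx[rep(seq_len(oh * ow), n), , drop = FALSE] +
    rep((seq_len(n) - 1L) * as.integer(L), each = oh * ow)
  cols <- xp[IDX]
  dim(cols) <- dim(IDX)
  y <- cols %*% layer$W
  y <- y + rep(layer$b, each = nrow(y))
  out <- array(y, c(oh * ow, n, layer$out_channels))
  out <- aperm(out, c(1L, 3L, 2L))
  dim(out) <- c(oh, ow, layer$out_channels, n)
  list(out = out,
       cache = list(cols = cols, IDX = IDX, in_dim = d, pad_len = L * n,
                    oh = oh, ow = ow))
}

backward_conv <- function(layer, cache, dout) {
  d <- cache$in_dim; n <- d[4]
  oh <- cache$oh; ow <- cache$ow
  dy <- dout
  dim(dy) <- c(oh * ow, layer$out_channels, n)
  dy <- aperm(dy, c(1L, 3L, 2L))
  dim(dy) <- c(oh * ow * n, layer$out_channels)
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dcols <- dy %*% t(layer$W)
  # scatter-add column by column: within one kernel offset every output
  # position targets a distinct input pixel, so plain indexed addition is
  # collision-free; collisions across offsets are handled by the loop
  dxp <- numeric(cache$pad_len)
  for (kcol in seq_len(ncol(dcols))) {
    ids <- cache$IDX[, kcol]
    dxp[ids] <- dxp[ids] + dcols[, kcol]
  }
  p <- layer$pad
  dim(dxp) <- c(d[1] + 2 * p, d[2] + 2 * p, d[3], n)
  dx <- if (p > 0) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
  dim(dx) <- d
  list(dx = dx, grads = list(W = dW, b = db))
}

forward_bn <- function(layer, x, training) {
  d <- dim(x)
  conv_mode <- length(d) == 4L
  xm <- if (conv_mode) {
    m <- aperm(x, c(3L, 1L, 2L, 4L)); dim(m) <- c(d[3], d[1] * d[2] * d[4]); m
  } else x
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  inv_sd <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - mu) * inv_sd
  ym <- layer$gamma * xhat + layer$beta
  y <- if (conv_mode) {
    dim(ym) <- c(d[3], d[1], d[2], d[4]); aperm(ym, c(2L, 3L, 1L, 4L))
  } else ym
  list(out = y, layer = layer,
       cache = list(xhat = xhat, inv_sd = inv_sd, dims = d, conv_mode = conv_mode,
                    training = training))
}

backward_bn <- function(layer, cache, dout) {
  d <- cache$dims
  dym <- if (cache$conv_mode) {
    m <- aperm(dout, c(3L, 1L, 2L, 4L)); dim(m) <- c(d[3], prod(d) / d[3]); m
  } else dout
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  N <- ncol(dym)
  dxhat <- dym * layer$gamma
  dxm <- if (cache$training) {
    cache$inv_sd / N * (N * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  } else {
    dxhat * cache$inv_sd
  }
  dx <- if (cache$conv_mode) {
    dim(dxm) <- c(d[3], d[1], d[2], d[4]); aperm(dxm, c(2L, 3L, 1L, 4L))
  } else dxm
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

forward_relu <- function(layer, x) {
  list(out = pmax(x, 0), cache = list(pos = x > 0))
}

backward_relu <- function(layer, cache, dout) {
  list(dx = dout * cache$pos, grads = NULL)
}

forward_maxpool <- function(layer, x) {
  d <- dim(x); h <- d[1]; w <- d[2]; ch <- d[3]; n <- d[4]
  k <- layer$size; s <- layer$stride; p <- layer$pad
  oh <- conv_out_size(h, k, s, p); ow <- conv_out_size(w, k, s, p)
  xp <- pad_batch(x, p)
  if (p > 0) {
    # padding must never win a max: fill with -Inf outside the valid region
    fill <- array(-Inf, dim(xp))
    fill[p + seq_len(h), p + seq_len(w), , ] <- x
    xp <- fill
  }
  hp <- h + 2 * p; wp <- w + 2 * p
  idx <- im2col_index(hp, wp, 1L, k, s, oh, ow)       # per-channel patches
  L <- hp * wp
  nslices <- ch * n
  IDX <- idx[rep(seq_len(oh * ow), nslices), , drop = FALSE] +
    rep((seq_len(nslices) - 1L) * L, each = oh * ow)
  cols <- matrix(xp[IDX], nrow(IDX), ncol(IDX))
  amx <- max.col(cols, ties.method = "first")
  y <- cols[cbind(seq_len(nrow(cols)), amx)]
  dim(y) <- c(oh, ow, ch, n)
  list(out = y,
       cache = list(win_idx = IDX[cbind(seq_len(nrow(IDX)), amx)],
                    pad_len = L * nslices, in_dim = d, pad = p))
}

backward_maxpool <- function(layer, cache, dout) {
  d <- cache$in_dim; p <- cache$pad
  acc <- rowsum(as.vector(dout), group = cache$win_idx)
  dxp <- numeric(cache$pad_len)
  dxp[as.integer(rownames(acc))] <- acc
  dim(dxp) <- c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4])
  dx <- if (p > 0) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
  dim(dx) <- d
  list(dx = dx, grads = NULL)
}

forward_gap <- function(layer, x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  y <- matrix(colMeans(xm), d[3], d[4])
  list(out = y, cache = list(in_dim = d))
}

backward_gap <- function(layer, cache, dout) {
  d <- cache$in_dim
  dx <- array(rep(as.vector(dout) / (d[1] * d[2]), each = d[1] * d[2]), d)
  list(dx = dx, grads = NULL)
}

forward_dropout <- function(layer, x, training) {
  if (!training || layer$rate == 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  keep <- 1 - layer$rate
  m <- array((stats::runif(length(x)) < keep) / keep, dim(x))
  list(out = x * m, cache = list(mask = m))
}

backward_dropout <- function(layer, cache, dout) {
  dx <- if (is.null(cache$mask)) dout else dout * cache$mask
  list(dx = dx, grads = NULL)
}

forward_dense <- function(layer, x) {
  y <- crossprod(layer$W, x) + layer$b
  list(out = y, cache = list(x = x))
}

backward_dense <- function(layer, cache, dout) {
  list(dx = layer$W %*% dout,
       grads = list(W = cache$x %*% t(dout), b = rowSums(dout)))
}

# --- network walkers ------------------------------------------------------

net_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    r <- switch(ly$type,
      conv = forward_conv(ly, x),
      bn = forward_bn(ly, x, training),
      relu = forward_relu(ly, x),
      maxpool = forward_maxpool(ly, x),
      gap = forward_gap(ly, x),
      dropout = forward_dropout(ly, x, training),
      dense = forward_dense(ly, x),
      residual = forward_residual(ly, x, training),
      stop("unknown layer type: ", ly$type)
    )
    x <- r$out
    caches[[i]] <- r$cache
    if (!is.null(r$layer)) layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    r <- switch(ly$type,
      conv = backward_conv(ly, caches[[i]], dout),
      bn = backward_bn(ly, caches[[i]], dout),
      relu = backward_relu(ly, caches[[i]], dout),
      maxpool = backward_maxpool(ly, caches[[i]], dout),
      gap = backward_gap(ly, caches[[i]], dout),
      dropout = backward_dropout(ly, caches[[i]], dout),
      dense = backward_dense(ly, caches[[i]], dout),
      residual = backward_residual(ly, caches[[i]], dout)
    )
    dout <- r$dx
    grads[i] <- list(r$grads)   # [[<- would drop the slot for NULL grads
  }
  list(dx = dout, grads = grads)
}

forward_residual <- function(layer, x, training) {
  main <- net_forward(layer$main, x, training)
  short <- if (is.null(layer$shortcut)) {
    list(out = x, caches = NULL, layers = NULL)
  } else net_forward(layer$shortcut, x, training)
  pre <- main$out + short$out
  layer$main <- main$layers
  if (!is.null(layer$shortcut)) layer$shortcut <- short$layers
  list(out = pmax(pre, 0), layer = layer,
       cache = list(main = main$caches, shortcut = short$caches, pos = pre > 0))
}

backward_residual <- function(layer, cache, dout) {
  dpre <- dout * cache$pos
  main <- net_backward(layer$main, cache$main, dpre)
  if (is.null(layer$shortcut)) {
    dx <- main$dx + dpre
    sgrads <- NULL
  } else {
    short <- net_backward(layer$shortcut, cache$shortcut, dpre)
    dx <- main$dx + short$dx
    sgrads <- short$grads
  }
  list(dx = dx, grads = list(main = main$grads, shortcut = sgrads))
}

# --- parameter bookkeeping ------------------------------------------------

# names of trainable / non-trainable arrays per layer type
.trainable_fields <- list(conv = c("W", "b"), dense = c("W", "b"),
                          bn = c("gamma", "beta"))
.nontrainable_fields <- list(bn = c("running_mean", "running_var"))

layer_param_count <- function(layer, include_nontrainable = TRUE) {
  if (layer$type == "residual") {
    n <- sum(vapply(layer$main, layer_param_count, 0,
                    include_nontrainable = include_nontrainable))
    if (!is.null(layer$shortcut))
      n <- n + sum(vapply(layer$shortcut, layer_param_count, 0,
                          include_nontrainable = include_nontrainable))
    return(n)
  }
  fields <- .trainable_fields[[layer$type]]
  if (include_nontrainable)
    fields <- c(fields, .nontrainable_fields[[layer$type]])
  if (is.null(fields)) return(0)
  sum(vapply(fields, function(f) length(layer[[f]]), 0))
}

# --- Adam optimizer -------------------------------------------------------

adam_init <- function() list(t = 0)

# one Adam step over every trainable array in `layers`, driven by `grads`
# (the structure net_backward returns); returns updated layers and state
adam_step <- function(layers, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  walk <- function(lys, grs, st) {
    for (i in seq_along(lys)) {
      g <- grs[[i]]
      if (is.null(g)) next
      ly <- lys[[i]]
      if (ly$type == "residual") {
        rm <- walk(ly$main, g$main, st[[as.character(i)]]$main %||% list())
        ly$main <- rm$layers
        sub <- list(main = rm$state)
        if (!is.null(ly$shortcut) && !is.null(g$shortcut)) {
          rs <- walk(ly$shortcut, g$shortcut, st[[as.character(i)]]$shortcut %||% list())
          ly$shortcut <- rs$layers
          sub$shortcut <- rs$state
        }
        st[[as.character(i)]] <- sub
      } else {
        slot <- st[[as.character(i)]] %||% list()
        for (f in names(g)) {
          m <- slot[[f]]$m %||% 0
          v <- slot[[f]]$v %||% 0
          m <- beta1 * m + (1 - beta1) * g[[f]]
          v <- beta2 * v + (1 - beta2) * g[[f]]^2
          mhat <- m / (1 - beta1^state$t)
          vhat <- v / (1 - beta2^state$t)
          ly[[f]] <- ly[[f]] - lr * mhat / (sqrt(vhat) + eps)
          slot[[f]] <- list(m = m, v = v)
        }
        st[[as.character(i)]] <- slot
      }
      lys[[i]] <- ly
    }
    list(layers = lys, state = st)
  }
  r <- walk(layers, grads, state$slots %||% list())
  list(layers = r$layers, state = list(t = state$t, slots = r$state))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

softmax_probs <- function(logits) {
  z <- logits - rep(apply(logits, 2, max), each = nrow(logits))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}
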