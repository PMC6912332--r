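#' Training configuration for the CNN stage
#'
#' The learning rate decays every epoch by the constant factor
#' `(end_lr / initial_lr)^(1 / (n_epochs - 1))`, so it starts at `initial_lr`
#' in epoch 1 and reaches `end_lr` exactly in the final epoch.
#'
#' @param initial_lr Learning rate of epoch 1 (default 1e-4).
#' @param end_lr Learning rate of the final epoch (default 1e-5).
#' @param n_epochs Number of epochs (default 10).
#' @param batch_size Minibatch size (default 8).
#' @param seed Integer seed making the run reproducible.
#' @return A list of class `train_config`.
#' @export
train_config <- function(initial_lr = 1e-4, end_lr = 1e-5, n_epochs = 10,
                         batch_size = 8, seed = 1) {
  stopifnot(initial_lr > 0, end_lr > 0, n_epochs >= 1, batch_size >= 1)
  if (n_epochs > 1 && end_lr >= initial_lr)
    stop("`end_lr` must be below `initial_lr`: the schedule is strictly decreasing",
         call. = FALSE)
  structure(list(initial_lr = initial_lr, end_lr = end_lr,
                 n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Per-epoch learning-rate schedule
#'
#' @param config A [train_config()].
#' @return Numeric vector of length `n_epochs`, geometrically decaying from
#'   `initial_lr` to `end_lr`.
#' @export
learning_rate_schedule <- function(config) {
  stopifnot(inherits(config, "train_config"))
  if (config$n_epochs == 1) return(config$initial_lr)
  f <- (config$end_lr / config$initial_lr)^(1 / (config$n_epochs - 1))
  config$initial_lr * f^(seq_len(config$n_epochs) - 1)
}

# --- backbone builders ----------------------------------------------------

build_tiny_backbone <- function(in_channels = 3) {
  chans <- c(8, 16, 24, 32)
  layers <- list()
  cin <- in_channels
  for (co in chans) {
    layers <- c(layers, list(layer_conv(cin, co, kernel = 3, stride = 2, pad = 1),
                             layer_relu()))
    cin <- co
  }
  list(layers = layers, out_channels = 32L, reduction = 16L)
}

# Basic two-conv residual block (18/34-layer backbones)
basic_block <- function(in_ch, out_ch, stride) {
  main <- list(
    layer_conv(in_ch, out_ch, kernel = 3, stride = stride, pad = 1),
    layer_bn(out_ch), layer_relu(),
    layer_conv(out_ch, out_ch, kernel = 3, stride = 1, pad = 1),
    layer_bn(out_ch)
  )
  shortcut <- if (stride != 1 || in_ch != out_ch) {
    list(layer_conv(in_ch, out_ch, kernel = 1, stride = stride, pad = 0),
         layer_bn(out_ch))
  } else NULL
  layer_residual(main, shortcut)
}

# 1x1 -> 3x3 -> 1x1 bottleneck block (50-layer backbone)
bottleneck_block <- function(in_ch, mid_ch, stride) {
  out_ch <- 4L * mid_ch
  main <- list(
    layer_conv(in_ch, mid_ch, kernel = 1, stride = stride, pad = 0),
    layer_bn(mid_ch), layer_relu(),
    layer_conv(mid_ch, mid_ch, kernel = 3, stride = 1, pad = 1),
    layer_bn(mid_ch), layer_relu(),
    layer_conv(mid_ch, out_ch, kernel = 1, stride = 1, pad = 0),
    layer_bn(out_ch)
  )
  shortcut <- if (stride != 1 || in_ch != out_ch) {
    list(layer_conv(in_ch, out_ch, kernel = 1, stride = stride, pad = 0),
         layer_bn(out_ch))
  } else NULL
  layer_residual(main, shortcut)
}

build_resnet_backbone <- function(kind) {
  cfg <- switch(kind,
    resnet18 = list(block = basic_block, reps = c(2, 2, 2, 2), expansion = 1L),
    resnet34 = list(block = basic_block, reps = c(3, 4, 6, 3), expansion = 1L),
    resnet50 = list(block = bottleneck_block, reps = c(3, 4, 6, 3), expansion = 4L)
  )
  layers <- list(
    layer_conv(3, 64, kernel = 7, stride = 2, pad = 3),
    layer_bn(64), layer_relu(),
    layer_maxpool(size = 3, stride = 2, pad = 1)
  )
  widths <- c(64, 128, 256, 512)
  in_ch <- 64L
  for (s in seq_along(widths)) {
    for (r in seq_len(cfg$reps[s])) {
      stride <- if (s > 1 && r == 1) 2L else 1L
      layers <- c(layers, list(cfg$block(in_ch, widths[s], stride)))
      in_ch <- widths[s] * cfg$expansion
    }
  }
  list(layers = layers, out_channels = in_ch, reduction = 32L)
}

#' Build the cascade's CNN classifier
#'
#' Assembles a convolutional backbone (a residual network, or the small
#' `tiny_test` stack of four strided convolution blocks for fast end-to-end
#' runs) topped by the classification head: global average pooling over the
#' final feature map, batch normalization over its `k` channels, dropout, and
#' a fully connected 2-unit output read through a softmax. The head adds
#' `k * 4` batch-norm parameters and `2 * (k + 1)` output-layer parameters.
#' Backbone convolutions carry bias terms and every batch-norm layer carries
#' scale, shift and running statistics, so the parameter count is the total
#' tensor count of the architecture.
#'
#' Weights are randomly initialized (He for convolutions, zeros for the output
#' layer so early training moves the decision boundary rather than fighting a
#' random one). [load_network_weights()] can replace them with externally
#' trained weights.
#'
#' @param backbone_kind `"resnet18"`, `"resnet34"`, `"resnet50"` or
#'   `"tiny_test"`.
#' @param dropout_rate Dropout probability in the head (default 0.5).
#' @param input_size Square input size in pixels (default 224).
#' @param seed Seed for weight initialization.
#' @return An object of class `cascade_cnn`: `spec` (backbone kind, feature
#'   shape `(m, n, k)`, dropout rate, `n_classes = 2`, input size, parameter
#'   count), `layers`, `trained`, `history`.
#' @export
build_classifier <- function(backbone_kind = c("tiny_test", "resnet18",
                                               "resnet34", "resnet50"),
                             dropout_rate = 0.5, input_size = 224, seed = 1) {
  backbone_kind <- match.arg(backbone_kind)
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  withr::with_seed(seed, {
    bb <- if (backbone_kind == "tiny_test") build_tiny_backbone()
          else build_resnet_backbone(backbone_kind)
    k <- bb$out_channels
    head <- list(layer_gap(), layer_bn(k), layer_dropout(dropout_rate),
                 layer_dense(k, 2, init = "zero"))
  })
  n_backbone <- length(bb$layers)
  layers <- c(bb$layers, head)
  fm <- input_size %/% bb$reduction
  net <- structure(
    list(spec = list(backbone_kind = backbone_kind,
                     feature_shape = c(fm, fm, k),
                     dropout_rate = dropout_rate, n_classes = 2L,
                     input_size = as.integer(input_size), param_count = NA_real_),
         layers = layers, n_backbone_layers = n_backbone,
         trained = FALSE, history = NULL),
    class = "cascade_cnn"
  )
  net$spec$param_count <- count_parameters(net)
  net
}

#' @export
print.cascade_cnn <- function(x, ...) {
  fs <- x$spec$feature_shape
  cat(sprintf(
    "<cascade_cnn %s: features (%d, %d, %d), dropout %.2f, %s params%s>\n",
    x$spec$backbone_kind, fs[1], fs[2], fs[3], x$spec$dropout_rate,
    format(x$spec$param_count, big.mark = ","),
    if (x$trained) ", trained" else ""))
  invisible(x)
}

#' Count network parameters
#'
#' Sums element counts over all weight tensors. With
#' `include_nontrainable = TRUE` (the default) batch-norm running statistics
#' are included, i.e. the "total params" accounting.
#'
#' @param network A `cascade_cnn`.
#' @param include_nontrainable Include batch-norm running mean/variance.
#' @param part `"all"`, `"backbone"` or `"head"`.
#' @return Integer-valued count.
#' @export
count_parameters <- function(network, include_nontrainable = TRUE,
                             part = c("all", "backbone", "head")) {
  stopifnot(inherits(network, "cascade_cnn"))
  part <- match.arg(part)
  idx <- switch(part,
    all = seq_along(network$layers),
    backbone = seq_len(network$n_backbone_layers),
    head = seq(network$n_backbone_layers + 1L, length(network$layers))
  )
  sum(vapply(network$layers[idx], layer_param_count, 0,
             include_nontrainable = include_nontrainable))
}

#' Replace a network's weights with externally trained ones
#'
#' Optional transfer-learning hook: weights saved by [save_network_weights()]
#' (an RDS list of layer parameter arrays) are loaded into a structurally
#' identical network.
#'
#' @param network A `cascade_cnn`.
#' @param path RDS file produced by [save_network_weights()].
#' @return The network with weights replaced.
#' @export
load_network_weights <- function(network, path) {
  stopifnot(inherits(network, "cascade_cnn"))
  saved <- readRDS(path)
  network$layers <- restore_layer_params(network$layers, saved)
  network
}

#' Save a network's weights
#' @param network A `cascade_cnn`.
#' @param path Output RDS path.
#' @return `path`, invisibly.
#' @export
save_network_weights <- function(network, path) {
  stopifnot(inherits(network, "cascade_cnn"))
  saveRDS(extract_layer_params(network$layers), path)
  invisible(path)
}

.param_fields <- c("W", "b", "gamma", "beta", "running_mean", "running_var")

extract_layer_params <- function(layers) {
  lapply(layers, function(ly) {
    if (ly$type == "residual") {
      list(type = "residual", main = extract_layer_params(ly$main),
           shortcut = if (is.null(ly$shortcut)) NULL
                      else extract_layer_params(ly$shortcut))
    } else ly[intersect(.param_fields, names(ly))]
  })
}

restore_layer_params <- function(layers, saved) {
  if (length(layers) != length(saved))
    stop("saved weights do not match the network architecture", call. = FALSE)
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "residual") {
      layers[[i]]$main <- restore_layer_params(layers[[i]]$main, saved[[i]]$main)
      if (!is.null(layers[[i]]$shortcut))
        layers[[i]]$shortcut <- restore_layer_params(layers[[i]]$shortcut,
                                                     saved[[i]]$shortcut)
    } else {
      for (f in names(saved[[i]])) {
        if (f == "type") next
        if (length(layers[[i]][[f]]) != length(saved[[i]][[f]]))
          stop("saved weights do not match the network architecture", call. = FALSE)
        layers[[i]][[f]] <- saved[[i]][[f]]
      }
    }
  }
  layers
}

# --- input preprocessing --------------------------------------------------

# gray_image -> (s, s, 3) array on the [0, 1] scale
preprocess_crop <- function(image, input_size) {
  px <- resize_bilinear(image$pixels, input_size, input_size) / 255
  array(px, c(input_size, input_size, 3))   # replicate gray to 3 channels
}

images_to_batch <- function(images, input_size) {
  n <- length(images)
  x <- array(0, c(input_size, input_size, 3, n))
  for (i in seq_len(n)) x[, , , i] <- preprocess_crop(images[[i]], input_size)
  x
}

# --- training -------------------------------------------------------------

#' Train the CNN classifier
#'
#' Minimizes 2-class cross-entropy with Adam under the geometric per-epoch
#' learning-rate decay of [train_config()]. Images are resampled to the
#' network input size and replicated to three channels. The run is fully
#' reproducible given `config$seed`. After each epoch the whole training set
#' is re-scored in inference mode (dropout off, batch-norm running statistics)
#' to record training accuracy.
#'
#' @param network A `cascade_cnn` from [build_classifier()].
#' @param images List of [gray_image()] tissue crops.
#' @param labels Character vector of `"benign"` / `"malign"`, same length.
#' @param config A [train_config()].
#' @return The trained network (`trained = TRUE`), with `history`: a data
#'   frame of per-epoch learning rate, mean minibatch loss, and training
#'   accuracy.
#' @export
train_classifier <- function(network, images, labels, config = train_config()) {
  stopifnot(inherits(network, "cascade_cnn"), inherits(config, "train_config"))
  if (length(images) != length(labels))
    stop("`images` and `labels` lengths differ", call. = FALSE)
  if (!all(labels %in% c("benign", "malign")))
    stop("labels must be 'benign' or 'malign'", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training needs at least one sample per class", call. = FALSE)
  s <- network$spec$input_size
  x_all <- images_to_batch(images, s)
  y_all <- rbind(benign = labels == "benign", malign = labels == "malign") * 1
  n <- length(images)
  lrs <- learning_rate_schedule(config)
  layers <- network$layers
  hist <- data.frame(epoch = seq_len(config$n_epochs), lr = lrs,
                     loss = NA_real_, batch_loss = NA_real_,
                     accuracy = NA_real_)
  withr::with_seed(config$seed, {
    opt <- adam_init()
    for (ep in seq_len(config$n_epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        take <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- x_all[, , , take, drop = FALSE]
        yb <- y_all[, take, drop = FALSE]
        fwd <- net_forward(layers, xb, training = TRUE)
        layers <- fwd$layers
        p <- softmax_probs(fwd$out)
        losses <- c(losses, -mean(log(colSums(p * yb) + 1e-12)))
        dlogits <- (p - yb) / ncol(yb)
        bwd <- net_backward(layers, fwd$caches, dlogits)
        stepped <- adam_step(layers, bwd$grads, opt, lrs[ep])
        layers <- stepped$layers
        opt <- stepped$state
      }
      # end-of-epoch pass over the whole training set in inference mode:
      # the canonical loss/accuracy, free of dropout and minibatch noise
      eval_p <- softmax_probs(net_forward(layers, x_all, training = FALSE)$out)
      hist$loss[ep] <- -mean(log(colSums(eval_p * y_all) + 1e-12))
      hist$batch_loss[ep] <- mean(losses)
      hist$accuracy[ep] <- mean((eval_p[2L, ] >= 0.5) == (labels == "malign"))
    }
  })
  network$layers <- layers
  network$trained <- TRUE
  network$history <- hist
  network
}

#' Predict benign/malign for a tissue crop
#'
#' Runs the network in inference mode (dropout inactive, batch-norm running
#' statistics). The image is labeled malign when the malign-class softmax
#' probability is at least 0.5.
#'
#' @param object A `cascade_cnn`.
#' @param image A [gray_image()] (or a list of them).
#' @param ... Unused.
#' @return For one image, a list with `label` and `prob_malign`; for a list
#'   of images, a data frame with those columns.
#' @export
predict.cascade_cnn <- function(object, image, ...) {
  single <- inherits(image, "gray_image")
  images <- if (single) list(image) else image
  x <- images_to_batch(images, object$spec$input_size)
  p <- softmax_probs(net_forward(object$layers, x, training = FALSE)$out)
  prob <- unname(p[2L, ])   # row 1 = benign, row 2 = malign, by construction
  label <- ifelse(prob >= 0.5, "malign", "benign")
  if (single) list(label = label[1], prob_malign = prob[1])
  else data.frame(label = label, prob_malign = prob)
}
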