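th <- asNamespace("thyrocascade")

test_that("head parameter accounting follows k*4 + 2*(k+1) for every k", {
  for (k in c(32, 512, 2048)) {
    bn <- th$layer_bn(k)
    fc <- th$layer_dense(k, 2)
    expect_equal(th$layer_param_count(bn, TRUE), k * 4)
    expect_equal(th$layer_param_count(bn, FALSE), k * 2)
    expect_equal(th$layer_param_count(fc, TRUE), 2 * (k + 1))
  }
  # the printed single-layer cases
  expect_equal(th$layer_param_count(th$layer_bn(2048), TRUE), 8192)
  expect_equal(th$layer_param_count(th$layer_dense(512, 2), TRUE), 1026)
})

test_that("backbone specs expose the documented feature shapes and head sizes", {
  r18 <- build_classifier("resnet18")
  r50 <- build_classifier("resnet50")
  expect_equal(r18$spec$feature_shape, c(7, 7, 512))
  expect_equal(r50$spec$feature_shape, c(7, 7, 2048))
  expect_equal(count_parameters(r18, part = "head"), 512 * 4 + 2 * 513)
  expect_equal(count_parameters(r50, part = "head"), 2048 * 4 + 2 * 2049)
  expect_equal(count_parameters(r18),
               count_parameters(r18, part = "backbone") +
                 count_parameters(r18, part = "head"))
  expect_error(build_classifier("vgg16"))
})

test_that("count_parameters matches a hand count on a toy network", {
  withr::with_seed(1, {
    layers <- list(th$layer_conv(2, 3, kernel = 3), th$layer_bn(3),
                   th$layer_relu(), th$layer_gap(), th$layer_dense(3, 2))
  })
  net <- structure(list(layers = layers, n_backbone_layers = 4L),
                   class = "cascade_cnn")
  # conv: 3*3*2*3 + 3 = 57; bn: 12 (6 trainable); dense: 3*2 + 2 = 8
  expect_equal(count_parameters(net), 57 + 12 + 8)
  expect_equal(count_parameters(net, include_nontrainable = FALSE), 57 + 6 + 8)
  expect_equal(count_parameters(net, part = "head"), 8)
})

test_that("learning-rate schedule hits both printed endpoints", {
  lrs <- learning_rate_schedule(train_config())
  expect_length(lrs, 10)
  expect_equal(lrs[1], 1e-4, tolerance = 1e-12)
  expect_equal(lrs[10], 1e-5, tolerance = 1e-12)
  expect_true(all(diff(lrs) < 0))
  expect_error(train_config(initial_lr = 1e-5, end_lr = 1e-4), "decreasing")
})

test_that("an untrained tiny network forward-passes to a softmax pair", {
  net <- build_classifier("tiny_test", seed = 2)
  expect_equal(net$spec$feature_shape, c(14, 14, 32))
  img <- speckle_crop(120, seed = 4)
  pr <- predict(net, img)
  expect_gte(pr$prob_malign, 0)
  expect_lte(pr$prob_malign, 1)
  # zero-initialized head: both logits equal, probability exactly 0.5,
  # and the documented boundary rule calls it malign
  expect_equal(pr$prob_malign, 0.5)
  expect_equal(pr$label, "malign")
})

test_that("analytic gradients match numerical differentiation", {
  withr::with_seed(6, {
    layers <- list(th$layer_conv(2, 3, kernel = 3, stride = 2, pad = 1),
                   th$layer_relu(),
                   th$layer_gap(),
                   th$layer_bn(3),
                   th$layer_dense(3, 2))
    x <- array(stats::runif(10 * 10 * 2 * 3), c(10, 10, 2, 3))
    y <- rbind(c(1, 0, 1), c(0, 1, 0))
  })
  loss_of <- function(lys) {
    out <- th$net_forward(lys, x, training = TRUE)$out
    p <- th$softmax_probs(out)
    -mean(log(colSums(p * y) + 1e-12))
  }
  fwd <- th$net_forward(layers, x, training = TRUE)
  p <- th$softmax_probs(fwd$out)
  analytic <- th$net_backward(fwd$layers, fwd$caches, (p - y) / ncol(y))$grads
  eps <- 1e-5
  for (li in c(1, 4, 5)) {
    for (f in names(analytic[[li]])) {
      for (pos in c(1L, length(layers[[li]][[f]]))) {
        pert <- layers
        pert[[li]][[f]][pos] <- pert[[li]][[f]][pos] + eps
        up <- loss_of(pert)
        pert[[li]][[f]][pos] <- pert[[li]][[f]][pos] - 2 * eps
        dn <- loss_of(pert)
        num <- (up - dn) / (2 * eps)
        expect_equal(analytic[[li]][[f]][pos], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("residual blocks propagate gradients through both paths", {
  withr::with_seed(8, {
    block <- th$basic_block(2, 2, stride = 2)   # projection shortcut
    layers <- list(block, th$layer_gap(), th$layer_dense(2, 2))
    x <- array(stats::runif(8 * 8 * 2 * 2), c(8, 8, 2, 2))
    y <- rbind(c(1, 0), c(0, 1))
  })
  loss_of <- function(lys) {
    p <- th$softmax_probs(th$net_forward(lys, x, training = FALSE)$out)
    -mean(log(colSums(p * y) + 1e-12))
  }
  fwd <- th$net_forward(layers, x, training = FALSE)
  p <- th$softmax_probs(fwd$out)
  g <- th$net_backward(fwd$layers, fwd$caches, (p - y) / 2)$grads
  eps <- 1e-5
  for (path in c("main", "shortcut")) {
    gW <- g[[1]][[path]][[1]]$W
    pert <- layers
    pert[[1]][[path]][[1]]$W[1] <- pert[[1]][[path]][[1]]$W[1] + eps
    up <- loss_of(pert)
    pert[[1]][[path]][[1]]$W[1] <- pert[[1]][[path]][[1]]$W[1] - 2 * eps
    dn <- loss_of(pert)
    expect_equal(gW[1], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("training separable speckle textures reaches perfect accuracy", {
  images <- c(lapply(1:6, function(s) speckle_crop(60, s)),
              lapply(7:12, function(s) speckle_crop(180, s)))
  labels <- rep(c("benign", "malign"), each = 6)
  net <- build_classifier("tiny_test", seed = 5)
  cfg <- train_config(batch_size = 4, seed = 9)
  tr <- train_classifier(net, images, labels, cfg)
  expect_true(tr$trained)
  expect_equal(nrow(tr$history), 10)
  expect_equal(max(tr$history$accuracy), 1)
  # loss non-increasing over the last five epochs
  expect_true(all(diff(utils::tail(tr$history$loss, 5)) <= 1e-9))
  # held-out crops from each texture class are labeled correctly
  expect_equal(predict(tr, speckle_crop(60, 99))$label, "benign")
  expect_equal(predict(tr, speckle_crop(180, 98))$label, "malign")
  # seeded determinism: an identical run reproduces the loss trace exactly
  tr2 <- train_classifier(net, images, labels, cfg)
  expect_identical(tr$history$loss, tr2$history$loss)
})

test_that("training refuses a single-class dataset", {
  imgs <- lapply(1:3, function(s) speckle_crop(100, s))
  net <- build_classifier("tiny_test", seed = 1)
  expect_error(train_classifier(net, imgs, rep("benign", 3)), "per class")
})

test_that("weights survive a save/load round trip", {
  net <- build_classifier("tiny_test", seed = 3)
  f <- tempfile(fileext = ".rds")
  save_network_weights(net, f)
  other <- build_classifier("tiny_test", seed = 77)
  restored <- load_network_weights(other, f)
  img <- speckle_crop(140, 21)
  expect_equal(predict(restored, img)$prob_malign, predict(net, img)$prob_malign)
})
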