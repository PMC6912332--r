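test_that("constant image yields a degenerate spectrum", {
  sp <- power_spectrum(gray_image(matrix(42, 16, 16)), 16)
  expect_true(sp$degenerate)
  expect_equal(sp$total_power, 0, tolerance = 1e-9)
  mk <- make_mask("circle", 16, radius = 3)
  expect_error(fftscore(sp, mk), "degenerate")
})

test_that("a single horizontal tone concentrates power in two symmetric bins", {
  side <- 32
  px <- 100 + 50 * cos(2 * pi * 4 * (seq_len(side) - 1) / side)
  img <- gray_image(matrix(px, side, side))     # varies along rows only
  sp <- power_spectrum(img, side)
  ctr <- side / 2 + 1
  ord <- order(sp$power, decreasing = TRUE)
  top2 <- arrayInd(ord[1:2], dim(sp$power))
  expect_setequal(top2[, 1], c(ctr - 4, ctr + 4))
  expect_equal(top2[, 2], c(ctr, ctr))
  expect_equal(sp$power[ctr - 4, ctr], sp$power[ctr + 4, ctr], tolerance = 1e-9)
  expect_gt(sum(sp$power[top2]) / sp$total_power, 0.999)
})

test_that("power grid matches the naive O(N^4) DFT oracle", {
  for (seed in c(101, 102)) {
    img <- random_gray(8, 8, seed)
    sp <- power_spectrum(img, 8)
    expect_equal(sp$power, naive_dft_power(img$pixels), tolerance = 1e-8)
  }
})

test_that("total power obeys the Parseval identity for the unnormalized DFT", {
  img <- random_gray(16, 16, 7)
  sp <- power_spectrum(img, 16)
  f <- img$pixels - mean(img$pixels)
  expect_equal(sp$total_power, 16^2 * sum(f^2), tolerance = 1e-6)
})

test_that("spectrum parameters are validated", {
  img <- random_gray(8, 8, 1)
  expect_error(power_spectrum(img, 7), "even")
  expect_error(power_spectrum(img, 6), "at least 8")
})

test_that("mask geometry follows its set definitions", {
  expect_equal(sum(make_mask("circle", 16, radius = 0)$select), 1)
  h <- make_mask("horizontal", 16, bar_half_width = 2)$select
  v <- make_mask("vertical", 16, bar_half_width = 2)$select
  p <- make_mask("plus", 16, bar_half_width = 2)$select
  expect_equal(sum(p), sum(h) + sum(v) - sum(h & v))
  expect_equal(p, h | v)
  # brute-force per-bin membership for circle_plus
  cp <- make_mask("circle_plus", 16, radius = 3, bar_half_width = 1)$select
  ctr <- 9
  for (i in 1:16) for (j in 1:16) {
    member <- (i - ctr)^2 + (j - ctr)^2 <= 9 || abs(i - ctr) <= 1 || abs(j - ctr) <= 1
    if (cp[i, j] != member) fail(sprintf("bin (%d,%d) mismatch", i, j))
  }
  succeed()
  # oversize geometry clips to the grid instead of erroring
  expect_equal(sum(make_mask("circle", 16, radius = 1000)$select), 256)
})

test_that("masks are symmetric under 180-degree rotation about the center", {
  for (mk in list(make_mask("circle", 32, radius = 7),
                  make_mask("plus", 32, bar_half_width = 3),
                  make_mask("circle_plus", 32, radius = 5, bar_half_width = 1))) {
    s <- mk$select; ctr <- 17
    for (i in 2:32) for (j in 2:32) {
      mi <- 2 * ctr - i; mj <- 2 * ctr - j
      if (mi >= 1 && mi <= 32 && mj >= 1 && mj <= 32 &&
          s[i, j] != s[mi, mj]) {
        fail(sprintf("%s asymmetric at (%d,%d)", mk$shape_kind, i, j))
      }
    }
  }
  succeed()
})

test_that("fftscore spans [0, 1] and matches the naive-DFT oracle ratio", {
  img <- random_gray(8, 8, 55)
  sp <- power_spectrum(img, 8)
  expect_equal(fftscore(sp, make_mask("circle", 8, radius = 100)), 1)
  expect_equal(fftscore(sp, make_mask("circle", 8, radius = 0)), 0)  # DC only
  mk <- make_mask("circle", 8, radius = 2)
  P <- naive_dft_power(img$pixels)
  dc <- P[5, 5]
  expect_equal(fftscore(sp, mk),
               (sum(P[mk$select]) - dc) / (sum(P) - dc), tolerance = 1e-8)
})

test_that("fftscore is invariant to intensity scale and brightness", {
  base <- random_gray(24, 24, 9)
  base <- gray_image(base$pixels * 0.35)        # headroom for scaling
  mk <- make_mask("circle_plus", 16, radius = 3, bar_half_width = 1)
  s0 <- fftscore(power_spectrum(base, 16), mk)
  scaled <- gray_image(base$pixels * 2.5)
  shifted <- gray_image(base$pixels + 30)
  expect_equal(fftscore(power_spectrum(scaled, 16), mk), s0, tolerance = 1e-9)
  expect_equal(fftscore(power_spectrum(shifted, 16), mk), s0, tolerance = 1e-9)
})

test_that("fftscore is monotone over nested masks", {
  img <- random_gray(32, 32, 13)
  sp <- power_spectrum(img, 32)
  radii <- c(2, 5, 9, 14)
  scores <- vapply(radii, function(r)
    fftscore(sp, make_mask("circle", 32, radius = r)), 0)
  expect_true(all(diff(scores) >= 0))
  # circle subset of circle_plus with the same radius
  expect_lte(fftscore(sp, make_mask("circle", 32, radius = 5)),
             fftscore(sp, make_mask("circle_plus", 32, radius = 5,
                                    bar_half_width = 2)))
})

test_that("threshold calibration reproduces its worked examples", {
  m1 <- calibrate_thresholds(c(0.10, 0.20, 0.30), c(0.25, 0.40, 0.50), alpha = 0)
  expect_equal(m1$direction, 1)
  expect_equal(m1$th_low, 0.25)
  expect_equal(m1$th_high, 0.30)
  # separable classes collapse to the midpoint: empty undecided band
  m2 <- calibrate_thresholds(c(0.1, 0.2), c(0.6, 0.7), alpha = 0)
  expect_equal(m2$th_low, 0.4)
  expect_equal(m2$th_high, 0.4)
  # reversed orientation is learned, not assumed
  m3 <- calibrate_thresholds(c(0.8, 0.9), c(0.1, 0.3), alpha = 0)
  expect_equal(m3$direction, -1)
  expect_error(calibrate_thresholds(0.5, c(0.1, 0.2)), "at least 2")
  expect_error(calibrate_thresholds(c(0.1, 0.2), c(0.3, 0.4), alpha = 0.5))
})

test_that("calibrated quantiles match a sort-and-interpolate oracle", {
  # distributions overlap enough that the quantile band stays open
  withr::with_seed(88, {
    ben <- stats::rnorm(200, 0.2, 0.1)
    mal <- stats::rnorm(200, 0.4, 0.1)
  })
  m <- calibrate_thresholds(ben, mal, alpha = 0.05)
  expect_equal(m$direction, 1)
  expect_equal(m$th_low, quantile_oracle(mal, 0.05), tolerance = 1e-12)
  expect_equal(m$th_high, quantile_oracle(ben, 0.95), tolerance = 1e-12)
})

test_that("tri-state classification respects the band and its boundaries", {
  m <- calibrate_thresholds(c(0.10, 0.20, 0.30), c(0.25, 0.40, 0.50), alpha = 0)
  expect_equal(classify_frequency(0.1, m), "benign")
  expect_equal(classify_frequency(0.25, m), "benign_malign")   # at TH_LOW
  expect_equal(classify_frequency(0.30, m), "benign_malign")   # at TH_HIGH
  expect_equal(classify_frequency(0.31, m), "malign")
  expect_equal(classify_frequency(c(0.1, 0.28, 0.9), m),
               c("benign", "benign_malign", "malign"))
})

test_that("alpha = 0 calibration never misclassifies its own training data", {
  for (seed in c(31, 32, 33)) {
    withr::with_seed(seed, {
      ben <- stats::rnorm(50, 0.3, 0.1)
      mal <- stats::rnorm(50, 0.45, 0.1)
    })
    m <- calibrate_thresholds(ben, mal, alpha = 0)
    expect_false(any(classify_frequency(ben, m) == "malign"))
    expect_false(any(classify_frequency(mal, m) == "benign"))
  }
})

test_that("rank-based AUC equals the all-pairs concordance oracle", {
  withr::with_seed(17, {
    pos <- stats::rnorm(25, 1); neg <- stats::rnorm(30)
    pos[1] <- neg[1]     # force a tie
  })
  expect_equal(roc_auc(pos, neg), auc_oracle(pos, neg), tolerance = 1e-12)
})

test_that("mask tuning returns the singleton candidate and honors tie-breaks", {
  fx <- phantom_fixture()
  take <- c(1:4, 11:14)                        # both classes present
  one <- tune_mask(fx$spectra[take], fx$labels[take], side = 256,
                   radii = 16, bar_half_widths = numeric())
  expect_equal(one$shape_kind, "circle")
  expect_equal(one$radius, 16)
})

test_that("plus-family masks rank at least as high as the circle on phantoms", {
  fx <- phantom_fixture()
  is_mal <- fx$labels == "malign"
  auc_of <- function(mk) {
    sc <- vapply(fx$spectra, fftscore, 0, mask = mk)
    a <- roc_auc(sc[is_mal], sc[!is_mal])
    max(a, 1 - a)
  }
  best_plus <- max(vapply(c(1, 2, 4), function(b)
    auc_of(make_mask("plus", 256, bar_half_width = b)), 0))
  expect_gte(best_plus, auc_of(make_mask("circle", 256, radius = 16)))
})

test_that("the tuned mask's ROC area matches the concordance oracle", {
  fx <- phantom_fixture()
  best <- tune_mask(fx$spectra, fx$labels, side = 256,
                    radii = c(16, 32), bar_half_widths = c(1, 4))
  sc <- attr(best, "scores")
  is_mal <- fx$labels == "malign"
  a <- auc_oracle(sc[is_mal], sc[!is_mal])
  expect_equal(attr(best, "auc"), max(a, 1 - a), tolerance = 1e-12)
})
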