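test_that("temporal mean images drop the first and last frame and average linearly", {
  frames <- array(5, dim = c(10, 4, 4))
  mi <- makeMeanImages(frames)
  expect_equal(dim(mi)[1], 8L)
  expect_equal(max(abs(mi - 5)), 0)
  # an impulse frame spreads across 3 consecutive means at 1/3 amplitude
  imp <- array(0, dim = c(7, 3, 3))
  imp[4, , ] <- 3
  mi2 <- makeMeanImages(imp)
  expect_equal(mi2[2, 1, 1], 1)
  expect_equal(mi2[3, 1, 1], 1)
  expect_equal(mi2[4, 1, 1], 1)
  expect_equal(mi2[1, 1, 1], 0)
  expect_error(makeMeanImages(array(0, dim = c(2, 3, 3))), "3 frames")
})

test_that("affine augmentation is identity at zero settings and preserves labels", {
  img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  expect_equal(affineTransformImage(img), img)
  ds <- genClassifierDataset(4, classes = c("walking", "grooming", "PER"),
                             imageSize = c(16, 16), seed = 2)
  cfg <- tinyClassifierConfig()
  aug <- augmentDataset(ds, cfg, seed = 5)
  # balanced totals: copies-per-image base times the largest class count
  expect_equal(unname(table(aug$y)), rep(cfg$copiesPerImage[1] * 4L, 3),
               ignore_attr = TRUE)
  expect_equal(levels(aug$y), levels(ds$y))
  # pixel range preserved
  expect_gte(min(aug$x), 0)
  expect_lte(max(aug$x), 1)
  # an unbalanced input still augments to balance
  ds2 <- ds
  keep <- c(which(ds2$y == "walking")[1:2], which(ds2$y != "walking"))
  ds2$x <- ds2$x[keep, , , , drop = FALSE]
  ds2$y <- droplevels(ds2$y[keep])
  aug2 <- augmentDataset(ds2, cfg, seed = 5)
  expect_equal(length(unique(table(aug2$y))), 1L)
})

test_that("the built network matches the configured topology exactly", {
  cfg <- deskClassifierConfig(seed = 1)
  m <- buildModel(cfg, 7)
  arch <- modelArchitecture(m)
  conv <- arch[arch$type == "conv", ]
  dense <- arch[arch$type == "dense", ]
  drops <- arch[arch$type == "dropout", ]
  expect_equal(nrow(conv), 6L)
  expect_equal(conv$size, cfg$convFilters)
  expect_equal(nrow(dense), 4L)
  expect_equal(dense$size[4], 7L)
  # each conv layer is followed by relu then pool
  for (i in conv$layer) {
    expect_equal(arch$type[arch$layer == i + 1], "relu")
    expect_equal(arch$type[arch$layer == i + 2], "pool")
  }
  expect_equal(nrow(arch[arch$type == "pool", ]), 6L)
  # dropout 0.2 after the last four conv blocks, 0.3 after first three dense
  expect_equal(sum(drops$rate == cfg$dropoutConv), 4L)
  expect_equal(sum(drops$rate == cfg$dropoutDense), 3L)
  convDropLayers <- drops$layer[drops$rate == cfg$dropoutConv]
  expect_true(all(convDropLayers > conv$layer[2]))
  # every conv kernel has 9 columns per input channel
  expect_equal(ncol(m$layers[[1]]$W), 9L * cfg$inputShape[3])
  expect_error(buildModel(cfg, 1), "nClasses")
})

test_that("analytic gradients match finite differences through all layer types", {
  cfg <- classifierConfig(inputShape = c(8, 8, 2), nConv = 2,
                          convFilters = c(3, 4), nDense = 2, denseWidths = 5,
                          seed = 2)
  m <- buildModel(cfg, 3)
  nnF <- flygate:::nnForward; nnB <- flygate:::nnBackward
  nnL <- flygate:::nnLoss
  set.seed(14)
  x <- array(rnorm(8 * 8 * 2 * 3), dim = c(8, 8, 2, 3))
  y <- 1:3
  fw <- nnF(m, x)
  ls <- nnL(fw$out, y)
  gr <- nnB(m, fw$caches, ls$dLogits)
  for (li in seq_along(m$layers)) {
    if (is.null(gr[[li]])) next
    for (k in sample(length(m$layers[[li]]$W), 4)) {
      eps <- 1e-5
      m2 <- m
      m2$layers[[li]]$W[k] <- m2$layers[[li]]$W[k] + eps
      l1 <- nnL(nnF(m2, x)$out, y)$loss
      m2$layers[[li]]$W[k] <- m2$layers[[li]]$W[k] - 2 * eps
      l0 <- nnL(nnF(m2, x)$out, y)$loss
      expect_equal(gr[[li]]$dW[k], (l1 - l0) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic under a fixed seed", {
  ds <- genClassifierDataset(6, classes = c("walking", "grooming"),
                             imageSize = c(16, 16), seed = 4)
  cfg <- tinyClassifierConfig(seed = 9)
  f1 <- suppressMessages(trainClassifier(ds, cfg))
  f2 <- suppressMessages(trainClassifier(ds, cfg))
  expect_identical(f1$model$layers, f2$model$layers)
  expect_identical(f1$heldOutAccuracy, f2$heldOutAccuracy)
})

test_that("an untrained network predicts at chance on balanced classes", {
  ds <- glyphTrainingSet()
  cfg <- deskClassifierConfig(seed = 21)
  m <- buildModel(cfg, nlevels(ds$y), classes = levels(ds$y))
  probs <- predictModel(m, ds$x)
  acc <- mean(max.col(probs, ties.method = "first") == as.integer(ds$y))
  expect_lt(abs(acc - 1 / 7), 0.12)
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
})

test_that("the desk-scale glyph task is learned to high held-out accuracy", {
  fit <- trainedGlyphModel()
  expect_gte(fit$heldOutAccuracy, 0.90)
  # training-set replay: most original images are recovered
  ds <- glyphTrainingSet()
  probs <- predictModel(fit$model, ds$x)
  acc <- mean(levels(ds$y)[max.col(probs, ties.method = "first")] == ds$y)
  expect_gte(acc, 0.90)
})

test_that("predictStream aligns to frames and feeds the ethogram filters", {
  fit <- trainedGlyphModel()
  ds <- glyphTrainingSet()
  # video of same-class runs over the four analysis behaviors (a real trial
  # is dominated by them; rare-state fractions are exercised elsewhere)
  analysisClasses <- c("grooming", "PER", "stopping", "walking")
  runLen <- 8L
  pick <- unlist(lapply(analysisClasses,
                        function(cl) which(ds$y == cl)[seq_len(runLen)]))
  video <- ds$x[pick, , , , drop = FALSE]
  probs <- predictStream(fit$model, video)
  expect_equal(nrow(probs), length(pick) - 2L)
  expect_equal(attr(probs, "frame"), seq(2L, length(pick) - 1L))
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  # a 3-frame video yields exactly one prediction
  expect_equal(nrow(predictStream(fit$model, ds$x[1:3, , , , drop = FALSE])),
               1L)
  # thresholded labels reach the 70 % labeling rate the trial filter needs
  stream <- thresholdLabels(probs, classes = colnames(probs))
  expect_equal(applyTrialExclusions(stream)$decision, "keep")
  expect_gt(mean(stream$label != "unlabeled"), 0.7)
  # labeled frames recover the class of their run
  runLab <- rep(analysisClasses, each = runLen)[attr(probs, "frame")]
  labeled <- stream$label != "unlabeled"
  expect_gt(mean(stream$label[labeled] == runLab[labeled]), 0.8)
})
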