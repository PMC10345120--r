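# Shared trained classifier fixture: the desk-scale glyph model is trained
# once per test run and reused by the classifier and acceptance tests.
.fixtures <- new.env(parent = emptyenv())

glyphTrainingSet <- function() {
  if (is.null(.fixtures$glyphs)) {
    .fixtures$glyphs <- genClassifierDataset(20, imageSize = c(64, 64),
                                             seed = 7)
  }
  .fixtures$glyphs
}

trainedGlyphModel <- function() {
  if (is.null(.fixtures$fit)) {
    cfg <- deskClassifierConfig(seed = 11)
    aug <- augmentDataset(glyphTrainingSet(), cfg)
    .fixtures$fit <- trainClassifier(aug, cfg)
  }
  .fixtures$fit
}

tinyClassifierConfig <- function(seed = 3) {
  classifierConfig(inputShape = c(16, 16, 3), nConv = 2,
                   convFilters = c(4, 8), nDense = 2, denseWidths = 12,
                   batchSize = 8, epochs = 3, lr = 0.05, seed = seed)
}
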