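test_that("image generation is deterministic and anatomy is class-shared", {
  cfg <- synthImageConfig(imageSize = 96L, seed = 13L)
  a <- generateBrainImage(cfg, "MS", 4)
  b <- generateBrainImage(cfg, "MS", 4)
  expect_identical(slicePixels(a), slicePixels(b))

  # zero effect and zero noise: MS and healthy are bit-identical because
  # lesion drawing is skipped and geometry depends only on (seed, index)
  cfg0 <- synthImageConfig(imageSize = 96L, lesionIntensityDelta = 0,
                           noiseSd = 0, seed = 13L)
  expect_identical(slicePixels(generateBrainImage(cfg0, "MS", 2)),
                   slicePixels(generateBrainImage(cfg0, "healthy", 2)))

  # different indices and seeds give different images
  expect_false(identical(slicePixels(generateBrainImage(cfg, "MS", 1)),
                         slicePixels(generateBrainImage(cfg, "MS", 2))))
})

test_that("lesions are hyperintense relative to surrounding tissue", {
  cfg <- synthImageConfig(imageSize = 128L, lesionIntensityDelta = 0.4,
                          noiseSd = 0.01, seed = 23L)
  for (i in 1:5) {
    g <- generateBrainImage(cfg, "MS", i, masks = TRUE)
    px <- slicePixels(g$image)
    expect_gt(sum(g$lesionMask), 0)
    tissue <- g$brainMask & !g$lesionMask
    expect_gt(mean(px[g$lesionMask]), mean(px[tissue]))
  }
  # healthy images carry no lesions
  h <- generateBrainImage(cfg, "healthy", 1, masks = TRUE)
  expect_identical(sum(h$lesionMask), 0L)
})

test_that("dataset generation writes loadable PNGs and a consistent manifest", {
  td <- withr::local_tempdir()
  cfg <- synthImageConfig(imageSize = 64L, nPerClass = 4L, seed = 3L)
  man <- generateDataset(cfg, td)
  expect_identical(nrow(man), 8L)
  expect_true(all(file.exists(man$path)))
  expect_setequal(unique(man$label), c("healthy", "MS"))
  # round-trip: every manifest path loads
  for (p in man$path) expect_s4_class(loadImage(p), "BrainSlice")
  # written 8-bit PNGs decode close to the in-memory image
  sl <- loadImage(man$path[1])
  ref <- generateBrainImage(cfg, man$label[1], 1L)
  expect_lt(max(abs(slicePixels(sl) - slicePixels(ref))), 1 / 255)

  td2 <- withr::local_tempdir()
  man2 <- generateDataset(synthImageConfig(imageSize = 64L, nPerClass = 4L,
                                           seed = 4L), td2)
  expect_false(identical(readBin(man$path[1], "raw", 5000),
                         readBin(man2$path[1], "raw", 5000)))
})

test_that("tabular generator: chance at zero separation, recovery at strong separation", {
  # null configuration: 1-NN CV accuracy within 3 binomial sd of chance
  tab0 <- generateTabular(synthTabularConfig(nSamples = 60L,
                                             classSeparation = 0,
                                             seed = 8L))
  fa <- stratifiedKFold(tab0$y, K = 10, seed = 1)
  wrong <- 0
  for (f in 1:10) {
    te <- which(foldIds(fa) == f); tr <- which(foldIds(fa) != f)
    pred <- knnPredict(tab0$X[tr, ], tab0$y[tr], tab0$X[te, ], k = 1)
    wrong <- wrong + sum(pred != as.character(tab0$y[te]))
  }
  expect_lt(abs((1 - wrong / 60) - 0.5), 3 * sqrt(0.25 / 60))

  # determinism
  tabA <- generateTabular(synthTabularConfig(seed = 9L))
  tabB <- generateTabular(synthTabularConfig(seed = 9L))
  expect_identical(tabA$X, tabB$X)
  expect_identical(tabA$informative, tabB$informative)

  # strong separation: mRMR puts all informative features in the top 5
  # in at least 95% of 100 seeds
  hits <- 0L
  for (s in 1:100) {
    tab <- generateTabular(synthTabularConfig(nSamples = 60L,
                                              nInformative = 3L,
                                              nNoise = 47L,
                                              classSeparation = 4,
                                              seed = s))
    top5 <- rankedOrder(mrmrRank(tab$X, tab$y, m = 5L))
    hits <- hits + all(tab$informative %in% top5)
  }
  expect_gte(hits, 95L)
})
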