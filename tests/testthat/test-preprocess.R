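test_that("images round-trip through disk with the stated dimension convention", {
  td <- withr::local_tempdir()
  # 200 high x 300 wide grayscale
  px <- matrix(runif(200 * 300), 200, 300)
  f <- file.path(td, "wide.png")
  EBImage::writeImage(EBImage::Image(t(px)), f, bits = 8L)
  sl <- loadImage(f)
  expect_s4_class(sl, "BrainSlice")
  expect_identical(dim(slicePixels(sl))[1:2], c(200L, 300L))
  expect_length(dim(slicePixels(sl)), 2L)  # grayscale stays 1-channel

  # RGB stays 3-channel
  rgb <- array(runif(64 * 96 * 3), c(64, 96, 3))
  f2 <- file.path(td, "rgb.png")
  EBImage::writeImage(EBImage::Image(aperm(rgb, c(2, 1, 3)),
                                     colormode = "Color"), f2, bits = 8L)
  sl2 <- loadImage(f2)
  expect_identical(dim(slicePixels(sl2)), c(64L, 96L, 3L))

  expect_error(loadImage(file.path(td, "missing.png")), "does not exist")
  bad <- file.path(td, "bad.png")
  writeLines("not an image", bad)
  expect_error(loadImage(bad), "undecodable")
})

test_that("brain-area crop recovers the bounding box of a known foreground", {
  d <- diskImage(size = 100L, cy = 50, cx = 50, r = 20)
  seg <- segmentBrainArea(d$slice)
  box <- seg$crop
  # ground-truth bbox from the mask that drew the disk (0-based half-open)
  rows <- range(which(rowSums(d$mask) > 0))
  cols <- range(which(colSums(d$mask) > 0))
  expect_lte(abs(box@top - (rows[1] - 1L)), 2)
  expect_lte(abs(box@bottom - rows[2]), 2)
  expect_lte(abs(box@left - (cols[1] - 1L)), 2)
  expect_lte(abs(box@right - cols[2]), 2)
  # cropped pixels equal the source restricted to the box
  expect_identical(slicePixels(seg$image),
                   slicePixels(d$slice)[(box@top + 1):box@bottom,
                                        (box@left + 1):box@right])
  # crop contains >= 99% of foreground pixels
  inBox <- d$mask[(box@top + 1):box@bottom, (box@left + 1):box@right]
  expect_gte(sum(inBox) / sum(d$mask), 0.99)
  # never enlarges
  expect_lte(prod(dim(slicePixels(seg$image))),
             prod(dim(slicePixels(d$slice))))
})

test_that("degenerate foregrounds fall back to the full frame", {
  flat <- new("BrainSlice", pixels = matrix(0, 50, 60))
  expect_warning(seg <- segmentBrainArea(flat), "full-frame")
  expect_identical(c(seg$crop@top, seg$crop@left, seg$crop@bottom,
                     seg$crop@right), c(0L, 0L, 50L, 60L))

  # foreground already touching all four borders
  px <- matrix(0, 40, 40)
  px[, 19:21] <- 1; px[19:21, ] <- 1  # cross spanning the frame
  seg2 <- segmentBrainArea(new("BrainSlice", pixels = px))
  expect_identical(c(seg2$crop@top, seg2$crop@left, seg2$crop@bottom,
                     seg2$crop@right), c(0L, 0L, 40L, 40L))
})

test_that("canonicalize yields bounded 224x224x3 output and is idempotent", {
  # all-255 in-memory integer array maps to all-ones, geometry unchanged
  sat <- new("BrainSlice", pixels = array(255, c(224, 224, 3)))
  suppressWarnings(cv <- canonicalizeImage(sat, segment = FALSE))
  expect_identical(dim(canonicalPixels(cv)), c(224L, 224L, 3L))
  expect_true(all(canonicalPixels(cv) == 1))

  # downscaling and channel replication
  gray <- new("BrainSlice", pixels = matrix(runif(448 * 448), 448, 448))
  cv2 <- canonicalizeImage(gray, segment = FALSE)
  expect_identical(dim(canonicalPixels(cv2)), c(224L, 224L, 3L))
  expect_identical(canonicalPixels(cv2)[, , 1], canonicalPixels(cv2)[, , 2])
  expect_identical(canonicalPixels(cv2)[, , 1], canonicalPixels(cv2)[, , 3])
  expect_true(all(canonicalPixels(cv2) >= 0 & canonicalPixels(cv2) <= 1))

  # idempotence on a realistic already-canonical image: the first crop
  # leaves the brain touching all borders, so a second pass is a no-op
  slice <- generateBrainImage(synthImageConfig(seed = 9), "MS", 2)
  cv3 <- canonicalizeImage(slice)
  again <- canonicalizeImage(
    new("BrainSlice", pixels = canonicalPixels(cv3),
        label = cv3@label, view = cv3@view))
  expect_lt(max(abs(canonicalPixels(again) - canonicalPixels(cv3))), 1e-6)
})

test_that("manifests resolve from CSV and from class-per-directory layouts", {
  fix <- easyImageSet()
  man <- readManifest(file.path(fix$dir, "manifest.csv"))
  expect_named(man, c("path", "label", "view"))
  expect_identical(nrow(man), 2L * fix$cfg$nPerClass)
  man2 <- readManifest(fix$dir)  # directory scan
  expect_setequal(normalizePath(man2$path), normalizePath(man$path))
  expect_error(readManifest(file.path(fix$dir, "nope.csv")), "not found")
})
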