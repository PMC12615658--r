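test_that("loadDataset reads class directories deterministically", {
  dir <- writtenImageDir(nPerClass = 3)
  s1 <- loadImageDataset(dir)
  expect_length(s1, 6)
  labs <- vapply(s1, function(s) s@label, integer(1))
  expect_equal(sum(labs == 1L), 3)
  expect_equal(sum(labs == 0L), 3)
  s2 <- loadImageDataset(dir)
  expect_identical(vapply(s1, function(s) s@id, character(1)),
                   vapply(s2, function(s) s@id, character(1)))
  expect_identical(s1[[1]]@pixels, s2[[1]]@pixels)
})

test_that("loadDataset fails on missing or empty class directories", {
  expect_error(loadImageDataset(tempfile("nope")), "does not exist")
  dir <- tempfile("partial")
  dir.create(file.path(dir, "with_locust"), recursive = TRUE)
  expect_error(loadImageDataset(dir), "without_locust")
  dir.create(file.path(dir, "without_locust"))
  expect_error(loadImageDataset(dir), "empty class directory")
})

test_that("resizeImage honours the shape contract and identity case", {
  img <- noisyImage(h = 32, w = 32)
  out <- resizeImage(img, 16, 16)
  expect_equal(imageDim(out), c(16L, 16L, 3L))
  expect_identical(out@label, img@label)
  expect_identical(out@id, img@id)
  # identity
  expect_identical(resizeImage(img, 32, 32)@pixels, img@pixels)
  # aspect not preserved
  wide <- noisyImage(h = 10, w = 30, id = "wide")
  expect_equal(imageDim(resizeImage(wide, 24, 24)), c(24L, 24L, 3L))
  expect_error(resizeImage(img, 0, 16), "positive")
})

test_that("computeMSE matches hand computations and is symmetric", {
  expect_equal(computeMSE(array(5, c(3, 3, 3)), array(5, c(3, 3, 3))), 0)
  expect_equal(computeMSE(array(0, c(2, 2, 1)), array(2, c(2, 2, 1))), 4)
  expect_equal(computeMSE(array(0, c(4, 4, 3)), array(255, c(4, 4, 3))),
               65025)
  a <- noisyImage(1)@pixels; b <- noisyImage(2)@pixels
  expect_equal(computeMSE(a, b), computeMSE(b, a))
  expect_error(computeMSE(a, array(0, c(2, 2, 3))), "shapes differ")
})

test_that("computePSNR returns the dB log-ratio with an Inf sentinel", {
  a <- array(7, c(4, 4, 3))
  expect_identical(computePSNR(a, a), Inf)
  # MSE = maxValue^2 -> 0 dB
  expect_equal(computePSNR(array(0, c(2, 2)), array(255, c(2, 2)), 255), 0)
  # MSE 4 on 8-bit scale
  expect_equal(computePSNR(array(0, c(2, 2, 1)), array(2, c(2, 2, 1)), 255),
               10 * log10(255^2 / 4), tolerance = 1e-12)
})

test_that("PSNR is strictly decreasing in MSE", {
  base <- array(0, c(8, 8, 3))
  psnrs <- vapply(c(1, 4, 16, 64), function(delta)
    computePSNR(base, base + delta, 255), numeric(1))
  expect_true(all(diff(psnrs) < 0))
})

test_that("qualityFilter partitions input and keeps constant images", {
  flat <- flatImage(120)
  for (sm in c("median3", "gaussian3")) {
    qf <- qualityFilter(list(flat), smoother = sm)
    expect_identical(qf$report$psnr_db, Inf)
    expect_true(qf$report$kept)
  }
  set <- list(flatImage(10, id = "a"), noisyImage(3, id = "b"),
              flatImage(200, id = "c"))
  qf <- qualityFilter(set, psnrThreshold = -Inf)
  expect_length(qf$kept, 3)
  qf2 <- qualityFilter(set, psnrThreshold = 25)
  expect_equal(sum(qf2$report$kept) + sum(!qf2$report$kept), 3)
  expect_error(qualityFilter(set, smoother = "boxcar"))
})

test_that("quality filtering separates pure noise from natural texture", {
  noise <- noisyImage(9, h = 32, w = 32, id = "pure_noise")
  smooth <- genImages(1, height = 32, width = 32, blobLength = c(8, 10),
                      blobWidth = c(3, 4), noiseSd = 0, seed = 5)$samples[[1]]
  report <- qualityFilter(list(noise, smooth), psnrThreshold = 25)$report
  expect_false(report$kept[report$image_id == "pure_noise"])
  expect_true(report$kept[report$image_id != "pure_noise"])
})

test_that("quality report round-trips through its delimited format", {
  qf <- qualityFilter(list(flatImage(), noisyImage()))
  path <- tempfile(fileext = ".csv")
  writeQualityReport(qf$report, path)
  back <- read.csv(path)
  expect_equal(back$image_id, qf$report$image_id)
  expect_equal(back$kept, qf$report$kept)
})
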