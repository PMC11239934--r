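test_that("grid averaging partitions exactly and matches hand-computed means", {
  # constant image: every grid value is the constant at every frame
  s <- constantStack(3.25, dims = c(57L, 43L), nFrames = 3L)
  gs <- gridAverage(s, 7L, 5L)
  expect_true(all(gs@values == 3.25))
  # default grid shape is 14 rows x 16 cols
  gsd <- gridAverage(constantStack(1, nFrames = 2L))
  expect_equal(dim(gsd@values)[1:2], c(14L, 16L))
  # 4 x 4 image of values 0..15 (row-major), 2 x 2 grid
  m <- matrix(0:15, 4, 4, byrow = TRUE)
  s2 <- ImageStack(array(m, c(4, 4, 1)), 1, 1)
  g2 <- gridAverage(s2, 2L, 2L)
  expect_equal(as.vector(t(g2@values[, , 1])), c(2.5, 4.5, 10.5, 12.5))
  # grid larger than image errors
  expect_error(gridAverage(s2, 5L, 2L), "larger than image")
  # partition covers every pixel exactly once (mean of means = mean)
  set.seed(2)
  arr <- array(runif(57 * 43), c(57, 43, 1))
  s3 <- ImageStack(arr, 1, 1)
  g3 <- gridAverage(s3, 7L, 5L)
  w <- outer(diff(g3@rowBreaks), diff(g3@colBreaks))
  expect_equal(sum(g3@values[, , 1] * w) / sum(w), mean(arr))
})

test_that("initial-window exclusion removes exactly the pre-cutoff frames", {
  x <- seriesFromVector(1:40, dt = 0.25)
  # cutoff 0 is the identity
  expect_identical(excludeInitial(x, 0)@values, x@values)
  # 0.25 h frames, 4.5 h cutoff: first 18 frames removed, t = 4.5 kept
  e <- excludeInitial(x, 4.5)
  expect_equal(dim(e@values)[3], 22L)
  expect_equal(e@timestamps[1], 4.5)
  expect_equal(as.vector(e@values[1, 1, ]), 19:40)
  # too-short remainder errors
  expect_error(excludeInitial(x, 9.6), "too short after exclusion")
})

test_that("temporal DFT matches analytic tones and the naive oracle", {
  # constant series: |X[0]| = N c, all other bins 0
  sp <- temporalSpectrum(seriesFromVector(rep(2.5, 20)))
  expect_equal(sp@values[1, 1, 1], 50)
  expect_equal(max(sp@values[1, 1, -1]), 0, tolerance = 1e-10)
  # pure cosine at bin 3: |X[3]| = A N / 2, other nonzero bins ~ 0
  N <- 64; A <- 1.7
  x <- A * cos(2 * pi * 3 * (0:(N - 1)) / N)
  spc <- temporalSpectrum(seriesFromVector(x))
  expect_equal(spc@values[1, 1, 4], A * N / 2, tolerance = 1e-8)
  expect_lt(max(spc@values[1, 1, -4]), 1e-10 * A * N)
  # random series vs naive O(N^2) oracle
  set.seed(3)
  y <- rnorm(128)
  spy <- temporalSpectrum(seriesFromVector(y))
  expect_lt(max(abs(spy@values[1, 1, ] - naiveDFTmag(y))), 1e-8)
  # non-uniform timestamps rejected
  bad <- seriesFromVector(1:10)
  bad@timestamps[5] <- bad@timestamps[5] + 0.1
  expect_error(temporalSpectrum(bad), "non-uniform")
})

test_that("band power sums inclusive bin ranges with Nyquist handling", {
  ones <- new("SpectrumGrid", values = array(1, c(2, 2, 81)),
              nFramesUsed = 160L, type = "magnitude",
              rowBreaks = 0:2, colBreaks = 0:2)
  b <- bandPower(ones, c(2, 30))
  expect_true(all(b == 29))          # 29 inclusive bins
  expect_equal(attr(b, "nBins"), 29L)
  # band [0, 0] on a constant series gives N c
  spc <- temporalSpectrum(seriesFromVector(rep(4, 25)))
  expect_equal(as.vector(bandPower(spc, c(0, 0))), 100)
  # random spectrum vs per-bin loop oracle
  set.seed(4)
  spr <- temporalSpectrum(seriesFromVector(rnorm(40)))
  got <- as.vector(bandPower(spr, c(2, 15)))
  want <- 0
  for (k in 2:15) want <- want + spr@values[1, 1, k + 1]
  expect_equal(got, want)
  # clipping and above-Nyquist behaviour
  expect_warning(bc <- bandPower(spr, c(2, 30)), "clipped")
  expect_equal(attr(bc, "nBins"), 19L)   # bins 2..20 for N = 40
  expect_error(bandPower(spr, c(25, 30)), "above Nyquist")
  expect_warning(bz <- bandPower(spr, c(25, 30), onAboveNyquist = "zero"),
                 "returning zeros")
  expect_true(all(bz == 0))
})

test_that("broadband correction annihilates impulses and preserves tones", {
  # single-frame impulse: flat magnitude spectrum, B = 29 a, H/nH = a, B* = 0
  N <- 160
  imp <- rep(0, N); imp[51] <- 3.7
  sp <- temporalSpectrum(seriesFromVector(imp))
  B <- bandPower(sp, c(2, 30))
  H <- bandPower(sp, c(30, 75))
  expect_equal(as.vector(B), 29 * 3.7, tolerance = 1e-9)
  Bs <- spikeCorrect(B, H, c(2, 30), c(30, 75))
  expect_lt(abs(as.vector(Bs)), 1e-9 * 3.7)
  # H = 0: B* = B (pure low-band tone passes unchanged)
  A <- 2.2
  tone <- A * cos(2 * pi * 3 * (0:(N - 1)) / N)
  spt <- temporalSpectrum(seriesFromVector(tone))
  Bt <- bandPower(spt, c(2, 30)); Ht <- bandPower(spt, c(30, 75))
  expect_equal(as.vector(Ht), 0, tolerance = 1e-9)
  Bst <- spikeCorrect(Bt, Ht, c(2, 30), c(30, 75))
  expect_equal(as.vector(Bst), A * N / 2, tolerance = 1e-8)
  # mode none is the identity; empty high band disables with a warning
  expect_identical(spikeCorrect(Bt, Ht, c(2, 30), c(30, 75), mode = "none"),
                   Bt)
  H0 <- Ht; attr(H0, "nBins") <- 0L
  expect_warning(out <- spikeCorrect(Bt, H0, c(2, 30), c(30, 75)),
                 "disabled")
  expect_equal(as.vector(out), as.vector(Bt))
  # literal mask mode: no effect beyond dropping the shared bin 30
  Bm <- spikeCorrect(Bt, Ht, c(2, 30), c(30, 75), mode = "mask", spec = spt)
  want <- sum(spt@values[1, 1, (2:29) + 1])
  expect_equal(as.vector(Bm), want)
})

test_that("SP-row selection keeps the flanking grid rows", {
  s <- constantStack(1, dims = c(140L, 160L), nFrames = 2L)
  gs <- gridAverage(s)   # 14 grid rows of 10 px
  ann <- LayerAnnotation(1, 140, 75)   # centre in grid row 8
  m <- selectSpRows(gs, ann, 4L)
  expect_equal(which(m), c(4:7, 9:12))
  expect_equal(attr(m, "spGridRow"), 8L)
  # half-rows covering the whole image with the centre row included
  expect_warning(m2 <- selectSpRows(gs, ann, 13L, includeCenter = TRUE),
                 "clipped")
  expect_true(all(m2))
  # edge clipping: centre near the top -> one-sided with warning
  annTop <- LayerAnnotation(1, 140, 12)
  expect_warning(m3 <- selectSpRows(gs, annTop, 4L), "clipped")
  expect_equal(which(m3), c(1, 3:6))
})

test_that("full reporter quantification is linear, condition-blind and exact on zero input", {
  ann <- defaultAnnotation()
  z <- constantStack(0, nFrames = 160L)
  q0 <- quantifyReporter(z, ann)
  expect_true(all(q0$B == 0) && all(q0$B_star == 0))
  expect_equal(nrow(q0), 14 * 16)
  expect_equal(attr(q0, "nFramesUsed"), 151L)
  # linearity: scaling the stack scales B and B_star by the same factor
  fx <- burstFixture()
  q1 <- quantifyReporter(fx$stack, ann)
  s2 <- ImageStack(frames(fx$stack) * 3, frameIntervalH = 0.5,
                   pixelSizeUm = 2)
  q2 <- quantifyReporter(s2, ann)
  expect_equal(q2$B, 3 * q1$B, tolerance = 1e-10)
  expect_equal(q2$B_star, 3 * q1$B_star, tolerance = 1e-10)
  # condition labels do not touch the per-grid computation
  q3 <- quantifyReporter(fx$stack, ann, condition = "treated")
  expect_equal(q3$B_star, q1$B_star)
  # determinism of the full composition
  q4 <- quantifyReporter(fx$stack, ann)
  expect_identical(q1$B_star, q4$B_star)
})

test_that("stage errors are labeled with the failing stage", {
  ann <- defaultAnnotation()
  short <- constantStack(1, nFrames = 10L, dt = 0.5)  # all frames < 4.5 h? no: 0..4.5
  cfg <- defaultConfig(); cfg$exclude_initial_h <- 6
  expect_error(quantifyReporter(short, ann, cfg), "exclude_initial")
  tiny <- constantStack(1, dims = c(10L, 10L), nFrames = 160L)
  expect_error(quantifyReporter(tiny, ann, defaultConfig()), "annotation")
})

test_that("violin plot data carries one value per SP-selected grid cell", {
  fx <- burstFixture()
  q <- quantifyReporter(fx$stack, fx$annotation)
  expect_equal(sum(q$in_sp_selection), 8 * 16)
  p <- plotReporterViolin(q)
  expect_s3_class(p, "ggplot")
})
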