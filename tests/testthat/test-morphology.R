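test_that("star and bipolar test cells classify by construction", {
  ann <- defaultAnnotation()
  star <- renderCellMask("MP", nArms = 4L, seed = 2L)
  r <- classifyPolarity(star, ann)
  expect_equal(r$morphology, "MP")
  expect_equal(r$nPrimaryNeurites, 4L)
  bp <- renderCellMask("BP", seed = 3L)
  rb <- classifyPolarity(bp, ann)
  expect_equal(rb$morphology, "BP")
  expect_equal(rb$nPrimaryNeurites, 2L)
  expect_true(rb$leadingProcess)
  # soma alone: zero neurites -> ambiguous
  soma <- matrix(0, 30, 30)
  soma[radmig:::.diskPixels(15, 15, 4, c(30, 30))] <- 1
  expect_equal(classifyPolarity(soma, ann)$morphology, "ambiguous")
  # disconnected masks are rejected
  two <- soma; two[2:3, 2:3] <- 1
  expect_error(classifyPolarity(two, ann), "disconnected")
})

test_that("classification is translation- and mirror-invariant", {
  ann <- defaultAnnotation()
  m <- renderCellMask("BP", canvas = 64L, seed = 4L)
  base <- classifyPolarity(m, ann)
  # translate by embedding at an offset
  big <- matrix(0, 100, 100)
  big[11:74, 23:86] <- m
  shifted <- classifyPolarity(big, ann)
  expect_equal(shifted$morphology, base$morphology)
  expect_equal(shifted$nPrimaryNeurites, base$nPrimaryNeurites)
  # mirror the lateral (column) axis; pial direction unchanged
  mirrored <- classifyPolarity(m[, ncol(m):1], ann)
  expect_equal(mirrored$morphology, base$morphology)
  expect_equal(mirrored$nPrimaryNeurites, base$nPrimaryNeurites)
})

test_that("50 noiseless generator cells classify at 100%", {
  ann <- defaultAnnotation()
  classes <- rep(c("MP", "BP"), 25)
  arms <- rep(3:5, length.out = 50)
  got <- vapply(1:50, function(i) {
    m <- renderCellMask(classes[i], nArms = arms[i], seed = i)
    classifyPolarity(m, ann)$morphology
  }, character(1))
  expect_identical(got, classes)
})

test_that("MP/BP composition fractions are normalized and recover a programmed decline", {
  rec <- function(mp, bp, amb = 0) {
    data.frame(morphology = c(rep("MP", mp), rep("BP", bp),
                              rep("ambiguous", amb)))
  }
  comp <- mpBpComposition(rec(6, 4), rec(2, 8, 1))
  expect_equal(comp$frac_mp, c(0.6, 0.2))
  expect_equal(comp$frac_mp + comp$frac_bp, c(1, 1))
  expect_equal(comp$n_ambiguous, c(0L, 1L))
  expect_error(mpBpComposition(rec(0, 0, 3), rec(1, 1)), "ambiguous")
  # programmed 80% -> 20% decline recovered from rendered frames
  p <- compositionFixtureParams()
  mm <- generateMigrationMovie(p)
  ann <- LayerAnnotation(1, 200, 100)
  c0 <- classifyFrame(frames(mm$stack)[, , 1], ann, threshold = 20)
  c1 <- classifyFrame(frames(mm$stack)[, , 21], ann, threshold = 20)
  comp2 <- mpBpComposition(c0, c1)
  truth <- mm$truth$tracks
  tf0 <- mean(truth$morphology[truth$frame == 1] == "MP")
  tf1 <- mean(truth$morphology[truth$frame == 21] == "MP")
  expect_equal(tf0, 0.8)
  expect_equal(tf1, 0.2)
  expect_lt(abs(comp2$frac_mp[1] - tf0), 0.10)
  expect_lt(abs(comp2$frac_mp[2] - tf1), 0.10)
})

test_that("bin assignment follows the half-open pial-first convention", {
  ann <- LayerAnnotation(0, 100, 50)
  expect_equal(as.integer(assignBins(10, ann, 5L)), 1L)
  # a cell exactly on the first interior boundary belongs to the next bin
  expect_equal(as.integer(assignBins(20, ann, 5L)), 2L)
  # the ventricular boundary itself closes the last bin
  expect_equal(as.integer(assignBins(100, ann, 5L)), 5L)
  # out-of-span cells are NA and counted
  b <- assignBins(c(-5, 50, 120), ann, 5L)
  expect_true(is.na(b[1]) && is.na(b[3]))
  expect_equal(attr(b, "n_out_of_span"), 2L)
  expect_error(assignBins(10, ann, 1L), "nBins")
  # flipped orientation: BIN 1 still pial-most
  annF <- LayerAnnotation(100, 0, 50)
  expect_equal(as.integer(assignBins(95, annF, 5L)), 1L)
})

test_that("bin assignment matches a brute-force oracle and reflects", {
  ann <- LayerAnnotation(0, 100, 50)
  nb <- 5L
  rows <- withr::with_seed(10L, runif(1000, -10, 110))
  got <- as.integer(assignBins(rows, ann, nb))
  edges <- seq(0, 100, length.out = nb + 1)
  oracle <- vapply(rows, function(r) {
    if (r < 0 || r > 100) return(NA_integer_)
    for (k in seq_len(nb)) {
      hi <- edges[k + 1]
      if (r >= edges[k] && (r < hi || (k == nb && r <= hi))) return(k)
    }
    NA_integer_
  }, integer(1))
  expect_identical(got, oracle)
  # reflection about mid-span maps BIN k -> BIN n+1-k (off boundaries)
  inSpan <- rows[rows > 0 & rows < 100 & abs(rows %% 20) > 1e-6]
  b1 <- as.integer(assignBins(inSpan, ann, nb))
  b2 <- as.integer(assignBins(100 - inSpan, ann, nb))
  expect_equal(b2, nb + 1L - b1)
})

test_that("zone assignment and zone signal read the right pixels", {
  ann <- defaultAnnotation()
  band <- c(60, 90)
  # uniform signal: every cell reads the constant
  s <- constantStack(100, dims = c(140L, 160L), nFrames = 3L)
  cells <- data.frame(row = c(20, 75, 120), col = c(30, 30, 30),
                      frame = c(1L, 2L, 3L))
  z <- zoneSignal(cells, s, ann, band)
  expect_equal(z$zone, c("above_SP", "in_SP", "below_SP"))
  expect_equal(z$zone_signal, rep(100, 3))
  # signal painted only inside the SP band separates zones with no overlap
  arr <- array(0, c(140, 160, 1))
  arr[60:90, , 1] <- 50
  sp <- ImageStack(arr, 0.5, 2)
  cells2 <- data.frame(row = c(rep(75, 5), rep(110, 5)),
                       col = seq(20, 100, 20))
  z2 <- zoneSignal(cells2, sp, ann, band)
  expect_true(min(z2$zone_signal[z2$zone == "in_SP"]) >
                max(z2$zone_signal[z2$zone == "below_SP"]))
  # zone for 200 random centroids matches direct interval comparison
  rows <- withr::with_seed(11L, runif(200, 1, 140))
  zr <- zoneSignal(data.frame(row = rows, col = rep(10, 200)), s, ann, band)
  oracle <- ifelse(rows >= 60 & rows <= 90, "in_SP",
                   ifelse(rows < 60, "above_SP", "below_SP"))
  expect_identical(zr$zone, oracle)
  # frame out of range errors
  expect_error(zoneSignal(data.frame(row = 10, col = 10, frame = 9L),
                          s, ann, band), "out of range")
})
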