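test_that("rotation is an exact isometry", {
  expect_equal(rotatePoints(c(1, 0), 90), matrix(c(0, 1), 1), tolerance = 1e-9)
  expect_equal(rotatePoints(c(3, 7), 123, center = c(3, 7)),
               matrix(c(3, 7), 1), tolerance = 1e-9)
  set.seed(10)
  pts <- matrix(rnorm(200), 100, 2)
  rot <- rotatePoints(pts, 37.3, center = c(1, -2))
  expect_lt(max(abs(dist(pts) - dist(rot))), 1e-9)
})

test_that("MER length matches rectangles, discs and the fine-grid oracle", {
  rect <- as.matrix(expand.grid(row = 1:10, col = 1:30))
  r <- merLength(rect)
  expect_equal(r$length, 30)
  expect_equal(r$width, 10)
  expect_equal(r$angle, 0)
  # the same rectangle rotated 45 degrees and re-rasterized
  rot <- unique(round(rotatePoints(rect, 45, c(5, 15))))
  expect_lt(abs(merLength(rot)$length - bruteMer(rot)), 1)
  expect_lt(abs(merLength(rot)$length - 30), 2)
  # disc of radius r: length within [2r - 1, 2r + 1]
  disc <- traceBoundary(makeGrainMask(grainSpec(40, 40, 0, 12, 12,
                                                shapeExponent = 2),
                                      c(80, 80)))@points
  expect_gte(merLength(disc)$length, 23)
  expect_lte(merLength(disc)$length, 25)
  # degenerate single point
  expect_equal(merLength(matrix(c(4, 4), 1))$length, 1)
})

test_that("grid MER brackets the rotating-calipers exact solution", {
  set.seed(11)
  for (i in 1:10) {
    len <- runif(1, 50, 100); asp <- runif(1, 1.8, 3.4)
    ct <- traceBoundary(makeGrainMask(
      grainSpec(120, 120, runif(1, 0, 180), len / 2, len / 2 / asp, 2.5),
      c(240, 240)))@points
    g <- merLength(ct, angleStep = 3)$length
    e <- merLength(ct, method = "exact")$length
    cosBound <- 1 / cos(1.5 * pi / 180)
    expect_gte(g, e * cos(1.5 * pi / 180) - 1)
    expect_lte(g, e * cosBound + 1)
    # finer grids never increase the minimum-area estimate
    g1 <- merLength(ct, angleStep = 1)$length
    expect_lte(merLength(ct, angleStep = 1)$width * g1,
               merLength(ct, angleStep = 3)$width * g + 1e-9)
  }
})

test_that("MED equals brute force and dominates MER on kernels", {
  expect_equal(medLength(rbind(c(0, 0), c(3, 4))), 5)
  rect <- as.matrix(expand.grid(row = 1:10, col = 1:30))
  expect_equal(medLength(rect), sqrt(29^2 + 9^2))
  expect_gt(medLength(rect), merLength(rect)$length)
  set.seed(12)
  for (i in 1:20) {
    ct <- matrix(runif(60, 0, 50), ncol = 2)
    expect_equal(medLength(ct), bruteMed(ct))
  }
  # elongated kernel contours: theoretical (diagonal) length >= MER length
  # up to the 1-px difference between the extent (max - min + 1) and the
  # point-distance conventions
  for (i in 1:5) {
    len <- runif(1, 60, 100); asp <- runif(1, 2, 3.4)
    ct <- traceBoundary(makeGrainMask(
      grainSpec(120, 120, runif(1, 0, 180), len / 2, len / 2 / asp, 2.5),
      c(240, 240)))@points
    expect_gte(medLength(ct), merLength(ct)$length - 1)
  }
  expect_error(medLength(matrix(c(1, 1), 1)),
               class = "hry_degenerate_contour")
})

test_that("CR sweeps through the major axis and stays above MER", {
  rect <- as.matrix(expand.grid(row = 1:10, col = 1:30))
  expect_gte(crLength(rect), 30)
  disc <- traceBoundary(makeGrainMask(grainSpec(40, 40, 0, 12, 12,
                                                shapeExponent = 2),
                                      c(80, 80)))@points
  expect_gte(crLength(disc), 23)
  expect_lte(crLength(disc), 25)
  set.seed(13)
  for (i in 1:8) {
    len <- runif(1, 50, 100); asp <- runif(1, 1.8, 3.4)
    ct <- traceBoundary(makeGrainMask(
      grainSpec(120, 120, runif(1, 0, 180), len / 2, len / 2 / asp, 2.5),
      c(240, 240)))@points
    expect_gte(crLength(ct), merLength(ct)$length - 1)
  }
  expect_error(crLength(matrix(c(1, 1), 1)),
               class = "hry_degenerate_contour")
})

test_that("the three-quarters rule is boundary inclusive", {
  expect_true(classifyHead(7, 7))
  expect_true(classifyHead(0.75 * 7, 7))
  expect_false(classifyHead(0.5 * 7, 7))
  expect_equal(classifyHead(c(5.25, 5.2499, 7), 7), c(TRUE, FALSE, TRUE))
  expect_error(classifyHead(-1, 7), class = "hry_bad_length")
  expect_error(classifyHead(5, 0), class = "hry_bad_length")
})

test_that("reference length averages the measured sample", {
  expect_equal(referenceLength(rep(7, 10)), 7)
  expect_equal(referenceLength(c(6.8, 6.9, 7.0, 7.1, 7.2,
                                 6.8, 6.9, 7.1, 7.2, 7.0)), 7)
  expect_warning(r <- referenceLength(c(7, 7.2)), class = "hry_small_reference")
  expect_equal(r, 7.1)
  expect_error(referenceLength(numeric(0)), class = "hry_bad_length")
  expect_error(referenceLength(c(7, -1, 7, 7, 7, 7, 7, 7, 7, 7)),
               class = "hry_bad_length")
})

test_that("head rice yield is the exact area ratio", {
  r <- headRiceYield(data.frame(area = c(7500, 2500), isHead = c(TRUE, FALSE)))
  expect_equal(hry(r), 0.75)
  expect_equal(r@Shr, 7500)
  expect_equal(r@Stotal, 10000)
  allHead <- headRiceYield(data.frame(area = c(10, 20), isHead = c(TRUE, TRUE)))
  expect_equal(hry(allHead), 1)
  expect_error(headRiceYield(data.frame(area = numeric(), isHead = logical())),
               class = "hry_empty_foreground")
  expect_error(headRiceYield(data.frame(area = c(5, 0), isHead = c(TRUE, TRUE))),
               class = "hry_bad_length")
})

test_that("HRY is invariant under scene transposition", {
  sc <- makeScene(30, seed = 14)
  cfg <- hryConfig(scaleMmPerPx = 1, referenceLengthMm = refLength(sc))
  mask <- preprocessImage(sceneImage(sc))
  r1 <- suppressWarnings(runMask(mask, cfg))
  r2 <- suppressWarnings(runMask(t(mask), cfg))
  expect_equal(nrow(perGrain(r1)), nrow(perGrain(r2)))
  expect_lte(abs(hry(r1) - hry(r2)), 0.005)
})
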