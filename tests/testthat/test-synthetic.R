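test_that("superellipse rasterization matches analytic geometry", {
  # circle: area within 5% of pi r^2
  for (r in c(10, 15, 24)) {
    m <- makeGrainMask(grainSpec(60, 60, 0, r, r, shapeExponent = 2),
                       c(120, 120))
    expect_lt(abs(sum(m) - pi * r^2) / (pi * r^2), 0.05)
  }
  # truncation to half length: MER length ~ semi-major axis
  m <- makeGrainMask(grainSpec(60, 60, 30, 40, 15, lengthFraction = 0.5),
                     c(120, 120))
  len <- merLength(traceBoundary(m)@points)$length
  expect_lt(abs(len - bruteMer(traceBoundary(m)@points)), 1 + 1e-9)
  expect_lt(abs(len - 40), 2)
  # orientation 0 and 90 give transposed masks
  m0 <- makeGrainMask(grainSpec(60, 60, 0, 30, 12), c(120, 120))
  m90 <- makeGrainMask(grainSpec(60, 60, 90, 30, 12), c(120, 120))
  expect_lt(abs(sum(m0) - sum(m90)) / sum(m0), 0.02)
  expect_identical(m0, t(m90))
})

test_that("invalid kernel specs are rejected", {
  expect_error(grainSpec(10, 10, 0, 5, 8), class = "hry_bad_spec")
  expect_error(grainSpec(10, 10, 0, 5, 2, lengthFraction = 0),
               class = "hry_bad_spec")
  expect_error(makeGrainMask(grainSpec(5, 5, 0, 20, 8), c(40, 40)),
               class = "hry_spec_outside")
})

test_that("singleton scenes have one component per kernel", {
  sc <- makeScene(100, clusterSizeWeights = c(1, 0, 0, 0, 0), seed = 11)
  expect_equal(truthCount(sc), 100)
  expect_equal(max(labelComponents(truthLabels(sc) > 0)), 100)
  expect_equal(nrow(sceneContacts(sc)), 0)
})

test_that("scene truth bookkeeping is exact and deterministic", {
  sc <- makeScene(25, seed = 5)
  expect_equal(truthTotalArea(sc), sum(truthLabels(sc) > 0))
  expect_lte(truthHeadArea(sc), truthTotalArea(sc))
  expect_equal(truthCount(sc), length(setdiff(unique(as.vector(truthLabels(sc))), 0L)))
  # every labeled region is 8-connected: per-grain pixel sets form one
  # component each (allowing that contact pixels belong to the earlier grain)
  ts <- truthSpecs(sc)
  for (g in sample(ts$grain, 5)) {
    expect_equal(max(labelComponents(truthLabels(sc) == g)), 1)
  }
  sc2 <- makeScene(25, seed = 5)
  expect_identical(sceneImage(sc), sceneImage(sc2))
  expect_identical(truthLabels(sc), truthLabels(sc2))
  sc3 <- makeScene(25, seed = 6)
  expect_false(identical(sceneImage(sc), sceneImage(sc3)))
})

test_that("broken fraction follows its binomial law", {
  frac <- unlist(lapply(1:2, function(i) {
    sc <- makeScene(250, brokenFraction = 0.2, seed = 20 + i)
    truthSpecs(sc)$broken
  }))
  n <- length(frac)
  ci <- 0.2 + c(-1, 1) * qnorm(0.995) * sqrt(0.2 * 0.8 / n)
  expect_gte(mean(frac), ci[1])
  expect_lte(mean(frac), ci[2])
})

test_that("contact overlap stays in the shallow-touch regime", {
  sc <- makeScene(60, clusterSizeWeights = c(0, 0.4, 0.3, 0.2, 0.1), seed = 31)
  ct <- sceneContacts(sc)
  expect_gt(nrow(ct), 20)
  expect_true(all(ct$overlapPx >= 3 & ct$overlapPx <= 150))
  # touching clusters are connected: component count = cluster count
  expect_equal(max(labelComponents(truthLabels(sc) > 0)),
               length(unique(truthSpecs(sc)$cluster)))
})

test_that("impossible densities raise a structured error", {
  expect_error(
    makeScene(200, seed = 1, canvasShape = c(700, 840)),
    class = "hry_density")
})

test_that("scenes round-trip through PNG + JSON export", {
  sc <- makeScene(8, seed = 3, noiseSpeckCount = 5)
  d <- withr::local_tempdir()
  paths <- writeScene(sc, d, "s1")
  expect_true(all(file.exists(paths)))
  lab <- readLabelsPNG(paths[["labels"]])
  expect_identical(lab, truthLabels(sc))
  img <- readGrainImage(paths[["image"]])
  expect_lt(max(abs(img - sceneImage(sc))), 1.01)  # 8-bit quantization
  side <- jsonlite::read_json(paths[["sidecar"]])
  expect_equal(side$truthTotalArea, truthTotalArea(sc))
})
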