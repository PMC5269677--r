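test_that("boundary tracing is closed, clockwise, and starts at the minimum", {
  # 3x5 solid rectangle: 12 perimeter pixels
  m <- rectMask(c(7, 9), 2, 4, 2, 6)
  b <- traceBoundary(m)
  p <- boundaryPoints(b)
  expect_equal(nrow(p), 12)
  expect_equal(unname(p[1, ]), c(2, 2))
  expect_false(anyDuplicated(p) > 0)
  # single pixel
  iso <- matrix(FALSE, 5, 5); iso[3, 3] <- TRUE
  expect_equal(nrow(boundaryPoints(traceBoundary(iso))), 1)
  # rasterized ellipse: closed, clockwise under (row, col) shoelace, min start
  em <- makeGrainMask(grainSpec(40, 40, 25, 20, 9), c(80, 80))
  ep <- boundaryPoints(traceBoundary(em))
  sa <- 0.5 * sum(ep[, 1] * c(ep[-1, 2], ep[1, 2]) -
                    c(ep[-1, 1], ep[1, 1]) * ep[, 2])
  expect_lt(sa, 0)
  idx <- which(em, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  expect_equal(unname(ep[1, ]), unname(idx[ord[1], ]))
  expect_lte(max(abs(ep[1, ] - ep[nrow(ep), ])), 1)
  # absent label errors
  expect_error(traceBoundary(matrix(FALSE, 5, 5)), class = "hry_no_component")
})

test_that("template size follows the 300:1 image-scale rule", {
  expect_equal(templateSizeForImage(c(2500, 3000)), 9L)
  expect_equal(templateSizeForImage(c(900, 900)), 3L)
  expect_equal(templateSizeForImage(c(100, 100)), 3L)
  expect_equal(templateSizeForImage(c(1250, 1500)), 5L)
})

test_that("ECMP at canonical geometries matches exhaustive counting", {
  edge <- matrix(FALSE, 40, 40); edge[, 1:20] <- TRUE
  expect_equal(ecmpAt(edge, c(20, 20), 9L), 45 / 81)
  convex <- matrix(FALSE, 40, 40); convex[20:40, 1:20] <- TRUE
  expect_equal(ecmpAt(convex, c(20, 20), 9L), 25 / 81)
  reflex <- matrix(TRUE, 40, 40); reflex[1:19, 21:40] <- FALSE
  expect_equal(ecmpAt(reflex, c(20, 20), 9L), 65 / 81)
  solid <- matrix(TRUE, 40, 40)
  expect_equal(ecmpAt(solid, c(20, 20), 9L), 1)
  expect_equal(ecmpAt(matrix(FALSE, 40, 40), c(20, 20), 9L), 0)
  # random cases incl. borders, against the double-loop oracle
  set.seed(1)
  m <- matrix(runif(50 * 50) < 0.5, 50, 50)
  for (i in 1:50) {
    ctr <- c(sample(50, 1), sample(50, 1))
    ts <- sample(c(3L, 5L, 9L), 1)
    expect_equal(ecmpAt(m, ctr, ts), bruteEcmp(m, ctr, ts))
  }
})

test_that("ECMP is invariant under transposition and 90-degree rotation", {
  set.seed(2)
  m <- matrix(runif(40 * 40) < 0.5, 40, 40)
  for (i in 1:20) {
    ctr <- c(sample(10:30, 1), sample(10:30, 1))
    expect_equal(ecmpAt(m, ctr, 9L), ecmpAt(t(m), rev(ctr), 9L))
    r90 <- t(m)[, nrow(m):1]   # rotate 90 degrees clockwise
    expect_equal(ecmpAt(m, ctr, 9L),
                 ecmpAt(r90, c(ctr[2], nrow(m) + 1 - ctr[1]), 9L))
  }
})

test_that("profiles are flat on circles and peaked at contact necks", {
  disc <- makeGrainMask(grainSpec(100, 100, 0, 60, 60, shapeExponent = 2),
                        c(200, 200))
  p <- ecmpProfile(disc, traceBoundary(disc), 9L)
  expect_equal(length(ecmpValues(p)), nrow(boundaryPoints(traceBoundary(disc))))
  expect_lte(diff(range(ecmpValues(p))), 0.15)
  expect_equal(mean(ecmpValues(p)), 0.55, tolerance = 0.05)
  # two touching kernels: exactly two peaks above 0.7 near the neck
  fx <- chainFixture(2, seed = 3)
  prof <- detectConcavePoints(fx$mask, traceBoundary(fx$mask), 9L, a = 3)
  idx <- concavePoints(prof)
  expect_equal(length(idx), 2)
  expect_true(all(ecmpValues(prof)[idx] > 0.7))
})

test_that("lambda reconstructs the printed threshold magnitude", {
  # profile engineered to E(k) = 0.48, sd = 0.08 -> lambda 0.72 with a = 3
  z <- rep(c(-1, 1), 50)
  k <- 0.48 + 0.08 * z / sd(z)
  b <- traceBoundary(rectMask(c(30, 30), 2, 28, 2, 26))  # perimeter 100
  stopifnot(nrow(boundaryPoints(b)) == 100)
  prof <- new("EcmpProfile", k = k, boundary = b, templateSize = 9L,
              lambda = NA_real_, a = NA_real_, concaveIndices = integer())
  expect_equal(lambda(computeLambda(prof, 3)), 0.72, tolerance = 1e-12)
  # constant profile: lambda = E(k); a = 0: lambda = E(k)
  kc <- rep(0.5, 100)
  profc <- new("EcmpProfile", k = kc, boundary = b, templateSize = 9L,
               lambda = NA_real_, a = NA_real_, concaveIndices = integer())
  expect_equal(lambda(computeLambda(profc, 3)), 0.5)
  expect_equal(lambda(computeLambda(prof, 0)), 0.48)
  onePx <- matrix(FALSE, 3, 3); onePx[2, 2] <- TRUE
  expect_error(computeLambda(new("EcmpProfile", k = 0.5,
                                 boundary = traceBoundary(onePx),
                                 templateSize = 9L, lambda = NA_real_,
                                 a = NA_real_, concaveIndices = integer()), 3),
               class = "hry_short_profile")
})

test_that("concave point counts follow the contact structure", {
  # isolated convex kernels: none (random geometries, both regimes)
  set.seed(4)
  for (i in 1:20) {
    len <- runif(1, 64, 104); asp <- runif(1, 1.8, 3.4)
    m <- smoothEdges(makeGrainMask(
      grainSpec(150, 150, runif(1, 0, 180), len / 2, len / 2 / asp, 2.5),
      c(300, 300)))
    prof <- detectConcavePoints(m, traceBoundary(m), 9L,
                                a = if (asp < 2.5) 3 else 2)
    expect_length(concavePoints(prof), 0)
  }
  # a three-kernel chain: 4 concave points, one per neck side
  fx <- chainFixture(3, seed = 5)
  prof <- detectConcavePoints(fx$mask, traceBoundary(fx$mask), 9L, a = fx$a)
  expect_equal(length(concavePoints(prof)), 4)
  # lambda must be computed first
  p0 <- ecmpProfile(fx$mask, traceBoundary(fx$mask), 9L)
  expect_error(findConcavePoints(p0), class = "hry_no_lambda")
  # constant profile finds nothing
  b <- traceBoundary(rectMask(c(20, 20), 3, 16, 4, 15))
  pc <- computeLambda(new("EcmpProfile",
                          k = rep(0.5, nrow(boundaryPoints(b))), boundary = b,
                          templateSize = 9L, lambda = NA_real_,
                          a = NA_real_, concaveIndices = integer()), 3)
  expect_length(findConcavePoints(pc), 0)
})

test_that("detected concave points localize at true contact necks", {
  for (seed in 1:3) {
    fx <- chainFixture(2, variety = if (seed %% 2) "japonica" else "indica",
                       seed = 30 + seed)
    prof <- detectConcavePoints(fx$mask, traceBoundary(fx$mask), 9L, a = fx$a)
    idx <- concavePoints(prof)
    expect_equal(length(idx), 2)
    pts <- boundaryPoints(prof)[idx, , drop = FALSE]
    necks <- rbind(
      as.matrix(fx$contacts[, c("neck1Row", "neck1Col")]),
      unname(as.matrix(fx$contacts[, c("neck2Row", "neck2Col")])))
    for (j in 1:2) {
      d <- sqrt((necks[, 1] - pts[j, 1])^2 + (necks[, 2] - pts[j, 2])^2)
      expect_lte(min(d), 5)
    }
  }
})
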