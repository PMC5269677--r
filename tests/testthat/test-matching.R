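# reflex-corner fixture: a large square with one quadrant removed;
# the inner corner is the concave point
reflexCornerFixture <- function() {
  m <- matrix(TRUE, 60, 60)
  m[1:29, 31:60] <- FALSE
  m
}

test_that("crossover points sit on the template perimeter", {
  m <- reflexCornerFixture()
  b <- traceBoundary(m)
  corner <- which(b@points[, 1] == 30 & b@points[, 2] == 31)
  cp <- crossoverPoints(m, b, corner, 9L)
  expect_equal(max(abs(cp$M - cp$A)), 4)      # Chebyshev (9-1)/2
  expect_equal(max(abs(cp$N - cp$A)), 4)
  expect_false(all(cp$M == cp$N))
  # the two crossovers lie one on each incident straight edge
  onH <- function(p) p[1] == 30 && p[2] >= 31   # horizontal edge, row 30
  onV <- function(p) p[2] == 30 && p[1] <= 29   # vertical edge, col 30
  expect_true((onH(cp$M) && onV(cp$N)) || (onV(cp$M) && onH(cp$N)))
  # symmetric two-kernel neck: |AM| and |AN| agree within a pixel
  m2 <- symmetricNeckFixture()
  prof <- detectConcavePoints(m2, traceBoundary(m2), 9L, a = 3)
  expect_equal(length(concavePoints(prof)), 2)
  for (t in concavePoints(prof)) {
    cp2 <- crossoverPoints(m2, prof@boundary, t, 9L)
    dAM <- sqrt(sum((cp2$M - cp2$A)^2))
    dAN <- sqrt(sum((cp2$N - cp2$A)^2))
    expect_lte(abs(dAM - dAN), 1.5)
  }
  # boundary shorter than the walk errors
  tiny <- matrix(FALSE, 8, 8); tiny[4:5, 4:5] <- TRUE
  bt <- traceBoundary(tiny)
  expect_error(crossoverPoints(tiny, bt, 1L, 9L),
               class = "hry_small_component")
})

test_that("the admissible wedge opens across the apex into the kernel", {
  A <- c(10, 10); M <- c(6, 10); N <- c(10, 6)  # crossovers up and left
  w <- admissibleRegion(list(A = A, M = M, N = N, inward = c(1, 1) / sqrt(2)))
  expect_true(w(c(14, 10)))    # on the ray opposite AM
  expect_true(w(c(10, 14)))    # on the ray opposite AN
  expect_true(w(c(14, 14)))    # inside the wedge
  expect_false(w(M))           # crossover itself: wrong side of the apex
  expect_false(w(c(6, 6)))     # behind the apex
  # degenerate collinear crossovers: half-plane toward the foreground
  wd <- admissibleRegion(list(A = A, M = c(10, 6), N = c(10, 14),
                              inward = c(1, 0)))
  expect_true(wd(c(14, 10)))
  expect_false(wd(c(6, 10)))
  # realistic neck: each concave point admits its opposite, not the
  # convex flanks
  m <- symmetricNeckFixture()
  prof <- detectConcavePoints(m, traceBoundary(m), 9L, a = 3)
  tab <- concavePointTable(m, prof, 1L)
  expect_equal(nrow(tab), 2)
  w1 <- admissibleRegion(list(A = c(tab$row[1], tab$col[1]),
                              M = c(tab$Mrow[1], tab$Mcol[1]),
                              N = c(tab$Nrow[1], tab$Ncol[1]),
                              inward = c(tab$inwardRow[1], tab$inwardCol[1])))
  expect_true(w1(c(tab$row[2], tab$col[2])))
  flank <- boundaryPoints(prof)[round(nrow(boundaryPoints(prof)) * 0.4), ]
  expect_false(w1(flank))
})

test_that("constrained matching pairs the true necks", {
  expect_equal(nrow(matchConcavePoints(NULL)), 0)
  # two-kernel cluster: one pair
  m <- symmetricNeckFixture()
  prof <- detectConcavePoints(m, traceBoundary(m), 9L, a = 3)
  tab <- concavePointTable(m, prof, 1L)
  prs <- matchConcavePoints(tab)
  expect_equal(nrow(prs), 1)
  # three-kernel chain, 4 points: of the 3 perfect matchings only the
  # truth pairing satisfies the wedge predicate for both pairs, and the
  # greedy matcher finds exactly it
  fx <- chainFixture(3, seed = 5)
  prof3 <- detectConcavePoints(fx$mask, traceBoundary(fx$mask), 9L, a = fx$a)
  tab3 <- concavePointTable(fx$mask, prof3, 1L)
  expect_equal(nrow(tab3), 4)
  admissible <- function(i, j) {
    w <- admissibleRegion(list(A = c(tab3$row[i], tab3$col[i]),
                               M = c(tab3$Mrow[i], tab3$Mcol[i]),
                               N = c(tab3$Nrow[i], tab3$Ncol[i]),
                               inward = c(tab3$inwardRow[i], tab3$inwardCol[i])))
    w(c(tab3$row[j], tab3$col[j]))
  }
  matchings <- list(rbind(c(1, 2), c(3, 4)), rbind(c(1, 3), c(2, 4)),
                    rbind(c(1, 4), c(2, 3)))
  ok <- vapply(matchings, function(mm) all(vapply(1:2, function(r)
    admissible(mm[r, 1], mm[r, 2]) && admissible(mm[r, 2], mm[r, 1]),
    logical(1))), logical(1))
  expect_equal(sum(ok), 1)
  truthPairs <- matchings[[which(ok)]]
  prs3 <- matchConcavePoints(tab3)
  expect_equal(nrow(prs3), 2)
  got <- vapply(seq_len(2), function(r)
    paste(sort(c(which(tab3$t == prs3$aT[r]), which(tab3$t == prs3$bT[r]))),
          collapse = "-"), "")
  want <- vapply(seq_len(2), function(r)
    paste(sort(truthPairs[r, ]), collapse = "-"), "")
  expect_setequal(got, want)
  # every pair joins concave points of one component; cuts cross a neck
  ct <- fx$contacts
  for (r in 1:nrow(prs3)) {
    mid <- c((prs3$aRow[r] + prs3$bRow[r]) / 2,
             (prs3$aCol[r] + prs3$bCol[r]) / 2)
    d <- sqrt((ct$contactRow - mid[1])^2 + (ct$contactCol - mid[2])^2)
    expect_lte(min(d), 6)
  }
})

test_that("cutting separates kernels and conserves pixels", {
  # no pairs: identity
  disc <- makeGrainMask(grainSpec(40, 40, 0, 15, 15), c(80, 80))
  lab <- separateGrains(disc, NULL)
  expect_equal(max(lab), 1)
  expect_identical(lab > 0, disc)
  # two-kernel cluster: two components, both near their truth areas
  s1 <- grainSpec(60, 80, 0, 36, 15)
  s2 <- grainSpec(60 + 2 * 15 - 3, 80, 0, 36, 15)
  m1 <- makeGrainMask(s1, c(160, 160)); m2 <- makeGrainMask(s2, c(160, 160))
  m <- smoothEdges(m1 | m2)
  prof <- detectConcavePoints(m, traceBoundary(m), 9L, a = 3)
  prs <- matchConcavePoints(concavePointTable(m, prof, 1L))
  lab2 <- separateGrains(m, prs)
  expect_equal(max(lab2), 2)
  areas <- tabulate(lab2)
  expect_lt(abs(areas[1] - sum(m1)) / sum(m1), 0.1)
  expect_lt(abs(areas[2] - sum(m2)) / sum(m2), 0.1)
  # pixel conservation: output areas = foreground - cleared cut pixels
  cutPx <- sum(m) - sum(lab2 > 0)
  expect_equal(sum(tabulate(lab2)), sum(m) - cutPx)
  expect_gte(cutPx, nrow(prs))           # at least the 1-px line
  # never creates foreground
  expect_true(all(!(lab2 > 0 & !m)))
  # a failed cut (pair on a convex blob) warns and keeps one component
  fake <- data.frame(component = 1, aT = 1, bT = 2,
                     aRow = 40, aCol = 26, bRow = 40, bCol = 28,
                     cutLength = 2)
  expect_warning(labF <- separateGrains(disc, fake), class = "hry_cut_failed")
  expect_equal(max(labF), 1)
})

test_that("matching commutes with mirroring", {
  fx <- chainFixture(2, seed = 9)
  m <- fx$mask
  mm <- m[, ncol(m):1]
  run <- function(msk) {
    prof <- detectConcavePoints(msk, traceBoundary(msk), 9L, a = 3)
    matchConcavePoints(concavePointTable(msk, prof, 1L))
  }
  p1 <- run(m); p2 <- run(mm)
  expect_equal(nrow(p1), nrow(p2))
  ends1 <- rbind(cbind(p1$aRow, p1$aCol), cbind(p1$bRow, p1$bCol))
  ends2 <- rbind(cbind(p2$aRow, ncol(m) + 1 - p2$aCol),
                 cbind(p2$bRow, ncol(m) + 1 - p2$bCol))
  for (i in seq_len(nrow(ends1))) {
    d <- sqrt((ends2[, 1] - ends1[i, 1])^2 + (ends2[, 2] - ends1[i, 2])^2)
    expect_lte(min(d), 1.5)
  }
})
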