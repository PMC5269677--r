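# Independent oracles and fixture builders. Oracles deliberately avoid the
# package's own code paths (own rotation math, exhaustive loops).

# exhaustive ECMP: double loop over the template window
bruteEcmp <- function(mask, center, templateSize) {
  h <- (templateSize - 1) / 2
  s <- 0
  for (dr in -h:h) for (dc in -h:h) {
    r <- center[1] + dr; c <- center[2] + dc
    if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) && mask[r, c])
      s <- s + 1
  }
  s / templateSize^2
}

# O(n^2) maximum pairwise distance
bruteMed <- function(contour) {
  best <- 0
  n <- nrow(contour)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((contour[i, ] - contour[j, ])^2))
    if (d > best) best <- d
  }
  best
}

# fine-grid minimum-enclosing-rectangle length with its own rotation math
bruteMer <- function(contour, step = 0.1) {
  ctr <- colMeans(contour)
  x <- contour[, 1] - ctr[1]; y <- contour[, 2] - ctr[2]
  best <- NULL
  for (ang in seq(0, 90 - 1e-9, by = step)) {
    th <- ang * pi / 180
    xr <- x * cos(th) - y * sin(th)
    yr <- x * sin(th) + y * cos(th)
    w <- diff(range(xr)) + 1; h <- diff(range(yr)) + 1
    if (is.null(best) || w * h < best$area)
      best <- list(area = w * h, length = max(w, h))
  }
  best$length
}

# direct 3x3 binary median by neighbourhood sorting (edge replication)
medianFilterOracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      rr <- min(max(r + dr, 1), nr); cc <- min(max(c + dc, 1), nc)
      v <- c(v, as.integer(mask[rr, cc]))
    }
    out[r, c] <- sort(v)[5] == 1L
  }
  out
}

# a solid rectangle mask
rectMask <- function(shape, r0, r1, c0, c1) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[r0:r1, c0:c1] <- TRUE
  m
}

# a chain cluster of k kernels rendered on its own canvas, with contact
# truth; uses the generator internals under a caller-fixed RNG state
chainFixture <- function(k, variety = "japonica", seed = 1) {
  profile <- varietyProfile(variety)
  m <- NULL
  withr::with_seed(seed, {
    for (rep in 1:50) {
      sp <- do.call(rbind, lapply(seq_len(k), function(i)
        riceHRY:::.sampleSpecGeometry(profile, 0, c(0.3, 0.7), NULL)))
      cl <- riceHRY:::.buildClusterChain(sp)
      if (!is.null(cl)) break
    }
    span <- 3 * max(sp$semiMajor) * k + 40
    ctr <- round(span / 2)
    m <- matrix(FALSE, span, span)
    for (j in seq_len(k)) {
      r <- cl$rasters[[j]]
      m[cbind(ctr + cl$centers[j, 1] + r$rel[, 1],
              ctr + cl$centers[j, 2] + r$rel[, 2])] <- TRUE
    }
    contacts <- cl$contacts
    for (col in c("contactRow", "neck1Row", "neck2Row"))
      contacts[[col]] <- contacts[[col]] + ctr
    for (col in c("contactCol", "neck1Col", "neck2Col"))
      contacts[[col]] <- contacts[[col]] + ctr
    list(mask = smoothEdges(m), contacts = contacts,
         a = if (identical(variety, "japonica")) 3 else 2)
  })
}

# two identical horizontal ellipses stacked vertically: a mirror-symmetric
# two-kernel neck
symmetricNeckFixture <- function() {
  s1 <- grainSpec(60, 80, 0, 36, 15)
  s2 <- grainSpec(60 + 2 * 15 - 3, 80, 0, 36, 15)
  m <- makeGrainMask(s1, c(160, 160)) | makeGrainMask(s2, c(160, 160))
  smoothEdges(m)
}
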