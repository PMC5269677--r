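#' @include AllClasses.R utils.R
NULL

#' Construct a single kernel specification
#'
#' A kernel is modelled as a superellipse (exponent \code{shapeExponent};
#' 2 gives an ellipse, ~2.5 matches the blunt-ended silhouette of milled
#' rice) whose major axis has half-length \code{semiMajor}. Broken kernels
#' are modelled by truncating the shape with a single chord perpendicular
#' to the major axis so that the remaining length is
#' \code{lengthFraction * 2 * semiMajor}; the truncated piece is recentred
#' on \code{center}. A kernel is \emph{broken} exactly when
#' \code{lengthFraction < 0.75}.
#'
#' @param centerRow,centerCol kernel centre, px (may be fractional; the
#'   generator uses integer centres).
#' @param orientation major-axis angle in degrees in [0, 180); 0 = along
#'   image columns.
#' @param semiMajor,semiMinor semi-axes in px; \code{semiMajor >=
#'   semiMinor > 0}.
#' @param shapeExponent superellipse exponent n (> 0).
#' @param lengthFraction fraction of the full kernel length retained, in
#'   (0, 1]; 1 = intact.
#' @return one-row data.frame with the spec fields plus the derived
#'   \code{broken} flag.
#' @examples
#' grainSpec(50, 50, orientation = 30, semiMajor = 20, semiMinor = 9)
#' @export
grainSpec <- function(centerRow, centerCol, orientation, semiMajor,
                      semiMinor, shapeExponent = 2.5, lengthFraction = 1) {
  if (!(semiMajor >= semiMinor && semiMinor > 0))
    .hryError("semiMajor >= semiMinor > 0 required", "hry_bad_spec")
  if (!(lengthFraction > 0 && lengthFraction <= 1))
    .hryError("lengthFraction must be in (0, 1]", "hry_bad_spec")
  if (shapeExponent <= 0)
    .hryError("shapeExponent must be > 0", "hry_bad_spec")
  data.frame(
    centerRow = centerRow, centerCol = centerCol,
    orientation = orientation %% 180,
    semiMajor = semiMajor, semiMinor = semiMinor,
    shapeExponent = shapeExponent,
    broken = lengthFraction < 0.75,
    lengthFraction = lengthFraction
  )
}

#' Variety profiles for the synthetic generator
#'
#' Two kernel-geometry regimes mirroring the two major rice subspecies:
#' japonica-like kernels are shorter and rounder (aspect ratio 1.8--2.2),
#' indica-like kernels longer and more slender (aspect 2.8--3.4). Lengths
#' are in px at the generator's working scale of 12 px/mm (a 3000 px wide
#' frame over a 250 mm belt): japonica 64--80 px (5.3--6.7 mm), indica
#' 84--104 px (7.0--8.7 mm).
#'
#' @param variety "japonica" or "indica", or a list with elements
#'   \code{lengthRange}, \code{aspectRange} (and optionally
#'   \code{shapeExponent}, \code{name}) to supply a custom profile.
#' @return list with \code{name}, \code{lengthRange} (px, full kernel),
#'   \code{aspectRange} and \code{shapeExponent}.
#' @export
varietyProfile <- function(variety = c("japonica", "indica")) {
  if (is.list(variety)) {
    variety$shapeExponent <- variety$shapeExponent %||% 2.5
    variety$name <- variety$name %||% "custom"
    stopifnot(length(variety$lengthRange) == 2L,
              length(variety$aspectRange) == 2L)
    return(variety)
  }
  switch(match.arg(variety),
    japonica = list(name = "japonica", lengthRange = c(64, 80),
                    aspectRange = c(1.8, 2.2), shapeExponent = 2.5),
    indica = list(name = "indica", lengthRange = c(84, 104),
                  aspectRange = c(2.8, 3.4), shapeExponent = 2.5)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rasterize one spec on a local grid centred on the kernel centre.
# Returns list(mask = logical matrix, dr0, dc0) where mask[1,1] is pixel
# offset (dr0, dc0) from the centre.
.rasterLocal <- function(spec) {
  a <- spec$semiMajor; b <- spec$semiMinor
  n <- spec$shapeExponent; f <- spec$lengthFraction
  R <- ceiling(a) + 1L
  off <- seq.int(-R, R)
  th <- spec$orientation * pi / 180
  dc <- matrix(off, 2L * R + 1L, 2L * R + 1L, byrow = TRUE)
  dr <- matrix(off, 2L * R + 1L, 2L * R + 1L)
  u <- dc * cos(th) + dr * sin(th)
  v <- -dc * sin(th) + dr * cos(th)
  # the retained piece of the full kernel, recentred: shift the major-axis
  # coordinate back into the original kernel frame before the inside test
  inside <- (abs(u + a * (f - 1)) / a)^n + (abs(v) / b)^n <= 1
  if (f < 1) inside <- inside & (u <= a * f)
  idx <- which(inside, arr.ind = TRUE)
  # rel: pixel offsets from the kernel centre, cached for placement math
  list(mask = inside, dr0 = -R, dc0 = -R,
       rel = cbind(idx[, 1L] - R - 1L, idx[, 2L] - R - 1L))
}

#' Rasterize one kernel specification onto a canvas
#'
#' @param spec one-row data.frame from [grainSpec()].
#' @param canvasShape integer (rows, cols).
#' @return logical matrix of shape \code{canvasShape} with the kernel's
#'   pixels TRUE.
#' @examples
#' m <- makeGrainMask(grainSpec(40, 40, 0, 15, 15, shapeExponent = 2), c(80, 80))
#' sum(m) / (pi * 15^2)  # close to 1
#' @export
makeGrainMask <- function(spec, canvasShape) {
  loc <- .rasterLocal(spec)
  idx <- which(loc$mask, arr.ind = TRUE)
  rows <- round(spec$centerRow) + loc$dr0 + idx[, 1L] - 1L
  cols <- round(spec$centerCol) + loc$dc0 + idx[, 2L] - 1L
  if (any(rows < 1L) || any(cols < 1L) ||
      any(rows > canvasShape[1L]) || any(cols > canvasShape[2L]))
    .hryError("grain extends outside the canvas", "hry_spec_outside")
  m <- matrix(FALSE, canvasShape[1L], canvasShape[2L])
  m[cbind(rows, cols)] <- TRUE
  m
}

# Sample one kernel's geometry from a profile.
.sampleSpecGeometry <- function(profile, brokenFraction, brokenLengthRange,
                                lengthFractionRange) {
  len <- stats::runif(1, profile$lengthRange[1L], profile$lengthRange[2L])
  asp <- stats::runif(1, profile$aspectRange[1L], profile$aspectRange[2L])
  lf <- if (!is.null(lengthFractionRange)) {
    stats::runif(1, lengthFractionRange[1L], lengthFractionRange[2L])
  } else if (stats::runif(1) < brokenFraction) {
    stats::runif(1, brokenLengthRange[1L], brokenLengthRange[2L])
  } else 1
  grainSpec(0, 0, stats::runif(1, 0, 180), len / 2, len / 2 / asp,
            profile$shapeExponent, lengthFraction = lf)
}

# Place grain masks of one cluster as a chain with 1-4 px contact overlap.
# Returns NULL on failure, else list(specs, masks (local rasters),
# offsets (integer centre positions relative to first grain), contacts).
.buildClusterChain <- function(specs, overlapRange = c(1L, 4L),
                               minCrossingAngle = 25) {
  k <- nrow(specs)
  rasters <- lapply(seq_len(k), function(i) .rasterLocal(specs[i, ]))
  bounds <- lapply(rasters, function(r) traceBoundary(r$mask)@points)
  centers <- matrix(0L, k, 2L)  # (row, col) of each centre, grain 1 at origin
  contacts <- NULL
  dirPrev <- stats::runif(1, 0, 360)
  if (k > 1L) for (i in 2:k) {
    placed <- FALSE
    for (try in seq_len(40L)) {
      phi <- if (i == 2L) stats::runif(1, 0, 360) else
        dirPrev + stats::runif(1, -60, 60)
      push <- sample.int(diff(overlapRange) + 1L, 1L) - 1L  # 0..3 extra px
      res <- .slideToContact(rasters[[i - 1L]], rasters[[i]],
                             centers[i - 1L, ], phi, push)
      if (is.null(res)) next
      # contacts must form sharp crevices on both sides: the two kernel
      # outlines have to cross at a substantial angle at each neck
      # endpoint, as pressed convex kernels do; near-tangential grazes
      # are re-drawn
      eps <- lapply(1:2, function(e) c(res[[paste0("neck", e, "Row")]],
                                       res[[paste0("neck", e, "Col")]]))
      angs <- vapply(eps, function(ep)
        .crossingAngle(bounds[[i - 1L]], rasters[[i - 1L]], centers[i - 1L, ],
                       bounds[[i]], rasters[[i]], res$center, ep),
        numeric(1L))
      if (any(angs < minCrossingAngle)) next
      if (!.contactReflex(rasters[[i - 1L]], centers[i - 1L, ],
                          rasters[[i]], res$center, eps)) next
      # reject contact with non-consecutive members (heavy occlusion guard)
      bad <- FALSE
      if (i > 2L) for (j in seq_len(i - 2L)) {
        if (.pixelOverlap(rasters[[j]], centers[j, ],
                          rasters[[i]], res$center) > 0L) { bad <- TRUE; break }
      }
      if (bad) next
      centers[i, ] <- res$center
      contacts <- rbind(contacts, data.frame(
        grainA = i - 1L, grainB = i,
        contactRow = res$contactRow, contactCol = res$contactCol,
        neck1Row = res$neck1Row, neck1Col = res$neck1Col,
        neck2Row = res$neck2Row, neck2Col = res$neck2Col,
        overlapPx = res$overlapPx))
      dirPrev <- phi
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  list(specs = specs, rasters = rasters, centers = centers,
       contacts = contacts)
}

# Move raster B along direction phi (degrees) from A's centre until the two
# masks first overlap, then push `push` px further. Returns centre of B and
# contact/neck coordinates (relative to A's centre), or NULL.
.slideToContact <- function(ra, rb, centerA, phi, push) {
  ux <- cos(phi * pi / 180); uy <- sin(phi * pi / 180)  # (col, row) direction
  # directional support radii: first possible contact is near their sum
  rA <- max(ra$rel[, 1L] * uy + ra$rel[, 2L] * ux)
  rB <- max(-(rb$rel[, 1L] * uy + rb$rel[, 2L] * ux))
  d <- ceiling(rA + rB + 3)
  hit <- NA
  while (d >= 0) {
    cB <- c(round(centerA[1L] + d * uy), round(centerA[2L] + d * ux))
    ov <- .pixelOverlap(ra, centerA, rb, cB)
    if (ov > 0L) { hit <- d; break }
    d <- d - 1
  }
  if (is.na(hit) || hit == 0) return(NULL)
  d <- max(hit - push, 1)
  cB <- c(round(centerA[1L] + d * uy), round(centerA[2L] + d * ux))
  ov <- .overlapPixels(ra, centerA, rb, cB)
  # at least a few shared pixels (a 1-px graze does not survive the 3x3
  # mask smoothing), at most a shallow lens (no heavy occlusion)
  if (nrow(ov) < 3L || nrow(ov) > 150L) return(NULL)
  ctr <- colMeans(ov)
  # neck endpoints: overlap extremes perpendicular to the centre line;
  # centre line direction is (uy, ux) in (row, col), perpendicular (ux, -uy)
  proj <- (ov[, 1L] - ctr[1L]) * ux - (ov[, 2L] - ctr[2L]) * uy
  p1 <- ov[which.min(proj), ]; p2 <- ov[which.max(proj), ]
  list(center = cB, contactRow = ctr[1L], contactCol = ctr[2L],
       neck1Row = p1[1L], neck1Col = p1[2L],
       neck2Row = p2[1L], neck2Col = p2[2L], overlapPx = nrow(ov))
}

# Angle (degrees, in [0, 90]) at which the outlines of two placed kernels
# cross at a neck endpoint: the angle between the local boundary tangent
# lines, estimated over +/-3 trace steps around the boundary point nearest
# the endpoint.
.crossingAngle <- function(bdA, ra, ca, bdB, rb, cb, endpoint) {
  tangent <- function(bd, r, ctr) {
    pts <- cbind(bd[, 1L] + ctr[1L] + r$dr0 - 1L,
                 bd[, 2L] + ctr[2L] + r$dc0 - 1L)
    n <- nrow(pts)
    if (n < 7L) return(NULL)
    t0 <- which.min((pts[, 1L] - endpoint[1L])^2 + (pts[, 2L] - endpoint[2L])^2)
    d <- pts[((t0 + 2L) %% n) + 1L, ] - pts[((t0 - 4L) %% n) + 1L, ]
    if (all(d == 0)) NULL else d / sqrt(sum(d^2))
  }
  dA <- tangent(bdA, ra, ca)
  dB <- tangent(bdB, rb, cb)
  if (is.null(dA) || is.null(dB)) return(90)
  acos(pmin(1, abs(sum(dA * dB)))) * 180 / pi
}

# Verify the generator's contact postcondition: each neck endpoint of a
# contact must be a sharp reflex corner of the two-kernel union as it will
# actually be rendered -- i.e. after the 3x3 edge smoothing the union
# boundary near the endpoint still covers at least the right-angle reflex
# fraction (65/81 ~ 0.80) of a 9x9 window. This guarantees every pairwise
# contact carries two concave points detectable above any adaptive
# threshold the varieties use.
.contactReflex <- function(ra, ca, rb, cb, endpoints, win = 9L, minFrac = 0.8) {
  px <- rbind(.placedPixels(ra, ca), .placedPixels(rb, cb))
  R <- 15L  # patch radius: covers smoothing (1) + window (4) + search (5)
  all(vapply(endpoints, function(ep) {
    ep <- round(ep)
    sel <- abs(px[, 1L] - ep[1L]) <= R & abs(px[, 2L] - ep[2L]) <= R
    if (!any(sel)) return(FALSE)
    patch <- matrix(FALSE, 2L * R + 1L, 2L * R + 1L)
    patch[cbind(px[sel, 1L] - ep[1L] + R + 1L,
                px[sel, 2L] - ep[2L] + R + 1L)] <- TRUE
    patch <- smoothEdges(patch)
    # union boundary pixels within 5 px of the endpoint
    idx <- which(patch, arr.ind = TRUE)
    ctr <- R + 1L
    idx <- idx[(idx[, 1L] - ctr)^2 + (idx[, 2L] - ctr)^2 <= 25, , drop = FALSE]
    if (!nrow(idx)) return(FALSE)
    edge <- !patch[cbind(idx[, 1L] - 1L, idx[, 2L])] |
      !patch[cbind(idx[, 1L] + 1L, idx[, 2L])] |
      !patch[cbind(idx[, 1L], idx[, 2L] - 1L)] |
      !patch[cbind(idx[, 1L], idx[, 2L] + 1L)]
    idx <- idx[edge, , drop = FALSE]
    if (!nrow(idx)) return(FALSE)
    max(ecmpAt(patch, idx, win)) >= minFrac
  }, logical(1L)))
}

# Absolute (row, col) pixel coordinates of a placed raster.
.placedPixels <- function(r, ctr) {
  cbind(ctr[1L] + r$rel[, 1L], ctr[2L] + r$rel[, 2L])
}

# Count overlapping pixels of two local rasters placed at given centres.
.pixelOverlap <- function(ra, ca, rb, cb) nrow(.overlapPixels(ra, ca, rb, cb))

# Coordinates (row, col) of overlapping pixels, in the frame of the centres.
.overlapPixels <- function(ra, ca, rb, cb) {
  pa <- cbind(ca[1L] + ra$rel[, 1L], ca[2L] + ra$rel[, 2L])
  # membership test of A's pixels in B's raster
  rr <- pa[, 1L] - cb[1L] - rb$dr0 + 1L
  cc <- pa[, 2L] - cb[2L] - rb$dc0 + 1L
  ok <- rr >= 1L & rr <= nrow(rb$mask) & cc >= 1L & cc <= ncol(rb$mask)
  ok[ok] <- rb$mask[cbind(rr[ok], cc[ok])]
  pa[ok, , drop = FALSE]
}

#' Generate a ground-truthed synthetic bulk-grain scene
#'
#' Emulates a top-down image of milled rice on a dark conveyor belt:
#' bright convex superellipse kernels (two variety regimes), touching
#' clusters of up to five kernels built as chains with 1--4 px contact
#' overlap, a controllable broken-kernel fraction, and small bright noise
#' specks. Clusters are separated from each other by a free margin so that
#' touching only occurs within clusters. The generator is a pure function
#' of its arguments including \code{seed}.
#'
#' @param nGrains total number of kernels (>= 1).
#' @param clusterSizeWeights probability weights for cluster sizes 1..5.
#' @param brokenFraction probability that a kernel is broken (truncated to
#'   \code{brokenLengthRange} of its full length).
#' @param variety variety profile name or list, see [varietyProfile()].
#' @param noiseSpeckCount number of bright specks (area 1--13 px).
#' @param seed integer RNG seed; identical seeds give bit-identical scenes.
#' @param canvasShape integer (rows, cols), or NULL to size the canvas so
#'   the kernel density matches a 150-grains-per-2500x3000 reference (the
#'   100--200 grains per 3000x2500 frame regime of the imaging rig).
#' @param brokenLengthRange range of \code{lengthFraction} for broken
#'   kernels.
#' @param lengthFractionRange if non-NULL, \emph{every} kernel draws its
#'   length fraction uniformly from this range (used to straddle the 3/4
#'   head/broken boundary); \code{brokenFraction} is then ignored.
#' @param maxAttempts placement attempts per cluster before giving up with
#'   a density error.
#' @return a [GrainScene-class].
#' @examples
#' sc <- makeScene(20, seed = 7)
#' sc
#' @export
makeScene <- function(nGrains,
                      clusterSizeWeights = c(0.5, 0.2, 0.15, 0.1, 0.05),
                      brokenFraction = 0.2,
                      variety = "japonica",
                      noiseSpeckCount = 20L,
                      seed = 1L,
                      canvasShape = NULL,
                      brokenLengthRange = c(0.3, 0.7),
                      lengthFractionRange = NULL,
                      maxAttempts = 400L) {
  if (nGrains < 1L) .hryError("nGrains must be >= 1", "hry_bad_spec")
  profile <- varietyProfile(variety)
  if (is.null(canvasShape)) {
    rows <- max(700L, ceiling(sqrt(nGrains * 50000 / 1.2)))
    canvasShape <- c(rows, ceiling(1.2 * rows))
  }
  .withSeed(seed, {
    # cluster size plan
    sizes <- integer()
    while (sum(sizes) < nGrains) {
      s <- sample.int(5L, 1L, prob = clusterSizeWeights)
      sizes <- c(sizes, min(s, nGrains - sum(sizes)))
    }
    labels <- matrix(0L, canvasShape[1L], canvasShape[2L])
    occupied <- matrix(FALSE, canvasShape[1L], canvasShape[2L])
    sep <- 12L
    allSpecs <- NULL
    allContacts <- NULL
    grainId <- 0L
    for (ci in seq_along(sizes)) {
      cl <- NULL
      for (att in seq_len(20L)) {
        sp <- do.call(rbind, lapply(seq_len(sizes[ci]), function(i)
          .sampleSpecGeometry(profile, brokenFraction, brokenLengthRange,
                              lengthFractionRange)))
        cl <- .buildClusterChain(sp)
        if (!is.null(cl)) break
      }
      if (is.null(cl))
        .hryError("could not assemble a touching cluster", "hry_density")
      # cluster extent relative to grain-1 centre
      lo <- c(Inf, Inf); hi <- c(-Inf, -Inf)
      for (i in seq_len(sizes[ci])) {
        r <- cl$rasters[[i]]
        lo <- pmin(lo, cl$centers[i, ] + c(r$dr0, r$dc0))
        hi <- pmax(hi, cl$centers[i, ] - c(r$dr0, r$dc0))
      }
      spanR <- hi[1L] - lo[1L] + 1L; spanC <- hi[2L] - lo[2L] + 1L
      if (canvasShape[1L] - spanR - 2L * sep < 1L ||
          canvasShape[2L] - spanC - 2L * sep < 1L)
        .hryError("canvas too small for a cluster", "hry_density")
      # cluster pixels relative to its bbox origin, and the same set
      # dilated by the inter-cluster separation margin (marked as occupied
      # once placed, so later clusters keep their distance)
      clPix <- NULL
      for (i in seq_len(sizes[ci]))
        clPix <- rbind(clPix, .placedPixels(cl$rasters[[i]],
                                            cl$centers[i, ] - lo + 1L))
      clPix <- unique(clPix)
      dil <- matrix(FALSE, spanR + 2L * sep, spanC + 2L * sep)
      dil[clPix + sep] <- TRUE
      dil <- EBImage::dilate(dil, EBImage::makeBrush(2L * sep + 1L, "box")) > 0
      dilPix <- which(dil, arr.ind = TRUE)
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        top <- sample.int(canvasShape[1L] - spanR - 2L * sep, 1L) + sep
        left <- sample.int(canvasShape[2L] - spanC - 2L * sep, 1L) + sep
        cand <- cbind(clPix[, 1L] + top - 1L, clPix[, 2L] + left - 1L)
        if (any(occupied[cand])) next
        occupied[cbind(dilPix[, 1L] + top - sep - 1L,
                       dilPix[, 2L] + left - sep - 1L)] <- TRUE
        shift <- c(top, left) - lo  # grain-1 centre in canvas coords
        for (i in seq_len(sizes[ci])) {
          grainId <- grainId + 1L
          r <- cl$rasters[[i]]
          idx <- which(r$mask, arr.ind = TRUE)
          prow <- cl$centers[i, 1L] + shift[1L] + r$dr0 + idx[, 1L] - 1L
          pcol <- cl$centers[i, 2L] + shift[2L] + r$dc0 + idx[, 2L] - 1L
          sel <- labels[cbind(prow, pcol)] == 0L
          labels[cbind(prow[sel], pcol[sel])] <- grainId
          spRow <- cl$specs[i, ]
          spRow$centerRow <- cl$centers[i, 1L] + shift[1L]
          spRow$centerCol <- cl$centers[i, 2L] + shift[2L]
          spRow$grain <- grainId
          spRow$cluster <- ci
          allSpecs <- rbind(allSpecs, spRow)
        }
        if (!is.null(cl$contacts)) {
          ct <- cl$contacts
          base <- grainId - sizes[ci]
          ct$grainA <- ct$grainA + base
          ct$grainB <- ct$grainB + base
          for (col in c("contactRow", "neck1Row", "neck2Row"))
            ct[[col]] <- ct[[col]] + shift[1L]
          for (col in c("contactCol", "neck1Col", "neck2Col"))
            ct[[col]] <- ct[[col]] + shift[2L]
          allContacts <- rbind(allContacts, ct)
        }
        placed <- TRUE
        break
      }
      if (!placed)
        .hryError("cannot place clusters: grain density too high for canvas",
                  "hry_density")
    }
    # bright noise specks on free background
    speckPix <- NULL
    if (noiseSpeckCount > 0L) for (i in seq_len(noiseSpeckCount)) {
      for (att in seq_len(200L)) {
        r0 <- sample.int(canvasShape[1L] - 12L, 1L) + 6L
        c0 <- sample.int(canvasShape[2L] - 12L, 1L) + 6L
        if (any(occupied[(r0 - 5L):(r0 + 5L), (c0 - 5L):(c0 + 5L)])) next
        rad <- sample(c(0.5, 1, 1.5, 2), 1L)
        occupied[(r0 - 5L):(r0 + 5L), (c0 - 5L):(c0 + 5L)] <- TRUE
        dd <- expand.grid(dr = -2:2, dc = -2:2)
        dd <- dd[dd$dr^2 + dd$dc^2 <= rad^2, ]
        speckPix <- rbind(speckPix, cbind(r0 + dd$dr, c0 + dd$dc))
        break
      }
    }
    # render: dark belt ~10, kernels ~200, specks ~180, Gaussian sigma 3
    img <- matrix(10 + stats::rnorm(prod(canvasShape), 0, 3),
                  canvasShape[1L], canvasShape[2L])
    fg <- labels > 0L
    img[fg] <- 200 + stats::rnorm(sum(fg), 0, 3)
    if (!is.null(speckPix))
      img[speckPix] <- 180 + stats::rnorm(nrow(speckPix), 0, 3)
    img[img < 0] <- 0; img[img > 255] <- 255
    # ground truth bookkeeping
    allSpecs <- allSpecs[order(allSpecs$grain), ]
    rownames(allSpecs) <- NULL
    refLen <- mean(profile$lengthRange)
    allSpecs$fullLengthPx <- 2 * allSpecs$semiMajor
    allSpecs$trueLengthPx <- allSpecs$lengthFraction * allSpecs$fullLengthPx
    allSpecs$isHead <- allSpecs$trueLengthPx >= 0.75 * refLen
    tab <- tabulate(labels, nbins = grainId)
    allSpecs$areaPx <- tab[allSpecs$grain]
    new("GrainScene", image = img, truthLabels = labels,
        truthSpecs = allSpecs,
        contacts = if (is.null(allContacts)) data.frame() else allContacts,
        refLengthPx = refLen, variety = profile$name,
        seed = as.integer(seed))
  })
}
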