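#' @include AllClasses.R utils.R preprocess.R
NULL

# clockwise 8-neighbour offsets starting at "up" (screen orientation,
# row index increasing downwards)
.DIRS <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
               c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
.DIRIDX <- local({
  m <- matrix(NA_integer_, 3L, 3L)
  for (i in 1:8) m[.DIRS[i, 1L] + 2L, .DIRS[i, 2L] + 2L] <- i
  m
})

#' Trace the outer boundary of one labeled component
#'
#' Moore neighbour tracing, clockwise in screen orientation, seeded at the
#' lexicographically smallest (row, then column) pixel of the component
#' and terminated by Jacob's criterion (re-entering the start pixel from
#' the same direction). Interior holes are ignored. The trace visits every
#' outer edge pixel; for simply connected blobs without 1-px appendages no
#' pixel repeats.
#'
#' @param mask logical matrix, or an integer label matrix from
#'   [labelComponents()].
#' @param componentLabel which component to trace (ignored for a logical
#'   mask containing a single component, where any TRUE pixel belongs).
#' @return a [Boundary-class].
#' @examples
#' m <- matrix(FALSE, 7, 9); m[2:4, 2:6] <- TRUE
#' nrow(boundaryPoints(traceBoundary(m)))  # 12 perimeter pixels
#' @export
traceBoundary <- function(mask, componentLabel = 1L) {
  if (is.logical(mask)) {
    comp <- mask
  } else {
    comp <- mask == componentLabel
  }
  if (!any(comp))
    .hryError("component label not present in mask", "hry_no_component")
  idx <- which(comp, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  s <- idx[ord[1L], ]
  if (nrow(idx) == 1L)
    return(new("Boundary", points = matrix(s, 1L, 2L,
                                           dimnames = list(NULL, c("row", "col"))),
               label = as.integer(componentLabel)))
  # pad by one so neighbour lookups never leave the matrix
  nr <- nrow(comp); nc <- ncol(comp)
  pm <- matrix(FALSE, nr + 2L, nc + 2L)
  pm[2:(nr + 1L), 2:(nc + 1L)] <- comp
  sPad <- s + 1L                      # padded coords
  # scan the 8 neighbours of `at` clockwise starting at backtrack dir `db`;
  # first foreground neighbour wins, new backtrack = previously scanned cell
  scanNext <- function(at, db) {
    for (step in 0:7) {
      di <- ((db - 1L + step) %% 8L) + 1L
      nb <- at + .DIRS[di, ]
      if (pm[nb[1L], nb[2L]]) {
        prevDir <- ((di - 2L) %% 8L) + 1L
        delta <- at + .DIRS[prevDir, ] - nb
        return(list(nxt = nb, db = .DIRIDX[delta[1L] + 2L, delta[2L] + 2L]))
      }
    }
    NULL
  }
  cur <- sPad
  db <- 1L                            # up: background, start is min-row
  pts <- matrix(0L, 4L * nrow(idx) + 8L, 2L)
  np <- 0L
  second <- NULL
  repeat {
    np <- np + 1L
    pts[np, ] <- cur - 1L
    mv <- scanNext(cur, db)
    if (is.null(mv)) break            # isolated pixel
    if (is.null(second)) second <- mv$nxt
    if (all(mv$nxt == sPad)) {
      # back at the start: closed iff the move after it repeats the trace
      la <- scanNext(sPad, mv$db)
      if (!is.null(la) && all(la$nxt == second)) break
    }
    cur <- mv$nxt
    db <- mv$db
    if (np >= nrow(pts)) break        # safety cap
  }
  colnames(pts) <- c("row", "col")
  new("Boundary", points = pts[seq_len(np), , drop = FALSE],
      label = as.integer(componentLabel))
}

#' ECMP template size for an image
#'
#' The square concavity template scales with the image at roughly 300:1
#' (a 3000x2500 px image uses a 9x9 template), clamped to at least 3x3 and
#' rounded down to odd.
#'
#' @param imageShape integer (rows, cols).
#' @return odd integer template side.
#' @examples
#' templateSizeForImage(c(2500, 3000))  # 9
#' @export
templateSizeForImage <- function(imageShape) {
  t <- round(max(imageShape) / 300)
  if (t %% 2 == 0) t <- t - 1
  as.integer(max(3, t))
}

#' Edge center mode proportion at a pixel
#'
#' The fraction of foreground pixels inside the square template centred on
#' \code{center}: PF / SM with SM = templateSize^2. Windows overhanging
#' the image edge are padded with background (biasing frame-edge kernels
#' toward "convex", which avoids false cuts). A straight edge scores about
#' 0.5, a 90-degree convex corner about 25/81 (9x9 template), a reflex
#' (concave) corner about 65/81 -- concave boundary points score HIGH.
#'
#' @param mask logical matrix.
#' @param center integer (row, col), or an n x 2 matrix of centres.
#' @param templateSize odd integer >= 3.
#' @return numeric ECMP value(s) in [0, 1].
#' @export
ecmpAt <- function(mask, center, templateSize) {
  stopifnot(templateSize >= 3L, templateSize %% 2L == 1L)
  if (is.null(dim(center))) center <- matrix(center, 1L, 2L)
  h <- (templateSize - 1L) %/% 2L
  ii <- .integralImage(mask)
  .windowSum(ii, center[, 1L] - h, center[, 1L] + h,
             center[, 2L] - h, center[, 2L] + h) / templateSize^2
}

#' ECMP profile along a component boundary
#'
#' Samples the ECMP concavity score k(t) at every boundary pixel in
#' clockwise order from the trace start, producing the signal whose peaks
#' above the adaptive threshold lambda mark concave points.
#'
#' @param mask logical matrix the boundary was traced on.
#' @param boundary a [Boundary-class].
#' @param templateSize odd integer; NULL = [templateSizeForImage()] of the
#'   mask shape.
#' @return an [EcmpProfile-class] with \code{k} filled and \code{lambda}
#'   unset.
#' @export
ecmpProfile <- function(mask, boundary, templateSize = NULL) {
  if (is.null(templateSize)) templateSize <- templateSizeForImage(dim(mask))
  stopifnot(templateSize >= 3L, templateSize %% 2L == 1L)
  pts <- boundary@points
  h <- (templateSize - 1L) %/% 2L
  # window sums only need the mask near the boundary: work on a padded bbox
  r0 <- max(1L, min(pts[, 1L]) - templateSize)
  r1 <- min(nrow(mask), max(pts[, 1L]) + templateSize)
  c0 <- max(1L, min(pts[, 2L]) - templateSize)
  c1 <- min(ncol(mask), max(pts[, 2L]) + templateSize)
  ii <- .integralImage(mask[r0:r1, c0:c1, drop = FALSE])
  rr <- pts[, 1L] - r0 + 1L
  cc <- pts[, 2L] - c0 + 1L
  k <- .windowSum(ii, rr - h, rr + h, cc - h, cc + h) / templateSize^2
  new("EcmpProfile", k = as.numeric(k), boundary = boundary,
      templateSize = as.integer(templateSize),
      lambda = NA_real_, a = NA_real_, concaveIndices = integer())
}

#' Adaptive concave-point threshold lambda
#'
#' lambda = E(k) + a * sd(k), where E(k) and sd(k) are the mean and sample
#' standard deviation of the profile over its N boundary samples and a is
#' the variety coefficient (about 3 for the shorter, rounder japonica
#' kernels and 2 for the longer indica kernels -- smaller a for longer
#' varieties). The threshold is clipped to at most 1; a constant profile
#' gives lambda = E(k), and downstream detection then finds no concave
#' points.
#'
#' @param profile an [EcmpProfile-class].
#' @param a positive variety coefficient.
#' @return the profile with \code{lambda} (and \code{a}) set; read the
#'   value with [lambda()].
#' @examples
#' m <- matrix(FALSE, 40, 40); m[10:30, 10:30] <- TRUE
#' p <- ecmpProfile(m, traceBoundary(m), 3L)
#' lambda(computeLambda(p, 3))
#' @export
computeLambda <- function(profile, a) {
  stopifnot(a >= 0)
  k <- profile@k
  if (length(k) < 2L)
    .hryError("profile needs at least 2 samples", "hry_short_profile")
  s <- stats::sd(k)
  lam <- mean(k) + a * s
  profile@lambda <- min(lam, 1)
  profile@a <- a
  profile
}

#' Detect concave points on an ECMP profile
#'
#' Partitions the boundary positions with k(t) >= lambda into maximal
#' contiguous runs (wrapping circularly across the trace start) and
#' returns one index per run: the peak (argmax of k, ties to the earliest
#' position in the run). An isolated convex kernel yields no concave
#' points; each pairwise contact between touching kernels yields two.
#'
#' The threshold is floored at \code{floor} (default 0.65): a straight
#' edge scores about 0.56 and rasterization staircase ripple stays below
#' ~0.63, while a genuine crevice corner is reflex and scores upward of
#' ~0.8, so the floor keeps near-constant profiles of convex kernels
#' (whose adaptive lambda collapses toward the mean) from triggering
#' spurious detections. It generalizes the constant-profile degenerate
#' case, where lambda = E(k) and nothing may be detected.
#'
#' @param profile an [EcmpProfile-class] with lambda computed (see
#'   [computeLambda()]).
#' @param floor absolute lower bound on the detection threshold.
#' @return integer vector of boundary indices (sorted, possibly empty).
#' @export
findConcavePoints <- function(profile, floor = 0.65) {
  if (is.na(profile@lambda))
    .hryError("lambda not computed; call computeLambda() first",
              "hry_no_lambda")
  k <- profile@k
  N <- length(k)
  if (N < 2L || diff(range(k)) < .Machine$double.eps) return(integer())
  w <- k >= max(profile@lambda, floor)
  if (!any(w) || all(w)) return(integer())
  # rotate so position 1 is below threshold, then take contiguous runs
  f <- which(!w)[1L]
  shift <- function(i) ((i + f - 2L) %% N) + 1L   # shifted pos -> original t
  ws <- w[shift(seq_len(N))]
  r <- rle(ws)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- integer()
  for (j in which(r$values)) {
    run <- shift(starts[j]:ends[j])
    peaks <- c(peaks, run[which.max(k[run])])
  }
  sort(peaks)
}

#' One-call concave point detection for a component
#'
#' Convenience wrapper: ECMP profile, lambda, and peak detection, with the
#' results stored on the returned profile.
#'
#' @inheritParams ecmpProfile
#' @param a variety coefficient for [computeLambda()].
#' @return an [EcmpProfile-class] with \code{lambda} and
#'   \code{concaveIndices} filled.
#' @export
detectConcavePoints <- function(mask, boundary, templateSize = NULL, a = 3) {
  p <- ecmpProfile(mask, boundary, templateSize)
  if (length(p@k) < 2L) return(p)
  p <- computeLambda(p, a)
  p@concaveIndices <- findConcavePoints(p)
  p
}
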