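#' @include AllClasses.R utils.R
NULL

#' Rotate points about a centre
#'
#' Standard continuous planar rotation (no re-rasterization): the points
#' are translated to the centre, rotated, and translated back. An exact
#' isometry up to floating point.
#'
#' @param points n x 2 matrix (or length-2 vector) of coordinates.
#' @param angle rotation angle in degrees (counter-clockwise in the
#'   coordinate system of the points).
#' @param center length-2 rotation centre, default the origin.
#' @return n x 2 matrix of rotated coordinates.
#' @examples
#' rotatePoints(c(1, 0), 90)  # -> (0, 1)
#' @export
rotatePoints <- function(points, angle, center = c(0, 0)) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  th <- angle * pi / 180
  x <- points[, 1L] - center[1L]
  y <- points[, 2L] - center[2L]
  cbind(x * cos(th) - y * sin(th) + center[1L],
        x * sin(th) + y * cos(th) + center[2L])
}

# pixel extent of a coordinate set: max - min + 1 (a contour of pixel
# centres spanning 30 columns measures 30)
.extent <- function(z) diff(range(z)) + 1

#' Kernel length by minimum enclosing rectangle
#'
#' Rotates the contour about its centroid over a grid of angles covering
#' 90 degrees (default step 3 degrees), fits the axis-aligned bounding
#' rectangle at each angle, and keeps the rectangle of minimum area (ties
#' to the smallest angle). The longer rectangle side is the kernel
#' length. \code{method = "exact"} replaces the grid by rotating calipers
#' on the convex hull (a bounding rectangle of minimum area has a side
#' collinear with a hull edge) and serves as the exact reference.
#'
#' @param contour n x 2 matrix of boundary pixel coordinates (row, col).
#' @param angleStep grid step in degrees.
#' @param method "grid" or "exact".
#' @return list with \code{length}, \code{width} (px, pixel-extent
#'   convention max-min+1) and \code{angle} (degrees; for "exact" the
#'   hull-edge angle of the optimal rectangle).
#' @examples
#' rect <- as.matrix(expand.grid(row = 1:10, col = 1:30))
#' merLength(rect)$length  # 30
#' @export
merLength <- function(contour, angleStep = 3, method = c("grid", "exact")) {
  method <- match.arg(method)
  if (is.null(dim(contour))) contour <- matrix(contour, ncol = 2L)
  if (nrow(contour) == 1L)
    return(list(length = 1, width = 1, angle = 0, degenerate = TRUE))
  ctr <- colMeans(contour)
  if (method == "grid") {
    angles <- seq(0, 90 - 1e-9, by = angleStep)
    best <- NULL
    for (ang in angles) {
      p <- rotatePoints(contour, ang, ctr)
      w <- .extent(p[, 1L]); h <- .extent(p[, 2L])
      if (is.null(best) || w * h < best$area - 1e-12)
        best <- list(area = w * h, length = max(w, h),
                     width = min(w, h), angle = ang)
    }
    return(best[c("length", "width", "angle")])
  }
  hull <- contour[grDevices::chull(contour[, 1L], contour[, 2L]), , drop = FALSE]
  if (nrow(hull) < 2L)
    return(list(length = 1, width = 1, angle = 0, degenerate = TRUE))
  best <- NULL
  nh <- nrow(hull)
  for (i in seq_len(nh)) {
    e <- hull[(i %% nh) + 1L, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len
    v <- c(-u[2L], u[1L])
    pu <- hull[, 1L] * u[1L] + hull[, 2L] * u[2L]
    pv <- hull[, 1L] * v[1L] + hull[, 2L] * v[2L]
    w <- .extent(pu); h <- .extent(pv)
    if (is.null(best) || w * h < best$area - 1e-12)
      best <- list(area = w * h, length = max(w, h), width = min(w, h),
                   angle = (atan2(u[2L], u[1L]) * 180 / pi) %% 180)
  }
  best[c("length", "width", "angle")]
}

#' Kernel length by maximum Euclidean distance
#'
#' The largest pairwise distance between contour points (the "theoretical
#' length"). Computed on the convex hull (the diameter of a point set is
#' attained between hull vertices), which equals the brute-force scan
#' over all pairs. Always at least the MER length for elongated kernels,
#' since the diagonal dominates the side -- which is why this
#' overestimates true kernel length.
#'
#' @param contour n x 2 matrix (n >= 2) of boundary coordinates.
#' @return numeric length in px.
#' @examples
#' medLength(rbind(c(0, 0), c(3, 4)))  # 5
#' @export
medLength <- function(contour) {
  if (is.null(dim(contour))) contour <- matrix(contour, ncol = 2L)
  if (nrow(contour) < 2L)
    .hryError("medLength needs at least 2 points", "hry_degenerate_contour")
  h <- contour[grDevices::chull(contour[, 1L], contour[, 2L]), , drop = FALSE]
  if (nrow(h) < 2L) h <- contour
  max(stats::dist(h))
}

#' Kernel length by centroid rotation
#'
#' Rotates the contour about its centroid over a grid covering 180
#' degrees and records the maximum horizontal extent encountered. A fast,
#' coarse comparator: the sweep covers every orientation of the major
#' axis, so the result dominates the MER length (to within a
#' grid-discretization pixel) but can overshoot toward the diagonal.
#'
#' @param contour n x 2 matrix (n >= 2) of boundary coordinates.
#' @param angleStep grid step in degrees.
#' @return numeric length in px (pixel-extent convention).
#' @export
crLength <- function(contour, angleStep = 3) {
  if (is.null(dim(contour))) contour <- matrix(contour, ncol = 2L)
  if (nrow(contour) < 2L)
    .hryError("crLength needs at least 2 points", "hry_degenerate_contour")
  ctr <- colMeans(contour)
  best <- 0
  for (ang in seq(0, 180 - 1e-9, by = angleStep)) {
    p <- rotatePoints(contour, ang, ctr)
    best <- max(best, .extent(p[, 2L]))
  }
  best
}

#' Head/broken classification at the three-quarters rule
#'
#' A milled kernel is head rice iff its length is at least three-fourths
#' of the reference full-kernel length (GB/T 21719-2008); the boundary is
#' inclusive, so an exactly-3/4 kernel counts as head.
#'
#' @param length kernel length(s); same units as \code{referenceLength}.
#' @param referenceLength reference full-kernel length (> 0).
#' @return logical vector, TRUE = head rice.
#' @export
classifyHead <- function(length, referenceLength) {
  if (any(length <= 0) || any(referenceLength <= 0))
    .hryError("lengths must be positive", "hry_bad_length")
  length >= 0.75 * referenceLength
}

#' Reference full-kernel length from a measured sample
#'
#' Arithmetic mean of the lengths of intact (head) kernels of the
#' variety; ten kernels is the intended sample size, fewer are accepted
#' with a warning.
#'
#' @param sampleLengths positive numeric vector of measured lengths.
#' @return numeric mean length.
#' @export
referenceLength <- function(sampleLengths) {
  if (!length(sampleLengths))
    .hryError("no sample lengths given", "hry_bad_length")
  if (any(sampleLengths <= 0))
    .hryError("sample lengths must be positive", "hry_bad_length")
  if (length(sampleLengths) < 10L)
    .hryWarning("fewer than 10 reference kernels", "hry_small_reference")
  mean(sampleLengths)
}

#' Head rice yield from per-kernel measurements
#'
#' Head rice yield is the pixel-area ratio S_hr / S_total, where S_hr
#' sums the areas of kernels classified as head rice and S_total sums all
#' kernel areas. Pixel area stands in for mass: kernels of one variety
#' have near-identical thickness and density, so mass is proportional to
#' projected area.
#'
#' @param perGrain data.frame with at least columns \code{area} (px) and
#'   \code{isHead} (logical); typically the table built by [runScene()].
#' @param referenceLength optional reference length recorded with the
#'   result (same units as the per-grain lengths).
#' @return a [HeadRiceResult-class].
#' @examples
#' headRiceYield(data.frame(area = c(7500, 2500), isHead = c(TRUE, FALSE)))
#' @export
headRiceYield <- function(perGrain, referenceLength = NA_real_) {
  if (!nrow(perGrain)) .hryError("empty grain table", "hry_empty_foreground")
  if (any(perGrain$area <= 0)) .hryError("areas must be positive", "hry_bad_length")
  Shr <- sum(perGrain$area[perGrain$isHead])
  St <- sum(perGrain$area)
  if (St == 0) .hryError("total grain area is zero", "hry_empty_foreground")
  counts <- c(grains = nrow(perGrain), head = sum(perGrain$isHead))
  new("HeadRiceResult", Shr = Shr, Stotal = St, hry = Shr / St,
      referenceLength = referenceLength, perGrain = perGrain,
      counts = counts)
}
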