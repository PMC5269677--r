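#' @import methods
NULL

#' GrainScene: a synthetic bulk-grain image with per-kernel ground truth
#'
#' Container produced by [makeScene()]. Holds the rendered intensity image,
#' the instance label map, and the per-grain specification table, so every
#' downstream stage (thresholding, separation, length measurement, head
#' rice yield) can be validated against known truth.
#'
#' @slot image numeric matrix, intensities on a 0--255 scale (dark belt
#'   background around 10, kernels around 200).
#' @slot truthLabels integer matrix of the same shape; 0 = background,
#'   k = pixels of grain k. Pixels shared by two touching kernels are
#'   assigned to the earlier-placed kernel.
#' @slot truthSpecs data.frame with one row per grain: centre, orientation,
#'   semi-axes, superellipse exponent, \code{broken} flag,
#'   \code{lengthFraction}, continuous true length (\code{trueLengthPx}),
#'   truth head/broken call (\code{isHead}), cluster id and pixel area.
#' @slot contacts data.frame describing each pairwise touch between
#'   kernels: the two grain indices, the contact centre and the two neck
#'   endpoints (where the kernel outlines cross), used to validate concave
#'   point localization.
#' @slot refLengthPx numeric, the variety reference full-kernel length
#'   (px) used for truth head/broken calls.
#' @slot variety character, name of the variety profile used.
#' @slot seed integer seed the scene was generated from.
#'
#' @seealso [makeScene()], [sceneImage()], [truthLabels()], [truthSpecs()]
#' @export
setClass("GrainScene", representation(
  image = "matrix",
  truthLabels = "matrix",
  truthSpecs = "data.frame",
  contacts = "data.frame",
  refLengthPx = "numeric",
  variety = "character",
  seed = "integer"
))

setValidity("GrainScene", function(object) {
  msg <- character()
  if (!identical(dim(object@image), dim(object@truthLabels)))
    msg <- c(msg, "image and truthLabels must have identical dimensions")
  nlab <- length(setdiff(unique(as.vector(object@truthLabels)), 0L))
  if (nlab != nrow(object@truthSpecs))
    msg <- c(msg, "number of distinct nonzero labels must equal nrow(truthSpecs)")
  if (length(msg)) msg else TRUE
})

#' Boundary: ordered outer edge trace of one connected component
#'
#' Closed, clockwise (in screen orientation, rows increasing downwards)
#' Moore trace of the outer boundary of an 8-connected component, starting
#' at the lexicographically smallest (row, then column) edge pixel.
#' Consecutive points are 8-neighbours and the last point is an
#' 8-neighbour of the first.
#'
#' @slot points integer matrix with columns \code{row}, \code{col}.
#' @slot label integer, the component label the trace belongs to.
#' @export
setClass("Boundary", representation(points = "matrix", label = "integer"))

setValidity("Boundary", function(object) {
  p <- object@points
  if (ncol(p) != 2L) return("points must have two columns (row, col)")
  if (nrow(p) > 1L) {
    d <- pmax(abs(diff(p[, 1L])), abs(diff(p[, 2L])))
    if (any(d > 1L)) return("consecutive boundary points must be 8-neighbours")
    wrap <- pmax(abs(p[1L, 1L] - p[nrow(p), 1L]), abs(p[1L, 2L] - p[nrow(p), 2L]))
    if (wrap > 1L) return("boundary must be closed (last point adjacent to first)")
  }
  TRUE
})

#' EcmpProfile: the ECMP concavity signal along one boundary
#'
#' The edge center mode proportion k(t) -- the fraction of foreground
#' pixels inside a square template centred on boundary pixel t -- sampled
#' clockwise along a [Boundary], together with the adaptive threshold
#' lambda = E(k) + a * sd(k) and the detected concave point indices.
#' Reflex (concave) boundary points cover more than half the template and
#' therefore score high; concave points are peaks of runs with
#' k(t) >= lambda.
#'
#' @slot k numeric vector of ECMP values in [0, 1], one per boundary point.
#' @slot boundary the [Boundary] the profile was sampled on.
#' @slot templateSize odd integer, side of the square template (px).
#' @slot lambda numeric threshold (NA until [computeLambda()] is applied).
#' @slot a numeric variety coefficient used for lambda (NA until set).
#' @slot concaveIndices integer vector of boundary indices of detected
#'   concave points (empty until [findConcavePoints()] results are stored).
#' @export
setClass("EcmpProfile", representation(
  k = "numeric",
  boundary = "Boundary",
  templateSize = "integer",
  lambda = "numeric",
  a = "numeric",
  concaveIndices = "integer"
))

setValidity("EcmpProfile", function(object) {
  msg <- character()
  if (length(object@k) != nrow(object@boundary@points))
    msg <- c(msg, "length(k) must equal the number of boundary points")
  if (any(object@k < 0 | object@k > 1))
    msg <- c(msg, "k values must lie in [0, 1]")
  if (length(object@concaveIndices) && !all(is.na(object@lambda)) &&
      any(object@k[object@concaveIndices] < object@lambda - 1e-12))
    msg <- c(msg, "every concave index must satisfy k(t) >= lambda")
  if (length(msg)) msg else TRUE
})

#' HryConfig: pipeline configuration
#'
#' @slot variety "japonica" or "indica"; sets the default lambda
#'   coefficient a (3 for japonica, 2 for indica) when \code{a} is NA.
#' @slot a numeric lambda coefficient; NA = derive from variety.
#' @slot templateSize "auto" (scale 300:1 from the image size) or an odd
#'   integer, stored as integer with NA meaning auto.
#' @slot minComponentArea numeric; speck-removal area threshold in px, NA =
#'   100 px at 3000x2500 scaled by (max image dim / 3000)^2.
#' @slot minGrainAreaPx numeric; smallest plausible kernel-fragment area,
#'   used for the 25% cut-fragment merge guard.
#' @slot angleStep numeric, degrees, rotation grid step for MER/CR.
#' @slot scaleMmPerPx numeric, mm per pixel.
#' @slot referenceLengthMm numeric, full-kernel reference length (mm).
#' @slot lengthMethod "mer", "med" or "cr".
#' @slot logLevel "quiet" or "info" (stage-boundary count logging).
#' @export
setClass("HryConfig", representation(
  variety = "character",
  a = "numeric",
  templateSize = "integer",
  minComponentArea = "numeric",
  minGrainAreaPx = "numeric",
  angleStep = "numeric",
  scaleMmPerPx = "numeric",
  referenceLengthMm = "numeric",
  lengthMethod = "character",
  logLevel = "character"
))

setValidity("HryConfig", function(object) {
  msg <- character()
  if (!object@variety %in% c("japonica", "indica"))
    msg <- c(msg, "variety must be 'japonica' or 'indica'")
  if (!is.na(object@a) && object@a <= 0) msg <- c(msg, "a must be > 0")
  if (!is.na(object@templateSize) &&
      (object@templateSize < 3L || object@templateSize %% 2L == 0L))
    msg <- c(msg, "templateSize must be an odd integer >= 3 (or NA for auto)")
  if (object@angleStep <= 0 || object@angleStep > 90)
    msg <- c(msg, "angleStep must be in (0, 90]")
  if (object@scaleMmPerPx <= 0) msg <- c(msg, "scaleMmPerPx must be > 0")
  if (object@referenceLengthMm <= 0) msg <- c(msg, "referenceLengthMm must be > 0")
  if (!object@lengthMethod %in% c("mer", "med", "cr"))
    msg <- c(msg, "lengthMethod must be one of 'mer', 'med', 'cr'")
  if (length(msg)) msg else TRUE
})

#' HeadRiceResult: per-image head rice yield result
#'
#' @slot Shr numeric, summed pixel area of head-rice kernels.
#' @slot Stotal numeric, summed pixel area of all kernels.
#' @slot hry numeric in [0, 1], exactly Shr / Stotal.
#' @slot referenceLength numeric, reference full-kernel length used for
#'   the three-quarters rule (same units as the per-grain lengths).
#' @slot perGrain data.frame with one row per separated kernel: label,
#'   area (px), length (px and mm), measuring method, head/broken call.
#' @slot counts named numeric vector of stage diagnostics (components in,
#'   concave points, matched pairs, grains out).
#' @export
setClass("HeadRiceResult", representation(
  Shr = "numeric",
  Stotal = "numeric",
  hry = "numeric",
  referenceLength = "numeric",
  perGrain = "data.frame",
  counts = "numeric"
))

setValidity("HeadRiceResult", function(object) {
  msg <- character()
  if (object@Shr > object@Stotal + 1e-9) msg <- c(msg, "Shr must be <= Stotal")
  if (object@Stotal > 0 &&
      abs(object@hry - object@Shr / object@Stotal) > 1e-12)
    msg <- c(msg, "hry must equal Shr / Stotal exactly")
  if (length(msg)) msg else TRUE
})
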