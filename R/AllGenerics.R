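#' @include AllClasses.R
NULL

#' Accessors for GrainScene
#'
#' @param x a [GrainScene-class].
#' @return \code{sceneImage}: the intensity matrix. \code{truthLabels}:
#'   the integer instance label matrix. \code{truthSpecs}: the per-grain
#'   specification data.frame. \code{truthCount}: number of grains.
#'   \code{truthHeadArea} / \code{truthTotalArea}: ground-truth pixel
#'   areas of head kernels and of all kernels. \code{sceneContacts}: the
#'   pairwise-contact table. \code{refLength}: reference full-kernel
#'   length in px.
#' @name GrainScene-accessors
#' @aliases sceneImage truthLabels truthSpecs truthCount truthHeadArea
#'   truthTotalArea sceneContacts refLength
#' @examples
#' sc <- makeScene(5, clusterSizeWeights = c(1, 0, 0, 0, 0), seed = 1)
#' truthCount(sc)
#' truthHeadArea(sc) <= truthTotalArea(sc)
NULL

#' @rdname GrainScene-accessors
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))
#' @rdname GrainScene-accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname GrainScene-accessors
#' @export
setGeneric("truthSpecs", function(x) standardGeneric("truthSpecs"))
#' @rdname GrainScene-accessors
#' @export
setGeneric("truthCount", function(x) standardGeneric("truthCount"))
#' @rdname GrainScene-accessors
#' @export
setGeneric("truthHeadArea", function(x) standardGeneric("truthHeadArea"))
#' @rdname GrainScene-accessors
#' @export
setGeneric("truthTotalArea", function(x) standardGeneric("truthTotalArea"))
#' @rdname GrainScene-accessors
#' @export
setGeneric("sceneContacts", function(x) standardGeneric("sceneContacts"))
#' @rdname GrainScene-accessors
#' @export
setGeneric("refLength", function(x) standardGeneric("refLength"))

#' @rdname GrainScene-accessors
setMethod("sceneImage", "GrainScene", function(x) x@image)
#' @rdname GrainScene-accessors
setMethod("truthLabels", "GrainScene", function(x) x@truthLabels)
#' @rdname GrainScene-accessors
setMethod("truthSpecs", "GrainScene", function(x) x@truthSpecs)
#' @rdname GrainScene-accessors
setMethod("truthCount", "GrainScene", function(x) nrow(x@truthSpecs))
#' @rdname GrainScene-accessors
setMethod("truthHeadArea", "GrainScene", function(x) {
  sum(x@truthSpecs$areaPx[x@truthSpecs$isHead])
})
#' @rdname GrainScene-accessors
setMethod("truthTotalArea", "GrainScene", function(x) sum(x@truthSpecs$areaPx))
#' @rdname GrainScene-accessors
setMethod("sceneContacts", "GrainScene", function(x) x@contacts)
#' @rdname GrainScene-accessors
setMethod("refLength", "GrainScene", function(x) x@refLengthPx)

#' Accessors for EcmpProfile and Boundary
#'
#' @param x an [EcmpProfile-class] or [Boundary-class].
#' @return \code{ecmpValues}: numeric vector k(t). \code{lambda}: the
#'   threshold (NA before [computeLambda()]). \code{concavePoints}:
#'   integer indices of stored concave points. \code{boundaryPoints}: the
#'   (row, col) matrix of a boundary trace.
#' @name EcmpProfile-accessors
#' @aliases ecmpValues lambda concavePoints boundaryPoints
NULL

#' @rdname EcmpProfile-accessors
#' @export
setGeneric("ecmpValues", function(x) standardGeneric("ecmpValues"))
#' @rdname EcmpProfile-accessors
#' @export
setGeneric("lambda", function(x) standardGeneric("lambda"))
#' @rdname EcmpProfile-accessors
#' @export
setGeneric("concavePoints", function(x) standardGeneric("concavePoints"))
#' @rdname EcmpProfile-accessors
#' @export
setGeneric("boundaryPoints", function(x) standardGeneric("boundaryPoints"))

#' @rdname EcmpProfile-accessors
setMethod("ecmpValues", "EcmpProfile", function(x) x@k)
#' @rdname EcmpProfile-accessors
setMethod("lambda", "EcmpProfile", function(x) x@lambda)
#' @rdname EcmpProfile-accessors
setMethod("concavePoints", "EcmpProfile", function(x) x@concaveIndices)
#' @rdname EcmpProfile-accessors
setMethod("boundaryPoints", "Boundary", function(x) x@points)
#' @rdname EcmpProfile-accessors
setMethod("boundaryPoints", "EcmpProfile", function(x) x@boundary@points)

#' Accessors for HeadRiceResult
#'
#' @param x a [HeadRiceResult-class].
#' @return \code{hry}: head rice yield in [0, 1]. \code{perGrain}: the
#'   per-kernel measurement table.
#' @name HeadRiceResult-accessors
#' @aliases hry perGrain
NULL

#' @rdname HeadRiceResult-accessors
#' @export
setGeneric("hry", function(x) standardGeneric("hry"))
#' @rdname HeadRiceResult-accessors
#' @export
setGeneric("perGrain", function(x) standardGeneric("perGrain"))

#' @rdname HeadRiceResult-accessors
setMethod("hry", "HeadRiceResult", function(x) x@hry)
#' @rdname HeadRiceResult-accessors
setMethod("perGrain", "HeadRiceResult", function(x) x@perGrain)

setMethod("show", "GrainScene", function(object) {
  cat("GrainScene:", nrow(object@image), "x", ncol(object@image),
      "px,", truthCount(object), "grains (", object@variety, "profile )\n")
  cat("  broken:", sum(object@truthSpecs$broken),
      " head-area fraction:",
      round(truthHeadArea(object) / truthTotalArea(object), 4),
      " seed:", object@seed, "\n")
})

setMethod("show", "Boundary", function(object) {
  cat("Boundary of component", object@label, ":", nrow(object@points),
      "edge pixels, start (", object@points[1, 1], ",",
      object@points[1, 2], ")\n")
})

setMethod("show", "EcmpProfile", function(object) {
  cat("EcmpProfile: N =", length(object@k),
      " template", object@templateSize, "x", object@templateSize,
      " E(k) =", round(mean(object@k), 4))
  if (!is.na(object@lambda)) cat("  lambda =", round(object@lambda, 4))
  if (length(object@concaveIndices))
    cat("  concave points:", length(object@concaveIndices))
  cat("\n")
})

setMethod("show", "HeadRiceResult", function(object) {
  cat("HeadRiceResult:", nrow(object@perGrain), "grains, HRY =",
      sprintf("%.4f", object@hry),
      sprintf("(S_hr = %d / S_total = %d px)\n",
              as.integer(object@Shr), as.integer(object@Stotal)))
})

setMethod("show", "HryConfig", function(object) {
  cat("HryConfig:", object@variety,
      "(a =", .lambdaCoefficient(object), ")",
      " template:", ifelse(is.na(object@templateSize), "auto",
                           object@templateSize),
      " length:", object@lengthMethod,
      " ref:", object@referenceLengthMm, "mm",
      " scale:", object@scaleMmPerPx, "mm/px\n")
})
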