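#' @include AllClasses.R AllGenerics.R utils.R preprocess.R concavity.R matching.R metrics.R
NULL

#' Build a pipeline configuration
#'
#' @param scaleMmPerPx mm per pixel of the imaging geometry (required; the
#'   camera standoff fixes it for a given rig).
#' @param referenceLengthMm reference full-kernel length in mm (required),
#'   normally the mean MER length of ten intact kernels of the variety,
#'   see [referenceLength()] and [calibrateReference()].
#' @param variety "japonica" or "indica"; selects the lambda coefficient
#'   a = 3 (japonica) or a = 2 (indica) unless \code{a} is given.
#' @param a explicit lambda coefficient (> 0), NA = derive from variety.
#' @param templateSize odd ECMP template side, NA = auto (300:1 image
#'   scale rule, [templateSizeForImage()]).
#' @param minComponentArea speck-removal threshold in px, NA = auto
#'   ([defaultMinArea()]).
#' @param minGrainAreaPx smallest plausible kernel fragment (px); the cut
#'   sliver guard merges post-cut components below 25% of this.
#' @param angleStep rotation grid step (degrees) for MER/CR.
#' @param lengthMethod "mer" (recommended), "med" or "cr".
#' @param logLevel "quiet" or "info".
#' @return an [HryConfig-class].
#' @examples
#' cfg <- hryConfig(scaleMmPerPx = 0.17, referenceLengthMm = 6.5)
#' @export
hryConfig <- function(scaleMmPerPx, referenceLengthMm,
                      variety = c("japonica", "indica"), a = NA_real_,
                      templateSize = NA_integer_,
                      minComponentArea = NA_real_,
                      minGrainAreaPx = 1000, angleStep = 3,
                      lengthMethod = c("mer", "med", "cr"),
                      logLevel = c("quiet", "info")) {
  new("HryConfig", variety = match.arg(variety), a = as.numeric(a),
      templateSize = as.integer(templateSize),
      minComponentArea = as.numeric(minComponentArea),
      minGrainAreaPx = minGrainAreaPx, angleStep = angleStep,
      scaleMmPerPx = scaleMmPerPx, referenceLengthMm = referenceLengthMm,
      lengthMethod = match.arg(lengthMethod),
      logLevel = match.arg(logLevel))
}

.lambdaCoefficient <- function(config) {
  if (!is.na(config@a)) config@a
  else switch(config@variety, japonica = 3, indica = 2)
}

.logInfo <- function(config, ...) {
  if (config@logLevel == "info") message(...)
}

# Bounding boxes of all labels: matrix with rows (r0, r1, c0, c1) per label.
.labelBoxes <- function(labs) {
  K <- max(labs)
  idx <- which(labs > 0L, arr.ind = TRUE)
  l <- labs[labs > 0L]
  cbind(r0 = tapply(idx[, 1L], l, min), r1 = tapply(idx[, 1L], l, max),
        c0 = tapply(idx[, 2L], l, min), c1 = tapply(idx[, 2L], l, max))[
          as.character(seq_len(K)), , drop = FALSE]
}

#' Separate touching kernels in a preprocessed mask
#'
#' The separation core: labels 8-connected components, traces each
#' component's outer boundary, computes the ECMP profile and threshold,
#' detects and matches concave points under the collaborative constraint,
#' and cuts the mask along matched pairs.
#'
#' @param mask logical foreground mask (already despeckled and smoothed).
#' @param config an [HryConfig-class].
#' @return list with \code{labels} (final kernel label matrix),
#'   \code{pairs} (matched concave-point pairs), \code{points} (concave
#'   point table) and \code{counts} (stage diagnostics).
#' @export
separateTouchingGrains <- function(mask, config) {
  labs <- labelComponents(mask)
  K <- max(labs)
  if (K == 0L) .hryError("empty foreground", "hry_empty_foreground")
  tsz <- if (is.na(config@templateSize))
    templateSizeForImage(dim(mask)) else config@templateSize
  a <- .lambdaCoefficient(config)
  boxes <- .labelBoxes(labs)
  cpAll <- NULL
  bigClusters <- 0L
  for (comp in seq_len(K)) {
    r0 <- max(1L, boxes[comp, "r0"] - tsz - 1L)
    r1 <- min(nrow(mask), boxes[comp, "r1"] + tsz + 1L)
    c0 <- max(1L, boxes[comp, "c0"] - tsz - 1L)
    c1 <- min(ncol(mask), boxes[comp, "c1"] + tsz + 1L)
    sub <- labs[r0:r1, c0:c1, drop = FALSE] == comp
    bd <- traceBoundary(sub)
    if (nrow(bd@points) < 2L * tsz + 2L) next  # too small to carry a neck
    prof <- detectConcavePoints(sub, bd, tsz, a)
    if (length(prof@concaveIndices) > 8L) bigClusters <- bigClusters + 1L
    tab <- concavePointTable(sub, prof, comp)
    if (!is.null(tab)) {
      for (cl in c("row", "Mrow", "Nrow")) tab[[cl]] <- tab[[cl]] + r0 - 1L
      for (cl in c("col", "Mcol", "Ncol")) tab[[cl]] <- tab[[cl]] + c0 - 1L
      cpAll <- rbind(cpAll, tab)
    }
  }
  if (bigClusters > 0L)
    .logInfo(config, bigClusters,
             " component(s) with > 8 concave points (cluster larger than",
             " the expected <= 5 kernels)")
  pairs <- matchConcavePoints(cpAll)
  finalLabs <- separateGrains(mask, pairs, 0.25 * config@minGrainAreaPx)
  counts <- c(componentsIn = K,
              concavePoints = if (is.null(cpAll)) 0L else nrow(cpAll),
              pairs = nrow(pairs), grainsOut = max(finalLabs))
  .logInfo(config, "components: ", K, " -> grains: ", max(finalLabs),
           " (", counts[["concavePoints"]], " concave points, ",
           counts[["pairs"]], " cuts)")
  list(labels = finalLabs, pairs = pairs, points = cpAll, counts = counts)
}

#' Measure every labeled kernel
#'
#' Traces each kernel's contour and measures its length with the
#' configured method (MER by default), converts to mm, and applies the
#' three-quarters head/broken rule against the configured reference
#' length.
#'
#' @param labels integer kernel label matrix.
#' @param config an [HryConfig-class].
#' @return data.frame with one row per kernel: \code{label}, \code{area}
#'   (px), \code{lengthPx}, \code{lengthMm}, \code{method}, \code{isHead}.
#' @export
measureGrains <- function(labels, config) {
  K <- max(labels)
  if (K == 0L) .hryError("no labeled grains", "hry_empty_foreground")
  boxes <- .labelBoxes(labels)
  sizes <- tabulate(labels, nbins = K)
  out <- vector("list", K)
  for (comp in seq_len(K)) {
    r0 <- boxes[comp, "r0"]; c0 <- boxes[comp, "c0"]
    sub <- labels[r0:boxes[comp, "r1"], c0:boxes[comp, "c1"],
                  drop = FALSE] == comp
    contour <- traceBoundary(sub)@points
    contour[, 1L] <- contour[, 1L] + r0 - 1L
    contour[, 2L] <- contour[, 2L] + c0 - 1L
    lenPx <- switch(config@lengthMethod,
      mer = merLength(contour, config@angleStep)$length,
      med = medLength(contour),
      cr = crLength(contour, config@angleStep))
    out[[comp]] <- data.frame(
      label = comp, area = sizes[comp], lengthPx = lenPx,
      lengthMm = lenPx * config@scaleMmPerPx,
      method = config@lengthMethod,
      isHead = unname(classifyHead(lenPx * config@scaleMmPerPx,
                                   config@referenceLengthMm)))
  }
  do.call(rbind, out)
}

#' Run the full pipeline on a preprocessed mask
#'
#' @param mask logical foreground mask.
#' @param config an [HryConfig-class].
#' @return a [HeadRiceResult-class]; the separation label matrix is
#'   attached as attribute \code{"labels"} of the result's
#'   \code{perGrain} table.
#' @export
runMask <- function(mask, config) {
  sep <- separateTouchingGrains(mask, config)
  pg <- measureGrains(sep$labels, config)
  res <- headRiceYield(pg, config@referenceLengthMm)
  res@counts <- c(res@counts, sep$counts)
  attr(res@perGrain, "labels") <- sep$labels
  res
}

#' Run the pipeline on a synthetic scene
#'
#' Preprocesses the scene's intensity image (threshold, despeckle,
#' smooth) and runs separation, measurement and head rice yield.
#'
#' @param scene a [GrainScene-class].
#' @param config an [HryConfig-class].
#' @return a [HeadRiceResult-class].
#' @examples
#' sc <- makeScene(12, seed = 2)
#' cfg <- hryConfig(scaleMmPerPx = 1, referenceLengthMm = refLength(sc))
#' runScene(sc, cfg)
#' @export
runScene <- function(scene, config) {
  # synthetic scenes are rendered at a fixed 12 px/mm kernel scale no
  # matter the canvas, so the automatic speck threshold and template size
  # are pinned to their reference-scale values (100 px, 9x9) instead of
  # the image-size rules meant for camera images
  minA <- if (is.na(config@minComponentArea))
    max(100, defaultMinArea(dim(scene@image))) else config@minComponentArea
  if (is.na(config@templateSize)) config@templateSize <- 9L
  mask <- preprocessImage(scene@image, minArea = minA)
  runMask(mask, config)
}

#' Run the pipeline on an image file
#'
#' @param imagePath PNG or TIFF file (grayscale or RGB; RGB is converted
#'   by luminance).
#' @param config an [HryConfig-class].
#' @param outDir if non-NULL, writes \code{grains.csv} (per-kernel table),
#'   \code{summary.json} (S_hr, S_total, hry, reference, counts) and
#'   \code{labels.png} into this directory.
#' @return a [HeadRiceResult-class].
#' @export
runImage <- function(imagePath, config, outDir = NULL) {
  img <- readGrainImage(imagePath)
  minA <- if (is.na(config@minComponentArea))
    defaultMinArea(dim(img)) else config@minComponentArea
  mask <- preprocessImage(img, minArea = minA)
  if (!any(mask)) .hryError("empty foreground", "hry_empty_foreground")
  res <- runMask(mask, config)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res@perGrain,
                     file.path(outDir, "grains.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(S_hr = res@Shr, S_total = res@Stotal, hry = res@hry,
           reference_length_mm = res@referenceLength,
           counts = as.list(res@counts)),
      file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
    writeLabelsPNG(attr(res@perGrain, "labels"),
                   file.path(outDir, "labels.png"))
  }
  res
}

#' Measure a reference length by imaging intact kernels
#'
#' Reproduces the reference protocol: a scene of \code{n} intact,
#' non-touching kernels of the variety is generated, each kernel's length
#' is measured with the configured method, and the mean is returned.
#' Using the same measurement path for the reference and for the grains
#' under test makes the (sub-pixel) rasterization and smoothing bias
#' cancel at the three-quarters boundary.
#'
#' @param variety profile name or list (see [varietyProfile()]).
#' @param seed RNG seed for the calibration scene.
#' @param n number of intact kernels (default 10).
#' @param angleStep,lengthMethod measurement parameters.
#' @param details if TRUE, return a list with the measured reference
#'   (\code{measuredPx}), the calibration kernels' true mean length
#'   (\code{trueMeanPx}) and the per-kernel measured lengths. The
#'   reference is \emph{defined by} the selected kernels, so benchmark
#'   ground truth for head/broken error rates is taken against
#'   \code{trueMeanPx}: the rates then quantify length-measurement error
#'   rather than the sampling luck of the ten selected kernels.
#' @return reference length in px (or a list, see \code{details}).
#' @export
calibrateReference <- function(variety, seed, n = 10L, angleStep = 3,
                               lengthMethod = c("mer", "med", "cr"),
                               details = FALSE) {
  lengthMethod <- match.arg(lengthMethod)
  sc <- makeScene(n, clusterSizeWeights = c(1, 0, 0, 0, 0),
                  brokenFraction = 0, variety = variety,
                  noiseSpeckCount = 0L, seed = seed)
  mask <- preprocessImage(sc@image,
                          minArea = max(100, defaultMinArea(dim(sc@image))))
  labs <- labelComponents(mask)
  cfg <- hryConfig(scaleMmPerPx = 1, referenceLengthMm = refLength(sc),
                   angleStep = angleStep, lengthMethod = lengthMethod)
  pg <- measureGrains(labs, cfg)
  measured <- referenceLength(pg$lengthPx)
  if (!details) return(measured)
  list(measuredPx = measured,
       trueMeanPx = mean(truthSpecs(sc)$trueLengthPx),
       lengthsPx = pg$lengthPx)
}

#' Synthetic benchmark of separation and head rice yield accuracy
#'
#' Generates seeded scenes, runs the full pipeline, and tabulates
#' per-scene separation accuracy (detected / actual kernel count), head
#' rice yield error against generator truth, and head-call omission and
#' false-detection rates obtained by matching each detected kernel to the
#' ground-truth kernel with maximal pixel overlap.
#'
#' @param nImages number of scenes.
#' @param grainsPerImage kernels per scene (scalar or vector recycled
#'   across scenes, e.g. \code{c(100, 150, 200)} for a density sweep).
#' @param clusterWeights cluster-size weights 1..5.
#' @param brokenFraction broken-kernel probability.
#' @param varieties character vector recycled across scenes.
#' @param seed base seed; scene i uses \code{seed + i}.
#' @param canvasShape fixed canvas (so grainsPerImage sweeps density), or
#'   NULL for density-matched auto sizing.
#' @param angleStep,lengthMethod measurement parameters.
#' @return list with \code{perImage} (data.frame), \code{summary} (mean
#'   accuracy, mean relative HRY error, head-call omission and
#'   false-detection rates) -- runtimes are informational only and not
#'   reported.
#' @export
runBenchmark <- function(nImages = 6L, grainsPerImage = 150L,
                         clusterWeights = c(0.5, 0.2, 0.15, 0.1, 0.05),
                         brokenFraction = 0.2,
                         varieties = c("japonica", "indica"),
                         seed = 1L, canvasShape = NULL,
                         angleStep = 3, lengthMethod = "mer") {
  grainsPerImage <- rep_len(grainsPerImage, nImages)
  varieties <- rep_len(varieties, nImages)
  refCache <- list()
  rows <- vector("list", nImages)
  headTally <- c(headMissed = 0, headTotal = 0, brokenCalledHead = 0,
                 brokenTotal = 0)
  for (i in seq_len(nImages)) {
    v <- varieties[i]
    if (is.null(refCache[[v]]))
      refCache[[v]] <- calibrateReference(v, seed = seed + 1000L + i,
                                          angleStep = angleStep,
                                          lengthMethod = lengthMethod,
                                          details = TRUE)
    sc <- makeScene(grainsPerImage[i], clusterSizeWeights = clusterWeights,
                    brokenFraction = brokenFraction, variety = v,
                    seed = seed + i, canvasShape = canvasShape)
    cfg <- hryConfig(scaleMmPerPx = 1,
                     referenceLengthMm = refCache[[v]]$measuredPx,
                     variety = v, angleStep = angleStep,
                     lengthMethod = lengthMethod)
    res <- runScene(sc, cfg)
    truthHry <- truthHeadArea(sc) / truthTotalArea(sc)
    m <- matchDetectedToTruth(attr(res@perGrain, "labels"), sc)
    calls <- merge(m, res@perGrain[, c("label", "isHead")], by = "label")
    # truth for the head-call error rates shares the calibration kernels'
    # reference (their true mean), isolating measurement error
    truthHead <- truthSpecs(sc)$trueLengthPx[calls$truthGrain] >=
      0.75 * refCache[[v]]$trueMeanPx
    headTally <- headTally + c(
      sum(truthHead & !calls$isHead), sum(truthHead),
      sum(!truthHead & calls$isHead), sum(!truthHead))
    rows[[i]] <- data.frame(
      scene = i, variety = v, seed = seed + i,
      nTrue = truthCount(sc), nDetected = nrow(res@perGrain),
      accuracy = nrow(res@perGrain) / truthCount(sc),
      hryTruth = truthHry, hryEst = res@hry,
      hryRelErr = abs(res@hry - truthHry) / truthHry)
  }
  perImage <- do.call(rbind, rows)
  list(perImage = perImage,
       summary = list(
         meanAccuracy = mean(perImage$accuracy),
         meanHryRelErr = mean(perImage$hryRelErr),
         omissionRate = unname(headTally[1L] / max(headTally[2L], 1)),
         falseDetectionRate = unname(headTally[3L] / max(headTally[4L], 1))))
}

#' Match detected kernels to ground-truth kernels by pixel overlap
#'
#' @param labels detected kernel label matrix.
#' @param scene the [GrainScene-class] the labels came from.
#' @return data.frame (label, truthGrain, overlap px).
#' @export
matchDetectedToTruth <- function(labels, scene) {
  truth <- truthLabels(scene)
  sel <- labels > 0L & truth > 0L
  d <- labels[sel]; t <- truth[sel]
  key <- split(t, d)
  rows <- lapply(names(key), function(dl) {
    tt <- table(key[[dl]])
    data.frame(label = as.integer(dl),
               truthGrain = as.integer(names(tt)[which.max(tt)]),
               overlap = as.integer(max(tt)))
  })
  do.call(rbind, rows)
}

#' Write / read a pipeline configuration as a flat key=value file
#'
#' @param config an [HryConfig-class].
#' @param path text file path.
#' @return \code{readConfig}: an [HryConfig-class] equal to the one
#'   written.
#' @export
writeConfig <- function(config, path) {
  kv <- c(
    variety = config@variety, a = format(config@a, digits = 17),
    templateSize = as.character(config@templateSize),
    minComponentArea = format(config@minComponentArea, digits = 17),
    minGrainAreaPx = format(config@minGrainAreaPx, digits = 17),
    angleStep = format(config@angleStep, digits = 17),
    scaleMmPerPx = format(config@scaleMmPerPx, digits = 17),
    referenceLengthMm = format(config@referenceLengthMm, digits = 17),
    lengthMethod = config@lengthMethod, logLevel = config@logLevel)
  writeLines(paste(names(kv), kv, sep = "="), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  num <- function(key) if (vals[[key]] == "NA") NA_real_ else
    as.numeric(vals[[key]])
  hryConfig(scaleMmPerPx = num("scaleMmPerPx"),
            referenceLengthMm = num("referenceLengthMm"),
            variety = vals[["variety"]], a = num("a"),
            templateSize = as.integer(num("templateSize")),
            minComponentArea = num("minComponentArea"),
            minGrainAreaPx = num("minGrainAreaPx"),
            angleStep = num("angleStep"),
            lengthMethod = vals[["lengthMethod"]],
            logLevel = vals[["logLevel"]])
}
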