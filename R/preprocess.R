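#' @include utils.R
NULL

#' Threshold a grayscale image into a foreground mask
#'
#' Separates bright kernels from the dark belt background. The default is
#' a global Otsu threshold on the intensity histogram (the dark, uniform
#' belt makes a single global threshold sufficient); \code{method =
#' "local"} thresholds block-wise with Otsu as a guard against vignetting,
#' falling back to the global threshold in near-constant blocks.
#'
#' @param image numeric matrix (single channel; convert RGB upstream by
#'   luminance, see [readGrainImage()]). Any intensity scale is accepted;
#'   values are rescaled internally.
#' @param polarity "bright" (kernels brighter than background, the normal
#'   belt geometry) or "dark" for inverted-contrast input, in which case
#'   the image is inverted before thresholding.
#' @param method "otsu" (global) or "local".
#' @param blocks number of blocks per side for \code{method = "local"}.
#' @return logical matrix; TRUE = kernel pixel. A constant image yields an
#'   all-FALSE mask with a warning.
#' @examples
#' sc <- makeScene(10, seed = 3)
#' m <- binarize(sceneImage(sc))
#' @export
binarize <- function(image, polarity = c("bright", "dark"),
                     method = c("otsu", "local"), blocks = 4L) {
  polarity <- match.arg(polarity)
  method <- match.arg(method)
  rng <- range(image)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2L]))) {
    .hryWarning("constant image: returning an empty mask", "hry_constant_image")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  x <- (image - rng[1L]) / diff(rng)
  if (polarity == "dark") x <- 1 - x
  gth <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  if (method == "otsu") return(x > gth)
  mask <- matrix(FALSE, nrow(x), ncol(x))
  rIdx <- split(seq_len(nrow(x)), cut(seq_len(nrow(x)), blocks, labels = FALSE))
  cIdx <- split(seq_len(ncol(x)), cut(seq_len(ncol(x)), blocks, labels = FALSE))
  for (ri in rIdx) for (ci in cIdx) {
    blk <- x[ri, ci, drop = FALSE]
    th <- if (stats::sd(blk) < 0.02) gth else
      EBImage::otsu(EBImage::Image(blk), range = c(0, 1))
    mask[ri, ci] <- blk > th
  }
  mask
}

#' Label 8-connected foreground components
#'
#' Connected component labeling with 8-connectivity (diagonal contact
#' joins components, preventing diagonal kernel fragments from splitting).
#' Built on \code{EBImage::bwlabel} (4-connected) followed by a union-find
#' merge of diagonally adjacent labels; labels are renumbered 1..K in
#' order of first (column-major) occurrence.
#'
#' @param mask logical matrix.
#' @return integer matrix; 0 = background.
#' @export
labelComponents <- function(mask) {
  lab <- matrix(as.integer(EBImage::bwlabel(mask * 1L)), nrow(mask), ncol(mask))
  K <- max(lab)
  if (K > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    # diagonal neighbour label pairs (down-right and down-left shifts)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]
    a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs)) {
      parent <- seq_len(K)
      find <- function(i) {
        while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
        i
      }
      for (p in seq_len(nrow(pairs))) {
        ra <- find(pairs[p, 1L]); rb <- find(pairs[p, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(K), find, integer(1L))
      lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
  }
  # renumber consecutively by first occurrence
  u <- unique(lab[lab > 0L])
  if (length(u)) {
    remap <- integer(max(u))
    remap[u] <- seq_along(u)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Remove small connected components (noise specks)
#'
#' Belt-reflection specks carry far fewer pixels than any kernel, so they
#' are removed by an area threshold on 8-connected components. Components
#' at or above \code{minArea} are kept bit-identical -- their edge pixels,
#' which the length measurement depends on, are untouched.
#'
#' @param mask logical matrix.
#' @param minArea components with fewer than this many pixels are removed;
#'   0 is the identity.
#' @return logical matrix.
#' @export
removeSmallComponents <- function(mask, minArea) {
  stopifnot(minArea >= 0)
  if (minArea == 0 || !any(mask)) return(mask)
  lab <- labelComponents(mask)
  sizes <- tabulate(lab)
  drop <- which(sizes < minArea)
  if (length(drop)) mask[lab %in% drop] <- FALSE
  mask
}

#' Default speck-removal threshold for an image size
#'
#' 100 px at the 3000x2500 reference scale, scaled by
#' \code{(max(dim)/3000)^2}.
#'
#' @param imageShape integer (rows, cols).
#' @return numeric area threshold in px.
#' @export
defaultMinArea <- function(imageShape) {
  max(1, round(100 * (max(imageShape) / 3000)^2))
}

#' Smooth kernel edges with a single 3x3 median filter
#'
#' For a 0/1 mask the 3x3 median is the majority vote: a pixel becomes
#' foreground iff at least 5 of the 9 pixels in its 3x3 neighbourhood are
#' foreground. The image border is handled by edge replication, so a
#' constant mask is a fixed point. Applied exactly once, after speck
#' removal. Never changes a pixel whose 3x3 neighbourhood is constant;
#' removes isolated pixels and 1-px spurs.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
smoothEdges <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- mask[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc), drop = FALSE]
  ii <- .integralImage(pad)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  s <- .windowSum(ii, rows, rows + 2L, cols, cols + 2L)
  matrix(s >= 5, nr, nc)
}

#' Full preprocessing: threshold, despeckle, smooth
#'
#' @param image numeric intensity matrix.
#' @param minArea speck threshold; NULL = [defaultMinArea()].
#' @param ... passed to [binarize()].
#' @return logical foreground mask.
#' @export
preprocessImage <- function(image, minArea = NULL, ...) {
  if (is.null(minArea)) minArea <- defaultMinArea(dim(image))
  smoothEdges(removeSmallComponents(binarize(image, ...), minArea))
}
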