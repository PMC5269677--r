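#' @include AllClasses.R utils.R
NULL

#' Read a grain image from PNG or TIFF
#'
#' RGB(A) images are converted to a single channel by Rec. 709 luminance.
#' Intensities are returned on a 0--255 scale regardless of the file's
#' bit depth.
#'
#' @param path image file; format decided by extension (.png, .tif(f)).
#' @return numeric intensity matrix (rows x cols).
#' @export
readGrainImage <- function(path) {
  if (!file.exists(path))
    .hryError(paste("cannot read image:", path), "hry_unreadable")
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    .hryError(paste("unsupported image format:", ext), "hry_unreadable"))
  if (length(dim(x)) == 3L) {
    if (dim(x)[3L] >= 3L)
      x <- 0.2126 * x[, , 1L] + 0.7152 * x[, , 2L] + 0.0722 * x[, , 3L]
    else x <- x[, , 1L]
  }
  x * 255
}

#' Export a binary mask as a 0/255 PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Export a label map as an RGB-encoded PNG
#'
#' 16-bit label values are split across the red (high byte) and green
#' (low byte) channels, so up to 65535 kernels round-trip exactly through
#' an ordinary 8-bit RGB PNG; [readLabelsPNG()] decodes.
#'
#' @param labels integer matrix.
#' @param path output path.
#' @export
writeLabelsPNG <- function(labels, path) {
  stopifnot(max(labels) < 65536L)
  arr <- array(0, dim = c(nrow(labels), ncol(labels), 3L))
  arr[, , 1L] <- (labels %/% 256L) / 255
  arr[, , 2L] <- (labels %% 256L) / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname writeLabelsPNG
#' @export
readLabelsPNG <- function(path) {
  arr <- png::readPNG(path)
  matrix(as.integer(round(arr[, , 1L] * 255) * 256L + round(arr[, , 2L] * 255)),
         dim(arr)[1L], dim(arr)[2L])
}

#' Write a synthetic scene to disk
#'
#' Produces \code{<name>.png} (intensity image), \code{<name>_labels.png}
#' (RGB-encoded instance labels) and \code{<name>.json} (per-grain specs,
#' contact table, truth areas, reference length, variety, seed).
#'
#' @param scene a [GrainScene-class].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return invisibly, the three paths written.
#' @export
writeScene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pImg <- file.path(dir, paste0(name, ".png"))
  pLab <- file.path(dir, paste0(name, "_labels.png"))
  pJson <- file.path(dir, paste0(name, ".json"))
  png::writePNG(scene@image / 255, pImg)
  writeLabelsPNG(scene@truthLabels, pLab)
  jsonlite::write_json(
    list(specs = scene@truthSpecs, contacts = scene@contacts,
         refLengthPx = scene@refLengthPx, variety = scene@variety,
         seed = scene@seed,
         truthHeadArea = truthHeadArea(scene),
         truthTotalArea = truthTotalArea(scene)),
    pJson, auto_unbox = TRUE, digits = NA)
  invisible(c(image = pImg, labels = pLab, sidecar = pJson))
}

#' Export an ECMP profile as CSV
#'
#' Columns t, row, col, k -- the boundary-index-versus-ECMP curve whose
#' peaks mark concave points.
#'
#' @param profile an [EcmpProfile-class].
#' @param path output CSV path.
#' @export
writeProfileCSV <- function(profile, path) {
  pts <- profile@boundary@points
  utils::write.csv(data.frame(t = seq_len(nrow(pts)), row = pts[, 1L],
                              col = pts[, 2L], k = profile@k),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export matched concave-point pairs as CSV
#'
#' @param pairs data.frame from [matchConcavePoints()].
#' @param path output CSV path.
#' @export
writePairsCSV <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' Write a separation overlay PNG
#'
#' Foreground in gray, cut lines in red, concave points in green --
#' the visual check that cuts run across necks.
#'
#' @param mask logical foreground mask (before cutting).
#' @param pairs matched pairs (may be NULL).
#' @param points concave-point table (may be NULL).
#' @param path output path.
#' @export
writeOverlayPNG <- function(mask, pairs, points, path) {
  arr <- array(0, dim = c(nrow(mask), ncol(mask), 3L))
  for (ch in 1:3) arr[, , ch][mask] <- 0.7
  if (!is.null(pairs) && nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      ln <- .bresenham(pairs$aRow[i], pairs$aCol[i],
                       pairs$bRow[i], pairs$bCol[i])
      arr[, , 1L][ln] <- 1; arr[, , 2L][ln] <- 0; arr[, , 3L][ln] <- 0
    }
  }
  if (!is.null(points) && nrow(points)) {
    px <- cbind(points$row, points$col)
    arr[, , 1L][px] <- 0; arr[, , 2L][px] <- 1; arr[, , 3L][px] <- 0
  }
  png::writePNG(arr, path)
  invisible(path)
}
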