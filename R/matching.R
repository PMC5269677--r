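#' @include AllClasses.R utils.R concavity.R
NULL

#' Template crossover points of a concave point
#'
#' Walks the boundary both ways from a concave point A until the walk
#' would leave the ECMP template window centred on A; the last pixels
#' still inside (on the window perimeter, Chebyshev distance
#' (templateSize-1)/2 from A for a straight edge) are the crossover points
#' M and N. M and N anchor the collaborative matching wedge.
#'
#' @param mask logical matrix (used to orient the degenerate wedge toward
#'   the local foreground).
#' @param boundary the [Boundary-class] the point lies on.
#' @param tIndex boundary index of the concave point.
#' @param templateSize odd template side used for detection.
#' @return list with \code{A}, \code{M}, \code{N} (each c(row, col)) and
#'   \code{inward}, the unit vector from A toward the local foreground
#'   centre of mass.
#' @export
crossoverPoints <- function(mask, boundary, tIndex, templateSize) {
  pts <- boundary@points
  N <- nrow(pts)
  h <- (templateSize - 1L) %/% 2L
  if (N < 2L * templateSize)
    .hryError("boundary shorter than the template walk", "hry_small_component")
  A <- pts[tIndex, ]
  walk <- function(dirStep) {
    last <- NULL
    for (s in seq_len(N - 1L)) {
      p <- pts[((tIndex - 1L + dirStep * s) %% N) + 1L, ]
      if (max(abs(p - A)) > h) return(last)
      last <- p
    }
    NULL
  }
  M <- walk(1L)
  Np <- walk(-1L)
  if (is.null(M) || is.null(Np))
    .hryError("boundary never leaves the template window", "hry_small_component")
  # local foreground direction, for the degenerate (collinear) wedge
  rr <- max(1L, A[1L] - h):min(nrow(mask), A[1L] + h)
  cc <- max(1L, A[2L] - h):min(ncol(mask), A[2L] + h)
  sub <- mask[rr, cc, drop = FALSE]
  fg <- which(sub, arr.ind = TRUE)
  ctr <- c(mean(rr[fg[, 1L]]), mean(cc[fg[, 2L]])) - A
  nrm <- sqrt(sum(ctr^2))
  inward <- if (nrm > 1e-9) ctr / nrm else c(0, 0)
  list(A = unname(A), M = unname(M), N = unname(Np), inward = inward)
}

#' Admissible matching region of a concave point
#'
#' The collaborative constraint: a candidate matching point for basic
#' point A must lie in the closed wedge with apex A bounded by the rays
#' from A pointing \emph{opposite} to AM and AN -- the continuations of
#' lines MA and NA through A, which point across the neck into the kernel
#' interior. If M, A, N are collinear the wedge degenerates to the open
#' half-plane on the foreground side of the MN line.
#'
#' @param cp a crossover list from [crossoverPoints()] (fields \code{A},
#'   \code{M}, \code{N}, \code{inward}).
#' @return a predicate \code{function(points)} taking an n x 2 matrix (or
#'   length-2 vector) of (row, col) positions and returning a logical
#'   vector.
#' @export
admissibleRegion <- function(cp) {
  A <- as.numeric(cp$A)
  u <- A - as.numeric(cp$M)   # direction opposite AM
  v <- A - as.numeric(cp$N)
  det <- u[1L] * v[2L] - u[2L] * v[1L]
  inward <- as.numeric(cp$inward)
  function(points) {
    if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
    dx <- points[, 1L] - A[1L]
    dy <- points[, 2L] - A[2L]
    if (abs(det) < 1e-9) {
      # collinear crossovers: open half-plane across A from the M-N line,
      # on the side of the local foreground
      return(dx * inward[1L] + dy * inward[2L] > 1e-9)
    }
    alpha <- (dx * v[2L] - dy * v[1L]) / det
    beta <- (u[1L] * dy - u[2L] * dx) / det
    alpha >= -1e-9 & beta >= -1e-9 & (abs(dx) + abs(dy) > 0)
  }
}

#' Build the concave-point table for one component
#'
#' @param mask logical matrix.
#' @param profile an [EcmpProfile-class] with concave points detected
#'   (see [detectConcavePoints()]).
#' @param componentLabel integer recorded with each point.
#' @return data.frame with one row per concave point: component label,
#'   boundary index, position, crossover points M and N and the inward
#'   unit vector.
#' @export
concavePointTable <- function(mask, profile, componentLabel = 1L) {
  idx <- profile@concaveIndices
  if (!length(idx)) return(NULL)
  rows <- lapply(idx, function(t) {
    cp <- crossoverPoints(mask, profile@boundary, t, profile@templateSize)
    data.frame(component = componentLabel, t = t,
               row = cp$A[1L], col = cp$A[2L],
               Mrow = cp$M[1L], Mcol = cp$M[2L],
               Nrow = cp$N[1L], Ncol = cp$N[2L],
               inwardRow = cp$inward[1L], inwardCol = cp$inward[2L])
  })
  do.call(rbind, rows)
}

#' Match concave points under the collaborative constraint
#'
#' Iterates basic points (BP) in boundary order within each component.
#' For each unmatched BP the candidate matching points are the other
#' unmatched concave points of the same component lying inside the BP's
#' admissible wedge; the nearest (Euclidean, ties to the smallest
#' boundary index) becomes its match and both points leave the pool. A BP
#' with no admissible candidate stays unmatched, which is reported by
#' omission, not an error: an unmatched point simply produces no cut.
#'
#' @param points data.frame from [concavePointTable()] (rows of several
#'   components may be concatenated), or NULL/empty.
#' @return data.frame of matched pairs (component, positions of both
#'   points, boundary indices, cut length in px), possibly with 0 rows.
#' @export
matchConcavePoints <- function(points) {
  empty <- data.frame(component = integer(), aT = integer(), bT = integer(),
                      aRow = integer(), aCol = integer(),
                      bRow = integer(), bCol = integer(),
                      cutLength = numeric())
  if (is.null(points) || nrow(points) == 0L) return(empty)
  out <- empty
  for (comp in unique(points$component)) {
    p <- points[points$component == comp, , drop = FALSE]
    p <- p[order(p$t), , drop = FALSE]
    matched <- rep(FALSE, nrow(p))
    for (i in seq_len(nrow(p))) {
      if (matched[i]) next
      cand <- which(!matched & seq_len(nrow(p)) != i)
      if (!length(cand)) next
      wedge <- admissibleRegion(list(
        A = c(p$row[i], p$col[i]), M = c(p$Mrow[i], p$Mcol[i]),
        N = c(p$Nrow[i], p$Ncol[i]),
        inward = c(p$inwardRow[i], p$inwardCol[i])))
      ok <- cand[wedge(cbind(p$row[cand], p$col[cand]))]
      if (!length(ok)) next
      d <- sqrt((p$row[ok] - p$row[i])^2 + (p$col[ok] - p$col[i])^2)
      j <- ok[order(d, p$t[ok])][1L]
      matched[c(i, j)] <- TRUE
      out <- rbind(out, data.frame(
        component = comp, aT = p$t[i], bT = p$t[j],
        aRow = p$row[i], aCol = p$col[i],
        bRow = p$row[j], bCol = p$col[j],
        cutLength = sqrt((p$row[j] - p$row[i])^2 + (p$col[j] - p$col[i])^2)))
    }
  }
  out
}

#' Cut a mask along matched concave-point pairs and relabel
#'
#' Rasterizes each matched pair's segment as a 1-px background line
#' (Bresenham), then relabels the 8-connected components. Components
#' smaller than \code{minFragmentArea} that lie within 2 px of a cut line
#' (cut slivers) are merged back into their largest neighbouring
#' component. Never creates foreground: the summed output component areas
#' equal the input foreground area minus the foreground pixels consumed
#' by the cut lines.
#'
#' @param mask logical matrix.
#' @param pairs data.frame from [matchConcavePoints()].
#' @param minFragmentArea px; 0 disables the fragment guard.
#' @return integer label matrix of the separated kernels.
#' @export
separateGrains <- function(mask, pairs, minFragmentArea = 0) {
  before <- max(labelComponents(mask))
  cut <- mask
  cutPix <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      ln <- .bresenham(pairs$aRow[i], pairs$aCol[i],
                       pairs$bRow[i], pairs$bCol[i])
      cut[ln] <- FALSE
      cutPix <- rbind(cutPix, ln)
    }
  }
  lab <- labelComponents(cut)
  npairs <- if (is.null(pairs)) 0L else nrow(pairs)
  if (npairs > 0L && max(lab) < before + npairs)
    .hryWarning("one or more cuts did not disconnect their component",
                "hry_cut_failed")
  if (minFragmentArea > 0 && max(lab) > 0L && !is.null(cutPix)) {
    sizes <- tabulate(lab)
    small <- which(sizes > 0L & sizes < minFragmentArea)
    for (s in small) {
      px <- which(lab == s, arr.ind = TRUE)
      # near a cut line? (Chebyshev distance <= 2)
      nearCut <- any(vapply(seq_len(nrow(cutPix)), function(j)
        any(pmax(abs(px[, 1L] - cutPix[j, 1L]),
                 abs(px[, 2L] - cutPix[j, 2L])) <= 2L), logical(1L)))
      if (!nearCut) next
      # neighbouring labels within Chebyshev distance 2 (across the cut)
      nb <- integer()
      for (dr in -2:2) for (dc in -2:2) {
        rr <- px[, 1L] + dr; cc <- px[, 2L] + dc
        ok <- rr >= 1L & rr <= nrow(lab) & cc >= 1L & cc <= ncol(lab)
        nb <- c(nb, lab[cbind(rr[ok], cc[ok])])
      }
      nb <- setdiff(unique(nb[nb > 0L]), s)
      if (length(nb)) {
        tgt <- nb[which.max(sizes[nb])]
        lab[lab == s] <- tgt
      }
    }
    # renumber consecutively
    u <- sort(unique(lab[lab > 0L]))
    remap <- integer(max(u)); remap[u] <- seq_along(u)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}
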