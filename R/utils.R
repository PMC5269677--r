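# Internal numeric helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Summed-area table: ii[i+1, j+1] = sum(m[1:i, 1:j]); m coerced to numeric.
.integralImage <- function(m) {
  ii <- apply(m, 2L, cumsum)
  if (is.null(dim(ii))) ii <- matrix(ii, nrow = 1L)
  ii <- t(apply(ii, 1L, cumsum))
  if (nrow(m) == 1L) ii <- matrix(ii, nrow = 1L)
  cbind(0, rbind(0, ii))[seq_len(nrow(m) + 1L), seq_len(ncol(m) + 1L), drop = FALSE]
}

# Rectangle sums over [r0, r1] x [c0, c1] (inclusive, clamped to the image;
# out-of-image area counts as zero). Vectorized over rectangles.
.windowSum <- function(ii, r0, r1, c0, c1) {
  r0 <- as.vector(r0); r1 <- as.vector(r1)
  c0 <- as.vector(c0); c1 <- as.vector(c1)
  nr <- nrow(ii) - 1L
  nc <- ncol(ii) - 1L
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  r1 <- pmin(r1, nr); c1 <- pmin(c1, nc)
  bad <- r0 > r1 | c0 > c1
  r0p <- pmin(r0, nr); c0p <- pmin(c0, nc)
  s <- ii[cbind(r1 + 1L, c1 + 1L)] - ii[cbind(r0p, c1 + 1L)] -
    ii[cbind(r1 + 1L, c0p)] + ii[cbind(r0p, c0p)]
  s[bad] <- 0
  s
}

# Integer line between two pixels (Bresenham), thickened to a 4-connected
# path: diagonal steps insert an intermediate orthogonal pixel, so clearing
# the line severs 8-connectivity across it. Returns a matrix (row, col)
# including both endpoints.
.bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  n <- 2L * (max(dr, dc) + 1L)
  out <- matrix(0L, n, 2L)
  r <- r0; c <- c0
  i <- 0L
  repeat {
    i <- i + 1L
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) break
    e2 <- 2L * err
    stepC <- e2 > -dr
    stepR <- e2 < dc
    if (stepC && stepR) {            # diagonal: bridge with an extra pixel
      i <- i + 1L
      out[i, ] <- c(r, c + sc)
    }
    if (stepC) { err <- err - dr; c <- c + sc }
    if (stepR) { err <- err + dc; r <- r + sr }
  }
  out[seq_len(i), , drop = FALSE]
}

# Condition constructors for structured errors.
.hryError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hryError")))
}
.hryWarning <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "hryWarning")))
}
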