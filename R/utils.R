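`%||%` <- function(a, b) if (is.null(a)) b else a

# Quantize doubles to single precision. ImageStack pixels are held on the
# float32 grid so that the 32-bit TIFF written by write_image() round-trips
# bit-identically.
float32 <- function(x) {
  out <- readBin(writeBin(as.double(x), raw(), size = 4L),
                 "double", n = length(x), size = 4L)
  if (is.array(x)) dim(out) <- dim(x)
  out
}

#' Derive a stream of child seeds from one master seed
#'
#' All randomness in the package flows from a single master seed: any routine
#' that needs several independent random components (animals in a cohort,
#' wells on a plate, ...) draws one child seed per component from this stream.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each usable with [set.seed()].
#' @export
seed_stream <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# Otsu threshold on an intensity matrix, on the matrix's own range.
otsu_threshold <- function(x) {
  rng <- range(x, finite = TRUE)
  if (rng[1] == rng[2]) return(rng[1])
  EBImage::otsu(x, range = rng, levels = 256L)
}

resolve_threshold <- function(threshold, x) {
  if (is.numeric(threshold)) return(threshold)
  if (identical(threshold, "otsu")) return(otsu_threshold(x))
  stop("unknown threshold spec: ", deparse(threshold))
}

# Local maxima of a matrix: pixels strictly greater than every neighbour
# within Chebyshev radius `radius` and strictly above `threshold`.
local_maxima <- function(x, radius = 2L, threshold = -Inf) {
  nr <- nrow(x); nc <- ncol(x)
  is_max <- x > threshold
  pad <- -Inf
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      if (dr == 0 && dc == 0) next
      shifted <- matrix(pad, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      shifted[rs, cs] <- x[rs - dr, cs - dc]
      is_max <- is_max & (x > shifted)
      if (!any(is_max)) break
    }
    if (!any(is_max)) break
  }
  which(is_max, arr.ind = TRUE)
}

# Stamp additive kernels (e.g., Gaussian spots) onto a matrix at integer
# pixel positions. `kernel` is a (2k+1)x(2k+1) matrix.
stamp_kernel <- function(img, rows, cols, kernel, amplitude = 1) {
  k <- (nrow(kernel) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  amplitude <- rep_len(amplitude, length(rows))
  for (i in seq_along(rows)) {
    r0 <- rows[i] - k; r1 <- rows[i] + k
    c0 <- cols[i] - k; c1 <- cols[i] + k
    rr <- max(1, r0):min(nr, r1)
    cc <- max(1, c0):min(nc, c1)
    img[rr, cc] <- img[rr, cc] +
      amplitude[i] * kernel[rr - r0 + 1L, cc - c0 + 1L, drop = FALSE]
  }
  img
}

gaussian_kernel <- function(sd_px, radius = ceiling(3 * sd_px)) {
  ax <- -radius:radius
  g <- exp(-ax^2 / (2 * sd_px^2))
  outer(g, g)
}

disk_kernel <- function(radius_px) {
  r <- ceiling(radius_px)
  ax <- -r:r
  d2 <- outer(ax^2, ax^2, "+")
  (d2 <= radius_px^2) * 1
}
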