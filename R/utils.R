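# Internal helpers: seeded RNG, centered FFT bookkeeping, small validators.

#' @keywords internal
stop_param <- function(...) stop(sprintf(...), call. = FALSE)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_param("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# k-space index convention: on an N-point axis the DC sample sits at 0-based
# index N/2 (1-based N/2 + 1); frequencies run -N/2 ... N/2-1. `fftshift`
# moves DC from index 1 (R's fft convention) to the centered position,
# `ifftshift` is its inverse. Used identically by simulator and recon.
fftshift_idx <- function(n) c((n %/% 2 + 1L):n, 1L:(n %/% 2))
ifftshift_idx <- function(n) c((n - n %/% 2 + 1L):n, 1L:(n - n %/% 2))

fftshift2 <- function(x) x[fftshift_idx(nrow(x)), fftshift_idx(ncol(x)), drop = FALSE]
ifftshift2 <- function(x) x[ifftshift_idx(nrow(x)), ifftshift_idx(ncol(x)), drop = FALSE]

# Centered 2D DFT pair. Analysis direction divides by the grid size so that
# K(0) is the image mean; synthesis is the plain DFT sum, so a same-size
# round trip is the identity and zero-filling preserves values at original
# grid positions.
fft2_centered <- function(img) {
  fftshift2(stats::fft(ifftshift2(img))) / length(img)
}

ifft2_centered <- function(ksp) {
  fftshift2(stats::fft(ifftshift2(ksp), inverse = TRUE))
}

# Central block extraction / centered zero-padding, both DC-preserving.
center_block <- function(x, n1, n2) {
  N1 <- nrow(x); N2 <- ncol(x)
  if (n1 > N1 || n2 > N2) stop_param("requested block (%d x %d) exceeds array (%d x %d)", n1, n2, N1, N2)
  i1 <- (N1 %/% 2 + 1L) + seq.int(-(n1 %/% 2), n1 - n1 %/% 2 - 1L)
  i2 <- (N2 %/% 2 + 1L) + seq.int(-(n2 %/% 2), n2 - n2 %/% 2 - 1L)
  x[i1, i2, drop = FALSE]
}

center_pad <- function(x, n1, n2) {
  N1 <- nrow(x); N2 <- ncol(x)
  if (n1 < N1 || n2 < N2) stop_param("pad size (%d x %d) smaller than array (%d x %d)", n1, n2, N1, N2)
  out <- matrix(complex(real = 0, imaginary = 0), n1, n2)
  i1 <- (n1 %/% 2 + 1L) + seq.int(-(N1 %/% 2), N1 - N1 %/% 2 - 1L)
  i2 <- (n2 %/% 2 + 1L) + seq.int(-(N2 %/% 2), N2 - N2 %/% 2 - 1L)
  out[i1, i2] <- x
  out
}

# Raised-cosine (Hanning) window on an N-point axis with maximum 1 at the
# centered DC index and zero at the first edge sample; sums to exactly N/2.
hanning_window <- function(n) {
  k <- seq_len(n) - 1L - n %/% 2
  0.5 * (1 + cos(2 * pi * k / n))
}

# Subpixel-coverage disk rasterizer on a square grid (mm coordinates, FOV
# centered on 0). Soft one-voxel edge keeps low-k spectra close to the
# continuous disk transform.
disk_coverage <- function(grid_shape, fov, center, radius) {
  n1 <- grid_shape[1]; n2 <- grid_shape[2]
  px <- fov[1] / n1
  x <- (seq_len(n1) - 1 - n1 %/% 2) * px
  y <- (seq_len(n2) - 1 - n2 %/% 2) * (fov[2] / n2)
  r <- sqrt(outer((x - center[1])^2, (y - center[2])^2, "+"))
  pmin(pmax(0.5 + (radius - r) / px, 0), 1)
}

ellipse_mask <- function(grid_shape, fov, center, semi_axes) {
  n1 <- grid_shape[1]; n2 <- grid_shape[2]
  x <- (seq_len(n1) - 1 - n1 %/% 2) * (fov[1] / n1)
  y <- (seq_len(n2) - 1 - n2 %/% 2) * (fov[2] / n2)
  outer(((x - center[1]) / semi_axes[1])^2, ((y - center[2]) / semi_axes[2])^2, "+") <= 1
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
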