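#' Centered unitary 2D Fourier transforms
#'
#' `fft2c()` maps an image-space plane to k-space with the DC sample at index
#' `N/2 + 1` (1-based) along each axis; `ifft2c()` is its exact inverse and,
#' because the transform is unitary ("ortho" normalization), also its adjoint.
#' Both axes must have even length so that the centered convention and the
#' 2x2 KeepCenter block around DC are well defined.
#'
#' @param x complex (or numeric) matrix with even dimensions.
#' @return A complex matrix of the same dimensions.
#' @examples
#' x <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
#' max(Mod(ifft2c(fft2c(x)) - x)) < 1e-12
#' @export
fft2c <- function(x) {
  check_plane(x)
  s <- sqrt(length(x))
  fftshift2(stats::fft(fftshift2(x))) / s
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  check_plane(x)
  s <- sqrt(length(x))
  fftshift2(stats::fft(fftshift2(x), inverse = TRUE)) / s
}

check_plane <- function(x) {
  if (!is.matrix(x)) stop("expected a 2D matrix")
  if (any(dim(x) %% 2L != 0L)) stop("plane dimensions must be even")
  if (!all(is.finite(Re(x))) || !all(is.finite(Im(x))))
    stop("non-finite values in input plane")
  invisible(x)
}

# Swap half-planes; for even N the shift is its own inverse, so one helper
# serves both fftshift and ifftshift.
fftshift2 <- function(x) {
  d <- dim(x)
  i <- c((d[1L] / 2L + 1L):d[1L], 1L:(d[1L] / 2L))
  j <- c((d[2L] / 2L + 1L):d[2L], 1L:(d[2L] / 2L))
  x[i, j, drop = FALSE]
}

shift_index <- function(n) c((n / 2L + 1L):n, 1L:(n / 2L))

# Batched centered unitary FFT over the first two dimensions of an array
# [pe, ro, ...]: fft2c() plane by plane, done with the C-level 2D transform
# per plane, which keeps the unrolled optimization loops fast in plain R.
fft2c_batch <- function(a, inverse = FALSE) {
  d <- dim(a)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) {
    return(if (inverse) ifft2c(a) else fft2c(a))
  }
  pe <- d[1L]; ro <- d[2L]; k <- prod(d[-c(1L, 2L)])
  if (pe %% 2L != 0L || ro %% 2L != 0L) stop("plane dimensions must be even")
  i1 <- shift_index(pe); i2 <- shift_index(ro)
  s <- sqrt(pe * ro)
  m <- array(a, c(pe, ro, k))
  m <- m[i1, i2, , drop = FALSE]
  for (j in seq_len(k))
    m[, , j] <- stats::fft(m[, , j], inverse = inverse)
  m <- m[i1, i2, , drop = FALSE] / s
  array(m, d)
}
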