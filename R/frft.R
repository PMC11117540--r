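#' @include AllClasses.R
NULL

.isPow2 <- function(n) n >= 1L && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

## Chirp exponent base for the stage filters. With convention "complex"
## the scaling factor K = exp(-i*pi*alpha/2) itself multiplies the chirp
## exponent, which makes the filter magnitude grow like
## exp(pi*sin(pi*alpha/2)*(m - N/2)^2 / 2^k): representable only for
## small N (<= 32 in double precision at alpha = 0.5). Convention "real"
## uses the real order alpha in the exponent instead, a pure-phase chirp
## valid at any length. "auto" picks "complex" whenever it cannot
## overflow, else "real".
.chirpBase <- function(alpha, chirp) {
  K <- exp(-1i * pi * alpha / 2)
  switch(chirp, complex = K, real = complex(real = alpha, imaginary = 0))
}

.resolveChirp <- function(N, alpha, chirp = c("auto", "complex", "real")) {
  chirp <- match.arg(chirp)
  if (chirp != "auto") return(chirp)
  ## worst exponent magnitude across stages occurs at k = 1, m = 0
  worst <- pi * abs(sin(pi * alpha / 2)) * (N / 2)^2 / 2
  if (worst < log(.Machine$double.xmax) / 4) "complex" else "real"
}

#' One stage of the fast FrFT filter loop
#'
#' Applies stage \code{k} of the transform to a length-\code{N} complex
#' signal: multiply by the stage chirp filter
#' \eqn{f_k(m) = ((m+1)/2)\,\exp(i\pi K (m-N/2)^2 / 2^k)}, take an
#' N-point FFT, scale by \eqn{K^{2^{k-1}}} with
#' \eqn{K = \exp(-i\pi\alpha/2)}, and inverse-FFT back.
#'
#' @param y complex (or numeric) vector of power-of-two length N.
#' @param k stage index, \code{1 <= k <= log2(N)}.
#' @param alpha fractional transform order.
#' @param chirp \code{"complex"} uses the complex scaling factor K inside
#'   the chirp exponent (as defined; numerically representable only for
#'   small N); \code{"real"} substitutes the real order alpha, giving a
#'   pure-phase chirp valid at any N; \code{"auto"} (default) picks
#'   \code{"complex"} when it cannot overflow.
#' @return Complex vector of length N.
#' @export
stageFilter <- function(y, k, alpha, chirp = c("auto", "complex", "real")) {
  N <- length(y)
  if (!.isPow2(N))
    stop("signal length ", N, " is not a power of two")
  if (k < 1L || k > log2(N)) stop("stage index k out of range 1..log2(N)")
  chirp <- .resolveChirp(N, alpha, chirp)
  K <- exp(-1i * pi * alpha / 2)
  B <- .chirpBase(alpha, chirp)
  m <- seq_len(N) - 1L
  f <- ((m + 1) / 2) * exp(1i * pi * B * (m - N / 2)^2 / 2^k)
  z <- fft(as.complex(y) * f)
  z <- z * K^(2^(k - 1))
  fft(z, inverse = TRUE) / N
}

#' Fast fractional Fourier transform of an EEG epoch
#'
#' Runs the full stage-filter loop (\code{k = 1..log2(N)}) on the input
#' signal and then evaluates the fractional coefficients
#' \deqn{c_k = \frac{1}{N} \sum_{n=0}^{N-1} y(n)\,
#'   e^{-i\pi\alpha (n-N/2)^2/N}\, e^{-i 2\pi n k/N}, \quad k=0..N-1,}
#' i.e. a chirp-modulated DFT of the filtered signal (computed with one
#' FFT). The ordered \eqn{(Re\,c_k, Im\,c_k)} pairs form the 2D scatter
#' used by [extractFeatures()].
#'
#' @param x real (or complex) vector whose length is a power of two.
#' @param alpha fractional transform order (default 0.5).
#' @param chirp stage-chirp convention, see [stageFilter()].
#' @return A [FrFTScatter-class].
#' @examples
#' sc <- fastFrFT(rnorm(64), alpha = 0.5)
#' head(scatterPoints(sc))
#' @export
fastFrFT <- function(x, alpha = 0.5, chirp = c("auto", "complex", "real")) {
  N <- length(x)
  if (!.isPow2(N)) {
    lo <- 2^floor(log2(max(N, 1)))
    stop("signal length ", N, " is not a power of two (nearest valid: ",
         lo, " and ", 2 * lo, ")")
  }
  if (!is.finite(alpha)) stop("alpha must be finite")
  chirp <- .resolveChirp(N, alpha, chirp)
  y <- as.complex(x)
  for (k in seq_len(as.integer(log2(N))))
    y <- stageFilter(y, k, alpha, chirp = chirp)
  n <- seq_len(N) - 1L
  kernel <- exp(-1i * pi * alpha * (n - N / 2)^2 / N)
  coeff <- fft(y * kernel) / N
  new("FrFTScatter", alpha = alpha, coefficients = coeff,
      yFiltered = y, chirp = chirp)
}
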