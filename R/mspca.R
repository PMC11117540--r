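#' @include wavelet.R
NULL

#' Kaiser-style principal component retention
#'
#' Retains the components whose eigenvalue is strictly greater than the
#' mean eigenvalue. If nothing qualifies (for instance when all
#' eigenvalues are equal) the first component is retained, so the
#' retained set is never empty.
#'
#' @param eigenvalues non-negative eigenvalues sorted in descending order.
#' @return Integer indices (1-based) of the retained components.
#' @examples
#' kaiserRetain(c(4, 1, 0.5, 0.5))  # 1
#' kaiserRetain(c(3, 2, 1))         # 1
#' @export
kaiserRetain <- function(eigenvalues) {
  if (length(eigenvalues) == 0L) stop("empty eigenvalue list")
  if (any(eigenvalues < -1e-12)) stop("eigenvalues must be non-negative")
  if (is.unsorted(rev(eigenvalues)))
    stop("eigenvalues must be sorted in descending order")
  keep <- which(eigenvalues > mean(eigenvalues))
  if (length(keep) == 0L) keep <- 1L
  keep
}

## PCA denoising of one band: rows = channels (variables), columns =
## observations. Channels are mean-centered, the covariance across
## channels is eigendecomposed, the data are projected onto the retained
## components and back-projected, and the channel means are restored.
.pcaFilter <- function(band) {
  nch <- nrow(band)
  if (nch < 2L) return(band)
  mu <- rowMeans(band)
  X <- band - mu                      # channels x obs, centered
  S <- (X %*% t(X)) / max(1L, ncol(X) - 1L)
  eig <- eigen(S, symmetric = TRUE)
  keep <- kaiserRetain(pmax(eig$values, 0))
  V <- eig$vectors[, keep, drop = FALSE]
  (V %*% (t(V) %*% X)) + mu
}

#' Multiscale PCA denoising of a multichannel EEG matrix
#'
#' Denoises correlated multichannel signals in four steps: (1) a 5-level
#' Symlet-4 wavelet decomposition of every channel; (2) PCA across
#' channels on each subband coefficient matrix, keeping only the
#' components passing [kaiserRetain()] and back-projecting; (3) the
#' inverse wavelet transform; (4) a final cross-channel PCA of the
#' reconstructed time-domain matrix, again with Kaiser-style retention.
#' The output has the shape of the input.
#'
#' @param signals numeric matrix, channels x time, with at least two
#'   channels (the method exploits cross-channel correlation).
#' @param levels wavelet decomposition depth (default 5).
#' @param finalPca apply the final time-domain PCA stage (default TRUE).
#' @return The denoised channels x time matrix.
#' @examples
#' t <- seq(0, 1, length.out = 256)
#' clean <- rbind(sin(2 * pi * 5 * t), sin(2 * pi * 5 * t + 0.5))
#' noisy <- clean + matrix(rnorm(512, sd = 0.5), nrow = 2)
#' den <- mspcaDenoise(noisy)
#' @export
mspcaDenoise <- function(signals, levels = 5L, finalPca = TRUE) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1L)
  if (nrow(signals) < 2L)
    stop("MSPCA needs at least 2 channels (PCA operates across channels)")
  if (anyNA(signals) || any(!is.finite(signals)))
    stop("signals must be finite")
  dec <- waveletDecompose(signals, levels = levels)
  dec$approx <- .pcaFilter(dec$approx)
  dec$details <- lapply(dec$details, .pcaFilter)
  rec <- waveletReconstruct(dec)
  if (finalPca) rec <- .pcaFilter(rec)
  dimnames(rec) <- dimnames(signals)
  rec
}

#' @rdname mspcaDenoise
#' @param recording an [EEGRecording-class] to denoise.
#' @return \code{denoiseRecording}: the recording with denoised samples.
#' @export
denoiseRecording <- function(recording, levels = 5L, finalPca = TRUE) {
  stopifnot(is(recording, "EEGRecording"))
  initialize(recording,
             samples = mspcaDenoise(recording@samples, levels = levels,
                                    finalPca = finalPca))
}
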