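#' @include AllClasses.R
NULL

## Symlet-4 analysis low-pass filter (standard published coefficients).
## The remaining three filters follow from the orthogonal QMF relations.
.SYM4_DEC_LO <- c(-0.075765714789273325, -0.02963552764599851,
                  0.49761866763201545, 0.80373875180591614,
                  0.29785779560527736, -0.099219543576847216,
                  -0.012603967262037833, 0.032223100604042702)
.SYM4_DEC_HI <- rev(.SYM4_DEC_LO) * (-1)^(seq_along(.SYM4_DEC_LO))
.SYM4_REC_LO <- rev(.SYM4_DEC_LO)
.SYM4_REC_HI <- rev(.SYM4_DEC_HI)

## Whole-sample symmetric extension by k samples on each side:
## x3 x2 x1 | x1 x2 ... xn | xn xn-1 xn-2
.symext <- function(x, k) {
  n <- length(x)
  if (k >= n) stop("signal too short for symmetric extension")
  x[c(rev(seq_len(k)), seq_len(n), n + 1L - seq_len(k))]
}

.convFull <- function(x, f) {
  # linear convolution via FFT (lengths here are a few thousand at most)
  stats::convolve(x, rev(f), type = "open")
}

## Single-level analysis step, symmetric boundary extension.
## Output length floor((n + F - 1) / 2) per band.
.dwtStep <- function(x) {
  Fl <- length(.SYM4_DEC_LO)
  ext <- .symext(x, Fl - 1L)
  nout <- (length(x) + Fl - 1L) %/% 2L
  pick <- 2L * seq_len(nout) + Fl - 1L
  list(a = .convFull(ext, .SYM4_DEC_LO)[pick],
       d = .convFull(ext, .SYM4_DEC_HI)[pick])
}

## Single-level synthesis step: exact inverse of .dwtStep for length n.
.idwtStep <- function(a, d, n) {
  Fl <- length(.SYM4_REC_LO)
  up <- function(cf) {
    u <- numeric(2L * length(cf))
    u[seq(1L, by = 2L, length.out = length(cf))] <- cf
    u
  }
  y <- .convFull(up(a), .SYM4_REC_LO) + .convFull(up(d), .SYM4_REC_HI)
  y[(Fl - 1L):(Fl - 2L + n)]
}

#' Multilevel Symlet-4 wavelet decomposition of multichannel signals
#'
#' Applies a 5-level (by default) discrete wavelet transform with the
#' Symlet-4 mother wavelet and symmetric boundary extension to every
#' channel (row) of the input matrix. The result stores, per band, a
#' channels-by-coefficients matrix: one approximation band at the
#' deepest level and one detail band per level.
#'
#' @param signals numeric matrix, channels x time (a vector is treated as
#'   one channel).
#' @param levels decomposition depth (default 5).
#' @return A list with elements \code{approx} (matrix), \code{details}
#'   (list of matrices, level 1 = finest first), \code{waveletName},
#'   \code{levels} and \code{origLengths} (per-level input lengths needed
#'   for exact inversion).
#' @examples
#' x <- matrix(rnorm(2 * 512), nrow = 2)
#' dec <- waveletDecompose(x)
#' max(abs(waveletReconstruct(dec) - x)) < 1e-8
#' @export
waveletDecompose <- function(signals, levels = 5L) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1L)
  levels <- as.integer(levels)
  if (ncol(signals) < 2L^levels)
    stop("input length ", ncol(signals), " too short for ", levels,
         " decomposition levels (need >= ", 2L^levels, ")")
  nch <- nrow(signals)
  details <- vector("list", levels)
  origLengths <- integer(levels)
  cur <- lapply(seq_len(nch), function(i) signals[i, ])
  for (lev in seq_len(levels)) {
    origLengths[lev] <- length(cur[[1]])
    step <- lapply(cur, .dwtStep)
    details[[lev]] <- do.call(rbind, lapply(step, `[[`, "d"))
    cur <- lapply(step, `[[`, "a")
  }
  list(approx = do.call(rbind, cur), details = details,
       waveletName = "sym4", levels = levels, origLengths = origLengths)
}

#' @rdname waveletDecompose
#' @param dec a decomposition produced by \code{waveletDecompose}.
#' @return \code{waveletReconstruct}: the reconstructed channels x time
#'   matrix (exact inverse up to numerical round-off).
#' @export
waveletReconstruct <- function(dec) {
  nch <- nrow(dec$approx)
  cur <- lapply(seq_len(nch), function(i) dec$approx[i, ])
  for (lev in rev(seq_len(dec$levels))) {
    n <- dec$origLengths[lev]
    cur <- lapply(seq_len(nch), function(i)
      .idwtStep(cur[[i]], dec$details[[lev]][i, ], n))
  }
  do.call(rbind, cur)
}
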