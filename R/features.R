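#' @include AllClasses.R
NULL

#' Canonical names of the 34 graphical features
#'
#' Order: SCCA, SCTA, SHCA, SDHC, SAHC, SSVL, SH45, SH135, AOCT, SDTC,
#' SATP, TACR, SCRA, TDSD, ELPA, CTM1..CTM19.
#' @return Character vector of length 34.
#' @export
graphicalFeatureNames <- function() {
  c("SCCA", "SCTA", "SHCA", "SDHC", "SAHC", "SSVL", "SH45", "SH135",
    "AOCT", "SDTC", "SATP", "TACR", "SCRA", "TDSD", "ELPA",
    sprintf("CTM%d", 1:19))
}

.asPoints <- function(points) {
  if (is(points, "FrFTScatter")) points <- scatterPoints(points)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be an N x 2 matrix")
  if (nrow(points) < 1L) stop("empty point cloud")
  if (anyNA(points) || any(!is.finite(points)))
    stop("points must be finite")
  unname(points)
}

## consecutive step vectors and their lengths
.steps <- function(p) {
  n <- nrow(p)
  if (n < 2L) return(matrix(numeric(), 0L, 2L))
  p[-1L, , drop = FALSE] - p[-n, , drop = FALSE]
}

#' Graphical features of an ordered 2D scatter
#'
#' Each function computes one (or one family) of the 34 geometric
#' descriptors of the ordered point cloud \eqn{P_i = (x_i, y_i)} produced
#' by [fastFrFT()]. Points may be given as an N x 2 matrix or as a
#' [FrFTScatter-class]. The "coordinate center" is the origin (0, 0).
#'
#' \describe{
#'   \item{\code{featSCCA} (F1)}{sum of circle areas with consecutive-point
#'     distance as diameter: \eqn{\sum \pi (d_i/2)^2}.}
#'   \item{\code{featSCTA} (F2)}{sum of triangle areas over consecutive
#'     point triples.}
#'   \item{\code{featHeron} (F3-F5)}{per consecutive triple, the
#'     circumcircle ("Heron's circular") via Heron's formula: returns the
#'     summed circumcircle areas (SHCA), the summed distances between
#'     successive circumcenters (SDHC), and the summed interior angles of
#'     successive circumcenter triples (SAHC). Degenerate (near-collinear)
#'     triples are skipped.}
#'   \item{\code{featSSVL} (F6)}{sum of consecutive-point distances.}
#'   \item{\code{featDiag} (F7, F8)}{summed point distances to the
#'     45-degree line (SH45) and to the 135-degree line (SH135).}
#'   \item{\code{featAOCT} (F9)}{area of the octagon obtained by
#'     intersecting the eight support half-planes at 45-degree spaced
#'     directions.}
#'   \item{\code{featSDTC} (F10)}{summed distances to the origin.}
#'   \item{\code{featSATP} (F11)}{summed interior angles at the middle
#'     point of consecutive triples, in radians.}
#'   \item{\code{featTACR} (F12)}{summed areas of triangles formed by
#'     consecutive point pairs and the origin.}
#'   \item{\code{featSCRA} (F13)}{summed per-point rectangle areas with
#'     sides equal to the two diagonal-line distances.}
#'   \item{\code{featTDSD} (F14)}{SD1 + SD2: sample standard deviations of
#'     the projections onto the two diagonal directions (Poincare-style
#'     descriptors).}
#'   \item{\code{featELPA} (F15)}{area of the covariance ellipse,
#'     \eqn{\pi\sqrt{\lambda_1 \lambda_2}}.}
#'   \item{\code{featCTM} (F16-F34)}{central tendency measures: the
#'     fraction of points within radius \eqn{(k/20)\,r_{max}} of the
#'     origin, for \eqn{k = 1..19}.}
#' }
#'
#' @param points N x 2 matrix of coordinates or a [FrFTScatter-class].
#' @return A single numeric value, except \code{featHeron} (length-3
#'   vector), \code{featDiag} (length-2) and \code{featCTM} (length-19).
#' @name graphicalFeatures
#' @examples
#' featSCCA(rbind(c(0, 0), c(2, 0)))       # pi
#' featSDTC(rbind(c(3, 4)))                # 5
#' featCTM(cbind(1:10, 0))[c(1, 2, 19)]    # 0, 0.1, 0.9
NULL

#' @rdname graphicalFeatures
#' @export
featSCCA <- function(points) {
  s <- .steps(.asPoints(points))
  if (nrow(s) == 0L) return(0)
  d2 <- rowSums(s^2)
  sum(pi * d2 / 4)
}

#' @rdname graphicalFeatures
#' @export
featSCTA <- function(points) {
  p <- .asPoints(points)
  n <- nrow(p)
  if (n < 3L) return(0)
  u <- p[2:(n - 1L), , drop = FALSE] - p[1:(n - 2L), , drop = FALSE]
  v <- p[3:n, , drop = FALSE] - p[1:(n - 2L), , drop = FALSE]
  sum(abs(u[, 1] * v[, 2] - u[, 2] * v[, 1]) / 2)
}

## circumcenters of consecutive triples; NA rows for degenerate triples
.circumData <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(list(R = numeric(), C = matrix(numeric(), 0L, 2L)))
  A <- p[1:(n - 2L), , drop = FALSE]
  B <- p[2:(n - 1L), , drop = FALSE]
  D <- p[3:n, , drop = FALSE]
  a <- sqrt(rowSums((B - D)^2))   # side opposite A
  b <- sqrt(rowSums((A - D)^2))
  cc <- sqrt(rowSums((A - B)^2))
  cross <- (B[, 1] - A[, 1]) * (D[, 2] - A[, 2]) -
           (B[, 2] - A[, 2]) * (D[, 1] - A[, 1])
  area <- abs(cross) / 2
  scale2 <- pmax(a, b, cc)^2
  ok <- area > 1e-12 * pmax(scale2, .Machine$double.xmin)
  R <- ifelse(ok, (a * b * cc) / (4 * area), NA_real_)
  ## circumcenter in A-relative coordinates (avoids cancellation of
  ## large squared magnitudes for distant, nearly collinear triples)
  bx <- B[, 1] - A[, 1]; by <- B[, 2] - A[, 2]
  dx <- D[, 1] - A[, 1]; dy <- D[, 2] - A[, 2]
  den <- 2 * (bx * dy - by * dx)
  b2 <- bx^2 + by^2
  d2 <- dx^2 + dy^2
  ux <- A[, 1] + (dy * b2 - by * d2) / den
  uy <- A[, 2] + (bx * d2 - dx * b2) / den
  C <- cbind(ux, uy)
  C[!ok, ] <- NA_real_
  list(R = R[ok], C = C[ok, , drop = FALSE])
}

#' @rdname graphicalFeatures
#' @export
featHeron <- function(points) {
  p <- .asPoints(points)
  cd <- .circumData(p)
  shca <- sum(pi * cd$R^2)
  C <- cd$C
  sdhc <- if (nrow(C) >= 2L) sum(sqrt(rowSums(.steps(C)^2))) else 0
  sahc <- if (nrow(C) >= 3L) .sumTripleAngles(C) else 0
  c(SHCA = shca, SDHC = sdhc, SAHC = sahc)
}

## sum of interior angles at the middle vertex of consecutive triples;
## triples with a zero-length arm are skipped
.sumTripleAngles <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  u <- p[1:(n - 2L), , drop = FALSE] - p[2:(n - 1L), , drop = FALSE]
  v <- p[3:n, , drop = FALSE] - p[2:(n - 1L), , drop = FALSE]
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  ok <- nu > 0 & nv > 0
  if (!any(ok)) return(0)
  cosang <- (u[ok, 1] * v[ok, 1] + u[ok, 2] * v[ok, 2]) / (nu[ok] * nv[ok])
  sum(acos(pmin(1, pmax(-1, cosang))))
}

#' @rdname graphicalFeatures
#' @export
featSSVL <- function(points) {
  s <- .steps(.asPoints(points))
  if (nrow(s) == 0L) return(0)
  sum(sqrt(rowSums(s^2)))
}

#' @rdname graphicalFeatures
#' @export
featDiag <- function(points) {
  p <- .asPoints(points)
  c(SH45 = sum(abs(p[, 1] - p[, 2])) / sqrt(2),
    SH135 = sum(abs(p[, 1] + p[, 2])) / sqrt(2))
}

#' @rdname graphicalFeatures
#' @export
featAOCT <- function(points) {
  p <- .asPoints(points)
  theta <- (0:7) * pi / 4
  ct <- cos(theta); st <- sin(theta)
  h <- vapply(1:8, function(j) max(p[, 1] * ct[j] + p[, 2] * st[j]),
              numeric(1))
  ## vertex j = intersection of support lines j and j+1
  verts <- matrix(0, 8L, 2L)
  for (j in 1:8) {
    jn <- if (j == 8L) 1L else j + 1L
    A <- rbind(c(ct[j], st[j]), c(ct[jn], st[jn]))
    verts[j, ] <- solve(A, c(h[j], h[jn]))
  }
  x <- verts[, 1]; y <- verts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' @rdname graphicalFeatures
#' @export
featSDTC <- function(points) {
  p <- .asPoints(points)
  sum(sqrt(rowSums(p^2)))
}

#' @rdname graphicalFeatures
#' @export
featSATP <- function(points) {
  .sumTripleAngles(.asPoints(points))
}

#' @rdname graphicalFeatures
#' @export
featTACR <- function(points) {
  p <- .asPoints(points)
  n <- nrow(p)
  if (n < 2L) return(0)
  a <- p[-n, , drop = FALSE]
  b <- p[-1L, , drop = FALSE]
  sum(abs(a[, 1] * b[, 2] - a[, 2] * b[, 1]) / 2)
}

#' @rdname graphicalFeatures
#' @export
featSCRA <- function(points) {
  p <- .asPoints(points)
  sum((abs(p[, 1] - p[, 2]) / sqrt(2)) * (abs(p[, 1] + p[, 2]) / sqrt(2)))
}

#' @rdname graphicalFeatures
#' @export
featTDSD <- function(points) {
  p <- .asPoints(points)
  if (nrow(p) < 2L) return(0)
  proj2 <- (p[, 1] + p[, 2]) / sqrt(2)   # along the identity line (SD2)
  proj1 <- (p[, 2] - p[, 1]) / sqrt(2)   # perpendicular to it (SD1)
  sd(proj1) + sd(proj2)
}

#' @rdname graphicalFeatures
#' @export
featELPA <- function(points) {
  p <- .asPoints(points)
  if (nrow(p) < 2L) return(0)
  S <- stats::cov(p)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  pi * sqrt(prod(pmax(ev, 0)))
}

#' @rdname graphicalFeatures
#' @export
featCTM <- function(points) {
  p <- .asPoints(points)
  r <- sqrt(rowSums(p^2))
  rmax <- max(r)
  if (rmax == 0) return(setNames(rep(1, 19), sprintf("CTM%d", 1:19)))
  ks <- 1:19
  v <- vapply(ks, function(k) mean(r <= (k / 20) * rmax), numeric(1))
  setNames(v, sprintf("CTM%d", ks))
}

#' Extract all 34 graphical features from a scatter
#'
#' Assembles the full feature vector in the canonical
#' [graphicalFeatureNames()] order.
#'
#' @param points N x 2 coordinate matrix or a [FrFTScatter-class].
#' @return Named numeric vector of length 34.
#' @examples
#' extractFeatures(cbind(rnorm(50), rnorm(50)))
#' @export
extractFeatures <- function(points) {
  p <- .asPoints(points)
  heron <- featHeron(p)
  diag2 <- featDiag(p)
  v <- c(SCCA = featSCCA(p), SCTA = featSCTA(p), heron,
         SSVL = featSSVL(p), diag2, AOCT = featAOCT(p),
         SDTC = featSDTC(p), SATP = featSATP(p), TACR = featTACR(p),
         SCRA = featSCRA(p), TDSD = featTDSD(p), ELPA = featELPA(p),
         featCTM(p))
  stopifnot(identical(names(v), graphicalFeatureNames()))
  v
}

#' Feature extraction for a whole epoch set
#'
#' Runs [fastFrFT()] and [extractFeatures()] on every epoch and stacks
#' the results with the epoch labels.
#'
#' @param epochs an [EpochSet-class].
#' @param alpha fractional transform order (default 0.5).
#' @param chirp stage-chirp convention, see [stageFilter()].
#' @return A [FeatureSet-class] with one row per epoch.
#' @export
epochFeatures <- function(epochs, alpha = 0.5,
                          chirp = c("auto", "complex", "real")) {
  stopifnot(is(epochs, "EpochSet"))
  chirp <- match.arg(chirp)
  n <- length(epochs)
  vals <- matrix(0, n, 34L)
  for (i in seq_len(n)) {
    sc <- fastFrFT(epochs@samples[i, ], alpha = alpha, chirp = chirp)
    vals[i, ] <- extractFeatures(sc)
  }
  FeatureSet(vals, labels = epochs@label)
}
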