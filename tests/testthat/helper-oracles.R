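# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: plain loops, direct DFT sums, polygon clipping.

# ---- fast FrFT: literal O(N^2) evaluation of the three formulas ----
directFrFT <- function(x, alpha, chirp = c("complex", "real")) {
  chirp <- match.arg(chirp)
  N <- length(x)
  K <- exp(-1i * pi * alpha / 2)
  B <- if (chirp == "complex") K else complex(real = alpha)
  dftDirect <- function(v, sign) {
    out <- complex(N)
    for (k in 0:(N - 1)) {
      s <- 0i
      for (n in 0:(N - 1)) s <- s + v[n + 1] * exp(sign * 2i * pi * n * k / N)
      out[k + 1] <- s
    }
    out
  }
  y <- as.complex(x)
  for (k in seq_len(log2(N))) {
    f <- complex(N)
    for (m in 0:(N - 1))
      f[m + 1] <- ((m + 1) / 2) * exp(1i * pi * B * (m - N / 2)^2 / 2^k)
    z <- dftDirect(y * f, -1)
    z <- z * K^(2^(k - 1))
    y <- dftDirect(z, +1) / N
  }
  cc <- complex(N)
  for (k in 0:(N - 1)) {
    s <- 0i
    for (n in 0:(N - 1))
      s <- s + y[n + 1] * exp(-1i * pi * alpha * (n - N / 2)^2 / N) *
        exp(-2i * pi * n * k / N)
    cc[k + 1] <- s / N
  }
  cc
}

# ---- geometric features, naive loop implementations ----

.oDist <- function(a, b) sqrt(sum((a - b)^2))

.oCircumcenter <- function(A, B, D) {
  # in A-relative coordinates, solve |C'|^2 = |C'-b|^2 = |C'-d|^2,
  # i.e. 2 b.C' = |b|^2 and 2 d.C' = |d|^2, then translate back
  b <- B - A; d <- D - A
  M <- rbind(2 * b, 2 * d)
  A + solve(M, c(sum(b^2), sum(d^2)))
}

.oTriples <- function(p) {
  n <- nrow(p)
  if (n < 3) return(list())
  lapply(seq_len(n - 2), function(i) list(A = p[i, ], B = p[i + 1, ],
                                          D = p[i + 2, ]))
}

.oAngleAt <- function(P, Q, R) {
  # interior angle at Q
  u <- P - Q; v <- R - Q
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  acos(min(1, max(-1, sum(u * v) / (nu * nv))))
}

# Sutherland-Hodgman clip of a polygon by half-plane n.x <= h
.oClip <- function(poly, nvec, h) {
  out <- matrix(numeric(), 0, 2)
  np <- nrow(poly)
  for (i in seq_len(np)) {
    cur <- poly[i, ]; nxt <- poly[if (i == np) 1 else i + 1, ]
    curIn <- sum(nvec * cur) <= h + 1e-9
    nxtIn <- sum(nvec * nxt) <= h + 1e-9
    if (curIn) out <- rbind(out, cur)
    if (curIn != nxtIn) {
      t <- (h - sum(nvec * cur)) / (sum(nvec * nxt) - sum(nvec * cur))
      out <- rbind(out, cur + t * (nxt - cur))
    }
  }
  out
}

.oShoelace <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]
  }
  abs(s) / 2
}

oracleFeatures <- function(p) {
  p <- unname(as.matrix(p))
  n <- nrow(p)
  out <- numeric(0)

  scca <- 0
  if (n >= 2) for (i in seq_len(n - 1))
    scca <- scca + pi * (.oDist(p[i, ], p[i + 1, ]) / 2)^2

  scta <- 0
  for (tr in .oTriples(p)) {
    u <- tr$B - tr$A; v <- tr$D - tr$A
    scta <- scta + abs(u[1] * v[2] - u[2] * v[1]) / 2
  }

  centers <- matrix(numeric(), 0, 2); radii <- numeric(0)
  for (tr in .oTriples(p)) {
    a <- .oDist(tr$B, tr$D); b <- .oDist(tr$A, tr$D); cc <- .oDist(tr$A, tr$B)
    # area from coordinates (cross product): Heron's side-based formula
    # cannot represent a needle triangle's height once it falls below
    # the rounding of the side lengths, so it is avoided here
    u <- tr$B - tr$A; v <- tr$D - tr$A
    area <- abs(u[1] * v[2] - u[2] * v[1]) / 2
    if (area > 1e-12 * max(a, b, cc)^2) {
      radii <- c(radii, a * b * cc / (4 * area))
      centers <- rbind(centers, .oCircumcenter(tr$A, tr$B, tr$D))
    }
  }
  shca <- sum(pi * radii^2)
  sdhc <- 0
  if (nrow(centers) >= 2) for (i in seq_len(nrow(centers) - 1))
    sdhc <- sdhc + .oDist(centers[i, ], centers[i + 1, ])
  sahc <- 0
  if (nrow(centers) >= 3) for (i in seq_len(nrow(centers) - 2)) {
    ang <- .oAngleAt(centers[i, ], centers[i + 1, ], centers[i + 2, ])
    if (!is.na(ang)) sahc <- sahc + ang
  }

  ssvl <- 0
  if (n >= 2) for (i in seq_len(n - 1)) ssvl <- ssvl + .oDist(p[i, ], p[i + 1, ])

  sh45 <- sum(sapply(seq_len(n), function(i) abs(p[i, 1] - p[i, 2]) / sqrt(2)))
  sh135 <- sum(sapply(seq_len(n), function(i) abs(p[i, 1] + p[i, 2]) / sqrt(2)))

  # octagon: clip a huge square by the 8 support half-planes
  big <- 10 * (max(abs(p)) + 1)
  poly <- rbind(c(-big, -big), c(big, -big), c(big, big), c(-big, big))
  for (j in 0:7) {
    nvec <- c(cos(j * pi / 4), sin(j * pi / 4))
    h <- max(apply(p, 1, function(q) sum(nvec * q)))
    poly <- .oClip(poly, nvec, h)
    if (nrow(poly) == 0) break
  }
  aoct <- .oShoelace(poly)

  sdtc <- sum(sapply(seq_len(n), function(i) .oDist(p[i, ], c(0, 0))))

  satp <- 0
  for (tr in .oTriples(p)) {
    ang <- .oAngleAt(tr$A, tr$B, tr$D)
    if (!is.na(ang)) satp <- satp + ang
  }

  tacr <- 0
  if (n >= 2) for (i in seq_len(n - 1))
    tacr <- tacr + abs(p[i, 1] * p[i + 1, 2] - p[i + 1, 1] * p[i, 2]) / 2

  scra <- sum(sapply(seq_len(n), function(i)
    (abs(p[i, 1] - p[i, 2]) / sqrt(2)) * (abs(p[i, 1] + p[i, 2]) / sqrt(2))))

  tdsd <- 0
  if (n >= 2) {
    pr1 <- sapply(seq_len(n), function(i) (p[i, 2] - p[i, 1]) / sqrt(2))
    pr2 <- sapply(seq_len(n), function(i) (p[i, 2] + p[i, 1]) / sqrt(2))
    sdv <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))
    tdsd <- sdv(pr1) + sdv(pr2)
  }

  elpa <- 0
  if (n >= 2) {
    mx <- mean(p[, 1]); my <- mean(p[, 2])
    sxx <- sum((p[, 1] - mx)^2) / (n - 1)
    syy <- sum((p[, 2] - my)^2) / (n - 1)
    sxy <- sum((p[, 1] - mx) * (p[, 2] - my)) / (n - 1)
    tr2 <- (sxx + syy) / 2
    disc <- sqrt(max(0, tr2^2 - (sxx * syy - sxy^2)))
    l1 <- tr2 + disc; l2 <- tr2 - disc
    elpa <- pi * sqrt(max(0, l1) * max(0, l2))
  }

  r <- sapply(seq_len(n), function(i) .oDist(p[i, ], c(0, 0)))
  rmax <- max(r)
  ctm <- if (rmax == 0) rep(1, 19) else
    sapply(1:19, function(k) sum(r <= k / 20 * rmax) / n)

  c(scca, scta, shca, sdhc, sahc, ssvl, sh45, sh135, aoct, sdtc, satp,
    tacr, scra, tdsd, elpa, ctm)
}

# relative error against the oracle, on the scale of the largest entry
relErr <- function(got, want) {
  max(abs(got - want)) / max(max(abs(want)), 1e-12)
}
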