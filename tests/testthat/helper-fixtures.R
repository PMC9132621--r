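# Shared fixtures, built in code at test time.

# Smooth two-axis ramp image with known analytic values.
makeRamp <- function(h, w) {
  outer(seq_len(h) / h, seq_len(w) / w, function(a, b) (a + b) / 2)
}

# Sinusoidal grating whose gradient orientation (unsigned, degrees) is
# `angleDeg` everywhere.
makeGrating <- function(side, angleDeg, wavelength = 8) {
  th <- angleDeg * pi / 180
  xy <- seq_len(side)
  Xc <- matrix(xy, side, side, byrow = TRUE)
  Yc <- matrix(xy, side, side)
  u <- cos(th) * Xc + sin(th) * Yc
  0.5 + 0.4 * sin(2 * pi * u / wavelength)
}

# Brute-force average pooling by explicit double loop (independent oracle).
poolOracle <- function(m, f) {
  h2 <- nrow(m) / f; w2 <- ncol(m) / f
  out <- matrix(0, h2, w2)
  for (i in seq_len(h2))
    for (j in seq_len(w2))
      out[i, j] <- mean(m[(i - 1) * f + 1:f, (j - 1) * f + 1:f])
  out
}

# Looped Sobel oracle with symmetric padding (pad mirrors the edge pixel).
sobelOracle <- function(p) {
  h <- nrow(p); w <- ncol(p)
  idx <- function(i, n) if (i < 1) 1 else if (i > n) n else i
  Sx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  Sy <- t(Sx)
  gx <- gy <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ax <- ay <- 0
    for (di in -1:1) for (dj in -1:1) {
      v <- p[idx(i + di, h), idx(j + dj, w)]
      ax <- ax + Sx[di + 2, dj + 2] * v
      ay <- ay + Sy[di + 2, dj + 2] * v
    }
    gx[i, j] <- ax; gy[i, j] <- ay
  }
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2),
       angle = (atan2(gy, gx) * 180 / pi) %% 180)
}

# Brute-force chi-square: equal-width binning + explicit contingency table.
chi2Oracle <- function(x, y, nBins) {
  rng <- range(x)
  if (diff(rng) <= 0) return(0)
  b <- pmin(floor((x - rng[1]) / diff(rng) * nBins) + 1, nBins)
  tab <- table(factor(b, levels = seq_len(nBins)), y)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum(ifelse(E > 0, (tab - E)^2 / E, 0))
}

# Mann-Whitney formulation of the AUC (rank-statistic oracle).
aucOracle <- function(yTrue, scores, positive) {
  pos <- scores[yTrue == positive]
  neg <- scores[yTrue != positive]
  s <- 0
  for (a in pos) s <- s + sum(a > neg) + 0.5 * sum(a == neg)
  s / (length(pos) * length(neg))
}

# Tiny labeled feature set: `nInf` columns carry the class signal, the rest
# are uniform noise.
makeInformative <- function(n, p, nInf, sd = 0.3, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), length.out = n))
  X <- matrix(runif(n * p), n)
  for (j in seq_len(nInf))
    X[, j] <- (as.numeric(y) - 1) + rnorm(n, 0, sd)
  list(X = X, y = y)
}

# Small standardized synthetic image cached across tests.
syntheticImage <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateSyntheticImages(nPerClass = 1, seed = 42)$images[[1]]
    cache
  }
})
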