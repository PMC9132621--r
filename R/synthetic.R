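#' Multiplicative gamma speckle
#'
#' Multiplies each pixel by an i.i.d. unit-mean gamma variate with shape
#' `looks` (variance `1/looks`), the fully-developed-speckle model for
#' ultrasound, then clips to `[0, 1]`. Before clipping the expectation of
#' every pixel equals its input value.
#'
#' @param img numeric intensity matrix in `[0, 1]`.
#' @param looks positive gamma shape; larger = weaker speckle.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return speckled matrix, clipped to `[0, 1]`.
#' @export
speckle <- function(img, looks = 4, seed = NULL) {
  .checkGray(img)
  if (!is.numeric(looks) || length(looks) != 1L || !is.finite(looks) ||
      looks <= 0)
    stop("'looks' must be a single positive number", call. = FALSE)
  draw <- function() matrix(rgamma(length(img), shape = looks,
                                   rate = looks), nrow(img))
  G <- if (is.null(seed)) draw() else .withSeed(seed, draw())
  out <- img * G
  out[out > 1] <- 1
  out[out < 0] <- 0
  out
}

# Separable Gaussian blur with edge-clamped padding.
.gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad <- function(x) x[c(rep(1L, r), seq_len(nrow(x)), rep(nrow(x), r)), ,
                       drop = FALSE]
  conv1 <- function(x) {
    xp <- pad(x)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k))
      out <- out + k[i] * xp[(i - 1L) + seq_len(nrow(x)), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

# Deterministic structural component of one image, given pre-drawn shape
# parameters; amplitude scales linearly with separability.
.linePhenotype <- function(side, separability, pars) {
  xy <- seq_len(side) / side - 0.5
  Xc <- matrix(xy, side, side, byrow = TRUE)
  Yc <- matrix(xy, side, side)
  th <- pars$theta
  u <- cos(th) * Xc + sin(th) * Yc          # across-line coordinate
  v <- -sin(th) * Xc + cos(th) * Yc         # along-line coordinate
  amp <- 0.55 * separability
  sigma <- pars$lineWidth
  env <- exp(-(v / 0.28)^2)                 # lines fade away from center
  S <- matrix(0, side, side)
  for (o in pars$offsets) {
    d <- u - o - pars$curvature * (v - pars$v0)^2
    S <- S + amp * exp(-d^2 / (2 * sigma^2)) * env
  }
  S
}

.domePhenotype <- function(side, separability, pars) {
  xy <- seq_len(side) / side - 0.5
  Xc <- matrix(xy, side, side, byrow = TRUE)
  Yc <- matrix(xy, side, side)
  amp <- 0.55 * separability
  # dome: bright ellipsoidal blob, brighter toward its upper rim
  dx <- (Xc - pars$cx) / pars$ax
  dy <- (Yc - pars$cy) / pars$ay
  r2 <- dx^2 + dy^2
  dome <- amp * exp(-r2^1.3) * (1 + 0.35 * pmin(pmax(-dy, 0), 1))
  # midline echogenic streak at the dome base, roughly vertical
  sx <- Xc - pars$cx - pars$tilt * (Yc - pars$cy)
  inSeg <- (Yc > pars$cy) & (Yc < pars$cy + pars$segLen)
  streak <- amp * 0.9 * exp(-sx^2 / (2 * pars$streakWidth^2)) * inSeg
  dome + streak
}

#' Generate a two-phenotype synthetic ultrasound-like dataset
#'
#' Class `"female"` images contain 2-4 bright parallel curvilinear bands
#' (random orientation, spacing and curvature); class `"male"` images a
#' dome-shaped bright blob with a midline echogenic streak — the
#' directional-versus-blob contrast the hybrid LPQ+HOG descriptor targets.
#' Structure amplitude scales linearly with `separability` (0 makes the two
#' classes identically distributed). Both classes share a smooth seeded
#' background, mild Gaussian blur, and unit-mean multiplicative gamma
#' speckle. Output is bit-reproducible given `seed`.
#'
#' @param nPerClass images per class (default 60, the benchmark size).
#' @param side image side in pixels (default 256).
#' @param separability structural contrast in `[0, 1]` (default 0.7).
#' @param speckleLooks gamma shape of the speckle (default 4).
#' @param seed integer seed.
#' @param dir optional output directory; when given, PNG images, a
#'   `manifest.csv` (columns path, label) and a `config.json` sidecar are
#'   written there.
#' @return list with `images` (list of matrices), `labels` (factor),
#'   `manifest` (data.frame or NULL), `config`.
#' @export
generateSyntheticImages <- function(nPerClass = 60L, side = 256L,
                                    separability = 0.7, speckleLooks = 4,
                                    seed = 1L, dir = NULL) {
  nPerClass <- .assertScalarCount(nPerClass, "nPerClass")
  side <- .assertScalarCount(side, "side", lo = 32L)
  if (!is.numeric(separability) || separability < 0 || separability > 1)
    stop("'separability' must be in [0, 1]", call. = FALSE)
  if (speckleLooks <= 0) stop("'speckleLooks' must be positive", call. = FALSE)
  labels <- factor(rep(c("female", "male"), each = nPerClass),
                   levels = c("female", "male"))
  images <- vector("list", 2L * nPerClass)
  .withSeed(seed, {
    for (i in seq_along(labels)) {
      # smooth low-frequency background: bilinearly upsampled coarse noise
      # plus a mild vertical gain ramp
      bg <- 0.25 + 0.08 * (matrix(seq_len(side), side, side) / side) +
        0.1 * .bilinearResize(matrix(rnorm(144), 12L), side, side)
      if (labels[i] == "female") {
        nl <- sample(2:4, 1L)
        spacing <- runif(1L, 0.035, 0.06)
        pars <- list(theta = runif(1L, 0, pi),
                     offsets = (seq_len(nl) - (nl + 1) / 2) * spacing,
                     lineWidth = runif(1L, 0.006, 0.011),
                     curvature = runif(1L, -0.6, 0.6),
                     v0 = runif(1L, -0.1, 0.1))
        S <- .linePhenotype(side, separability, pars)
      } else {
        pars <- list(cx = runif(1L, -0.08, 0.08),
                     cy = runif(1L, -0.12, 0),
                     ax = runif(1L, 0.1, 0.16),
                     ay = runif(1L, 0.08, 0.13),
                     tilt = runif(1L, -0.2, 0.2),
                     segLen = runif(1L, 0.12, 0.2),
                     streakWidth = runif(1L, 0.005, 0.009))
        S <- .domePhenotype(side, separability, pars)
      }
      img <- bg + S
      img[img < 0] <- 0
      img[img > 1] <- 1
      img <- .gaussBlur(img, 1)
      img <- speckle(img, speckleLooks)     # uses the seeded stream
      images[[i]] <- img
    }
  })
  manifest <- NULL
  cfg <- list(nPerClass = nPerClass, side = side,
              separability = separability, speckleLooks = speckleLooks,
              seed = as.integer(seed))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, sprintf("%s_%03d.png", labels,
                                    c(seq_len(nPerClass),
                                      seq_len(nPerClass))))
    for (i in seq_along(images)) png::writePNG(images[[i]], paths[i])
    manifest <- data.frame(path = paths, label = as.character(labels))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE)
  }
  list(images = images, labels = labels, manifest = manifest, config = cfg)
}
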