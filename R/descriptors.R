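#' Descriptor parameter bundles
#'
#' `lpqParams()` configures the local phase quantization descriptor: a
#' short-term Fourier transform with a uniform square window is evaluated at
#' the four lowest non-zero frequency pairs, the eight real/imaginary
#' coefficients are optionally whitened under an exponential spatial
#' correlation model (`rho`), sign-quantized into an 8-bit code, and
#' histogrammed over the 256 possible codes. `hogParams()` configures the
#' histogram of oriented gradients: magnitude-weighted unsigned orientation
#' histograms per cell, one block of cells, L2-Hys block normalization. The
#' defaults are the unique common parameterization that yields 36 values on
#' a 16x16 patch (2x2 cells of 8x8 pixels, 9 bins).
#'
#' @param windowSide odd STFT window side, >= 3 (default 3).
#' @param rho exponential correlation coefficient for whitening (default 0.9).
#' @param decorrelate logical; apply the whitening transform (default TRUE).
#' @param normalize logical; return the code histogram normalized to sum 1
#'   (default) rather than raw counts.
#' @return a parameter list consumed by [lpqDescriptor()] / [hogDescriptor()].
#' @export
lpqParams <- function(windowSide = 3L, rho = 0.9, decorrelate = TRUE,
                      normalize = TRUE) {
  windowSide <- .assertScalarCount(windowSide, "windowSide", lo = 3L)
  if (windowSide %% 2L == 0L)
    stop("'windowSide' must be odd", call. = FALSE)
  list(windowSide = windowSide, rho = rho, decorrelate = isTRUE(decorrelate),
       normalize = isTRUE(normalize))
}

#' @rdname lpqParams
#' @param cellSide cell side in pixels (default 8).
#' @param blockCells cells per block side (default 2).
#' @param nBins unsigned orientation bins over `[0, 180)` degrees (default 9).
#' @export
hogParams <- function(cellSide = 8L, blockCells = 2L, nBins = 9L) {
  list(cellSide = .assertScalarCount(cellSide, "cellSide"),
       blockCells = .assertScalarCount(blockCells, "blockCells"),
       nBins = .assertScalarCount(nBins, "nBins"))
}

# ---- gradients ----------------------------------------------------------

# Symmetric reflect-pad by one pixel (the pad mirrors the edge pixel
# itself). On 16x16 patches this keeps oblique gradient directions intact
# at the border, where mirroring about the edge would zero the cross-border
# derivative and fabricate axis-aligned orientations.
.reflectPad1 <- function(m) {
  m[c(1L, seq_len(nrow(m)), nrow(m)), c(1L, seq_len(ncol(m)), ncol(m))]
}

#' Sobel gradient field of a patch
#'
#' 3x3 Sobel cross-correlation with symmetric reflective border padding
#' (the one-pixel pad mirrors the edge pixel). `gx` responds
#' to horizontal (column-direction) intensity change, `gy` to vertical.
#' The angle is the standard image-processing convention
#' `atan2(gy, gx)` reduced to the unsigned range `[0, 180)` degrees.
#'
#' @param patch numeric intensity matrix, at least 3x3.
#' @return list with matrices `gx`, `gy`, `magnitude`, `angle` (degrees).
#' @export
computeGradients <- function(patch) {
  .checkGray(patch, "patch")
  if (nrow(patch) < 3L || ncol(patch) < 3L)
    stop("patch smaller than the 3x3 Sobel kernel", call. = FALSE)
  p <- .reflectPad1(patch)
  h <- nrow(patch); w <- ncol(patch)
  sub <- function(dr, dc) p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  # Sx = [-1 0 1; -2 0 2; -1 0 1] (columns = x)
  gx <- (sub(-1L, 1L) + 2 * sub(0L, 1L) + sub(1L, 1L)) -
        (sub(-1L, -1L) + 2 * sub(0L, -1L) + sub(1L, -1L))
  gy <- (sub(1L, -1L) + 2 * sub(1L, 0L) + sub(1L, 1L)) -
        (sub(-1L, -1L) + 2 * sub(-1L, 0L) + sub(-1L, 1L))
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180
  ang[ang >= 180] <- 0          # guard the closed end after rounding
  list(gx = gx, gy = gy, magnitude = mag, angle = ang)
}

# ---- LPQ ----------------------------------------------------------------

# One-dimensional STFT kernels over offsets -r..r at frequency a = 1/w.
# q1 = (row w0, col w1): frequency along x; q2 transposed; q3/q4 diagonals.
.lpqKernels <- function(windowSide) {
  r <- (windowSide - 1L) / 2L
  s <- seq(-r, r)
  a <- 1 / windowSide
  w0 <- rep(1 + 0i, windowSide)
  w1 <- exp(-2i * pi * a * s)
  w2 <- Conj(w1)
  list(s = s,
       freqs = list(list(row = w0, col = w1),
                    list(row = w1, col = w0),
                    list(row = w1, col = w1),
                    list(row = w1, col = w2)))
}

# Band matrix for a valid 1-d cross-correlation along an axis of length n.
.bandMatrix <- function(k, n) {
  w <- length(k)
  B <- matrix(0 + 0i, n - w + 1L, n)
  for (i in seq_len(n - w + 1L)) B[i, i + seq_len(w) - 1L] <- k
  B
}

# Whitening transform for the 8 STFT coefficients under an exponential
# spatial correlation model; deterministic (tiny diagonal jitter breaks
# eigenvalue ties reproducibly).
.lpqWhitening <- function(windowSide, rho) {
  ker <- .lpqKernels(windowSide)
  pos <- expand.grid(sr = ker$s, sc = ker$s)      # sr fastest, column-major
  Dst <- as.matrix(stats::dist(pos))
  C <- rho^Dst
  rows <- list()
  for (f in ker$freqs) {
    flt <- outer(f$row, f$col)                    # [sr, sc]
    rows[[length(rows) + 1L]] <- Re(as.vector(flt))
    rows[[length(rows) + 1L]] <- Im(as.vector(flt))
  }
  M <- do.call(rbind, rows)
  D <- M %*% C %*% t(M)
  A <- diag(1 + seq(7e-7, 0, by = -1e-7))
  e <- eigen(A %*% D %*% A, symmetric = TRUE)
  t(e$vectors)                                    # rows = whitening directions
}

# Memoized band matrices keyed by (kernel id, axis length, window side).
.lpqBandCache <- new.env(parent = emptyenv())

.lpqBands <- function(windowSide, n) {
  key <- sprintf("w%d_n%d", windowSide, n)
  if (is.null(.lpqBandCache[[key]])) {
    ker <- .lpqKernels(windowSide)
    .lpqBandCache[[key]] <- list(
      b0 = .bandMatrix(ker$freqs[[1L]]$row, n),   # w0 (constant window)
      b1 = .bandMatrix(ker$freqs[[2L]]$row, n),   # w1
      b2 = .bandMatrix(Conj(ker$freqs[[2L]]$row), n))  # w2 = conj(w1)
  }
  .lpqBandCache[[key]]
}

# Complex STFT responses on the valid region of `img`: an (h-w+1)(w-w+1) x 8
# real matrix, columns Re/Im interleaved per frequency
# (order: (0,a), (a,0), (a,a), (a,-a) as row/col kernel pairs).
.lpqResponses <- function(img, params) {
  br <- .lpqBands(params$windowSide, nrow(img))
  bc <- if (ncol(img) == nrow(img)) br else .lpqBands(params$windowSide, ncol(img))
  ci <- img + 0i
  pairs <- list(list(br$b0, bc$b1), list(br$b1, bc$b0),
                list(br$b1, bc$b1), list(br$b1, bc$b2))
  out <- matrix(0, (nrow(img) - params$windowSide + 1L) *
                   (ncol(img) - params$windowSide + 1L), 8L)
  col <- 0L
  for (pr in pairs) {
    resp <- pr[[1L]] %*% ci %*% t(pr[[2L]])
    out[, col + 1L] <- Re(resp)
    out[, col + 2L] <- Im(resp)
    col <- col + 2L
  }
  out
}

#' Local phase quantization descriptor
#'
#' Classic LPQ on the valid region of the patch (no padding): with a 3x3
#' window a 16x16 patch yields a 14x14 field of 8-bit codes. Codes are the
#' sign bits (`>= 0` maps to 1) of the — optionally whitened — eight
#' real/imaginary STFT coefficients at the four lowest frequencies; the
#' descriptor is their histogram over codes 0..255. The filters have zero DC
#' response, so the descriptor is exactly invariant to additive intensity
#' shifts.
#'
#' @param patch numeric intensity matrix with sides >= `windowSide`.
#' @param params see [lpqParams()].
#' @return numeric vector of length 256 (sums to 1 when normalized).
#' @export
lpqDescriptor <- function(patch, params = lpqParams()) {
  .checkGray(patch, "patch")
  if (nrow(patch) < params$windowSide || ncol(patch) < params$windowSide)
    stop("patch smaller than the LPQ window", call. = FALSE)
  resp <- .lpqResponses(patch, params)
  if (params$decorrelate)
    resp <- resp %*% t(.lpqWhitening(params$windowSide, params$rho))
  codes <- as.integer((resp >= 0) %*% 2^(0:7))
  h <- tabulate(codes + 1L, nbins = 256L)
  if (params$normalize) h / length(codes) else h
}

# ---- HOG ----------------------------------------------------------------

#' Histogram of oriented gradients descriptor
#'
#' Magnitude-weighted unsigned orientation histograms (linear interpolation
#' between the two adjacent bin centers, circular over `[0, 180)`) per cell,
#' concatenated over one block of cells and L2-Hys normalized (L2 norm with
#' an epsilon guard, clip at 0.2, renormalize). With the defaults a 16x16
#' patch gives 2x2 cells x 9 bins = 36 values; an all-flat patch maps to the
#' all-zero vector.
#'
#' @param patch numeric intensity matrix; its sides must equal
#'   `cellSide * blockCells`.
#' @param params see [hogParams()].
#' @return numeric vector of length `blockCells^2 * nBins`.
#' @export
hogDescriptor <- function(patch, params = hogParams()) {
  .checkGray(patch, "patch")
  side <- params$cellSide * params$blockCells
  if (nrow(patch) != side || ncol(patch) != side)
    stop(sprintf("patch must be %dx%d for the configured cell geometry",
                 side, side), call. = FALSE)
  g <- computeGradients(patch)
  nb <- params$nBins
  binWidth <- 180 / nb
  cpos <- g$angle / binWidth - 0.5
  i0 <- floor(cpos)
  frac <- cpos - i0
  b0 <- (as.integer(i0) %% nb)
  b1 <- (b0 + 1L) %% nb
  w0 <- g$magnitude * (1 - frac)
  w1 <- g$magnitude * frac
  cellOf <- function(idx) (idx - 1L) %/% params$cellSide + 1L
  cr <- cellOf(row(patch)); cc <- cellOf(col(patch))
  cellId <- (cr - 1L) * params$blockCells + cc        # row-major cells
  nCells <- params$blockCells^2
  hist <- numeric(nCells * nb)
  acc <- function(bin, wt) {
    idx <- (cellId - 1L) * nb + bin + 1L
    v <- vapply(split(as.vector(wt), as.vector(idx)), sum, 0)
    hist[as.integer(names(v))] <<- hist[as.integer(names(v))] + v
  }
  acc(b0, w0)
  acc(b1, w1)
  eps <- 1e-12
  v <- hist / sqrt(sum(hist^2) + eps^2)
  v <- pmin(v, 0.2)
  v / sqrt(sum(v^2) + eps^2)
}

# ---- concatenation ------------------------------------------------------

#' Hybrid per-patch descriptor (LPQ then HOG)
#'
#' @param patch 16x16 numeric intensity matrix (with default parameters).
#' @param lpq,hog parameter bundles.
#' @return numeric vector of length 292: values 1..256 are the LPQ
#'   histogram, 257..292 the HOG block. The order is frozen; downstream
#'   selected-feature indices depend on it.
#' @export
patchFeatures <- function(patch, lpq = lpqParams(), hog = hogParams()) {
  c(lpqDescriptor(patch, lpq), hogDescriptor(patch, hog))
}

# LPQ histograms for every patch at once (256 x nPatches). The stacked
# band-matrix products reproduce the per-patch valid STFT responses exactly;
# only the (histogram-irrelevant) spatial flattening order differs.
.lpqAll <- function(arr, params) {
  s <- dim(arr)[1L]; n3 <- dim(arr)[3L]
  v <- s - params$windowSide + 1L
  bands <- .lpqBands(params$windowSide, s)
  A <- matrix(arr, s, s * n3) + 0i
  pairs <- list(c("b0", "b1"), c("b1", "b0"), c("b1", "b1"), c("b1", "b2"))
  resp <- matrix(0, v * v * n3, 8L)
  for (fi in seq_along(pairs)) {
    Br <- bands[[pairs[[fi]][1L]]]
    Bc <- bands[[pairs[[fi]][2L]]]
    B1 <- Br %*% A                                   # v x (s n3)
    B1p <- matrix(aperm(array(B1, c(v, s, n3)), c(2L, 1L, 3L)), s, v * n3)
    C <- Bc %*% B1p                                  # per-patch transpose of the response
    resp[, 2L * fi - 1L] <- Re(C)
    resp[, 2L * fi] <- Im(C)
  }
  if (params$decorrelate)
    resp <- resp %*% t(.lpqWhitening(params$windowSide, params$rho))
  codes <- as.integer((resp >= 0) %*% 2^(0:7))
  patchIdx <- rep(seq_len(n3), each = v * v)
  H <- matrix(tabulate((patchIdx - 1L) * 256L + codes + 1L,
                       nbins = 256L * n3), 256L, n3)
  if (params$normalize) H / (v * v) else H
}

# HOG blocks for every patch at once (36 x nPatches), matching
# hogDescriptor() per patch to floating tolerance.
.hogAll <- function(arr, params) {
  s <- dim(arr)[1L]; n3 <- dim(arr)[3L]
  if (s != params$cellSide * params$blockCells)
    stop("patch side disagrees with the HOG cell geometry", call. = FALSE)
  padIdx <- c(1L, seq_len(s), s)
  P <- arr[padIdx, padIdx, , drop = FALSE]
  sub <- function(dr, dc)
    P[(2L + dr):(s + 1L + dr), (2L + dc):(s + 1L + dc), , drop = FALSE]
  gx <- (sub(-1L, 1L) + 2 * sub(0L, 1L) + sub(1L, 1L)) -
        (sub(-1L, -1L) + 2 * sub(0L, -1L) + sub(1L, -1L))
  gy <- (sub(1L, -1L) + 2 * sub(1L, 0L) + sub(1L, 1L)) -
        (sub(-1L, -1L) + 2 * sub(-1L, 0L) + sub(-1L, 1L))
  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  ang[ang >= 180] <- 0
  nb <- params$nBins
  cpos <- ang / (180 / nb) - 0.5
  i0 <- floor(cpos)
  frac <- cpos - i0
  b0 <- as.integer(i0) %% nb
  b1 <- (b0 + 1L) %% nb
  cellOf <- function(idx) (idx - 1L) %/% params$cellSide
  cellId <- cellOf(row(matrix(0, s, s))) * params$blockCells +
    cellOf(col(matrix(0, s, s)))                    # 0-based, row-major
  nCells <- params$blockCells^2
  per <- nCells * nb
  base <- rep(seq_len(n3) - 1L, each = s * s) * per +
    rep(as.vector(cellId), n3) * nb
  w <- c(as.vector(mag * (1 - frac)), as.vector(mag * frac))
  idx <- c(base + as.vector(b0), base + as.vector(b1)) + 1L
  tot <- numeric(per * n3)
  rs <- rowsum(w, idx)
  tot[as.integer(rownames(rs))] <- rs
  H <- matrix(tot, per, n3)
  eps <- 1e-12
  V <- sweep(H, 2L, sqrt(colSums(H^2) + eps^2), "/")
  V <- pmin(V, 0.2)
  sweep(V, 2L, sqrt(colSums(V^2) + eps^2), "/")
}

#' Per-image feature vector from a patch set
#'
#' Concatenates the 292-value hybrid descriptor of every patch in the frozen
#' patch order; the standard 341-patch set yields length 99,572. Computation
#' is vectorized across patches and agrees with [patchFeatures()] applied
#' patch by patch.
#'
#' @param ps a [PatchSet-class].
#' @param lpq,hog parameter bundles.
#' @return numeric vector of length `nPatches * 292`.
#' @export
imageFeatureVector <- function(ps, lpq = lpqParams(), hog = hogParams()) {
  stopifnot(is(ps, "PatchSet"))
  as.vector(rbind(.lpqAll(ps@patches, lpq), .hogAll(ps@patches, hog)))
}

#' Feature provenance table for a patch set
#'
#' One row per feature column of the per-image vector: patch index, pyramid
#' level, tile coordinates, descriptor family and within-descriptor index.
#'
#' @param ps a [PatchSet-class].
#' @return data.frame with `nPatches * 292` rows.
#' @export
featureProvenance <- function(ps) {
  stopifnot(is(ps, "PatchSet"))
  prov <- ps@provenance
  n <- nrow(prov)
  per <- 292L
  data.frame(
    feature = seq_len(n * per),
    patch = rep(prov$patch, each = per),
    level = rep(prov$level, each = per),
    row = rep(prov$row, each = per),
    col = rep(prov$col, each = per),
    family = rep(rep(c("lpq", "hog"), c(256L, 36L)), n),
    withinIndex = rep(c(seq_len(256L), seq_len(36L)), n))
}

#' Extract the full feature matrix for a set of images
#'
#' Runs standardization, pyramid decomposition, patch division and hybrid
#' descriptor extraction for every image and assembles a
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with one assay `"features"` (features x images), feature provenance as
#' `rowData` and image ids/labels as `colData`.
#'
#' @param images either a character vector of image paths, a list of
#'   intensity matrices, or a manifest `data.frame` with columns
#'   `path` and `label`.
#' @param labels optional label vector (ignored when a manifest is given).
#' @param side standardization side (default 256).
#' @param lpq,hog descriptor parameter bundles.
#' @param verbose print one progress line per 20 images.
#' @return a `SummarizedExperiment`.
#' @export
extractFeatures <- function(images, labels = NULL, side = 256L,
                            lpq = lpqParams(), hog = hogParams(),
                            verbose = FALSE) {
  ids <- NULL
  if (is.data.frame(images)) {
    if (!all(c("path", "label") %in% names(images)))
      stop("manifest must have columns 'path' and 'label'", call. = FALSE)
    if (nrow(images) == 0L) stop("empty manifest", call. = FALSE)
    labels <- images$label
    ids <- basename(images$path)
    images <- as.character(images$path)
  }
  getImage <- if (is.character(images)) {
    ids <- if (is.null(ids)) basename(images) else ids
    function(i) resizeToStandard(loadGrayImage(images[i]), side)
  } else {
    ids <- if (is.null(ids)) sprintf("image_%03d", seq_along(images)) else ids
    function(i) resizeToStandard(images[[i]], side)
  }
  nImg <- if (is.character(images)) length(images) else length(images)
  cols <- vector("list", nImg)
  prov <- NULL
  for (i in seq_len(nImg)) {
    ps <- extractPatches(buildPyramid(getImage(i)))
    if (is.null(prov)) prov <- featureProvenance(ps)
    cols[[i]] <- imageFeatureVector(ps, lpq, hog)
    if (verbose && i %% 20L == 0L)
      message(sprintf("extracted %d / %d images", i, nImg))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- ids
  cd <- DataFrame(id = ids)
  if (!is.null(labels)) cd$label <- factor(labels)
  SummarizedExperiment(assays = list(features = X),
                       rowData = DataFrame(prov), colData = cd)
}
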