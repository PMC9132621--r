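#' Load a raster image as a grayscale intensity matrix
#'
#' Reads JPEG/PNG/TIFF, converts color inputs to single-channel luminance
#' (ITU-R BT.601 weights 0.299/0.587/0.114) and rescales intensities to
#' `[0, 1]`. The returned matrix is row-major in the usual R sense: rows are
#' image rows (top to bottom), columns are image columns.
#'
#' @param path path to a readable raster file.
#' @return numeric matrix of intensities in `[0, 1]`.
#' @export
loadGrayImage <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("'path' must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop("image file does not exist: ", path, call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop("failed to read image '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) {
    nch <- dim(dat)[3L]
    if (nch >= 3L) {
      w <- c(0.299, 0.587, 0.114)
      dat <- dat[, , 1L] * w[1L] + dat[, , 2L] * w[2L] + dat[, , 3L] * w[3L]
    } else {
      dat <- dat[, , 1L]
    }
  }
  m <- t(dat)                       # EBImage stores x (cols) first
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

.checkGray <- function(img, name = "img") {
  if (!is.matrix(img) || !is.numeric(img) || !all(is.finite(img)))
    stop("'", name, "' must be a finite numeric matrix", call. = FALSE)
  invisible(img)
}

# Mean over consecutive blocks of `f` rows (exact arithmetic means).
.poolRows <- function(m, f) {
  if (f == 1L) return(m)
  matrix(colMeans(matrix(m, nrow = f)), nrow = nrow(m) / f)
}

#' Average pooling (non-overlapping block means)
#'
#' Each output pixel is the arithmetic mean of its `factor x factor` source
#' block; the global image mean is preserved exactly.
#'
#' @param img numeric intensity matrix.
#' @param factor block side; both image sides must be divisible by it.
#' @return pooled matrix with sides `dim(img) / factor`.
#' @export
averagePool <- function(img, factor) {
  .checkGray(img)
  factor <- .assertScalarCount(factor, "factor")
  if (nrow(img) %% factor != 0L || ncol(img) %% factor != 0L)
    stop(sprintf("image sides (%d x %d) not divisible by pooling factor %d",
                 nrow(img), ncol(img), factor), call. = FALSE)
  t(.poolRows(t(.poolRows(img, factor)), factor))
}

# Plain bilinear resample with pixel-center alignment and edge clamping.
.bilinearResize <- function(img, outH, outW) {
  h <- nrow(img); w <- ncol(img)
  mapAxis <- function(nOut, nIn) {
    x <- (seq_len(nOut) - 0.5) * nIn / nOut + 0.5
    x <- pmin(pmax(x, 1), nIn)
    i0 <- pmin(floor(x), nIn - 1L)
    list(i0 = as.integer(i0), frac = x - i0)
  }
  ry <- mapAxis(outH, h); rx <- mapAxis(outW, w)
  top <- img[ry$i0, rx$i0, drop = FALSE] * (1 - rx$frac)[col(matrix(0, outH, outW))] +
    img[ry$i0, rx$i0 + 1L, drop = FALSE] * rx$frac[col(matrix(0, outH, outW))]
  bot <- img[ry$i0 + 1L, rx$i0, drop = FALSE] * (1 - rx$frac)[col(matrix(0, outH, outW))] +
    img[ry$i0 + 1L, rx$i0 + 1L, drop = FALSE] * rx$frac[col(matrix(0, outH, outW))]
  top * (1 - ry$frac) + bot * ry$frac
}

# Exact area-average resample (anti-aliased downscale): each output pixel is
# the mean of its source rectangle, with fractional edge pixels weighted by
# overlap. Implemented separably via sparse-free weight matrices.
.areaWeights <- function(nOut, nIn) {
  W <- matrix(0, nOut, nIn)
  scale <- nIn / nOut
  for (i in seq_len(nOut)) {
    a <- (i - 1) * scale; b <- i * scale
    j0 <- floor(a) + 1; j1 <- ceiling(b)
    for (j in j0:j1) {
      ov <- min(b, j) - max(a, j - 1)
      if (ov > 0) W[i, j] <- ov
    }
    W[i, ] <- W[i, ] / scale
  }
  W
}

.areaResize <- function(img, outH, outW) {
  .areaWeights(outH, nrow(img)) %*% img %*% t(.areaWeights(outW, ncol(img)))
}

#' Standardize an image to a square side
#'
#' Resamples to `side x side` (default 256). Upscaling and mild downscaling
#' use bilinear interpolation with pixel-center alignment; shrinking an axis
#' by a factor of 2 or more switches to an exact area average, the
#' anti-aliased form of downscaling. Output is clipped to `[0, 1]`.
#'
#' @param img numeric intensity matrix.
#' @param side output side; must be a positive multiple of 16 because the
#'   downstream patch division tiles 16x16.
#' @return `side x side` matrix in `[0, 1]`.
#' @export
resizeToStandard <- function(img, side = 256L) {
  .checkGray(img)
  side <- .assertScalarCount(side, "side")
  if (side %% 16L != 0L)
    stop("'side' must be a positive multiple of 16 (patch division requires it)",
         call. = FALSE)
  if (nrow(img) == 0L || ncol(img) == 0L)
    stop("empty image", call. = FALSE)
  if (nrow(img) == side && ncol(img) == side) return(img)
  out <- if (nrow(img) >= 2L * side || ncol(img) >= 2L * side)
    .areaResize(img, side, side)
  else
    .bilinearResize(img, side, side)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Build the five-level average-pooling pyramid
#'
#' Level 0 is the 256x256 input; levels 1-4 are produced by average pooling
#' with block sides 2, 4, 8 and 16, giving sides 128, 64, 32 and 16.
#'
#' @param img 256x256 numeric intensity matrix.
#' @return an [ImagePyramid-class] with factors `c(1, 2, 4, 8, 16)`.
#' @export
buildPyramid <- function(img) {
  .checkGray(img)
  if (nrow(img) != 256L || ncol(img) != 256L)
    stop(sprintf("pyramid input must be 256x256, got %dx%d",
                 nrow(img), ncol(img)), call. = FALSE)
  factors <- c(1L, 2L, 4L, 8L, 16L)
  levels <- lapply(factors, function(f) averagePool(img, f))
  new("ImagePyramid", levels = levels, factors = factors)
}

#' Tile every pyramid level into fixed-size patches
#'
#' Each level is divided into non-overlapping `patchSide x patchSide` tiles.
#' For the standard pyramid this yields 256 + 64 + 16 + 4 + 1 = 341 patches.
#' Ordering is frozen (selected feature indices are only meaningful under
#' it): levels coarse-to-fine never — always original first, then the pooled
#' levels in order; within a level, row-major (row blocks outer, column
#' blocks inner).
#'
#' @param pyr an [ImagePyramid-class].
#' @param patchSide tile side in pixels (default 16).
#' @return a [PatchSet-class]; provenance records (level, row, col) per patch.
#' @export
extractPatches <- function(pyr, patchSide = 16L) {
  stopifnot(is(pyr, "ImagePyramid"))
  patchSide <- .assertScalarCount(patchSide, "patchSide")
  sides <- vapply(pyr@levels, nrow, 1L)
  if (any(sides %% patchSide != 0L))
    stop("every level side must be divisible by the patch side", call. = FALSE)
  nPerLevel <- (sides %/% patchSide)^2
  total <- sum(nPerLevel)
  patches <- array(0, dim = c(patchSide, patchSide, total))
  prov <- data.frame(patch = seq_len(total), level = NA_integer_,
                     row = NA_integer_, col = NA_integer_)
  k <- 0L
  for (li in seq_along(pyr@levels)) {
    L <- pyr@levels[[li]]
    nb <- nrow(L) %/% patchSide
    for (r in seq_len(nb)) {
      for (cc in seq_len(nb)) {
        k <- k + 1L
        patches[, , k] <- L[(r - 1L) * patchSide + seq_len(patchSide),
                            (cc - 1L) * patchSide + seq_len(patchSide)]
        prov$level[k] <- li - 1L
        prov$row[k] <- r
        prov$col[k] <- cc
      }
    }
  }
  new("PatchSet", patches = patches, provenance = prov,
      patchSide = patchSide)
}

#' Export a patch set as PNG tiles for visual inspection
#'
#' @param ps a [PatchSet-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
writePatchTiles <- function(ps, dir) {
  stopifnot(is(ps, "PatchSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(ps@patches)[3L]
  paths <- file.path(dir, sprintf("patch_%03d_L%d_r%d_c%d.png",
                                  seq_len(n), ps@provenance$level,
                                  ps@provenance$row, ps@provenance$col))
  for (i in seq_len(n)) png::writePNG(ps@patches[, , i], paths[i])
  invisible(paths)
}
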