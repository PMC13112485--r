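#' Canonical feature names
#'
#' The 16 image descriptors, in the fixed order used throughout the
#' package: five co-occurrence (GLCM) texture measures, six first-order
#' intensity statistics, four single-level Haar wavelet sub-band energies,
#' and the edge density.
#'
#' @return character vector of length 16.
#' @export
featureNames <- function() {
  c("glcm_contrast", "glcm_correlation", "glcm_energy", "glcm_homogeneity",
    "glcm_entropy",
    "intensity_mean", "intensity_std", "skewness", "kurtosis", "q10", "q90",
    "wavelet_energy_LL", "wavelet_energy_LH", "wavelet_energy_HL",
    "wavelet_energy_HH",
    "edge_density")
}

#' Load and normalize a grayscale image
#'
#' Reads a raster image (PNG or JPEG, via EBImage), converts multi-channel
#' input to luminance, resizes to the canonical 256 x 256 resolution with
#' bilinear interpolation, and rescales intensities to integers in 0..255.
#' A numeric matrix may be passed directly; matrices with values in [0, 1]
#' are rescaled by 255, others are assumed to already be on the 0..255
#' scale.
#'
#' @param x file path, numeric matrix, or `EBImage::Image`.
#' @param size target side length (default 256).
#' @return integer-valued matrix `size` x `size` with entries in 0..255.
#' @export
preprocessImage <- function(x, size = 256L) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("cannot read image file: ", x)
    x <- EBImage::readImage(x)
  }
  if (is(x, "Image")) {
    if (EBImage::colorMode(x) == EBImage::Color)
      x <- EBImage::channel(x, "luminance")
    if (length(dim(x)) > 2L) x <- EBImage::getFrame(x, 1L)
    if (any(dim(x)[1:2] != size)) x <- EBImage::resize(x, w = size, h = size)
    m <- EBImage::imageData(x)[, , drop = TRUE] * 255
  } else if (is.matrix(x)) {
    m <- x
    if (any(dim(m) != size)) {
      img <- EBImage::Image(m / max(1, max(m)))
      scl <- max(1, max(m))
      m <- EBImage::imageData(EBImage::resize(img, w = size, h = size)) * scl
    }
    if (max(m) <= 1) m <- m * 255
  } else {
    stop("unsupported image input of class ", class(x)[1L])
  }
  m <- round(pmin(pmax(m, 0), 255))
  storage.mode(m) <- "integer"
  m
}

#' Co-occurrence (GLCM) texture descriptors
#'
#' Quantizes the image to `levels` gray levels, accumulates symmetric
#' normalized co-occurrence matrices at distance 1 for the four standard
#' angles (0, 45, 90, 135 degrees), computes contrast, correlation, energy,
#' homogeneity and entropy (base-2, over nonzero cells) per angle, and
#' averages over angles. A zero-variance image has a single co-occurrence
#' cell; its correlation is defined as 1.
#'
#' @param img integer-valued matrix with entries in 0..255 (see
#'   [preprocessImage()]).
#' @param levels number of quantized gray levels (default 32).
#' @param distance pixel offset distance (default 1).
#' @return named numeric vector of the 5 GLCM descriptors.
#' @export
glcmFeatures <- function(img, levels = 32L, distance = 1L) {
  stopifnot(is.matrix(img))
  q <- pmin(img %/% as.integer(ceiling(256 / levels)), levels - 1L)
  nr <- nrow(q); nc <- ncol(q)
  offsets <- list(c(0L, distance), c(distance, distance),
                  c(distance, 0L), c(distance, -distance))
  lv <- seq_len(levels) - 1L
  out <- matrix(NA_real_, nrow = length(offsets), ncol = 5L)
  for (a in seq_along(offsets)) {
    dr <- offsets[[a]][1L]; dc <- offsets[[a]][2L]
    r1 <- seq.int(max(1L, 1L - dr), min(nr, nr - dr))
    c1 <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
    g1 <- q[r1, c1, drop = FALSE]
    g2 <- q[r1 + dr, c1 + dc, drop = FALSE]
    counts <- tabulate(as.integer(g1) * levels + as.integer(g2) + 1L,
                       nbins = levels * levels)
    P <- matrix(counts, levels, levels, byrow = TRUE)
    P <- P + t(P)                      # symmetric
    P <- P / sum(P)                    # normalized
    pi_ <- rowSums(P)
    mu <- sum(lv * pi_)
    sig2 <- sum((lv - mu)^2 * pi_)
    D <- outer(lv, lv, "-")
    contrast <- sum(P * D^2)
    correlation <- if (sig2 > 0)
      sum(P * outer(lv - mu, lv - mu)) / sig2 else 1
    energy <- sum(P^2)
    homogeneity <- sum(P / (1 + D^2))
    entropy <- -sum(P[P > 0] * log2(P[P > 0]))
    out[a, ] <- c(contrast, correlation, energy, homogeneity, entropy)
  }
  stats::setNames(colMeans(out),
                  c("glcm_contrast", "glcm_correlation", "glcm_energy",
                    "glcm_homogeneity", "glcm_entropy"))
}

#' First-order intensity statistics
#'
#' Over the flattened pixel intensities: mean, population standard
#' deviation, Fisher skewness, excess kurtosis, and the 10th and 90th
#' percentiles (linear interpolation between order statistics). Skewness
#' and kurtosis of a constant image are defined as 0.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of the 6 statistics.
#' @export
firstOrderStats <- function(img) {
  v <- as.numeric(img)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s > 0) {
    skew <- mean((v - m)^3) / s^3
    kurt <- mean((v - m)^4) / s^4 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  qq <- quantile(v, c(0.1, 0.9), names = FALSE, type = 7)
  stats::setNames(c(m, s, skew, kurt, qq[1L], qq[2L]),
                  c("intensity_mean", "intensity_std", "skewness",
                    "kurtosis", "q10", "q90"))
}

# single-level orthonormal 2-D Haar transform; returns the four sub-bands.
# Convention: HL is high-pass across columns / low-pass across rows, so a
# vertical step edge (variation along the column index) loads HL.
haarSubbands <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr %% 2L != 0L || nc %% 2L != 0L)
    stop("Haar decomposition requires even image dimensions")
  a <- img[seq(1L, nr, 2L), seq(1L, nc, 2L)]
  b <- img[seq(1L, nr, 2L), seq(2L, nc, 2L)]
  cc <- img[seq(2L, nr, 2L), seq(1L, nc, 2L)]
  d <- img[seq(2L, nr, 2L), seq(2L, nc, 2L)]
  list(LL = (a + b + cc + d) / 2,
       LH = (a + b - cc - d) / 2,
       HL = (a - b + cc - d) / 2,
       HH = (a - b - cc + d) / 2)
}

#' Haar wavelet sub-band energies
#'
#' Single-level orthonormal 2-D Haar decomposition; the energy of each
#' sub-band (LL, LH, HL, HH) is the sum of its squared coefficients divided
#' by the pixel count, so values are comparable across resolutions. The
#' transform is orthogonal: the four unnormalized energies sum to the total
#' image energy.
#'
#' @inheritParams glcmFeatures
#' @return named non-negative numeric vector of the 4 sub-band energies.
#' @export
waveletEnergies <- function(img) {
  sb <- haarSubbands(img)
  n <- length(img)
  stats::setNames(vapply(sb, function(s) sum(s^2) / n, numeric(1L)),
                  c("wavelet_energy_LL", "wavelet_energy_LH",
                    "wavelet_energy_HL", "wavelet_energy_HH"))
}

# Sobel gradient magnitude with replicate border padding
sobelMagnitude <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  P <- matrix(0, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- img
  P[1L, ] <- P[2L, ]; P[nr + 2L, ] <- P[nr + 1L, ]
  P[, 1L] <- P[, 2L]; P[, nc + 2L] <- P[, nc + 1L]
  sh <- function(dr, dc) P[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  gx <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L))
  gy <- (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L))
  sqrt(gx^2 + gy^2)
}

#' Edge density from intensity gradients
#'
#' Computes the Sobel gradient magnitude and flags a pixel as an edge when
#' its magnitude strictly exceeds the adaptive threshold mean + 1 standard
#' deviation of the magnitude map. The returned density is the fraction of
#' flagged pixels, in [0, 1]; a constant image has zero gradient everywhere
#' and density 0.
#'
#' @inheritParams glcmFeatures
#' @return scalar in [0, 1].
#' @export
edgeDensity <- function(img) {
  mag <- sobelMagnitude(img)
  thr <- mean(mag) + stats::sd(mag)
  mean(mag > thr)
}

#' Extract the canonical 16-descriptor feature vector
#'
#' Concatenates [glcmFeatures()], [firstOrderStats()], [waveletEnergies()]
#' and [edgeDensity()] in the order of [featureNames()]. Deterministic:
#' identical images give identical vectors.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of length 16, all finite.
#' @export
extractFeatures <- function(img) {
  v <- c(glcmFeatures(img), firstOrderStats(img), waveletEnergies(img),
         edge_density = edgeDensity(img))
  names(v) <- featureNames()
  if (any(!is.finite(v)))
    stop("non-finite feature value: ",
         paste(featureNames()[!is.finite(v)], collapse = ", "))
  v
}

#' Build a feature table from images
#'
#' Applies [preprocessImage()] and [extractFeatures()] to each input and
#' binds the rows into a data frame with the 16 canonical feature columns
#' plus an optional `label` column.
#'
#' @param images list of image inputs accepted by [preprocessImage()], or a
#'   character vector of file paths.
#' @param labels optional vector of class labels, one per image.
#' @param size canonical resolution passed to [preprocessImage()].
#' @return data frame with 16 feature columns (and `label` if given).
#' @export
extractFeatureTable <- function(images, labels = NULL, size = 256L) {
  if (is.character(images)) images <- as.list(images)
  rows <- lapply(images, function(x)
    extractFeatures(preprocessImage(x, size = size)))
  tab <- as.data.frame(do.call(rbind, rows))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(tab))
    tab$label <- labels
  }
  tab
}

#' Fit a per-feature standardizer
#'
#' Computes column means and (sample) standard deviations of the feature
#' columns so the table can be z-transformed to zero mean and unit spread.
#' Constant columns get scale 0 and are mapped to zero by
#' [applyStandardizer()] instead of dividing by zero.
#'
#' @param table data frame or matrix of feature columns (a `label` column,
#'   if present, is ignored).
#' @return a [FeatureStandardizer-class].
#' @export
fitStandardizer <- function(table) {
  X <- featureMatrix(table)
  if (nrow(X) < 2L) stop("standardizer fitting requires at least 2 rows")
  new("FeatureStandardizer",
      center = colMeans(X),
      scale = apply(X, 2L, stats::sd))
}

#' Apply a fitted standardizer
#'
#' @param model a [FeatureStandardizer-class].
#' @param table data frame or matrix with the columns the model was fitted
#'   on (a `label` column is carried through untouched).
#' @return object of the same shape with standardized feature columns.
#' @export
applyStandardizer <- function(model, table) {
  stopifnot(is(model, "FeatureStandardizer"))
  X <- featureMatrix(table)
  if (ncol(X) != length(model@center))
    stop("table has ", ncol(X), " feature columns but the model expects ",
         length(model@center))
  scl <- ifelse(model@scale > 0, model@scale, 1)
  Z <- sweep(sweep(X, 2L, model@center), 2L, scl, "/")
  Z[, model@scale == 0] <- 0
  if (is.data.frame(table)) {
    out <- table
    out[colnames(X)] <- as.data.frame(Z)
    out
  } else {
    Z
  }
}

# numeric feature matrix from a table, dropping any label column
featureMatrix <- function(table) {
  if (is.data.frame(table)) {
    table <- table[setdiff(names(table), "label")]
    as.matrix(table)
  } else {
    as.matrix(table)
  }
}

#' Read or write a feature table as CSV
#'
#' Plain CSV with a header of the canonical feature names (plus `label`),
#' written at full double precision so tables round-trip losslessly.
#'
#' @param table data frame to write.
#' @param file path.
#' @return `readFeatureTable` returns the data frame; `writeFeatureTable`
#'   returns `file` invisibly.
#' @export
writeFeatureTable <- function(table, file) {
  utils::write.csv(format(table, digits = 17, scientific = TRUE,
                          trim = TRUE),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(file) {
  utils::read.csv(file, check.names = FALSE)
}
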