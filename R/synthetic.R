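#' Simulate a two-class 16-feature table
#'
#' Class-conditional Gaussian feature rows standing in for extracted image
#' descriptors: every column is independent normal noise with spread
#' `noiseSd`, and the class means differ by a Euclidean distance of
#' `separation * noiseSd`, spread evenly over the first `nInformative`
#' columns (per-dimension gap `separation * noiseSd / sqrt(nInformative)`).
#' `separation` is therefore the distance between the class means in
#' within-class standard-deviation units, whatever the number of
#' informative dimensions. Columns carry the canonical [featureNames()] and
#' a `label` column codes the classes 0 (healthy) and 1 (tumor).
#'
#' @param nPerClass integer vector of length 2, rows per class (default
#'   100 each).
#' @param separation distance between the class means in pooled-noise
#'   units (default 3).
#' @param nInformative number of columns carrying the separation, in 1..16
#'   (default 4).
#' @param noiseSd within-class standard deviation (default 1).
#' @param seed integer seed; identical configurations and seeds give
#'   identical tables.
#' @return data frame with 16 feature columns and a `label` column.
#' @export
simulateFeatureTable <- function(nPerClass = c(100L, 100L), separation = 3,
                                 nInformative = 4L, noiseSd = 1,
                                 seed = 1L) {
  stopifnot(length(nPerClass) == 2L, all(nPerClass >= 1L),
            separation >= 0, nInformative >= 1L, nInformative <= 16L,
            noiseSd > 0)
  set.seed(as.integer(seed))
  d <- 16L
  n0 <- nPerClass[1L]; n1 <- nPerClass[2L]
  mu0 <- rep(0, d)
  mu1 <- rep(0, d)
  mu1[seq_len(nInformative)] <- separation * noiseSd / sqrt(nInformative)
  X <- rbind(
    matrix(rnorm(n0 * d, sd = noiseSd), n0, d, byrow = TRUE) +
      matrix(mu0, n0, d, byrow = TRUE),
    matrix(rnorm(n1 * d, sd = noiseSd), n1, d, byrow = TRUE) +
      matrix(mu1, n1, d, byrow = TRUE)
  )
  colnames(X) <- featureNames()
  tab <- as.data.frame(X)
  tab$label <- rep(c(0L, 1L), c(n0, n1))
  tab
}

# seeded band-limited noise field: white noise smoothed with a Gaussian
# kernel and rescaled to the requested standard deviation
textureField <- function(size, sigma, amplitude) {
  w <- matrix(rnorm(size * size), size, size)
  if (sigma > 0) w <- EBImage::imageData(EBImage::gblur(EBImage::Image(w),
                                                        sigma = sigma))
  s <- stats::sd(as.numeric(w))
  if (s > 0) w <- w / s * amplitude
  w
}

#' Simulate grayscale phantom images for the two classes
#'
#' Emulates the discriminative structure the feature pipeline assumes:
#' healthy phantoms are bright, high-contrast textured fields (fine-grained
#' band-limited noise of large amplitude on a high base intensity), tumor
#' phantoms are dimmer, smoother fields carrying a low-intensity smooth
#' blob. Consequently the class-averaged intensity mean and co-occurrence
#' contrast are both higher for the healthy class. Pixel values are clipped
#' to 0..255 and rounded.
#'
#' @param nPerClass integer vector of length 2: healthy and tumor image
#'   counts (default 20 each).
#' @param size image side length (default 256).
#' @param healthyMean,tumorMean base intensities (defaults 180 and 120;
#'   healthy must exceed tumor).
#' @param healthyTexture,tumorTexture texture-field standard deviations
#'   (defaults 40 and 10; healthy must exceed tumor). Healthy texture is
#'   fine-grained (smoothing sigma 1), tumor texture smooth (sigma 4).
#' @param blobRadius,blobDepth Gaussian blob scale in pixels and intensity
#'   drop at its center (defaults 40 and 60); the blob center is jittered
#'   around the image center.
#' @param noiseSd additive white pixel noise (default 5).
#' @param seed integer seed.
#' @return list with `images` (list of integer matrices) and `labels`
#'   (0 = healthy, 1 = tumor).
#' @export
simulatePhantoms <- function(nPerClass = c(20L, 20L), size = 256L,
                             healthyMean = 180, tumorMean = 120,
                             healthyTexture = 40, tumorTexture = 10,
                             blobRadius = 40, blobDepth = 60,
                             noiseSd = 5, seed = 1L) {
  stopifnot(length(nPerClass) == 2L, all(nPerClass >= 1L),
            size %% 2L == 0L,
            healthyMean > tumorMean, healthyTexture > tumorTexture)
  set.seed(as.integer(seed))
  coords <- seq_len(size)
  makeImage <- function(label) {
    if (label == 0L) {
      m <- healthyMean + textureField(size, sigma = 1, healthyTexture)
    } else {
      m <- tumorMean + textureField(size, sigma = 4, tumorTexture)
      cx <- size / 2 + runif(1, -size / 8, size / 8)
      cy <- size / 2 + runif(1, -size / 8, size / 8)
      r2 <- outer((coords - cy)^2, (coords - cx)^2, "+")
      m <- m - blobDepth * exp(-r2 / (2 * blobRadius^2))
    }
    m <- m + matrix(rnorm(size * size, sd = noiseSd), size, size)
    m <- round(pmin(pmax(m, 0), 255))
    storage.mode(m) <- "integer"
    m
  }
  labels <- rep(c(0L, 1L), nPerClass)
  list(images = lapply(labels, makeImage), labels = labels)
}

#' Write simulated phantoms to PNG files
#'
#' @param phantoms result of [simulatePhantoms()].
#' @param dir output directory (created if missing); images are written as
#'   `phantom_0001.png`, ... and a `labels.csv` with columns `file` and
#'   `label`.
#' @return path of the labels CSV, invisibly.
#' @export
writePhantoms <- function(phantoms, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("phantom_%04d.png", seq_along(phantoms$images))
  for (i in seq_along(phantoms$images)) {
    EBImage::writeImage(EBImage::Image(phantoms$images[[i]] / 255),
                        file.path(dir, files[i]))
  }
  labfile <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(file = files, label = phantoms$labels),
                   labfile, row.names = FALSE)
  invisible(labfile)
}
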