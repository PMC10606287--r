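#' Colour intensity of an RGB triple
#'
#' The scalar colour statistic used for grading: the plain sum of the three
#' 8-bit channel values, ranging 0 (black) to 765 (white). Green unripe
#' fruit is dark (low CI); ripening shifts the peel toward bright yellow and
#' brown, raising CI.
#'
#' @param r,g,b channel values in [0, 255]; vectorised.
#' @return Numeric vector of sums in [0, 765].
#' @examples
#' colorIntensity(90, 107, 8)   # 205
#' @export
colorIntensity <- function(r, g, b) {
  .checkChannel(r); .checkChannel(g); .checkChannel(b)
  r + g + b
}

.checkChannel <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 255))
    stop("channel values must lie in [0, 255]")
  invisible(x)
}

#' RGB to HSV conversion
#'
#' Standard hexcone transform, on the scales used throughout the package:
#' hue in degrees [0, 360), saturation = (max - min)/max x 100 (0 when
#' max = 0), value = max/255 x 100. Hue of an achromatic colour is 0 by
#' convention. Delegates to \code{grDevices::rgb2hsv}.
#'
#' @param r,g,b channel values in [0, 255]; vectorised.
#' @return Data frame with columns \code{hue}, \code{saturation},
#'   \code{value}.
#' @examples
#' rgbToHsv(90, 107, 8)  # hue ~70.3, saturation ~92.5, value ~42.0
#' @export
rgbToHsv <- function(r, g, b) {
  .checkChannel(r); .checkChannel(g); .checkChannel(b)
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  data.frame(hue = hsv["h", ] * 360,
             saturation = hsv["s", ] * 100,
             value = hsv["v", ] * 100,
             row.names = NULL)
}

#' HSV to RGB conversion
#'
#' Analytic hexcone inverse; returns continuous (unrounded) channel values
#' so callers control quantisation.
#'
#' @param h hue in degrees [0, 360).
#' @param s saturation in percent [0, 100].
#' @param v value in percent [0, 100].
#' @return Data frame with columns \code{r}, \code{g}, \code{b} in [0, 255].
#' @examples
#' round(hsvToRgb(70.3, 92.5, 42.0))
#' @export
hsvToRgb <- function(h, s, v) {
  if (any(h < 0 | h >= 360) || any(s < 0 | s > 100) || any(v < 0 | v > 100))
    stop("need h in [0,360), s and v in [0,100]")
  vmax <- v / 100 * 255
  c_ <- vmax * s / 100
  hp <- h / 60
  x <- c_ * (1 - abs(hp %% 2 - 1))
  m <- vmax - c_
  sector <- floor(hp) %% 6
  r <- g <- b <- numeric(length(h))
  pick <- function(a, b_, c2) cbind(a, b_, c2)
  rgb0 <- matrix(0, length(h), 3)
  rgb0[sector == 0, ] <- pick(c_, x, 0)[sector == 0, , drop = FALSE]
  rgb0[sector == 1, ] <- pick(x, c_, 0)[sector == 1, , drop = FALSE]
  rgb0[sector == 2, ] <- pick(0, c_, x)[sector == 2, , drop = FALSE]
  rgb0[sector == 3, ] <- pick(0, x, c_)[sector == 3, , drop = FALSE]
  rgb0[sector == 4, ] <- pick(x, 0, c_)[sector == 4, , drop = FALSE]
  rgb0[sector == 5, ] <- pick(c_, 0, x)[sector == 5, , drop = FALSE]
  data.frame(r = rgb0[, 1] + m, g = rgb0[, 2] + m, b = rgb0[, 3] + m)
}

#' Crop a region of interest around the fruit
#'
#' Returns the smallest axis-aligned rectangle centred on the fruit-mask
#' centroid whose mask coverage reaches at least \code{minFraction} of the
#' total fruit area (0.6 by default, the grading protocol's "at least 60%
#' of the fruit" rule). The mask is carried along with the crop.
#'
#' @param image an \linkS4class{ImageSample}.
#' @param minFraction required fraction of the total fruit area inside the
#'   crop, in (0, 1].
#' @return A cropped \linkS4class{ImageSample}.
#' @examples
#' rec <- sampleFeatures("EXTRA", 1, seed = 1)
#' img <- renderLemon(rec, size = 96, seed = 1)
#' cropRoi(img)
#' @export
cropRoi <- function(image, minFraction = 0.6) {
  stopifnot(is(image, "ImageSample"))
  if (minFraction <= 0 || minFraction > 1)
    stop("minFraction must be in (0, 1]")
  m <- fruitMask(image)
  total <- sum(m)
  if (total == 0) stop("fruit mask is empty")
  H <- nrow(m); W <- ncol(m)
  cr <- round(mean(which(m, arr.ind = TRUE)[, 1]))
  cc <- round(mean(which(m, arr.ind = TRUE)[, 2]))
  maxHalfR <- min(cr - 1, H - cr)
  maxHalfC <- min(cc - 1, W - cc)
  # cumulative-sum table for O(1) rectangle coverage queries
  S <- matrix(0, H + 1, W + 1)
  S[-1, -1] <- t(apply(apply(m + 0, 2, cumsum), 1, cumsum))
  rectCount <- function(r1, r2, c1, c2)
    S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
  coverage <- function(s) {
    hr <- floor(s * maxHalfR); hc <- floor(s * maxHalfC)
    rectCount(cr - hr, cr + hr, cc - hc, cc + hc) / total
  }
  if (coverage(1) < minFraction)
    stop("no centred rectangle reaches the requested coverage (",
         signif(coverage(1), 3), " < ", minFraction, ")")
  lo <- 0; hi <- 1
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (coverage(mid) >= minFraction) hi <- mid else lo <- mid
  }
  hr <- floor(hi * maxHalfR); hc <- floor(hi * maxHalfC)
  rows <- (cr - hr):(cr + hr); cols <- (cc - hc):(cc + hc)
  ImageSample(pixels(image)[rows, cols, , drop = FALSE],
              m[rows, cols, drop = FALSE], pxPerCm(image),
              if (is.na(image@category)) NA_character_ else image@category)
}

#' Per-channel histograms over the fruit mask
#'
#' Tallies masked pixels into 256 bins per channel (bin b counts pixels with
#' channel value exactly b). Counts in each channel sum to the mask area.
#'
#' @param image an \linkS4class{ImageSample}.
#' @return Integer 256 x 3 matrix, columns R, G, B; rownames "0".."255".
#' @examples
#' img <- ImageSample(array(rep(c(10L, 20L, 30L), each = 25), c(5, 5, 3)))
#' colSums(channelHistograms(img))
#' @export
channelHistograms <- function(image) {
  stopifnot(is(image, "ImageSample"))
  m <- fruitMask(image)
  if (sum(m) == 0) stop("fruit mask is empty")
  p <- pixels(image)
  h <- vapply(1:3, function(k) tabulate(p[, , k][m] + 1L, nbins = 256L),
              integer(256))
  dimnames(h) <- list(0:255, c("R", "G", "B"))
  h
}

#' Histogram peaks (channel modes)
#'
#' The 8-bit value of the most populated bin per channel; ties are broken
#' toward the lowest bin.
#'
#' @param histograms a 256 x 3 count matrix from
#'   \code{\link{channelHistograms}}.
#' @return Named integer vector \code{c(r, g, b)} of peak channel values.
#' @examples
#' h <- matrix(0L, 256, 3); h[108, 1] <- h[121, 2] <- h[18, 3] <- 5L
#' histogramPeaks(h)
#' @export
histogramPeaks <- function(histograms) {
  stopifnot(is.matrix(histograms), nrow(histograms) == 256,
            ncol(histograms) == 3, all(histograms >= 0))
  peaks <- apply(histograms, 2, which.max) - 1L  # which.max: first (lowest) max
  names(peaks) <- c("r", "g", "b")
  peaks
}

#' Extract the grading colour features from an image
#'
#' Reduces the fruit pixels to one representative RGB triple — the mask mean
#' (default) or the histogram-peak triple — then computes colour intensity
#' and HSV from it.
#'
#' @param image an \linkS4class{ImageSample}.
#' @param mode "mask_mean" or "histogram_peak".
#' @return One-row data.frame: \code{hue}, \code{saturation}, \code{value},
#'   \code{color_intensity}.
#' @examples
#' rec <- sampleFeatures("EXTRA", 1, seed = 3)
#' img <- renderLemon(rec, size = 96, noiseSd = 0, blemishes = 0, seed = 3)
#' extractFeatures(img)
#' @export
extractFeatures <- function(image, mode = c("mask_mean", "histogram_peak")) {
  mode <- match.arg(mode)
  stopifnot(is(image, "ImageSample"))
  if (mode == "mask_mean") {
    m <- fruitMask(image)
    p <- pixels(image)
    rep_rgb <- vapply(1:3, function(k) mean(p[, , k][m]), numeric(1))
  } else {
    rep_rgb <- as.numeric(histogramPeaks(channelHistograms(image)))
  }
  hsv <- rgbToHsv(rep_rgb[1], rep_rgb[2], rep_rgb[3])
  cbind(hsv, color_intensity = colorIntensity(rep_rgb[1], rep_rgb[2], rep_rgb[3]))
}

#' Load an RGB image from a PNG file
#'
#' Reads an 8-bit PNG and optionally derives a fruit mask by thresholding
#' against a dark uniform background (fruit pixels are those whose maximum
#' channel exceeds \code{bgCutoff}). Intended for generator output or
#' studio-style frames; it is not a general segmentation method.
#'
#' @param path PNG file path.
#' @param pxPerCm pixel scale to record.
#' @param bgCutoff 8-bit threshold on the per-pixel channel maximum; set to
#'   NA to mark every pixel as fruit.
#' @return An \linkS4class{ImageSample}.
#' @export
readImageSample <- function(path, pxPerCm = 20, bgCutoff = 32) {
  if (!file.exists(path)) stop("no such file: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  p <- round(a[, , 1:3] * 255)
  storage.mode(p) <- "integer"
  mask <- if (is.na(bgCutoff)) matrix(TRUE, dim(p)[1], dim(p)[2])
          else pmax(p[, , 1], p[, , 2], p[, , 3]) > bgCutoff
  ImageSample(p, mask, pxPerCm)
}
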