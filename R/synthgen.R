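# run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  force(expr)
}

# mean and sd of a Gaussian(mu, sig) truncated to [lo, hi], plus the mass Z
# kept by the truncation (the rejection sampler's acceptance probability)
.truncMoments <- function(mu, sig, lo, hi) {
  a <- (lo - mu) / sig; b <- (hi - mu) / sig
  # far-tail degenerate cases: essentially all mass at one bound
  if (a >= 8) return(list(mean = lo, sd = 0, Z = 0))
  if (b <= -8) return(list(mean = hi, sd = 0, Z = 0))
  a <- max(a, -37); b <- min(b, 37)
  Z <- stats::pnorm(b) - stats::pnorm(a)
  d <- (stats::dnorm(a) - stats::dnorm(b)) / Z
  m <- mu + sig * d
  v <- sig^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / Z - d^2)
  list(mean = m, sd = sqrt(max(v, 0)), Z = Z)
}

.parentCache <- new.env(parent = emptyenv())

# Parent Gaussian parameters whose truncation to [lo, hi] reproduces the
# target mean exactly and the target SD as closely as the family allows,
# subject to a rejection-sampling acceptance probability of at least 1%.
# Where truncation is negligible this returns (mean, sd) unchanged.
.truncParent <- function(mean, sd, lo, hi) {
  key <- paste(mean, sd, lo, hi, sep = "|")
  hit <- .parentCache[[key]]
  if (!is.null(hit)) return(hit)

  muFor <- function(sig) {       # truncated mean is increasing in mu
    f <- function(mu) .truncMoments(mu, sig, lo, hi)$mean - mean
    loB <- mean - sig; hiB <- mean + sig
    while (f(loB) > 0) loB <- loB - 5 * sig
    while (f(hiB) < 0) hiB <- hiB + 5 * sig
    stats::uniroot(f, c(loB, hiB), tol = 1e-12)$root
  }
  zFor <- function(sig) .truncMoments(muFor(sig), sig, lo, hi)$Z
  sigHi <- sd * 30
  if (zFor(sigHi) < 0.01)        # cap sigma where acceptance drops to 1%
    sigHi <- exp(stats::uniroot(function(ls) zFor(exp(ls)) - 0.01,
                                log(c(sd / 10, sigHi)), tol = 1e-10)$root)
  obj <- function(ls) {
    sig <- exp(ls)
    (.truncMoments(muFor(sig), sig, lo, hi)$sd - sd)^2
  }
  sig <- exp(stats::optimize(obj, log(c(sd / 10, sigHi)), tol = 1e-13)$minimum)
  mu <- muFor(sig)
  got <- .truncMoments(mu, sig, lo, hi)
  res <- list(mu = mu, sigma = sig, mean = got$mean, sd = got$sd)
  .parentCache[[key]] <- res
  res
}

# Gaussian truncated to [lo, hi] by reject-and-resample (keeps unimodality)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  guard <- 0L
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncation range too far from the mean")
  }
  x
}

#' Draw synthetic lemon records for one category
#'
#' Each of the seven grading properties is drawn independently from a
#' Gaussian truncated to its physical range (hue [0,360), saturation/value
#' [0,100], colour intensity [0,765], weight/ratio/thickness positive). The
#' parent Gaussian is moment-calibrated so the emitted (post-truncation)
#' sample mean matches the profile mean exactly and the sample SD matches
#' the profile SD as closely as a truncated Gaussian allows; where the range
#' barely clips the distribution this reduces to the profile's own mean and
#' SD. Draws are reproducible for a fixed seed.
#'
#' @param category category name ("EXTRA", "CAT_I", "CAT_II") or code 1-3.
#' @param n number of records (>= 1).
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{id}, \code{category}, \code{code}
#'   and the seven properties in \code{\link{featureNames}} order.
#' @examples
#' head(sampleFeatures("EXTRA", 5, seed = 1))
#' @export
sampleFeatures <- function(category, n, seed) {
  category <- .checkCategory(category)
  if (length(category) != 1L) stop("one category at a time")
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  prof <- categoryProfiles(category)
  .withSeed(seed, {
    vals <- lapply(featureNames(), function(p) {
      rng <- .propertyRange(p)
      par <- .truncParent(prof[[paste0(p, "_mean")]],
                          prof[[paste0(p, "_sd")]], rng[1], rng[2])
      .rtruncnorm(n, par$mu, par$sigma, rng[1], rng[2])
    })
    names(vals) <- featureNames()
    data.frame(id = sprintf("%s-%04d", tolower(category), seq_len(n)),
               category = category, code = prof$code, vals,
               stringsAsFactors = FALSE)
  })
}

#' Feature matrix from a record table
#'
#' @param records data.frame of lemon records (from
#'   \code{\link{sampleFeatures}} or a manifest).
#' @return Numeric n x 7 matrix in \code{\link{featureNames}} order.
#' @export
featureMatrix <- function(records) {
  miss <- setdiff(featureNames(), names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  as.matrix(records[, featureNames(), drop = FALSE])
}

# default blemish budget (total area cm^2, count) per category:
# EXTRA spotless, Category I under the 1 cm^2 rule, Category II above it
.blemishDefault <- function(category) {
  switch(category,
    EXTRA = list(area_cm2 = 0, count = 0L),
    CAT_I = list(area_cm2 = stats::runif(1, 0.3, 0.8),
                 count = sample(1:3, 1)),
    CAT_II = list(area_cm2 = stats::runif(1, 1.2, 3.0),
                  count = sample(1:3, 1)))
}

#' Render a synthetic lemon image from a record
#'
#' Draws an elliptical fruit (axis ratio = the record's diameter/length
#' ratio) on a uniform dark background, fills it with per-pixel Gaussian
#' colour noise around a base colour, and stamps feathered brown blemish
#' patches sized by the category's defect rule (none for "extra", under
#' 1 cm^2 total for Category I, over 1 cm^2 for Category II).
#'
#' The base colour comes from the record's own HSV (\code{colorSource =
#' "record"}, default) so that feature extraction on a noiseless frame
#' round-trips the record; \code{colorSource = "peaks"} instead uses the
#' category's representative RGB histogram-peak triple, reproducing the
#' published per-category channel modes. The two references are measured on
#' different things (per-fruit averages vs one frame's histogram modes) and
#' do not coincide, so both are offered.
#'
#' @param record one-row data.frame from \code{\link{sampleFeatures}}.
#' @param size frame side in pixels (>= 64); frames are square.
#' @param blemishes NULL for the category default, 0 for none, a single
#'   number for a total area in cm^2, or \code{list(area_cm2 =, count =)}.
#' @param noiseSd per-channel Gaussian noise SD (8-bit units); 0 gives a
#'   constant-colour fruit.
#' @param pxPerCm pixel scale (default 20), recorded in the sample so the
#'   1 cm^2 defect rule is checkable.
#' @param colorSource "record" or "peaks" (see Details).
#' @param seed integer RNG seed.
#' @return An \linkS4class{ImageSample} with the ground-truth category set.
#' @examples
#' rec <- sampleFeatures("CAT_II", 1, seed = 2)
#' img <- renderLemon(rec, size = 128, seed = 2)
#' img
#' @export
renderLemon <- function(record, size = 256, blemishes = NULL, noiseSd = 6,
                        pxPerCm = 20, colorSource = c("record", "peaks"),
                        seed = 1) {
  colorSource <- match.arg(colorSource)
  if (nrow(record) != 1L) stop("render one record at a time")
  if (size < 64) stop("size must be >= 64 pixels")
  category <- .checkCategory(record$category)
  prof <- categoryProfiles(category)

  base <- if (colorSource == "record") {
    as.numeric(round(hsvToRgb(record$hue, record$saturation, record$value)))
  } else {
    c(prof$peak_r, prof$peak_g, prof$peak_b)
  }

  .withSeed(seed, {
    if (is.null(blemishes)) blemishes <- .blemishDefault(category)
    if (is.numeric(blemishes) && length(blemishes) == 1L)
      blemishes <- list(area_cm2 = blemishes,
                        count = if (blemishes > 0) sample(1:3, 1) else 0L)

    cx <- (size + 1) / 2; cy <- (size + 1) / 2
    a <- 0.42 * size                      # semi-axis along image columns
    b <- a * min(record$dl_ratio, 1 / record$dl_ratio)
    xs <- matrix(seq_len(size), size, size, byrow = TRUE)
    ys <- matrix(seq_len(size), size, size)
    mask <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1

    fruitArea_cm2 <- sum(mask) / pxPerCm^2
    if (blemishes$area_cm2 >= fruitArea_cm2)
      stop("blemish area (", blemishes$area_cm2, " cm^2) exceeds fruit area (",
           signif(fruitArea_cm2, 3), " cm^2)")

    px <- array(0, c(size, size, 3))
    bg <- c(18, 18, 22)                   # dark field, distinct from peel hues
    for (k in 1:3) {
      chan <- matrix(bg[k], size, size)
      fr <- base[k] + if (noiseSd > 0)
        stats::rnorm(sum(mask), 0, noiseSd) else 0
      chan[mask] <- fr
      px[, , k] <- chan
    }

    if (blemishes$count > 0 && blemishes$area_cm2 > 0) {
      areas_px <- blemishes$area_cm2 * pxPerCm^2 *
        as.numeric(stats::rmultinom(1, 1000, rep(1, blemishes$count))) / 1000
      bl_hsv <- c(30, max(record$saturation, 50), record$value * 0.6)
      bl_rgb <- as.numeric(hsvToRgb(bl_hsv[1], bl_hsv[2], bl_hsv[3]))
      feather <- 1.5                      # px, Gaussian edge roll-off
      for (r_px in sqrt(pmax(areas_px, 1) / pi)) {
        # centre inside the ellipse shrunk so the patch stays on the fruit
        repeat {
          u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
          if (u^2 + v^2 <= 1) break
        }
        bx <- cx + u * max(a - r_px, 0); by <- cy + v * max(b - r_px, 0)
        d <- sqrt((xs - bx)^2 + (ys - by)^2)
        # Gaussian roll-off entirely inside the patch radius, so the altered
        # area never exceeds the nominal blemish budget
        edge <- max(r_px - 3 * feather, 0)
        w <- ifelse(d <= edge, 1, exp(-(d - edge)^2 / (2 * feather^2)))
        w[d > r_px] <- 0
        w[!mask] <- 0
        for (k in 1:3)
          px[, , k] <- (1 - w) * px[, , k] + w * bl_rgb[k]
      }
    }

    px <- round(pmin(pmax(px, 0), 255))
    ImageSample(px, mask, pxPerCm, category)
  })
}

#' Generate a balanced synthetic dataset on disk
#'
#' Draws \code{nPerClass} records per category, optionally renders a PNG per
#' record, and writes a manifest CSV (columns id, category_code, hue_deg,
#' saturation_pct, value_pct, color_intensity, weight_g, dl_ratio,
#' thickness_mm, image_path). The default replication sizes are 20 per class
#' for the training pool and 10 per class for the held-out second set.
#'
#' @param dir output directory (created if missing).
#' @param nPerClass records per category (>= 1).
#' @param seed integer RNG seed.
#' @param withImages render and write PNG frames?
#' @param imageSize frame side in pixels.
#' @param manifest manifest file name within \code{dir}.
#' @param pxPerCm pixel scale for rendered frames.
#' @return Invisibly, the record data.frame (with \code{image_path}).
#' @examples
#' d <- tempfile(); recs <- generateDataset(d, nPerClass = 2, seed = 1,
#'                                          withImages = FALSE)
#' nrow(recs)
#' @export
generateDataset <- function(dir, nPerClass = 20, seed = 1, withImages = FALSE,
                            imageSize = 128, manifest = "manifest.csv",
                            pxPerCm = 20) {
  if (nPerClass < 1) stop("nPerClass must be >= 1")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) stop("cannot write to ", dir)
  cats <- names(categoryLabels())
  recs <- do.call(rbind, lapply(seq_along(cats), function(i)
    sampleFeatures(cats[i], nPerClass, seed = seed + (i - 1L))))
  recs$image_path <- NA_character_
  if (withImages) {
    for (i in seq_len(nrow(recs))) {
      path <- file.path(dir, paste0(recs$id[i], ".png"))
      img <- renderLemon(recs[i, ], size = imageSize, pxPerCm = pxPerCm,
                         seed = seed + 1000L + i)
      png::writePNG(pixels(img) / 255, target = path)
      recs$image_path[i] <- path
    }
  }
  man <- data.frame(id = recs$id, category_code = recs$code,
                    hue_deg = recs$hue, saturation_pct = recs$saturation,
                    value_pct = recs$value,
                    color_intensity = recs$color_intensity,
                    weight_g = recs$weight, dl_ratio = recs$dl_ratio,
                    thickness_mm = recs$thickness,
                    image_path = recs$image_path)
  utils::write.csv(man, file.path(dir, manifest), row.names = FALSE)
  invisible(recs)
}

#' Read a manifest CSV back into a record table
#'
#' @param path manifest CSV written by \code{\link{generateDataset}}.
#' @return data.frame in \code{\link{sampleFeatures}} layout.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "category_code", "hue_deg", "saturation_pct", "value_pct",
            "color_intensity", "weight_g", "dl_ratio", "thickness_mm")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  data.frame(id = man$id, category = .checkCategory(man$category_code),
             code = as.integer(man$category_code), hue = man$hue_deg,
             saturation = man$saturation_pct, value = man$value_pct,
             color_intensity = man$color_intensity, weight = man$weight_g,
             dl_ratio = man$dl_ratio, thickness = man$thickness_mm,
             image_path = if (is.null(man$image_path)) NA_character_
                          else man$image_path,
             stringsAsFactors = FALSE)
}
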