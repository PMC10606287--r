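#' Per-category statistical profiles of Persian lemons
#'
#' Calibration constants of the synthetic generator: for each quality
#' category, the mean and standard deviation of the seven grading properties
#' (hue in degrees, saturation and value in percent, colour intensity as the
#' sum of the three 8-bit channel values, weight in grams, diameter/length
#' ratio, peel thickness in mm), the representative RGB histogram-peak
#' triple, and the colour-intensity display range.
#'
#' Colour separates the grades strongly — green, high-saturation, dark fruit
#' for "extra"; yellowing, brighter fruit for Category I; brown-shifted,
#' bright fruit for Category II — while weight, sphericity and peel
#' thickness overlap heavily across grades.
#'
#' @param category optional category name or code; when given, the single
#'   matching profile row is returned.
#' @return A data.frame with one row per category and columns
#'   \code{category}, \code{code}, \code{<property>_mean},
#'   \code{<property>_sd} for the seven properties, \code{peak_r},
#'   \code{peak_g}, \code{peak_b}, \code{ci_lo}, \code{ci_hi}.
#' @examples
#' categoryProfiles()
#' categoryProfiles("EXTRA")$weight_mean
#' @export
categoryProfiles <- function(category = NULL) {
  p <- data.frame(
    category = c("EXTRA", "CAT_I", "CAT_II"),
    code = 1:3,
    hue_mean = c(126.83, 87.83, 60.95),
    hue_sd = c(7.23, 25.60, 9.08),
    saturation_mean = c(95.60, 87.85, 62.44),
    saturation_sd = c(7.21, 11.07, 17.36),
    value_mean = c(42.39, 78.65, 91.84),
    value_sd = c(20.85, 12.05, 4.88),
    color_intensity_mean = c(127.43, 341.2, 538.55),
    color_intensity_sd = c(56.62, 68.54, 57.49),
    weight_mean = c(26.50, 25.69, 23.05),
    weight_sd = c(3.00, 3.02, 3.08),
    dl_ratio_mean = c(0.92, 0.91, 0.97),
    dl_ratio_sd = c(0.08, 0.06, 0.07),
    thickness_mean = c(1.50, 1.48, 1.29),
    thickness_sd = c(0.29, 0.32, 0.33),
    peak_r = c(90L, 124L, 111L),
    peak_g = c(107L, 120L, 82L),
    peak_b = c(8L, 17L, 29L),
    ci_lo = c(35, 245, 455),
    ci_hi = c(210, 420, 630),
    stringsAsFactors = FALSE
  )
  stopifnot(all(diff(p$color_intensity_mean) > 0))  # EXTRA < CAT_I < CAT_II
  if (is.null(category)) return(p)
  p[p$category == .checkCategory(category), , drop = FALSE]
}

#' Names of the seven grading properties, in the fixed feature order
#'
#' The order is the feature-vector convention used by the classifier:
#' hue, saturation, value, colour intensity, weight, diameter/length ratio,
#' peel thickness.
#'
#' @return Character vector of length 7.
#' @examples
#' featureNames()
#' @export
featureNames <- function() {
  c("hue", "saturation", "value", "color_intensity",
    "weight", "dl_ratio", "thickness")
}

# physical truncation range per property
.propertyRange <- function(property) {
  switch(property,
    hue = c(0, 360 - 1e-9),
    saturation = c(0, 100),
    value = c(0, 100),
    color_intensity = c(0, 765),
    weight = c(1e-9, Inf),
    dl_ratio = c(1e-9, Inf),
    thickness = c(1e-9, Inf),
    stop("unknown property: ", property))
}
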