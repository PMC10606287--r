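#' Fit a per-feature z-score standardizer
#'
#' Learns column means and SDs. Fit this on the training split only, then
#' apply to every split: the seven raw properties span about three orders of
#' magnitude (colour intensity vs peel thickness), which would saturate the
#' sigmoid hidden layer if fed raw.
#'
#' @param x numeric matrix (rows = samples).
#' @return A \linkS4class{Standardizer}.
#' @examples
#' std <- fitStandardizer(featureMatrix(sampleFeatures("EXTRA", 10, 1)))
#' @export
fitStandardizer <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    warning("constant feature(s); unit scale used: ",
            paste(colnames(x)[scl == 0], collapse = ", "))
    scl[scl == 0] <- 1
  }
  new("Standardizer", center = ctr, scale = scl)
}

#' Apply / invert a standardizer
#'
#' @param std a \linkS4class{Standardizer}.
#' @param x numeric matrix with the same columns the standardizer was fit on.
#' @return Matrix of the same shape.
#' @examples
#' m <- featureMatrix(sampleFeatures("EXTRA", 10, 1))
#' std <- fitStandardizer(m)
#' all.equal(unstandardize(std, standardize(std, m)), m)
#' @export
standardize <- function(std, x) {
  stopifnot(is(std, "Standardizer"))
  x <- as.matrix(x)
  if (ncol(x) != length(std@center)) stop("column count mismatch")
  sweep(sweep(x, 2, std@center, "-"), 2, std@scale, "/")
}

#' @rdname standardize
#' @export
unstandardize <- function(std, x) {
  stopifnot(is(std, "Standardizer"))
  x <- as.matrix(x)
  if (ncol(x) != length(std@center)) stop("column count mismatch")
  sweep(sweep(x, 2, std@scale, "*"), 2, std@center, "+")
}
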