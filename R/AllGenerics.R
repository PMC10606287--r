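#' @rdname ImageSample-class
#' @param object,x an object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname ImageSample-class
#' @export
setGeneric("fruitMask", function(x) standardGeneric("fruitMask"))

#' @rdname ImageSample-class
#' @export
setGeneric("pxPerCm", function(x) standardGeneric("pxPerCm"))

#' @rdname EvalReport-class
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname EvalReport-class
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname EvalReport-class
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname Trajectory-class
#' @export
setGeneric("settleTime", function(x) standardGeneric("settleTime"))

#' @rdname Trajectory-class
#' @export
setGeneric("finalAngle", function(x) standardGeneric("finalAngle"))

#' @rdname Trajectory-class
#' @export
setGeneric("settled", function(x) standardGeneric("settled"))

#' @rdname ImageSample-class
#' @aliases pixels,ImageSample-method
setMethod("pixels", "ImageSample", function(x) x@pixels)

#' @rdname ImageSample-class
#' @aliases fruitMask,ImageSample-method
setMethod("fruitMask", "ImageSample", function(x) x@fruitMask)

#' @rdname ImageSample-class
#' @aliases pxPerCm,ImageSample-method
setMethod("pxPerCm", "ImageSample", function(x) x@pxPerCm)

#' @rdname EvalReport-class
#' @aliases confusionMatrix,EvalReport-method
setMethod("confusionMatrix", "EvalReport", function(x) x@confusion)

#' @rdname EvalReport-class
#' @aliases accuracy,EvalReport-method
setMethod("accuracy", "EvalReport", function(x) x@accuracy)

#' @rdname EvalReport-class
#' @aliases rocPoints,EvalReport-method
setMethod("rocPoints", "EvalReport", function(x) x@roc)

#' @rdname Trajectory-class
#' @aliases settleTime,Trajectory-method
setMethod("settleTime", "Trajectory", function(x) x@settleTime)

#' @rdname Trajectory-class
#' @aliases finalAngle,Trajectory-method
setMethod("finalAngle", "Trajectory", function(x) x@finalAngle)

#' @rdname Trajectory-class
#' @aliases settled,Trajectory-method
setMethod("settled", "Trajectory", function(x) x@settled)

setMethod("show", "ImageSample", function(object) {
  d <- dim(object@pixels)
  cat("ImageSample:", d[1], "x", d[2], "RGB,",
      sum(object@fruitMask), "fruit px,",
      object@pxPerCm, "px/cm")
  if (!is.na(object@category)) cat(", category", object@category)
  cat("\n")
})

setMethod("show", "LemonNet", function(object) {
  cat("LemonNet: 7 inputs -> 5 sigmoid -> 3 softmax (",
      7 * 5 + 5 + 5 * 3 + 3, "parameters )\n")
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport: accuracy", sprintf("%.1f%%", object@accuracy), "\n")
  cm <- object@confusion
  dimnames(cm) <- list(true = names(categoryLabels()),
                       predicted = names(categoryLabels()))
  print(cm)
  cat("per-class TPR:", sprintf("%.3f", object@perClassTPR), "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory: target", object@targetAngle, "deg, final",
      sprintf("%.2f", object@finalAngle), "deg,",
      if (object@settled) sprintf("settled at %.3f s", object@settleTime)
      else "not settled", "\n")
})

setMethod("show", "MotorParams", function(object) {
  cat("MotorParams:", object@phases, "phases,", object@stepAngle,
      "deg step, L", object@Lmin, "-", object@Lmax, "H, R",
      object@resistance, "ohm,", object@driveVoltage, "V drive,",
      object@frictionModel, "friction\n")
})

setMethod("show", "LemonGrader", function(object) {
  cat("LemonGrader: trained 7-5-3 network,",
      nrow(object@history), "epochs\n")
})
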