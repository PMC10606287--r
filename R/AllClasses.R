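#' @import methods
NULL

#' Quality categories of export Persian lemons
#'
#' Integer-coded grade labels: 1 = Category "extra" (no defects),
#' 2 = Category I (superficial defects under 1 cm^2), 3 = Category II
#' (defects over 1 cm^2). The codes match the confusion-matrix output
#' labelling used throughout the package.
#'
#' @return Named integer vector of length three.
#' @examples
#' categoryLabels()
#' @export
categoryLabels <- function() {
  c(EXTRA = 1L, CAT_I = 2L, CAT_II = 3L)
}

.checkCategory <- function(category) {
  labs <- categoryLabels()
  if (is.numeric(category)) {
    if (!all(category %in% labs))
      stop("unknown category code(s): ", paste(setdiff(category, labs), collapse = ", "))
    return(names(labs)[match(as.integer(category), labs)])
  }
  category <- toupper(as.character(category))
  if (!all(category %in% names(labs)))
    stop("unknown category: ", paste(setdiff(category, names(labs)), collapse = ", "))
  category
}

#' ImageSample: an RGB frame with its fruit mask
#'
#' A rendered or loaded 8-bit RGB image together with a boolean mask marking
#' fruit pixels, the pixel scale, and (optionally) the ground-truth category.
#'
#' @slot pixels integer array H x W x 3, values in [0, 255].
#' @slot fruitMask logical matrix H x W; TRUE on fruit pixels.
#' @slot pxPerCm numeric scalar, pixels per centimetre.
#' @slot category character, one of "EXTRA", "CAT_I", "CAT_II", or NA.
#'
#' @export
setClass("ImageSample",
  representation(pixels = "array", fruitMask = "matrix",
                 pxPerCm = "numeric", category = "character"),
  prototype(pxPerCm = 20, category = NA_character_))

setValidity("ImageSample", function(object) {
  p <- object@pixels
  m <- object@fruitMask
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (!is.logical(m) || !identical(dim(m), dim(p)[1:2]))
    return("fruitMask must be a logical H x W matrix matching pixels")
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("pixel values must lie in [0, 255]")
  if (sum(m) == 0)
    return("fruit mask is empty")
  if (length(object@pxPerCm) != 1L || object@pxPerCm <= 0)
    return("pxPerCm must be a positive scalar")
  TRUE
})

#' Construct an ImageSample
#'
#' @param pixels H x W x 3 numeric/integer array of 8-bit channel values.
#' @param fruitMask logical H x W matrix; defaults to all-TRUE.
#' @param pxPerCm pixels per centimetre (default 20).
#' @param category optional ground-truth category label or code.
#' @return An \linkS4class{ImageSample}.
#' @examples
#' img <- ImageSample(array(128L, dim = c(8, 8, 3)))
#' dim(pixels(img))
#' @export
ImageSample <- function(pixels, fruitMask = NULL, pxPerCm = 20,
                        category = NA_character_) {
  storage.mode(pixels) <- "integer"
  if (is.null(fruitMask))
    fruitMask <- matrix(TRUE, nrow = dim(pixels)[1], ncol = dim(pixels)[2])
  if (!is.na(category)) category <- .checkCategory(category)
  new("ImageSample", pixels = pixels, fruitMask = fruitMask,
      pxPerCm = as.numeric(pxPerCm), category = as.character(category))
}

#' Standardizer: per-feature z-score transform
#'
#' Location (mean) and scale (SD) learned from training data only; used to
#' put the seven input properties, whose raw scales differ by orders of
#' magnitude, on comparable footing before the sigmoid hidden layer.
#'
#' @slot center numeric named vector of feature means.
#' @slot scale numeric named vector of feature SDs (all > 0).
#' @export
setClass("Standardizer",
  representation(center = "numeric", scale = "numeric"))

setValidity("Standardizer", function(object) {
  if (length(object@center) != length(object@scale))
    return("center and scale lengths differ")
  if (any(!is.finite(object@scale)) || any(object@scale <= 0))
    return("all scales must be finite and > 0")
  TRUE
})

#' LemonNet: the 7-5-3 shallow classifier
#'
#' Feed-forward network with seven standardized inputs, five sigmoid hidden
#' units and a three-way softmax output, the architecture used for lemon
#' grading.
#'
#' @slot W1 numeric 7 x 5 input-to-hidden weights.
#' @slot b1 numeric length-5 hidden biases.
#' @slot W2 numeric 5 x 3 hidden-to-output weights.
#' @slot b2 numeric length-3 output biases.
#' @export
setClass("LemonNet",
  representation(W1 = "matrix", b1 = "numeric",
                 W2 = "matrix", b2 = "numeric"))

setValidity("LemonNet", function(object) {
  if (!identical(dim(object@W1), c(7L, 5L))) return("W1 must be 7 x 5")
  if (length(object@b1) != 5L) return("b1 must have length 5")
  if (!identical(dim(object@W2), c(5L, 3L))) return("W2 must be 5 x 3")
  if (length(object@b2) != 3L) return("b2 must have length 3")
  if (!all(is.finite(c(object@W1, object@b1, object@W2, object@b2))))
    return("all weights must be finite")
  TRUE
})

#' TrainingConfig: scaled-conjugate-gradient training settings
#'
#' @slot splitFractions numeric length-3 (train, validation, test); sums to 1.
#' @slot maxEpochs integer cap on SCG iterations.
#' @slot patience integer; consecutive validation checks without improvement
#'   tolerated before early stopping.
#' @slot sigma0 numeric; SCG finite-difference step scale.
#' @slot lambda0 numeric; initial SCG trust-region (raindrop) parameter.
#' @slot initScale numeric; half-width of the uniform weight initialisation
#'   before fan-in scaling.
#' @slot seed integer RNG seed for init and splitting.
#' @export
setClass("TrainingConfig",
  representation(splitFractions = "numeric", maxEpochs = "integer",
                 patience = "integer", sigma0 = "numeric",
                 lambda0 = "numeric", initScale = "numeric", seed = "integer"))

setValidity("TrainingConfig", function(object) {
  f <- object@splitFractions
  if (length(f) != 3L || any(f < 0) || abs(sum(f) - 1) > 1e-8)
    return("splitFractions must be three non-negative numbers summing to 1")
  if (object@patience < 1L) return("patience must be >= 1")
  if (object@maxEpochs < 1L) return("maxEpochs must be >= 1")
  if (object@sigma0 <= 0 || object@lambda0 < 0)
    return("sigma0 must be > 0 and lambda0 >= 0")
  TRUE
})

#' Construct a TrainingConfig
#'
#' Defaults mirror the standard scaled-conjugate-gradient setup: 70/15/15
#' random split, at most 1000 epochs, validation patience 6, sigma 1e-4,
#' lambda 1e-6.
#'
#' @param splitFractions train/validation/test fractions (sum to 1).
#' @param maxEpochs maximum SCG iterations.
#' @param patience consecutive non-improving validation checks before stop.
#' @param sigma0,lambda0 SCG constants.
#' @param initScale weight-init half-width before fan-in scaling.
#' @param seed RNG seed.
#' @return A \linkS4class{TrainingConfig}.
#' @examples
#' trainingConfig(seed = 7)
#' @export
trainingConfig <- function(splitFractions = c(0.70, 0.15, 0.15),
                           maxEpochs = 1000L, patience = 6L,
                           sigma0 = 1e-4, lambda0 = 1e-6,
                           initScale = 0.5, seed = 1L) {
  new("TrainingConfig", splitFractions = splitFractions,
      maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
      sigma0 = sigma0, lambda0 = lambda0, initScale = initScale,
      seed = as.integer(seed))
}

#' MotorParams: variable-reluctance stepper-motor constants
#'
#' Physical constants of the three-phase variable-reluctance stepper used by
#' the sorter: per-phase inductance swings between \code{Lmin} (unaligned)
#' and \code{Lmax} (aligned) as a raised cosine of shaft angle.
#'
#' @slot phases integer, number of phases (3).
#' @slot stepAngle numeric, degrees per step (120).
#' @slot Lmax,Lmin numeric, max/min winding inductance (H).
#' @slot resistance numeric, winding resistance (ohm).
#' @slot inertia numeric, total rotor inertia (kg m^2).
#' @slot friction numeric, friction coefficient; interpretation set by
#'   \code{frictionModel}.
#' @slot frictionModel character, "viscous" (N m s/rad) or "coulomb" (N m).
#' @slot driveVoltage numeric, supply voltage on the energized phase (V).
#' @slot initialPosition numeric, initial shaft angle (degrees).
#' @export
setClass("MotorParams",
  representation(phases = "integer", stepAngle = "numeric",
                 Lmax = "numeric", Lmin = "numeric", resistance = "numeric",
                 inertia = "numeric", friction = "numeric",
                 frictionModel = "character", driveVoltage = "numeric",
                 initialPosition = "numeric"))

setValidity("MotorParams", function(object) {
  if (object@Lmax <= object@Lmin || object@Lmin <= 0)
    return("need Lmax > Lmin > 0")
  if (any(c(object@resistance, object@inertia, object@friction,
            object@driveVoltage) <= 0))
    return("resistance, inertia, friction and driveVoltage must be > 0")
  if (abs(object@stepAngle * object@phases - 360) > 1e-9)
    return("stepAngle x phases must equal 360 degrees")
  if (!object@frictionModel %in% c("viscous", "coulomb"))
    return("frictionModel must be 'viscous' or 'coulomb'")
  TRUE
})

#' Construct MotorParams
#'
#' Defaults are the prototype's printed constants: 3 phases, 120 degree step,
#' inductance 0.002-0.01 H, 1.2 ohm winding, inertia 2e-5 kg m^2, friction
#' 0.001 (viscous N m s/rad by default), initial position 0 degrees. The
#' drive voltage is not printed in the prototype description; the 12 V
#' default settles the shaft comfortably within the 1 s response budget.
#'
#' @param phases number of phases.
#' @param stepAngle step angle in degrees.
#' @param Lmax,Lmin winding inductance bounds (H).
#' @param resistance winding resistance (ohm).
#' @param inertia rotor inertia (kg m^2).
#' @param friction friction coefficient.
#' @param frictionModel "viscous" or "coulomb".
#' @param driveVoltage supply voltage (V).
#' @param initialPosition initial shaft angle (degrees).
#' @return A \linkS4class{MotorParams}.
#' @examples
#' motorParams()
#' @export
motorParams <- function(phases = 3L, stepAngle = 120, Lmax = 0.01,
                        Lmin = 0.002, resistance = 1.2, inertia = 2e-5,
                        friction = 0.001, frictionModel = "viscous",
                        driveVoltage = 12, initialPosition = 0) {
  new("MotorParams", phases = as.integer(phases), stepAngle = stepAngle,
      Lmax = Lmax, Lmin = Lmin, resistance = resistance, inertia = inertia,
      friction = friction, frictionModel = frictionModel,
      driveVoltage = driveVoltage, initialPosition = initialPosition)
}

#' PulseCommand: gating command for one motor phase
#'
#' Exactly one of the three pulse generators is armed: the phase whose
#' alignment angle is the sorting target for the predicted category. The
#' onset delay encodes classifier confidence.
#'
#' @slot phase integer in 1..3, the active phase.
#' @slot delay numeric, onset delay in seconds (>= 0).
#' @slot amplitude numeric, 0 or 1.
#' @slot targetAngle numeric, target shaft angle in degrees (0, +120, -120).
#' @export
setClass("PulseCommand",
  representation(phase = "integer", delay = "numeric",
                 amplitude = "numeric", targetAngle = "numeric"))

setValidity("PulseCommand", function(object) {
  if (!object@phase %in% 1:3) return("phase must be 1, 2 or 3")
  if (object@delay < 0) return("delay must be >= 0")
  if (!object@amplitude %in% c(0, 1)) return("amplitude must be 0 or 1")
  if (!object@targetAngle %in% c(0, 120, -120))
    return("targetAngle must be 0, +120 or -120 degrees")
  TRUE
})

#' Trajectory: simulated motor response
#'
#' Time series of shaft state plus the settle diagnosis: the settle time is
#' the first instant after which the shaft stays within 1 degree of target
#' for the rest of the horizon.
#'
#' @slot states data.frame with columns time_s, theta_deg, omega_rad_s,
#'   i1_A, i2_A, i3_A, pulse_amplitude.
#' @slot settleTime numeric, seconds (NA if never settled).
#' @slot settled logical.
#' @slot finalAngle numeric, degrees.
#' @slot targetAngle numeric, degrees.
#' @export
setClass("Trajectory",
  representation(states = "data.frame", settleTime = "numeric",
                 settled = "logical", finalAngle = "numeric",
                 targetAngle = "numeric"))

setValidity("Trajectory", function(object) {
  tm <- object@states$time_s
  if (is.null(tm) || is.unsorted(tm, strictly = TRUE))
    return("states$time_s must be strictly increasing")
  if (object@settled && object@settleTime > max(tm))
    return("settleTime exceeds the simulation horizon")
  TRUE
})

#' EvalReport: confusion matrix, accuracy and ROC points
#'
#' @slot confusion integer 3 x 3 matrix, rows = true class, cols = predicted.
#' @slot accuracy numeric, overall percent correct.
#' @slot perClassTPR numeric length-3 true-positive rates.
#' @slot roc list of three data.frames (fpr, tpr, threshold), one per class.
#' @slot crossEntropy numeric, mean cross-entropy (NA when probabilities
#'   were not supplied).
#' @export
setClass("EvalReport",
  representation(confusion = "matrix", accuracy = "numeric",
                 perClassTPR = "numeric", roc = "list",
                 crossEntropy = "numeric"))

setValidity("EvalReport", function(object) {
  cm <- object@confusion
  if (!identical(dim(cm), c(3L, 3L))) return("confusion must be 3 x 3")
  if (any(cm < 0)) return("confusion counts must be >= 0")
  acc <- 100 * sum(diag(cm)) / sum(cm)
  if (abs(acc - object@accuracy) > 1e-8)
    return("accuracy must equal 100 * trace / total")
  TRUE
})

#' LemonGrader: a trained grading model
#'
#' Bundles the fitted \linkS4class{Standardizer}, the trained
#' \linkS4class{LemonNet}, the training history and the configuration, so
#' prediction can be applied to raw (unstandardized) feature rows.
#'
#' @slot net \linkS4class{LemonNet}.
#' @slot standardizer \linkS4class{Standardizer}.
#' @slot history data.frame of per-epoch train/validation/test cross-entropy.
#' @slot config \linkS4class{TrainingConfig}.
#' @export
setClass("LemonGrader",
  representation(net = "LemonNet", standardizer = "Standardizer",
                 history = "data.frame", config = "TrainingConfig"))
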