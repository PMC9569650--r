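#' @rdname ShiftTable-class
#' @param object an object with a peptide identifier.
#' @export
setGeneric("peptideId", function(object) standardGeneric("peptideId"))

#' @rdname ShiftTable-class
#' @export
setGeneric("shifts", function(object) standardGeneric("shifts"))

#' @rdname ConformerEnsemble-class
#' @param object an ensemble-like object.
#' @export
setGeneric("nModels", function(object) standardGeneric("nModels"))

#' @rdname ConformerEnsemble-class
#' @export
setGeneric("nResidues", function(object) standardGeneric("nResidues"))

#' Back-calculate chemical shifts for one conformer
#'
#' Applies a shift predictor to model \code{model} of a conformer ensemble.
#' Predictors are deterministic total functions from geometry to a
#' [ShiftTable]; the built-in [toyShiftPredictor()] applies documented
#' dihedral-basin offsets to random-coil values, while external predictors
#' can be plugged in as plain functions \code{f(ensemble, model)}.
#'
#' @param predictor a [ToyShiftPredictor] or a function
#'   \code{(ensemble, model) -> ShiftTable}.
#' @param ensemble a [ConformerEnsemble].
#' @param model model index (1-based).
#' @return a [ShiftTable] of predicted shifts.
#' @export
setGeneric("predictShifts",
  function(predictor, ensemble, model) standardGeneric("predictShifts"))
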