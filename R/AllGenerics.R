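#' @include AllClasses.R
NULL

#' @rdname LimbMeasurements-class
#' @param object,x a `LimbMeasurements` object.
#' @export
setGeneric("measurementMatrix",
           function(x) standardGeneric("measurementMatrix"))

#' @rdname LimbMeasurements-class
#' @export
setGeneric("speciesOf", function(x) standardGeneric("speciesOf"))

#' @rdname LimbMeasurements-class
#' @export
setGeneric("lifeStage", function(x) standardGeneric("lifeStage"))

#' @rdname LimbMeasurements-class
#' @export
setGeneric("sizeProxy", function(x) standardGeneric("sizeProxy"))

#' @rdname LimbMeasurements-class
#' @export
setGeneric("isLogScale", function(x) standardGeneric("isLogScale"))

#' @rdname LimbMeasurements-class
#' @export
setGeneric("missingFraction", function(x) standardGeneric("missingFraction"))

#' Natural-log transform of a measurement table
#'
#' Applies the natural logarithm to all element lengths and to the size
#' proxy. Allometric coefficients are ratios of per-element log growth
#' rates, so the base cancels after unit-norm scaling; natural logs are used
#' throughout. Transforming an already-log table is an error.
#' @param x a [LimbMeasurements] object on the linear scale.
#' @return the table on the log scale (`isLogScale(x)` is `TRUE`).
#' @export
setGeneric("logTransform", function(x) standardGeneric("logTransform"))

#' Collapse a measurement table to species means
#'
#' One column per species; every element cell (and the size proxy) becomes
#' the arithmetic mean of that species' values. Intended for imputed,
#' log-scale tables, where the mean of logs is the log geometric mean.
#' @param x a [LimbMeasurements] object, complete (no missing cells).
#' @return a [LimbMeasurements] with one specimen per species.
#' @export
setGeneric("speciesMeans", function(x) standardGeneric("speciesMeans"))

#' @rdname AllometricVector-class
#' @param object,x an `AllometricVector`.
#' @export
setGeneric("vectorCoefficients",
           function(x) standardGeneric("vectorCoefficients"))

#' @rdname AllometricVector-class
#' @export
setGeneric("varianceFraction", function(x) standardGeneric("varianceFraction"))

#' Extract an axis of a PCA result as an AllometricVector
#' @param x a [PPCAResult].
#' @param which axis index (1 = pPC1).
#' @export
setGeneric("axisVector", function(x, which = 1L) standardGeneric("axisVector"))

#' @rdname AngleTestSet-class
#' @param x an `AngleTestSet`.
#' @export
setGeneric("angleMatrix", function(x) standardGeneric("angleMatrix"))

#' @rdname AngleTestSet-class
#' @export
setGeneric("meanAngle", function(x) standardGeneric("meanAngle"))
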