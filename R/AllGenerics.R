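#' @include AllGenerics.R
NULL

#' Generics used across the package
#'
#' Accessor and analysis generics shared by the spectral containers.
#'
#' @param object,x an object of one of the package's S4 classes.
#' @param ... further arguments passed to methods.
#' @name procspec-generics
#' @keywords internal
NULL

#' @rdname procspec-generics
#' @export
setGeneric("batchId", function(object) standardGeneric("batchId"))

#' @rdname procspec-generics
#' @export
setGeneric("acqTimes", function(object) standardGeneric("acqTimes"))

#' @rdname procspec-generics
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @rdname procspec-generics
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname procspec-generics
#' @export
setGeneric("nSpectra", function(object) standardGeneric("nSpectra"))

#' @rdname procspec-generics
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname procspec-generics
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname procspec-generics
#' @export
setGeneric("lodValues", function(object) standardGeneric("lodValues"))

#' @rdname procspec-generics
#' @export
setGeneric("excluded", function(object) standardGeneric("excluded"))

#' @rdname procspec-generics
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname procspec-generics
#' @export
setGeneric("batchIds", function(object) standardGeneric("batchIds"))

#' Wavelength-wise Pearson correlation with moisture
#'
#' @param object a [PairedData], [SpectraBatch] (with `refs`) or
#'   [ProcessDataset].
#' @param ... method-specific arguments, see
#'   [correlationSpectrum,PairedData-method].
#' @export
setGeneric("correlationSpectrum",
           function(object, ...) standardGeneric("correlationSpectrum"))
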