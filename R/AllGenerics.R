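#' Channel labels of a montage or recording
#' @param x a [Montage-class] or [EEGRecording-class].
#' @return character vector of channel labels.
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' Sampling rate in Hz
#' @param x an [EEGRecording-class] or [WindowedBandSeries-class].
#' @return numeric scalar, Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Number of time samples
#' @param x an [EEGRecording-class].
#' @return integer.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Artifact mask
#' @param x an [EEGRecording-class].
#' @return logical vector, TRUE where rejected.
#' @export
setGeneric("artifactMask", function(x) standardGeneric("artifactMask"))

#' Tabular view of a result container
#' @param x a [ConnectivityFrame-class] or [EigenvalueSeries-class].
#' @return data.frame.
#' @export
setGeneric("connTable", function(x) standardGeneric("connTable"))

#' Chosen number of k-means states
#' @param x a [StateLabels-class].
#' @return integer.
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' Per-window emotional flag
#' @param x a [StateLabels-class].
#' @return logical vector.
#' @export
setGeneric("emotionalFlag", function(x) standardGeneric("emotionalFlag"))
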