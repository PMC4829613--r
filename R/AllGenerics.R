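#' @rdname EpochedTrialSet-accessors
#' @export
setGeneric("preSignals", function(x) standardGeneric("preSignals"))

#' @rdname EpochedTrialSet-accessors
#' @export
setGeneric("postSignals", function(x) standardGeneric("postSignals"))

#' @rdname EpochedTrialSet-accessors
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))

#' @rdname EpochedTrialSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EpochedTrialSet-accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' Accessors for EpochedTrialSet objects
#'
#' \code{preSignals}/\code{postSignals} return the spontaneous and evoked
#' segment matrices (time samples in rows, trials in columns);
#' \code{trialData} returns the per-trial metadata as a data.frame;
#' \code{samplingRate} the sampling rate in Hz; \code{profiles} the
#' ground-truth individual profiles of a simulated cohort (NULL for recorded
#' data).
#'
#' @param x an [EpochedTrialSet-class].
#' @return See the per-accessor description.
#' @name EpochedTrialSet-accessors
#' @aliases preSignals postSignals trialData samplingRate profiles
NULL

#' @rdname EpochedTrialSet-accessors
setMethod("preSignals", "EpochedTrialSet", function(x) assay(x, "pre"))

#' @rdname EpochedTrialSet-accessors
setMethod("postSignals", "EpochedTrialSet", function(x) assay(x, "post"))

#' @rdname EpochedTrialSet-accessors
setMethod("trialData", "EpochedTrialSet",
          function(x) as.data.frame(colData(x)))

#' @rdname EpochedTrialSet-accessors
setMethod("samplingRate", "EpochedTrialSet",
          function(x) metadata(x)$sampling_rate)

#' @rdname EpochedTrialSet-accessors
setMethod("profiles", "EpochedTrialSet",
          function(x) metadata(x)$profiles)
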