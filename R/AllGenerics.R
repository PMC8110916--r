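#' Accessors for transcript and audio objects
#'
#' `utterances()` returns the list of utterance records; `docTokens()` the
#' per-utterance token lists; `subjectId()` the participant identifier;
#' `samples()` and `sampleRate()` the waveform and rate; `clipDuration()`
#' the clip length in seconds.
#'
#' @param x a [TranscriptDoc-class] or [AudioClip-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("utterances", function(x) standardGeneric("utterances"))
#' @rdname accessors
#' @export
setGeneric("docTokens", function(x) standardGeneric("docTokens"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("docMeta", function(x) standardGeneric("docMeta"))
#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("clipDuration", function(x) standardGeneric("clipDuration"))

#' @rdname accessors
#' @export
setMethod("utterances", "TranscriptDoc", function(x) x@utterances)
#' @rdname accessors
#' @export
setMethod("docTokens", "TranscriptDoc",
          function(x) lapply(x@utterances, `[[`, "tokens"))
#' @rdname accessors
#' @export
setMethod("subjectId", "TranscriptDoc", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("docMeta", "TranscriptDoc", function(x) x@meta)
#' @rdname accessors
#' @export
setMethod("samples", "AudioClip", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("sampleRate", "AudioClip", function(x) x@rate)
#' @rdname accessors
#' @export
setMethod("clipDuration", "AudioClip", function(x) length(x@samples) / x@rate)

#' Extract the full feature battery
#'
#' @param x object to extract features from (a [SpeechCohort-class], or a
#'   single [TranscriptDoc-class] with its clip).
#' @param ... passed to methods.
#' @return a [FeatureSet-class] (for cohorts) or a named numeric vector of
#'   length 509 (for a single subject).
#' @export
setGeneric("extractFeatures", function(x, ...) standardGeneric("extractFeatures"))
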