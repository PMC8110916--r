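#' @import methods
NULL

#' Participant transcript of one picture description
#'
#' A `TranscriptDoc` holds the participant-tier utterances of a single
#' CHAT-transcribed picture description, after normalization: annotation
#' codes stripped, filled pauses ("um"/"uh") and unfilled pause marks
#' counted per utterance, investigator tiers dropped.
#'
#' Each element of `utterances` is a list with components `speaker`
#' (tier code, e.g. "PAR"), `tokens` (normalized word strings), `fillers`
#' (count of filled-pause tokens), `filler_tokens` (the fillers themselves,
#' e.g. "um"), `pauses` (count of unfilled pause marks), `pause_lengths`
#' (nominal length class 1--3 per mark) and `raw` (the original tier line).
#'
#' @slot subjectId single participant identifier.
#' @slot utterances list of utterance records (participant tier only).
#' @slot meta named list; recognised entries: `age`, `sex` ("M"/"F"),
#'   `label` ("AD"/"non-AD"), `mmse` (integer in \[0, 30\]).
#'
#' @export
setClass("TranscriptDoc",
  representation(subjectId = "character", utterances = "list", meta = "list"))

setValidity("TranscriptDoc", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  for (u in object@utterances) {
    if (!all(c("speaker", "tokens", "fillers", "pauses") %in% names(u)))
      msg <- c(msg, "utterance missing required fields")
    else if (u$fillers < 0 || u$pauses < 0)
      msg <- c(msg, "filler/pause counts must be non-negative")
  }
  mm <- object@meta$mmse
  if (!is.null(mm) && !is.na(mm) && (mm < 0 || mm > 30))
    msg <- c(msg, "mmse must lie in [0, 30]")
  if (length(msg)) msg else TRUE
})

#' Mono audio clip
#'
#' Dimensionless amplitudes in \[-1, 1\] at a fixed sampling rate; one clip
#' per participant holds the combined speech of the picture description.
#'
#' @slot samples numeric vector of amplitudes.
#' @slot rate sampling rate in Hz.
#' @export
setClass("AudioClip", representation(samples = "numeric", rate = "numeric"))

setValidity("AudioClip", function(object) {
  if (length(object@rate) != 1L || object@rate <= 0)
    return("rate must be a single positive number")
  if (length(object@samples) < 1L) return("clip must contain samples")
  TRUE
})

#' Model specification
#'
#' Family, hyperparameters, number of selected features and seed for one
#' classifier or regressor configuration. Families: `svm_rbf`, `nn`, `rf`,
#' `nb` (classification); `linreg`, `ridge` (MMSE regression).
#'
#' @slot family one of "svm_rbf", "nn", "rf", "nb", "linreg", "ridge".
#' @slot hyper named list of family hyperparameters.
#' @slot k number of features retained by univariate selection.
#' @slot seed integer seed used by stochastic families (rf, nn).
#' @export
setClass("ModelSpec",
  representation(family = "character", hyper = "list",
                 k = "numeric", seed = "numeric"))

setValidity("ModelSpec", function(object) {
  fams <- c("svm_rbf", "nn", "rf", "nb", "linreg", "ridge")
  if (!object@family %in% fams)
    return(paste("family must be one of:", paste(fams, collapse = ", ")))
  if (object@k < 1) return("k must be >= 1")
  TRUE
})

#' Fitted selection + prediction pipeline
#'
#' @slot spec the [ModelSpec-class] the model was fit under.
#' @slot selection list with `indices` (selected feature columns) and
#'   `scores` (per-feature selection statistic on the training data).
#' @slot scaler list with `center`/`scale` (training z-score statistics)
#'   or `NULL` for families taking raw features.
#' @slot fit the underlying fitted predictor object.
#' @slot task "classification" or "regression".
#' @slot featureNames column names of the training matrix.
#' @export
setClass("FittedModel",
  representation(spec = "ModelSpec", selection = "list", scaler = "ANY",
                 fit = "ANY", task = "character", featureNames = "character"))

#' Raw synthetic or loaded cohort: transcripts, audio, metadata
#'
#' @slot docs list of [TranscriptDoc-class], one per subject.
#' @slot clips list of [AudioClip-class], parallel to `docs`.
#' @slot meta data.frame with columns subject_id, age, sex, label, mmse.
#' @export
setClass("SpeechCohort",
  representation(docs = "list", clips = "list", meta = "data.frame"))

setValidity("SpeechCohort", function(object) {
  n <- nrow(object@meta)
  if (length(object@docs) != n || length(object@clips) != n)
    return("docs, clips and meta must describe the same subjects")
  need <- c("subject_id", "age", "sex", "label", "mmse")
  if (!all(need %in% names(object@meta)))
    return(paste("meta must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' Feature matrix container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' 509-feature battery: one assay `features` (features x subjects), rowData
#' columns `family` and `category` from the feature registry, and colData
#' with subject label, MMSE and demographics.
#'
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("FeatureSet", contains = "SummarizedExperiment")

setMethod("show", "TranscriptDoc", function(object) {
  nt <- sum(vapply(object@utterances, function(u) length(u$tokens), 1L))
  cat("TranscriptDoc", object@subjectId, "-", length(object@utterances),
      "utterances,", nt, "tokens\n")
  if (!is.null(object@meta$label)) cat("  label:", object@meta$label, "\n")
})

setMethod("show", "AudioClip", function(object) {
  cat(sprintf("AudioClip: %.2f s at %d Hz\n",
              length(object@samples) / object@rate, as.integer(object@rate)))
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@family, " k =", object@k, " seed =", object@seed, "\n")
})

setMethod("show", "SpeechCohort", function(object) {
  cat("SpeechCohort:", nrow(object@meta), "subjects (",
      sum(object@meta$label == "AD"), "AD /",
      sum(object@meta$label != "AD"), "non-AD )\n")
})
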