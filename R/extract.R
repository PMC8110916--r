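# Assembly of the full 509-feature battery and the FeatureSet container.

#' Bundle of shared extraction resources
#'
#' Loads the norm lexicon, reference wordlist, content-unit inventory and
#' the two embedding providers once, for reuse across a cohort.
#'
#' @param norms,wordlist,content_units,emb,emb2 overrides for individual
#'   resources.
#' @return list of resources consumed by [extractFeatures()].
#' @export
extractorResources <- function(norms = readNormLexicon(),
                               wordlist = readWordlist(),
                               content_units = readContentUnits(),
                               emb = hashEmbeddingProvider(),
                               emb2 = hashEmbeddingProvider(
                                 salt = "secondary")) {
  list(norms = norms, wordlist = wordlist, content_units = content_units,
       emb = emb, emb2 = emb2)
}

#' @describeIn extractFeatures full battery for one subject: a named
#'   509-vector in registry order. Undefined features are zero-imputed;
#'   the logical attribute `defined` records which features were genuinely
#'   computed.
#' @param clip the subject's [AudioClip-class] (NULL to skip audio-derived
#'   features).
#' @param resources an [extractorResources()] bundle.
#' @param spec a [frameSpec()] for acoustic analysis.
#' @export
setMethod("extractFeatures", "TranscriptDoc",
  function(x, clip = NULL, resources = extractorResources(),
           spec = frameSpec()) {
    reg <- featureRegistry()
    tagged <- tagTranscript(x)
    trees <- parseTranscript(tagged)
    toks <- docTokens(x)

    if (!is.null(clip)) {
      seg <- silenceSegmentation(clip, spec)
      speechDur <- sum((seg$end - seg$start)[seg$kind == "speech"])
      audioDur <- clipDuration(clip)
      aco <- acousticFeatures(clip, x, spec)
    } else {
      speechDur <- NA_real_; audioDur <- NA_real_
      aco <- stats::setNames(rep(NA_real_, sum(reg$category == "acoustic")),
                             reg$name[reg$category == "acoustic"])
    }

    vals <- c(
      syntacticComplexityFeatures(trees),
      productionRuleFeatures(trees),
      posFeatures(tagged),
      lexicalRichness(unlist(toks)),
      coherenceFeatures(x, resources$emb),
      speechGraphFeatures(toks),
      miscLexicalFeatures(x, tagged, resources$norms, resources$wordlist,
                          audio_dur = audioDur, speech_dur = speechDur),
      aco,
      contentUnitRatios(x, resources$content_units),
      globalCoherenceDistances(x, resources$content_units,
                               resources$emb, resources$emb2))

    stopifnot(setequal(names(vals), reg$name))
    vals <- vals[reg$name]
    defined <- !is.na(vals)
    vals[!defined] <- 0
    attr(vals, "defined") <- defined
    vals
  })

#' @describeIn extractFeatures extract the battery for every subject of a
#'   cohort, returning a [FeatureSet-class].
#' @export
setMethod("extractFeatures", "SpeechCohort",
  function(x, resources = extractorResources(), spec = frameSpec()) {
    n <- nrow(x@meta)
    reg <- featureRegistry()
    mat <- matrix(0, nrow(reg), n,
                  dimnames = list(reg$name, x@meta$subject_id))
    def <- matrix(FALSE, nrow(reg), n, dimnames = dimnames(mat))
    for (i in seq_len(n)) {
      v <- extractFeatures(x@docs[[i]], clip = x@clips[[i]],
                           resources = resources, spec = spec)
      mat[, i] <- as.numeric(v)
      def[, i] <- attr(v, "defined")
    }
    FeatureSet(mat, meta = x@meta, defined = def)
  })

#' Construct a FeatureSet
#'
#' Wraps a features x subjects matrix (rows must match the registry) and
#' per-subject metadata into the [FeatureSet-class] container.
#'
#' @param features numeric matrix, 509 x n, rownames = registry names.
#' @param meta data.frame with subject_id, age, sex, label, mmse.
#' @param defined optional logical matrix marking genuinely computed
#'   entries (FALSE = zero-imputed).
#' @return a [FeatureSet-class].
#' @export
FeatureSet <- function(features, meta, defined = NULL) {
  reg <- featureRegistry()
  if (!identical(rownames(features), reg$name))
    stop("feature rows must match the registry names in order")
  assays <- list(features = features)
  if (!is.null(defined)) assays$defined <- defined
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(family = reg$family,
                                   category = reg$category,
                                   row.names = reg$name),
    colData = S4Vectors::DataFrame(meta, row.names = meta$subject_id))
  new("FeatureSet", se)
}

#' Feature matrix of a FeatureSet (subjects x features)
#'
#' @param fs a [FeatureSet-class].
#' @return numeric matrix, subjects in rows.
#' @export
featureMatrix <- function(fs) {
  t(SummarizedExperiment::assay(fs, "features"))
}

#' Class labels of a FeatureSet
#' @param fs a [FeatureSet-class].
#' @return factor with levels c("non-AD", "AD").
#' @export
featureLabels <- function(fs) {
  factor(SummarizedExperiment::colData(fs)$label, levels = c("non-AD", "AD"))
}

#' MMSE scores of a FeatureSet
#' @param fs a [FeatureSet-class].
#' @return numeric vector.
#' @export
featureMMSE <- function(fs) {
  as.numeric(SummarizedExperiment::colData(fs)$mmse)
}

#' Write a FeatureSet to CSV
#'
#' Subjects in rows: `subject_id,age,sex,label,mmse` followed by the 509
#' feature columns.
#'
#' @param fs a [FeatureSet-class].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(fs, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(fs))
  out <- cbind(cd[, c("subject_id", "age", "sex", "label", "mmse")],
               featureMatrix(fs))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a FeatureSet from CSV written by [writeFeatureCSV()]
#' @param path CSV path.
#' @return a [FeatureSet-class].
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  metaCols <- c("subject_id", "age", "sex", "label", "mmse")
  mat <- t(as.matrix(df[, setdiff(names(df), metaCols)]))
  colnames(mat) <- df$subject_id
  FeatureSet(mat, df[, metaCols])
}
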