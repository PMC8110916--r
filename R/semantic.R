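# The 25 picture-content semantic features, scored against a Cookie Theft
# content-unit lexicon.

#' Load a content-unit lexicon
#'
#' CSV with columns `unit,category,synonyms,anchors`; `synonyms` and
#' `anchors` are |-separated word lists. The packaged default is the
#' standard Cookie Theft inventory (boy, girl, woman, kitchen, window,
#' curtains, cupboard, exterior view, sink, water, dishes, plate,
#' dishcloth, cookie, jar, stool, overflowing, falling, taking, washing,
#' asking, unconcerned) grouped into subject/place/object/action.
#'
#' @param path CSV path; default the packaged inventory.
#' @return data.frame with list-columns `synonyms` and `anchors`.
#' @export
readContentUnits <- function(path = system.file("extdata",
                                                "content_units.csv",
                                                package = "speechAD")) {
  cu <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit", "category", "synonyms", "anchors")
  if (!all(need %in% names(cu)))
    stop("content-unit lexicon must have columns: ",
         paste(need, collapse = ", "))
  if (anyDuplicated(cu$unit)) stop("content-unit names must be unique")
  cu$synonyms <- strsplit(tolower(cu$synonyms), "|", fixed = TRUE)
  cu$anchors <- strsplit(tolower(cu$anchors), "|", fixed = TRUE)
  if (any(lengths(cu$synonyms) < 1))
    stop("every content unit needs at least one synonym")
  cu
}

# which units are mentioned by the document's lemmas (or raw tokens)
.mentionedUnits <- function(lemmas, lex) {
  vapply(lex$synonyms, function(syn) any(syn %in% lemmas), TRUE)
}

#' Content-unit mention ratios and content-lemma frequencies
#'
#' A unit counts as mentioned when any of its synonyms appears among the
#' document's lemmatized tokens. Emits distinct-mentioned:total ratios
#' overall and for the object and action categories, plus the frequency
#' proportion (occurrences / total tokens) of each designated content
#' lemma: 10 features.
#'
#' @param doc a [TranscriptDoc-class] (lemmatized via the packaged tagger)
#'   or a character vector of lemmas.
#' @param lex content-unit lexicon from [readContentUnits()].
#' @return named numeric vector of length 10; ratios are 0 for an empty
#'   transcript.
#' @export
contentUnitRatios <- function(doc, lex = readContentUnits()) {
  lemmas <- if (is(doc, "TranscriptDoc")) {
    unlist(lapply(tagTranscript(doc), `[[`, "lemma"))
  } else tolower(doc)
  nm <- c("cu_ratio_distinct", "cu_ratio_objects", "cu_ratio_actions",
          paste0("wordfreq_", .WORDFREQ_LEMMAS))
  out <- stats::setNames(numeric(length(nm)), nm)
  hit <- .mentionedUnits(lemmas, lex)
  out["cu_ratio_distinct"] <- mean(hit)
  for (cat in c("objects", "actions")) {
    sel <- lex$category == sub("s$", "", cat)
    out[paste0("cu_ratio_", cat)] <-
      if (any(sel)) mean(hit[sel]) else 0
  }
  n <- length(lemmas)
  if (n > 0)
    out[paste0("wordfreq_", .WORDFREQ_LEMMAS)] <-
      vapply(.WORDFREQ_LEMMAS, function(l) sum(lemmas == l) / n, 1)
  out
}

# anchor embedding per category and overall: mean of anchor word vectors
.anchorEmbeddings <- function(lex, emb) {
  unitVecs <- lapply(lex$anchors, function(ws)
    rowMeans(vapply(ws, emb$embed, numeric(emb$dim))))
  cats <- c("subject", "place", "object", "action")
  out <- list(overall = Reduce(`+`, unitVecs) / length(unitVecs))
  for (cat in cats) {
    sel <- which(lex$category == cat)
    out[[cat]] <- if (length(sel))
      Reduce(`+`, unitVecs[sel]) / length(sel) else NULL
  }
  out
}

#' Global coherence distances to content units
#'
#' Each utterance's mean-token embedding is compared by cosine distance to
#' anchor embeddings of the content-unit inventory, under two embedding
#' inventories (primary and secondary). Per inventory: mean/min/max
#' distance to the overall anchor and mean distance to each category
#' anchor (subject/place/object/action); plus the standard deviation of
#' the primary overall distances: 15 features.
#'
#' @param doc a [TranscriptDoc-class] or list of token vectors.
#' @param lex content-unit lexicon.
#' @param emb primary embedding provider.
#' @param emb2 secondary embedding provider.
#' @return named numeric vector of length 15; all NA when no utterance is
#'   embeddable.
#' @export
globalCoherenceDistances <- function(doc, lex = readContentUnits(),
                                     emb = hashEmbeddingProvider(),
                                     emb2 = hashEmbeddingProvider(
                                       salt = "secondary")) {
  reg <- featureRegistry()
  nm <- reg$name[reg$family == "global_coherence"]
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  tokLists <- if (is(doc, "TranscriptDoc")) docTokens(doc) else doc

  for (inv in c("primary", "secondary")) {
    e <- if (inv == "primary") emb else emb2
    embs <- Filter(Negate(is.null),
                   lapply(tokLists, .utteranceEmbedding, emb = e))
    if (!length(embs)) next
    anchors <- .anchorEmbeddings(lex, e)
    dOverall <- vapply(embs, function(v)
      1 - .cosineSim(v, anchors$overall), 1)
    out[paste0("gcoh_", inv, "_mean")] <- mean(dOverall)
    out[paste0("gcoh_", inv, "_min")] <- min(dOverall)
    out[paste0("gcoh_", inv, "_max")] <- max(dOverall)
    for (cat in c("subject", "place", "object", "action")) {
      if (is.null(anchors[[cat]])) next
      dc <- vapply(embs, function(v) 1 - .cosineSim(v, anchors[[cat]]), 1)
      out[paste0("gcoh_", inv, "_", cat)] <- mean(dc)
    }
    if (inv == "primary")
      out["gcoh_primary_sd"] <-
        if (length(dOverall) > 1) stats::sd(dOverall) else 0
  }
  out
}
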