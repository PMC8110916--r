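# Lexicon-based POS tagging, lemmatization and a deterministic chunk
# parser producing flat constituency trees. Both are pluggable: any tagger
# returning per-utterance (token, tag, utag, lemma) tables and any list of
# bracketed trees can be supplied to the feature functions instead.

.lexiconEntry <- function(words, tag, lemmas = NULL) {
  data.frame(word = words, tag = tag,
             lemma = if (is.null(lemmas)) words else lemmas,
             stringsAsFactors = FALSE)
}

.taggerLexicon <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lx <- rbind(
      .lexiconEntry(c("the", "a", "an", "this", "that", "these", "those",
                      "some", "any", "no", "another", "each", "every"), "DT"),
      .lexiconEntry(c("all", "both"), "PDT"),
      .lexiconEntry(c("he", "she", "it", "they", "them", "him", "i", "you",
                      "we"), "PRP"),
      .lexiconEntry(c("his", "her", "its", "their", "my", "your"), "PRP$"),
      .lexiconEntry("there", "EX"),
      .lexiconEntry(c("boy", "girl", "woman", "mother", "mom", "lady",
                      "child", "kid", "brother", "sister", "son", "daughter",
                      "kitchen", "window", "curtain", "cupboard", "cabinet",
                      "closet", "counter", "sink", "water", "dish", "plate",
                      "cloth", "dishcloth", "towel", "cookie", "biscuit",
                      "jar", "lid", "stool", "chair", "floor", "garden",
                      "yard", "path", "house", "faucet", "tap", "hand",
                      "foot", "head", "dress", "apron", "cup", "summer",
                      "day", "picture", "thing", "overflow", "action",
                      "scene", "stuff", "shelf", "seat", "leg", "wind",
                      "lot", "everything", "top"),
                    "NN"),
      .lexiconEntry(c("cookies", "dishes", "plates", "curtains", "cups",
                      "things", "hands", "jars", "stools", "windows",
                      "biscuits", "towels", "legs", "shelves", "kids"),
                    "NNS",
                    c("cookie", "dish", "plate", "curtain", "cup", "thing",
                      "hand", "jar", "stool", "window", "biscuit", "towel",
                      "leg", "shelf", "kid")),
      .lexiconEntry(c("children", "feet", "women"), "NNS",
                    c("child", "foot", "woman")),
      .lexiconEntry(c("is", "has", "does"), "VBZ", c("be", "have", "do")),
      .lexiconEntry(c("are", "am", "have", "do"), "VBP",
                    c("be", "be", "have", "do")),
      .lexiconEntry(c("was", "were", "had", "did"), "VBD",
                    c("be", "be", "have", "do")),
      .lexiconEntry(c("will", "can", "could", "would", "may", "might"), "MD"),
      .lexiconEntry(c("taking", "stealing", "reaching", "falling", "tipping",
                      "wobbling", "slipping", "overflowing", "running",
                      "spilling", "washing", "drying", "wiping", "standing",
                      "asking", "wanting", "laughing", "ignoring",
                      "noticing", "looking", "getting", "climbing",
                      "handing", "going", "doing", "daydreaming", "dreaming",
                      "trying", "holding", "dripping", "grabbing"), "VBG",
                    c("take", "steal", "reach", "fall", "tip", "wobble",
                      "slip", "overflow", "run", "spill", "wash", "dry",
                      "wipe", "stand", "ask", "want", "laugh", "ignore",
                      "notice", "look", "get", "climb", "hand", "go", "do",
                      "daydream", "dream", "try", "hold", "drip", "grab")),
      .lexiconEntry(c("takes", "steals", "reaches", "falls", "tips",
                      "overflows", "runs", "spills", "washes", "dries",
                      "wipes", "stands", "asks", "wants", "laughs",
                      "ignores", "notices", "looks", "gets", "climbs",
                      "goes", "sees", "seems", "drips"), "VBZ",
                    c("take", "steal", "reach", "fall", "tip", "overflow",
                      "run", "spill", "wash", "dry", "wipe", "stand", "ask",
                      "want", "laugh", "ignore", "notice", "look", "get",
                      "climb", "go", "see", "seem", "drip")),
      .lexiconEntry(c("fell", "took", "spilled", "asked", "washed",
                      "slipped", "reached", "wanted", "overflowed", "stood",
                      "forgot", "noticed", "dropped"), "VBD",
                    c("fall", "take", "spill", "ask", "wash", "slip",
                      "reach", "want", "overflow", "stand", "forget",
                      "notice", "drop")),
      .lexiconEntry(c("be", "fall", "take", "get", "wash", "spill", "reach",
                      "notice", "see", "grab", "climb"), "VB"),
      .lexiconEntry(c("fallen", "taken", "gone", "done", "finished"), "VBN",
                    c("fall", "take", "go", "do", "finish")),
      .lexiconEntry(c("little", "young", "small", "big", "full", "empty",
                      "wet", "dirty", "clean", "tall", "high", "open",
                      "busy", "careless", "unconcerned", "indifferent",
                      "oblivious", "distracted", "unaware", "wooden",
                      "soapy", "beautiful", "sunny", "nice", "warm",
                      "three-legged"), "JJ"),
      .lexiconEntry(c("really", "just", "very", "quietly", "quickly",
                      "carefully", "almost", "already", "still", "now",
                      "then", "away", "outside", "too", "also", "maybe",
                      "probably", "precariously", "dangerously",
                      "completely", "totally", "meanwhile"), "RB"),
      .lexiconEntry(c("over", "down", "up", "off"), "RP"),
      .lexiconEntry(c("in", "on", "of", "from", "behind", "near", "beside",
                      "at", "with", "into", "onto", "under", "by",
                      "through", "about", "while", "because", "as", "out"),
                    "IN"),
      .lexiconEntry("to", "TO"),
      .lexiconEntry(c("and", "but", "or", "so"), "CC"),
      .lexiconEntry(c("oh", "well", "yeah", "hm", "okay", "um", "uh"), "UH"),
      .lexiconEntry(c("who", "what"), "WP"),
      .lexiconEntry("which", "WDT"),
      .lexiconEntry(c("one", "two", "three"), "CD"))
    stopifnot(!anyDuplicated(lx$word))
    cache <<- lx
    cache
  }
})

.tagWord <- function(word) {
  lx <- .taggerLexicon()
  i <- match(word, lx$word)
  if (!is.na(i)) return(c(tag = lx$tag[i], lemma = lx$lemma[i]))
  # suffix fallback for out-of-lexicon words
  if (grepl("ing$", word) && nchar(word) > 4)
    return(c(tag = "VBG", lemma = sub("ing$", "", word)))
  if (grepl("ed$", word) && nchar(word) > 3)
    return(c(tag = "VBD", lemma = sub("ed$", "", word)))
  if (grepl("ly$", word) && nchar(word) > 3)
    return(c(tag = "RB", lemma = word))
  if (grepl("s$", word) && !grepl("ss$", word) && nchar(word) > 3)
    return(c(tag = "NNS", lemma = sub("s$", "", word)))
  c(tag = "NN", lemma = word)
}

#' Tag a transcript with POS tags and lemmas
#'
#' Lexicon-driven tagging over the picture-description vocabulary with
#' suffix fallbacks for unseen words. Returns one data.frame per utterance
#' with columns `token`, `tag` (Penn Treebank), `utag` (universal) and
#' `lemma`. Auxiliary uses of "be"/"have"/"do"/modals map to universal AUX.
#'
#' @param doc a [TranscriptDoc-class], or a list of token vectors.
#' @return list of data.frames (class `PosTaggedDoc`).
#' @export
tagTranscript <- function(doc) {
  tokLists <- if (is(doc, "TranscriptDoc")) docTokens(doc) else doc
  out <- lapply(tokLists, function(tokens) {
    tokens <- tolower(tokens)
    if (!length(tokens))
      return(data.frame(token = character(0), tag = character(0),
                        utag = character(0), lemma = character(0)))
    tl <- t(vapply(tokens, .tagWord, c(tag = "", lemma = "")))
    tags <- unname(tl[, "tag"]); lemmas <- unname(tl[, "lemma"])
    utag <- unname(.PTB_TO_UD[tags])
    utag[is.na(utag)] <- "X"
    # be/have/do followed by a participle act as auxiliaries
    aux <- lemmas %in% c("be", "have", "do") &
      c(tags[-1] %in% c("VBG", "VBN"), FALSE)
    utag[aux | tags == "MD"] <- "AUX"
    data.frame(token = tokens, tag = tags, utag = utag, lemma = lemmas,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  class(out) <- c("PosTaggedDoc", "list")
  out
}

# ---- chunk parser -----------------------------------------------------

.leaf <- function(tag, token) list(label = tag, token = token, leaf = TRUE)
.node <- function(label, children) list(label = label, children = children,
                                        leaf = FALSE)

# Chunk one tagged utterance into a flat tree rooted at S.
.parseUtterance <- function(tt) {
  n <- nrow(tt)
  if (n == 0) return(.node("S", list()))
  tags <- tt$tag
  leaves <- lapply(seq_len(n), function(i) .leaf(tags[i], tt$token[i]))

  chunks <- list()
  i <- 1
  pushNP <- function(js) chunks[[length(chunks) + 1L]] <<-
    .node("NP", leaves[js])
  while (i <= n) {
    tg <- tags[i]
    if (tg %in% c("PRP", "EX", "WP", "WDT")) { pushNP(i); i <- i + 1; next }
    if (tg %in% c("PDT", "DT", "PRP$", "JJ", "CD") ||
        (tg %in% .NOUN_TAGS)) {
      # try det/adj/number run ending in nouns
      j <- i
      if (tags[j] == "PDT") j <- j + 1
      if (j <= n && tags[j] %in% c("DT", "PRP$")) j <- j + 1
      while (j <= n && (tags[j] %in% c("JJ", "CD") ||
             (tags[j] == "VBG" && j < n && tags[j + 1] %in%
                c(.NOUN_TAGS, "JJ") && j > i))) j <- j + 1
      k <- j
      while (k <= n && tags[k] %in% .NOUN_TAGS) k <- k + 1
      if (k > j) { pushNP(i:(k - 1)); i <- k; next }
      if (tg == "JJ") {  # predicative adjective run -> ADJP
        k <- i
        while (k <= n && tags[k] == "JJ") k <- k + 1
        chunks[[length(chunks) + 1L]] <- .node("ADJP", leaves[i:(k - 1)])
        i <- k; next
      }
      if (tg %in% c("DT")) { pushNP(i); i <- i + 1; next }
      chunks[[length(chunks) + 1L]] <- leaves[[i]]; i <- i + 1; next
    }
    if (tg %in% c("RB", "RBR", "RBS")) {
      if (i < n && tags[i + 1] == "JJ") {
        chunks[[length(chunks) + 1L]] <- .node("ADJP", leaves[i:(i + 1)])
        i <- i + 2; next
      }
      k <- i
      while (k <= n && tags[k] %in% c("RB", "RBR", "RBS")) k <- k + 1
      chunks[[length(chunks) + 1L]] <- .node("ADVP", leaves[i:(k - 1)])
      i <- k; next
    }
    if (tg == "RP") {
      chunks[[length(chunks) + 1L]] <- .node("PRT", leaves[i]); i <- i + 1
      next
    }
    if (tg == "UH") {
      chunks[[length(chunks) + 1L]] <- .node("INTJ", leaves[i]); i <- i + 1
      next
    }
    chunks[[length(chunks) + 1L]] <- leaves[[i]]
    i <- i + 1
  }

  # attach prepositions to a following NP chunk -> PP
  merged <- list()
  i <- 1
  while (i <= length(chunks)) {
    ch <- chunks[[i]]
    if (isTRUE(ch$leaf) && ch$label %in% c("IN", "TO") &&
        i < length(chunks) && !isTRUE(chunks[[i + 1]]$leaf) &&
        chunks[[i + 1]]$label == "NP") {
      merged[[length(merged) + 1L]] <- .node("PP", list(ch, chunks[[i + 1]]))
      i <- i + 2
    } else {
      merged[[length(merged) + 1L]] <- ch
      i <- i + 1
    }
  }
  chunks <- merged

  # verb clusters absorb following complements -> VP
  isVerbLeaf <- function(ch) isTRUE(ch$leaf) && ch$label %in% .VERB_TAGS
  top <- list()
  i <- 1
  while (i <= length(chunks)) {
    if (isVerbLeaf(chunks[[i]])) {
      kids <- list()
      while (i <= length(chunks) && isVerbLeaf(chunks[[i]])) {
        kids[[length(kids) + 1L]] <- chunks[[i]]; i <- i + 1
      }
      while (i <= length(chunks) && !isTRUE(chunks[[i]]$leaf) &&
             chunks[[i]]$label %in% c("NP", "PP", "ADVP", "ADJP", "PRT")) {
        # stop if this NP is the subject of a following verb
        if (chunks[[i]]$label == "NP" && i < length(chunks) &&
            isVerbLeaf(chunks[[i + 1]])) break
        kids[[length(kids) + 1L]] <- chunks[[i]]; i <- i + 1
      }
      top[[length(top) + 1L]] <- .node("VP", kids)
    } else {
      top[[length(top) + 1L]] <- chunks[[i]]
      i <- i + 1
    }
  }
  .node("S", top)
}

#' Parse a tagged transcript into constituency trees
#'
#' Deterministic chunk parsing: noun/prepositional/adverb/adjective phrases
#' are grouped from the tag sequence, verb clusters absorb their
#' complements into VPs, and each utterance is rooted at S. The resulting
#' trees drive the production-rule, phrasal and syntactic-complexity
#' feature families; gold trees from fixtures can be substituted anywhere
#' a tree list is accepted.
#'
#' @param tagged a `PosTaggedDoc` from [tagTranscript()], or a
#'   [TranscriptDoc-class] (tagged on the fly).
#' @return list of trees (nested `list(label, children)`; leaves carry
#'   `token`).
#' @export
parseTranscript <- function(tagged) {
  if (is(tagged, "TranscriptDoc")) tagged <- tagTranscript(tagged)
  lapply(tagged, .parseUtterance)
}

# bracketed string form, useful for fixtures and debugging
.treeToString <- function(tree) {
  if (isTRUE(tree$leaf)) return(paste0("(", tree$label, " ", tree$token, ")"))
  inner <- vapply(tree$children, .treeToString, "")
  paste0("(", tree$label, if (length(inner)) " " else "",
         paste(inner, collapse = " "), ")")
}

#' Parse a bracketed tree string
#'
#' Reads `(S (NP (DT the) (NN boy)) (VP (VBZ falls)))` notation into the
#' tree structure used by the feature functions; used by tests to supply
#' gold trees.
#'
#' @param s bracketed tree string.
#' @return a tree.
#' @export
readBracketedTree <- function(s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1]]
  pos <- 1L
  parse1 <- function() {
    stopifnot(toks[pos] == "(")
    pos <<- pos + 1L
    label <- toks[pos]; pos <<- pos + 1L
    if (toks[pos] != "(" && toks[pos] != ")") {
      tok <- toks[pos]; pos <<- pos + 1L
      stopifnot(toks[pos] == ")"); pos <<- pos + 1L
      return(.leaf(label, tok))
    }
    kids <- list()
    while (toks[pos] == "(") kids[[length(kids) + 1L]] <- parse1()
    stopifnot(toks[pos] == ")"); pos <<- pos + 1L
    .node(label, kids)
  }
  parse1()
}
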