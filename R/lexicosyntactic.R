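# The 297 lexico-syntactic features. Each family function returns a named
# numeric vector using the registry's names; values that are undefined for
# an input are returned as NA and zero-imputed (with a "defined" flag) at
# assembly time in extractFeatures().

.NOUN_TAGS <- c("NN", "NNS", "NNP", "NNPS")
.VERB_TAGS <- c("MD", "VB", "VBD", "VBG", "VBN", "VBP", "VBZ")
.FUNCTION_TAGS <- c("DT", "PDT", "IN", "TO", "CC", "MD", "PRP", "PRP$",
                    "EX", "WDT", "WP", "WP$", "POS")
.LIGHT_VERB_LEMMAS <- c("be", "have", "do", "get", "take", "give", "make",
                        "go", "come")
.DEMONSTRATIVES <- c("this", "that", "these", "those")
.INFLECTED_TAGS <- c("VBD", "VBG", "VBN", "VBZ")
.PROPOSITION_TAGS <- c(.VERB_TAGS, "JJ", "JJR", "JJS", "RB", "RBR", "RBS",
                       "IN", "TO", "CC")

#' POS-tag based features
#'
#' 53 Penn Treebank tag proportions, 18 universal tag proportions, 5 word
#' category proportions (demonstratives, function words, light verbs,
#' inflected verbs, propositional words), 3 guarded noun/pronoun ratios
#' and the average word length in letters: 80 features.
#'
#' @param tagged a `PosTaggedDoc` from [tagTranscript()].
#' @return named numeric vector of length 80; all NA when the document has
#'   no tokens.
#' @export
posFeatures <- function(tagged) {
  tt <- do.call(rbind, tagged)
  reg <- featureRegistry()
  nm <- reg$name[reg$family %in% c("word_category", "noun_ratio", "length",
                                   "universal_pos", "pos_tags")]
  # registry order within this op: wordcat, ratios, length, upos, pos
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (is.null(tt) || nrow(tt) == 0) return(out)
  n <- nrow(tt)

  posCounts <- table(factor(tt$tag, levels = .PTB_TAGS))
  out[paste0("pos_", .sanitizeTag(.PTB_TAGS))] <- as.numeric(posCounts) / n
  uposCounts <- table(factor(tt$utag, levels = .UD_TAGS))
  out[paste0("upos_", .UD_TAGS)] <- as.numeric(uposCounts) / n

  isVerb <- tt$tag %in% .VERB_TAGS
  out["wordcat_demonstratives"] <- sum(tt$lemma %in% .DEMONSTRATIVES) / n
  out["wordcat_function_words"] <- sum(tt$tag %in% .FUNCTION_TAGS) / n
  out["wordcat_light_verbs"] <-
    sum(isVerb & tt$lemma %in% .LIGHT_VERB_LEMMAS) / n
  out["wordcat_inflected_verbs"] <- sum(tt$tag %in% .INFLECTED_TAGS) / n
  out["wordcat_propositions"] <- sum(tt$tag %in% .PROPOSITION_TAGS) / n

  nouns <- sum(tt$tag %in% .NOUN_TAGS)
  verbs <- sum(isVerb & tt$tag != "MD")
  prons <- sum(tt$tag %in% c("PRP", "PRP$"))
  out["ratio_noun_to_noun_verb"] <- .safeRatio(nouns, nouns + verbs)
  out["ratio_noun_to_verb"] <- .safeRatio(nouns, verbs)
  out["ratio_pronoun_to_noun_pronoun"] <- .safeRatio(prons, nouns + prons)

  out["avg_word_length"] <- mean(nchar(gsub("[^a-z]", "",
                                            tolower(tt$token))))
  out
}

# traverse a tree collecting productions and per-label node sizes
.collectProductions <- function(tree, acc) {
  if (isTRUE(tree$leaf)) return(acc)
  if (length(tree$children)) {
    kidLabels <- vapply(tree$children, `[[`, "", "label")
    acc$rules <- c(acc$rules,
                   paste0(tree$label, "->", paste(kidLabels, collapse = "_")))
    acc$nodeLabel <- c(acc$nodeLabel, tree$label)
    acc$nodeSize <- c(acc$nodeSize, .countLeaves(tree))
    for (ch in tree$children) acc <- .collectProductions(ch, acc)
  }
  acc
}

.countLeaves <- function(tree) {
  if (isTRUE(tree$leaf)) return(1L)
  sum(vapply(tree$children, .countLeaves, 1L))
}

.treeDepth <- function(tree) {
  if (isTRUE(tree$leaf)) return(0L)
  if (!length(tree$children)) return(0L)
  1L + max(vapply(tree$children, .treeDepth, 1L))
}

#' Production-rule and phrasal-type features
#'
#' Proportions of each production in the frozen 104-rule inventory among
#' all productions of the document's constituency trees, plus 13 phrasal
#' statistics: proportion among all productions, mean span length in
#' tokens and rate per utterance for NP/VP/PP/ADVP, and the ADJP
#' proportion. Productions outside the inventory count toward the
#' denominator only.
#'
#' @param trees list of constituency trees (see [parseTranscript()]).
#' @return named numeric vector of length 117; all NA for an empty tree
#'   list, phrase mean lengths NA when the phrase type is absent.
#' @export
productionRuleFeatures <- function(trees) {
  reg <- featureRegistry()
  nm <- reg$name[reg$family %in% c("production_rules", "phrasal_ratios")]
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  acc <- list(rules = character(0), nodeLabel = character(0),
              nodeSize = integer(0))
  for (tr in trees) acc <- .collectProductions(tr, acc)
  total <- length(acc$rules)
  if (total == 0) return(out)

  counts <- table(factor(acc$rules, levels = .RULE_INVENTORY))
  out[paste0("rule_", .sanitizeRule(.RULE_INVENTORY))] <-
    as.numeric(counts) / total

  nUtt <- length(trees)
  for (ph in c("NP", "VP", "PP", "ADVP")) {
    sel <- acc$nodeLabel == ph
    out[paste0("phrasal_", ph, "_prop")] <- sum(sel) / total
    out[paste0("phrasal_", ph, "_meanlen")] <-
      if (any(sel)) mean(acc$nodeSize[sel]) else NA_real_
    out[paste0("phrasal_", ph, "_rate")] <- sum(sel) / nUtt
  }
  out["phrasal_ADJP_prop"] <- sum(acc$nodeLabel == "ADJP") / total
  out
}

# per-leaf Yngve scores: sum over the path of right-sibling counts
.yngveScores <- function(tree) {
  scores <- numeric(0)
  walk <- function(node, depth) {
    if (isTRUE(node$leaf)) { scores <<- c(scores, depth); return() }
    nk <- length(node$children)
    for (i in seq_len(nk)) walk(node$children[[i]], depth + (nk - i))
  }
  walk(tree, 0)
  scores
}

# per-leaf Frazier scores: length of the maximal leftmost-child chain
# ending at the leaf
.frazierScores <- function(tree) {
  scores <- numeric(0)
  walk <- function(node, chain) {
    if (isTRUE(node$leaf)) { scores <<- c(scores, chain); return() }
    nk <- length(node$children)
    for (i in seq_len(nk))
      walk(node$children[[i]], if (i == 1L) chain + 1 else 0)
  }
  walk(tree, 0)
  scores
}

#' Syntactic complexity features
#'
#' 36 statistics of utterance length and parse-tree shape: for each of 7
#' per-utterance measures (length in tokens, length in letters, tree
#' depth, mean and max Yngve depth, mean Frazier depth, clause count
#' proxied by VP nodes) the mean/sd/min/max/median across utterances, plus
#' the utterance count.
#'
#' @param trees list of constituency trees.
#' @return named numeric vector of length 36; NA when no utterance has
#'   content.
#' @export
syntacticComplexityFeatures <- function(trees) {
  reg <- featureRegistry()
  nm <- reg$name[reg$family == "syntactic_complexity"]
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  trees <- Filter(function(tr) length(tr$children) > 0, trees)
  if (!length(trees)) return(out)

  countVP <- function(node) {
    if (isTRUE(node$leaf)) return(0L)
    own <- as.integer(node$label == "VP")
    own + sum(vapply(node$children, countVP, 1L))
  }
  leafChars <- function(tree) {
    if (isTRUE(tree$leaf)) return(nchar(tree$token))
    sum(vapply(tree$children, leafChars, 1L))
  }
  meas <- vapply(trees, function(tr) {
    yn <- .yngveScores(tr)
    c(utt_len_tokens = .countLeaves(tr),
      utt_len_chars = leafChars(tr),
      tree_depth = .treeDepth(tr),
      yngve_mean = mean(yn),
      yngve_max = max(yn),
      frazier_mean = mean(.frazierScores(tr)),
      clause_count = countVP(tr))
  }, numeric(7))

  for (m in .SYNT_MEASURES) {
    x <- meas[m, ]
    out[paste0("synt_", m, "_mean")] <- mean(x)
    out[paste0("synt_", m, "_sd")] <- if (length(x) > 1) stats::sd(x) else 0
    out[paste0("synt_", m, "_min")] <- min(x)
    out[paste0("synt_", m, "_max")] <- max(x)
    out[paste0("synt_", m, "_median")] <- stats::median(x)
  }
  out["synt_num_utterances"] <- length(trees)
  out
}

#' Lexical richness indices
#'
#' Six vocabulary-richness statistics over the pooled token stream:
#' type-token ratio V/N, moving-average TTR (window 20), Brunet's
#' W = N^(V^-0.165), Honore's R = 100 log(N) / (1 - V1/V) with hapax count
#' V1 (guarded: when V1 = V the denominator is replaced by the documented
#' constant 1e-3), Guiraud's index V/sqrt(N) and Sichel's S = V2/V.
#'
#' @param tokens character vector of (case-folded) tokens.
#' @param mattr_window window length for the moving-average TTR.
#' @return named numeric vector of length 6; all NA for an empty stream.
#' @examples
#' lexicalRichness(c("a", "b", "c", "b"))["richness_ttr"]  # 0.75
#' @export
lexicalRichness <- function(tokens, mattr_window = 20L) {
  nm <- paste0("richness_", .RICHNESS_NAMES)
  out <- stats::setNames(rep(NA_real_, 6L), nm)
  tokens <- tolower(tokens)
  N <- length(tokens)
  if (N == 0) return(out)
  tab <- table(tokens)
  V <- length(tab)
  V1 <- sum(tab == 1L)
  V2 <- sum(tab == 2L)

  out["richness_ttr"] <- V / N
  if (N <= mattr_window) {
    out["richness_mattr"] <- V / N
  } else {
    windows <- vapply(seq_len(N - mattr_window + 1L), function(i)
      length(unique(tokens[i:(i + mattr_window - 1L)])) / mattr_window, 1)
    out["richness_mattr"] <- mean(windows)
  }
  out["richness_brunet_w"] <- N^(V^-0.165)
  hden <- 1 - V1 / V
  if (hden <= 0) hden <- 1e-3
  out["richness_honore_r"] <- 100 * log(N) / hden
  out["richness_guiraud"] <- V / sqrt(N)
  out["richness_sichel"] <- V2 / V
  out
}

#' Utterance coherence features
#'
#' Embeds each non-empty utterance as the mean of its token vectors and
#' computes 15 local-coherence statistics (consecutive-utterance cosine
#' similarity and distance: mean/sd/min/max/median each; fractions of
#' consecutive pairs with similarity below 0.5, 0.3 and 0; mean lag-2
#' similarity; first-to-last similarity) and 5 utterance-distance features
#' over all pairs (fractions below the same thresholds, average and
#' minimum pairwise cosine distance).
#'
#' @param doc a [TranscriptDoc-class] or list of token vectors.
#' @param emb an embedding provider.
#' @return named numeric vector of length 20; all NA with fewer than two
#'   embeddable utterances.
#' @export
coherenceFeatures <- function(doc, emb = hashEmbeddingProvider()) {
  reg <- featureRegistry()
  nm <- reg$name[reg$family %in% c("local_coherence", "utterance_distances")]
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  tokLists <- if (is(doc, "TranscriptDoc")) docTokens(doc) else doc
  embs <- Filter(Negate(is.null),
                 lapply(tokLists, .utteranceEmbedding, emb = emb))
  n <- length(embs)
  if (n < 2) return(out)

  consec <- vapply(seq_len(n - 1),
                   function(i) .cosineSim(embs[[i]], embs[[i + 1]]), 1)
  out["coh_consec_sim_mean"] <- mean(consec)
  out["coh_consec_sim_sd"] <- if (n > 2) stats::sd(consec) else 0
  out["coh_consec_sim_min"] <- min(consec)
  out["coh_consec_sim_max"] <- max(consec)
  out["coh_consec_sim_median"] <- stats::median(consec)
  d <- 1 - consec
  out["coh_consec_dist_mean"] <- mean(d)
  out["coh_consec_dist_sd"] <- if (n > 2) stats::sd(d) else 0
  out["coh_consec_dist_min"] <- min(d)
  out["coh_consec_dist_max"] <- max(d)
  out["coh_consec_dist_median"] <- stats::median(d)
  out["coh_consec_below_05"] <- mean(consec < 0.5)
  out["coh_consec_below_03"] <- mean(consec < 0.3)
  out["coh_consec_below_0"] <- mean(consec < 0)
  if (n >= 3) {
    lag2 <- vapply(seq_len(n - 2),
                   function(i) .cosineSim(embs[[i]], embs[[i + 2]]), 1)
    out["coh_lag2_sim_mean"] <- mean(lag2)
  }
  out["coh_first_last_sim"] <- .cosineSim(embs[[1]], embs[[n]])

  pairs <- utils::combn(n, 2)
  sims <- vapply(seq_len(ncol(pairs)), function(j)
    .cosineSim(embs[[pairs[1, j]]], embs[[pairs[2, j]]]), 1)
  out["dist_frac_below_05"] <- mean(sims < 0.5)
  out["dist_frac_below_03"] <- mean(sims < 0.3)
  out["dist_frac_below_0"] <- mean(sims < 0)
  out["dist_avg_pairwise"] <- mean(1 - sims)
  out["dist_min_pairwise"] <- min(1 - sims)
  out
}

#' Speech-graph features
#'
#' Builds the word-adjacency multigraph of the document (one node per word
#' type, one directed edge per consecutive token pair within an utterance)
#' and emits 13 topology statistics: node count, edge count (with
#' multiplicity), repeated-edge count (ordered pairs seen more than once),
#' L1 self-loops, L2 two-cycles, L3 three-cycles, largest weakly and
#' strongly connected component sizes, density (distinct non-loop edges /
#' N(N-1)), diameter and average shortest path on the distinct-edge
#' digraph (0 by convention for single-node graphs), mean total degree
#' (2E/N with multiplicity) and the global clustering coefficient of the
#' undirected projection.
#'
#' @param tokenLists list of per-utterance token vectors (or a
#'   [TranscriptDoc-class]).
#' @return named numeric vector of length 13; all NA without tokens.
#' @export
speechGraphFeatures <- function(tokenLists) {
  nm <- paste0("graph_", .GRAPH_STATS)
  out <- stats::setNames(rep(NA_real_, 13L), nm)
  if (is(tokenLists, "TranscriptDoc")) tokenLists <- docTokens(tokenLists)
  tokenLists <- lapply(tokenLists, tolower)
  words <- unique(unlist(tokenLists))
  N <- length(words)
  if (N == 0) return(out)

  from <- character(0); to <- character(0)
  for (u in tokenLists) {
    if (length(u) >= 2) {
      from <- c(from, u[-length(u)])
      to <- c(to, u[-1])
    }
  }
  E <- length(from)
  out["graph_nodes"] <- N
  out["graph_edges"] <- E
  out["graph_mean_degree"] <- 2 * E / N

  if (E == 0) {
    out[c("graph_repeated_edges", "graph_l1", "graph_l2", "graph_l3",
          "graph_density", "graph_diameter", "graph_aspl", "graph_cc")] <- 0
    out["graph_lcc"] <- 1
    out["graph_lsc"] <- 1
    return(out)
  }

  key <- paste(from, to, sep = "\r")
  multiplicity <- table(key)
  out["graph_repeated_edges"] <- sum(multiplicity > 1)

  A <- matrix(0L, N, N, dimnames = list(words, words))
  for (k in names(multiplicity)) {
    ft <- strsplit(k, "\r", fixed = TRUE)[[1]]
    A[ft[1], ft[2]] <- 1L
  }
  out["graph_l1"] <- sum(diag(A))
  Ao <- A; diag(Ao) <- 0L
  out["graph_l2"] <- sum(Ao * t(Ao)) / 2
  out["graph_l3"] <- sum(diag(Ao %*% Ao %*% Ao)) / 3
  out["graph_density"] <- if (N > 1) sum(Ao) / (N * (N - 1)) else 0

  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  out["graph_lcc"] <- max(igraph::components(g, mode = "weak")$csize)
  out["graph_lsc"] <- max(igraph::components(g, mode = "strong")$csize)
  if (N > 1) {
    dm <- igraph::distances(g, mode = "out")
    finite <- dm[is.finite(dm) & dm > 0]
    out["graph_diameter"] <- if (length(finite)) max(finite) else 0
    out["graph_aspl"] <- if (length(finite)) mean(finite) else 0
  } else {
    out["graph_diameter"] <- 0
    out["graph_aspl"] <- 0
  }
  gu <- igraph::as_undirected(
    igraph::graph_from_adjacency_matrix(Ao, mode = "directed"),
    mode = "collapse")
  cc <- igraph::transitivity(gu, type = "global")
  out["graph_cc"] <- if (is.nan(cc)) 0 else cc
  out
}

#' Norm, cohesion, rate and dictionary features
#'
#' 12 lexical-norm means (imageability, age of acquisition, familiarity,
#' concreteness over all words / nouns / verbs), 9 sentiment-norm means
#' (valence, arousal, dominance over the same scopes), the proportion of
#' tokens absent from the reference wordlist, the tense-switch cohesion
#' statistic (changes between past and present utterance tense divided by
#' utterance count) and 2 rate features (words per second of audio,
#' syllables per second of speech).
#'
#' @param doc a [TranscriptDoc-class].
#' @param tagged optional `PosTaggedDoc` (computed if missing).
#' @param norms norm lexicon data.frame from [readNormLexicon()].
#' @param wordlist character vector from [readWordlist()].
#' @param audio_dur total audio duration in seconds (NA to skip rates).
#' @param speech_dur spoken-segment duration in seconds.
#' @return named numeric vector of length 25.
#' @export
miscLexicalFeatures <- function(doc, tagged = NULL,
                                norms = readNormLexicon(),
                                wordlist = readWordlist(),
                                audio_dur = NA_real_,
                                speech_dur = NA_real_) {
  reg <- featureRegistry()
  nm <- reg$name[reg$family %in% c("lexical_norms", "sentiment_norms",
                                   "invalid_words", "cohesion", "rate")]
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (is.null(tagged)) tagged <- tagTranscript(doc)
  tt <- do.call(rbind, tagged)
  if (is.null(tt) || nrow(tt) == 0) return(out)

  idx <- match(tolower(tt$lemma), norms$word)
  scopes <- list(all = rep(TRUE, nrow(tt)),
                 nouns = tt$tag %in% .NOUN_TAGS,
                 verbs = tt$tag %in% .VERB_TAGS)
  for (col in c(.NORM_NAMES, .SENTIMENT_NAMES)) {
    vals <- norms[[col]][idx]
    prefix <- if (col %in% .NORM_NAMES) "norm_" else "sentiment_"
    for (sc in names(scopes)) {
      v <- vals[scopes[[sc]]]
      v <- v[!is.na(v)]
      out[paste0(prefix, col, "_", sc)] <- if (length(v)) mean(v) else NA_real_
    }
  }

  out["invalid_word_prop"] <- mean(!tolower(tt$token) %in% wordlist)

  tense <- vapply(tagged, function(u) {
    if (!nrow(u)) return(NA_character_)
    past <- sum(u$tag == "VBD")
    pres <- sum(u$tag %in% c("VBZ", "VBP"))
    if (past == 0 && pres == 0) return(NA_character_)
    if (past > pres) "past" else "pres"
  }, "")
  tns <- tense[!is.na(tense)]
  switches <- if (length(tns) > 1) sum(tns[-1] != tns[-length(tns)]) else 0L
  out["cohesion_tense_switches"] <- switches / length(tagged)

  if (!is.na(audio_dur) && audio_dur > 0)
    out["rate_words_per_sec"] <- nrow(tt) / audio_dur
  if (!is.na(speech_dur) && speech_dur > 0)
    out["rate_syllables_per_sec"] <-
      sum(.countSyllablesV(tt$token)) / speech_dur
  out
}
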