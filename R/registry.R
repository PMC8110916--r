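# The canonical feature registry: 509 named features in a fixed order,
# partitioned 297 lexico-syntactic / 187 acoustic / 25 semantic. Family
# sizes are frozen here; the extractor must emit exactly these names.

# 36 word-level Penn Treebank tags + 17 punctuation/extended tags = 53.
.PTB_TAGS <- c(
  "CC", "CD", "DT", "EX", "FW", "IN", "JJ", "JJR", "JJS", "LS", "MD",
  "NN", "NNS", "NNP", "NNPS", "PDT", "POS", "PRP", "PRP$", "RB", "RBR",
  "RBS", "RP", "SYM", "TO", "UH", "VB", "VBD", "VBG", "VBN", "VBP",
  "VBZ", "WDT", "WP", "WP$", "WRB",
  "PERIOD", "COMMA", "COLON", "LRB", "RRB", "QUOTE_OPEN", "QUOTE_CLOSE",
  "HASH", "DOLLAR", "HYPH", "NFP", "ADD", "AFX", "GW", "XX", "SP", "NIL")

# 18 universal (coarse) tags, spaCy convention.
.UD_TAGS <- c(
  "ADJ", "ADP", "ADV", "AUX", "CCONJ", "DET", "INTJ", "NOUN", "NUM",
  "PART", "PRON", "PROPN", "PUNCT", "SCONJ", "SYM", "VERB", "X", "SPACE")

# fine -> coarse tag mapping
.PTB_TO_UD <- c(
  CC = "CCONJ", CD = "NUM", DT = "DET", EX = "PRON", FW = "X", IN = "ADP",
  JJ = "ADJ", JJR = "ADJ", JJS = "ADJ", LS = "X", MD = "AUX", NN = "NOUN",
  NNS = "NOUN", NNP = "PROPN", NNPS = "PROPN", PDT = "DET", POS = "PART",
  PRP = "PRON", "PRP$" = "PRON", RB = "ADV", RBR = "ADV", RBS = "ADV",
  RP = "PART", SYM = "SYM", TO = "PART", UH = "INTJ", VB = "VERB",
  VBD = "VERB", VBG = "VERB", VBN = "VERB", VBP = "VERB", VBZ = "VERB",
  WDT = "DET", WP = "PRON", "WP$" = "PRON", WRB = "ADV",
  AUXZ = "AUX", AUXP = "AUX", AUXD = "AUX")

# Frozen 104-rule production inventory (LHS -> RHS tag/phrase sequence).
# Rules outside the inventory count toward the production total but are
# not features themselves.
.RULE_INVENTORY <- c(
  # sentence-level (20)
  "S->NP_VP", "S->VP", "S->NP", "S->NP_PP", "S->ADVP_NP_VP",
  "S->NP_ADVP_VP", "S->INTJ_NP_VP", "S->CC_NP_VP", "S->NP_VP_CC_NP_VP",
  "S->NP_VP_CC_VP", "S->PP_NP_VP", "S->INTJ_VP", "S->ADVP_VP", "S->INTJ",
  "S->ADVP", "S->PP", "S->ADJP", "S->NP_NP", "S->VP_CC_VP", "S->NP_CC_NP",
  # noun phrases (30)
  "NP->PRP", "NP->EX", "NP->DT", "NP->NN", "NP->NNS", "NP->NNP",
  "NP->DT_NN", "NP->DT_NNS", "NP->DT_NNP", "NP->JJ_NN", "NP->JJ_NNS",
  "NP->DT_JJ_NN", "NP->DT_JJ_NNS", "NP->DT_JJ_JJ_NN", "NP->PRP$_NN",
  "NP->PRP$_NNS", "NP->PRP$_JJ_NN", "NP->DT_NN_NN", "NP->NN_NN",
  "NP->NN_NNS", "NP->DT_NN_NNS", "NP->CD_NN", "NP->CD_NNS", "NP->DT_CD_NN",
  "NP->PDT_DT_NN", "NP->DT_JJ_NN_NN", "NP->WP", "NP->WDT", "NP->DT_VBG_NN",
  "NP->JJ_JJ_NN",
  # verb phrases (36)
  "VP->VBZ", "VP->VBZ_NP", "VP->VBZ_PP", "VP->VBZ_ADJP", "VP->VBZ_ADVP",
  "VP->VBZ_NP_PP", "VP->VBZ_VBG", "VP->VBZ_VBG_NP", "VP->VBZ_VBG_PP",
  "VP->VBZ_VBG_NP_PP", "VP->VBZ_VBG_ADVP", "VP->VBZ_VBG_PRT",
  "VP->VBZ_VBN", "VP->VBD", "VP->VBD_NP", "VP->VBD_PP", "VP->VBD_ADVP",
  "VP->VBD_PRT", "VP->VBD_VBG", "VP->VBD_VBG_PP", "VP->VBP", "VP->VBP_NP",
  "VP->VBP_VBG", "VP->VBP_VBG_NP", "VP->VBG", "VP->VBG_NP", "VP->VBG_PP",
  "VP->VBG_NP_PP", "VP->VBG_ADVP", "VP->VBG_PRT", "VP->VB", "VP->VB_NP",
  "VP->MD_VB", "VP->MD_VB_NP", "VP->VBZ_VBG_NP_ADVP", "VP->VBZ_VBG_PP_PP",
  # prepositional phrases (6)
  "PP->IN_NP", "PP->TO_NP", "PP->IN", "PP->TO", "PP->IN_VBG", "PP->IN_ADVP",
  # adverb/adjective phrases, particles, interjections (12)
  "ADVP->RB", "ADVP->RB_RB", "ADVP->RBR", "ADVP->RB_RB_RB", "ADVP->RBS",
  "ADJP->JJ", "ADJP->JJ_JJ", "ADJP->RB_JJ", "ADJP->JJR",
  "PRT->RP", "INTJ->UH", "NP->DT_JJ_VBG_NN")

.SYNT_MEASURES <- c("utt_len_tokens", "utt_len_chars", "tree_depth",
                    "yngve_mean", "yngve_max", "frazier_mean", "clause_count")
.SYNT_STATS <- c("mean", "sd", "min", "max", "median")

.NORM_NAMES <- c("imageability", "aoa", "familiarity", "concreteness")
.SENTIMENT_NAMES <- c("valence", "arousal", "dominance")
.NORM_SCOPES <- c("all", "nouns", "verbs")

.RICHNESS_NAMES <- c("ttr", "mattr", "brunet_w", "honore_r",
                     "guiraud", "sichel")

.WORDCAT_NAMES <- c("demonstratives", "function_words", "light_verbs",
                    "inflected_verbs", "propositions")

.GRAPH_STATS <- c("nodes", "edges", "repeated_edges", "l1", "l2", "l3",
                  "lcc", "lsc", "density", "diameter", "aspl",
                  "mean_degree", "cc")

.WORDFREQ_LEMMAS <- c("cookie", "boy", "water", "sink", "stool", "jar",
                      "window")

.MOMENT_STATS <- c("mean", "var", "skew", "kurt")

.sanitizeTag <- function(tag) gsub("\\$", "S", tag)

.sanitizeRule <- function(rule) {
  r <- gsub("->", "__", rule, fixed = TRUE)
  gsub("\\$", "S", r)
}

# Assemble the full 509-row registry data.frame.
.buildRegistry <- function() {
  fam <- function(names, family, category)
    data.frame(name = names, family = family, category = category,
               stringsAsFactors = FALSE)

  lex <- rbind(
    fam(as.vector(outer(.SYNT_MEASURES, .SYNT_STATS,
                        function(m, s) paste0("synt_", m, "_", s))),
        "syntactic_complexity", "lexicosyntactic"),
    fam("synt_num_utterances", "syntactic_complexity", "lexicosyntactic"),
    fam(paste0("rule_", .sanitizeRule(.RULE_INVENTORY)),
        "production_rules", "lexicosyntactic"),
    fam(c(as.vector(outer(c("prop", "meanlen", "rate"),
                          c("NP", "VP", "PP", "ADVP"),
                          function(s, p) paste0("phrasal_", p, "_", s))),
          "phrasal_ADJP_prop"),
        "phrasal_ratios", "lexicosyntactic"),
    fam(as.vector(outer(.NORM_SCOPES, .NORM_NAMES,
                        function(s, n) paste0("norm_", n, "_", s))),
        "lexical_norms", "lexicosyntactic"),
    fam(paste0("richness_", .RICHNESS_NAMES),
        "lexical_richness", "lexicosyntactic"),
    fam(paste0("wordcat_", .WORDCAT_NAMES), "word_category", "lexicosyntactic"),
    fam(c("ratio_noun_to_noun_verb", "ratio_noun_to_verb",
          "ratio_pronoun_to_noun_pronoun"),
        "noun_ratio", "lexicosyntactic"),
    fam("avg_word_length", "length", "lexicosyntactic"),
    fam(paste0("upos_", .UD_TAGS), "universal_pos", "lexicosyntactic"),
    fam(paste0("pos_", .sanitizeTag(.PTB_TAGS)), "pos_tags", "lexicosyntactic"),
    fam(c(paste0("coh_consec_sim_", .SYNT_STATS),
          paste0("coh_consec_dist_", .SYNT_STATS),
          "coh_consec_below_05", "coh_consec_below_03", "coh_consec_below_0",
          "coh_lag2_sim_mean", "coh_first_last_sim"),
        "local_coherence", "lexicosyntactic"),
    fam(c("dist_frac_below_05", "dist_frac_below_03", "dist_frac_below_0",
          "dist_avg_pairwise", "dist_min_pairwise"),
        "utterance_distances", "lexicosyntactic"),
    fam(paste0("graph_", .GRAPH_STATS), "speech_graph", "lexicosyntactic"),
    fam("cohesion_tense_switches", "cohesion", "lexicosyntactic"),
    fam(c("rate_words_per_sec", "rate_syllables_per_sec"),
        "rate", "lexicosyntactic"),
    fam("invalid_word_prop", "invalid_words", "lexicosyntactic"),
    fam(as.vector(outer(.NORM_SCOPES, .SENTIMENT_NAMES,
                        function(s, n) paste0("sentiment_", n, "_", s))),
        "sentiment_norms", "lexicosyntactic"))

  mfccNames <- as.vector(vapply(
    c("", "d_", "dd_"),
    function(kind) as.vector(vapply(1:14, function(i)
      paste0("mfcc", sprintf("%02d", i), "_", kind, .MOMENT_STATS),
      character(4))),
    character(56)))

  aco <- rbind(
    fam(c("pause_total_dur", "pause_mean_dur", "pause_long_count",
          "pause_short_count", "pause_word_ratio", "filler_count",
          "filler_word_ratio", "pause_speech_ratio", "pause_per_word_dur"),
        "pauses_fillers", "acoustic"),
    fam(c("f0_mean", "f0_min", "f0_max", "f0_median"), "f0", "acoustic"),
    fam(c("dur_audio", "dur_speech"), "duration", "acoustic"),
    fam(paste0("zcr_", .MOMENT_STATS), "zcr", "acoustic"),
    fam(mfccNames, "mfcc", "acoustic"))

  sem <- rbind(
    fam(c("cu_ratio_distinct", "cu_ratio_objects", "cu_ratio_actions",
          paste0("wordfreq_", .WORDFREQ_LEMMAS)),
        "word_frequency", "semantic"),
    fam(c(as.vector(outer(c("mean", "min", "max", "subject", "place",
                            "object", "action"),
                          c("primary", "secondary"),
                          function(s, i) paste0("gcoh_", i, "_", s))),
          "gcoh_primary_sd"),
        "global_coherence", "semantic"))

  reg <- rbind(lex, aco, sem)
  reg$index <- seq_len(nrow(reg))
  rownames(reg) <- NULL
  reg
}

#' The canonical 509-feature registry
#'
#' Returns the packaged feature catalogue: one row per feature with columns
#' `name`, `family`, `category` ("lexicosyntactic"/"acoustic"/"semantic")
#' and `index` (position in every extracted feature vector). The registry is
#' frozen: extraction always emits exactly these features in this order.
#'
#' @return data.frame with 509 rows.
#' @examples
#' reg <- featureRegistry()
#' table(reg$category)
#' @export
featureRegistry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- .buildRegistry()
    cache
  }
})

#' Write the registry to CSV
#'
#' Exports [featureRegistry()] in the packaged `registry.csv` layout
#' (`name,family,category,index`).
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportRegistry <- function(path) {
  utils::write.csv(featureRegistry(), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expected per-family feature counts
#'
#' The fixed number of features in each registry family; summing within
#' category gives the 297/187/25 partition of the 509-feature battery.
#'
#' @return named integer vector, one entry per family.
#' @export
registryFamilyCounts <- function() {
  reg <- featureRegistry()
  vapply(split(reg$name, reg$family), length, 1L)[unique(reg$family)]
}
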