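test_that("POS proportions equal hand counts on a fixed document", {
  doc <- parseChat(paste(
    "*PAR:\tthe boy is taking a cookie .",
    "*PAR:\tshe is washing the dishes .", sep = "\n"))
  tagged <- tagTranscript(doc)
  f <- posFeatures(tagged)
  # 12 tokens: DT x3, NN x1 (boy), VBZ x2, VBG x2, PRP x1, NNS x2? hand:
  # the/DT boy/NN is/VBZ taking/VBG a/DT cookie/NN
  # she/PRP is/VBZ washing/VBG the/DT dishes/NNS
  expect_equal(unname(f["pos_DT"]), 3 / 11)
  expect_equal(unname(f["pos_NN"]), 2 / 11)
  expect_equal(unname(f["pos_VBZ"]), 2 / 11)
  expect_equal(unname(f["pos_VBG"]), 2 / 11)
  expect_equal(unname(f["pos_PRP"]), 1 / 11)
  expect_equal(unname(f["pos_NNS"]), 1 / 11)
  expect_equal(sum(f[startsWith(names(f), "pos_")]), 1)
  expect_equal(sum(f[startsWith(names(f), "upos_")]), 1)
  # nouns 3, verbs 4 (2 aux uses still VBZ), pronouns 1
  expect_equal(unname(f["ratio_noun_to_noun_verb"]), 3 / 7)
  expect_equal(unname(f["ratio_pronoun_to_noun_pronoun"]), 1 / 4)
  expect_equal(unname(f["avg_word_length"]),
               mean(nchar(c("the", "boy", "is", "taking", "a", "cookie",
                            "she", "is", "washing", "the", "dishes"))))
})

test_that("single-tag degenerate documents give degenerate proportions", {
  tagged <- tagTranscript(list(c("boy", "girl", "water")))
  f <- posFeatures(tagged)
  expect_equal(unname(f["pos_NN"]), 1)
  expect_equal(sum(f[setdiff(grep("^pos_", names(f), value = TRUE),
                             "pos_NN")]), 0)
  # zero tokens -> everything undefined
  f0 <- posFeatures(tagTranscript(list(character(0))))
  expect_true(all(is.na(f0)))
})

test_that("production rules match a hand expansion of a known tree", {
  tree <- readBracketedTree(
    "(S (NP (DT the) (NN boy)) (VP (VBZ falls)))")
  f <- productionRuleFeatures(list(tree))
  # productions: S->NP_VP, NP->DT_NN, VP->VBZ : 3 total
  expect_equal(unname(f["rule_S__NP_VP"]), 1 / 3)
  expect_equal(unname(f["rule_NP__DT_NN"]), 1 / 3)
  expect_equal(unname(f["rule_VP__VBZ"]), 1 / 3)
  expect_equal(unname(f["phrasal_NP_meanlen"]), 2)
  expect_equal(unname(f["phrasal_NP_prop"]), 1 / 3)
  expect_equal(unname(f["phrasal_NP_rate"]), 1)
  # no PP anywhere
  expect_equal(unname(f["phrasal_PP_prop"]), 0)
  expect_true(is.na(f["phrasal_PP_meanlen"]))
  expect_true(all(is.na(productionRuleFeatures(list()))))
})

test_that("the chunk parser produces inventory rules on simple clauses", {
  trees <- parseTranscript(tagTranscript(list(
    c("the", "boy", "is", "taking", "a", "cookie"))))
  f <- productionRuleFeatures(trees)
  expect_gt(f["rule_S__NP_VP"], 0)
  expect_gt(f["rule_VP__VBZ_VBG_NP"], 0)
  sc <- syntacticComplexityFeatures(trees)
  expect_equal(unname(sc["synt_utt_len_tokens_mean"]), 6)
  expect_equal(unname(sc["synt_num_utterances"]), 1)
  expect_gte(sc["synt_tree_depth_mean"], 2)
})

test_that("lexical richness indices match their closed forms", {
  f <- lexicalRichness(c("a", "b", "c", "b"))
  expect_equal(unname(f["richness_ttr"]), 0.75)
  expect_equal(unname(f["richness_brunet_w"]), 4^(3^-0.165))
  expect_equal(unname(f["richness_honore_r"]), 100 * log(4) / (1 - 2 / 3))
  expect_equal(unname(f["richness_guiraud"]), 3 / 2)
  expect_equal(unname(f["richness_sichel"]), 1 / 3)

  # single token: W = 1
  expect_equal(unname(lexicalRichness("x")["richness_brunet_w"]), 1)
  # all distinct -> Honore guard, finite and capped
  g <- lexicalRichness(c("a", "b", "c"))
  expect_equal(unname(g["richness_honore_r"]), 100 * log(3) / 1e-3)
  expect_true(is.finite(g["richness_honore_r"]))
})

test_that("richness matches the counting oracle on random streams", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(2:60, 1)
    toks <- sample(letters[1:8], n, replace = TRUE)
    f <- lexicalRichness(toks)
    o <- oracleRichness(toks)
    expect_equal(unname(f["richness_ttr"]), unname(o["ttr"]))
    expect_equal(unname(f["richness_brunet_w"]), unname(o["brunet"]))
    expect_equal(unname(f["richness_honore_r"]), unname(o["honore"]))
    expect_equal(unname(f["richness_guiraud"]), unname(o["guiraud"]))
    expect_equal(unname(f["richness_sichel"]), unname(o["sichel"]))
  }
})

test_that("coherence features behave on identical and orthogonal vectors", {
  emb <- hashEmbeddingProvider()
  same <- coherenceFeatures(list(c("boy", "cookie"), c("boy", "cookie"),
                                 c("boy", "cookie")), emb)
  expect_equal(unname(same["coh_consec_dist_mean"]), 0, tolerance = 1e-12)
  expect_equal(unname(same["dist_avg_pairwise"]), 0, tolerance = 1e-12)
  expect_equal(unname(same["dist_frac_below_05"]), 0)

  # constructed orthogonal embedding provider
  e1 <- c(1, 0); e2 <- c(0, 1)
  orth <- list(embed = function(w) if (w == "a") e1 else e2, dim = 2L)
  two <- coherenceFeatures(list("a", "b"), orth)
  expect_equal(unname(two["coh_consec_sim_mean"]), 0)
  expect_equal(unname(two["dist_avg_pairwise"]), 1)

  expect_true(all(is.na(coherenceFeatures(list(c("a", "b")), emb))))
  # invariant to padding with empty utterances
  padded <- coherenceFeatures(list(c("boy"), character(0), c("water")), emb)
  plain <- coherenceFeatures(list(c("boy"), c("water")), emb)
  expect_equal(padded, plain)
})

test_that("pairwise distance features match brute force on random docs", {
  emb <- hashEmbeddingProvider()
  set.seed(99)
  vocab <- c("boy", "girl", "water", "cookie", "stool", "jar", "window")
  for (i in 1:20) {
    utts <- lapply(seq_len(sample(3:6, 1)), function(j)
      sample(vocab, sample(1:4, 1), replace = TRUE))
    f <- coherenceFeatures(utts, emb)
    vecs <- lapply(utts, function(u)
      rowMeans(vapply(u, emb$embed, numeric(emb$dim))))
    sims <- c()
    for (a in seq_along(vecs)) for (b in seq_along(vecs))
      if (a < b) sims <- c(sims, oracleCosine(vecs[[a]], vecs[[b]]))
    expect_equal(unname(f["dist_avg_pairwise"]), mean(1 - sims),
                 tolerance = 1e-10)
    expect_equal(unname(f["dist_min_pairwise"]), min(1 - sims),
                 tolerance = 1e-10)
    expect_equal(unname(f["dist_frac_below_05"]), mean(sims < 0.5))
    cons <- vapply(seq_len(length(vecs) - 1), function(j)
      oracleCosine(vecs[[j]], vecs[[j + 1]]), 1)
    expect_equal(unname(f["coh_consec_sim_mean"]), mean(cons),
                 tolerance = 1e-10)
  }
})

test_that("speech-graph statistics are exact on tiny known graphs", {
  f <- speechGraphFeatures(list(c("the", "boy")))
  expect_equal(unname(f[c("graph_nodes", "graph_edges", "graph_l1")]),
               c(2, 1, 0))
  f2 <- speechGraphFeatures(list(c("the", "the")))
  expect_equal(unname(f2["graph_l1"]), 1)
  f3 <- speechGraphFeatures(list(c("a", "b", "a")))
  expect_equal(unname(f3["graph_l2"]), 1)
  f4 <- speechGraphFeatures(list("lonely"))
  expect_equal(unname(f4[c("graph_diameter", "graph_aspl")]), c(0, 0))
})

test_that("speech-graph statistics match the brute-force oracle", {
  set.seed(7)
  vocab <- letters[1:7]
  for (i in 1:25) {
    nUtt <- sample(1:3, 1)
    utts <- lapply(seq_len(nUtt), function(j)
      sample(vocab, sample(2:20, 1), replace = TRUE))
    f <- speechGraphFeatures(utts)
    o <- oracleGraphStats(utts)
    for (nm in names(o))
      expect_equal(unname(f[paste0("graph_", nm)]), unname(o[nm]),
                   tolerance = 1e-10, label = paste("stat", nm, "case", i))
  }
})

test_that("norm, dictionary, cohesion and rate features are computed", {
  doc <- parseChat(paste(
    "*PAR:\tthe boy fell .",
    "*PAR:\tshe is washing the dishes .",
    "*PAR:\tthe boy took a thingy .", sep = "\n"))
  f <- miscLexicalFeatures(doc, audio_dur = 10, speech_dur = 8)
  # thingy is the only non-dictionary token (12 tokens total)
  expect_equal(unname(f["invalid_word_prop"]), 1 / 13)
  # tense: past, pres, past -> 2 switches over 3 utterances
  expect_equal(unname(f["cohesion_tense_switches"]), 2 / 3)
  expect_equal(unname(f["rate_words_per_sec"]), 13 / 10)
  expect_true(is.finite(f["norm_imageability_all"]))
  expect_true(is.finite(f["sentiment_valence_nouns"]))

  one <- miscLexicalFeatures(parseChat("*PAR:\tthe boy fell ."))
  expect_equal(unname(one["cohesion_tense_switches"]), 0)
  expect_true(is.na(one["rate_words_per_sec"]))
})
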