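# Regenerates the packaged extdata resources from the code inventories.
# Run from the repository root: Rscript tools/make_extdata.R

suppressMessages(pkgload::load_all(".", quiet = TRUE))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

## feature registry ------------------------------------------------------
exportRegistry("inst/extdata/registry.csv")

## content-unit lexicon --------------------------------------------------
cu <- data.frame(
  unit = c("boy", "girl", "woman", "kitchen", "window", "curtains",
           "cupboard", "exterior", "sink", "water", "dishes", "plate",
           "dishcloth", "cookie", "jar", "stool", "overflow", "falling",
           "taking", "washing", "asking", "unconcerned"),
  category = c("subject", "subject", "subject", "place", "place", "place",
               "place", "place", "object", "object", "object", "object",
               "object", "object", "object", "object", "action", "action",
               "action", "action", "action", "action"),
  synonyms = c("boy|brother|son|kid",
               "girl|sister|daughter",
               "woman|mother|mom|lady",
               "kitchen",
               "window",
               "curtain",
               "cupboard|cabinet|closet",
               "garden|yard|path|outside",
               "sink|faucet|tap",
               "water",
               "dish",
               "plate",
               "dishcloth|cloth|towel",
               "cookie|biscuit",
               "jar",
               "stool",
               "overflow|spill|drip",
               "fall|tip|wobble|slip|drop",
               "take|steal|grab|reach|climb",
               "wash|dry|wipe",
               "ask",
               "unconcerned|indifferent|oblivious|unaware|distracted|daydream|ignore"),
  anchors = c("boy|child", "girl|child", "woman|mother", "kitchen",
              "window", "curtain", "cupboard", "garden|outside",
              "sink", "water", "dish", "plate", "cloth|towel",
              "cookie", "jar", "stool", "overflow|spill", "fall|tip",
              "take|steal", "wash|dry", "ask", "unconcerned|oblivious"))
write.csv(cu, "inst/extdata/content_units.csv", row.names = FALSE)

## synthetic norm lexicon ------------------------------------------------
# deterministic plausible values from the word hash; SYNTHETIC stand-in
# for published norm inventories
lx <- speechAD:::.taggerLexicon()
words <- sort(unique(c(lx$word, lx$lemma)))
h <- vapply(words, function(w) speechAD:::.strHash(paste0("norm:", w)), 1L)
u <- function(salt) vapply(words, function(w)
  (speechAD:::.strHash(paste0(salt, ":", w)) %% 10007L) / 10007, 1)
norms <- data.frame(
  word = words,
  imageability = round(250 + 400 * u("img"), 1),
  aoa = round(2 + 10 * u("aoa"), 2),
  familiarity = round(300 + 350 * u("fam"), 1),
  concreteness = round(1.5 + 3.5 * u("conc"), 2),
  valence = round(2.5 + 5 * u("val"), 2),
  arousal = round(2 + 5 * u("aro"), 2),
  dominance = round(2.5 + 4.5 * u("dom"), 2))
write.csv(norms, "inst/extdata/norms_synthetic.csv", row.names = FALSE)

## reference wordlist ----------------------------------------------------
# lexicon vocabulary plus common English words; deliberately excludes
# spelled discourse vocalizations (hm, yeah, okay) and neologisms, which
# count as non-dictionary tokens
extra <- c("time", "man", "year", "way", "work", "life", "world", "school",
           "state", "family", "student", "group", "country", "problem",
           "fact", "place", "week", "company", "system", "program",
           "question", "government", "number", "night", "point", "home",
           "room", "mr", "area", "money", "story", "month", "book", "eye",
           "job", "word", "business", "issue", "side", "kind", "head",
           "far", "house", "service", "friend", "father", "power", "hour",
           "game", "line", "end", "member", "law", "car", "city",
           "community", "name", "president", "team", "minute", "idea",
           "body", "information", "back", "parent", "face", "others",
           "level", "office", "door", "health", "person", "art", "war",
           "history", "party", "result", "change", "morning", "reason",
           "research", "girl", "guy", "moment", "air", "teacher", "force",
           "education")
wl <- sort(unique(c(setdiff(c(lx$word, lx$lemma),
                            c("hm", "yeah", "okay", "um", "uh")), extra)))
write.csv(data.frame(word = wl), "inst/extdata/wordlist.csv",
          row.names = FALSE)

cat("extdata written:", paste(list.files("inst/extdata"), collapse = ", "),
    "\n")
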