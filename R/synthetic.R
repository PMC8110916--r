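# Synthetic cohort generator: CHAT transcripts + schematic audio with
# planted AD vs non-AD effects and feature-linked MMSE. The per-group
# generation rates are calibrated so that pipeline-extracted group means
# land on the published reference values for the planted features
# (distinct-content-unit ratios, pronoun:(pronoun+noun) ratio, average
# word length, non-dictionary-word proportion, adverb use, coherence).

# One utterance template per content unit mentions only that unit's
# synonyms plus neutral vocabulary, so the distinct-unit ratio is an exact
# binomial in the mention probability. <...> marks substitutable NPs.
.UNIT_TEMPLATES <- list(
  boy = c("<the boy> is standing there", "there is <a boy>"),
  girl = c("<the girl> is laughing", "there is <a girl> too"),
  woman = c("<the mother> is busy", "<the woman> is standing there"),
  kitchen = c("this is <the kitchen>", "<the kitchen> is busy"),
  window = c("<the window> is open"),
  curtains = c("<the curtains> are open"),
  cupboard = c("<the cupboard> is open", "<the cupboard> is up high"),
  exterior = c("there is <a path> outside", "there is <a garden> outside"),
  sink = c("<the sink> is full"),
  water = c("<the water> is running", "there is water on <the floor>"),
  dishes = c("<the dishes> are done", "she is doing <the dishes>"),
  plate = c("there is <a plate> on <the counter>"),
  dishcloth = c("<the towel> is wet", "she is holding <a cloth>"),
  cookie = c("<the cookies> are up there", "he wants <a cookie>"),
  jar = c("<the jar> is up on <the shelf>", "<the jar> is open"),
  stool = c("<the stool> has three legs", "he is up on <the stool>"),
  overflow = c("it is overflowing", "it is spilling over"),
  falling = c("he is falling over", "it is tipping over"),
  taking = c("he is taking one", "he is reaching up"),
  washing = c("she is washing them", "she is drying them"),
  asking = c("she is asking for one"),
  unconcerned = c("she is unconcerned", "she is daydreaming"))

.UNIT_CATEGORY <- c(
  boy = "subject", girl = "subject", woman = "subject",
  kitchen = "place", window = "place", curtains = "place",
  cupboard = "place", exterior = "place",
  sink = "object", water = "object", dishes = "object", plate = "object",
  dishcloth = "object", cookie = "object", jar = "object", stool = "object",
  overflow = "action", falling = "action", taking = "action",
  washing = "action", asking = "action", unconcerned = "action")

.NEUTRAL_TEMPLATES <- c("it is a nice day", "there is a lot going on",
                        "it is summer", "that is everything",
                        "this is a busy picture")

.NP_PRONOUN <- c(boy = "he", girl = "she", mother = "she", woman = "she",
                 lady = "she", curtains = "they", dishes = "they",
                 legs = "they")

.NEOLOGISMS <- c("thingy", "doodad")
.DISCOURSE_INVALID <- c("hm", "yeah", "okay")

# age-band pattern mirroring the matched design (band start, males,
# females per group); recycled for other group sizes
.AGE_BANDS <- data.frame(
  band = c(50, 55, 60, 65, 70, 75),
  m = c(1, 5, 3, 6, 6, 3),
  f = c(0, 4, 6, 10, 8, 2))

#' Cohort generation configuration
#'
#' Per-group generation rates, the MMSE model and audio parameters. The
#' defaults plant the reference group effects: content-unit mention
#' probability 0.27 (AD) vs 0.45 (non-AD), with pronoun substitution,
#' adjective/adverb insertion, non-dictionary discourse tokens, filler and
#' pause rates and utterance repetition calibrated per group. MMSE is a
#' linear function of each subject's realized planted quantities plus
#' Gaussian noise, clipped to \[0, 30\].
#'
#' @param n_per_group subjects per group (default 54).
#' @param seed master seed; all randomness derives from it.
#' @param null_effects when TRUE both groups use the average of the two
#'   default parameter sets (no planted differences).
#' @param audio_rate audio sampling rate in Hz.
#' @param ad,nonad named lists overriding individual group rates.
#' @return list of class `CohortConfig`.
#' @export
cohortConfig <- function(n_per_group = 54L, seed = 1L, null_effects = FALSE,
                         audio_rate = 16000, ad = list(), nonad = list()) {
  stopifnot(n_per_group >= 2)
  adDef <- list(
    p_np = 0.35, p_object = 0.28, p_action = 0.15,
    pron_sub = 0.29, adj_rate = 0.04,
    adj_words = c("big", "wet", "full"),
    adv_rate = 0.25, invalid_rate = 0.58, starter_rate = 0.55,
    filler_rate = 0.55, pause_rate = 0.85, long_pause_rate = 0.30,
    repeat_prob = 0.42, neutral_utts = 2L)
  naDef <- list(
    p_np = 0.5425, p_object = 0.47, p_action = 0.30,
    pron_sub = 0.03, adj_rate = 0.22,
    adj_words = c("little", "wooden", "soapy", "clean"),
    adv_rate = 0.15, invalid_rate = 0.40, starter_rate = 0.08,
    filler_rate = 0.15, pause_rate = 0.30, long_pause_rate = 0.10,
    repeat_prob = 0.03, neutral_utts = 1L)
  adP <- utils::modifyList(adDef, ad)
  naP <- utils::modifyList(naDef, nonad)
  for (p in list(adP, naP)) {
    rates <- unlist(p[c("p_np", "p_object", "p_action", "pron_sub",
                        "adj_rate", "adv_rate", "filler_rate",
                        "repeat_prob")])
    if (any(rates < 0 | rates > 1))
      stop("probability parameters must lie in [0, 1]")
  }
  if (null_effects) {
    numNames <- setdiff(names(adP), c("neutral_utts", "adj_words"))
    avg <- Map(function(a, b) (a + b) / 2, adP[numNames], naP[numNames])
    avg$neutral_utts <- 1L
    avg$adj_words <- union(adP$adj_words, naP$adj_words)
    adP <- avg; naP <- avg
  }
  structure(list(
    n_per_group = as.integer(n_per_group), seed = as.integer(seed),
    audio_rate = audio_rate,
    groups = list(AD = adP, `non-AD` = naP),
    mmse = list(intercept = -2, b_content = 70, b_wordlen = 8,
                b_pronoun = -14, noise_sd = 1.8)),
    class = "CohortConfig")
}

# split a template into utterance items; NPs marked <det noun>
.parseTemplate <- function(tpl) {
  toks <- strsplit(tpl, " ", fixed = TRUE)[[1]]
  items <- list(); cur <- NULL
  for (tk in toks) {
    if (startsWith(tk, "<")) cur <- character(0)
    clean <- gsub("[<>]", "", tk)
    if (!is.null(cur)) {
      cur <- c(cur, clean)
      if (endsWith(tk, ">")) {
        items[[length(items) + 1L]] <- list(kind = "np", words = cur)
        cur <- NULL
      }
    } else items[[length(items) + 1L]] <- list(kind = "w", words = clean)
  }
  items
}

# realize a template as a token vector under group parameters
.realizeUtterance <- function(tpl, g) {
  items <- .parseTemplate(tpl)
  out <- character(0)
  firstNP <- TRUE
  for (it in items) {
    if (it$kind == "np") {
      head <- it$words[length(it$words)]
      if (stats::runif(1) < g$pron_sub) {
        pron <- .NP_PRONOUN[head]
        if (is.na(pron)) pron <- "it"
        out <- c(out, unname(pron))
      } else {
        words <- it$words
        if (stats::runif(1) < g$adj_rate && length(words) > 1) {
          adj <- sample(g$adj_words, 1)
          words <- c(words[1], adj, words[-1])
        }
        out <- c(out, words)
      }
      firstNP <- FALSE
    } else out <- c(out, it$words)
  }
  if (stats::runif(1) < g$adv_rate) {
    adv <- sample(c("just", "really", "very", "probably"), 1)
    vpos <- which(out %in% c("is", "are", "has", "can"))
    if (length(vpos)) out <- append(out, adv, after = vpos[1])
    else out <- c(adv, out)
  }
  if (stats::runif(1) < g$invalid_rate) {
    if (stats::runif(1) < 0.25)
      out <- c(out, "the", sample(.NEOLOGISMS, 1))
    else out <- c(sample(.DISCOURSE_INVALID, 1), out)
  }
  if (stats::runif(1) < g$starter_rate)
    out <- c(sample(c("and", "so"), 1), out)
  out
}

.makeUtteranceRecord <- function(tokens, g) {
  fillers <- character(0); fpos <- integer(0)
  if (stats::runif(1) < g$filler_rate) {
    fillers <- sample(c("um", "uh"), 1)
    fpos <- sample(0:min(2, length(tokens)), 1)
  }
  plens <- integer(0); ppos <- integer(0)
  if (stats::runif(1) < g$pause_rate) {
    long <- stats::runif(1) < g$long_pause_rate
    plens <- if (long) 3L else sample(1:2, 1)
    ppos <- sample(seq_len(max(1, length(tokens) - 1)), 1)
  }
  list(speaker = "PAR", raw = paste(tokens, collapse = " "),
       tokens = tokens, fillers = length(fillers),
       filler_tokens = fillers, filler_positions = fpos,
       pauses = length(plens), pause_lengths = plens,
       pause_positions = ppos, retraced = 0L, unintelligible = 0L)
}

# schematic audio: one tone segment per utterance, silences inserted for
# the utterance's pause marks; tiny inter-utterance gaps stay below the
# pause-detection floor
.synthesizeAudio <- function(utts, rate) {
  segs <- list()
  gap <- numeric(round(0.1 * rate))
  pauseDur <- c(0.3, 0.7, 1.2)
  for (i in seq_along(utts)) {
    u <- utts[[i]]
    f <- 150 + 45 * ((i - 1) %% 5) + stats::runif(1, -10, 10)
    dur <- 0.25 + 0.09 * length(u$tokens)
    t <- seq(0, dur, by = 1 / rate)
    tone <- 0.4 * sin(2 * pi * f * t) * (0.8 + 0.2 * sin(2 * pi * 3 * t))
    if (u$pauses > 0) {
      for (pl in u$pause_lengths) {
        cut <- sample(seq_len(length(tone) - 1), 1)
        tone <- c(tone[1:cut], numeric(round(pauseDur[pl] * rate)),
                  tone[(cut + 1):length(tone)])
      }
    }
    segs[[length(segs) + 1L]] <- c(tone, gap)
  }
  new("AudioClip", samples = unlist(segs), rate = rate)
}

# quick planted-quantity summary used by the MMSE model
.plantedSummary <- function(utts, mentioned) {
  toks <- unlist(lapply(utts, `[[`, "tokens"))
  lx <- .taggerLexicon()
  tags <- lx$tag[match(toks, lx$word)]
  prons <- sum(tags %in% c("PRP", "PRP$"), na.rm = TRUE)
  nouns <- sum(tags %in% c("NN", "NNS"), na.rm = TRUE) +
    sum(is.na(tags))                      # neologisms tag as nouns
  list(content = mean(mentioned),
       wordlen = mean(nchar(toks)),
       pronoun = .safeRatio(prons, prons + nouns))
}

#' Generate a synthetic cohort
#'
#' Builds `2 * n_per_group` subjects: transcripts from the content-unit
#' template grammar with group-specific generation rates, matching
#' schematic audio (tones with inserted silences mirroring the transcript
#' pause marks), demographics balanced across groups within age bands,
#' and MMSE driven by each subject's realized planted quantities. The
#' same seed always yields an identical cohort; the caller's RNG state is
#' left untouched.
#'
#' @param cfg a [cohortConfig()].
#' @return a [SpeechCohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(n_per_group = 3, seed = 7))
#' coh
#' @export
generateCohort <- function(cfg = cohortConfig()) {
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv())
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        globalenv()))
  units <- names(.UNIT_TEMPLATES)
  n <- cfg$n_per_group

  # demographic slots recycled from the matched age-band pattern
  slots <- do.call(rbind, lapply(seq_len(nrow(.AGE_BANDS)), function(i)
    data.frame(band = .AGE_BANDS$band[i],
               sex = rep(c("M", "F"), c(.AGE_BANDS$m[i], .AGE_BANDS$f[i])))))
  slots <- slots[rep(seq_len(nrow(slots)), length.out = n), ]

  docs <- list(); clips <- list(); meta <- list()
  subjIdx <- 0L
  for (grp in c("AD", "non-AD")) {
    g <- cfg$groups[[grp]]
    for (i in seq_len(n)) {
      subjIdx <- subjIdx + 1L
      # double arithmetic: exact below 2^53, no integer overflow
      set.seed(as.integer((as.numeric(cfg$seed) * 100003 +
                             subjIdx * 7919) %% 2147483647))
      sid <- sprintf("S%03d", subjIdx)

      # noun-based units lose their mention when the head NP is
      # pronoun-substituted; compensate so the realized mention rate
      # matches the configured target
      comp <- 1 / (1 - 0.85 * g$pron_sub)
      pCat <- c(subject = min(1, g$p_np * comp),
                place = min(1, g$p_np * comp),
                object = min(1, g$p_object * comp),
                action = g$p_action)
      mentioned <- stats::runif(length(units)) <
        pCat[.UNIT_CATEGORY[units]]
      if (!any(mentioned)) mentioned[sample(length(units), 1)] <- TRUE
      utts <- list()
      for (u in units[mentioned]) {
        tpl <- sample(.UNIT_TEMPLATES[[u]], 1)
        utts[[length(utts) + 1L]] <-
          .makeUtteranceRecord(.realizeUtterance(tpl, g), g)
      }
      for (j in seq_len(g$neutral_utts)) {
        tpl <- sample(.NEUTRAL_TEMPLATES, 1)
        utts[[length(utts) + 1L]] <-
          .makeUtteranceRecord(.realizeUtterance(tpl, g), g)
      }
      utts <- utts[sample(length(utts))]
      # perseverative repetition of an earlier utterance
      reps <- which(stats::runif(length(utts)) < g$repeat_prob)
      for (r in reps) {
        src <- utts[[sample(length(utts), 1)]]
        utts[[length(utts) + 1L]] <- src
      }

      planted <- .plantedSummary(utts, mentioned)
      mm <- cfg$mmse
      mmse <- mm$intercept + mm$b_content * planted$content +
        mm$b_wordlen * (planted$wordlen - 3.5) +
        mm$b_pronoun * planted$pronoun +
        stats::rnorm(1, 0, mm$noise_sd)
      mmse <- as.integer(round(.clip(mmse, 0, 30)))

      age <- slots$band[i] + sample(0:4, 1)
      docMeta <- list(age = age, sex = slots$sex[i], label = grp,
                      mmse = mmse)
      docs[[subjIdx]] <- new("TranscriptDoc", subjectId = sid,
                             utterances = utts, meta = docMeta)
      clips[[subjIdx]] <- .synthesizeAudio(utts, cfg$audio_rate)
      meta[[subjIdx]] <- data.frame(subject_id = sid, age = age,
                                    sex = slots$sex[i], label = grp,
                                    mmse = mmse)
    }
  }
  new("SpeechCohort", docs = docs, clips = clips,
      meta = do.call(rbind, meta))
}

#' Write a cohort to disk
#'
#' Emits one `.cha` and one `.wav` per subject plus `meta.csv`, exactly in
#' the formats the transcript/audio readers consume.
#'
#' @param cohort a [SpeechCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(nrow(cohort@meta))) {
    sid <- cohort@meta$subject_id[i]
    writeChat(cohort@docs[[i]], file.path(dir, paste0(sid, ".cha")))
    writeWavClip(cohort@clips[[i]], file.path(dir, paste0(sid, ".wav")))
  }
  utils::write.csv(cohort@meta, file.path(dir, "meta.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir directory containing `.cha`, `.wav` and `meta.csv`.
#' @return a [SpeechCohort-class].
#' @export
readCohortDir <- function(dir) {
  meta <- readMeta(file.path(dir, "meta.csv"))
  docs <- list(); clips <- list()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$subject_id[i]
    doc <- parseChat(readLines(file.path(dir, paste0(sid, ".cha"))),
                     subject_id = sid)
    doc@meta <- list(age = meta$age[i], sex = meta$sex[i],
                     label = meta$label[i], mmse = meta$mmse[i])
    docs[[i]] <- doc
    clips[[i]] <- readWavClip(file.path(dir, paste0(sid, ".wav")))
  }
  new("SpeechCohort", docs = docs, clips = clips, meta = meta)
}
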