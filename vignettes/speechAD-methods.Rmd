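---
title: "Speech and language markers of Alzheimer's disease: methods and design"
author: "speechAD package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech and language markers of Alzheimer's disease: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous speech elicited by the Cookie Theft picture-description task
carries measurable traces of Alzheimer's disease (AD): descriptions become
less informative (fewer picture content units), lexically simpler (shorter,
less specific words, more pronouns), less coherent across utterances, and
more disfluent (fillers, pauses). `speechAD` implements a fixed battery of
509 engineered features over CHAT-format transcripts and the associated
audio, together with the classification, regression and statistical
protocol used to turn these features into AD/non-AD predictions and MMSE
(Mini-Mental State Examination, 0--30) estimates.

Because the clinical corpora this methodology is normally applied to are
access-restricted, the package ships a first-class synthetic cohort
generator that plants known group effects. Every stage of the pipeline --
parsing, feature extraction, selection, model fitting, cross-validation,
differentiation statistics -- is exercised and tested against these
synthetic cohorts.

## The feature battery

The battery is frozen in a registry (`featureRegistry()`): 509 named
features, partitioned into 297 lexico-syntactic, 187 acoustic and 25
picture-content semantic features. The registry fixes both the names and
the order; extraction always emits exactly this vector. Family sizes:

* lexico-syntactic: syntactic complexity 36, production-rule proportions
  104, phrasal-type ratios 13, lexical norms 12, lexical richness 6, word
  categories 5, noun ratios 3, average word length 1, universal POS 18,
  Penn Treebank POS 53, local coherence 15, utterance distances 5,
  speech-graph statistics 13, tense cohesion 1, speaking rate 2,
  non-dictionary proportion 1, sentiment norms 9;
* acoustic: pauses/fillers 9, fundamental frequency 4, durations 2,
  zero-crossing rate 4, MFCC moments 168 (14 static + 14 delta + 14
  delta-delta coefficients, each summarized by mean, variance, skewness
  and excess kurtosis);
* semantic: content-unit mention ratios and content-lemma frequencies 10,
  utterance-to-content-unit coherence distances 15.

Where a published family count fixes *how many* features exist but not
*which*, the registry freezes an explicit choice. The 104-rule production
inventory, the 53/18 tag inventories, the 15 local-coherence statistics,
the 36 syntactic-complexity statistics (five summary statistics over seven
per-utterance measures -- token and letter length, tree depth, Yngve mean
and max, Frazier mean, VP-count clause proxy -- plus the utterance count)
and the split of the 10 word-frequency features into 3 content-unit ratios
plus 7 content-lemma frequencies are all such frozen choices: they make
the counts reproducible, which is what the battery's contracts assert.
Productions and tags outside the inventories count toward denominators but
are not features themselves.

### Conventions that had to be fixed

* **Missing values.** A feature undefined on an input (no voiced frame, a
  single utterance, an empty transcript) is recorded as undefined and
  zero-imputed in the assembled vector; the `defined` attribute (and
  assay) preserves the flag. Modeling operates on the imputed matrix.
* **Honoré's R.** With hapax count equal to the type count the statistic
  diverges; the guard replaces the vanishing denominator with the
  documented constant `1e-3`, which preserves the ordering of documents.
* **Kurtosis** is excess kurtosis (normal gives 0); skewness is the
  classical moment ratio.
* **"Similarity below threshold 0"** is read literally: the fraction of
  utterance pairs with negative cosine similarity.
* **Syllables** are counted by a vowel-group heuristic with a silent-e
  rule and a small exception list.
* **Tense switches** come from the fine POS tags (past vs present tag
  groups), divided by the utterance count.
* **Retracing.** Material scoped by CHAT retracing codes (`[/]`, `[//]`)
  is excised from the lexical token stream and tallied separately; other
  bracket codes are dropped while the words they annotate are kept.
  Whether the original protocol counted retraced tokens in lexical
  features is not recoverable; excision mirrors common DementiaBank
  practice.

### Pluggable resources

The tagger, parser, lemmatizer, embeddings, norm lexicons and the
content-unit inventory sit behind plain interfaces. The packaged defaults
are deterministic and self-contained:

* a lexicon POS tagger with suffix fallbacks and a chunk parser producing
  flat constituency trees (gold tags and bracketed trees can be supplied
  instead -- the tests do this);
* hash-based unit-vector embeddings (`hashEmbeddingProvider()`): every
  word maps to a fixed pseudo-random unit vector keyed by a string hash,
  so extraction is deterministic with no model downloads; word2vec-format
  text vectors can be loaded with `readWordVectors()` for production use;
* a synthetic norm lexicon and a compact English wordlist under
  `inst/extdata/` (the published norm inventories cannot be
  redistributed); the wordlist deliberately excludes spelled discourse
  vocalizations ("hm", "yeah", "okay") and neologisms, which therefore
  count as non-dictionary tokens;
* the standard Cookie Theft content-unit inventory (22 units in
  subject/place/object/action categories) as an editable CSV.

With hash embeddings, cosine distances between utterances concentrate
near 1 (random unit vectors are nearly orthogonal), so the *absolute*
values of embedding-based features differ from what trained word2vec/GloVe
vectors would give; their *relative* behavior (repetition lowers
distances, content words move utterances toward content-unit anchors) is
preserved, and that is what the tests assert.

### Acoustic analysis

Framing defaults to 25 ms Hann windows with a 10 ms hop. MFCCs use a
26-filter mel bank and an orthonormal DCT-II; the 0th (energy) coefficient
is included among the 14 static coefficients, which is the standard
decomposition reaching 42 coefficients with deltas and delta-deltas.
Silence is declared where frame log-energy falls 20 dB below the clip's
median frame log-energy for at least 150 ms; pauses of 1.0 s or more are
"long", pauses in [0.15, 1.0) s are "short". All thresholds are relative,
so the features are invariant to global amplitude scaling. Fillers are
counted from the transcript (manual transcription is authoritative), not
detected from audio. F0 is the autocorrelation peak in 75--500 Hz on
voiced frames.

## Modeling and evaluation protocol

Feature selection is univariate: top-k by one-way ANOVA F between the
class-conditional distributions for classification, and top-k by the
F statistic of the squared Pearson correlation with MMSE for regression.
Ties break toward the lower feature index for determinism; zero-variance
features score 0.

The four classifier configurations use fixed hyperparameters: SVM with an
RBF kernel (gamma 0.001, C = 100, k = 10 features), a two-hidden-layer
network of 10 ReLU units each trained with Adam for 200 full-batch epochs
(k = 10), a 200-tree random forest with minimum node size 2 (k = 50), and
Gaussian naive Bayes with balanced priors and variance smoothing 1e-10
(k = 80). MMSE regression is ordinary least squares or closed-form ridge
on standardized features (reference settings: ridge k = 25 with alpha 10,
k = 35 with alpha 12, linear k = 15 or 20), with predictions clipped to
[0, 30]. Features are z-scored with training statistics for SVM, the
network and the regressors; tree and Bayes models take raw features.
Whether the original protocol standardized features is unstated; fixing
it is required for reproducibility.

Evaluation offers leave-one-subject-out CV and label-stratified 10-fold
CV, with metrics averaged over three seeds (defaults 1, 2, 3), majority
voting over an odd number of seed-variant models for test predictions,
and accuracy/precision/recall/specificity/F1 (AD positive) plus AUROC by
the rank statistic. Selection and standardization are refit inside every
training fold -- the alternative leaks held-out labels, and the test suite
asserts the guard by poisoning held-out rows. Model families are compared
with the Kruskal--Wallis H test over per-run accuracies.

The differentiation analysis applies Welch's t-test per feature (the
equal-variance choice is not documented in the protocol this follows;
Welch is the robust default) and flags significance at alpha and at the
Bonferroni level alpha/m with m the number of features actually tested
(0.05/509 is approximately 9.8e-5). The regression-weight report averages
each feature's standardized ridge coefficient over LOSO folds (zero when
unselected) and pairs it with the feature's marginal MMSE correlation,
reporting the five most positive and five most negative weights.

## The synthetic cohort generator

`generateCohort()` builds balanced cohorts (default 54 + 54, mirroring a
matched train-set design, with sex matched subject-for-subject within
5-year age bands from 50 to 80). Transcripts come from a template grammar
over the content-unit inventory: each unit has templates whose content
words involve only that unit's synonyms, so the distinct-content-unit
ratio is an exact binomial in the configured mention probability. Group
differences are planted through per-group rates: content-unit mention
probabilities (objects 0.28 vs 0.47, actions 0.15 vs 0.30, others set so
the overall ratios land at 0.27 vs 0.45), pronoun substitution of noun
phrases (with mention probabilities compensated by 1/(1 - 0.85 q) for the
mentions that substitution erases), adjective and adverb insertion,
non-dictionary discourse tokens and neologisms, filler and pause-mark
rates, sentence starters, and perseverative utterance repetition. The
rates were calibrated once so that the *pipeline-extracted* group means
land on the reference values for the planted features (content ratios,
pronoun:(pronoun+noun) 0.35 vs 0.23, word length 3.57 vs 3.78 letters,
non-dictionary proportion 0.11 vs 0.08) and then frozen.

MMSE is a linear function of each subject's realized planted quantities
(content ratio, mean word length, pronoun ratio) plus Gaussian noise
(sd 1.8), clipped to [0, 30]. Group means come out near 18 (AD) and 27
(non-AD); the non-AD tail is wider than in the clinical tables because
the content ratio's binomial noise at 22 units bounds how tight a
feature-driven MMSE can be.

Audio is deliberately schematic: one amplitude-modulated tone segment per
utterance with silences inserted to match the transcript's pause marks
(0.3 / 0.7 / 1.2 s for the three mark lengths) and sub-threshold
inter-utterance gaps. This exercises the MFCC, ZCR, F0 and
pause-detection code paths against known ground truth; it does not mimic
real speech spectra, so passing acoustic tests demonstrates computational
correctness, not clinical validity. The same caveat applies to the
cohort as a whole: recovery results on synthetic cohorts show that the
pipeline can detect effects of the planted kind and size, not that it
detects AD.

One master seed drives everything through per-subject substreams, so a
cohort is bit-reproducible, and generation restores the caller's RNG
state.

### What the generator does not emulate

Natural language variation beyond the template grammar; disfluencies more
complex than fillers, pause marks and whole-utterance repetition;
realistic speech acoustics; annotation noise in CHAT files; and the exact
published group separations of embedding-geometry features (average
pairwise utterance distance 0.91 vs 0.94, fraction of pairs below
similarity 0.5), which depend on trained-embedding geometry that
deterministic hash vectors do not reproduce -- the generator plants a
directional effect there, not the printed values.

## Problem sizes used in tests

The test suite runs the full pipeline at the study design (54 + 54
subjects, three generation seeds) for the recovery checks, a 4 + 4
cohort for structural tests, 100 random small instances (up to 60 tokens
or a few seconds of audio) per brute-force oracle, and 20 replicates of
the 509-feature Gaussian power simulation for the Bonferroni recovery
criterion. `scripts/acceptance.R` recomputes the same quantities from
scratch with seeds derived from its `--seed` argument.

## Known limitations

* The tagger/parser are vocabulary-driven approximations; on open-domain
  English they fall back to suffix heuristics, and the production-rule
  inventory reflects their flat chunk grammar rather than a treebank
  parser's output.
* Hash embeddings make coherence features deterministic but compress
  their dynamic range; load real vectors for clinical use.
* BERT-style transfer-learning models and t-SNE/attention visualizations
  are out of scope.
* Published headline accuracies on the restricted clinical dataset are
  not reproducible here; the package's claims are the registry counts,
  the protocol laws, and parameter recovery on its own synthetic cohorts.
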