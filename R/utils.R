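# Small numeric helpers shared across feature families.

# 31-bit polynomial rolling hash; deterministic across platforms, no RNG.
# Products stay below 2^36 so double arithmetic is exact.
.strHash <- function(s) {
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

.cosineSim <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# mean, variance, skewness, excess kurtosis of a series (moment estimators;
# normal -> kurtosis 0). Degenerate series give 0 spread moments.
.seriesMoments <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) return(c(mean = 0, var = 0, skew = 0, kurt = 0))
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= .Machine$double.eps * max(1, m^2)) {
    return(c(mean = m, var = 0, skew = 0, kurt = 0))
  }
  c(mean = m, var = v,
    skew = e1071::skewness(x, type = 1),
    kurt = e1071::kurtosis(x, type = 1))
}

# ratio with guarded denominator: 0/0 -> default
.safeRatio <- function(num, den, default = 0) {
  if (is.na(den) || den == 0) return(default)
  num / den
}

# Vowel-group syllable heuristic with a silent-e rule and a fixed
# exception list; adequate for the restricted picture-description lexicon.
.syllableExceptions <- c(
  the = 1, a = 1, cookie = 2, cookies = 2, everything = 3,
  unconcerned = 3, indifferent = 4, oblivious = 4, overflowing = 4
)

.countSyllables <- function(word) {
  w <- tolower(gsub("[^a-z']", "", tolower(word)))
  if (!nzchar(w)) return(0L)
  exc <- .syllableExceptions[w]
  if (!is.na(exc)) return(as.integer(exc))
  groups <- gregexpr("[aeiouy]+", w)[[1]]
  n <- if (groups[1] == -1) 0L else length(groups)
  # silent final e ("plate", "table" keeps the -le syllable)
  if (grepl("[^aeiouy]e$", w) && !grepl("le$", w) && n > 1) n <- n - 1L
  max(n, 1L)
}

.countSyllablesV <- function(words) {
  if (!length(words)) return(integer(0))
  vapply(words, .countSyllables, 1L, USE.NAMES = FALSE)
}

# clip numeric vector into [lo, hi]
.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
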