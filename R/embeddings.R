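# Word embedding providers and norm-lexicon resources.

#' Deterministic hash-based embedding provider
#'
#' Maps every word to a fixed-dimension unit vector derived from a string
#' hash of the word and a salt: identical words always map to identical
#' vectors, distinct words to quasi-orthogonal ones, and no model download
#' or RNG state is involved. This is the default provider for coherence
#' and content-unit distance features; word2vec/GloVe-style text vectors
#' can be loaded with [readWordVectors()] for production use.
#'
#' @param dim vector dimension (default 50).
#' @param salt salt string; different salts give independent inventories.
#' @return an embedding provider: list with `embed(word)`, `dim`, `name`.
#' @examples
#' emb <- hashEmbeddingProvider()
#' v <- emb$embed("cookie")
#' sum(v^2)  # unit norm
#' @export
hashEmbeddingProvider <- function(dim = 50L, salt = "primary") {
  cache <- new.env(parent = emptyenv())
  embed <- function(word) {
    word <- tolower(word)
    hit <- cache[[word]]
    if (!is.null(hit)) return(hit)
    h <- vapply(seq_len(dim), function(i)
      .strHash(paste0(salt, ":", word, ":", i)), 1L)
    v <- (h %% 200003L) / 200003 * 2 - 1
    v <- v / sqrt(sum(v * v))
    cache[[word]] <- v
    v
  }
  list(embed = embed, dim = as.integer(dim),
       name = paste0("hash-", salt, "-", dim))
}

#' Load word vectors in word2vec text format
#'
#' Plain-text format: optional "n dim" header line, then one word followed
#' by `dim` floats per line. Out-of-vocabulary words map to the zero-mean
#' fallback vector (the mean of all loaded vectors).
#'
#' @param path text-format vector file.
#' @return an embedding provider (see [hashEmbeddingProvider()]).
#' @export
readWordVectors <- function(path) {
  lines <- readLines(path)
  if (length(lines) && grepl("^\\s*\\d+\\s+\\d+\\s*$", lines[1]))
    lines <- lines[-1]
  parts <- strsplit(trimws(lines), "\\s+")
  words <- vapply(parts, `[[`, "", 1L)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]),
                  numeric(length(parts[[1]]) - 1L)))
  rownames(mat) <- tolower(words)
  fallback <- colMeans(mat)
  embed <- function(word) {
    word <- tolower(word)
    if (word %in% rownames(mat)) mat[word, ] else fallback
  }
  list(embed = embed, dim = ncol(mat), name = paste0("w2v:", basename(path)))
}

# mean-of-token-vectors utterance embedding; NULL when no token
.utteranceEmbedding <- function(tokens, emb) {
  if (!length(tokens)) return(NULL)
  vs <- vapply(tokens, emb$embed, numeric(emb$dim))
  rowMeans(matrix(vs, nrow = emb$dim))
}

#' Load a lexical/sentiment norm lexicon
#'
#' CSV with columns `word,imageability,aoa,familiarity,concreteness,
#' valence,arousal,dominance`. Lookups are case-insensitive on lemmas.
#' The packaged default (`norms_synthetic.csv`) is a synthetic lexicon
#' covering the picture-description vocabulary with plausible norm ranges;
#' it stands in for published norm inventories, which cannot be
#' redistributed here.
#'
#' @param path CSV path; default the packaged synthetic lexicon.
#' @return data.frame keyed by lower-case `word`.
#' @export
readNormLexicon <- function(path = system.file("extdata",
                                               "norms_synthetic.csv",
                                               package = "speechAD")) {
  nl <- utils::read.csv(path, stringsAsFactors = FALSE)
  nl$word <- tolower(nl$word)
  nl
}

#' Load the reference English wordlist
#'
#' One word per line (CSV with single column `word`); tokens absent from
#' the list count as non-dictionary words. The packaged list covers the
#' picture-description vocabulary plus common English words.
#'
#' @param path CSV path; default the packaged list.
#' @return character vector of lower-case words.
#' @export
readWordlist <- function(path = system.file("extdata", "wordlist.csv",
                                            package = "speechAD")) {
  tolower(utils::read.csv(path, stringsAsFactors = FALSE)$word)
}
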