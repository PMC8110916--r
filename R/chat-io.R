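# CHAT transcript parsing, serialization, WAV audio and metadata I/O.

#' Normalize one CHAT main-tier line
#'
#' Strips CHAT annotation codes from the content of a main tier and returns
#' the lexical tokens together with filled-pause and unfilled-pause counts.
#' Handled codes: retracing/repetition (`[/]`, `[//]`, with optional
#' `<...>` scope) whose retraced material is excised from the token stream
#' but tallied; event codes `&=...`; fragment codes `&...`; filled pauses
#' `&-um`/`&-uh`/`&um`/`&uh` (counted and kept aside, not lexical tokens);
#' unintelligible `xxx`; pause marks `(.)`, `(..)`, `(...)` (counted with
#' nominal length 1--3); other bracketed codes are dropped while the words
#' they scope are kept; utterance terminators and punctuation are dropped.
#' Tokens are lower-cased; parenthesized elisions are restored
#' (`(be)cause` -> `because`).
#'
#' @param raw_tier tier content after the `*XXX:` marker.
#' @return list with `tokens`, `fillers`, `filler_tokens`,
#'   `filler_positions`, `pauses`, `pause_lengths`, `pause_positions`,
#'   `retraced` (count of excised retracings), `unintelligible` (count of
#'   xxx regions).
#' @export
normalizeTier <- function(raw_tier) {
  s <- raw_tier

  # group retracings: "<the boy> [/]" -> drop scoped material
  retraced <- 0L
  repeat {
    m <- regexpr("<[^<>]*>\\s*\\[/+\\]|<[^<>]*>\\s*\\[//\\]", s)
    if (m == -1) break
    retraced <- retraced + 1L
    s <- paste0(substr(s, 1, m - 1),
                substr(s, m + attr(m, "match.length"), nchar(s)))
  }
  # single-word retracing: "word [/]" or "word [//]"
  repeat {
    m <- regexpr("[^ \t<>]+\\s*\\[/+\\]|[^ \t<>]+\\s*\\[//\\]", s)
    if (m == -1) break
    retraced <- retraced + 1L
    s <- paste0(substr(s, 1, m - 1),
                substr(s, m + attr(m, "match.length"), nchar(s)))
  }
  # remaining bracket codes: drop the code, keep scoped words
  s <- gsub("\\[[^][]*\\]", " ", s)
  s <- gsub("[<>]", " ", s)

  pieces <- strsplit(trimws(s), "\\s+")[[1]]
  pieces <- pieces[nzchar(pieces)]

  tokens <- character(0)
  filler_tokens <- character(0)
  filler_positions <- integer(0)
  pause_lengths <- integer(0)
  pause_positions <- integer(0)
  unintelligible <- 0L

  for (p in pieces) {
    if (grepl("^\\(\\.{1,3}\\)$", p)) {               # unfilled pause mark
      pause_lengths <- c(pause_lengths, nchar(p) - 2L)
      pause_positions <- c(pause_positions, length(tokens))
      next
    }
    if (grepl("^&-?(um+|uh+|er+|eh+|mm+)$", p, ignore.case = TRUE)) {
      f <- tolower(sub("^&-?", "", p))
      f <- if (grepl("^um", f)) "um" else if (grepl("^uh", f)) "uh" else f
      filler_tokens <- c(filler_tokens, f)
      filler_positions <- c(filler_positions, length(tokens))
      next
    }
    if (grepl("^&=", p)) next                          # event code
    if (grepl("^&", p)) next                           # phonological fragment
    if (grepl("^(xxx|yyy|www)$", p, ignore.case = TRUE)) {
      unintelligible <- unintelligible + 1L
      next
    }
    if (grepl("^\\+", p)) next                         # terminator codes
    if (grepl("^[.?!,;:]+$", p)) next                  # punctuation
    if (grepl("^0", p)) next                           # omitted word marker
    w <- gsub("[()]", "", p)                           # restore elisions
    w <- sub("@[a-z:]+$", "", w)                       # special-form suffix
    w <- tolower(gsub("[^a-z'+-]", "", tolower(w)))
    w <- gsub("^[-'+]+|[-'+]+$", "", w)
    if (nzchar(w)) tokens <- c(tokens, w)
  }

  list(tokens = tokens,
       fillers = length(filler_tokens),
       filler_tokens = filler_tokens,
       filler_positions = filler_positions,
       pauses = length(pause_lengths),
       pause_lengths = pause_lengths,
       pause_positions = pause_positions,
       retraced = retraced,
       unintelligible = unintelligible)
}

#' Parse a CHAT transcript
#'
#' Reads CHAT-format text, keeps only main tiers of the participant
#' (default tier code `PAR`), normalizes each tier via [normalizeTier()]
#' and returns a [TranscriptDoc-class]. Dependent tiers (`%...`), other
#' speakers and headers are dropped; `@ID` headers for the participant are
#' parsed into metadata when present. Continuation lines (leading tab) are
#' joined to the tier they continue. Empty input yields an empty document.
#'
#' @param text a single string of CHAT text, or a character vector of lines.
#' @param subject_id identifier for the document; defaults to the `@PID` /
#'   `@ID` code or `"unknown"`.
#' @param participant tier code treated as the participant (default "PAR").
#' @return a [TranscriptDoc-class].
#' @examples
#' doc <- parseChat("*PAR:\tthe boy is taking a cookie .")
#' docTokens(doc)
#' @export
parseChat <- function(text, subject_id = NULL, participant = "PAR") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else as.character(text)
  meta <- list()
  utts <- list()
  cur_speaker <- NULL
  cur_content <- NULL

  flush <- function() {
    if (is.null(cur_speaker)) return()
    if (identical(cur_speaker, participant)) {
      norm <- normalizeTier(cur_content)
      utts[[length(utts) + 1L]] <<- c(
        list(speaker = cur_speaker, raw = cur_content), norm)
    }
    cur_speaker <<- NULL; cur_content <<- NULL
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    first <- substr(ln, 1, 1)
    if (first == "\t" || first == " ") {              # continuation line
      if (!is.null(cur_speaker))
        cur_content <- paste(cur_content, trimws(ln))
      next
    }
    flush()
    if (first == "@") {
      if (grepl("^@ID:", ln)) {
        fields <- strsplit(trimws(sub("^@ID:", "", ln)), "|", fixed = TRUE)[[1]]
        if (length(fields) >= 5 && fields[3] == participant) {
          age <- suppressWarnings(as.numeric(sub(";.*$", "", fields[4])))
          if (!is.na(age)) meta$age <- age
          sx <- toupper(substr(fields[5], 1, 1))
          if (sx %in% c("M", "F")) meta$sex <- sx
          if (is.null(subject_id) && nzchar(fields[2]))
            subject_id <- fields[2]
        }
      }
      next
    }
    if (first == "%") next                            # dependent tier
    if (first == "*") {
      m <- regmatches(ln, regexec("^\\*([A-Za-z0-9]+):[ \t]?(.*)$", ln))[[1]]
      if (length(m) == 0)
        stop("malformed tier marker at line ", i, ": ", ln)
      cur_speaker <- m[2]
      cur_content <- m[3]
      next
    }
    stop("unrecognized CHAT line at line ", i, ": ", ln)
  }
  flush()

  new("TranscriptDoc",
      subjectId = if (is.null(subject_id)) "unknown" else subject_id,
      utterances = utts, meta = meta)
}

#' Serialize a transcript back to CHAT text
#'
#' Inverse of [parseChat()] on the supported dialect: emits headers, one
#' `*PAR:` tier per utterance with filled pauses (`&-um`) and pause marks
#' (`(.)`) re-inserted at their recorded positions.
#'
#' @param doc a [TranscriptDoc-class].
#' @return a single CHAT-format string.
#' @export
serializeChat <- function(doc) {
  meta <- doc@meta
  age <- if (is.null(meta$age)) "" else paste0(meta$age, ";")
  sex <- if (is.null(meta$sex)) "" else
    ifelse(meta$sex == "M", "male", "female")
  hdr <- c("@UTF8", "@Begin", "@Languages:\teng",
           paste0("@ID:\teng|", doc@subjectId, "|PAR|", age, "|", sex,
                  "|||Participant|||"))
  tiers <- vapply(doc@utterances, function(u) {
    items <- u$tokens
    # insert pauses then fillers from the back so positions stay valid
    ins <- rbind(
      if (length(u$pause_positions))
        data.frame(pos = u$pause_positions,
                   txt = vapply(u$pause_lengths, function(l)
                     paste0("(", strrep(".", l), ")"), ""))
      else NULL,
      if (length(u$filler_positions))
        data.frame(pos = u$filler_positions,
                   txt = paste0("&-", u$filler_tokens))
      else NULL)
    if (!is.null(ins) && nrow(ins)) {
      ins <- ins[order(-ins$pos), , drop = FALSE]
      for (j in seq_len(nrow(ins))) {
        p <- ins$pos[j]
        items <- append(items, ins$txt[j], after = p)
      }
    }
    paste0("*PAR:\t", paste(c(items, "."), collapse = " "))
  }, "")
  paste(c(hdr, tiers, "@End"), collapse = "\n")
}

#' Write a transcript to a .cha file
#' @param doc a [TranscriptDoc-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeChat <- function(doc, path) {
  writeLines(serializeChat(doc), path)
  invisible(path)
}

#' Read a PCM WAV file as a mono clip
#'
#' Minimal RIFF/WAVE reader for uncompressed PCM (8/16/32-bit integer).
#' Stereo input is mixed to mono by channel mean; amplitudes are scaled to
#' \[-1, 1\].
#'
#' @param path WAV file path.
#' @return an [AudioClip-class].
#' @export
readWavClip <- function(path) {
  if (!file.exists(path)) stop("cannot open WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format   = readBin(con, "integer", 1, 2, endian = "little"),
        channels = readBin(con, "integer", 1, 2, endian = "little"),
        rate     = readBin(con, "integer", 1, 4, endian = "little"),
        byterate = readBin(con, "integer", 1, 4, endian = "little"),
        align    = readBin(con, "integer", 1, 2, endian = "little"),
        bits     = readBin(con, "integer", 1, 2, endian = "little"))
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt chunk")
      bytes <- fmt$bits %/% 8
      n <- size %/% bytes
      data <- switch(as.character(fmt$bits),
        "8"  = (readBin(con, "integer", n, 1, signed = FALSE,
                        endian = "little") - 128) / 128,
        "16" = readBin(con, "integer", n, 2, endian = "little") / 32768,
        "32" = readBin(con, "integer", n, 4, endian = "little") / 2147483648,
        stop("unsupported bit depth: ", fmt$bits))
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(data)) stop("malformed WAV: no data chunk in ", path)
  if (!fmt$format %in% c(1L)) stop("unsupported WAV encoding: ", fmt$format)
  if (fmt$channels > 1) {
    data <- rowMeans(matrix(data, ncol = fmt$channels, byrow = TRUE))
  }
  new("AudioClip", samples = as.numeric(data), rate = fmt$rate)
}

#' Write a clip as 16-bit PCM WAV
#' @param clip an [AudioClip-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeWavClip <- function(clip, path) {
  x <- as.integer(.clip(round(clip@samples * 32768), -32768, 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # PCM
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(clip@rate), con, 4, endian = "little")
  writeBin(as.integer(clip@rate) * 2L, con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4, endian = "little")
  writeBin(x, con, 2, endian = "little")
  invisible(path)
}

#' Read a participant metadata table
#'
#' CSV with columns `subject_id,age,sex,label,mmse`; `label` and `mmse`
#' may be empty for unlabeled data.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readMeta <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "label", "mmse")
  if (!all(need %in% names(m)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  m
}
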