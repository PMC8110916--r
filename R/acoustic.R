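# The 187 acoustic/temporal features: MFCC frame moments, zero-crossing
# rate, fundamental frequency, energy-based silence segmentation and
# pause/duration statistics.

#' Frame specification
#'
#' Window length, hop and window function for short-time analysis.
#' Defaults: 25 ms Hann window, 10 ms hop.
#'
#' @param window_s window length in seconds.
#' @param hop_s hop in seconds; must satisfy 0 < hop <= window.
#' @param window window function name ("hann" or "rect").
#' @return list of class `FrameSpec`.
#' @export
frameSpec <- function(window_s = 0.025, hop_s = 0.010, window = "hann") {
  stopifnot(hop_s > 0, hop_s <= window_s)
  structure(list(window_s = window_s, hop_s = hop_s, window = window),
            class = "FrameSpec")
}

# signal -> frames matrix (win x nframes); returns NULL if too short
.frameSignal <- function(x, rate, spec) {
  win <- round(spec$window_s * rate)
  hop <- round(spec$hop_s * rate)
  n <- length(x)
  if (n < 2 * win) return(NULL)
  starts <- seq(1, n - win + 1, by = hop)
  mat <- matrix(x[outer(seq_len(win) - 1L, starts, `+`)], nrow = win)
  list(frames = mat, starts = starts, win = win, hop = hop)
}

.windowVector <- function(win, type) {
  if (type == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  else rep(1, win)
}

.hzToMel <- function(f) 2595 * log10(1 + f / 700)
.melToHz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank: nfilt x (nfft/2 + 1)
.melFilterbank <- function(nfilt, nfft, rate, fmin = 0, fmax = rate / 2) {
  mels <- seq(.hzToMel(fmin), .hzToMel(fmax), length.out = nfilt + 2)
  hz <- .melToHz(mels)
  bins <- floor((nfft + 1) * hz / rate)
  fb <- matrix(0, nfilt, nfft %/% 2 + 1)
  for (m in seq_len(nfilt)) {
    lo <- bins[m]; ce <- bins[m + 1]; hi <- bins[m + 2]
    if (ce == lo) ce <- lo + 1
    if (hi == ce) hi <- ce + 1
    for (k in lo:ce) if (k >= 0 && k <= nfft %/% 2 && ce > lo)
      fb[m, k + 1] <- (k - lo) / (ce - lo)
    for (k in ce:hi) if (k >= 0 && k <= nfft %/% 2 && hi > ce)
      fb[m, k + 1] <- (hi - k) / (hi - ce)
  }
  fb
}

# orthonormal DCT-II matrix rows 0..(ncoef-1), applied to nfilt energies
.dctMatrix <- function(ncoef, nfilt) {
  m <- outer(0:(ncoef - 1), 0:(nfilt - 1), function(k, n)
    cos(pi * k * (2 * n + 1) / (2 * nfilt)))
  m <- m * sqrt(2 / nfilt)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

# delta coefficients: regression over +/- 2 frames, edge-replicated
.deltas <- function(mat, N = 2L) {
  TT <- ncol(mat)
  if (TT == 1L) return(mat * 0)
  pad <- cbind(mat[, rep(1, N), drop = FALSE], mat,
               mat[, rep(TT, N), drop = FALSE])
  den <- 2 * sum((1:N)^2)
  out <- matrix(0, nrow(mat), TT)
  for (t in seq_len(TT)) {
    tc <- t + N
    acc <- 0
    for (n in 1:N) acc <- acc + n * (pad[, tc + n] - pad[, tc - n])
    out[, t] <- acc / den
  }
  out
}

#' Per-frame MFCC matrix
#'
#' 14 static mel-frequency cepstral coefficients per frame (including the
#' 0th energy coefficient), computed with a 26-filter mel bank over the
#' windowed power spectrum and an orthonormal DCT-II.
#'
#' @param clip an [AudioClip-class].
#' @param spec a [frameSpec()].
#' @param ncoef static coefficients to keep (default 14).
#' @param nfilt mel filters (default 26).
#' @return matrix ncoef x nframes, or NULL if the clip is shorter than two
#'   windows.
#' @export
mfccMatrix <- function(clip, spec = frameSpec(), ncoef = 14L, nfilt = 26L) {
  fr <- .frameSignal(samples(clip), sampleRate(clip), spec)
  if (is.null(fr)) return(NULL)
  win <- fr$win
  nfft <- 2^ceiling(log2(win))
  w <- .windowVector(win, spec$window)
  frames <- fr$frames * w
  padded <- rbind(frames, matrix(0, nfft - win, ncol(frames)))
  spec_fft <- stats::mvfft(padded)
  power <- (Mod(spec_fft[1:(nfft %/% 2 + 1), , drop = FALSE])^2) / nfft
  fb <- .melFilterbank(nfilt, nfft, sampleRate(clip))
  melE <- fb %*% power
  melE[melE < 1e-30] <- 1e-30
  dct <- .dctMatrix(ncoef, nfilt)
  dct %*% log(melE)
}

#' MFCC frame-moment features
#'
#' 42 coefficients per frame (14 static + 14 delta + 14 delta-delta), each
#' summarized across frames by mean, variance, skewness and excess
#' kurtosis: 168 features.
#'
#' @inheritParams mfccMatrix
#' @return named numeric vector of length 168; all NA for clips shorter
#'   than two analysis windows.
#' @export
mfccMomentFeatures <- function(clip, spec = frameSpec()) {
  reg <- featureRegistry()
  nm <- reg$name[reg$family == "mfcc"]
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  cc <- mfccMatrix(clip, spec)
  if (is.null(cc)) return(out)
  blocks <- list(cc, .deltas(cc), .deltas(.deltas(cc)))
  prefixes <- c("", "d_", "dd_")
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    for (i in 1:14) {
      mom <- .seriesMoments(b[i, ])
      out[paste0("mfcc", sprintf("%02d", i), "_", prefixes[bi],
                 .MOMENT_STATS)] <- mom
    }
  }
  out
}

#' Zero-crossing-rate and fundamental-frequency features
#'
#' Per-frame zero-crossing rate (crossings per second of the frame) is
#' summarized by mean/variance/skewness/kurtosis. F0 is estimated on
#' voiced frames (relative energy above threshold, autocorrelation peak
#' strength above `voicing_thresh`) as the autocorrelation peak in the
#' 75--500 Hz lag range, summarized by mean/min/max/median.
#'
#' @inheritParams mfccMatrix
#' @param f0_range allowed F0 range in Hz.
#' @param voicing_thresh minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @return named numeric vector of length 8; F0 entries NA when no frame
#'   is voiced.
#' @export
zcrF0Features <- function(clip, spec = frameSpec(),
                          f0_range = c(75, 500), voicing_thresh = 0.3) {
  out <- stats::setNames(rep(NA_real_, 8L),
                         c(paste0("zcr_", .MOMENT_STATS),
                           "f0_mean", "f0_min", "f0_max", "f0_median"))
  rate <- sampleRate(clip)
  fr <- .frameSignal(samples(clip), rate, spec)
  if (is.null(fr)) return(out)
  frames <- fr$frames
  win <- fr$win

  s <- sign(frames); s[s == 0] <- 1
  crossings <- colSums(s[-1, , drop = FALSE] != s[-win, , drop = FALSE])
  zcr <- crossings / (win / rate)
  out[paste0("zcr_", .MOMENT_STATS)] <- .seriesMoments(zcr)

  energy <- colMeans(frames^2)
  eThresh <- max(energy) * 1e-4
  lagMin <- max(2L, floor(rate / f0_range[2]))
  lagMax <- min(win - 1L, ceiling(rate / f0_range[1]))
  if (lagMax <= lagMin) return(out)
  # autocorrelation of every frame at once via FFT (Wiener-Khinchin)
  keep <- which(energy > eThresh)
  f0s <- numeric(0)
  if (length(keep)) {
    fr2 <- frames[, keep, drop = FALSE]
    fr2 <- sweep(fr2, 2, colMeans(fr2))
    nfft <- 2^ceiling(log2(win + lagMax))
    padded <- rbind(fr2, matrix(0, nfft - win, ncol(fr2)))
    sp <- stats::mvfft(padded)
    ac <- Re(stats::mvfft(Mod(sp)^2, inverse = TRUE)) / nfft
    denom <- ac[1, ]
    ok <- denom > 0
    acn <- ac[(lagMin + 1L):(lagMax + 1L), ok, drop = FALSE] /
      matrix(denom[ok], lagMax - lagMin + 1L, sum(ok), byrow = TRUE)
    pk <- apply(acn, 2, which.max)
    pkv <- acn[cbind(pk, seq_along(pk))]
    voiced <- pkv >= voicing_thresh
    f0s <- rate / (lagMin + pk[voiced] - 1L)
  }
  if (length(f0s)) {
    out["f0_mean"] <- mean(f0s)
    out["f0_min"] <- min(f0s)
    out["f0_max"] <- max(f0s)
    out["f0_median"] <- stats::median(f0s)
  }
  out
}

#' Energy-based silence segmentation
#'
#' A frame is silent when its log-energy falls `threshold_db` below the
#' clip's median frame log-energy; silent runs of at least `min_pause_s`
#' become pause segments. Segments are non-overlapping, ordered and tile
#' the clip. Thresholds are relative, so segmentation is invariant to
#' global amplitude scaling.
#'
#' @inheritParams mfccMatrix
#' @param threshold_db drop below median log-energy declaring silence.
#' @param min_pause_s minimum silent run counted as a pause.
#' @return data.frame with columns `start`, `end` (seconds), `kind`
#'   ("speech"/"pause").
#' @export
silenceSegmentation <- function(clip, spec = frameSpec(),
                                threshold_db = 20, min_pause_s = 0.15) {
  rate <- sampleRate(clip)
  dur <- clipDuration(clip)
  fr <- .frameSignal(samples(clip), rate, spec)
  if (is.null(fr))
    return(data.frame(start = 0, end = dur, kind = "speech"))
  energy <- colMeans(fr$frames^2)
  logE <- 10 * log10(pmax(energy, 1e-12))
  thr <- stats::median(logE) - threshold_db
  silent <- logE < thr

  times <- (fr$starts - 1) / rate
  hop_s <- fr$hop / rate
  segs <- data.frame(start = numeric(0), end = numeric(0),
                     kind = character(0))
  r <- rle(silent)
  idx <- cumsum(c(1, r$lengths))
  for (j in seq_along(r$values)) {
    i0 <- idx[j]; i1 <- idx[j + 1] - 1
    s <- times[i0]
    e <- if (i1 < length(times)) times[i1] + hop_s else dur
    kind <- if (r$values[j] && (e - s) >= min_pause_s) "pause" else "speech"
    segs <- rbind(segs, data.frame(start = s, end = e, kind = kind))
  }
  # merge adjacent same-kind segments (short silences folded into speech)
  merged <- segs[1, ]
  if (nrow(segs) > 1) for (j in 2:nrow(segs)) {
    if (segs$kind[j] == merged$kind[nrow(merged)]) {
      merged$end[nrow(merged)] <- segs$end[j]
    } else merged <- rbind(merged, segs[j, ])
  }
  merged$end[nrow(merged)] <- dur
  merged
}

#' Pause, filler and duration features
#'
#' From the silence segmentation and the transcript: total and mean pause
#' duration, long (>= `long_s`) and short (in \[`min_pause_s`, `long_s`))
#' pause counts, pause-count:word-count ratio, filler count (um + uh, from
#' the transcript), filler:word ratio, pause-duration:speech-duration
#' ratio, pause-duration:word-count ratio, and total audio and speech
#' durations.
#'
#' @param clip an [AudioClip-class].
#' @param seg segmentation from [silenceSegmentation()] (recomputed when
#'   NULL).
#' @param doc the subject's [TranscriptDoc-class] (word/filler counts).
#' @param long_s long-pause threshold in seconds.
#' @param spec a [frameSpec()] for recomputing the segmentation.
#' @return named numeric vector of length 11; word-ratio entries NA when
#'   the transcript has no words.
#' @export
pauseDurationFeatures <- function(clip, seg = NULL, doc = NULL,
                                  long_s = 1.0, spec = frameSpec()) {
  nm <- c("pause_total_dur", "pause_mean_dur", "pause_long_count",
          "pause_short_count", "pause_word_ratio", "filler_count",
          "filler_word_ratio", "pause_speech_ratio", "pause_per_word_dur",
          "dur_audio", "dur_speech")
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (is.null(seg)) seg <- silenceSegmentation(clip, spec)
  durs <- seg$end - seg$start
  isP <- seg$kind == "pause"
  pauseDur <- sum(durs[isP])
  speechDur <- sum(durs[!isP])
  out["pause_total_dur"] <- pauseDur
  out["pause_mean_dur"] <- if (any(isP)) mean(durs[isP]) else 0
  out["pause_long_count"] <- sum(isP & durs >= long_s)
  out["pause_short_count"] <- sum(isP & durs < long_s)
  out["pause_speech_ratio"] <- .safeRatio(pauseDur, speechDur)
  out["dur_audio"] <- clipDuration(clip)
  out["dur_speech"] <- speechDur

  nWords <- 0L; nFillers <- 0L
  if (!is.null(doc)) {
    nWords <- sum(vapply(utterances(doc), function(u) length(u$tokens), 1L))
    nFillers <- sum(vapply(utterances(doc), function(u)
      sum(u$filler_tokens %in% c("um", "uh")), 1L))
  }
  out["filler_count"] <- nFillers
  if (nWords > 0) {
    out["pause_word_ratio"] <- sum(isP) / nWords
    out["filler_word_ratio"] <- nFillers / nWords
    out["pause_per_word_dur"] <- pauseDur / nWords
  }
  out
}

#' All acoustic features for one subject
#'
#' Assembles the 187-feature acoustic family block (pauses/fillers, F0,
#' durations, ZCR, MFCC moments) in registry order.
#'
#' @inheritParams pauseDurationFeatures
#' @return named numeric vector of length 187.
#' @export
acousticFeatures <- function(clip, doc = NULL, spec = frameSpec()) {
  seg <- silenceSegmentation(clip, spec)
  pd <- pauseDurationFeatures(clip, seg, doc, spec = spec)
  zf <- zcrF0Features(clip, spec)
  c(pd[c("pause_total_dur", "pause_mean_dur", "pause_long_count",
         "pause_short_count", "pause_word_ratio", "filler_count",
         "filler_word_ratio", "pause_speech_ratio", "pause_per_word_dur")],
    zf[c("f0_mean", "f0_min", "f0_max", "f0_median")],
    pd[c("dur_audio", "dur_speech")],
    zf[paste0("zcr_", .MOMENT_STATS)],
    mfccMomentFeatures(clip, spec))
}
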