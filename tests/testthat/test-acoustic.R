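makeClip <- function(x, rate = 16000) new("AudioClip", samples = x,
                                          rate = rate)

test_that("MFCC block has the right shape and constant signals have zero
           spread moments", {
  t <- seq(0, 2, by = 1 / 16000)
  clip <- makeClip(0.5 * sin(2 * pi * 440 * t))
  f <- mfccMomentFeatures(clip)
  expect_length(f, 168)
  expect_true(all(is.finite(f)))

  # perfectly periodic signal aligned with the hop -> identical frames
  rate <- 16000
  frame <- sin(2 * pi * 100 * seq(0, 0.16, by = 1 / rate))[1:(rate * 0.16)]
  clip2 <- makeClip(rep(frame, 20), rate)
  f2 <- mfccMomentFeatures(clip2)
  expect_lt(max(abs(f2[grep("_var$", names(f2))])), 1e-10)

  short <- makeClip(numeric(100))
  expect_true(all(is.na(mfccMomentFeatures(short))))
})

test_that("per-coefficient MFCC means match a direct per-frame DFT
           recomputation", {
  t <- seq(0, 1, by = 1 / 8000)
  clip <- makeClip(0.7 * sin(2 * pi * 440 * t), 8000)
  got <- mfccMatrix(clip)

  # independent recomputation: loop over frames, plain DFT sums
  spec <- frameSpec()
  win <- round(spec$window_s * 8000); hop <- round(spec$hop_s * 8000)
  x <- samples(clip)
  starts <- seq(1, length(x) - win + 1, by = hop)
  nfft <- 2^ceiling(log2(win))
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  fb <- speechAD:::.melFilterbank(26, nfft, 8000)
  dct <- speechAD:::.dctMatrix(14, 26)
  for (j in c(1, 5, length(starts))) {
    fr <- x[starts[j]:(starts[j] + win - 1)] * hann
    fr <- c(fr, numeric(nfft - win))
    k <- 0:(nfft / 2)
    dft <- vapply(k, function(kk)
      abs(sum(fr * exp(-2i * pi * kk * (0:(nfft - 1)) / nfft)))^2 / nfft, 1)
    mel <- as.numeric(fb %*% dft)
    mel[mel < 1e-30] <- 1e-30
    ref <- as.numeric(dct %*% log(mel))
    expect_equal(got[, j], ref, tolerance = 1e-6)
  }
})

test_that("square-wave ZCR equals the analytic crossing rate", {
  rate <- 16000
  k <- 0:(rate - 1)
  # cosine phase puts every sign change mid-window, so each 25 ms frame
  # holds exactly 5 crossings of the 100 Hz square wave
  sq <- sign(cos(2 * pi * 100 * k / rate))
  f <- zcrF0Features(makeClip(sq, rate))
  expect_equal(unname(f["zcr_mean"]), 200)
  expect_equal(unname(f["zcr_var"]), 0)
})

test_that("F0 of a pure tone is recovered within 5 Hz", {
  t <- seq(0, 2, by = 1 / 16000)
  f <- zcrF0Features(makeClip(0.5 * sin(2 * pi * 440 * t)))
  expect_lt(abs(f["f0_median"] - 440), 5)
  expect_lt(abs(f["f0_mean"] - 440), 5)

  silent <- zcrF0Features(makeClip(numeric(16000)))
  expect_true(all(is.na(silent[c("f0_mean", "f0_min", "f0_max",
                                 "f0_median")])))
  expect_equal(unname(silent["zcr_mean"]), 0)
})

test_that("moment features match brute force on the stored frame series", {
  set.seed(5)
  x <- rnorm(500)
  expect_equal(speechAD:::.seriesMoments(x), oracleMoments(x),
               tolerance = 1e-12)
})

test_that("planted silences segment into long and short pauses", {
  rate <- 16000
  tone <- function(d) 0.5 * sin(2 * pi * 300 * seq(0, d, by = 1 / rate))
  x <- c(tone(1), numeric(1.2 * rate), tone(1), numeric(0.3 * rate),
         tone(1))
  clip <- makeClip(x, rate)
  seg <- silenceSegmentation(clip)
  expect_equal(seg$end[-nrow(seg)], seg$start[-1])  # tiles the clip
  expect_equal(seg$start[1], 0)
  expect_equal(seg$end[nrow(seg)], clipDuration(clip))

  doc <- parseChat("*PAR:\tthe boy is on the stool .")
  f <- pauseDurationFeatures(clip, seg, doc)
  expect_equal(unname(f["pause_long_count"]), 1)
  expect_equal(unname(f["pause_short_count"]), 1)
  expect_equal(unname(f["pause_total_dur"]), 1.5, tolerance = 0.08)
  expect_equal(unname(f["dur_audio"]), clipDuration(clip))
  expect_equal(unname(f["dur_speech"] + f["pause_total_dur"]),
               clipDuration(clip), tolerance = 0.05)
  expect_equal(unname(f["filler_count"]), 0)

  # no silence at all
  solid <- makeClip(tone(2), rate)
  fs <- pauseDurationFeatures(solid, doc = doc)
  expect_equal(unname(fs["pause_long_count"]), 0)
  expect_equal(unname(fs["pause_total_dur"]), 0)
  expect_equal(unname(fs["dur_speech"]), clipDuration(solid))
})

test_that("filler ratios come from the transcript", {
  doc <- parseChat(paste(rep("*PAR:\t&-um the boy is taking a cookie .",
                             5), collapse = "\n"))
  t <- seq(0, 1, by = 1 / 16000)
  f <- pauseDurationFeatures(makeClip(sin(880 * t)), doc = doc)
  expect_equal(unname(f["filler_count"]), 5)
  expect_equal(unname(f["filler_word_ratio"]), 5 / 30)
})

test_that("features are invariant to global amplitude scaling", {
  coh <- tinyCohort()
  clip <- coh@clips[[1]]
  doc <- coh@docs[[1]]
  base <- acousticFeatures(clip, doc)
  for (k in c(0.5, 2)) {
    scaled <- new("AudioClip", samples = samples(clip) * k,
                  rate = sampleRate(clip))
    f <- acousticFeatures(scaled, doc)
    idx <- grep("^(pause|dur|zcr|f0)", names(base))
    expect_equal(f[idx], base[idx], tolerance = 1e-6)
  }
})

test_that("the acoustic block emits exactly 187 features in registry
           order", {
  coh <- tinyCohort()
  f <- acousticFeatures(coh@clips[[1]], coh@docs[[1]])
  reg <- featureRegistry()
  expect_equal(names(f), reg$name[reg$category == "acoustic"])
})
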