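test_that("minimal well-formed records parse to participant utterances", {
  doc <- parseChat("*PAR:\tthe boy is taking a cookie .")
  expect_length(utterances(doc), 1)
  expect_equal(docTokens(doc)[[1]],
               c("the", "boy", "is", "taking", "a", "cookie"))

  expect_length(utterances(parseChat("*INV:\tokay .")), 0)
  expect_length(utterances(parseChat("")), 0)
})

test_that("fillers, pauses and CHAT codes normalize as documented", {
  doc <- parseChat("*PAR:\t&-um the boy (.) fell .")
  u <- utterances(doc)[[1]]
  expect_equal(u$tokens, c("the", "boy", "fell"))
  expect_equal(u$fillers, 1)
  expect_equal(u$filler_tokens, "um")
  expect_equal(u$pauses, 1)

  n <- normalizeTier("the the [/] dog")
  expect_equal(n$tokens, c("the", "dog"))
  expect_equal(n$retraced, 1)

  n2 <- normalizeTier("xxx .")
  expect_equal(n2$tokens, character(0))
  expect_equal(n2$unintelligible, 1)

  n3 <- normalizeTier("&-uh water (...) overflowing")
  expect_equal(n3$tokens, c("water", "overflowing"))
  expect_equal(n3$fillers, 1)
  expect_equal(n3$pauses, 1)
  expect_equal(n3$pause_lengths, 3L)

  n4 <- normalizeTier("<the water is> [//] the tap is running &=laughs")
  expect_equal(n4$tokens, c("the", "tap", "is", "running"))
})

test_that("malformed tier markers raise an error naming the line", {
  expect_error(parseChat("*:\tno speaker ."), "line 1")
  expect_error(parseChat(c("*PAR:\tfine .", "garbage line")), "line 2")
})

test_that("header metadata is parsed for the participant", {
  doc <- parseChat(fixtureChatText())
  expect_equal(docMeta(doc)$age, 67)
  expect_equal(docMeta(doc)$sex, "M")
  expect_equal(subjectId(doc), "fix01")
  expect_length(utterances(doc), 4)  # investigator and %mor dropped
})

test_that("participant token counts match hand counts on the fixture", {
  doc <- parseChat(fixtureChatText())
  # hand counts: 6, 4 (um excluded), 5 (retracing excised), 4 (xxx dropped)
  expect_equal(vapply(utterances(doc), function(u) length(u$tokens), 1L),
               c(6L, 4L, 5L, 4L))
})

test_that("serialize/parse round-trips the supported CHAT subset", {
  doc <- parseChat(fixtureChatText())
  doc2 <- parseChat(serializeChat(doc))
  expect_equal(docTokens(doc2), docTokens(doc))
  expect_equal(lapply(utterances(doc2), `[[`, "fillers"),
               lapply(utterances(doc), `[[`, "fillers"))
  expect_equal(lapply(utterances(doc2), `[[`, "pause_lengths"),
               lapply(utterances(doc), `[[`, "pause_lengths"))
  # parsing is deterministic
  expect_identical(docTokens(parseChat(fixtureChatText())), docTokens(doc))
})

test_that("WAV round-trip error stays within the quantization step", {
  t <- seq(0, 1, by = 1 / 16000)
  clip <- new("AudioClip", samples = 0.8 * sin(2 * pi * 440 * t),
              rate = 16000)
  path <- tempfile(fileext = ".wav")
  writeWavClip(clip, path)
  back <- readWavClip(path)
  expect_equal(sampleRate(back), 16000)
  expect_length(samples(back), length(samples(clip)))
  expect_lt(max(abs(samples(back) - samples(clip))), 1 / 32767)
})

test_that("silence and stereo clips read as specified", {
  path <- tempfile(fileext = ".wav")
  writeWavClip(new("AudioClip", samples = numeric(16000), rate = 16000),
               path)
  z <- readWavClip(path)
  expect_length(samples(z), 16000)
  expect_true(all(samples(z) == 0))

  # hand-written stereo file with identical channels reads as its mono mix
  x <- as.integer(round(sin(2 * pi * 100 * seq(0, 0.1, by = 1 / 8000)) *
                          10000))
  inter <- as.vector(rbind(x, x))
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(inter) * 2), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(2L, con, 2, endian = "little")       # stereo
  writeBin(8000L, con, 4, endian = "little")
  writeBin(32000L, con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(length(inter) * 2L, con, 4, endian = "little")
  writeBin(inter, con, 2, endian = "little")
  close(con)
  st <- readWavClip(path)
  expect_equal(samples(st), x / 32768, tolerance = 1e-12)
  expect_error(readWavClip(tempfile()), "cannot|No such|not a")
})
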