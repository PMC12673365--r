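# Tone synthesis, partial removal, morphing and loudness matching.

pure_spec <- function(n_partials = 1, noise = 0, attack = 0) {
  amps <- numeric(max(n_partials, 10))
  amps[seq_len(n_partials)] <- 1
  tone_spec("pure", partial_amps = amps, noise_level = noise,
            attack_level = attack, duration = 1)
}

test_that("synthesis is deterministic given a seed", {
  spec <- tone_presets()$flute
  a <- synth_tone(spec, seed = 11)
  b <- synth_tone(spec, seed = 11)
  expect_identical(a$samples, b$samples)
  c <- synth_tone(spec, seed = 12)
  expect_false(identical(a$samples, c$samples))
})

test_that("a one-partial spec synthesizes a pure tone at f0", {
  a <- synth_tone(pure_spec(), seed = 1)
  expect_equal(spectral_centroid(a), 261.63, tolerance = 0.02)
  sp <- mean_spectrum(a)
  expect_equal(sp$freq[which.max(sp$mag_db)], 261.63,
               tolerance = 44100 / 4096)
})

test_that("removing the only partial of a sine leaves near silence", {
  a <- synth_tone(pure_spec(), seed = 1)
  r <- remove_partials(a, 1, f0 = 261.63)
  expect_lt(sqrt(mean(r$samples^2)), 0.001 * sqrt(mean(a$samples^2)))
})

test_that("removing the fundamental of a two-partial tone moves the centroid to 2 f0", {
  a <- synth_tone(pure_spec(2), seed = 1)
  r <- remove_partials(a, 1, f0 = 261.63)
  expect_equal(spectral_centroid(r), 2 * 261.63, tolerance = 44100 / 4096)
})

test_that("partial removal composes and preserves the inter-notch floor", {
  a <- synth_tone(tone_presets()$violin, seed = 5)
  r3 <- remove_partials(a, 3, f0 = 261.63)
  r23 <- remove_partials(remove_partials(a, 2, f0 = 261.63), 3,
                         f0 = 261.63)
  expect_lt(max(abs(r3$samples - r23$samples)), 1e-9)
  # the noise floor between notches is untouched (within 1 dB), while the
  # notched partials are attenuated by 60 dB or more
  fa <- abs(fft(a$samples)); fr <- abs(fft(r3$samples))
  n <- length(fa)
  f <- pmin((seq_len(n) - 1), n - (seq_len(n) - 1)) * 44100 / n
  dist <- abs(f - round(f / 261.63) * 261.63)
  between <- dist > 33 & f > 100 & f < 5000
  expect_lt(max(abs(20 * log10(fr[between] / fa[between]))), 1)
  at <- which(dist <= 5 & round(f / 261.63) %in% 1:3 & f < 1000)
  expect_lt(20 * log10(max(fr[at]) / max(fa[at])), -60)
})

test_that("partials above Nyquist are rejected", {
  a <- synth_tone(pure_spec(), seed = 1)
  expect_error(remove_partials(a, 100, f0 = 261.63), "Nyquist")
  expect_error(tone_spec("x", f0 = 5000, partial_amps = rep(1, 10)),
               "Nyquist")
})

test_that("morph endpoints reproduce the inputs and midpoints interpolate", {
  p <- tone_presets()
  a <- loudness_match(synth_tone(p$horn, seed = 1))
  b <- loudness_match(synth_tone(p$violin, seed = 2))
  m0 <- morph(a, b, 0); m1 <- morph(a, b, 1); m5 <- morph(a, b, 0.5)
  expect_equal(spectral_centroid(m0), spectral_centroid(a),
               tolerance = 0.01)
  expect_equal(harmonicity_strength(m0), harmonicity_strength(a),
               tolerance = 0.01)
  expect_equal(spectral_centroid(m1), spectral_centroid(b),
               tolerance = 0.01)
  ca <- spectral_centroid(a); cb <- spectral_centroid(b)
  cm <- spectral_centroid(m5)
  expect_gt(cm, min(ca, cb))
  expect_lt(cm, max(ca, cb))
  short <- audio(a$samples[1:1000], a$sample_rate)
  wrong_rate <- audio(b$samples, 48000)
  expect_error(morph(a, wrong_rate, 0.5), "sample rates")
  expect_error(morph(a, short, 0.5), "lengths")
})

test_that("morph ratios follow the seven-stage design", {
  expect_equal(morph_stages(), c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1))
})

test_that("loudness matching lands every stimulus on the target", {
  p <- tone_presets()
  set <- list(synth_tone(p$flute, seed = 1), synth_tone(p$piano, seed = 2),
              synth_tone(p$horn, seed = 3))
  matched <- loudness_match(set, target_lufs = -30)
  lufs <- vapply(matched, loudness_lufs, numeric(1))
  expect_true(all(abs(lufs - (-30)) <= 0.1))
  expect_lt(diff(range(lufs)), 0.2)          # pairwise spread
  expect_true(all(vapply(matched, function(a)
    max(abs(a$samples)), numeric(1)) <= 1))  # no clipping

  # an already-matched input gets unit gain; half amplitude needs gain 2
  again <- loudness_match(matched[[1]], target_lufs = -30)
  expect_equal(attr(again, "gains")[1], 1, tolerance = 0.01)
  halved <- audio(matched[[1]]$samples / 2, 44100)
  rematched <- loudness_match(halved, target_lufs = -30)
  expect_equal(attr(rematched, "gains")[1], 2, tolerance = 0.02)

  expect_error(loudness_match(audio(numeric(44100), 44100)), "silence")
})
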