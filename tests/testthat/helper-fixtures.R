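# Shared fixtures. The partial-reduction stimulus set and the calibrated
# cohort are expensive to build, so they are cached per session; everything
# is generated in code from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, expr, envir = .fixture_cache)
  .fixture_cache[[key]]
}

study_partial_features <- function(seed = 1L) {
  cached(paste0("sf", seed), partial_study_features(seed = seed))
}

study_cohort <- function(seed = 1L) {
  cached(paste0("cohort", seed), make_cohort(seed = seed))
}

sine_audio <- function(freq = 440, dur = 1, sr = 44100, amp = 0.5) {
  audio(amp * sin(2 * pi * freq * (seq_len(round(dur * sr)) - 1) / sr), sr)
}

# A feature table with the study's qualitative structure (centroid rising,
# harmonicity falling, percussive loudness rising over the reduction
# levels) but no audio behind it — for fast simulator tests.
toy_features <- function(instruments = c("flute", "violin", "horn",
                                         "piano", "oboe"),
                         n_levels = 10L) {
  rows <- lapply(instruments, function(ins) {
    lv <- 0:n_levels
    data.frame(stimulus_id = paste0(ins, "_k", lv), instrument = ins,
               type = ifelse(lv == 0, "original", "partial"), level = lv,
               spectral_centroid = 800 + 250 * lv,
               harmonicity_strength = 0.9 - 0.06 * lv,
               percussive_loudness = -55 + 1.8 * lv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
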