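# Low-level signal plumbing shared by the stimulus and feature modules:
# an invertible short-time Fourier transform (Hann analysis window, weighted
# overlap-add resynthesis), the ITU-R BS.1770 gated loudness meter, minimal
# PCM WAV read/write, and a seed-scoped RNG helper.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' Short-time Fourier transform
#'
#' One-sided STFT with a periodic Hann window. The signal is zero-padded by
#' half a window on both sides so that frames are centred on the original
#' samples; [istft()] inverts the transform by weighted overlap-add.
#'
#' @param x numeric signal.
#' @param n_fft window/FFT length in samples.
#' @param hop hop size in samples.
#' @return complex matrix, `n_fft/2 + 1` frequency bins by frames, with
#'   attributes `n_fft`, `hop`, `n_samples`.
#' @keywords internal
stft <- function(x, n_fft = 4096L, hop = 1024L) {
  if (length(x) < n_fft / 2) stop("input shorter than one analysis window")
  pad <- n_fft %/% 2L
  xp <- c(numeric(pad), x, numeric(pad))
  n_frames <- 1L + (length(xp) - n_fft) %/% hop
  w <- hann_window(n_fft)
  idx <- outer(seq_len(n_fft), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- matrix(xp[idx], nrow = n_fft) * w
  spec <- stats::mvfft(frames)[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
  structure(spec, n_fft = n_fft, hop = hop, n_samples = length(x))
}

#' Inverse short-time Fourier transform
#'
#' @param spec complex one-sided spectrogram as returned by [stft()] (or a
#'   modified copy carrying the same attributes).
#' @param n_samples output length; defaults to the length recorded by
#'   [stft()].
#' @return numeric signal.
#' @keywords internal
istft <- function(spec, n_samples = attr(spec, "n_samples")) {
  n_fft <- attr(spec, "n_fft")
  hop <- attr(spec, "hop")
  full <- rbind(spec, Conj(spec[(n_fft %/% 2L):2L, , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / n_fft
  w <- hann_window(n_fft)
  frames <- frames * w
  n_frames <- ncol(frames)
  out_len <- n_fft + (n_frames - 1L) * hop
  y <- numeric(out_len)
  wsum <- numeric(out_len)
  for (j in seq_len(n_frames)) {
    i <- (j - 1L) * hop
    y[(i + 1L):(i + n_fft)] <- y[(i + 1L):(i + n_fft)] + frames[, j]
    wsum[(i + 1L):(i + n_fft)] <- wsum[(i + 1L):(i + n_fft)] + w^2
  }
  y <- y / pmax(wsum, 1e-12)
  pad <- n_fft %/% 2L
  y[(pad + 1L):(pad + n_samples)]
}

stft_bin_freqs <- function(spec, sample_rate) {
  n_fft <- attr(spec, "n_fft")
  (seq_len(nrow(spec)) - 1L) * sample_rate / n_fft
}

# --- ITU-R BS.1770 loudness -------------------------------------------------

# K-weighting prefilter biquads for an arbitrary sample rate. The shelving
# and high-pass parametrisation reproduces the coefficient table printed in
# BS.1770-4 at fs = 48 kHz (asserted in the test suite).
k_weighting_coefficients <- function(sample_rate) {
  shelf <- {
    f0 <- 1681.9744509555319; G <- 3.99984385397; Q <- 0.7071752369554193
    K <- tan(pi * f0 / sample_rate)
    Vh <- 10^(G / 20)
    Vb <- Vh^0.499666774155
    a0 <- 1 + K / Q + K^2
    list(b = c(Vh + Vb * K / Q + K^2, 2 * (K^2 - Vh), Vh - Vb * K / Q + K^2) / a0,
         a = c(1, 2 * (K^2 - 1) / a0, (1 - K / Q + K^2) / a0))
  }
  highpass <- {
    f0 <- 38.13547087602444; Q <- 0.5003270373238773
    K <- tan(pi * f0 / sample_rate)
    a0 <- 1 + K / Q + K^2
    list(b = c(1, -2, 1),
         a = c(1, 2 * (K^2 - 1) / a0, (1 - K / Q + K^2) / a0))
  }
  list(shelf = shelf, highpass = highpass)
}

k_weight <- function(x, sample_rate) {
  co <- k_weighting_coefficients(sample_rate)
  y <- signal::filter(co$shelf$b, co$shelf$a, x)
  as.numeric(signal::filter(co$highpass$b, co$highpass$a, y))
}

#' Integrated loudness per ITU-R BS.1770
#'
#' Gated loudness measurement of a mono signal: K-weighting prefilter
#' (high-shelf plus high-pass), mean square over 400 ms blocks with 75 %
#' overlap, an absolute gate at -70 LUFS and a relative gate 10 LU below the
#' absolutely-gated level.
#'
#' @param x numeric mono signal or an audio object from [synth_tone()].
#' @param sample_rate sample rate in Hz (taken from the audio object when
#'   one is given).
#' @return integrated loudness in LUFS. When no block passes the absolute
#'   gate the floor value -70 is returned with attribute `gated_out = TRUE`.
#' @export
loudness_lufs <- function(x, sample_rate = NULL) {
  if (is_audio(x)) {
    sample_rate <- x$sample_rate
    x <- x$samples
  }
  if (is.null(sample_rate)) stop("sample_rate is required for a bare signal")
  if (all(x == 0)) stop("cannot measure the loudness of digital silence")
  y <- k_weight(x, sample_rate)
  block <- round(0.400 * sample_rate)
  step <- round(0.100 * sample_rate)
  if (length(y) < block) stop("signal shorter than one 400 ms gating block")
  starts <- seq(1L, length(y) - block + 1L, by = step)
  ms <- vapply(starts, function(i) mean(y[i:(i + block - 1L)]^2), numeric(1))
  lb <- -0.691 + 10 * log10(pmax(ms, 1e-30))
  keep <- lb > -70
  if (!any(keep))
    return(structure(-70, gated_out = TRUE))
  ungated <- -0.691 + 10 * log10(mean(ms[keep]))
  keep2 <- keep & lb > (ungated - 10)
  if (!any(keep2)) keep2 <- keep
  structure(-0.691 + 10 * log10(mean(ms[keep2])), gated_out = FALSE)
}

# --- minimal PCM WAV i/o ----------------------------------------------------

#' Read and write mono PCM WAV files
#'
#' Minimal RIFF/WAVE support for the stimulus set: mono, 16- or 24-bit
#' integer PCM. Samples are scaled to \[-1, 1\].
#'
#' @param path file path.
#' @param audio audio object (see [synth_tone()]).
#' @param bits bit depth, 16 or 24.
#' @return `read_wav` returns an audio object; `write_wav` returns `path`
#'   invisibly.
#' @export
write_wav <- function(audio, path, bits = 16L) {
  stopifnot(is_audio(audio), bits %in% c(16L, 24L))
  x <- pmin(pmax(audio$samples, -1), 1)
  scale <- 2^(bits - 1) - 1
  ints <- as.integer(round(x * scale))
  bytes_per <- bits %/% 8L
  data_size <- length(ints) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(audio$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(audio$sample_rate * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16L) {
    writeBin(ints, con, size = 2, endian = "little")
  } else {
    raw3 <- vapply(ints, function(v) {
      if (v < 0) v <- v + 2^24
      as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256))
    }, raw(3))
    writeBin(as.vector(raw3), con)
  }
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, raw(), n = size)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      n_channels <- as.integer(fmt[3]) + 256L * as.integer(fmt[4])
      rate <- sum(as.integer(fmt[5:8]) * 256^(0:3))
      bits <- as.integer(fmt[15]) + 256L * as.integer(fmt[16])
      if (n_channels != 1L) stop("only mono WAV is supported")
      if (!bits %in% c(16L, 24L)) stop("only 16/24-bit PCM is supported")
      if (bits == 16L) {
        x <- readBin(con, integer(), n = size %/% 2L, size = 2,
                     signed = TRUE, endian = "little") / (2^15 - 1)
      } else {
        raw_data <- readBin(con, raw(), n = size)
        m <- matrix(as.integer(raw_data), nrow = 3)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        v <- ifelse(v >= 2^23, v - 2^24, v)
        x <- v / (2^23 - 1)
      }
      return(audio(x, rate, provenance = list(op = "read_wav", path = path)))
    } else {
      invisible(readBin(con, raw(), n = size + size %% 2L))
    }
  }
}
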