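#' Front-end configuration
#'
#' Bundles the parameters of the acoustic front-end: Rasta-PLP static
#' coefficients plus delta and delta-delta appended by a 5-tap FIR
#' regression filter, computed on 15 ms Hamming-windowed frames with 50 %
#' overlap at 16 kHz.
#'
#' @param F Number of static PLP cepstral coefficients (the PLP model
#'   order); even, between 10 and 20. The feature dimension is \code{3 * F}.
#' @param frame_length Frame length in seconds (default 0.015).
#' @param frame_shift Frame shift in seconds; fixed at half the frame
#'   length (50 % overlap).
#' @param rasta Apply RASTA band-pass filtering of the log critical-band
#'   energies (default \code{TRUE}).
#' @param delta_filter_len Length of the FIR derivative filter (default 5,
#'   i.e. a regression over \code{+/-} 2 frames).
#' @param sample_rate Sample rate in Hz; the front-end operates at 16 kHz.
#' @return An object of class \code{frontend_config}.
#' @export
frontend_config <- function(F = 12L, frame_length = 0.015,
                            frame_shift = frame_length / 2,
                            rasta = TRUE, delta_filter_len = 5L,
                            sample_rate = 16000L) {
  F <- as.integer(F)
  if (F %% 2L != 0L || F < 10L || F > 20L)
    stop("F must be an even integer in 10..20")
  if (abs(frame_shift - frame_length / 2) > 1e-12)
    stop("frame_shift must equal frame_length / 2 (50% overlap)")
  if (delta_filter_len != 5L) stop("delta filter length is fixed at 5")
  structure(list(F = F, frame_length = frame_length,
                 frame_shift = frame_shift, rasta = isTRUE(rasta),
                 delta_filter_len = 5L,
                 sample_rate = as.integer(sample_rate)),
            class = "frontend_config")
}

#' Per-utterance feature matrix
#'
#' Container for the N x D matrix of frame feature vectors together with
#' frame-center times, as produced by the front-end or by the feature-mode
#' synthetic corpus generator.
#'
#' @param values Numeric N x D matrix, one row per frame.
#' @param frame_times Numeric vector of N frame-center times in seconds.
#' @param utterance_id Utterance identifier.
#' @return An object of class \code{frame_matrix}.
#' @export
frame_matrix <- function(values, frame_times, utterance_id = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) != length(frame_times))
    stop("frame_times length must match the number of rows")
  if (nrow(values) > 0 && !all(is.finite(values))) stop("non-finite feature values")
  structure(list(values = values, frame_times = as.numeric(frame_times),
                 utterance_id = utterance_id),
            class = "frame_matrix")
}

#' @export
print.frame_matrix <- function(x, ...) {
  cat(sprintf("<frame_matrix> %s: %d frames x %d dims, %.3f s\n",
              x$utterance_id, nrow(x$values), ncol(x$values),
              if (length(x$frame_times)) max(x$frame_times) else 0))
  invisible(x)
}

#' @export
dim.frame_matrix <- function(x) dim(x$values)

#' Load a waveform and normalize it for the front-end
#'
#' Reads (or accepts) a mono waveform, low-pass filters and downsamples it
#' to the target rate when the source rate is higher, and peak-normalizes
#' the amplitude to \code{max |s| = 1}. An all-zero signal is returned as
#' zeros (no division by zero). Source rates below the target are an
#' error: the analysis bandwidth is defined at 16 kHz and upsampling would
#' fabricate spectrum.
#'
#' @param x Path to a WAV file, or a numeric waveform with a
#'   \code{sample_rate} attribute (or \code{sample_rate} passed).
#' @param target_sr Target sample rate in Hz (default 16000).
#' @param sample_rate Source rate in Hz when \code{x} is a bare numeric
#'   vector.
#' @param channel Channel selector forwarded to [read_wav()].
#' @return Numeric waveform at \code{target_sr}, peak-normalized, with the
#'   \code{sample_rate} attribute set.
#' @export
load_and_normalize <- function(x, target_sr = 16000L, sample_rate = NULL,
                               channel = NULL) {
  if (is.character(x)) x <- read_wav(x, channel = channel)
  sr <- attr(x, "sample_rate") %||% sample_rate
  if (is.null(sr)) stop("source sample rate unknown")
  x <- as.numeric(x)
  if (sr < target_sr) stop("source rate below ", target_sr, " Hz; upsampling is not supported")
  if (sr > target_sr) {
    g <- gcd_int(as.integer(target_sr), as.integer(sr))
    n_out <- round(length(x) * target_sr / sr)
    x <- as.numeric(signal::resample(x, target_sr / g, sr / g))
    # polyphase resampler may over/under-run by a sample; fix the length
    if (length(x) > n_out) x <- x[seq_len(n_out)]
    if (length(x) < n_out) x <- c(x, numeric(n_out - length(x)))
  }
  m <- max(abs(x))
  if (m > 0) x <- x / m
  attr(x, "sample_rate") <- as.integer(target_sr)
  x
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Extract Rasta-PLP + delta + delta-delta features
#'
#' Implements the perceptual linear prediction front-end on 15 ms / 50 %
#' overlap Hamming frames: power spectrum, Bark-scale critical-band
#' integration, equal-loudness pre-emphasis, RASTA band-pass filtering of
#' the log band energies (when enabled), intensity-loudness power law
#' (cube root), an autoregressive model of order \code{F} via
#' Levinson-Durbin, and the cepstral recursion keeping coefficients
#' \code{c1..cF} (the energy term \code{c0} is excluded). Delta and
#' delta-delta coefficients are appended with [append_deltas()], giving
#' \code{D = 3 * F} columns.
#'
#' @param wave Numeric waveform at 16 kHz (see [load_and_normalize()]).
#' @param config A [frontend_config()].
#' @return A [frame_matrix()] with \code{3 * F} columns and frame-center
#'   times \code{(i - 1) * frame_shift + frame_length / 2}.
#' @export
extract_rasta_plp <- function(wave, config = frontend_config()) {
  sr <- config$sample_rate
  flen <- round(config$frame_length * sr)
  fshift <- round(config$frame_shift * sr)
  x <- as.numeric(wave)
  if (length(x) < flen) stop("waveform shorter than one frame")

  n_frames <- floor((length(x) - flen) / fshift) + 1L
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(flen - 1L)) / (flen - 1L))
  nfft <- 2^ceiling(log2(flen))
  starts <- (seq_len(n_frames) - 1L) * fshift

  # power spectrum, one row per frame
  pspec <- matrix(0, n_frames, nfft / 2 + 1L)
  for (i in seq_len(n_frames)) {
    fr <- x[starts[i] + seq_len(flen)] * win
    sp <- stats::fft(c(fr, numeric(nfft - flen)))
    pspec[i, ] <- Mod(sp[seq_len(nfft / 2 + 1L)])^2
  }

  fb <- bark_filterbank(sr, nfft)
  aspec <- pspec %*% t(fb$weights)              # N x nbands
  # equal-loudness pre-emphasis on the critical-band spectrum
  aspec <- sweep(aspec, 2L, equal_loudness(fb$center_hz), "*")

  if (config$rasta) {
    la <- log(pmax(aspec, 1e-40))
    la <- apply(la, 2L, rasta_filter)
    aspec <- exp(la)
  }
  aspec <- aspec^0.33                           # intensity-loudness power law

  # duplicate edge bands, even-symmetric IDFT -> autocorrelation
  nb <- ncol(aspec)
  aug <- cbind(aspec[, 1L], aspec, aspec[, nb])
  n_aug <- nb + 2L
  sym <- cbind(aug, aug[, seq(n_aug - 1L, 2L), drop = FALSE])
  r <- t(apply(sym, 1L, function(s) {
    Re(stats::fft(s, inverse = TRUE))[seq_len(config$F + 1L)] / length(s)
  }))

  static <- t(apply(r, 1L, function(ri) {
    lpc_to_cepstra(levinson_durbin(ri, config$F), config$F)
  }))
  feats <- append_deltas(static, config$delta_filter_len)
  times <- (seq_len(n_frames) - 1L) * config$frame_shift + config$frame_length / 2
  frame_matrix(feats, times)
}

# RASTA band-pass on one band's log-energy trajectory: FIR numerator
# 0.2, 0.1, 0, -0.1, -0.2 (zero DC gain) over pole 0.94.
rasta_filter <- function(x) {
  b <- c(0.2, 0.1, 0, -0.1, -0.2)
  as.numeric(signal::filter(b, c(1, -0.94), x))
}

hz2bark <- function(hz) 6 * asinh(hz / 600)
bark2hz <- function(z) 600 * sinh(z / 6)

# Trapezoidal critical-band filters on the FFT bin grid, unit Bark spacing.
bark_filterbank <- function(sr, nfft) {
  nyq_bark <- hz2bark(sr / 2)
  nbands <- ceiling(nyq_bark) + 1L
  bin_bark <- hz2bark(seq(0L, nfft / 2) * sr / nfft)
  centers <- (seq_len(nbands) - 1L) * nyq_bark / (nbands - 1L)
  w <- matrix(0, nbands, nfft / 2 + 1L)
  for (b in seq_len(nbands)) {
    d <- bin_bark - centers[b]
    w[b, ] <- 10^pmin(0, pmin(d + 0.5, -2.5 * (d - 0.5)))
  }
  list(weights = w, center_hz = bark2hz(centers))
}

# Equal-loudness weighting E(w) evaluated at the band center frequencies.
equal_loudness <- function(hz) {
  w2 <- (2 * pi * hz)^2
  ((w2 + 56.8e6) * w2^2) / ((w2 + 6.3e6)^2 * (w2 + 0.38e9))
}

# Levinson-Durbin recursion: autocorrelation r[0..p] -> AR coefficients
# a[1..p] of A(z) = 1 + sum a_k z^-k. Degenerate (flat/zero) spectra give
# zero coefficients.
levinson_durbin <- function(r, p) {
  if (r[1] <= 0 || abs(r[1]) < 1e-300) return(numeric(p))
  a <- numeric(p)
  e <- r[1]
  for (m in seq_len(p)) {
    acc <- r[m + 1L]
    if (m > 1L) acc <- acc + sum(a[seq_len(m - 1L)] * r[m:2])
    k <- -acc / e
    a_new <- a
    a_new[m] <- k
    if (m > 1L) a_new[seq_len(m - 1L)] <- a[seq_len(m - 1L)] + k * a[(m - 1L):1]
    a <- a_new
    e <- e * (1 - k^2)
    if (e <= 0) break
  }
  a
}

# Cepstra c1..cF of the all-pole model 1/A(z) (gain term c0 dropped).
lpc_to_cepstra <- function(a, F) {
  cc <- numeric(F)
  for (m in seq_len(F)) {
    am <- if (m <= length(a)) a[m] else 0
    s <- 0
    if (m > 1L) {
      for (k in seq_len(m - 1L)) {
        amk <- if ((m - k) <= length(a)) a[m - k] else 0
        s <- s + k * cc[k] * amk
      }
    }
    cc[m] <- -am - s / m
  }
  cc
}

#' Append delta and delta-delta coefficients
#'
#' Applies the length-5 antisymmetric linear-regression FIR filter
#' (taps proportional to \code{-2,-1,0,1,2}, normalized by 10) to each
#' static coefficient trajectory, with edge frames replicated so the frame
#' count is preserved; the same filter applied to the deltas gives the
#' delta-deltas.
#'
#' @param static Numeric N x F matrix of static coefficients.
#' @param filter_len FIR length; fixed at 5.
#' @return Numeric N x 3F matrix \code{[static, delta, delta-delta]}.
#' @export
append_deltas <- function(static, filter_len = 5L) {
  static <- as.matrix(static)
  if (filter_len != 5L) stop("delta filter length is fixed at 5")
  d1 <- delta_fir(static)
  d2 <- delta_fir(d1)
  cbind(static, d1, d2)
}

delta_fir <- function(m) {
  n <- nrow(m)
  pad <- rbind(m[rep(1L, 2L), , drop = FALSE], m, m[rep(n, 2L), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (k in -2:2) {
    if (k == 0) next
    out <- out + (k / 10) * pad[(3L + k):(n + 2L + k), , drop = FALSE]
  }
  out
}
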