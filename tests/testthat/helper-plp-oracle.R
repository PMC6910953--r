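# Independently coded reference implementation of the Rasta-PLP static
# coefficients: explicit loops, autocorrelation by direct cosine sums,
# AR coefficients by solving the Toeplitz normal equations, cepstra from
# the FFT of the log AR spectrum. Shares only the published recipe
# constants with the package implementation.
oracle_rasta_plp_static <- function(x, F, rasta = TRUE, sr = 16000) {
  flen <- 240L; fshift <- 120L; nfft <- 256L
  n <- floor((length(x) - flen) / fshift) + 1L
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(flen - 1)) / (flen - 1))
  hz2b <- function(f) 6 * asinh(f / 600)
  nyqb <- hz2b(sr / 2)
  nb <- ceiling(nyqb) + 1L
  centers <- (0:(nb - 1)) * nyqb / (nb - 1)
  binb <- hz2b((0:(nfft / 2)) * sr / nfft)

  E <- matrix(0, n, nb)
  for (i in seq_len(n)) {
    fr <- x[((i - 1) * fshift + 1):((i - 1) * fshift + flen)] * ham
    sp <- Mod(stats::fft(c(fr, numeric(nfft - flen)))[1:(nfft / 2 + 1)])^2
    for (b in seq_len(nb)) {
      w <- 10^pmin(0, pmin(binb - centers[b] + 0.5,
                           -2.5 * (binb - centers[b] - 0.5)))
      E[i, b] <- sum(w * sp)
    }
  }
  eql <- function(f) {
    w2 <- (2 * pi * f)^2
    ((w2 + 56.8e6) * w2^2) / ((w2 + 6.3e6)^2 * (w2 + 0.38e9))
  }
  for (b in seq_len(nb)) E[, b] <- E[, b] * eql(600 * sinh(centers[b] / 6))

  if (rasta) {
    bb <- c(0.2, 0.1, 0, -0.1, -0.2)
    for (b in seq_len(nb)) {
      lx <- log(pmax(E[, b], 1e-40))
      y <- numeric(n)
      for (t in seq_len(n)) {
        acc <- 0
        for (k in 0:4) if (t - k >= 1) acc <- acc + bb[k + 1] * lx[t - k]
        if (t > 1) acc <- acc + 0.94 * y[t - 1]
        y[t] <- acc
      }
      E[, b] <- exp(y)
    }
  }
  E <- E^0.33

  static <- matrix(0, n, F)
  B <- nb + 2L
  for (i in seq_len(n)) {
    a <- c(E[i, 1], E[i, ], E[i, nb])
    r <- numeric(F + 1L)
    for (k in 0:F) {
      s <- a[1] + (-1)^k * a[B]
      for (j in 1:(B - 2)) s <- s + 2 * a[j + 1] * cos(pi * j * k / (B - 1))
      r[k + 1] <- s / (2 * (B - 1))
    }
    if (r[1] <= 0) next
    ar <- tryCatch(-solve(stats::toeplitz(r[1:F]), r[2:(F + 1)]),
                   error = function(e) numeric(F))
    Nf <- 1024L
    Aw <- stats::fft(c(1, ar, numeric(Nf - F - 1L)))
    # for minimum-phase A the IDFT of log(1/|A|^2) is the complex cepstrum
    q <- Re(stats::fft(log(1 / Mod(Aw)^2), inverse = TRUE)) / Nf
    static[i, ] <- q[2:(F + 1)]
  }
  static
}
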