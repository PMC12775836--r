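# Internal numerical helpers: DPSS tapers, 1/f noise, Welch PSD.

.dpss_cache <- new.env(parent = emptyenv())

# Discrete prolate spheroidal sequences via the symmetric tridiagonal
# eigenproblem (Percival & Walden).  n samples, time-bandwidth product nw,
# k tapers.  Columns are unit-energy tapers, most concentrated first.
dpss_tapers <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  i <- seq_len(n) - 1
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  A <- diag(d)
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- e
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- e
  eg <- eigen(A, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  # unit energy; conventional sign: symmetric tapers have positive mean,
  # antisymmetric ones a positive initial upslope
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    s <- sum(v[, j])
    if (abs(s) > 1e-8) { if (s < 0) v[, j] <- -v[, j] }
    else if (v[2, j] - v[1, j] < 0) v[, j] <- -v[, j]
  }
  .dpss_cache[[key]] <- v
  v
}

# 1/f^a Gaussian noise via spectral shaping; returns an n-vector of unit
# variance (approximately).
pink_noise <- function(n, exponent = 1) {
  nf <- n %/% 2 + 1
  f <- seq_len(nf) - 1
  amp <- c(0, f[-1]^(-exponent / 2))
  re <- stats::rnorm(nf) * amp
  im <- stats::rnorm(nf) * amp
  im[1] <- 0
  if (n %% 2 == 0) im[nf] <- 0
  spec <- complex(real = re, imaginary = im)
  full <- c(spec, Conj(rev(spec[2:(nf - 1 + n %% 2)])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Welch power spectral density with a Hann window.  x sampled at fs Hz;
# segment length nseg samples, 50% overlap.  Returns freq (Hz) and psd
# (units^2 / Hz) so that sum(psd) * df approximates var(x).
welch_psd <- function(x, fs, nseg) {
  n <- length(x)
  nseg <- min(nseg, n)
  step <- max(1, floor(nseg / 2))
  starts <- seq(1, n - nseg + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  u <- sum(win^2)
  nf <- nseg %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * win)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / (u * fs)
  }
  psd <- acc / length(starts)
  # one-sided: double all bins except DC (and Nyquist if present)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / nseg, psd = psd * dbl)
}

# trapezoidal band integral of a PSD
band_power <- function(freq, psd, lo, hi) {
  sel <- freq >= lo & freq <= hi
  if (sum(sel) < 2) return(0)
  f <- freq[sel]; p <- psd[sel]
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

# centred moving average over w samples, edges padded by replication
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  pad <- w %/% 2
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  y <- as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))
  y[pad + seq_along(x)]
}
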