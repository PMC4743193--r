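# Zero-phase Butterworth band-pass, implemented as a cascade of biquad
# (second-order) sections. Expanding an order-4 band-pass into a single
# degree-8 polynomial is numerically fragile when the lower corner sits far
# below Nyquist (roots crowd near z = 1); factored sections keep the
# forward-backward filter linear to ~1e-12. Edge transients are suppressed
# by odd-reflection padding spanning a few periods of the lowest pass-band
# frequency.

design_bandpass <- function(order, low_hz, high_hz, fs) {
  k <- seq_len(order)
  proto <- exp(1i * (pi / 2 + pi * (2 * k - 1) / (2 * order)))  # LHP circle
  w1 <- 2 * fs * tan(pi * low_hz / fs)   # prewarped corner frequencies
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  disc <- sqrt((bw * proto)^2 - 4 * w0^2)
  poles_s <- c((bw * proto + disc) / 2, (bw * proto - disc) / 2)
  poles_z <- (2 * fs + poles_s) / (2 * fs - poles_s)            # bilinear
  up <- poles_z[Im(poles_z) > 0]
  if (length(up) != order)
    stop("internal: band-pass pole pairing failed")  # not reachable for valid bands
  sections <- lapply(up, function(p)
    c(1, -2 * Re(p), Mod(p)^2))  # denominator; numerator is (1, 0, -1)
  # unit gain at the (digital) centre frequency, applied once per pass
  zc <- exp(-1i * 2 * atan(w0 / (2 * fs)))
  h <- vapply(sections, function(a)
    (1 - zc^2) / (1 + a[2] * zc + a[3] * zc^2), complex(1))
  list(sections = sections, gain = 1 / prod(Mod(h)),
       pad = as.integer(ceiling(3 * fs / low_hz)))
}

sos_pass <- function(des, x) {
  for (a in des$sections)
    x <- as.numeric(signal::filter(signal::Arma(b = c(1, 0, -1), a = a), x))
  des$gain * x
}

zerophase_bandpass <- function(des, x) {
  n <- length(x)
  npad <- min(n - 1L, des$pad)
  ext <- c(2 * x[1] - x[(npad + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - npad)])
  ext <- sos_pass(des, ext)
  ext <- rev(sos_pass(des, rev(ext)))
  ext[(npad + 1):(npad + n)]
}
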