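# Published orthonormal wavelet coefficients (sum = sqrt(2)), used as
# independent references for bandwidth and vanishing-moment checks.
DB2_H <- c(0.48296291314469025, 0.836516303737469,
           0.22414386804185735, -0.12940952255092145)
DB6_H <- c(-0.00107730108530848, 0.00477725751094551, 0.000553842201161496,
           -0.03158203931748603, 0.02752286553030573, 0.09750160558732304,
           -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
           0.75113390802109544, 0.49462389039845306, 0.11154074335010947)
SYM6_H <- c(0.01540410932702737, 0.00349071208421747, -0.11799011114819057,
            -0.04831174258563300, 0.49105594192674662, 0.78764114103019400,
            0.33792942172762180, -0.07263752278646252, -0.02106029251230056,
            0.04472490177066578, 0.00176771186424280, -0.00780070832503415)

# the designed length-12 / 4-VM bank is expensive enough to cache per session
testBankEnv <- new.env(parent = emptyenv())
omsbmBank <- function() {
  if (is.null(testBankEnv$fb))
    testBankEnv$fb <- designMinBandwidthFilter(12L, 4L, 5L)
  testBankEnv$fb
}

# numerical quadrature oracle for the mean-squared bandwidth:
# (1/2pi) Int_-pi^pi w^2 |H(w)|^2 dw, independent of the closed form
quadratureBandwidth <- function(h) {
  f <- function(w) {
    sapply(w, function(wi) {
      H <- sum(h * exp(-1i * wi * (0:(length(h) - 1))))
      wi^2 * Mod(H)^2 / (2 * pi)
    })
  }
  integrate(f, -pi, pi, subdivisions = 2000L, rel.tol = 1e-10)$value
}

simpleEpochSet <- function(n = 10, nSamp = 128, fs = 64, nc = 2, seed = 1) {
  set.seed(seed)
  dat <- array(rnorm(n * nSamp * nc), dim = c(n, nSamp, nc),
               dimnames = list(NULL, NULL, paste0("ch", seq_len(nc))))
  new("EpochSet", data = dat,
      labels = factor(rep(c("A", "B"), length.out = n), levels = c("A", "B")),
      epochLen = nSamp / fs, fs = fs, subject = rep("t", n))
}
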