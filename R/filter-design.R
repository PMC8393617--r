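## Design of the minimum RMS-bandwidth orthogonal wavelet filter.
##
## The mean-squared bandwidth of a lowpass filter h is
##   B^2 = (1/2pi) Int_{-pi}^{pi} w^2 |H(w)|^2 dw
##       = (pi^2/3) r[0] + 4 sum_{k>=1} (-1)^k r[k] / k^2
## with r the autocorrelation of h. For an orthogonal filter r[0] = 1 and all
## non-zero even lags vanish, so B^2 is a *linear* functional of the odd-lag
## autocorrelation values, and the design problem
##   minimize B^2(r)  s.t.  r orthogonal, p vanishing moments, R(w) >= 0
## is convex. We solve it as a semi-infinite linear program: moment and
## orthogonality equalities are eliminated analytically (null-space
## parameterization), the spectral nonnegativity R(w) >= 0 is enforced on a
## frequency grid refined by a cutting-plane exchange loop, and each LP is
## solved by a log-barrier interior-point iteration. The structural zero of
## order 2p at w = pi (forced by the moment constraints) is divided out in
## the Chebyshev basis so the barrier stays well conditioned near pi.
## The lowpass itself is then recovered by spectral factorization.

#' Autocorrelation sequence of a filter
#'
#' Deterministic (non-circular) autocorrelation \code{r[k] = sum_n h[n] h[n+k]}
#' for lags \code{0..length(h)-1}.
#'
#' @param h numeric coefficient vector.
#' @return numeric vector of lag values, lag 0 first.
#' @export
autocorrelation <- function(h) {
  L <- length(h)
  vapply(0:(L - 1L), function(k) sum(h[1:(L - k)] * h[(1 + k):L]), 0.0)
}

## R(w) = r[0] + 2 sum r[k] cos(wk), evaluated for a full lag vector
evalSpectrum <- function(r, w) {
  ks <- seq_along(r)[-1] - 1L
  r[1] + 2 * drop(cos(outer(w, ks)) %*% r[-1])
}

## Autocorrelation of the length-2p Daubechies filter, zero-padded to L lags.
## Used as a strictly feasible interior start: its spectrum is the maxflat
## halfband R(w) = 2 cos(w/2)^{2p} sum_j C(p-1+j, j) sin(w/2)^{2j}, positive
## everywhere except for an exact order-2p zero at pi.
daubechiesAutocorrelation <- function(p, L = 2L * p) {
  stopifnot(p >= 1, L >= 2 * p)
  a <- 1
  for (i in seq_len(p))
    a <- convolve(c(a, 0), rev(c(0.5, 0.5)), type = "open")
  s <- 0
  for (j in 0:(p - 1)) {
    pw <- 1
    for (i in seq_len(j))
      pw <- convolve(c(pw, 0), rev(c(0.5, -0.5)), type = "open")
    tt <- choose(p - 1 + j, j) * pw
    n <- max(length(s), length(tt))
    s <- c(s, numeric(n - length(s))) + c(tt, numeric(n - length(tt)))
  }
  Rpow <- 2 * convolve(c(a, numeric(length(s) - 1)),
                       rev(c(s, numeric(length(a) - 1))), type = "open")[1:(2 * p)]
  ## power basis (in x = cos w) -> Chebyshev -> lag values
  n <- length(Rpow) - 1L
  Tk <- list(1, c(0, 1))
  if (n >= 2) for (k in 2:n)
    Tk[[k + 1]] <- (c(0, 2 * Tk[[k]]) - c(Tk[[k - 1]], 0, 0))[1:(k + 1)]
  M <- matrix(0, n + 1, n + 1)
  for (k in 0:n) M[1:(k + 1), k + 1] <- Tk[[k + 1]]
  cheb <- solve(M, Rpow)
  r <- numeric(L)
  r[1] <- cheb[1]
  if (length(cheb) > 1) r[seq_along(cheb)[-1]] <- cheb[-1] / 2
  r
}

## Divide a Chebyshev-coefficient polynomial by (x + 1), assuming the
## remainder is structurally zero; least-squares solve of the banded system.
chebDivideByXPlus1 <- function(cc) {
  n <- length(cc) - 1L
  A <- matrix(0, n + 1, n)
  for (j in 0:(n - 1)) {
    col <- j + 1L
    A[j + 1, col] <- A[j + 1, col] + 1
    A[j + 2, col] <- A[j + 2, col] + 0.5
    if (j == 0) A[2, col] <- A[2, col] + 0.5
    else if (j == 1) A[1, col] <- A[1, col] + 0.5
    else A[j, col] <- A[j, col] + 0.5
  }
  qr.solve(A, cc)
}

evalChebyshev <- function(cc, x) {
  n <- length(cc) - 1L
  T0 <- rep(1, length(x)); T1 <- x
  out <- cc[1] * T0
  if (n >= 1) out <- out + cc[2] * T1
  if (n >= 2) for (k in 2:n) {
    T2 <- 2 * x * T1 - T0
    out <- out + cc[k + 1] * T2
    T0 <- T1; T1 <- T2
  }
  out
}

## Chebyshev coefficients of Q = R / (2 + 2x)^p for a full lag vector r
lagsToDeflatedCheb <- function(r, p) {
  q <- c(r[1], 2 * r[-1])
  for (i in seq_len(p)) q <- chebDivideByXPlus1(q) / 2
  q
}

#' Minimum mean-squared-bandwidth orthogonal autocorrelation
#'
#' Solves the convex filter-design program: minimize the mean-squared
#' bandwidth \code{B^2(r)} over autocorrelation sequences of length \code{L}
#' subject to unit energy (\code{r[0] = 1}), double-shift orthogonality
#' (zero even lags), \code{p} vanishing moments (a zero of order \code{2p}
#' of the spectrum at \code{w = pi}) and spectral nonnegativity
#' \code{R(w) >= 0}.
#'
#' @param L even filter length, \code{L >= 2}.
#' @param p number of vanishing moments, \code{1 <= p <= L/2}.
#' @return named list with \code{r} (full lag vector, lag 0 first),
#'   \code{b_sq} (the minimized mean-squared bandwidth, radians^2/sample^2)
#'   and \code{minR} (minimum of the spectrum over a dense grid).
#' @export
minBandwidthAutocorrelation <- function(L, p) {
  if (length(L) != 1L || L %% 2 != 0 || L < 2)
    stop("L must be a single even integer >= 2")
  if (length(p) != 1L || p < 1 || p > L / 2)
    stop(sprintf("p must satisfy 1 <= p <= L/2 = %d (infeasible otherwise)", L / 2))
  L <- as.integer(L); p <- as.integer(p)
  ks <- seq(1L, L - 1L, by = 2L)
  m <- length(ks)
  full <- function(rodd) { r <- numeric(L); r[1] <- 1; r[ks + 1] <- rodd; r }

  ## moment equalities on the odd lags (scaled for conditioning)
  Aeq <- rbind(rep(1, m)); beq <- 0.5
  if (p >= 2) for (j in 1:(p - 1)) {
    Aeq <- rbind(Aeq, (ks / (L - 1))^(2 * j)); beq <- c(beq, 0)
  }
  r0odd <- drop(MASS::ginv(Aeq) %*% beq)
  N <- pracma::nullspace(Aeq)
  rdb <- daubechiesAutocorrelation(p, L)

  if (is.null(N) || ncol(N) == 0L) {
    ## fully determined (p = L/2): the maxflat/Daubechies autocorrelation
    r <- rdb
    dense <- seq(0, pi, length.out = 20001)
    return(list(r = r, b_sq = bandwidthFromLags(r), minR = min(evalSpectrum(r, dense))))
  }
  d <- ncol(N)
  cvec <- drop((1 / ks^2) %*% N)  # B^2 = pi^2/3 - 4 * sum r[k]/k^2: maximize cvec.t
  t0 <- drop(t(N) %*% (rdb[ks + 1] - r0odd))
  if (max(abs(r0odd + drop(N %*% t0) - rdb[ks + 1])) > 1e-8)
    stop("internal error: interior start not in the constraint subspace")

  ## affine map t -> Chebyshev coefficients of the deflated spectrum Q
  q0 <- lagsToDeflatedCheb(full(r0odd), p)
  Qcols <- vapply(seq_len(d), function(j) {
    rj <- numeric(L); rj[ks + 1] <- N[, j]
    lagsToDeflatedCheb(rj, p)
  }, numeric(L - p))

  solveBarrier <- function(xs, t, t0) {
    B0 <- evalChebyshev(q0, xs)
    Bm <- vapply(seq_len(d), function(j) evalChebyshev(Qcols[, j], xs),
                 numeric(length(xs)))
    if (is.null(dim(Bm))) Bm <- matrix(Bm, nrow = length(xs))
    qv <- function(t) B0 + drop(Bm %*% t)
    lam <- 0
    while (!all(qv(t) > 0) && lam < 1) { lam <- lam + 0.05; t <- t + 0.05 * (t0 - t) }
    if (!all(qv(t) > 0)) t <- t0
    mu <- 1e-2
    while (mu > 1e-12) {
      for (it in 1:50) {
        s <- qv(t)
        g <- -cvec - mu * drop(t(Bm) %*% (1 / s))
        H <- mu * t(Bm) %*% (Bm / s^2)
        dt <- tryCatch(-solve(H, g),
                       error = function(e) -drop(MASS::ginv(H) %*% g))
        lam2 <- -sum(g * dt)
        if (!is.finite(lam2) || lam2 < 1e-16) break
        a <- 1
        while (a > 1e-14 && !all(qv(t + a * dt) > 0)) a <- a / 2
        fobj <- function(tt) -sum(cvec * tt) - mu * sum(log(qv(tt)))
        f0 <- fobj(t)
        while (a > 1e-14 && fobj(t + a * dt) > f0 - 0.25 * a * lam2) a <- a / 2
        if (a <= 1e-14) break
        t <- t + a * dt
      }
      mu <- mu / 10
    }
    t
  }

  xs <- cos(seq(0, pi, length.out = 1025))
  dense <- seq(0, pi, length.out = 20001)
  t <- t0
  r <- NULL; Rd <- NULL
  for (outer in 1:12) {
    t <- solveBarrier(xs, t, t0)
    r <- full(r0odd + drop(N %*% t))
    Rd <- evalSpectrum(r, dense)
    viol <- which(Rd < -1e-10)
    if (!length(viol)) break
    runs <- split(viol, cumsum(c(1, diff(viol) > 1)))
    news <- vapply(runs, function(ix) dense[ix[which.min(Rd[ix])]], 0.0)
    news <- vapply(news, function(w0)
      optimize(function(w) evalSpectrum(r, w),
               c(max(0, w0 - 2e-3), min(pi, w0 + 2e-3)))$minimum, 0.0)
    xs <- sort(unique(c(xs, cos(news))))
  }
  if (min(Rd) < -1e-8)
    stop("cutting-plane refinement did not reach a nonnegative spectrum; solver stalled")
  list(r = r, b_sq = bandwidthFromLags(r), minR = min(Rd))
}

bandwidthFromLags <- function(r) {
  ks <- seq_along(r)[-1] - 1L
  pi^2 / 3 * r[1] + 4 * sum((-1)^ks * r[-1] / ks^2)
}

#' Spectral factorization of an autocorrelation sequence
#'
#' Recovers a real lowpass filter \code{h} with \code{autocorrelation(h) = r}
#' by root splitting of the product polynomial. Zeros at \code{z = -1} are
#' deflated analytically and assigned half their multiplicity; the remaining
#' roots are split by reciprocal pairs under the minimum-phase convention
#' (smallest-modulus half kept). Two Gauss-Newton polish stages follow, both
#' constrained to keep the \code{(1+z)^p} factor exact: the first fits
#' \code{autocorrelation(h)} to \code{r}, the second enforces the even-lag
#' orthogonality conditions to machine precision. \code{h} is scaled to unit
#' energy with \code{sum(h) > 0}.
#'
#' @param r autocorrelation lag vector (lag 0 first), with \code{r[0] > 0}
#'   and a nonnegative spectrum.
#' @return numeric lowpass coefficient vector of the same length.
#' @export
spectralFactorize <- function(r) {
  L <- length(r)
  if (L < 2) stop("r must have length >= 2")
  dense <- seq(0, pi, length.out = 8192)
  if (min(evalSpectrum(r, dense)) < -1e-7 * r[1])
    stop("spectral density is negative beyond tolerance; project R(w) onto the nonnegative cone before factorization")

  pc <- c(rev(r[-1]), r)               # ascending coefficients of z^{L-1} P(z)
  q <- pc; nAtMinus1 <- 0L
  repeat {
    val <- sum(q * (-1)^(seq_along(q) - 1L))
    if (abs(val) > 1e-7 * sum(abs(q))) break
    n <- length(q) - 1L
    b <- numeric(n); b[n] <- q[n + 1]
    if (n >= 2) for (i in (n - 1):1) b[i] <- q[i + 1] - b[i + 1]
    q <- b; nAtMinus1 <- nAtMinus1 + 1L
    if (length(q) == 1L) break
  }
  if (nAtMinus1 %% 2L != 0L)
    stop("odd multiplicity of the zero at z = -1; r is not a valid autocorrelation")
  vm <- nAtMinus1 %/% 2L

  keep <- complex(0)
  if (length(q) > 1L) {
    rt <- polyroot(q)
    rt <- rt[order(Mod(rt))]
    keep <- rt[seq_len(length(rt) %/% 2L)]
    near <- abs(Mod(keep) - 1) < 1e-3   # touching double roots split radially
    keep[near] <- exp(1i * Arg(keep[near]))
  }
  bb <- 1 + 0i
  for (z0 in keep) bb <- c(bb, 0) - c(0, bb) * z0
  b <- Re(bb)                           # reduced factor, length L - vm

  bin <- choose(vm, 0:vm)               # exact (1 + z)^vm factor
  nb <- L - vm
  C <- matrix(0, L, nb)
  for (j in seq_len(nb)) C[j:(j + vm), j] <- bin
  h <- drop(C %*% b)
  sc <- sqrt(r[1] / sum(h^2)); b <- b * sc; h <- h * sc
  if (sum(h) < 0) { b <- -b; h <- -h }

  acfJac <- function(h, lags) {
    J <- matrix(0, length(lags), L)
    for (i in seq_along(lags)) {
      k <- lags[i]
      for (n in seq_len(L)) {
        v <- 0
        if (n + k <= L) v <- v + h[n + k]
        if (n - k >= 1) v <- v + h[n - k]
        J[i, n] <- v
      }
    }
    J
  }
  ## stage 1: fit the full autocorrelation
  allLags <- 0:(L - 1L)
  for (it in 1:40) {
    h <- drop(C %*% b)
    Fv <- autocorrelation(h) - r
    if (max(abs(Fv)) < 1e-13) break
    J <- acfJac(h, allLags) %*% C
    db <- drop(solve(t(J) %*% J + 1e-12 * diag(nb), t(J) %*% Fv))
    b <- b - db
  }
  ## stage 2: exact orthogonality on the even lags (min-norm correction);
  ## only meaningful when r itself is an orthogonal-filter autocorrelation
  evk <- seq(0L, L - 2L, by = 2L)
  orthogonalInput <- abs(r[1] - 1) < 1e-6 &&
    (L <= 2 || max(abs(r[seq(3L, L - 1L, by = 2L)])) < 1e-6)
  target <- r[1] * (evk == 0L)
  if (orthogonalInput) for (it in 1:50) {
    h <- drop(C %*% b)
    Fv <- vapply(evk, function(k) sum(h[1:(L - k)] * h[(1 + k):L]), 0.0) - target
    if (max(abs(Fv)) < 1e-15) break
    J <- acfJac(h, evk) %*% C
    b <- b - drop(MASS::ginv(J) %*% Fv)
  }
  h <- drop(C %*% b)
  if (sum(h) < 0) h <- -h
  resid <- max(abs(autocorrelation(h) - r))
  if (resid > 1e-5)
    stop(sprintf("factorization residual %.2e exceeds 1e-5", resid))
  h
}

#' Conjugate-quadrature highpass from a lowpass
#'
#' \code{g[n] = (-1)^n h[L-1-n]} (index origin 0).
#'
#' @param h lowpass coefficients.
#' @return highpass coefficients of the same length.
#' @export
cqfHighpass <- function(h) {
  L <- length(h)
  (-1)^(0:(L - 1L)) * rev(h)
}

#' Construct a wavelet filter bank from lowpass coefficients
#'
#' @param h lowpass coefficients (orthonormal convention,
#'   \code{sum(h) = sqrt(2)}).
#' @param levels decomposition depth.
#' @param vanishingMoments vanishing-moment count; counted from \code{h}
#'   when missing.
#' @return a \linkS4class{WaveletFilterBank}.
#' @export
waveletFilterBank <- function(h, levels = 5L, vanishingMoments = NULL) {
  g <- cqfHighpass(h)
  if (is.null(vanishingMoments)) vanishingMoments <- countVanishingMoments(g)
  new("WaveletFilterBank", h = h, g = g, levels = as.integer(levels),
      vanishingMoments = as.integer(vanishingMoments))
}

#' Design the minimum RMS-bandwidth orthogonal wavelet filter bank
#'
#' Composes \code{\link{minBandwidthAutocorrelation}} and
#' \code{\link{spectralFactorize}}, then builds the conjugate-quadrature
#' highpass. The result is the orthogonal filter of length \code{L} with
#' \code{p} vanishing moments whose lowpass has the smallest mean-squared
#' bandwidth; the default \code{(12, 4, 5)} is the configuration used for
#' the six-subband EEG decomposition.
#'
#' @param L even filter length.
#' @param p vanishing moments.
#' @param levels decomposition depth.
#' @return a \linkS4class{WaveletFilterBank}.
#' @examples
#' fb <- designMinBandwidthFilter(2, 1, 1)  # the Haar bank
#' lowpass(fb)
#' @export
designMinBandwidthFilter <- function(L = 12L, p = 4L, levels = 5L) {
  sol <- minBandwidthAutocorrelation(L, p)
  h <- spectralFactorize(sol$r)
  fb <- waveletFilterBank(h, levels = levels, vanishingMoments = p)
  for (m in 0:(p - 1L)) {
    mom <- sum((0:(L - 1L))^m * highpass(fb))
    if (abs(mom) >= 1e-6)
      stop(sprintf("designed highpass misses vanishing moment %d (sum %.2e)", m, mom))
  }
  fb
}

#' Mean-squared (RMS) bandwidth of a filter
#'
#' \code{B^2 = (1/2pi) Int w^2 |H(w)|^2 dw}, evaluated in closed form from
#' the filter autocorrelation:
#' \code{B^2 = (pi^2/3) r[0] + 4 sum_k (-1)^k r[k]/k^2}.
#'
#' @param h numeric coefficient vector.
#' @return list with \code{b_sq} (mean-squared bandwidth) and \code{b}
#'   (its square root), both in radians/sample units.
#' @export
rmsBandwidth <- function(h) {
  if (!length(h) || any(!is.finite(h))) stop("h must be non-empty and finite")
  b_sq <- if (length(h) == 1L) pi^2 / 3 * h^2 else bandwidthFromLags(autocorrelation(h))
  list(b_sq = b_sq, b = sqrt(b_sq))
}

#' Count vanishing moments of a highpass filter
#'
#' Largest \code{p} such that \code{|sum_n n^m g[n]| < tol} for all
#' \code{m = 0..p-1} (index origin 0).
#'
#' @param g highpass coefficients.
#' @param tol moment tolerance.
#' @return integer vanishing-moment count.
#' @export
countVanishingMoments <- function(g, tol = 1e-6) {
  if (!length(g)) stop("g must be non-empty")
  if (tol <= 0) stop("tol must be positive")
  n <- 0:(length(g) - 1L)
  p <- 0L
  for (m in 0:(length(g) - 1L)) {
    if (abs(sum(n^m * g)) >= tol) break
    p <- p + 1L
  }
  p
}

#' Write / read a filter bank as a plain-text coefficient file
#'
#' One lowpass coefficient per line, preceded by header lines
#' \code{#L=<length>}, \code{#p=<vanishing moments>},
#' \code{#levels=<depth>}.
#'
#' @param fb a \linkS4class{WaveletFilterBank}.
#' @param path file path.
#' @return \code{readFilterBank} returns the reconstructed
#'   \linkS4class{WaveletFilterBank}; \code{writeFilterBank} returns
#'   \code{path} invisibly.
#' @export
writeFilterBank <- function(fb, path) {
  stopifnot(is(fb, "WaveletFilterBank"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#L=%d", length(fb@h)),
               sprintf("#p=%d", fb@vanishingMoments),
               sprintf("#levels=%d", fb@levels),
               sprintf("%.17g", fb@h)), con)
  invisible(path)
}

#' @rdname writeFilterBank
#' @export
readFilterBank <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    x <- sub(sprintf("^#%s=", key), "", grep(sprintf("^#%s=", key), hdr, value = TRUE))
    if (!length(x)) NA_integer_ else as.integer(x[1])
  }
  h <- as.numeric(lines[!grepl("^#", lines) & nzchar(lines)])
  L <- getv("L")
  if (!is.na(L) && L != length(h))
    stop(sprintf("header says L=%d but %d coefficients found", L, length(h)))
  lv <- getv("levels"); if (is.na(lv)) lv <- 5L
  p <- getv("p")
  waveletFilterBank(h, levels = lv,
                    vanishingMoments = if (is.na(p)) NULL else p)
}
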