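# deterministic cosinor signal
cosinor_signal <- function(mesor, amplitude, peak, times, period = 24) {
  mesor + amplitude * cos(2 * pi * (times - peak) / period)
}

# independent nonlinear least-squares oracle: coarse grid over the peak time
# with profiled linear parameters, then Nelder-Mead refinement of
# (mesor, amplitude, peak) on the raw sum of squares
oracle_cosinor_nls <- function(values, times, period = 24) {
  rss_at <- function(phi) {
    x <- cos(2 * pi * (times - phi) / period)
    sum(stats::residuals(stats::lm(values ~ x))^2)
  }
  grid <- seq(0, period - 0.05, by = 0.05)
  phi0 <- grid[which.min(vapply(grid, rss_at, numeric(1)))]
  x0 <- cos(2 * pi * (times - phi0) / period)
  cf <- stats::coef(stats::lm(values ~ x0))
  obj <- function(p) {
    sum((values - p[1] - p[2] * cos(2 * pi * (times - p[3]) / period))^2)
  }
  opt <- stats::optim(c(cf[1], cf[2], phi0), obj,
                      control = list(reltol = 1e-14, maxit = 5000))
  opt <- stats::optim(opt$par, obj,
                      control = list(reltol = 1e-14, maxit = 5000))
  p <- opt$par
  if (p[2] < 0) {  # canonical form: non-negative amplitude
    p[2] <- -p[2]
    p[3] <- p[3] + period / 2
  }
  list(mesor = unname(p[1]), amplitude = unname(p[2]),
       peak_time = unname(p[3]) %% period)
}

# direct, loop-based transcription of the published SparCC estimator without
# pair exclusion, kept independent of the package's matrix-algebra path
sparcc_basic_oracle <- function(x, pseudocount = 1e-6) {
  x <- x + pseudocount
  x <- x / rowSums(x)
  lx <- log(x)
  d <- ncol(x)
  tmat <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) tmat[i, j] <- stats::var(lx[, i] - lx[, j])
  }
  a <- matrix(1, d, d)
  diag(a) <- d - 1
  omega <- solve(a, rowSums(tmat))
  r <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      r[i, j] <- (omega[i] + omega[j] - tmat[i, j]) /
        (2 * sqrt(omega[i] * omega[j]))
    }
  }
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  r
}

# compositions closed from a log-normal basis with one optionally correlated
# pair (taxa 1 and 2)
basis_fractions <- function(seed, n = 500, d = 5, rho = 0, mu = rep(0, d)) {
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n * d), n, d)
    if (rho != 0) z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
    w <- exp(sweep(z, 2, mu, "+"))
    w / rowSums(w)
  })
}

# repeated-cow sampling times: n_days x clock grid per cow
cow_design <- function(n_cows = 12, clock = c(2, 8, 14, 20), n_days = 2) {
  data.frame(
    cow = rep(sprintf("c%02d", seq_len(n_cows)), each = length(clock) * n_days),
    time = rep(rep(clock, n_days), n_cows)
  )
}
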