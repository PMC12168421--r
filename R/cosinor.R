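#' Fit a single-group cosinor model
#'
#' Ordinary least squares fit of the linearized cosinor model
#' \deqn{y = M + \beta \cos(2\pi t/P) + \gamma \sin(2\pi t/P) + \epsilon}
#' with fixed period \code{P} (24 h by default, the daily feeding cycle).
#' The rhythm parameters are the mesor \eqn{M} (rhythm-adjusted mean),
#' amplitude \eqn{A = \sqrt{\beta^2+\gamma^2}} (half the predictable
#' peak-to-trough change within a cycle) and peak time
#' \eqn{\phi = (P/2\pi)\,\mathrm{atan2}(\gamma,\beta) \bmod P}, the clock time
#' at which the fitted rhythm attains its maximum.
#'
#' Rhythmicity is tested with the 2-degree-of-freedom F test of
#' \eqn{H_0:\beta=\gamma=0} against the intercept-only model. A constant
#' series carries no evidence of rhythm and returns \code{rhythm_p = 1};
#' a series fitted exactly (zero residual variance with non-zero amplitude)
#' returns \code{rhythm_p = 0} with \code{degenerate = TRUE}.
#'
#' Observations from repeated days are pooled as repeated 24-h cycles
#' (times are used modulo the period through the harmonic regressors).
#'
#' @param values numeric measurement series.
#' @param times numeric sampling times in hours (any origin; only
#'   \code{times %% period} matters).
#' @param period rhythm period in hours, fixed at 24 by default.
#' @return An object of class \code{cosinor_fit}: a list with elements
#'   \code{mesor}, \code{amplitude}, \code{peak_time}, \code{rhythm_p},
#'   \code{beta}, \code{gamma}, \code{residual_sd}, \code{n_obs},
#'   \code{subject_var} (0 for a fixed-effects fit), \code{degenerate},
#'   \code{period} and \code{vcov} (covariance of \code{(mesor, beta, gamma)}).
#' @examples
#' t <- seq(0, 42, by = 6)
#' y <- 10 + 3 * cos(2 * pi * (t - 14) / 24)
#' fit_cosinor(y, t)
#' @seealso [fit_cosinor_mixed()], [compare_rhythms()]
#' @export
fit_cosinor <- function(values, times, period = 24) {
  if (length(values) != length(times)) {
    stop("`values` and `times` must have the same length")
  }
  if (anyNA(values) || anyNA(times)) {
    keep <- stats::complete.cases(values, times)
    values <- values[keep]
    times <- times[keep]
  }
  n <- length(values)
  if (n < 4) stop("cosinor fit requires at least 4 observations")
  tmod <- round(times %% period, 9)
  if (length(unique(tmod)) < 3) {
    stop("rank deficiency: fewer than 3 distinct times modulo the period")
  }
  w <- 2 * pi / period
  cosx <- cos(w * times)
  sinx <- sin(w * times)
  fit <- stats::lm(values ~ cosx + sinx)
  cf <- stats::coef(fit)
  mesor <- unname(cf[1L])
  beta <- unname(cf["cosx"])
  gamma <- unname(cf["sinx"])
  amplitude <- sqrt(beta^2 + gamma^2)
  peak_time <- (atan2(gamma, beta) / w) %% period

  rss1 <- sum(stats::residuals(fit)^2)
  rss0 <- sum((values - mean(values))^2)
  df2 <- n - 3L
  scale2 <- mean(values^2) + 1
  degenerate <- FALSE
  if (rss0 <= n * scale2 * 1e-24) {
    # constant series: no evidence of rhythm, avoid 0/0 in the F statistic
    rhythm_p <- 1
  } else if (rss1 <= rss0 * 1e-12) {
    rhythm_p <- 0
    degenerate <- TRUE
  } else {
    fstat <- ((rss0 - rss1) / 2) / (rss1 / df2)
    rhythm_p <- stats::pf(fstat, 2, df2, lower.tail = FALSE)
  }

  structure(list(
    mesor = mesor, amplitude = amplitude, peak_time = peak_time,
    rhythm_p = rhythm_p, beta = beta, gamma = gamma,
    residual_sd = sqrt(rss1 / df2), n_obs = n, subject_var = 0,
    degenerate = degenerate, period = period,
    vcov = suppressWarnings(stats::vcov(fit))
  ), class = "cosinor_fit")
}

#' Fit a mixed-effects cosinor model with per-subject random intercepts
#'
#' Same fixed-effect structure as [fit_cosinor()] plus a Gaussian random
#' intercept per subject (cow), estimated by REML via \pkg{lme4}. Rhythmicity
#' is tested with a 2-df Wald chi-square test on the harmonic coefficients.
#' When the random-intercept variance is estimated at zero the fixed effects
#' coincide with the ordinary cosinor fit and \code{subject_var = 0}.
#'
#' Series that are fitted exactly by harmonic + subject terms (e.g. noiseless
#' simulations) are handled by a deterministic exact-fit path: fixed effects
#' come from the least-squares fit with sum-coded subject contrasts (so the
#' mesor is the mean of the subject-specific mesors), \code{subject_var} is
#' the variance of the subject intercepts, and the fit is flagged degenerate.
#'
#' @inheritParams fit_cosinor
#' @param subject_ids subject (cow) identifier per observation.
#' @return A \code{cosinor_fit} with \code{subject_var} set to the estimated
#'   random-intercept variance.
#' @export
fit_cosinor_mixed <- function(values, times, subject_ids, period = 24) {
  subject_ids <- factor(subject_ids)
  if (nlevels(subject_ids) < 2L) {
    warning("only one subject supplied; falling back to fit_cosinor()")
    fit <- fit_cosinor(values, times, period)
    fit$single_subject <- TRUE
    return(fit)
  }
  if (any(table(subject_ids) < 3L)) {
    stop("each subject needs at least 3 observations")
  }
  n <- length(values)
  w <- 2 * pi / period
  dat <- data.frame(
    y = values,
    cosx = cos(w * times), sinx = sin(w * times),
    subject = subject_ids
  )

  # exact-fit path: full fixed-effects model with sum-coded subjects
  dummy <- stats::lm(y ~ cosx + sinx + subject, data = dat,
                     contrasts = list(subject = "contr.sum"))
  rss_dummy <- sum(stats::residuals(dummy)^2)
  scale2 <- mean(values^2) + 1
  if (rss_dummy <= n * scale2 * 1e-20) {
    cf <- stats::coef(dummy)
    mesor <- unname(cf[1L])
    beta <- unname(cf["cosx"])
    gamma <- unname(cf["sinx"])
    amplitude <- sqrt(beta^2 + gamma^2)
    eff <- cf[grepl("^subject", names(cf))]
    eff <- c(eff, -sum(eff))             # sum-coded: last level implied
    subject_var <- stats::var(eff)
    rhythm_p <- if (amplitude > sqrt(scale2) * 1e-9) 0 else 1
    return(structure(list(
      mesor = mesor, amplitude = amplitude,
      peak_time = (atan2(gamma, beta) / w) %% period,
      rhythm_p = rhythm_p, beta = beta, gamma = gamma,
      residual_sd = 0, n_obs = n, subject_var = subject_var,
      degenerate = TRUE, period = period,
      vcov = matrix(0, 3, 3)
    ), class = "cosinor_fit"))
  }

  m <- suppressWarnings(suppressMessages(lme4::lmer(
    y ~ cosx + sinx + (1 | subject), data = dat, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")
  )))
  fe <- lme4::fixef(m)
  mesor <- unname(fe[1L])
  beta <- unname(fe["cosx"])
  gamma <- unname(fe["sinx"])
  amplitude <- sqrt(beta^2 + gamma^2)
  vc <- as.data.frame(lme4::VarCorr(m))
  subject_var <- vc$vcov[vc$grp == "subject"][1L]
  sigma <- vc$sdcor[vc$grp == "Residual"][1L]
  V <- as.matrix(stats::vcov(m))

  b <- c(beta, gamma)
  Vh <- V[2:3, 2:3]
  rhythm_p <- tryCatch({
    wald <- drop(t(b) %*% solve(Vh, b))
    stats::pchisq(wald, df = 2, lower.tail = FALSE)
  }, error = function(e) {
    if (amplitude > sqrt(scale2) * 1e-9) 0 else 1
  })

  structure(list(
    mesor = mesor, amplitude = amplitude,
    peak_time = (atan2(gamma, beta) / w) %% period,
    rhythm_p = rhythm_p, beta = beta, gamma = gamma,
    residual_sd = sigma, n_obs = n, subject_var = subject_var,
    degenerate = FALSE, period = period, vcov = V
  ), class = "cosinor_fit")
}

#' Circular difference between two peak times
#'
#' Maps the difference \code{peak_a - peak_b} onto the half-open interval
#' \code{(-period/2, period/2]}; a difference of exactly half a period is
#' reported as \code{+period/2}.
#'
#' @param peak_a,peak_b peak times in hours within \code{[0, period)}.
#' @param period period in hours.
#' @return signed circular difference in hours.
#' @examples
#' circular_peak_diff(19, 7)  # 12
#' circular_peak_diff(2, 23)  # 3
#' @export
circular_peak_diff <- function(peak_a, peak_b, period = 24) {
  d <- ((peak_a - peak_b + period / 2) %% period) - period / 2
  half <- period / 2
  ifelse(d < -half + 1e-9, d + period, d)
}

# Wald p-value robust to the zero-variance (noiseless) limit
.wald_p <- function(est, se, scale) {
  if (!is.finite(se) || se <= scale * 1e-10) {
    return(if (abs(est) <= scale * 1e-7) 1 else 0)
  }
  2 * stats::pnorm(-abs(est / se))
}

#' Compare rhythm parameters between two groups
#'
#' Fits a joint cosinor model in which a group indicator interacts with the
#' intercept and both harmonic terms, then tests the between-group difference
#' in mesor, amplitude and peak time on the
#' \eqn{(M, A, \phi)} parameterization using the delta method on the
#' coefficient covariance (Wald tests). With subject identifiers a per-subject
#' random intercept is included (subjects are treated as distinct across
#' groups). Differences are reported as group B minus group A; the peak-time
#' difference is the circular difference mapped into \code{(-12, 12]}.
#'
#' When the amplitude of either group is estimated at less than
#' \code{amp_se_ratio} standard errors, the acrophase is considered
#' unidentifiable: \code{p_peak} is set to 1 and
#' \code{peak_unidentifiable = TRUE}.
#'
#' @param values_a,times_a measurement series and times for group A.
#' @param values_b,times_b measurement series and times for group B.
#' @param subjects_a,subjects_b optional subject identifiers; supply both to
#'   obtain the mixed-model comparison.
#' @param period period in hours.
#' @param amp_se_ratio identifiability threshold for the peak-time test.
#' @return An object of class \code{rhythm_comparison}: list with the two
#'   group fits (\code{fit_a}, \code{fit_b}), differences \code{d_mesor},
#'   \code{d_amplitude}, \code{d_peak}, p-values \code{p_mesor},
#'   \code{p_amplitude}, \code{p_peak}, and \code{peak_unidentifiable}.
#' @export
compare_rhythms <- function(values_a, times_a, values_b, times_b,
                            subjects_a = NULL, subjects_b = NULL,
                            period = 24, amp_se_ratio = 2) {
  mixed <- !is.null(subjects_a) && !is.null(subjects_b)
  fit_a <- tryCatch(
    if (mixed) fit_cosinor_mixed(values_a, times_a, subjects_a, period)
    else fit_cosinor(values_a, times_a, period),
    error = function(e) stop("group A failed cosinor preconditions: ",
                             conditionMessage(e)))
  fit_b <- tryCatch(
    if (mixed) fit_cosinor_mixed(values_b, times_b, subjects_b, period)
    else fit_cosinor(values_b, times_b, period),
    error = function(e) stop("group B failed cosinor preconditions: ",
                             conditionMessage(e)))

  w <- 2 * pi / period
  k <- period / (2 * pi)
  dat <- data.frame(
    y = c(values_a, values_b),
    cosx = cos(w * c(times_a, times_b)),
    sinx = sin(w * c(times_a, times_b)),
    grp = factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
  )
  if (mixed) {
    dat$subject <- factor(paste(dat$grp, c(as.character(subjects_a),
                                           as.character(subjects_b))))
  }

  if (mixed) {
    rss_chk <- sum(stats::residuals(stats::lm(
      y ~ grp * (cosx + sinx) + subject, data = dat))^2)
  } else {
    rss_chk <- sum(stats::residuals(stats::lm(
      y ~ grp * (cosx + sinx), data = dat))^2)
  }
  exact <- rss_chk <= nrow(dat) * (mean(dat$y^2) + 1) * 1e-20

  if (mixed && !exact) {
    m <- suppressWarnings(suppressMessages(lme4::lmer(
      y ~ grp * (cosx + sinx) + (1 | subject), data = dat, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore"))))
    cf <- lme4::fixef(m)
    V <- as.matrix(stats::vcov(m))
  } else {
    m <- stats::lm(y ~ grp * (cosx + sinx), data = dat)
    cf <- stats::coef(m)
    V <- suppressWarnings(stats::vcov(m))
    if (exact) V[] <- 0
  }
  nm <- names(cf)
  idx <- c(mesor_a = which(nm == "(Intercept)"),
           d_mesor = which(nm == "grpb"),
           beta_a = which(nm == "cosx"),
           gamma_a = which(nm == "sinx"),
           d_beta = which(nm == "grpb:cosx"),
           d_gamma = which(nm == "grpb:sinx"))
  cf <- cf[idx]; V <- V[idx, idx, drop = FALSE]
  names(cf) <- names(idx)
  dimnames(V) <- list(names(idx), names(idx))
  ba <- cf[["beta_a"]]; ga <- cf[["gamma_a"]]
  bb <- ba + cf[["d_beta"]]; gb <- ga + cf[["d_gamma"]]
  Aa <- sqrt(ba^2 + ga^2); Ab <- sqrt(bb^2 + gb^2)
  yscale <- stats::sd(dat$y) + 1e-8

  # mesor difference
  d_mesor <- cf[["d_mesor"]]
  p_mesor <- .wald_p(d_mesor, sqrt(V["d_mesor", "d_mesor"]), yscale)

  # amplitude difference via delta method on (beta_a, gamma_a, d_beta, d_gamma)
  d_amplitude <- Ab - Aa
  eps <- .Machine$double.eps
  gA <- c(0, 0, bb / max(Ab, eps) - ba / max(Aa, eps),
          gb / max(Ab, eps) - ga / max(Aa, eps),
          bb / max(Ab, eps), gb / max(Ab, eps))
  se_amp <- sqrt(max(0, drop(t(gA) %*% V %*% gA)))
  p_amplitude <- .wald_p(d_amplitude, se_amp, yscale)

  # peak-time difference via delta method on atan2
  d_peak <- circular_peak_diff(fit_b$peak_time, fit_a$peak_time, period)
  gP <- c(0, 0,
          k * (-gb / max(Ab^2, eps) + ga / max(Aa^2, eps)),
          k * (bb / max(Ab^2, eps) - ba / max(Aa^2, eps)),
          k * (-gb / max(Ab^2, eps)),
          k * (bb / max(Ab^2, eps)))
  se_peak <- sqrt(max(0, drop(t(gP) %*% V %*% gP)))

  # amplitude identifiability per group (phase undefined at zero amplitude)
  gAa <- c(0, 0, ba / max(Aa, eps), ga / max(Aa, eps), 0, 0)
  gAb <- c(0, 0, bb / max(Ab, eps), gb / max(Ab, eps),
           bb / max(Ab, eps), gb / max(Ab, eps))
  se_Aa <- sqrt(max(0, drop(t(gAa) %*% V %*% gAa)))
  se_Ab <- sqrt(max(0, drop(t(gAb) %*% V %*% gAb)))
  ident_a <- se_Aa <= yscale * 1e-10 || Aa / se_Aa >= amp_se_ratio
  ident_b <- se_Ab <= yscale * 1e-10 || Ab / se_Ab >= amp_se_ratio
  peak_unidentifiable <- !(ident_a && ident_b)
  p_peak <- if (peak_unidentifiable) 1 else .wald_p(d_peak, se_peak, period * 1e-2)

  structure(list(
    fit_a = fit_a, fit_b = fit_b,
    d_mesor = d_mesor, d_amplitude = d_amplitude, d_peak = d_peak,
    p_mesor = p_mesor, p_amplitude = p_amplitude, p_peak = p_peak,
    peak_unidentifiable = peak_unidentifiable, period = period,
    mixed = mixed
  ), class = "rhythm_comparison")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat("Cosinor fit (period", x$period, "h)\n")
  cat(sprintf("  mesor %.4g  amplitude %.4g  peak %.2f h  rhythm p %.3g\n",
              x$mesor, x$amplitude, x$peak_time, x$rhythm_p))
  cat(sprintf("  n = %d  residual sd %.4g  subject var %.4g%s\n",
              x$n_obs, x$residual_sd, x$subject_var,
              if (isTRUE(x$degenerate)) "  [degenerate fit]" else ""))
  invisible(x)
}

#' @export
print.rhythm_comparison <- function(x, ...) {
  cat("Rhythm comparison (B - A)\n")
  cat(sprintf("  d_mesor %.4g (p %.3g)  d_amplitude %.4g (p %.3g)  d_peak %.2f h (p %.3g)\n",
              x$d_mesor, x$p_mesor, x$d_amplitude, x$p_amplitude,
              x$d_peak, x$p_peak))
  if (x$peak_unidentifiable) cat("  peak-time test unidentifiable (low amplitude)\n")
  invisible(x)
}
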