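.all_groups <- c("ALF", "DF", "NF", "RFT2d", "RFT7d")
.class_labels <- c("FTR", "MFR", "CCR", "InCCR", "GCR", "LCR",
                   "ARRHYTHMIC", "RHYTHMIC_UNCLASSIFIED", "NEVER_RHYTHMIC")
# feeding start (h) used to derive after-feeding strata per group
.feed_start <- c(ALF = 8, DF = 8, NF = 20, RFT2d = 8, RFT7d = 8)

#' Define a synthetic study design
#'
#' Captures the sampling layout and variance components of a simulated
#' rumen time-series study: 12 cows sampled every 6 h (clock times 2, 8,
#' 14, 20) over 2 days per group by default. Noise and cow heterogeneity act
#' on the latent log-abundance scale.
#'
#' @param n_cows cows per group.
#' @param groups group names, a subset of ALF/DF/NF/RFT2d/RFT7d.
#' @param clock_times sampling clock times in hours, each in \code{[0, 24)}.
#' @param n_days number of repeated sampling days.
#' @param n_taxa taxa per kingdom.
#' @param kingdoms kingdoms to simulate.
#' @param noise_sd observation noise sd on the latent log scale.
#' @param cow_effect_sd sd of per-cow (per-taxon) random intercepts on the
#'   latent log scale.
#' @param seed integer seed; the study is a pure function of the design.
#' @return a \code{study_design} list.
#' @export
study_design <- function(n_cows = 12, groups = .all_groups,
                         clock_times = c(2, 8, 14, 20), n_days = 2,
                         n_taxa = 100, kingdoms = "bacteria",
                         noise_sd = 0.1, cow_effect_sd = 0.3, seed = 1) {
  if (any(clock_times < 0 | clock_times >= 24)) {
    stop("clock times must lie in [0, 24)")
  }
  if (n_days < 1 || n_cows < 1 || n_taxa < 1) stop("counts must be >= 1")
  if (noise_sd < 0 || cow_effect_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  if (!all(groups %in% .all_groups)) {
    stop("unknown group(s): ",
         paste(setdiff(groups, .all_groups), collapse = ", "))
  }
  structure(list(
    n_cows = n_cows, groups = groups, clock_times = clock_times,
    n_days = n_days, n_taxa = n_taxa, kingdoms = kingdoms,
    noise_sd = noise_sd, cow_effect_sd = cow_effect_sd, seed = seed
  ), class = "study_design")
}

#' Generate a cosinor series
#'
#' The generative inverse of the cosinor model:
#' \eqn{y(t) = M + A\cos(2\pi (t - \phi)/P) + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2)} i.i.d.
#'
#' @param mesor rhythm-adjusted mean (latent units).
#' @param amplitude rhythm amplitude, \eqn{\ge 0}.
#' @param peak_time peak time in hours.
#' @param times sampling times in hours.
#' @param noise_sd Gaussian noise sd, \eqn{\ge 0}.
#' @param period period in hours.
#' @param seed optional integer seed (noise drawn from the current RNG
#'   stream when NULL).
#' @return numeric vector of length \code{length(times)}.
#' @export
generate_rhythmic_series <- function(mesor, amplitude, peak_time, times,
                                     noise_sd = 0, period = 24,
                                     seed = NULL) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  base <- mesor + amplitude * cos(2 * pi * (times - peak_time) / period)
  noise <- if (noise_sd == 0) {
    0
  } else if (is.null(seed)) {
    stats::rnorm(length(times), 0, noise_sd)
  } else {
    withr::with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  }
  base + noise
}

# draw per-group truth parameters for one kingdom's taxa.
# rhythmic taxa are built in anti-phase pairs of equal mesor and amplitude so
# the latent community total carries no 24-h harmonic: otherwise closure would
# impose an apparent rhythm on every ground-truth-arrhythmic taxon and the
# intended class labels would not describe the generated relative abundances.
.draw_truth <- function(n_taxa, class_mix, groups, kingdom,
                        balance_phases = TRUE) {
  labels <- rep(names(class_mix), times = class_mix)
  taxon_id <- sprintf("%s_t%03d", substr(kingdom, 1, 3), seq_len(n_taxa))
  rows <- list()
  i <- 1L
  while (i <= n_taxa) {
    lab <- labels[i]
    paired <- balance_phases && i < n_taxa && labels[i + 1L] == lab
    mesor <- stats::rnorm(1, 0, 0.75)
    amp <- stats::runif(1, 0.3, 0.5)
    phi <- stats::runif(1, 0, 24)
    mfr_shift <- sample(c(-1, 1), 1) * stats::runif(1, 3, 6)
    members <- if (paired) c(i, i + 1L) else i
    for (m in seq_along(members)) {
      ph <- (phi + (m - 1L) * 12) %% 24
      par_g <- lapply(groups, function(g) {
        p <- list(mesor = mesor, amplitude = amp, peak_time = ph,
                  rhythmic = TRUE)
        off <- function(x) { x$amplitude <- 0; x$rhythmic <- FALSE; x }
        switch(lab,
          FTR = if (g == "NF") { p$peak_time <- (ph + 12) %% 24; p } else p,
          MFR = if (g == "NF") { p$peak_time <- (ph + mfr_shift) %% 24; p }
                else p,
          RHYTHMIC_UNCLASSIFIED = if (g == "NF") off(p) else p,
          ARRHYTHMIC = off(p),
          NEVER_RHYTHMIC = if (g %in% c("RFT2d", "RFT7d")) off(p) else p,
          CCR = p,
          InCCR = if (g == "RFT7d") {
            p$peak_time <- (ph + 6) %% 24
            p$amplitude <- amp * 1.6
            p
          } else p,
          GCR = if (g == "RFT2d") off(p) else p,
          LCR = if (g == "RFT7d") off(p) else p,
          stop("unknown class label: ", lab))
      })
      names(par_g) <- groups
      rows[[members[m]]] <- list(taxon_id = taxon_id[members[m]],
                                 kingdom = kingdom, class = lab,
                                 params = par_g)
    }
    i <- i + length(members)
  }
  rows
}

#' Generate a complete synthetic study
#'
#' Simulates a multi-group rumen time-series study with known ground truth.
#' Per-taxon latent log-abundances are cosinor signals plus per-cow Gaussian
#' random intercepts plus i.i.d. Gaussian noise; relative abundances are
#' obtained by softmax-style closure per sample (exponentiate, divide by the
#' sample sum). FTR taxa shift their peak by exactly +12 h between DF and
#' NF; MFR taxa by a draw of 3-6 h (outside the 12 +/- 3 h window); GCR taxa
#' are arrhythmic at RFT2d and rhythmic at RFT7d (LCR the reverse); InCCR
#' taxa change amplitude and peak between RFT2d and RFT7d.
#'
#' By default rhythmic taxa come in anti-phase pairs of matched mesor and
#' amplitude, so the latent community total carries no 24-h harmonic and the
#' recorded truth labels remain valid for the closed (relative) abundances;
#' the diurnal rhythm of total microbial load is carried separately by the
#' qPCR layer. Set \code{balance_phases = FALSE} to expose the
#' closure-induced apparent rhythms that an unbalanced community produces.
#'
#' @param design a [study_design()].
#' @param class_mix named integer vector of taxon counts per intended class
#'   (names among FTR, MFR, CCR, InCCR, GCR, LCR, ARRHYTHMIC,
#'   RHYTHMIC_UNCLASSIFIED, NEVER_RHYTHMIC), summing to \code{n_taxa}.
#' @param balance_phases pair rhythmic taxa in anti-phase (see Details).
#' @return a \code{synthetic_study} list: \code{abundance} and \code{latent}
#'   (per-kingdom samples x taxa matrices), \code{metadata},
#'   \code{qpcr}, \code{fermentation}, \code{truth} (long data frame of
#'   per-group ground-truth parameters), \code{design}.
#' @export
generate_study <- function(design, class_mix, balance_phases = TRUE) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% .class_labels)) {
    stop("class_mix must be named with known class labels")
  }
  if (sum(class_mix) != design$n_taxa) {
    stop("class_mix counts must sum to n_taxa (",
         sum(class_mix), " vs ", design$n_taxa, ")")
  }
  withr::with_seed(design$seed, {
    md <- expand.grid(
      clock_time = design$clock_times,
      day = seq_len(design$n_days),
      cow_id = sprintf("cow%02d", seq_len(design$n_cows)),
      group = design$groups,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    md$sample_id <- sprintf("%s_%s_d%d_h%02.0f", md$group, md$cow_id,
                            md$day, md$clock_time)
    afh <- (md$clock_time - .feed_start[md$group]) %% 24
    md$after_feeding_h <- ifelse(afh == 0, 24, afh)
    md <- md[, c("sample_id", "cow_id", "group", "clock_time",
                 "after_feeding_h", "day")]

    abundance <- list()
    latent <- list()
    truth_rows <- list()
    for (kd in design$kingdoms) {
      truths <- .draw_truth(design$n_taxa, class_mix, design$groups, kd,
                            balance_phases)
      taxa <- vapply(truths, `[[`, character(1), "taxon_id")
      cow_eff <- matrix(stats::rnorm(design$n_cows * design$n_taxa,
                                     0, design$cow_effect_sd),
                        nrow = design$n_cows,
                        dimnames = list(sprintf("cow%02d",
                                                seq_len(design$n_cows)),
                                        taxa))
      z <- matrix(0, nrow(md), design$n_taxa,
                  dimnames = list(md$sample_id, taxa))
      for (j in seq_along(truths)) {
        tr <- truths[[j]]
        for (g in design$groups) {
          rows <- md$group == g
          p <- tr$params[[g]]
          z[rows, j] <- p$mesor +
            p$amplitude * cos(2 * pi * (md$clock_time[rows] -
                                        p$peak_time) / 24) +
            cow_eff[md$cow_id[rows], j] +
            stats::rnorm(sum(rows), 0, design$noise_sd)
        }
        truth_rows[[length(truth_rows) + 1L]] <- do.call(rbind, lapply(
          design$groups, function(g) {
            p <- tr$params[[g]]
            data.frame(taxon_id = tr$taxon_id, kingdom = kd, group = g,
                       mesor = p$mesor, amplitude = p$amplitude,
                       peak_time = p$peak_time, rhythmic = p$rhythmic,
                       class = tr$class, stringsAsFactors = FALSE)
          }))
      }
      latent[[kd]] <- z
      ez <- exp(z)
      abundance[[kd]] <- ez / rowSums(ez)
    }

    # rhythmic total microbial load (copies/mL), peak in the evening,
    # with plausible qPCR record fields consistent with the totals
    load_base <- c(bacteria = 10.5, archaea = 8.5, protozoa = 5.5)
    qpcr <- do.call(rbind, lapply(design$kingdoms, function(kd) {
      base <- if (kd %in% names(load_base)) load_base[[kd]] else 9
      log10_total <- generate_rhythmic_series(
        base, 0.12, 19, md$clock_time,
        noise_sd = if (design$noise_sd > 0) 0.04 else 0)
      total <- 10^log10_total
      dna_conc <- 20; eluted_volume <- 100; dna_input <- 30
      fluid_volume <- 1
      data.frame(sample_id = md$sample_id, kingdom = kd,
                 mean_copy = total * dna_input * fluid_volume /
                   (dna_conc * eluted_volume),
                 dna_conc = dna_conc, eluted_volume = eluted_volume,
                 dna_input = dna_input, fluid_volume = fluid_volume,
                 total_copies = total, stringsAsFactors = FALSE)
    }))

    fermentation <- generate_fermentation_series(
      md, noise_frac = if (design$noise_sd > 0) 0.03 else 0)
  })

  structure(list(
    abundance = abundance, latent = latent, metadata = md, qpcr = qpcr,
    fermentation = fermentation,
    truth = do.call(rbind, truth_rows), design = design,
    class_mix = class_mix
  ), class = "synthetic_study")
}

# default fermentation rhythm parameters: VFA peaks in the evening
# (16:00-20:00), pH and NH3-N about 12 h opposed, magnitudes typical of
# high-grain lactating-cow rumen fluid
.ferm_defaults <- function() {
  list(
    mesor = c(acetate = 65, propionate = 22, butyrate = 12, isobutyrate = 1,
              valerate = 2, isovalerate = 1.5, ph = 6.4, nh3n = 10),
    amplitude = c(acetate = 6, propionate = 2.5, butyrate = 1.2,
                  isobutyrate = 0.1, valerate = 0.25, isovalerate = 0.15,
                  ph = 0.2, nh3n = 2.5),
    peak = c(acetate = 18, propionate = 18, butyrate = 18, isobutyrate = 19,
             valerate = 18, isovalerate = 19, ph = 6, nh3n = 6)
  )
}

#' Generate a fermentation time series
#'
#' Each fermentation variable (six VFAs in mM, pH, NH3-N in mg/dL) is a
#' positive cosinor series over the samples of a metadata table; VFA peaks
#' default to the evening (18:00-19:00) with pH and ammonia about 12 h
#' opposed. TVFA is the per-record sum of the six VFAs.
#'
#' @param metadata sample metadata data frame (needs \code{sample_id} and
#'   \code{clock_time}).
#' @param peak_map optional named vector of peak hours overriding the
#'   defaults for any of the variables.
#' @param amplitude_map optional named amplitude overrides.
#' @param noise_frac Gaussian noise sd as a fraction of each variable's
#'   mesor.
#' @return data frame with \code{sample_id}, the six VFA columns, \code{ph},
#'   \code{nh3n} and \code{tvfa}.
#' @export
generate_fermentation_series <- function(metadata, peak_map = NULL,
                                         amplitude_map = NULL,
                                         noise_frac = 0.03) {
  par <- .ferm_defaults()
  if (!is.null(peak_map)) {
    if (any(peak_map < 0 | peak_map >= 24)) {
      stop("peak hours must lie in [0, 24)")
    }
    par$peak[names(peak_map)] <- peak_map
  }
  if (!is.null(amplitude_map)) par$amplitude[names(amplitude_map)] <- amplitude_map
  out <- data.frame(sample_id = metadata$sample_id,
                    stringsAsFactors = FALSE)
  for (v in names(par$mesor)) {
    y <- generate_rhythmic_series(
      par$mesor[[v]], par$amplitude[[v]], par$peak[[v]],
      metadata$clock_time,
      noise_sd = noise_frac * par$mesor[[v]])
    out[[v]] <- pmax(y, 1e-6)
  }
  out$tvfa <- rowSums(out[, .vfa_names])
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic rumen study:",
      paste(names(x$abundance), collapse = "/"), "\n")
  cat("  ", nrow(x$metadata), "samples,", x$design$n_taxa,
      "taxa per kingdom, groups:",
      paste(x$design$groups, collapse = ", "), "\n")
  cat("  class mix:",
      paste(sprintf("%s=%d", names(x$class_mix), x$class_mix),
            collapse = ", "), "\n")
  invisible(x)
}
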