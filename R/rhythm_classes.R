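#' @keywords internal
"_PACKAGE"

# closed label vocabularies per contrast
.feeding_labels <- c("FTR", "MFR", "RHYTHMIC_UNCLASSIFIED", "ARRHYTHMIC")
.rft_labels <- c("CCR", "InCCR", "GCR", "LCR", "NEVER_RHYTHMIC")

#' Classify a taxon's rhythm response to feeding-time restriction
#'
#' Applies the categorical rules used for the daytime- versus nighttime-
#' restricted feeding contrast (DF vs NF). A taxon rhythmic in both groups is
#' feeding-time responsive (FTR) when its peak-time shift between the groups
#' lies within 12 +/- 3 h (circularly, endpoints inclusive), and multi-factor
#' responsive (MFR) otherwise. A taxon rhythmic in exactly one group is
#' labelled \code{RHYTHMIC_UNCLASSIFIED}; one rhythmic in neither is
#' \code{ARRHYTHMIC}.
#'
#' @param fit_df,fit_nf \code{cosinor_fit} objects for the same taxon in the
#'   daytime- and nighttime-feeding groups.
#' @param alpha rhythmicity significance threshold.
#' @param window inclusive bounds, in hours, of the absolute circular peak
#'   shift that counts as feeding-time driven (default \code{c(9, 15)},
#'   i.e. 12 +/- 3 h).
#' @return a single label, one of \code{"FTR"}, \code{"MFR"},
#'   \code{"RHYTHMIC_UNCLASSIFIED"}, \code{"ARRHYTHMIC"}.
#' @export
classify_feeding_response <- function(fit_df, fit_nf, alpha = 0.05,
                                      window = c(9, 15)) {
  ra <- fit_df$rhythm_p < alpha
  rb <- fit_nf$rhythm_p < alpha
  if (!ra && !rb) return("ARRHYTHMIC")
  if (xor(ra, rb)) return("RHYTHMIC_UNCLASSIFIED")
  shift <- abs(circular_peak_diff(fit_df$peak_time, fit_nf$peak_time,
                                  fit_df$period))
  if (shift >= window[1] && shift <= window[2]) "FTR" else "MFR"
}

#' Classify a taxon's rhythm response to rumen fluid transplantation
#'
#' Applies the categorical rules for the 48-h versus 7-day post-transplant
#' contrast (RFT2d vs RFT7d): gained circadian rhythm (GCR) when arrhythmic
#' at 48 h but rhythmic at 7 days, lost (LCR) for the reverse,
#' \code{NEVER_RHYTHMIC} when rhythmic in neither; taxa rhythmic in both are
#' consistent (CCR) when none of the mesor, amplitude and peak-time
#' between-group tests is significant, and inconsistent (InCCR) otherwise.
#'
#' @param fit_2d,fit_7d \code{cosinor_fit} objects for the same taxon at 48 h
#'   and 7 days after transplantation.
#' @param comparison a [compare_rhythms()] result built from the two groups;
#'   only required when the taxon is rhythmic in both.
#' @param alpha significance threshold.
#' @return one of \code{"CCR"}, \code{"InCCR"}, \code{"GCR"}, \code{"LCR"},
#'   \code{"NEVER_RHYTHMIC"}.
#' @export
classify_rft_response <- function(fit_2d, fit_7d, comparison = NULL,
                                  alpha = 0.05) {
  ra <- fit_2d$rhythm_p < alpha
  rb <- fit_7d$rhythm_p < alpha
  if (!ra && rb) return("GCR")
  if (ra && !rb) return("LCR")
  if (!ra && !rb) return("NEVER_RHYTHMIC")
  if (is.null(comparison)) {
    stop("a rhythm comparison is required to separate CCR from InCCR")
  }
  ps <- c(comparison$p_mesor, comparison$p_amplitude, comparison$p_peak)
  if (min(ps) >= alpha) "CCR" else "InCCR"
}

#' Per-taxon rhythm classification for a two-group contrast
#'
#' Fits the cosinor model to every taxon of an abundance table in the two
#' groups of a contrast and applies the corresponding classification rules:
#' FTR/MFR for \code{"DF_vs_NF"} and CCR/InCCR/GCR/LCR for
#' \code{"RFT2d_vs_RFT7d"}. The rules are generic over any feature table
#' (relative abundance, estimated absolute abundance, pathway abundance).
#'
#' @param abundance samples x taxa numeric matrix with sample ids as row
#'   names (any non-negative feature values).
#' @param metadata data frame with columns \code{sample_id}, \code{cow_id},
#'   \code{group}, \code{clock_time}.
#' @param contrast \code{"DF_vs_NF"} or \code{"RFT2d_vs_RFT7d"}; the two
#'   group names are taken from the contrast name.
#' @param alpha rhythmicity / difference significance threshold. Raw p-values
#'   are used by default; set \code{p_adjust = "BH"} for a
#'   Benjamini-Hochberg-adjusted rhythmicity screen.
#' @param window FTR window in hours (feeding contrast only).
#' @param detection per-group rhythmicity screen: \code{"single"} (default)
#'   uses the single-group cosinor F test on the pooled cow series --
#'   conservative under cow heterogeneity, mirroring the single-group screen
#'   of the source methodology; \code{"mixed"} uses the random-intercept
#'   Wald test from [fit_cosinor_mixed()].
#' @param mixed use per-cow random intercepts in the between-group
#'   comparison (mixed cosinor) when TRUE.
#' @param p_adjust \code{"none"} (default) or \code{"BH"}.
#' @param period period in hours.
#' @return data frame with one row per taxon: \code{taxon_id},
#'   \code{contrast}, \code{label}, group-wise rhythm p-values and peak times,
#'   \code{d_peak} and the three parameter-difference p-values (NA when not
#'   computed).
#' @export
classify_taxa <- function(abundance, metadata,
                          contrast = c("DF_vs_NF", "RFT2d_vs_RFT7d"),
                          alpha = 0.05, window = c(9, 15),
                          detection = c("single", "mixed"), mixed = TRUE,
                          p_adjust = c("none", "BH"), period = 24) {
  contrast <- match.arg(contrast)
  detection <- match.arg(detection)
  p_adjust <- match.arg(p_adjust)
  groups <- strsplit(contrast, "_vs_")[[1L]]
  md <- metadata[metadata$group %in% groups, , drop = FALSE]
  if (!all(groups %in% md$group)) {
    stop("metadata lacks samples for both groups of contrast ", contrast)
  }
  miss <- setdiff(md$sample_id, rownames(abundance))
  if (length(miss)) stop("abundance table lacks samples: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  taxa <- colnames(abundance)
  sel <- lapply(groups, function(g) md[md$group == g, , drop = FALSE])

  fit_one <- function(vals, m) {
    if (detection == "mixed") {
      fit_cosinor_mixed(vals, m$clock_time, m$cow_id, period)
    } else {
      fit_cosinor(vals, m$clock_time, period)
    }
  }
  fits_a <- lapply(taxa, function(tx)
    fit_one(abundance[sel[[1]]$sample_id, tx], sel[[1]]))
  fits_b <- lapply(taxa, function(tx)
    fit_one(abundance[sel[[2]]$sample_id, tx], sel[[2]]))

  p_a <- vapply(fits_a, `[[`, numeric(1), "rhythm_p")
  p_b <- vapply(fits_b, `[[`, numeric(1), "rhythm_p")
  if (p_adjust == "BH") {
    p_a <- stats::p.adjust(p_a, "BH")
    p_b <- stats::p.adjust(p_b, "BH")
  }

  out <- data.frame(
    taxon_id = taxa, contrast = contrast, label = NA_character_,
    p_a = p_a, p_b = p_b,
    peak_a = vapply(fits_a, `[[`, numeric(1), "peak_time"),
    peak_b = vapply(fits_b, `[[`, numeric(1), "peak_time"),
    d_peak = NA_real_, p_mesor = NA_real_, p_amplitude = NA_real_,
    p_peak = NA_real_, stringsAsFactors = FALSE
  )
  out$d_peak <- circular_peak_diff(out$peak_b, out$peak_a, period)

  for (i in seq_along(taxa)) {
    fa <- fits_a[[i]]; fb <- fits_b[[i]]
    fa$rhythm_p <- p_a[i]; fb$rhythm_p <- p_b[i]
    if (contrast == "DF_vs_NF") {
      out$label[i] <- classify_feeding_response(fa, fb, alpha, window)
    } else {
      cmp <- NULL
      if (p_a[i] < alpha && p_b[i] < alpha) {
        va <- abundance[sel[[1]]$sample_id, taxa[i]]
        vb <- abundance[sel[[2]]$sample_id, taxa[i]]
        cmp <- compare_rhythms(
          va, sel[[1]]$clock_time, vb, sel[[2]]$clock_time,
          subjects_a = if (mixed) sel[[1]]$cow_id else NULL,
          subjects_b = if (mixed) sel[[2]]$cow_id else NULL,
          period = period)
        out$p_mesor[i] <- cmp$p_mesor
        out$p_amplitude[i] <- cmp$p_amplitude
        out$p_peak[i] <- cmp$p_peak
      }
      out$label[i] <- classify_rft_response(fa, fb, cmp, alpha)
    }
  }
  out
}

#' Summarize rhythm classes by taxon count and abundance share
#'
#' For each label, reports the number of member taxa and the summed mean
#' relative abundance of those taxa across the supplied samples, in percent
#' of total reads (the convention in which class proportions such as
#' "61.17% of total bacterial reads" are expressed).
#'
#' @param classes data frame with columns \code{taxon_id} and \code{label}
#'   (e.g. from [classify_taxa()]).
#' @param abundance samples x taxa matrix of relative abundances (fractions)
#'   restricted to the samples of the contrast being summarized.
#' @param label_set optional character vector of labels to report (defaults
#'   to the closed vocabulary of the contrast, inferred from the labels
#'   present); labels without member taxa get zero rows.
#' @return data frame with columns \code{label}, \code{n_taxa},
#'   \code{mean_abundance_pct}.
#' @export
summarize_classes <- function(classes, abundance, label_set = NULL) {
  miss <- setdiff(classes$taxon_id, colnames(abundance))
  if (length(miss)) {
    stop("labeled taxa missing from abundance table: ",
         paste(utils::head(miss, 3), collapse = ", "))
  }
  if (is.null(label_set)) {
    label_set <- if (any(classes$label %in% .rft_labels)) .rft_labels
                 else .feeding_labels
    label_set <- union(label_set, unique(classes$label))
  }
  mean_ab <- colMeans(abundance[, classes$taxon_id, drop = FALSE]) * 100
  n_taxa <- vapply(label_set, function(l) sum(classes$label == l), integer(1))
  pct <- vapply(label_set, function(l)
    sum(mean_ab[classes$label == l]), numeric(1))
  data.frame(label = label_set, n_taxa = n_taxa,
             mean_abundance_pct = unname(pct),
             stringsAsFactors = FALSE, row.names = NULL)
}
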