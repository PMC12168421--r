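#' Copy number of a qPCR plasmid standard
#'
#' Copies per nanogram of a plasmid standard of molecular weight \code{A}
#' (g/mol) carrying an amplicon of length \code{n} (bp):
#' \deqn{(N_L \cdot A \cdot 10^{-9}) / (660 \cdot n)}
#' where \eqn{N_L} is the Avogadro constant and 660 g/mol/bp the average
#' weight of a DNA base pair.
#'
#' @param molecular_weight molecular weight of the standard, g/mol.
#' @param amplicon_length amplicon length in bp.
#' @param avogadro Avogadro constant, molecules per mol.
#' @return copies per ng of standard.
#' @export
standard_copy_number <- function(molecular_weight, amplicon_length,
                                 avogadro = 6.02e23) {
  if (any(molecular_weight <= 0) || any(amplicon_length <= 0) ||
      avogadro <= 0) {
    stop("standard parameters must be positive")
  }
  (avogadro * molecular_weight * 1e-9) / (660 * amplicon_length)
}

#' Total marker-gene copies per millilitre of rumen fluid
#'
#' \deqn{(M_Q \cdot C \cdot V_D) / (S \cdot V)}
#' where \eqn{M_Q} is the quantitative mean copy number from qPCR, \eqn{C}
#' the DNA concentration (ng/ul), \eqn{V_D} the eluted DNA volume (ul),
#' \eqn{S} the DNA amount subjected to qPCR (ng) and \eqn{V} the rumen fluid
#' volume extracted (mL).
#'
#' @param mean_copy qPCR quantitative mean copy number (M_Q).
#' @param dna_conc sample DNA concentration in ng/ul (C).
#' @param eluted_volume eluted DNA volume in ul (V_D).
#' @param dna_input DNA input to qPCR in ng (S).
#' @param fluid_volume rumen fluid volume extracted in mL (V).
#' @return copies per mL of rumen fluid.
#' @export
copies_per_ml <- function(mean_copy, dna_conc, eluted_volume, dna_input,
                          fluid_volume) {
  args <- cbind(mean_copy, dna_conc, eluted_volume, dna_input, fluid_volume)
  if (any(args <= 0)) stop("all qPCR record fields must be positive")
  (mean_copy * dna_conc * eluted_volume) / (dna_input * fluid_volume)
}

#' Estimated absolute abundance
#'
#' Total marker-gene copies multiplied by relative abundance, giving each
#' taxon's estimated copies per mL. Applied table-wide the row sums equal
#' the per-sample totals.
#'
#' @param rel_abundance relative abundance fraction(s) in \code{[0, 1]}.
#' @param total_copies total copies per mL for the same sample(s).
#' @return estimated absolute abundance, copies per mL.
#' @export
estimated_absolute_abundance <- function(rel_abundance, total_copies) {
  if (any(rel_abundance < 0) || any(rel_abundance > 1)) {
    stop("relative abundances must lie in [0, 1]")
  }
  rel_abundance * total_copies
}

#' Estimated absolute abundance table
#'
#' @param abundance samples x taxa matrix of relative abundances (fractions).
#' @param total_copies named vector of total copies per mL, one per sample
#'   (names matched to the table's row names).
#' @return matrix of estimated absolute abundances (copies/mL).
#' @export
eaa_table <- function(abundance, total_copies) {
  if (is.null(names(total_copies))) {
    if (length(total_copies) != nrow(abundance)) {
      stop("need one total per sample")
    }
  } else {
    miss <- setdiff(rownames(abundance), names(total_copies))
    if (length(miss)) stop("missing totals for samples: ",
                           paste(utils::head(miss, 3), collapse = ", "))
    total_copies <- total_copies[rownames(abundance)]
  }
  estimated_absolute_abundance(abundance, 1) * as.numeric(total_copies)
}

#' Shannon diversity
#'
#' \eqn{H = -\sum p_i \log_b p_i} with base 2 by default; zero-abundance
#' taxa contribute nothing.
#'
#' @param x non-negative counts or fractions for one sample.
#' @param base logarithm base (2 by default).
#' @return Shannon diversity value.
#' @export
shannon <- function(x, base = 2) {
  if (any(x < 0)) stop("abundances must be non-negative")
  s <- sum(x)
  if (s <= 0) stop("diversity undefined for an all-zero sample")
  p <- x[x > 0] / s
  -sum(p * log(p, base = base))
}

#' Chao1 estimated richness
#'
#' \eqn{S_{obs} + F_1^2 / (2 F_2)} where \eqn{F_1} and \eqn{F_2} are the
#' singleton and doubleton counts; when \eqn{F_2 = 0} the bias-corrected form
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} is used.
#'
#' @param counts non-negative integer counts for one sample.
#' @return Chao1 richness estimate (always \eqn{\ge S_{obs}}).
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("chao1 requires integer counts")
  }
  counts <- round(counts)
  if (sum(counts) == 0) stop("richness undefined for an all-zero sample")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Rarefy a count vector to fixed depth
#'
#' Seeded subsampling without replacement, for diversity comparisons at a
#' common depth.
#'
#' @param counts non-negative integer counts.
#' @param depth target depth (must not exceed the total count).
#' @param seed integer seed.
#' @return rarefied integer counts of the same length.
#' @export
rarefy_counts <- function(counts, depth, seed = 1) {
  counts <- round(counts)
  if (depth > sum(counts)) stop("depth exceeds total count")
  withr::with_seed(seed, {
    pool <- rep(seq_along(counts), counts)
    drawn <- sample(pool, depth)
    tabulate(drawn, nbins = length(counts))
  })
}
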