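# names of the six measured volatile fatty acids, in reporting order
.vfa_names <- c("acetate", "propionate", "butyrate", "isobutyrate",
                "valerate", "isovalerate")

#' Molar percentages of total VFA
#'
#' Each volatile fatty acid's share of total VFA (TVFA = sum of acetate,
#' propionate, butyrate, isobutyrate, valerate and isovalerate), in percent.
#' The iso-acids are included in the denominator.
#'
#' @param rec a named numeric vector or one-row data frame containing the six
#'   VFA concentrations in mM (columns \code{acetate}, \code{propionate},
#'   \code{butyrate}, \code{isobutyrate}, \code{valerate},
#'   \code{isovalerate}).
#' @return named numeric vector of percentages summing to 100.
#' @export
molar_percentages <- function(rec) {
  v <- vapply(.vfa_names, function(nm) as.numeric(rec[[nm]]), numeric(1))
  if (any(v < 0)) stop("VFA concentrations must be non-negative")
  tvfa <- sum(v)
  if (tvfa <= 0) stop("molar percentages undefined when TVFA is zero")
  100 * v / tvfa
}

#' Estimated methane statistic ECH4
#'
#' The molar amount of methane generated per mole of total VFA produced,
#' from the fermentation stoichiometry:
#' \deqn{ECH_4 = 2\,Acetate\% - Propionate\% + 2\,Butyrate\% - Valerate\%}
#' with inputs as molar percentages of TVFA.
#'
#' @param acetate_pct,propionate_pct,butyrate_pct,valerate_pct molar
#'   percentages (non-negative).
#' @return ECH4 value.
#' @examples
#' ech4(65, 20, 12, 3)  # 131
#' @export
ech4 <- function(acetate_pct, propionate_pct, butyrate_pct, valerate_pct) {
  if (any(c(acetate_pct, propionate_pct, butyrate_pct, valerate_pct) < 0)) {
    stop("molar percentages must be non-negative")
  }
  2 * acetate_pct - propionate_pct + 2 * butyrate_pct - valerate_pct
}

#' Acetate to propionate ratio
#'
#' @param acetate,propionate concentrations in mM (propionate > 0).
#' @return the A/P ratio.
#' @export
acetate_propionate_ratio <- function(acetate, propionate) {
  if (any(propionate <= 0)) stop("A/P ratio undefined for zero propionate")
  acetate / propionate
}

#' Annotate a fermentation table with derived statistics
#'
#' Adds TVFA, per-VFA molar percentages, the A/P ratio and ECH4 to a
#' fermentation record table.
#'
#' @param ferm data frame with the six VFA columns in mM (plus any others,
#'   e.g. \code{ph} and \code{nh3n}, which are carried through).
#' @return the input with columns \code{tvfa}, \code{<vfa>_pct},
#'   \code{ap_ratio} and \code{ech4} appended.
#' @export
annotate_fermentation <- function(ferm) {
  miss <- setdiff(.vfa_names, names(ferm))
  if (length(miss)) stop("fermentation table lacks columns: ",
                         paste(miss, collapse = ", "))
  vmat <- as.matrix(ferm[, .vfa_names])
  ferm$tvfa <- rowSums(vmat)
  pct <- 100 * sweep(vmat, 1, ferm$tvfa, "/")
  colnames(pct) <- paste0(.vfa_names, "_pct")
  ferm <- cbind(ferm, as.data.frame(pct))
  ferm$ap_ratio <- acetate_propionate_ratio(ferm$acetate, ferm$propionate)
  ferm$ech4 <- ech4(ferm$acetate_pct, ferm$propionate_pct,
                    ferm$butyrate_pct, ferm$valerate_pct)
  ferm
}
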