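# write a data frame as TSV with a units comment line and full numeric
# precision (round-trip within 1e-12)
.write_tsv <- function(df, path, units = NULL) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) sprintf("%.17g", col))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units)) writeLines(paste0("# units: ", units), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write an abundance table to TSV
#'
#' Samples as rows (first column \code{sample_id}), taxa as columns; a
#' leading comment line records the units/mode.
#'
#' @param abundance samples x taxa numeric matrix with row names.
#' @param path output file.
#' @param mode \code{"fractions"} (rows sum to 1) or \code{"counts"}.
#' @export
write_abundance_table <- function(abundance, path,
                                  mode = c("fractions", "counts")) {
  mode <- match.arg(mode)
  df <- data.frame(sample_id = rownames(abundance),
                   as.data.frame(abundance), check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path,
             units = if (mode == "fractions")
               "relative abundance (fraction); mode: fractions"
             else "read counts; mode: counts")
  invisible(path)
}

#' Read an abundance table from TSV
#'
#' @param path TSV written by [write_abundance_table()] (first column
#'   \code{sample_id}, taxa as remaining columns).
#' @param mode expected mode; \code{"fractions"} tables are validated to
#'   have rows summing to 1 within 1e-6.
#' @param normalize with \code{mode = "counts"}, close rows to fractions.
#' @return samples x taxa numeric matrix (attribute \code{mode} records the
#'   returned scale).
#' @export
read_abundance_table <- function(path, mode = c("fractions", "counts"),
                                 normalize = FALSE) {
  mode <- match.arg(mode)
  df <- .read_tsv(path)
  if (names(df)[1] != "sample_id") stop("first column must be sample_id")
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate taxon ids in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(m < 0)) {
    bad <- rownames(m)[which(rowSums(m < 0) > 0)[1]]
    stop("negative abundance in row ", bad)
  }
  rs <- rowSums(m)
  if (mode == "fractions") {
    if (any(rs == 0)) {
      stop("row sums to 0 in fractions mode: ",
           rownames(m)[which(rs == 0)[1]])
    }
    if (any(abs(rs - 1) > 1e-6)) {
      stop("rows do not sum to 1 in fractions mode: ",
           rownames(m)[which(abs(rs - 1) > 1e-6)[1]])
    }
  } else if (normalize) {
    if (any(rs == 0)) stop("cannot normalize an all-zero row")
    m <- m / rs
    mode <- "fractions"
  }
  attr(m, "mode") <- mode
  m
}

#' Write / read sample metadata
#'
#' Metadata columns: \code{sample_id}, \code{cow_id}, \code{group}
#' (ALF/DF/NF/RFT2d/RFT7d), \code{clock_time} (decimal hours in
#' \code{[0, 24)}), \code{after_feeding_h}, \code{day}.
#'
#' @param metadata metadata data frame.
#' @param path TSV file.
#' @export
write_sample_metadata <- function(metadata, path) {
  .write_tsv(metadata, path,
             units = "clock_time and after_feeding_h in hours")
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  md <- .read_tsv(path)
  need <- c("sample_id", "cow_id", "group", "clock_time")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids")
  if (!all(md$group %in% .all_groups)) {
    stop("unknown group(s): ",
         paste(setdiff(unique(md$group), .all_groups), collapse = ", "))
  }
  if (any(md$clock_time < 0 | md$clock_time >= 24)) {
    stop("clock_time must lie in [0, 24)")
  }
  md
}

#' Write / read a qPCR record table
#'
#' Columns: \code{sample_id}, \code{kingdom}, \code{mean_copy} (M_Q),
#' \code{dna_conc} (C, ng/ul), \code{eluted_volume} (V_D, ul),
#' \code{dna_input} (S, ng), \code{fluid_volume} (V, mL). On reading, total
#' copies per mL are (re)computed from the records via [copies_per_ml()].
#'
#' @param qpcr qPCR record data frame.
#' @param path TSV file.
#' @export
write_qpcr_table <- function(qpcr, path) {
  .write_tsv(qpcr, path,
             units = "mean_copy copies; dna_conc ng/ul; eluted_volume ul; dna_input ng; fluid_volume mL; total_copies copies/mL")
  invisible(path)
}

#' @rdname write_qpcr_table
#' @export
read_qpcr_table <- function(path) {
  q <- .read_tsv(path)
  need <- c("sample_id", "kingdom", "mean_copy", "dna_conc",
            "eluted_volume", "dna_input", "fluid_volume")
  miss <- setdiff(need, names(q))
  if (length(miss)) stop("qPCR table lacks columns: ",
                         paste(miss, collapse = ", "))
  q$total_copies <- copies_per_ml(q$mean_copy, q$dna_conc,
                                  q$eluted_volume, q$dna_input,
                                  q$fluid_volume)
  q
}

#' Write / read a fermentation table
#'
#' Columns: \code{sample_id}, the six VFAs (mM), \code{ph}, \code{nh3n}
#' (mg/dL); \code{tvfa} is recomputed on reading.
#'
#' @param ferm fermentation data frame.
#' @param path TSV file.
#' @export
write_fermentation_table <- function(ferm, path) {
  .write_tsv(ferm, path, units = "VFA mM; ph unitless; nh3n mg/dL")
  invisible(path)
}

#' @rdname write_fermentation_table
#' @export
read_fermentation_table <- function(path) {
  f <- .read_tsv(path)
  miss <- setdiff(c("sample_id", .vfa_names), names(f))
  if (length(miss)) stop("fermentation table lacks columns: ",
                         paste(miss, collapse = ", "))
  f$tvfa <- rowSums(f[, .vfa_names])
  f
}

#' Write ground-truth rhythm parameters
#'
#' @param truth truth data frame from [generate_study()].
#' @param path TSV file.
#' @export
write_truth_table <- function(truth, path) {
  .write_tsv(truth, path,
             units = "mesor/amplitude latent log-abundance; peak_time hours")
  invisible(path)
}
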