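#' Default pipeline configuration
#'
#' A small simulate-and-analyze configuration exercising every stage:
#' simulation, per-contrast rhythm classification, quantification (estimated
#' absolute abundance, alpha diversity), fermentation statistics, one
#' SparCC network with modules/roles/niche breadth, and cross-kingdom
#' Mantel tests.
#'
#' @param seed integer master seed; every stochastic stage derives its own
#'   substream from it.
#' @param outdir output directory.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1, outdir = "rumenrhythm_out") {
  list(
    seed = seed,
    outdir = outdir,
    simulate = list(
      n_cows = 8, n_taxa = 24, n_days = 2,
      clock_times = c(2, 8, 14, 20),
      groups = c("ALF", "DF", "NF", "RFT2d", "RFT7d"),
      kingdoms = c("bacteria", "archaea"),
      noise_sd = 0.05, cow_effect_sd = 0.3,
      class_mix = c(FTR = 6, MFR = 4, ARRHYTHMIC = 4,
                    CCR = 2, InCCR = 2, GCR = 3, LCR = 3)
    ),
    contrasts = c("DF_vs_NF", "RFT2d_vs_RFT7d"),
    alpha = 0.05,
    window = c(9, 15),
    mixed = TRUE,
    network = list(group = "ALF", r_threshold = 0.3, p_threshold = 0.05,
                   n_boot = 50),
    mantel = list(method = "spearman", permutations = 199)
  )
}

.check_config <- function(config) {
  if (is.null(config$seed)) stop("config needs a seed")
  if (is.null(config$outdir)) stop("config needs an outdir")
  if (is.null(config$simulate)) {
    need <- c("abundance_paths", "metadata_path")
    miss <- setdiff(need, names(config))
    if (length(miss)) {
      stop("config must either contain a `simulate` block or input paths (",
           paste(miss, collapse = ", "), ")")
    }
    for (p in c(unlist(config$abundance_paths), config$metadata_path,
                config$qpcr_path, config$fermentation_path)) {
      if (!file.exists(p)) stop("missing input file: ", p)
    }
  }
  groups <- if (!is.null(config$simulate)) config$simulate$groups
            else config$groups
  for (ct in config$contrasts) {
    gs <- strsplit(ct, "_vs_")[[1]]
    if (length(gs) != 2 || !all(gs %in% groups)) {
      stop("contrast ", ct, " requires both of its groups in the design")
    }
  }
  if (!is.null(config$network) && !(config$network$group %in% groups)) {
    stop("network group ", config$network$group, " not in the design")
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- simulate (or load inputs), fit and
#' classify rhythms per contrast, quantify (estimated absolute abundance,
#' alpha diversity), fermentation statistics, SparCC network with modules /
#' Zi-Pi roles / niche breadth / feature-rhythm correlations, and
#' cross-kingdom Mantel tests -- writing every stage's TSV plus a
#' machine-readable JSON manifest (seed, thresholds, output checksums).
#' Re-running with the same configuration reproduces byte-identical outputs.
#'
#' @param config configuration list (see [default_pipeline_config()]) or the
#'   path to a YAML file holding one.
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config$simulate$class_mix)) {
    config$simulate$class_mix <- unlist(config$simulate$class_mix)
  }
  .check_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  results <- list()

  # --- stage 1: inputs -------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    design <- study_design(
      n_cows = sim$n_cows, groups = sim$groups,
      clock_times = sim$clock_times, n_days = sim$n_days,
      n_taxa = sim$n_taxa, kingdoms = sim$kingdoms,
      noise_sd = sim$noise_sd, cow_effect_sd = sim$cow_effect_sd,
      seed = seed)
    study <- generate_study(design, sim$class_mix)
    abundance <- study$abundance
    metadata <- study$metadata
    qpcr <- study$qpcr
    ferm <- study$fermentation
    for (kd in names(abundance)) {
      write_abundance_table(abundance[[kd]],
                            file.path(outdir, paste0("abundance_", kd, ".tsv")))
    }
    write_sample_metadata(metadata, file.path(outdir, "metadata.tsv"))
    write_qpcr_table(qpcr, file.path(outdir, "qpcr.tsv"))
    write_fermentation_table(ferm, file.path(outdir, "fermentation.tsv"))
    write_truth_table(study$truth, file.path(outdir, "truth.tsv"))
    results$study <- study
  } else {
    abundance <- lapply(config$abundance_paths, read_abundance_table)
    metadata <- read_sample_metadata(config$metadata_path)
    qpcr <- if (!is.null(config$qpcr_path))
      read_qpcr_table(config$qpcr_path) else NULL
    ferm <- if (!is.null(config$fermentation_path))
      read_fermentation_table(config$fermentation_path) else NULL
  }

  # --- stage 2: rhythm classification per contrast ---------------------
  alpha <- config$alpha %||% 0.05
  window <- config$window %||% c(9, 15)
  mixed <- config$mixed %||% TRUE
  results$classification <- list()
  for (ct in config$contrasts) {
    for (kd in names(abundance)) {
      cls <- classify_taxa(abundance[[kd]], metadata, contrast = ct,
                           alpha = alpha, window = window, mixed = mixed)
      groups <- strsplit(ct, "_vs_")[[1]]
      samp <- metadata$sample_id[metadata$group %in% groups]
      summ <- summarize_classes(cls, abundance[[kd]][samp, , drop = FALSE])
      .write_tsv(cls, file.path(outdir,
                                sprintf("classification_%s_%s.tsv", kd, ct)),
                 units = "peaks hours; p-values unitless")
      .write_tsv(summ, file.path(outdir,
                                 sprintf("class_summary_%s_%s.tsv", kd, ct)),
                 units = "mean_abundance_pct percent of total reads")
      results$classification[[paste(kd, ct, sep = ".")]] <-
        list(classes = cls, summary = summ)
    }
  }

  # --- stage 3: quantification -----------------------------------------
  if (!is.null(qpcr)) {
    for (kd in names(abundance)) {
      qk <- qpcr[qpcr$kingdom == kd, ]
      totals <- stats::setNames(qk$total_copies, qk$sample_id)
      eaa <- eaa_table(abundance[[kd]], totals)
      write_abundance_table(eaa, file.path(outdir, paste0("eaa_", kd, ".tsv")),
                            mode = "counts")
      results$eaa[[kd]] <- eaa
    }
  }
  alpha_div <- do.call(rbind, lapply(names(abundance), function(kd) {
    data.frame(sample_id = rownames(abundance[[kd]]), kingdom = kd,
               shannon = apply(abundance[[kd]], 1, shannon),
               stringsAsFactors = FALSE)
  }))
  .write_tsv(alpha_div, file.path(outdir, "alpha_diversity.tsv"),
             units = "shannon bits (log2)")
  results$alpha_diversity <- alpha_div

  # --- stage 4: fermentation -------------------------------------------
  if (!is.null(ferm)) {
    ferm_out <- annotate_fermentation(ferm)
    write_fermentation_table(ferm_out, file.path(outdir,
                                                 "fermentation_derived.tsv"))
    results$fermentation <- ferm_out
  }

  # --- stage 5: network ecology ----------------------------------------
  if (!is.null(config$network)) {
    net_cfg <- config$network
    samp <- metadata$sample_id[metadata$group == net_cfg$group]
    tabs <- lapply(names(abundance), function(kd) {
      m <- abundance[[kd]][samp, , drop = FALSE]
      colnames(m) <- paste(kd, colnames(m), sep = "|")
      m
    })
    joint <- do.call(cbind, tabs)
    joint <- joint / rowSums(joint)
    kingdoms <- stats::setNames(
      rep(names(abundance), vapply(tabs, ncol, integer(1))),
      colnames(joint))
    est <- sparcc_bootstrap(joint, n_boot = net_cfg$n_boot %||% 100,
                            seed = seed + 1L)
    net <- build_network(est, r_threshold = net_cfg$r_threshold %||% 0.3,
                         p_threshold = net_cfg$p_threshold %||% 0.05,
                         kingdoms = kingdoms)
    mods <- detect_modules(net)
    feats <- node_features(net)
    roles <- zi_pi(net, mods$membership)
    nb <- levins_niche_breadth(joint, metadata$clock_time[match(samp,
                                                      metadata$sample_id)])
    node_tab <- Reduce(function(a, b) merge(a, b, by = "taxon_id"),
                       list(feats, roles, nb))
    node_tab$kingdom <- kingdoms[node_tab$taxon_id]
    edges <- igraph::as_data_frame(net, what = "edges")
    edge_tab <- data.frame(taxon_a = edges$from, taxon_b = edges$to,
                           r = edges$weight, stringsAsFactors = FALSE)
    .write_tsv(node_tab, file.path(outdir, "network_nodes.tsv"),
               units = "Zi/Pi unitless; B Levins breadth")
    .write_tsv(edge_tab, file.path(outdir, "network_edges.tsv"),
               units = "r SparCC correlation")
    # node features vs rhythm parameters of the same group
    grp_md <- metadata[metadata$group == net_cfg$group, ]
    params <- do.call(rbind, lapply(names(abundance), function(kd) {
      tab <- abundance[[kd]][grp_md$sample_id, , drop = FALSE]
      do.call(rbind, lapply(colnames(tab), function(tx) {
        f <- fit_cosinor(tab[, tx], grp_md$clock_time)
        data.frame(taxon_id = paste(kd, tx, sep = "|"), mesor = f$mesor,
                   amplitude = f$amplitude, rhythm_p = f$rhythm_p,
                   stringsAsFactors = FALSE)
      }))
    }))
    fr <- feature_rhythm_correlation(
      feats[, c("taxon_id", "degree", "weighted_degree", "closeness",
                "betweenness")], params)
    .write_tsv(fr, file.path(outdir, "feature_rhythm_correlation.tsv"),
               units = "rho Spearman")
    results$network <- list(est = est, net = net, modules = mods,
                            nodes = node_tab, edges = edge_tab,
                            correlations = fr)
  }

  # --- stage 6: cross-kingdom Mantel tests -----------------------------
  if (length(abundance) >= 2 && !is.null(config$mantel)) {
    kds <- names(abundance)
    pairs <- utils::combn(kds, 2, simplify = FALSE)
    mt <- do.call(rbind, lapply(seq_along(pairs), function(i) {
      pr <- pairs[[i]]
      d1 <- bray_curtis(abundance[[pr[1]]])
      d2 <- bray_curtis(abundance[[pr[2]]])
      res <- mantel_test(d1, d2, method = config$mantel$method %||% "spearman",
                         permutations = config$mantel$permutations %||% 999,
                         seed = seed + 2L + i)
      data.frame(kingdom_a = pr[1], kingdom_b = pr[2], r = res$r, p = res$p,
                 stringsAsFactors = FALSE)
    }))
    .write_tsv(mt, file.path(outdir, "mantel.tsv"),
               units = "r Mantel correlation")
    results$mantel <- mt
  }

  # --- manifest ---------------------------------------------------------
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = "rumenrhythm",
    version = as.character(utils::packageVersion("rumenrhythm")),
    seed = seed,
    alpha = alpha, window = window,
    r_threshold = config$network$r_threshold %||% NA,
    p_threshold = config$network$p_threshold %||% NA,
    n_boot = config$network$n_boot %||% NA,
    outputs = as.list(tools::md5sum(file.path(outdir, files)))
  )
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
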