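# log-ratio variance matrix T_ij = var(log(x_i / x_j)) over samples
.logratio_var <- function(logx) {
  d <- ncol(logx)
  v <- apply(logx, 2, stats::var)
  cv <- stats::cov(logx)
  outer(v, v, "+") - 2 * cv + diag(0, d)
}

# solve the basis-variance system under the sparsity assumption, with an
# exclusion mask of strongly correlated pairs removed from the equations
.solve_basis <- function(tmat, include) {
  m <- include * 1
  diag(m) <- rowSums(include)
  rhs <- rowSums(tmat * include)
  omega <- solve(m, rhs)
  pmax(omega, .Machine$double.eps)
}

.cor_from_basis <- function(tmat, omega) {
  r <- (outer(omega, omega, "+") - tmat) / (2 * sqrt(outer(omega, omega)))
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  r
}

#' SparCC correlation estimate for compositional data
#'
#' Estimates correlations among the latent (basis) abundances underlying a
#' compositional table from the log-ratio variances
#' \eqn{T_{ij} = \mathrm{var}(\log x_i/x_j)}. Under the sparsity assumption
#' the basis variances \eqn{\omega_i} solve the linear system
#' \eqn{\sum_{j \ne i} T_{ij} = (D-1)\omega_i + \sum_{j \ne i} \omega_j},
#' and \eqn{r_{ij} = (\omega_i + \omega_j - T_{ij}) /
#' (2\sqrt{\omega_i\omega_j})}, clipped to \eqn{[-1, 1]}. The most strongly
#' correlated pair above \code{exclusion_threshold} is then iteratively
#' removed from the equations and the system re-solved, up to
#' \code{exclusion_rounds} times, to protect the sparsity assumption.
#'
#' Zeros are handled by a fixed pseudocount on the relative abundances
#' (rows are renormalized afterwards). With a fixed pseudocount the
#' procedure is deterministic, so \code{inner_iterations} (kept for
#' interface parity with count-resampling variants of the estimator) does
#' not alter the result.
#'
#' @param x samples x taxa matrix of relative abundances (or counts, which
#'   are closed to fractions), at least 5 taxa and 10 samples.
#' @param inner_iterations retained for interface parity; see Details.
#' @param exclusion_threshold absolute correlation above which a pair may be
#'   excluded from the basis-variance equations.
#' @param exclusion_rounds maximum number of exclusion iterations.
#' @param pseudocount value added to every entry before taking logs.
#' @return object of class \code{sparcc_cor}: list with \code{taxa},
#'   \code{r} (symmetric, unit diagonal), \code{p} (NULL until
#'   [sparcc_bootstrap()] is run), \code{n_bootstrap}, \code{excluded}
#'   (logical matrix of pairs removed from the equations) and
#'   \code{dropped} (zero-variance taxa removed from the input).
#' @references Friedman & Alm's log-ratio variance estimator for sparse
#'   compositional correlation.
#' @export
sparcc <- function(x, inner_iterations = 20, exclusion_threshold = 0.1,
                   exclusion_rounds = 10, pseudocount = 1e-6) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("taxon", seq_len(ncol(x)))
  zero_var <- apply(x, 2, function(col) stats::var(col) == 0)
  dropped <- colnames(x)[zero_var]
  if (length(dropped)) {
    warning("dropping zero-variance taxa: ", paste(dropped, collapse = ", "))
    x <- x[, !zero_var, drop = FALSE]
  }
  d <- ncol(x)
  if (d < 5) stop("SparCC requires at least 5 taxa (basis-variance system)")
  if (nrow(x) < 10) stop("SparCC requires at least 10 samples")

  x <- x + pseudocount
  x <- x / rowSums(x)
  logx <- log(x)
  tmat <- .logratio_var(logx)

  include <- matrix(TRUE, d, d)
  diag(include) <- FALSE
  omega <- .solve_basis(tmat, include)
  r <- .cor_from_basis(tmat, omega)
  if (exclusion_rounds > 0) {
    for (round in seq_len(exclusion_rounds)) {
      cand <- abs(r)
      cand[!include] <- -Inf
      cand[lower.tri(cand, diag = TRUE)] <- -Inf
      top <- arrayInd(which.max(cand), dim(cand))
      i <- top[1]; j <- top[2]
      if (!is.finite(cand[i, j]) || cand[i, j] <= exclusion_threshold) break
      # keep the system solvable: each taxon needs >= 2 included partners
      if (sum(include[i, ]) <= 2 || sum(include[j, ]) <= 2) break
      include[i, j] <- include[j, i] <- FALSE
      omega <- .solve_basis(tmat, include)
      r <- .cor_from_basis(tmat, omega)
    }
  }
  structure(list(
    taxa = colnames(x), r = r, p = NULL, n_bootstrap = 0,
    excluded = !include & upper.tri(include), dropped = dropped,
    pseudocount = pseudocount,
    exclusion_threshold = exclusion_threshold,
    exclusion_rounds = exclusion_rounds
  ), class = "sparcc_cor")
}

#' Bootstrap significance for SparCC correlations
#'
#' Builds a null distribution by resampling, in each replicate, every taxon's
#' column independently with replacement across samples -- preserving each
#' taxon's marginal distribution while breaking inter-taxon association --
#' and re-running the SparCC estimator. The two-sided p-value per pair is
#' the fraction of null replicates with \eqn{|r_{boot}| \ge |r_{obs}|}, with
#' the continuity floor \eqn{1/(n_{boot}+1)}:
#' \eqn{p = (1 + \#\{|r^*| \ge |r|\}) / (n_{boot} + 1)}.
#'
#' @param x samples x taxa table as in [sparcc()].
#' @param n_boot number of null replicates (the study convention is 100).
#' @param seed integer seed.
#' @param ... passed on to [sparcc()].
#' @return a \code{sparcc_cor} with the \code{p} matrix filled in
#'   (diagonal NA).
#' @export
sparcc_bootstrap <- function(x, n_boot = 100, seed = 1, ...) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  est <- sparcc(x, ...)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("taxon", seq_len(ncol(x)))
  x <- x[, est$taxa, drop = FALSE]
  n <- nrow(x)
  robs <- abs(est$r)
  count <- matrix(0L, nrow(robs), ncol(robs))
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      xb <- apply(x, 2, function(col) col[sample.int(n, n, replace = TRUE)])
      colnames(xb) <- est$taxa
      eb <- tryCatch(suppressWarnings(sparcc(xb, ...)),
                     error = function(e) NULL)
      rb <- robs * 0
      if (!is.null(eb)) {
        pos <- match(eb$taxa, est$taxa)
        rb[pos, pos] <- abs(eb$r)
      }
      count <- count + (rb >= robs)
    }
  })
  p <- (1 + count) / (n_boot + 1)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(est$r) <- list(est$taxa, est$taxa)
  est$p <- p
  est$n_bootstrap <- n_boot
  est
}

#' Build a signed co-occurrence network from a correlation estimate
#'
#' Keeps edges with \code{|r| > r_threshold} (strict) and
#' \code{p < p_threshold} (strict); isolated nodes are retained with
#' degree 0. If no p matrix is available only the correlation filter
#' applies.
#'
#' @param est a \code{sparcc_cor} (or any list with \code{taxa}, \code{r}
#'   and optionally \code{p}).
#' @param r_threshold absolute-correlation cutoff (default 0.3).
#' @param p_threshold significance cutoff (default 0.05).
#' @param kingdoms optional named vector tagging each taxon with its
#'   kingdom, stored as a vertex attribute.
#' @return an \pkg{igraph} undirected graph with edge attribute
#'   \code{weight} (signed r) and \code{abs_weight}.
#' @export
build_network <- function(est, r_threshold = 0.3, p_threshold = 0.05,
                          kingdoms = NULL) {
  r <- est$r
  taxa <- est$taxa
  keep <- abs(r) > r_threshold
  if (!is.null(est$p)) keep <- keep & (est$p < p_threshold)
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  keep[is.na(keep)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    from = taxa[idx[, 1]], to = taxa[idx[, 2]],
    weight = r[keep], stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = taxa, stringsAsFactors = FALSE))
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$abs_weight <- abs(igraph::E(g)$weight)
  }
  if (!is.null(kingdoms)) {
    igraph::V(g)$kingdom <- unname(kingdoms[igraph::V(g)$name])
  }
  g
}

#' Topological node features of a microbial network
#'
#' Degree, weighted degree (sum of absolute edge correlations), closeness
#' and betweenness. Shortest paths are unweighted; closeness is computed
#' within each connected component as \eqn{(n_{comp}-1)/\sum d} and
#' isolated nodes get closeness 0; betweenness excludes path endpoints.
#'
#' @param net an igraph network from [build_network()].
#' @return data frame with columns \code{taxon_id}, \code{degree},
#'   \code{weighted_degree}, \code{closeness}, \code{betweenness}.
#' @export
node_features <- function(net) {
  nm <- igraph::V(net)$name
  deg <- igraph::degree(net)
  wdeg <- if (igraph::ecount(net) > 0) {
    igraph::strength(net, weights = abs(igraph::E(net)$weight))
  } else rep(0, length(nm))
  dmat <- igraph::distances(net, weights = NA)
  clo <- vapply(seq_along(nm), function(i) {
    d <- dmat[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else length(d) / sum(d)
  }, numeric(1))
  btw <- igraph::betweenness(net, directed = FALSE, weights = NA)
  data.frame(taxon_id = nm, degree = unname(deg),
             weighted_degree = unname(wdeg), closeness = clo,
             betweenness = unname(btw), stringsAsFactors = FALSE)
}

#' Detect network modules by greedy modularity maximization
#'
#' Agglomerative (fast-greedy) modularity optimization on absolute edge
#' weights. The algorithm is deterministic; \code{seed} is accepted for
#' interface uniformity with the stochastic stages.
#'
#' @param net an igraph network.
#' @param seed unused by the deterministic algorithm; kept so that module
#'   detection slots into seeded pipelines uniformly.
#' @return list with \code{membership} (named integer vector) and
#'   \code{modularity} (Q of the returned partition).
#' @export
detect_modules <- function(net, seed = 1) {
  nm <- igraph::V(net)$name
  if (igraph::ecount(net) == 0) {
    memb <- seq_along(nm)
    names(memb) <- nm
    return(list(membership = memb, modularity = 0))
  }
  cm <- igraph::cluster_fast_greedy(net,
                                    weights = abs(igraph::E(net)$weight))
  memb <- igraph::membership(cm)
  q <- igraph::modularity(net, memb, weights = abs(igraph::E(net)$weight))
  if (q <= 0) {
    # no split beats the trivial partition (e.g. a complete graph)
    memb[] <- 1L
    q <- igraph::modularity(net, memb, weights = abs(igraph::E(net)$weight))
  }
  list(membership = memb, modularity = q)
}

#' Within-module (Zi) and among-module (Pi) connectivity and node roles
#'
#' \eqn{Z_i = (k_i - \bar{k}_{m})/\sigma_{k_m}} standardizes each node's
#' within-module degree against its module's mean and standard deviation
#' (\eqn{Z_i = 0} when the module is degenerate), and
#' \eqn{P_i = 1 - \sum_s (k_{is}/k_i)^2} measures how evenly a node's links
#' spread over modules (\eqn{P_i = 0} for isolated nodes). Roles follow the
#' strict thresholds: network hubs \eqn{Z_i > 2.5, P_i > 0.62}; module hubs
#' \eqn{Z_i > 2.5, P_i \le 0.62}; connectors \eqn{Z_i \le 2.5, P_i > 0.62};
#' peripheral otherwise.
#'
#' @param net an igraph network.
#' @param membership module assignment per node (named, as from
#'   [detect_modules()]).
#' @return data frame with \code{taxon_id}, \code{module}, \code{Zi},
#'   \code{Pi}, \code{role}.
#' @export
zi_pi <- function(net, membership) {
  nm <- igraph::V(net)$name
  if (!all(nm %in% names(membership))) {
    stop("membership must cover all network nodes")
  }
  memb <- membership[nm]
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  adj <- (adj != 0) * 1
  k <- rowSums(adj)
  mods <- sort(unique(memb))
  # k_is: links from node i into module s
  kis <- vapply(mods, function(s) rowSums(adj[, memb == s, drop = FALSE]),
                numeric(length(nm)))
  if (is.null(dim(kis))) kis <- matrix(kis, nrow = length(nm))
  kin <- kis[cbind(seq_along(nm), match(memb, mods))]
  zi <- numeric(length(nm))
  for (s in mods) {
    in_s <- memb == s
    mu <- mean(kin[in_s])
    sdv <- stats::sd(kin[in_s])
    zi[in_s] <- if (is.na(sdv) || sdv == 0) 0 else (kin[in_s] - mu) / sdv
  }
  pi <- ifelse(k == 0, 0, 1 - rowSums((kis / pmax(k, 1))^2))
  role <- ifelse(zi > 2.5,
                 ifelse(pi > 0.62, "network_hub", "module_hub"),
                 ifelse(pi > 0.62, "connector", "peripheral"))
  data.frame(taxon_id = nm, module = unname(memb), Zi = zi, Pi = pi,
             role = role, stringsAsFactors = FALSE)
}

#' Levins' niche breadth
#'
#' \eqn{B_j = 1/\sum_{i=1}^{N} P_{ij}^2} where \eqn{P_{ij}} is the share of
#' taxon \eqn{j}'s abundance found in community \eqn{i} (so
#' \eqn{\sum_i P_{ij} = 1}); \eqn{1 \le B_j \le N}. Communities are sample
#' strata (e.g. sampling times); a taxon's abundance per community is the
#' mean over the community's samples.
#'
#' @param abundance samples x taxa matrix.
#' @param communities factor of length \code{nrow(abundance)} assigning each
#'   sample to a community.
#' @return data frame with \code{taxon_id}, \code{B}, \code{N}.
#' @export
levins_niche_breadth <- function(abundance, communities) {
  communities <- factor(communities)
  n_comm <- nlevels(communities)
  comm_mean <- apply(abundance, 2, function(col)
    tapply(col, communities, mean))
  comm_mean <- matrix(comm_mean, nrow = n_comm,
                      dimnames = list(levels(communities),
                                      colnames(abundance)))
  tot <- colSums(comm_mean)
  if (any(tot <= 0)) {
    stop("niche breadth undefined for all-zero taxa: ",
         paste(utils::head(colnames(abundance)[tot <= 0], 3), collapse = ", "))
  }
  p <- sweep(comm_mean, 2, tot, "/")
  b <- 1 / colSums(p^2)
  data.frame(taxon_id = colnames(abundance), B = unname(b), N = n_comm,
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(x, y) = \sum |x_i - y_i| / \sum (x_i + y_i)} between all sample
#' pairs of an abundance table.
#'
#' @param abundance samples x taxa matrix.
#' @return a \code{dist} object.
#' @export
bray_curtis <- function(abundance) {
  vegan::vegdist(as.matrix(abundance), method = "bray")
}

#' Mantel test between two distance matrices
#'
#' Correlates the off-diagonal entries of two distance matrices (Spearman by
#' default) and assesses significance by permuting the sample labels of the
#' second matrix: \eqn{p = (1 + \#\{|r^*| \ge |r|\})/(n_{perm} + 1)}
#' (two-sided, with a floor of \eqn{1/(n_{perm}+1)}).
#'
#' @param d1,d2 \code{dist} objects or square symmetric matrices over the
#'   same samples (matched by names when present).
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @param permutations number of label permutations.
#' @param seed integer seed.
#' @return list with \code{r}, \code{p}, \code{permutations}, \code{method}.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        permutations = 999, seed = 1) {
  method <- match.arg(method)
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2))) {
      stop("distance matrices are over different sample sets")
    }
    m2 <- m2[rownames(m1), rownames(m1)]
  } else if (!all(dim(m1) == dim(m2))) {
    stop("distance matrices have mismatched dimensions")
  }
  n <- nrow(m1)
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  r_obs <- stats::cor(v1, m2[lt], method = method)
  count <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(permutations)) {
      idx <- sample.int(n)
      rp <- stats::cor(v1, m2[idx, idx][lt], method = method)
      if (abs(rp) >= abs(r_obs)) count <- count + 1L
    }
  })
  list(r = r_obs, p = (1 + count) / (permutations + 1),
       permutations = permutations, method = method)
}

#' Rank correlations between node features and rhythm parameters
#'
#' Spearman correlation (with p-value) between each network node feature and
#' each circadian rhythm parameter over the shared taxa, including the
#' amplitude/mesor ratio and the rhythmicity p-value among the parameters
#' when available.
#'
#' @param features data frame with \code{taxon_id} and numeric feature
#'   columns (e.g. from [node_features()]).
#' @param params data frame with \code{taxon_id} and numeric rhythm
#'   parameter columns (e.g. mesor, amplitude, rhythm_p).
#' @return data frame with \code{feature}, \code{parameter}, \code{rho},
#'   \code{p}, \code{n} and a \code{degenerate} flag for constant inputs
#'   (rho and p reported as NA).
#' @export
feature_rhythm_correlation <- function(features, params) {
  shared <- intersect(features$taxon_id, params$taxon_id)
  if (length(shared) < 3) stop("fewer than 3 shared taxa")
  f <- features[match(shared, features$taxon_id), , drop = FALSE]
  p <- params[match(shared, params$taxon_id), , drop = FALSE]
  if (all(c("amplitude", "mesor") %in% names(p)) &&
      !"amp_mesor_ratio" %in% names(p)) {
    p$amp_mesor_ratio <- p$amplitude / p$mesor
  }
  fcols <- names(f)[vapply(f, is.numeric, logical(1))]
  pcols <- names(p)[vapply(p, is.numeric, logical(1))]
  out <- expand.grid(feature = fcols, parameter = pcols,
                     stringsAsFactors = FALSE)
  out$rho <- NA_real_
  out$p <- NA_real_
  out$n <- length(shared)
  out$degenerate <- FALSE
  for (i in seq_len(nrow(out))) {
    xv <- f[[out$feature[i]]]
    yv <- p[[out$parameter[i]]]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
      out$degenerate[i] <- TRUE
      next
    }
    ct <- suppressWarnings(stats::cor.test(xv, yv, method = "spearman",
                                           exact = FALSE))
    out$rho[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out
}

#' @export
print.sparcc_cor <- function(x, ...) {
  cat("SparCC correlation estimate:", length(x$taxa), "taxa\n")
  off <- abs(x$r[upper.tri(x$r)])
  cat(sprintf("  mean |r| %.3f  max |r| %.3f  excluded pairs %d\n",
              mean(off), max(off), sum(x$excluded)))
  if (!is.null(x$p)) cat("  bootstrap p available (n_boot =",
                         x$n_bootstrap, ")\n")
  invisible(x)
}
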