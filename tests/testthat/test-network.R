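test_that("SparCC matches a direct transcription of the estimator", {
  x <- basis_fractions(41, n = 200, rho = 0.8)
  est <- sparcc(x, exclusion_rounds = 0)
  expect_equal(unname(est$r), sparcc_basic_oracle(x), tolerance = 1e-9)
})

test_that("SparCC output is a valid correlation estimate", {
  x <- basis_fractions(42, rho = 0.8)
  est <- sparcc(x)
  expect_equal(unname(diag(est$r)), rep(1, 5))
  expect_equal(est$r, t(est$r), tolerance = 1e-9)
  expect_true(all(abs(est$r) <= 1))
  # permutation invariance to taxon order
  perm <- c(3, 1, 5, 2, 4)
  xp <- x[, perm]
  colnames(xp) <- paste0("taxon", perm)
  estp <- sparcc(xp)
  expect_equal(unname(estp$r), unname(est$r[perm, perm]), tolerance = 1e-9)
})

test_that("SparCC recovers a planted basis correlation and rejects nulls", {
  x <- basis_fractions(43, rho = 0.8)
  est <- sparcc(x)
  expect_lt(abs(est$r[1, 2] - 0.8), 0.1)
  null_r <- abs(est$r[upper.tri(est$r)])
  null_r <- null_r[-1]  # drop the planted pair (1,2)
  expect_true(all(null_r < 0.15))
  # fully independent basis
  xn <- basis_fractions(44, rho = 0)
  en <- sparcc(xn)
  expect_true(all(abs(en$r[upper.tri(en$r)]) < 0.15))
})

test_that("SparCC beats naive Pearson under dominant-taxon closure", {
  x <- basis_fractions(45, rho = 0, mu = c(3, 0, 0, 0, 0))
  est <- sparcc(x)
  pear <- stats::cor(x)
  expect_lt(mean(abs(est$r[upper.tri(est$r)])),
            mean(abs(pear[upper.tri(pear)])))
})

test_that("SparCC input preconditions are enforced", {
  x <- basis_fractions(46)
  expect_error(sparcc(x[, 1:4]), "at least 5 taxa")
  expect_error(sparcc(x[1:9, ]), "at least 10 samples")
  xz <- cbind(x, constant = 0.1)
  xz <- xz / rowSums(xz)
  xz[, 6] <- 0.2  # exactly constant taxon
  expect_warning(ez <- sparcc(xz), "zero-variance")
  expect_equal(length(ez$taxa), 5)
})

test_that("bootstrap p-values respect the floor and ceiling", {
  x <- basis_fractions(47, rho = 0)
  x[, 2] <- 2 * x[, 1]
  x <- x / rowSums(x)
  est <- sparcc_bootstrap(x, n_boot = 100, seed = 5)
  off <- est$p[upper.tri(est$p)]
  expect_true(all(off >= 1 / 101 - 1e-12 & off <= 1))
  # perfectly coupled pair sits at the floor
  expect_equal(est$p[1, 2], 1 / 101)
})

test_that("bootstrap p-values are approximately uniform under the null", {
  # pool pairs from several independent null datasets for a stable KS check
  ps <- unlist(lapply(1:10, function(s) {
    x <- basis_fractions(400 + s, n = 100, rho = 0)
    est <- sparcc_bootstrap(x, n_boot = 100, seed = s)
    est$p[upper.tri(est$p)]
  }))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.15)
})

test_that("network construction applies strict thresholds", {
  taxa <- c("a", "b", "c")
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.5
  r[1, 3] <- r[3, 1] <- 0.25
  r[2, 3] <- r[3, 2] <- -0.4
  p <- matrix(0.01, 3, 3)
  p[2, 3] <- p[3, 2] <- 0.2
  net <- build_network(list(taxa = taxa, r = r, p = p))
  expect_equal(igraph::ecount(net), 1)
  expect_equal(igraph::vcount(net), 3)       # isolated nodes retained
  # r = 0.3 exactly is excluded
  r[1, 2] <- r[2, 1] <- 0.3
  net2 <- build_network(list(taxa = taxa, r = r, p = p))
  expect_equal(igraph::ecount(net2), 0)
  # thresholds (0, 1) keep every finite-p pair
  net3 <- build_network(list(taxa = taxa, r = r, p = p),
                        r_threshold = 0, p_threshold = 1)
  expect_equal(igraph::ecount(net3), 3)
})

test_that("node features follow the closed-form graph examples", {
  path_est <- list(taxa = c("a", "b", "c"),
                   r = {m <- diag(3); m[1, 2] <- m[2, 1] <- 0.5
                        m[2, 3] <- m[3, 2] <- 0.6; m},
                   p = matrix(1e-3, 3, 3))
  nf <- node_features(build_network(path_est))
  expect_equal(nf$degree, c(1, 2, 1))
  expect_equal(nf$weighted_degree, c(0.5, 1.1, 0.6))
  expect_equal(nf$betweenness[2], 1)
  expect_equal(nf$closeness[2], 1)
  # triangle: all betweenness zero
  tri <- list(taxa = c("a", "b", "c"),
              r = {m <- matrix(0.5, 3, 3); diag(m) <- 1; m},
              p = matrix(1e-3, 3, 3))
  expect_equal(node_features(build_network(tri))$betweenness, rep(0, 3))
  # two disjoint edges: component-restricted closeness is 1 for all
  dj <- list(taxa = letters[1:4],
             r = {m <- diag(4); m[1, 2] <- m[2, 1] <- 0.5
                  m[3, 4] <- m[4, 3] <- 0.5; m},
             p = matrix(1e-3, 4, 4))
  expect_equal(node_features(build_network(dj))$closeness, rep(1, 4))
})

test_that("module detection recovers canonical modular graphs", {
  r <- diag(8)
  for (i in 1:4) for (j in 1:4) if (i != j) r[i, j] <- 0.8
  for (i in 5:8) for (j in 5:8) if (i != j) r[i, j] <- 0.8
  r[4, 5] <- r[5, 4] <- 0.5
  est <- list(taxa = letters[1:8], r = r, p = matrix(1e-4, 8, 8))
  net <- build_network(est)
  mods <- detect_modules(net)
  memb <- mods$membership
  expect_equal(length(unique(memb[1:4])), 1)
  expect_equal(length(unique(memb[5:8])), 1)
  expect_false(memb[1] == memb[5])
  expect_gt(mods$modularity, 0)
  # determinism
  expect_identical(memb, detect_modules(net)$membership)
  # complete graph: single module, Q <= 0 for any non-trivial split
  rc <- matrix(0.9, 6, 6); diag(rc) <- 1
  netc <- build_network(list(taxa = letters[1:6], r = rc,
                             p = matrix(1e-4, 6, 6)))
  mc <- detect_modules(netc)
  expect_equal(length(unique(mc$membership)), 1)
  # edgeless: one module per node, Q = 0
  nete <- build_network(list(taxa = letters[1:3], r = diag(3),
                             p = matrix(1, 3, 3)))
  me <- detect_modules(nete)
  expect_equal(length(unique(me$membership)), 3)
  expect_equal(me$modularity, 0)
})

test_that("Zi/Pi and roles follow their closed forms", {
  # star of 4 leaves inside one module: all of b's edges internal -> Pi 0
  r <- diag(5)
  for (j in 2:5) r[1, j] <- r[j, 1] <- 0.5
  net <- build_network(list(taxa = letters[1:5], r = r,
                            p = matrix(1e-3, 5, 5)))
  memb <- stats::setNames(rep(1L, 5), letters[1:5])
  zp <- zi_pi(net, memb)
  expect_equal(zp$Pi, rep(0, 5))
  # node with 2 edges in module A and 2 in module B -> Pi = 0.5
  r2 <- diag(5)
  for (j in 2:5) r2[1, j] <- r2[j, 1] <- 0.5
  net2 <- build_network(list(taxa = letters[1:5], r = r2,
                             p = matrix(1e-3, 5, 5)))
  memb2 <- stats::setNames(c(1L, 1L, 1L, 2L, 2L), letters[1:5])
  zp2 <- zi_pi(net2, memb2)
  expect_equal(zp2$Pi[zp2$taxon_id == "a"], 0.5)
  # equal within-degrees (clique) -> Zi = 0 -> peripheral at low Pi
  rq <- matrix(0.7, 4, 4); diag(rq) <- 1
  netq <- build_network(list(taxa = letters[1:4], r = rq,
                             p = matrix(1e-3, 4, 4)))
  zq <- zi_pi(netq, stats::setNames(rep(1L, 4), letters[1:4]))
  expect_true(all(zq$Zi == 0))
  expect_true(all(zq$role == "peripheral"))
  expect_true(all(zp$role == "peripheral"))
  # Pi <= 1 - 1/M for M modules
  expect_true(all(zp2$Pi <= 1 - 1 / 2 + 1e-12))
  expect_error(zi_pi(net2, memb2[1:3]), "cover")
})

test_that("Levins' niche breadth matches its closed forms", {
  ab <- cbind(even = rep(0.25, 4), single = c(1, 0, 0, 0),
              half = c(0.3, 0.3, 0, 0))
  rownames(ab) <- paste0("s", 1:4)
  nb <- levins_niche_breadth(ab, paste0("c", 1:4))
  expect_equal(nb$B[nb$taxon_id == "even"], 4)
  expect_equal(nb$B[nb$taxon_id == "single"], 1)
  expect_equal(nb$B[nb$taxon_id == "half"], 2)
  expect_true(all(nb$B >= 1 & nb$B <= nb$N))
  ab0 <- cbind(ab, zero = 0)
  expect_error(levins_niche_breadth(ab0, paste0("c", 1:4)), "all-zero")
})

test_that("Bray-Curtis distances match their definition", {
  m <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 1)
  expect_equal(d["a", "c"], 0)
})

test_that("the Mantel test hits the permutation floor on identical inputs", {
  d1 <- withr::with_seed(51, stats::dist(matrix(stats::runif(60), 15)))
  mt <- mantel_test(d1, d1, permutations = 999, seed = 1)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 1000)
})

test_that("the Mantel test is calibrated under the null", {
  ps <- vapply(1:100, function(i) {
    withr::with_seed(600 + i, {
      d1 <- stats::dist(matrix(stats::runif(48), 12))
      d2 <- stats::dist(matrix(stats::runif(48), 12))
    })
    mantel_test(d1, d2, permutations = 199, seed = i)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("Mantel agrees directionally with the vegan implementation", {
  withr::with_seed(52, {
    base <- matrix(stats::runif(60), 15)
    d1 <- stats::dist(base)
    d2 <- stats::dist(base + matrix(stats::rnorm(60, 0, 0.2), 15))
  })
  ours <- mantel_test(d1, d2, method = "pearson", permutations = 499, seed = 2)
  ref <- vegan::mantel(d1, d2, method = "pearson", permutations = 499)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(ours$p, 0.05)
})

test_that("feature-rhythm correlations handle exact and degenerate inputs", {
  f <- data.frame(taxon_id = letters[1:6], degree = 1:6, flat = 1)
  p <- data.frame(taxon_id = letters[1:6], amplitude = (1:6) / 10,
                  mesor = c(6, 5, 4, 3, 2, 1))
  out <- feature_rhythm_correlation(f, p)
  expect_equal(out$rho[out$feature == "degree" & out$parameter == "amplitude"],
               1)
  expect_equal(out$rho[out$feature == "degree" & out$parameter == "mesor"],
               -1)
  flat_rows <- out[out$feature == "flat", ]
  expect_true(all(flat_rows$degenerate))
  expect_true(all(is.na(flat_rows$rho)))
  expect_error(feature_rhythm_correlation(f[1:2, ], p), "3 shared")
})
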