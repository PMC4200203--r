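test_that("signed adjacency maps correlations onto [0, 1]", {
  s <- rnorm(10)
  expr <- rbind(a = s, b = s, c = -s, d = rnorm(10))
  colnames(expr) <- paste0("s", 1:10)
  net <- signed_adjacency(expr, power = 6)
  expect_equal(net$adjacency["a", "b"], 1)            # r = 1
  expect_equal(net$adjacency["a", "c"], 0)            # r = -1
  expect_true(all(net$adjacency >= 0 & net$adjacency <= 1))
  expect_equal(diag(net$adjacency), setNames(rep(1, 4), rownames(expr)))
  # r = 0 -> 0.5^6 under the signed map
  expect_equal(((1 + 0) / 2)^6, 0.015625)
  expect_message(signed_adjacency(rbind(expr, e = rep(2, 10))),
                 "zero-variance")
  expect_error(signed_adjacency(expr[, 1:2]), "3 samples")
})

test_that("scale-free fit index matches a direct log-log regression", {
  set.seed(10)
  # construct a power-law connectivity sample
  k <- (1 - runif(3000))^(-1 / 1.5)   # Pareto tail, alpha ~ 2.5
  k <- k[k < 60]
  got <- scale_free_fit(k, n_bins = 10)
  # oracle regression
  br <- seq(min(k), max(k), length.out = 11)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length); mk <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  fit <- lm(log10(freq[keep]) ~ log10(mk[keep]))
  expect_equal(got, -sign(coef(fit)[[2]]) * summary(fit)$r.squared)
  expect_gte(got, 0.9)

  # narrow-band uniform connectivity is not scale-free
  ku <- runif(2000, 10, 11)
  expect_lt(scale_free_fit(ku), 0.5)
  expect_error(scale_free_fit(rep(3, 50)), "identical")
})

test_that("TOM follows its closed form", {
  # three nodes, all pairwise adjacency 0.5
  net <- list(adjacency = matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3, 3,
                                 dimnames = list(letters[1:3], letters[1:3])),
              genes = letters[1:3])
  class(net) <- "coexpression_network"
  tom <- tom_similarity(net)$tom
  expect_equal(tom["a", "b"], 0.5)  # (0.25 + 0.5) / (1 + 1 - 0.5)
  expect_true(isSymmetric(tom))
  expect_equal(diag(tom), setNames(rep(1, 3), letters[1:3]))

  # no third-party paths: empty off-diagonal adjacency -> TOM 0
  net0 <- net; net0$adjacency <- diag(3)
  dimnames(net0$adjacency) <- dimnames(net$adjacency)
  tom0 <- tom_similarity(net0)$tom
  expect_true(all(tom0[upper.tri(tom0)] == 0))

  # complete graph with unit weights -> TOM 1 everywhere
  net1 <- net; net1$adjacency <- matrix(1, 3, 3,
                                        dimnames = dimnames(net$adjacency))
  tom1 <- tom_similarity(net1)$tom
  expect_true(all(tom1 == 1))
})

test_that("planted blocks are recovered exactly; noise and identical profiles behave", {
  set.seed(20)
  f1 <- rnorm(12); f2 <- rnorm(12)
  blockA <- t(replicate(40, f1 + rnorm(12, 0, 0.25)))
  blockB <- t(replicate(40, f2 + rnorm(12, 0, 0.25)))
  expr <- rbind(blockA, blockB)
  dimnames(expr) <- list(sprintf("g%02d", 1:80), paste0("s", 1:12))
  net <- tom_similarity(signed_adjacency(expr))
  cl <- cluster_and_cut(net, min_module_size = 10)
  truth <- rep(1:2, each = 40)
  expect_equal(adjusted_rand(truth, cl$labels), 1)

  # i.i.d. noise: at least 90% unassigned
  set.seed(21)
  noise <- matrix(rnorm(200 * 24), 200, 24,
                  dimnames = list(sprintf("n%03d", 1:200), paste0("s", 1:24)))
  cn <- cluster_and_cut(tom_similarity(signed_adjacency(noise)))
  expect_gte(mean(cn$labels == 0), 0.9)

  # identical profiles cluster into a single all-member module
  ident <- matrix(rep(rnorm(12), each = 40), 40, 12,
                  dimnames = list(sprintf("i%02d", 1:40), paste0("s", 1:12)))
  ni <- tom_similarity(signed_adjacency(ident))
  ci <- cluster_and_cut(ni, min_module_size = 10)
  expect_equal(unname(table(ci$labels)[["1"]]), 40L)

  # fewer genes than the size floor -> everything unassigned, with warning
  expect_warning(tiny <- cluster_and_cut(ni, min_module_size = 100),
                 "fewer genes")
  expect_true(all(tiny$labels == 0))
})

test_that("module eigengenes are first principal components", {
  set.seed(30)
  prof <- rnorm(10)
  ident <- t(replicate(8, 3 * prof + 5))
  dimnames(ident) <- list(sprintf("g%d", 1:8), paste0("s", 1:10))
  labels <- setNames(rep(1L, 8), rownames(ident))
  me <- module_eigengene(ident, labels)
  # identical profiles: eigengene is the standardized shared profile,
  # unit-normalized; kME = 1 for every member
  z <- (prof - mean(prof)) / sd(prof)
  expect_equal(unname(me[1, ]), z / sqrt(sum(z^2)), tolerance = 1e-10)
  k <- kme(ident, me)
  expect_equal(unname(k$kme[, 1]), rep(1, 8), tolerance = 1e-10)
  expect_true(all(k$p[, 1] < 1e-10))

  # first-PC optimality: variance explained equals the top eigenvalue of
  # the standardized gene covariance across samples
  set.seed(31)
  mixed <- matrix(rnorm(60), 6, 10,
                  dimnames = list(sprintf("m%d", 1:6), paste0("s", 1:10)))
  lab2 <- setNames(rep(1L, 6), rownames(mixed))
  me2 <- module_eigengene(mixed, lab2)
  zs <- t(scale(t(mixed)))
  ev <- eigen(crossprod(zs), symmetric = TRUE)
  expect_equal(abs(sum(zs %*% t(me2) * (zs %*% t(me2)))),
               ev$values[1], tolerance = 1e-8)
  expect_equal(abs(sum(me2[1, ] * ev$vectors[, 1])), 1, tolerance = 1e-8)

  # negating all member profiles flips the eigengene
  me3 <- module_eigengene(-mixed, lab2)
  expect_equal(unname(me3[1, ]), unname(-me2[1, ]), tolerance = 1e-10)

  expect_error(module_eigengene(matrix(1, 2, 5,
                                       dimnames = list(c("a", "b"), NULL)),
                                setNames(c(1L, 1L), c("a", "b"))),
               "constant")
})

test_that("module merging follows the eigengene-correlation rule", {
  set.seed(40)
  f <- rnorm(12)
  m1 <- t(replicate(10, f + rnorm(12, 0, 0.3)))
  m2 <- t(replicate(10, f + rnorm(12, 0, 0.3)))    # correlated with m1
  m3 <- t(replicate(10, rnorm(12)))                 # independent
  expr <- rbind(m1, m2, m3)
  dimnames(expr) <- list(sprintf("g%02d", 1:30), paste0("s", 1:12))
  labels <- setNames(rep(1:3, each = 10), rownames(expr))
  merged <- merge_modules(expr, labels, cut = 0.75)
  expect_equal(length(unique(merged$labels)), 2L)
  expect_equal(unname(merged$labels["g01"]), unname(merged$labels["g11"]))
  expect_false(merged$labels["g01"] == merged$labels["g21"])

  # all pairwise eigengene correlations below the cut: labels unchanged
  set.seed(41)
  indep <- rbind(t(replicate(10, rnorm(12))), t(replicate(10, rnorm(12))))
  dimnames(indep) <- list(sprintf("h%02d", 1:20), paste0("s", 1:12))
  li <- setNames(rep(1:2, each = 10), rownames(indep))
  mi <- merge_modules(indep, li, cut = 0.75)
  expect_equal(length(unique(mi$labels)), 2L)

  # idempotence
  again <- merge_modules(expr, merged$labels, cut = 0.75)
  expect_equal(again$labels, merged$labels)
})

test_that("merging matches an exhaustive merge-order search on a 4-module toy", {
  set.seed(42)
  f1 <- rnorm(12); f2 <- rnorm(12)
  mk <- function(base, sdv) t(replicate(8, base + rnorm(12, 0, sdv)))
  expr <- rbind(mk(f1, 0.2), mk(f1, 0.2), mk(f2, 0.2), mk(f2, 0.2))
  dimnames(expr) <- list(sprintf("g%02d", 1:32), paste0("s", 1:12))
  labels <- setNames(rep(1:4, each = 8), rownames(expr))
  got <- merge_modules(expr, labels, cut = 0.75)

  # oracle: explore every order of admissible merges; collect the reachable
  # final partitions (as partitions of the gene set)
  partition_of <- function(lab) unname(lapply(split(names(lab), lab), sort))
  finals <- new.env(parent = emptyenv())
  explore <- function(lab) {
    mods <- sort(unique(lab))
    me <- module_eigengene(expr, lab)
    cc <- cor(t(me)); diag(cc) <- -Inf
    idx <- which(cc > 0.75, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    if (!nrow(idx)) {
      key <- paste(vapply(partition_of(lab), paste, "", collapse = ","),
                   collapse = ";")
      assign(key, TRUE, envir = finals)
      return(invisible())
    }
    for (r in seq_len(nrow(idx))) {
      lab2 <- lab
      lab2[lab2 == mods[idx[r, 2]]] <- mods[idx[r, 1]]
      explore(lab2)
    }
  }
  explore(labels)
  keys <- ls(finals)
  expect_length(keys, 1L)  # toy built so the final partition is unique
  got_key <- paste(vapply(unname(lapply(split(names(got$labels),
                                              got$labels), sort)),
                          paste, "", collapse = ","), collapse = ";")
  expect_equal(got_key, keys)
})

test_that("module-trait correlation flags planted associations", {
  stage <- rep(c(1, 0), c(6, 18))
  me <- rbind(ME1 = stage + rnorm(24, 0, 0.05),
              ME2 = rnorm(24))
  colnames(me) <- paste0("s", 1:24)
  traits <- data.frame(twocell = stage, other = rnorm(24),
                       const = rep(1, 24))
  expect_warning(mt <- module_trait_correlation(me, traits), "constant")
  expect_true(mt$flags["ME1", "twocell"])
  expect_false(mt$flags["ME2", "twocell"])
  expect_true(is.na(mt$r["ME1", "const"]))
  # eigengene equal to a one-hot indicator: r = 1
  me2 <- rbind(ME1 = stage)
  colnames(me2) <- paste0("s", 1:24)
  mt2 <- module_trait_correlation(me2, data.frame(twocell = stage))
  expect_equal(mt2$r["ME1", "twocell"], 1)
  # consistent sample permutation leaves r unchanged
  perm <- sample(24)
  mt3 <- module_trait_correlation(me[, perm, drop = FALSE],
                                  traits[perm, c("twocell", "other")])
  expect_equal(mt3$r, mt$r[, c("twocell", "other")])
})

test_that("hub edges are the top-weighted intra-module pairs", {
  set.seed(50)
  expr <- matrix(rnorm(20 * 12), 20, 12,
                 dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:12)))
  net <- tom_similarity(signed_adjacency(expr))
  labels <- setNames(rep(c(1L, 2L), each = 10), rownames(expr))
  ed <- hub_edges(net, labels, module = 1L, top_k = 5)
  expect_equal(nrow(ed), 5L)
  # full-sort oracle
  g <- names(labels)[labels == 1L]
  sub <- net$tom[g, g]
  allw <- sort(sub[upper.tri(sub)], decreasing = TRUE)
  expect_equal(ed$weight, allw[1:5])
  # top_k larger than the edge count returns all edges
  ed_all <- hub_edges(net, labels, module = 1L, top_k = 1000)
  expect_equal(nrow(ed_all), choose(10, 2))
  # 3-gene module has at most 3 edges
  lab3 <- setNames(c(1L, 1L, 1L, rep(0L, 17)), rownames(expr))
  expect_lte(nrow(hub_edges(net, lab3, 1L)), 3L)
  expect_equal(nrow(hub_edges(net, labels, module = 99L)), 0L)
})

test_that("hypergeometric enrichment equals the exact tail sum, BH adjusted", {
  universe <- sprintf("u%03d", 1:100)
  module <- universe[1:10]
  gene_set <- universe[c(1:8, 50:61)]  # overlap 8 of 20
  res <- module_enrichment(module, list(myset = gene_set), universe)
  # exhaustive hypergeometric tail: sum over overlaps >= 8
  tail_sum <- sum(vapply(8:10, function(k)
    choose(20, k) * choose(80, 10 - k) / choose(100, 10), numeric(1)))
  expect_equal(res$p, tail_sum, tolerance = 1e-12)

  # module = universe: every set has p = 1
  res2 <- module_enrichment(universe, list(a = gene_set, b = universe[1:3]),
                            universe)
  expect_true(all(res2$p == 1))

  # BH keeps ordering and adjusted >= raw
  set.seed(60)
  sets <- lapply(1:8, function(i) sample(universe, 20))
  names(sets) <- paste0("set", 1:8)
  res3 <- module_enrichment(module, sets, universe)
  expect_true(all(res3$p_adj >= res3$p))
  expect_true(all(diff(res3$p_adj[order(res3$p)]) >= 0))
  expect_error(module_enrichment(module, sets, character()), "empty")
})
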