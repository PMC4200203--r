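#' Signed weighted co-expression adjacency
#'
#' Builds the signed adjacency `a_ij = ((1 + r_ij)/2)^power` from the Pearson
#' correlation `r` of gene expression profiles; perfectly anti-correlated
#' genes get adjacency 0, perfectly correlated genes 1. The soft-threshold
#' power (default 6) is the conventional choice making such networks
#' approximately scale-free. The naive map `r^power` (which destroys the
#' sign for even powers) is available for comparison via `signed = FALSE`.
#'
#' @param expr numeric matrix, genes x samples (at least 3 samples);
#'   zero-variance genes are removed with a message
#' @param power soft-threshold exponent beta (default 6)
#' @param signed use the signed map (default `TRUE`)
#' @return object of class `coexpression_network`: list with `genes`, `cor`,
#'   `adjacency`, `k` (connectivity), `power`; `tom` is filled by
#'   [tom_similarity()]
#' @export
signed_adjacency <- function(expr, power = 6, signed = TRUE) {
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  v <- apply(expr, 1L, sd)
  if (any(v == 0)) {
    message("removing ", sum(v == 0), " zero-variance gene(s)")
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2L) stop("need at least 2 variable genes")
  r <- cor(t(expr))
  a <- if (signed) ((1 + r) / 2)^power else r^power
  diag(a) <- 1
  k <- rowSums(a) - 1
  structure(list(genes = rownames(expr), cor = r, adjacency = a, k = k,
                 power = power, tom = NULL),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, beta = %g, %s TOM\n",
              length(x$genes), x$power,
              if (is.null(x$tom)) "without" else "with"))
  invisible(x)
}

#' Scale-free topology fit index
#'
#' Bins the connectivity vector into `n_bins` equal-width bins and regresses
#' `log10(frequency)` on `log10(mean connectivity)` over the non-empty bins;
#' returns the signed fit index `-sign(slope) * R^2`, which approaches 1 for
#' a power-law (scale-free) degree distribution.
#'
#' @param k connectivity vector (e.g. `network$k`)
#' @param n_bins number of bins (default 10)
#' @return signed R-squared
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  if (length(unique(k)) < 2L) stop("all connectivities identical")
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mk <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & mk > 0
  if (sum(keep) < 2L) stop("fewer than two non-empty bins")
  fit <- stats::lm(log10(freq[keep]) ~ log10(mk[keep]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[[2L]]) * r2
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over third parties `u != i, j`; `TOM_ii = 1`.
#' Topological overlap smooths the adjacency by shared network neighbours
#' and is the standard input dissimilarity (as `1 - TOM`) for module
#' detection.
#'
#' @param network a `coexpression_network`
#' @return the network with `$tom` filled in
#' @export
tom_similarity <- function(network) {
  a <- network$adjacency
  diag(a) <- 0
  l <- a %*% a               # l_ij = sum_u a_iu a_uj, u != i,j by diag 0
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  network$tom <- tom
  network
}

#' Module detection by average-linkage clustering with a simplified dynamic
#' tree cut
#'
#' Clusters `1 - TOM` by average-linkage hierarchical clustering and cuts
#' the dendrogram statically at the `cut_quantile` quantile of merge
#' heights. When `deep_split` is on, every resulting branch is then examined
#' recursively: candidate sub-cut heights over the branch's internal merges
#' are scanned, each one is scored by the number of coherent sub-branches
#' (at least `min_module_size` genes, mean internal merge height at least
#' `min_gap` below the static cut height) it would produce, and the branch
#' is re-cut at the best height whenever that yields two or more coherent
#' sub-branches; genes attaching only above the sub-cut fall off as
#' unassigned. A final cluster is kept as a module only when it is coherent
#' by the same rule (or has near-zero internal heights, i.e. identical
#' profiles). Everything else is labelled 0 (unassigned, the "grey" pool).
#' Modules are numbered 1, 2, ... by decreasing size. Correlated
#' sub-modules produced by an aggressive split are reunited downstream by
#' [merge_modules()].
#'
#' @param network a `coexpression_network` with TOM (or a TOM matrix)
#' @param min_module_size smallest module size (default 30)
#' @param deep_split recursively split heterogeneous branches (default TRUE)
#' @param cut_quantile static cut at this quantile of merge heights
#'   (default 0.99)
#' @param min_gap coherence gap on the 1-TOM scale (default 0.1)
#' @param n_scan number of candidate sub-cut heights scanned per branch
#'   (default 60)
#' @return list with `labels` (named integer vector, 0 = unassigned) and
#'   `dendrogram` (the `hclust` object)
#' @export
cluster_and_cut <- function(network, min_module_size = 30L,
                            deep_split = TRUE, cut_quantile = 0.99,
                            min_gap = 0.1, n_scan = 60L) {
  tom <- if (inherits(network, "coexpression_network")) network$tom
         else network
  if (is.null(tom)) stop("run tom_similarity() first")
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom)))
  n <- nrow(tom)
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all unassigned")
    return(list(labels = setNames(rep(0L, n), genes), dendrogram = NULL))
  }
  d <- 1 - tom
  hc <- hclust(as.dist(d), method = "average")
  h_cut <- unname(quantile(hc$height, cut_quantile))
  raw <- cutree(hc, h = h_cut)

  # leaf sets of every internal merge node
  nm <- nrow(hc$merge)
  merge_leaves <- vector("list", nm)
  for (i in seq_len(nm)) {
    l <- hc$merge[i, 1L]; r <- hc$merge[i, 2L]
    merge_leaves[[i]] <- c(if (l < 0) -l else merge_leaves[[l]],
                           if (r < 0) -r else merge_leaves[[r]])
  }
  merge_sizes <- lengths(merge_leaves)

  first_leaf <- vapply(merge_leaves, `[`, integer(1L), 1L)
  internal_nodes <- function(members) {
    inset <- logical(n); inset[members] <- TRUE
    which(vapply(seq_len(nm), function(i)
      merge_sizes[i] <= length(members) &&
        all(inset[merge_leaves[[i]]]), logical(1L)))
  }
  # coherence of a branch: mean internal merge height well below the static
  # cut (or essentially zero, i.e. identical profiles)
  coh_value_v <- function(mh) ((h_cut - mh) >= min_gap) | (mh < min_gap)
  recurse <- function(members) {
    if (length(members) < min_module_size) return(list())
    nodes <- internal_nodes(members)
    if (deep_split && length(nodes) >= 2L) {
      hs <- sort(unique(hc$height[nodes]))
      cand <- if (length(hs) > n_scan)
        unique(unname(quantile(hs, seq(0, 1, length.out = n_scan),
                               type = 1L)))
      else hs
      cand <- cand[cand < max(hs)]
      if (length(cand)) {
        ct <- cutree(hc, h = cand)  # n x length(cand), components in C
        if (is.null(dim(ct))) ct <- matrix(ct, ncol = 1L)
        best <- NULL; best_score <- 1L
        for (j in rev(seq_along(cand))) {  # highest cut wins at equal score
          grp <- ct[members, j]
          sizes <- table(grp)
          big <- names(sizes)[sizes >= min_module_size]
          if (length(big) < 2L) next
          keep_nodes <- nodes[hc$height[nodes] <= cand[j]]
          node_grp <- as.character(ct[first_leaf[keep_nodes], j])
          mh <- tapply(hc$height[keep_nodes], node_grp, mean)
          okn <- intersect(big, names(mh))
          ok <- okn[coh_value_v(mh[okn])]
          if (length(ok) > best_score) {
            best <- split(members, grp)[ok]
            best_score <- length(ok)
          }
        }
        if (!is.null(best))
          return(unlist(lapply(best, recurse), recursive = FALSE))
      }
    }
    list(members)
  }

  clusters <- unlist(lapply(split(seq_len(n), raw), recurse),
                     recursive = FALSE)
  keep <- vapply(clusters, function(m) {
    if (length(m) < min_module_size) return(FALSE)
    hs <- hc$height[internal_nodes(m)]
    if (!length(hs)) return(FALSE)
    mh <- mean(hs)
    (h_cut - mh) >= min_gap || mh < min_gap
  }, logical(1L))
  labels <- setNames(rep(0L, n), genes)
  kept <- clusters[keep]
  if (length(kept)) {
    ord <- order(-vapply(kept, length, integer(1L)),
                 vapply(kept, min, integer(1L)))
    for (m in seq_along(ord)) labels[kept[[ord[m]]]] <- m
  }
  list(labels = labels, dendrogram = hc)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' member-gene expression (each gene standardized to mean 0, sd 1 across
#' samples), unit-normalized and sign-oriented so its mean correlation with
#' the member genes is non-negative.
#'
#' @param expr matrix, genes x samples
#' @param labels named integer module labels (0 = unassigned, skipped)
#' @return matrix, modules x samples, rownames `ME<label>`
#' @export
module_eigengene <- function(expr, labels) {
  mods <- sort(unique(labels[labels != 0L]))
  if (!length(mods)) stop("no modules")
  out <- matrix(NA_real_, length(mods), ncol(expr),
                dimnames = list(paste0("ME", mods), colnames(expr)))
  for (m in seq_along(mods)) {
    g <- names(labels)[labels == mods[m]]
    sub <- expr[g, , drop = FALSE]
    s <- apply(sub, 1L, sd)
    if (any(s == 0)) stop("constant gene in module ", mods[m])
    z <- (sub - rowMeans(sub)) / s
    sv <- svd(z, nu = 0L, nv = 1L)
    e <- sv$v[, 1L]
    e <- e / sqrt(sum(e^2))
    if (mean(cor(t(z), e)) < 0) e <- -e
    out[m, ] <- e
  }
  out
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively merges the pair of modules whose eigengenes are most highly
#' correlated, while that correlation exceeds `cut` (default 0.75),
#' recomputing the merged eigengene after every merge. Ties break toward the
#' smallest label pair; merged modules keep the smaller label.
#'
#' @param expr matrix, genes x samples
#' @param labels named module labels (0 ignored)
#' @param cut merge when eigengene correlation is strictly above this value
#' @return list with `labels` (relabelled 1..K by decreasing size) and
#'   `eigengenes` of the merged modules
#' @export
merge_modules <- function(expr, labels, cut = 0.75) {
  labels <- labels
  repeat {
    mods <- sort(unique(labels[labels != 0L]))
    if (length(mods) < 2L) break
    me <- module_eigengene(expr, labels)
    cc <- cor(t(me))
    diag(cc) <- -Inf
    best <- max(cc)
    if (best <= cut) break
    idx <- which(cc == best, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE][1L, ]
    keep_lab <- mods[idx[1L]]
    drop_lab <- mods[idx[2L]]
    labels[labels == drop_lab] <- keep_lab
  }
  # relabel by decreasing size, deterministic
  mods <- sort(unique(labels[labels != 0L]))
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(labels == m), integer(1L))
    new <- setNames(order(order(-sizes, mods)), mods)
    out <- labels
    for (m in mods) out[labels == m] <- new[[as.character(m)]]
    labels <- out
  }
  list(labels = labels,
       eigengenes = if (length(mods)) module_eigengene(expr, labels)
                    else NULL)
}

#' Refine module membership by kME
#'
#' Recomputes the module eigengenes from the current labels, then reassigns
#' every gene to the module whose eigengene it correlates with most
#' strongly, provided that kME reaches `min_kme`; genes below the cut become
#' unassigned (label 0). This membership-based refinement both rescues
#' genes the tree cut left grey and strips passengers the dendrogram
#' absorbed without genuine membership; it is the conventional final step
#' after module detection and merging.
#'
#' @param expr matrix, genes x samples
#' @param labels named module labels (0 = unassigned)
#' @param min_kme minimal kME for membership (default 0.7)
#' @return updated label vector (module numbering preserved)
#' @export
assign_by_kme <- function(expr, labels, min_kme = 0.7) {
  mods <- sort(unique(labels[labels != 0L]))
  if (!length(mods)) return(labels)
  me <- module_eigengene(expr, labels)
  k <- cor(t(expr[names(labels), , drop = FALSE]), t(me))
  best <- apply(k, 1L, which.max)
  bestv <- k[cbind(seq_along(best), best)]
  out <- ifelse(bestv >= min_kme, mods[best], 0L)
  setNames(as.integer(out), names(labels))
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's profile with each module eigengene,
#' with asymptotic p-values from the t distribution on `n - 2` degrees of
#' freedom.
#'
#' @param expr matrix, genes x samples
#' @param eigengenes matrix, modules x samples (from [module_eigengene()])
#' @return list with `kme` and `p` (genes x modules matrices)
#' @export
kme <- function(expr, eigengenes) {
  r <- cor(t(expr), t(eigengenes))
  n <- ncol(expr)
  tstat <- r * sqrt((n - 2) / pmax(1e-12, 1 - r^2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(kme = r, p = p)
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with each numeric sample
#' trait (one-hot stage indicators, genotype, ordinal time), with asymptotic
#' p-values; modules with `r > flag_r` and `p < flag_p` against a trait are
#' flagged as trait-specific.
#'
#' @param eigengenes matrix, modules x samples
#' @param traits data.frame/matrix, samples x traits (numeric; constant
#'   traits yield `NA` with a warning)
#' @param flag_r,flag_p flagging thresholds (defaults 0.7 and 1e-4)
#' @return list with `r`, `p` (modules x traits) and `flags` (logical)
#' @export
module_trait_correlation <- function(eigengenes, traits, flag_r = 0.7,
                                     flag_p = 1e-4) {
  tr <- as.matrix(traits)
  if (nrow(tr) != ncol(eigengenes))
    stop("traits must have one row per sample")
  const <- apply(tr, 2L, sd) == 0
  if (any(const)) warning("constant trait(s): ",
                          paste(colnames(tr)[const], collapse = ", "))
  r <- suppressWarnings(cor(t(eigengenes), tr))
  n <- ncol(eigengenes)
  tstat <- r * sqrt((n - 2) / pmax(1e-12, 1 - r^2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  flags <- !is.na(r) & r > flag_r & p < flag_p
  list(r = r, p = p, flags = flags)
}

#' Strongest intra-module edges
#'
#' Ranks the edges inside a module by TOM weight (falling back to adjacency
#' when the TOM has not been computed) and returns the `top_k` strongest
#' with their nodes.
#'
#' @param network a `coexpression_network`
#' @param labels named module labels
#' @param module module label to extract
#' @param top_k number of edges (default 100)
#' @param use `"tom"` (default) or `"adjacency"`
#' @return data.table `gene_a`, `gene_b`, `weight`, strongest first
#' @export
hub_edges <- function(network, labels, module, top_k = 100L,
                      use = c("tom", "adjacency")) {
  use <- match.arg(use)
  w <- if (use == "tom" && !is.null(network$tom)) network$tom
       else network$adjacency
  g <- names(labels)[labels == module]
  g <- intersect(g, rownames(w))
  if (length(g) < 2L)
    return(data.table::data.table(gene_a = character(),
                                  gene_b = character(), weight = numeric()))
  sub <- w[g, g, drop = FALSE]
  iu <- which(upper.tri(sub), arr.ind = TRUE)
  ed <- data.table::data.table(gene_a = g[iu[, 1L]], gene_b = g[iu[, 2L]],
                               weight = sub[iu])
  data.table::setorder(ed, -weight, gene_a, gene_b)
  head(ed, top_k)
}

#' Hypergeometric gene-set enrichment with BH adjustment
#'
#' Upper-tail hypergeometric test of the overlap between a module and each
#' gene set over a common universe, with Benjamini-Hochberg adjustment
#' across sets. A local stand-in for web-service enrichment tools.
#'
#' @param module_genes character vector
#' @param gene_sets named list of character vectors
#' @param universe character vector of all genes
#' @return data.table `set`, `n_set`, `n_overlap`, `p`, `p_adj`
#' @export
module_enrichment <- function(module_genes, gene_sets, universe) {
  if (!length(universe)) stop("empty universe")
  module_genes <- intersect(module_genes, universe)
  res <- data.table::rbindlist(lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    ov <- length(intersect(module_genes, s))
    p <- phyper(ov - 1L, length(s), length(universe) - length(s),
                length(module_genes), lower.tail = FALSE)
    data.table::data.table(set = nm, n_set = length(s), n_overlap = ov, p = p)
  }))
  res[, p_adj := p.adjust(p, method = "BH")]
  res[]
}
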