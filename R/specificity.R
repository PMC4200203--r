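#' Jensen-Shannon temporal specificity scores
#'
#' For each feature, the expression vector across conditions is transformed
#' as `v_c = log10(FPKM_c + 1)` (condition = individual sample, or the mean
#' FPKM within a stage when `groups` is given), normalized to a probability
#' vector `p = v / sum(v)`, and scored against each condition's unit vector
#' `e_c` as `score_c = 1 - JSdist(p, e_c)`, where `JSdist` is the square root
#' of the Jensen-Shannon divergence in base-2 logarithms (so the distance
#' lies in \[0, 1\] and a transcript expressed exclusively in one condition
#' scores exactly 1 there). All-zero features score 0 in every condition by
#' convention. The maximal score over conditions summarizes a feature's
#' specificity.
#'
#' @param expr numeric matrix, features x samples (FPKM, non-negative)
#' @param groups optional factor/character of length `ncol(expr)` grouping
#'   samples into conditions (e.g. stages); default: each sample is its own
#'   condition
#' @return list with `scores` (features x conditions matrix), `max_score`
#'   and `argmax` (named vectors per feature)
#' @export
specificity_scores <- function(expr, groups = NULL) {
  if (any(expr < 0)) stop("FPKM matrix must be non-negative")
  if (is.null(groups)) {
    cond <- expr
  } else {
    groups <- as.character(groups)
    if (length(groups) != ncol(expr))
      stop("groups must have one entry per sample")
    lev <- unique(groups)
    cond <- matrix(0, nrow(expr), length(lev),
                   dimnames = list(rownames(expr), lev))
    for (g in lev)
      cond[, g] <- rowMeans(expr[, groups == g, drop = FALSE])
  }
  if (ncol(cond) < 2L) stop("need at least two conditions")
  v <- log10(cond + 1)
  tot <- rowSums(v)
  p <- v / ifelse(tot > 0, tot, 1)
  nc <- ncol(cond)
  scores <- matrix(0, nrow(expr), nc,
                   dimnames = list(rownames(expr), colnames(cond)))
  for (cidx in seq_len(nc)) {
    e <- numeric(nc); e[cidx] <- 1
    scores[, cidx] <- 1 - sqrt(.jsd_rows(p, e))
  }
  scores[tot == 0, ] <- 0  # unexpressed: maximally non-specific
  mx <- apply(scores, 1L, max)
  am <- colnames(scores)[apply(scores, 1L, which.max)]
  list(scores = scores, max_score = mx,
       argmax = setNames(am, rownames(expr)))
}

# Jensen-Shannon divergence (base-2) of each row of p against vector q
.jsd_rows <- function(p, q) {
  qm <- matrix(q, nrow(p), length(q), byrow = TRUE)
  m <- (p + qm) / 2
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  h <- function(mat) -rowSums(plogp(mat))
  pmax(0, h(m) - (h(p) + h(qm)) / 2)
}

#' Jensen-Shannon distance between two probability vectors
#'
#' Square root of the base-2 Jensen-Shannon divergence; lies in \[0, 1\].
#'
#' @param p,q probability vectors of equal length
#' @return scalar distance
#' @export
js_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  sqrt(.jsd_rows(matrix(p, nrow = 1L), q)[1L])
}

#' Between-sample correlation structure of lncRNAs versus mRNAs
#'
#' Computes the sample-by-sample Spearman correlation matrix within each
#' feature class and compares the two sets of off-diagonal coefficients with
#' a two-sample t test (lncRNA-based sample correlations are expected to be
#' lower when lncRNAs are more specific).
#'
#' @param expr_lnc,expr_mrna matrices, features x samples, with identical
#'   sample columns
#' @param method correlation method (default `"spearman"`)
#' @return list with `cor_lnc`, `cor_mrna` (sample x sample matrices),
#'   `t_statistic`, `p_value`, `mean_lnc`, `mean_mrna`
#' @export
sample_correlation_compare <- function(expr_lnc, expr_mrna,
                                       method = "spearman") {
  if (!identical(colnames(expr_lnc), colnames(expr_mrna)))
    stop("the two matrices must cover the same samples")
  if (ncol(expr_lnc) < 3L) stop("need at least 3 samples")
  cl <- cor(expr_lnc, method = method)
  cm <- cor(expr_mrna, method = method)
  ol <- cl[upper.tri(cl)]
  om <- cm[upper.tri(cm)]
  tt <- t.test(ol, om)
  list(cor_lnc = cl, cor_mrna = cm,
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_lnc = mean(ol), mean_mrna = mean(om))
}

#' Maximal expression per feature
#'
#' @param expr matrix, features x samples (FPKM)
#' @param groups optional named list of feature-id vectors; when given,
#'   quantile summaries are reported per group
#' @param probs quantiles to report (default quartiles)
#' @return list with `max_fpkm` (named vector) and `summary` (data.table per
#'   group when `groups` is given)
#' @export
max_expression_distribution <- function(expr, groups = NULL,
                                        probs = c(0.25, 0.5, 0.75)) {
  mx <- apply(expr, 1L, max)
  out <- list(max_fpkm = mx)
  if (!is.null(groups)) {
    out$summary <- data.table::rbindlist(lapply(names(groups), function(g) {
      v <- mx[intersect(groups[[g]], names(mx))]
      data.table::data.table(group = g, n = length(v),
                             q = probs, value = unname(quantile(v, probs)))
    }))
  }
  out
}

#' Mean conservation of transcripts
#'
#' The conservation of a transcript is the arithmetic mean of the per-base
#' conservation scores over its exons; bases without a score are ignored.
#' Transcripts with no scored base are `NA` (undefined, not zero).
#'
#' @param x a `transcript_set`
#' @param track conservation `RleList` with `NA` for unscored bases
#' @return named numeric vector per transcript (`NA` when undefined)
#' @export
transcript_conservation <- function(x, track) {
  stopifnot(inherits(x, "transcript_set"))
  res <- .exon_stat(x, track, "meansum")
  # v1 = sum of scored values, v2 = count of NA bases in-track; bases beyond
  # the track are unscored as well
  res[, in_track := 0L]
  for (ch in unique(res$chrom)) {
    if (!ch %in% names(track)) next
    len <- length(track[[ch]])
    idx <- which(res$chrom == ch)
    res$in_track[idx] <- pmax(0L, pmin(res$end[idx], len) -
                                pmax(res$start[idx], 0L))
  }
  agg <- res[, .(s = sum(v1), n_scored = sum(in_track) - sum(v2)),
             by = transcript_id]
  out <- ifelse(agg$n_scored > 0, agg$s / agg$n_scored, NA_real_)
  setNames(out, agg$transcript_id)[x$tx$transcript_id]
}
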