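#' Transcription start sites of a transcript set
#'
#' @param x a `transcript_set`
#' @return data.table with `transcript_id`, `chrom`, `strand`, `tss`
#'   (0-based position of the first transcribed base; for unknown strand the
#'   leftmost coordinate is used)
#' @export
tss_table <- function(x) {
  stopifnot(inherits(x, "transcript_set"))
  x$tx[, .(transcript_id, chrom, strand,
           tss = ifelse(strand == "-", span_end - 1L, span_start))]
}

#' Neighbouring gene pairs
#'
#' Builds unordered feature pairs that lie close on the genome. In
#' `genebody` mode two features are neighbours when the minimal span-to-span
#' gap is strictly below `max_gap` (overlapping spans have gap 0), ignoring
#' strand. In `tss` mode the criterion is `|TSS - TSS| < max_gap`. A feature
#' may appear in several pairs.
#'
#' @param features a `transcript_set`; the `biotype` metadata column
#'   (values containing `"lnc"` are treated as lncRNA, everything else as
#'   coding) sets the `pair_class`
#' @param max_gap distance cutoff in bases (default 10000, strict `<`)
#' @param mode `"genebody"` or `"tss"`
#' @return data.table of pairs: `id_a`, `id_b` (sorted within pair),
#'   `pair_class` (`"lnc:coding"`, `"coding:coding"` or `"lnc:lnc"`),
#'   `genebody_gap`, `tss_gap`
#' @export
find_neighbors <- function(features, max_gap = 10000L,
                           mode = c("genebody", "tss")) {
  mode <- match.arg(mode)
  stopifnot(inherits(features, "transcript_set"))
  txt <- features$tx
  if (mode == "genebody") {
    gr <- GenomicRanges::GRanges(txt$chrom,
      IRanges::IRanges(txt$span_start + 1L, txt$span_end))
  } else {
    ts <- tss_table(features)$tss
    gr <- GenomicRanges::GRanges(txt$chrom, IRanges::IRanges(ts + 1L, ts + 1L))
  }
  hits <- GenomicRanges::findOverlaps(gr, maxgap = as.integer(max_gap) - 1L,
                                      drop.self = TRUE,
                                      drop.redundant = TRUE)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  if (!length(i))
    return(data.table::data.table(id_a = character(), id_b = character(),
                                  pair_class = character(),
                                  genebody_gap = integer(),
                                  tss_gap = integer()))
  is_lnc <- grepl("lnc", ifelse(is.na(txt$biotype), "", txt$biotype),
                  ignore.case = TRUE)
  gap_of <- function(i, j) {
    pmax(0L, pmax(txt$span_start[i], txt$span_start[j]) -
              pmin(txt$span_end[i], txt$span_end[j]))
  }
  ts <- tss_table(features)$tss
  pc <- ifelse(is_lnc[i] & is_lnc[j], "lnc:lnc",
        ifelse(!is_lnc[i] & !is_lnc[j], "coding:coding", "lnc:coding"))
  a <- pmin(txt$transcript_id[i], txt$transcript_id[j])
  b <- pmax(txt$transcript_id[i], txt$transcript_id[j])
  out <- data.table::data.table(
    id_a = a, id_b = b, pair_class = pc,
    genebody_gap = gap_of(i, j), tss_gap = abs(ts[i] - ts[j]))
  out <- unique(out, by = c("id_a", "id_b"))
  data.table::setorder(out, id_a, id_b)
  out[]
}

#' Expression correlation of gene pairs
#'
#' Pearson correlation of `log2(FPKM + pseudo)` expression vectors across
#' samples for each pair; pairs with a constant vector on either side get
#' `NA`.
#'
#' @param pairs data.table with `id_a`, `id_b` (e.g. from [find_neighbors()])
#' @param expr numeric matrix, features x samples (FPKM)
#' @param pseudo pseudo-count added before the log (default 0.05)
#' @return `pairs` with a `pearson_r` column appended
#' @export
pair_correlation <- function(pairs, expr, pseudo = 0.05) {
  pairs <- data.table::as.data.table(pairs)
  miss <- setdiff(unique(c(pairs$id_a, pairs$id_b)), rownames(expr))
  if (length(miss))
    stop("features absent from expression matrix: ",
         paste(head(miss, 5L), collapse = ", "))
  lg <- log2(expr + pseudo)
  z <- .row_standardize(lg)
  r <- rowSums(z[pairs$id_a, , drop = FALSE] *
               z[pairs$id_b, , drop = FALSE]) / (ncol(lg) - 1L)
  out <- data.table::copy(pairs)
  out[, pearson_r := r]
  out[]
}

.row_standardize <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  z <- (m - mu) / s
  z[s == 0, ] <- NA_real_  # constant vectors flagged as undefined
  z
}

#' Random coding-pair correlation null
#'
#' For each of `n_perm` permutations, samples `n_pairs` distinct random
#' unordered pairs of coding features (uniform, without replacement within a
#' permutation) and computes [pair_correlation()] for each.
#'
#' @param coding_ids character vector of coding feature ids (length >= 2)
#' @param expr expression matrix, features x samples
#' @param n_pairs pairs per permutation
#' @param n_perm number of permutations (default 100)
#' @param seed RNG seed
#' @param pseudo pseudo-count for the log transform
#' @return list with `pooled` (all correlations), `per_perm` (list of
#'   numeric vectors) and `mean` of the pooled distribution (undefined
#'   correlations excluded)
#' @export
random_pair_null <- function(coding_ids, expr, n_pairs, n_perm = 100L,
                             seed = 1L, pseudo = 0.05) {
  n <- length(coding_ids)
  if (n < 2L) stop("need at least two coding features")
  total <- as.double(n) * (n - 1) / 2
  if (n_pairs > total) stop("n_pairs exceeds the number of distinct pairs")
  set.seed(seed)
  lg <- log2(expr[coding_ids, , drop = FALSE] + pseudo)
  z <- .row_standardize(lg)
  per_perm <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    k <- sort(sample(total, n_pairs))
    # decode linear upper-triangle index into (i, j), i < j
    cum <- cumsum(seq(n - 1L, 1L))
    i <- vapply(k, function(kk) which(kk <= cum)[1L], integer(1L))
    base <- c(0, cum)[i]
    j <- i + (k - base)
    per_perm[[p]] <- rowSums(z[i, , drop = FALSE] * z[j, , drop = FALSE]) /
      (ncol(z) - 1L)
  }
  pooled <- unlist(per_perm)
  list(pooled = pooled, per_perm = per_perm,
       mean = mean(pooled, na.rm = TRUE))
}

#' Compare two correlation (or any numeric) distributions
#'
#' Two-sample Kolmogorov-Smirnov test plus the two distribution means.
#' Undefined values (`NA`) are dropped.
#'
#' @param dist_a,dist_b numeric vectors
#' @return list with `ks_statistic`, `p_value`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`
#' @export
compare_distributions <- function(dist_a, dist_b) {
  a <- dist_a[!is.na(dist_a)]
  b <- dist_b[!is.na(dist_b)]
  if (!length(a) || !length(b)) stop("empty distribution")
  kt <- suppressWarnings(ks.test(a, b))
  list(ks_statistic = unname(kt$statistic), p_value = kt$p.value,
       mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b))
}

#' Orientation and signed TSS distance of gene pairs
#'
#' For each pair a reference gene is chosen: the coding gene in lnc:coding
#' pairs, and a seeded random member in coding:coding pairs. The signed TSS
#' distance runs from the reference TSS to the partner TSS, positive
#' downstream of the reference gene's transcription direction. Opposite
#' strands with the partner TSS at or upstream of the reference TSS
#' (distance <= 0) are `divergent` (bidirectional-promoter candidates);
#' opposite strands with the partner TSS downstream are `convergent`; same
#' strand is `tandem`. Pairs whose reference strand is unknown are flagged
#' `NA`.
#'
#' @param pairs pair table (from [find_neighbors()])
#' @param features the `transcript_set` the pairs refer to
#' @param seed seed for the random reference choice in coding:coding pairs
#' @return `pairs` with `ref_id`, `tss_distance`, `orientation` appended
#' @export
orientation_class <- function(pairs, features, seed = 1L) {
  stopifnot(inherits(features, "transcript_set"))
  pairs <- data.table::copy(data.table::as.data.table(pairs))
  ts <- tss_table(features)
  tssv <- setNames(ts$tss, ts$transcript_id)
  strv <- setNames(ts$strand, ts$transcript_id)
  is_lnc <- grepl("lnc", ifelse(is.na(features$tx$biotype), "",
                                features$tx$biotype), ignore.case = TRUE)
  lncv <- setNames(is_lnc, features$tx$transcript_id)
  set.seed(seed)
  flip <- runif(nrow(pairs)) < 0.5
  ref <- ifelse(lncv[pairs$id_a] & !lncv[pairs$id_b], pairs$id_b,
         ifelse(lncv[pairs$id_b] & !lncv[pairs$id_a], pairs$id_a,
                ifelse(flip, pairs$id_a, pairs$id_b)))
  partner <- ifelse(ref == pairs$id_a, pairs$id_b, pairs$id_a)
  rs <- strv[ref]
  d <- ifelse(rs == "+", tssv[partner] - tssv[ref],
       ifelse(rs == "-", tssv[ref] - tssv[partner], NA_integer_))
  opp <- strv[ref] %in% c("+", "-") & strv[partner] %in% c("+", "-") &
    strv[ref] != strv[partner]
  same <- strv[ref] %in% c("+", "-") & strv[ref] == strv[partner]
  ori <- rep(NA_character_, nrow(pairs))
  ori[same] <- "tandem"
  ori[opp & !is.na(d) & d <= 0] <- "divergent"
  ori[opp & !is.na(d) & d > 0] <- "convergent"
  pairs[, `:=`(ref_id = ref, tss_distance = as.integer(d),
               orientation = ori)]
  pairs[]
}

#' TSS-window enrichment of lncRNA start sites
#'
#' For each lncRNA TSS, the nearest coding TSS on the same chromosome is
#' found and the signed distance (positive downstream of the coding gene's
#' direction) recorded; the fraction of lncRNAs within each `+/- window` and
#' a binned histogram of signed distances are reported.
#'
#' @param lnc,coding `transcript_set` objects (coding needs known strands)
#' @param windows half-widths in bases (default `c(2000, 5000, 10000)`)
#' @param bin_width histogram bin width in bases (default 100)
#' @param max_dist histogram range half-width (default 10000)
#' @return list with `fractions` (named by window), `histogram` (data.table
#'   `bin_start`, `bin_end`, `count`), `distances` (signed, `NA` when no
#'   coding TSS shares the chromosome)
#' @export
tss_window_stats <- function(lnc, coding, windows = c(2000L, 5000L, 10000L),
                             bin_width = 100L, max_dist = 10000L) {
  lt <- tss_table(lnc)
  ct <- tss_table(coding)
  d <- rep(NA_integer_, nrow(lt))
  for (ch in unique(lt$chrom)) {
    li <- which(lt$chrom == ch)
    ci <- which(ct$chrom == ch)
    if (!length(ci)) next
    for (k in li) {
      dd <- lt$tss[k] - ct$tss[ci]
      best <- ci[which.min(abs(dd))]
      sgn <- if (ct$strand[best] == "-") -1L else 1L
      d[k] <- sgn * (lt$tss[k] - ct$tss[best])
    }
  }
  fr <- vapply(windows, function(w) mean(!is.na(d) & abs(d) <= w),
               numeric(1L))
  names(fr) <- paste0("within_", windows)
  breaks <- seq(-max_dist, max_dist, by = bin_width)
  dd <- d[!is.na(d) & abs(d) <= max_dist]
  dd <- pmin(dd, max_dist - 1L)
  cnt <- table(cut(dd, breaks = breaks, right = FALSE))
  hist <- data.table::data.table(bin_start = breaks[-length(breaks)],
                                 bin_end = breaks[-1L],
                                 count = as.integer(cnt))
  list(fractions = fr, histogram = hist, distances = d)
}
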