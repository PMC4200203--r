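#' Per-base signal tracks
#'
#' Coverage and conservation tracks are held as [S4Vectors::RleList] objects
#' named by chromosome: read depth per base (coverage; 0 outside covered
#' regions) or a conservation score per base (`NA` where no score exists).
#' `read_bedgraph()` parses a 4-column bedGraph (0-based half-open) into this
#' form; `write_bedgraph()` is its inverse and omits the background value so
#' parse -> write -> parse is the identity on the data model.
#'
#' @param file bedGraph path
#' @param chrom_lengths named integer vector of chromosome lengths
#' @param background value for bases not covered by any interval: `0` for
#'   read coverage (default), `NA` for conservation
#' @return an `RleList` named by chromosome
#' @export
read_bedgraph <- function(file, chrom_lengths, background = 0) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    score = as.numeric(gr$score))
  build_track(dt, chrom_lengths, background)
}

#' @rdname read_bedgraph
#' @param intervals data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `score`; intervals must not overlap
#' @export
build_track <- function(intervals, chrom_lengths, background = 0) {
  dt <- data.table::as.data.table(intervals)
  data.table::setorder(dt, chrom, start)
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    d <- dt[chrom == ch]
    if (!nrow(d)) return(S4Vectors::Rle(as.numeric(background), len))
    if (any(d$start[-1L] < d$end[-nrow(d)]))
      stop("overlapping bedGraph intervals on ", ch)
    if (d$end[nrow(d)] > len) stop("interval beyond chromosome end on ", ch)
    gaps <- c(d$start, len) - c(0L, d$end)
    vals <- c(rbind(as.numeric(background), c(d$score, 0)))
    lens <- c(rbind(gaps, c(d$end - d$start, 0L)))
    keep <- lens > 0L
    S4Vectors::Rle(vals[keep], lens[keep])
  })
  names(out) <- names(chrom_lengths)
  methods::as(out, "RleList")
}

#' @rdname read_bedgraph
#' @param track an `RleList` track
#' @return for `write_bedgraph`, `file` invisibly
#' @export
write_bedgraph <- function(track, file) {
  con <- base::file(file, open = "wt")
  on.exit(close(con))
  for (ch in names(track)) {
    r <- track[[ch]]
    v <- S4Vectors::runValue(r)
    len <- S4Vectors::runLength(r)
    ends <- cumsum(len)
    starts <- ends - len
    keep <- !is.na(v) & v != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                       format(v[keep], trim = TRUE, scientific = FALSE)),
               con)
  }
  invisible(file)
}

#' Per-base values of a track over an interval
#'
#' @param track an `RleList` track
#' @param chrom chromosome
#' @param start,end 0-based half-open interval
#' @param background value returned for bases outside the track
#' @return numeric vector of length `end - start`
#' @export
track_values <- function(track, chrom, start, end, background = 0) {
  n <- end - start
  out <- rep(as.numeric(background), n)
  if (!chrom %in% names(track)) return(out)
  r <- track[[chrom]]
  len <- length(r)
  lo <- max(start, 0L); hi <- min(end, len)
  if (hi > lo)
    out[(lo - start + 1L):(hi - start)] <-
      as.numeric(S4Vectors::window(r, lo + 1L, hi))
  out
}

# per-transcript exonic statistic helper: f(chrom_rle, starts0, ends) applied
# per chromosome; exon bases beyond the track count as `background`
.exon_stat <- function(x, track, stat = c("covered", "max", "meansum"),
                       min_depth = 1) {
  stat <- match.arg(stat)
  ex <- x$exons
  res <- data.table::data.table(transcript_id = ex$transcript_id,
                                chrom = ex$chrom, start = ex$start,
                                end = ex$end, v1 = 0, v2 = 0)
  for (ch in unique(res$chrom)) {
    idx <- which(res$chrom == ch)
    if (!ch %in% names(track)) next
    r <- track[[ch]]
    len <- length(r)
    s <- pmin(pmax(res$start[idx], 0L), len)
    e <- pmin(res$end[idx], len)
    ok <- which(e > s)
    if (!length(ok)) next
    vw <- IRanges::Views(r, start = s[ok] + 1L, end = e[ok])
    if (stat == "covered") {
      bin <- r >= min_depth
      vwb <- IRanges::Views(bin, start = s[ok] + 1L, end = e[ok])
      res$v1[idx[ok]] <- IRanges::viewSums(vwb, na.rm = TRUE)
    } else if (stat == "max") {
      res$v1[idx[ok]] <- IRanges::viewMaxs(vw, na.rm = TRUE)
    } else {
      res$v1[idx[ok]] <- IRanges::viewSums(vw, na.rm = TRUE)
      nas <- IRanges::Views(methods::as(is.na(r), "Rle"),
                            start = s[ok] + 1L, end = e[ok])
      res$v2[idx[ok]] <- IRanges::viewSums(nas, na.rm = TRUE)
    }
  }
  res
}

#' Transcript reconstruction integrity
#'
#' Fraction of a transcript's exonic bases covered at depth at least
#' `min_depth`. A transcript is conventionally called well-reconstructed at
#' integrity >= 0.75.
#'
#' @param x a `transcript_set`
#' @param cov coverage `RleList`
#' @param min_depth minimum read depth counting a base as covered (default 1)
#' @return named numeric vector in \[0, 1\] per transcript
#' @export
transcript_integrity <- function(x, cov, min_depth = 1) {
  stopifnot(inherits(x, "transcript_set"))
  res <- .exon_stat(x, cov, "covered", min_depth = min_depth)
  agg <- res[, .(frac = sum(v1) / sum(end - start)), by = transcript_id]
  setNames(agg$frac, agg$transcript_id)[x$tx$transcript_id]
}

#' Maximum exonic read coverage
#'
#' Maximum per-base read depth over a transcript's exons; the pipeline's
#' low-expression filter removes transcripts whose maximum coverage falls
#' below a learned threshold (3.77881 reads/base by default).
#'
#' @inheritParams transcript_integrity
#' @return named numeric vector per transcript
#' @export
max_coverage <- function(x, cov) {
  stopifnot(inherits(x, "transcript_set"))
  res <- .exon_stat(x, cov, "max")
  agg <- res[, .(m = max(v1)), by = transcript_id]
  setNames(agg$m, agg$transcript_id)[x$tx$transcript_id]
}

#' ROC threshold learning from scores and labels
#'
#' Builds the ROC of `scores` as a predictor of the positive `labels` over
#' all candidate thresholds (the sorted unique scores; prediction is
#' `score >= threshold`), returns the area under the curve and the threshold
#' maximizing Youden's J = sensitivity + specificity - 1, ties broken toward
#' the smaller threshold.
#'
#' @param scores numeric scores
#' @param labels logical labels (TRUE = positive class)
#' @return list with `threshold`, `auc`, and the ROC table `roc`
#'   (threshold, sensitivity, specificity, youden)
#' @export
learn_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("threshold learning needs both labels present")
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1L))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1L))
  youden <- sens + spec - 1
  best <- which(youden == max(youden))[1L]  # thr sorted: first = smallest
  auc <- (sum(rank(scores)[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(threshold = thr[best], auc = auc,
       roc = data.frame(threshold = thr, sensitivity = sens,
                        specificity = spec, youden = youden))
}

#' Learn the minimal read-coverage threshold from reference transcripts
#'
#' For the coding and the non-coding reference class separately, transcripts
#' are labelled well-reconstructed when their best integrity across samples
#' reaches `integrity_cut`; the maximum exonic coverage across samples is the
#' ROC score and the per-class threshold maximizes Youden's J
#' ([learn_threshold()]). The final threshold is the average of the two class
#' thresholds. When a class carries a single label only, its threshold falls
#' back to `default` with a warning.
#'
#' @param coding,noncoding `transcript_set` objects of reference coding and
#'   non-coding transcripts
#' @param cov_list list of per-sample coverage `RleList` tracks
#' @param integrity_cut integrity defining well-reconstructed (default 0.75)
#' @param min_depth depth counting a base as covered (default 1)
#' @param default fallback threshold in reads/base (default 3.77881)
#' @return list with `threshold` (final), `threshold_coding`,
#'   `threshold_noncoding`, `auc_coding`, `auc_noncoding`
#' @export
learn_coverage_threshold <- function(coding, noncoding, cov_list,
                                     integrity_cut = 0.75, min_depth = 1,
                                     default = 3.77881) {
  one_class <- function(x) {
    score <- rep(0, n_transcripts(x))
    integ <- rep(0, n_transcripts(x))
    for (cov in cov_list) {
      score <- pmax(score, max_coverage(x, cov))
      integ <- pmax(integ, transcript_integrity(x, cov, min_depth))
    }
    lab <- integ >= integrity_cut
    if (all(lab) || !any(lab)) {
      warning("single-label reference class; using default threshold")
      return(list(threshold = default, auc = NA_real_))
    }
    learn_threshold(score, lab)
  }
  a <- one_class(coding)
  b <- one_class(noncoding)
  list(threshold = (a$threshold + b$threshold) / 2,
       threshold_coding = a$threshold, threshold_noncoding = b$threshold,
       auc_coding = a$auc, auc_noncoding = b$auc)
}
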