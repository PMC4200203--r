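#' Cuffcompare-style class codes
#'
#' Classify each query transcript against a reference transcript set with the
#' cuffcompare-style relation codes:
#'
#' * `=` complete intron-chain match (both multi-exon, compatible strand)
#' * `c` contained: the query's intron chain is a contiguous sub-chain of the
#'   reference's and the query lies within the reference span
#' * `j` at least one splice junction (intron, both coordinates) shared
#' * `e` single-exon query overlapping a reference exon
#' * `o` other same/compatible-strand exonic overlap
#' * `s` a query intron overlaps a reference intron on the opposite strand
#' * `i` query fully contained in a reference intron
#' * `p` possible polymerase run-on: query within `p_window` bases downstream
#'   of a reference 3' end, without exonic overlap
#' * `x` exonic overlap on the opposite strand (both strands known)
#' * `u` none of the above (intergenic / unknown)
#'
#' Exactly one code is returned per query, chosen over all nearby references
#' by the fixed priority `=`, `c`, `j`, `e`, `o`, `s`, `i`, `p`, `x`, `u`.
#' Unknown strand (`"*"`) is compatible with either strand; `s` and `x`
#' require both strands to be known. `u` is the fallback whenever no
#' positional code applies (including queries on chromosomes absent from the
#' reference).
#'
#' @param query,reference `transcript_set` objects
#' @param p_window run-on window in bases downstream of a reference 3' end
#'   (default 2000)
#' @return data.table with columns `transcript_id`, `class_code`, `ref_id`
#'   (`NA` for `u`)
#' @examples
#' q <- transcript_set(data.frame(transcript_id = "q", chrom = "c", strand = "+",
#'                                start = c(0L, 200L), end = c(100L, 300L)))
#' classify_transcripts(q, q)$class_code  # "="
#' @export
classify_transcripts <- function(query, reference, p_window = 2000L) {
  stopifnot(inherits(query, "transcript_set"),
            inherits(reference, "transcript_set"))
  qtx <- query$tx
  out <- data.table::data.table(transcript_id = qtx$transcript_id,
                                class_code = "u", ref_id = NA_character_)
  if (!nrow(qtx) || !nrow(reference$tx)) return(out[])

  qspan <- GenomicRanges::GRanges(qtx$chrom,
    IRanges::IRanges(qtx$span_start + 1L, qtx$span_end), strand = "*")
  rtx <- reference$tx
  rspan <- GenomicRanges::GRanges(rtx$chrom,
    IRanges::IRanges(rtx$span_start + 1L, rtx$span_end), strand = "*")
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    qspan, rspan, maxgap = as.integer(p_window), ignore.strand = TRUE))
  if (!length(hits)) return(out[])

  qex <- split(query$exons[, .(start, end)],
               factor(query$exons$transcript_id, levels = qtx$transcript_id))
  rex <- split(reference$exons[, .(start, end)],
               factor(reference$exons$transcript_id,
                      levels = rtx$transcript_id))

  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  prio <- c("=" = 1, "c" = 2, "j" = 3, "e" = 4, "o" = 5, "s" = 6, "i" = 7,
            "p" = 8, "x" = 9, "u" = 10)
  for (qi in unique(qh)) {
    ridx <- sh[qh == qi]
    codes <- vapply(ridx, function(ri) {
      .pair_code(qtx[qi], qex[[qi]], rtx[ri], rex[[ri]], p_window)
    }, character(1L))
    best <- min(prio[codes])
    if (best < 10) {
      cand <- rtx$transcript_id[ridx[prio[codes] == best]]
      out[qi, `:=`(class_code = names(prio)[best],
                   ref_id = sort(cand)[1L])]
    }
  }
  out[]
}

# one (query, reference) pair -> class code
.pair_code <- function(qt, qe, rt, re, p_window) {
  compat <- qt$strand == "*" || rt$strand == "*" || qt$strand == rt$strand
  opposite <- qt$strand %in% c("+", "-") && rt$strand %in% c("+", "-") &&
    qt$strand != rt$strand
  exon_ov <- .any_overlap(qe, re)
  qn <- nrow(qe); rn <- nrow(re)

  if (compat && qn > 1L && rn > 1L && qt$chain == rt$chain) return("=")
  if (compat && qn > 1L && rn > 1L &&
      .is_contiguous_subchain(qt$chain, rt$chain) &&
      qt$span_start >= rt$span_start && qt$span_end <= rt$span_end)
    return("c")
  if (compat && qn > 1L && rn > 1L &&
      length(intersect(strsplit(qt$chain, "|", fixed = TRUE)[[1L]],
                       strsplit(rt$chain, "|", fixed = TRUE)[[1L]])))
    return("j")
  if (compat && qn == 1L && exon_ov) return("e")
  if (compat && exon_ov) return("o")
  if (opposite && qn > 1L && rn > 1L &&
      .any_overlap(.gaps(qe), .gaps(re))) return("s")
  if (rn > 1L && !exon_ov) {
    g <- .gaps(re)
    if (any(qt$span_start >= g$start & qt$span_end <= g$end)) return("i")
  }
  if (!exon_ov && rt$strand %in% c("+", "-") && compat) {
    d <- if (rt$strand == "+") qt$span_start - rt$span_end
         else rt$span_start - qt$span_end
    if (d >= 0 && d <= p_window) return("p")
  }
  if (opposite && exon_ov) return("x")
  "u"
}

.any_overlap <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(FALSE)
  for (i in seq_len(nrow(a)))
    if (any(b$start < a$end[i] & b$end > a$start[i])) return(TRUE)
  FALSE
}

.gaps <- function(ex) {
  n <- nrow(ex)
  if (n < 2L) return(data.table::data.table(start = integer(), end = integer()))
  data.table::data.table(start = ex$end[-n], end = ex$start[-1L])
}

.is_contiguous_subchain <- function(qchain, rchain) {
  if (qchain == "" || rchain == "") return(FALSE)
  q <- strsplit(qchain, "|", fixed = TRUE)[[1L]]
  r <- strsplit(rchain, "|", fixed = TRUE)[[1L]]
  if (length(q) >= length(r)) return(FALSE)
  idx <- match(q[1L], r)
  if (is.na(idx)) return(FALSE)
  identical(r[idx:(idx + length(q) - 1L)], q)
}

#' Collapse redundant transcript structures
#'
#' Transcripts with identical structure collapse to one record. Multi-exon
#' structures are identical when they share chromosome, a strand-compatible
#' assignment and the full intron chain; single-exon structures when they
#' share the exact exon interval. Exon extents of a collapsed group are merged
#' (outermost terminal boundaries; internal boundaries are fixed by the shared
#' junctions). The representative keeps the lexicographically smallest
#' transcript id; `n_collapsed` counts group size.
#'
#' @param x a `transcript_set`
#' @return a `transcript_set` with per-transcript `n_collapsed` metadata
#' @export
deduplicate <- function(x) {
  stopifnot(inherits(x, "transcript_set"))
  if (!nrow(x$tx)) return(x)
  txt <- data.table::copy(x$tx)
  txt[, key1 := ifelse(chain == "",
                       paste0(chrom, ":", span_start, "-", span_end, ":SE"),
                       paste0(chrom, ":", chain))]
  # strand-compatible grouping: "*" joins a known strand when unambiguous
  txt[, grp_strand := {
    known <- unique(strand[strand %in% c("+", "-")])
    if (length(known) == 1L) ifelse(strand == "*", known, strand) else strand
  }, by = key1]
  txt[, grp := paste0(key1, ":", grp_strand)]

  ex <- merge(x$exons, txt[, .(transcript_id, grp, grp_strand)],
              by = "transcript_id", sort = FALSE)
  grp_tab <- txt[, .(rep_id = sort(transcript_id)[1L], n_collapsed = .N,
                     members = list(sort(transcript_id))), by = grp]

  # merge exon extents within each group: exon rank aligns because the
  # junction chain (or single exon) is shared
  ex[, rank := seq_len(.N), by = transcript_id]
  mex <- ex[, .(start = min(start), end = max(end), chrom = chrom[1L],
                strand = grp_strand[1L]), by = .(grp, rank)]
  mex <- merge(mex, grp_tab[, .(grp, rep_id)], by = "grp", sort = FALSE)
  meta_bt <- txt[, .(transcript_id, biotype)]
  res <- transcript_set(
    mex[, .(transcript_id = rep_id, chrom, strand, start, end)],
    tx = merge(grp_tab[, .(transcript_id = rep_id, n_collapsed, members)],
               meta_bt, by = "transcript_id", all.x = TRUE, sort = FALSE))
  res
}

#' Group transcripts into loci
#'
#' A locus is a connected component of the exonic-overlap graph on compatible
#' strands: transcripts sharing at least one exonic base on the same strand
#' belong to one locus, and unknown-strand transcripts connect to either
#' strand.
#'
#' @param x a `transcript_set`
#' @return data.table with columns `transcript_id`, `locus` (integer label,
#'   numbered by leftmost span)
#' @export
assign_loci <- function(x) {
  stopifnot(inherits(x, "transcript_set"))
  ids <- x$tx$transcript_id
  if (!length(ids))
    return(data.table::data.table(transcript_id = character(),
                                  locus = integer()))
  gr <- GenomicRanges::GRanges(
    x$exons$chrom,
    IRanges::IRanges(x$exons$start + 1L, x$exons$end),
    strand = x$exons$strand)
  hits <- GenomicRanges::findOverlaps(gr, gr)  # "*" overlaps both strands
  e_from <- match(x$exons$transcript_id[S4Vectors::queryHits(hits)], ids)
  e_to <- match(x$exons$transcript_id[S4Vectors::subjectHits(hits)], ids)
  g <- igraph::graph_from_edgelist(cbind(e_from, e_to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(ids) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(ids)]
  # deterministic numbering by leftmost, then chrom
  o <- order(x$tx$chrom, x$tx$span_start, x$tx$span_end, ids)
  relabel <- integer(max(comp))
  nxt <- 0L
  for (i in o) {
    if (relabel[comp[i]] == 0L) { nxt <- nxt + 1L; relabel[comp[i]] <- nxt }
  }
  data.table::data.table(transcript_id = ids, locus = relabel[comp])
}
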