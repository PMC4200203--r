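#' Spliced transcript sequences
#'
#' Extracts each transcript's exonic sequence from the genome and splices it.
#' Minus-strand transcripts are reverse-complemented so the returned sequence
#' is strand-oriented; unknown-strand transcripts are returned in forward
#' genome orientation.
#'
#' @param x a `transcript_set`
#' @param genome a [Biostrings::DNAStringSet] named by chromosome
#' @return a `DNAStringSet` named by transcript id
#' @export
transcript_sequences <- function(x, genome) {
  stopifnot(inherits(x, "transcript_set"),
            inherits(genome, "DNAStringSet"))
  ex <- x$exons
  missing_chr <- setdiff(unique(ex$chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  pieces <- character(nrow(ex))
  for (ch in unique(ex$chrom)) {
    idx <- which(ex$chrom == ch)
    g <- genome[[ch]]
    if (any(ex$start[idx] < 0L) || any(ex$end[idx] > length(g)))
      stop("exon coordinates outside genome on ", ch)
    pieces[idx] <- as.character(
      Biostrings::Views(g, ex$start[idx] + 1L, ex$end[idx]))
  }
  dt <- data.table::data.table(transcript_id = ex$transcript_id, s = pieces)
  spl <- dt[, .(s = paste(s, collapse = "")), by = transcript_id]
  out <- Biostrings::DNAStringSet(setNames(spl$s, spl$transcript_id))
  out <- out[x$tx$transcript_id]
  minus <- x$tx$strand == "-"
  if (any(minus))
    out[minus] <- Biostrings::reverseComplement(out[minus])
  out
}

#' ORF features of a nucleotide sequence
#'
#' Scans the three forward reading frames for open reading frames
#' (`ATG ... TAA/TAG/TGA`, stop included in the length); `ATG` runs reaching
#' the end of the sequence without a stop are recorded as integrity-deficient
#' ORFs. `N` never matches a codon; other non-ACGT characters are an error.
#'
#' @param seq a character scalar or [Biostrings::DNAString]
#' @param min_orf minimal ORF length in codons for `frame_count_ge_min`
#'   (default 30)
#' @return list with `longest_orf_codons`, `orf_coverage` (fraction of the
#'   sequence inside the longest ORF), `has_start`, `has_stop` (integrity of
#'   the longest ORF), `frame_count_ge_min`
#' @examples
#' orf_features("ATGAAATAA")$longest_orf_codons  # 3
#' @export
orf_features <- function(seq, min_orf = 30L) {
  s <- toupper(as.character(seq))
  if (grepl("[^ACGTN]", s)) stop("sequence contains non-ACGTN characters")
  len <- nchar(s)
  empty <- list(longest_orf_codons = 0L, orf_coverage = 0,
                has_start = FALSE, has_stop = FALSE, frame_count_ge_min = 0L)
  if (len < 3L) return(empty)
  stops <- c("TAA", "TAG", "TGA")
  best <- c(codons = 0L, start = FALSE, stop = FALSE)
  frames_ge <- 0L
  for (f in 1:3) {
    starts_at <- seq.int(f, len - 2L, by = 3L)
    if (!length(starts_at)) next
    cods <- substring(s, starts_at, starts_at + 2L)
    is_stop <- cods %in% stops
    is_atg <- cods == "ATG"
    frame_best <- 0L
    # runs delimited by stop codons (and sequence end)
    run_end <- c(which(is_stop), length(cods) + 1L)
    run_start <- 1L
    for (re in run_end) {
      if (re > run_start) {
        atg <- which(is_atg[run_start:(re - 1L)])
        if (length(atg)) {
          first_atg <- run_start + atg[1L] - 1L
          complete <- re <= length(cods)  # ends at a real stop codon
          ncod <- (re - first_atg) + as.integer(complete)
          if (ncod > best[["codons"]] ||
              (ncod == best[["codons"]] && complete && !best[["stop"]])) {
            best <- c(codons = ncod, start = TRUE, stop = complete)
          }
          frame_best <- max(frame_best, ncod)
        }
      }
      run_start <- re + 1L
    }
    if (frame_best >= min_orf) frames_ge <- frames_ge + 1L
  }
  if (best[["codons"]] == 0L) return(empty)
  list(longest_orf_codons = as.integer(best[["codons"]]),
       orf_coverage = 3 * best[["codons"]] / len,
       has_start = as.logical(best[["start"]]),
       has_stop = as.logical(best[["stop"]]),
       frame_count_ge_min = frames_ge)
}

#' Coding-potential score
#'
#' A deterministic, documented stand-in for SVM-based coding-potential
#' classifiers, on the same scale and orientation: scores below -0.5 are
#' called non-coding. The score is a calibrated monotone map of the ORF
#' features,
#' \deqn{score = -2 + 4.8 (0.5 \frac{L}{L+90} + 0.4 \cdot cov +
#'   0.05 \cdot integrity)}
#' with \eqn{L} the longest ORF in codons, \eqn{cov} the fraction of the
#' transcript covered by that ORF and \eqn{integrity} = (has start + has
#' stop)/2. A transcript with no ORF scores -2; an intact ORF covering more
#' than 90% of a transcript of at least 300 nt scores above +1.
#'
#' @param features output of [orf_features()] (or a list of such)
#' @return numeric score (vector when `features` is a list of feature lists)
#' @export
coding_score <- function(features) {
  one <- function(f) {
    L <- f$longest_orf_codons
    integ <- (as.numeric(f$has_start) + as.numeric(f$has_stop)) / 2
    g <- 0.5 * L / (L + 90) + 0.4 * f$orf_coverage + 0.05 * integ
    -2 + 4.8 * g
  }
  if (!is.null(features$longest_orf_codons)) return(one(features))
  vapply(features, one, numeric(1L))
}

#' Coding-potential classification of transcripts
#'
#' Scores each transcript's spliced sequence with [coding_score()]. Known
#' strands are scanned in the three forward frames of the oriented sequence;
#' unknown-strand transcripts are scanned in both orientations and the
#' better-scoring orientation is used.
#'
#' @param x a `transcript_set`
#' @param genome a `DNAStringSet` named by chromosome
#' @param min_orf minimal ORF in codons for the frame count feature
#' @param cutoff classification cutoff: non-coding iff `score < cutoff`
#'   (default -0.5; the boundary value itself is coding-side)
#' @return data.table with `transcript_id`, `score`, `noncoding` (logical),
#'   `orientation_used`
#' @export
coding_potential <- function(x, genome, min_orf = 30L, cutoff = -0.5) {
  stopifnot(inherits(x, "transcript_set"))
  seqs <- transcript_sequences(x, genome)
  ids <- names(seqs)
  strands <- setNames(x$tx$strand, x$tx$transcript_id)[ids]
  score <- numeric(length(ids))
  orient <- rep("forward", length(ids))
  for (i in seq_along(ids)) {
    sc <- coding_score(orf_features(seqs[[i]], min_orf))
    if (strands[i] == "*") {
      rc <- coding_score(orf_features(
        Biostrings::reverseComplement(seqs[[i]]), min_orf))
      if (rc > sc) { sc <- rc; orient[i] <- "reverse" }
    }
    score[i] <- sc
  }
  data.table::data.table(transcript_id = ids, score = score,
                         noncoding = score < cutoff,
                         orientation_used = orient)
}

#' Protein-homology filter
#'
#' Candidates with any protein or profile hit below the E-value cutoff are
#' called coding, mirroring a blastp/HMMER screen; the packaged default is a
#' null oracle with no hits, under which every candidate is retained.
#'
#' @param ids candidate transcript ids
#' @param hits data.frame of hits with columns `query`, `subject`, `evalue`,
#'   `tool`, or `NULL` for the null oracle
#' @param e_cut E-value cutoff (default `1e-4`; a hit strictly below it marks
#'   the query coding)
#' @return list with `coding` and `noncoding` id vectors
#' @export
homology_filter <- function(ids, hits = NULL, e_cut = 1e-4) {
  if (is.null(hits) || !nrow(hits))
    return(list(coding = character(), noncoding = ids))
  hits <- data.table::as.data.table(hits)
  if (!all(c("query", "evalue") %in% names(hits)))
    stop("hits need 'query' and 'evalue' columns")
  if (any(!is.finite(hits$evalue)) || any(hits$evalue <= 0))
    stop("malformed homology hit: E-values must be positive")
  coding <- intersect(ids, unique(hits$query[hits$evalue < e_cut]))
  list(coding = coding, noncoding = setdiff(ids, coding))
}

#' Read a tabular homology hit file
#'
#' Expects a TSV with header columns `query`, `subject`, `evalue`, `tool`
#' (e.g. parsed blastp/hmmsearch output).
#'
#' @param file path
#' @return data.frame of hits
#' @export
read_homology_hits <- function(file) {
  read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
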