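#' Length and exon-count filters
#'
#' Single-exon transcripts and transcripts shorter than 200 nt are excluded
#' from lncRNA catalogs; 200 nt exactly is retained (the exclusion is
#' strictly "< 200 nt").
#'
#' @param x a `transcript_set`
#' @param min_length minimal summed exon length in bases (default 200)
#' @param require_multiexon require at least two exons (default `TRUE`)
#' @return the filtered `transcript_set`
#' @export
basic_filters <- function(x, min_length = 200L, require_multiexon = TRUE) {
  stopifnot(inherits(x, "transcript_set"))
  keep <- x$tx$tx_len >= min_length
  if (require_multiexon) keep <- keep & x$tx$n_exons >= 2L
  subset_transcripts(x, x$tx$transcript_id[keep])
}

#' Remove candidates matching known annotation
#'
#' Classifies every candidate against each reference annotation set
#' ([classify_transcripts()]) and removes it when its class code against any
#' reference is in `removed_codes` (default: the seven overlap codes
#' `=`, `c`, `j`, `e`, `o`, `p`, `s`; intronic `i`, antisense `x` and
#' intergenic `u` candidates are retained as novel).
#'
#' @param x candidate `transcript_set`
#' @param references a single `transcript_set` or named list of them (one per
#'   annotation source)
#' @param removed_codes class codes triggering removal
#' @param p_window run-on window passed to [classify_transcripts()]
#' @return list with `retained` (`transcript_set`), `removed_ids`, and
#'   `codes` (long data.table of per-source class codes)
#' @export
remove_known <- function(x, references,
                         removed_codes = c("=", "c", "j", "e", "o", "p", "s"),
                         p_window = 2000L) {
  stopifnot(inherits(x, "transcript_set"))
  if (inherits(references, "transcript_set")) references <- list(references)
  if (is.null(names(references)))
    names(references) <- paste0("ref", seq_along(references))
  codes <- data.table::rbindlist(lapply(names(references), function(nm) {
    cc <- classify_transcripts(x, references[[nm]], p_window = p_window)
    cc[, source := nm]
    cc
  }))
  removed <- unique(codes$transcript_id[codes$class_code %in% removed_codes])
  retained <- setdiff(x$tx$transcript_id, removed)
  list(retained = subset_transcripts(x, retained),
       removed_ids = removed, codes = codes[])
}

#' Annotate candidates against a lncRNA database
#'
#' Coordinate-overlap comparison against a non-coding RNA database: a
#' candidate is database-matched when its class code against the database is
#' in `matched_codes` (default `=`, `c`, `j`, `e`, `o`). Matched candidates
#' stay in the catalog; the split only annotates which are already collected.
#'
#' @param x candidate `transcript_set`
#' @param lnc_db database annotation as a `transcript_set`
#' @param matched_codes codes counting as a database match
#' @return list with `matched_ids`, `novel_ids`, `codes`
#' @export
annotate_known_lncrna <- function(x, lnc_db,
                                  matched_codes = c("=", "c", "j", "e", "o")) {
  stopifnot(inherits(x, "transcript_set"))
  cc <- classify_transcripts(x, lnc_db)
  matched <- cc$transcript_id[cc$class_code %in% matched_codes]
  list(matched_ids = matched,
       novel_ids = setdiff(x$tx$transcript_id, matched),
       codes = cc)
}
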