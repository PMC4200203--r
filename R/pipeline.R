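#' lncRNA discovery pipeline
#'
#' Runs the full filtering cascade from per-sample assembler outputs to a
#' novel-lncRNA catalog, in order: non-redundant union (bookkeeping) ->
#' two-assembler/two-sample consensus -> maximum-coverage threshold ->
#' reconstruction integrity -> splice-motif strand inference (unresolvable
#' transcripts are dropped) -> length/exon filters -> removal of candidates
#' matching known annotation -> lncRNA-database annotation -> coding-potential
#' and protein-homology screening. A `filter_report` records transcript and
#' locus counts per stage.
#'
#' The coverage threshold is the pipeline constant 3.77881 reads/base unless
#' reference coding and non-coding sets are supplied for ROC learning
#' ([learn_coverage_threshold()]). Coverage and integrity are evaluated per
#' transcript as the maximum over the samples in which it was assembled.
#'
#' @param assemblies `transcript_set` of all assembler outputs with
#'   `assembler` and `sample_id` metadata (see [consensus_filter()])
#' @param cov_list named list (by sample id) of coverage `RleList` tracks
#' @param genome `DNAStringSet` named by chromosome
#' @param references named list of reference annotation `transcript_set`s
#' @param lnc_db optional lncRNA database `transcript_set`
#' @param coverage_threshold reads/base cutoff (default 3.77881); ignored
#'   when `learn_from` is given
#' @param learn_from optional list with elements `coding` and `noncoding`
#'   (`transcript_set`s) used to learn the threshold
#' @param integrity_cut integrity cutoff (default 0.75)
#' @param min_depth depth counting a base as covered (default 1)
#' @param min_length,require_multiexon passed to [basic_filters()]
#' @param removed_codes passed to [remove_known()]
#' @param coding_cutoff coding-score cutoff (default -0.5, non-coding strictly
#'   below)
#' @param min_orf minimal ORF in codons for the frame-count feature
#' @param homology_hits optional data.frame of protein/profile hits for
#'   [homology_filter()] (default: null oracle, no hits)
#' @param e_cut homology E-value cutoff (default 1e-4)
#' @param consensus_slack single-exon end slack for [consensus_filter()]
#' @return an object of class `lncrna_catalog`: list with `catalog`
#'   (`transcript_set` of novel lncRNAs), `report` (`filter_report`
#'   data.frame), `threshold` used, `codes` (per-source class codes of the
#'   candidates), `db_matched_ids`, `coding_scores`, and `loci` (locus
#'   assignment of the catalog)
#' @export
run_pipeline <- function(assemblies, cov_list, genome, references,
                         lnc_db = NULL,
                         coverage_threshold = 3.77881, learn_from = NULL,
                         integrity_cut = 0.75, min_depth = 1,
                         min_length = 200L, require_multiexon = TRUE,
                         removed_codes = c("=", "c", "j", "e", "o", "p", "s"),
                         coding_cutoff = -0.5, min_orf = 30L,
                         homology_hits = NULL, e_cut = 1e-4,
                         consensus_slack = 25L) {
  stopifnot(inherits(assemblies, "transcript_set"))
  report <- list()
  note <- function(stage, n_in, x) {
    n_out <- n_transcripts(x)
    n_loci <- if (n_out) max(assign_loci(x)$locus) else 0L
    report[[length(report) + 1L]] <<-
      data.frame(stage = stage, n_in = n_in, n_out = n_out,
                 n_loci_out = n_loci)
    n_out
  }

  n0 <- n_transcripts(assemblies)
  dedup <- deduplicate(assemblies)
  n <- note("non-redundant union", n0, dedup)

  cons <- consensus_filter(assemblies, slack = consensus_slack)
  n <- note("consensus (2 assemblers same sample / 2 samples same assembler)",
            n, cons)

  # samples each retained structure was assembled in
  sample_of <- setNames(assemblies$tx$sample_id, assemblies$tx$transcript_id)
  present <- lapply(seq_len(nrow(cons$tx)), function(i)
    unique(sample_of[cons$tx$members[[i]]]))
  names(present) <- cons$tx$transcript_id

  thr <- coverage_threshold
  learned <- NULL
  if (!is.null(learn_from)) {
    learned <- learn_coverage_threshold(learn_from$coding,
                                        learn_from$noncoding, cov_list,
                                        integrity_cut = integrity_cut,
                                        min_depth = min_depth,
                                        default = coverage_threshold)
    thr <- learned$threshold
  }

  stat_over_samples <- function(x, fun) {
    out <- setNames(rep(0, n_transcripts(x)), x$tx$transcript_id)
    for (sm in names(cov_list)) {
      ids <- names(present)[vapply(present, function(p) sm %in% p,
                                   logical(1L))]
      ids <- intersect(ids, names(out))
      if (!length(ids)) next
      v <- fun(subset_transcripts(x, ids), cov_list[[sm]])
      out[ids] <- pmax(out[ids], v)
    }
    out
  }

  mc <- stat_over_samples(cons, max_coverage)
  keep <- names(mc)[mc >= thr]
  covset <- subset_transcripts(cons, keep)
  n <- note(sprintf("max coverage >= %.5f reads/base", thr), n, covset)

  integ <- stat_over_samples(covset, function(s, cv)
    transcript_integrity(s, cv, min_depth = min_depth))
  intset <- subset_transcripts(covset, names(integ)[integ >= integrity_cut])
  n <- note(sprintf("integrity >= %.2f", integrity_cut), n, intset)

  stranded <- infer_strand(intset, genome)
  stranded <- subset_transcripts(stranded,
                                 stranded$tx$transcript_id[
                                   stranded$tx$strand %in% c("+", "-")])
  n <- note("strand resolved from splice motifs", n, stranded)

  basic <- basic_filters(stranded, min_length = min_length,
                         require_multiexon = require_multiexon)
  n <- note(sprintf("multi-exon and >= %d nt", min_length), n, basic)

  rk <- remove_known(basic, references, removed_codes = removed_codes)
  n <- note("not matching known annotation", n, rk$retained)

  db_matched <- character()
  if (!is.null(lnc_db) && n_transcripts(rk$retained) > 0) {
    ann <- annotate_known_lncrna(rk$retained, lnc_db)
    db_matched <- ann$matched_ids
  }

  candidates <- rk$retained
  cp <- if (n_transcripts(candidates) > 0)
    coding_potential(candidates, genome, min_orf = min_orf,
                     cutoff = coding_cutoff)
  else data.table::data.table(transcript_id = character(), score = numeric(),
                              noncoding = logical(),
                              orientation_used = character())
  nc <- subset_transcripts(candidates,
                           cp$transcript_id[cp$noncoding])
  n <- note(sprintf("coding score < %.1f", coding_cutoff), n, nc)

  hf <- homology_filter(nc$tx$transcript_id, homology_hits, e_cut = e_cut)
  final <- subset_transcripts(nc, hf$noncoding)
  n <- note(sprintf("no protein/profile homology (E < %g)", e_cut), n, final)

  report <- do.call(rbind, report)
  class(report) <- c("filter_report", "data.frame")
  structure(list(
    catalog = final,
    report = report,
    threshold = thr, learned = learned,
    codes = rk$codes,
    db_matched_ids = intersect(db_matched, final$tx$transcript_id),
    coding_scores = cp,
    loci = assign_loci(final)
  ), class = "lncrna_catalog")
}

#' @export
print.lncrna_catalog <- function(x, ...) {
  cat("lncRNA catalog:", n_transcripts(x$catalog), "novel lncRNAs in",
      if (nrow(x$loci)) max(x$loci$locus) else 0L, "loci\n")
  cat(sprintf("coverage threshold: %.5f reads/base%s\n", x$threshold,
              if (is.null(x$learned)) " (pipeline constant)" else " (learned)"))
  cat(length(x$db_matched_ids), "catalog entries match the lncRNA database\n")
  cat("\nFilter cascade:\n")
  print.data.frame(x$report, row.names = FALSE)
  invisible(x)
}

#' @export
print.filter_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Match catalog structures to an annotation by structure key
#'
#' Multi-exon structures match on chromosome + intron chain; single-exon
#' structures on the exact exon interval. Used to compare a recovered catalog
#' with planted truth.
#'
#' @param catalog,annotation `transcript_set` objects
#' @return character vector of `annotation` transcript ids whose structure
#'   appears in `catalog`
#' @export
match_catalog <- function(catalog, annotation) {
  key <- function(x) ifelse(x$tx$chain == "",
                            paste0(x$tx$chrom, ":", x$tx$span_start, "-",
                                   x$tx$span_end),
                            paste0(x$tx$chrom, ":", x$tx$chain))
  annotation$tx$transcript_id[key(annotation) %in% key(catalog)]
}
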