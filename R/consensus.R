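#' Two-assembler / two-sample consensus filter
#'
#' A transcript structure is retained when it was (a) detected by two
#' different assemblers in the same sample, or (b) detected in at least two
#' different samples by the same assembler. Structures are keyed by
#' chromosome + intron chain; single-exon structures are keyed by their exon
#' interval with `slack` bases of end tolerance (assembled ends are noisy).
#' Retained structures are collapsed to one record with merged exon extents:
#' outermost terminal exon boundaries over the group, internal boundaries
#' fixed by the shared junctions.
#'
#' @param x a `transcript_set` whose metadata carries `assembler` and
#'   `sample_id` columns (the per-sample assembler provenance)
#' @param slack end tolerance in bases for single-exon keying (default 25)
#' @return a `transcript_set` of retained merged structures; metadata columns
#'   `n_obs`, `n_samples`, `n_assemblers` record support, `members` the
#'   contributing transcript ids
#' @export
consensus_filter <- function(x, slack = 25L) {
  stopifnot(inherits(x, "transcript_set"))
  txt <- data.table::copy(x$tx)
  if (!nrow(txt)) return(x)
  if (!all(c("assembler", "sample_id") %in% names(txt)))
    stop("consensus_filter needs 'assembler' and 'sample_id' metadata")

  txt[, key1 := .structure_keys(.SD, slack)]
  support <- txt[, .(
    retained = .consensus_retained(assembler, sample_id),
    n_obs = .N,
    n_samples = data.table::uniqueN(sample_id),
    n_assemblers = data.table::uniqueN(assembler),
    rep_id = sort(transcript_id)[1L],
    members = list(sort(transcript_id)),
    biotype = {
      bt <- unique(biotype[!is.na(biotype)])
      if (length(bt) == 1L) bt else NA_character_
    },
    strand = {
      s <- unique(strand[strand %in% c("+", "-")])
      if (length(s) == 1L) s else "*"
    }
  ), by = key1]
  kept <- support[retained == TRUE]
  if (!nrow(kept)) {
    return(transcript_set(data.frame(transcript_id = character(),
                                     chrom = character(), start = integer(),
                                     end = integer()), validate = FALSE))
  }
  ex <- merge(x$exons[, .(transcript_id, chrom, start, end)],
              txt[, .(transcript_id, key1)], by = "transcript_id",
              sort = FALSE)
  ex <- ex[key1 %in% kept$key1]
  ex[, rank := seq_len(.N), by = transcript_id]
  mex <- ex[, .(chrom = chrom[1L], start = min(start), end = max(end)),
            by = .(key1, rank)]
  mex <- merge(mex, kept[, .(key1, rep_id, strand)], by = "key1",
               sort = FALSE)
  transcript_set(
    mex[, .(transcript_id = rep_id, chrom, strand, start, end)],
    tx = kept[, .(transcript_id = rep_id, n_obs, n_samples, n_assemblers,
                  members, biotype)])
}

# consensus rule on the provenance of one structure key
.consensus_retained <- function(assembler, sample_id) {
  by_sample <- tapply(assembler, sample_id, function(a) length(unique(a)))
  if (any(by_sample >= 2L)) return(TRUE)
  by_asm <- tapply(sample_id, assembler, function(s) length(unique(s)))
  any(by_asm >= 2L)
}

# structure key per transcript: chrom + intron chain, or slack-clustered
# single-exon interval
.structure_keys <- function(txt, slack) {
  keys <- character(nrow(txt))
  multi <- txt$chain != ""
  keys[multi] <- paste0(txt$chrom[multi], ":", txt$chain[multi])
  se <- which(!multi)
  if (length(se)) {
    se_dt <- data.table::data.table(
      idx = se, chrom = txt$chrom[se],
      start = txt$span_start[se], end = txt$span_end[se])
    data.table::setorder(se_dt, chrom, start, end)
    cl_start <- cl_end <- 0L
    cl_chrom <- ""
    cl_id <- 0L
    lab <- integer(nrow(se_dt))
    for (i in seq_len(nrow(se_dt))) {
      if (se_dt$chrom[i] != cl_chrom ||
          abs(se_dt$start[i] - cl_start) > slack ||
          abs(se_dt$end[i] - cl_end) > slack) {
        cl_id <- cl_id + 1L
        cl_chrom <- se_dt$chrom[i]
        cl_start <- se_dt$start[i]
        cl_end <- se_dt$end[i]
      }
      lab[i] <- cl_id
    }
    keys[se_dt$idx] <- paste0(se_dt$chrom, ":SE", lab)
  }
  keys
}

#' Infer transcript strand from splice-junction motifs
#'
#' Assemblies from non-strand-specific libraries carry no strand; the
#' canonical splice motif recovers it. If every intron of a transcript reads
#' `GT..AG` on the forward genome strand the transcript is `+`; if every
#' intron reads `CT..AC` (i.e. `GT..AG` on the reverse strand) it is `-`;
#' single-exon, mixed or non-canonical transcripts stay `"*"` (unknown).
#'
#' @param x a `transcript_set`
#' @param genome a [Biostrings::DNAStringSet] named by chromosome
#' @param apply if `TRUE` (default) return `x` with strands replaced by the
#'   inferred values; if `FALSE` return the named character vector of
#'   inferred strands
#' @return a `transcript_set` or a named character vector (see `apply`)
#' @export
infer_strand <- function(x, genome, apply = TRUE) {
  stopifnot(inherits(x, "transcript_set"),
            inherits(genome, "DNAStringSet"))
  missing_chr <- setdiff(unique(x$tx$chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  for (ch in unique(x$tx$chrom)) {
    sub <- x$tx[chrom == ch]
    if (any(sub$span_start < 0L) ||
        any(sub$span_end > length(genome[[ch]])))
      stop("transcript span outside genome on ", ch)
  }
  intr <- intron_table(x)
  strands <- setNames(rep("*", nrow(x$tx)), x$tx$transcript_id)
  if (nrow(intr)) {
    intr[, motif := {
      glen <- length(genome[[chrom[1L]]])
      if (any(start < 0L) || any(end > glen))
        stop("intron coordinates outside genome on ", chrom[1L])
      m <- rep("....", .N)
      ok <- (end - start) >= 4L  # motif needs at least 4 intronic bases
      if (any(ok)) {
        donor <- as.character(Biostrings::Views(genome[[chrom[1L]]],
                                                start[ok] + 1L,
                                                start[ok] + 2L))
        accept <- as.character(Biostrings::Views(genome[[chrom[1L]]],
                                                 end[ok] - 1L, end[ok]))
        m[ok] <- paste0(donor, accept)
      }
      m
    }, by = chrom]
    per_tx <- intr[, .(
      strand = if (all(motif == "GTAG")) "+"
               else if (all(motif == "CTAC")) "-" else "*"
    ), by = transcript_id]
    strands[per_tx$transcript_id] <- per_tx$strand
  }
  if (!apply) return(strands)
  ex <- data.table::copy(x$exons)
  ex[, strand := strands[transcript_id]]
  meta_cols <- setdiff(names(x$tx),
                       c("chrom", "strand", "n_exons", "tx_len",
                         "span_start", "span_end", "chain"))
  transcript_set(ex, tx = x$tx[, meta_cols, with = FALSE], validate = FALSE)
}
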