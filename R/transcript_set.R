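#' Transcript set
#'
#' A `transcript_set` holds a collection of (possibly spliced) transcript
#' models: an exon table in 0-based half-open coordinates plus per-transcript
#' metadata. It is the unit flowing through every pipeline filter.
#'
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end` (0-based half-open) and optionally `strand` (`"+"`, `"-"` or `"*"`
#'   for unknown), `gene_id`.
#' @param tx optional per-transcript metadata data.frame keyed by
#'   `transcript_id`; recognised columns include `gene_id`, `biotype`,
#'   `assembler`, `sample_id`. Metadata for ids absent from `exons` is dropped.
#' @param validate check exon-structure invariants (sorted, non-overlapping,
#'   introns of at least 1 base). Default `TRUE`.
#'
#' @return An object of class `transcript_set` with elements `exons`
#'   (data.table, sorted) and `tx` (data.table, one row per transcript with
#'   derived columns `n_exons`, `tx_len`, `span_start`, `span_end`, `chain`).
#'   The `chain` column is the intron-chain key: `""` for single-exon
#'   transcripts, otherwise `"<start>-<end>|..."` over the ordered introns.
#' @examples
#' ts <- transcript_set(data.frame(
#'   transcript_id = "t1", chrom = "chr1", strand = "+",
#'   start = c(100L, 300L), end = c(200L, 400L)))
#' tx_table(ts)$chain  # "200-300"
#' @export
transcript_set <- function(exons, tx = NULL, validate = TRUE) {
  ex <- data.table::as.data.table(exons)
  required <- c("transcript_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(ex))
  if (length(missing_cols))
    stop("exon table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"strand" %in% names(ex)) ex[, strand := "*"]
  if (!"gene_id" %in% names(ex)) ex[, gene_id := transcript_id]
  ex[, `:=`(transcript_id = as.character(transcript_id),
            gene_id = as.character(gene_id),
            chrom = as.character(chrom),
            strand = as.character(strand),
            start = as.integer(start), end = as.integer(end))]
  ex[is.na(strand) | !(strand %in% c("+", "-")), strand := "*"]
  data.table::setkey(ex, transcript_id, start)
  data.table::setorder(ex, transcript_id, start, end)
  if (validate) .validate_exons(ex)

  txt <- ex[, .(
    gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
    n_exons = .N, tx_len = sum(end - start),
    span_start = start[1L], span_end = end[.N],
    chain = .chain_key(start, end)
  ), by = transcript_id]

  if (!is.null(tx)) {
    meta <- data.table::as.data.table(tx)
    if (!"transcript_id" %in% names(meta))
      stop("tx metadata needs a transcript_id column")
    meta[, transcript_id := as.character(transcript_id)]
    keep <- setdiff(names(meta), c(names(txt)))
    # metadata may override gene_id/biotype-style annotation columns
    for (col in c("gene_id", "biotype")) {
      if (col %in% names(meta)) keep <- union(keep, col)
    }
    meta <- meta[, unique(c("transcript_id", keep)), with = FALSE]
    over <- intersect(setdiff(names(meta), "transcript_id"), names(txt))
    if (length(over)) txt[, (over) := NULL]
    txt <- merge(txt, meta, by = "transcript_id", all.x = TRUE, sort = FALSE)
  }
  if (!"biotype" %in% names(txt)) txt[, biotype := NA_character_]
  data.table::setorder(txt, chrom, span_start, span_end, transcript_id)
  structure(list(exons = ex, tx = txt), class = "transcript_set")
}

.chain_key <- function(start, end) {
  n <- length(start)
  if (n < 2L) return("")
  paste(end[-n], start[-1L], sep = "-", collapse = "|")
}

.validate_exons <- function(ex) {
  if (any(ex$end <= ex$start))
    stop("exon with end <= start (coordinates are 0-based half-open)")
  bad <- ex[, if (.N > 1L) any(start[-1L] <= end[-.N]) else FALSE,
            by = transcript_id][V1 == TRUE]
  if (nrow(bad))
    stop("overlapping or adjacent exons (introns must be >= 1 base) in: ",
         paste(head(bad$transcript_id, 5L), collapse = ", "))
  invisible(TRUE)
}

#' @rdname transcript_set
#' @param x a `transcript_set`
#' @export
tx_table <- function(x) {
  stopifnot(inherits(x, "transcript_set"))
  data.table::copy(x$tx)
}

#' @rdname transcript_set
#' @export
exon_table <- function(x) {
  stopifnot(inherits(x, "transcript_set"))
  data.table::copy(x$exons)
}

#' @rdname transcript_set
#' @export
n_transcripts <- function(x) nrow(x$tx)

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts, %d exons, %d chromosome(s)\n",
              nrow(x$tx), nrow(x$exons), length(unique(x$tx$chrom))))
  bt <- table(x$tx$biotype, useNA = "ifany")
  if (length(bt) > 1L || !all(is.na(names(bt))))
    cat("  biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "),
        "\n")
  invisible(x)
}

#' Subset a transcript set by transcript id
#'
#' @param x a `transcript_set`
#' @param ids character vector of transcript ids to keep
#' @return a `transcript_set` restricted to `ids`
#' @export
subset_transcripts <- function(x, ids) {
  stopifnot(inherits(x, "transcript_set"))
  ex <- x$exons[transcript_id %in% ids]
  meta_cols <- setdiff(names(x$tx),
                       c("gene_id", "chrom", "strand", "n_exons", "tx_len",
                         "span_start", "span_end", "chain"))
  transcript_set(ex, tx = x$tx[transcript_id %in% ids, meta_cols,
                               with = FALSE],
                 validate = FALSE)
}

#' Intron table of a transcript set
#'
#' Introns are the gaps between consecutive exons, 0-based half-open.
#'
#' @param x a `transcript_set`
#' @return data.table with columns `transcript_id`, `chrom`, `strand`,
#'   `start`, `end`, `intron_rank`; zero rows for single-exon transcripts.
#' @export
intron_table <- function(x) {
  stopifnot(inherits(x, "transcript_set"))
  x$exons[, if (.N > 1L) .(
    chrom = chrom[1L], strand = strand[1L],
    start = end[-.N], end = start[-1L], intron_rank = seq_len(.N - 1L)
  ), by = transcript_id]
}

#' Intron chain of a single transcript
#'
#' @param x a `transcript_set`
#' @param id transcript id (may be omitted when `x` has one transcript)
#' @return list with `chrom` and an integer matrix `introns` (columns
#'   `start`, `end`; zero rows for single-exon transcripts)
#' @export
intron_chain <- function(x, id = NULL) {
  stopifnot(inherits(x, "transcript_set"))
  if (is.null(id)) {
    if (nrow(x$tx) != 1L) stop("id required for a multi-transcript set")
    id <- x$tx$transcript_id
  }
  ex <- x$exons[transcript_id == id]
  if (!nrow(ex)) stop("unknown transcript id: ", id)
  n <- nrow(ex)
  introns <- if (n < 2L) {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  } else {
    cbind(start = ex$end[-n], end = ex$start[-1L])
  }
  list(chrom = ex$chrom[1L], introns = introns)
}

#' Convert a transcript set to a GRangesList of exons
#'
#' @param x a `transcript_set`
#' @return `GRangesList` (1-based ranges) named by transcript id
#' @export
as_granges_list <- function(x) {
  stopifnot(inherits(x, "transcript_set"))
  gr <- GenomicRanges::GRanges(
    seqnames = x$exons$chrom,
    ranges = IRanges::IRanges(start = x$exons$start + 1L, end = x$exons$end),
    strand = x$exons$strand)
  S4Vectors::split(gr, x$exons$transcript_id)
}

# ---- GTF / BED I/O ---------------------------------------------------------

#' Read transcripts from a GTF file
#'
#' Exon records are read (via rtracklayer) and converted to the package's
#' 0-based half-open convention. `gene_id`, `transcript_id` and, when present,
#' `biotype` attributes are preserved.
#'
#' @param file path to a GTF file
#' @return a `transcript_set`
#' @export
read_gtf <- function(file) {
  gr <- rtracklayer::import(file, format = "gtf")
  gr <- gr[gr$type == "exon"]
  md <- S4Vectors::mcols(gr)
  ex <- data.frame(
    transcript_id = as.character(md$transcript_id),
    gene_id = if ("gene_id" %in% names(md)) as.character(md$gene_id)
              else as.character(md$transcript_id),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr))
  tx <- NULL
  if ("biotype" %in% names(md)) {
    tx <- unique(data.frame(transcript_id = ex$transcript_id,
                            biotype = as.character(md$biotype)))
  }
  transcript_set(ex, tx = tx)
}

#' Write a transcript set to GTF
#'
#' Emits one `transcript` and per-exon `exon` records per transcript,
#' 1-based inclusive, sorted by chromosome and start so output is
#' reproducible byte-for-byte.
#'
#' @param x a `transcript_set`
#' @param file output path
#' @param source source field for column 2 (default `"cleavecat"`)
#' @return `file`, invisibly
#' @export
write_gtf <- function(x, file, source = "cleavecat") {
  stopifnot(inherits(x, "transcript_set"))
  ex <- data.table::copy(x$exons)
  bt <- x$tx[, .(transcript_id, biotype)]
  ex <- merge(ex, bt, by = "transcript_id", sort = FALSE)
  data.table::setorder(ex, chrom, start, end, transcript_id)
  attr_str <- function(g, t, b) {
    base <- sprintf('gene_id "%s"; transcript_id "%s";', g, t)
    ifelse(is.na(b), base, paste0(base, sprintf(' biotype "%s";', b)))
  }
  lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$chrom, source, ex$start + 1L, ex$end, ex$strand,
                   attr_str(ex$gene_id, ex$transcript_id, ex$biotype))
  writeLines(lines, file)
  invisible(file)
}

#' Write a transcript set as BED12
#'
#' One BED12 line per transcript (0-based half-open, block-structured exons).
#'
#' @inheritParams write_gtf
#' @param score score column (recycled), default 0
#' @return `file`, invisibly
#' @export
write_bed12 <- function(x, file, score = 0L) {
  stopifnot(inherits(x, "transcript_set"))
  ex <- x$exons
  b <- ex[, .(
    chrom = chrom[1L], start = start[1L], end = end[.N],
    strand = if (strand[1L] %in% c("+", "-")) strand[1L] else ".",
    n = .N,
    sizes = paste0(paste(end - start, collapse = ","), ","),
    starts = paste0(paste(start - start[1L], collapse = ","), ",")
  ), by = transcript_id]
  data.table::setorder(b, chrom, start, end, transcript_id)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                   b$chrom, b$start, b$end, b$transcript_id,
                   as.integer(score), b$strand, b$start, b$end,
                   b$n, b$sizes, b$starts)
  writeLines(lines, file)
  invisible(file)
}
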