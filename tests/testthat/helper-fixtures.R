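# Shared fixtures, generated once per test run and memoized.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, maker) {
  if (!exists(name, envir = .fx_cache)) assign(name, maker(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# small complete study: fast enough for most end-to-end checks
fx_small_study <- function() fx("small_study", function() {
  simulate_study(simulation_config(
    seed = 7, n_chromosomes = 2, chrom_length = 1.3e6,
    n_coding_genes = 120, n_lncRNA_genes = 60))
})

# expression-only fixture with 6 planted stage modules
fx_expr <- function() fx("expr", function() {
  generate_expression(simulation_config(
    seed = 3, n_coding_genes = 450, n_lncRNA_genes = 150))
})

# quick transcript_set builder: ex = list of exon matrices (0-based
# half-open), one per transcript
make_ts <- function(ex, strand = "+", chrom = "chr1", ids = NULL,
                    biotype = NULL) {
  if (is.null(ids)) ids <- sprintf("t%02d", seq_along(ex))
  strand <- rep_len(strand, length(ex))
  chrom <- rep_len(chrom, length(ex))
  tab <- do.call(rbind, lapply(seq_along(ex), function(i) {
    m <- ex[[i]]
    data.frame(transcript_id = ids[i], chrom = chrom[i], strand = strand[i],
               start = m[, 1], end = m[, 2])
  }))
  tx <- if (!is.null(biotype))
    data.frame(transcript_id = ids, biotype = rep_len(biotype, length(ids)))
  else NULL
  transcript_set(tab, tx = tx)
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}

# independent brute-force class-code oracle: literal re-derivation of the
# code definitions using plain interval arithmetic over one query/reference
# pair, then the fixed priority over all references
oracle_pair_code <- function(qe, qs, re, rs, p_window = 2000) {
  ov <- function(a, b) {
    hit <- FALSE
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
      if (a[i, 1] < b[j, 2] && b[j, 1] < a[i, 2]) hit <- TRUE
    hit
  }
  introns <- function(m) {
    if (nrow(m) < 2) return(matrix(numeric(0), ncol = 2))
    cbind(m[-nrow(m), 2], m[-1, 1])
  }
  qi <- introns(qe); ri <- introns(re)
  compat <- qs == "*" || rs == "*" || qs == rs
  opp <- qs %in% c("+", "-") && rs %in% c("+", "-") && qs != rs
  qspan <- range(qe); rspan <- range(re)
  shared <- 0
  if (nrow(qi) && nrow(ri))
    for (i in seq_len(nrow(qi))) for (j in seq_len(nrow(ri)))
      if (qi[i, 1] == ri[j, 1] && qi[i, 2] == ri[j, 2]) shared <- shared + 1
  sub_contig <- FALSE
  if (nrow(qi) && nrow(ri) && nrow(qi) < nrow(ri)) {
    for (off in 0:(nrow(ri) - nrow(qi))) {
      if (all(qi == ri[(off + 1):(off + nrow(qi)), , drop = FALSE]))
        sub_contig <- TRUE
    }
  }
  exov <- ov(qe, re)
  if (compat && nrow(qi) > 0 && nrow(ri) > 0 && nrow(qi) == nrow(ri) &&
      all(qi == ri)) return("=")
  if (compat && sub_contig && qspan[1] >= rspan[1] && qspan[2] <= rspan[2])
    return("c")
  if (compat && shared > 0) return("j")
  if (compat && nrow(qe) == 1 && exov) return("e")
  if (compat && exov) return("o")
  if (opp && nrow(qi) && nrow(ri) && ov(qi, ri)) return("s")
  if (nrow(ri) && !exov) {
    for (j in seq_len(nrow(ri)))
      if (qspan[1] >= ri[j, 1] && qspan[2] <= ri[j, 2]) return("i")
  }
  if (!exov && rs %in% c("+", "-") && compat) {
    d <- if (rs == "+") qspan[1] - rspan[2] else rspan[1] - qspan[2]
    if (d >= 0 && d <= p_window) return("p")
  }
  if (opp && exov) return("x")
  "u"
}

oracle_classify <- function(qe, qs, refs, p_window = 2000) {
  prio <- c("=", "c", "j", "e", "o", "s", "i", "p", "x", "u")
  codes <- vapply(refs, function(r)
    oracle_pair_code(qe, qs, r$exons, r$strand, p_window), character(1))
  codes[order(match(codes, prio))][1]
}

# random toy transcript on a short chromosome: exon structure with >= 1 nt
# introns
random_toy_tx <- function(max_exons = 4, span = 3000) {
  k <- sample.int(max_exons, 1)
  bounds <- sort(sample.int(span, 2 * k))
  m <- matrix(bounds, ncol = 2, byrow = TRUE)
  # enforce half-open validity and 1-base introns
  ok <- m[, 2] > m[, 1]
  m <- m[ok, , drop = FALSE]
  if (!nrow(m)) m <- matrix(c(0, 100), ncol = 2)
  if (nrow(m) > 1) {
    keep <- c(TRUE, m[-1, 1] > m[-nrow(m), 2])
    m <- m[keep, , drop = FALSE]
  }
  list(exons = m, strand = sample(c("+", "-", "*"), 1))
}

# the packaged full-scale study fixture (default configuration, fixed seed)
fx_full_study <- function() fx("full_study", function() {
  simulate_study(simulation_config(seed = 101))
})
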