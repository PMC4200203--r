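test_that("transcript_set validates exon structure and derives chains", {
  ts <- make_ts(list(rbind(c(100, 200), c(300, 400))))
  expect_equal(tx_table(ts)$chain, "200-300")
  expect_equal(tx_table(ts)$tx_len, 200L)
  ic <- intron_chain(ts)
  expect_equal(unname(ic$introns[1, ]), c(200L, 300L))

  single <- make_ts(list(rbind(c(0, 500))))
  expect_equal(nrow(intron_chain(single)$introns), 0L)
  expect_equal(tx_table(single)$chain, "")

  # adjacent exons (zero-length intron) are invalid
  expect_error(make_ts(list(rbind(c(0, 100), c(100, 200)))), "adjacent")
  expect_error(make_ts(list(rbind(c(100, 100)))), "end <= start")
})

test_that("intron chain equals brute-force gap enumeration", {
  set.seed(41)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    toy <- random_toy_tx(max_exons = k, span = 5000)
    ts <- make_ts(list(toy$exons), strand = toy$strand)
    got <- intron_chain(ts)$introns
    m <- toy$exons
    want <- if (nrow(m) > 1) cbind(m[-nrow(m), 2], m[-1, 1])
            else matrix(numeric(0), ncol = 2)
    expect_equal(unname(got), unname(want),
                 ignore_attr = TRUE)
    expect_equal(nrow(got), nrow(m) - 1L)
  }
})

test_that("GTF round-trips through the package readers", {
  ts <- make_ts(list(rbind(c(100, 200), c(300, 450)), rbind(c(700, 900))),
                strand = c("+", "-"), biotype = c("lncRNA", "protein_coding"))
  f <- tempfile(fileext = ".gtf")
  write_gtf(ts, f)
  back <- read_gtf(f)
  expect_equal(exon_table(back)[, .(transcript_id, chrom, strand, start, end)],
               exon_table(ts)[, .(transcript_id, chrom, strand, start, end)])
  expect_equal(sort(tx_table(back)$biotype), sort(tx_table(ts)$biotype))

  # write -> read -> write is byte-identical
  f2 <- tempfile(fileext = ".gtf")
  write_gtf(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("BED12 writer emits block-structured records", {
  ts <- make_ts(list(rbind(c(100, 200), c(300, 450))))
  f <- tempfile(fileext = ".bed")
  write_bed12(ts, f)
  fields <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(fields[1:4], c("chr1", "100", "450", "t01"))
  expect_equal(fields[10:12], c("2", "100,150,", "0,200,"))
})

test_that("class codes match their defining relations", {
  q <- make_ts(list(rbind(c(0, 100), c(200, 300))))
  expect_equal(classify_transcripts(q, q)$class_code, "=")

  ref <- make_ts(list(rbind(c(0, 100), c(200, 300), c(400, 500))),
                 ids = "ref")
  # query sharing one reference intron but with a foreign second intron -> j
  qj <- make_ts(list(rbind(c(50, 100), c(200, 260), c(270, 310))), ids = "qj")
  expect_equal(classify_transcripts(qj, ref)$class_code, "j")
  # contiguous sub-chain inside the span -> c
  qc <- make_ts(list(rbind(c(10, 100), c(200, 300))), ids = "qc")
  expect_equal(classify_transcripts(qc, ref)$class_code, "c")
  # chromosome absent from the references -> u
  qu <- make_ts(list(rbind(c(0, 100), c(200, 300))), chrom = "chrZ")
  expect_equal(classify_transcripts(qu, ref)$class_code, "u")
  # single-exon query overlapping a reference exon -> e
  qe <- make_ts(list(rbind(c(20, 80))))
  expect_equal(classify_transcripts(qe, ref)$class_code, "e")
  # fully inside an intron -> i
  qi <- make_ts(list(rbind(c(110, 130), c(150, 190))))
  expect_equal(classify_transcripts(qi, ref)$class_code, "i")
  # downstream run-on within 2 kb, no overlap -> p
  qp <- make_ts(list(rbind(c(600, 700))))
  expect_equal(classify_transcripts(qp, ref)$class_code, "p")
  # opposite strand exonic overlap -> x
  qx <- make_ts(list(rbind(c(20, 80))), strand = "-")
  expect_equal(classify_transcripts(qx, ref)$class_code, "x")
  # opposite-strand intron overlap without exon overlap -> s
  qs <- make_ts(list(rbind(c(110, 140), c(320, 390))), strand = "-")
  expect_equal(classify_transcripts(qs, ref)$class_code, "s")
})

test_that("classify agrees with the exhaustive oracle on random toys", {
  set.seed(99)
  for (rep in 1:200) {
    qt <- random_toy_tx()
    refs <- lapply(seq_len(sample.int(3, 1)), function(i) random_toy_tx())
    ref_ts <- make_ts(lapply(refs, `[[`, "exons"),
                      strand = vapply(refs, `[[`, character(1), "strand"),
                      ids = sprintf("r%d", seq_along(refs)))
    q_ts <- make_ts(list(qt$exons), strand = qt$strand, ids = "q")
    got <- classify_transcripts(q_ts, ref_ts)$class_code
    want <- oracle_classify(qt$exons, qt$strand, refs)
    expect_equal(got, want, info = sprintf("rep %d", rep))
  }
})

test_that("strand inference reads splice motifs", {
  # genome with a planted GT..AG intron at [100, 200)
  g <- strrep("A", 300)
  substr(g, 101, 102) <- "GT"; substr(g, 199, 200) <- "AG"
  genome <- Biostrings::DNAStringSet(c(chr1 = g))
  ts <- make_ts(list(rbind(c(0, 100), c(200, 300))), strand = "*")
  expect_equal(unname(infer_strand(ts, genome, apply = FALSE)), "+")

  g2 <- strrep("A", 300)
  substr(g2, 101, 102) <- "CT"; substr(g2, 199, 200) <- "AC"
  genome2 <- Biostrings::DNAStringSet(c(chr1 = g2))
  expect_equal(unname(infer_strand(ts, genome2, apply = FALSE)), "-")

  # mixed motifs across two introns -> unknown
  g3 <- strrep("A", 500)
  substr(g3, 101, 102) <- "GT"; substr(g3, 199, 200) <- "AG"
  substr(g3, 301, 302) <- "CT"; substr(g3, 399, 400) <- "AC"
  genome3 <- Biostrings::DNAStringSet(c(chr1 = g3))
  ts2 <- make_ts(list(rbind(c(0, 100), c(200, 300), c(400, 500))),
                 strand = "*")
  expect_equal(unname(infer_strand(ts2, genome3, apply = FALSE)), "*")

  # invariant under exon order: construction sorts exons canonically
  ts_perm <- transcript_set(data.frame(
    transcript_id = "t01", chrom = "chr1", strand = "*",
    start = c(200L, 0L), end = c(300L, 100L)))
  expect_equal(unname(infer_strand(ts_perm, genome, apply = FALSE)), "+")

  expect_error(infer_strand(make_ts(list(rbind(c(0, 100), c(200, 400)))),
                            genome), "outside genome")
})

test_that("consensus rule matches exhaustive truth-table evaluation", {
  exo <- rbind(c(0, 100), c(200, 300))
  combos <- expand.grid(A1 = c(FALSE, TRUE), A2 = c(FALSE, TRUE),
                        A3 = c(FALSE, TRUE), B1 = c(FALSE, TRUE),
                        B2 = c(FALSE, TRUE), B3 = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    pres <- unlist(combos[i, ])
    if (!any(pres)) next
    labs <- names(pres)[pres]
    ex <- do.call(rbind, lapply(labs, function(l)
      data.frame(transcript_id = paste0("tx@", l), chrom = "chr1",
                 strand = "*", start = exo[, 1], end = exo[, 2])))
    tx <- data.frame(transcript_id = paste0("tx@", labs),
                     assembler = substr(labs, 1, 1),
                     sample_id = substr(labs, 2, 2))
    ts <- transcript_set(ex, tx = tx)
    got <- n_transcripts(consensus_filter(ts)) == 1L
    # brute-force rule evaluation
    asm <- substr(labs, 1, 1); sm <- substr(labs, 2, 2)
    want <- any(vapply(unique(sm), function(s)
      length(unique(asm[sm == s])) >= 2, logical(1))) ||
      any(vapply(unique(asm), function(a)
        length(unique(sm[asm == a])) >= 2, logical(1)))
    expect_equal(got, want, info = paste(labs, collapse = ","))
  }
})

test_that("consensus merges exon extents and is monotone in added samples", {
  # same junction, different terminal extents, retained via rule (b)
  ex <- rbind(
    data.frame(transcript_id = "a@A@s1", chrom = "chr1", strand = "*",
               start = c(10L, 200L), end = c(100L, 300L)),
    data.frame(transcript_id = "a@A@s2", chrom = "chr1", strand = "*",
               start = c(0L, 200L), end = c(100L, 320L)))
  tx <- data.frame(transcript_id = c("a@A@s1", "a@A@s2"),
                   assembler = "A", sample_id = c("s1", "s2"))
  res <- consensus_filter(transcript_set(ex, tx = tx))
  expect_equal(n_transcripts(res), 1L)
  expect_equal(exon_table(res)$start, c(0L, 200L))
  expect_equal(exon_table(res)$end, c(100L, 320L))

  # single observation -> removed
  one <- transcript_set(ex[1:2, ],
                        tx = data.frame(transcript_id = "a@A@s1",
                                        assembler = "A", sample_id = "s1"))
  expect_equal(n_transcripts(consensus_filter(one)), 0L)
})

test_that("deduplication collapses identical structures; loci are exonic-overlap components", {
  ts <- make_ts(list(rbind(c(0, 100), c(200, 300)),
                     rbind(c(0, 100), c(200, 300)),
                     rbind(c(250, 400)),
                     rbind(c(5000, 5100))),
                ids = c("a", "b", "c", "d"))
  dd <- deduplicate(ts)
  expect_equal(n_transcripts(dd), 3L)
  expect_equal(tx_table(dd)[transcript_id == "a"]$n_collapsed, 2L)

  loci <- assign_loci(ts)
  # a, b, c overlap exonically (c overlaps exon 2 of a/b); d is separate
  expect_equal(length(unique(loci$locus)), 2L)
  expect_equal(loci[transcript_id == "a"]$locus,
               loci[transcript_id == "c"]$locus)
  expect_false(loci[transcript_id == "a"]$locus ==
                 loci[transcript_id == "d"]$locus)
})

test_that("locus count equals brute-force union-find on a random toy", {
  set.seed(5)
  toys <- lapply(1:10, function(i) random_toy_tx(span = 2000))
  ts <- make_ts(lapply(toys, `[[`, "exons"),
                strand = vapply(toys, `[[`, character(1), "strand"),
                ids = sprintf("t%02d", 1:10))
  got <- assign_loci(ts)
  # union-find oracle over exonic overlap with strand compatibility
  parent <- 1:10
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  compat <- function(s1, s2) s1 == "*" || s2 == "*" || s1 == s2
  ovl <- function(a, b) {
    hit <- FALSE
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
      if (a[i, 1] < b[j, 2] && b[j, 1] < a[i, 2]) hit <- TRUE
    hit
  }
  for (i in 1:9) for (j in (i + 1):10) {
    if (compat(toys[[i]]$strand, toys[[j]]$strand) &&
        ovl(toys[[i]]$exons, toys[[j]]$exons)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(1:10, find, integer(1))
  want_k <- length(unique(roots))
  expect_equal(length(unique(got$locus)), want_k)
  # same partition, not just the same count
  oracle_part <- split(sprintf("t%02d", 1:10), roots)
  got_part <- split(got$transcript_id, got$locus)
  expect_setequal(unname(lapply(oracle_part, sort)),
                  unname(lapply(got_part, sort)))
})
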