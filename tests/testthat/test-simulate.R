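test_that("configuration invariants are enforced", {
  expect_error(simulation_config(assembler_dropout = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(module_cor = -0.1), "\\[0, 1\\]")
  expect_error(simulation_config(n_samples = 23), "sum to n_samples")
  expect_error(simulation_config(n_coding_genes = 0), "positive")
  # sizing error when the genome cannot hold the genes
  expect_error(generate_genome(simulation_config(chrom_length = 5e4)),
               "too short")
})

test_that("a fixed seed reproduces the study byte-for-byte", {
  cfg <- simulation_config(seed = 5, n_chromosomes = 1, chrom_length = 1.2e6,
                           n_coding_genes = 60, n_lncRNA_genes = 30)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  Biostrings::writeXStringSet(g1$genome, file.path(d1, "g.fa"))
  Biostrings::writeXStringSet(g2$genome, file.path(d2, "g.fa"))
  write_gtf(g1$annotation, file.path(d1, "a.gtf"))
  write_gtf(g2$annotation, file.path(d2, "a.gtf"))
  expect_identical(readLines(file.path(d1, "g.fa")),
                   readLines(file.path(d2, "g.fa")))
  expect_identical(readLines(file.path(d1, "a.gtf")),
                   readLines(file.path(d2, "a.gtf")))
})

test_that("every planted intron carries the canonical motif on its strand", {
  st <- fx_small_study()
  intr <- intron_table(st$annotation)
  for (ch in unique(intr$chrom)) {
    sub <- intr[chrom == ch]
    g <- st$genome[[ch]]
    donor <- as.character(Biostrings::Views(g, sub$start + 1, sub$start + 2))
    accept <- as.character(Biostrings::Views(g, sub$end - 1, sub$end))
    motif <- paste0(donor, accept)
    expect_true(all(motif[sub$strand == "+"] == "GTAG"))
    expect_true(all(motif[sub$strand == "-"] == "CTAC"))
  }
})

test_that("divergent pairs have head-to-head geometry with small TSS gaps", {
  st <- fx_small_study()
  dp <- st$ground_truth$divergent_pairs
  expect_gt(nrow(dp), 5)
  txt <- tx_table(st$annotation)
  ts <- tss_table(st$annotation)
  tssv <- setNames(ts$tss, ts$transcript_id)
  strv <- setNames(ts$strand, ts$transcript_id)
  # brute-force scan of the emitted annotation
  seps <- abs(tssv[dp$lnc_id] - tssv[dp$coding_id])
  expect_true(all(strv[dp$lnc_id] != strv[dp$coding_id]))
  expect_gt(mean(seps <= 400), 0.6)   # mostly drawn from 0-400
  expect_true(all(seps <= 2000))
  # orientation_class agrees: planted pairs classify divergent
  oc <- orientation_class(data.frame(id_a = dp$coding_id, id_b = dp$lnc_id),
                          st$annotation)
  expect_true(all(oc$orientation == "divergent"))
})

test_that("degenerate noise parameters make assemblers emit exactly the truth", {
  cfg <- simulation_config(seed = 9, n_chromosomes = 1, chrom_length = 1.2e6,
                           n_coding_genes = 60, n_lncRNA_genes = 30,
                           assembler_dropout = 0, fragmentation_rate = 0,
                           noise_tx_rate = 0, n_samples = 4,
                           stage_design = data.frame(
                             stage = c("oocyte", "twocell"),
                             genotype = "WT", n = c(2, 2)))
  gen <- generate_genome(cfg)
  asm <- generate_assembler_outputs(gen$annotation, cfg)
  tx <- tx_table(asm$assemblies)
  expect_length(asm$noise_ids, 0)
  # every truth transcript in every sample for both assemblers
  expect_equal(nrow(tx), n_transcripts(gen$annotation) * 4 * 2)
  expect_setequal(unique(tx$source_id), tx_table(gen$annotation)$transcript_id)
  # structures identical to the truth
  one <- subset_transcripts(asm$assemblies,
                            tx$transcript_id[tx$assembler == "asmA" &
                                               tx$sample_id == "S01"])
  expect_setequal(tx_table(one)$chain, tx_table(gen$annotation)$chain)
})

test_that("noise transcripts are tracked and dropout follows its rate", {
  st <- fx_small_study()
  tx <- tx_table(st$assemblies)
  expect_true(all(st$ground_truth$noise_tx_ids %in% tx$transcript_id))
  expect_true(all(tx[is_noise == TRUE]$transcript_id %in%
                    st$ground_truth$noise_tx_ids))
  # dropout: the emission rate of expressed transcripts approximates
  # 1 - assembler_dropout (binomial check at ~3 sigma)
  cfg <- simulation_config(seed = 13, n_chromosomes = 1, chrom_length = 1.2e6,
                           n_coding_genes = 60, n_lncRNA_genes = 30,
                           assembler_dropout = 0.5, fragmentation_rate = 0,
                           noise_tx_rate = 0)
  gen <- generate_genome(cfg)
  asm <- generate_assembler_outputs(gen$annotation, cfg)
  n_slots <- n_transcripts(gen$annotation) * cfg$n_samples * 2
  rate <- nrow(tx_table(asm$assemblies)) / n_slots
  se <- sqrt(0.5 * 0.5 / n_slots)
  expect_lt(abs(rate - 0.5), 4 * se)
})

test_that("coverage encodes expression, gaps and noise as designed", {
  st <- fx_small_study()
  ann <- st$annotation
  # zero FPKM in a sample -> zero exonic coverage there
  zero_feat <- rownames(st$expr)[apply(st$expr == 0, 1, any) &
                                   rowSums(st$expr) > 0][1]
  zsample <- names(which(st$expr[zero_feat, ] == 0))
  mc <- max_coverage(subset_transcripts(ann, zero_feat),
                     st$coverage[[zsample[1]]])
  expect_equal(unname(mc), 0)
  # gapped transcripts are excluded from the well-reconstructed set
  expect_length(intersect(st$ground_truth$gapped_ids,
                          st$ground_truth$well_reconstructed_ids), 0)
  # their planted integrity is ~0.6, verified by brute-force base counting
  gid <- st$ground_truth$gapped_ids[1]
  integ <- 0
  gset <- subset_transcripts(ann, gid)
  ex <- exon_table(gset)
  for (sm in names(st$coverage)) {
    vals <- unlist(lapply(seq_len(nrow(ex)), function(i)
      track_values(st$coverage[[sm]], ex$chrom[i], ex$start[i], ex$end[i])))
    integ <- max(integ, mean(vals >= 1))
  }
  expect_lt(integ, 0.75)
  expect_equal(max(vapply(st$coverage, function(cv)
    unname(transcript_integrity(gset, cv)), numeric(1))), integ)
  # well-reconstructed labels agree with recomputation from the tracks
  well <- st$ground_truth$well_reconstructed_ids
  some <- sample(tx_table(ann)$transcript_id, 25)
  for (id in some) {
    sset <- subset_transcripts(ann, id)
    best <- max(vapply(st$coverage, function(cv)
      transcript_integrity(sset, cv), numeric(1)))
    expect_equal(id %in% well, best >= 0.75, info = id)
  }
})

test_that("integrity recomputed from a written bedGraph matches in-memory", {
  st <- fx_small_study()
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(st$coverage[[3]], f)
  back <- read_bedgraph(f, st$chrom_lengths)
  expect_equal(transcript_integrity(st$annotation, back),
               transcript_integrity(st$annotation, st$coverage[[3]]))
})

test_that("conservation tracks separate coding from non-coding exons", {
  st <- fx_small_study()
  ph <- st$conservation$phastcons
  vals <- unlist(lapply(names(ph), function(ch) {
    v <- as.numeric(S4Vectors::runValue(ph[[ch]]))
    v[!is.na(v)]
  }))
  expect_true(all(vals >= 0 & vals <= 1))
  # missing rate on exonic bases near the configured value
  ex <- exon_table(st$annotation)
  base_vals <- unlist(lapply(which(ex$chrom == "chr1"), function(i)
    track_values(ph, "chr1", ex$start[i], ex$end[i], background = NaN)))
  expect_lt(abs(mean(is.na(base_vals)) - 0.1), 0.02)
})

test_that("planted expression carries module structure and lower lncRNA levels", {
  ep <- fx_expr()
  expect_true(all(ep$expr >= 0))
  # within-module pairwise correlation approximately matches the target
  lab <- ep$module_labels
  m1 <- names(lab)[lab == 3 & ep$feature_type[names(lab)] == "coding"]
  cc <- cor(t(log2(ep$expr[m1, ] + 0.05)))
  expect_gt(mean(cc[upper.tri(cc)]), 0.65)
  expect_lt(mean(cc[upper.tri(cc)]), 0.95)
  # eigengene of the 2-cell module tracks the 2-cell stage
  lg <- log10(ep$expr + 1)
  hi <- ep$module_hi[[3]]   # module 3 template: 2-cell high
  mods <- names(lab)[lab == 3]
  me <- module_eigengene(lg, setNames(rep(1L, length(mods)), mods))
  expect_gt(cor(as.numeric(me), as.numeric(hi)), 0.7)
  # lncRNAs lower expressed than mRNAs on average (maximum FPKM)
  mx <- apply(ep$expr, 1, max)
  lnc <- names(ep$feature_type)[ep$feature_type == "lnc"]
  cod <- names(ep$feature_type)[ep$feature_type == "coding"]
  expect_lt(mean(mx[lnc]), mean(mx[cod]))
})

test_that("written study files round-trip through the package readers", {
  cfg <- simulation_config(seed = 15, n_chromosomes = 1, chrom_length = 6e5,
                           n_coding_genes = 30, n_lncRNA_genes = 15,
                           n_samples = 4,
                           stage_design = data.frame(
                             stage = c("oocyte", "twocell"),
                             genotype = "WT", n = c(2, 2)))
  st <- simulate_study(cfg, outdir = td <- tempfile())
  ann <- read_gtf(file.path(td, "annotation_truth.gtf"))
  expect_equal(exon_table(ann)[, .(transcript_id, chrom, start, end)],
               exon_table(st$annotation)[, .(transcript_id, chrom, start,
                                             end)])
  genome <- Biostrings::readDNAStringSet(file.path(td, "genome.fa"))
  expect_equal(as.character(genome[[1]]), as.character(st$genome[[1]]))
  expr <- read.table(file.path(td, "expression_fpkm.tsv"), header = TRUE,
                     sep = "\t", row.names = 1, check.names = FALSE)
  expect_equal(as.matrix(expr), st$expr, tolerance = 1e-12)
  expect_true(file.exists(file.path(td, "asmA_S01.gtf")))
  expect_true(file.exists(file.path(td, "coverage_S01.bedGraph")))
})
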