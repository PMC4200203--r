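#' Simulation configuration
#'
#' Parameters of the synthetic study generator. Defaults emulate the
#' cleavage-stage single-cell design: 24 samples (4 oocytes split between
#' wild-type and a dicer-null analog, 8 two-cell, 6 four-cell and 6
#' eight-cell samples), protein-coding transcripts averaging 3162 nt over 11
#' exons, lncRNAs averaging 550 nt over 3.7 exons, and six planted
#' co-expression modules tied to stages.
#'
#' @param seed master RNG seed; every generator derives its sub-stream from
#'   it deterministically
#' @param n_chromosomes,chrom_length genome shape
#' @param n_coding_genes,n_lncRNA_genes gene counts
#' @param coding_length_mean,coding_exons_mean coding transcript geometry
#' @param lnc_length_mean,lnc_exons_mean lncRNA geometry
#' @param intron_mean mean intron length in bases
#' @param n_samples total samples; must equal the sum of `stage_design$n`
#' @param stage_design data.frame with columns `stage`, `genotype`, `n`
#' @param n_modules planted co-expression modules (default 6)
#' @param module_cor target within-module expression correlation
#' @param divergent_frac fraction of lncRNAs planted head-to-head with a
#'   coding gene (TSS separation mostly 0-400 bases)
#' @param known_lnc_frac fraction of regular lncRNAs included in the
#'   reference ("known") annotation
#' @param db_frac fraction of novel lncRNAs additionally collected in the
#'   lncRNA-database annotation
#' @param gapped_frac fraction of lncRNAs planted with coverage gaps
#'   (reconstruction integrity below 0.75)
#' @param single_exon_decoy_frac,short_decoy_frac,coding_decoy_frac decoy
#'   fractions (relative to `n_lncRNA_genes`) exercising the single-exon,
#'   length and coding-potential filters
#' @param assembler_dropout probability a transcript expressed in a sample is
#'   missed by one assembler there
#' @param fragmentation_rate probability an emitted copy is fragmented
#'   (terminal-exon truncation keeping all junctions, or a single-exon piece
#'   with broken junctions)
#' @param noise_tx_rate spurious transcripts per true transcript per
#'   assembler-sample set
#' @param coverage_depth_expressed,coverage_depth_noise mean reads/base of
#'   expressed transcripts and of noise loci
#' @param conservation_missing_rate fraction of exonic bases without a
#'   conservation score
#' @param lnc_dropout probability a lncRNA's FPKM is zeroed outside its
#'   module's high-expression samples (stage-specific dropout)
#' @return a validated list of class `simulation_config`
#' @export
simulation_config <- function(
    seed = 1L,
    n_chromosomes = 4L, chrom_length = 4.2e6,
    n_coding_genes = 1000L, n_lncRNA_genes = 500L,
    coding_length_mean = 3162, coding_exons_mean = 11,
    lnc_length_mean = 550, lnc_exons_mean = 3.7,
    intron_mean = 400,
    n_samples = 24L,
    stage_design = data.frame(
      stage = c("oocyte", "oocyte", "twocell", "fourcell", "eightcell"),
      genotype = c("WT", "dicerKO", "WT", "WT", "WT"),
      n = c(2L, 2L, 8L, 6L, 6L)),
    n_modules = 6L, module_cor = 0.8,
    divergent_frac = 0.3, known_lnc_frac = 0.3, db_frac = 0.1,
    gapped_frac = 0.08,
    single_exon_decoy_frac = 0.08, short_decoy_frac = 0.05,
    coding_decoy_frac = 0.05,
    assembler_dropout = 0.2, fragmentation_rate = 0.1,
    noise_tx_rate = 0.1,
    coverage_depth_expressed = 10, coverage_depth_noise = 1,
    conservation_missing_rate = 0.1,
    lnc_dropout = 0.5) {
  cfg <- as.list(environment())
  probs <- c("module_cor", "divergent_frac", "known_lnc_frac", "db_frac",
             "gapped_frac", "single_exon_decoy_frac", "short_decoy_frac",
             "coding_decoy_frac", "assembler_dropout", "fragmentation_rate",
             "conservation_missing_rate", "lnc_dropout")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  counts <- c("n_chromosomes", "chrom_length", "n_coding_genes",
              "n_lncRNA_genes", "n_samples", "n_modules")
  for (p in counts) if (cfg[[p]] <= 0) stop(p, " must be positive")
  if (sum(stage_design$n) != n_samples)
    stop("stage_design sample counts must sum to n_samples")
  class(cfg) <- "simulation_config"
  cfg
}

# deterministic sub-stream per generator: all randomness flows from one seed
.sub_seed <- function(cfg, offset) set.seed(cfg$seed * 101L + offset)

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# ---- genome + annotation ---------------------------------------------------

#' Generate a synthetic genome and annotation with planted truth
#'
#' Places non-overlapping coding genes, lncRNAs and decoy structures along
#' random-sequence chromosomes. Every intron of a stranded transcript carries
#' the canonical splice motif (GT..AG on its strand), coding genes carry an
#' embedded open reading frame covering ~92% of the spliced transcript, and
#' lncRNA spliced sequences have their ORFs capped (at most 30 codons and
#' 22% of the transcript) so they are genuinely non-coding. A configurable
#' fraction of lncRNAs is placed head-to-head (divergent) with a coding
#' gene, TSS separations drawn mostly from 0-400 bases. The reference
#' ("known") annotation contains the coding genes and a fraction of the
#' lncRNAs; the rest are withheld as novel truth.
#'
#' @param config a [simulation_config()]
#' @return list with `genome` (`DNAStringSet`), `annotation` (full truth
#'   `transcript_set`), `reference` (known annotation), `lnc_db`
#'   (database-style annotation overlapping part of the novel set), and
#'   `truth` (id bookkeeping: `lnc_ids`, `known_lnc_ids`, `novel_lnc_ids`,
#'   `gapped_ids`, `decoy_ids`, `coding_ids`, `db_ids`, `divergent_pairs`)
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  .sub_seed(cfg, 1L)

  n_se <- round(cfg$single_exon_decoy_frac * cfg$n_lncRNA_genes)
  n_short <- round(cfg$short_decoy_frac * cfg$n_lncRNA_genes)
  n_cd <- round(cfg$coding_decoy_frac * cfg$n_lncRNA_genes)
  n_gap <- round(cfg$gapped_frac * cfg$n_lncRNA_genes)

  roster <- data.table::data.table(
    gene_id = c(sprintf("COD%04d", seq_len(cfg$n_coding_genes)),
                sprintf("LNC%04d", seq_len(cfg$n_lncRNA_genes)),
                if (n_se) sprintf("SED%03d", seq_len(n_se)),
                if (n_short) sprintf("SHD%03d", seq_len(n_short)),
                if (n_cd) sprintf("CDD%03d", seq_len(n_cd))),
    type = c(rep("coding", cfg$n_coding_genes),
             rep("lnc", cfg$n_lncRNA_genes),
             rep("single_exon_decoy", n_se), rep("short_decoy", n_short),
             rep("coding_decoy", n_cd)))
  # gapped lncRNAs: planted low-integrity subset of the lncRNAs
  lnc_ids <- roster$gene_id[roster$type == "lnc"]
  gapped_ids <- if (n_gap) sample(lnc_ids, n_gap) else character()
  n_known <- round(cfg$known_lnc_frac * length(lnc_ids))
  known_lnc_ids <- if (n_known)
    sample(setdiff(lnc_ids, gapped_ids), n_known) else character()
  divergent_lnc <- sample(setdiff(lnc_ids, gapped_ids),
                          round(cfg$divergent_frac * length(lnc_ids)))

  draw_structure <- function(type) {
    if (type == "coding" || type == "coding_decoy") {
      k <- 2L + rpois(1L, cfg$coding_exons_mean - 2)
      len <- max(600L, round(exp(rnorm(1L, log(cfg$coding_length_mean) -
                                         0.35^2 / 2, 0.35))))
    } else if (type == "lnc") {
      k <- 2L + rpois(1L, cfg$lnc_exons_mean - 2)
      len <- max(250L, round(exp(rnorm(1L, log(cfg$lnc_length_mean) -
                                         0.4^2 / 2, 0.4))))
    } else if (type == "single_exon_decoy") {
      k <- 1L
      len <- round(runif(1L, 300, 1500))
    } else { # short_decoy
      k <- 2L
      len <- round(runif(1L, 80, 199))
    }
    len <- max(len, 30L * k)
    w <- rgamma(k, 2)
    sizes <- floor(len * w / sum(w))
    sizes[k] <- len - sum(sizes[-k])
    # enforce a 25-base exon minimum without changing the total length
    for (it in seq_len(4L * k)) {
      low <- which(sizes < 25L)
      if (!length(low)) break
      hi <- which.max(sizes)
      if (hi == low[1L]) break
      need <- 25L - sizes[low[1L]]
      sizes[low[1L]] <- 25L
      sizes[hi] <- sizes[hi] - need
    }
    introns <- if (k > 1L)
      100L + round(rexp(k - 1L, 1 / max(1, cfg$intron_mean - 100))) else
      integer()
    list(sizes = as.integer(sizes), introns = as.integer(introns))
  }

  # pair divergent lncRNAs with distinct coding genes
  coding_ids <- roster$gene_id[roster$type == "coding"]
  partner <- setNames(sample(coding_ids, length(divergent_lnc)),
                      divergent_lnc)
  sep_of <- function(n) {
    many <- runif(n) < 0.85
    ifelse(many, pmin(400L, 20L + round(rexp(n, 1 / 120))),
           round(runif(n, 400, 2000)))
  }

  # placement: shuffle standalone units; a divergent pair is one unit
  standalone <- setdiff(roster$gene_id, c(divergent_lnc, partner))
  units <- c(as.list(standalone),
             lapply(seq_along(divergent_lnc), function(i)
               c(partner[i], divergent_lnc[i])))
  units <- units[sample.int(length(units))]

  type_of <- setNames(roster$type, roster$gene_id)
  exon_rows <- vector("list", nrow(roster))
  row_i <- 0L
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  cursor <- setNames(rep(1000L, cfg$n_chromosomes), chrom_names)
  chrom_i <- 1L

  place_gene <- function(gid, ch, start, strand) {
    st <- draw_structure(type_of[[gid]])
    k <- length(st$sizes)
    ex_start <- integer(k); ex_end <- integer(k)
    pos <- start
    for (e in seq_len(k)) {
      ex_start[e] <- pos
      ex_end[e] <- pos + st$sizes[e]
      pos <- ex_end[e] + if (e < k) st$introns[e] else 0L
    }
    row_i <<- row_i + 1L
    exon_rows[[row_i]] <<- data.table::data.table(
      transcript_id = gid, gene_id = gid, chrom = ch, strand = strand,
      start = ex_start, end = ex_end)
    max(ex_end)
  }

  for (u in units) {
    ch <- chrom_names[chrom_i]
    chrom_i <- chrom_i %% cfg$n_chromosomes + 1L
    gap <- 2500L + round(rexp(1L, 1 / 1500))
    pos <- cursor[[ch]] + gap
    if (length(u) == 1L) {
      endpos <- place_gene(u, ch, pos, sample(c("+", "-"), 1L))
    } else {
      cod <- u[1L]; lnc <- u[2L]
      sep <- sep_of(1L)
      cod_strand <- sample(c("+", "-"), 1L)
      if (cod_strand == "+") {
        # lncRNA on '-' upstream of the coding TSS, head-to-head
        st_l <- draw_structure("lnc")
        lnc_span <- sum(st_l$sizes) + sum(st_l$introns)
        k <- length(st_l$sizes)
        ex_start <- integer(k); ex_end <- integer(k)
        p <- pos
        for (e in seq_len(k)) {
          ex_start[e] <- p; ex_end[e] <- p + st_l$sizes[e]
          p <- ex_end[e] + if (e < k) st_l$introns[e] else 0L
        }
        row_i <- row_i + 1L
        exon_rows[[row_i]] <- data.table::data.table(
          transcript_id = lnc, gene_id = lnc, chrom = ch, strand = "-",
          start = ex_start, end = ex_end)
        cod_start <- max(ex_end) - 1L + sep  # TSS separation = sep
        endpos <- place_gene(cod, ch, cod_start, "+")
      } else {
        # coding on '-', lncRNA on '+' to its right
        endpos <- place_gene(cod, ch, pos, "-")
        lnc_start <- endpos - 1L + sep
        endpos <- max(endpos, place_gene(lnc, ch, lnc_start, "+"))
      }
    }
    if (endpos + 1000L > cfg$chrom_length)
      stop("chromosome too short for requested gene count; increase ",
           "chrom_length or n_chromosomes")
    cursor[[ch]] <- endpos
  }
  exons <- data.table::rbindlist(exon_rows[seq_len(row_i)])

  # random genome as per-base character vectors, then sequence edits
  bases <- c("A", "C", "G", "T")
  seqs <- lapply(chrom_names, function(ch)
    sample(bases, cfg$chrom_length, replace = TRUE))
  names(seqs) <- chrom_names

  # spliced-sequence edits first (exonic bases): embed ORFs in coding genes,
  # cap ORFs in lncRNAs and decoys; batched per chromosome to avoid copying
  ex_by_tx <- split(exons, exons$transcript_id)
  edit_pos <- setNames(vector("list", length(chrom_names)), chrom_names)
  edit_chr <- edit_pos
  for (gid in names(ex_by_tx)) {
    e <- ex_by_tx[[gid]]
    data.table::setorder(e, start)
    ch <- e$chrom[1L]; strand <- e$strand[1L]
    L <- sum(e$end - e$start)
    ty <- type_of[[gid]]
    spliced <- if (ty %in% c("coding", "coding_decoy"))
      .orf_bearing_sequence(L) else .orf_capped_sequence(L)
    fwd <- if (strand == "-") .revcomp_chars(spliced) else spliced
    pos <- unlist(lapply(seq_len(nrow(e)), function(r)
      (e$start[r] + 1L):e$end[r]))
    edit_pos[[ch]] <- c(edit_pos[[ch]], list(pos))
    edit_chr[[ch]] <- c(edit_chr[[ch]], list(fwd))
  }
  for (ch in chrom_names) {
    if (!length(edit_pos[[ch]])) next
    s <- seqs[[ch]]
    s[unlist(edit_pos[[ch]])] <- unlist(edit_chr[[ch]])
    seqs[[ch]] <- s
  }

  # canonical splice motifs on the annotated strand of every intron
  tmp_ts <- transcript_set(exons, validate = FALSE)
  intr <- intron_table(tmp_ts)
  if (nrow(intr)) {
    for (ch in unique(intr$chrom)) {
      sub <- intr[chrom == ch]
      plus <- sub$strand == "+"
      s <- seqs[[ch]]
      s[sub$start + 1L] <- ifelse(plus, "G", "C")
      s[sub$start + 2L] <- "T"
      s[sub$end - 1L] <- "A"
      s[sub$end] <- ifelse(plus, "G", "C")
      seqs[[ch]] <- s
    }
  }

  genome <- Biostrings::DNAStringSet(
    setNames(vapply(seqs, paste, character(1L), collapse = ""), chrom_names))

  biotype_of <- c(coding = "protein_coding", lnc = "lncRNA",
                  single_exon_decoy = "lncRNA", short_decoy = "lncRNA",
                  coding_decoy = "novel_coding")
  meta <- data.table::data.table(
    transcript_id = roster$gene_id,
    biotype = biotype_of[roster$type])
  annotation <- transcript_set(exons, tx = meta)

  reference_ids <- c(coding_ids, known_lnc_ids)
  reference <- subset_transcripts(annotation, reference_ids)

  novel_lnc_ids <- setdiff(lnc_ids, union(known_lnc_ids, gapped_ids))
  db_ids <- sample(novel_lnc_ids, round(cfg$db_frac * length(novel_lnc_ids)))
  lnc_db <- subset_transcripts(annotation, db_ids)

  list(genome = genome, annotation = annotation, reference = reference,
       lnc_db = lnc_db,
       truth = list(
         coding_ids = coding_ids, lnc_ids = lnc_ids,
         known_lnc_ids = known_lnc_ids, novel_lnc_ids = novel_lnc_ids,
         gapped_ids = gapped_ids,
         decoy_ids = roster$gene_id[roster$type %in%
           c("single_exon_decoy", "short_decoy", "coding_decoy")],
         db_ids = db_ids,
         divergent_pairs = data.table::data.table(
           lnc_id = divergent_lnc, coding_id = unname(partner))))
}

# spliced sequence of length L with an intact ORF covering ~92% of it
.orf_bearing_sequence <- function(L) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, L, replace = TRUE)
  n_cod <- max(3L, floor(L * 0.92 / 3))
  orf_nt <- 3L * n_cod
  off <- max(0L, floor((L - orf_nt) / 2))
  all_cod <- apply(expand.grid(bases, bases, bases), 1L, paste,
                   collapse = "")
  safe <- setdiff(all_cod, .STOP_CODONS)
  body <- sample(safe, n_cod - 2L, replace = TRUE)
  orf <- c("ATG", body, "TAA")
  s[(off + 1L):(off + orf_nt)] <- unlist(strsplit(orf, ""))
  # no stray in-frame stop can appear: the body excludes stop codons
  s
}

# spliced sequence of length L whose ORFs are capped (non-coding by
# construction): any ORF longer than the cap gets a stop codon inserted
.orf_capped_sequence <- function(L) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, L, replace = TRUE)
  cap <- max(5L, min(30L, floor(0.22 * L / 3)))
  for (iter in 1:200) {
    hit <- .longest_orf_hit(s, cap)
    if (is.null(hit)) break
    # overwrite the codon at the cap position with TAA
    pos <- hit$start_nt + 3L * (cap - 2L)
    s[pos:(pos + 2L)] <- c("T", "A", "A")
  }
  s
}

# first ORF (any forward frame) longer than `cap` codons; NULL when none
.longest_orf_hit <- function(s, cap) {
  L <- length(s)
  if (L < 3L) return(NULL)
  str <- paste(s, collapse = "")
  for (f in 1:3) {
    starts_at <- seq.int(f, L - 2L, by = 3L)
    if (!length(starts_at)) next
    cods <- substring(str, starts_at, starts_at + 2L)
    is_stop <- cods %in% .STOP_CODONS
    is_atg <- cods == "ATG"
    run_start <- 1L
    for (re in c(which(is_stop), length(cods) + 1L)) {
      if (re > run_start) {
        atg <- which(is_atg[run_start:(re - 1L)])
        if (length(atg)) {
          first_atg <- run_start + atg[1L] - 1L
          ncod <- (re - first_atg) + as.integer(re <= length(cods))
          if (ncod > cap)
            return(list(start_nt = starts_at[first_atg], codons = ncod))
        }
      }
      run_start <- re + 1L
    }
  }
  NULL
}

.revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[x]))
}

# ---- expression ------------------------------------------------------------

#' Generate a staged expression matrix with planted co-expression modules
#'
#' Builds a features x samples FPKM matrix over the configured stage design.
#' Each planted module follows a latent stage profile (oocyte-WT,
#' oocyte-dicer-null, 2-cell, 4-cell, 8-cell, or monotone "time", cycled when
#' more modules are requested); member genes mix the latent profile with
#' independent noise so within-module pairwise correlation is approximately
#' `module_cor`. Expression is log-normal on top of the latent factor;
#' lncRNAs get a lower baseline than mRNAs and stage-specific dropout (FPKM
#' zeroed outside their module's high samples), making them lower-expressed
#' and more stage-specific. Module 0 is unstructured background. When a
#' `generate_genome()` result is supplied, planted divergent lncRNAs join
#' their coding partner's module so neighbour pairs are co-expressed.
#'
#' @param config a [simulation_config()]
#' @param genome_sim optional result of [generate_genome()]
#' @return list with `expr` (matrix), `meta` (sample metadata: `sample_id`,
#'   `stage`, `genotype`, `time_index`), `module_labels` (named integer,
#'   0 = background), `module_hi` (list of logical high-sample indicators
#'   per module), `feature_type` (named character)
#' @export
generate_expression <- function(config, genome_sim = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  .sub_seed(cfg, 2L)

  sd_ <- cfg$stage_design
  stage <- rep(sd_$stage, sd_$n)
  genotype <- rep(sd_$genotype, sd_$n)
  stage_order <- unique(sd_$stage)
  time_index <- match(stage, stage_order)
  ns <- cfg$n_samples
  meta <- data.frame(sample_id = sprintf("S%02d", seq_len(ns)),
                     stage = stage, genotype = genotype,
                     time_index = time_index)

  if (!is.null(genome_sim)) {
    ann <- genome_sim$annotation$tx
    ids <- ann$transcript_id
    bt <- setNames(ann$biotype, ids)
    ftype <- ifelse(bt == "protein_coding", "coding",
             ifelse(bt == "novel_coding", "coding", "lnc"))
    div <- genome_sim$truth$divergent_pairs
  } else {
    ids <- c(sprintf("COD%04d", seq_len(cfg$n_coding_genes)),
             sprintf("LNC%04d", seq_len(cfg$n_lncRNA_genes)))
    ftype <- setNames(c(rep("coding", cfg$n_coding_genes),
                        rep("lnc", cfg$n_lncRNA_genes)), ids)
    div <- NULL
  }
  ftype <- setNames(as.character(ftype), ids)

  # latent module profiles: high-sample indicator + noise, standardized
  templates <- list(
    function(m) m$stage == "oocyte" & m$genotype == "WT",
    function(m) m$stage == "oocyte" & m$genotype != "WT",
    function(m) m$stage == "twocell",
    function(m) m$stage == "fourcell",
    function(m) m$stage == "eightcell",
    function(m) m$time_index >= max(m$time_index) - 1L)
  hi_list <- lapply(seq_len(cfg$n_modules), function(m) {
    f <- templates[[(m - 1L) %% length(templates) + 1L]]
    hi <- f(meta)
    if (!any(hi) || all(hi)) hi <- meta$time_index >= 3L  # degenerate design
    hi
  })
  latent <- lapply(hi_list, function(hi) {
    f <- as.numeric(hi) + rnorm(ns, 0, 0.15)
    (f - mean(f)) / sd(f)
  })

  # module assignment (background fraction 0.15), divergent pairs co-modular
  labels <- setNames(integer(length(ids)), ids)
  bg <- runif(length(ids)) < 0.15
  labels[!bg] <- sample.int(cfg$n_modules, sum(!bg), replace = TRUE)
  if (!is.null(div) && nrow(div)) {
    part_lab <- labels[div$coding_id]
    part_lab[part_lab == 0L] <- sample.int(cfg$n_modules,
                                           sum(part_lab == 0L),
                                           replace = TRUE)
    labels[div$coding_id] <- part_lab
    labels[div$lnc_id] <- part_lab
  }

  rho <- cfg$module_cor
  mu <- ifelse(ftype == "coding", rnorm(length(ids), 4, 0.7),
               rnorm(length(ids), 1.5, 0.7))
  amp <- 1.5
  z <- matrix(rnorm(length(ids) * ns), length(ids), ns)
  for (m in seq_len(cfg$n_modules)) {
    sel <- labels == m
    if (!any(sel)) next
    z[sel, ] <- sqrt(rho) * matrix(latent[[m]], sum(sel), ns, byrow = TRUE) +
      sqrt(1 - rho) * z[sel, , drop = FALSE]
  }
  expr <- 2^(mu + amp * z)

  # stage-specific dropout for lncRNAs outside their module's high samples
  for (m in seq_len(cfg$n_modules)) {
    sel <- which(labels == m & ftype == "lnc")
    if (!length(sel)) next
    lo <- !hi_list[[m]]
    drop <- matrix(runif(length(sel) * sum(lo)) < cfg$lnc_dropout,
                   length(sel), sum(lo))
    expr[sel, lo][drop] <- 0
  }
  dimnames(expr) <- list(ids, meta$sample_id)
  list(expr = expr, meta = meta, module_labels = labels,
       module_hi = hi_list, feature_type = ftype)
}

# ---- assembler outputs -----------------------------------------------------

#' Emulate per-sample outputs of two transcript assemblers
#'
#' For every sample and each of two assemblers, each transcript expressed in
#' that sample (FPKM above `min_fpkm`) is emitted with probability
#' `1 - assembler_dropout`; an emitted copy is fragmented with probability
#' `fragmentation_rate` (terminal-exon truncation preserving all junctions,
#' or a single-exon piece with broken junctions, equally likely). Spurious
#' noise transcripts (mostly single-exon, placed in intergenic gaps) are
#' added at `noise_tx_rate` per true transcript per set and recorded.
#'
#' @param annotation truth `transcript_set` (from [generate_genome()])
#' @param config a [simulation_config()]
#' @param expr optional expression matrix gating per-sample presence
#'   (default: every transcript present in every sample)
#' @param chrom_lengths named chromosome lengths (for noise placement);
#'   defaults to the configured `chrom_length`
#' @param min_fpkm minimal FPKM for a transcript to be assemblable in a
#'   sample (default 0.5)
#' @return list with `assemblies` (one `transcript_set`, metadata columns
#'   `assembler`, `sample_id`, `source_id`, `is_noise`) and `noise_ids`
#' @export
generate_assembler_outputs <- function(annotation, config, expr = NULL,
                                       chrom_lengths = NULL,
                                       min_fpkm = 0.5) {
  stopifnot(inherits(annotation, "transcript_set"),
            inherits(config, "simulation_config"))
  cfg <- config
  .sub_seed(cfg, 3L)
  if (is.null(chrom_lengths))
    chrom_lengths <- setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                              sprintf("chr%d", seq_len(cfg$n_chromosomes)))
  samples <- if (!is.null(expr)) colnames(expr) else
    sprintf("S%02d", seq_len(cfg$n_samples))
  ids <- annotation$tx$transcript_id
  present_mat <- if (!is.null(expr))
    expr[ids, samples, drop = FALSE] > min_fpkm
  else matrix(TRUE, length(ids), length(samples),
              dimnames = list(ids, samples))

  ex_all <- annotation$exons[, .(transcript_id, chrom, start, end)]
  data.table::setkey(ex_all, transcript_id)
  # intergenic gaps for noise placement (50 b margins)
  spans <- annotation$tx[, .(chrom, span_start, span_end)]
  gaps <- spans[, {
    o <- order(span_start)
    s <- span_start[o]; e <- span_end[o]
    gs <- c(0L, cummax(e) + 50L)
    ge <- c(s - 50L, chrom_lengths[[.BY$chrom]])
    keep <- ge - gs > 1200L
    .(gap_start = gs[keep], gap_end = ge[keep])
  }, by = chrom]

  out_ex <- list()
  n_noise <- round(cfg$noise_tx_rate * length(ids))
  for (asm in c("asmA", "asmB")) {
    for (sm in samples) {
      pres <- ids[present_mat[, sm]][
        runif(sum(present_mat[, sm])) >= cfg$assembler_dropout]
      if (length(pres)) {
        frag <- runif(length(pres)) < cfg$fragmentation_rate
        full_ids <- pres[!frag]
        rec_of <- function(src) paste0(src, "@", asm, "@", sm)
        if (length(full_ids)) {
          fe <- ex_all[J(full_ids)]
          fe[, rec := rec_of(transcript_id)]
          out_ex[[length(out_ex) + 1L]] <-
            fe[, .(transcript_id = rec, chrom, start, end,
                   source_id = transcript_id)]
        }
        for (fid in pres[frag]) {
          fe <- ex_all[J(fid)]
          n <- nrow(fe)
          if (n >= 2L && runif(1L) < 0.5) {
            # terminal truncation: junctions preserved
            w1 <- fe$end[1L] - fe$start[1L]
            wn <- fe$end[n] - fe$start[n]
            fe$start[1L] <- fe$start[1L] +
              sample.int(max(1L, w1 - 10L), 1L) - 1L
            fe$end[n] <- fe$end[n] - (sample.int(max(1L, wn - 10L), 1L) - 1L)
          } else {
            # single-exon piece: junctions broken
            r <- sample.int(n, 1L)
            w <- fe$end[r] - fe$start[r]
            lo <- fe$start[r]; hi <- fe$end[r]
            if (w > 60L) {
              lo <- fe$start[r] + sample.int(w - 60L, 1L) - 1L
              hi <- min(fe$end[r], lo + 50L + sample.int(w - 50L, 1L))
            }
            fe <- fe[r]
            fe$start <- lo; fe$end <- hi
          }
          out_ex[[length(out_ex) + 1L]] <-
            fe[, .(transcript_id = rec_of(fid), chrom, start, end,
                   source_id = fid)]
        }
      }
      if (n_noise > 0L && nrow(gaps)) {
        gi <- sample.int(nrow(gaps), n_noise, replace = TRUE,
                         prob = gaps$gap_end - gaps$gap_start)
        ne <- lapply(seq_len(n_noise), function(i) {
          g <- gaps[gi[i]]
          nid <- sprintf("NOI_%s_%s_%03d", asm, sm, i)
          multi <- runif(1L) < 0.3
          room <- g$gap_end - g$gap_start
          if (multi) {
            sizes <- round(runif(2L, 80, 250))
            intr <- round(runif(1L, 100, 500))
            span <- sum(sizes) + intr
            if (span + 10L > room) { multi <- FALSE }
          }
          if (!multi) {
            len <- min(room - 10L, round(runif(1L, 200, 1000)))
            s0 <- g$gap_start + sample.int(max(1L, room - len), 1L)
            return(data.table::data.table(
              transcript_id = nid, chrom = g$chrom, start = s0,
              end = s0 + len, source_id = NA_character_))
          }
          s0 <- g$gap_start + sample.int(max(1L, room - span), 1L)
          data.table::data.table(
            transcript_id = nid, chrom = g$chrom,
            start = c(s0, s0 + sizes[1L] + intr),
            end = c(s0 + sizes[1L], s0 + span),
            source_id = NA_character_)
        })
        out_ex[[length(out_ex) + 1L]] <- data.table::rbindlist(ne)
      }
    }
  }
  ex <- data.table::rbindlist(out_ex)
  # provenance from the record id (truth: <src>@<assembler>@<sample>;
  # noise: NOI_<assembler>_<sample>_<i>)
  sp <- data.table::tstrsplit(ex$transcript_id, "@", fixed = TRUE)
  has_at <- grepl("@", ex$transcript_id, fixed = TRUE)
  ex[, assembler := ifelse(has_at, sp[[2L]],
                           sub("^NOI_(asm[AB])_.*$", "\\1", transcript_id))]
  ex[, sample_id := ifelse(has_at, sp[[3L]],
                           sub("^NOI_asm[AB]_([^_]+)_.*$", "\\1",
                               transcript_id))]
  tx <- unique(ex[, .(transcript_id, assembler, sample_id,
                      source_id, is_noise = is.na(source_id))])
  assemblies <- transcript_set(
    ex[, .(transcript_id, chrom, start, end)],
    tx = tx, validate = FALSE)
  list(assemblies = assemblies,
       noise_ids = tx$transcript_id[tx$is_noise])
}

# ---- coverage --------------------------------------------------------------

#' Generate per-sample read-coverage tracks
#'
#' Exonic read depth is proportional to the sample FPKM around
#' `coverage_depth_expressed` reads/base (clamped to 0.5-3x); transcripts
#' with zero FPKM in a sample get no coverage there. Planted "gapped"
#' transcripts are covered over only 60% of their exonic bases (5'-most
#' part), so their reconstruction integrity stays below 0.75. Noise loci
#' from the assembler emulation receive `coverage_depth_noise` reads/base in
#' the sample they were emitted in.
#'
#' @param annotation truth `transcript_set`
#' @param expr expression matrix (features x samples)
#' @param config a [simulation_config()]
#' @param gapped_ids transcripts planted with coverage gaps
#' @param noise optional `transcript_set` of noise records (with
#'   `sample_id` metadata), e.g. the assemblies restricted to noise ids
#' @param chrom_lengths named chromosome lengths
#' @return named list (by sample) of coverage `RleList` tracks
#' @export
generate_coverage <- function(annotation, expr, config,
                              gapped_ids = character(), noise = NULL,
                              chrom_lengths = NULL) {
  stopifnot(inherits(annotation, "transcript_set"),
            inherits(config, "simulation_config"))
  cfg <- config
  .sub_seed(cfg, 4L)
  if (is.null(chrom_lengths))
    chrom_lengths <- setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                              sprintf("chr%d", seq_len(cfg$n_chromosomes)))
  ex <- data.table::copy(annotation$exons)
  # gapped transcripts: keep only the leftmost 60% of exonic bases
  if (length(gapped_ids)) {
    gex <- ex[transcript_id %in% gapped_ids]
    gex <- gex[, {
      keep_n <- floor(0.6 * sum(end - start))
      cum <- cumsum(end - start)
      last <- which(cum >= keep_n)[1L]
      e2 <- end
      e2[last] <- end[last] - (cum[last] - keep_n)
      .(chrom = chrom[seq_len(last)], start = start[seq_len(last)],
        end = e2[seq_len(last)])
    }, by = transcript_id]
    gex <- gex[end > start]
    ex <- rbind(ex[!transcript_id %in% gapped_ids,
                   .(transcript_id, chrom, start, end)],
                gex[, .(transcript_id, chrom, start, end)])
  } else {
    ex <- ex[, .(transcript_id, chrom, start, end)]
  }
  samples <- colnames(expr)
  noise_ex <- if (!is.null(noise)) noise$exons else NULL
  noise_sm <- if (!is.null(noise))
    setNames(noise$tx$sample_id, noise$tx$transcript_id) else NULL
  out <- lapply(samples, function(sm) {
    fpkm <- expr[, sm]
    depth <- cfg$coverage_depth_expressed *
      pmin(pmax(fpkm / 10, 0.5), 3)
    depth[fpkm <= 0] <- 0
    d <- depth[ex$transcript_id]
    sel <- !is.na(d) & d > 0
    ranges <- ex[sel]
    w <- round(d[sel])
    if (!is.null(noise_ex)) {
      nsel <- noise_sm[noise_ex$transcript_id] == sm
      if (any(nsel)) {
        ranges <- rbind(ranges,
                        noise_ex[nsel, .(transcript_id, chrom, start, end)])
        w <- c(w, rep(max(1, round(cfg$coverage_depth_noise)), sum(nsel)))
      }
    }
    if (!nrow(ranges)) {
      return(methods::as(lapply(chrom_lengths, function(l)
        S4Vectors::Rle(0, l)), "RleList"))
    }
    gr <- GenomicRanges::GRanges(
      ranges$chrom, IRanges::IRanges(ranges$start + 1L, ranges$end),
      seqlengths = chrom_lengths)
    GenomicRanges::coverage(gr, weight = w)
  })
  names(out) <- samples
  out
}

# ---- conservation ----------------------------------------------------------

#' Generate phastCons-like and phyloP-like conservation tracks
#'
#' Exonic bases of coding transcripts draw from a higher-score distribution
#' than lncRNA exonic bases (phastCons-like: Beta(8,2) vs Beta(2,8), in
#' \[0,1\]; phyloP-like: N(2,1) vs N(0,1), unbounded). A
#' `conservation_missing_rate` fraction of exonic bases carries no score,
#' and bases outside exons are unscored.
#'
#' @param annotation truth `transcript_set` (biotypes distinguish coding
#'   from non-coding)
#' @param config a [simulation_config()]
#' @param chrom_lengths named chromosome lengths
#' @return list with `phastcons` and `phylop` `RleList` tracks (`NA` =
#'   missing score)
#' @export
generate_conservation <- function(annotation, config, chrom_lengths = NULL) {
  stopifnot(inherits(annotation, "transcript_set"),
            inherits(config, "simulation_config"))
  cfg <- config
  .sub_seed(cfg, 5L)
  if (is.null(chrom_lengths))
    chrom_lengths <- setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                              sprintf("chr%d", seq_len(cfg$n_chromosomes)))
  bt <- setNames(annotation$tx$biotype, annotation$tx$transcript_id)
  is_coding <- bt[annotation$exons$transcript_id] %in%
    c("protein_coding", "novel_coding")
  ex <- annotation$exons
  phast <- list(); phylo <- list()
  for (ch in names(chrom_lengths)) {
    len <- as.integer(chrom_lengths[[ch]])
    v1 <- rep(NA_real_, len)
    v2 <- rep(NA_real_, len)
    idx <- which(ex$chrom == ch)
    if (length(idx)) {
      pos <- unlist(lapply(idx, function(i) (ex$start[i] + 1L):ex$end[i]))
      cod <- rep(is_coding[idx], ex$end[idx] - ex$start[idx])
      n <- length(pos)
      s1 <- ifelse(cod, rbeta(n, 8, 2), rbeta(n, 2, 8))
      s2 <- ifelse(cod, rnorm(n, 2, 1), rnorm(n, 0, 1))
      miss <- runif(n) < cfg$conservation_missing_rate
      s1[miss] <- NA_real_
      s2[miss] <- NA_real_
      v1[pos] <- s1
      v2[pos] <- s2
    }
    phast[[ch]] <- S4Vectors::Rle(v1)
    phylo[[ch]] <- S4Vectors::Rle(v2)
  }
  list(phastcons = methods::as(phast, "RleList"),
       phylop = methods::as(phylo, "RleList"))
}

# ---- whole study -----------------------------------------------------------

#' Generate a complete synthetic study
#'
#' Runs every generator off one seed and assembles the ground truth:
#' genome + annotation, staged expression with planted modules, two
#' assemblers' per-sample outputs, per-sample coverage and two conservation
#' tracks. `ground_truth$true_novel_ids` is the exact transcript set the
#' discovery pipeline is expected to recover (novel, well-reconstructed,
#' multi-exonic lncRNAs); `well_reconstructed_ids` is recomputed from the
#' emitted coverage (best integrity across samples at depth >= 1), not
#' assumed.
#'
#' @param config a [simulation_config()]
#' @param outdir optional directory; when given, all inputs are written as
#'   plain-text files (FASTA, GTF, bedGraph, TSV)
#' @return list with `genome`, `annotation`, `reference`, `lnc_db`,
#'   `expr`, `meta`, `module_labels`, `module_hi`, `feature_type`,
#'   `assemblies`, `coverage`, `conservation`, `chrom_lengths`,
#'   `ground_truth`
#' @export
simulate_study <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  chrom_lengths <- setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                            sprintf("chr%d", seq_len(cfg$n_chromosomes)))
  gen <- generate_genome(cfg)
  ep <- generate_expression(cfg, gen)
  asm <- generate_assembler_outputs(gen$annotation, cfg, expr = ep$expr,
                                    chrom_lengths = chrom_lengths)
  noise_set <- subset_transcripts(asm$assemblies, asm$noise_ids)
  cov <- generate_coverage(gen$annotation, ep$expr, cfg,
                           gapped_ids = gen$truth$gapped_ids,
                           noise = noise_set,
                           chrom_lengths = chrom_lengths)
  consv <- generate_conservation(gen$annotation, cfg,
                                 chrom_lengths = chrom_lengths)

  # recompute reconstruction quality from the emitted coverage
  integ <- rep(0, n_transcripts(gen$annotation))
  names(integ) <- gen$annotation$tx$transcript_id
  for (sm in names(cov))
    integ <- pmax(integ, transcript_integrity(gen$annotation, cov[[sm]]))
  well <- names(integ)[integ >= 0.75]

  true_novel <- intersect(gen$truth$novel_lnc_ids, well)
  gt <- list(
    true_lncRNA_ids = gen$truth$lnc_ids,
    true_novel_ids = true_novel,
    known_lnc_ids = gen$truth$known_lnc_ids,
    gapped_ids = gen$truth$gapped_ids,
    decoy_ids = gen$truth$decoy_ids,
    db_ids = gen$truth$db_ids,
    divergent_pairs = gen$truth$divergent_pairs,
    noise_tx_ids = asm$noise_ids,
    well_reconstructed_ids = well,
    module_labels = ep$module_labels)

  out <- list(genome = gen$genome, annotation = gen$annotation,
              reference = gen$reference, lnc_db = gen$lnc_db,
              expr = ep$expr, meta = ep$meta,
              module_labels = ep$module_labels, module_hi = ep$module_hi,
              feature_type = ep$feature_type,
              assemblies = asm$assemblies, coverage = cov,
              conservation = consv, chrom_lengths = chrom_lengths,
              ground_truth = gt)
  if (!is.null(outdir)) write_study(out, outdir)
  out
}

#' Write a simulated study to plain-text files
#'
#' @param study result of [simulate_study()]
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  Biostrings::writeXStringSet(study$genome, p("genome.fa"))
  write_gtf(study$annotation, p("annotation_truth.gtf"))
  write_gtf(study$reference, p("annotation_known.gtf"))
  write_gtf(study$lnc_db, p("lncrna_db.gtf"))
  asm <- study$assemblies
  for (a in unique(asm$tx$assembler)) {
    for (sm in unique(asm$tx$sample_id)) {
      sub <- subset_transcripts(
        asm, asm$tx$transcript_id[asm$tx$assembler == a &
                                    asm$tx$sample_id == sm])
      write_gtf(sub, p(sprintf("%s_%s.gtf", a, sm)), source = a)
    }
  }
  for (sm in names(study$coverage))
    write_bedgraph(study$coverage[[sm]], p(sprintf("coverage_%s.bedGraph",
                                                   sm)))
  write_bedgraph(study$conservation$phastcons, p("phastcons.bedGraph"))
  write_bedgraph(study$conservation$phylop, p("phylop.bedGraph"))
  em <- data.frame(transcript_id = rownames(study$expr), study$expr,
                   check.names = FALSE)
  write.table(em, p("expression_fpkm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(study$meta, p("sample_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gt <- study$ground_truth
  gtab <- data.frame(
    transcript_id = names(gt$module_labels),
    module = unname(gt$module_labels),
    is_lncRNA = names(gt$module_labels) %in% gt$true_lncRNA_ids,
    is_true_novel = names(gt$module_labels) %in% gt$true_novel_ids,
    is_known_lnc = names(gt$module_labels) %in% gt$known_lnc_ids,
    is_gapped = names(gt$module_labels) %in% gt$gapped_ids,
    well_reconstructed = names(gt$module_labels) %in%
      gt$well_reconstructed_ids)
  write.table(gtab, p("ground_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(outdir)
}
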