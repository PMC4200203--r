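---
title: "cleavecat: methods, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cleavecat: methods, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific model behind `cleavecat`, the
conventions and parameter defaults the implementation commits to, the
design choices made where the methodology was genuinely open, and what the
synthetic-data module does and does not emulate.

## The discovery model

The package targets the situation where transcript structures were
assembled per sample from single-cell RNA-seq (e.g. 24 blastomeres across
oocyte, 2-cell, 4-cell and 8-cell stages) by two independent assemblers,
from a non-strand-specific library. Such assemblies are dominated by three
error modes: spurious loci from background reads, fragmentary structures
(missing terminal sequence, broken junctions), and unknown strand. Each
filter in `run_pipeline()` addresses one mode:

* **Reproducibility (consensus).** A structure is believable if two
  assemblers found it in the same cell, or one assembler found it in at
  least two cells. Structures are identified by chromosome + intron chain;
  single-exon structures by their interval with ±25 b end slack
  (assembler ends are noisy; junctions are not). Exon extents of a retained
  group are merged to the outermost terminal boundaries — junction-identical
  structures are the same transcript observed with different end
  completeness.
* **Expression support (coverage).** Transcripts whose maximum exonic depth
  never reaches the threshold (default 3.77881 reads/base) are background.
  "Maximum coverage" is the maximum per-base depth over the transcript's
  exons, taken over the samples in which it was assembled — single-cell
  tracks are sparse, and assembly already pooled evidence across cells, so
  requiring the threshold in a single designated sample would be
  arbitrarily strict. A per-transcript mean-depth alternative was
  considered and rejected: a uniform-low background locus can have the same
  mean as a sharply expressed short transcript.
* **Structural completeness (integrity).** Integrity is the fraction of
  exonic bases covered at depth ≥ 1 (`min_depth` configurable; "covered by
  reads" does not name a depth, and 1 is the weakest faithful reading);
  transcripts below 0.75 are fragmentary reconstructions.
* **Orientation (splice motifs).** A transcript is `+` if every intron
  reads `GT..AG` on the forward genome strand, `-` if every intron reads
  `CT..AC`, otherwise unknown. Unresolvable transcripts are dropped at this
  stage: every downstream analysis that matters here (antisense codes, TSS
  geometry, ORF orientation) needs a strand, and a multi-exon transcript
  with no consistent canonical junctions is itself suspect.
* **Size.** Single-exon and < 200 nt transcripts are excluded; 200 nt
  exactly is retained (the exclusion is strictly "< 200").
* **Novelty (class codes).** Candidates are classified against each
  reference annotation source with cuffcompare-style codes and removed when
  any source yields one of `=`, `c`, `j`, `e`, `o`, `p`, `s`. Intronic
  (`i`), antisense (`x`) and intergenic (`u`) candidates are novel. A
  separate lncRNA-database comparison (codes `=`, `c`, `j`, `e`, `o`)
  annotates which novel transcripts are already collected without removing
  them.
* **Coding potential.** See below.

### Class-code conventions

The relation codes are re-implemented with one fixed priority,
`= > c > j > e > o > s > i > p > x > u`, evaluated over all references
within 2 kb of the query; exactly one code is returned.

Decisions the code set forced:

* `=` requires a non-empty identical intron chain on both sides. Two
  overlapping single-exon transcripts are `e`/`o`, never `=` — without
  junctions there is no chain to match.
* Strand compatibility: unknown (`*`) matches either strand; `s` and `x`
  require both strands known. Assemblies from non-strand-specific data must
  not trigger antisense codes spuriously.
* `p` (polymerase run-on) uses a 2 kb window downstream of a reference
  3' end (configurable), requires a known reference strand and no exonic
  overlap.
* `u` is the fallback whenever no positional code applies. Defining `u`
  only as "no reference within 2 kb" leaves a gap — a query 400 b
  *upstream* of a reference on the opposite strand (a divergent promoter
  partner, exactly the geometry lncRNA discovery cares about) overlaps
  nothing, is not intronic and is not downstream. Totality requires a
  fallback, and `u` is the only sensible one.

### Loci

"Locus" is defined operationally as a connected component of the
exonic-overlap graph on compatible strands (unknown strand connects to
both). This is a choice, not an inference: annotation-free locus notions
differ between tools, and exonic overlap is the weakest relation under
which two transcripts cannot be counted as independent discoveries.

### Coverage-threshold learning

The default constant 3.77881 reads/base can be re-learned from reference
transcripts: per class (coding, non-coding), transcripts are labelled
well-reconstructed at integrity ≥ 0.75, the ROC of maximum coverage as a
predictor of that label is built over all candidate thresholds (the sorted
unique scores; prediction is score ≥ threshold), and the threshold
maximizing Youden's *J* = sensitivity + specificity − 1 is chosen, ties
toward the smaller threshold. The final threshold averages the two class
thresholds. The area under the curve alone does not select a point on the
curve, so a point-picking rule had to be fixed; Youden's *J* is the
standard choice and the one an exhaustive threshold scan reproduces (this
equivalence is tested). A class in which every reference transcript carries
the same label cannot be learned from; it falls back to the default with a
warning.

### Coding potential

The published coding-potential classifiers in this space are trained SVMs
over ORF features plus protein-database homology; neither the trained model
nor the database is something a reusable pipeline should silently embed.
`cleavecat` keeps the decision *surface semantics* — the score orientation
and the −0.5 cutoff (non-coding strictly below; the boundary value itself
is coding-side) — with a documented deterministic score over the same
feature family:

$$\mathrm{score} = -2 + 4.8\left(0.5\,\frac{L}{L+90} +
  0.4\,\mathrm{cov} + 0.05\,\mathrm{integrity}\right)$$

with $L$ the longest ORF in codons (ATG through stop, stop included; 3
forward frames of the strand-oriented sequence; both orientations scanned
and the better used when the strand is unknown), cov the fraction of the
transcript inside that ORF, and integrity = (has start + has stop)/2. The
calibration anchors are: no ORF ⟹ score = −2 ≤ −1; an intact ORF covering
more than 90 % of a ≥ 300 nt transcript ⟹ score ≥ +1. The half-saturation
constant of 90 codons sits at the conventional ~100-codon boundary between
lncRNA-like and mRNA-like ORFs, and the score is strictly monotone in each
feature. The protein/profile homology screen is a pluggable oracle
(tabular hits with `query`, `subject`, `evalue`, `tool`); any hit with
E < 10⁻⁴ from either tool marks the candidate coding, and the packaged
default is a null oracle (no hits), under which the homology step is the
identity on the non-coding side. Real blastp/hmmsearch output can replace
it without code changes. The score is *not* a reimplementation of any
trained classifier and its absolute values are not comparable to one; only
the cutoff semantics are preserved. This is the package's most important
documented limitation.

## Neighbour-gene analyses

Gene-body mode pairs features whose span-to-span gap is strictly below
10 kb ignoring strand; TSS mode pairs features by |TSS − TSS| < 10 kb. The
two modes are deliberately separate, mirroring the two analyses they
support. Pair co-expression is Pearson correlation of log₂(FPKM + 0.05);
pairs with a constant transformed vector are flagged undefined and
excluded from distributions (their count is retained). The null is built
from random coding:coding pairs — n_pairs distinct unordered pairs per
permutation, uniformly without replacement, 100 permutations by default,
all seeded. In coding:coding pairs the reference TSS is chosen at random
(seeded) for signed distances.

Orientation truth table (reference = the coding gene; distance measured
from the reference TSS, positive downstream of its transcription
direction): opposite strands with the partner TSS at or upstream of the
reference TSS (distance ≤ 0) is divergent; opposite strands with the
partner TSS strictly downstream is convergent — including the nested case
where gene bodies overlap, which no convention in the literature fixes;
same strand is tandem; unknown reference strand is flagged undefined. The
boundary choice (distance ≤ 0 divergent) makes the exact-TSS-coincidence
case divergent, the bidirectional-promoter reading.

## Temporal specificity

For each feature, condition values are $v_c = \log_{10}(\mathrm{FPKM}_c +
1)$ (per sample by default, matching a 24-cell design; a stage-grouped mode
averages FPKM within stages first), normalized to a probability vector
$p$. The specificity for condition $c$ is $1 - \sqrt{\mathrm{JSD}_2(p,
e_c)}$ with base-2 logarithms, so the distance lies in [0, 1] and exclusive
expression scores exactly 1 — this exactness is the package's analytic
anchor and is asserted to identity, not to tolerance. An all-zero feature
scores 0 in every condition: an unexpressed transcript is maximally
non-specific by convention, and the alternative (undefined) would silently
drop features from downstream summaries.

## The co-expression network

The network is authored from scratch (no external network package):

* signed adjacency $a_{ij} = ((1 + r_{ij})/2)^\beta$, $\beta = 6$ — "a
  signed correlation matrix raised to a power" is ambiguous because even
  powers destroy sign; the standard signed-network map is used, with the
  naive $r^\beta$ available behind a flag for comparison;
* topological overlap
  $\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 -
  a_{ij})$, $\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}$;
* average-linkage clustering of $1 - \mathrm{TOM}$ with a simplified
  dynamic tree cut: a static cut at the 0.99 quantile of merge heights,
  then recursive branch splitting. The splitting rule scans candidate
  sub-cut heights over a branch's internal merges and re-cuts at the height
  that maximizes the number of *coherent* sub-branches (≥ `min_module_size`
  genes, default 30, and mean internal merge height at least `min_gap` =
  0.1 below the static cut height, or essentially zero for identical
  profiles). A simple largest-gap rule was tried first and fails in a
  characteristic way: background genes attach to module branches over a
  continuous range of heights and fill the gap between module tops and
  between-module merges. The scan criterion is robust to that, and genes
  attaching only above the chosen sub-cut fall off as unassigned — which is
  the desired behaviour for passengers. Clusters failing coherence or size
  are labelled 0 (grey);
* module eigengenes are first principal components of the standardized
  member expression, unit-normalized, sign-oriented to correlate
  positively with members on average; modules with eigengene correlation
  strictly above 0.75 are merged iteratively (highest pair first,
  recomputing after each merge, ties toward smaller labels) — merging also
  repairs any over-splitting by the aggressive branch scan;
* a final kME refinement reassigns every gene to its best-correlated
  module eigengene when that kME reaches 0.7, and greys it otherwise. This
  both rescues genes the dendrogram stranded and strips passengers it
  absorbed; it is the conventional membership step after detection and
  merging.

The network input is log₁₀(FPKM + 1) expression. The log₂(FPKM + 0.05)
transform used for pair correlations (where it is prescribed) is a poor
network input: zeros map to −4.32, and for low-expressed, dropout-prone
lncRNAs those spikes dominate the variance and destroy module membership.
log₁₀(x + 1) compresses the zero gap to the scale of low expression and is
the same transform the specificity score uses.

Module–trait correlations use Pearson r with asymptotic t p-values on
n − 2 degrees of freedom (n = 24 samples here); modules with r > 0.7 and
p < 10⁻⁴ against a stage indicator, genotype or ordinal time are flagged
stage-specific. A permutation scheme was considered; asymptotics match the
magnitudes this flag rule was designed around and keep the flag
deterministic. Gene-set enrichment is a local hypergeometric upper-tail
test with Benjamini–Hochberg adjustment across sets — a stand-in for
web-service enrichment tools, exact but annotation-free.

## The synthetic-data module

`simulate_study()` generates, from one seed, every input the pipeline
consumes. Sub-streams are derived deterministically per generator
(`seed * 101 + offset`), so each generator is reproducible independently of
call order, and a fixed seed yields byte-identical files.

What it emulates and why:

* **Gene geometry.** Coding transcripts average 3162 nt over 11 exons,
  lncRNAs 550 nt over 3.7 exons (log-normal lengths, shifted-Poisson exon
  counts with a minimum of 2 for multi-exonic truth); intron means 400 b;
  genes placed without overlap at ≥ 2.5 kb spacing (beyond the 2 kb run-on
  window, so spacing never manufactures `p` codes). 30 % of lncRNAs are
  placed head-to-head with a coding gene, TSS separations mostly 0–400 b
  (85 % from a capped exponential, the rest up to 2 kb).
* **Sequence.** Chromosomes are uniform random DNA; every intron of a
  stranded transcript gets the canonical motif written on its strand;
  coding genes carry an embedded intact ORF covering ~92 % of the spliced
  transcript; lncRNA (and short/single-exon decoy) spliced sequences have
  their ORFs capped at ≤ 30 codons and ≤ 22 % of the transcript by
  iteratively inserting stops — synthetic lncRNAs are genuinely non-coding
  under the package's own score, mirroring real lncRNA ORF statistics
  rather than assuming the classifier's blind spot.
* **Expression.** 24 samples: 2 wild-type and 2 dicer-null oocytes, 8
  two-cell, 6 four-cell, 6 eight-cell. Six planted modules follow latent
  stage profiles (oocyte-WT, oocyte-dicer-null, 2-cell, 4-cell, 8-cell,
  monotone time); member genes mix the latent factor with noise so pairwise
  within-module correlation targets `module_cor` (default 0.8). Expression
  is log-normal on the latent structure (no generative model is published
  for these data; this is the minimal structure the downstream analyses
  assume). lncRNAs get a lower baseline than mRNAs and stage-specific
  dropout (FPKM zeroed with probability 0.5 outside their module's high
  samples), making them lower-expressed and more stage-specific by
  construction. Planted divergent lncRNAs join their coding partner's
  module, which is what makes neighbour pairs co-expressed. 15 % of genes
  are unstructured background (module 0). The dicer-null genotype exists so
  module–trait analysis can separate the two oocyte modules.
* **Assembler noise.** Per assembler × sample, each transcript expressed
  there (FPKM > 0.5) is emitted with probability 1 − dropout (default
  dropout 0.2); an emitted copy is fragmented with probability 0.1 —
  either terminal-exon truncation (all junctions kept) or a single-exon
  piece (junctions broken), equally likely. Proper sub-chain fragments are
  deliberately not generated: under intron-chain keying, two independent
  sub-chain fragments of the same transcript can collide on the same key
  and fabricate a consensus-passing structure that no filter can
  distinguish from a genuine novel isoform, which would make exact
  planted-truth bookkeeping ill-defined. Terminal truncations merge
  harmlessly into their parent's key; single-exon pieces are removed by the
  multi-exon filter. Noise transcripts (~0.1 per true transcript per set,
  70 % single-exon) are placed in intergenic gaps and appear exactly once,
  so the consensus rule is what removes them.
* **Coverage.** Exonic depth scales with FPKM around 10 reads/base
  (clamped ×0.5–×3), zero where unexpressed; 8 % of lncRNAs are planted
  "gapped" — only the 5'-most 60 % of exonic bases covered, integrity
  0.6 < 0.75; noise loci get ~1 read/base, below the 3.77881 cutoff. The
  ground-truth label `well_reconstructed_ids` is recomputed from the
  emitted tracks, never assumed.
* **Conservation.** phastCons-like scores in [0, 1] (coding exon bases
  Beta(8, 2), non-coding Beta(2, 8)) and phyloP-like scores (N(2, 1) vs
  N(0, 1)); 10 % of exonic bases carry no score, and non-exonic bases are
  unscored. Per-transcript conservation averages only scored exonic bases
  and is undefined (not zero) when no base is scored.

What it does **not** emulate: read-level sequencing (no FASTQ, no error
model, no alignment), assembler-specific artifact spectra, isoform
diversity within genes (one transcript per gene), GC/mappability structure
in coverage, realistic genome composition (repeats, paralogy — so the null
homology oracle is exactly right on synthetic data), and inter-cell
variance structure beyond the stage design (exposed as configuration, not
fixed). Consequently, passing tests demonstrate that the *algorithms* are
correct and the pipeline's filters compose as designed under realistic
noise modes — not that the defaults are tuned for any particular real
dataset.

## Problem sizes and determinism

The packaged fixtures are: a full-scale study of 1000 coding genes, 500
lncRNAs plus ~90 decoys on a 4 × 4.2 Mb genome with 24 samples (the
pipeline-recovery, neighbour and specificity checks); a 600-gene expression
fixture with 6 planted modules (network recovery); and a small 180-gene
study for fast unit-level checks. These sizes keep every synthetic claim
testable at desk scale while leaving headroom above every filter's
boundary cases. All stochastic tests fix seeds; clustering and merging have
no randomness and lexicographic tie-breaks, so whole-pipeline runs are
deterministic given a seed.

## Known limitations

* The coding-potential score shares only cutoff semantics with trained
  classifiers; absolute scores are not comparable (see above).
* The simplified dynamic tree cut is not the hybrid PAM-assisted variant;
  it is validated by planted-partition recovery, not label-for-label
  agreement with any external implementation.
* Single-exon consensus keying uses greedy ±25 b clustering, which is not
  transitive-closure clustering; with pathological end jitter two
  observations of one structure can land in different clusters.
* The `u` fallback means "unclassified proximal" and "intergenic" share a
  code, as in the original code scheme.
* FPKM is consumed as given; no normalization, batch correction or
  quantification is performed.
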