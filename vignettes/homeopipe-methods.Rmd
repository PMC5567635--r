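---
title: "Models and methods behind homeopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind homeopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeopipe)
```

`homeopipe` analyses RNA-seq contrasts between accessions of an
allotetraploid whose two parental subgenomes ("AT", maternal; "AA",
paternal-like) are diverged enough (~83% transcript identity, i.e. a
substitution divergence of ~0.17) that most read pairs can be attributed to
one subgenome. This vignette documents the models, the tunable parameters and
their defaults, the numerical choices, and the limits of what the synthetic
validation can show.

## The synthetic study generator

The generator produces a complete study with known truth at every level, so
each downstream stage is testable by parameter recovery rather than by
eyeballing.

**Subgenomes.** One ancestral transcript is drawn per homoeologous pair
(lengths uniform on `transcript_len_range`, default 500–2500 bp, the typical
cDNA range); each copy is then mutated independently at a per-copy, per-site
substitution rate `m` solved from the target divergence `d` via
`P(differ) = 2m - (4/3)m^2 = d`, so the expected pairwise identity is exactly
`1 - d` (default `d = 0.17`). Substitutions are uniform over sites and over
the three alternative bases; there are no indels anywhere in the pipeline, by
design — the variant logic downstream is substitution-only and removes indel
records on input. Unpaired genes (default 1,500 per subgenome) receive novel
sequences; the default of 13,394 pairs matches the realistic scale of a
well-annotated homoeolog map, with the note that the published count could
denote genes rather than pairs — we treat it as pairs and expose the universe
size everywhere as a parameter.

**Accession variants.** Substitutions are planted on the AT transcripts of
both accessions at `accession_snp_rate` per bp (default 0.002 — published
analyses in this area report SNP totals rather than per-bp densities, so the
density is a free parameter chosen to land in the tens-of-thousands regime
at the default scale). A fraction `shared_snp_fraction` (default 0.72) is shared between the
accessions (same position and allele); fractions of the shared (0.75) and
private (0.5) categories are additionally planted into members of a
`panel_size`-member reference panel, populating all six cells of the
shared/private-by-panel partition with counts recorded exactly at generation
time. Panel members also carry background variants absent from both
accessions, so panel-similarity ranking has signal. Planted quality scores
are uniform on `qual_range` (default 20–60) to exercise the strict
`quality > 30` filter.

**Expression.** Baseline expression is log-normal
(`expr_meanlog = 3`, `expr_sdlog = 1.2`; a heavy tail that mimics FPKM
distributions without fitting any real dataset) and is drawn **once per
pair**, shared by both members: homoeologs are strongly correlated in real
data, and a shared baseline is what makes the per-pair `log2(AT/AA)` ratio a
meaningful dominance readout rather than a ratio of unrelated draws. The AT
member is multiplied by `2^dominance_log2` (default 1, i.e. two-fold AT
dominance; the sign is configurable because reports on the direction of
dominance in this system are inconsistent with one another, and the package
takes no side — it simply reports the signed ratio). `n_de_genes` (default 148) receive `±de_log2fc` between the
accessions; `n_coordinated_pairs` of them (default 21) are applied to both
members of a pair in the same direction, and the remaining DE genes are
sampled one-per-pair so no additional pair is completely DE by construction.

**Reads and counts.** Per sample, a per-gene log-normal replicate noise
(`rep_noise_sdlog = 0.2`, i.e. ~20% biological CV, a typical figure for
controlled-growth model organisms) multiplies the accession's expression;
`reads_per_sample` fragments are then drawn from a multinomial with
probabilities proportional to expression × length — exactly the model under
which FPKM is proportional to expression. Fragment lengths are normal
(300 ± 50 bp, truncated to the read length and the transcript); mate 1 reads
the fragment start, mate 2 the reverse complement of its end (2 × 150 bp
defaults; fragments shorter than a read yield two fully overlapping mates);
sequencing errors are uniform substitutions at `seq_error_rate` (default
0.001). `simulate_counts()` exposes the count level of this model directly —
identical multinomial, no sequence generation — which is what the DE
calibration and power suites use to reach deep coverage cheaply. All stages
derive their RNG streams deterministically from the single study seed;
identical configurations are bit-identical.

**What the generator does not emulate.** Splicing and isoforms, indels,
positional/GC bias, quality-score structure (FASTQ qualities are constant),
organellar sequences, and library-size variation between samples (every
sample has the same fragment count). Tests passing on this generator
therefore validate the pipeline's logic and statistics, not its robustness
to these real-data artefacts.

## Read assignment

Instead of alignment to a concatenated reference followed by routing on the
reference name, the built-in assigner scores each fragment against a
canonical k-mer index of each subgenome: the score of a gene is the number of
distinct canonical k-mers (lexicographic minimum of a k-mer and its reverse
complement, giving strand-agnosticism without alignment) shared with the
fragment, both mates pooled; a subgenome's score is its best gene's score,
and the winner takes the fragment only when its lead is at least `min_margin`
(default 2), otherwise the fragment is ambiguous. `k = 21` is long enough
that random 21-mer collisions are negligible (4^21 ≈ 4×10^12) and short
enough that at 17% divergence essentially every 150-bp mate spans several
subgenome-diagnostic k-mers; at the defaults, error-free fragments show zero
misassignment and <1% ambiguity in the test suite. K-mers are encoded as
base-4 integers in doubles (exact up to k = 26) via a single rolling
`stats::filter()` pass, which is what makes the pure-R implementation fast
enough for desk-scale studies. For externally aligned data,
`separate_alignments()` preserves the classical semantics exactly: records
are routed by the subgenome of their reference sequence, unmapped records are
dropped and counted.

Ambiguous fragments are excluded from per-gene counts and subgenome totals
but included in the library-wide mapped total that FPKM divides by — the
behaviour of a mapper that reports but does not resolve multi-mapped reads.
This is switchable in the sense that the totals are exposed; the choice
matters little at 17% divergence where ambiguity is rare.

## Differential expression

DE between accessions is a per-gene two-sample t-test on `log2(FPKM + 1)`
with BH correction at `q ≤ 0.05`. Two deliberate choices:

* **Pooled variance rather than Welch.** With three replicates per group the
  Welch–Satterthwaite approximation is measurably conservative (true size
  ~0.035 at nominal 0.05 under normality), which breaks null calibration;
  with a balanced design and a common noise model the pooled test is exact
  (measured pooled null fraction 0.0498 over 50 simulated seeds). Welch
  remains available via `var_equal = FALSE` for unbalanced or
  heteroskedastic designs.
* **No normalization factors.** FPKM's per-million denominator is taken as
  is. When strongly DE genes hold a non-trivial share of the library, this
  induces the classic composition artefact: all other genes shift slightly
  the other way, and with enough such mass the shift becomes significant.
  In simulations where DE genes hold ~6% of the library this inflates the
  realised FDR above the BH target in direction-imbalanced seeds, while at
  the study-like regime (~1% of genes DE) control is clean. Median-of-ratios
  or TMM factors would remove the artefact but are deliberately out of scope;
  users contrasting datasets with large DE mass should be aware.

A gene with constant replicate values in both groups gets `p = 1` when the
group means agree and `p = 0` otherwise. Genes with zero counts everywhere
are skipped. Note also that t-tests at n = 3 have limited power at
BH-stringent thresholds: with default noise, 8-fold changes are recovered
with high sensitivity when DE genes are a few percent of the universe, but
sensitivity drops steeply at very small DE fractions where the BH threshold
tightens — an intrinsic property of the replicate count, not of the
implementation.

## Pair statistics

`join_pairs()` decomposes a DEG list into AT-only, AA-only and complete
pairs; its arithmetic identities (`total = at_only + aa_only + 2*pairs` and
the subgenome margins) hold by construction and are re-asserted by
`verify_report()`. The permutation test draws gene sets of the DEG's size
uniformly without replacement from the full quantified universe — paired
and unpaired genes alike — and uses the add-one tail estimator, so a
reported `p` below `1/R` can only arise when the observed pair count exceeds
the recorded null maximum; this is the conservative, standard estimator for
permutation tests. The closed-form distribution in
`pair_enrichment_exact()` (condition on the number of complete pairs, then
half-pairs, then singletons) is exact at any scale through log-space binomial
coefficients and is the oracle the Monte-Carlo path is tested against on all
small universes. Direction concordance uses the exact two-sided sign test.

## Variants

The caller is a homozygous-consensus threshold caller for inbred-line
transcript-space data: mates of assigned fragments are placed on their gene
by modal k-mer offset (ungapped, consistent with the substitution-only read
model), and a site is called when depth ≥ `min_depth` (4) and one
non-reference base holds ≥ `min_alt_frac` (0.9) of the coverage. Quality is
the Phred-scaled binomial tail `-10 log10 P(X ≥ alt_depth)` with
`X ~ Binomial(depth, error_rate = 0.01)`, capped at 99 — a documented,
monotone score, not a genotype likelihood. A VCF input path accepts calls
from a full caller instead. Set algebra is over `(transcript, position,
alternate allele)` keys; a reference-allele disagreement at a shared key is
an error rather than a silent mismatch. "In panel" means present in at least
one panel member. The chi-square for SNP density in DEGs is the two-cell
bp-weighted goodness-of-fit on observed vs expected in-DEG counts; a 2×2
contingency variant (no continuity correction) is available behind
`method = "contingency"` since published observed-vs-expected tables are
ambiguous between the two layouts.

## Term enrichment

Plain one-sided hypergeometric tails per term, deliberately uncorrected, with
the conventional reporting filter (`p < 0.05` strictly, and at least two
annotated genes in the DEG set). Graph-aware decorrelation of nested terms
(topGO-style weighting) is out of scope, so enriched-term lists are not
expected to match analyses run with weighted algorithms. Because the test is
exact and discrete, its null p-values are super-uniform —
`P(p ≤ u) ≤ u`, with strict inequality at most thresholds — so "uniform
p-values under the null" is the wrong check; the suite asserts
super-uniformity and exact agreement with `fisher.test`. Stress-category
assignment takes a user-supplied term→category table; a gene whose reported
terms mix two or more distinct stress categories collapses to
"general", and terms without a category default to "not_stress".

## Problem sizes and determinism

The test suite and acceptance script run entirely on generated data at sizes
chosen for tight feedback: tens to hundreds of pairs and 10^3–10^5 fragments
per sample for pipeline stages, 500 pairs at deep counts for dominance
recovery (recovered within ±0.1 of the planted log2 ratio), 50 seeds for
null calibration, and the full 10^6 replicates on a 13,394-pair universe for
the headline permutation bound (about a minute, vectorised per draw). Every
stochastic path is seeded; `run_study()` re-run with the same configuration
reproduces its report exactly.

## Known limitations

Gapped or spliced alignment, base-quality-aware scoring, isoform
quantification, dispersion modelling and count-model DE (a negative-binomial
stage would be the natural upgrade at n = 3), normalization factors, genotype
likelihoods and phasing, and genomic (intron-containing) coordinates are all
out of scope. The assigner's margin rule is an explicit, documented stand-in
for whatever multi-mapping resolution a full aligner pipeline would apply;
its behaviour is validated against truth on simulated data only.
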