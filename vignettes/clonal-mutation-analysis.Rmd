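---
title: "Reference-free gene-level mutation analysis of clonal transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free gene-level mutation analysis of clonal transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemut)
```

## The problem

Long-lived asexual (clonal) animal lineages -- planarian laboratory strains
maintained by fission for decades are the motivating case -- accumulate
somatic mutations in their stem-cell population. Because every animal
descends from one individual, any allele not present in the ancestor must
have arisen during clonal propagation, and it will typically be carried by
only a fraction of cells. Quantifying this mutation load from sequencing
data poses two problems:

1. **No usable genome reference.** The very mutation density that makes the
   system interesting defeats de novo genome assembly (k-mer spectra show
   neither a homozygous nor a heterozygous peak structure; contigs stay
   short). The only workable reference is a transcriptome assembly.
2. **Isoforms cause multi-mapping.** Mapping reads to an isoform-level
   transcriptome assembly sends reads from exons shared between splice
   variants to several reference records at once, corrupting both read
   counts and variant calls.

`clonemut` implements a pipeline around the *Reference Gene Model*: a
virtual, intron-less gene sequence built per gene (isogroup) by
concatenating the assembly's contigs (approximately exons) in genomic
order, as recorded in the assembler's contig graph. Each gene then has a
single reference record; reads from any isoform map to one place, and
mutation statistics can be computed per gene.

## The Reference Gene Model

The assembler's output is treated as a directed graph per gene: nodes are
contigs, edges record observed adjacency of contigs in isoforms (isotigs),
and each isotig is a path. `linearize_gene()` produces:

* a topological order of the gene's contigs (Kahn's algorithm);
* the virtual sequence = concatenation of contig sequences in that order,
  with no spacer bases, so alignments may legitimately cross junctions;
* a table of half-open contig intervals on the virtual sequence, which
  `model_to_isotig_coords()` inverts to move between model coordinates and
  any isotig's spliced coordinates.

Where the graph under-determines the order, the output must still be
deterministic across runs and platforms, so ties are broken explicitly: at
each step the candidate contig on the most isotig paths is taken first,
then the lexicographically smallest id. Disconnected components are emitted
in order of their smallest contig id; contigs on no isotig path are
appended last, sorted by id, and flagged as orphans. Isotigs keep their
identity: the gene's *representative* isotig (highest homology score, ties
broken by length then id; longest with a warning if no scores exist) is the
sequence used for ORF prediction and effect annotation.

On simulated data, where the true exon order is known, the virtual
sequence equals the concatenation of the exons in genomic order -- the
model-correctness tests assert exactly this, plus conservation of length
and the subsequence property for every isotig path.

## Read mapping

Reads are mapped with an affine-gap Smith--Waterman local aligner
(implemented in C++; full dynamic programming, so reported scores equal
exhaustive-DP scores by construction -- the test suite still checks this
against an independently written R implementation of the recurrences, and
against `Biostrings::pairwiseAlignment`). Candidate references are
shortlisted with exact 15-mer seeds on both strands; each candidate is then
aligned in full. A read from an isoform missing an internal exon either
crosses the exon's contig with a reference deletion or is soft-clipped at
the junction, whichever scores higher under the gap model.

Default scoring is `match +1, mismatch -2, gap open -4, gap extend -1`
(a length-L gap costs open + L x extend), minimum seed 15, minimum
reported score 30, and an optional 5' hard trim to 200 bp for short-read
libraries (on by default, mirroring quality-motivated trimming of later
sequencing cycles). All are `scoring_params()` arguments.

Reads achieving their best score on more than one gene are flagged
*ambiguous* and excluded from counts and pileups; this prevents cross-gene
repeats from inflating SNP depth. Mates are mapped independently and not
forced concordant (gene-length references make distance constraints
unreliable for short genes); pairing is used only for bookkeeping.

Two design facts worth knowing when interpreting results:

* Local alignment is blind to variants within a base or two of a read
  end: the terminal mismatch scores no better than a soft clip, so
  alt-carrying reads clip exactly at the variant. Sites at the extreme
  ends of a gene model therefore lose alternate observations.
* Counting per gene against the model recovers true per-gene totals on
  multi-isoform genes, whereas counting against the raw isotig set (the
  `count_reads_per_isotig()` control mode) counts shared-exon reads once
  per tying isotig -- the quantitative motivation for the model.

## Variant calling and the clonal filter

`build_pileup()` tallies per-position base counts (insertions attributed
to the preceding reference position; a spanning deletion increments every
deleted position). `call_variants()` emits a record per site and class
when any alternate allele is seen at least `min_alt_count = 2` times
(suppressing singleton sequencing errors). Zygosity is classified
heterozygous when the maximum alternate fraction is below 0.95 --- the
threshold is configurable since only the concept, not the cutoff, is
standard. SNP calls within 5 bp of a called InDel are masked, a cheap
surrogate for local realignment.

The clonal filter (`filter_clonal()`) is the scientific heart of the SNP
analysis. In a clonal strain, allele fractions carry signal about origin:

* fractions near **0.5** look like heterozygosity the ancestral animal
  already had (or mapping of diverged paralogs) -- not new mutation;
* fractions near **1.0** indicate sites where the assembly consensus
  itself carries the minor state, or cross-platform reference bias;
* **low fractions** (a few percent to ~30%) are what somatic mutations
  propagating through a stem-cell population actually produce.

Only sites with an alternate fraction inside the closed windows
[0.06, 0.30] or [0.70, 0.94] (the mirrored band) at depth >= 3 PASS;
everything else is labelled `low_depth`, `low_fraction` or
`ancestral_or_platform`. Window endpoints are treated as closed: the
thresholds are conventionally quoted as plain ranges (0.06–0.30,
0.70–0.94) without open/closed qualification, and the inclusive reading
is the conservative one. InDels face only the depth rule by default (the windows
are a SNP-rate filter); `filter_config(filter_indels = TRUE)` extends
them. The filter is idempotent and monotone in window width, and both
properties are tested.

`snp_density()` reports per-gene PASS SNPs per 1000 bp, the genome-wide
rate, and a 1-SNP/kb-binned histogram.

## ORFs, coding effects, and codon neutrality

`predict_longest_orf()` scans all six frames for the longest run of
non-stop codons starting at an ATG (an `--open-ended` analogue is
available via `require_atg = FALSE`), keeping ORFs of >= 100 amino acids
(boundary inclusive). The run may end at the frame's last complete codon,
accommodating 3'-incomplete transcripts. Ties: lowest frame number, then
leftmost start. `Biostrings::translate()` is called with
`no.init.codon = TRUE`; otherwise alternative initiators (TTG/CTG) at the
window start are silently translated as Met and fabricate ORF starts.

Variants are lifted from model coordinates to the representative isotig
via the model's contig intervals before annotation; variants in contigs
absent from the representative are excluded from effect tallies and
counted separately. `annotate_effects()` classifies SNPs as synonymous
coding / non-synonymous coding / stop gained by translating the mutated
codon, and InDels as frame shift (length not divisible by 3), codon
insertion/deletion (in-frame, codon-aligned), or codon change plus codon
insertion/deletion (in-frame, straddling); any in-frame InDel creating a
premature stop is reported as stop gained.

The pseudo-SNP neutrality simulation asks: if single-base substitutions
hit codons at random, what fraction changes the encoded amino acid?
`neutral_substitution_probability()` computes this by exact enumeration of
all 9 single-base substitutions of each codon, weight-averaged over a
codon distribution, or by seeded Monte-Carlo (which converges to the
enumeration and serves as its internal cross-check). With the standard
nuclear code and uniform weights on the 61 sense codons the exact value is
415/549 = 75.6%, which rounds to the conventional 76% control value for
the standard codon table only when stop-gained changes count as
substitutions -- they do by default (`include_stop_gain = FALSE` gives
71.4%, a visibly different figure). Per-codon
counts of synonymous + non-synonymous + stop-gained substitutions must sum
to 9; this conservation, and consistency between the enumeration and
`annotate_effects()`, are tested.

`codon_position_bias()` reports the distribution of in-ORF SNPs over codon
positions 1/2/3. Planting mutations with third-position excess lowers the
realized non-synonymous fraction below the neutral probability computed
from the same codon table -- the selection surrogate the tests reproduce.

## k-mer spectrum characterization

`kmer_spectrum()` counts canonical k-mers (lexicographic minimum of k-mer
and reverse complement; k must be odd so no k-mer is self-complementary)
and returns the abundance histogram. `classify_spectrum()` smooths the
histogram (moving average, window 5 bins), finds the noise boundary
(first local minimum; when the histogram rises from abundance 1 there is
no error limb and the boundary is the origin) and peaks beyond it with a
prominence of at least 5% of the largest smoothed bin. One peak is
*monomodal* (homozygous-like), two peaks in a roughly 2:1 abundance
relation (|log2 ratio - 1| <= 0.45) are *bimodal* (heterozygous diploid),
and no detectable peak or boundary is *no-peak* -- the signature of a
genome whose dense, multi-fraction allele diversity blurs the spectrum,
as in the clonal strain. The peak-detection thresholds are configurable;
spectrum shapes are conventionally judged by eye, so only qualitative
classification is claimed, and the tests assert exactly the three
qualitative outcomes on purpose-built simulations.

## Gene-level statistics

`classify_mutation_load()` extracts, among non-transposon genes with
representative length > 600 bp, the *high-load* set (>= 20 PASS SNPs/kb)
and the *mutation-free* set (0 PASS SNPs); `category_bias()` reports
log2(n_high / n_zero) per functional category, with one-sided sentinels
where only one set is populated (the heat-plot "*" convention). Counts,
not within-category fractions, form the ratio; the legend wording reads
as a count ratio, and the alternative would only rescale all categories
by a constant under equal category sizes.

`differential_expression()` reproduces a thresholded selection chain:
loess normalization on the MA plane (span 0.3, genes expressed in both
libraries; other genes fall back to the median offset), a two-sided
binomial test of each gene's count split against the normalized expected
proportion, and the filter chain -- count >= 10 in both libraries,
p < 0.001, normalized fold change >= 2 (either direction, pseudo-count
0.5), annotation present. The *selection thresholds*, not the test
internals, drive which genes survive; the binomial test is a transparent
stand-in for an MA-plot random-sampling test. The default p-value is the
**mid-p** two-sided binomial: the classical exact test is conservative at
alpha = 0.001 because of discreteness, and the mid-p correction is the
standard fix that makes the null false-positive rate track the nominal
level (verified by simulation in the test suite: 20 x 5,000 null genes
give a rate within 3 binomial standard errors of alpha).
`p_method = "exact"` restores the classical test.

## The synthetic-data generator

`sim_config()` + `simulate_loci()` / `simulate_mutations()` /
`simulate_reads()` / `simulate_assembly()` generate a clonal transcriptome
with full ground truth. What it emulates, and the defaults:

* **Loci**: 2-6 exons of 150-500 bp; 1-3 isoforms per locus, each a
  strictly increasing exon subsequence; the first isoform contains every
  exon (so the locus is fully expressed and the concatenated exon sequence
  is well-defined truth for the model builder).
* **Mutations**: Poisson-placed at 10 sites/kb by default -- the scale of
  mutation load measured in clonal planarian strains (≈9 PASS SNPs/kb). Per-site alternate
  alleles: usually one, sometimes two or three distinct substitution
  bases; a fourth alternate, when configured, is a single-base deletion,
  which is how a site reaches five alleles (reference + 4) as seen in
  SNP-rich regions. Allelic fractions come from a three-component
  mixture -- clonal band U[0.06, 0.30] (weight 0.7), ancestral-like
  U[0.48, 0.52] (0.2), platform-like U[0.95, 0.99] (0.1). The true
  fraction distribution in the animal is unknown; this mixture is a
  modelling choice that represents the three classes the filter is built
  to separate, not an inference from data.
* **Reads**: fragments drawn from isoforms proportional to expression
  weight; one allele sampled per fragment per overlapping site (mates are
  the same molecule), then independent substitution errors (0.5% short,
  1% long). Short reads are 2 x 200 bp (post-trim scale), fragments
  N(300, 30); long reads single-end U[300, 700] -- the two-platform scale
  without flowgram or homopolymer error modelling. Indel sequencing
  errors default to 0 so truth evaluation stays exact.
* **Assembly**: one contig per exon, edges from observed isoform
  adjacencies, one isotig per isoform -- an idealized, noise-free
  assembler summary.

What passing tests therefore do and do not show: they validate the
*algorithms* -- linearization, alignment, calling, filtering, effect
classification, the statistics -- under conditions where the truth is
knowable. They do not validate robustness to mis-assembly, chimeric
contigs, indel-rich platforms, expression-dependent coverage bias, or
contamination, none of which the generator produces.

## Numerical choices and test conditions

* Seeds fix all randomness end-to-end; each simulator stage draws from a
  seed offset so stages are individually reproducible.
* Parameter-recovery simulations use 4 genes x 10 seeds at 100x coverage
  with fractions planted in a central clonal band U[0.15, 0.25]. The
  central band makes the recovery test measure *calling*: fractions
  planted against the window edges are truncated by binomial jitter (a
  property of the window filter, exercised by the dedicated
  filter-semantics test, which plants all three mixture classes and
  checks that PASS calls are clonal with error shrinking in coverage).
  Recovery is assessed on the callable region (sites with pileup depth
  >= min depth), the usual normalization for recovery evaluations, since
  no caller can recover a site without reads.
* The filter-semantics simulation plants the platform-like class at
  U[0.96, 0.99] ("close to 1.0"): a class planted exactly at 0.95 sits
  one binomial standard deviation from the 0.94 window edge at realistic
  depth, which no finite coverage can separate.
* Problem sizes throughout the suite (tens of genes, coverages 15-240x,
  30-40 kb spectrum genomes, 5,000-gene DE nulls over 20 replicates) are
  chosen so each check has clear statistical resolution at desk scale;
  all tolerances are stated in the tests as multiples of the relevant
  binomial/Poisson standard errors, never tuned constants.

## Known limitations

* The aligner is exact but quadratic per candidate; it is sized for
  simulated datasets and method validation, not for tens of millions of
  reads.
* No base-quality model: qualities are written as a constant, and calling
  does not weight by quality.
* The k-mer counter is an exact in-memory counter, suitable for up to
  ~10^7 distinct k-mers.
* Genotype likelihoods, phasing, somatic-caller statistics, and Ka/Ks are
  out of scope; the filter chain operates on raw counts and fractions by
  design.
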