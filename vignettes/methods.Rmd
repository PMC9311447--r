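---
title: "Methods: de novo reference reconstruction, methylation and SNP calling for double-digest bisulfite libraries"
author: "bsgbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Reduced-representation bisulfite sequencing with restriction enzymes
(epiGBS-style genotyping-by-sequencing of converted DNA) measures cytosine
methylation and genetic variation in the same multiplexed library, for
species with or without a reference genome. Each read pair carries, at its
5' end, a 3-nt unique molecular identifier (UMI), a sample barcode, a
single control nucleotide (CN) and the remnant of the restriction-enzyme
cut site, followed by the bisulfite-converted insert; short inserts read
through into the reverse-complemented custom part of the opposite adapter
and then the standard Illumina adapter.

Bisulfite treatment converts unmethylated cytosines to uracil (read as T).
A fragment's original top strand (Watson) therefore shows C→T changes in
top-strand coordinates, and the original bottom strand (Crick) shows G→A
changes. The CN — an unmethylated adapter cytosine — always converts, so
its sequenced state identifies the strand of origin: Watson pairs read T in
R1 and C in R2, Crick pairs the reverse.

`bsgbs` implements the complete computational method: UMI-based PCR-clone
removal, demultiplexing with strand annotation and overhang validation, 3'
adapter trimming, de novo reconstruction of the unconverted reference loci,
directional three-letter alignment, per-cytosine methylation calling, and
double-masked diploid SNP calling — together with a synthetic library
generator carrying exact ground truth, and the evaluation procedures
(cluster-vs-truth statistics, precision–sensitivity sweeps, CpG
destranding, coverage-filtered methylation correlation, Ward clustering).

# The simulator and its chemistry

`sim_config()` / `simulate_library()` generate a random genome, digest it
in silico with a frequent + rare cutter pair (MspI `C^CGG` and NsiI
`ATGCA^T` by default), size-select dual-cut fragments, draw per-sample
diploid genotypes and per-cytosine methylation probabilities, and emit
error-models reads with the full adapter anatomy.

The reference study conditions — the generator defaults — are: a 2-Mb
random genome at GC 0.5, 200 dual-cut loci of 120–350 bp, 4 samples,
30 read pairs per locus, sample and strand class, complete conversion, no
sequencing error, no PCR duplication, no SNPs, and a methylation model of
CG ~ Beta(2, 2), CHG = 0.3, CHH = 0.05 — levels typical of a plant
methylome with stochastic CG variation.

Choices worth explaining:

* **Read length 200 bp.** The de novo branch reconstructs a locus exactly
  only when its two reads overlap. With the 10 bp of custom adapter
  removed at demultiplexing, 200-bp reads cover the whole 120–350 bp
  size-selection window (2 × 190 − 350 = 30 ≥ 10 overlap columns).
  Tests that exercise read-through arithmetic set 150 bp explicitly.
* **Strand stratification.** By default exactly `coverage` molecules are
  drawn per strand class (`stratify_strands = TRUE`), guaranteeing the
  per-strand depth that the depth-sensitive stages (dedup bounds,
  both-strand SNP evidence) are specified against; with
  `stratify_strands = FALSE` each molecule picks a strand at random.
* **Conversion model.** Each unmethylated cytosine converts independently
  with probability `conversion` (default 1); methylated cytosines never
  convert. Methylation states are drawn per molecule from the per-sample,
  per-site truth probabilities, so a site's methylated read count is
  exactly Binomial(depth, p) — the property the recovery tests check.
* **Adapter-fill protection.** The library chemistry uses hemimethylated
  adapters whose nick-translation repair fills the enzyme-overhang span
  with 5-methyl-C. Consequently the bottom-strand cytosines inside that
  span (2 bp at an MspI end, 4 bp at an NsiI end) never convert and always
  read as methylated. The simulator reproduces this and flags the affected
  sites in the truth table (`adapter_protected`), because they are a
  library artifact, not a property of the genomic methylome: evaluations
  exclude them, exactly as a careful analyst would mask the corresponding
  M-bias cycles in real data. This protection is also what makes the
  overhang validation's single-mismatch allowance sufficient: exactly one
  genomic, convertible base remains per remnant.
* **CN conversion.** The control nucleotide is assumed fully converted
  (the letters of the strand convention are written as-is); partial CN
  conversion would couple demultiplexing loss to conversion efficiency
  and is not modelled.
* **SNP-created cytosines.** A SNP allele that creates a cytosine absent
  from the reference methylome is treated as unmethylated.

What the generator does *not* emulate: indels, adapter-synthesis errors,
quality-score profiles (qualities are a constant, default Q37),
between-sample coverage variation, chimeric fragments, contaminating DNA,
or lane effects. Passing tests therefore demonstrate correctness of the
algorithms under clean conditions, not robustness to every artifact of
real libraries.

# Demultiplexing

PCR clones are identified by an identical (UMI1, UMI2, R1, R2) tuple; the
first pair encountered is kept and UMIs are stripped. Note that two
independent molecules with identical sequence *and* identical 6 nt of UMI
are indistinguishable by design; with a 3-nt UMI this collision is rare
but not impossible at high per-fragment depth.

Each barcode pair expands into a Watson key (bc1+T, bc2+C) and a Crick key
(bc1+C, bc2+T); reads are assigned by exact-length prefix match with a
configurable number of mismatches (default 0). A sliding-window quality
filter (window 15% of the read, mean phred ≥ 10) runs after barcode
matching.

The overhang check then validates the bases following the keys. The strand
class fixes which remnant type each mate carries — a Watson R1 enters its
fragment at the left end (top-strand remnant), its R2 at the right end
(bottom-strand remnant); for Crick pairs the roles swap — but which enzyme
cut which end is unknown, so both enzyme assignments are scored and the
one matching more remnant bases wins. Scoring by matched bases (rather
than by mismatch count) matters: a 1-bp remnant can trivially "match" any
read, and must not outrank a 5-bp remnant with one rescued conversion. A
consequence of the single-mismatch allowance is that enzyme pairs whose
remnants are 1 bp on both mates in one orientation cannot produce
overhang rejections at all.

Two rescue modes are provided. `any_single_mismatch` replaces the
mismatched base with the expected remnant base. This replication-faithful
mode has a known side effect: a converted (unmethylated) remnant cytosine
is rewritten to C and subsequently counted as methylated. `ct_only`
accepts only conversion-consistent mismatches (expected C / observed T, or
expected G / observed A) and rewrites nothing, which keeps remnant
cytosines unbiased; the methylation-recovery tests use it for exactly that
reason.

# Trimming and the directional re-merge

Per mate: the Illumina adapter is located at the 3' end (first exact
occurrence, otherwise the longest read-suffix/adapter-prefix overlap of at
least `min_overlap` columns with ≤ 10 % mismatches) and the read truncated
there; one base is removed from the 5' end (the nick-translation fill-in
position); if an adapter was found, a further `hard_trim = 10` bases are
removed from the 3' end (the reverse-complemented UMI + barcode + CN of
the opposite adapter); pairs with a mate shorter than 20 bp are dropped.
With the default `min_overlap = 3`, a genomic 3-mer occasionally matches
the adapter prefix by chance (~1/64 per read) — the same behaviour as the
standard trimming tools; tests that assert exact length arithmetic raise
`min_overlap` to 10.

Watson R1 and Crick R2 reads carry top-strand sequence, Watson R2 and
Crick R1 bottom-strand sequence; `merge_directional()` re-merges them into
a conventional directional mate-1/mate-2 library, so that mate 1 always
runs forward in locus coordinates.

# De novo reference reconstruction

Untrimmed, demultiplexed reads of all samples are processed per strand
class:

1. **Assembly.** R1 is merged with the reverse complement of R2 at the
   best overlap (≥ 10 columns, ≤ 10 % mismatches; mismatch columns take
   the higher-quality base). Bases extending past the other mate's
   fragment end — residual adapter — are excluded. Pairs without an
   acceptable overlap are joined with an 8-N spacer (N never matches in
   any downstream comparison). Crick assemblies are reverse-complemented
   into top-strand orientation.
2. **Three-letter dedup.** Sequences are grouped by their three-letter
   encoding (Watson: C→T; Crick in top orientation: G→A), which makes the
   grouping independent of the methylation state. Groups outside
   [`min_depth`, `max_depth`] (defaults 10 / 10 000) are discarded. Each
   group's consensus is the per-column majority over the original
   letters; exact ties give N.
3. **Binary pairing.** Watson and Crick groups are paired by the binary
   encoding (C→T and G→A simultaneously; alphabet {A,T}) of their
   *encoded keys* — not of their consensi, because a methylation level
   near 50 % produces majority-tie Ns in the consensus that the partner
   strand resolves. Equal keys are paired greedily by descending depth.
4. **Consensus reconstruction.** Per column: agreement keeps the letter;
   Watson T with Crick C resolves to C; Watson G with Crick A resolves to
   G; an N takes the partner's letter unless that letter is
   conversion-ambiguous on the partner's strand (T on Watson, A on
   Crick); any other disagreement gives N. On error-free data this
   inverts the conversion exactly, for any methylation pattern.
5. **Identity clustering.** Reconstructed consensi are clustered greedily
   in descending-depth order: a sequence joins the first centroid with
   pairwise identity ≥ `identity` (default 0.99; matches / alignment
   columns, N never matching), else founds a new centroid. Identity can
   never exceed the ratio of the two lengths, which prunes almost all
   comparisons; the remaining unequal-length pairs are aligned with a
   compiled Needleman–Wunsch routine. Centroids are emitted padded with
   `NNNN` on both sides.

Raising `min_depth` can only remove strand clusters, so the final cluster
count is non-increasing in it; raising `identity` makes merging harder,
so the count is non-decreasing — the behaviour the parameter-sweep test
checks. Unpaired strand clusters are discarded by default because their
converted letter class is unrecoverable (C/T on Watson, G/A on Crick);
`keep_unpaired = TRUE` emits them with those positions masked to N.

# Directional bisulfite alignment

The reference (de novo clusters or an external FASTA) is converted twice
(C→T and G→A). After the directional re-merge every pair is probed in two
orientations: the C→T pattern with mate 1 forward (tag OT, informative
for reference-C methylation) and the G→A pattern with mate 1 forward
(tag OB, reference G). Against an external reference a locus may lie on
the minus strand of its contig, which flips both mates; `mode =
"nondirectional"` adds those two reverse probes and is used by the
reference branch of the pipeline.

Candidate placements are seeded with exact 20-mers in converted space
(N-containing k-mers never seed; seeds are tried every 7 bases until one
hits) and scored by ungapped extension, match +1 / mismatch −1, reference
N columns neutral, bases overhanging the reference ends clipped.
Restriction fragments have fixed ends and the generator produces no
indels, so gapped extension is deliberately not attempted; an unseeded
read is reported unaligned. Both mates must place on the same cluster;
the unique best joint score wins with mapping quality 40, equal best
scores at distinct placements give AMBIGUOUS, and per-mate scores below
`min_score_frac` (default 0.6) times the read length give UNALIGNED.
Aligned records store the read in reference-forward orientation, which
makes the methylation and masking rules purely positional. Terminal bases
clipped at the reference boundary (residual adapter of fragments whose
read-through was too short to be recognised at trimming) are removed from
the stored record.

# Methylation calling

At each reference C covered by an OT record, read C counts as methylated
and read T as unmethylated; at each reference G covered by an OB record,
read G and read A respectively; other letters are ignored. Where the
mates of a pair overlap, each position is counted once, from mate 1.
Context (CG/CHG/CHH) is derived from the reference; at cluster edges or
against padding Ns the context is unknowable and is reported as CHH with
N in the trinucleotide. Counts are written as a per-sample CX-style
report (cluster, position, strand, methylated, unmethylated, context,
trinucleotide). `mbias()` reports the methylated fraction per read cycle,
mate and context; under the simulator the adapter-fill artifact is
visible as elevated methylation in the first few cycles, mirroring the
M-bias patterns seen in real reduced-representation libraries. No
base-quality threshold is applied by default (`min_base_qual = 0`),
matching the upstream tools' defaults.

# Double-masked SNP calling

Bisulfite conversion is indistinguishable from a C→T (top) or G→A
(bottom) substitution on the converted strand, so variant calling uses
only opposite-strand evidence at such positions. `double_mask()` rewrites
OT read states C/T over a reference C to C, and OB states G/A over a
reference G to G, with qualities kept. Two further read states are
conversion-ambiguous but not covered by the reference-base rule: an OT T
over a non-C reference base could be a converted *alternate* C, and an OB
A over a non-G reference base a converted alternate G. Left unmasked
these mimic wrong alternate alleles (a C→G SNP would be called C→A from
the bottom strand's converted reading). `double_mask()` therefore nulls
them to N by default (`alt_masking = TRUE`); the identity of an alternate
allele then always comes from the strand that reads it unambiguously.

The caller is per-site and diploid: observations passing the base- and
mapping-quality thresholds (defaults 1 and 10; minimum coverage 0) give
genotype likelihoods under a symmetric error model (P(b|a) = 1−ε if b=a
else ε/3, ε from the base quality), a uniform prior over genotypes, the
maximum-likelihood genotype per sample, GQ as the phred difference
between the best and second-best genotype, and QUAL as the phred-scaled
probability that all samples are homozygous reference (capped at 3000).
Sites with QUAL > 0 and at least one non-reference allele are emitted;
`filter_snps()` keeps single-nucleotide substitutions.

One bias is inherent to replace-with-reference masking and intentionally
preserved: at a homozygous-alternate C→T (or G→A) SNP, the converted
strand's masked observations all read as reference, so the caller sees a
50/50 mixture and returns a heterozygous genotype. The allele itself is
correct; only the zygosity is pulled toward het. This is why the
evaluation offers squash-ploidy (allele-level) comparison, and why
genotype-aware comparisons of such callers show an excess of heterozygous
calls at true homozygous sites. A site covered by only one strand class
can never produce a call at a conversion-confoundable position at all —
the both-strand filter in the evaluation module quantifies how much of a
baseline is thereby undetectable.

# Evaluation utilities

* `cluster_truth_stats()`: clusters (padding stripped) are matched
  against the true loci; a cluster counts as uniquely matched when
  exactly one locus achieves the best full-length agreement.
* `pr_curve()`: at each quality threshold, a call is a true positive if a
  baseline record exists at the same position with the same alternate
  allele (and the same genotype unless `squash_ploidy`); precision =
  TP/(TP+FP), sensitivity = TP/(TP+FN). Multiallelic records are
  decomposed per allele first (`decompose_variants()`).
* `both_strand_filter()`: keeps baseline positions with at least one OT
  and one OB observation.
* `destrand_cpg()`: merges the + strand C at p with the − strand C at
  p+1 into one CpG record with summed counts.
* `methylation_r2()`: restricts two proportion sets to shared sites with
  coverage ≥ 10 in both (with group aggregation, counts are summed across
  samples first and the threshold becomes 10 × the number of samples) and
  reports R² of the least-squares fit.
* `ward_clusters()`: agglomerative clustering under Ward's
  minimum-variance criterion on correlation (1 − Pearson) or Euclidean
  distances. `hclust`'s `ward.D2` is used because it implements the
  minimum-variance update for unsquared dissimilarities; trees export to
  Newick via `ape`.

# Numerical choices in the tests

The test suite validates parameter recovery with family-wise exact
binomial bounds: with tens of thousands of sites, per-site 99 % intervals
are guaranteed to exclude ~1 % of correct estimates, so the per-site level
is Bonferroni-adjusted to an overall α = 0.01. Degenerate truth levels
(0 and 1) are checked exactly. The acceptance-scale simulations use 200
loci × 4 samples × 30 pairs per strand (48 000 pairs) for reconstruction
and methylation, 60 loci with 50 SNPs for variant recovery, and 50 loci
at 30 % PCR duplication for clone removal — sizes chosen so the whole
suite re-runs in a few minutes on a single core while keeping per-site
depths at the levels the method targets (≥ 20–30×).

# Known limitations

* No indel simulation, alignment or calling; columns are strictly
  positional.
* The aligner has no gapped extension and no fuzzy seeding; heavily
  eroded reads (beyond ~20 % mismatches) go unaligned rather than being
  rescued.
* Identity clustering keeps the founding centroid rather than recomputing
  a members' consensus.
* Clone removal uses exact UMI matching; sequencing errors inside a UMI
  would split true clones (not exercised by the error-free defaults).
* The het-ward zygosity bias at conversion-type homozygous SNPs described
  above.
* With several heterozygous SNPs on one fragment, three-letter dedup
  splits the fragment's depth across haplotype combinations; at modest
  coverage such loci can fall below `min_depth` and drop out of the de
  novo reference (their reads then simply stay unaligned).
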