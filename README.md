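# bsgbs

Double-digest reduced-representation bisulfite sequencing (epiGBS-style
genotyping-by-sequencing of converted DNA) measures cytosine methylation
and SNPs in the same multiplexed library, for model and non-model species
alike. `bsgbs` is a complete R implementation of the computational method
for such libraries, aimed at molecular ecologists and methods developers
who want every stage — from raw multiplexed FASTQ to per-cytosine
methylation calls and a multi-sample VCF — as inspectable, testable R
functions rather than an opaque pipeline of external tools.

## What it does

Reads arrive with a 3-nt UMI, a sample barcode, one control nucleotide
(CN) and the restriction-enzyme overhang remnant at the 5' end. The
stages, each usable on its own:

* **Clone removal** — PCR duplicates are identified by an identical
  (UMI pair + read pair) tuple and collapsed (`remove_clones()`).
* **Demultiplexing and strand annotation** — each barcode pair expands
  with the expected CN letters (Watson: T in R1, C in R2; Crick: C/T);
  reads match exactly, the restriction overhang is validated with a
  single rescued mismatch, and every pair is labelled with its sample and
  strand class (`demultiplex()`).
* **De novo reference** — untrimmed reads are assembled per strand class,
  deduplicated in three-letter space (Watson C→T, Crick G→A, so
  methylation state does not affect grouping), Watson and Crick clusters
  are paired by their common binary encoding (C→T *and* G→A — the two
  strands of one locus become identical), and the per-column
  Watson/Crick letter combinations recover the original, unconverted
  sequence: T/C ⇒ C, G/A ⇒ G. Reconstructed consensi are clustered by
  identity and N-padded (`build_reference()`).
* **Trimming** — Illumina 3' adapter removal, the filled-in first base,
  a 10-bp hard trim of the opposite custom adapter, a 20-bp length
  filter, and the directional re-merge (Watson R1 ∪ Crick R2 as mate 1)
  (`trim_reads()`, `merge_directional()`).
* **Alignment** — three-letter seed-and-extend against C→T and G→A
  converted references, proper-pair constrained, OT/OB strand-tagged
  (`build_index()`, `align_pairs()`, `write_sam()`).
* **Methylation** — per-cytosine counts on both strands with CG/CHG/CHH
  context, mate-overlap handled once, CX-style reports and M-bias tables
  (`call_methylation()`, `write_cx_report()`, `mbias()`).
* **SNPs** — double masking rewrites conversion-confoundable read states
  (C/T over reference C on OT reads, G/A over reference G on OB reads) to
  the reference base so variants are called from opposite-strand evidence
  only; a per-site diploid maximum-likelihood caller emits a multi-sample
  VCF with GT:GQ:DP (`double_mask()`, `call_variants()`, `write_vcf()`).
* **Evaluation** — precision–sensitivity sweeps over variant quality
  (with squash-ploidy allele-level matching and a both-strand coverage
  filter), CpG destranding, coverage-filtered methylation R², Ward
  clustering of samples, and cluster-vs-truth statistics.
* **Simulator** — `simulate_library()` generates whole libraries with
  exact ground truth (loci from an in silico digestion, per-sample
  genotypes and methylomes, clone labels), reproducing the full read
  anatomy including bisulfite conversion, adapter read-through and the
  hemimethylated-adapter overhang protection. `digest()` alone estimates
  the complexity reduction of an enzyme pair on any genome.

`run_pipeline()` orchestrates everything from a flat key=value config
(de novo or reference mode) and writes a consolidated JSON run report;
`inst/scripts/bsgbs.R` is a thin command-line front end.

## A worked example

```r
library(bsgbs)

cfg <- sim_config(n_loci = 50, n_samples = 2, coverage = 15, seed = 7)
sim <- simulate_library(cfg)            # 3000 read pairs, exact truth
cl  <- remove_clones(sim$reads)
dm  <- demultiplex(cl$reads, cfg$barcodes, as.list(cfg$enzymes))
dn  <- build_reference(dm$reads)
str(dn$stats)
#> List of 7
#>  $ watson_pairs_assembled: int 1500
#>  $ crick_pairs_assembled : int 1500
#>  $ watson_strand_clusters: int 50
#>  $ crick_strand_clusters : int 50
#>  $ paired_clusters       : int 50
#>  $ unpaired_clusters     : int 0
#>  $ final_clusters        : int 50
```

All 50 simulated loci come back as exactly one cluster each; stripping
the N padding reproduces the true locus sequences. Aligning the trimmed
reads and calling methylation:

```r
tr    <- trim_reads(dm$reads)
mates <- merge_directional(tr$reads)
aln   <- align_pairs(mates$mate1, mates$mate2, build_index(dn$reference))
aln$stats$mapping_rate
#> [1] 1
meth <- call_methylation(aln$records, dn$reference)
head(meth, 4)
#>   sample   cluster pos strand count_methylated count_unmethylated context trinucleotide
#> 1    S01 cluster_1   6      -               15                  0      CG           CGN
#> 2    S01 cluster_1   7      -               15                  0     CHG           CCG
#> 3    S01 cluster_1  11      -                0                 15     CHH           CAT
#> 4    S01 cluster_1  12      +                7                  8     CHG           CAG
```

Each row is one cytosine of one strand: 15 of 15 reads methylated at the
CG site, a 7/15 split at a CHG site whose true methylation probability
was drawn near 0.5. With no SNPs simulated, double masking leaves the
variant caller empty-handed, as it should:

```r
vars <- filter_snps(call_variants(double_mask(aln$records, dn$reference),
                                  dn$reference))
nrow(vars)
#> [1] 0
```

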