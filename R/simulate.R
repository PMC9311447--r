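# Synthetic library generator.
#
# Emulates the full read anatomy of a double-digest bisulfite library:
# 3-nt UMI, sample barcode, one control nucleotide (CN), restriction-enzyme
# overhang remnant, bisulfite-converted insert and 3' read-through into the
# reverse-complemented opposite custom adapter followed by the standard
# Illumina adapter. Every molecule carries exact ground truth (locus, sample,
# strand, haplotype, methylation states), so downstream stages can be
# validated against a known answer.

#' Standard Illumina adapter used for 3' read-through
#' @export
ILLUMINA_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

#' Deterministic default barcode set
#'
#' Generates up to 96 distinct 6-bp barcode pairs, avoiding homopolymer runs
#' of three and extreme GC. The set is a pure function of `n` (no RNG), so a
#' library design is reproducible independently of the simulation seed.
#'
#' @param n number of samples.
#' @return data.frame with columns `sample`, `bc1`, `bc2`.
#' @export
default_barcodes <- function(n) {
  kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 6),
                                       stringsAsFactors = FALSE))
  ok <- !grepl("AAA|CCC|GGG|TTT", kmers)
  gc <- nchar(gsub("[AT]", "", kmers))
  kmers <- kmers[ok & gc >= 2 & gc <= 4]
  step <- 17L  # coprime stride through the pool; spreads edit distance
  idx <- (seq_len(2L * n) - 1L) * step %% length(kmers) + 1L
  if (anyDuplicated(idx) || 2L * n > length(kmers))
    stop("barcode pool exhausted for n = ", n)
  picks <- kmers[idx]
  data.frame(sample = sprintf("S%02d", seq_len(n)),
             bc1 = picks[seq_len(n)],
             bc2 = picks[n + seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Collects all tunable parameters of the synthetic library. The defaults are
#' the package's reference study conditions: a random 2-Mb genome digested
#' with MspI + NsiI, dual-cut fragments of 120-350 bp capped at 200 loci,
#' 4 samples at 30 read pairs per locus, sample and strand, complete bisulfite
#' conversion, no sequencing error, no PCR duplication, no SNPs, and a
#' methylation model of CG ~ Beta(2,2), CHG = 0.3, CHH = 0.05.
#'
#' @param genome_length random genome length (bp); ignored if `genome` given.
#' @param genome optional explicit genome sequence.
#' @param gc_content GC fraction of the random genome.
#' @param enzymes character vector of two enzyme names (frequent + rare).
#' @param size_range fragment size selection window (bp, inclusive).
#' @param n_loci cap on the number of loci (first `n_loci` in genome order);
#'   `Inf` keeps all.
#' @param n_samples number of multiplexed samples.
#' @param barcodes barcode data.frame (`sample`, `bc1`, `bc2`);
#'   default [default_barcodes()].
#' @param umi_length UMI length (3 in the standard adapter design).
#' @param read_length sequencing read length.
#' @param coverage read pairs per locus, per sample, per strand class.
#' @param conversion bisulfite conversion efficiency for unmethylated
#'   cytosines (methylated cytosines never convert).
#' @param error_rate per-base substitution sequencing error rate.
#' @param pcr_duplicate_rate expected fraction of read pairs that are PCR
#'   clones of another pair.
#' @param heterozygosity per-eligible-base SNP site probability; ignored when
#'   `n_snps` is set.
#' @param n_snps exact number of SNP sites to place (NULL = use
#'   `heterozygosity`).
#' @param meth_model named list for CG/CHG/CHH: a single number is a fixed
#'   methylation probability, two numbers are Beta shape parameters.
#' @param phred_quality constant base quality written to FASTQ.
#' @param stratify_strands if `TRUE` (default) exactly `coverage` molecules
#'   are drawn per strand class; if `FALSE` each molecule picks Watson or
#'   Crick with equal probability.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return a `bsgbs_sim_config` list.
#' @export
sim_config <- function(genome_length = 2e6,
                       genome = NULL,
                       gc_content = 0.5,
                       enzymes = c("MspI", "NsiI"),
                       size_range = c(120, 350),
                       n_loci = 200,
                       n_samples = 4,
                       barcodes = NULL,
                       umi_length = 3,
                       read_length = 200,
                       coverage = 30,
                       conversion = 1.0,
                       error_rate = 0,
                       pcr_duplicate_rate = 0,
                       heterozygosity = 0,
                       n_snps = NULL,
                       meth_model = list(CG = c(2, 2), CHG = 0.3, CHH = 0.05),
                       phred_quality = 37,
                       stratify_strands = TRUE,
                       seed = 1) {
  if (is.null(barcodes)) barcodes <- default_barcodes(n_samples)
  if (nrow(barcodes) < n_samples)
    stop("barcode table has fewer rows than n_samples")
  barcodes <- barcodes[seq_len(n_samples), , drop = FALSE]
  if (anyDuplicated(paste(barcodes$bc1, barcodes$bc2)))
    stop("duplicate (bc1, bc2) combination in barcode table")
  structure(
    list(genome_length = genome_length, genome = genome,
         gc_content = gc_content, enzymes = enzymes, size_range = size_range,
         n_loci = n_loci, n_samples = n_samples, barcodes = barcodes,
         umi_length = as.integer(umi_length),
         read_length = as.integer(read_length), coverage = coverage,
         conversion = conversion, error_rate = error_rate,
         pcr_duplicate_rate = pcr_duplicate_rate,
         heterozygosity = heterozygosity, n_snps = n_snps,
         meth_model = meth_model, phred_quality = as.integer(phred_quality),
         stratify_strands = isTRUE(stratify_strands), seed = seed),
    class = "bsgbs_sim_config")
}

# draw n methylation probabilities for one context: a scalar model value is a
# fixed level, a length-2 value gives Beta shape parameters
draw_meth_p <- function(context, n, model) {
  par <- model[[context]]
  if (length(par) == 1L) rep(par, n) else rbeta(n, par[1], par[2])
}

#' Draw ground truth for a set of loci
#'
#' Places SNP sites (never inside the enzyme remnants at the fragment ends),
#' draws diploid genotypes per sample at allele frequency 0.5, and draws a
#' true methylation probability for every cytosine of both strands per
#' sample from the configured context model.
#'
#' @param loci data.frame from [select_loci()].
#' @param config a [sim_config()].
#' @return a `bsgbs_truth` list with elements `loci`, `snps` (site table),
#'   `genotypes` (per sample), `methylation` (per sample, per cytosine).
#' @export
simulate_truth <- function(loci, config) {
  stopifnot(nrow(loci) > 0)
  samples <- config$barcodes$sample

  # eligible SNP positions exclude the remnant bases at both ends
  elig <- lapply(seq_len(nrow(loci)), function(i) {
    L <- loci$length[i]
    lrem <- nchar(enzyme_remnant(loci$left_enzyme[i], "left"))
    rrem <- nchar(enzyme_remnant(loci$right_enzyme[i], "right"))
    if (L - rrem < lrem + 1L) integer(0) else (lrem + 1L):(L - rrem)
  })
  pos_tab <- data.frame(
    locus = rep(loci$id, lengths(elig)),
    pos = unlist(elig),
    stringsAsFactors = FALSE)

  if (!is.null(config$n_snps)) {
    k <- min(config$n_snps, nrow(pos_tab))
    snp_idx <- sort(sample.int(nrow(pos_tab), k))
  } else {
    snp_idx <- which(runif(nrow(pos_tab)) < config$heterozygosity)
  }
  snps <- pos_tab[snp_idx, , drop = FALSE]
  if (nrow(snps)) {
    seqs <- setNames(loci$sequence, loci$id)
    snps$ref <- substring(seqs[snps$locus], snps$pos, snps$pos)
    snps$alt <- vapply(snps$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
      USE.NAMES = FALSE)
    # diploid genotypes at allele frequency 0.5 (Hardy-Weinberg)
    gt <- expand.grid(site = seq_len(nrow(snps)), sample = samples,
                      stringsAsFactors = FALSE)
    dose <- rbinom(nrow(gt), 2, 0.5)
    genotypes <- data.frame(
      sample = gt$sample,
      locus = snps$locus[gt$site], pos = snps$pos[gt$site],
      ref = snps$ref[gt$site], alt = snps$alt[gt$site],
      genotype = c("0/0", "0/1", "1/1")[dose + 1L],
      stringsAsFactors = FALSE)
  } else {
    snps$ref <- character(0); snps$alt <- character(0)
    genotypes <- data.frame(sample = character(0), locus = character(0),
                            pos = integer(0), ref = character(0),
                            alt = character(0), genotype = character(0),
                            stringsAsFactors = FALSE)
  }
  rownames(snps) <- NULL

  # per-sample methylation probabilities at every cytosine of both strands
  ctx_all <- lapply(seq_len(nrow(loci)), function(i) {
    ctx <- cytosine_contexts(loci$sequence[i])
    if (nrow(ctx)) ctx$locus <- loci$id[i]
    ctx
  })
  ctx_all <- do.call(rbind, ctx_all[vapply(ctx_all, nrow, 1L) > 0])
  meth <- do.call(rbind, lapply(samples, function(s) {
    m <- ctx_all
    m$sample <- s
    m$p_meth <- NA_real_
    for (cx in c("CG", "CHG", "CHH")) {
      sel <- m$context == cx
      m$p_meth[sel] <- draw_meth_p(cx, sum(sel), config$meth_model)
    }
    m
  }))
  meth <- meth[, c("sample", "locus", "pos", "strand", "context",
                   "trinucleotide", "p_meth")]
  rownames(meth) <- NULL

  # adapter-fill protection: the hemimethylated adapters repair the enzyme
  # overhang with 5-methyl-C dNTPs, so bottom-strand cytosines inside the
  # overhang span at each fragment end never convert and always read as
  # methylated. These sites are flagged so evaluations can treat them as
  # the library artifact they are.
  span <- function(enz, side) {
    e <- get_enzyme(enz)
    if (side == "left") max(0L, e$cut_offset_bottom - e$cut_offset_top)
    else max(0L, e$cut_offset_top - e$cut_offset_bottom)
  }
  dL <- setNames(vapply(loci$left_enzyme, span, 0L, side = "left"), loci$id)
  dR <- setNames(vapply(loci$right_enzyme, span, 0L, side = "right"), loci$id)
  llen <- setNames(loci$length, loci$id)
  meth$adapter_protected <- meth$strand == "-" &
    (meth$pos <= dL[meth$locus] | meth$pos > llen[meth$locus] - dR[meth$locus])

  structure(list(loci = loci, snps = snps, genotypes = genotypes,
                 methylation = meth, config = config),
            class = "bsgbs_truth")
}

#' Simulate reads from a truth set
#'
#' For every locus, sample and strand class the configured number of
#' molecules is drawn. Each molecule picks one haplotype per SNP site,
#' undergoes strand-specific bisulfite conversion (Watson: unmethylated
#' top-strand C to T; Crick: unmethylated bottom-strand C to T, i.e. G to A
#' in top-strand coordinates), and is read from both ends: R1 = UMI +
#' barcode + CN + remnant + insert, R2 likewise from the opposite end. When
#' the insert is shorter than the read length the read continues into the
#' reverse complement of the opposite custom adapter and then the standard
#' Illumina adapter. PCR duplicates replicate sequence and UMI; sequencing
#' errors are applied last.
#'
#' @param truth a `bsgbs_truth` from [simulate_truth()].
#' @param config the [sim_config()] used to build the truth.
#' @return list with `reads` (data.frame: `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`) and `clones` (data.frame: `read_id`, `molecule_id`, `locus`,
#'   `sample`, `strand`).
#' @export
simulate_reads <- function(truth, config) {
  loci <- truth$loci
  bc <- config$barcodes
  rl <- config$read_length
  meth_split <- split(truth$methylation,
                      paste(truth$methylation$locus, truth$methylation$sample))
  gt_split <- if (nrow(truth$genotypes))
    split(truth$genotypes, paste(truth$genotypes$locus, truth$genotypes$sample))
  else list()

  rand_umis <- function(n, len)
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1))

  res_r1 <- vector("list", nrow(loci) * nrow(bc))
  res_r2 <- res_r1
  res_mol <- res_r1
  slot <- 0L

  for (i in seq_len(nrow(loci))) {
    S <- loci$sequence[i]
    chars <- strsplit(S, "")[[1]]
    L <- length(chars)
    for (s in seq_len(nrow(bc))) {
      key <- paste(loci$id[i], bc$sample[s])
      if (config$stratify_strands) {
        n_w <- config$coverage; n_c <- config$coverage
      } else {
        n_w <- rbinom(1, 2 * config$coverage, 0.5)
        n_c <- 2 * config$coverage - n_w
      }
      n <- n_w + n_c
      if (n == 0L) next
      mat <- matrix(chars, nrow = L, ncol = n)

      # haplotypes: one allele draw per molecule and het site
      gt <- gt_split[[key]]
      if (!is.null(gt)) {
        for (j in seq_len(nrow(gt))) {
          al <- switch(gt$genotype[j],
            "0/0" = rep(gt$ref[j], n),
            "1/1" = rep(gt$alt[j], n),
            "0/1" = ifelse(runif(n) < 0.5, gt$ref[j], gt$alt[j]))
          mat[gt$pos[j], ] <- al
        }
      }

      mt <- meth_split[[key]]
      convert <- function(cols, positions, p, from, to, protected = NULL) {
        # bisulfite conversion of one strand class: methylated bases stay,
        # unmethylated bases convert with the configured efficiency
        if (!length(positions) || !length(cols)) return()
        sub <- mat[positions, cols, drop = FALSE]
        is_from <- sub == from
        p_eff <- if (is.null(protected)) p else ifelse(protected, 1, p)
        meth <- matrix(runif(length(positions) * length(cols)) <
                         rep(p_eff, length(cols)), nrow = length(positions))
        conv <- matrix(runif(length(positions) * length(cols)) <
                         config$conversion, nrow = length(positions))
        sub[is_from & !meth & conv] <- to
        mat[positions, cols] <<- sub
        # SNP-created bases of the convertible letter (not in the truth
        # methylome) are treated as unmethylated
        extra <- setdiff(which(chars != from), positions)
        if (length(extra)) {
          sub2 <- mat[extra, cols, drop = FALSE]
          hit <- sub2 == from &
            matrix(runif(length(extra) * length(cols)) < config$conversion,
                   nrow = length(extra))
          sub2[hit] <- to
          mat[extra, cols] <<- sub2
        }
      }
      w_cols <- seq_len(n_w)
      c_cols <- if (n_c > 0) n_w + seq_len(n_c) else integer(0)
      mp <- mt[mt$strand == "+", ]
      mm <- mt[mt$strand == "-", ]
      convert(w_cols, mp$pos, mp$p_meth, "C", "T")
      convert(c_cols, mm$pos, mm$p_meth, "G", "A", mm$adapter_protected)

      mols_top <- apply(mat, 2, paste, collapse = "")
      umi1 <- rand_umis(n, config$umi_length)
      umi2 <- rand_umis(n, config$umi_length)

      mk_pair <- function(idx, cn1, cn2, mol5) {
        # mol5: molecule sequence 5'->3' as R1 reads it
        pre1 <- paste0(umi1[idx], bc$bc1[s], cn1)
        pre2 <- paste0(umi2[idx], bc$bc2[s], cn2)
        pad <- strrep("A", rl)
        r1 <- substr(paste0(pre1, mol5, revcomp(pre2), ILLUMINA_ADAPTER, pad),
                     1L, rl)
        r2 <- substr(paste0(pre2, revcomp(mol5), revcomp(pre1),
                            ILLUMINA_ADAPTER, pad), 1L, rl)
        list(r1 = r1, r2 = r2)
      }
      slot <- slot + 1L
      w <- mk_pair(w_cols, "T", "C", mols_top[w_cols])
      cr <- if (n_c > 0)
        mk_pair(c_cols, "C", "T", revcomp(mols_top[c_cols]))
      else list(r1 = character(0), r2 = character(0))
      res_r1[[slot]] <- c(w$r1, cr$r1)
      res_r2[[slot]] <- c(w$r2, cr$r2)
      res_mol[[slot]] <- data.frame(
        molecule_id = sprintf("mol_%s_%s_%s_%d", loci$id[i], bc$sample[s],
                              rep(c("W", "C"), c(n_w, n_c)),
                              c(seq_len(n_w), seq_len(max(n_c, 0L)))[seq_len(n)]),
        locus = loci$id[i], sample = bc$sample[s],
        strand = rep(c("Watson", "Crick"), c(n_w, n_c)),
        stringsAsFactors = FALSE)
    }
  }

  r1 <- unlist(res_r1[seq_len(slot)], use.names = FALSE)
  r2 <- unlist(res_r2[seq_len(slot)], use.names = FALSE)
  mol <- do.call(rbind, res_mol[seq_len(slot)])

  # PCR duplication: each molecule is observed 1 + Poisson(r / (1 - r)) times
  # so the expected clone fraction equals pcr_duplicate_rate
  r <- config$pcr_duplicate_rate
  copies <- if (r > 0) 1L + stats::rpois(length(r1), r / (1 - r))
            else rep(1L, length(r1))
  idx <- rep(seq_along(r1), copies)
  r1 <- r1[idx]; r2 <- r2[idx]; mol <- mol[idx, , drop = FALSE]

  # shuffle so clones and samples are interleaved as in a real lane
  ord <- sample.int(length(r1))
  r1 <- r1[ord]; r2 <- r2[ord]; mol <- mol[ord, , drop = FALSE]

  # sequencing errors last (uniform substitution to one of the other bases)
  if (config$error_rate > 0) {
    r1 <- inject_errors(r1, config$error_rate)
    r2 <- inject_errors(r2, config$error_rate)
  }

  ids <- sprintf("read_%07d", seq_along(r1))
  qual <- constant_qual(rl, config$phred_quality)
  list(
    reads = data.frame(id = ids, seq1 = r1, qual1 = qual,
                       seq2 = r2, qual2 = qual, stringsAsFactors = FALSE),
    clones = data.frame(read_id = ids, molecule_id = mol$molecule_id,
                        locus = mol$locus, sample = mol$sample,
                        strand = mol$strand, stringsAsFactors = FALSE))
}

inject_errors <- function(seqs, rate) {
  len <- nchar(seqs[1])
  hit <- which(runif(length(seqs) * len) < rate)
  if (!length(hit)) return(seqs)
  read_i <- (hit - 1L) %/% len + 1L
  pos_i <- (hit - 1L) %% len + 1L
  for (k in seq_along(hit)) {
    old <- substr(seqs[read_i[k]], pos_i[k], pos_i[k])
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    substr(seqs[read_i[k]], pos_i[k], pos_i[k]) <- new
  }
  seqs
}

#' Simulate a complete multiplexed library
#'
#' Runs the whole generator: random genome (unless supplied), in silico
#' digestion, size selection, truth drawing and read simulation, under a
#' single seed so the output is byte-identical across runs.
#'
#' @param config a [sim_config()].
#' @return list with `truth` (`bsgbs_truth`), `reads`, `clones` and
#'   `genome`.
#' @export
simulate_library <- function(config = sim_config()) {
  set.seed(config$seed)
  genome <- if (!is.null(config$genome)) config$genome
            else random_genome(config$genome_length, config$gc_content)
  frags <- digest(genome, as.list(config$enzymes))
  loci <- select_loci(frags, config$size_range, require_dual = TRUE)
  if (nrow(loci) == 0L) stop("no loci produced by digestion/size selection")
  if (is.finite(config$n_loci) && nrow(loci) > config$n_loci) {
    loci <- loci[seq_len(config$n_loci), , drop = FALSE]
    loci$id <- sprintf("locus_%04d", seq_len(nrow(loci)))
  }
  truth <- simulate_truth(loci, config)
  sim <- simulate_reads(truth, config)
  list(truth = truth, reads = sim$reads, clones = sim$clones, genome = genome)
}

#' Write a simulated library to disk
#'
#' Emits gzip FASTQ for both mates, the true loci as FASTA and the truth
#' tables as TSV (`snps.tsv`, `meth.tsv`, `clones.tsv`).
#'
#' @param sim result of [simulate_library()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_library <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(data.frame(id = sim$reads$id, seq = sim$reads$seq1,
                         qual = sim$reads$qual1),
              file.path(dir, "R1.fastq.gz"))
  write_fastq(data.frame(id = sim$reads$id, seq = sim$reads$seq2,
                         qual = sim$reads$qual2),
              file.path(dir, "R2.fastq.gz"))
  write_fasta(setNames(sim$truth$loci$sequence, sim$truth$loci$id),
              file.path(dir, "loci.fasta"))
  tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(sim$truth$genotypes, "snps.tsv")
  tsv(sim$truth$methylation, "meth.tsv")
  tsv(sim$clones, "clones.tsv")
  bc <- sim$truth$config$barcodes
  write.table(bc, file.path(dir, "barcodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
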