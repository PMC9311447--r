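# Double masking and diploid SNP calling.

test_that("double masking rewrites conversion-confoundable states only", {
  ref <- c(cl = "AACGTTACGA")
  # OT read with T over the reference C at pos 3: becomes C
  r <- double_mask(make_record("cl", 1, "AATGTTACGA"), ref)
  expect_equal(substr(r$seq, 3, 3), "C")
  # OT read with A over a reference C: genuine mismatch evidence kept
  r2 <- double_mask(make_record("cl", 1, "AAAGTTACGA"), ref)
  expect_equal(substr(r2$seq, 3, 3), "A")
  # OB read with A over a reference G: becomes G
  r3 <- double_mask(make_record("cl", 1, "AACATTACGA", strand = "OB"), ref)
  expect_equal(substr(r3$seq, 4, 4), "G")
  # conversion-ambiguous states over other reference bases are nulled:
  # an OT T over reference G could be a converted alternate C
  r4 <- double_mask(make_record("cl", 1, "AACTTTACGA"), ref)
  expect_equal(substr(r4$seq, 4, 4), "N")
  r4b <- double_mask(make_record("cl", 1, "AACTTTACGA"), ref,
                     alt_masking = FALSE)
  expect_equal(substr(r4b$seq, 4, 4), "T")

  bad <- make_record("cl", 1, "AACGTTACGA")
  bad$bisulfite_strand <- NA
  expect_error(double_mask(bad, ref), "strand")
})

# independent brute-force genotype likelihood over the ten diploid
# genotypes from four alleles
brute_genotype <- function(bases, q) {
  eps <- 10^(-q / 10)
  alleles <- c("A", "C", "G", "T")
  gts <- expand.grid(a1 = alleles, a2 = alleles, stringsAsFactors = FALSE)
  gts <- gts[as.integer(factor(gts$a1, alleles)) <=
               as.integer(factor(gts$a2, alleles)), ]
  ll <- apply(gts, 1, function(g) {
    sum(log10(0.5 * ifelse(bases == g[1], 1 - eps, eps / 3) +
              0.5 * ifelse(bases == g[2], 1 - eps, eps / 3)))
  })
  gts[which.max(ll), ]
}

test_that("genotype calls match a brute-force likelihood oracle", {
  ref <- c(cl = "AAAGTTACGA")
  q20 <- rawToChar(as.raw(20 + 33))
  mk <- function(base, i, sample = "S01") {
    r <- make_record("cl", 1, paste0("AA", base, "GTTACGA"),
                     sample = sample, id = paste0("r", i),
                     qual_char = q20)
    r
  }
  # 10 observations of alt C at the ref-A position 3 -> hom alt
  recs <- do.call(rbind, lapply(1:10, mk, base = "C"))
  v <- call_variants(recs, ref, min_map_qual = 0)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 3L)
  expect_equal(v$alt, "C")
  oracle <- brute_genotype(rep("C", 10), 20)
  expect_equal(unname(v$genotypes[[1]]["S01"]), "1/1")
  expect_identical(unlist(unname(oracle)), c("C", "C"))
  expect_gt(v$gqs[[1]][["S01"]], 0)
  expect_gt(v$qual, 20)

  # 5 ref + 5 alt -> het, matching the oracle
  recs2 <- rbind(do.call(rbind, lapply(1:5, mk, base = "A")),
                 do.call(rbind, lapply(6:10, mk, base = "C")))
  v2 <- call_variants(recs2, ref, min_map_qual = 0)
  expect_equal(unname(v2$genotypes[[1]]["S01"]), "0/1")
  oracle2 <- brute_genotype(c(rep("A", 5), rep("C", 5)), 20)
  expect_setequal(unlist(unname(oracle2)), c("A", "C"))

  # all-reference observations produce no record
  recs3 <- do.call(rbind, lapply(1:10, mk, base = "A"))
  expect_equal(nrow(call_variants(recs3, ref, min_map_qual = 0)), 0L)

  # mapping-quality threshold excludes reads
  low <- recs; low$mapq <- 5L
  expect_equal(nrow(call_variants(low, ref, min_map_qual = 10)), 0L)
})

test_that("indel-like records are filtered, SNPs kept", {
  recs <- data.frame(cluster = "c", pos = 1:3,
                     ref = c("A", "AC", "A"),
                     alt = c("G", "A", "AT"),
                     qual = 1, stringsAsFactors = FALSE)
  kept <- filter_snps(recs)
  expect_equal(kept$pos, 1L)
  multi <- data.frame(cluster = "c", pos = 1L, ref = "A", alt = "C,T",
                      qual = 1, stringsAsFactors = FALSE)
  expect_equal(nrow(filter_snps(multi)), 1L)
})

test_that("VCF output parses with an independent reader", {
  skip_if_not_installed("vcfR")
  cfg <- tiny_config(seed = 71, n_snps = 8)
  sim <- simulate_library(cfg)
  x <- align_sim(sim, cfg)
  masked <- double_mask(x$aln$records, x$reference)
  vars <- filter_snps(call_variants(masked, x$reference))
  expect_gt(nrow(vars), 0L)
  f <- file.path(tempdir(), "out.vcf")
  write_vcf(vars, cfg$barcodes$sample, x$reference, f)
  v <- vcfR::read.vcfR(f, verbose = FALSE)
  expect_equal(nrow(v@fix), nrow(vars))
  expect_equal(as.integer(v@fix[, "POS"]), vars$pos)
  gt <- vcfR::extract.gt(v)
  expect_equal(ncol(gt), cfg$n_samples)
  # header-only VCF for zero records
  write_vcf(vars[0, ], cfg$barcodes$sample, x$reference, f)
  v0 <- vcfR::read.vcfR(f, verbose = FALSE)
  expect_equal(nrow(v0@fix), 0L)
})

test_that("a SNP-free library yields zero variant records", {
  cfg <- tiny_config(seed = 72)
  sim <- simulate_library(cfg)
  x <- align_sim(sim, cfg)
  masked <- double_mask(x$aln$records, x$reference)
  expect_equal(nrow(call_variants(masked, x$reference)), 0L)
})

test_that("C>T SNPs need opposite-strand coverage to be callable", {
  set.seed(73)
  locus <- paste0("CGG", random_genome(100), "ATGCA")
  p <- 50
  substr(locus, p, p) <- "C"
  ref <- c(cl = paste0("NNNN", locus, "NNNN"))
  alt_read <- locus
  substr(alt_read, p, p) <- "T"
  # OT-only coverage of the C>T SNP: fully masked, no call
  ot <- do.call(rbind, lapply(1:10, function(i)
    make_record("cl", 5, alt_read, id = paste0("o", i))))
  masked_ot <- double_mask(ot, ref)
  expect_equal(nrow(call_variants(masked_ot, ref, min_map_qual = 0)), 0L)
  # one OB read showing the alternate T makes the site callable
  ob <- make_record("cl", 5, alt_read, id = "b1", strand = "OB")
  masked_all <- double_mask(rbind(ot, ob), ref)
  v <- call_variants(masked_all, ref, min_map_qual = 0)
  expect_equal(v$pos, p + 4L)
  expect_equal(v$alt, "T")
})
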