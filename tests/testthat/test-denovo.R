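# De novo reference reconstruction: encodings, assembly, dedup, pairing,
# consensus, identity clustering.

test_that("three-letter and binary encodings are definitional", {
  expect_equal(three_letter_encode("ACGGAT", "WATSON"), "ATGGAT")
  expect_equal(three_letter_encode("ACGGAT", "CRICK"), "ACAAAT")
  expect_equal(three_letter_encode("TTTT", "WATSON"), "TTTT")
  expect_equal(binary_encode("ACGGAT"), "ATAAAT")
  expect_equal(binary_encode(""), "")
  expect_equal(binary_encode("ACGTN"), "ATATN")
  # encoding commutation
  expect_equal(binary_encode(three_letter_encode("ACGGAT", "WATSON")),
               binary_encode("ACGGAT"))
})

test_that("pair assembly emits the insert and joins non-overlapping mates", {
  set.seed(41)
  insert <- random_genome(80)
  r1 <- paste0(insert, "GACCTGAGTC", substr(ILLUMINA_ADAPTER, 1, 50))
  r2 <- paste0(revcomp(insert), "TGGTCAATCG", substr(ILLUMINA_ADAPTER, 1, 50))
  expect_equal(assemble_or_join(r1, r2), insert)

  # exact reverse complement assembles to r1
  a <- random_genome(60)
  expect_equal(assemble_or_join(a, revcomp(a)), a)

  # long fragment: partial overlap unions the two sides
  frag <- random_genome(200)
  expect_equal(assemble_or_join(substr(frag, 1, 140),
                                revcomp(substr(frag, 61, 200))), frag)

  # no overlap at all: joined with the 8-N spacer
  x <- random_genome(50); y <- random_genome(50)
  joined <- assemble_or_join(x, y)
  expect_equal(nchar(joined), 108L)
  expect_equal(joined, paste0(x, "NNNNNNNN", revcomp(y)))
})

test_that("dedup groups by encoding and takes per-column majorities", {
  # 12 Watson copies of a locus whose second base is a methylatable C:
  # 4 retain C, 8 converted to T -> majority is T at that column
  seqs <- c(rep("ACGGAT", 4), rep("ATGGAT", 8))
  cl <- dedup_consensus(seqs, "WATSON", min_depth = 10)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$depth, 12L)
  expect_equal(cl$encoded_key, "ATGGAT")
  expect_equal(cl$consensus, "ATGGAT")
  # with 7 of 12 methylated the majority flips to C
  seqs2 <- c(rep("ACGGAT", 7), rep("ATGGAT", 5))
  expect_equal(dedup_consensus(seqs2, "WATSON", 10)$consensus, "ACGGAT")
  # exact ties give N
  seqs3 <- c(rep("ACGGAT", 6), rep("ATGGAT", 6))
  expect_equal(dedup_consensus(seqs3, "WATSON", 10)$consensus, "ANGGAT")

  expect_equal(nrow(dedup_consensus(rep("ACGGAT", 5), "WATSON", 10)), 0L)
  expect_equal(nrow(dedup_consensus(rep("ACGGAT", 11), "WATSON", 10,
                                    max_depth = 10)), 0L)
})

test_that("binary pairing matches Watson with Crick and respects depth order", {
  w <- dedup_consensus(c(rep("ATGGAT", 12), rep("TTTTTT", 10)), "WATSON", 10)
  k <- dedup_consensus(rep("ACAAAT", 11), "CRICK", 10)
  p <- pair_watson_crick(w, k)
  expect_equal(nrow(p$pairs), 1L)
  expect_equal(p$pairs$watson, "ATGGAT")
  expect_equal(p$pairs$crick, "ACAAAT")
  expect_equal(nrow(p$unpaired), 1L)      # the TTTTTT Watson cluster

  # two Watson clusters sharing a binary key (A/G differences collapse),
  # one Crick partner: the highest-depth Watson cluster is paired
  w2 <- dedup_consensus(c(rep("AAGGAT", 15), rep("AGGGAT", 12)),
                        "WATSON", 10)
  expect_equal(nrow(w2), 2L)
  k2 <- dedup_consensus(rep("AAAAAT", 11), "CRICK", 10)
  p2 <- pair_watson_crick(w2, k2)
  expect_equal(nrow(p2$pairs), 1L)
  expect_equal(p2$pairs$watson_depth, 15L)
  expect_equal(p2$pairs$watson, "AAGGAT")
})

test_that("consensus reconstruction inverts bisulfite conversion", {
  expect_equal(reconstruct_consensus("ATGGAT", "ACAAAT"), "ACGGAT")
  expect_equal(reconstruct_consensus("ACGGAT", "ACAAAT"), "ACGGAT")
  expect_equal(reconstruct_consensus("AAGGAT", "ACAAAT"), "ANGGAT")

  # property: reconstruct(convert_watson(s), convert_crick(s)) == s for
  # any methylation pattern
  set.seed(42)
  for (i in 1:25) {
    s <- random_genome(sample(30:80, 1))
    ch <- strsplit(s, "")[[1]]
    w <- ch; cpos <- which(ch == "C")
    conv <- cpos[runif(length(cpos)) < runif(1)]
    w[conv] <- "T"
    k <- ch; gpos <- which(ch == "G")
    convg <- gpos[runif(length(gpos)) < runif(1)]
    k[convg] <- "A"
    expect_equal(reconstruct_consensus(paste(w, collapse = ""),
                                       paste(k, collapse = "")), s)
  }
})

test_that("identity clustering is greedy with N-padding of centroids", {
  two_same <- data.frame(sequence = rep("ACGTACGTAC", 2),
                         watson_depth = c(5L, 3L), crick_depth = c(5L, 3L))
  cl <- cluster_identity(two_same)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$members, 2L)
  expect_equal(cl$sequence, "NNNNACGTACGTACNNNN")
  expect_equal(cl$watson_depth, 8L)

  set.seed(43)
  base <- random_genome(100)
  var5 <- base
  for (p in c(10, 30, 50, 70, 90)) substr(var5, p, p) <-
      setdiff(c("A","C","G","T"), substr(base, p, p))[1]
  pairdf <- data.frame(sequence = c(base, var5),
                       watson_depth = c(10L, 5L), crick_depth = c(10L, 5L))
  expect_equal(nrow(cluster_identity(pairdf, identity = 0.99)), 2L)
  expect_equal(nrow(cluster_identity(pairdf, identity = 0.95)), 1L)

  empty <- cluster_identity(pairdf[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("full reconstruction recovers the true loci exactly", {
  cfg <- tiny_config(seed = 44)
  sim <- simulate_library(cfg)
  dm <- demux_sim(sim, cfg)
  dn <- build_reference(dm$reads, min_depth = 10)
  stripped <- gsub("^N+|N+$", "", dn$reference)
  expect_setequal(stripped, sim$truth$loci$sequence)
  expect_equal(dn$stats$final_clusters, nrow(sim$truth$loci))
  expect_true(all(startsWith(dn$reference, "NNNN")))
  expect_true(all(endsWith(dn$reference, "NNNN")))
})
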