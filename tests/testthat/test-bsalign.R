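# Directional bisulfite alignment and SAM output.

test_that("index construction validates the reference", {
  ref <- c(a = "NNNNACGTNNNN")
  idx <- build_index(ref)
  expect_equal(unname(idx$ct["a"]), "NNNNATGTNNNN")
  expect_equal(unname(idx$ga["a"]), "NNNNACATNNNN")
  expect_error(build_index(character(0)), "empty")
  expect_error(build_index(c(a = "ACGT", a = "ACGT")), "unique")
})

test_that("simulated pairs align uniquely at the true padded offset", {
  cfg <- tiny_config(seed = 51)
  sim <- simulate_library(cfg)
  x <- align_sim(sim, cfg)
  expect_equal(x$aln$stats$aligned, x$aln$stats$pairs)
  rec <- x$aln$records
  tl <- truth_lookup(rec$id, sim$clones)
  expect_true(all(rec$cluster == tl$locus))
  expect_true(all(rec$mapq == 40L))
  # demux stripped the key, trimming the first base: mate 1 starts at
  # locus position 2, i.e. padded position 6
  m1 <- rec[rec$mate == 1L & !rec$reverse, ]
  expect_true(all(m1$start == 6L))
  # bisulfite strand equals the true strand class
  expect_true(all((rec$bisulfite_strand == "OT") ==
                    (tl$strand == "Watson")))
})

test_that("reads matching duplicated clusters are ambiguous, junk unaligned", {
  set.seed(52)
  locus <- random_genome(120)
  ref2 <- c(c1 = paste0("NNNN", locus, "NNNN"),
            c2 = paste0("NNNN", locus, "NNNN"))
  idx <- build_index(ref2)
  m1 <- data.frame(id = "p1", sample = "S01", strand = "Watson",
                   seq = chartr("C", "T", substr(locus, 2, 100)),
                   qual = strrep("F", 99), stringsAsFactors = FALSE)
  m2 <- data.frame(id = "p1", sample = "S01", strand = "Watson",
                   seq = revcomp(substr(locus, 10, 110)),
                   qual = strrep("F", 101), stringsAsFactors = FALSE)
  res <- align_pairs(m1, m2, idx)
  expect_equal(res$status, "AMBIGUOUS")

  junk <- data.frame(id = "p2", sample = "S01", strand = "Watson",
                     seq = random_genome(100), qual = strrep("F", 100),
                     stringsAsFactors = FALSE)
  res2 <- align_pairs(junk, junk, idx)
  expect_equal(res2$status, "UNALIGNED")
})

test_that("alignment scoring is insensitive to conversion state", {
  set.seed(53)
  locus <- random_genome(150)
  ref <- c(cl = paste0("NNNN", locus, "NNNN"))
  idx <- build_index(ref)
  unconv <- substr(locus, 1, 100)
  conv <- chartr("C", "T", unconv)
  mk <- function(s, id) data.frame(id = id, sample = "S01",
                                   strand = "Watson", seq = s,
                                   qual = strrep("F", nchar(s)),
                                   stringsAsFactors = FALSE)
  mate2 <- mk(revcomp(substr(locus, 40, 150)), "x")
  r_unconv <- align_pairs(mk(unconv, "x"), mate2, idx)
  r_conv <- align_pairs(mk(conv, "x"), mate2, idx)
  expect_equal(r_unconv$status, "ALIGNED")
  expect_equal(r_conv$status, "ALIGNED")
  expect_equal(r_unconv$records$start, r_conv$records$start)
})

test_that("mapping rate degrades as loci become near-identical", {
  set.seed(54)
  base <- random_genome(200)
  mutate <- function(s, k) {
    for (p in sample(seq_len(nchar(s)), k))
      substr(s, p, p) <- sample(setdiff(c("A","C","G","T"),
                                        substr(s, p, p)), 1)
    s
  }
  mk_lib <- function(divergence) {
    loci <- c(base, mutate(base, divergence))
    ref <- setNames(paste0("NNNN", loci, "NNNN"), c("a", "b"))
    idx <- build_index(ref)
    m1 <- data.frame(id = sprintf("p%d", 1:20), sample = "S01",
                     strand = "Watson",
                     seq = chartr("C", "T", substr(rep(loci, 10), 1, 120)),
                     qual = strrep("F", 120), stringsAsFactors = FALSE)
    m2 <- data.frame(id = m1$id, sample = "S01", strand = "Watson",
                     seq = revcomp(substr(rep(loci, 10), 60, 200)),
                     qual = strrep("F", 141), stringsAsFactors = FALSE)
    align_pairs(m1, m2, idx)$stats$mapping_rate
  }
  # identical loci: everything ambiguous; diverged loci: everything unique
  expect_equal(mk_lib(0), 0)
  expect_gt(mk_lib(40), mk_lib(0))
})

test_that("SAM output is valid, tagged and rejects unsorted records", {
  cfg <- tiny_config(seed = 55)
  sim <- simulate_library(cfg)
  x <- align_sim(sim, cfg)
  sam <- file.path(tempdir(), "aln.sam")
  write_sam(x$aln$records, x$reference, sam)
  lines <- readLines(sam)
  expect_equal(sum(grepl("^@SQ", lines)), length(x$reference))
  expect_equal(sum(grepl("^@RG", lines)), cfg$n_samples)
  body <- lines[!grepl("^@", lines)]
  expect_equal(length(body), nrow(x$aln$records))
  f <- strsplit(body[1], "\t")[[1]]
  expect_equal(length(f) >= 11, TRUE)
  expect_true(any(grepl("XG:Z:(CT|GA)", body[1])))
  expect_true(any(grepl("RG:Z:", body[1])))
  # flags mark proper pairs
  expect_true(all(bitwAnd(as.integer(sapply(strsplit(body, "\t"),
                                            `[`, 2)), 3L) == 3L))
  shuffled <- x$aln$records[rev(seq_len(nrow(x$aln$records))), ]
  expect_error(write_sam(shuffled, x$reference, sam), "sorted")
})

test_that("empty record sets give a header-only SAM", {
  ref <- c(a = "NNNNACGTACGTNNNN")
  sam <- file.path(tempdir(), "empty.sam")
  write_sam(data.frame(), ref, sam)
  lines <- readLines(sam)
  expect_true(all(grepl("^@", lines)))
  expect_true(any(grepl("^@SQ\tSN:a\t", lines)))
})
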