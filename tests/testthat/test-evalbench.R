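# Evaluation utilities: cluster-vs-truth, PR curves, strand filter,
# destranding, methylation correlation, Ward clustering.

test_that("cluster-vs-truth statistics handle exact, tied and empty cases", {
  loci <- c("ACGTACGTAC", "TTGGAACCGG")
  exact <- paste0("NNNN", loci, "NNNN")
  st <- cluster_truth_stats(exact, loci)
  expect_equal(st$n_clusters, 2L)
  expect_equal(st$fraction_uniquely_matched, 1.0)
  expect_equal(st$mean_mismatches, 0.0)

  tied <- cluster_truth_stats(paste0("NNNN", loci[1], "NNNN"),
                              c(loci[1], loci[1]))
  expect_equal(tied$fraction_uniquely_matched, 0.0)

  none <- cluster_truth_stats(character(0), loci)
  expect_equal(none$n_clusters, 0L)

  mm <- loci[1]; substr(mm, 3, 3) <- "T"
  one_off <- cluster_truth_stats(paste0("NNNN", mm, "NNNN"), loci)
  expect_equal(one_off$mean_mismatches, 1.0)
})

test_that("precision and sensitivity follow their definitions", {
  calls <- data.frame(cluster = "c", pos = 1:10, alt = "A",
                      genotype = "0/1", qual = 10,
                      stringsAsFactors = FALSE)
  base <- data.frame(cluster = "c", pos = c(1:9, 11:13), alt = "A",
                     genotype = "0/1", stringsAsFactors = FALSE)
  pr <- pr_curve(calls, base, qual_grid = 0)
  expect_equal(pr$tp, 9L)
  expect_equal(pr$fp, 1L)
  expect_equal(pr$precision, 0.9)
  expect_equal(pr$sensitivity, 9 / 12)

  # genotype mismatch is TP under squash-ploidy, FP+FN otherwise
  c1 <- data.frame(cluster = "c", pos = 1L, alt = "A", genotype = "0/1",
                   qual = 50, stringsAsFactors = FALSE)
  b1 <- data.frame(cluster = "c", pos = 1L, alt = "A", genotype = "1/1",
                   stringsAsFactors = FALSE)
  expect_equal(pr_curve(c1, b1, squash_ploidy = TRUE, qual_grid = 0)$tp, 1L)
  strict <- pr_curve(c1, b1, squash_ploidy = FALSE, qual_grid = 0)
  expect_equal(c(strict$tp, strict$fp, strict$fn), c(0L, 1L, 1L))

  expect_error(pr_curve(c1, b1[0, ]), "baseline")
})

test_that("pr_curve agrees with a brute-force matcher on random sets", {
  set.seed(81)
  brute <- function(calls, base, squash, q) {
    sel <- which(calls$qual >= q)
    tp <- 0L; matched <- rep(FALSE, nrow(base))
    for (i in sel) {
      hit <- FALSE
      for (j in seq_len(nrow(base))) {
        same <- calls$cluster[i] == base$cluster[j] &&
          calls$pos[i] == base$pos[j] && calls$alt[i] == base$alt[j] &&
          (squash || calls$genotype[i] == base$genotype[j])
        if (same) { hit <- TRUE; matched[j] <- TRUE }
      }
      tp <- tp + hit
    }
    c(tp = tp, fp = length(sel) - tp, fn = sum(!matched))
  }
  for (rep_i in 1:20) {
    nc <- sample(0:15, 1); nb <- sample(1:15, 1)
    calls <- data.frame(cluster = sample(c("x", "y"), nc, TRUE),
                        pos = sample(1:6, nc, TRUE),
                        alt = sample(c("A", "G"), nc, TRUE),
                        genotype = sample(c("0/1", "1/1"), nc, TRUE),
                        qual = sample(0:30, nc, TRUE),
                        stringsAsFactors = FALSE)
    calls <- calls[!duplicated(calls[, c("cluster", "pos", "alt")]), ]
    base <- data.frame(cluster = sample(c("x", "y"), nb, TRUE),
                       pos = sample(1:6, nb, TRUE),
                       alt = sample(c("A", "G"), nb, TRUE),
                       genotype = sample(c("0/1", "1/1"), nb, TRUE),
                       stringsAsFactors = FALSE)
    base <- base[!duplicated(base[, c("cluster", "pos", "alt")]), ]
    sq <- sample(c(TRUE, FALSE), 1)
    q <- sample(0:30, 1)
    pr <- pr_curve(calls, base, squash_ploidy = sq, qual_grid = q)
    bf <- brute(calls, base, sq, q)
    expect_equal(c(pr$tp, pr$fp, pr$fn), unname(bf))
  }
})

test_that("sensitivity and candidate count decrease with the threshold", {
  set.seed(82)
  calls <- data.frame(cluster = "c", pos = 1:40, alt = "A",
                      genotype = "0/1", qual = runif(40, 0, 100),
                      stringsAsFactors = FALSE)
  base <- data.frame(cluster = "c", pos = seq(1, 40, by = 2), alt = "A",
                     genotype = "0/1", stringsAsFactors = FALSE)
  pr <- pr_curve(calls, base)
  expect_true(all(diff(pr$sensitivity) <= 1e-12))
  expect_true(all(diff(pr$tp + pr$fp) <= 0))
})

test_that("the both-strand filter keeps only dual-covered positions", {
  base <- data.frame(cluster = "c", pos = c(10L, 50L, 90L))
  recs <- rbind(make_record("c", 1, strrep("A", 60), id = "a"),
                make_record("c", 40, strrep("A", 30), id = "b",
                            strand = "OB"))
  kept <- both_strand_filter(base, recs)
  expect_equal(kept$pos, 50L)   # pos 10 OT-only, pos 90 uncovered
  expect_equal(nrow(both_strand_filter(base, recs[0, ])), 0L)
})

test_that("CpG destranding merges the two strands of a dinucleotide", {
  recs <- data.frame(sample = "s", cluster = "c",
                     pos = c(5L, 6L, 20L),
                     strand = c("+", "-", "+"),
                     count_methylated = c(3L, 2L, 7L),
                     count_unmethylated = c(1L, 2L, 0L),
                     context = "CG", stringsAsFactors = FALSE)
  d <- destrand_cpg(recs)
  expect_equal(nrow(d), 2L)
  merged <- d[d$pos == 5, ]
  expect_equal(c(merged$count_methylated, merged$count_unmethylated),
               c(5L, 3L))
  solo <- d[d$pos == 20, ]
  expect_equal(solo$count_methylated, 7L)

  bad <- recs; bad$context[1] <- "CHH"
  expect_error(destrand_cpg(bad), "CG")
})

test_that("methylation R2 applies coverage filters and least squares", {
  mk <- function(p, m, u) data.frame(cluster = "c", pos = p,
                                     count_methylated = m,
                                     count_unmethylated = u,
                                     stringsAsFactors = FALSE)
  a <- mk(1:3, c(0L, 5L, 10L), c(10L, 5L, 0L))
  r <- methylation_r2(a, a)
  expect_equal(r$r_squared, 1.0)
  expect_equal(r$n_sites, 3L)

  b <- mk(1:3, c(10L, 5L, 0L), c(0L, 5L, 10L))  # perfect negative fit
  rn <- methylation_r2(a, b)
  expect_equal(rn$r_squared, 1.0)
  expect_equal(unname(coef(rn$fit)[2]), -1.0)

  # a site with coverage 9 in one set is excluded
  low <- a; low$count_unmethylated[1] <- 8L
  rl <- methylation_r2(low, a, min_cov = 10)
  expect_equal(rl$n_sites, 2L)

  expect_error(methylation_r2(mk(1, 5L, 5L), mk(1, 5L, 5L)), "shared")
})

test_that("accession aggregation sums counts before the proportion", {
  per_sample <- data.frame(sample = rep(c("s1", "s2"), each = 2),
                           cluster = "c", pos = rep(c(1L, 2L), 2),
                           count_methylated = c(10L, 0L, 0L, 10L),
                           count_unmethylated = c(0L, 10L, 10L, 0L),
                           stringsAsFactors = FALSE)
  ref <- data.frame(cluster = "c", pos = c(1L, 2L),
                    count_methylated = c(5L, 5L),
                    count_unmethylated = c(5L, 5L),
                    stringsAsFactors = FALSE)
  r <- methylation_r2(per_sample, ref, min_cov = 10,
                      aggregate_by_group = TRUE)
  # both aggregated sites have proportion 0.5 == reference: perfect but
  # degenerate fit is caught by lm; just check the sites survived the
  # 10x-per-sample (20x total) rule
  expect_equal(r$n_sites, 2L)
})

test_that("Ward clustering separates simulated populations", {
  expect_error(ward_clusters(matrix(1:4, nrow = 1)), "2 samples")
  cm <- matrix(c(1, 1, 1, 1, 2, 3), nrow = 2, byrow = TRUE)
  expect_error(ward_clusters(cm, "correlation"), "constant")

  set.seed(83)
  popA <- matrix(rep(c(2, 0, 2, 0, 2, 0, 2, 0), 3), nrow = 3,
                 byrow = TRUE) + matrix(runif(24, 0, 0.1), nrow = 3)
  popB <- matrix(rep(c(0, 2, 0, 2, 0, 2, 0, 2), 3), nrow = 3,
                 byrow = TRUE) + matrix(runif(24, 0, 0.1), nrow = 3)
  m <- rbind(popA, popB)
  rownames(m) <- c(paste0("A", 1:3), paste0("B", 1:3))
  hc <- ward_clusters(m, "euclidean")
  grp <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(grp[1:3])), 1L)
  expect_equal(length(unique(grp[4:6])), 1L)
  expect_true(grp[1] != grp[4])

  # identical samples merge at height zero
  dup <- rbind(popA[1, ], popA[1, ])
  hc0 <- ward_clusters(dup, "euclidean")
  expect_equal(hc0$height, 0)

  nwk <- tree_newick(hc)
  phy <- ape::read.tree(text = nwk)
  expect_equal(sort(phy$tip.label), sort(rownames(m)))
})
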