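# Clone removal, barcode expansion, quality filter, overhang rescue,
# demultiplexing.

test_that("clone removal keys on UMI pair plus both sequences", {
  pair <- function(id, u1, s1, u2, s2) data.frame(
    id = id, seq1 = paste0(u1, s1), qual1 = strrep("F", 3 + nchar(s1)),
    seq2 = paste0(u2, s2), qual2 = strrep("F", 3 + nchar(s2)),
    stringsAsFactors = FALSE)
  same <- rbind(pair("a", "AAA", "ACGTACGT", "CCC", "TTGGAACC"),
                pair("b", "AAA", "ACGTACGT", "CCC", "TTGGAACC"))
  res <- remove_clones(same)
  expect_equal(nrow(res$reads), 1L)
  expect_equal(res$stats$clones_removed, 1L)
  expect_equal(res$reads$seq1, "ACGTACGT")  # UMI stripped

  diff_umi <- rbind(pair("a", "AAA", "ACGTACGT", "CCC", "TTGGAACC"),
                    pair("b", "AAG", "ACGTACGT", "CCC", "TTGGAACC"))
  expect_equal(nrow(remove_clones(diff_umi)$reads), 2L)

  empty <- remove_clones(same[0, ])
  expect_equal(nrow(empty$reads), 0L)
  expect_equal(empty$stats$clones_removed, 0L)
})

test_that("barcode expansion appends the control nucleotides", {
  tab <- data.frame(sample = "S1", bc1 = "ACGT", bc2 = "GGAA",
                    stringsAsFactors = FALSE)
  ex <- expand_barcodes(tab)
  expect_equal(nrow(ex), 2L)
  w <- ex[ex$strand == "Watson", ]
  expect_equal(c(w$key1, w$key2), c("ACGTT", "GGAAC"))
  k <- ex[ex$strand == "Crick", ]
  expect_equal(c(k$key1, k$key2), c("ACGTC", "GGAAT"))

  expect_equal(nrow(expand_barcodes(tab[0, ])), 0L)
  expect_equal(nrow(expand_barcodes(default_barcodes(44))), 88L)
  expect_error(expand_barcodes(rbind(tab, tab)), "duplicate")
})

test_that("sliding-window quality filter flags low-quality stretches", {
  q <- function(v) rawToChar(as.raw(v + 33L))
  expect_true(quality_pass(q(rep(40, 100))))
  expect_false(quality_pass(q(rep(2, 100))))
  # window length ceil(0.15 * 100) = 15; the final window mean is 2
  expect_false(quality_pass(q(c(rep(40, 85), rep(2, 15)))))
  # a single low base cannot drag a 15-base window below 10
  expect_true(quality_pass(q(c(rep(40, 99), 2))))
})

test_that("overhang rescue accepts at most one (replaced) mismatch", {
  r <- rescue_overhang("TGG", "CGG")
  expect_equal(r$status, "ACCEPT_REPLACED")
  expect_equal(r$sequence, "CGG")
  expect_equal(rescue_overhang("CGG", "CGG")$status, "ACCEPT_EXACT")
  expect_equal(rescue_overhang("ATG", "CGG")$status, "REJECT")
  expect_equal(rescue_overhang("TG", "CGG")$status, "REJECT")

  # ct_only accepts conversion-consistent mismatches without rewriting
  r2 <- rescue_overhang("TGG", "CGG", mode = "ct_only")
  expect_equal(r2$status, "ACCEPT_REPLACED")
  expect_equal(r2$sequence, "TGG")
  # expected-G / observed-A is conversion-consistent, other letters not
  expect_equal(rescue_overhang("CAG", "CGG", mode = "ct_only")$status,
               "ACCEPT_REPLACED")
  expect_equal(rescue_overhang("CTG", "CGG", mode = "ct_only")$status,
               "REJECT")
  expect_equal(rescue_overhang("TGCAT", "TGCAT", mode = "ct_only")$status,
               "ACCEPT_EXACT")
})

test_that("demultiplexing recovers sample and strand exactly on clean reads", {
  cfg <- tiny_config(seed = 21)
  sim <- simulate_library(cfg)
  cl <- remove_clones(sim$reads)
  dm <- demultiplex(cl$reads, cfg$barcodes, as.list(cfg$enzymes))
  tl <- truth_lookup(dm$reads$id, sim$clones)
  expect_equal(nrow(dm$reads), nrow(sim$reads))
  expect_true(all(dm$reads$sample == tl$sample))
  expect_true(all(dm$reads$strand == tl$strand))
  # conservation: drops + retained == clone-removed input
  st <- dm$stats
  expect_equal(st$ambiguous_barcode_drops + st$low_quality_drops +
                 st$ambiguous_radtag_drops + sum(st$retained),
               st$input_pairs)
  # headers carry the annotation
  expect_true(all(grepl("\\|S\\d+\\|(Watson|Crick)$", dm$reads$id)))
})

test_that("invalid control nucleotides and overhangs are dropped and tallied", {
  cfg <- tiny_config(seed = 22)
  sim <- simulate_library(cfg)
  cl <- remove_clones(sim$reads)
  reads <- cl$reads
  # mutate the CN of the first pair to (T, T): matches no expanded key
  cn_pos <- 6 + 1
  substr(reads$seq1[1], cn_pos, cn_pos) <- "T"
  substr(reads$seq2[1], cn_pos, cn_pos) <- "T"
  dm <- demultiplex(reads, cfg$barcodes, as.list(cfg$enzymes))
  expect_equal(dm$stats$ambiguous_barcode_drops, 1L)
  expect_true(length(dm$stats$observed_unexpected_barcodes) >= 1)
})

test_that("pairs failing the overhang check in every orientation are dropped", {
  # an enzyme pair whose R2-side remnants are both 5 bp (NsiI TGCAT,
  # PstI TGCAG), so a wrecked R2 overhang cannot be rescued; with a 1-bp
  # remnant a drop is impossible because at most one mismatch can exist
  bc <- data.frame(sample = "S01", bc1 = "ACGTAC", bc2 = "GGTTAA",
                   stringsAsFactors = FALSE)
  good <- data.frame(
    id = "ok", seq1 = paste0("ACGTAC", "T", "T", random_genome(40)),
    qual1 = strrep("F", 48),
    seq2 = paste0("GGTTAA", "C", "TGCAG", random_genome(40)),
    qual2 = strrep("F", 52), stringsAsFactors = FALSE)
  bad <- good
  bad$id <- "bad"
  substr(bad$seq2, 8, 12) <- "AACCA"   # >= 2 mismatches to both remnants
  dm <- demultiplex(rbind(good, bad), bc, list("NsiI", "PstI"))
  expect_equal(nrow(dm$reads), 1L)
  expect_equal(sub("\\|.*$", "", dm$reads$id), "ok")
  expect_equal(dm$stats$ambiguous_radtag_drops, 1L)
})

test_that("ct_only rescue never rewrites read bases", {
  cfg <- tiny_config(seed = 23)
  sim <- simulate_library(cfg)
  cl <- remove_clones(sim$reads)
  dm <- demux_sim(sim, cfg, rescue = "ct_only")
  # compare retained reads against the raw clone-removed sequences: only
  # the key prefix may have been stripped, nothing rewritten
  raw <- cl$reads[match(sub("\\|.*$", "", dm$reads$id), cl$reads$id), ]
  keylen <- 6 + 1
  expect_identical(dm$reads$seq1, substring(raw$seq1, keylen + 1))
  expect_identical(dm$reads$seq2, substring(raw$seq2, keylen + 1))
})
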