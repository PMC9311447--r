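# Clone removal, barcode expansion, demultiplexing and Watson/Crick
# annotation.
#
# Reads arrive with the custom adapter parts still attached:
# UMI + barcode + control nucleotide (CN) + enzyme-overhang remnant + insert.
# PCR clones are identified by identical UMI pair plus identical read pair,
# barcodes are expanded with the expected CN letters (Watson: T in R1 and C
# in R2; Crick: C in R1 and T in R2), and only reads whose post-key bases
# match an expected restriction overhang (one mismatch allowed, replaced)
# are retained.

#' Remove PCR clones by UMI + sequence identity
#'
#' Among read pairs sharing an identical (UMI1, UMI2, remaining R1, remaining
#' R2) tuple, the first encountered pair is kept; UMIs (first `umi_length`
#' bases and qualities of each mate) are stripped from the retained reads.
#'
#' @param reads data.frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param umi_length UMI length in bases.
#' @return list with `reads` (deduplicated, UMIs stripped) and `stats`
#'   (`input_pairs`, `clones_removed`, `clone_fraction`, `too_short_dropped`).
#' @export
remove_clones <- function(reads, umi_length = 3) {
  n_in <- nrow(reads)
  if (n_in == 0L) {
    return(list(reads = reads,
                stats = list(input_pairs = 0L, clones_removed = 0L,
                             clone_fraction = 0, too_short_dropped = 0L)))
  }
  long_enough <- nchar(reads$seq1) >= umi_length & nchar(reads$seq2) >= umi_length
  short <- sum(!long_enough)
  reads <- reads[long_enough, , drop = FALSE]

  key <- paste(reads$seq1, reads$seq2, sep = "\r")  # UMI is part of the seq
  dup <- duplicated(key)
  reads <- reads[!dup, , drop = FALSE]
  reads$seq1 <- substring(reads$seq1, umi_length + 1L)
  reads$qual1 <- substring(reads$qual1, umi_length + 1L)
  reads$seq2 <- substring(reads$seq2, umi_length + 1L)
  reads$qual2 <- substring(reads$qual2, umi_length + 1L)
  rownames(reads) <- NULL
  list(reads = reads,
       stats = list(input_pairs = n_in,
                    clones_removed = sum(dup),
                    clone_fraction = sum(dup) / n_in,
                    too_short_dropped = short))
}

#' Expand a barcode table with control nucleotides
#'
#' Each (bc1, bc2) combination yields two expanded keys: the Watson key with
#' T appended to bc1 and C to bc2, and the Crick key with C appended to bc1
#' and T to bc2.
#'
#' @param barcodes data.frame with `sample`, `bc1`, `bc2`.
#' @return data.frame with `sample`, `strand` (`Watson`/`Crick`), `key1`,
#'   `key2`.
#' @export
expand_barcodes <- function(barcodes) {
  if (nrow(barcodes) == 0L)
    return(data.frame(sample = character(0), strand = character(0),
                      key1 = character(0), key2 = character(0),
                      stringsAsFactors = FALSE))
  if (anyDuplicated(paste(barcodes$bc1, barcodes$bc2)))
    stop("duplicate (bc1, bc2) combination in barcode table")
  data.frame(
    sample = rep(barcodes$sample, each = 2L),
    strand = rep(c("Watson", "Crick"), nrow(barcodes)),
    key1 = as.vector(rbind(paste0(barcodes$bc1, "T"),
                           paste0(barcodes$bc1, "C"))),
    key2 = as.vector(rbind(paste0(barcodes$bc2, "C"),
                           paste0(barcodes$bc2, "T"))),
    stringsAsFactors = FALSE)
}

#' Sliding-window base quality filter
#'
#' A read fails when any sliding window (length `ceiling(window_fraction *
#' read length)`, step 1) has mean phred quality below `threshold`.
#'
#' @param qual phred+33 quality string.
#' @param threshold minimum acceptable window mean.
#' @param window_fraction window length as a fraction of the read length.
#' @return `TRUE` if the read passes.
#' @export
quality_pass <- function(qual, threshold = 10, window_fraction = 0.15) {
  q <- as.integer(charToRaw(qual)) - 33L
  n <- length(q)
  if (n == 0L) stop("empty quality string")
  w <- ceiling(window_fraction * n)
  if (w >= n) return(mean(q) >= threshold)
  cs <- cumsum(c(0L, q))
  means <- (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
  all(means >= threshold)
}

# IUPAC-aware single-base agreement: expected may carry ambiguity codes
base_matches <- function(observed, expected) {
  mapply(function(o, e) o %in% IUPAC_SETS[[e]], observed, expected,
         USE.NAMES = FALSE)
}

#' Validate or rescue a restriction-enzyme overhang
#'
#' Compares the observed read bases with the expected enzyme remnant. Zero
#' mismatches accept the read as-is; one mismatch is rescued by replacing
#' the observed bases with the expected remnant (mode `any_single_mismatch`),
#' or only when the mismatch is explainable by bisulfite conversion
#' (expected C observed T, or expected G observed A; mode `ct_only`, which
#' accepts without rewriting). Two or more mismatches reject.
#'
#' @param observed observed bases at the overhang position.
#' @param expected expected remnant (IUPAC codes allowed).
#' @param mode rescue mode.
#' @return list with `status` (`ACCEPT_EXACT`, `ACCEPT_REPLACED`, `REJECT`)
#'   and `sequence` (the possibly rewritten overhang).
#' @export
rescue_overhang <- function(observed, expected,
                            mode = c("any_single_mismatch", "ct_only")) {
  mode <- match.arg(mode)
  if (nchar(observed) != nchar(expected))
    return(list(status = "REJECT", sequence = observed))
  ob <- strsplit(observed, "")[[1]]
  ex <- strsplit(expected, "")[[1]]
  mism <- which(!base_matches(ob, ex))
  if (length(mism) == 0L)
    return(list(status = "ACCEPT_EXACT", sequence = observed))
  if (length(mism) == 1L) {
    i <- mism
    if (mode == "any_single_mismatch") {
      ob[i] <- ex[i]
      return(list(status = "ACCEPT_REPLACED",
                  sequence = paste(ob, collapse = "")))
    }
    conv_ok <- (ex[i] == "C" && ob[i] == "T") || (ex[i] == "G" && ob[i] == "A")
    if (conv_ok)
      return(list(status = "ACCEPT_REPLACED", sequence = observed))
  }
  list(status = "REJECT", sequence = observed)
}

#' Demultiplex clone-removed reads by sample and strand
#'
#' A pair is assigned when its mate prefixes match exactly one expanded
#' barcode key pair at the allowed mismatch counts. After key stripping, the
#' bases following the keys are checked against the expected restriction
#' overhangs (R1 against one enzyme's remnant, R2 against the other's; both
#' enzyme-to-mate assignments are tried because fragment orientation is
#' unknown), allowing one rescued mismatch per mate. A sliding-window
#' quality filter is applied between barcode matching and the overhang
#' check. Assigned reads keep the overhang and gain `sample` and `strand`
#' annotations.
#'
#' @param reads clone-removed reads (UMIs stripped).
#' @param barcodes barcode table (`sample`, `bc1`, `bc2`).
#' @param enzymes the two restriction enzymes (names or objects).
#' @param mismatches_r1,mismatches_r2 allowed barcode+CN key mismatches.
#' @param rescue_mode overhang rescue mode, see [rescue_overhang()].
#' @param quality_threshold,window_fraction see [quality_pass()].
#' @return list with `reads` (assigned pairs with `sample`, `strand`) and
#'   `stats` (a `DemuxStats`-style list).
#' @export
demultiplex <- function(reads, barcodes, enzymes,
                        mismatches_r1 = 0, mismatches_r2 = 0,
                        rescue_mode = "any_single_mismatch",
                        quality_threshold = 10, window_fraction = 0.15) {
  keys <- expand_barcodes(barcodes)
  enzymes <- lapply(enzymes, get_enzyme)
  if (length(enzymes) == 1L) enzymes <- c(enzymes, enzymes)
  n_in <- nrow(reads)
  stats <- list(input_pairs = n_in, ambiguous_barcode_drops = 0L,
                low_quality_drops = 0L, ambiguous_radtag_drops = 0L,
                retained = integer(0),
                observed_unexpected_barcodes = list())

  if (n_in == 0L) {
    reads$sample <- character(0); reads$strand <- character(0)
    stats$retained <- setNames(integer(nrow(barcodes)), barcodes$sample)
    return(list(reads = reads, stats = stats))
  }

  # barcode lengths may differ across samples: try every key-length class
  key_class <- split(seq_len(nrow(keys)),
                     paste(nchar(keys$key1), nchar(keys$key2)))
  assign_idx <- rep(NA_integer_, n_in)
  ambiguous <- rep(FALSE, n_in)
  for (cls in key_class) {
    l1 <- nchar(keys$key1[cls[1]]); l2 <- nchar(keys$key2[cls[1]])
    p1 <- substr(reads$seq1, 1L, l1)
    p2 <- substr(reads$seq2, 1L, l2)
    for (k in cls) {
      m1 <- mismatch_count_vec(p1, keys$key1[k])
      m2 <- mismatch_count_vec(p2, keys$key2[k])
      hit <- m1 <= mismatches_r1 & m2 <= mismatches_r2
      newly <- hit & !ambiguous
      clash <- newly & !is.na(assign_idx) & assign_idx != k
      ambiguous[clash] <- TRUE
      assign_idx[clash] <- NA_integer_
      assign_idx[newly & is.na(assign_idx) & !ambiguous] <- k
    }
  }

  unmatched <- is.na(assign_idx) & !ambiguous
  if (any(unmatched)) {
    # tally unexpected barcode-like prefixes at the modal key lengths
    l1 <- max(nchar(keys$key1)); l2 <- max(nchar(keys$key2))
    tab <- table(paste(substr(reads$seq1[unmatched], 1L, l1),
                       substr(reads$seq2[unmatched], 1L, l2)))
    stats$observed_unexpected_barcodes <- as.list(sort(tab, decreasing = TRUE))
  }
  stats$ambiguous_barcode_drops <- sum(is.na(assign_idx))

  keep <- which(!is.na(assign_idx))
  out <- reads[keep, , drop = FALSE]
  kidx <- assign_idx[keep]
  out$sample <- keys$sample[kidx]
  out$strand <- keys$strand[kidx]
  # strip the matched keys (barcode + CN)
  out$seq1 <- substring(out$seq1, nchar(keys$key1[kidx]) + 1L)
  out$qual1 <- substring(out$qual1, nchar(keys$key1[kidx]) + 1L)
  out$seq2 <- substring(out$seq2, nchar(keys$key2[kidx]) + 1L)
  out$qual2 <- substring(out$qual2, nchar(keys$key2[kidx]) + 1L)

  # quality filter (drops the whole pair when either mate fails)
  if (nrow(out)) {
    q_ok <- vapply(out$qual1, quality_pass, logical(1),
                   threshold = quality_threshold,
                   window_fraction = window_fraction, USE.NAMES = FALSE) &
            vapply(out$qual2, quality_pass, logical(1),
                   threshold = quality_threshold,
                   window_fraction = window_fraction, USE.NAMES = FALSE)
    stats$low_quality_drops <- sum(!q_ok)
    out <- out[q_ok, , drop = FALSE]
  }

  # overhang validation. The remnant type expected on each mate follows
  # from the strand class established by the control nucleotide: a Watson
  # R1 enters the fragment at its left end (top-strand remnant) and its R2
  # at the right end (bottom-strand remnant); for Crick pairs the roles
  # swap. Which enzyme cut which end is unknown, so both enzyme
  # assignments are scored and the one with fewer total mismatches wins.
  if (nrow(out)) {
    orients_for <- function(strand_class) {
      if (strand_class == "Watson") list(
        list(r1 = enzyme_remnant(enzymes[[1]], "left"),
             r2 = enzyme_remnant(enzymes[[2]], "right")),
        list(r1 = enzyme_remnant(enzymes[[2]], "left"),
             r2 = enzyme_remnant(enzymes[[1]], "right")))
      else list(
        list(r1 = enzyme_remnant(enzymes[[2]], "right"),
             r2 = enzyme_remnant(enzymes[[1]], "left")),
        list(r1 = enzyme_remnant(enzymes[[1]], "right"),
             r2 = enzyme_remnant(enzymes[[2]], "left")))
    }
    done <- rep(FALSE, nrow(out))
    for (sc in c("Watson", "Crick")) {
      idx <- which(out$strand == sc)
      if (!length(idx)) next
      ors <- orients_for(sc)
      # score accepted orientations by matched remnant bases, so a long
      # remnant with one rescued conversion outranks a short remnant that
      # matches trivially
      score <- matrix(-Inf, nrow = length(idx), ncol = 2)
      checks <- vector("list", 2)
      for (oi in 1:2) {
        r1c <- overhang_check_vec(out$seq1[idx], ors[[oi]]$r1, rescue_mode)
        r2c <- overhang_check_vec(out$seq2[idx], ors[[oi]]$r2, rescue_mode)
        checks[[oi]] <- list(r1 = r1c, r2 = r2c)
        ok <- r1c$ok & r2c$ok
        score[ok, oi] <- (nchar(ors[[oi]]$r1) - r1c$nm[ok]) +
                         (nchar(ors[[oi]]$r2) - r2c$nm[ok])
      }
      pick <- ifelse(score[, 1] >= score[, 2] & is.finite(score[, 1]), 1L,
                     ifelse(is.finite(score[, 2]), 2L, NA_integer_))
      for (oi in 1:2) {
        sel <- which(pick == oi)
        if (!length(sel)) next
        fix1 <- sel[checks[[oi]]$r1$replace[sel]]
        fix2 <- sel[checks[[oi]]$r2$replace[sel]]
        if (length(fix1))
          substr(out$seq1[idx[fix1]], 1L, nchar(ors[[oi]]$r1)) <- ors[[oi]]$r1
        if (length(fix2))
          substr(out$seq2[idx[fix2]], 1L, nchar(ors[[oi]]$r2)) <- ors[[oi]]$r2
        done[idx[sel]] <- TRUE
      }
    }
    stats$ambiguous_radtag_drops <- sum(!done)
    out <- out[done, , drop = FALSE]
  }

  out$id <- paste(out$id, out$sample, out$strand, sep = "|")
  rownames(out) <- NULL
  ret <- table(factor(out$sample, levels = barcodes$sample))
  stats$retained <- setNames(as.integer(ret), names(ret))
  list(reads = out, stats = stats)
}

# vectorised overhang check of many reads against one expected remnant;
# returns acceptance and whether the observed bases should be rewritten to
# the expected remnant (single-mismatch rescue). Rewriting is suppressed
# when the remnant carries IUPAC ambiguity codes (only validation then) or
# in ct_only mode (conversion-consistent mismatches accepted unmodified).
overhang_check_vec <- function(seqs, expected, mode) {
  w <- nchar(expected)
  ex <- strsplit(expected, "")[[1]]
  concrete <- all(ex %in% c("A", "C", "G", "T"))
  obs <- substr(seqs, 1L, w)
  n <- length(obs)
  mism <- matrix(FALSE, nrow = w, ncol = n)
  om <- matrix(unlist(lapply(obs, function(x)
    strsplit(x, "")[[1]][seq_len(w)]), use.names = FALSE), nrow = w)
  for (j in seq_len(w))
    mism[j, ] <- !(om[j, ] %in% IUPAC_SETS[[ex[j]]])
  nm <- colSums(mism)
  short <- nchar(obs) < w
  nm[short] <- w
  if (mode == "ct_only") {
    # the single mismatch must look like bisulfite conversion
    conv_ok <- rep(FALSE, n)
    one <- which(nm == 1L)
    if (length(one)) {
      j <- apply(mism[, one, drop = FALSE], 2, which)
      o <- om[cbind(j, one)]
      e <- ex[j]
      conv_ok[one] <- (e == "C" & o == "T") | (e == "G" & o == "A")
    }
    list(ok = nm == 0L | (nm == 1L & conv_ok), replace = rep(FALSE, n),
         nm = nm)
  } else {
    list(ok = nm <= 1L, replace = nm == 1L & concrete, nm = nm)
  }
}

# vectorised mismatch count of many strings against one key (equal lengths)
mismatch_count_vec <- function(x, key) {
  if (!length(x)) return(integer(0))
  kb <- charToRaw(key)
  lens <- nchar(x)
  out <- rep.int(length(kb), length(x))
  ok <- lens == length(kb)
  if (any(ok)) {
    m <- matrix(unlist(lapply(x[ok], charToRaw), use.names = FALSE),
                nrow = length(kb))
    out[ok] <- colSums(m != kb)
  }
  out
}
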