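# Directional three-letter bisulfite alignment.
#
# The reference is converted twice (C->T and G->A). A mate pair from the
# original top strand (OT) matches the C->T reference with mate 1 forward;
# a pair from the original bottom strand (OB) matches the G->A reference
# with mate 2 forward. Candidate placements come from exact k-mer seeds in
# converted space and are scored by ungapped extension (match +1, mismatch
# -1); restriction fragments have fixed ends and no indels, so gapped
# alignment is not attempted and unseeded reads are reported unaligned.

#' Build a bisulfite alignment index
#'
#' Holds the two converted copies of the reference (all C to T and all G to
#' A); the k-mer seed tables are materialised in compiled code at alignment
#' time.
#'
#' @param reference named character vector of cluster sequences (N-padded
#'   de novo clusters or any reference FASTA contents).
#' @param k seed k-mer length (N-containing k-mers never seed).
#' @return a `bsgbs_index` list.
#' @export
build_index <- function(reference, k = 20) {
  if (length(reference) == 0L) stop("empty reference")
  if (is.null(names(reference)) || anyDuplicated(names(reference)))
    stop("reference sequences must have unique names")
  structure(list(reference = reference,
                 ct = chartr("C", "T", reference),
                 ga = chartr("G", "A", reference),
                 k = as.integer(k)),
            class = "bsgbs_index")
}

#' Align trimmed directional mate pairs to the reference
#'
#' Mate 1 carries top-strand sequence by construction of
#' [merge_directional()]. Each pair is probed in OT orientation (both mates
#' matched against the C->T reference) and OB orientation (against the G->A
#' reference); both mates must place on the same cluster within the insert
#' constraint. The unique best-scoring cluster wins (mapping quality 40);
#' equal best scores on two or more clusters give AMBIGUOUS, and a best
#' score under `min_score_frac` times the read length gives UNALIGNED.
#'
#' @param mate1,mate2 data.frames (`id`, `sample`, `strand`, `seq`, `qual`)
#'   from [merge_directional()].
#' @param index a [build_index()] result.
#' @param min_score_frac minimum acceptable per-mate score as a fraction of
#'   read length.
#' @param mode `"directional"` probes OT/OB only; `"nondirectional"` also
#'   probes the complementary orientations (mates swapped).
#' @return list with `records` (two rows per aligned pair: `id`, `sample`,
#'   `cluster`, `start`, `end`, `cigar`, `mapq`, `bisulfite_strand`,
#'   `mate`, `reverse`, `seq`, `qual` in reference-forward orientation),
#'   `status` (per input pair: `ALIGNED`/`AMBIGUOUS`/`UNALIGNED`) and
#'   `stats`.
#' @export
align_pairs <- function(mate1, mate2, index, min_score_frac = 0.6,
                        mode = c("directional", "nondirectional")) {
  mode <- match.arg(mode)
  n <- nrow(mate1)
  stopifnot(nrow(mate2) == n, all(mate1$id == mate2$id))
  k <- index$k
  refs <- index$reference
  ref_len <- nchar(refs)
  empty <- list(records = data.frame(), status = character(0),
                stats = list(pairs = 0L, aligned = 0L, ambiguous = 0L,
                             unaligned = 0L, mapping_rate = 0))
  if (n == 0L) return(empty)

  # encoded probes per orientation. After the directional re-merge, mate 1
  # of every pair runs forward in locus coordinates: Watson-derived pairs
  # show a C->T pattern (informative for reference C, tag OT) and
  # Crick-derived pairs a G->A pattern (reference G, tag OB). Against an
  # external reference a locus may lie on the minus strand of its contig,
  # which flips both mates; those two reverse probes are enabled by the
  # nondirectional mode.
  rc2 <- revcomp(mate2$seq)
  orientations <- list(
    list(tag = "OT", e1 = chartr("C", "T", mate1$seq),
         e2 = chartr("C", "T", rc2), conv = index$ct,
         rev1 = FALSE, rev2 = TRUE),
    list(tag = "OB", e1 = chartr("G", "A", mate1$seq),
         e2 = chartr("G", "A", rc2), conv = index$ga,
         rev1 = FALSE, rev2 = TRUE))
  if (mode == "nondirectional") {
    rc1 <- revcomp(mate1$seq)
    orientations <- c(orientations, list(
      list(tag = "OB", e1 = chartr("G", "A", rc1),
           e2 = chartr("G", "A", mate2$seq), conv = index$ga,
           rev1 = TRUE, rev2 = FALSE),
      list(tag = "OT", e1 = chartr("C", "T", rc1),
           e2 = chartr("C", "T", mate2$seq), conv = index$ct,
           rev1 = TRUE, rev2 = FALSE)))
  }

  l1 <- nchar(mate1$seq)
  l2 <- nchar(mate2$seq)
  res <- lapply(orientations, function(o)
    align_orientation_cpp(o$e1, o$e2, o$conv, k))
  joint <- vapply(res, function(m) {
    sc <- as.numeric(m[, 4] + m[, 5])
    bad <- m[, 1] == 0L | m[, 4] < min_score_frac * l1 |
           m[, 5] < min_score_frac * l2
    sc[bad] <- -Inf
    sc
  }, numeric(n))
  if (n == 1L) joint <- matrix(joint, nrow = 1)
  best_sc <- do.call(pmax, as.data.frame(joint))
  pick <- max.col(joint, ties.method = "first")
  pick[!is.finite(best_sc)] <- NA_integer_

  # ambiguity: a within-orientation tie at distinct placements, or an
  # equal best joint score in another orientation at a different placement
  ambiguous <- rep(FALSE, n)
  for (oi in seq_along(res)) {
    sel <- !is.na(pick) & pick == oi
    ambiguous[sel & res[[oi]][, 6] == 1L] <- TRUE
    for (oj in seq_along(res)) {
      if (oj == oi) next
      same_best <- sel & is.finite(joint[, oj]) & joint[, oj] == best_sc
      diff_place <- res[[oi]][, 1] != res[[oj]][, 1] |
                    res[[oi]][, 2] != res[[oj]][, 2] |
                    res[[oi]][, 3] != res[[oj]][, 3]
      ambiguous[same_best & diff_place] <- TRUE
    }
  }

  status <- ifelse(is.na(pick), "UNALIGNED",
                   ifelse(ambiguous, "AMBIGUOUS", "ALIGNED"))
  va <- which(status == "ALIGNED")
  records <- data.frame()
  if (length(va)) {
    ori_tag <- vapply(orientations, `[[`, character(1), "tag")
    ori_rev1 <- vapply(orientations, `[[`, logical(1), "rev1")
    ori_rev2 <- vapply(orientations, `[[`, logical(1), "rev2")
    po <- pick[va]
    cl <- s1 <- s2 <- integer(length(va))
    for (oi in seq_along(res)) {
      sel <- po == oi
      cl[sel] <- res[[oi]][va[sel], 1]
      s1[sel] <- res[[oi]][va[sel], 2]
      s2[sel] <- res[[oi]][va[sel], 3]
    }
    rl <- ref_len[cl]
    rev1 <- ori_rev1[po]; rev2 <- ori_rev2[po]
    seq1r <- ifelse(rev1, revcomp(mate1$seq[va]), mate1$seq[va])
    qual1r <- ifelse(rev1, revstring(mate1$qual[va]), mate1$qual[va])
    seq2r <- ifelse(rev2, revcomp(mate2$seq[va]), mate2$seq[va])
    qual2r <- ifelse(rev2, revstring(mate2$qual[va]), mate2$qual[va])
    # clip bases hanging over the reference ends (residual adapter)
    s1c <- pmax(1L, s1); e1c <- pmin(s1 + l1[va] - 1L, rl)
    s2c <- pmax(1L, s2); e2c <- pmin(s2 + l2[va] - 1L, rl)
    mk <- function(mate, sc, ec, s0, seqr, qualr, rev) data.frame(
      id = mate1$id[va], sample = mate1$sample[va],
      cluster = names(refs)[cl],
      start = sc, end = ec,
      cigar = paste0(ec - sc + 1L, "M"),
      mapq = 40L,
      bisulfite_strand = ori_tag[po],
      mate = mate,
      reverse = rev,
      seq = substr(seqr, sc - s0 + 1L, ec - s0 + 1L),
      qual = substr(qualr, sc - s0 + 1L, ec - s0 + 1L),
      stringsAsFactors = FALSE)
    records <- rbind(mk(1L, s1c, e1c, s1, seq1r, qual1r, rev1),
                     mk(2L, s2c, e2c, s2, seq2r, qual2r, rev2))
    records <- records[order(records$cluster, records$start, records$id), ]
    rownames(records) <- NULL
  }
  list(records = records, status = status,
       stats = list(pairs = n,
                    aligned = sum(status == "ALIGNED"),
                    ambiguous = sum(status == "AMBIGUOUS"),
                    unaligned = sum(status == "UNALIGNED"),
                    mapping_rate = if (n) sum(status == "ALIGNED") / n else 0))
}

revstring <- function(x) {
  vapply(x, function(s) rawToChar(rev(charToRaw(s))), character(1),
         USE.NAMES = FALSE)
}

#' Write alignment records as SAM
#'
#' Emits a coordinate-sorted SAM file with one @SQ line per reference
#' cluster, one @RG line per sample (SM field = sample), proper-pair flags
#' and an XG tag carrying the bisulfite strand ("CT" for OT, "GA" for OB).
#'
#' @param records alignment records from [align_pairs()] (must be sorted by
#'   cluster then start).
#' @param reference the named reference vector the records refer to.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, reference, path) {
  if (nrow(records)) {
    o <- order(records$cluster, records$start)
    if (!identical(o, seq_len(nrow(records))))
      stop("records must be sorted by cluster, then start")
  }
  ref_order <- sort(names(reference))
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", ref_order,
            nchar(reference[ref_order])),
    sprintf("@RG\tID:%s\tSM:%s", unique(records$sample),
            unique(records$sample)))
  lines <- header
  if (nrow(records)) {
    # mate coordinates looked up within each pair
    key <- paste(records$id, records$cluster)
    other <- match(paste(records$id, records$cluster), key)
    # match() finds self; build explicit partner index per id
    idx_by_id <- split(seq_len(nrow(records)), records$id)
    partner <- integer(nrow(records))
    for (ii in idx_by_id) {
      if (length(ii) == 2L) partner[ii] <- rev(ii) else partner[ii] <- ii
    }
    flag <- 1L + 2L +                      # paired, proper pair
      ifelse(records$reverse, 16L, 0L) +
      ifelse(records$reverse[partner], 32L, 0L) +
      ifelse(records$mate == 1L, 64L, 128L)
    tlen <- ifelse(records$start <= records$start[partner],
                   records$end[partner] - records$start + 1L,
                   -(records$end - records$start[partner] + 1L))
    xg <- ifelse(records$bisulfite_strand == "OT", "CT", "GA")
    lines <- c(lines, sprintf(
      "%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t%s\tRG:Z:%s\tXG:Z:%s",
      records$id, flag, records$cluster, records$start, records$mapq,
      records$cigar, records$start[partner], tlen, records$seq,
      records$qual, records$sample, xg))
  }
  writeLines(lines, path)
  invisible(path)
}
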