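# 3' adapter trimming and directional re-merge.
#
# Demultiplexed reads still carry, at the 3' end of short fragments, the
# reverse-complemented custom part of the opposite adapter (UMI + barcode +
# CN, 10 bp in the standard design) followed by the standard Illumina
# adapter. Trimming removes the Illumina adapter, the filled-in first base
# at the 5' end, and (where an adapter was found) a further hard-trimmed
# 10 bp covering the custom adapter part.

# Locate the 3' adapter start in each read: first exact occurrence of the
# full adapter, otherwise the longest read-suffix / adapter-prefix overlap
# (>= min_overlap) with at most 10% mismatches. Returns the 1-based cut
# position, or NA when no adapter is found.
adapter_cut_pos <- function(seqs, adapter, min_overlap = 3,
                            max_mismatch_frac = 0.1) {
  n <- length(seqs)
  cut <- rep(NA_integer_, n)
  if (!n) return(cut)
  hit <- regexpr(adapter, seqs, fixed = TRUE)
  cut[hit > 0L] <- as.integer(hit[hit > 0L])
  lens <- nchar(seqs)
  todo <- is.na(cut)
  alen <- nchar(adapter)
  for (o in rev(seq(min_overlap, min(alen, max(lens))))) {
    if (!any(todo)) break
    idx <- which(todo & lens >= o)
    if (!length(idx)) next
    sfx <- substring(seqs[idx], lens[idx] - o + 1L)
    mm <- mismatch_count_vec(sfx, substr(adapter, 1L, o))
    ok <- mm <= floor(max_mismatch_frac * o)
    cut[idx[ok]] <- lens[idx[ok]] - o + 1L
    todo[idx[ok]] <- FALSE
  }
  cut
}

#' Trim demultiplexed read pairs
#'
#' Per mate: (1) truncate at the detected Illumina adapter start; (2) remove
#' one base from the 5' end (the filled-in position); (3) if an adapter was
#' found, hard-trim a further `hard_trim` bases from the 3' end (the custom
#' adapter remnant); (4) drop the pair when either mate ends up shorter than
#' `min_len`.
#'
#' @param reads data.frame with `seq1`, `qual1`, `seq2`, `qual2` (plus any
#'   annotation columns, which are preserved).
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum read-suffix/adapter overlap to trim.
#' @param hard_trim extra 3' bases removed after adapter removal.
#' @param min_len minimum mate length after trimming.
#' @return list with `reads` (trimmed, dropped pairs removed) and `stats`
#'   (`input_pairs`, `adapter_trimmed_r1`, `adapter_trimmed_r2`,
#'   `dropped_short`).
#' @export
trim_reads <- function(reads, adapter = ILLUMINA_ADAPTER, min_overlap = 3,
                       hard_trim = 10, min_len = 20) {
  n <- nrow(reads)
  trim_mate <- function(seq, qual) {
    cut <- adapter_cut_pos(seq, adapter, min_overlap)
    end <- ifelse(is.na(cut), nchar(seq), cut - 1L)
    end <- ifelse(is.na(cut), end, pmax(end - hard_trim, 0L))
    seq <- substr(seq, 2L, end)
    qual <- substr(qual, 2L, end)
    list(seq = seq, qual = qual, trimmed = sum(!is.na(cut)))
  }
  m1 <- trim_mate(reads$seq1, reads$qual1)
  m2 <- trim_mate(reads$seq2, reads$qual2)
  keep <- nchar(m1$seq) >= min_len & nchar(m2$seq) >= min_len
  out <- reads
  out$seq1 <- m1$seq; out$qual1 <- m1$qual
  out$seq2 <- m2$seq; out$qual2 <- m2$qual
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out,
       stats = list(input_pairs = n,
                    adapter_trimmed_r1 = m1$trimmed,
                    adapter_trimmed_r2 = m2$trimmed,
                    dropped_short = sum(!keep)))
}

#' Re-merge Watson and Crick reads into a directional library
#'
#' Watson R1 and Crick R2 reads carry top-strand sequence; Watson R2 and
#' Crick R1 carry bottom-strand sequence. Combining them accordingly yields
#' a conventional directional mate-1/mate-2 pair of read sets.
#'
#' @param reads trimmed, strand-annotated pairs (columns `id`, `sample`,
#'   `strand`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @return list of two data.frames `mate1` and `mate2` (columns `id`,
#'   `sample`, `strand`, `seq`, `qual`), pairing preserved row-by-row.
#' @export
merge_directional <- function(reads) {
  stopifnot(all(c("strand", "seq1", "seq2") %in% names(reads)))
  if (any(is.na(reads$seq1)) || any(is.na(reads$seq2)))
    stop("unpaired reads: both mates are required for every id")
  bad <- !reads$strand %in% c("Watson", "Crick")
  if (any(bad)) stop("unknown strand label: ", reads$strand[which(bad)[1]])
  w <- reads$strand == "Watson"
  mate1 <- data.frame(
    id = reads$id, sample = reads$sample, strand = reads$strand,
    seq = ifelse(w, reads$seq1, reads$seq2),
    qual = ifelse(w, reads$qual1, reads$qual2),
    stringsAsFactors = FALSE)
  mate2 <- data.frame(
    id = reads$id, sample = reads$sample, strand = reads$strand,
    seq = ifelse(w, reads$seq2, reads$seq1),
    qual = ifelse(w, reads$qual2, reads$qual1),
    stringsAsFactors = FALSE)
  list(mate1 = mate1, mate2 = mate2)
}
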