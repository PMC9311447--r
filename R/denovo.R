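# De novo reconstruction of unconverted reference loci.
#
# Watson and Crick reads of one locus are fully converted on opposite
# strands: collapsing the conversion-confounded letter (three-letter
# encoding) makes reads of one strand class comparable, and collapsing both
# letters (binary encoding, alphabet {A,T}) makes Watson and Crick
# representations of one locus identical, which is what allows pairing them
# and reconstructing the original four-letter sequence.

#' Three-letter encode a sequence
#'
#' Watson reads are compared after C->T collapse; Crick reads (represented
#' in top-strand orientation) after G->A collapse.
#'
#' @param seq DNA string(s) over ACGTN.
#' @param strand_class `"WATSON"` or `"CRICK"`.
#' @return encoded string(s).
#' @export
three_letter_encode <- function(seq, strand_class = c("WATSON", "CRICK")) {
  strand_class <- match.arg(strand_class)
  if (strand_class == "WATSON") chartr("C", "T", seq) else chartr("G", "A", seq)
}

#' Binary encode a sequence (purines to A, pyrimidines to T)
#'
#' Applies C->T and G->A simultaneously; N is preserved. Watson and Crick
#' three-letter encodings of one locus share the same binary encoding.
#'
#' @param seq DNA string(s).
#' @return string(s) over A/T/N.
#' @export
binary_encode <- function(seq) {
  chartr("CG", "TA", seq)
}

#' Assemble or join a read pair
#'
#' If the 3' end of R1 overlaps the reverse complement of R2 (>=
#' `min_overlap` columns, <= `max_mismatch_frac` mismatches) the
#' overlap-consensus is emitted; read-through bases extending beyond the
#' other mate's fragment end (adapter sequence) are thereby excluded. Pairs
#' without a detectable overlap are joined with an 8-N spacer.
#'
#' @param r1,r2 character vectors of mate sequences (same length).
#' @param q1,q2 optional quality strings (mismatch columns take the
#'   higher-quality base; R1 wins ties).
#' @param min_overlap minimum overlap columns.
#' @param max_mismatch_frac maximum mismatch fraction inside the overlap.
#' @return character vector of assembled/joined sequences.
#' @export
assemble_or_join <- function(r1, r2, q1 = NULL, q2 = NULL,
                             min_overlap = 10, max_mismatch_frac = 0.1) {
  n <- length(r1)
  stopifnot(length(r2) == n)
  if (!n) return(character(0))
  rcr2 <- revcomp(r2)
  if (is.null(q1)) q1 <- strrep("I", nchar(r1))
  if (is.null(q2)) q2 <- strrep("I", nchar(r2))
  merge_pairs_cpp(r1, rcr2, q1, revstring(q2),
                  as.integer(min_overlap), max_mismatch_frac)
}

#' Deduplicate reads by three-letter encoding and build strand consensi
#'
#' Sequences (one strand class, top-strand orientation) are grouped by
#' identical three-letter encoding (equal length required). Per group the
#' consensus is the per-column majority over the original letters (ties
#' give N); groups outside `[min_depth, max_depth]` are discarded.
#'
#' @param sequences character vector of assembled sequences.
#' @param strand_class `"WATSON"` or `"CRICK"`.
#' @param min_depth,max_depth cluster depth bounds (inclusive).
#' @return data.frame with `encoded_key`, `consensus`, `depth`,
#'   `strand_class`, ordered by decreasing depth.
#' @export
dedup_consensus <- function(sequences, strand_class, min_depth = 10,
                            max_depth = 10000) {
  empty <- data.frame(encoded_key = character(0), consensus = character(0),
                      depth = integer(0), strand_class = character(0),
                      stringsAsFactors = FALSE)
  if (!length(sequences)) return(empty)
  enc <- three_letter_encode(sequences, strand_class)
  groups <- split(sequences, enc)
  depth <- lengths(groups)
  groups <- groups[depth >= min_depth & depth <= max_depth]
  if (!length(groups)) return(empty)
  cons <- vapply(groups, majority_consensus, character(1))
  out <- data.frame(encoded_key = names(groups), consensus = cons,
                    depth = as.integer(lengths(groups)),
                    strand_class = strand_class,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$depth, out$encoded_key), , drop = FALSE]
}

# per-column majority letter over ACGTN; ties give N
majority_consensus <- function(seqs) {
  if (length(seqs) == 1L) return(seqs)
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
              ncol = length(seqs))
  letters5 <- c("A", "C", "G", "T", "N")
  counts <- vapply(letters5, function(l) rowSums(m == l),
                   numeric(nrow(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  top <- apply(counts, 1, max)
  maj <- letters5[apply(counts, 1, which.max)]
  tied <- rowSums(counts == top) > 1L
  maj[tied] <- "N"
  paste(maj, collapse = "")
}

#' Pair Watson and Crick strand clusters by binary encoding
#'
#' Clusters whose binary encodings are identical are paired; when several
#' clusters share a key they are paired greedily by descending depth, and
#' leftovers stay unpaired.
#'
#' @param watson,crick data.frames from [dedup_consensus()] (Crick already
#'   in top-strand orientation).
#' @return list with `pairs` (data.frame: `watson`, `crick`, `watson_depth`,
#'   `crick_depth`) and `unpaired` (data.frame of leftover clusters).
#' @export
pair_watson_crick <- function(watson, crick) {
  # keys come from the encoded reads, not the majority consensus: the
  # consensus can hold N at methylation-tie columns, which the partner
  # strand resolves after pairing
  wkey <- binary_encode(watson$encoded_key)
  ckey <- binary_encode(crick$encoded_key)
  pairs <- list()
  used_c <- rep(FALSE, nrow(crick))
  used_w <- rep(FALSE, nrow(watson))
  for (key in unique(wkey)) {
    wi <- which(wkey == key)          # already depth-ordered
    ci <- which(ckey == key & !used_c)
    np <- min(length(wi), length(ci))
    if (np == 0L) next
    wi <- wi[seq_len(np)]; ci <- ci[seq_len(np)]
    used_w[wi] <- TRUE; used_c[ci] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      watson = watson$consensus[wi], crick = crick$consensus[ci],
      watson_depth = watson$depth[wi], crick_depth = crick$depth[ci],
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(watson = character(0), crick = character(0),
                           watson_depth = integer(0),
                           crick_depth = integer(0), stringsAsFactors = FALSE)
  unpaired <- rbind(
    watson[!used_w, c("consensus", "depth", "strand_class")],
    crick[!used_c, c("consensus", "depth", "strand_class")])
  rownames(pairs) <- rownames(unpaired) <- NULL
  list(pairs = pairs, unpaired = unpaired)
}

#' Reconstruct the unconverted consensus from a Watson/Crick pair
#'
#' Per column: equal letters are kept; Watson T with Crick C resolves to C
#' (the T was a converted cytosine); Watson G with Crick A resolves to G
#' (the A was a converted guanine on the bottom strand). An N on one side
#' takes the partner's letter unless that letter is conversion-ambiguous on
#' the partner's strand (T on Watson, A on Crick), in which case N is kept.
#' Any other disagreement gives N.
#'
#' @param watson_seq,crick_top_seq equal-length consensi, top-strand
#'   orientation.
#' @return reconstructed DNA string.
#' @export
reconstruct_consensus <- function(watson_seq, crick_top_seq) {
  w <- charToRaw(watson_seq); c <- charToRaw(crick_top_seq)
  stopifnot(length(w) == length(c))
  T_ <- charToRaw("T"); C_ <- charToRaw("C")
  G_ <- charToRaw("G"); A_ <- charToRaw("A"); N_ <- charToRaw("N")
  out <- rep(N_, length(w))
  eq <- w == c
  out[eq] <- w[eq]
  out[w == T_ & c == C_] <- C_
  out[w == G_ & c == A_] <- G_
  wn <- w == N_ & c != N_
  out[wn & c != A_] <- c[wn & c != A_]
  cn <- c == N_ & w != N_
  out[cn & w != T_] <- w[cn & w != T_]
  rawToChar(out)
}

#' Greedy centroid clustering of reconstructed consensi by identity
#'
#' Sequences are processed in descending total-depth order; each joins the
#' first centroid with pairwise identity >= `identity` (matches over
#' alignment columns, N never matching) or founds a new centroid. Centroids
#' are emitted N-padded (`NNNN` on both sides) as the reference.
#'
#' @param consensi data.frame with `sequence`, `watson_depth`,
#'   `crick_depth`.
#' @param identity identity threshold in (0, 1].
#' @return data.frame with `id`, `sequence` (padded), `watson_depth`,
#'   `crick_depth`, `members`, `length` (unpadded).
#' @export
cluster_identity <- function(consensi, identity = 0.99) {
  if (nrow(consensi) == 0L)
    return(data.frame(id = character(0), sequence = character(0),
                      watson_depth = integer(0), crick_depth = integer(0),
                      members = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  total <- consensi$watson_depth + consensi$crick_depth
  ord <- order(-total, consensi$sequence)
  consensi <- consensi[ord, , drop = FALSE]
  cent_seq <- character(0)
  cent_w <- integer(0); cent_c <- integer(0); cent_m <- integer(0)
  for (i in seq_len(nrow(consensi))) {
    s <- consensi$sequence[i]
    joined <- FALSE
    ls <- nchar(s)
    for (j in seq_along(cent_seq)) {
      lc <- nchar(cent_seq[j])
      # identity can never exceed the length ratio under global alignment
      if (min(ls, lc) / max(ls, lc) < identity) next
      if (pair_identity(s, cent_seq[j]) >= identity) {
        cent_w[j] <- cent_w[j] + consensi$watson_depth[i]
        cent_c[j] <- cent_c[j] + consensi$crick_depth[i]
        cent_m[j] <- cent_m[j] + 1L
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      cent_seq <- c(cent_seq, s)
      cent_w <- c(cent_w, consensi$watson_depth[i])
      cent_c <- c(cent_c, consensi$crick_depth[i])
      cent_m <- c(cent_m, 1L)
    }
  }
  data.frame(id = sprintf("cluster_%d", seq_along(cent_seq)),
             sequence = paste0("NNNN", cent_seq, "NNNN"),
             watson_depth = cent_w, crick_depth = cent_c,
             members = cent_m, length = nchar(cent_seq),
             stringsAsFactors = FALSE)
}

# global pairwise identity: matches / alignment columns, N never matches.
# Equal lengths compare column-wise; unequal lengths are globally aligned
# in compiled code.
pair_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == lb) return(match_columns(a, b) / la)
  global_identity_cpp(a, b)
}

#' Assemble mate pairs of both strand classes
#'
#' Runs [assemble_or_join()] per strand class and reverse-complements the
#' Crick results into top-strand orientation.
#'
#' @param reads demultiplexed reads (columns `seq1`, `qual1`, `seq2`,
#'   `qual2`, `strand`).
#' @param min_overlap assembly overlap minimum.
#' @return list with `watson` and `crick_top` character vectors.
#' @export
assemble_strands <- function(reads, min_overlap = 10) {
  w <- reads[reads$strand == "Watson", , drop = FALSE]
  k <- reads[reads$strand == "Crick", , drop = FALSE]
  list(watson = assemble_or_join(w$seq1, w$seq2, w$qual1, w$qual2,
                                 min_overlap = min_overlap),
       crick_top = revcomp(assemble_or_join(k$seq1, k$seq2, k$qual1,
                                            k$qual2,
                                            min_overlap = min_overlap)))
}

#' Build a de novo reference from demultiplexed, untrimmed reads
#'
#' Runs the full reconstruction: mate assembly per strand class (Crick
#' results reverse-complemented into top-strand orientation), three-letter
#' deduplication with depth bounds, binary Watson/Crick pairing, per-column
#' consensus reconstruction, and identity clustering with N-padding.
#'
#' @param reads demultiplexed reads of all samples (columns `seq1`, `qual1`,
#'   `seq2`, `qual2`, `strand`).
#' @param min_depth,max_depth dedup depth bounds.
#' @param identity identity-clustering threshold.
#' @param min_overlap assembly overlap minimum.
#' @param keep_unpaired emit unpaired strand clusters with
#'   conversion-ambiguous positions set to N.
#' @param assembled optional result of [assemble_strands()]; lets parameter
#'   sweeps over the clustering stage reuse one assembly.
#' @return list with `reference` (named character vector of padded cluster
#'   sequences), `clusters` (per-cluster stats) and `stats` (assembly and
#'   pairing tallies).
#' @export
build_reference <- function(reads, min_depth = 10, max_depth = 10000,
                            identity = 0.99, min_overlap = 10,
                            keep_unpaired = FALSE, assembled = NULL) {
  if (is.null(assembled))
    assembled <- assemble_strands(reads, min_overlap = min_overlap)
  asm_w <- assembled$watson
  asm_c <- assembled$crick_top
  wc <- dedup_consensus(asm_w, "WATSON", min_depth, max_depth)
  cc <- dedup_consensus(asm_c, "CRICK", min_depth, max_depth)
  paired <- pair_watson_crick(wc, cc)
  recon <- data.frame(
    sequence = mapply(reconstruct_consensus, paired$pairs$watson,
                      paired$pairs$crick, USE.NAMES = FALSE),
    watson_depth = paired$pairs$watson_depth,
    crick_depth = paired$pairs$crick_depth,
    stringsAsFactors = FALSE)
  if (keep_unpaired && nrow(paired$unpaired)) {
    up <- paired$unpaired
    masked <- ifelse(up$strand_class == "WATSON",
                     chartr("T", "N", three_letter_encode(up$consensus, "WATSON")),
                     chartr("A", "N", three_letter_encode(up$consensus, "CRICK")))
    recon <- rbind(recon, data.frame(
      sequence = masked,
      watson_depth = ifelse(up$strand_class == "WATSON", up$depth, 0L),
      crick_depth = ifelse(up$strand_class == "CRICK", up$depth, 0L),
      stringsAsFactors = FALSE))
  }
  clusters <- cluster_identity(recon, identity = identity)
  reference <- setNames(clusters$sequence, clusters$id)
  list(reference = reference, clusters = clusters,
       stats = list(watson_pairs_assembled = length(asm_w),
                    crick_pairs_assembled = length(asm_c),
                    watson_strand_clusters = nrow(wc),
                    crick_strand_clusters = nrow(cc),
                    paired_clusters = nrow(paired$pairs),
                    unpaired_clusters = nrow(paired$unpaired),
                    final_clusters = nrow(clusters)))
}
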