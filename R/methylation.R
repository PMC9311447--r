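# Per-cytosine methylation calling from strand-tagged alignments.
#
# OT reads are informative for top-strand cytosines (read C = methylated,
# read T = unmethylated at reference C positions); OB reads for
# bottom-strand cytosines (read G / read A at reference G positions).
# Overlapping mate positions are counted once, from mate 1.

# per-record base calls restricted to informative reference positions
informative_calls <- function(records, reference) {
  if (nrow(records) == 0L)
    return(data.table::data.table(sample = character(0),
      cluster = character(0), pos = integer(0), strand = character(0),
      base = character(0), mate = integer(0), id = character(0),
      reverse = logical(0), start = integer(0), end = integer(0),
      qual = integer(0)))
  cpos <- lapply(reference, function(s) {
    ch <- strsplit(s, "")[[1]]
    list(C = which(ch == "C"), G = which(ch == "G"))
  })
  n <- nrow(records)
  pos_l <- vector("list", n)
  base_l <- vector("list", n)
  qual_l <- vector("list", n)
  nper <- integer(n)
  for (i in seq_len(n)) {
    want <- if (records$bisulfite_strand[i] == "OT") "C" else "G"
    p <- cpos[[records$cluster[i]]][[want]]
    p <- p[p >= records$start[i] & p <= records$end[i]]
    nper[i] <- length(p)
    if (!length(p)) next
    off <- p - records$start[i] + 1L
    ch <- charToRaw(records$seq[i])[off]
    pos_l[[i]] <- p
    base_l[[i]] <- rawToChar(ch, multiple = TRUE)
    qual_l[[i]] <- as.integer(charToRaw(records$qual[i])[off]) - 33L
  }
  ri <- rep.int(seq_len(n), nper)
  data.table::data.table(
    sample = records$sample[ri], cluster = records$cluster[ri],
    pos = unlist(pos_l, use.names = FALSE),
    strand = ifelse(records$bisulfite_strand[ri] == "OT", "+", "-"),
    base = unlist(base_l, use.names = FALSE),
    mate = records$mate[ri], id = records$id[ri],
    reverse = records$reverse[ri], start = records$start[ri],
    end = records$end[ri],
    qual = unlist(qual_l, use.names = FALSE))
}

#' Call per-cytosine methylation
#'
#' Counts methylated and unmethylated observations at every covered
#' cytosine of both reference strands, resolving mate overlap in favour of
#' mate 1 and annotating each site with its CG/CHG/CHH context derived from
#' the reference. Positions inside the N padding carry no C/G and are never
#' reported.
#'
#' @param records alignment records from [align_pairs()].
#' @param reference named reference vector.
#' @param min_base_qual minimum base quality for a call (0 disables).
#' @return data.frame with `sample`, `cluster`, `pos`, `strand`,
#'   `count_methylated`, `count_unmethylated`, `context`, `trinucleotide`.
#' @export
call_methylation <- function(records, reference, min_base_qual = 0) {
  missing_ref <- setdiff(unique(records$cluster), names(reference))
  if (length(missing_ref))
    stop("alignments reference absent sequences: ",
         paste(head(missing_ref), collapse = ", "))
  calls <- informative_calls(records, reference)
  if (nrow(calls) == 0L)
    return(data.frame(sample = character(0), cluster = character(0),
                      pos = integer(0), strand = character(0),
                      count_methylated = integer(0),
                      count_unmethylated = integer(0),
                      context = character(0), trinucleotide = character(0),
                      stringsAsFactors = FALSE))
  if (min_base_qual > 0) calls <- calls[calls$qual >= min_base_qual, ]
  # no-overlap rule: a (pair, position) covered by both mates counts once,
  # from mate 1
  data.table::setorder(calls, id, cluster, pos, mate)
  calls <- calls[!duplicated(calls[, c("id", "cluster", "pos")]), ]

  meth_base <- ifelse(calls$strand == "+", "C", "G")
  unmeth_base <- ifelse(calls$strand == "+", "T", "A")
  calls$m <- as.integer(calls$base == meth_base)
  calls$u <- as.integer(calls$base == unmeth_base)
  calls <- calls[calls$m + calls$u > 0L, ]   # other letters ignored

  agg <- calls[, list(count_methylated = sum(m), count_unmethylated = sum(u)),
               by = c("sample", "cluster", "pos", "strand")]
  data.table::setorder(agg, sample, cluster, pos, strand)

  # annotate context from the reference
  ctx <- data.table::rbindlist(lapply(names(reference), function(cl) {
    cc <- cytosine_contexts(reference[[cl]])
    cc$cluster <- cl
    cc
  }))
  merged <- merge(agg, ctx, by = c("cluster", "pos", "strand"),
                  all.x = TRUE, sort = FALSE)
  out <- as.data.frame(merged[, c("sample", "cluster", "pos", "strand",
                                  "count_methylated", "count_unmethylated",
                                  "context", "trinucleotide")])
  out <- out[order(out$sample, out$cluster, out$pos, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Write a CX-style cytosine report
#'
#' One tab-separated line per covered cytosine:
#' cluster, position, strand, methylated count, unmethylated count,
#' context, trinucleotide.
#'
#' @param records data.frame from [call_methylation()] (a single sample).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(records, path) {
  records <- records[order(records$cluster, records$pos), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s",
                   records$cluster, records$pos, records$strand,
                   records$count_methylated, records$count_unmethylated,
                   records$context, records$trinucleotide)
  writeLines(lines, path)
  invisible(path)
}

#' Read a CX report written by [write_cx_report()]
#'
#' @param path CX report path.
#' @return data.frame with the CX columns.
#' @export
read_cx_report <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("cluster", "pos", "strand",
                                 "count_methylated", "count_unmethylated",
                                 "context", "trinucleotide"))
  df
}

#' Per-cycle methylation fractions (M-bias)
#'
#' Computes the fraction of methylated calls at each read cycle (position
#' within the sequenced read), separately per mate and context.
#'
#' @param records alignment records from [align_pairs()].
#' @param reference named reference vector.
#' @return data.frame with `mate`, `context`, `cycle`, `n_meth`,
#'   `n_unmeth`, `fraction_methylated`.
#' @export
mbias <- function(records, reference) {
  calls <- informative_calls(records, reference)
  if (nrow(calls) == 0L)
    return(data.frame(mate = integer(0), context = character(0),
                      cycle = integer(0), n_meth = integer(0),
                      n_unmeth = integer(0),
                      fraction_methylated = numeric(0)))
  data.table::setorder(calls, id, cluster, pos, mate)
  calls <- calls[!duplicated(calls[, c("id", "cluster", "pos")]), ]
  calls$cycle <- ifelse(calls$reverse, calls$end - calls$pos + 1L,
                        calls$pos - calls$start + 1L)
  meth_base <- ifelse(calls$strand == "+", "C", "G")
  unmeth_base <- ifelse(calls$strand == "+", "T", "A")
  calls$m <- as.integer(calls$base == meth_base)
  calls$u <- as.integer(calls$base == unmeth_base)
  calls <- calls[calls$m + calls$u > 0L, ]
  ctx <- data.table::rbindlist(lapply(names(reference), function(cl) {
    cc <- cytosine_contexts(reference[[cl]])
    cc$cluster <- cl
    cc
  }))
  calls <- merge(calls, ctx, by = c("cluster", "pos", "strand"), sort = FALSE)
  agg <- calls[, list(n_meth = sum(m), n_unmeth = sum(u)),
               by = c("mate", "context", "cycle")]
  agg$fraction_methylated <- agg$n_meth / (agg$n_meth + agg$n_unmeth)
  out <- as.data.frame(agg)
  out <- out[order(out$mate, out$context, out$cycle), ]
  rownames(out) <- NULL
  out
}
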