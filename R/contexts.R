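# Cytosine context annotation shared by the simulator (truth methylomes) and
# the methylation caller (reference-derived context of each reported site).

#' Enumerate cytosines of both strands with sequence context
#'
#' Lists every cytosine of the top strand (`+`, a `C` in `seq`) and of the
#' bottom strand (`-`, a `G` in `seq`), classified as CG, CHG or CHH from the
#' reference sequence. Context that runs off the end of the sequence, or into
#' `N`s, is classified CHH with `N` in the trinucleotide (the true context is
#' unknowable there).
#'
#' @param seq a single DNA string (may contain N).
#' @return data.frame with columns `pos` (1-based), `strand` (`+`/`-`),
#'   `context`, `trinucleotide`.
#' @export
cytosine_contexts <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  at <- function(i) ifelse(i >= 1 & i <= L, chars[pmax(pmin(i, L), 1)], "N")

  out <- list()
  cpos <- which(chars == "C")
  if (length(cpos)) {
    n1 <- at(cpos + 1L); n2 <- at(cpos + 2L)
    ctx <- ifelse(n1 == "G", "CG",
           ifelse(n1 %in% c("A", "C", "T") & n2 == "G", "CHG", "CHH"))
    out$plus <- data.frame(pos = cpos, strand = "+", context = ctx,
                           trinucleotide = paste0("C", n1, n2),
                           stringsAsFactors = FALSE)
  }
  gpos <- which(chars == "G")
  if (length(gpos)) {
    n1 <- at(gpos - 1L); n2 <- at(gpos - 2L)
    ctx <- ifelse(n1 == "C", "CG",
           ifelse(n1 %in% c("A", "G", "T") & n2 == "C", "CHG", "CHH"))
    # trinucleotide reported on the strand carrying the cytosine
    out$minus <- data.frame(pos = gpos, strand = "-", context = ctx,
                            trinucleotide = paste0("C",
                              chartr("ACGTN", "TGCAN", n1),
                              chartr("ACGTN", "TGCAN", n2)),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(pos = integer(0), strand = character(0),
                      context = character(0), trinucleotide = character(0),
                      stringsAsFactors = FALSE)
  res <- res[order(res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
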