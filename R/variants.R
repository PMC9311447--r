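# Double-masked SNP calling.
#
# Bisulfite conversion makes C/T (on OT reads, at reference C) and G/A (on
# OB reads, at reference G) uninformative for variants. Double masking
# rewrites those read states to the reference base, so that variant
# evidence at cytosine positions can only come from the opposite strand;
# a per-site diploid maximum-likelihood caller then genotypes each sample.

#' Double-mask strand-tagged alignments
#'
#' For OT records, read bases C or T over a reference C become C; for OB
#' records, read bases G or A over a reference G become G. Qualities are
#' kept (masking changes identity only); every other column is untouched.
#'
#' @param records alignment records from [align_pairs()].
#' @param reference named reference vector.
#' @param alt_masking additionally null (to N) the conversion-ambiguous
#'   observations the reference-base rule does not cover: an OT read's T
#'   over a non-C reference base could be a converted alternate C, and an
#'   OB read's A over a non-G reference base a converted alternate G, so
#'   neither can testify to the identity of an alternate allele; the
#'   opposite strand carries that information unambiguously.
#' @return the records with masked `seq`.
#' @export
double_mask <- function(records, reference, alt_masking = TRUE) {
  if (nrow(records) == 0L) return(records)
  if (is.null(records$bisulfite_strand) ||
      any(is.na(records$bisulfite_strand)))
    stop("records must carry a bisulfite_strand tag")
  refraw <- lapply(reference, charToRaw)
  C_ <- charToRaw("C"); T_ <- charToRaw("T")
  G_ <- charToRaw("G"); A_ <- charToRaw("A"); N_ <- charToRaw("N")
  for (i in seq_len(nrow(records))) {
    ot <- records$bisulfite_strand[i] == "OT"
    rr <- refraw[[records$cluster[i]]][records$start[i]:records$end[i]]
    sr <- charToRaw(records$seq[i])
    if (ot) {
      hit <- which(rr == C_ & (sr == C_ | sr == T_))
      if (length(hit)) sr[hit] <- C_
      if (alt_masking) {
        amb <- which(rr != C_ & sr == T_)
        if (length(amb)) sr[amb] <- N_
      }
    } else {
      hit <- which(rr == G_ & (sr == G_ | sr == A_))
      if (length(hit)) sr[hit] <- G_
      if (alt_masking) {
        amb <- which(rr != G_ & sr == A_)
        if (length(amb)) sr[amb] <- N_
      }
    }
    records$seq[i] <- rawToChar(sr)
  }
  records
}

# log10 genotype likelihood of observed bases under a symmetric error model
# P(b | a) = 1 - eps if b == a else eps / 3
genotype_loglik <- function(bases, eps, a1, a2) {
  p1 <- ifelse(bases == a1, 1 - eps, eps / 3)
  p2 <- ifelse(bases == a2, 1 - eps, eps / 3)
  sum(log10(0.5 * p1 + 0.5 * p2))
}

#' Call diploid SNVs from masked alignments
#'
#' Per column, observations failing the base- and mapping-quality
#' thresholds are excluded; per sample a diploid maximum-likelihood
#' genotype (uniform prior over genotypes) is computed under a symmetric
#' sequencing-error model, with GQ the phred difference between the best
#' and second-best genotype. QUAL is the phred-scaled probability that all
#' samples are homozygous reference (capped at 3000); sites with QUAL > 0
#' and at least one non-reference allele are emitted.
#'
#' @param records masked alignment records (see [double_mask()]).
#' @param reference named reference vector.
#' @param min_coverage minimum site coverage to process a site.
#' @param min_base_qual exclude observations below this base quality.
#' @param min_map_qual exclude observations below this mapping quality.
#' @return data.frame with `cluster`, `pos`, `ref`, `alt`
#'   (comma-separated), `qual`, and per sample `genotype` (`0/0`-style),
#'   `gq`, `depth` nested as list-columns `genotypes`, `gqs`, `depths`
#'   keyed by sample name; plus a flat per-sample long table in
#'   `attr(, "sample_calls")`.
#' @export
call_variants <- function(records, reference, min_coverage = 0,
                          min_base_qual = 1, min_map_qual = 10) {
  empty <- variant_empty()
  if (nrow(records) == 0L) return(empty)
  if (is.null(records$sample) || any(is.na(records$sample)))
    stop("records must carry a sample (read group)")
  records <- records[records$mapq >= min_map_qual, , drop = FALSE]
  if (nrow(records) == 0L) return(empty)

  # candidate sites: columns with at least one non-reference observation
  # (all other columns cannot yield a non-reference allele or QUAL > 0)
  cand <- list()
  for (i in seq_len(nrow(records))) {
    refseg <- charToRaw(substr(reference[[records$cluster[i]]],
                               records$start[i], records$end[i]))
    sr <- charToRaw(records$seq[i])
    mm <- which(sr != refseg)
    if (length(mm)) {
      # N on either side is no variant evidence
      n_ <- charToRaw("N")
      mm <- mm[sr[mm] != n_ & refseg[mm] != n_]
      if (length(mm))
        cand[[length(cand) + 1L]] <- data.frame(
          cluster = records$cluster[i], pos = records$start[i] + mm - 1L,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty)
  sites <- unique(do.call(rbind, cand))
  sites <- sites[order(sites$cluster, sites$pos), , drop = FALSE]

  samples <- sort(unique(records$sample))
  out <- vector("list", nrow(sites))
  for (si in seq_len(nrow(sites))) {
    cl <- sites$cluster[si]; p <- sites$pos[si]
    ref_base <- substr(reference[[cl]], p, p)
    cover <- which(records$cluster == cl & records$start <= p &
                   records$end >= p)
    if (length(cover) < min_coverage) next
    off <- p - records$start[cover] + 1L
    bases <- substring(records$seq[cover], off, off)
    bq <- as.integer(vapply(seq_along(cover), function(j)
      charToRaw(records$qual[cover[j]])[off[j]], raw(1))) - 33L
    # no-overlap handling: count each (pair, position) once, mate 1 first
    o <- order(records$id[cover], records$mate[cover])
    keep1 <- !duplicated(records$id[cover][o])
    sel <- o[keep1]
    bases <- bases[sel]; bq <- bq[sel]
    smp <- records$sample[cover][sel]
    ok <- bq >= min_base_qual & bases %in% c("A", "C", "G", "T")
    bases <- bases[ok]; bq <- bq[ok]; smp <- smp[ok]
    if (!length(bases)) next
    alts <- setdiff(names(sort(table(bases), decreasing = TRUE)), ref_base)
    if (!length(alts)) next
    alleles <- c(ref_base, alts)
    gts <- expand.grid(a1 = seq_along(alleles), a2 = seq_along(alleles))
    gts <- gts[gts$a1 <= gts$a2, , drop = FALSE]

    gt_s <- character(length(samples)); gq_s <- integer(length(samples))
    dp_s <- integer(length(samples)); p00 <- numeric(length(samples))
    any_nonref <- FALSE
    for (k in seq_along(samples)) {
      bi <- smp == samples[k]
      dp_s[k] <- sum(bi)
      if (!any(bi)) { gt_s[k] <- "./."; gq_s[k] <- 0L; p00[k] <- 0; next }
      eps <- pmax(10^(-bq[bi] / 10), 1e-10)
      ll <- vapply(seq_len(nrow(gts)), function(g)
        genotype_loglik(bases[bi], eps, alleles[gts$a1[g]],
                        alleles[gts$a2[g]]), numeric(1))
      o2 <- order(ll, decreasing = TRUE)
      best <- o2[1]
      gt_s[k] <- paste0(gts$a1[best] - 1L, "/", gts$a2[best] - 1L)
      gq_s[k] <- as.integer(round(pmin(10 * (ll[best] - ll[o2[2]]), 99)))
      if (gt_s[k] != "0/0") any_nonref <- TRUE
      # posterior of hom-ref under a uniform genotype prior
      lmax <- max(ll)
      p00[k] <- -10 * (ll[1] - lmax - log10(sum(10^(ll - lmax))))
      # note: gts row 1 is (1,1) = hom-ref by construction of expand.grid
    }
    qual <- min(sum(p00), 3000)
    if (qual <= 0 || !any_nonref) next
    out[[si]] <- data.frame(
      cluster = cl, pos = p, ref = ref_base,
      alt = paste(alts, collapse = ","), qual = qual,
      genotypes = I(list(setNames(gt_s, samples))),
      gqs = I(list(setNames(gq_s, samples))),
      depths = I(list(setNames(dp_s, samples))),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

variant_empty <- function() {
  data.frame(cluster = character(0), pos = integer(0), ref = character(0),
             alt = character(0), qual = numeric(0),
             genotypes = I(list()), gqs = I(list()), depths = I(list()),
             stringsAsFactors = FALSE)
}

#' Keep single-nucleotide substitutions only
#'
#' @param records variant records (`ref`, `alt` columns; `alt` may be
#'   comma-separated).
#' @return records whose ref and every alt allele are single bases.
#' @export
filter_snps <- function(records) {
  if (nrow(records) == 0L) return(records)
  alt_ok <- vapply(strsplit(records$alt, ","), function(a)
    all(nchar(a) == 1L), logical(1))
  out <- records[nchar(records$ref) == 1L & alt_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write variant records as VCF 4.2
#'
#' One multi-sample VCF with FORMAT GT:GQ:DP, contig headers for the
#' reference and one genotype column per sample.
#'
#' @param records variant records from [call_variants()] (sorted).
#' @param samples sample names (column order).
#' @param reference named reference vector (contig lengths).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, samples, reference, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsgbs",
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            nchar(reference)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  lines <- header
  if (nrow(records)) {
    gt_cols <- vapply(seq_len(nrow(records)), function(i) {
      g <- records$genotypes[[i]][samples]
      gq <- records$gqs[[i]][samples]
      dp <- records$depths[[i]][samples]
      paste(sprintf("%s:%d:%d", g, gq, dp), collapse = "\t")
    }, character(1))
    lines <- c(lines, sprintf(
      "%s\t%d\t.\t%s\t%s\t%.2f\tPASS\t.\tGT:GQ:DP\t%s",
      records$cluster, records$pos, records$ref, records$alt,
      records$qual, gt_cols))
  }
  writeLines(lines, path)
  invisible(path)
}
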