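# Benchmarking utilities: cluster-vs-truth statistics, precision/
# sensitivity sweeps over variant quality (with squash-ploidy and
# both-strand filtering), CpG destranding, coverage-filtered methylation
# correlation and Ward clustering of samples.

#' Compare reconstructed clusters against true loci
#'
#' Strips the N padding from each cluster and matches it against every true
#' locus; a cluster is uniquely matched when exactly one locus achieves the
#' best full-length agreement. Mean mismatches are reported over matched
#' clusters.
#'
#' @param clusters cluster data.frame from [cluster_identity()] /
#'   [build_reference()] (`sequence` column, N-padded) or a named character
#'   vector of padded sequences.
#' @param loci true locus data.frame (`sequence` column) or character
#'   vector.
#' @return list with `n_clusters`, `fraction_uniquely_matched`,
#'   `mean_mismatches`.
#' @export
cluster_truth_stats <- function(clusters, loci) {
  cseq <- if (is.data.frame(clusters)) clusters$sequence else clusters
  lseq <- if (is.data.frame(loci)) loci$sequence else loci
  cseq <- gsub("^N+|N+$", "", cseq)
  if (!length(cseq))
    return(list(n_clusters = 0L, fraction_uniquely_matched = 0,
                mean_mismatches = 0))
  matched <- logical(length(cseq))
  mism <- rep(NA_real_, length(cseq))
  llen <- nchar(lseq)
  for (i in seq_along(cseq)) {
    same_len <- which(llen == nchar(cseq[i]))
    if (!length(same_len)) next
    d <- vapply(lseq[same_len], hamming, numeric(1), a = cseq[i],
                USE.NAMES = FALSE)
    best <- min(d)
    if (sum(d == best) == 1L) {
      matched[i] <- TRUE
      mism[i] <- best
    }
  }
  list(n_clusters = length(cseq),
       fraction_uniquely_matched = mean(matched),
       mean_mismatches = if (any(matched)) mean(mism[matched]) else 0)
}

#' Decompose variant records into per-sample allele rows
#'
#' Expands multiallelic records into one row per alternate allele and
#' re-expresses the chosen sample's genotype relative to that allele
#' (`0/1`, `1/1`, or `0/0` when the sample carries other alleles only).
#'
#' @param records variant records from [call_variants()].
#' @param sample sample name.
#' @return data.frame with `cluster`, `pos`, `ref`, `alt`, `genotype`,
#'   `qual`; rows where the sample carries no copy of the allele are
#'   dropped.
#' @export
decompose_variants <- function(records, sample) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    alts <- strsplit(records$alt[i], ",")[[1]]
    gt <- records$genotypes[[i]][[sample]]
    if (is.null(gt) || gt %in% c("./.", "0/0")) next
    al <- as.integer(strsplit(gt, "/")[[1]])
    for (j in seq_along(alts)) {
      copies <- sum(al == j)
      if (copies == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        cluster = records$cluster[i], pos = records$pos[i],
        ref = records$ref[i], alt = alts[j],
        genotype = if (copies == 2L) "1/1" else "0/1",
        qual = records$qual[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cluster = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      genotype = character(0), qual = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Precision-sensitivity sweep over variant quality
#'
#' At each quality threshold, a call is a true positive when a baseline
#' record exists at the same position with the same alternate allele (and,
#' unless `squash_ploidy`, the same genotype). Precision is TP / (TP + FP)
#' and sensitivity TP / (TP + FN), with FN the baseline records unmatched
#' by calls at or above the threshold.
#'
#' @param calls data.frame of decomposed calls (`cluster`, `pos`, `alt`,
#'   `genotype`, `qual`).
#' @param baseline data.frame of baseline records (`cluster`, `pos`,
#'   `alt`, `genotype`).
#' @param squash_ploidy ignore genotype agreement (allele-level match).
#' @param qual_grid thresholds; default 0 plus every distinct call quality.
#' @return data.frame with `qual_threshold`, `tp`, `fp`, `fn`, `precision`,
#'   `sensitivity`.
#' @export
pr_curve <- function(calls, baseline, squash_ploidy = FALSE,
                     qual_grid = NULL) {
  if (nrow(baseline) == 0L) stop("empty baseline set")
  if (is.null(qual_grid))
    qual_grid <- sort(unique(c(0, calls$qual)))
  bkey <- paste(baseline$cluster, baseline$pos, baseline$alt)
  bfull <- paste(bkey, baseline$genotype)
  out <- lapply(qual_grid, function(q) {
    sel <- calls$qual >= q
    ckey <- paste(calls$cluster[sel], calls$pos[sel], calls$alt[sel])
    cfull <- paste(ckey, calls$genotype[sel])
    if (squash_ploidy) {
      tp_call <- ckey %in% bkey
      matched_base <- bkey %in% ckey
    } else {
      tp_call <- cfull %in% bfull
      matched_base <- bfull %in% cfull
    }
    tp <- sum(tp_call); fp <- sum(!tp_call); fn <- sum(!matched_base)
    data.frame(qual_threshold = q, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               sensitivity = tp / (tp + fn))
  })
  do.call(rbind, out)
}

#' Keep baseline positions covered by both bisulfite strands
#'
#' @param baseline data.frame with `cluster`, `pos`.
#' @param records alignment records (strand-tagged).
#' @return the baseline rows with at least one OT and one OB observation.
#' @export
both_strand_filter <- function(baseline, records) {
  if (nrow(baseline) == 0L || nrow(records) == 0L)
    return(baseline[integer(0), , drop = FALSE])
  keep <- vapply(seq_len(nrow(baseline)), function(i) {
    cov <- records$cluster == baseline$cluster[i] &
      records$start <= baseline$pos[i] & records$end >= baseline$pos[i]
    any(records$bisulfite_strand[cov] == "OT") &&
      any(records$bisulfite_strand[cov] == "OB")
  }, logical(1))
  out <- baseline[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Destrand CpG methylation counts
#'
#' Combines the two cytosines of a CpG dinucleotide: the + strand C at
#' position p and the - strand C at p + 1 merge into one record at p with
#' summed counts.
#'
#' @param records CG-context cytosine records (as from
#'   [call_methylation()]; a `sample` column is respected if present).
#' @return combined records with `count_methylated`,
#'   `count_unmethylated` and coordinate `pos`.
#' @export
destrand_cpg <- function(records) {
  if (nrow(records) && any(records$context != "CG"))
    stop("destranding applies to CG-context records only")
  if (!"sample" %in% names(records)) records$sample <- "all"
  anchor <- ifelse(records$strand == "+", records$pos, records$pos - 1L)
  agg <- aggregate(
    cbind(count_methylated, count_unmethylated) ~ sample + cluster + anchor,
    data = transform(records, anchor = anchor), FUN = sum)
  names(agg)[names(agg) == "anchor"] <- "pos"
  agg$context <- "CG"
  agg <- agg[order(agg$sample, agg$cluster, agg$pos), ]
  rownames(agg) <- NULL
  agg
}

#' Coverage-filtered methylation correlation
#'
#' Restricts two per-site methylation sets to shared sites meeting the
#' coverage threshold in both, then reports the coefficient of
#' determination of the least-squares fit of `set_b` proportions on
#' `set_a` proportions. With `aggregate_by_group = TRUE`, counts of all
#' samples in a set are summed per site first (a coverage-weighted average
#' proportion) and the required total coverage is `min_cov` times the
#' number of samples.
#'
#' @param set_a,set_b data.frames with `cluster`, `pos`,
#'   `count_methylated`, `count_unmethylated` (and `sample` when
#'   per-sample).
#' @param min_cov minimum per-sample coverage.
#' @param aggregate_by_group sum counts across samples per site.
#' @return list with `r_squared`, `n_sites`, `fit` (the `lm` object).
#' @export
methylation_r2 <- function(set_a, set_b, min_cov = 10,
                           aggregate_by_group = FALSE) {
  prep <- function(x) {
    if (aggregate_by_group && "sample" %in% names(x)) {
      ns <- length(unique(x$sample))
      x <- aggregate(cbind(count_methylated, count_unmethylated) ~
                       cluster + pos, data = x, FUN = sum)
      need <- min_cov * ns
    } else {
      need <- min_cov
      if ("sample" %in% names(x) && length(unique(x$sample)) > 1L)
        stop("multiple samples in a non-aggregated set")
    }
    x$coverage <- x$count_methylated + x$count_unmethylated
    x <- x[x$coverage >= need, , drop = FALSE]
    x$p <- x$count_methylated / x$coverage
    x$key <- paste(x$cluster, x$pos)
    x
  }
  a <- prep(set_a); b <- prep(set_b)
  shared <- intersect(a$key, b$key)
  if (length(shared) < 2L)
    stop("fewer than 2 shared sites after coverage filtering")
  pa <- a$p[match(shared, a$key)]
  pb <- b$p[match(shared, b$key)]
  fit <- lm(pb ~ pa)
  # R^2 from the fit's residuals (identical to summary()'s value, without
  # the perfect-fit warning on exact data)
  ss_tot <- sum((pb - mean(pb))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot
        else NaN
  list(r_squared = r2, n_sites = length(shared), fit = fit)
}

#' Ward clustering of samples
#'
#' Agglomerative clustering under Ward's minimum-variance criterion
#' (`hclust` method `ward.D2`) on correlation (1 - Pearson) or Euclidean
#' distances between sample feature vectors (methylation proportions or
#' genotype dosages).
#'
#' @param mat numeric matrix, samples in rows.
#' @param distance `"correlation"` or `"euclidean"`.
#' @return an `hclust` merge tree.
#' @export
ward_clusters <- function(mat, distance = c("correlation", "euclidean")) {
  distance <- match.arg(distance)
  if (nrow(mat) < 2L) stop("at least 2 samples required")
  if (distance == "correlation") {
    sds <- apply(mat, 1, stats::sd)
    if (any(sds == 0))
      stop("constant feature rows: correlation distance undefined")
    d <- stats::as.dist(1 - cor(t(mat)))
  } else {
    d <- dist(mat)
  }
  hclust(d, method = "ward.D2")
}

#' Export a merge tree as Newick text
#'
#' @param hc an `hclust` object from [ward_clusters()].
#' @param path optional output file.
#' @return the Newick string, invisibly when written to `path`.
#' @export
tree_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Baseline variant records from simulator truth
#'
#' @param truth a `bsgbs_truth`.
#' @param sample sample name.
#' @return data.frame with `cluster` (locus id), `pos`, `ref`, `alt`,
#'   `genotype` for the sample's non-reference genotypes.
#' @export
truth_variants <- function(truth, sample) {
  g <- truth$genotypes
  g <- g[g$sample == sample & g$genotype != "0/0", , drop = FALSE]
  data.frame(cluster = g$locus, pos = g$pos, ref = g$ref, alt = g$alt,
             genotype = g$genotype, stringsAsFactors = FALSE)
}
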