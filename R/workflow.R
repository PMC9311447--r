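# Pipeline orchestration: demux -> trim -> (de novo | reference) -> align
# -> methylation -> variants -> report, with per-stage outputs that can be
# reused independently.

#' Read a flat key=value configuration file
#'
#' Lines of the form `key=value`; `#` starts a comment. Values that parse
#' as numbers are coerced; comma-separated values become vectors.
#'
#' @param path config file.
#' @return named list.
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (grepl(",", val)) val <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    if (all(!is.na(num))) val <- num
    out[[key]] <- val
  }
  out
}

pipeline_defaults <- function() {
  list(mode = "denovo", enzymes = c("MspI", "NsiI"),
       mismatches_r1 = 0, mismatches_r2 = 0,
       rescue = "any_single_mismatch",
       adapter = ILLUMINA_ADAPTER, min_len = 20, hard_trim = 10,
       min_depth = 10, max_depth = 10000, identity = 0.99,
       min_score_frac = 0.6, umi_length = 3,
       min_base_qual = 1, min_map_qual = 10)
}

#' Run the full pipeline
#'
#' Executes demultiplexing (with clone removal), trimming, reference
#' construction (de novo mode) or loading (reference mode), alignment,
#' methylation calling and SNP calling, writing each stage's outputs under
#' `out_dir`. Completed stages (detected by their `.done` markers) are
#' skipped unless `force = TRUE`.
#'
#' @param config named list or path to a flat key=value file. Required
#'   keys: `r1`, `r2` (FASTQ paths), `barcodes` (TSV:
#'   sample/barcode_R1/barcode_R2). Optional: `mode`
#'   (`denovo`/`reference`), `reference` (FASTA, reference mode),
#'   `enzymes`, `min_depth`, `max_depth`, `identity`, and the other
#'   [pipeline_defaults()] entries.
#' @param out_dir output directory.
#' @param force rerun completed stages.
#' @return list with the stage results (`demux`, `trim`, `reference`,
#'   `align`, `methylation`, `variants`, `report`).
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- read_flat_config(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (identical(cfg$mode, "legacy"))
    stop("legacy mode is not supported by this implementation; ",
         "use mode=denovo or mode=reference", call. = FALSE)
  if (!cfg$mode %in% c("denovo", "reference"))
    stop("invalid mode: ", cfg$mode, call. = FALSE)
  for (key in c("r1", "r2", "barcodes"))
    if (is.null(cfg[[key]]) || !file.exists(cfg[[key]]))
      stop("config error: missing input ", key, call. = FALSE)
  if (cfg$mode == "reference" &&
      (is.null(cfg$reference) || !file.exists(cfg$reference)))
    stop("config error: reference mode requires a reference FASTA",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  done <- function(stage) file.path(out_dir, paste0(stage, ".done"))
  stats_all <- list()

  barcodes <- read_barcode_file(cfg$barcodes)

  # --- demux ---------------------------------------------------------------
  demux_dir <- file.path(out_dir, "demux")
  if (force || !file.exists(done("demux"))) {
    r1 <- read_fastq(cfg$r1); r2 <- read_fastq(cfg$r2)
    reads <- data.frame(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
                        seq2 = r2$seq, qual2 = r2$qual,
                        stringsAsFactors = FALSE)
    cl <- remove_clones(reads, umi_length = cfg$umi_length)
    dm <- demultiplex(cl$reads, barcodes, as.list(cfg$enzymes),
                      mismatches_r1 = cfg$mismatches_r1,
                      mismatches_r2 = cfg$mismatches_r2,
                      rescue_mode = cfg$rescue)
    dir.create(demux_dir, showWarnings = FALSE)
    write_pairs_tsv(dm$reads, file.path(demux_dir, "assigned.tsv"))
    for (s in unique(dm$reads$sample)) for (st in c("Watson", "Crick")) {
      sel <- dm$reads$sample == s & dm$reads$strand == st
      if (!any(sel)) next
      write_fastq(data.frame(id = dm$reads$id[sel], seq = dm$reads$seq1[sel],
                             qual = dm$reads$qual1[sel]),
                  file.path(demux_dir, sprintf("%s_%s_R1.fastq.gz", s, st)))
      write_fastq(data.frame(id = dm$reads$id[sel], seq = dm$reads$seq2[sel],
                             qual = dm$reads$qual2[sel]),
                  file.path(demux_dir, sprintf("%s_%s_R2.fastq.gz", s, st)))
    }
    demux_stats <- list(clone_removal = cl$stats, demultiplexing = dm$stats)
    jsonlite::write_json(demux_stats, file.path(demux_dir, "stats.json"),
                         auto_unbox = TRUE)
    assigned <- dm$reads
    file.create(done("demux"))
  } else {
    assigned <- read_pairs_tsv(file.path(demux_dir, "assigned.tsv"))
    demux_stats <- jsonlite::read_json(file.path(demux_dir, "stats.json"),
                                       simplifyVector = TRUE)
  }
  stats_all <- c(stats_all, demux_stats)

  # --- trim ----------------------------------------------------------------
  trim_dir <- file.path(out_dir, "trim")
  if (force || !file.exists(done("trim"))) {
    tr <- trim_reads(assigned, adapter = cfg$adapter,
                     hard_trim = cfg$hard_trim, min_len = cfg$min_len)
    dir.create(trim_dir, showWarnings = FALSE)
    write_pairs_tsv(tr$reads, file.path(trim_dir, "trimmed.tsv"))
    jsonlite::write_json(tr$stats, file.path(trim_dir, "stats.json"),
                         auto_unbox = TRUE)
    trimmed <- tr$reads
    trim_stats <- tr$stats
    file.create(done("trim"))
  } else {
    trimmed <- read_pairs_tsv(file.path(trim_dir, "trimmed.tsv"))
    trim_stats <- jsonlite::read_json(file.path(trim_dir, "stats.json"),
                                      simplifyVector = TRUE)
  }
  stats_all$trimming <- trim_stats

  # --- reference -----------------------------------------------------------
  ref_path <- file.path(out_dir, "reference.fasta")
  if (cfg$mode == "reference") {
    reference <- read_fasta(cfg$reference)
    denovo_stats <- list(mode = "reference", clusters = length(reference))
    clusters <- NULL
  } else if (force || !file.exists(done("denovo"))) {
    dn <- build_reference(assigned, min_depth = cfg$min_depth,
                          max_depth = cfg$max_depth,
                          identity = cfg$identity)
    reference <- dn$reference
    clusters <- dn$clusters
    write_fasta(reference, ref_path)
    write.table(dn$clusters[, c("id", "length", "watson_depth",
                                "crick_depth", "members")],
                file.path(out_dir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    denovo_stats <- dn$stats
    jsonlite::write_json(dn$stats, file.path(out_dir, "denovo_stats.json"),
                         auto_unbox = TRUE)
    file.create(done("denovo"))
  } else {
    reference <- read_fasta(ref_path)
    clusters <- read.delim(file.path(out_dir, "clusters.tsv"),
                           stringsAsFactors = FALSE)
    denovo_stats <- jsonlite::read_json(
      file.path(out_dir, "denovo_stats.json"), simplifyVector = TRUE)
  }
  stats_all$reference_construction <- denovo_stats

  # --- align ---------------------------------------------------------------
  mates <- merge_directional(trimmed)
  index <- build_index(reference)
  aln <- align_pairs(mates$mate1, mates$mate2, index,
                     min_score_frac = cfg$min_score_frac)
  write_sam(aln$records, reference, file.path(out_dir, "alignments.sam"))
  stats_all$alignment <- aln$stats

  # --- methylation ---------------------------------------------------------
  meth <- call_methylation(aln$records, reference)
  meth_dir <- file.path(out_dir, "methylation")
  dir.create(meth_dir, showWarnings = FALSE)
  meth_summary <- list()
  for (s in unique(meth$sample)) {
    ms <- meth[meth$sample == s, , drop = FALSE]
    write_cx_report(ms, file.path(meth_dir, paste0(s, ".CX_report.txt")))
    tot <- tapply(ms$count_methylated,
                  ms$context, sum)
    cov <- tapply(ms$count_methylated + ms$count_unmethylated,
                  ms$context, sum)
    meth_summary[[s]] <- as.list(round(100 * tot / cov, 2))
  }
  mb <- mbias(aln$records, reference)
  write.table(mb, file.path(meth_dir, "mbias.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stats_all$methylation <- list(percent_methylated_by_sample = meth_summary)

  # --- variants ------------------------------------------------------------
  masked <- double_mask(aln$records, reference)
  vars <- call_variants(masked, reference,
                        min_base_qual = cfg$min_base_qual,
                        min_map_qual = cfg$min_map_qual)
  vars <- filter_snps(vars)
  write_vcf(vars, sort(unique(barcodes$sample)), reference,
            file.path(out_dir, "variants.vcf"))
  stats_all$variants <- list(n_sites = nrow(vars))

  # --- report --------------------------------------------------------------
  report <- write_run_report(stats_all, out_dir)

  invisible(list(demux_stats = demux_stats, trim_stats = trim_stats,
                 reference = reference, clusters = clusters,
                 alignments = aln, methylation = meth, variants = vars,
                 report = report, out_dir = out_dir))
}

#' Read a barcode file
#'
#' TSV with header `sample`, `barcode_R1`, `barcode_R2` (or `bc1`/`bc2`).
#'
#' @param path barcode TSV.
#' @return data.frame with `sample`, `bc1`, `bc2`.
#' @export
read_barcode_file <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df) <- sub("^barcode_R1$", "bc1", names(df))
  names(df) <- sub("^barcode_R2$", "bc2", names(df))
  stopifnot(all(c("sample", "bc1", "bc2") %in% names(df)))
  df
}

write_pairs_tsv <- function(reads, path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_pairs_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write the consolidated run report
#'
#' Collects the per-stage statistics into one JSON file plus a short
#' human-readable summary (clone removal, demultiplexing including
#' unexpected barcodes, assembly/identity clustering, trimming, alignment,
#' methylation percentages and M-bias availability).
#'
#' @param stats named list of per-stage statistics.
#' @param out_dir output directory.
#' @return the stats list, invisibly.
#' @export
write_run_report <- function(stats, out_dir) {
  jsonlite::write_json(stats, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  txt <- c("bsgbs run report", "================", "")
  for (sec in names(stats)) {
    txt <- c(txt, sec, strrep("-", nchar(sec)))
    flat <- unlist(stats[[sec]])
    if (length(flat) > 40) flat <- flat[seq_len(40)]
    txt <- c(txt, paste0("  ", names(flat), ": ", flat), "")
  }
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(stats)
}
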