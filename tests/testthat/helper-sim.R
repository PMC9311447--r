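# Shared fixture builders. All simulated libraries in the unit tests are
# small (a dozen loci, two samples) so individual files stay fast; the
# acceptance tests use the full reference study conditions.

tiny_config <- function(..., seed = 101) {
  sim_config(genome_length = 1.5e5, n_loci = 12, n_samples = 2,
             coverage = 12, seed = seed, ...)
}

# demultiplexed reads straight from a simulated library
demux_sim <- function(sim, cfg, rescue = "any_single_mismatch") {
  cl <- remove_clones(sim$reads, umi_length = cfg$umi_length)
  demultiplex(cl$reads, cfg$barcodes, as.list(cfg$enzymes),
              rescue_mode = rescue)
}

# true loci as an N-padded reference (reference-branch style)
true_reference <- function(truth) {
  setNames(paste0("NNNN", truth$loci$sequence, "NNNN"), truth$loci$id)
}

# map read ids (possibly suffixed with |sample|strand) back to truth rows
truth_lookup <- function(ids, clones) {
  clones[match(sub("\\|.*$", "", ids), clones$read_id), ]
}

# align a simulated library end to end; reference defaults to the true loci
align_sim <- function(sim, cfg, reference = NULL,
                      rescue = "any_single_mismatch", ...) {
  dm <- demux_sim(sim, cfg, rescue = rescue)
  tr <- trim_reads(dm$reads)
  mates <- merge_directional(tr$reads)
  if (is.null(reference)) reference <- true_reference(sim$truth)
  aln <- align_pairs(mates$mate1, mates$mate2, build_index(reference), ...)
  list(demux = dm, trimmed = tr, mates = mates, reference = reference,
       aln = aln)
}

# minimal alignment-record builder for hand-constructed pileups
make_record <- function(cluster, start, seq, sample = "S01", id = "r1",
                        mate = 1L, strand = "OT", qual_char = "F",
                        mapq = 40L, reverse = FALSE) {
  data.frame(id = id, sample = sample, cluster = cluster, start = start,
             end = start + nchar(seq) - 1L,
             cigar = paste0(nchar(seq), "M"), mapq = mapq,
             bisulfite_strand = strand, mate = mate, reverse = reverse,
             seq = seq, qual = strrep(qual_char, nchar(seq)),
             stringsAsFactors = FALSE)
}
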