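# Restriction enzymes and in silico digestion.
#
# Fragment boundaries are defined by the top-strand cut position alone; the
# overhang geometry is collapsed to that single coordinate. What matters for
# read anatomy is the remnant: the motif bases a read is expected to start
# with at each fragment end.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupac_to_regex <- function(motif) {
  chars <- strsplit(motif, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad))
    stop("unknown IUPAC code(s) in recognition site: ", paste(bad, collapse = ", "))
  paste(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Define a restriction enzyme
#'
#' @param name enzyme name.
#' @param recognition recognition motif (IUPAC codes allowed).
#' @param cut_offset_top 0-based position of the top-strand cut inside the
#'   motif: the cut falls after `cut_offset_top` motif bases
#'   (MspI C^CGG has `cut_offset_top = 1`).
#' @param cut_offset_bottom bottom-strand cut position, stored for reference;
#'   fragment boundaries use the top-strand cut only.
#' @return an object of class `bsgbs_enzyme`.
#' @examples
#' mspi <- restriction_enzyme("MspI", "CCGG", 1, 3)
#' enzyme_remnant(mspi, "left")   # "CGG"
#' enzyme_remnant(mspi, "right")  # "G"
#' @export
restriction_enzyme <- function(name, recognition, cut_offset_top,
                               cut_offset_bottom = nchar(recognition) - cut_offset_top) {
  recognition <- toupper(recognition)
  iupac_to_regex(recognition)   # validates codes
  stopifnot(cut_offset_top >= 0, cut_offset_top <= nchar(recognition),
            cut_offset_bottom >= 0, cut_offset_bottom <= nchar(recognition))
  structure(list(name = name, recognition = recognition,
                 cut_offset_top = as.integer(cut_offset_top),
                 cut_offset_bottom = as.integer(cut_offset_bottom)),
            class = "bsgbs_enzyme")
}

#' Built-in restriction enzymes
#'
#' A small registry of enzymes commonly used in reduced-representation
#' protocols; MspI + NsiI is the classic frequent + rare double-digest pair.
#'
#' @return named list of `bsgbs_enzyme` objects.
#' @export
known_enzymes <- function() {
  list(
    MspI  = restriction_enzyme("MspI",  "CCGG",   1, 3),
    NsiI  = restriction_enzyme("NsiI",  "ATGCAT", 5, 1),
    PstI  = restriction_enzyme("PstI",  "CTGCAG", 5, 1),
    EcoRI = restriction_enzyme("EcoRI", "GAATTC", 1, 5),
    Csp6I = restriction_enzyme("Csp6I", "GTAC",   1, 3),
    AseI  = restriction_enzyme("AseI",  "ATTAAT", 2, 4))
}

#' @rdname restriction_enzyme
#' @param x an enzyme name (looked up in [known_enzymes()]) or a
#'   `bsgbs_enzyme` object.
#' @export
get_enzyme <- function(x) {
  if (inherits(x, "bsgbs_enzyme")) return(x)
  enz <- known_enzymes()[[as.character(x)]]
  if (is.null(enz)) stop("unknown enzyme: ", x)
  enz
}

#' Expected read-start remnant of an enzyme
#'
#' After the cut, a fragment whose left end was produced by the enzyme begins
#' (top strand) with the motif bases downstream of the cut; a fragment whose
#' right end was produced by it is read from the bottom strand starting with
#' the reverse complement of the motif bases upstream of the cut.
#'
#' @param enzyme enzyme object or name.
#' @param side `"left"` (top-strand 5' remnant, expected at the start of the
#'   read entering the fragment from its left end) or `"right"` (bottom-strand
#'   5' remnant, expected at the start of the read entering from the right).
#' @return remnant string (may contain IUPAC codes if the motif does).
#' @export
enzyme_remnant <- function(enzyme, side = c("left", "right")) {
  enzyme <- get_enzyme(enzyme)
  side <- match.arg(side)
  if (side == "left") {
    substring(enzyme$recognition, enzyme$cut_offset_top + 1L,
              nchar(enzyme$recognition))
  } else {
    revcomp_iupac(substring(enzyme$recognition, 1L, enzyme$cut_offset_top))
  }
}

# reverse complement that preserves IUPAC ambiguity codes
revcomp_iupac <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(comp, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' In silico digestion of a genome
#'
#' Cuts the genome at every top-strand cut site of the given enzymes and
#' returns the ordered fragments. Fragment concatenation reproduces the input
#' exactly; each internal boundary is labelled with the enzyme that cut it.
#'
#' @param genome a single DNA string over A/C/G/T.
#' @param enzymes list (or character vector of names) of one or more enzymes.
#' @param contig contig name recorded in the fragment coordinates.
#' @return data.frame with columns `id`, `sequence`, `left_enzyme`,
#'   `right_enzyme` (`"genome_end"` at the termini), `contig`, `start`, `end`
#'   (1-based inclusive), `length`.
#' @examples
#' digest("CCGGCCGG", list(get_enzyme("MspI")))$sequence  # "C" "CGGC" "CGG"
#' @export
digest <- function(genome, enzymes, contig = "genome") {
  stopifnot(is.character(genome), length(genome) == 1L)
  genome <- toupper(genome)
  if (grepl("[^ACGT]", genome))
    stop("genome must contain only A/C/G/T")
  enzymes <- lapply(enzymes, get_enzyme)

  cuts <- data.frame(pos = integer(0), enzyme = character(0))
  for (enz in enzymes) {
    # lookahead finds overlapping motif occurrences too
    m <- gregexpr(paste0("(?=", iupac_to_regex(enz$recognition), ")"),
                  genome, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      cuts <- rbind(cuts, data.frame(
        pos = as.integer(m) + enz$cut_offset_top - 1L,  # cut after this base
        enzyme = enz$name))
    }
  }
  L <- nchar(genome)
  cuts <- cuts[cuts$pos >= 1L & cuts$pos < L, , drop = FALSE]
  cuts <- cuts[!duplicated(cuts$pos), , drop = FALSE]
  cuts <- cuts[order(cuts$pos), , drop = FALSE]

  starts <- c(1L, cuts$pos + 1L)
  ends <- c(cuts$pos, L)
  data.frame(
    id = sprintf("%s_frag%04d", contig, seq_along(starts)),
    sequence = substring(genome, starts, ends),
    left_enzyme = c("genome_end", cuts$enzyme),
    right_enzyme = c(cuts$enzyme, "genome_end"),
    contig = contig, start = starts, end = ends,
    length = ends - starts + 1L,
    stringsAsFactors = FALSE)
}

#' Size-select digestion fragments into candidate loci
#'
#' @param fragments data.frame from [digest()].
#' @param size_range numeric length 2, inclusive fragment-length range.
#' @param require_dual if `TRUE`, keep only fragments whose two ends were cut
#'   by two different enzymes (the rare + frequent cutter design).
#' @return the retained fragments, renumbered as `locus_<k>` in genome order.
#' @export
select_loci <- function(fragments, size_range, require_dual = TRUE) {
  keep <- fragments$length >= size_range[1] & fragments$length <= size_range[2]
  if (require_dual) {
    keep <- keep &
      fragments$left_enzyme != "genome_end" &
      fragments$right_enzyme != "genome_end" &
      fragments$left_enzyme != fragments$right_enzyme
  }
  out <- fragments[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no fragments retained by size/dual-cut selection")
  out$id <- sprintf("locus_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
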