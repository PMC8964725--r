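# Nucleic-acid strings, strand/coordinate conventions and codon synonymy.
#
# All reference coordinates in this package are 0-based, half-open.
# Nick-relative edit offsets are 1-based signed integers (+1 = first base 3'
# of the nick on the PAM strand); the conversion to reference coordinates
# happens in offset_to_ref() only.

pc_stop <- function(msg, class) {
  stop(structure(class = c(class, "pegcraft_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Validate a DNA sequence string
#'
#' @param x character scalar, 5'->3'.
#' @param allow_n allow the ambiguity code N (used for PAM patterns).
#' @param allow_empty allow the empty string.
#' @return `x`, upper-cased, invisibly usable downstream.
#' @export
dna <- function(x, allow_n = FALSE, allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    pc_stop("sequence must be a single character string", "pegcraft_invalid_seq")
  x <- toupper(x)
  if (!allow_empty && !nzchar(x))
    pc_stop("sequence must be non-empty", "pegcraft_invalid_seq")
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alphabet), x))
    pc_stop(sprintf("invalid character in sequence (alphabet %s): %s", alphabet, x),
            "pegcraft_invalid_seq")
  x
}

#' Reverse complement of a DNA string
#'
#' Strict Watson-Crick reverse complement over {A,C,G,T} (N maps to N).
#'
#' @param seq character scalar DNA sequence.
#' @return the reverse complement, 5'->3'.
#' @examples
#' revcomp("GATTACA")  # "TGTAATC"
#' @export
revcomp <- function(seq) {
  seq <- dna(seq, allow_n = TRUE, allow_empty = TRUE)
  if (!nzchar(seq)) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

subseq0 <- function(seq, start, end) {
  # 0-based half-open substring
  if (start < 0 || end > nchar(seq) || start > end)
    pc_stop("substring out of range", "pegcraft_range")
  substr(seq, start + 1L, end)
}

#' Reading-frame annotation
#'
#' Anchors codon structure on a reference sequence: `frame_anchor` is the
#' 0-based reference coordinate of any codon-position-1 base on the coding
#' strand; `cds` is the 0-based half-open interval within which synonymy is
#' defined.
#'
#' @param coding_strand "+" or "-" relative to the reference.
#' @param frame_anchor 0-based coordinate of a codon-position-1 base.
#' @param cds_start,cds_end 0-based half-open CDS interval.
#' @return an object of class `reading_frame`.
#' @export
reading_frame <- function(coding_strand, frame_anchor, cds_start, cds_end) {
  stopifnot(coding_strand %in% c("+", "-"))
  frame_anchor <- as.integer(frame_anchor)
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_start > cds_end) pc_stop("cds_start > cds_end", "pegcraft_range")
  if (frame_anchor < cds_start || frame_anchor >= cds_end)
    pc_stop("frame_anchor must lie inside the CDS interval", "pegcraft_range")
  structure(list(coding_strand = coding_strand, frame_anchor = frame_anchor,
                 cds_start = cds_start, cds_end = cds_end),
            class = "reading_frame")
}

#' Codon position of a reference coordinate
#'
#' Position of the base within its codon (1, 2 or 3) on the coding strand.
#' Cycles forward along the coding strand's 5'->3' direction, i.e. in
#' decreasing reference coordinate when the coding strand is "-".
#'
#' @param coord 0-based reference coordinate (vectorised).
#' @param frame a [reading_frame()].
#' @return integer vector in {1,2,3}.
#' @export
codon_position <- function(coord, frame) {
  stopifnot(inherits(frame, "reading_frame"))
  coord <- as.integer(coord)
  if (any(coord < frame$cds_start | coord >= frame$cds_end))
    pc_stop("coordinate outside the CDS interval", "pegcraft_out_of_frame")
  d <- if (frame$coding_strand == "+") coord - frame$frame_anchor
       else frame$frame_anchor - coord
  (d %% 3L) + 1L
}

#' The standard genetic code as a codon table
#'
#' @return named character vector mapping all 64 DNA codons to amino acids
#'   ("*" for stop), translation table 1.
#' @export
codon_table <- function() Biostrings::GENETIC_CODE

check_codon <- function(codon) {
  codon <- dna(codon)
  if (nchar(codon) != 3L)
    pc_stop("codon must be a 3-mer", "pegcraft_invalid_seq")
  codon
}

#' Are two codons synonymous?
#'
#' TRUE iff both encode the same amino acid; two stop codons count as
#' synonymous.
#'
#' @param codon_a,codon_b DNA 3-mers.
#' @param table a codon table as returned by [codon_table()].
#' @export
is_synonymous <- function(codon_a, codon_b, table = codon_table()) {
  codon_a <- check_codon(codon_a); codon_b <- check_codon(codon_b)
  unname(table[[codon_a]] == table[[codon_b]])
}

#' Synonymous single-base alternatives at one codon position
#'
#' All bases b different from `codon[pos]` whose substitution at `pos`
#' yields a codon encoding the same amino acid. May be empty (e.g. ATG, TGG).
#'
#' @param codon DNA 3-mer.
#' @param pos codon position, 1..3.
#' @param table a codon table.
#' @return character vector of bases, alphabetically sorted.
#' @export
synonymous_alternatives <- function(codon, pos, table = codon_table()) {
  codon <- check_codon(codon)
  pos <- as.integer(pos)
  stopifnot(pos %in% 1:3)
  ref <- substr(codon, pos, pos)
  alts <- setdiff(c("A", "C", "G", "T"), ref)
  keep <- vapply(alts, function(b) {
    alt_codon <- codon
    substr(alt_codon, pos, pos) <- b
    is_synonymous(codon, alt_codon, table)
  }, logical(1))
  sort(alts[keep])
}

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
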