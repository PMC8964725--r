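# sgRNA scaffold model and C/G-stabilized hairpin variants.
#
# The scaffold is carried in the DNA alphabet; T->U conversion happens only
# at serialization (rna_out()). Hairpins are described by an explicit
# base-pair map: ordered (i, j) position pairs, 1-based within the scaffold,
# bottom pair first, nested within each hairpin. The default model is the
# canonical 76-nt SpCas9 sgRNA scaffold with its three 3'-side structural
# elements (nexus, small hairpin, terminal hairpin). The small hairpin --
# the element destabilized by the free swinging of the adjacent RTT/PBS
# extension -- is modelled with its bottom A.G mismatch "pair" included, so
# that converting the first non-C/G pair to C/G places a C/G pair at the
# hairpin bottom.

SCAFFOLD_SEQ <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC"

#' Scaffold model: sequence plus hairpin base-pair map
#'
#' @param sequence scaffold sequence, DNA alphabet, 5'->3'.
#' @param hairpins list of hairpins; each hairpin is an integer matrix with
#'   columns `i` (5' position) and `j` (3' position), 1-based, bottom pair in
#'   the first row, pairs nested.
#' @param small_hairpin_index which hairpin is the small hairpin engineered
#'   in the stabilized variants.
#' @return object of class `scaffold_model`.
#' @export
scaffold_model <- function(sequence, hairpins, small_hairpin_index) {
  sequence <- dna(sequence)
  n <- nchar(sequence)
  for (h in hairpins) {
    stopifnot(is.matrix(h), ncol(h) == 2L)
    if (any(h[, 1] >= h[, 2]) || any(h < 1L) || any(h > n))
      pc_stop("invalid base-pair coordinates", "pegcraft_range")
    if (nrow(h) > 1L) {
      # nested: bottom-up means i increasing, j decreasing
      if (any(diff(h[, 1]) <= 0L) || any(diff(h[, 2]) >= 0L))
        pc_stop("hairpin pairs must be nested, bottom pair first", "pegcraft_range")
    }
  }
  stopifnot(small_hairpin_index >= 1L, small_hairpin_index <= length(hairpins))
  structure(list(sequence = sequence, hairpins = hairpins,
                 small_hairpin_index = as.integer(small_hairpin_index)),
            class = "scaffold_model")
}

#' Default SpCas9 scaffold model
#'
#' Canonical 76-nt scaffold with a pair map for the nexus (2-bp stem), the
#' small hairpin (A.G mismatch at the bottom, then 4 canonical pairs, GAAA
#' loop) and the 3'-terminal hairpin (5 canonical pairs).
#'
#' @return a [scaffold_model()].
#' @export
default_scaffold <- function() {
  scaffold_model(
    SCAFFOLD_SEQ,
    hairpins = list(
      cbind(i = c(33L, 34L), j = c(41L, 40L)),                      # nexus
      cbind(i = c(48L, 49L, 50L, 51L, 52L),                         # small hairpin
            j = c(61L, 60L, 59L, 58L, 57L)),
      cbind(i = c(62L, 63L, 64L, 65L, 66L),                         # terminal hairpin
            j = c(76L, 75L, 74L, 73L, 72L))
    ),
    small_hairpin_index = 2L
  )
}

is_cg_pair <- function(b5, b3) (b5 == "C" && b3 == "G") || (b5 == "G" && b3 == "C")

#' Stabilize the scaffold small hairpin (apegRNA variants)
#'
#' Variant `apegRNA-1` inserts one C/G pair at the bottom of the small
#' hairpin (output 2 nt longer). Variant `apegRNA-k` (k >= 2) replaces the
#' (k-1)-th non-C/G pair of the small hairpin, counted bottom-up, with C on
#' the 5' side and G on the 3' side; `apegRNA-2` therefore puts a C/G pair at
#' the bottom of the small hairpin. `regular` returns the scaffold unchanged.
#'
#' @param model a [scaffold_model()].
#' @param variant one of "regular", "apegRNA-1" .. "apegRNA-5".
#' @return scaffold sequence (character scalar).
#' @export
stabilize_scaffold <- function(model, variant = "apegRNA-2") {
  stopifnot(inherits(model, "scaffold_model"))
  variant <- match.arg(variant, c("regular", paste0("apegRNA-", 1:5)))
  seq <- model$sequence
  if (variant == "regular") return(seq)
  hp <- model$hairpins[[model$small_hairpin_index]]
  if (variant == "apegRNA-1") {
    i0 <- hp[1, 1]; j0 <- hp[1, 2]
    return(paste0(subseq0(seq, 0L, i0 - 1L), "C",
                  subseq0(seq, i0 - 1L, j0), "G",
                  subseq0(seq, j0, nchar(seq))))
  }
  k <- as.integer(sub("apegRNA-", "", variant)) - 1L
  bases5 <- substring(seq, hp[, 1], hp[, 1])
  bases3 <- substring(seq, hp[, 2], hp[, 2])
  non_cg <- which(!mapply(is_cg_pair, bases5, bases3))
  if (length(non_cg) < k)
    pc_stop(sprintf("%s undefined: small hairpin has only %d non-C/G pair(s)",
                    variant, length(non_cg)), "pegcraft_variant_undefined")
  row <- hp[non_cg[k], ]
  substr(seq, row[1], row[1]) <- "C"
  substr(seq, row[2], row[2]) <- "G"
  seq
}

#' Serialize a DNA-alphabet guide sequence as RNA
#'
#' @param seq DNA sequence.
#' @return the same sequence with T replaced by U.
#' @export
rna_out <- function(seq) chartr("T", "U", dna(seq, allow_empty = TRUE))
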