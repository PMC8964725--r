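# Seeded amplicon-read simulator: emits reads with known outcome-class
# proportions so that the designer and the quantifier can be validated
# end-to-end without external sequencing data.

SIM_CLASSES <- c("unedited", "intended_only", "intended_plus_ssm",
                 "ssm_only", "unintended_indel", "scaffold_byproduct")

#' Simulation specification
#'
#' @param proportions named numeric vector/list over the outcome classes
#'   `unedited`, `intended_only`, `intended_plus_ssm`, `ssm_only`,
#'   `unintended_indel`, `scaffold_byproduct` (missing classes default to
#'   0); must sum to 1 within 1e-9.
#' @param n_reads number of reads.
#' @param read_length read length; NULL (default) emits the full amplicon.
#' @param error_rate per-base uniform substitution error probability,
#'   0 <= e < 0.25.
#' @param seed integer RNG seed; a fixed seed makes the output byte-identical.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(proportions, n_reads, read_length = NULL,
                     error_rate = 0, seed = 1L) {
  p <- stats::setNames(rep(0, length(SIM_CLASSES)), SIM_CLASSES)
  proportions <- unlist(proportions)
  bad <- setdiff(names(proportions), SIM_CLASSES)
  if (length(bad))
    pc_stop(paste("unknown outcome class:", paste(bad, collapse = ", ")),
            "pegcraft_invalid_spec")
  p[names(proportions)] <- proportions
  if (abs(sum(p) - 1) > 1e-9)
    pc_stop("class proportions must sum to 1", "pegcraft_invalid_spec")
  n_reads <- as.integer(n_reads)
  if (n_reads < 1L) pc_stop("n_reads must be positive", "pegcraft_invalid_spec")
  if (error_rate < 0 || error_rate >= 0.25)
    pc_stop("error_rate must be in [0, 0.25)", "pegcraft_invalid_spec")
  structure(list(proportions = p, n_reads = n_reads,
                 read_length = read_length, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Largest-remainder apportionment of reads to classes
#'
#' Floors `n * p`, then distributes the remaining reads to the classes with
#' the largest fractional parts (ties broken by class order).
#'
#' @param p numeric vector of proportions (summing to 1).
#' @param n total count.
#' @return integer vector summing to `n`.
#' @export
largest_remainder <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(counts), names(p))
}

# Edited template carrying the intended edit and/or the SSMs.
# ssm offsets are edited-strand offsets; translate to coordinates on the
# template being built.
sim_template <- function(ref, with_edit, with_ssm) {
  e <- if (with_edit) ref$edit else NULL
  seq <- if (is.null(e)) ref$reference else apply_edit(ref, e)$seq
  if (with_ssm && nrow(ref$ssms)) {
    offs <- if (with_edit) ref$ssms$position else ssm_ref_offsets(ref)
    coords <- offset_to_edited(ref, e, offs)
    alt <- ref$ssms$alt_base
    if (ref$strand == "-") alt <- comp_base(alt)
    for (k in seq_along(coords))
      substr(seq, coords[k] + 1L, coords[k] + 1L) <- alt[k]
  }
  seq
}

# One random unintended 1-3-nt indel inside the quantification window of the
# unedited reference; resampled so that it can neither be mistaken for the
# intended indel nor for a scaffold-derived insertion.
sim_unintended_indel <- function(ref, w) {
  intended <- intended_event(ref)
  refv <- utf8ToInt(ref$reference)
  for (try in 1:100) {
    len <- sample(3L, 1L)
    if (stats::runif(1) < 0.5) { # deletion
      start <- sample(seq(w[1], w[2] - len), 1L)
      norm <- left_align_indel(refv, start, del_end = start + len)
      # left-normalization must not carry the event outside the window
      if (norm$pos < w[1]) next
      if (!is.null(intended) && intended$kind == "deletion" &&
          norm$pos == intended$coord && norm$end == intended$end) next
      return(paste0(subseq0(ref$reference, 0L, norm$pos),
                    subseq0(ref$reference, norm$end, nchar(ref$reference))))
    }
    pos <- sample(seq(w[1] + 1L, w[2] - 1L), 1L)
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    norm <- left_align_indel(refv, pos, ins_seq = seq)
    if (norm$pos < w[1]) next
    if (detect_scaffold_incorporation(norm$pos, norm$seq, ref)) next
    if (!is.null(intended) && intended$kind == "insertion" &&
        norm$pos == intended$coord && norm$seq == intended$seq) next
    return(paste0(subseq0(ref$reference, 0L, norm$pos), norm$seq,
                  subseq0(ref$reference, norm$pos, nchar(ref$reference))))
  }
  pc_stop("could not draw an unintended indel", "pegcraft_invalid_spec")
}

# Scaffold-incorporation byproduct: the reverse complement of the
# scaffold's 3'-terminal `len` bases inserted at the nick.
sim_scaffold_byproduct <- function(ref, len = 5L) {
  scaf <- ref$scaffold
  ins <- revcomp(substr(scaf, nchar(scaf) - len + 1L, nchar(scaf)))
  if (ref$strand == "-") ins <- revcomp(ins)
  b <- ref$nick_coord
  paste0(subseq0(ref$reference, 0L, b), ins,
         subseq0(ref$reference, b, nchar(ref$reference)))
}

#' Simulate amplicon reads with known outcome-class proportions
#'
#' Builds one template per outcome class by applying that class's events to
#' the reference (the intended edit, the design's SSMs, a random 1-3-nt
#' indel inside the quantification window, or a scaffold-derived insertion
#' at the nick), apportions reads to classes by largest-remainder rounding,
#' and overlays uniform substitution sequencing errors. With a fixed seed
#' the output is byte-identical across runs.
#'
#' @param ref an [amplicon_ref()] (carrying edit, SSMs and scaffold).
#' @param spec a [sim_spec()].
#' @param fastq optional path; when given, reads are also written as
#'   standard 4-line FASTQ (constant quality "I").
#' @param scaffold_insert_len length of the simulated scaffold insertion
#'   (default 5).
#' @return data frame (truth table) with `id`, `class`, `seq`.
#' @export
simulate_reads <- function(ref, spec, fastq = NULL, scaffold_insert_len = 5L) {
  stopifnot(inherits(ref, "amplicon_ref"), inherits(spec, "sim_spec"))
  needs_ssm <- any(spec$proportions[c("intended_plus_ssm", "ssm_only")] > 0)
  if (needs_ssm && !nrow(ref$ssms))
    pc_stop("SSM classes requested but the amplicon carries no SSMs",
            "pegcraft_invalid_spec")
  needs_edit <- any(spec$proportions[c("intended_only", "intended_plus_ssm")] > 0)
  if (needs_edit && is.null(ref$edit))
    pc_stop("intended-edit classes requested but no edit is specified",
            "pegcraft_invalid_spec")
  w <- quant_window(ref)
  counts <- largest_remainder(spec$proportions, spec$n_reads)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  fixed_templates <- list(
    unedited = ref$reference,
    intended_only = if (needs_edit) sim_template(ref, TRUE, FALSE),
    intended_plus_ssm = if (needs_edit && needs_ssm) sim_template(ref, TRUE, TRUE),
    ssm_only = if (needs_ssm) sim_template(ref, FALSE, TRUE),
    scaffold_byproduct = sim_scaffold_byproduct(ref, scaffold_insert_len))

  cls <- rep(names(counts), counts)
  seqs <- character(length(cls))
  for (i in seq_along(cls)) {
    seqs[i] <- if (cls[i] == "unintended_indel") sim_unintended_indel(ref, w)
               else fixed_templates[[cls[i]]]
  }
  if (!is.null(spec$read_length)) {
    L <- as.integer(spec$read_length)
    if (L < w[2] - w[1])
      pc_stop("read_length shorter than the quantification window",
              "pegcraft_invalid_spec")
    seqs <- vapply(seqs, function(s) {
      n <- nchar(s)
      if (n <= L) return(s)
      start <- max(0L, min((n - L) %/% 2L, w[1]))
      if (start + L < w[2]) start <- max(0L, min(w[1], n - L))
      subseq0(s, start, start + L)
    }, character(1), USE.NAMES = FALSE)
  }
  if (spec$error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seqs, function(s) {
      n <- nchar(s)
      hit <- which(stats::runif(n) < spec$error_rate)
      if (!length(hit)) return(s)
      sv <- strsplit(s, "")[[1]]
      for (k in hit) sv[k] <- sample(setdiff(bases, sv[k]), 1L)
      paste(sv, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  out <- data.frame(id = sprintf("read%06d", seq_along(cls)), class = cls,
                    seq = seqs)
  if (!is.null(fastq)) write_fastq(out, fastq)
  out
}

#' Write reads as 4-line FASTQ
#'
#' @param reads data frame with `id` and `seq` columns.
#' @param path output path.
#' @param quality_char constant base-quality character (default "I", Q40).
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  quals <- Biostrings::PhredQuality(vapply(nchar(reads$seq),
                                           function(n) strrep(quality_char, n),
                                           character(1)))
  qs <- Biostrings::QualityScaledDNAStringSet(x, quals)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read a 4-line FASTQ file
#'
#' @param path FASTQ path.
#' @return data frame with `id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(x), seq = as.character(x))
}

#' Generate a random prime-editing target for simulation studies
#'
#' Draws a random reference sequence, plants a 20-nt protospacer with an
#' NGG PAM, annotates a CDS covering the quantification window with a
#' chosen or random ORF phase on either coding strand, and specifies a
#' random +1..+6 single-base substitution edit.
#'
#' @param seed integer seed (NULL to use the current RNG state).
#' @param strand protospacer strand ("+" or "-").
#' @param coding_strand coding strand for the reading frame.
#' @param phase "ORF1", "ORF2", "ORF3" or NULL for random.
#' @param ref_len reference length (default 240).
#' @param edit_offset nick-relative offset of the substitution (default
#'   random in 1..6).
#' @return list with `target`, `frame`, `edit`, `phase`.
#' @export
sim_target <- function(seed = NULL, strand = "+", coding_strand = strand,
                       phase = NULL, ref_len = 240L, edit_offset = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  sv <- sample(bases, ref_len, replace = TRUE)
  s <- ref_len %/% 2L - 10L   # protospacer start
  if (strand == "+") {
    sv[(s + 21L):(s + 23L)] <- c(sv[s + 21L], "G", "G")
  } else {
    sv[(s - 2L):s] <- c("C", "C", sv[s])
  }
  reference <- paste(sv, collapse = "")
  target <- target_spec(reference, s, 20L, strand)
  if (is.null(phase)) phase <- sample(c("ORF1", "ORF2", "ORF3"), 1L)
  # pick the frame anchor so that the wobble position among offsets +1..+3
  # matches the requested phase
  wobble_offset <- c(ORF2 = 1L, ORF3 = 2L, ORF1 = 3L)[[phase]]
  wob_coord <- offset_to_ref(target, wobble_offset)
  anchor <- if (coding_strand == "+") wob_coord - 2L else wob_coord + 2L
  frame <- reading_frame(coding_strand, anchor, 0L, ref_len)
  if (is.null(edit_offset)) edit_offset <- sample(6L, 1L)
  coord <- offset_to_ref(target, edit_offset)
  refb <- pam_strand_base(reference, strand, coord)
  altb <- sample(setdiff(bases, refb), 1L)
  edit <- edit_spec("substitution", edit_offset, refb, altb)
  list(target = target, frame = frame, edit = edit, phase = phase)
}
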