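# Exhaustive mismatch-tolerant off-target scan (Cas-OFFinder-style):
# PAM match is a gate; mismatches are Hamming distance over the spacer-length
# site only. N in the subject never counts as a match.

#' Scan subject sequences for pegRNA-dependent off-target candidate sites
#'
#' Reports every position, on both strands of every subject sequence, where
#' the PAM pattern matches immediately 3' of a spacer-length site and the
#' Hamming distance between spacer and site is at most `max_mismatches`
#' (default 5). PAM bases are a gate and are not counted as mismatches; an N
#' in the PAM pattern matches A/C/G/T only, and any N in the subject counts
#' as a mismatch.
#'
#' @param spacer spacer sequence, 17-24 nt.
#' @param subject named character vector of subject sequences (or a single
#'   sequence).
#' @param max_mismatches maximum Hamming distance (default 5).
#' @param pam_pattern PAM pattern (default "NGG").
#' @return data frame sorted by (sequence, coordinate): `seqname`, `start`,
#'   `end` (0-based half-open site interval), `strand`, `site_sequence`
#'   (spacer orientation), `pam_observed`, `mismatch_count`.
#' @export
scan_offtargets <- function(spacer, subject, max_mismatches = 5L,
                            pam_pattern = "NGG") {
  spacer <- dna(spacer)
  if (nchar(spacer) < 17L || nchar(spacer) > 24L)
    pc_stop("spacer length must be 17-24", "pegcraft_range")
  pam_pattern <- dna(pam_pattern, allow_n = TRUE)
  max_mismatches <- as.integer(max_mismatches)
  if (is.null(names(subject)))
    names(subject) <- if (length(subject) == 1L) "subject"
                      else paste0("subject", seq_along(subject))
  rows <- list()
  for (nm in names(subject)) {
    seq <- dna(subject[[nm]], allow_n = TRUE)
    for (strand in c("+", "-")) {
      hits <- scan_one_strand(spacer, seq, strand, max_mismatches, pam_pattern)
      if (nrow(hits)) {
        hits$seqname <- nm
        rows[[length(rows) + 1L]] <- hits
      }
    }
  }
  empty <- data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      site_sequence = character(), pam_observed = character(),
                      mismatch_count = integer())
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)[, names(empty)]
  out <- out[order(out$seqname, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# One strand of one subject. On "-", candidate sites are read off the
# reverse complement and coordinates are mapped back to the forward strand.
scan_one_strand <- function(spacer, seq, strand, max_mm, pam_pattern) {
  L <- nchar(spacer)
  plen <- nchar(pam_pattern)
  scanned <- if (strand == "+") seq else revcomp(seq)
  n <- nchar(scanned)
  empty <- data.frame(start = integer(), end = integer(), strand = character(),
                      site_sequence = character(), pam_observed = character(),
                      mismatch_count = integer())
  if (n < L + plen) return(empty)
  sv <- strsplit(scanned, "")[[1]]
  gv <- strsplit(spacer, "")[[1]]
  pv <- strsplit(pam_pattern, "")[[1]]
  # mismatch counts for every site start, vectorised over starts
  starts <- 1:(n - L - plen + 1L)
  mm <- integer(length(starts))
  for (k in 0:(L - 1L)) mm <- mm + (sv[starts + k] != gv[k + 1L])
  pam_ok <- rep(TRUE, length(starts))
  for (k in 0:(plen - 1L)) {
    sb <- sv[starts + L + k]
    pam_ok <- pam_ok & if (pv[k + 1L] == "N") sb %in% c("A", "C", "G", "T")
                       else sb == pv[k + 1L]
  }
  keep <- which(pam_ok & mm <= max_mm)
  if (!length(keep)) return(empty)
  res <- data.frame(
    start = starts[keep] - 1L, end = starts[keep] - 1L + L,
    strand = strand,
    site_sequence = vapply(starts[keep],
                           function(s) paste(sv[s:(s + L - 1L)], collapse = ""),
                           character(1)),
    pam_observed = vapply(starts[keep],
                          function(s) paste(sv[(s + L):(s + L + plen - 1L)],
                                            collapse = ""),
                          character(1)),
    mismatch_count = mm[keep])
  if (strand == "-") {
    # map [start,end) on the reverse complement back to forward coordinates
    res$start2 <- nchar(seq) - res$end
    res$end <- nchar(seq) - res$start
    res$start <- res$start2
    res$start2 <- NULL
  }
  res
}

#' Write off-target hits as 6-column BED
#'
#' @param hits data frame from [scan_offtargets()].
#' @param path output path.
#' @export
offtargets_to_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$seqname, start = hits$start, end = hits$end,
                    name = hits$site_sequence, score = hits$mismatch_count,
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
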