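# Semi-global read alignment (read global, reference local) via a compiled
# affine-gap Gotoh aligner, with explicit event calling. Indels are
# left-aligned against the reference so that equivalent placements compare
# equal.

#' Align amplicon reads to a reference
#'
#' Best-scoring semi-global alignment: the read is aligned end-to-end
#' against a substring of the reference. Default scores: match +2,
#' mismatch -4; a gap of length k costs `gap_opening + k * gap_extension`
#' (6 + k). Reads scoring below `min_score` (default: half the maximum
#' attainable score, `match * read_length / 2`) are flagged unaligned and
#' excluded from all denominators downstream.
#'
#' Under affine-gap scoring, a cluster of substitutions can be
#' score-preferred as an equal-length insertion/deletion pair; since such a
#' pair is a multi-nucleotide substitution in disguise, reads whose only
#' indels are one insertion and one deletion of equal length within
#' `mnv_max_span` nt of each other are re-called gap-free as substitutions
#' (`mnv_collapse`).
#'
#' @param reads character vector of read sequences.
#' @param reference reference sequence.
#' @param match,mismatch,gap_opening,gap_extension alignment scores.
#' @param min_score numeric scalar or vector; NULL for the default rule.
#' @param mnv_collapse collapse equal-length ins/del pairs into
#'   substitutions (default TRUE).
#' @param mnv_max_span maximum distance between the pair (default 12).
#' @return object of class `read_alignments`: per-read `aligned`, `score`,
#'   `cov_start`/`cov_end` (0-based half-open covered interval) and an
#'   `events` data frame (`read`, `type` in sub/ins/del, `coord`, `end`,
#'   `seq`).
#' @export
align_reads <- function(reads, reference, match = 2, mismatch = -4,
                        gap_opening = 6, gap_extension = 1,
                        min_score = NULL, mnv_collapse = TRUE,
                        mnv_max_span = 12L) {
  reference <- dna(reference)
  n_total <- length(reads)
  if (is.null(min_score)) min_score <- match * nchar(reads) / 2
  min_score <- rep_len(min_score, n_total)
  # amplicon read sets are highly redundant (a few templates dominate):
  # align unique sequences once and expand the results afterwards
  uniq <- unique(reads)
  idx <- match(reads, uniq)
  n <- length(uniq)
  pa <- sg_align_batch(uniq, reference, match, mismatch,
                       gap_opening, gap_extension)
  score <- pa$score
  aligned <- rep(TRUE, n)  # threshold is applied per original read below
  substart <- pa$start + 1L   # 1-based start of the aligned subject region
  subend <- pa$end
  pstr <- pa$pattern
  sstr <- pa$subject
  refv <- utf8ToInt(reference)
  gap <- utf8ToInt("-")

  ev_read <- list(); ev_type <- list(); ev_coord <- list()
  ev_end <- list(); ev_seq <- list()
  add <- function(i, type, coord, end, seq) {
    k <- length(ev_read) + 1L
    ev_read[[k]] <<- rep.int(i, length(coord))
    ev_type[[k]] <<- rep.int(type, length(coord))
    ev_coord[[k]] <<- coord; ev_end[[k]] <<- end; ev_seq[[k]] <<- seq
  }
  for (i in seq_len(n)) {
    if (!aligned[i]) next
    pv <- utf8ToInt(pstr[i]); sv <- utf8ToInt(sstr[i])
    sgap <- sv == gap; pgap <- pv == gap
    refpos <- cumsum(!sgap) + substart[i] - 1L  # 1-based ref pos of subject base
    ins <- list(); del <- list()
    if (any(sgap)) {
      r <- rle(sgap)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        pos <- if (starts[j] == 1L) substart[i] - 1L else refpos[starts[j]]
        ins[[length(ins) + 1L]] <-
          left_align_indel(refv, pos, ins_seq = intToUtf8(pv[starts[j]:ends[j]]))
      }
    }
    if (any(pgap)) {
      r <- rle(pgap)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        del[[length(del) + 1L]] <-
          left_align_indel(refv, refpos[starts[j]] - 1L,
                           del_end = refpos[ends[j]])
      }
    }
    # MNV normalization: a single equal-length insertion/deletion pair a few
    # bases apart is score-preferred over a cluster of substitutions under
    # affine-gap scoring, but represents a multi-nucleotide substitution;
    # re-call the read gap-free in that case.
    if (mnv_collapse && length(ins) == 1L && length(del) == 1L &&
        nchar(ins[[1]]$seq) == del[[1]]$end - del[[1]]$pos &&
        abs(ins[[1]]$pos - del[[1]]$pos) <= mnv_max_span) {
      rv <- pv[!pgap]                 # the read itself
      ref_span <- refv[substart[i]:subend[i]]
      if (length(rv) == length(ref_span)) {
        mism <- which(rv != ref_span)
        if (length(mism))
          add(i, "sub", substart[i] - 1L + mism - 1L, substart[i] - 1L + mism,
              strsplit(intToUtf8(rv[mism]), "")[[1]])
        next
      }
    }
    sub_idx <- which(!sgap & !pgap & pv != sv)
    if (length(sub_idx))
      add(i, "sub", refpos[sub_idx] - 1L, refpos[sub_idx],
          strsplit(intToUtf8(pv[sub_idx]), "")[[1]])
    for (x in ins) add(i, "ins", x$pos, x$pos, x$seq)
    for (x in del) add(i, "del", x$pos, x$end, "")
  }
  uev <- data.frame(read = as.integer(unlist(ev_read)),
                    type = as.character(unlist(ev_type)),
                    coord = as.integer(unlist(ev_coord)),
                    end = as.integer(unlist(ev_end)),
                    seq = as.character(unlist(ev_seq)),
                    stringsAsFactors = FALSE)
  # expand unique-read results back onto the original read set
  score_all <- score[idx]
  aligned_all <- score_all >= min_score
  groups <- split(which(aligned_all), idx[aligned_all])
  if (nrow(uev)) {
    counts <- vapply(as.character(uev$read), function(j) {
      g <- groups[[j]]; if (is.null(g)) 0L else length(g)
    }, integer(1))
    events <- data.frame(
      read = as.integer(unlist(groups[as.character(uev$read)], use.names = FALSE)),
      type = rep(uev$type, counts),
      coord = rep(uev$coord, counts),
      end = rep(uev$end, counts),
      seq = rep(uev$seq, counts),
      stringsAsFactors = FALSE)
    events <- events[order(events$read), , drop = FALSE]
    rownames(events) <- NULL
  } else {
    events <- data.frame(read = integer(), type = character(),
                         coord = integer(), end = integer(),
                         seq = character())
  }
  structure(list(n = n_total, aligned = aligned_all, score = score_all,
                 cov_start = ifelse(aligned_all, substart[idx] - 1L, NA_integer_),
                 cov_end = ifelse(aligned_all, subend[idx], NA_integer_),
                 events = events, reference = reference),
            class = "read_alignments")
}

# Shift an indel to its leftmost equivalent placement on the reference.
# `refv` is the reference as an integer (utf8) vector. For an insertion,
# `pos` is the 0-based coordinate the sequence is inserted before; for a
# deletion, [pos, del_end) is the removed interval.
left_align_indel <- function(refv, pos, ins_seq = NULL, del_end = NULL) {
  if (!is.null(ins_seq)) {
    iv <- utf8ToInt(ins_seq)
    while (pos > 0L && refv[pos] == iv[length(iv)]) {
      iv <- c(refv[pos], iv[-length(iv)])
      pos <- pos - 1L
    }
    return(list(pos = pos, seq = intToUtf8(iv)))
  }
  end <- del_end
  while (pos > 0L && refv[pos] == refv[end]) {
    pos <- pos - 1L; end <- end - 1L
  }
  list(pos = pos, end = end)
}

#' Align a single read (convenience wrapper)
#'
#' @inheritParams align_reads
#' @param read a single read sequence.
#' @return list with `aligned`, `score`, `covered` (0-based half-open),
#'   `substitutions`, `insertions`, `deletions` data frames.
#' @export
align_read <- function(read, reference, ...) {
  a <- align_reads(read, reference, ...)
  ev <- a$events
  list(aligned = a$aligned[1], score = a$score[1],
       covered = c(a$cov_start[1], a$cov_end[1]),
       substitutions = ev[ev$type == "sub", c("coord", "seq")],
       insertions = ev[ev$type == "ins", c("coord", "seq")],
       deletions = ev[ev$type == "del", c("coord", "end")])
}
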