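# Editing-outcome classification and the frequency definitions used for
# amplicon quantification.

#' Amplicon reference with target, edit and design annotations
#'
#' Bundles a [target_spec()] with the intended edit, the same-sense
#' substitutions carried by the pegRNA and the scaffold sequence, i.e.
#' everything the outcome classifier needs.
#'
#' @param target a [target_spec()].
#' @param edit an [edit_spec()] or NULL.
#' @param ssms SSM data frame (`position`, `ref_base`, `alt_base`, PAM
#'   strand) or NULL; a `peg_design` may be passed via `design` instead.
#' @param scaffold scaffold sequence (character); defaults to the canonical
#'   scaffold or, if `design` is given, the design's scaffold.
#' @param design optional `peg_design` supplying `ssms` and `scaffold`.
#' @return object of class `amplicon_ref` (also a `target_spec`).
#' @export
amplicon_ref <- function(target, edit = NULL, ssms = NULL, scaffold = NULL,
                         design = NULL) {
  stopifnot(inherits(target, "target_spec"))
  if (!is.null(design)) {
    if (is.null(ssms)) ssms <- design$ssms
    if (is.null(scaffold)) scaffold <- design$scaffold
  }
  if (is.null(ssms)) ssms <- empty_ssms()
  if (is.null(scaffold)) scaffold <- SCAFFOLD_SEQ
  if (!is.null(edit)) check_edit_ref(target, edit)
  out <- target
  out$edit <- edit
  out$ssms <- ssms
  out$scaffold <- dna(scaffold)
  class(out) <- c("amplicon_ref", "target_spec")
  out
}

#' Quantification window around the target site
#'
#' The reference interval used for indel quantification: from 8 nt upstream
#' of the protospacer 5' end to 52 nt downstream of the protospacer 3' end,
#' in protospacer-strand orientation; 8 + 20 + 52 = 80 bp for a 20-nt
#' protospacer, with the PAM inside the downstream span.
#'
#' @param ref a [target_spec()] or [amplicon_ref()].
#' @param upstream,downstream window offsets (defaults 8 and 52).
#' @return 0-based half-open interval `c(start, end)` on the reference.
#' @export
quant_window <- function(ref, upstream = 8L, downstream = 52L) {
  s <- ref$proto_start; e <- ref$proto_start + ref$proto_len
  w <- if (ref$strand == "+") c(s - upstream, e + downstream)
       else c(s - downstream, e + upstream)
  if (w[1] < 0L || w[2] > nchar(ref$reference))
    pc_stop("quantification window exceeds the amplicon", "pegcraft_range")
  as.integer(w)
}

# Reference coordinates of the SSM offsets. SSM positions are edited-strand
# offsets; on a read aligned to the unedited reference they surface at the
# corresponding reference offsets (shifted across an intended indel).
ssm_ref_offsets <- function(ref) {
  if (!nrow(ref$ssms)) return(integer(0))
  p <- ref$ssms$position
  e <- ref$edit
  if (is.null(e) || e$kind == "substitution") return(p)
  if (e$kind == "insertion") {
    d <- nchar(e$alt_allele)
    ifelse(p >= e$offset + d, p - d, p)
  } else {
    d <- nchar(e$ref_allele)
    ifelse(p >= e$offset, p + d, p)
  }
}

# Intended-edit description in reference coordinates, left-normalized for
# indels: list(kind, coords/base expectations or indel event).
intended_event <- function(ref) {
  e <- ref$edit
  if (is.null(e)) return(NULL)
  if (e$kind == "substitution") {
    coords <- offset_to_ref(ref, e$offset + seq_len(nchar(e$alt_allele)) - 1L)
    alt <- strsplit(e$alt_allele, "")[[1]]
    if (ref$strand == "-") alt <- comp_base(alt)
    return(list(kind = "substitution", coords = coords, alt = alt))
  }
  refv <- utf8ToInt(ref$reference)
  iv <- edit_ref_interval(ref, e)
  if (e$kind == "insertion") {
    seq <- e$alt_allele
    if (ref$strand == "-") seq <- revcomp(seq)
    norm <- left_align_indel(refv, iv[1], ins_seq = seq)
    list(kind = "insertion", coord = norm$pos, seq = norm$seq)
  } else {
    norm <- left_align_indel(refv, iv[1], del_end = iv[2])
    list(kind = "deletion", coord = norm$pos, end = norm$end)
  }
}

#' Detect pegRNA scaffold incorporation in one insertion event
#'
#' An insertion is called scaffold-derived when it lies within `max_dist` nt
#' of the nick, is at least `min_len` nt long, and matches the reverse
#' complement of the scaffold's 3'-terminal run of equal length with at most
#' `max_mismatch` mismatches.
#'
#' @param ins_coord 0-based insertion coordinate (sequence inserted before
#'   it); vectorised.
#' @param ins_seq inserted sequence(s), reference orientation.
#' @param ref an [amplicon_ref()].
#' @param min_len,max_mismatch,max_dist detector thresholds (defaults 3, 1, 5).
#' @return logical vector.
#' @export
detect_scaffold_incorporation <- function(ins_coord, ins_seq, ref,
                                          min_len = 3L, max_mismatch = 1L,
                                          max_dist = 5L) {
  if (!length(ins_coord)) return(logical(0))
  scaf <- ref$scaffold
  sl <- nchar(scaf)
  mapply(function(pos, seq) {
    len <- nchar(seq)
    if (len < min_len || len > sl) return(FALSE)
    if (abs(pos - ref$nick_coord) > max_dist) return(FALSE)
    pam_seq <- if (ref$strand == "-") revcomp(seq) else seq
    expect <- revcomp(substr(scaf, sl - len + 1L, sl))
    sum(utf8ToInt(pam_seq) != utf8ToInt(expect)) <= max_mismatch
  }, ins_coord, ins_seq, USE.NAMES = FALSE)
}

#' Classify aligned reads into editing-outcome records
#'
#' Applies the outcome definitions per read: intended edit present iff the
#' edit allele is observed at its locus; SSM flags per design offset;
#' unintended indel iff the read carries an insertion/deletion inside the
#' quantification window that is neither the intended indel nor a
#' scaffold-derived insertion; scaffold incorporation per
#' [detect_scaffold_incorporation()]. Coverage flags record whether each
#' read spans the edit locus, the nick (+/- 1 nt) and the full window.
#'
#' @param alns a `read_alignments` object from [align_reads()].
#' @param ref an [amplicon_ref()].
#' @param scaffold_params list of detector thresholds (`min_len`,
#'   `max_mismatch`, `max_dist`).
#' @return data frame, one row per read.
#' @export
classify_reads <- function(alns, ref, scaffold_params = list()) {
  stopifnot(inherits(alns, "read_alignments"))
  sp <- utils::modifyList(list(min_len = 3L, max_mismatch = 1L, max_dist = 5L),
                          scaffold_params)
  w <- quant_window(ref)
  ev <- alns$events
  n <- alns$n
  intended <- intended_event(ref)
  b <- ref$nick_coord

  is_ins <- ev$type == "ins"
  is_del <- ev$type == "del"
  is_indel <- is_ins | is_del

  scaffold_hit <- rep(FALSE, nrow(ev))
  scaffold_hit[is_ins] <- detect_scaffold_incorporation(
    ev$coord[is_ins], ev$seq[is_ins], ref,
    sp$min_len, sp$max_mismatch, sp$max_dist)

  intended_hit <- rep(FALSE, nrow(ev))
  if (!is.null(intended)) {
    if (intended$kind == "insertion") {
      intended_hit <- is_ins & ev$coord == intended$coord &
        ev$seq == intended$seq
    } else if (intended$kind == "deletion") {
      intended_hit <- is_del & ev$coord == intended$coord &
        ev$end == intended$end
    }
  }

  in_window <- ifelse(is_ins, ev$coord >= w[1] & ev$coord <= w[2],
                      ev$coord < w[2] & ev$end > w[1])
  unintended <- is_indel & in_window & !intended_hit & !scaffold_hit

  tab <- function(flag) tabulate(ev$read[flag], nbins = n)
  n_indels <- tab(is_indel)
  rec <- data.frame(
    read = seq_len(n),
    aligned = alns$aligned,
    n_indels = n_indels,
    has_unintended_indel_in_window = tab(unintended) > 0L,
    has_scaffold_incorporation = tab(scaffold_hit) > 0L)

  # intended edit
  if (is.null(intended)) {
    rec$has_intended_edit <- FALSE
  } else if (intended$kind == "substitution") {
    hit <- rep(TRUE, n)
    for (k in seq_along(intended$coords)) {
      at <- ev$type == "sub" & ev$coord == intended$coords[k] &
        ev$seq == intended$alt[k]
      hit <- hit & tab(at) > 0L
    }
    rec$has_intended_edit <- hit
  } else {
    rec$has_intended_edit <- tab(intended_hit) > 0L
  }
  rec$has_intended_indel_exact <- if (!is.null(intended) &&
                                      intended$kind != "substitution")
    rec$has_intended_edit & n_indels == 1L else FALSE

  # SSM flags
  ssm_offs <- ssm_ref_offsets(ref)
  rec$n_ssm <- 0L
  if (length(ssm_offs)) {
    coords <- offset_to_ref(ref, ssm_offs)
    alts <- ref$ssms$alt_base
    if (ref$strand == "-") alts <- comp_base(alts)
    for (k in seq_along(coords)) {
      at <- ev$type == "sub" & ev$coord == coords[k] & ev$seq == alts[k]
      rec$n_ssm <- rec$n_ssm + (tab(at) > 0L)
    }
  }
  rec$has_ssm <- rec$n_ssm > 0L

  # coverage
  cs <- alns$cov_start; ce <- alns$cov_end
  covered <- function(lo, hi) alns$aligned & !is.na(cs) & cs <= lo & ce >= hi
  if (is.null(intended)) {
    rec$covers_edit <- covered(b - 1L, b + 1L)
  } else if (intended$kind == "substitution") {
    rec$covers_edit <- covered(min(intended$coords), max(intended$coords) + 1L)
  } else {
    rec$covers_edit <- covered(b - 1L, b + 1L)
  }
  rec$covers_nick <- covered(b - 1L, b + 1L)
  rec$covers_window <- covered(w[1], w[2])
  rec[!rec$aligned, setdiff(names(rec), c("read", "aligned"))] <- NA
  rec
}

freq_entry <- function(num, den) {
  list(value = if (den > 0L) num / den else NA_real_, numerator = num,
       denominator = den)
}

#' Intended single-base (substitution) editing frequency
#'
#' Reads carrying the intended substitution and no indel, divided by reads
#' covering the edit position.
#'
#' @param records data frame from [classify_reads()].
#' @return list with `value`, `numerator`, `denominator`.
#' @export
intended_substitution_frequency <- function(records) {
  den <- sum(records$covers_edit, na.rm = TRUE)
  num <- sum(records$covers_edit & records$has_intended_edit &
               records$n_indels == 0L, na.rm = TRUE)
  freq_entry(num, den)
}

#' Intended indel frequency
#'
#' Reads whose only indel is exactly the designed insertion/deletion,
#' divided by reads covering the target site (nick +/- 1 nt).
#'
#' @param records data frame from [classify_reads()].
#' @param ref an [amplicon_ref()] with an insertion/deletion edit.
#' @return list with `value`, `numerator`, `denominator`.
#' @export
intended_indel_frequency <- function(records, ref) {
  if (is.null(ref$edit) || ref$edit$kind == "substitution")
    pc_stop("intended_indel_frequency requires an insertion/deletion edit",
            "pegcraft_usage")
  den <- sum(records$covers_nick, na.rm = TRUE)
  num <- sum(records$covers_nick & records$has_intended_indel_exact,
             na.rm = TRUE)
  freq_entry(num, den)
}

#' Unintended indel frequency in the quantification window
#'
#' Reads containing at least one unintended inserted and/or deleted
#' nucleotide inside the window, divided by reads aligned across the whole
#' window. For insertion/deletion designs the intended indel itself is not
#' counted.
#'
#' @param records data frame from [classify_reads()].
#' @param mode "substitution_experiment" or "indel_experiment"
#'   (classification already excludes the intended indel; the mode is kept
#'   for the reporting surface).
#' @return list with `value`, `numerator`, `denominator`.
#' @export
unintended_indel_frequency <- function(records,
                                       mode = c("substitution_experiment",
                                                "indel_experiment")) {
  match.arg(mode)
  den <- sum(records$covers_window, na.rm = TRUE)
  num <- sum(records$covers_window & records$has_unintended_indel_in_window,
             na.rm = TRUE)
  freq_entry(num, den)
}

#' Incomplete-product and byproduct frequencies
#'
#' Incomplete products are reads carrying only same-sense substitutions
#' (no intended edit, no indel, no scaffold insertion); byproducts are reads
#' whose only event class is a scaffold-derived insertion. Both are divided
#' by reads covering the target site.
#'
#' @param records data frame from [classify_reads()].
#' @return list with elements `incomplete` and `byproduct`, each a
#'   `value`/`numerator`/`denominator` list.
#' @export
incomplete_and_byproduct_frequencies <- function(records) {
  den <- sum(records$covers_edit, na.rm = TRUE)
  inc <- sum(records$covers_edit & records$has_ssm &
               !records$has_intended_edit & records$n_indels == 0L &
               !records$has_scaffold_incorporation, na.rm = TRUE)
  byp <- sum(records$covers_edit & records$has_scaffold_incorporation &
               !records$has_intended_edit & !records$has_ssm &
               !records$has_unintended_indel_in_window, na.rm = TRUE)
  list(incomplete = freq_entry(inc, den), byproduct = freq_entry(byp, den))
}

#' Per-position base-substitution frequencies
#'
#' For every position of the quantification window and every substitution
#' type: reads carrying that substitution and no indel, divided by the reads
#' covering the position. Positions with depth below `min_depth` (default
#' 1000) are reported as missing (NA frequency).
#'
#' @param alns a `read_alignments` object.
#' @param records data frame from [classify_reads()].
#' @param ref an [amplicon_ref()].
#' @param min_depth minimum per-position read depth (default 1000).
#' @return data frame: `coord` (0-based), `ref_base`, `alt_base`, `count`,
#'   `depth`, `freq` (NA where depth < `min_depth`); three rows per
#'   position, one per alternative base.
#' @export
substitution_frequencies <- function(alns, records, ref, min_depth = 1000L) {
  w <- quant_window(ref)
  coords <- w[1]:(w[2] - 1L)
  width <- length(coords)
  # per-position depth among aligned reads, via a difference array
  diffs <- numeric(width + 1L)
  cs <- pmax(alns$cov_start[alns$aligned], w[1])
  ce <- pmin(alns$cov_end[alns$aligned], w[2])
  ok <- !is.na(cs) & cs < ce
  for (i in which(ok)) {
    diffs[cs[i] - w[1] + 1L] <- diffs[cs[i] - w[1] + 1L] + 1
    diffs[ce[i] - w[1] + 1L] <- diffs[ce[i] - w[1] + 1L] - 1
  }
  depth <- cumsum(diffs[seq_len(width)])
  refb <- strsplit(subseq0(ref$reference, w[1], w[2]), "")[[1]]
  alt_rows <- lapply(c("A", "C", "G", "T"), function(b) {
    keep <- refb != b
    data.frame(coord = coords[keep], ref_base = refb[keep], alt_base = b,
               count = 0L, depth = as.integer(depth[keep]))
  })
  out <- do.call(rbind, alt_rows)
  out <- out[order(out$coord, out$alt_base), , drop = FALSE]
  ev <- alns$events
  clean <- records$read[records$aligned & records$n_indels == 0L]
  subs <- ev[ev$type == "sub" & ev$read %in% clean &
               ev$coord >= w[1] & ev$coord < w[2], , drop = FALSE]
  if (nrow(subs)) {
    key <- paste(subs$coord, subs$seq)
    cnt <- table(key)
    idx <- match(paste(out$coord, out$alt_base), names(cnt))
    out$count <- ifelse(is.na(idx), 0L, as.integer(cnt[idx]))
  }
  out$freq <- ifelse(out$depth >= min_depth, out$count / out$depth, NA_real_)
  rownames(out) <- NULL
  out
}

#' Indel frequency at a pegRNA-dependent off-target site
#'
#' Applies the same 80-bp window construction and unintended-indel counting
#' at an off-target locus carrying its own protospacer/PAM geometry.
#'
#' @param reads character vector of reads from the off-target amplicon.
#' @param ot_site a [target_spec()] (or [amplicon_ref()]) for the off-target
#'   locus.
#' @param ... passed to [align_reads()].
#' @return list with `value`, `numerator`, `denominator`.
#' @export
ot_indel_frequency <- function(reads, ot_site, ...) {
  ref <- if (inherits(ot_site, "amplicon_ref")) ot_site
         else amplicon_ref(ot_site)
  alns <- align_reads(reads, ref$reference, ...)
  rec <- classify_reads(alns, ref)
  unintended_indel_frequency(rec)
}

#' Quantify editing outcomes from amplicon reads
#'
#' End-to-end pipeline: align reads to the reference, classify each read,
#' and assemble every outcome frequency plus the per-position substitution
#' matrix.
#'
#' @param ref an [amplicon_ref()].
#' @param reads character vector of reads, a data frame with a `seq` column,
#'   or a FASTQ path.
#' @param min_depth depth threshold for the substitution matrix.
#' @param mode "auto" picks substitution vs indel reporting from the edit
#'   kind.
#' @param scaffold_params thresholds for the scaffold-insertion detector.
#' @param ... passed to [align_reads()].
#' @return object of class `outcome_table`.
#' @export
quantify <- function(ref, reads, min_depth = 1000L,
                     mode = c("auto", "substitution", "indel"),
                     scaffold_params = list(), ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "amplicon_ref"))
  if (is.data.frame(reads)) reads <- reads$seq
  if (length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fastq|fq)$", reads)) reads <- read_fastq(reads)$seq
  if (mode == "auto")
    mode <- if (!is.null(ref$edit) && ref$edit$kind != "substitution")
      "indel" else "substitution"
  alns <- align_reads(reads, ref$reference, ...)
  rec <- classify_reads(alns, ref, scaffold_params)
  ib <- incomplete_and_byproduct_frequencies(rec)
  freqs <- list(
    unintended_indel = unintended_indel_frequency(
      rec, if (mode == "indel") "indel_experiment" else "substitution_experiment"),
    incomplete_product = ib$incomplete,
    byproduct = ib$byproduct)
  freqs$intended_edit <- if (mode == "indel") intended_indel_frequency(rec, ref)
                         else intended_substitution_frequency(rec)
  structure(list(
    total_reads = sum(alns$aligned), n_input = length(reads), mode = mode,
    window = quant_window(ref), frequencies = freqs,
    substitutions = substitution_frequencies(alns, rec, ref, min_depth),
    records = rec, alignments = alns),
    class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  cat(sprintf("outcome_table: %d/%d reads aligned (%s mode), window [%d,%d)\n",
              x$total_reads, x$n_input, x$mode, x$window[1], x$window[2]))
  for (nm in c("intended_edit", "unintended_indel", "incomplete_product",
               "byproduct")) {
    f <- x$frequencies[[nm]]
    cat(sprintf("  %-20s %8.4f  (%d / %d)\n", nm, f$value, f$numerator,
                f$denominator))
  }
  invisible(x)
}

#' Outcome frequencies as a one-row data frame
#'
#' @param x an `outcome_table`.
#' @param ... unused.
#' @return data frame with one column per reported frequency.
#' @export
as.data.frame.outcome_table <- function(x, ...) {
  vals <- lapply(x$frequencies, `[[`, "value")
  data.frame(total_reads = x$total_reads,
             intended_edit = vals$intended_edit,
             unintended_indel = vals$unintended_indel,
             incomplete_product = vals$incomplete_product,
             byproduct = vals$byproduct)
}
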