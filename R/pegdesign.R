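# pegRNA construction and the same-sense-mutation (SSM) placement rule.
#
# RTT positions are counted from the 3' base of the RTT as position 1, so
# RTT position p templates the PAM-strand base at nick-relative offset +p.
# The high-efficiency rule places one or two additional synonymous
# substitutions at RTT positions drawn from the catalog {1},{5},{6},{2,5},
# {3,6}; which of these are wobble (codon position 3) positions depends on
# the register between the gene's reading frame and the RTT 3' end (the ORF
# phase).

#' Primer-binding-site sequence
#'
#' Reverse complement of the `pbs_len` PAM-strand bases immediately 5' of
#' the nick.
#'
#' @param target a [target_spec()].
#' @param pbs_len PBS length, 1..17 (default 13).
#' @return PBS sequence, 5'->3'.
#' @export
build_pbs <- function(target, pbs_len = 13L) {
  pbs_len <- as.integer(pbs_len)
  if (pbs_len < 1L || pbs_len > 17L)
    pc_stop("pbs_len must be in 1..17", "pegcraft_range")
  coords <- offset_to_ref(target, -(1:pbs_len))
  if (any(coords < 0L) || any(coords >= nchar(target$reference)))
    pc_stop("PBS extends beyond the reference", "pegcraft_range")
  seg <- pam_strand_base(target$reference, target$strand, rev(coords)) # 5'->3'
  revcomp(paste(seg, collapse = ""))
}

#' Reverse-transcription-template sequence
#'
#' Reverse complement of the edited PAM-strand segment spanning nick-relative
#' offsets +1..+rtt_len, with the intended edit and any same-sense
#' substitutions applied. RTT position p (3' end = position 1) templates
#' offset +p.
#'
#' @param target a [target_spec()].
#' @param edit an [edit_spec()] or NULL for no edit.
#' @param rtt_len RTT length.
#' @param ssms data frame with columns `position`, `ref_base`, `alt_base`
#'   (PAM strand), e.g. from [choose_ssm()]; NULL for none.
#' @return RTT sequence, 5'->3'.
#' @export
build_rtt <- function(target, edit = NULL, rtt_len = 13L, ssms = NULL) {
  rtt_len <- as.integer(rtt_len)
  if (rtt_len < 1L) pc_stop("rtt_len must be positive", "pegcraft_range")
  if (!is.null(edit)) {
    need <- if (edit$kind == "deletion") edit$offset
            else edit$offset + nchar(edit$alt_allele) - 1L
    if (need > rtt_len)
      pc_stop("rtt_len does not cover the edit", "pegcraft_range")
    ed <- apply_edit(target, edit)
  } else {
    ed <- list(seq = target$reference, delta = 0L)
  }
  coords <- offset_to_edited(target, edit, 1:rtt_len)
  if (any(coords < 0L) || any(coords >= nchar(ed$seq)))
    pc_stop("rtt_len extends beyond the reference", "pegcraft_range")
  seg <- pam_strand_base(ed$seq, target$strand, coords) # offsets +1..+rtt_len
  if (!is.null(ssms) && nrow(ssms)) {
    if (any(ssms$position > rtt_len))
      pc_stop("SSM position beyond rtt_len", "pegcraft_range")
    if (!is.null(edit) && any(ssms$position %in% edit_offsets(edit)))
      pc_stop("SSM collides with the intended edit", "pegcraft_conflict")
    for (r in seq_len(nrow(ssms))) {
      p <- ssms$position[r]
      if (seg[p] != ssms$ref_base[r])
        pc_stop(sprintf("SSM ref base mismatch at RTT position %d", p),
                "pegcraft_conflict")
      seg[p] <- ssms$alt_base[r]
    }
  }
  revcomp(paste(seg, collapse = ""))
}

#' ORF phase at the RTT 3' end
#'
#' Determines the register between the coding frame and the first bases
#' written by the RTT: exactly one of nick-relative offsets +1..+3 is a
#' wobble (codon position 3) base. The phase is labelled so that each
#' phase's recommended single-SSM catalog positions are wobble positions:
#' wobble at +1 (hence +4, +7) is ORF2; at +2 (+5, +8) is ORF3; at +3
#' (+6, +9) is ORF1.
#'
#' @param target a [target_spec()].
#' @param frame a [reading_frame()].
#' @return "ORF1", "ORF2" or "ORF3".
#' @export
rtt_wobble_phase <- function(target, frame) {
  coords <- offset_to_ref(target, 1:3)
  cp <- codon_position(coords, frame)  # errors if outside CDS
  w <- which(cp == 3L)
  stopifnot(length(w) == 1L)
  c("ORF2", "ORF3", "ORF1")[w]
}

#' SSM scheme catalog
#'
#' The five recommended RTT position sets for additional same-sense
#' substitutions, ordered by reported median fold-improvement:
#' \{2,5\} (1.90) > \{5\} (1.62) > \{3,6\} (1.41) > \{6\} (1.32) > \{1\} (1.28).
#'
#' @return list of integer vectors.
#' @export
ssm_scheme_catalog <- function() {
  list(c(2L, 5L), 5L, c(3L, 6L), 6L, 1L)
}

#' Recommended SSM schemes for an ORF phase
#'
#' ORF1 -> \{3,6\} then \{6\}; ORF2 -> \{1\}; ORF3 -> \{2,5\} then \{5\}.
#' Dual schemes come first: two additional substitutions gave the largest
#' median gains.
#'
#' @param phase "ORF1", "ORF2" or "ORF3".
#' @return list of integer vectors (RTT positions).
#' @export
recommended_schemes <- function(phase) {
  switch(match.arg(phase, c("ORF1", "ORF2", "ORF3")),
         ORF1 = list(c(3L, 6L), 6L),
         ORF2 = list(1L),
         ORF3 = list(c(2L, 5L), 5L))
}

scheme_label <- function(scheme) paste(scheme, collapse = "/")

# Extract the codon containing edited-sequence coordinate `coord` on the
# coding strand; returns list(codon, pos_in_codon, coords 5'->3').
codon_at <- function(seq, frame, coord) {
  cp <- codon_position(coord, frame)
  step <- if (frame$coding_strand == "+") 1L else -1L
  start <- coord - step * (cp - 1L)
  coords <- start + step * (0:2)
  if (any(coords < frame$cds_start | coords >= frame$cds_end))
    pc_stop("codon extends outside the CDS", "pegcraft_out_of_frame")
  bases <- vapply(coords, function(k) subseq0(seq, k, k + 1L), character(1))
  if (frame$coding_strand == "-") bases <- comp_base(bases)
  list(codon = paste(bases, collapse = ""), pos = cp, coords = coords)
}

# Lift a reading frame onto the edited sequence. The anchor is moved in
# +3 steps if it falls inside a deletion; the CDS end absorbs the length
# change of an edit internal to it.
lift_frame <- function(frame, ed) {
  a <- ed$lift(frame$frame_anchor)
  tries <- 0L
  while (is.na(a) && tries < 64L) {
    tries <- tries + 1L
    a <- ed$lift(frame$frame_anchor + 3L * tries)
  }
  if (is.na(a)) pc_stop("cannot lift frame anchor across the edit",
                        "pegcraft_out_of_frame")
  s <- frame$cds_start
  e <- frame$cds_end
  s2 <- if (s <= ed$pos) s else max(ed$pos, s + ed$delta)
  e2 <- if (e <= ed$pos) e else max(ed$pos, e + ed$delta)
  reading_frame(frame$coding_strand, a, s2, e2)
}

#' Choose same-sense substitutions for an SSM scheme
#'
#' For each RTT position in the scheme, finds an alternative base such that
#' the containing codon -- evaluated on the sequence carrying the intended
#' edit -- still encodes the same amino acid. Deterministic tie-break: the
#' alphabetically smallest synonymous base on the PAM strand. The
#' substitution type is otherwise unconstrained, since the type of the
#' additional substitution does not materially affect efficiency.
#'
#' @param target a [target_spec()].
#' @param frame a [reading_frame()].
#' @param scheme integer vector of RTT positions (e.g. `c(3, 6)`).
#' @param edit an [edit_spec()] or NULL.
#' @return data frame with columns `position`, `ref_base`, `alt_base`
#'   (PAM strand).
#' @export
choose_ssm <- function(target, frame, scheme, edit = NULL) {
  scheme <- sort(as.integer(scheme))
  if (!is.null(edit) && any(scheme %in% edit_offsets(edit)))
    pc_stop("SSM scheme position collides with the intended edit",
            "pegcraft_conflict")
  if (!is.null(edit)) {
    ed <- apply_edit(target, edit)
    fr <- lift_frame(frame, ed)
  } else {
    ed <- list(seq = target$reference, delta = 0L)
    fr <- frame
  }
  out <- data.frame(position = scheme, ref_base = NA_character_,
                    alt_base = NA_character_)
  for (r in seq_along(scheme)) {
    coord <- offset_to_edited(target, edit, scheme[r])
    if (coord < fr$cds_start || coord >= fr$cds_end)
      pc_stop(sprintf("RTT position %d lies outside the CDS", scheme[r]),
              "pegcraft_out_of_frame")
    cd <- codon_at(ed$seq, fr, coord)
    alts <- synonymous_alternatives(cd$codon, cd$pos)
    if (!length(alts))
      pc_stop(sprintf("no synonymous alternative at RTT position %d (codon %s)",
                      scheme[r], cd$codon), "pegcraft_infeasible")
    # alternatives are on the coding strand; express on the PAM strand
    if (fr$coding_strand != target$strand) alts <- comp_base(alts)
    out$ref_base[r] <- pam_strand_base(ed$seq, target$strand, coord)
    out$alt_base[r] <- min(alts)
  }
  out
}

peg_design <- function(name, target, edit, scheme, ssms, scaffold_variant,
                       scaffold_seq, spacer, rtt, pbs) {
  structure(list(name = name, scheme = scheme, ssms = ssms,
                 scaffold_variant = scaffold_variant, spacer = spacer,
                 scaffold = scaffold_seq, rtt = rtt, pbs = pbs,
                 edit = if (is.null(edit)) NA_character_ else edit$name,
                 full_sequence = paste0(spacer, scaffold_seq, rtt, pbs)),
            class = "peg_design")
}

#' @export
print.peg_design <- function(x, ...) {
  cat(sprintf("pegRNA design %s [%s]\n  spacer %s\n  RTT %s  PBS %s\n  SSMs: %s\n",
              x$name, x$scaffold_variant, x$spacer, x$rtt, x$pbs,
              if (nrow(x$ssms)) paste(sprintf("+%d%s>%s", x$ssms$position,
                                              x$ssms$ref_base, x$ssms$alt_base),
                                      collapse = ", ") else "none"))
  invisible(x)
}

#' Tabulate a list of pegRNA designs
#'
#' @param designs list of `peg_design` objects.
#' @return data frame, one row per design.
#' @export
designs_table <- function(designs) {
  if (!length(designs))
    return(data.frame(name = character(), edit = character(),
                      scheme = character(), ssms = character(),
                      scaffold_variant = character(), spacer = character(),
                      rtt = character(), pbs = character(),
                      full_sequence = character()))
  do.call(rbind, lapply(designs, function(d) data.frame(
    name = d$name, edit = d$edit, scheme = scheme_label(d$scheme),
    ssms = if (nrow(d$ssms)) paste(sprintf("%d:%s>%s", d$ssms$position,
                                           d$ssms$ref_base, d$ssms$alt_base),
                                   collapse = ";") else "",
    scaffold_variant = d$scaffold_variant, spacer = d$spacer,
    rtt = d$rtt, pbs = d$pbs, full_sequence = d$full_sequence)))
}

default_rtt_len <- function(edit) {
  end3 <- if (is.null(edit)) 0L
          else if (edit$kind == "deletion") edit$offset
          else edit$offset + nchar(edit$alt_allele) - 1L
  max(13L, end3 + 6L)
}

design_one <- function(target, edit, scheme, ssms, variant, model,
                       pbs_len, rtt_len, prefix) {
  scaffold_seq <- stabilize_scaffold(model, variant)
  name <- sprintf("%speg%s_p%s", prefix,
                  if (is.null(edit)) "" else paste0("_", edit$name),
                  if (length(scheme)) scheme_label(scheme) else "0")
  peg_design(name, target, edit, scheme, ssms, variant, scaffold_seq,
             target$spacer,
             build_rtt(target, edit, rtt_len, ssms),
             build_pbs(target, pbs_len))
}

empty_ssms <- function() data.frame(position = integer(),
                                    ref_base = character(),
                                    alt_base = character())

#' Design spegRNAs (same-sense-mutation pegRNAs) for a target
#'
#' Emits one design per feasible SSM scheme, recommended schemes for the
#' target's ORF phase first (dual scheme before single). With
#' `extended = TRUE`, the remaining catalog schemes whose positions admit
#' synonymous substitutions (necessarily at codon positions 1 or 2) follow,
#' in order of reported median gain. At most 5 designs are emitted and every
#' design carries at most 4 additional substitutions.
#'
#' @param target a [target_spec()].
#' @param edit an [edit_spec()].
#' @param frame a [reading_frame()].
#' @param pbs_len PBS length (default 13).
#' @param rtt_len RTT length; default `max(13, edit 3' end + 6)`.
#' @param extended also try non-recommended catalog schemes.
#' @param scaffold a [scaffold_model()] (default [default_scaffold()]).
#' @param scaffold_variant scaffold variant label (default "regular").
#' @return list of `peg_design` objects (possibly empty, with a warning).
#' @export
design_spegrnas <- function(target, edit, frame, pbs_len = 13L,
                            rtt_len = NULL, extended = FALSE,
                            scaffold = default_scaffold(),
                            scaffold_variant = "regular") {
  if (is.null(rtt_len)) rtt_len <- default_rtt_len(edit)
  phase <- rtt_wobble_phase(target, frame)
  rec <- recommended_schemes(phase)
  schemes <- rec
  if (extended) {
    rest <- Filter(function(s) !any(vapply(rec, identical, logical(1), s)),
                   ssm_scheme_catalog())
    schemes <- c(rec, rest)
  }
  designs <- list()
  for (scheme in schemes) {
    if (length(designs) >= 5L) break
    ssms <- tryCatch(choose_ssm(target, frame, scheme, edit),
                     pegcraft_infeasible = function(e) NULL,
                     pegcraft_conflict = function(e) NULL,
                     pegcraft_out_of_frame = function(e) NULL)
    if (is.null(ssms)) next
    stopifnot(nrow(ssms) <= 4L)
    designs[[length(designs) + 1L]] <-
      design_one(target, edit, scheme, ssms, scaffold_variant, scaffold,
                 pbs_len, rtt_len, prefix = "s")
  }
  if (!length(designs))
    warning("no feasible SSM scheme for this target; use the regular pegRNA")
  designs
}

#' Design aspegRNAs: stabilized scaffold combined with SSM schemes
#'
#' Combines the apegRNA-2 scaffold (C/G pair at the bottom of the small
#' hairpin) with every feasible SSM scheme. When no reading frame is
#' supplied (e.g. a non-coding indel target), a single design with the
#' stabilized scaffold and no SSMs is returned, with a warning.
#'
#' @inheritParams design_spegrnas
#' @param variant stabilized scaffold variant (default "apegRNA-2").
#' @return list of `peg_design` objects.
#' @export
design_aspegrna <- function(target, edit, frame = NULL, pbs_len = 13L,
                            rtt_len = NULL, extended = FALSE,
                            scaffold = default_scaffold(),
                            variant = "apegRNA-2") {
  if (is.null(rtt_len)) rtt_len <- default_rtt_len(edit)
  plain <- function() {
    warning("no CDS annotation or no feasible SSM scheme; emitting the ",
            "stabilized-scaffold design without SSMs")
    list(design_one(target, edit, integer(0), empty_ssms(), variant,
                    scaffold, pbs_len, rtt_len, prefix = "a"))
  }
  if (is.null(frame)) return(plain())
  designs <- withCallingHandlers(
    design_spegrnas(target, edit, frame, pbs_len, rtt_len, extended,
                    scaffold, scaffold_variant = variant),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!length(designs)) return(plain())
  for (i in seq_along(designs))
    designs[[i]]$name <- sub("^s", "as", designs[[i]]$name)
  designs
}

#' Candidate nicking sgRNAs for the PE3 strategy
#'
#' Enumerates all 20-mers on the strand opposite the pegRNA protospacer
#' whose PAM matches `pam_pattern` and whose implied nick falls within the
#' given distance window of the pegRNA nick; sorted by distance.
#'
#' @param target a [target_spec()].
#' @param window integer pair: allowed nick-to-nick distance (default
#'   `c(40, 100)`).
#' @param spacer_len candidate spacer length (default 20).
#' @return data frame: `spacer`, `start`, `end`, `strand`, `pam`,
#'   `nick_distance` (0-based half-open site coordinates).
#' @export
design_nick_sgrna <- function(target, window = c(40L, 100L), spacer_len = 20L) {
  ref <- target$reference
  n <- nchar(ref)
  strand <- if (target$strand == "+") "-" else "+"
  plen <- nchar(target$pam_pattern)
  hits <- list()
  for (s in 0:(n - spacer_len)) {
    if (strand == "+") {
      if (s + spacer_len + plen > n) next
      pam <- subseq0(ref, s + spacer_len, s + spacer_len + plen)
      if (!pam_matches(pam, target$pam_pattern)) next
      spacer <- subseq0(ref, s, s + spacer_len)
      nick <- s + spacer_len - 3L
    } else {
      if (s - plen < 0L) next
      pam <- revcomp(subseq0(ref, s - plen, s))
      if (!pam_matches(pam, target$pam_pattern)) next
      spacer <- revcomp(subseq0(ref, s, s + spacer_len))
      nick <- s + 3L
    }
    d <- abs(nick - target$nick_coord)
    if (d < window[1] || d > window[2]) next
    hits[[length(hits) + 1L]] <- data.frame(
      spacer = spacer, start = s, end = s + spacer_len, strand = strand,
      pam = pam, nick_distance = d)
  }
  if (!length(hits))
    return(data.frame(spacer = character(), start = integer(),
                      end = integer(), strand = character(),
                      pam = character(), nick_distance = integer()))
  out <- do.call(rbind, hits)
  out[order(out$nick_distance, out$start), , drop = FALSE]
}

#' Cloning oligos for a pegRNA design
#'
#' Two annealed pairs: the spacer pair and the 3'-extension (RTT+PBS) pair.
#' Forward oligo = 5' overhang + part; reverse oligo = 5' overhang +
#' reverse complement of the part. Overhangs are plasmid-specific and
#' configurable.
#'
#' @param design a `peg_design`.
#' @param overhangs list with `spacer_fwd`, `spacer_rev`, `ext_fwd`,
#'   `ext_rev` 5' overhangs (defaults: BsaI-style ACCG/AAAC for the spacer,
#'   none for the extension).
#' @return data frame: `part`, `forward`, `reverse`.
#' @export
emit_oligos <- function(design,
                        overhangs = list(spacer_fwd = "ACCG",
                                         spacer_rev = "AAAC",
                                         ext_fwd = "", ext_rev = "")) {
  ext <- paste0(design$rtt, design$pbs)
  data.frame(
    part = c("spacer", "extension"),
    forward = c(paste0(overhangs$spacer_fwd, design$spacer),
                paste0(overhangs$ext_fwd, ext)),
    reverse = c(paste0(overhangs$spacer_rev, revcomp(design$spacer)),
                paste0(overhangs$ext_rev, revcomp(ext))))
}
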