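# Target and edit specifications, and the single boundary where 1-based
# nick-relative offsets are converted to 0-based reference coordinates.

#' Define a prime-editing target on a reference sequence
#'
#' The protospacer is given as a 0-based half-open interval on the reference
#' together with the strand it lies on (the "PAM strand"). The PAM must sit
#' immediately 3' of the protospacer on that strand and match `pam_pattern`
#' (N matches any of A/C/G/T). The nick is placed 3 nt 5' of the PAM, i.e.
#' between protospacer positions 17 and 18 for a 20-mer, the canonical
#' SpCas9-nickase cut used by prime editors.
#'
#' @param reference reference/amplicon sequence (character scalar).
#' @param proto_start 0-based start of the protospacer on the reference.
#' @param proto_len protospacer length (default 20; 17-24 allowed).
#' @param strand "+" or "-": strand of the protospacer (= PAM strand).
#' @param pam_pattern PAM pattern, default "NGG".
#' @return object of class `target_spec` with the derived nick coordinate.
#' @export
target_spec <- function(reference, proto_start, proto_len = 20L,
                        strand = "+", pam_pattern = "NGG") {
  reference <- dna(reference)
  proto_start <- as.integer(proto_start)
  proto_len <- as.integer(proto_len)
  pam_pattern <- dna(pam_pattern, allow_n = TRUE)
  stopifnot(strand %in% c("+", "-"))
  if (proto_len < 17L || proto_len > 24L)
    pc_stop("protospacer length must be 17-24", "pegcraft_range")
  L <- nchar(reference)
  plen <- nchar(pam_pattern)
  if (proto_start < 0L || proto_start + proto_len > L)
    pc_stop("protospacer outside reference", "pegcraft_range")
  if (strand == "+") {
    if (proto_start + proto_len + plen > L)
      pc_stop("no room for PAM 3' of protospacer", "pegcraft_range")
    pam_obs <- subseq0(reference, proto_start + proto_len,
                       proto_start + proto_len + plen)
    spacer <- subseq0(reference, proto_start, proto_start + proto_len)
    nick <- proto_start + proto_len - 3L
  } else {
    if (proto_start - plen < 0L)
      pc_stop("no room for PAM 3' of protospacer", "pegcraft_range")
    pam_obs <- revcomp(subseq0(reference, proto_start - plen, proto_start))
    spacer <- revcomp(subseq0(reference, proto_start, proto_start + proto_len))
    # nick boundary: between reference coords (proto_start+2) and (proto_start+3)
    nick <- proto_start + 3L
  }
  if (!pam_matches(pam_obs, pam_pattern))
    pc_stop(sprintf("PAM %s does not match pattern %s", pam_obs, pam_pattern),
            "pegcraft_pam_mismatch")
  structure(list(reference = reference, proto_start = proto_start,
                 proto_len = proto_len, strand = strand,
                 pam_pattern = pam_pattern, pam = pam_obs,
                 spacer = spacer, nick_coord = nick),
            class = "target_spec")
}

pam_matches <- function(obs, pattern) {
  if (nchar(obs) != nchar(pattern)) return(FALSE)
  ob <- strsplit(obs, "")[[1]]
  pb <- strsplit(pattern, "")[[1]]
  all(ifelse(pb == "N", ob %in% c("A", "C", "G", "T"), ob == pb))
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf("target_spec: %d-nt protospacer at [%d,%d) on %s strand, PAM %s, nick at %d\n",
              x$proto_len, x$proto_start, x$proto_start + x$proto_len,
              x$strand, x$pam, x$nick_coord))
  invisible(x)
}

#' Convert a nick-relative offset to a reference coordinate
#'
#' Offsets are 1-based signed integers on the PAM strand: +1 is the first
#' base 3' of the nick (the base templated by RTT position 1), -1 the first
#' base 5' of the nick (the first PBS-complementary base). This is the only
#' function converting between the two coordinate systems.
#'
#' @param target a [target_spec()].
#' @param offset integer vector of non-zero offsets.
#' @return 0-based reference coordinates.
#' @export
offset_to_ref <- function(target, offset) {
  offset <- as.integer(offset)
  if (any(offset == 0L)) pc_stop("offset 0 is undefined", "pegcraft_range")
  b <- target$nick_coord
  if (target$strand == "+") {
    ifelse(offset > 0L, b + offset - 1L, b + offset)
  } else {
    ifelse(offset > 0L, b - offset, b - offset - 1L)
  }
}

# PAM-strand base(s) at given reference coordinates of `seq`
pam_strand_base <- function(seq, strand, coord) {
  b <- vapply(coord, function(k) subseq0(seq, k, k + 1L), character(1))
  if (strand == "-") b <- comp_base(b)
  b
}

#' Specify an intended edit at a nick-relative offset
#'
#' Edits are written on the PAM strand. `offset` is the 1-based position 3'
#' of the nick: a substitution "+5G-to-T" replaces the reference base at
#' offset +5; an insertion "+1GATins" inserts GAT so that the inserted bases
#' occupy offsets +1..+3; a deletion "+1TGAdel" removes the reference bases
#' at offsets +1..+3.
#'
#' @param kind "substitution", "insertion" or "deletion".
#' @param offset positive integer, nick-relative.
#' @param ref_allele reference allele on the PAM strand ("" for insertion).
#' @param alt_allele replacement/inserted allele ("" for deletion).
#' @return object of class `edit_spec`.
#' @export
edit_spec <- function(kind, offset, ref_allele = "", alt_allele = "") {
  kind <- match.arg(kind, c("substitution", "insertion", "deletion"))
  offset <- as.integer(offset)
  if (offset < 1L) pc_stop("edit offset must be positive", "pegcraft_range")
  ref_allele <- dna(ref_allele, allow_empty = TRUE)
  alt_allele <- dna(alt_allele, allow_empty = TRUE)
  ok <- switch(kind,
    substitution = nzchar(ref_allele) && nchar(ref_allele) == nchar(alt_allele),
    insertion    = !nzchar(ref_allele) && nzchar(alt_allele),
    deletion     = nzchar(ref_allele) && !nzchar(alt_allele))
  if (!ok) pc_stop("alleles inconsistent with edit kind", "pegcraft_invalid_edit")
  structure(list(kind = kind, offset = offset, ref_allele = ref_allele,
                 alt_allele = alt_allele, name = format_edit_name(kind, offset,
                                                                  ref_allele, alt_allele)),
            class = "edit_spec")
}

format_edit_name <- function(kind, offset, ref_allele, alt_allele) {
  switch(kind,
    substitution = sprintf("+%d%s-to-%s", offset, ref_allele, alt_allele),
    insertion    = sprintf("+%d%sins", offset, alt_allele),
    deletion     = sprintf("+%d%sdel", offset, ref_allele))
}

#' Parse an edit name such as "+5G-to-T" or "+1GATins"
#'
#' Round-trips with [edit_spec()]: `parse_edit(e$name)` reproduces `e`.
#'
#' @param name edit name string.
#' @return an `edit_spec`.
#' @export
parse_edit <- function(name) {
  name <- trimws(name)
  m <- regmatches(name, regexec("^\\+([0-9]+)([ACGT]+)-to-([ACGT]+)$", name))[[1]]
  if (length(m)) return(edit_spec("substitution", m[2], m[3], m[4]))
  m <- regmatches(name, regexec("^\\+([0-9]+)([ACGT]+)ins$", name))[[1]]
  if (length(m)) return(edit_spec("insertion", m[2], "", m[3]))
  m <- regmatches(name, regexec("^\\+([0-9]+)([ACGT]+)del$", name))[[1]]
  if (length(m)) return(edit_spec("deletion", m[2], m[3], ""))
  pc_stop(sprintf("cannot parse edit name: %s", name), "pegcraft_invalid_edit")
}

# Offsets occupied by the edit on the edited PAM strand (empty for deletion)
edit_offsets <- function(edit) {
  switch(edit$kind,
    substitution = edit$offset + seq_len(nchar(edit$alt_allele)) - 1L,
    insertion    = edit$offset + seq_len(nchar(edit$alt_allele)) - 1L,
    deletion     = integer(0))
}

# Net length change introduced by the edit
edit_delta <- function(edit) {
  nchar(edit$alt_allele) - nchar(edit$ref_allele)
}

# Reference-coordinate footprint of the edit:
#  substitution: interval of replaced bases
#  insertion: zero-length interval at the insertion point
#  deletion: interval of removed bases
edit_ref_interval <- function(target, edit) {
  k <- edit$offset
  if (edit$kind == "insertion") {
    pos <- if (target$strand == "+") target$nick_coord + k - 1L
           else target$nick_coord - k + 1L
    return(c(pos, pos))
  }
  m <- nchar(edit$ref_allele)
  coords <- offset_to_ref(target, k:(k + m - 1L))
  c(min(coords), max(coords) + 1L)
}

# Verify substitution/deletion ref alleles against the reference
check_edit_ref <- function(target, edit) {
  if (edit$kind == "insertion") return(invisible(TRUE))
  iv <- edit_ref_interval(target, edit)
  obs <- subseq0(target$reference, iv[1], iv[2])
  if (target$strand == "-") obs <- revcomp(obs)
  if (obs != edit$ref_allele)
    pc_stop(sprintf("ref allele mismatch: expected %s at offsets +%d.., found %s",
                    edit$ref_allele, edit$offset, obs), "pegcraft_invalid_edit")
  invisible(TRUE)
}

#' Apply an intended edit to the reference sequence
#'
#' Returns the fully edited sequence plus the bookkeeping needed to lift
#' reference coordinates into edited-sequence coordinates.
#'
#' @param target a [target_spec()].
#' @param edit an [edit_spec()].
#' @return list with `seq` (edited sequence), `delta` (net length change),
#'   `pos`/`end` (0-based reference interval replaced) and `lift`, a function
#'   mapping reference coordinates to edited coordinates (NA inside a
#'   deletion).
#' @export
apply_edit <- function(target, edit) {
  check_edit_ref(target, edit)
  ref <- target$reference
  iv <- edit_ref_interval(target, edit)
  allele <- edit$alt_allele
  if (target$strand == "-" && nzchar(allele)) allele <- revcomp(allele)
  edited <- paste0(subseq0(ref, 0L, iv[1]), allele, subseq0(ref, iv[2], nchar(ref)))
  delta <- edit_delta(edit)
  lift <- function(coord) {
    coord <- as.integer(coord)
    out <- ifelse(coord < iv[1], coord,
           ifelse(coord >= iv[2], coord + delta, NA_integer_))
    if (edit$kind == "substitution")
      out <- ifelse(coord >= iv[1] & coord < iv[2], coord, out)
    out
  }
  list(seq = edited, delta = delta, pos = iv[1], end = iv[2], lift = lift)
}

# Edited-sequence coordinate of nick-relative offset +p on the edited PAM
# strand (offsets count along the edited strand; the intended edit sits at
# its own offsets).
offset_to_edited <- function(target, edit, offset) {
  offset <- as.integer(offset)
  stopifnot(all(offset >= 1L))
  delta <- if (is.null(edit)) 0L else edit_delta(edit)
  b <- target$nick_coord
  if (target$strand == "+") b + offset - 1L else (b + delta) - offset
}
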