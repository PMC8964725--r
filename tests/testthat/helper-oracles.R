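# Independent brute-force oracles used to validate the package's
# implementations on small instances.

BASES <- c("A", "C", "G", "T")

# Translate a DNA string via Biostrings (independent of the codon logic in
# the package, which works base-by-base).
oracle_translate <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     no.init.codon = TRUE))
}

# Brute-force synonymous alternatives: substitute every base at pos and
# compare translations.
oracle_syn_alts <- function(codon, pos) {
  ref <- substr(codon, pos, pos)
  alts <- setdiff(BASES, ref)
  keep <- vapply(alts, function(b) {
    mut <- codon
    substr(mut, pos, pos) <- b
    oracle_translate(mut) == oracle_translate(codon)
  }, logical(1))
  sort(alts[keep])
}

# Sliding-window off-target oracle: count mismatches at every position on
# both strands, gate on the PAM.
oracle_scan <- function(spacer, subject, max_mm, pam = "NGG") {
  L <- nchar(spacer)
  plen <- nchar(pam)
  gv <- strsplit(spacer, "")[[1]]
  pv <- strsplit(pam, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    seq <- if (strand == "+") subject else pegcraft::revcomp(subject)
    sv <- strsplit(seq, "")[[1]]
    n <- length(sv)
    if (n < L + plen) next
    for (s in 1:(n - L - plen + 1)) {
      site <- sv[s:(s + L - 1)]
      pamb <- sv[(s + L):(s + L + plen - 1)]
      pam_ok <- all(ifelse(pv == "N", pamb %in% BASES, pamb == pv))
      if (!pam_ok) next
      mm <- sum(site != gv)
      if (mm > max_mm) next
      st <- if (strand == "+") s - 1 else nchar(subject) - (s - 1 + L)
      hits[[length(hits) + 1]] <- data.frame(
        start = st, strand = strand, mismatch_count = mm)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(), strand = character(),
                                       mismatch_count = integer()))
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Gotoh affine-gap dynamic program for pattern-global / subject-local
# alignment; gap of length k costs open + k * ext. Returns the best score.
oracle_semiglobal_score <- function(pattern, subject, match = 2, mismatch = -4,
                                    open = 6, ext = 1) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  np <- length(p); ns <- length(s)
  NEG <- -1e9
  # M: p[i] aligned to s[j]; Ip: gap in subject (pattern base consumed);
  # Is: gap in pattern (subject base consumed)
  M <- matrix(NEG, np + 1, ns + 1)
  Ip <- matrix(NEG, np + 1, ns + 1)
  Is <- matrix(NEG, np + 1, ns + 1)
  M[1, ] <- 0  # subject-local: free leading subject bases
  for (i in 2:(np + 1)) {
    Ip[i, 1] <- -(open + (i - 1) * ext)
    for (j in seq_len(ns + 1)[-1]) {
      sc <- if (p[i - 1] == s[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], Ip[i - 1, j - 1], Is[i - 1, j - 1]) + sc
      Ip[i, j] <- max(M[i - 1, j] - open - ext, Ip[i - 1, j] - ext)
      Is[i, j] <- max(M[i, j - 1] - open - ext, Is[i, j - 1] - ext)
    }
    if (ns == 0) next
  }
  max(M[np + 1, ], Ip[np + 1, ])  # free trailing subject bases
}

# Exact Wilcoxon signed-rank tail probability by literal enumeration of all
# 2^m sign assignments.
oracle_signrank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^m - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(m - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  if (alternative == "greater") mean(ws >= w_obs) else mean(ws <= w_obs)
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

mutate_bases <- function(seq, n_mut) {
  v <- strsplit(seq, "")[[1]]
  idx <- sample(length(v), n_mut)
  for (i in idx) v[i] <- sample(setdiff(BASES, v[i]), 1)
  paste(v, collapse = "")
}

# A deterministic toy target: 20-nt protospacer at the start of the
# reference, nick after protospacer position 17, PAM-strand segment
# +1..+9 = GGTGCTAAA (codons GGT|GCT|AAA when the frame anchor sits at +1).
toy_orf1_target <- function() {
  ref <- paste0(strrep("A", 17), "GGTGCTAAA", strrep("C", 24))
  target <- target_spec(ref, 0, 20, "+", pam_pattern = "NNN")
  frame <- reading_frame("+", 17, 0, nchar(ref))
  list(target = target, frame = frame)
}
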