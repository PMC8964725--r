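test_that("build_pbs reverse-complements the bases 5' of the nick", {
  ref <- paste0("ACGTACGTACGTACGTACGT", "TGG", strrep("A", 10))
  t <- target_spec(ref, 0, 20, "+")
  expect_identical(build_pbs(t, 4), "TACG")  # rc of protospacer bases 14-17 "CGTA"
  expect_error(build_pbs(t, 0), class = "pegcraft_range")
  p13 <- build_pbs(t, 13)
  expect_identical(nchar(p13), 13L)
  expect_true(grepl(revcomp(p13), substr(ref, 1, 20), fixed = TRUE))
})

test_that("build_rtt templates the edited +1..+rtt_len segment with SSMs applied", {
  toy <- toy_orf1_target()
  expect_identical(build_rtt(toy$target, NULL, 9), "TTTAGCACC")
  ssm <- data.frame(position = 6L, ref_base = "T", alt_base = "A")
  expect_identical(build_rtt(toy$target, NULL, 9, ssm), "TTTTGCACC")
  expect_error(build_rtt(toy$target, edit_spec("substitution", 5, "C", "A"), 4),
               class = "pegcraft_range")
  expect_error(build_rtt(toy$target, edit_spec("substitution", 6, "T", "A"), 9,
                         ssm), class = "pegcraft_conflict")
  # insertion shifts the templated segment
  ins <- edit_spec("insertion", 1, "", "GAT")
  expect_identical(build_rtt(toy$target, ins, 6), revcomp("GATGGT"))
})

test_that("wobble phase is read from the codon register at offsets +1..+3", {
  ref <- paste0(strrep("A", 17), "GGTGCTAAA", strrep("C", 24))
  t <- target_spec(ref, 0, 20, "+", pam_pattern = "NNN")
  # anchor at +1 => codon_position(+1) = 1 => wobble at +3 => ORF1
  expect_identical(rtt_wobble_phase(t, reading_frame("+", 17, 0, 50)), "ORF1")
  # codon_position(+1) = 3 => ORF2 ; = 2 => ORF3
  expect_identical(rtt_wobble_phase(t, reading_frame("+", 15, 0, 50)), "ORF2")
  expect_identical(rtt_wobble_phase(t, reading_frame("+", 16, 0, 50)), "ORF3")
  expect_error(rtt_wobble_phase(t, reading_frame("+", 2, 0, 10)),
               class = "pegcraft_out_of_frame")
})

test_that("recommended schemes per phase match the design rule, duals first", {
  expect_identical(recommended_schemes("ORF1"), list(c(3L, 6L), 6L))
  expect_identical(recommended_schemes("ORF2"), list(1L))
  expect_identical(recommended_schemes("ORF3"), list(c(2L, 5L), 5L))
  cat5 <- ssm_scheme_catalog()
  expect_identical(cat5, list(c(2L, 5L), 5L, c(3L, 6L), 6L, 1L))
})

test_that("choose_ssm picks the alphabetically smallest synonymous base", {
  toy <- toy_orf1_target()
  s1 <- choose_ssm(toy$target, toy$frame, 6)
  expect_identical(s1$position, 6L)
  expect_identical(s1$ref_base, "T")
  expect_identical(s1$alt_base, "A")  # GCT -> GCA
  s2 <- choose_ssm(toy$target, toy$frame, c(3, 6))
  expect_identical(s2$alt_base, c("A", "A"))  # GGT -> GGA, GCT -> GCA
  # Met codon at the scheme position is infeasible
  ref <- paste0(strrep("A", 17), "ATGGGTAAA", strrep("C", 24))
  t <- target_spec(ref, 0, 20, "+", pam_pattern = "NNN")
  fr <- reading_frame("+", 17, 0, 50)
  expect_error(choose_ssm(t, fr, 3), class = "pegcraft_infeasible")
  expect_error(choose_ssm(toy$target, toy$frame, 6,
                          edit_spec("substitution", 6, "T", "G")),
               class = "pegcraft_conflict")
})

test_that("choose_ssm evaluates codons on the edited sequence", {
  toy <- toy_orf1_target()
  # +1 G-to-T turns GGT into TGT (Cys); position 3 must now preserve Cys
  s <- choose_ssm(toy$target, toy$frame, 3, edit_spec("substitution", 1, "G", "T"))
  expect_identical(s$alt_base, "C")  # TGT -> TGC
})

test_that("design_spegrnas emits recommended-first designs and warns when none fit", {
  toy <- toy_orf1_target()
  e <- edit_spec("substitution", 1, "G", "T")
  d <- design_spegrnas(toy$target, e, toy$frame)
  expect_length(d, 2)
  expect_identical(d[[1]]$scheme, c(3L, 6L))
  expect_identical(d[[2]]$scheme, 6L)
  expect_true(all(vapply(d, function(x) nrow(x$ssms) <= 4, logical(1))))
  # ORF2 target whose +1 codon is ATG: no wobble synonym
  sv <- rep("A", 60); sv[16:18] <- c("A", "T", "G")
  t2 <- target_spec(paste(sv, collapse = ""), 0, 20, "+", pam_pattern = "NNN")
  fr2 <- reading_frame("+", 15, 0, 60)
  expect_identical(rtt_wobble_phase(t2, fr2), "ORF2")
  expect_warning(d2 <- design_spegrnas(t2, edit_spec("substitution", 4, "A", "C"),
                                       fr2),
                 "no feasible")
  expect_length(d2, 0)
})

test_that("extended designs are capped at 5 and SSM positions stay in the catalog", {
  set.seed(7)
  for (i in 1:20) {
    st <- sim_target(strand = sample(c("+", "-"), 1),
                     coding_strand = sample(c("+", "-"), 1))
    d <- tryCatch(
      design_spegrnas(st$target, st$edit, st$frame, extended = TRUE),
      warning = function(w) list())
    expect_lte(length(d), 5)
    for (x in d) {
      expect_true(all(x$ssms$position %in% c(1L, 2L, 3L, 5L, 6L)))
      expect_lte(nrow(x$ssms), 4)
    }
  }
})

test_that("same-sense guarantee: SSMs never change the translated protein", {
  set.seed(11)
  for (i in 1:150) {
    st <- sim_target(strand = sample(c("+", "-"), 1),
                     coding_strand = sample(c("+", "-"), 1))
    designs <- tryCatch(
      design_spegrnas(st$target, st$edit, st$frame, extended = TRUE),
      warning = function(w) list())
    if (!length(designs)) next
    ar_edit <- amplicon_ref(st$target, st$edit)
    seq_edit <- apply_edit(st$target, st$edit)$seq
    for (d in designs) {
      ar <- amplicon_ref(st$target, st$edit, design = d)
      seq_both <- pegcraft:::sim_template(ar, TRUE, TRUE)
      cds <- function(s) {
        # frame-aligned coding-strand sequence (anchor = codon position 1)
        fr <- st$frame
        if (fr$coding_strand == "-") {
          s <- revcomp(s)
          start0 <- (nchar(s) - 1 - fr$frame_anchor) %% 3
        } else {
          start0 <- fr$frame_anchor %% 3
        }
        len <- nchar(s) - start0
        substr(s, start0 + 1, start0 + len - (len %% 3))
      }
      expect_identical(oracle_translate(cds(seq_both)),
                       oracle_translate(cds(seq_edit)),
                       info = sprintf("case %d design %s", i, d$name))
    }
  }
})

test_that("aspegRNA designs combine the stabilized scaffold with feasible SSMs", {
  toy <- toy_orf1_target()
  e <- edit_spec("substitution", 1, "G", "T")
  d <- design_aspegrna(toy$target, e, toy$frame)
  expect_length(d, 2)
  a2 <- stabilize_scaffold(default_scaffold(), "apegRNA-2")
  for (x in d) {
    expect_identical(x$scaffold_variant, "apegRNA-2")
    expect_identical(x$scaffold, a2)
    expect_gt(nrow(x$ssms), 0)
  }
  # no CDS annotation: stabilized scaffold, empty SSM set, warning
  expect_warning(d2 <- design_aspegrna(toy$target, edit_spec("insertion", 1, "", "GAT"),
                                       frame = NULL), "without SSMs")
  expect_length(d2, 1)
  expect_identical(nrow(d2[[1]]$ssms), 0L)
  expect_identical(d2[[1]]$scaffold, a2)
})

test_that("nicking-sgRNA candidates match brute-force enumeration of opposite-strand sites", {
  set.seed(19)
  ref <- paste0(strrep("A", 10), random_dna(20), "TGG", random_dna(167))
  t <- target_spec(ref, 10, 20, "+")
  cand <- design_nick_sgrna(t, window = c(0, 300))
  # brute force: minus-strand 20-mers whose PAM (revcomp of the 3 bases 5'
  # of the site on the forward strand) matches NGG
  sv <- strsplit(ref, "")[[1]]
  expected <- 0
  for (s in 3:(nchar(ref) - 20)) {
    if (sv[s - 1] == "C" && sv[s - 2] == "C") expected <- expected + 1
  }
  expect_identical(nrow(cand), as.integer(expected))
  expect_true(all(cand$strand == "-"))
  expect_true(!is.unsorted(cand$nick_distance))
  expect_identical(nrow(design_nick_sgrna(t, window = c(0, 0))), 0L)
})

test_that("cloning oligos anneal: reverse core is the reverse complement of the forward core", {
  toy <- toy_orf1_target()
  d <- design_spegrnas(toy$target, edit_spec("substitution", 1, "G", "T"),
                       toy$frame)[[1]]
  ol <- emit_oligos(d, overhangs = list(spacer_fwd = "", spacer_rev = "",
                                        ext_fwd = "", ext_rev = ""))
  expect_identical(ol$forward[1], d$spacer)
  expect_identical(ol$reverse[1], revcomp(ol$forward[1]))
  expect_identical(ol$reverse[2], revcomp(ol$forward[2]))
  ol2 <- emit_oligos(d)
  expect_identical(nchar(ol2$forward[1]), 24L)  # ACCG + 20-nt spacer
})
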