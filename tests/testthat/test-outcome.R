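test_that("the quantification window spans 8 nt upstream to 52 nt past the protospacer", {
  set.seed(14)
  ref <- paste0(random_dna(100), random_dna(20), "TGG", random_dna(77))
  t <- target_spec(ref, 100, 20, "+")
  expect_identical(quant_window(t), c(92L, 172L))
  expect_identical(diff(quant_window(t)), 80L)
  # minus strand: mirrored about the protospacer, still 80 bp
  refm <- paste0(random_dna(100), "CCT", random_dna(20), random_dna(77))
  tm <- target_spec(refm, 103, 20, "-")
  expect_identical(quant_window(tm), c(103L - 52L, 123L + 8L))
  expect_identical(diff(quant_window(tm)), 80L)
  # protospacer too close to the amplicon edge
  near <- target_spec(paste0(random_dna(5), random_dna(20), "AGGTTTTT",
                             strrep("A", 60)), 5, 20, "+")
  expect_error(quant_window(near), class = "pegcraft_range")
})

test_that("window length is 8 + protospacer length + 52 for any protospacer length", {
  set.seed(15)
  for (L in c(17L, 19L, 20L, 24L)) {
    ref <- paste0(random_dna(60), random_dna(L), "CGG", random_dna(80))
    t <- target_spec(ref, 60, L, "+")
    expect_identical(diff(quant_window(t)), 60L + L)
  }
})

test_that("scaffold-incorporation detection needs length >= 3, proximity and sequence match", {
  set.seed(16)
  st <- sim_target(seed = 21)
  ar <- amplicon_ref(st$target, st$edit)   # default scaffold ends ...GTCGGTGC
  b <- ar$nick_coord
  expect_true(detect_scaffold_incorporation(b, "GCACC", ar))
  expect_false(detect_scaffold_incorporation(b, "TTTTT", ar))
  expect_false(detect_scaffold_incorporation(b, "GC", ar))     # below floor
  expect_false(detect_scaffold_incorporation(b + 10L, "GCACC", ar)) # too far
  expect_true(detect_scaffold_incorporation(b, "GCACT", ar))   # 1 mismatch ok
  expect_false(detect_scaffold_incorporation(b, "GCTAT", ar))  # 2 mismatches
})

make_reads <- function(ar, classes, seed = 1) {
  p <- table(classes) / length(classes)
  sp <- sim_spec(as.list(p), n_reads = length(classes), error_rate = 0,
                 seed = seed)
  simulate_reads(ar, sp)
}

test_that("classification flags intended edits, SSM-only reads and windowed indels", {
  st <- sim_target(seed = 22, phase = "ORF1", edit_offset = 4)
  d <- design_spegrnas(st$target, st$edit, st$frame)[[1]]
  ar <- amplicon_ref(st$target, st$edit, design = d)
  reads <- make_reads(ar, rep(c("intended_only", "ssm_only", "unedited"),
                              c(2, 2, 2)))
  alns <- align_reads(reads$seq, ar$reference)
  rec <- classify_reads(alns, ar)
  intended <- rec[reads$class == "intended_only", ]
  expect_true(all(intended$has_intended_edit))
  expect_false(any(intended$has_ssm | intended$has_unintended_indel_in_window |
                     intended$has_scaffold_incorporation))
  ssm <- rec[reads$class == "ssm_only", ]
  expect_true(all(ssm$has_ssm))
  expect_false(any(ssm$has_intended_edit))
  expect_false(any(rec[reads$class == "unedited",
                       c("has_intended_edit", "has_ssm")] == TRUE))
})

test_that("a deletion 30 nt 3' of the PAM is inside the window; 60 nt is outside", {
  set.seed(23)
  ref <- paste0(random_dna(60), random_dna(20), "AGG", random_dna(117))
  t <- target_spec(ref, 60, 20, "+")
  ar <- amplicon_ref(t)
  pam_end <- 83L  # protospacer [60,80) + 3-nt PAM
  del_read <- function(pos) paste0(substr(ref, 1, pos), substr(ref, pos + 2,
                                                               nchar(ref)))
  alns <- align_reads(c(del_read(pam_end + 30L), del_read(pam_end + 60L)),
                      ar$reference)
  rec <- classify_reads(alns, ar)
  expect_true(rec$has_unintended_indel_in_window[1])
  expect_false(rec$has_unintended_indel_in_window[2])
})

test_that("substitution frequencies follow the no-indel numerator and depth gating", {
  st <- sim_target(seed = 24)
  ar <- amplicon_ref(st$target, st$edit)
  reads <- make_reads(ar, rep(c("intended_only", "unintended_indel", "unedited"),
                              c(4, 1, 5)))
  alns <- align_reads(reads$seq, ar$reference)
  rec <- classify_reads(alns, ar)
  sub <- substitution_frequencies(alns, rec, ar, min_depth = 10)
  co <- offset_to_ref(ar, ar$edit$offset)
  alt <- if (ar$strand == "-") chartr("ACGT", "TGCA", ar$edit$alt_allele)
         else ar$edit$alt_allele
  row <- sub[sub$coord == co & sub$alt_base == alt, ]
  expect_identical(row$count, 4L)
  expect_identical(row$depth, 10L)
  expect_equal(row$freq, 0.40)
  # depth below the threshold is reported missing
  sub11 <- substitution_frequencies(alns, rec, ar, min_depth = 11)
  expect_true(all(is.na(sub11$freq)))
  # unedited positions report frequency 0
  expect_true(all(sub$freq[sub$coord != co] == 0))
})

test_that("intended indel frequency counts only reads whose sole indel is the designed one", {
  set.seed(25)
  ref <- paste0(random_dna(60), random_dna(20), "TGG", random_dna(117))
  t <- target_spec(ref, 60, 20, "+")
  e <- edit_spec("insertion", 1, "", "GAT")
  ar <- amplicon_ref(t, e)
  b <- t$nick_coord
  exact <- apply_edit(t, e)$seq
  # compound: the intended insertion plus an extra 1-nt deletion 20 nt away
  compound <- paste0(substr(exact, 1, b + 30), substr(exact, b + 32, nchar(exact)))
  reads <- c(rep(exact, 6), compound, rep(ref, 3))
  alns <- align_reads(reads, ref)
  rec <- classify_reads(alns, ar)
  f <- intended_indel_frequency(rec, ar)
  expect_identical(f$numerator, 6L)
  expect_identical(f$denominator, 10L)
  expect_equal(f$value, 0.60)
  # the compound read still counts as unintended-indel-containing
  u <- unintended_indel_frequency(rec, "indel_experiment")
  expect_identical(u$numerator, 1L)
  expect_equal(u$value, 0.10)
  # calling the indel frequency on a substitution design is a usage error
  ar_sub <- amplicon_ref(t, edit_spec("substitution", 1,
                                      substr(ref, b + 1, b + 1),
                                      setdiff(BASES, substr(ref, b + 1, b + 1))[1]))
  expect_error(intended_indel_frequency(rec, ar_sub), class = "pegcraft_usage")
})

test_that("unintended indel frequency divides windowed-indel reads by window-spanning reads", {
  st <- sim_target(seed = 26)
  ar <- amplicon_ref(st$target, st$edit)
  reads <- make_reads(ar, rep(c("unintended_indel", "unedited"), c(2, 18)))
  alns <- align_reads(reads$seq, ar$reference)
  rec <- classify_reads(alns, ar)
  u <- unintended_indel_frequency(rec)
  expect_identical(u$numerator, 2L)
  expect_identical(u$denominator, 20L)
  expect_equal(u$value, 0.10)
})

test_that("incomplete products and byproducts are mutually exclusive 'only' classes", {
  st <- sim_target(seed = 27, phase = "ORF3", edit_offset = 4)
  d <- design_spegrnas(st$target, st$edit, st$frame)[[1]]
  ar <- amplicon_ref(st$target, st$edit, design = d)
  reads <- make_reads(ar, rep(c("ssm_only", "scaffold_byproduct",
                                "intended_plus_ssm", "unedited"),
                              c(1, 2, 2, 5)))
  alns <- align_reads(reads$seq, ar$reference)
  rec <- classify_reads(alns, ar)
  ib <- incomplete_and_byproduct_frequencies(rec)
  expect_equal(ib$incomplete$value, 0.10)
  expect_equal(ib$byproduct$value, 0.20)
  # reads with both the intended edit and SSMs are counted in neither
  both <- rec[reads$class == "intended_plus_ssm", ]
  expect_true(all(both$has_intended_edit & both$has_ssm))
  expect_identical(ib$incomplete$numerator + ib$byproduct$numerator, 3L)
  # partition sanity: no read is both incomplete and byproduct
  inc_flag <- rec$has_ssm & !rec$has_intended_edit & rec$n_indels == 0
  byp_flag <- rec$has_scaffold_incorporation & !rec$has_ssm &
    !rec$has_intended_edit
  expect_false(any(inc_flag & byp_flag, na.rm = TRUE))
})

test_that("off-target indel frequency recovers a planted 10% indel rate exactly at error 0", {
  set.seed(28)
  ot_ref <- paste0(random_dna(70), random_dna(20), "GGG", random_dna(87))
  ot <- target_spec(ot_ref, 70, 20, "+")
  ar <- amplicon_ref(ot)
  reads <- make_reads(ar, rep(c("unintended_indel", "unedited"), c(50, 450)),
                      seed = 5)
  f <- ot_indel_frequency(reads$seq, ot)
  expect_equal(f$value, 0.10)
  expect_identical(f$denominator, 500L)
  f0 <- ot_indel_frequency(rep(ot_ref, 20), ot)
  expect_equal(f0$value, 0)
})

test_that("quantify reproduces simulated class proportions exactly at error 0", {
  st <- sim_target(seed = 29, strand = "-", coding_strand = "+", phase = "ORF2", edit_offset = 4)
  d <- design_spegrnas(st$target, st$edit, st$frame)
  expect_gte(length(d), 1)
  ar <- amplicon_ref(st$target, st$edit, design = d[[1]])
  sp <- sim_spec(c(unedited = .35, intended_only = .2, intended_plus_ssm = .15,
                   ssm_only = .1, unintended_indel = .12,
                   scaffold_byproduct = .08),
                 n_reads = 400, error_rate = 0, seed = 31)
  reads <- simulate_reads(ar, sp)
  ot <- quantify(ar, reads, min_depth = 10)
  f <- ot$frequencies
  expect_equal(f$intended_edit$value, 0.35)
  expect_equal(f$unintended_indel$value, 0.12)
  expect_equal(f$incomplete_product$value, 0.10)
  expect_equal(f$byproduct$value, 0.08)
  expect_identical(ot$total_reads, 400L)
  # numerators never exceed the shared denominators
  for (nm in names(f)) expect_lte(f[[nm]]$numerator, f[[nm]]$denominator)
  df <- as.data.frame(ot)
  expect_equal(df$intended_edit, 0.35)
})
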