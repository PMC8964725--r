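test_that("reads that are reference substrings align with zero events", {
  set.seed(8)
  ref <- random_dna(200)
  read <- substr(ref, 31, 170)
  a <- align_read(read, ref)
  expect_true(a$aligned)
  expect_identical(a$covered, c(30L, 170L))
  expect_identical(nrow(a$substitutions), 0L)
  expect_identical(nrow(a$insertions), 0L)
  expect_identical(nrow(a$deletions), 0L)
})

test_that("single events are called at their known coordinates", {
  set.seed(9)
  ref <- random_dna(200)
  read <- substr(ref, 21, 180)
  # substitution at reference coordinate 100 (0-based)
  rs <- read
  old <- substr(rs, 81, 81)
  substr(rs, 81, 81) <- setdiff(BASES, old)[1]
  a <- align_read(rs, ref)
  expect_identical(a$substitutions$coord, 100L)
  expect_identical(a$substitutions$seq, setdiff(BASES, old)[1])
  # 2-nt deletion of reference coords [100, 102)
  rd <- paste0(substr(read, 1, 80), substr(read, 83, nchar(read)))
  ad <- align_read(rd, ref)
  expect_identical(nrow(ad$deletions), 1L)
  del <- ad$deletions
  expect_identical(del$end - del$coord, 2L)
  # left-aligned equivalent of the planted interval
  expect_identical(substr(ref, del$coord + 1, nchar(ref)),
                   paste0(substr(ref, 101, 102),
                          substr(ref, del$end + 1, nchar(ref))))
  # insertion before reference coordinate 100
  ri <- paste0(substr(read, 1, 80), "CTTG", substr(read, 81, nchar(read)))
  ai <- align_read(ri, ref)
  expect_identical(nrow(ai$insertions), 1L)
  expect_identical(nchar(ai$insertions$seq), 4L)
})

test_that("random unrelated reads fall below the alignment threshold", {
  set.seed(10)
  ref <- random_dna(200)
  a <- align_read(random_dna(120), ref)
  expect_false(a$aligned)
})

test_that("indels in repeats are left-aligned deterministically", {
  set.seed(11)
  left <- random_dna(30); right <- random_dna(30)
  ref <- paste0(left, "AAAAAA", right)
  # delete one A of the A6 run: every placement is equivalent; expect leftmost
  read <- paste0(left, "AAAAA", right)
  a <- align_read(read, ref)
  expect_identical(a$deletions$coord, 30L)
  expect_identical(a$deletions$end, 31L)
  # insert one extra A: leftmost placement before the run
  read2 <- paste0(left, "AAAAAAA", right)
  a2 <- align_read(read2, ref)
  expect_identical(a2$insertions$coord, 30L)
  expect_identical(a2$insertions$seq, "A")
})

test_that("alignment scores equal the quadratic-time Gotoh oracle on small instances", {
  set.seed(12)
  for (case in 1:30) {
    ns <- sample(30:60, 1)
    subject <- random_dna(ns)
    start <- sample(1:10, 1)
    len <- sample(15:(ns - start), 1)
    read <- substr(subject, start, start + len - 1)
    # perturb: substitutions and/or a small indel
    read <- mutate_bases(read, sample(0:3, 1))
    if (runif(1) < 0.5 && nchar(read) > 20) {
      p <- sample(5:(nchar(read) - 5), 1)
      read <- if (runif(1) < 0.5)
        paste0(substr(read, 1, p), random_dna(sample(1:3, 1)),
               substr(read, p + 1, nchar(read)))
      else paste0(substr(read, 1, p), substr(read, p + 1 + sample(1:3, 1),
                                             nchar(read)))
    }
    a <- align_reads(read, subject, min_score = -Inf)
    expect_equal(a$score[1], oracle_semiglobal_score(read, subject),
                 info = sprintf("case %d", case))
  }
})

test_that("alignment scores agree with an independent pairwise-alignment library", {
  set.seed(13)
  submat <- Biostrings::nucleotideSubstitutionMatrix(2, -4, baseOnly = TRUE)
  for (case in 1:10) {
    subject <- random_dna(sample(60:120, 1))
    read <- mutate_bases(substr(subject, 5, nchar(subject) - 5),
                         sample(0:4, 1))
    mine <- align_reads(read, subject, min_score = -Inf)$score[1]
    bs <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(read), Biostrings::DNAString(subject),
      type = "global-local", substitutionMatrix = submat,
      gapOpening = 6, gapExtension = 1))
    expect_equal(mine, bs, info = sprintf("case %d", case))
  }
})

test_that("equal-length ins/del pairs are re-called as multi-nucleotide substitutions", {
  set.seed(14)
  ref <- random_dna(200)
  # plant 3 clustered substitutions that affine-gap scoring may prefer to
  # explain as a del+ins pair; the caller must report substitutions only
  read <- ref
  for (k in c(100, 101, 103)) {
    old <- substr(read, k, k)
    substr(read, k, k) <- setdiff(BASES, old)[1]
  }
  a <- align_read(read, ref)
  expect_identical(nrow(a$insertions) + nrow(a$deletions), 0L)
  expect_identical(sort(a$substitutions$coord), c(99L, 100L, 102L))
  # a lone deletion is untouched by the normalization
  rd <- paste0(substr(ref, 1, 99), substr(ref, 102, 200))
  ad <- align_read(rd, ref)
  expect_identical(nrow(ad$deletions), 1L)
})
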