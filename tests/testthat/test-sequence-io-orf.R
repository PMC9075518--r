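test_that("FASTA round-trips through write and read", {
  set.seed(1)
  recs <- lapply(1:100, function(i)
    transcript_record(paste0("tx", i), random_transcript(sample(60:300, 1))))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f)
  back <- read_fasta(f, type = "nucleotide")
  expect_equal(vapply(back, `[[`, "", "id"), vapply(recs, `[[`, "", "id"),
               ignore_attr = TRUE)
  expect_equal(vapply(back, `[[`, "", "seq"), vapply(recs, `[[`, "", "seq"),
               ignore_attr = TRUE)
})

test_that("duplicate ids and empty files are rejected", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), f)
  expect_error(read_fasta(f), "duplicate.*a")
  f2 <- withr::local_tempfile(fileext = ".fa")
  file.create(f2)
  expect_error(read_fasta(f2), "empty")
  expect_error(write_fasta(c(a = "MK", a = "ML"), f), "duplicate")
})

test_that("simple complete ORF is translated with frame and coordinates", {
  orfs <- translate_six_frames(transcript_record("t", "ATGAAATAA"), min_aa = 2)
  pep <- vapply(orfs, `[[`, "", "seq")
  i <- which(pep == "MK")
  expect_length(i, 1)
  expect_identical(orfs[[i]]$frame, 1L)
  expect_true(orfs[[i]]$complete)
  expect_identical(c(orfs[[i]]$start_nt, orfs[[i]]$end_nt), c(0L, 6L))
})

test_that("reverse-strand ORFs are reported in forward coordinates", {
  # reverse complement of ATGAAATAA
  orfs <- translate_six_frames(transcript_record("t", "TTATTTCAT"), min_aa = 2)
  pep <- vapply(orfs, `[[`, "", "seq")
  i <- which(pep == "MK")
  expect_length(i, 1)
  o <- orfs[[i]]
  expect_identical(o$frame, -1L)
  expect_true(o$complete)
  # coordinates map back through the transcript exactly
  expect_identical(peptide_at(transcript_record("t", "TTATTTCAT"),
                              o$start_nt, o$end_nt, o$frame), "MK")
})

test_that("ORFs without start or stop are reported as incomplete", {
  orfs <- translate_six_frames(transcript_record("t", "AAAAAA"), min_aa = 2)
  pep <- vapply(orfs, `[[`, "", "seq")
  expect_true("KK" %in% pep)
  expect_false(any(vapply(orfs, `[[`, TRUE, "complete")))
})

test_that("input validation names offending symbols", {
  expect_error(translate_six_frames(transcript_record("t", "ACGT"), min_aa = 0),
               "min_aa")
  expect_error(transcript_record("t", "ACGJ"), "J")
  expect_error(transcript_record("t", ""), "non-empty")
})

test_that("translation of a sequence and its reverse complement give the same peptide set", {
  set.seed(42)
  for (k in 1:10) {
    s <- random_transcript(sample(120:400, 1))
    rc <- paste(rev(c(A = "T", C = "G", G = "C", T = "A")[
      strsplit(s, "")[[1]]]), collapse = "")
    p1 <- sort(vapply(translate_six_frames(transcript_record("a", s), min_aa = 10),
                      `[[`, "", "seq"))
    p2 <- sort(vapply(translate_six_frames(transcript_record("b", rc), min_aa = 10),
                      `[[`, "", "seq"))
    expect_identical(p1, p2)
  }
})

test_that("concatenation preserves ORFs fully contained in either part", {
  set.seed(5)
  guard <- "TAATAATAA"  # stops in all three frames, encodes no methionine
  for (k in 1:5) {
    pep_a <- paste0("M", random_protein_no_m(25))
    pep_b <- paste0("M", random_protein_no_m(35))
    a <- paste0(guard, encode_cds(pep_a), "TGA", guard)
    b <- paste0(guard, encode_cds(pep_b), "TAA", guard)
    peps <- function(s) {
      o <- translate_six_frames(transcript_record("x", s), min_aa = 10)
      vapply(o, `[[`, "", "seq")[vapply(o, `[[`, TRUE, "complete")]
    }
    expect_true(pep_a %in% peps(a))
    expect_true(all(c(pep_a, pep_b) %in% peps(paste0(a, b))))
    expect_true(all(c(pep_a, pep_b) %in% peps(paste0(b, a))))
  }
})
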