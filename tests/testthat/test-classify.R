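classify_template <- function(cl) {
  tm <- make_template(cl)
  p <- protein_record(cl, tm$seq, complete = TRUE)
  det <- detect_acds(p)
  core <- trim_core(det$hits[1, ], p)
  prof <- physchem_profile(p, acd_core = core)
  assign_cluster(p, det$hits[1, ], prof)
}

test_that("each monomeric template recovers its own subcluster label", {
  for (cl in c("A1", "A2", "B1", "B2", "B3")) {
    asg <- classify_template(cl)
    expect_identical(asg$label, cl)
    expect_gt(nrow(asg$fired_rules), 0)
  }
})

test_that("B1 fires on the lysine-rich motif inside beta5-L57", {
  asg <- classify_template("B1")
  expect_true("B1_KKKxKK_b5L57" %in% asg$fired_rules$rule)
  expect_true("B1_EExxEE_corroboration" %in% asg$fired_rules$rule)
})

test_that("dimeric proteins are rejected by the monomeric classifier", {
  tm <- make_template("dimeric")
  p <- protein_record("dim", tm$seq)
  det <- detect_acds(p)
  prof <- physchem_profile(p)
  expect_error(assign_cluster(p, det$hits, prof), "monomeric classifier only")
})

test_that("a protein without a hit is unassigned", {
  p <- protein_record("none", random_protein(120, seed = 20))
  prof <- physchem_profile(p)
  asg <- assign_cluster(p, NULL, prof)
  expect_identical(asg$label, "unassigned")
  expect_identical(nrow(asg$fired_rules), 0L)
})

test_that("classification is deterministic and batch-order independent", {
  labs1 <- vapply(c("B3", "A1", "B1", "A2", "B2"),
                  function(cl) classify_template(cl)$label, "")
  labs2 <- vapply(c("A1", "A2", "B1", "B2", "B3"),
                  function(cl) classify_template(cl)$label, "")
  expect_identical(sort(unname(labs1)), sort(unname(labs2)))
})

test_that("NLS scan finds VxP-type and basic-rich candidates", {
  # basic-rich: >= 4 K/R in a 6-residue window
  nls <- scan_nls(protein_record("p", "AAAKVKKKAAAA"))
  expect_true(any(nls$kind == "basic-rich"))
  expect_gte(nls$basic_count[nls$kind == "basic-rich"][1], 4)
  # A1 template carries V-K-P in its beta4-L45 zone
  tm <- make_template("A1")
  p <- protein_record("A1", tm$seq)
  det <- detect_acds(p)
  nls2 <- scan_nls(p, det$hits)
  expect_true(any(nls2$kind == "VxP-type"))
  # featureless sequence yields nothing
  expect_identical(nrow(scan_nls(protein_record("a", strrep("A", 50)))), 0L)
})

test_that("column statistics follow the information-content definitions", {
  stats <- column_stats(rep(c("AD", "AE"), each = 10), t = 0.5)
  # column 1: all A, no gaps
  expect_equal(stats$ic_bits[1], log2(20))
  expect_identical(stats$consensus[1], "A")
  # column 2: half D half E
  expect_equal(stats$ic_bits[2], log2(20) - 1)
  expect_identical(stats$consensus[2], "x")
})

test_that("uniform and all-gap columns degenerate correctly", {
  rows <- vapply(1:20, function(i) paste0(AA[i], "-"), "")
  stats <- column_stats(rows)
  expect_equal(stats$ic_bits[1], 0)
  expect_identical(stats$consensus[1], "x")
  expect_true(is.na(stats$ic_bits[2]))
  expect_identical(stats$consensus[2], "x")
  expect_equal(stats$gap_fraction[2], 1)
})

test_that("information content decreases as a conserved column is randomized", {
  set.seed(21)
  n <- 40
  col <- rep("A", n)
  ic <- numeric(0)
  for (k in c(0, 5, 10, 20, 30)) {
    mixed <- col
    if (k > 0) mixed[seq_len(k)] <- sample(AA, k, replace = TRUE)
    ic <- c(ic, column_stats(mixed)$ic_bits[1])
  }
  expect_true(all(diff(ic) <= 1e-9))
})
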