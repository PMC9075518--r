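test_that("GRAVY matches the Kyte-Doolittle mean", {
  expect_equal(gravy("A"), 1.8)
  expect_equal(gravy("VKIV"), 2.25)
  s <- random_protein(60, seed = 2)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(gravy(s), gravy(perm))
  # X excluded from the average
  expect_equal(gravy("AXA"), 1.8)
  expect_error(gravy(""), "non-empty")
})

test_that("GRAVY of a concatenation is the length-weighted mean of parts", {
  set.seed(3)
  for (k in 1:20) {
    a <- random_protein(sample(5:50, 1))
    b <- random_protein(sample(5:50, 1))
    expected <- (nchar(a) * gravy(a) + nchar(b) * gravy(b)) /
      (nchar(a) + nchar(b))
    expect_equal(gravy(paste0(a, b)), expected)
  }
})

test_that("molecular weight is residue masses plus one water", {
  expect_equal(molecular_weight("G"), 57.0519 + 18.0153, tolerance = 1e-6)
  a <- random_protein(30, seed = 4); b <- random_protein(40)
  expect_equal(molecular_weight(paste0(a, b)),
               molecular_weight(a) + molecular_weight(b) - 18.0153)
  # strictly increasing in length
  s <- random_protein(10, seed = 5)
  expect_gt(molecular_weight(paste0(s, "G")), molecular_weight(s))
})

test_that("pI of a glycine dipeptide equals the analytic terminal balance", {
  # only termini ionize: pI = (pK_N + pK_C) / 2
  for (tab in c("sms", "emboss")) {
    pk <- acdminer:::PKA_TABLES[[tab]]
    expect_equal(isoelectric_point("GG", tab), (pk$nterm + pk$cterm) / 2,
                 tolerance = 0.01)
    expect_equal(isoelectric_point("GG", tab), grid_pi("GG", tab),
                 tolerance = 0.01)
  }
})

test_that("appending basic/acidic residues shifts pI monotonically", {
  set.seed(6)
  for (k in 1:10) {
    s <- random_protein(sample(10:80, 1))
    expect_gte(isoelectric_point(paste0(s, "K")) + 1e-6, isoelectric_point(s))
    expect_lte(isoelectric_point(paste0(s, "D")) - 1e-6, isoelectric_point(s))
  }
})

test_that("bisection pI agrees with the seqinr Bjellqvist implementation", {
  skip_if_not_installed("seqinr")
  set.seed(7)
  for (k in 1:25) {
    s <- random_protein(sample(20:200, 1))
    expect_equal(isoelectric_point(s, "bjellqvist"),
                 seqinr::computePI(strsplit(s, "")[[1]]),
                 tolerance = 0.02)
  }
})

test_that("molecular weight agrees with seqinr::pmw", {
  skip_if_not_installed("seqinr")
  set.seed(8)
  for (k in 1:10) {
    s <- random_protein(sample(20:200, 1))
    expect_equal(molecular_weight(s), seqinr::pmw(strsplit(s, "")[[1]]),
                 tolerance = 0.05)
  }
})

test_that("group summaries use linear-interpolation quartiles over complete rows", {
  profs <- do.call(rbind, lapply(1:4, function(i)
    physchem_profile(protein_record(paste0("p", i), "MKVL",
                                    complete = TRUE))))
  profs$mw_kda <- c(1, 2, 3, 4)
  s <- summarize_groups(profs, rep("g", 4), metrics = "mw_kda")
  expect_equal(s$q1, 1.75)
  expect_equal(s$q3, 3.25)
  # identical values collapse the range
  profs$mw_kda <- rep(2, 4)
  s2 <- summarize_groups(profs, rep("g", 4), metrics = "mw_kda")
  expect_equal(s2$q1, s2$q3)
  # incomplete rows are excluded from n
  profs$complete <- c(TRUE, TRUE, FALSE, FALSE)
  s3 <- summarize_groups(profs, rep("g", 4), metrics = "mw_kda")
  expect_equal(s3$n, 2)
  # a group with no complete rows yields n = 0 and null ranges
  s4 <- summarize_groups(profs, c("g", "g", "h", "h"), metrics = "mw_kda")
  h <- s4[s4$group == "h", ]
  expect_equal(h$n, 0)
  expect_true(is.na(h$q1) && is.na(h$q3))
})

test_that("template profiles fall in the published boxes", {
  a1 <- make_template("A1")
  core <- substr(a1$seq, a1$cores$start[1] + 1, a1$cores$end[1])
  prof <- physchem_profile(protein_record("A1", a1$seq, complete = TRUE),
                           acd_core = core)
  expect_gte(prof$mw_kda, 9.7); expect_lte(prof$mw_kda, 10.1)
  a2 <- make_template("A2")
  prof2 <- physchem_profile(protein_record("A2", a2$seq, complete = TRUE))
  expect_gte(prof2$pi_protein, 9.2); expect_lte(prof2$pi_protein, 10.2)
})
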