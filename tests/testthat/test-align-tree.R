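core_of <- function(cl) {
  tm <- make_template(cl)
  p <- protein_record(cl, tm$seq)
  trim_core(detect_acds(p)$hits[1, ], p)
}

test_that("aligning a core with itself gives identical gap-free rows", {
  core <- core_of("B1")
  aln <- align_cores(c(a = core, b = core))
  expect_identical(aln$rows[1], aln$rows[2])
  expect_false(grepl("-", aln$rows[1], fixed = TRUE))
  expect_identical(gsub("-", "", aln$rows[1]), core)
})

test_that("L57 length differences confine gaps to L57 columns", {
  a1 <- core_of("A1")   # short L57
  b1 <- core_of("B1")
  aln <- align_cores(c(a1 = a1, b1 = b1))
  gap_cols <- which(strsplit(aln$rows[1], "")[[1]] == "-" |
                      strsplit(aln$rows[2], "")[[1]] == "-")
  expect_true(all(aln$anchors[gap_cols] == "L57"))
  expect_gte(aln$n_columns, 60); expect_lte(aln$n_columns, 96)
})

test_that("ungapping alignment rows reproduces the input cores exactly", {
  cores <- vapply(c("A1", "A2", "B1", "B2", "B3"), core_of, "")
  aln <- align_cores(cores)
  for (id in aln$ids)
    expect_identical(ungap_row(aln, id), unname(cores[id]))
  expect_true(all(diff(match(aln$anchors, unique(aln$anchors))) >= 0))
})

test_that("unalignable cores are excluded with a warning", {
  cores <- c(a = core_of("B2"), b = core_of("B3"),
             junk = random_protein(70, seed = 30))
  expect_warning(aln <- align_cores(cores), "unalignable")
  expect_setequal(aln$ids, c("a", "b"))
})

test_that("p-distances count mismatches over comparable columns", {
  expect_equal(p_distance_matrix(c(a = "ACDEF", b = "ACDEF"))["a", "b"], 0)
  r1 <- strrep("A", 80)
  r2 <- paste0(strrep("A", 75), strrep("C", 5))
  expect_equal(p_distance_matrix(c(a = r1, b = r2))["a", "b"], 0.0625)
  # gapped columns are excluded pairwise
  d <- p_distance_matrix(c(a = "AC-EF", b = "ACD-F"))
  expect_equal(d["a", "b"], 0)
  set.seed(31)
  rows <- vapply(1:5, function(i) random_protein(40), "")
  names(rows) <- paste0("s", 1:5)
  d2 <- p_distance_matrix(rows)
  expect_true(isSymmetric(d2))
  expect_true(all(diag(d2) == 0))
  # a pair with no comparable columns is flagged
  expect_warning(d3 <- p_distance_matrix(c(a = "A-", b = "-A")),
                 "no comparable")
  expect_true(is.na(d3["a", "b"]))
})

test_that("three-taxon NJ solves the three-point formulas", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
})

test_that("NJ recovers additive trees exactly", {
  set.seed(32)
  for (k in 1:10) {
    src <- ape::rtree(5, br = function(n) runif(n, 0.1, 1))
    src <- ape::unroot(src)
    d <- ape::cophenetic.phylo(src)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    tr <- neighbor_joining(d)
    # same unrooted topology
    expect_equal(ape::dist.topo(ape::unroot(tr), src), 0, ignore_attr = TRUE)
    # path distances reproduced to 1e-9
    d2 <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_lt(max(abs(d2 - d)), 1e-9)
  }
})

test_that("NJ agrees with the ape reference implementation on random matrices", {
  set.seed(33)
  for (k in 1:5) {
    n <- 8
    m <- matrix(runif(n * n, 0.05, 1), n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr1 <- neighbor_joining(d)
    tr2 <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(tr1), ape::unroot(tr2)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("ultrametric sister pairs end up as siblings", {
  d <- matrix(0.8, 4, 4,
              dimnames = list(c("a1", "a2", "b1", "b2"),
                              c("a1", "a2", "b1", "b2")))
  diag(d) <- 0
  d["a1", "a2"] <- d["a2", "a1"] <- 0.1
  d["b1", "b2"] <- d["b2", "b1"] <- 0.1
  tr <- neighbor_joining(d)
  expect_true(is_split(tr, c("a1", "a2")))
  expect_true(is_split(tr, c("b1", "b2")))
})

test_that("negative branch lengths are clamped to zero", {
  # a non-additive matrix known to produce a negative NJ branch
  d <- matrix(c(0, 0.1, 0.6, 0.65,
                0.1, 0, 0.62, 0.6,
                0.6, 0.62, 0, 0.02,
                0.65, 0.6, 0.02, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are deterministic and saturate for clear splits", {
  cores <- vapply(c("A1", "A2", "B1", "B2", "B3"), core_of, "")
  cores <- c(cores, A1b = unname(cores["A1"]))
  aln <- align_cores(cores)
  t1 <- bootstrap_supports(aln, n_reps = 50, seed = 9)
  t2 <- bootstrap_supports(aln, n_reps = 50, seed = 9)
  expect_identical(t1$supports, t2$supports)
  # identical duplicated sequences always cluster together
  expect_equal(split_support(t1, c("A1", "A1b")), 100)
  # newick round-trips through the ape writer/parser
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(t1$tree, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, aln$ids)
})

test_that("tree leaf set equals the input id set", {
  set.seed(34)
  rows <- vapply(1:6, function(i) random_protein(50), "")
  names(rows) <- paste0("x", 1:6)
  tr <- neighbor_joining(p_distance_matrix(rows))
  expect_setequal(tr$tip.label, names(rows))
  expect_error(neighbor_joining(matrix(c(0, NA, NA, 0), 2)), "NA")
  expect_warning(
    neighbor_joining(matrix(c(0, 1, 1, 0), 2,
                            dimnames = list(c("a", "b"), c("a", "b")))),
    "degenerate")
})
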