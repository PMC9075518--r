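test_that("templates validate against their boxes and carry their motifs", {
  for (cl in c("A1", "A2", "B1", "B2", "B3")) {
    tm <- make_template(cl)
    expect_s3_class(tm, "shsp_template")
  }
  b1 <- make_template("B1")
  core <- substr(b1$seq, b1$cores$start[1] + 1, b1$cores$end[1])
  expect_gt(nrow(scan_motif(core, "K-K-K-X-K-K")), 0)
  expect_gt(nrow(scan_motif(core, "F-X-S-E-S")), 0)
  expect_error(make_template("Z9"), "unknown cluster")
})

test_that("the dimeric template has two cores, a 15-40 aa linker and a divergent upstream core", {
  tm <- make_template("dimeric")
  expect_equal(nrow(tm$cores), 2)
  linker <- tm$cores$start[2] - tm$cores$end[1]
  expect_gte(linker, 15); expect_lte(linker, 40)
  up <- substr(tm$seq, tm$cores$start[1] + 1, tm$cores$end[1])
  for (cl in c("A1", "A2", "B1", "B2", "B3")) {
    mono <- make_template(cl)
    mc <- substr(mono$seq, mono$cores$start[1] + 1, mono$cores$end[1])
    n <- min(nchar(up), nchar(mc))
    diff_frac <- mean(strsplit(substr(up, 1, n), "")[[1]] !=
                        strsplit(substr(mc, 1, n), "")[[1]])
    expect_gte(diff_frac, 0.30)
  }
})

test_that("generation is byte-identical for a fixed config and seed", {
  cfg <- generator_config(n_per_cluster = c(A1 = 2, B1 = 2, dimeric = 1),
                          seed = 99)
  r1 <- generate_repertoire(cfg)
  r2 <- generate_repertoire(cfg)
  expect_identical(r1, r2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_repertoire(cfg, out_dir = d1)
  generate_repertoire(cfg, out_dir = d2)
  for (f in c("transcripts.fa", "proteins.fa", "truth.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("truth rows cover plants plus decoys and map onto recovered ORFs", {
  cfg <- generator_config(n_per_cluster = c(A1 = 2, A2 = 1, B1 = 2,
                                            B2 = 1, B3 = 1, dimeric = 1),
                          n_decoy_random = 3, n_decoy_near_miss = 3,
                          seed = 17)
  rep <- generate_repertoire(cfg)
  expect_equal(nrow(rep$truth), 8 + 6)
  expect_equal(length(rep$transcripts), nrow(rep$truth))
  for (i in seq_len(nrow(rep$truth))) {
    tr <- rep$truth[i, ]
    orfs <- translate_six_frames(
      transcript_record(tr$transcript_id, rep$transcripts[[tr$transcript_id]]))
    peps <- vapply(orfs, `[[`, "", "seq")
    expect_true(rep$proteins[[tr$protein_id]] %in% peps)
    # planted core coordinates index the emitted protein correctly
    if (tr$cluster != "decoy") {
      core <- substr(rep$proteins[[tr$protein_id]],
                     tr$acd1_start + 1, tr$acd1_end)
      expect_gte(nchar(core), 60); expect_lte(nchar(core), 85)
    }
  }
  # completeness flags mirror the truncation rule
  for (i in seq_len(nrow(rep$truth))) {
    tr <- rep$truth[i, ]
    orfs <- translate_six_frames(
      transcript_record(tr$transcript_id, rep$transcripts[[tr$transcript_id]]))
    peps <- vapply(orfs, `[[`, "", "seq")
    j <- which(peps == rep$proteins[[tr$protein_id]])[1]
    expect_identical(orfs[[j]]$complete, tr$complete)
  }
})

test_that("zero mutation gives perfect recovery of labels and architectures", {
  cfg <- generator_config(n_per_cluster = c(A1 = 3, A2 = 3, B1 = 3,
                                            B2 = 3, B3 = 3, dimeric = 3),
                          rate_strand = 0, rate_loop = 0, indel_rate = 0,
                          truncated_fraction = 0,
                          n_decoy_random = 0, n_decoy_near_miss = 0,
                          seed = 23)
  rep <- generate_repertoire(cfg)
  for (i in seq_len(nrow(rep$truth))) {
    tr <- rep$truth[i, ]
    p <- protein_record(tr$protein_id, rep$proteins[[tr$protein_id]],
                        complete = TRUE)
    det <- detect_acds(p)
    if (tr$cluster == "dimeric") {
      expect_identical(det$architecture$label, "dimeric")
    } else {
      expect_identical(det$architecture$label, "monomeric")
      prof <- physchem_profile(p, acd_core = trim_core(det$hits[1, ], p))
      expect_identical(assign_cluster(p, det$hits[1, ], prof)$label,
                       tr$cluster)
    }
  }
})

test_that("mean detection score degrades monotonically with substitution rate", {
  rates <- c(0, 0.02, 0.05, 0.10)
  means <- vapply(rates, function(r) {
    cfg <- generator_config(n_per_cluster = c(A2 = 4, B1 = 4, B2 = 4),
                            rate_strand = r, rate_loop = r, indel_rate = 0,
                            truncated_fraction = 0,
                            n_decoy_random = 0, n_decoy_near_miss = 0,
                            seed = 41)
    rep <- generate_repertoire(cfg)
    scores <- vapply(rep$truth$protein_id, function(pid) {
      det <- detect_one(rep$proteins[[pid]], id = pid, threshold_bits = -Inf)
      det$hits$score_bits[1]
    }, 0)
    mean(scores)
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(seed = 1, rate_strand = 1.5), "rates")
  expect_error(generator_config(), "seed is mandatory")
})
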