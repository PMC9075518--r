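# End-to-end pipeline: translate -> scan -> profile -> classify ->
# align -> tree -> report.

#' Pipeline run configuration
#'
#' @param input Path to a transcript (nucleotide) or protein FASTA.
#' @param input_type "auto", "nucleotide" or "protein".
#' @param out_dir Output directory (created if needed).
#' @param min_aa Minimum ORF length for translation.
#' @param threshold_bits Detection threshold (default: bundled model's).
#' @param pka_table pKa set name for pI.
#' @param bootstrap_reps Bootstrap replicates for the tree.
#' @param seed Mandatory seed (bootstrap resampling).
#' @return list with class "run_config".
#' @export
run_config <- function(input, input_type = "auto", out_dir, min_aa = 50L,
                       threshold_bits = NULL, pka_table = "sms",
                       bootstrap_reps = 100L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(input = input, input_type = input_type, out_dir = out_dir,
                 min_aa = as.integer(min_aa),
                 threshold_bits = threshold_bits, pka_table = pka_table,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full sHsp discovery pipeline
#'
#' Translates transcripts (six frames), de-duplicates identical
#' peptides, detects ACDs, profiles physicochemistry, classifies
#' monomeric sHsps into subclusters, scans NLS motifs, aligns the ACD
#' cores and builds a bootstrapped NJ tree. Stage outputs are written
#' under \code{out_dir} with stable filenames; a rerun with the same
#' config and inputs is byte-identical. Internal count identities of the
#' summary are asserted on every run.
#'
#' @param config A [run_config()].
#' @return list with class "shsp_run": summary (named list of counts),
#'   proteins, hits, architectures, profiles, assignments, nls,
#'   alignment, tree (NULL when fewer than 3 cores), paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$input))
    stop("stage translate: input not found: ", config$input, call. = FALSE)
  records <- read_fasta(config$input, config$input_type)
  is_nt <- inherits(records[[1L]], "transcript_record")

  # translate
  if (is_nt) {
    proteins <- list()
    for (tr in records)
      proteins <- c(proteins, translate_six_frames(tr, min_aa = config$min_aa))
  } else proteins <- records
  if (!length(proteins))
    stop("stage translate: no ORFs of length >= ", config$min_aa,
         call. = FALSE)

  # de-duplicate identical peptides (keep first id as representative)
  seqs <- vapply(proteins, `[[`, "", "seq")
  rep_of <- match(seqs, seqs)
  unique_idx <- which(rep_of == seq_along(seqs))

  model <- default_acd_model()
  thr <- if (is.null(config$threshold_bits)) model$threshold_bits
         else config$threshold_bits

  hits <- list(); arch <- list(); profiles <- list()
  assignments <- list(); nls <- list(); cores <- character(0)
  for (i in unique_idx) {
    p <- proteins[[i]]
    det <- detect_acds(p, model, thr)
    arch[[length(arch) + 1L]] <- det$architecture
    if (nrow(det$hits)) hits[[length(hits) + 1L]] <- det$hits
    core1 <- if (nrow(det$hits)) trim_core(det$hits[1L, ], p) else NULL
    prof <- physchem_profile(p, acd_core = core1,
                             pka_table = config$pka_table)
    profiles[[length(profiles) + 1L]] <- prof
    if (det$architecture$label == "monomeric") {
      asg <- assign_cluster(p, det$hits[1L, ], prof)
      assignments[[length(assignments) + 1L]] <- data.frame(
        protein_id = asg$protein_id, label = asg$label,
        confidence = asg$confidence,
        rules = paste(asg$fired_rules$rule, collapse = ";"),
        stringsAsFactors = FALSE)
      nlsi <- scan_nls(p, det$hits)
      if (nrow(nlsi)) nls[[length(nls) + 1L]] <- nlsi
    }
    if (nrow(det$hits)) {
      for (k in seq_len(nrow(det$hits)))
        cores[sprintf("%s|acd%d", p$id, k)] <-
          trim_core(det$hits[k, ], p)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else NULL
  arch <- do.call(rbind, arch)
  profiles <- do.call(rbind, profiles)
  assignments <- if (length(assignments)) do.call(rbind, assignments) else
    data.frame(protein_id = character(0), label = character(0),
               confidence = numeric(0), rules = character(0))
  nls <- if (length(nls)) do.call(rbind, nls) else
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), kind = character(0),
               basic_count = integer(0))

  # propagate architecture calls and labels to exact-duplicate peptides
  # (duplicates are collapsed for computation but kept in the counts)
  ids <- vapply(proteins, `[[`, "", "id")
  if (any(rep_of != seq_along(seqs))) {
    dup <- which(rep_of != seq_along(seqs))
    extra_arch <- arch[match(ids[rep_of[dup]], arch$protein_id), ]
    extra_arch$protein_id <- ids[dup]
    arch <- rbind(arch, extra_arch)
    if (nrow(assignments)) {
      hit <- !is.na(match(ids[rep_of[dup]], assignments$protein_id))
      extra <- assignments[match(ids[rep_of[dup]], assignments$protein_id), ]
      extra <- extra[hit, , drop = FALSE]
      if (nrow(extra)) {
        extra$protein_id <- ids[dup][hit]
        assignments <- rbind(assignments, extra)
      }
    }
  }

  alignment <- NULL; tree <- NULL
  if (length(cores) >= 2L)
    alignment <- align_cores(cores, model)
  if (!is.null(alignment) && length(alignment$ids) >= 3L)
    tree <- bootstrap_supports(alignment, config$bootstrap_reps,
                               seed = config$seed)

  n_with_acd <- sum(arch$n_acd >= 1L)
  per_cluster <- table(factor(assignments$label[
    assignments$protein_id %in% arch$protein_id[arch$label == "monomeric"]],
    levels = c("A1", "A2", "B1", "B2", "B3", "unassigned")))
  summary <- list(
    n_input = length(records),
    n_orfs = length(proteins),
    n_unique_proteins = length(unique_idx),
    n_with_acd = n_with_acd,
    n_monomeric = sum(arch$label == "monomeric"),
    n_dimeric = sum(arch$label == "dimeric"),
    n_multi = sum(arch$label == "multi"),
    per_cluster = as.list(per_cluster))
  # internal identities, asserted on every run
  stopifnot(summary$n_monomeric + summary$n_dimeric + summary$n_multi ==
              summary$n_with_acd)
  stopifnot(sum(unlist(summary$per_cluster)) == summary$n_monomeric)

  out <- structure(list(summary = summary, proteins = proteins,
                        hits = hits, architectures = arch,
                        profiles = profiles, assignments = assignments,
                        nls = nls, alignment = alignment, tree = tree,
                        config = config),
                   class = "shsp_run")
  if (!is.null(config$out_dir)) write_run_outputs(out, config$out_dir)
  out
}

#' @keywords internal
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(run$proteins, file.path(out_dir, "proteins.fa"))
  if (!is.null(run$hits)) tsv(run$hits, "hits.tsv")
  tsv(run$architectures, "architectures.tsv")
  tsv(run$profiles, "profiles.tsv")
  tsv(run$assignments, "assignments.tsv")
  tsv(run$nls, "nls.tsv")
  if (!is.null(run$alignment)) {
    write_fasta(stats::setNames(run$alignment$rows, run$alignment$ids),
                file.path(out_dir, "cores_aligned.fa"))
    tsv(column_stats(run$alignment), "column_stats.tsv")
  }
  if (!is.null(run$tree)) {
    ape::write.tree(run$tree$tree, file.path(out_dir, "tree.nwk"))
    dm <- p_distance_matrix(run$alignment)
    utils::write.table(round(dm, 6), file.path(out_dir, "distances.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  cfg <- run$config; class(cfg) <- NULL
  cfg$out_dir <- NULL  # self-referential; outputs live in this directory
  jsonlite::write_json(list(config = cfg, summary = run$summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.shsp_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<shsp_run> %d input records, %d ORFs (%d unique): %d with ACD (%d monomeric, %d dimeric, %d multi)\n",
    s$n_input, s$n_orfs, s$n_unique_proteins, s$n_with_acd, s$n_monomeric,
    s$n_dimeric, s$n_multi))
  pc <- unlist(s$per_cluster)
  cat(" per cluster:", paste(names(pc), pc, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Fetch protein sequences for a GenBank accession range
#'
#' Downloads one FASTA record per accession via NCBI efetch and caches
#' them locally; reruns with a warm cache never touch the network.
#'
#' @param accessions Either a character vector of accessions or a range
#'   string like \code{"MZ261736:MZ261811"}.
#' @param cache_dir Cache directory.
#' @param offline_only If TRUE, never attempt the network.
#' @return Path to the cached multi-FASTA; missing accessions are
#'   reported with a warning and the run continues.
#' @export
fetch_accessions <- function(accessions,
                             cache_dir = file.path(tempdir(), "acdminer_cache"),
                             offline_only = FALSE) {
  if (length(accessions) == 1L && grepl(":", accessions, fixed = TRUE)) {
    parts <- strsplit(accessions, ":", fixed = TRUE)[[1L]]
    pre <- sub("[0-9]+$", "", parts)
    num <- as.integer(sub("^[A-Za-z]+", "", parts))
    if (length(unique(pre)) != 1L || anyNA(num))
      stop("invalid accession range: ", accessions, call. = FALSE)
    width <- nchar(sub("^[A-Za-z]+", "", parts[1L]))
    accessions <- sprintf(paste0("%s%0", width, "d"), pre[1L],
                          num[1L]:num[2L])
  }
  ok <- grepl("^[A-Z]{1,4}[0-9]{5,8}(\\.[0-9]+)?$", accessions)
  if (!all(ok))
    stop("invalid accession format: ",
         paste(accessions[!ok], collapse = ", "), call. = FALSE)
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  combined <- file.path(cache_dir, "accessions.fa")
  cached <- file.path(cache_dir, paste0(accessions, ".fa"))
  missing <- accessions[!file.exists(cached)]
  if (length(missing)) {
    if (offline_only)
      stop("accessions not cached and offline_only = TRUE: ",
           paste(missing, collapse = ", "), call. = FALSE)
    base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
                   "efetch.fcgi?db=protein&rettype=fasta&retmode=text&id=")
    failed <- character(0)
    for (acc in missing) {
      dest <- file.path(cache_dir, paste0(acc, ".fa"))
      status <- tryCatch(
        utils::download.file(paste0(base, acc), dest, quiet = TRUE),
        error = function(e) 1L, warning = function(w) 1L)
      if (!identical(status, 0L) || !file.size(dest) > 0) {
        unlink(dest)
        failed <- c(failed, acc)
      }
    }
    if (length(failed) == length(missing))
      stop("network fetch failed for all missing accessions; ",
           "retry when a connection is available", call. = FALSE)
    if (length(failed))
      warning("missing accessions (skipped): ",
              paste(failed, collapse = ", "))
  }
  have <- cached[file.exists(cached)]
  txt <- unlist(lapply(have, readLines))
  writeLines(txt, combined)
  combined
}
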