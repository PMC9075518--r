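# Synthetic transcriptome generator with ground truth.

#' Generator configuration
#'
#' Defines a synthetic repertoire: how many planted genes per subcluster
#' template (and dimeric), per-site substitution rates applied separately
#' to strand and loop/flank columns (motif-constrained signature
#' positions are never mutated, mirroring the near-total conservation of
#' those residues in the family's logos), loop indel settings (indels are
#' confined to unconstrained L57 positions outside constrained spans and
#' to the termini; strand columns never receive indels), decoy counts,
#' UTR lengths, the truncated (incomplete) fraction and the mandatory
#' seed.
#'
#' @param n_per_cluster Named integer vector over
#'   A1, A2, B1, B2, B3, dimeric.
#' @param rate_strand,rate_loop Substitution rates per unconstrained
#'   site in strand vs loop/flank columns.
#' @param indel_rate Per-loop/terminus probability of one indel event.
#' @param max_indel_len Maximum indel length (residues).
#' @param n_decoy_random Random background ORFs.
#' @param n_decoy_near_miss Decoys carrying exactly one signature motif.
#' @param utr_range 5'/3' UTR length range (nt).
#' @param truncated_fraction Fraction of planted genes emitted without a
#'   terminating stop codon (complete = FALSE).
#' @param seed Mandatory RNG seed.
#' @return list with class "generator_config".
#' @export
generator_config <- function(n_per_cluster = c(A1 = 5, A2 = 5, B1 = 5,
                                               B2 = 5, B3 = 5, dimeric = 5),
                             rate_strand = 0.01, rate_loop = 0.05,
                             indel_rate = 0.1, max_indel_len = 2L,
                             n_decoy_random = 10L, n_decoy_near_miss = 10L,
                             utr_range = c(30L, 120L),
                             truncated_fraction = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  rates <- c(rate_strand, rate_loop, indel_rate, truncated_fraction)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  labels <- c("A1", "A2", "B1", "B2", "B3", "dimeric")
  n <- stats::setNames(rep(0L, 6L), labels)
  n[names(n_per_cluster)] <- as.integer(n_per_cluster)
  structure(list(n_per_cluster = n, rate_strand = rate_strand,
                 rate_loop = rate_loop, indel_rate = indel_rate,
                 max_indel_len = as.integer(max_indel_len),
                 n_decoy_random = as.integer(n_decoy_random),
                 n_decoy_near_miss = as.integer(n_decoy_near_miss),
                 utr_range = as.integer(utr_range),
                 truncated_fraction = truncated_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# codon table for seeded back-translation
#' @keywords internal
codons_by_aa <- function() {
  if (is.null(.acdminer_env$codons_by_aa)) {
    gc <- Biostrings::GENETIC_CODE
    .acdminer_env$codons_by_aa <- split(names(gc), unname(gc))
  }
  .acdminer_env$codons_by_aa
}

#' @keywords internal
back_translate <- function(aa_chars) {
  cb <- codons_by_aa()
  paste(vapply(aa_chars, function(a) {
    opts <- cb[[a]]
    if (is.null(opts)) "NNN" else opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
}

# mutate one template copy; returns chars + updated annotation
#' @keywords internal
mutate_template <- function(tmpl, config) {
  ch <- strsplit(tmpl$seq, "")[[1L]]
  n <- length(ch)
  kind <- rep("flank", n)
  core_index <- rep(NA_integer_, n)
  region <- rep("flank", n)
  for (i in seq_len(nrow(tmpl$regions))) {
    r <- tmpl$regions[i, ]
    if (r$end > r$start) {
      idx <- (r$start + 1L):r$end
      kind[idx] <- r$kind
      region[idx] <- r$region
      core_index[idx] <- r$core_index
    }
  }
  constrained <- rep(FALSE, n)
  constrained[tmpl$constrained + 1L] <- TRUE

  # substitutions
  rate <- ifelse(kind == "strand", config$rate_strand, config$rate_loop)
  rate[constrained] <- 0
  hit <- stats::runif(n) < rate
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(a)
      sample(setdiff(AA20, a), 1L), "")

  # indels: unconstrained L57 stretches outside constrained spans + termini
  splice <- function(ch, meta, pos, del = 0L, ins = character(0),
                     ins_meta = NULL) {
    # pos: 1-based position at which to delete `del` chars / insert before
    if (del > 0L) {
      keep <- setdiff(seq_along(ch), pos:(pos + del - 1L))
      ch <- ch[keep]; meta <- meta[keep, , drop = FALSE]
    }
    if (length(ins)) {
      before <- seq_len(pos - 1L)
      after <- if (pos <= length(ch)) pos:length(ch) else integer(0)
      ch <- c(ch[before], ins, ch[after])
      meta <- rbind(meta[before, , drop = FALSE],
                    ins_meta[rep(1L, length(ins)), , drop = FALSE],
                    meta[after, , drop = FALSE])
    }
    list(ch = ch, meta = meta)
  }
  meta <- data.frame(kind = kind, region = region, core_index = core_index,
                     constrained = constrained, stringsAsFactors = FALSE)
  do_indel <- function(idx_free, reg, ci) {
    if (stats::runif(1) >= config$indel_rate || !length(idx_free))
      return(invisible(NULL))
    len <- sample.int(config$max_indel_len, 1L)
    if (reg == "L57") {
      g <- sum(meta$region == "L57" & meta$core_index %in% ci)
      if (stats::runif(1) < 0.5 && g - len >= L57_MIN &&
          length(idx_free) >= len) {
        st <- splice(ch, meta, idx_free[1L], del = min(len, length(idx_free)))
      } else if (g + len <= L57_MAX) {
        ins <- sample(AA20, len, replace = TRUE)
        st <- splice(ch, meta, idx_free[1L], ins = ins,
                     ins_meta = data.frame(kind = "loop", region = reg,
                                           core_index = ci,
                                           constrained = FALSE))
      } else return(invisible(NULL))
    } else {
      if (stats::runif(1) < 0.5 && length(idx_free) > len + 2L) {
        st <- splice(ch, meta, idx_free[2L], del = len)
      } else {
        ins <- sample(AA20, len, replace = TRUE)
        st <- splice(ch, meta, idx_free[1L], ins = ins,
                     ins_meta = data.frame(kind = "flank", region = reg,
                                           core_index = NA_integer_,
                                           constrained = FALSE))
      }
    }
    ch <<- st$ch; meta <<- st$meta
    invisible(NULL)
  }
  for (ci in unique(stats::na.omit(meta$core_index))) {
    sel <- which(meta$region == "L57" & meta$core_index == ci &
                   !meta$constrained)
    # only the contiguous free stretch after the constrained span
    cons <- which(meta$region == "L57" & meta$core_index == ci &
                    meta$constrained)
    if (length(cons)) sel <- sel[sel > max(cons)]
    do_indel(sel, "L57", ci)
  }
  ntd <- which(meta$region == "NTD")[-1L]   # keep the initiator M
  do_indel(ntd, "NTD", NA_integer_)
  do_indel(which(meta$region == "CTD"), "CTD", NA_integer_)

  # core spans after mutation
  cores <- do.call(rbind, lapply(unique(stats::na.omit(meta$core_index)),
    function(i) {
      idx <- which(meta$core_index == i)
      data.frame(core_index = i, start = min(idx) - 1L, end = max(idx))
    }))
  list(seq = paste(ch, collapse = ""), cores = cores)
}

#' Generate a synthetic transcriptome repertoire with ground truth
#'
#' Plants mutated copies of the cluster templates (wrapped in ATG..stop
#' with random UTRs; an in-frame stop terminates the 5' UTR so the
#' planted ORF translates exactly), adds random-background decoy ORFs
#' and near-miss decoys carrying exactly one signature motif, and emits
#' a ground-truth table. A configurable fraction of planted genes is
#' truncated (no terminating stop, no 3' UTR) to exercise the
#' incomplete-sequence rule. Deterministic for a fixed seed.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional directory; when given, writes
#'   \code{transcripts.fa}, \code{proteins.fa} and \code{truth.tsv}.
#' @return list: transcripts (named character), proteins (named
#'   character), truth (data.frame: transcript_id, protein_id, cluster,
#'   acd1_start, acd1_end, acd2_start, acd2_end, complete).
#' @export
generate_repertoire <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  res <- with_seed(config$seed, {
    transcripts <- character(0); proteins <- character(0)
    truth <- list()
    rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")
    utr <- function() {
      n <- sample(config$utr_range[1L]:config$utr_range[2L], 1L)
      rand_nt(n)
    }
    stops <- c("TAA", "TAG", "TGA")
    add_gene <- function(pid, aa, cores, cluster) {
      truncated <- stats::runif(1) < config$truncated_fraction
      cds <- back_translate(strsplit(aa, "")[[1L]])
      tid <- paste0("tx_", pid)
      if (truncated) {
        tx <- paste0(cds)  # ORF abuts the 3' contig edge
      } else {
        tx <- paste0(utr(), "TAA", cds, sample(stops, 1L), utr())
      }
      transcripts[tid] <<- tx
      proteins[pid] <<- aa
      truth[[length(truth) + 1L]] <<- data.frame(
        transcript_id = tid, protein_id = pid, cluster = cluster,
        acd1_start = if (!is.null(cores)) cores$start[1L] else NA_integer_,
        acd1_end = if (!is.null(cores)) cores$end[1L] else NA_integer_,
        acd2_start = if (!is.null(cores) && nrow(cores) > 1L)
          cores$start[2L] else NA_integer_,
        acd2_end = if (!is.null(cores) && nrow(cores) > 1L)
          cores$end[2L] else NA_integer_,
        complete = !truncated, stringsAsFactors = FALSE)
    }
    for (cl in names(config$n_per_cluster)) {
      n <- config$n_per_cluster[[cl]]
      if (n == 0L) next
      tmpl <- make_template(cl)
      for (k in seq_len(n)) {
        mut <- mutate_template(tmpl, config)
        add_gene(sprintf("%s_%02d", cl, k), mut$seq, mut$cores, cl)
      }
    }
    # decoys: random background ORFs
    bg <- rep(1 / 20, 20)
    for (k in seq_len(config$n_decoy_random)) {
      len <- sample(120:260, 1L)
      aa <- paste(c("M", sample(AA20, len - 1L, TRUE, prob = bg)),
                  collapse = "")
      add_gene(sprintf("decoy_rand_%02d", k), aa, NULL, "decoy")
    }
    # near-miss decoys: exactly one signature motif on random background
    near_motifs <- c("LKVEAP",   # beta9 anchor instance
                     "ALPSAA",   # L78 L-P doublet alone
                     "KKKIKK",   # B1 lysine motif
                     "FQSESA",   # B1 serine motif
                     "GKHEER")   # B3 motif
    for (k in seq_len(config$n_decoy_near_miss)) {
      len <- sample(120:260, 1L)
      aa <- c("M", sample(setdiff(AA20, c("L", "P")), len - 1L, TRUE))
      mot <- strsplit(near_motifs[((k - 1L) %% length(near_motifs)) + 1L],
                      "")[[1L]]
      at <- sample(10:(len - length(mot) - 5L), 1L)
      aa[at:(at + length(mot) - 1L)] <- mot
      add_gene(sprintf("decoy_near_%02d", k), paste(aa, collapse = ""),
               NULL, "decoy")
    }
    list(transcripts = transcripts, proteins = proteins,
         truth = do.call(rbind, truth))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(res$transcripts, file.path(out_dir, "transcripts.fa"))
    write_fasta(res$proteins, file.path(out_dir, "proteins.fa"))
    utils::write.table(res$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
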