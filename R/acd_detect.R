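# ACD detection: anchored motifs + PSSM scoring, architecture calls.

#' Detect alpha-crystallin domains in a protein
#'
#' A hit requires, in order: (a) a match of the beta9 anchor motif
#' \code{L-X-(V/T)-(E/K)-(A/L)-(P/K)}; (b) at least one of the L78
#' doublets (L-P or V-D) upstream of it inside the L78 span implied by
#' the core geometry; and (c) a PSSM log-odds score over the implied
#' beta3..beta9 window of at least \code{threshold_bits}. The variable
#' L57 bridge length (4-14 residues) is chosen to maximize the score.
#' Candidate hits are selected greedily best-score-first without overlap
#' (ties: leftmost wins). The architecture label follows the surviving
#' hit count: none, monomeric (1), dimeric (2), multi (>2).
#'
#' @param protein A [protein_record()] or amino-acid string.
#' @param model An "acd_model" (default: bundled model).
#' @param threshold_bits Detection threshold in bits (default: the
#'   model's calibrated threshold).
#' @return list with elements \code{hits} (data.frame: protein_id,
#'   start, end, score_bits, l57_len, rank and anchor_* columns, all
#'   coordinates 0-based half-open) and \code{architecture} (data.frame:
#'   protein_id, n_acd, label).
#' @export
detect_acds <- function(protein, model = default_acd_model(),
                        threshold_bits = model$threshold_bits) {
  if (is.character(protein)) protein <- protein_record("protein", protein)
  if (!is.finite(threshold_bits) && !identical(threshold_bits, -Inf))
    stop("threshold_bits must be finite (or -Inf to disable)", call. = FALSE)
  ch <- check_protein_seq(protein$seq)
  n <- length(ch)
  empty_hits <- data.frame(
    protein_id = character(0), start = integer(0), end = integer(0),
    score_bits = numeric(0), l57_len = integer(0), rank = character(0),
    stringsAsFactors = FALSE)
  min_len <- BLOCK1_LEN + L57_MIN + BLOCK2_LEN
  cands <- list()
  if (n >= min_len) {
    arr <- block_score_arrays(ch, model)
    b9 <- scan_motif(protein$seq, B9_MOTIF)
    for (i in seq_len(nrow(b9))) {
      e9 <- b9$end[i]                       # 0-based end of the core
      if (e9 < min_len) next
      # (b) an L78 doublet inside the implied L78 span [e9-25, e9-17)
      l78_lo <- e9 - 25L
      l78_hi <- e9 - 17L
      if (l78_lo < 0L) next
      # one extra char so a doublet starting at the last L78 position fits
      l78_seq <- substr(protein$seq, l78_lo + 1L, l78_hi + 1L)
      has_doublet <- any(vapply(L78_DOUBLETS, function(p)
        nrow(scan_motif(l78_seq, p)) > 0L, TRUE))
      if (!has_doublet) next
      # (c) best-scoring bridge length
      s2_start <- e9 - BLOCK2_LEN           # 0-based
      s2 <- arr$s2[s2_start + 1L]
      best_score <- -Inf; best_g <- NA_integer_
      for (g in L57_MIN:L57_MAX) {
        start <- e9 - BLOCK2_LEN - g - BLOCK1_LEN
        if (start < 0L) next
        sc <- arr$s1[start + 1L] + s2
        if (sc > best_score + 1e-12 ||
            (abs(sc - best_score) <= 1e-12 && !is.na(best_g) && g > best_g)) {
          best_score <- sc; best_g <- g
        }
      }
      if (!is.na(best_g) && best_score >= threshold_bits) {
        cands[[length(cands) + 1L]] <- list(
          start = e9 - BLOCK2_LEN - best_g - BLOCK1_LEN, end = e9,
          score = best_score, g = best_g)
      }
    }
  }
  hits <- empty_hits
  if (length(cands)) {
    cd <- do.call(rbind, lapply(cands, as.data.frame))
    cd <- cd[order(-cd$score, cd$start), , drop = FALSE]
    keep <- logical(nrow(cd))
    for (i in seq_len(nrow(cd))) {
      ok <- TRUE
      for (j in which(keep)) {
        if (cd$start[i] < cd$end[j] && cd$start[j] < cd$end[i]) { ok <- FALSE; break }
      }
      keep[i] <- ok
    }
    cd <- cd[keep, , drop = FALSE]
    cd <- cd[order(cd$start), , drop = FALSE]
    nh <- nrow(cd)
    rank <- if (nh == 1L) "only" else
      c("upstream", rep("internal", max(0L, nh - 2L)), "downstream")
    hits <- data.frame(
      protein_id = protein$id, start = cd$start, end = cd$end,
      score_bits = cd$score, l57_len = cd$g, rank = rank,
      stringsAsFactors = FALSE)
    # anchor positions (protein coordinates, 0-based starts)
    for (r in ACD_REGIONS$region) {
      off <- ACD_OFFSETS[[r]]
      pos <- ifelse(off < BLOCK1_LEN, hits$start + off,
                    ifelse(off == BLOCK1_LEN, hits$start + BLOCK1_LEN,
                           hits$start + BLOCK1_LEN + hits$l57_len +
                             (off - BLOCK1_LEN - L57_MAX)))
      hits[[paste0("anchor_", r)]] <- as.integer(pos)
    }
  }
  n_acd <- nrow(hits)
  label <- if (n_acd == 0L) "none" else if (n_acd == 1L) "monomeric"
    else if (n_acd == 2L) "dimeric" else "multi"
  list(hits = hits,
       architecture = data.frame(protein_id = protein$id, n_acd = n_acd,
                                 label = label, stringsAsFactors = FALSE))
}

#' Extract the beta3..beta9 core of a detected hit
#'
#' @param hit One row of a \code{detect_acds()} hits data.frame.
#' @param protein The [protein_record()] (or string) the hit belongs to.
#' @return Amino-acid string of the core; length in \[60, 85\].
#' @export
trim_core <- function(hit, protein) {
  if (is.character(protein)) protein <- protein_record("protein", protein)
  if (!identical(hit$protein_id, protein$id) && !is.null(hit$protein_id) &&
      nzchar(hit$protein_id) && protein$id != "protein")
    stop("hit does not belong to this protein (", hit$protein_id,
         " vs ", protein$id, ")", call. = FALSE)
  if (hit$start < 0L || hit$end > nchar(protein$seq) || hit$start >= hit$end)
    stop("hit coordinates out of range for protein ", protein$id,
         call. = FALSE)
  core <- substr(protein$seq, hit$start + 1L, hit$end)
  stopifnot(nchar(core) >= 60L, nchar(core) <= 85L)
  core
}
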