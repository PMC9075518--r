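# Six-frame translation and ORF extraction.

#' @keywords internal
translate_frame <- function(nt_chars, code) {
  n <- length(nt_chars)
  n_codon <- n %/% 3L
  if (n_codon == 0L) return(character(0))
  idx <- seq_len(n_codon * 3L)
  codons <- paste0(nt_chars[idx[c(TRUE, FALSE, FALSE)]],
                   nt_chars[idx[c(FALSE, TRUE, FALSE)]],
                   nt_chars[idx[c(FALSE, FALSE, TRUE)]])
  aa <- code[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  unname(aa)
}

#' Six-frame translation with ORF extraction
#'
#' Translates a transcript in all six reading frames and reports ORFs.
#' Within each frame the peptide is split at stop codons; a segment that
#' is terminated by a stop codon and contains a methionine is reported
#' from its first M with \code{complete = TRUE}. Segments lacking an
#' internal start or stop (including those abutting a contig edge) are
#' reported whole with \code{complete = FALSE}. Reverse-strand ORFs are
#' reported in forward-strand, 0-based half-open coordinates spanning the
#' peptide codons (stop codon excluded).
#'
#' @param transcript A [transcript_record()] (or nucleotide string).
#' @param genetic_code NCBI genetic-code table id (default "1",
#'   standard).
#' @param min_aa Minimum reported peptide length (default 50).
#' @return list of [protein_record()] objects.
#' @export
translate_six_frames <- function(transcript, genetic_code = "1", min_aa = 50L) {
  if (is.character(transcript))
    transcript <- transcript_record("transcript", transcript)
  if (min_aa < 1L) stop("min_aa must be >= 1", call. = FALSE)
  ch <- check_nt_seq(transcript$seq, paste0("transcript ", transcript$id))
  code <- Biostrings::getGeneticCode(genetic_code)
  L <- length(ch)
  rc <- rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch])
  out <- list()
  k <- 0L
  for (strand in c(1L, -1L)) {
    chars <- if (strand == 1L) ch else rc
    for (off in 0L:2L) {
      aa <- translate_frame(chars[(off + 1L):L], code)
      if (!length(aa)) next
      frame <- strand * (off + 1L)
      # segment boundaries between stop codons
      stops <- which(aa == "*")
      seg_start <- c(1L, stops + 1L)            # aa index, 1-based
      seg_end <- c(stops - 1L, length(aa))      # inclusive
      terminated <- c(rep(TRUE, length(stops)), FALSE)
      for (s in seq_along(seg_start)) {
        a <- seg_start[s]; b <- seg_end[s]
        if (b < a) next
        pep <- aa[a:b]
        m_pos <- which(pep == "M")[1L]
        if (terminated[s] && !is.na(m_pos)) {
          a <- a + m_pos - 1L
          pep <- pep[m_pos:length(pep)]
          complete <- TRUE
        } else complete <- FALSE
        if (length(pep) < min_aa) next
        # nt coords within this strand's sequence (0-based half-open)
        nt_a <- off + (a - 1L) * 3L
        nt_b <- off + (b) * 3L
        if (strand == 1L) {
          fwd <- c(nt_a, nt_b)
        } else {
          fwd <- c(L - nt_b, L - nt_a)
        }
        k <- k + 1L
        out[[k]] <- protein_record(
          id = sprintf("%s|orf%d", transcript$id, k),
          seq = paste(pep, collapse = ""),
          source_transcript = transcript$id,
          frame = frame, start_nt = fwd[1L], end_nt = fwd[2L],
          complete = complete)
      }
    }
  }
  out
}

#' Extract the peptide encoded at given forward-strand coordinates
#'
#' Utility to check that ORF coordinates map back to the transcript.
#'
#' @param transcript A [transcript_record()].
#' @param start_nt,end_nt 0-based half-open forward coordinates.
#' @param frame Frame sign determines the strand.
#' @param genetic_code Genetic-code table id.
#' @return Amino-acid string.
#' @export
peptide_at <- function(transcript, start_nt, end_nt, frame, genetic_code = "1") {
  ch <- check_nt_seq(transcript$seq)
  sub <- ch[(start_nt + 1L):end_nt]
  if (frame < 0L)
    sub <- rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[sub])
  paste(translate_frame(sub, Biostrings::getGeneticCode(genetic_code)),
        collapse = "")
}
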