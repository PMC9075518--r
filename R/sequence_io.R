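# FASTA I/O and record constructors.

#' Transcript record
#'
#' @param id Unique identifier.
#' @param seq Nucleotide string over A,C,G,T,N.
#' @param description Free-text description.
#' @return list with class "transcript_record".
#' @export
transcript_record <- function(id, seq, description = "") {
  if (!nzchar(id)) stop("transcript id must be non-empty", call. = FALSE)
  check_nt_seq(seq, paste0("transcript ", id))
  structure(list(id = id, seq = toupper(seq), description = description),
            class = "transcript_record")
}

#' Protein record
#'
#' A translated ORF (or a raw protein). Coordinates, when present, are
#' 0-based half-open on the forward strand of the source transcript.
#'
#' @param id Identifier.
#' @param seq Amino-acid string (20-letter alphabet plus X).
#' @param source_transcript Source transcript id or NULL.
#' @param frame Reading frame in +1..+3, -1..-3, or NULL.
#' @param start_nt,end_nt 0-based half-open forward-strand coordinates of
#'   the peptide codons, or NULL.
#' @param complete TRUE when the ORF has an initiator M and a terminating
#'   stop codon inside the transcript.
#' @return list with class "protein_record".
#' @export
protein_record <- function(id, seq, source_transcript = NULL, frame = NULL,
                           start_nt = NULL, end_nt = NULL, complete = NA) {
  check_protein_seq(seq, paste0("protein ", id))
  if (is.null(frame) && (!is.null(start_nt) || !is.null(end_nt)))
    stop("coordinates require a frame", call. = FALSE)
  structure(list(id = id, seq = toupper(seq),
                 source_transcript = source_transcript, frame = frame,
                 start_nt = start_nt, end_nt = end_nt,
                 complete = complete),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein %s> %d aa%s%s\n", x$id, nchar(x$seq),
              if (!is.null(x$frame)) sprintf(", frame %+d", x$frame) else "",
              if (isTRUE(x$complete)) ", complete" else ", incomplete"))
  invisible(x)
}

#' Read a FASTA file
#'
#' Reads nucleotide or amino-acid FASTA into a list of records. The
#' sequence type is auto-detected unless given.
#'
#' @param path Path to a FASTA file.
#' @param type "auto", "nucleotide" or "protein".
#' @return list of [transcript_record()] or [protein_record()] objects.
#' @export
read_fasta <- function(path, type = c("auto", "nucleotide", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  desc <- sub("^\\S+\\s*", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(ss))
  if (type == "auto") {
    chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1L]])
    type <- if (all(chars %in% c("A", "C", "G", "T", "N", "U")))
      "nucleotide" else "protein"
  }
  if (type == "nucleotide") {
    mapply(function(i, s, d) transcript_record(i, gsub("U", "T", s), d),
           ids, seqs, desc, SIMPLIFY = FALSE, USE.NAMES = TRUE)
  } else {
    mapply(function(i, s) protein_record(i, s),
           ids, seqs, SIMPLIFY = FALSE, USE.NAMES = TRUE)
  }
}

#' Write records to FASTA
#'
#' @param records list of transcript or protein records (or a named
#'   character vector of sequences).
#' @param path Output path.
#' @param width Line-wrap width (max 80 columns).
#' @return Invisibly, the path.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    ids <- names(records); seqs <- unname(records)
  } else {
    ids <- vapply(records, `[[`, "", "id")
    seqs <- vapply(records, `[[`, "", "seq")
  }
  if (anyDuplicated(ids))
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, filepath = path, width = min(width, 80L))
  invisible(path)
}
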