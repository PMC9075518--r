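# Rule-based subcluster assignment, NLS scanning, column statistics.

# classifier rule motifs (built lazily: file collation order)
rule_motifs <- function() {
  if (is.null(.acdminer_env$rule_motifs))
    .acdminer_env$rule_motifs <- list(
      b1_lysine = motif_pattern("K-K-K-X-K-K", name = "b1_lysine",
                                region = "b5-L57"),
      b1_serine = motif_pattern("F-X-S-E-S", name = "b1_serine",
                                region = "L34"),
      b1_acidic = motif_pattern("E-E-X-X-E-E", name = "b1_acidic",
                                region = "L57-b7"),
      b3_core = motif_pattern("L-D-V-X-X-F-X-P-E-E", name = "b3_core",
                              region = "b3-L34"),
      b3_gkhee = motif_pattern("G-K-H-E-E-(R/K)", name = "b3_gkhee",
                               region = "b5-L57"))
  .acdminer_env$rule_motifs
}

# numeric cut-offs sit just outside the published interquartile ranges to
# absorb dispersion beyond the IQR; all editable here
CLASSIFIER_CUTOFFS <- list(
  a1_core_len_max = 69L, a1_protein_len_max = 130L, a1_pi_max = 4.8,
  a2_protein_len_min = 300L, a2_pi_min = 8.5)

#' @keywords internal
hit_zone <- function(hit, zone) {
  # returns 0-based half-open [lo, hi) protein coordinates of a zone
  switch(zone,
    "b3-L34" = c(hit$anchor_b3, hit$anchor_b4),
    "L34" = c(hit$anchor_L34, hit$anchor_b4),
    "b4-L45" = c(hit$anchor_b4, hit$anchor_b5),
    "b5-L57" = c(hit$anchor_b5, hit$anchor_b7),
    "L57-b7" = c(hit$anchor_L57, hit$anchor_b7 + 6L),
    "b7" = c(hit$anchor_b7, hit$anchor_b7 + 6L),
    stop("unknown zone: ", zone))
}

#' @keywords internal
motif_in_zone <- function(seq, hit, pattern) {
  z <- hit_zone(hit, pattern$region)
  m <- scan_motif(substr(seq, z[1L] + 1L, z[2L]), pattern)
  if (nrow(m)) m$start <- m$start + z[1L]
  if (nrow(m)) m$end <- m$end + z[1L]
  m
}

#' Assign a monomeric sHsp to a subcluster
#'
#' Evaluates the subcluster rules in precedence order A1, A2, B1, B3,
#' then B2 as the residual class for any protein with a detected ACD:
#' \itemize{
#' \item A1: core length <= 69 and protein length < 130 and protein
#'   pI < 4.8 and no conserved arginine in beta7;
#' \item A2: protein length >= 300 and protein pI >= 8.5;
#' \item B1: lysine-rich K-K-K-X-K-K in the beta5-L57 zone or the
#'   serine-rich F-X-S-E-S in L34 (the acidic E-E-X-X-E-E in L57-beta7
#'   is recorded as corroboration);
#' \item B3: L-D-V-X-X-F-X-P-E-E in beta3-L34 or G-K-H-E-E-(R/K) in
#'   beta5-L57;
#' \item otherwise B2; "unassigned" only when no ACD hit is supplied.
#' }
#'
#' @param protein A [protein_record()] or string.
#' @param hit One row of the \code{detect_acds()} hits data.frame for
#'   this protein (or NULL for no hit).
#' @param profile One-row [physchem_profile()] data.frame.
#' @return list with class "cluster_assignment": protein_id, label,
#'   fired_rules (data.frame rule/start/end), confidence.
#' @export
assign_cluster <- function(protein, hit, profile) {
  if (is.character(protein)) protein <- protein_record("protein", protein)
  if (!is.null(hit) && is.data.frame(hit) && nrow(hit) > 1L)
    stop("monomeric classifier only: protein has multiple ACD hits",
         call. = FALSE)
  fired <- data.frame(rule = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  lab <- "unassigned"; conf <- 0
  if (!is.null(hit) && nrow(hit) == 1L) {
    co <- CLASSIFIER_CUTOFFS
    core_len <- hit$end - hit$start
    b7_seq <- substr(protein$seq, hit$anchor_b7 + 1L, hit$anchor_b7 + 6L)
    a1_conds <- c(core_len <= co$a1_core_len_max,
                  profile$length_aa < co$a1_protein_len_max,
                  profile$pi_protein < co$a1_pi_max,
                  !grepl("R", b7_seq, fixed = TRUE))
    a2_conds <- c(profile$length_aa >= co$a2_protein_len_min,
                  profile$pi_protein >= co$a2_pi_min)
    b1_lys <- motif_in_zone(protein$seq, hit, rule_motifs()$b1_lysine)
    b1_ser <- motif_in_zone(protein$seq, hit, rule_motifs()$b1_serine)
    b1_aci <- motif_in_zone(protein$seq, hit, rule_motifs()$b1_acidic)
    b3_cor <- motif_in_zone(protein$seq, hit, rule_motifs()$b3_core)
    b3_gkh <- motif_in_zone(protein$seq, hit, rule_motifs()$b3_gkhee)
    add_fired <- function(rule, m) {
      if (nrow(m))
        fired <<- rbind(fired, data.frame(rule = rule, start = m$start[1L],
                                          end = m$end[1L]))
    }
    if (all(a1_conds)) {
      lab <- "A1"; conf <- 1
      fired <- rbind(fired, data.frame(rule = "A1_size_pi_noR",
                                       start = hit$start, end = hit$end))
    } else if (all(a2_conds)) {
      lab <- "A2"; conf <- 1
      fired <- rbind(fired, data.frame(rule = "A2_length_basic_pi",
                                       start = 0L,
                                       end = profile$length_aa))
    } else if (nrow(b1_lys) || nrow(b1_ser)) {
      lab <- "B1"
      add_fired("B1_KKKxKK_b5L57", b1_lys)
      add_fired("B1_FxSES_L34", b1_ser)
      add_fired("B1_EExxEE_corroboration", b1_aci)
      conf <- (min(1L, nrow(b1_lys)) + min(1L, nrow(b1_ser)) +
                 min(1L, nrow(b1_aci))) / 3
    } else if (nrow(b3_cor) || nrow(b3_gkh)) {
      lab <- "B3"
      add_fired("B3_LDVxxFxPEE_b3L34", b3_cor)
      add_fired("B3_GKHEER_b5L57", b3_gkh)
      conf <- (min(1L, nrow(b3_cor)) + min(1L, nrow(b3_gkh))) / 2
    } else {
      lab <- "B2"; conf <- 1
      fired <- rbind(fired, data.frame(rule = "B2_residual_with_ACD",
                                       start = hit$start, end = hit$end))
    }
  }
  structure(list(protein_id = protein$id, label = lab,
                 fired_rules = fired, confidence = conf),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment %s> %s (confidence %.2f; rules: %s)\n",
              x$protein_id, x$label, x$confidence,
              if (nrow(x$fired_rules)) paste(x$fired_rules$rule, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Scan for nuclear-localization-signal-like motifs
#'
#' Reports (i) V-(R/K)-P matches inside the beta4-L45 zone of the hit
#' and (ii) any 6-residue window carrying at least 4 K/R residues
#' (overlapping qualifying windows are merged into maximal spans).
#'
#' @param protein A [protein_record()] or string.
#' @param hit One hits row for the protein, or NULL (then only the
#'   basic-rich scan runs).
#' @return data.frame: protein_id, start, end, kind ("VxP-type" or
#'   "basic-rich"), basic_count.
#' @export
scan_nls <- function(protein, hit = NULL) {
  if (is.character(protein)) protein <- protein_record("protein", protein)
  out <- data.frame(protein_id = character(0), start = integer(0),
                    end = integer(0), kind = character(0),
                    basic_count = integer(0), stringsAsFactors = FALSE)
  if (!is.null(hit) && nrow(hit) >= 1L) {
    for (i in seq_len(nrow(hit))) {
      m <- motif_in_zone(protein$seq, hit[i, ],
                         motif_pattern("V-(R/K)-P", region = "b4-L45"))
      if (nrow(m))
        out <- rbind(out, data.frame(
          protein_id = protein$id, start = m$start, end = m$end,
          kind = "VxP-type",
          basic_count = vapply(seq_len(nrow(m)), function(k) {
            w <- substr(protein$seq, m$start[k] + 1L, m$end[k])
            sum(strsplit(w, "")[[1L]] %in% c("K", "R"))
          }, 0L)))
    }
  }
  ch <- strsplit(protein$seq, "")[[1L]]
  n <- length(ch)
  if (n >= 6L) {
    basic <- as.integer(ch %in% c("K", "R"))
    win <- stats::filter(basic, rep(1L, 6L), sides = 1)
    starts0 <- which(win[6:n] >= 4L) - 1L      # 0-based window starts
    if (length(starts0)) {
      # merge overlapping windows into maximal spans
      spans <- list(c(starts0[1L], starts0[1L] + 6L))
      for (s in starts0[-1L]) {
        last <- spans[[length(spans)]]
        if (s <= last[2L]) spans[[length(spans)]][2L] <- s + 6L
        else spans[[length(spans) + 1L]] <- c(s, s + 6L)
      }
      for (sp in spans)
        out <- rbind(out, data.frame(
          protein_id = protein$id, start = sp[1L], end = sp[2L],
          kind = "basic-rich",
          basic_count = sum(basic[(sp[1L] + 1L):sp[2L]])))
    }
  }
  out
}

#' Per-column statistics of an anchored alignment
#'
#' For each column: residue counts, gap fraction, information content
#' (IC = log2(20) minus the Shannon entropy of the residue frequencies,
#' gaps excluded) and the consensus residue at threshold \code{t}
#' (\code{'x'} when no residue reaches the threshold). The output is a
#' per-column frequency/IC table directly consumable as a sequence-logo
#' matrix.
#'
#' @param msa An "anchored_alignment" (see [align_cores()]) or character
#'   vector of equal-length aligned rows.
#' @param t Consensus threshold in \[0, 1\] (default 0.5).
#' @param small_sample_correction Subtract the (19 / (2 ln2 n))
#'   small-sample bias from IC (default FALSE).
#' @return data.frame: column (1-based), anchor label (if available),
#'   n_residues, gap_fraction, ic_bits, consensus, plus one frequency
#'   column per residue.
#' @export
column_stats <- function(msa, t = 0.5, small_sample_correction = FALSE) {
  rows <- if (inherits(msa, "anchored_alignment")) msa$rows else msa
  labels <- if (inherits(msa, "anchored_alignment")) msa$anchors else NULL
  if (!length(rows)) stop("empty alignment", call. = FALSE)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    stop("alignment is not rectangular", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  n <- nrow(mat)
  out <- vector("list", ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    gaps <- sum(col == "-")
    res <- col[col != "-" & col != "X"]
    cnt <- table(factor(res, levels = AA20))
    m <- length(res)
    if (m == 0L) {
      ic <- NA_real_; cons <- "x"; freqs <- rep(NA_real_, 20L)
    } else {
      freqs <- as.numeric(cnt) / m
      p <- freqs[freqs > 0]
      ic <- log2(20) + sum(p * log2(p))
      if (small_sample_correction) ic <- max(0, ic - 19 / (2 * log(2) * m))
      # a tie at the threshold (e.g. an even two-residue split at t = 0.5)
      # has no single consensus residue
      cons <- if (max(freqs) >= t && sum(freqs == max(freqs)) == 1L)
        AA20[which.max(freqs)] else "x"
    }
    row <- data.frame(column = j,
                      anchor = if (is.null(labels)) NA_character_ else labels[j],
                      n_residues = m, gap_fraction = gaps / n,
                      ic_bits = ic, consensus = cons,
                      stringsAsFactors = FALSE)
    for (k in seq_along(AA20)) row[[AA20[k]]] <- freqs[k]
    out[[j]] <- row
  }
  do.call(rbind, out)
}
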