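#' Grand average of hydropathicity (GRAVY)
#'
#' Arithmetic mean of per-residue Kyte-Doolittle hydropathy values.
#' Unknown residues (\code{X}) are excluded from the average.
#'
#' @param seq Amino-acid string (20-letter alphabet plus \code{X}).
#' @return A single numeric GRAVY value in \[-4.5, 4.5\].
#' @examples
#' gravy("VKIV")  # 2.25
#' @export
gravy <- function(seq) {
  ch <- check_protein_seq(seq)
  ch <- ch[ch != "X"]
  if (!length(ch))
    stop("sequence has no scorable residues (all X)", call. = FALSE)
  mean(KD_HYDROPATHY[ch])
}

#' Protein molecular weight (average masses)
#'
#' Sum of average residue masses plus one water. \code{X} residues are
#' assigned the mean residue mass of the 20 standard amino acids.
#'
#' @param seq Amino-acid string.
#' @return Molecular weight in Daltons.
#' @examples
#' molecular_weight("G")  # ~75.07
#' @export
molecular_weight <- function(seq) {
  ch <- check_protein_seq(seq)
  m <- AA_AVG_MASS[ch]
  m[is.na(m)] <- mean(AA_AVG_MASS)  # X
  sum(m) + WATER_MASS
}

#' @keywords internal
resolve_pka_table <- function(pka_table) {
  if (is.character(pka_table)) {
    if (!pka_table %in% names(PKA_TABLES))
      stop("unknown pKa table '", pka_table, "'; available: ",
           paste(names(PKA_TABLES), collapse = ", "), call. = FALSE)
    tab <- PKA_TABLES[[pka_table]]
    tab$name <- pka_table
    tab
  } else if (is.list(pka_table)) {
    stopifnot(all(c("acidic", "basic", "nterm", "cterm") %in% names(pka_table)))
    if (is.null(pka_table$name)) pka_table$name <- "custom"
    pka_table
  } else stop("pka_table must be a table name or a list", call. = FALSE)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus, the acidic
#' side chains (D, E, C, Y) and the basic side chains (K, R, H).
#' \code{X} residues carry no charge.
#'
#' @param seq Amino-acid string.
#' @param pH pH value (may be a vector).
#' @param pka_table Name of a bundled pKa set ("sms", "emboss",
#'   "bjellqvist") or a custom list.
#' @return Net charge (same length as \code{pH}).
#' @export
net_charge <- function(seq, pH, pka_table = "sms") {
  ch <- check_protein_seq(seq)
  tab <- resolve_pka_table(pka_table)
  ch_known <- ch[ch != "X"]
  counts <- table(factor(ch_known, levels = AA20))

  nt_res <- ch[1L]
  ct_res <- ch[length(ch)]
  pk_nt <- tab$nterm
  if (!is.null(tab$nterm_by_residue) && nt_res %in% names(tab$nterm_by_residue))
    pk_nt <- tab$nterm_by_residue[[nt_res]]
  pk_ct <- tab$cterm
  if (!is.null(tab$cterm_by_residue) && ct_res %in% names(tab$cterm_by_residue))
    pk_ct <- tab$cterm_by_residue[[ct_res]]

  pos <- 1 / (1 + 10^(pH - pk_nt))          # protonated N-terminus
  neg <- -1 / (1 + 10^(pk_ct - pH))         # deprotonated C-terminus
  for (r in names(tab$basic))
    pos <- pos + counts[[r]] / (1 + 10^(pH - tab$basic[[r]]))
  for (r in names(tab$acidic))
    neg <- neg - counts[[r]] / (1 + 10^(tab$acidic[[r]] - pH))
  pos + neg
}

#' Theoretical isoelectric point
#'
#' pH of zero net charge, found by bisection on \[0, 14\] to a charge
#' tolerance of 1e-4. The charge model is the standard
#' Henderson-Hasselbalch sum over termini and ionizable side chains.
#'
#' @inheritParams net_charge
#' @param tol Bisection stops when |charge| < tol.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka_table = "sms", tol = 1e-4) {
  lo <- 0; hi <- 14
  qlo <- net_charge(seq, lo, pka_table)
  qhi <- net_charge(seq, hi, pka_table)
  # net charge is monotone decreasing in pH; guard degenerate edges
  if (qlo <= 0) return(lo)
  if (qhi >= 0) return(hi)
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid, pka_table)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical profile of a protein and (optionally) its ACD core
#'
#' @param protein A protein record (see [protein_record()]) or a plain
#'   amino-acid string.
#' @param acd_core Optional amino-acid string of the ACD core (beta3 to
#'   beta9 span) to profile alongside the whole protein.
#' @param pka_table pKa set used for pI.
#' @return A one-row data.frame: protein_id, length_aa, mw_kda,
#'   pi_protein, pi_acd, gravy_protein, gravy_acd, complete, pka_table.
#' @export
physchem_profile <- function(protein, acd_core = NULL, pka_table = "sms") {
  if (is.character(protein)) protein <- protein_record(id = "protein", seq = protein)
  tab <- resolve_pka_table(pka_table)
  data.frame(
    protein_id = protein$id,
    length_aa = nchar(protein$seq),
    mw_kda = molecular_weight(protein$seq) / 1000,
    pi_protein = isoelectric_point(protein$seq, tab),
    pi_acd = if (is.null(acd_core)) NA_real_ else isoelectric_point(acd_core, tab),
    gravy_protein = gravy(protein$seq),
    gravy_acd = if (is.null(acd_core)) NA_real_ else gravy(acd_core),
    complete = isTRUE(protein$complete),
    pka_table = tab$name,
    stringsAsFactors = FALSE)
}

#' Per-group interquartile summaries of physicochemical profiles
#'
#' Mirrors the classic per-cluster property table: per group and metric,
#' Q1 and Q3 (linear-interpolation quantiles) over complete sequences
#' only. Incomplete sequences are excluded from n and from the ranges.
#'
#' @param profiles data.frame as returned by rbind-ing
#'   [physchem_profile()] rows.
#' @param labels Character vector of group labels, parallel to
#'   \code{profiles} rows.
#' @param metrics Which profile columns to summarize.
#' @return data.frame with one row per group x metric: group, n, metric,
#'   q1, q3.
#' @export
summarize_groups <- function(profiles, labels,
                             metrics = c("mw_kda", "length_aa", "pi_protein",
                                         "pi_acd", "gravy_protein", "gravy_acd")) {
  stopifnot(is.data.frame(profiles))
  if (length(labels) != nrow(profiles))
    stop("labels must cover all profiles", call. = FALSE)
  out <- list()
  for (g in unique(labels)) {
    sub <- profiles[labels == g & profiles$complete, , drop = FALSE]
    n <- nrow(sub)
    for (m in metrics) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      if (n == 0L || !length(v)) {
        q <- c(NA_real_, NA_real_)
      } else {
        q <- unname(stats::quantile(v, c(0.25, 0.75), type = 7))
      }
      out[[length(out) + 1L]] <- data.frame(
        group = g, n = n, metric = m, q1 = q[1L], q3 = q[2L],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(group = character(0), n = integer(0),
                      metric = character(0), q1 = numeric(0),
                      q3 = numeric(0)))
  do.call(rbind, out)
}
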