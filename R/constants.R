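# Residue-level constant tables used across the package.

#' @keywords internal
AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# Kyte-Doolittle hydropathy scale
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Average (isotope-averaged) residue masses in Da; add one water per chain.
AA_AVG_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)

WATER_MASS <- 18.0153

# Ionizable-group pKa sets. Each table: side-chain pKa for D,E,C,Y (acidic)
# and K,R,H (basic), plus terminal pKa. "nterm"/"cterm" are defaults;
# "nterm_by_residue"/"cterm_by_residue" optionally override by the
# first/last residue (the ExPASy/Bjellqvist convention).
PKA_TABLES <- list(
  # classic textbook set used by SMS-family web calculators
  sms = list(
    acidic = c(D = 3.65, E = 4.25, C = 8.33, Y = 10.07),
    basic  = c(K = 10.53, R = 12.48, H = 6.00),
    nterm = 8.2, cterm = 3.65,
    nterm_by_residue = NULL, cterm_by_residue = NULL),
  emboss = list(
    acidic = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
    basic  = c(K = 10.8, R = 12.5, H = 6.5),
    nterm = 8.6, cterm = 3.6,
    nterm_by_residue = NULL, cterm_by_residue = NULL),
  # ExPASy-style set with residue-specific terminal pKa
  bjellqvist = list(
    acidic = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00),
    basic  = c(K = 10.00, R = 12.00, H = 5.98),
    nterm = 7.5,
    cterm = 3.55,
    nterm_by_residue = c(A = 7.59, E = 7.70, M = 7.00, P = 8.36,
                         S = 6.93, T = 6.82, V = 7.44),
    cterm_by_residue = c(D = 4.55, E = 4.75))
)

#' @keywords internal
valid_protein_chars <- function() c(AA20, "X")

#' @keywords internal
check_protein_seq <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a non-empty string", call. = FALSE)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(ch), valid_protein_chars())
  if (length(bad))
    stop("invalid amino-acid symbol(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  ch
}

#' @keywords internal
check_nt_seq <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a non-empty string", call. = FALSE)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(ch), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("invalid nucleotide symbol(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  ch
}

# RNG hygiene: run code under a private seed, restoring global state.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
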