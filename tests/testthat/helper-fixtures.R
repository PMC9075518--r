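# shared fixtures, all generated in code

AA <- c("A","R","N","D","C","Q","E","G","H","I",
        "L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA, n, replace = TRUE), collapse = "")
}

random_transcript <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent per-residue tables for oracle checks (typed in separately
# from the package constants)
ORACLE_KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)
ORACLE_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                 C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                 H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                 M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                 T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

# grid-search pI oracle at 0.001 pH resolution
grid_pi <- function(seq, pka_table = "sms") {
  grid <- seq(0, 14, by = 0.001)
  q <- abs(net_charge(seq, grid, pka_table))
  grid[which.min(q)]
}

detect_one <- function(seq, id = "p", ...) {
  detect_acds(protein_record(id, seq), ...)
}

# one fixed codon per amino acid, for hand back-translation in tests
CODON1 <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
            Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
            L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
            S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

encode_cds <- function(pep)
  paste(CODON1[strsplit(pep, "")[[1]]], collapse = "")

random_protein_no_m <- function(n)
  paste(sample(setdiff(AA, "M"), n, replace = TRUE), collapse = "")
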