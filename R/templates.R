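# Frozen cluster templates.
#
# One template per monomeric subcluster (A1, A2, B1, B2, B3) plus a
# dimeric template with two tandem ACD cores. Region strings are laid
# out on the canonical core geometry (see ACD_REGIONS); the paired
# "skeleton" strings mark the motif-constrained positions (any position
# that is not "." in the skeleton is a signature/anchor residue and is
# exempt from mutation in the synthetic generator, mirroring the strong
# purifying selection visible in the family's sequence logos). Filler
# residues were chosen once, deterministically, so that each template's
# physicochemical profile falls inside the published per-cluster
# interquartile box; they are validated against those boxes at run time.

MONO_SKELETONS <- list(
  A1 = c(b3 = "......", L34 = "..G....", b4 = "....VK", L45 = "P....",
         b5 = ".....", L57 = ".....", b7 = ".....Q", L78 = ".LP.VD..",
         b8 = "..A...", L89 = "..G..", b9 = "LEVEAP"),
  A2 = c(b3 = "......", L34 = "..G....", b4 = "....VK", L45 = "P....",
         b5 = ".....", L57 = ".............", b7 = ".....R",
         L78 = ".LP.VD..", b8 = "..A...", L89 = "..G..", b9 = "LKTKLK"),
  B1 = c(b3 = "......", L34 = "F.SES..", b4 = "....VK", L45 = "P....",
         b5 = ".....", L57 = "KKK.KKEE..EE", b7 = ".....R",
         L78 = ".LP.VD..", b8 = ".SSF..", L89 = "..G..", b9 = "LSVEAP"),
  B2 = c(b3 = "......", L34 = "F......", b4 = "....VK", L45 = "P....",
         b5 = ".....", L57 = "............", b7 = ".....R",
         L78 = ".LP.VD..", b8 = ".SSF..", L89 = "..G..", b9 = "LQVELP"),
  B3 = c(b3 = "..LDV.", L34 = ".F.PEE.", b4 = "....VK", L45 = "P....",
         b5 = ".....", L57 = ".GKHEER.....", b7 = ".....R",
         L78 = ".LP.VD..", b8 = ".SSF..", L89 = "..G..", b9 = "LRTEAP"))

DIMERIC_SKELETONS <- list(
  up = c(b3 = "......", L34 = ".......", b4 = "....VK", L45 = "P....",
         b5 = ".....", L57 = "............", b7 = ".....R",
         L78 = ".LP.VD..", b8 = "......", L89 = "..G..", b9 = "LPTKAK"),
  down = MONO_SKELETONS$B2)

ACD_TEMPLATE_SPECS <- list(
  A1 = list(
    ntd = "MLLRHFINTNEE",
    cores = list(c(b3 = "DIDMDF", L34 = "WKGDSPA", b4 = "SRANVK",
                   L45 = "PVVGG", b5 = "QAFRA", L57 = "EVSVN",
                   b7 = "DISYLQ", L78 = "ALPSVDAA", b8 = "LWAFIA",
                   L89 = "KMGEA", b9 = "LEVEAP")),
    linkers = character(0),
    ctd = "FYQAQGLNTHFEG",
    skeletons = list(MONO_SKELETONS$A1)),
  A2 = list(
    ntd = paste0("MLEENRSRVVQTNTAQNQVLKVPKQAAPGENRGLARPSKHLEELGYPREPLESGS",
                 "AQWRGKRSKLNRSSLRLQELGQQASVSCPELGSERAETVANLKELKPAKVEQYVN",
                 "AVNLQRGQEEQEVSRLKTQNNAQVETYQPLGVIAEVRENKCGSLHKHLTLVKTQA",
                 "LPVQTETPSSTNDALGLGSFGTHVSYSTGQNPVVCLKNALGTEPPPRNKYTRGSP",
                 "STEGACTLNA"),
    cores = list(c(b3 = "ANWMVY", L34 = "WLGKTGQ", b4 = "SMQLVK",
                   L45 = "PLTEE", b5 = "VEFID", L57 = "RPTWLQLAVVLTQ",
                   b7 = "QYRYNR", L78 = "ALPRVDTR", b8 = "LWAYEY",
                   L89 = "CMGIA", b9 = "LKTKLK")),
    linkers = character(0),
    ctd = paste0("ELVPLVVGNFQPGVLTPSQGTTSEVGRGNGTQIGNNTCSRLPSQALQTKGVVNRN",
                 "NLLPRVAWMTRP"),
    skeletons = list(MONO_SKELETONS$A2)),
  B1 = list(
    ntd = paste0("MVQPTLTDNSTSEAVLAATPPNMNKEKECTCQTKEQPGPRVIFPWAHQSVLQLSV",
                 "EVERKSYTCKVTDNQGVQEKGVDVA"),
    cores = list(c(b3 = "DAESQN", L34 = "FQSESQT", b4 = "PNSWVK",
                   L45 = "PWYFE", b5 = "LLSRP", L57 = "KKKIKKEERFEE",
                   b7 = "ELVALR", L78 = "NLPLVDTI", b8 = "TSSFPA",
                   L89 = "KAGVE", b9 = "LSVEAP")),
    linkers = character(0),
    ctd = "KAVEEKVGWDASGGLVVNQPNQLNCSQPQLATTKWRNS",
    skeletons = list(MONO_SKELETONS$B1)),
  B2 = list(
    ntd = paste0("MLSAANPLSANGLHVQLSVVQQQVSKSHPSHWSDSPTDNAHPSNPADGELEKKQT",
                 "EAPPHKQKGDSHGVK"),
    cores = list(c(b3 = "SASKFQ", L34 = "FWLSREQ", b4 = "KAQLVK",
                   L45 = "PTNKK", b5 = "TWSRA", L57 = "QTPDNLSLDVGL",
                   b7 = "DIQGTR", L78 = "HLPPVDAQ", b8 = "YSSFST",
                   L89 = "CDGEA", b9 = "LQVELP")),
    linkers = character(0),
    ctd = "GLGGQEGLHAVATKGSSVPTVTLLQQHEVVAGQFLKVP",
    skeletons = list(MONO_SKELETONS$B2)),
  B3 = list(
    ntd = paste0("MMTWRQQHEYGAGQTRYLEWRKEYNKLNSAVCGLGLSHAVVGYRDNEEPWPRSKA",
                 "TFVQLMEVDIPASLRVLPSMQIGGPHDPLS"),
    cores = list(c(b3 = "ASLDVW", L34 = "CFIPEEG", b4 = "MRSDVK",
                   L45 = "PETKV", b5 = "SWPFD", L57 = "KGKHEERLCAHA",
                   b7 = "QMPDNR", L78 = "ALPSVDRD", b8 = "LSSFVI",
                   L89 = "TQGIA", b9 = "LRTEAP")),
    linkers = character(0),
    ctd = "EHRGVINSHQLKGRDNWTKPRTNLNAFNRTEETNVRACT",
    skeletons = list(MONO_SKELETONS$B3)),
  dimeric = list(
    ntd = "MNETKKANQLSSKGTKGENGDNSEPKGNESDAGVDVVAEG",
    cores = list(
      c(b3 = "HFTNNH", L34 = "NNRVTFK", b4 = "AMQSVK", L45 = "PILVF",
        b5 = "GGVQE", L57 = "IIHCTKNHNIVR", b7 = "AMSFKR",
        L78 = "WLPPVDWT", b8 = "KRHICF", L89 = "RWGPC", b9 = "LPTKAK"),
      c(b3 = "SASKFK", L34 = "FWGSRAQ", b4 = "KAQKVK", L45 = "PTNKK",
        b5 = "TTSRA", L57 = "QTPDNLSTDVQL", b7 = "DIIGTR",
        L78 = "HLPEVDFT", b8 = "YSSFAT", L89 = "HDGEM", b9 = "LQVELP")),
    linkers = "QGNPQNSVAQGEVEDSQEENQAATV",
    ctd = "VADATNQQADVGGGLLEADPAVSAESNTVQ",
    skeletons = DIMERIC_SKELETONS)
)

# published per-cluster interquartile boxes (whole protein and ACD core)
CLUSTER_PROPERTY_BOXES <- list(
  A1 = list(mw_kda = c(9.7, 10.1), length_aa = c(89, 91),
            pi_protein = c(4.1, 4.3), pi_acd = c(3.9, 4.1),
            gravy_protein = c(-0.12, -0.04), gravy_acd = c(0.01, 0.15),
            core_len = c(63, 69)),
  A2 = list(mw_kda = c(40.0, 41.8), length_aa = c(359, 381),
            pi_protein = c(9.2, 10.2), pi_acd = c(8.6, 10.1),
            gravy_protein = c(-0.69, -0.54), gravy_acd = c(-0.31, -0.16),
            core_len = c(71, 79)),
  B1 = list(mw_kda = c(16.3, 25.5), length_aa = c(142, 241),
            pi_protein = c(4.9, 6.0), pi_acd = c(4.8, 5.2),
            gravy_protein = c(-0.72, -0.46), gravy_acd = c(-0.75, -0.62),
            core_len = c(71, 79)),
  B2 = list(mw_kda = c(17.9, 23.0), length_aa = c(158, 204),
            pi_protein = c(5.7, 7.5), pi_acd = c(6.0, 8.7),
            gravy_protein = c(-0.66, -0.58), gravy_acd = c(-0.75, -0.61),
            core_len = c(71, 79)),
  B3 = list(mw_kda = c(21.3, 23.9), length_aa = c(187, 205),
            pi_protein = c(6.4, 8.0), pi_acd = c(4.5, 6.0),
            gravy_protein = c(-0.80, -0.65), gravy_acd = c(-0.59, -0.44),
            core_len = c(71, 79)))

#' @keywords internal
template_seed_cores <- function() {
  out <- character(0)
  for (cl in names(ACD_TEMPLATE_SPECS)) {
    for (core in ACD_TEMPLATE_SPECS[[cl]]$cores) {
      g <- nchar(core[["L57"]])
      core[["L57"]] <- paste0(core[["L57"]],
                              paste(rep("-", L57_MAX - g), collapse = ""))
      out <- c(out, paste(core, collapse = ""))
    }
  }
  out
}

#' Cluster template protein
#'
#' Returns the deterministic template protein for a monomeric subcluster
#' (A1, A2, B1, B2, B3) or for the dimeric (two tandem ACD cores)
#' architecture. Monomeric templates are validated against the
#' per-cluster physicochemical interquartile boxes and the call errors
#' naming the violated box if a template falls outside one.
#'
#' @param cluster One of "A1", "A2", "B1", "B2", "B3", "dimeric".
#' @return Object of class "shsp_template": list with elements cluster,
#'   seq, regions (data.frame with 0-based half-open start/end, region
#'   kind and core index), cores (data.frame of core spans), constrained
#'   (0-based positions exempt from mutation in the generator).
#' @export
make_template <- function(cluster) {
  if (!cluster %in% names(ACD_TEMPLATE_SPECS))
    stop("unknown cluster label: ", cluster, call. = FALSE)
  sp <- ACD_TEMPLATE_SPECS[[cluster]]
  parts <- list()           # element, region, kind, seq, core_index
  add <- function(region, seq, kind, core_index = NA_integer_)
    parts[[length(parts) + 1L]] <<- list(region = region, seq = seq,
                                         kind = kind, core_index = core_index)
  add("NTD", sp$ntd, "flank")
  for (i in seq_along(sp$cores)) {
    for (r in ACD_REGIONS$region)
      add(r, sp$cores[[i]][[r]],
          ACD_REGIONS$kind[ACD_REGIONS$region == r], i)
    if (i < length(sp$cores)) add("linker", sp$linkers[i], "flank")
  }
  add("CTD", sp$ctd, "flank")
  seqs <- vapply(parts, `[[`, "", "seq")
  lens <- nchar(seqs)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  regions <- data.frame(
    region = vapply(parts, `[[`, "", "region"),
    kind = vapply(parts, `[[`, "", "kind"),
    core_index = vapply(parts, `[[`, NA_integer_, "core_index"),
    start = starts, end = starts + lens,
    stringsAsFactors = FALSE)
  seq <- paste(seqs, collapse = "")

  # constrained positions: skeleton non-dot positions within core regions
  constrained <- integer(0)
  for (i in seq_along(sp$cores)) {
    skel <- sp$skeletons[[i]]
    for (r in ACD_REGIONS$region) {
      row <- regions[regions$region == r & regions$core_index == i, ]
      sk <- strsplit(skel[[r]], "")[[1L]]
      constrained <- c(constrained, row$start + which(sk != ".") - 1L)
    }
  }
  constrained <- sort(c(0L, constrained))  # initiator M kept

  core_rows <- regions[!is.na(regions$core_index), ]
  cores <- do.call(rbind, lapply(unique(core_rows$core_index), function(i) {
    sub <- core_rows[core_rows$core_index == i, ]
    data.frame(core_index = i, start = min(sub$start), end = max(sub$end))
  }))

  tmpl <- structure(list(cluster = cluster, seq = seq, regions = regions,
                         cores = cores, constrained = constrained),
                    class = "shsp_template")

  if (cluster %in% names(CLUSTER_PROPERTY_BOXES)) {
    box <- CLUSTER_PROPERTY_BOXES[[cluster]]
    core_seq <- substr(seq, cores$start[1L] + 1L, cores$end[1L])
    prof <- physchem_profile(protein_record(cluster, seq, complete = TRUE),
                             acd_core = core_seq)
    vals <- c(mw_kda = prof$mw_kda, length_aa = prof$length_aa,
              pi_protein = prof$pi_protein, pi_acd = prof$pi_acd,
              gravy_protein = prof$gravy_protein, gravy_acd = prof$gravy_acd,
              core_len = nchar(core_seq))
    for (m in names(box)) {
      if (vals[[m]] < box[[m]][1L] || vals[[m]] > box[[m]][2L])
        stop(sprintf(
          "template %s violates the %s box [%g, %g] (got %g)",
          cluster, m, box[[m]][1L], box[[m]][2L], vals[[m]]), call. = FALSE)
    }
  } else {
    # dimeric template invariants
    if (nrow(cores) != 2L)
      stop("dimeric template must carry two cores", call. = FALSE)
    linker_len <- cores$start[2L] - cores$end[1L]
    if (linker_len < 15L || linker_len > 40L)
      stop("dimeric linker length outside [15, 40]", call. = FALSE)
  }
  tmpl
}

#' @export
print.shsp_template <- function(x, ...) {
  cat(sprintf("<shsp_template %s> %d aa, %d ACD core(s)\n",
              x$cluster, nchar(x$seq), nrow(x$cores)))
  invisible(x)
}
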