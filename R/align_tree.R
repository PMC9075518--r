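# Anchored alignment of ACD cores, p-distances, neighbor joining,
# bootstrap supports.

#' Anchored multiple alignment of ACD cores
#'
#' Each core (as produced by [trim_core()]) is re-anchored against the
#' model (beta9 motif + L78 doublet + PSSM window) and laid onto the
#' canonical 74-column core geometry: the two strand blocks map
#' column-for-column, and the variable L57 loop is placed into the L57
#' columns by affine-gap dynamic programming (gap open 10, extend 1,
#' BLOSUM62 similarity) against the model's L57 consensus. Columns that
#' are gap in every row are dropped.
#'
#' @param cores Named character vector (id -> core string) or list of
#'   (id, core) pairs; at least 2 cores.
#' @param model An "acd_model".
#' @return Object of class "anchored_alignment": list with ids, rows
#'   (gapped strings), anchors (per-column region label), n_columns.
#'   Cores failing to re-anchor are excluded with a warning.
#' @export
align_cores <- function(cores, model = default_acd_model()) {
  if (is.list(cores)) {
    ids <- vapply(cores, function(x) x[[1L]], "")
    seqs <- vapply(cores, function(x) x[[2L]], "")
  } else {
    ids <- names(cores); seqs <- unname(cores)
  }
  if (length(seqs) < 2L) stop("need at least 2 cores", call. = FALSE)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("cores must be named", call. = FALSE)

  l57_cols <- (BLOCK1_LEN + 1L):(BLOCK1_LEN + L57_MAX)
  l57_consensus <- strsplit(substr(model$consensus, l57_cols[1L],
                                   l57_cols[L57_MAX]), "")[[1L]]
  rows <- character(0); kept <- character(0)
  col_labels <- rep(ACD_REGIONS$region, ACD_REGIONS$length)
  for (i in seq_along(seqs)) {
    core <- seqs[i]
    det <- detect_acds(protein_record(ids[i], core), model,
                       threshold_bits = -Inf)
    h <- det$hits
    h <- h[h$start == 0L & h$end == nchar(core), , drop = FALSE]
    if (nrow(h) != 1L) {
      warning("core ", ids[i],
              " is unalignable (fails to match the anchor motifs); excluded")
      next
    }
    g <- h$l57_len[1L]
    block1 <- substr(core, 1L, BLOCK1_LEN)
    l57 <- substr(core, BLOCK1_LEN + 1L, BLOCK1_LEN + g)
    block2 <- substr(core, BLOCK1_LEN + g + 1L, nchar(core))
    l57_aln <- align_loop(strsplit(l57, "")[[1L]], l57_consensus)
    rows <- c(rows, paste0(block1, l57_aln, block2))
    kept <- c(kept, ids[i])
  }
  if (length(rows) < 2L)
    stop("fewer than 2 cores could be anchored", call. = FALSE)
  # drop all-gap columns
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  keep_col <- colSums(mat != "-") > 0L
  mat <- mat[, keep_col, drop = FALSE]
  structure(list(ids = kept,
                 rows = apply(mat, 1L, paste, collapse = ""),
                 anchors = col_labels[keep_col],
                 n_columns = ncol(mat)),
            class = "anchored_alignment")
}

# global alignment of a loop (<= ncol residues) onto profile columns;
# gaps are inserted into the sequence only (the profile defines the
# column space). Affine penalties, BLOSUM62 match scores.
#' @keywords internal
align_loop <- function(seq_chars, cons_chars,
                       gap_open = 10, gap_extend = 1) {
  n <- length(seq_chars); m <- length(cons_chars)
  if (n == m) return(paste(seq_chars, collapse = ""))
  if (n > m) stop("loop longer than its column space", call. = FALSE)
  if (n == 0L) return(paste(rep("-", m), collapse = ""))
  bl <- blosum62()
  sub <- function(a, b) {
    if (a %in% rownames(bl) && b %in% rownames(bl)) bl[a, b] else 0
  }
  NEG <- -1e9
  # M[i+1, j+1]: best score aligning seq[1..i] to columns[1..j] ending in
  # a match; D: ending in a column gap (deletion in the sequence)
  M <- matrix(NEG, n + 1L, m + 1L); D <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (j in seq_len(m)) D[1L, j + 1L] <- -gap_open - gap_extend * (j - 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (j >= i) {
        s <- sub(seq_chars[i], cons_chars[j])
        M[i + 1L, j + 1L] <- max(M[i, j], D[i, j]) + s
      }
      D[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open,
                               D[i + 1L, j] - gap_extend)
    }
  }
  # traceback
  out <- character(m)
  i <- n; j <- m
  state <- if (M[i + 1L, j + 1L] >= D[i + 1L, j + 1L]) "M" else "D"
  while (j > 0L) {
    if (state == "M") {
      out[j] <- seq_chars[i]
      state <- if (M[i, j] >= D[i, j]) "M" else "D"
      i <- i - 1L; j <- j - 1L
    } else {
      out[j] <- "-"
      state <- if (M[i + 1L, j] - gap_open >= D[i + 1L, j] - gap_extend)
        "M" else "D"
      j <- j - 1L
    }
  }
  paste(out, collapse = "")
}

#' @keywords internal
blosum62 <- function() {
  if (is.null(.acdminer_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .acdminer_env$blosum62 <- e$BLOSUM62
  }
  .acdminer_env$blosum62
}

#' @export
print.anchored_alignment <- function(x, ...) {
  cat(sprintf("<anchored_alignment> %d sequences x %d columns\n",
              length(x$ids), x$n_columns))
  invisible(x)
}

#' Ungap one row of an anchored alignment
#' @param msa An "anchored_alignment".
#' @param id Sequence id.
#' @return The ungapped core string.
#' @export
ungap_row <- function(msa, id) {
  gsub("-", "", x = msa$rows[match(id, msa$ids)], fixed = TRUE)
}

#' Pairwise p-distance matrix of an alignment
#'
#' d(i, j) = mismatches / compared columns, where columns with a gap in
#' either row are excluded pairwise. A pair with zero comparable columns
#' gets NA and is flagged with a warning.
#'
#' @param msa An "anchored_alignment" or character vector of aligned
#'   rows.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(msa) {
  rows <- if (inherits(msa, "anchored_alignment")) msa$rows else msa
  ids <- if (inherits(msa, "anchored_alignment")) msa$ids else names(rows)
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment is not rectangular", call. = FALSE)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cmp <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(cmp)) {
      warning("no comparable columns for pair (", ids[i], ", ", ids[j], ")")
      d[i, j] <- d[j, i] <- NA_real_
    } else {
      d[i, j] <- d[j, i] <- mean(mat[i, cmp] != mat[j, cmp])
    }
  }
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard neighbor-joining agglomeration on a symmetric distance
#' matrix. Negative branch lengths are clamped to zero with the deficit
#' moved to the sibling edge, preserving path lengths through the parent.
#'
#' @param d Symmetric non-negative distance matrix with row/col names
#'   (>= 3 taxa; with 2 taxa a degenerate 2-leaf tree is returned with a
#'   warning).
#' @return An [ape::read.tree()]-style "phylo" object.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (any(is.na(d))) stop("distance matrix contains NA", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) stop("matrix not symmetric", call. = FALSE)
  if (n < 3L) {
    warning("fewer than 3 taxa: returning degenerate tree")
    txt <- sprintf("(%s:%f,%s:%f);", labels[1L], d[1L, 2L] / 2,
                   labels[2L], d[1L, 2L] / 2)
    return(ape::read.tree(text = txt))
  }
  # agglomerate, carrying subtrees as newick fragments
  sub <- labels
  Dm <- d
  dimnames(Dm) <- list(labels, labels)
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(Dm) > 3L) {
    m <- nrow(Dm)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1L, ]
    i <- min(ij); j <- max(ij)
    vi <- 0.5 * Dm[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- Dm[i, j] - vi
    # clamp negatives, moving the deficit to the sibling edge
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vj <- max(vj, 0)
    merged <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(vi), sub[j], fmt(vj))
    dnew <- 0.5 * (Dm[i, -c(i, j)] + Dm[j, -c(i, j)] - Dm[i, j])
    dnew <- pmax(dnew, 0)
    keep <- setdiff(seq_len(m), c(i, j))
    Dm2 <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    sub <- c(sub[keep], merged)
    dimnames(Dm2) <- NULL
    Dm <- Dm2
  }
  # final three subtrees joined at an unrooted trifurcation
  v1 <- (Dm[1L, 2L] + Dm[1L, 3L] - Dm[2L, 3L]) / 2
  v2 <- (Dm[1L, 2L] + Dm[2L, 3L] - Dm[1L, 3L]) / 2
  v3 <- (Dm[1L, 3L] + Dm[2L, 3L] - Dm[1L, 2L]) / 2
  vs <- c(v1, v2, v3)
  for (k in 1:3) if (vs[k] < 0) {
    others <- setdiff(1:3, k)
    vs[others] <- vs[others] + vs[k] / 2
    vs[k] <- 0
  }
  vs <- pmax(vs, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1L], fmt(vs[1L]),
                 sub[2L], fmt(vs[2L]), sub[3L], fmt(vs[3L]))
  ape::read.tree(text = txt)
}

#' Bootstrap supports for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the p-distance
#' NJ tree per replicate, and reports for each internal edge of the full
#' tree the percentage of replicates containing the same bipartition.
#' Deterministic for a fixed seed.
#'
#' @param msa An "anchored_alignment" (or aligned character vector).
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed RNG seed (mandatory).
#' @return list with class "distance_tree": tree (a "phylo" with
#'   node labels = support percentages), supports (per internal node),
#'   n_reps, seed.
#' @export
bootstrap_supports <- function(msa, n_reps = 100L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  rows <- if (inherits(msa, "anchored_alignment")) msa$rows else msa
  ids <- if (inherits(msa, "anchored_alignment")) msa$ids else names(rows)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- ids
  full <- neighbor_joining(p_distance_matrix(stats::setNames(rows, ids)))
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(k) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      sub <- mat[, cols, drop = FALSE]
      rws <- apply(sub, 1L, paste, collapse = "")
      dk <- suppressWarnings(p_distance_matrix(stats::setNames(rws, ids)))
      dk[is.na(dk)] <- max(dk, na.rm = TRUE)
      neighbor_joining(dk)
    })
  })
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- round(100 * counts / n_reps)
  tree <- full
  tree$node.label <- as.character(supports)
  structure(list(tree = tree, supports = supports, n_reps = n_reps,
                 seed = seed),
            class = "distance_tree")
}

#' @export
print.distance_tree <- function(x, ...) {
  cat(sprintf("<distance_tree> %d tips, %d bootstrap replicates (seed %s)\n",
              length(x$tree$tip.label), x$n_reps, format(x$seed)))
  invisible(x)
}

#' Is a set of tips an (unrooted) monophyletic group in a tree?
#'
#' TRUE when some edge of the tree bipartitions the leaves into exactly
#' this set versus the rest.
#'
#' @param tree A "phylo" object.
#' @param tips Character vector of tip labels.
#' @return logical.
#' @export
is_split <- function(tree, tips) {
  labs <- tree$tip.label
  target <- sort(match(tips, labs))
  if (anyNA(target)) stop("tips not in tree", call. = FALSE)
  parts <- ape::prop.part(tree)
  for (p in parts) {
    p <- sort(p)
    if (identical(p, target) ||
        identical(sort(setdiff(seq_along(labs), p)), target))
      return(TRUE)
  }
  # prop.part misses some splits on unrooted trees rooted arbitrarily;
  # also test each edge's descendant set directly
  n_tip <- length(labs)
  for (node in (n_tip + 1L):(n_tip + tree$Nnode)) {
    desc <- tips_under(tree, node)
    if (identical(sort(desc), target) ||
        identical(sort(setdiff(seq_len(n_tip), desc)), target))
      return(TRUE)
  }
  FALSE
}

#' @keywords internal
tips_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[1L]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  out
}

#' Bootstrap support of a given tip set in a distance tree
#'
#' @param dtree A "distance_tree" from [bootstrap_supports()].
#' @param tips Character vector of tip labels.
#' @return Support percentage of the edge splitting off \code{tips}, or
#'   NA when the group is not a split of the tree.
#' @export
split_support <- function(dtree, tips) {
  tree <- dtree$tree
  labs <- tree$tip.label
  target <- sort(match(tips, labs))
  n_tip <- length(labs)
  for (node in (n_tip + 1L):(n_tip + tree$Nnode)) {
    desc <- sort(tips_under(tree, node))
    if (identical(desc, target) ||
        identical(sort(setdiff(seq_len(n_tip), desc)), target))
      return(as.numeric(tree$node.label[node - n_tip]))
  }
  NA_real_
}
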