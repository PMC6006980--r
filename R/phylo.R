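# Self-contained phylogenetic machinery: progressive multiple alignment
# (UPGMA guide tree, profile merging), p-distances, neighbor joining with
# deterministic tie-breaking, and nonparametric bootstrap supports.
# Trees are ape "phylo" objects; newick IO goes through ape.

#' Build a validated distance matrix
#'
#' @param values Square numeric matrix, symmetric, zero diagonal,
#'   non-negative (triangle violations are permitted; NJ does not require
#'   metricity).
#' @param labels Taxon labels; defaults to `rownames(values)`.
#' @return Matrix of class `distance_matrix`.
#' @export
distance_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(labels)) stop("distance_matrix: labels required")
  stopifnot(nrow(values) == ncol(values), length(labels) == nrow(values))
  if (anyDuplicated(labels)) stop("distance_matrix: duplicate labels")
  if (any(values < 0)) stop("distance_matrix: negative distances forbidden")
  if (max(abs(values - t(values))) > 1e-8)
    stop("distance_matrix: matrix not symmetric")
  if (any(abs(diag(values)) > 1e-12))
    stop("distance_matrix: nonzero diagonal")
  dimnames(values) <- list(labels, labels)
  class(values) <- c("distance_matrix", "matrix")
  values
}

#' Progressive multiple sequence alignment
#'
#' Pairwise global alignments give guide distances (one minus fractional
#' identity); an average-linkage (UPGMA) guide tree orders profile
#' merges; profiles are aligned with the affine-gap kernel using
#' column-frequency cross-scores.
#'
#' @param records List of [protein_record] objects (or a named character
#'   vector of sequences).
#' @inheritParams pairwise_align
#' @return Character matrix of aligned sequences (rows named by record
#'   id), columns >= the longest input. A single record is returned as a
#'   one-row matrix unchanged.
#' @export
progressive_msa <- function(records, sub_matrix = blosum62(),
                            gap_open = 10, gap_ext = 1) {
  if (is.character(records))
    records <- mapply(protein_record, names(records), records,
                      SIMPLIFY = FALSE)
  ids <- vapply(records, function(r) r$id, character(1))
  seqs <- vapply(records, function(r) r$sequence, character(1))
  k <- length(seqs)
  if (k == 0L) stop("progressive_msa: no records")
  mats <- lapply(seqs, function(s) matrix(strsplit(s, "")[[1]], nrow = 1))
  if (k == 1L) {
    out <- mats[[1]]; rownames(out) <- ids
    return(out)
  }
  # guide distances from pairwise global alignments
  D <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    al <- pairwise_align(seqs[i], seqs[j], sub_matrix, gap_open, gap_ext)
    D[i, j] <- D[j, i] <- 1 - al$identity
  }
  merges <- stats::hclust(stats::as.dist(D), method = "average")$merge
  groups <- vector("list", nrow(merges))
  rows_of <- vector("list", nrow(merges))
  get_node <- function(x) {
    if (x < 0) list(mat = mats[[-x]], rows = -x) else
      list(mat = groups[[x]], rows = rows_of[[x]])
  }
  for (r in seq_len(nrow(merges))) {
    a <- get_node(merges[r, 1]); b <- get_node(merges[r, 2])
    pa <- .seqs_to_profile(a$mat); pb <- .seqs_to_profile(b$mat)
    if (is.null(dim(pa))) pa <- matrix(pa, ncol = 1)
    if (is.null(dim(pb))) pb <- matrix(pb, ncol = 1)
    res <- .align_dp(.profile_sim(pa, pb, sub_matrix), gap_open, gap_ext,
                     FALSE)
    groups[[r]] <- .merge_profiles(a$mat, b$mat, res$a_idx, res$b_idx)
    rows_of[[r]] <- c(a$rows, b$rows)
  }
  out <- groups[[nrow(merges)]]
  ord <- order(rows_of[[nrow(merges)]])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- ids
  out
}

#' p-distances from an alignment
#'
#' Proportion of differing residues over pairwise gap-deleted columns
#' (columns where either sequence has a gap are ignored for that pair).
#'
#' @param aln Character matrix from [progressive_msa()] (rows = taxa).
#' @return A [distance_matrix].
#' @export
p_distance <- function(aln) {
  k <- nrow(aln)
  D <- matrix(0, k, k)
  for (i in seq_len(max(k - 1, 0))) for (j in (i + 1):k) {
    ok <- aln[i, ] != "-" & aln[j, ] != "-"
    D[i, j] <- D[j, i] <- if (any(ok)) mean(aln[i, ok] != aln[j, ok]) else 1
  }
  distance_matrix(D, rownames(aln))
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining by Q-matrix minimization. Ties in the
#' Q-matrix are broken by the lexicographically smallest joined label
#' pair (an internal node carries the smallest leaf label below it), so
#' the output is deterministic. Negative branch lengths are clamped to
#' zero for display; the raw values are retained in
#' `attr(tree, "raw_lengths")`.
#'
#' @param dm A [distance_matrix] (or plain labelled symmetric matrix)
#'   over at least 3 taxa.
#' @return Unrooted `phylo` tree (ape) over all labels.
#' @export
nj_tree <- function(dm) {
  D <- unclass(as.matrix(dm))
  labs <- rownames(D)
  n <- nrow(D)
  if (n < 3L) stop("nj_tree: need at least 3 labels")
  nwk <- labs             # growing newick fragment per active node
  minleaf <- labs         # smallest leaf label below each active node
  raw <- data.frame(node = character(), raw_length = numeric())
  clamp <- function(x) max(x, 0)
  note <- function(lab, x) {
    if (x < 0) raw[nrow(raw) + 1L, ] <<- list(lab, x)
  }
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-9, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(p) {
      pr <- sort(c(minleaf[p[1]], minleaf[p[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- dij - li
    note(minleaf[i], li); note(minleaf[j], lj)
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], clamp(li),
                       nwk[j], clamp(lj))
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    minleaf <- c(minleaf[keep], min(minleaf[c(i, j)]))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], "")
    D <- D2
    n <- n - 1L
  }
  # resolve the last three nodes by the three-point formulas
  x1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  x2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  x3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  note(minleaf[1], x1); note(minleaf[2], x2); note(minleaf[3], x3)
  text <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                  nwk[1], clamp(x1), nwk[2], clamp(x2), nwk[3], clamp(x3))
  tree <- ape::read.tree(text = text)
  attr(tree, "raw_lengths") <- raw
  tree
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal edge of the original tree with
#' the percentage of replicate trees containing its bipartition.
#'
#' @param aln Character matrix from [progressive_msa()], >= 2 columns.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; fixed seeds give identical supports.
#' @return The NJ tree of the full alignment with `node.label` set to
#'   bootstrap percentages in `[0, 100]` (root label `NA`) and an
#'   attribute `scale_note` recording the branch-length unit (amino-acid
#'   substitutions per position).
#' @export
bootstrap_tree <- function(aln, n_replicates = 1000L, seed = 1L) {
  stopifnot(ncol(aln) >= 2L, n_replicates >= 1L)
  orig <- nj_tree(p_distance(aln))
  set.seed(seed)
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(aln), replace = TRUE)
    reps[[b]] <- nj_tree(p_distance(aln[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(orig, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- counts / n_replicates * 100
  support[1] <- NA  # root of the unrooted representation: trivial split
  orig$node.label <- support
  attr(orig, "scale_note") <- "amino acid substitutions per position"
  attr(orig, "bootstrap_replicates") <- n_replicates
  orig
}

#' Write / read a tree in newick format
#'
#' Thin wrappers over ape; provided so the pipeline's tree objects have a
#' single serialization point.
#'
#' @param tree `phylo` object.
#' @param path File path.
#' @return `write_newick` returns `path` invisibly; `read_newick` returns
#'   a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
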